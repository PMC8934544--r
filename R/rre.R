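#' Idealized focal length of the emmetropic zebrafish eye
#'
#' In fish the cornea contributes essentially no optical power under water
#' and the spherical crystalline lens dominates, so the focal length scales
#' nearly linearly with lens radius (Matthiessen's ratio). The default
#' coefficients come from a regression of lens radius against retinal radius
#' in emmetropic wild-type eyes across 2-6 months post-fertilization:
#' `focal = lensRadius * 2.182 + 11.699` (micrometres).
#'
#' @param lensRadius lens radius, micrometres (> 0; the value at 0 is the
#'   regression intercept).
#' @param slopeCoeff slope of the linear focal-length model.
#' @param intercept intercept, micrometres.
#' @return idealized focal length, micrometres (vectorized).
#' @examples
#' idealizedFocalLength(100)  # 229.899
#' @export
idealizedFocalLength <- function(lensRadius, slopeCoeff = 2.182,
                                 intercept = 11.699) {
  stopifnot(all(lensRadius >= 0))
  lensRadius * slopeCoeff + intercept
}

#' Relative refractive error from ocular geometry
#'
#' `RRE = 1 - retinalRadius / idealizedFocalLength(lensRadius)`. An eye
#' whose retina sits exactly at the idealized focal plane scores 0
#' (emmetropia); values below zero indicate myopia (retina beyond the focal
#' plane), values above zero hyperopia (retina short of it).
#'
#' @param lensRadius lens radius, micrometres.
#' @param retinalRadius distance from the lens centre to the inner retinal
#'   surface along the optical axis, micrometres.
#' @param slopeCoeff,intercept coefficients of [idealizedFocalLength()].
#' @return relative refractive error (dimensionless, vectorized).
#' @export
relativeRefractiveError <- function(lensRadius, retinalRadius,
                                    slopeCoeff = 2.182, intercept = 11.699) {
  stopifnot(all(lensRadius > 0), all(retinalRadius > 0))
  focal <- idealizedFocalLength(lensRadius, slopeCoeff, intercept)
  if (any(focal <= 0)) stop("idealized focal length must be positive")
  1 - retinalRadius / focal
}

#' Relative refractive error of a measured eye
#'
#' Operationalizes the radii from SD-OCT biometry: the lens radius is half
#' the axial lens diameter (spherical-lens assumption) and the retinal
#' radius is the distance from the lens centre to the inner retinal surface,
#' i.e. lens radius plus vitreous chamber depth.
#'
#' @param record a [BiometryRecord-class].
#' @param ... passed to [relativeRefractiveError()].
#' @return relative refractive error (dimensionless).
#' @export
rreFromBiometry <- function(record, ...) {
  stopifnot(is(record, "BiometryRecord"))
  lensR <- record@lensDiameter / 2
  relativeRefractiveError(lensR, lensR + record@vcd, ...)
}
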