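#' Axial length of an eye
#'
#' Sum of the six axial compartments (cornea, anterior chamber, lens,
#' vitreous chamber, retina, RPE), in micrometres.
#'
#' @param object an [EyeGeometry-class] or [BiometryRecord-class].
#' @return numeric scalar, micrometres.
#' @export
setGeneric("axialLength", function(object) standardGeneric("axialLength"))

#' @describeIn axialLength implied axial length of a geometry specification.
#' @export
setMethod("axialLength", "EyeGeometry", function(object) {
  unname(sum(geometryValues(object)[.COMPONENT_NAMES_GEOM]))
})

#' @describeIn axialLength measured axial length of a biometry record.
#' @export
setMethod("axialLength", "BiometryRecord", function(object) object@axialLength)

.COMPONENT_NAMES_GEOM <- c("cornealThickness", "acd", "lensDiameter", "vcd",
                           "retinalThickness", "rpeThickness")

#' Numeric view of an eye geometry
#'
#' @param object an [EyeGeometry-class].
#' @return named numeric with the six axial components and the two
#'   equatorial diameters, micrometres.
#' @export
geometryValues <- function(object) {
  c(cornealThickness = object@cornealThickness, acd = object@acd,
    lensDiameter = object@lensDiameter, vcd = object@vcd,
    retinalThickness = object@retinalThickness,
    rpeThickness = object@rpeThickness,
    equatorialDiameterX = object@equatorialDiameterX,
    equatorialDiameterY = object@equatorialDiameterY)
}

#' Estimated genotype effect(s) of a mixed-model fit
#' @param object a [MixedFit-class].
#' @return named numeric of genotype coefficients vs the reference.
#' @export
setGeneric("effectSize", function(object) standardGeneric("effectSize"))

#' @describeIn effectSize genotype coefficients of the CS mixed model.
#' @export
setMethod("effectSize", "MixedFit", function(object) object@effectSize)

#' P-value(s) of a mixed-model fit
#' @param object a [MixedFit-class].
#' @return named numeric of per-coefficient p-values.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @describeIn pValue p-values of the genotype coefficients.
#' @export
setMethod("pValue", "MixedFit", function(object) object@pValue)

#' Interface positions of a segmentation result
#' @param object a [BoundarySet-class].
#' @return named numeric(7), optical-path micrometres.
#' @export
setGeneric("boundaryPositions",
           function(object) standardGeneric("boundaryPositions"))

#' @describeIn boundaryPositions positions of the seven interfaces.
#' @export
setMethod("boundaryPositions", "BoundarySet", function(object) object@positions)

#' @describeIn BiometryRecord one-row data.frame of the endpoints, with
#'   qc flags collapsed into a `;`-separated string.
#' @param x a [BiometryRecord-class].
#' @param row.names,optional,... ignored, present for generic consistency.
#' @export
as.data.frame.BiometryRecord <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    corneal_thickness = x@cornealThickness, acd = x@acd,
    lens_diameter = x@lensDiameter, vcd = x@vcd,
    retinal_thickness = x@retinalThickness, rpe_thickness = x@rpeThickness,
    axial_length = x@axialLength, eye_volume = x@eyeVolume,
    qc_flags = paste(x@qcFlags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "EyeGeometry", function(object) {
  v <- geometryValues(object)
  cat("EyeGeometry (geometric µm)\n")
  cat(sprintf("  %-20s %8.1f\n", names(v), v), sep = "")
  cat(sprintf("  %-20s %8.1f\n", "axialLength", axialLength(object)))
})

setMethod("show", "OctVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "OctVolume %d x %d x %d (x, y, z) | z pitch %.3g µm (optical), lateral pitch %.3g µm\n",
    d[1], d[2], d[3], object@zPitch, object@lateralPitch))
})

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet at A-scan column [%d, %d] (optical µm)\n",
              object@axis[1], object@axis[2]))
  cat(sprintf("  %-15s %9.2f\n", names(object@positions), object@positions),
      sep = "")
})

setMethod("show", "BiometryRecord", function(object) {
  df <- as.data.frame(object)
  cat("BiometryRecord (geometric µm)\n")
  for (nm in setdiff(names(df), c("eye_volume", "qc_flags")))
    cat(sprintf("  %-20s %9.2f\n", nm, df[[nm]]))
  cat(sprintf("  %-20s %9.4g mm³\n", "eye_volume", df$eye_volume / 1e9))
  if (nzchar(df$qc_flags)) cat("  qc:", df$qc_flags, "\n")
})

setMethod("show", "RefractionCalibration", function(object) {
  cat(sprintf(
    "RefractionCalibration: D = %.4g * slope + %.4g (R² = %.4f, %d lenses)\n",
    object@gain, object@offset, object@fitR2, nrow(object@lensPoints)))
})

setMethod("show", "RefractionResult", function(object) {
  cat(sprintf("RefractionResult: %.2f ± %.2f D (n = %d frames)\n",
              object@meanDiopters, object@sdDiopters, object@nMeasurements))
  if (length(object@qcFlags)) cat("  qc:", paste(object@qcFlags, collapse = ";"), "\n")
})

setMethod("show", "AngleTrace", function(object) {
  cat(sprintf(
    "AngleTrace: %.1f s at %g Hz | drum %g deg/s (%s), %g cycles/deg\n",
    max(object@time) - min(object@time), object@sampleRate,
    object@stimulus$drum_velocity, object@stimulus$direction,
    object@stimulus$spatial_frequency))
})

setMethod("show", "OkrResult", function(object) {
  if (object@noResponse) {
    cat("OkrResult: no detectable optokinetic response\n")
  } else {
    cat(sprintf("OkrResult: gain T>N %.3f, N>T %.3f; ETMs/15s: %s (%d segments)\n",
                object@gainTn, object@gainNt,
                paste(object@etmPer15s, collapse = ","), object@nSegments))
  }
})

setMethod("show", "MixedFit", function(object) {
  cat(sprintf("MixedFit [%s], reference '%s' (%d fish, %d eyes)%s\n",
              object@metric, object@reference, object@nFish, object@nEyes,
              if (object@converged) "" else "  [NOT CONVERGED]"))
  for (g in names(object@effectSize)) {
    cat(sprintf("  %-14s effect %9.3f  SE %7.3f  t(%g) = %6.2f  p = %.3g %s\n",
                g, object@effectSize[[g]], object@se[[g]], object@df[[g]],
                object@tValue[[g]], object@pValue[[g]],
                pStars(object@pValue[[g]])))
  }
  cat(sprintf("  sigma2 fish %.4g, eye %.4g, ICC %.3f\n",
              object@sigmaFish2, object@sigmaEye2, object@icc))
})
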