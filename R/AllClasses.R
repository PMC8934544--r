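#' @import methods
NULL

#' Axial eye geometry of a zebrafish model eye
#'
#' Holds the six axial compartment thicknesses (geometric micrometres, i.e.
#' physical distance, not optical path) plus the two equatorial diameters of
#' the globe. The implied axial length is the sum of the six axial
#' compartments: cornea, anterior chamber, lens, vitreous chamber, retina and
#' retinal pigment epithelium (RPE).
#'
#' @slot cornealThickness,acd,lensDiameter,vcd,retinalThickness,rpeThickness
#'   axial compartment thicknesses in micrometres. `acd` (anterior chamber
#'   depth) may be zero: in the adult zebrafish eye the lens can be in contact
#'   with the back of the cornea. All others must be strictly positive.
#' @slot equatorialDiameterX,equatorialDiameterY equatorial diameters of the
#'   globe (micrometres), used for the ellipsoid eye-volume estimate.
#' @seealso [makeEyeGeometry()], [renderOctVolume()]
#' @export
setClass("EyeGeometry",
  representation(
    cornealThickness = "numeric", acd = "numeric", lensDiameter = "numeric",
    vcd = "numeric", retinalThickness = "numeric", rpeThickness = "numeric",
    equatorialDiameterX = "numeric", equatorialDiameterY = "numeric"
  )
)

setValidity("EyeGeometry", function(object) {
  v <- geometryValues(object)
  if (any(!is.finite(v))) return("all geometry fields must be finite")
  pos <- v[setdiff(names(v), "acd")]
  if (any(pos <= 0)) {
    return(paste0("fields must be > 0: ",
                  paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (v[["acd"]] < 0) return("acd must be >= 0 (lens may touch the cornea)")
  TRUE
})

#' Per-compartment refractive indices for optical-path correction
#'
#' SD-OCT depth is optical path length; dividing each compartment's optical
#' extent by its refractive index yields the geometric thickness. Defaults:
#' cornea 1.33, lens 1.40 (gradient-index lens as a bulk value), anterior and
#' vitreous chambers 1.34, retina 1.38. The RPE is assigned the retinal index.
#'
#' @slot cornea,lens,anteriorChamber,vitreous,retina,rpe refractive indices,
#'   each in `[1.0, 1.6]`.
#' @seealso [refractiveIndices()], [correctOpticalPath()]
#' @export
setClass("RefractiveIndexSet",
  representation(cornea = "numeric", lens = "numeric",
                 anteriorChamber = "numeric", vitreous = "numeric",
                 retina = "numeric", rpe = "numeric")
)

setValidity("RefractiveIndexSet", function(object) {
  v <- c(object@cornea, object@lens, object@anteriorChamber,
         object@vitreous, object@retina, object@rpe)
  if (any(!is.finite(v)) || any(v < 1.0) || any(v > 1.6))
    return("all refractive indices must lie in [1.0, 1.6]")
  TRUE
})

#' A 3-D SD-OCT intensity volume
#'
#' The z (depth) axis is in optical-path space: a structure of geometric
#' thickness t inside a medium of refractive index n occupies t * n
#' micrometres of depth. Intensities are arbitrary units.
#'
#' @slot data numeric array `[x, y, z]` of intensities.
#' @slot zPitch depth sampling pitch, micrometres of optical path per pixel.
#' @slot lateralPitch lateral sampling pitch, geometric micrometres per pixel.
#' @export
setClass("OctVolume",
  representation(data = "array", zPitch = "numeric", lateralPitch = "numeric")
)

setValidity("OctVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3-D array")
  if (length(object@zPitch) != 1L || object@zPitch <= 0)
    return("zPitch must be a single positive number")
  if (length(object@lateralPitch) != 1L || object@lateralPitch <= 0)
    return("lateralPitch must be a single positive number")
  TRUE
})

#' Segmented axial interface positions
#'
#' Sub-pixel z positions (optical-path micrometres, 0 at the shallowest
#' pixel) of the seven ocular interfaces along the central axis, in
#' anterior-to-posterior order: cornea-outer, cornea-inner, lens-anterior,
#' lens-posterior, retina-inner, retina/RPE, RPE-outer.
#'
#' @slot positions named numeric(7), strictly increasing, optical micrometres.
#' @slot axis integer(2), the `[x, y]` column index of the central A-scan.
#' @slot zPitch depth pitch of the source volume (µm/pixel).
#' @export
setClass("BoundarySet",
  representation(positions = "numeric", axis = "integer", zPitch = "numeric")
)

.BOUNDARY_NAMES <- c("cornea_outer", "cornea_inner", "lens_anterior",
                     "lens_posterior", "retina_inner", "retina_rpe",
                     "rpe_outer")
.COMPONENT_NAMES <- c("corneal_thickness", "acd", "lens_diameter", "vcd",
                      "retinal_thickness", "rpe_thickness")

setValidity("BoundarySet", function(object) {
  p <- object@positions
  if (length(p) != 7L || !identical(names(p), .BOUNDARY_NAMES))
    return("positions must be the 7 named interfaces in order")
  if (any(diff(p) <= 0)) return("interface positions must strictly increase")
  if (any(p < 0)) return("interface positions must be non-negative")
  TRUE
})

#' Per-eye biometric endpoints
#'
#' Geometric (index-corrected) thickness of each ocular compartment, the
#' axial length (their sum), and an ellipsoid eye-volume estimate.
#'
#' @slot cornealThickness,acd,lensDiameter,vcd,retinalThickness,rpeThickness
#'   geometric micrometres.
#' @slot axialLength micrometres; equals the sum of the six compartments.
#' @slot eyeVolume cubic micrometres, from the ellipsoid
#'   (4/3)*pi*a*b*c with the axial semi-axis and the two equatorial
#'   semi-axes measured on the mid-depth en-face slice; `NA` when the
#'   equatorial extent is not measurable.
#' @slot qcFlags character vector of quality-control labels (possibly empty).
#' @export
setClass("BiometryRecord",
  representation(
    cornealThickness = "numeric", acd = "numeric", lensDiameter = "numeric",
    vcd = "numeric", retinalThickness = "numeric", rpeThickness = "numeric",
    axialLength = "numeric", eyeVolume = "numeric", qcFlags = "character"
  )
)

setValidity("BiometryRecord", function(object) {
  comp <- c(object@cornealThickness, object@acd, object@lensDiameter,
            object@vcd, object@retinalThickness, object@rpeThickness)
  if (any(comp < 0)) return("geometric thicknesses must be >= 0")
  if (abs(object@axialLength - sum(comp)) > 0.01)
    return("axialLength must equal the component sum within 0.01 um")
  TRUE
})

#' Photorefraction slope-to-diopter calibration
#'
#' Ordinary least squares fit of diopters against pupil brightness-gradient
#' slope, obtained by imaging through ophthalmic trial lenses of known power:
#' `diopters = gain * slope + offset`.
#'
#' @slot gain diopters per (intensity a.u. / pupil radius).
#' @slot offset diopters.
#' @slot fitR2 coefficient of determination of the calibration fit.
#' @slot lensPoints data.frame with columns `slope`, `diopters`.
#' @export
setClass("RefractionCalibration",
  representation(gain = "numeric", offset = "numeric", fitR2 = "numeric",
                 lensPoints = "data.frame")
)

setValidity("RefractionCalibration", function(object) {
  if (nrow(object@lensPoints) < 2L ||
      length(unique(object@lensPoints$slope)) < 2L)
    return("calibration needs >= 2 distinct slope points")
  if (!is.na(object@fitR2) && (object@fitR2 < 0 || object@fitR2 > 1))
    return("fitR2 must lie in [0, 1]")
  TRUE
})

#' Averaged photorefraction result for one eye
#'
#' @slot meanDiopters mean refractive error over frames (D).
#' @slot sdDiopters standard deviation over frames (D; 0 with a qc flag when
#'   only one frame was usable).
#' @slot nMeasurements number of frames that produced a slope.
#' @slot slopes per-frame brightness slopes (a.u. per pupil radius).
#' @slot qcFlags character vector of quality-control labels.
#' @export
setClass("RefractionResult",
  representation(meanDiopters = "numeric", sdDiopters = "numeric",
                 nMeasurements = "integer", slopes = "numeric",
                 qcFlags = "character")
)

#' Binocular eye-angle time series
#'
#' Uniformly sampled eye azimuth angles for the left and right eye of one
#' fish during optokinetic stimulation, with the stimulus parameters attached.
#'
#' @slot time seconds, uniform sampling.
#' @slot angleLeft,angleRight eye angles in degrees.
#' @slot sampleRate Hz.
#' @slot stimulus list with `drum_velocity` (deg/s), `spatial_frequency`
#'   (cycles/deg) and `direction` (`"cw"` or `"ccw"`).
#' @export
setClass("AngleTrace",
  representation(time = "numeric", angleLeft = "numeric",
                 angleRight = "numeric", sampleRate = "numeric",
                 stimulus = "list")
)

setValidity("AngleTrace", function(object) {
  n <- length(object@time)
  if (length(object@angleLeft) != n || length(object@angleRight) != n)
    return("time and angle vectors must have equal length")
  if (n >= 3) {
    dt <- diff(object@time)
    if (max(dt) - min(dt) > 0.01 * mean(dt))
      return("sampling must be uniform within 1%")
  }
  if (!all(is.finite(c(object@angleLeft, object@angleRight))))
    return("angles must be finite")
  TRUE
})

#' Optokinetic response summary for one fish
#'
#' @slot gainTn,gainNt optokinetic gain (slow-phase eye velocity / drum
#'   velocity) for temporal-to-nasal and nasal-to-temporal eye movements;
#'   `NA` when no response was detected.
#' @slot etmPer15s integer vector of eye-tracking-movement counts per
#'   consecutive 15-s interval.
#' @slot nSegments number of slow-phase segments used.
#' @slot noResponse flag: no slow-phase segment reached the r-squared
#'   acceptance threshold.
#' @export
setClass("OkrResult",
  representation(gainTn = "numeric", gainNt = "numeric",
                 etmPer15s = "integer", nSegments = "integer",
                 noResponse = "logical")
)

#' Compound-symmetry mixed-model fit
#'
#' Genotype fixed effect on a per-eye metric with a random fish intercept,
#' which induces a compound-symmetry covariance between the two eyes of a
#' fish; fitted by REML. Effects are expressed against the reference
#' (wild-type) genotype.
#'
#' @slot metric name of the analyzed metric.
#' @slot reference reference genotype label.
#' @slot effectSize named numeric, genotype coefficients (metric units).
#' @slot se,tValue,df,pValue named numerics parallel to `effectSize`.
#' @slot sigmaFish2,sigmaEye2 between-fish and within-fish (between-eye)
#'   variance components.
#' @slot icc intraclass correlation `sigmaFish2 / (sigmaFish2 + sigmaEye2)`.
#' @slot nFish,nEyes sample sizes.
#' @slot converged logical convergence flag.
#' @export
setClass("MixedFit",
  representation(
    metric = "character", reference = "character",
    effectSize = "numeric", se = "numeric", tValue = "numeric",
    df = "numeric", pValue = "numeric",
    sigmaFish2 = "numeric", sigmaEye2 = "numeric", icc = "numeric",
    nFish = "integer", nEyes = "integer", converged = "logical"
  )
)

setValidity("MixedFit", function(object) {
  if (any(c(object@sigmaFish2, object@sigmaEye2) < 0, na.rm = TRUE))
    return("variance components must be non-negative")
  if (!is.na(object@icc) && (object@icc < 0 || object@icc > 1))
    return("icc must lie in [0, 1]")
  if (any(object@pValue <= 0 | object@pValue > 1, na.rm = TRUE))
    return("p-values must lie in (0, 1]")
  TRUE
})
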