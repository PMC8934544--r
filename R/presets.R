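#' Construct an eye geometry
#'
#' @param cornealThickness,acd,lensDiameter,vcd,retinalThickness,rpeThickness
#'   axial compartment thicknesses, geometric micrometres.
#' @param equatorialDiameterX,equatorialDiameterY equatorial diameters of the
#'   globe, micrometres.
#' @return an [EyeGeometry-class].
#' @examples
#' g <- eyeGeometry(30, 35, 500, 300, 126, 14, 1100, 1100)
#' axialLength(g)
#' @export
eyeGeometry <- function(cornealThickness, acd, lensDiameter, vcd,
                        retinalThickness, rpeThickness,
                        equatorialDiameterX, equatorialDiameterY) {
  new("EyeGeometry",
      cornealThickness = as.numeric(cornealThickness), acd = as.numeric(acd),
      lensDiameter = as.numeric(lensDiameter), vcd = as.numeric(vcd),
      retinalThickness = as.numeric(retinalThickness),
      rpeThickness = as.numeric(rpeThickness),
      equatorialDiameterX = as.numeric(equatorialDiameterX),
      equatorialDiameterY = as.numeric(equatorialDiameterY))
}

#' Refractive indices of the ocular compartments
#'
#' @param cornea,lens,anteriorChamber,vitreous,retina,rpe per-compartment
#'   refractive indices. Defaults are the standard literature values used
#'   throughout the package: cornea 1.33, lens 1.40 (bulk value for the
#'   gradient-index fish lens), anterior and vitreous chamber 1.34,
#'   retina 1.38. No separate RPE index is established for zebrafish, so the
#'   RPE inherits the retinal index by default.
#' @return a [RefractiveIndexSet-class].
#' @export
refractiveIndices <- function(cornea = 1.33, lens = 1.40,
                              anteriorChamber = 1.34, vitreous = 1.34,
                              retina = 1.38, rpe = retina) {
  new("RefractiveIndexSet", cornea = cornea, lens = lens,
      anteriorChamber = anteriorChamber, vitreous = vitreous,
      retina = retina, rpe = rpe)
}

# Wild-type baseline geometries per age (months post-fertilization).
# Retinal thickness follows the measured thinning of the maturing WT retina
# (152 -> 137 -> 126 um over 2 -> 6 mpf); the remaining absolute baselines
# are plausible adult-zebrafish constants chosen once (only genotype
# differences are asserted against measured values), subject to two
# consistency constraints: (i) WT eyes should be emmetropic under the
# focal-length model, i.e. lens radius + VCD ~ 2.182 * lens radius + 11.7
# (the regression was calibrated on WT eyes), and (ii) the WT vitreous
# chamber must exceed the mutant VCD reductions (-135 to -288 um) by enough
# that every mutant preset keeps an anatomically positive, optically
# resolvable vitreous chamber.
.WT_BASE <- list(
  `2mpf` = c(cornealThickness = 25, acd = 30, lensDiameter = 500, vcd = 305,
             retinalThickness = 152, rpeThickness = 12,
             equatorialDiameterX = 1180, equatorialDiameterY = 1180),
  `4mpf` = c(cornealThickness = 28, acd = 32, lensDiameter = 550, vcd = 335,
             retinalThickness = 137, rpeThickness = 13,
             equatorialDiameterX = 1260, equatorialDiameterY = 1260),
  `6mpf` = c(cornealThickness = 30, acd = 35, lensDiameter = 600, vcd = 366,
             retinalThickness = 126, rpeThickness = 14,
             equatorialDiameterX = 1350, equatorialDiameterY = 1350)
)

# Per-component genotype deltas (mutant minus WT), geometric um. Components
# without a significant difference carry delta 0. The printed per-component
# effects do not sum exactly to the printed axial-length effect for prss56
# (rounding of the per-panel values); the small residual is absorbed into the
# VCD delta so that the implied axial delta equals the printed axial effect,
# axial length being the headline endpoint.
#   prss56 axial: -157 (2mpf), -260 (4mpf), -330 (6mpf)
.DELTAS <- list(
  prss56_2mpf = c(lensDiameter = -32, vcd = -135, retinalThickness = 7,
                  rpeThickness = 3),
  prss56_4mpf = c(acd = -7, lensDiameter = -34, vcd = -233,
                  retinalThickness = 19, rpeThickness = -5),
  prss56_6mpf = c(cornealThickness = 5, acd = -6, lensDiameter = -73,
                  vcd = -288, retinalThickness = 32),
  fbn1_2mpf = c(acd = 3),
  fbn1_4mpf = c(acd = 11),
  fbn1_6mpf = c(acd = 27, vcd = -51, retinalThickness = 10)
)

.presetTable <- local({
  out <- list()
  for (age in names(.WT_BASE)) out[[paste0("wt_", age)]] <- .WT_BASE[[age]]
  for (nm in names(.DELTAS)) {
    age <- sub(".*_", "", nm)
    v <- .WT_BASE[[age]]
    d <- .DELTAS[[nm]]
    v[names(d)] <- v[names(d)] + d
    # eye growth of the globe scales with the axial change
    ax <- sum(v[1:6]) / sum(.WT_BASE[[age]][1:6])
    v[c("equatorialDiameterX", "equatorialDiameterY")] <-
      v[c("equatorialDiameterX", "equatorialDiameterY")] * ax
    out[[nm]] <- v
  }
  out
})

#' Registered model-eye geometry presets
#'
#' @return character vector of preset names (`wt_2mpf`, `prss56_6mpf`, ...),
#'   covering wild-type, `prss56` and `fbn1` mutants at 2, 4 and 6 months
#'   post-fertilization.
#' @export
listEyePresets <- function() names(.presetTable)

#' Look up a preset mean eye geometry
#'
#' Presets encode the wild-type baseline per age together with the measured
#' per-compartment genotype differences of the `prss56` (posterior
#' microphthalmia) and `fbn1` (Marfan) mutant lines; compartments without a
#' significant genotype difference are identical to the wild-type preset.
#'
#' @param preset one of [listEyePresets()].
#' @return the preset mean [EyeGeometry-class] (deterministic; cohort noise
#'   is added by [makeCohort()]).
#' @examples
#' wt <- makeEyeGeometry("wt_6mpf")
#' mut <- makeEyeGeometry("prss56_6mpf")
#' geometryValues(mut)[["vcd"]] - geometryValues(wt)[["vcd"]]
#' @export
makeEyeGeometry <- function(preset) {
  if (!is.character(preset) || length(preset) != 1L ||
      !preset %in% names(.presetTable)) {
    stop("unknown preset '", preset, "'; known presets: ",
         paste(names(.presetTable), collapse = ", "))
  }
  v <- .presetTable[[preset]]
  eyeGeometry(v[["cornealThickness"]], v[["acd"]], v[["lensDiameter"]],
              v[["vcd"]], v[["retinalThickness"]], v[["rpeThickness"]],
              v[["equatorialDiameterX"]], v[["equatorialDiameterY"]])
}

# Downstream assay presets per genotype/age. Refraction (diopters): the WT
# baseline is mildly hyperopic (small-eye retinoscopic artifact); the fbn1
# lens subluxation adds +8 D at 4 mpf and +12 D at 6 mpf. prss56 eyes are too
# small for photorefraction and carry NA. OKR slow-phase velocity (deg/s
# under a 20 deg/s drum) and IOP (mmHg) baselines are plausible constants;
# mutant IOP is elevated, prss56 optokinetic gain is reduced.
.ASSAY_PRESETS <- local({
  ages <- c("2mpf", "4mpf", "6mpf")
  refr <- c(wt = 5, fbn1 = 5, prss56 = NA_real_)
  refrDelta <- list(fbn1 = c(`2mpf` = 0, `4mpf` = 8, `6mpf` = 12))
  okrV <- c(wt = 15, fbn1 = 15, prss56 = 7.5)
  iop <- c(wt = 11, fbn1 = 14, prss56 = 14)
  out <- list()
  for (g in c("wt", "prss56", "fbn1")) for (age in ages) {
    d <- if (!is.null(refrDelta[[g]])) refrDelta[[g]][[age]] else 0
    out[[paste0(g, "_", age)]] <- list(
      refraction_d = unname(refr[[g]] + d),
      okr_velocity = unname(okrV[[g]]),
      iop_mmhg = unname(iop[[g]]))
  }
  out
})

#' Downstream assay presets for a genotype/age label
#'
#' @param preset one of [listEyePresets()].
#' @return list with `refraction_d` (mean refractive error, D; `NA` where
#'   photorefraction is not feasible), `okr_velocity` (slow-phase eye
#'   velocity, deg/s) and `iop_mmhg` (true intraocular pressure, mmHg).
#' @export
assayPresets <- function(preset) {
  if (!preset %in% names(.ASSAY_PRESETS))
    stop("unknown preset '", preset, "'; known presets: ",
         paste(names(.ASSAY_PRESETS), collapse = ", "))
  .ASSAY_PRESETS[[preset]]
}
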