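#' Control-group mean viscoelastic parameters
#'
#' Reference (saline-treated control) group means of the four ROI-averaged
#' viscoelastic parameters in the hippocampal region and the whole brain
#' parenchyma, in Pa (phi in rad). These are the cell means the longitudinal
#' study generator is built around. The tabulated loss tangent is an
#' ROI-average of per-pixel `atan(G''/G')` values and therefore differs from
#' `atan(mean G'' / mean G')`.
#'
#' @return A data.frame with columns `roi`, `parameter`, `mean`.
#' @export
control_means <- function() {
  data.frame(
    roi = rep(c("hippocampus", "whole_brain"), each = 4),
    parameter = rep(c("Gp", "Gpp", "absG", "phi"), 2),
    mean = c(4608, 1388, 4816, 0.549,
             5234, 1447, 5432, 0.574),
    stringsAsFactors = FALSE
  )
}

.study_time_points <- c("baseline", "3", "6", "10", "14", "18")
.study_parameters <- c("Gp", "Gpp", "absG", "phi")

#' Treatment-effect specification for the longitudinal study generator
#'
#' Encodes, per treatment and time point, the multiplicative effect on the
#' storage (`Gp`) and loss (`Gpp`) modulus relative to the control means,
#' plus the between-animal and within-animal (residual) standard deviations
#' per parameter.
#'
#' The default is the transient 6-dpi stiffening: MPTP multiplies `Gp` by
#' 1.51 and `Gpp` by 1.27 at 6 dpi (all other cells 1). Default standard
#' deviations are the control hippocampal SEMs scaled by `sqrt(5)` (n = 5
#' animals) for the between-animal component, with a smaller within-animal
#' (scan-rescan) component of 20% of that.
#'
#' @param gp_mult,gpp_mult Named numeric vectors of multipliers for the MPTP
#'   group, names from `c("baseline","3","6","10","14","18")`; unnamed cells
#'   default to 1.
#' @param between_animal_sd Named vector `c(Gp=, Gpp=)`, Pa.
#' @param within_animal_sd Named vector `c(Gp=, Gpp=)`, Pa.
#' @return An object of class `mre_effect_spec`.
#' @export
effect_spec <- function(gp_mult = c("6" = 1.51),
                        gpp_mult = c("6" = 1.27),
                        between_animal_sd = c(Gp = 0.719e3 * sqrt(5),
                                              Gpp = 0.125e3 * sqrt(5)),
                        within_animal_sd = 0.2 * c(Gp = 0.719e3 * sqrt(5),
                                                   Gpp = 0.125e3 * sqrt(5))) {
  full <- function(x) {
    out <- stats::setNames(rep(1, length(.study_time_points)), .study_time_points)
    if (length(x)) out[names(x)] <- x
    out
  }
  gp_mult <- full(gp_mult); gpp_mult <- full(gpp_mult)
  if (any(c(gp_mult, gpp_mult) <= 0)) stop("effect multipliers must be > 0")
  if (any(c(between_animal_sd, within_animal_sd) < 0)) stop("sds must be >= 0")
  structure(list(gp_mult = gp_mult, gpp_mult = gpp_mult,
                 between_animal_sd = between_animal_sd,
                 within_animal_sd = within_animal_sd),
            class = "mre_effect_spec")
}

#' Simulate a balanced longitudinal MRE study table
#'
#' Generates a long-format table of ROI-averaged viscoelastic parameters for
#' a balanced design of 2 treatment groups (CTR, MPTP) x `n_per_group`
#' animals x 6 time points (baseline, 3, 6, 10, 14, 18 dpi) x 2 ROIs
#' (whole_brain, hippocampus). The two groups contain distinct animals
#' (fully between-subjects Treatment factor).
#'
#' Generative model per (animal, parameter): a single random intercept
#' `N(0, between_animal_sd)` shared across time points and ROIs, plus an
#' independent residual `N(0, within_animal_sd)` per record; MPTP cell means
#' are control means times the multipliers of `effects`. `absG` and `phi`
#' are derived per record from the sampled `Gp`, `Gpp`.
#'
#' @param means Control means, a data.frame as from [control_means()] (only
#'   rows with parameter `Gp`/`Gpp` are used as generative cell means).
#' @param effects An [effect_spec()].
#' @param n_per_group Animals per treatment group (>= 2).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @return A data.frame (`StudyTable`) with columns `animal_id`, `treatment`,
#'   `time_point`, `roi`, `parameter`, `value`.
#' @export
simulate_longitudinal_study <- function(means = control_means(),
                                        effects = effect_spec(),
                                        n_per_group = 5, seed = 1) {
  stopifnot(inherits(effects, "mre_effect_spec"))
  if (n_per_group < 2) stop("n_per_group must be >= 2 for a balanced ANOVA design")
  set.seed(seed)
  rois <- unique(means$roi)
  tps <- .study_time_points
  treatments <- c("CTR", "MPTP")
  base <- function(roi, par)
    means$mean[means$roi == roi & means$parameter == par][1]

  # one row per (treatment, animal, time, roi); roi varies fastest
  grid <- expand.grid(roi = rois, time_point = tps,
                      animal = seq_len(n_per_group), treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nrec <- nrow(grid)
  # animal random intercepts, one per (treatment, animal, parameter)
  akey <- paste(grid$treatment, grid$animal)
  alev <- unique(akey)
  icpt_gp <- stats::setNames(
    stats::rnorm(length(alev), 0, effects$between_animal_sd[["Gp"]]), alev)
  icpt_gpp <- stats::setNames(
    stats::rnorm(length(alev), 0, effects$between_animal_sd[["Gpp"]]), alev)

  mgp <- ifelse(grid$treatment == "MPTP", effects$gp_mult[grid$time_point], 1)
  mgpp <- ifelse(grid$treatment == "MPTP", effects$gpp_mult[grid$time_point], 1)
  base_gp <- vapply(grid$roi, base, numeric(1), par = "Gp")
  base_gpp <- vapply(grid$roi, base, numeric(1), par = "Gpp")
  gp <- base_gp * mgp + icpt_gp[akey] +
    stats::rnorm(nrec, 0, effects$within_animal_sd[["Gp"]])
  gpp <- base_gpp * mgpp + icpt_gpp[akey] +
    stats::rnorm(nrec, 0, effects$within_animal_sd[["Gpp"]])

  out <- data.frame(
    animal_id = rep(sprintf("%s_%02d", grid$treatment, grid$animal), each = 4),
    treatment = rep(grid$treatment, each = 4),
    time_point = rep(grid$time_point, each = 4),
    roi = rep(grid$roi, each = 4),
    parameter = rep(.study_parameters, nrec),
    value = as.vector(rbind(gp, gpp, sqrt(gp^2 + gpp^2), atan(gpp / gp))),
    stringsAsFactors = FALSE)
  out$time_point <- factor(out$time_point, levels = tps)
  out$treatment <- factor(out$treatment, levels = treatments)
  out
}
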