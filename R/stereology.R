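#' Series-scaled total cell count
#'
#' Scales a count obtained on a 1-in-`series_interval` section series to the
#' whole-brain estimate: `raw_count * series_interval`. With the default
#' 1-in-12 series (sections 480 um apart) a count of 37 cells estimates 444
#' cells per brain.
#'
#' @param raw_count Cells counted in the sampled sections (>= 0).
#' @param series_interval Section sampling interval (>= 1; default 12).
#' @return Estimated total cell count (vectorised, exact product — no
#'   rounding).
#' @export
series_total <- function(raw_count, series_interval = 12) {
  if (any(raw_count < 0)) stop("raw_count must be >= 0")
  if (any(series_interval < 1)) stop("series_interval must be >= 1")
  raw_count * series_interval
}

#' Absolute number of double-labeled cells from a sampled proportion
#'
#' Converts the proportion of double-labeled cells observed in a sample
#' (e.g. 50 BrdU-positive cells scored for Nestin/GFP or NeuN
#' co-expression) into an absolute estimate:
#' `(n_double_of_sample / sample_size) * total_marker_estimate`.
#'
#' @param n_double_of_sample Double-labeled cells in the sample
#'   (`0 <= n <= sample_size`).
#' @param sample_size Sample size (> 0; typically 50).
#' @param total_marker_estimate Estimated total cells carrying the primary
#'   marker.
#' @return Absolute double-labeled cell estimate; bounded above by
#'   `total_marker_estimate`.
#' @export
double_label_absolute <- function(n_double_of_sample, sample_size,
                                  total_marker_estimate) {
  if (any(sample_size <= 0)) stop("sample_size must be > 0")
  if (any(n_double_of_sample < 0 | n_double_of_sample > sample_size))
    stop("n_double_of_sample must lie in [0, sample_size]")
  (n_double_of_sample / sample_size) * total_marker_estimate
}

#' Optical fractionator sampling specification
#'
#' Geometry of the optical fractionator: counting frame and sampling grid
#' footprints (um), optical disector height and physical section thickness
#' (um), the section series interval and the guard zone below the section
#' surface. Defaults follow a 30x30 um frame in a 120x100 um grid, a 20 um
#' disector starting 5 um below the surface of 40 um sections, on a 1-in-12
#' series. The guard zone positions the disector but does not enter the
#' sampling fractions.
#'
#' @param frame Counting-frame side lengths, um (length 2).
#' @param grid Sampling-grid step lengths, um (length 2).
#' @param disector_height Optical disector height, um.
#' @param slice_thickness Section thickness, um.
#' @param series_interval Section sampling interval.
#' @param guard_zone Guard zone below the surface, um.
#' @return An object of class `mre_fractionator_spec`.
#' @export
fractionator_spec <- function(frame = c(30, 30), grid = c(120, 100),
                              disector_height = 20, slice_thickness = 40,
                              series_interval = 12, guard_zone = 5) {
  stopifnot(length(frame) == 2, length(grid) == 2)
  if (any(frame <= 0) || any(grid <= 0) || disector_height <= 0 ||
      slice_thickness <= 0 || series_interval < 1 || guard_zone < 0)
    stop("all fractionator dimensions must be positive")
  if (any(frame > grid))
    stop("counting frame must fit inside the sampling grid")
  if (disector_height + guard_zone > slice_thickness)
    stop("disector height plus guard zone exceeds the slice thickness")
  structure(list(frame = frame, grid = grid,
                 disector_height = disector_height,
                 slice_thickness = slice_thickness,
                 series_interval = series_interval, guard_zone = guard_zone),
            class = "mre_fractionator_spec")
}

#' Optical fractionator total cell estimate
#'
#' `N = sum_Q * ssf^-1 * asf^-1 * hsf^-1`, where the inverse sampling
#' fractions are the section factor (`series_interval`), the area factor
#' (`grid area / frame area`) and the height factor
#' (`slice_thickness / disector_height`). At the defaults the combined
#' factor is `12 * (12000/900) * (40/20) = 320`.
#'
#' @param sum_Q Cells counted in all disectors (>= 0).
#' @param spec An [fractionator_spec()].
#' @return The total cell estimate, with the three inverse fractions
#'   attached as attribute `"factors"`.
#' @export
#'
#' @examples
#' fractionator_estimate(100, fractionator_spec())  # 32000
fractionator_estimate <- function(sum_Q, spec = fractionator_spec()) {
  stopifnot(inherits(spec, "mre_fractionator_spec"))
  if (any(sum_Q < 0)) stop("sum_Q must be >= 0")
  inv_ssf <- spec$series_interval
  inv_asf <- prod(spec$grid) / prod(spec$frame)
  inv_hsf <- spec$slice_thickness / spec$disector_height
  out <- sum_Q * inv_ssf * inv_asf * inv_hsf
  attr(out, "factors") <- c(section = inv_ssf, area = inv_asf, height = inv_hsf)
  out
}

#' Simulate per-animal cell-count records
#'
#' Draws integer cell counts for a balanced 2 treatments x 6 time points x
#' `n_per_group` design around specified cell means. Counts are
#' negative-binomial (overdispersed Poisson) with per-record standard
#' deviation `sd`: for `sd = 0` counts equal the rounded means; for
#' `0 < sd^2 <= mean` a Poisson draw is used; otherwise a negative binomial
#' with `size = mean^2 / (sd^2 - mean)`.
#'
#' @param means Data.frame with columns `marker`, `treatment`, `time_point`,
#'   `mean` (cells) and optionally `sd` (cells) and `region`.
#' @param n_per_group Animals per (treatment, time point) cell.
#' @param sd Default per-record sd used where `means$sd` is absent.
#' @param seed Integer seed (deterministic tables under a fixed seed).
#' @return A data.frame of CountRecords: `animal_id`, `treatment`,
#'   `time_point`, `marker`, `region`, `raw_count`, `sections_counted`,
#'   `series_interval`, `value` (the count, for the ANOVA functions).
#' @export
simulate_counts <- function(means, n_per_group = 5, sd = NULL, seed = 1) {
  need <- c("marker", "treatment", "time_point", "mean")
  if (!all(need %in% names(means))) stop("means lacks columns: ",
                                         paste(setdiff(need, names(means)), collapse = ", "))
  if (any(means$mean < 0)) stop("means must be >= 0")
  if (!"sd" %in% names(means))
    means$sd <- if (is.null(sd)) sqrt(means$mean) else sd
  if (!"region" %in% names(means)) means$region <- "GCL_SGZ"
  set.seed(seed)
  rows <- vector("list", 0)
  for (r in seq_len(nrow(means))) {
    mu <- means$mean[r]; s <- means$sd[r]
    for (a in seq_len(n_per_group)) {
      cnt <- if (s == 0 || mu == 0) {
        round(mu)
      } else if (s^2 <= mu) {
        stats::rpois(1, mu)
      } else {
        stats::rnbinom(1, size = mu^2 / (s^2 - mu), mu = mu)
      }
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = sprintf("%s_%s_%02d", means$treatment[r],
                            means$time_point[r], a),
        treatment = means$treatment[r], time_point = means$time_point[r],
        marker = means$marker[r], region = means$region[r],
        raw_count = cnt, sections_counted = 4L, series_interval = 12L,
        value = cnt, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
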