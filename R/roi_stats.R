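#' ROI-average of an elastogram
#'
#' Averages each of the four per-pixel viscoelastic maps (`Gp`, `Gpp`,
#' `absG`, `phi`) over the valid pixels of a named ROI. Each derived map is
#' averaged independently: the tabulated loss tangent is the mean of
#' per-pixel `atan(G''/G')`, not the `atan` of the mean-component ratio
#' (`avg_order = "complex_first"` gives the latter).
#'
#' @param elastogram An `mre_elastogram`.
#' @param mask Integer label matrix aligned to the elastogram grid.
#' @param roi_name Name of the ROI to average.
#' @param roi_labels Named integer vector mapping ROI names to label values,
#'   default `c(parenchyma = 1, hippocampus = 2)`.
#' @param avg_order `"maps"` (default; average each derived map) or
#'   `"complex_first"` (average complex `G*` first, then derive).
#' @return A one-row data.frame: `roi`, means of the four parameters (Pa /
#'   rad), `n_pixels` (ROI size), `n_valid`, `invalid_fraction`.
#' @export
roi_average <- function(elastogram, mask, roi_name,
                        roi_labels = c(parenchyma = 1, hippocampus = 2),
                        avg_order = c("maps", "complex_first")) {
  stopifnot(inherits(elastogram, "mre_elastogram"), is.matrix(mask))
  avg_order <- match.arg(avg_order)
  if (!all(dim(mask) == dim(elastogram$valid_mask)))
    stop("mask shape does not match the elastogram")
  if (!roi_name %in% names(roi_labels))
    stop("unknown ROI: ", roi_name)
  inroi <- mask == roi_labels[[roi_name]]
  if (!any(inroi)) stop("ROI '", roi_name, "' contains no pixels")
  sel <- inroi & elastogram$valid_mask
  if (!any(sel))
    stop("ROI '", roi_name, "' contains no valid pixels")
  if (avg_order == "maps") {
    gp <- mean(elastogram$gp[sel]); gpp <- mean(elastogram$gpp[sel])
    absg <- mean(elastogram$absg[sel]); phi <- mean(elastogram$phi[sel])
  } else {
    g <- mean(elastogram$gstar[sel])
    gp <- Re(g); gpp <- Im(g); absg <- Mod(g); phi <- atan(gpp / gp)
  }
  data.frame(roi = roi_name, Gp = gp, Gpp = gpp, absG = absg, phi = phi,
             n_pixels = sum(inroi), n_valid = sum(sel),
             invalid_fraction = 1 - sum(sel) / sum(inroi),
             stringsAsFactors = FALSE)
}

#' Percent change relative to a reference
#'
#' `100 * (value / reference - 1)`. No rounding is applied here; integer
#' rounding belongs to the report layer.
#'
#' @param value,reference Numeric (reference must be strictly positive).
#' @return Percent change (vectorised).
#' @export
#'
#' @examples
#' percent_change(6971, 4608)  # ~51.3
percent_change <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be strictly positive")
  100 * (value / reference - 1)
}

.check_balanced <- function(tab, factors) {
  counts <- table(tab[factors])
  if (any(counts != counts[1])) {
    bad <- which(counts != counts[1], arr.ind = TRUE)[1, ]
    stop("unbalanced design at cell: ",
         paste(mapply(function(f, i) paste0(f, "=", dimnames(counts)[[f]][i]),
                      factors, bad), collapse = ", "))
  }
  invisible(counts[1])
}

.anova_result <- function(df) {
  stopifnot(all(c("effect", "stratum", "ss", "df", "ms", "f", "p") %in% names(df)))
  structure(df, class = c("mre_anova", "data.frame"))
}

#' Mixed-design (repeated-measures) two-way ANOVA
#'
#' Univariate mixed-design ANOVA of a longitudinal study table for one
#' (parameter, ROI): Treatment as the between-subjects factor tested against
#' subjects-within-groups, Time and Treatment x Time as within-subjects
#' factors tested against the Time x subjects-within-groups error. No
#' sphericity correction is applied, so for 2 groups x n animals x t time
#' points the dfs are Treatment (1, 2n-2), Time (t-1, (2n-2)(t-1)) and
#' interaction (t-1, (2n-2)(t-1)).
#'
#' @param table A StudyTable as from [simulate_longitudinal_study()] (or any
#'   data.frame with `animal_id`, `treatment`, `time_point`, `value` and
#'   optionally `parameter`, `roi`).
#' @param parameter,roi Select one parameter/ROI when those columns exist.
#' @return An `mre_anova` data.frame with one row per effect and per error
#'   stratum: `effect`, `stratum`, `ss`, `df`, `ms`, `f`, `p`.
#' @export
rm_two_way_anova <- function(table, parameter = NULL, roi = NULL) {
  tab <- table
  if (!is.null(parameter) && "parameter" %in% names(tab))
    tab <- tab[tab$parameter == parameter, ]
  if (!is.null(roi) && "roi" %in% names(tab))
    tab <- tab[tab$roi == roi, ]
  need <- c("animal_id", "treatment", "time_point", "value")
  if (!all(need %in% names(tab))) stop("table lacks columns: ",
                                       paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(is.na(tab$value))) stop("missing values are not supported (complete cases required)")
  tab$treatment <- factor(tab$treatment)
  tab$time_point <- factor(tab$time_point)
  tab$animal_id <- factor(tab$animal_id)
  .check_balanced(tab, c("treatment", "time_point"))
  if (any(table(tab$animal_id, tab$time_point) != 1))
    stop("need exactly one record per animal and time point")

  fit <- stats::aov(value ~ treatment * time_point + Error(animal_id),
                    data = tab)
  sm <- summary(fit)
  # between-subjects stratum
  bt <- as.data.frame(sm[["Error: animal_id"]][[1]])
  wt <- as.data.frame(sm[["Error: Within"]][[1]])
  rn <- function(x) trimws(rownames(x))
  pick <- function(tabl, name) {
    i <- match(name, rn(tabl))
    c(ss = tabl[i, "Sum Sq"], df = tabl[i, "Df"], ms = tabl[i, "Mean Sq"],
      f = if ("F value" %in% colnames(tabl)) tabl[i, "F value"] else NA,
      p = if ("Pr(>F)" %in% colnames(tabl)) tabl[i, "Pr(>F)"] else NA)
  }
  tr <- pick(bt, "treatment"); se <- pick(bt, "Residuals")
  ti <- pick(wt, "time_point"); ix <- pick(wt, "treatment:time_point")
  we <- pick(wt, "Residuals")
  .anova_result(data.frame(
    effect = c("treatment", "subjects_error", "time", "treatment:time",
               "within_error"),
    stratum = c("between", "between", "within", "within", "within"),
    ss = c(tr["ss"], se["ss"], ti["ss"], ix["ss"], we["ss"]),
    df = c(tr["df"], se["df"], ti["df"], ix["df"], we["df"]),
    ms = c(tr["ms"], se["ms"], ti["ms"], ix["ms"], we["ms"]),
    f = c(tr["f"], NA, ti["f"], ix["f"], NA),
    p = c(tr["p"], NA, ti["p"], ix["p"], NA),
    stringsAsFactors = FALSE))
}

#' Fully between-subjects two-way ANOVA
#'
#' Standard fixed-effects two-way ANOVA for designs where every (treatment,
#' time) cell holds distinct animals (e.g. histological groups sacrificed
#' per time point). For a 2 x 6 design with n = 5 per cell the dfs are
#' (1, 48), (5, 48) and (5, 48).
#'
#' If the total sum of squares is zero (all observations identical) the F
#' statistics are undefined and returned as `NA` with a warning.
#'
#' @param table Data.frame with `treatment`, `time_point`, `value` (one row
#'   per animal).
#' @return An `mre_anova` data.frame.
#' @export
two_way_anova <- function(table) {
  tab <- table
  need <- c("treatment", "time_point", "value")
  if (!all(need %in% names(tab))) stop("table lacks columns: ",
                                       paste(setdiff(need, names(tab)), collapse = ", "))
  tab$treatment <- factor(tab$treatment)
  tab$time_point <- factor(tab$time_point)
  .check_balanced(tab, c("treatment", "time_point"))
  ss_tot <- sum((tab$value - mean(tab$value))^2)
  if (ss_tot == 0) {
    warning("zero total sum of squares: all observations identical, F undefined")
    lv <- function(f) nlevels(tab[[f]])
    dfe <- nrow(tab) - lv("treatment") * lv("time_point")
    return(.anova_result(data.frame(
      effect = c("treatment", "time", "treatment:time", "residual_error"),
      stratum = "between",
      ss = 0, df = c(lv("treatment") - 1, lv("time_point") - 1,
                     (lv("treatment") - 1) * (lv("time_point") - 1), dfe),
      ms = 0, f = NA_real_, p = NA_real_, stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(value ~ treatment * time_point, data = tab)
  an <- as.data.frame(summary(fit)[[1]])
  rn <- trimws(rownames(an))
  i <- function(name) match(name, rn)
  idx <- c(i("treatment"), i("time_point"), i("treatment:time_point"),
           i("Residuals"))
  .anova_result(data.frame(
    effect = c("treatment", "time", "treatment:time", "residual_error"),
    stratum = "between",
    ss = an[idx, "Sum Sq"], df = an[idx, "Df"], ms = an[idx, "Mean Sq"],
    f = c(an[idx[1:3], "F value"], NA), p = c(an[idx[1:3], "Pr(>F)"], NA),
    stringsAsFactors = FALSE))
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' Pairwise two-sample t comparisons within an explicitly enumerated family,
#' with adjusted p = `min(1, m * p)` where `m` is the family size. Two
#' families are supported, mirroring post-hoc tests after a two-way design:
#'
#' * `"group_by_time"`: CTR vs MPTP at each time point (default family size
#'   m = number of time points);
#' * `"time_by_group"`: all time-point pairs within each treatment group
#'   (default m = number of pairs, per group family).
#'
#' The error term is taken from the fitted design: for `design = "between"`,
#' the residual mean square with its df; for `design = "rm"`, group
#' comparisons at a time point use the Satterthwaite-pooled combination of
#' the between-subjects and within-subjects error strata
#' (`(MS_subj + (t-1) MS_within) / t`), while time comparisons within a
#' group use the within-subjects error.
#'
#' @param table Study/count table (see [rm_two_way_anova()] /
#'   [two_way_anova()] for required columns; one record per animal and time).
#' @param parameter,roi Optional filters when those columns exist.
#' @param family `"group_by_time"` or `"time_by_group"`.
#' @param design `"rm"` (mixed) or `"between"` (fully between-subjects).
#' @param m Family size for the Bonferroni correction; default is the number
#'   of comparisons in the family.
#' @return A data.frame with one row per comparison: `family`, `contrast`,
#'   `estimate` (mean difference), `t`, `df`, `p_raw`, `p_adj`, `m`.
#' @export
bonferroni_pairwise <- function(table, parameter = NULL, roi = NULL,
                                family = c("group_by_time", "time_by_group"),
                                design = c("rm", "between"), m = NULL) {
  family <- match.arg(family)
  design <- match.arg(design)
  tab <- table
  if (!is.null(parameter) && "parameter" %in% names(tab))
    tab <- tab[tab$parameter == parameter, ]
  if (!is.null(roi) && "roi" %in% names(tab))
    tab <- tab[tab$roi == roi, ]
  tab$treatment <- factor(tab$treatment)
  tab$time_point <- factor(tab$time_point)
  n_cell <- .check_balanced(tab, c("treatment", "time_point"))
  tps <- levels(tab$time_point)
  trs <- levels(tab$treatment)
  t_levels <- length(tps)

  # error variance of a cell mean (per observation) and its df
  if (design == "between") {
    an <- two_way_anova(tab)
    mse <- an$ms[an$effect == "residual_error"]
    dfe <- an$df[an$effect == "residual_error"]
    var_time <- var_group <- mse
    df_time <- df_group <- dfe
  } else {
    an <- rm_two_way_anova(tab)
    ms_s <- an$ms[an$effect == "subjects_error"]
    df_s <- an$df[an$effect == "subjects_error"]
    ms_w <- an$ms[an$effect == "within_error"]
    df_w <- an$df[an$effect == "within_error"]
    # between-group contrast at one time point mixes both variance components
    var_group <- (ms_s + (t_levels - 1) * ms_w) / t_levels
    df_group <- var_group^2 / ((ms_s / t_levels)^2 / df_s +
                                 ((t_levels - 1) * ms_w / t_levels)^2 / df_w)
    var_time <- ms_w
    df_time <- df_w
  }

  cellmean <- function(tr, tp)
    mean(tab$value[tab$treatment == tr & tab$time_point == tp])

  rows <- list()
  if (family == "group_by_time") {
    for (tp in tps) {
      est <- cellmean(trs[2], tp) - cellmean(trs[1], tp)
      se <- sqrt(2 * var_group / n_cell)
      tstat <- est / se
      rows[[length(rows) + 1]] <- data.frame(
        family = family,
        contrast = sprintf("%s-%s@%s", trs[2], trs[1], tp),
        estimate = est, t = tstat, df = df_group,
        p_raw = 2 * stats::pt(-abs(tstat), df_group), stringsAsFactors = FALSE)
    }
  } else {
    for (tr in trs) {
      for (a in seq_len(t_levels - 1)) for (b in (a + 1):t_levels) {
        est <- cellmean(tr, tps[b]) - cellmean(tr, tps[a])
        se <- sqrt(2 * var_time / n_cell)
        tstat <- est / se
        rows[[length(rows) + 1]] <- data.frame(
          family = family,
          contrast = sprintf("%s-%s@%s", tps[b], tps[a], tr),
          estimate = est, t = tstat, df = df_time,
          p_raw = 2 * stats::pt(-abs(tstat), df_time), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (nrow(out) == 0) stop("empty comparison family")
  fam_m <- if (is.null(m)) {
    if (family == "group_by_time") nrow(out) else nrow(out) / length(trs)
  } else m
  out$m <- fam_m
  out$p_adj <- pmin(1, fam_m * out$p_raw)
  out
}
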