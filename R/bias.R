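#' Direction of a lesion-deficit association
#'
#' Combines Bayesian evidence with the frequentist sign: below the
#' Bayes-factor cut-off the unit carries no evidence; above it, a
#' slope indicating damage-predicts-worse is labelled `"damaging"`,
#' and the reverse association (damage predicting *better*
#' performance) is labelled `"protective"`.  Works from the slope
#' estimate so it is immune to the opposed z/t export conventions.
#'
#' @param bf10 Bayes factor(s).
#' @param estimate slope(s) of the score on the damage predictor
#'   (negative = damage worsens).  Alternatively pass a NiiStat-style
#'   `z` (same sign convention).
#' @param thresholds an [evidence_thresholds()].
#' @return Factor with levels `damaging`, `protective`, `no_evidence`;
#'   missing or untestable inputs give `no_evidence`.
#' @export
direction_label <- function(bf10, estimate,
                            thresholds = evidence_thresholds()) {
  lab <- ifelse(is.na(bf10) | is.na(estimate) |
                  bf10 <= thresholds$bf_cutoff, "no_evidence",
         ifelse(estimate < 0, "damaging",
         ifelse(estimate > 0, "protective", "no_evidence")))
  factor(lab, levels = c("damaging", "protective", "no_evidence"))
}

#' Align statistics across analysis samples
#'
#' Joins per-unit (region or voxel) logBF and frequentist statistics
#' from several sub-sample analyses of the same cohort into one long
#' table plus pairwise logBF deltas, the raw material for
#' logBF-versus-t/z scatter diagnostics.  Every tested unit is kept,
#' not only supra-threshold ones.
#'
#' @param results named list (by sample name) of `region_stat_table`s
#'   from [run_rlsm_bayesian()] or `voxel_stat_map`s from [run_vlsm()].
#' @return List of class `sample_comparison`: `long` (data.frame
#'   `unit`, `sample`, `log_bf`, `stat` where `stat` is the
#'   regionwise t or voxelwise z), and `delta` (data.frame of
#'   `log_bf(sample_a) - log_bf(sample_b)` for every ordered pair).
#' @export
compare_samples <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("`results` must be a named list keyed by sample")
  pull <- function(r) {
    if (inherits(r, "voxel_stat_map"))
      data.frame(unit = as.character(r$table$voxel),
                 log_bf = r$table$log_bf, stat = r$table$z)
    else
      data.frame(unit = r$region, log_bf = r$log_bf, stat = r$t)
  }
  tabs <- lapply(results, pull)
  units <- tabs[[1]]$unit
  for (t in tabs[-1]) {
    if (!identical(t$unit, units))
      stop("sample results are not aligned on the same units")
  }
  long <- do.call(rbind, lapply(names(tabs), function(nm)
    cbind(sample = nm, tabs[[nm]])))
  rownames(long) <- NULL
  pairs <- expand.grid(b = names(tabs), a = names(tabs),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, c("a", "b")]
  delta <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    data.frame(unit = units, sample_a = a, sample_b = b,
               delta_log_bf = tabs[[a]]$log_bf - tabs[[b]]$log_bf)
  }))
  rownames(delta) <- NULL
  structure(list(long = long, delta = delta), class = "sample_comparison")
}

#' logBF difference between two samples for one unit
#'
#' Convenience accessor on a [compare_samples()] result.
#'
#' @param x a `sample_comparison`.
#' @param unit unit (region name or voxel index as character).
#' @param a,b sample names; returns `log_bf(a) - log_bf(b)`.
#' @return Numeric scalar.
#' @export
delta_log_bf <- function(x, unit, a, b) {
  d <- x$delta
  row <- d$unit == unit & d$sample_a == a & d$sample_b == b
  if (sum(row) != 1L) stop("no unique delta for ", unit, ": ", a, " vs ", b)
  d$delta_log_bf[row]
}

#' Summarize a batch of resampling-control analyses
#'
#' For each region, counts how often it was included across the
#' control resamples, how often it was "uncovered" (Bayes factor above
#' the cut-off), and the mean and SD of the Bayes factor over the
#' uncovered resamples only.  The SD over a single uncovered resample
#' is reported as 0; a never-uncovered region has undefined moments.
#'
#' @param tables list of `region_stat_table`s from
#'   [run_rlsm_bayesian()] over [resample_cohort()] draws.
#' @param thresholds an [evidence_thresholds()].
#' @return data.frame of class `bias_summary`: `region`,
#'   `included_count`, `uncovered_count`, `mean_bf`, `sd_bf`
#'   (`NA` when undefined).
#' @export
summarize_resamples <- function(tables, thresholds = evidence_thresholds()) {
  if (length(tables) == 0L) stop("no resample tables supplied")
  regions <- tables[[1]]$region
  inc <- matrix(FALSE, length(regions), length(tables))
  bf <- matrix(NA_real_, length(regions), length(tables))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    if (!identical(t$region, regions)) stop("tables list different regions")
    inc[, j] <- t$included & !is.na(t$bf10)
    bf[, j] <- t$bf10
  }
  unc <- inc & !is.na(bf) & bf > thresholds$bf_cutoff
  out <- data.frame(
    region = regions,
    included_count = rowSums(inc),
    uncovered_count = rowSums(unc),
    mean_bf = NA_real_, sd_bf = NA_real_)
  for (i in seq_along(regions)) {
    v <- bf[i, unc[i, ]]
    if (length(v) >= 1L) {
      out$mean_bf[i] <- mean(v)
      out$sd_bf[i] <- if (length(v) >= 2L) stats::sd(v) else 0
    }
  }
  class(out) <- c("bias_summary", class(out))
  out
}

#' Render a resampling summary in report style
#'
#' Formats mean (SD) of the Bayes factor as e.g. `"29.70 (0)"`, with
#' `"- (-)"` for regions never uncovered.
#'
#' @param x a [summarize_resamples()] result.
#' @return data.frame with `region`, `included`, `uncovered`,
#'   `average_bf` columns of formatted strings.
#' @export
format_resample_summary <- function(x) {
  fmt <- function(m, s) {
    if (is.na(m)) return("- (-)")
    sprintf("%.2f (%s)", m, ifelse(s == 0, "0", sprintf("%.2f", s)))
  }
  data.frame(region = x$region,
             included = x$included_count,
             uncovered = x$uncovered_count,
             average_bf = mapply(fmt, x$mean_bf, x$sd_bf))
}

#' Run the size-matched resampling control end to end
#'
#' Draws `n_iter` control cohorts from `x` (keeping all patients not
#' of `target_class` plus `keep` random ones of it), reruns the
#' regionwise Bayesian analysis on each, and tallies how often each
#' region is uncovered.  The load table is computed once and subset
#' per draw; region inclusion is re-derived within each draw.
#'
#' @param x a classified [cohort()] with volumes (typically the
#'   isolated sub-sample).
#' @param parc a [parcellation()].
#' @param score `"hand"` or `"finger"`.
#' @param target_class,keep,n_iter,seed see
#'   [resample_isolated_control()].
#' @param covariates optional covariate names as in [run_vlsm()].
#' @param thresholds an [evidence_thresholds()].
#' @param min_patients region inclusion threshold per draw.
#' @return List: `summary` (a [summarize_resamples()] data.frame),
#'   `plan` (the resampling plan), `tables` (per-draw region tables).
#' @export
resample_control_analysis <- function(x, parc, score = "hand",
                                      target_class = "isolated_hand",
                                      keep = 8L, n_iter = 10000L, seed = 1L,
                                      covariates = character(0),
                                      thresholds = evidence_thresholds(),
                                      min_patients = 5L) {
  plan <- resample_isolated_control(x, target_class, keep, n_iter, seed)
  full_tab <- build_load_table(x, parc, min_patients)
  y_all <- x$records[[paste0(score, "_score")]]
  Z_all <- .study_covariates(x, covariates)
  tables <- lapply(plan$draws, function(idx) {
    tab <- subset_load_table(full_tab, idx)
    run_rlsm_bayesian(tab, y_all[idx],
                      if (is.null(Z_all)) NULL else Z_all[idx, , drop = FALSE],
                      thresholds)
  })
  list(summary = summarize_resamples(tables, thresholds),
       plan = plan, tables = tables)
}
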