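#' Configuration for an end-to-end mapping study
#'
#' Defines the analysis grid: which sub-samples to run, which score
#' each sub-sample is analysed with (the `shared_hand` sample is only
#' meaningful for the hand score and `shared_finger` for the finger
#' score; `full` and `isolated` take both), covariate variants,
#' methods, and the statistical settings.
#'
#' @param samples subset of `c("full", "shared_hand", "shared_finger",
#'   "isolated")`.
#' @param methods subset of `c("vlsm", "rlsm")`.
#' @param covariate_variants list of covariate-name vectors (each a
#'   subset of `c("lesion_size", "weeks_post_stroke")`); each variant
#'   is run for every cell.
#' @param min_overlap,fdr_q,thresholds voxelwise settings, see
#'   [run_vlsm()].
#' @param n_perm,alpha regionwise permutation settings, see
#'   [run_rlsm_frequentist()].
#' @param min_patients regionwise inclusion threshold.
#' @param bf_method `"bic"` or `"jzs"`.
#' @param seed master seed for the permutation streams.
#' @return Object of class `study_config`.
#' @export
study_config <- function(samples = c("full", "shared_hand", "shared_finger",
                                     "isolated"),
                         methods = c("vlsm", "rlsm"),
                         covariate_variants = list(character(0)),
                         min_overlap = 5L, fdr_q = 0.01,
                         thresholds = evidence_thresholds(),
                         n_perm = 50000L, alpha = 0.01,
                         min_patients = 5L,
                         bf_method = "bic", seed = 1L) {
  if (length(samples) == 0L) stop("no samples requested")
  samples <- match.arg(samples, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(samples = samples, methods = methods,
                 covariate_variants = covariate_variants,
                 min_overlap = min_overlap, fdr_q = fdr_q,
                 thresholds = thresholds, n_perm = n_perm, alpha = alpha,
                 min_patients = min_patients, bf_method = bf_method,
                 seed = seed),
            class = "study_config")
}

# the sample -> score mapping of the analysis grid
.sample_scores <- function(sample) {
  switch(sample,
         full = c("hand", "finger"),
         shared_hand = "hand",
         shared_finger = "finger",
         isolated = c("hand", "finger"))
}

#' Run the full sub-sample x score x covariate analysis grid
#'
#' Executes every requested cell -- voxelwise maps and/or regionwise
#' tables, frequentist and Bayesian side by side -- on the cohort's
#' four analysis samples, and collects cross-sample comparisons per
#' score.  With `out_dir` set, all tables, maps and a reproducibility
#' manifest (seed, thresholds, settings) are written to disk.
#'
#' @param x a classified [cohort()] with volumes.
#' @param parc a [parcellation()] (needed for `"rlsm"`).
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @return Object of class `study_bundle`: `cells` (named
#'   `sample.score.covariates` -> list with `vlsm` map and/or `rlsm`
#'   frequentist + Bayesian tables), `comparisons` (per score, a
#'   [compare_samples()] over the regionwise Bayesian tables of the
#'   first covariate variant), `manifest`, and `failures` (per-cell
#'   error messages, if any; their presence marks the bundle
#'   incomplete).
#' @export
run_study <- function(x, parc = NULL, config = study_config(),
                      out_dir = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(config, "study_config"))
  if ("rlsm" %in% config$methods && is.null(parc))
    stop("regionwise analyses need a parcellation")
  subs <- lapply(stats::setNames(config$samples, config$samples),
                 function(s) build_subsample(x, s))
  load_tabs <- if ("rlsm" %in% config$methods)
    lapply(subs, build_load_table, parc = parc,
           min_patients = config$min_patients)
  cells <- list(); failures <- list()
  for (sample in config$samples) {
    for (score in .sample_scores(sample)) {
      for (cv in config$covariate_variants) {
        key <- paste(sample, score,
                     if (length(cv)) paste(cv, collapse = "+") else "none",
                     sep = ".")
        cell <- list()
        res <- tryCatch({
          if ("vlsm" %in% config$methods) {
            cell$vlsm <- run_vlsm(subs[[sample]], score, covariates = cv,
                                  min_overlap = config$min_overlap,
                                  fdr_q = config$fdr_q,
                                  thresholds = config$thresholds,
                                  bf_method = config$bf_method)
          }
          if ("rlsm" %in% config$methods) {
            y <- subs[[sample]]$records[[paste0(score, "_score")]]
            Z <- .study_covariates(subs[[sample]], cv)
            cell$rlsm_freq <- run_rlsm_frequentist(
              load_tabs[[sample]], y, Z, n_perm = config$n_perm,
              alpha = config$alpha, seed = config$seed)
            cell$rlsm_bayes <- run_rlsm_bayesian(
              load_tabs[[sample]], y, Z, thresholds = config$thresholds,
              bf_method = config$bf_method)
          }
          cell
        }, error = function(e) e)
        if (inherits(res, "error")) failures[[key]] <- conditionMessage(res)
        else cells[[key]] <- res
      }
    }
  }
  comparisons <- list()
  if ("rlsm" %in% config$methods) {
    cv0 <- config$covariate_variants[[1]]
    cv0key <- if (length(cv0)) paste(cv0, collapse = "+") else "none"
    for (score in c("hand", "finger")) {
      keys <- paste(config$samples, score, cv0key, sep = ".")
      have <- keys %in% names(cells)
      smp <- config$samples[have]
      if (sum(have) >= 2L) {
        comparisons[[score]] <- compare_samples(
          stats::setNames(lapply(keys[have], function(k) cells[[k]]$rlsm_bayes),
                          smp))
      }
    }
  }
  manifest <- list(n_patients = cohort_size(x),
                   class_counts = as.list(table(x$records$deficit_class)),
                   samples = config$samples, methods = config$methods,
                   covariate_variants = lapply(config$covariate_variants,
                                               function(v) as.list(v)),
                   seed = config$seed, n_perm = config$n_perm,
                   min_overlap = config$min_overlap,
                   min_patients = config$min_patients,
                   fdr_q = config$fdr_q, alpha = config$alpha,
                   bf_cutoff = config$thresholds$bf_cutoff,
                   bf_method = config$bf_method,
                   complete = length(failures) == 0L)
  bundle <- structure(list(cells = cells, comparisons = comparisons,
                           manifest = manifest, failures = failures),
                      class = "study_bundle")
  if (!is.null(out_dir)) write_study_bundle(bundle, out_dir)
  bundle
}

#' Write a study bundle to disk
#'
#' One directory per cell (voxel maps, region CSVs), scatter-ready
#' comparison CSVs, and `manifest.json`.
#'
#' @param bundle a [run_study()] result.
#' @param out_dir destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(bundle$cells)) {
    cell <- bundle$cells[[key]]
    cdir <- file.path(out_dir, key)
    dir.create(cdir, showWarnings = FALSE)
    if (!is.null(cell$vlsm)) write_vlsm(cell$vlsm, cdir)
    if (!is.null(cell$rlsm_freq))
      write_region_table(cell$rlsm_freq, file.path(cdir, "rlsm_frequentist.csv"))
    if (!is.null(cell$rlsm_bayes))
      write_region_table(cell$rlsm_bayes, file.path(cdir, "rlsm_bayesian.csv"))
  }
  for (score in names(bundle$comparisons)) {
    utils::write.csv(bundle$comparisons[[score]]$long,
                     file.path(out_dir, sprintf("scatter_%s.csv", score)),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d cells (%s)%s\n", length(x$cells),
              paste(names(x$cells), collapse = ", "),
              if (length(x$failures))
                paste0("; INCOMPLETE, failures: ",
                       paste(names(x$failures), collapse = ", "))
              else ""))
  invisible(x)
}
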