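#' Per-voxel lesion overlap across a cohort
#'
#' @param x a [cohort()] with volumes.
#' @return 3D integer array: number of patients lesioned at each voxel.
#' @export
voxel_overlap_map <- function(x) {
  stopifnot(inherits(x, "cohort"), !is.null(x$volumes))
  counts <- array(0L, dim = dim(x$volumes[[1]]$mask))
  for (v in x$volumes) counts <- counts + v$mask
  counts
}

#' Voxels with sufficient lesion coverage for testing
#'
#' Only voxels damaged in at least `min_overlap` patients (default 5)
#' are tested; no upper cap on lesion frequency is applied.
#'
#' @inheritParams voxel_overlap_map
#' @param min_overlap minimum patient count per voxel (>= 1).
#' @return Integer vector of linear voxel indices into the grid.
#' @export
voxel_overlap_filter <- function(x, min_overlap = 5L) {
  stopifnot(min_overlap >= 1L)
  which(voxel_overlap_map(x) >= min_overlap)
}

#' Voxelwise lesion-symptom mapping
#'
#' For every voxel damaged in at least `min_overlap` patients, fits the
#' behavioural score on the binary damage indicator (plus optional
#' covariates), yielding the frequentist slope/t/p/z and the Bayes
#' factor for the damage term.  Frequentist significance is controlled
#' by Benjamini-Hochberg FDR across the tested voxels only; Bayesian
#' evidence is flagged at `bf10 > bf_cutoff`.
#'
#' @param x a classified [cohort()] with volumes.
#' @param score `"hand"` or `"finger"`.
#' @param covariates subset of `c("lesion_size", "weeks_post_stroke")`.
#' @param min_overlap minimum patients lesioned per tested voxel.
#' @param fdr_q FDR level for the frequentist map.
#' @param thresholds an [evidence_thresholds()].
#' @param bf_method `"bic"` or `"jzs"` (see
#'   [bayes_factor_univariate()]; `"jzs"` is markedly slower voxelwise).
#' @return Object of class `voxel_stat_map`: `table` is a data.frame
#'   with one row per tested voxel (`voxel` linear index, `i,j,k`,
#'   `overlap`, `estimate`, `t`, `p`, `z`, `bf10`, `log_bf`,
#'   `freq_sig`, `bayes_sig`); `dim`, `voxel_dims_mm`, `affine` and
#'   `config` describe the grid and the run.
#' @export
run_vlsm <- function(x, score = c("hand", "finger"),
                     covariates = character(0),
                     min_overlap = 5L, fdr_q = 0.01,
                     thresholds = evidence_thresholds(),
                     bf_method = c("bic", "jzs")) {
  score <- match.arg(score)
  bf_method <- match.arg(bf_method)
  stopifnot(inherits(x, "cohort"), !is.null(x$volumes))
  y <- x$records[[paste0(score, "_score")]]
  Z <- .study_covariates(x, covariates)
  idx <- voxel_overlap_filter(x, min_overlap)
  gdim <- dim(x$volumes[[1]]$mask)
  cfg <- list(score = score, covariates = covariates,
              min_overlap = min_overlap, fdr_q = fdr_q,
              thresholds = thresholds, bf_method = bf_method)
  if (length(idx) == 0L || stats::var(y) == 0) {
    if (stats::var(y) == 0)
      warning("score is constant; all voxels untestable")
    else
      warning("no voxel reaches the overlap threshold; empty map")
    tab <- data.frame(voxel = integer(0), i = integer(0), j = integer(0),
                      k = integer(0), overlap = integer(0),
                      estimate = numeric(0), t = numeric(0), p = numeric(0),
                      z = numeric(0), bf10 = numeric(0), log_bf = numeric(0),
                      freq_sig = logical(0), bayes_sig = logical(0))
    return(structure(list(table = tab, dim = gdim,
                          voxel_dims_mm = x$volumes[[1]]$voxel_dims_mm,
                          affine = x$volumes[[1]]$affine, config = cfg),
                     class = "voxel_stat_map"))
  }
  X <- vapply(x$volumes, function(v) as.numeric(v$mask[idx]),
              numeric(length(idx)))
  X <- t(X)  # patients x voxels
  res <- .mass_univariate(y, X, Z)
  if (bf_method == "jzs") {
    for (v in which(!res$untestable)) {
      b <- bayes_factor_univariate(y, X[, v], Z, method = "jzs")
      res$bf10[v] <- b$bf10
      res$log_bf[v] <- b$log_bf
    }
  }
  counts <- voxel_overlap_map(x)[idx]
  ok <- !res$untestable
  freq_sig <- rep(FALSE, length(idx))
  freq_sig[ok] <- fdr_bh(res$p[ok], fdr_q)
  bayes_sig <- ok & !is.na(res$bf10) & res$bf10 > thresholds$bf_cutoff
  ijk <- arrayInd(idx, gdim)
  tab <- data.frame(voxel = idx, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                    overlap = counts,
                    estimate = res$estimate, t = res$t, p = res$p, z = res$z,
                    bf10 = res$bf10, log_bf = res$log_bf,
                    freq_sig = freq_sig, bayes_sig = bayes_sig)
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, dim = gdim,
                 voxel_dims_mm = x$volumes[[1]]$voxel_dims_mm,
                 affine = x$volumes[[1]]$affine, config = cfg),
            class = "voxel_stat_map")
}

# resolve covariate names to a numeric matrix from the cohort records
.study_covariates <- function(x, covariates) {
  if (length(covariates) == 0L) return(NULL)
  cols <- c(lesion_size = "lesion_size_mm3",
            weeks_post_stroke = "weeks_post_stroke")
  bad <- setdiff(covariates, names(cols))
  if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
  m <- as.matrix(x$records[, cols[covariates], drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat(sprintf("<voxel_stat_map> %s score, %d tested voxels, %d FDR-significant, %d with BF > %g\n",
              x$config$score, nrow(x$table), sum(x$table$freq_sig),
              sum(x$table$bayes_sig), x$config$thresholds$bf_cutoff))
  invisible(x)
}

#' Summarize flagged voxels of a statistical map
#'
#' Counts and extrema over the voxels carrying a significance /
#' evidence flag, optionally broken down by atlas parcel, including
#' the percentage of each parcel covered by flagged voxels.
#'
#' @param map a `voxel_stat_map` from [run_vlsm()].
#' @param flag `"bayes_sig"` or `"freq_sig"`.
#' @param parc optional [parcellation()] on the same grid.
#' @return List: `n_voxels`, `bf_max` (over all tested voxels, the
#'   conventional reporting style), `bf_max_flagged`, `z_extreme`
#'   (largest |z| among flagged voxels, signed), and, with a
#'   parcellation, `per_region` (data.frame region, n_flagged,
#'   parcel_voxels, percent_covered).  Extrema are `NA` when no voxel
#'   is flagged.
#' @export
summarize_voxels <- function(map, flag = c("bayes_sig", "freq_sig"),
                             parc = NULL) {
  flag <- match.arg(flag)
  tab <- map$table
  sel <- tab[[flag]]
  out <- list(
    flag = flag,
    n_voxels = sum(sel),
    bf_max = if (nrow(tab)) max(tab$bf10, na.rm = TRUE) else NA_real_,
    bf_max_flagged = if (any(sel)) max(tab$bf10[sel], na.rm = TRUE) else NA_real_,
    z_extreme = if (any(sel)) tab$z[sel][which.max(abs(tab$z[sel]))] else NA_real_)
  if (!is.null(parc)) {
    if (!identical(dim(parc$labels), map$dim))
      stop("parcellation grid does not match the map")
    all_labels <- as.integer(names(parc$names))
    sizes <- tabulate(parc$labels, nbins = max(all_labels))[all_labels]
    flagged_labels <- parc$labels[tab$voxel[sel]]
    hits <- tabulate(flagged_labels[flagged_labels > 0L],
                     nbins = max(all_labels))[all_labels]
    out$per_region <- data.frame(
      region = unname(parc$names),
      n_flagged = hits,
      parcel_voxels = sizes,
      percent_covered = ifelse(sizes > 0, 100 * hits / sizes, NA_real_))
  }
  out
}

#' Write voxelwise results to disk
#'
#' Emits NIfTI maps for z, logBF and the two flag masks, the voxel
#' table as CSV, and a JSON summary.
#'
#' @param map a `voxel_stat_map`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_vlsm <- function(map, dir, prefix = "vlsm") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fill <- function(col, default = 0) {
    a <- array(default, dim = map$dim)
    a[map$table$voxel] <- col
    a
  }
  paths <- character(0)
  for (nm in c("z", "log_bf")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    .write_nifti_array(fill(map$table[[nm]]), map$voxel_dims_mm, map$affine, p)
    paths <- c(paths, p)
  }
  for (nm in c("freq_sig", "bayes_sig")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    .write_nifti_array(fill(as.integer(map$table[[nm]])), map$voxel_dims_mm,
                       map$affine, p)
    paths <- c(paths, p)
  }
  csv <- file.path(dir, paste0(prefix, "_voxels.csv"))
  utils::write.csv(map$table, csv, row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  s <- summarize_voxels(map, "bayes_sig")
  jsonlite::write_json(list(score = map$config$score,
                            n_tested = nrow(map$table),
                            n_bayes_sig = s$n_voxels,
                            bf_max = s$bf_max,
                            n_freq_sig = sum(map$table$freq_sig)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, csv, js))
}
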