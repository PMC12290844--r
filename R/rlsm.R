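#' Patients-by-regions lesion-load table
#'
#' Computes each patient's lesion load (fraction of parcel voxels
#' damaged) for every atlas region.  A region enters the analysis only
#' if at least `min_patients` patients have a nonzero load there,
#' mirroring the voxelwise minimum-overlap rule.
#'
#' @param x a [cohort()] with volumes.
#' @param parc a [parcellation()] on the cohort grid.
#' @param min_patients inclusion threshold (default 5).
#' @return Object of class `lesion_load_table`: `loads` (numeric
#'   matrix, patients x regions, rownames patient ids), `included`
#'   (named logical), `damaged_count` (named integer),
#'   `min_patients`.
#' @export
build_load_table <- function(x, parc, min_patients = 5L) {
  stopifnot(inherits(x, "cohort"), !is.null(x$volumes))
  first <- lesion_load(x$volumes[[1]], parc)
  loads <- t(vapply(x$volumes, lesion_load, parc = parc,
                    FUN.VALUE = first))
  rownames(loads) <- x$records$patient_id
  damaged <- colSums(loads > 0)
  included <- damaged >= min_patients
  if (!any(included))
    stop("no region is damaged in at least ", min_patients, " patients")
  structure(list(loads = loads, included = included,
                 damaged_count = damaged, min_patients = min_patients),
            class = "lesion_load_table")
}

#' @export
print.lesion_load_table <- function(x, ...) {
  cat(sprintf("<lesion_load_table> %d patients x %d regions (%d included at >= %d damaged)\n",
              nrow(x$loads), ncol(x$loads), sum(x$included), x$min_patients))
  invisible(x)
}

# subset a load table to a patient index vector, re-deriving inclusion
subset_load_table <- function(tab, idx) {
  loads <- tab$loads[idx, , drop = FALSE]
  damaged <- colSums(loads > 0)
  structure(list(loads = loads, included = damaged >= tab$min_patients,
                 damaged_count = damaged, min_patients = tab$min_patients),
            class = "lesion_load_table")
}

#' Regionwise frequentist GLM with maximum-statistic permutation
#' correction
#'
#' Per included region, the behavioural score is regressed on the
#' continuous lesion load (plus covariates).  Familywise error across
#' regions is controlled with the permutation distribution of the
#' maximum |t|: scores are permuted directly when there are no
#' covariates, and by the Freedman-Lane scheme (permuting
#' reduced-model residuals) otherwise.  One permutation set is drawn
#' from `seed` and shared by all regions, as max-statistic coherence
#' requires.  Reported t follows the regionwise convention (positive t
#' = damage predicts worse performance).
#'
#' @param tab a [build_load_table()] result.
#' @param scores numeric behavioural scores aligned with the table rows.
#' @param covariates optional numeric matrix aligned with the rows.
#' @param n_perm number of permutations (default 50000).
#' @param alpha corrected significance level (default 0.01).
#' @param seed integer seed for the permutation stream.
#' @param scheme `"random"` Monte-Carlo permutations, or
#'   `"exhaustive"` to enumerate all `n!` score orderings (n <= 8).
#' @return data.frame of class `region_stat_table`: `region`, `t`
#'   (damage-worsens-positive), `p_uncorrected`, `p_corrected`,
#'   `estimate`, `included`, `sig` (`p_corrected < alpha`).  Excluded
#'   or untestable regions carry `NA` statistics.
#' @export
run_rlsm_frequentist <- function(tab, scores, covariates = NULL,
                                 n_perm = 50000L, alpha = 0.01,
                                 seed = 1L, scheme = c("random", "exhaustive")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(tab, "lesion_load_table"))
  y <- as.numeric(scores)
  n <- nrow(tab$loads)
  if (length(y) != n) stop("scores do not align with the load table")
  if (stats::var(y) == 0) stop("constant score vector")
  X <- tab$loads[, tab$included, drop = FALSE]
  Z <- .cov_matrix(covariates, n)
  obs <- .mass_univariate(y, X, Z)
  testable <- !obs$untestable

  # permutation null of max |t|: permute reduced-model residuals,
  # re-project, and correlate against the residualized loads
  C <- cbind(1, Z)
  Q <- qr.Q(qr(C))
  res_y <- drop(y - Q %*% crossprod(Q, y))
  fit_y <- y - res_y
  Xr <- X[, testable, drop = FALSE] - Q %*% crossprod(Q, X[, testable, drop = FALSE])
  Xu <- sweep(Xr, 2, sqrt(colSums(Xr^2)), "/")
  df <- n - ncol(C) - 1L

  perm_idx <- if (scheme == "exhaustive") {
    if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
    .all_permutations(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n)))
  }
  n_used <- ncol(perm_idx)
  max_t <- numeric(n_used)
  # blocked matrix products keep memory bounded at large n_perm
  block <- 2048L
  for (start in seq(1L, n_used, by = block)) {
    cols <- start:min(start + block - 1L, n_used)
    Yp <- fit_y + matrix(res_y[perm_idx[, cols]], nrow = n)
    Ypr <- Yp - Q %*% crossprod(Q, Yp)
    norms <- sqrt(colSums(Ypr^2))
    r <- crossprod(Xu, sweep(Ypr, 2, norms, "/"))
    tmat <- abs(r) * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.xmin))
    max_t[cols] <- apply(tmat, 2, max)
  }
  t_obs <- abs(obs$t[testable])
  p_corr_testable <- vapply(t_obs, function(t0)
    (1 + sum(max_t >= t0 - 1e-12)) / (1 + n_used), numeric(1))

  out <- data.frame(region = colnames(tab$loads),
                    t = NA_real_, p_uncorrected = NA_real_,
                    p_corrected = NA_real_, estimate = NA_real_,
                    included = tab$included, sig = FALSE,
                    stringsAsFactors = FALSE)
  rows <- which(tab$included)[testable]
  out$t[which(tab$included)] <- -obs$t        # positive = damage worsens
  out$estimate[which(tab$included)] <- obs$estimate
  out$p_uncorrected[which(tab$included)] <- obs$p
  out$p_corrected[rows] <- p_corr_testable
  out$sig <- !is.na(out$p_corrected) & out$p_corrected < alpha
  attr(out, "n_perm") <- n_used
  attr(out, "seed") <- if (scheme == "random") seed else NA_integer_
  attr(out, "scheme") <- scheme
  class(out) <- c("region_stat_table", class(out))
  rownames(out) <- NULL
  out
}

# all permutations of 1..n as an n x n! index matrix
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow = n, ncol = n * ncol(sub))
  col <- 1L
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      rest <- sub[, j]
      rest[rest >= pos] <- rest[rest >= pos] + 1L
      out[, col] <- append(rest, pos, after = pos - 1L)
      col <- col + 1L
    }
  }
  out
}

#' Regionwise Bayesian GLM on lesion loads
#'
#' Per included region, the Bayes factor for the lesion-load term in
#' the score model, with the evidence flag at `bf10 > bf_cutoff`.
#' The reported t (damage-worsens-positive) is carried alongside so
#' Bayesian evidence can be checked for reverse associations.
#'
#' @inheritParams run_rlsm_frequentist
#' @param thresholds an [evidence_thresholds()].
#' @param bf_method `"bic"` or `"jzs"`.
#' @return data.frame of class `region_stat_table`: `region`, `bf10`,
#'   `log_bf`, `t`, `estimate`, `included`, `evidence` (bf10 above the
#'   cut-off).  Constant-load regions are included but untestable
#'   (`NA` statistics).
#' @export
run_rlsm_bayesian <- function(tab, scores, covariates = NULL,
                              thresholds = evidence_thresholds(),
                              bf_method = c("bic", "jzs")) {
  bf_method <- match.arg(bf_method)
  stopifnot(inherits(tab, "lesion_load_table"))
  y <- as.numeric(scores)
  n <- nrow(tab$loads)
  if (length(y) != n) stop("scores do not align with the load table")
  if (stats::var(y) == 0) stop("constant score vector")
  X <- tab$loads[, tab$included, drop = FALSE]
  Z <- .cov_matrix(covariates, n)
  res <- .mass_univariate(y, X, Z)
  if (bf_method == "jzs") {
    for (v in which(!res$untestable)) {
      b <- bayes_factor_univariate(y, X[, v], Z, method = "jzs")
      res$bf10[v] <- b$bf10
      res$log_bf[v] <- b$log_bf
    }
  }
  out <- data.frame(region = colnames(tab$loads),
                    bf10 = NA_real_, log_bf = NA_real_, t = NA_real_,
                    estimate = NA_real_, included = tab$included,
                    evidence = FALSE, stringsAsFactors = FALSE)
  inc <- which(tab$included)
  out$bf10[inc] <- res$bf10
  out$log_bf[inc] <- res$log_bf
  out$t[inc] <- -res$t
  out$estimate[inc] <- res$estimate
  out$evidence <- !is.na(out$bf10) & out$bf10 > thresholds$bf_cutoff
  attr(out, "bf_method") <- bf_method
  class(out) <- c("region_stat_table", class(out))
  rownames(out) <- NULL
  out
}

#' Write a region table and its run metadata
#'
#' @param x a `region_stat_table`.
#' @param path CSV destination; a `.json` sidecar records permutation
#'   count, seed and method when present.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(n_perm = attr(x, "n_perm"), seed = attr(x, "seed"),
               scheme = attr(x, "scheme"), bf_method = attr(x, "bf_method"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta))
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
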