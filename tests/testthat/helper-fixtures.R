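# fixtures and independent oracles shared across test files

# volume from linear indices on a small grid
vol_from_idx <- function(idx, dim = c(6L, 6L, 6L), dims_mm = c(1, 1, 1),
                         id = NULL) {
  m <- array(0L, dim)
  m[idx] <- 1L
  lesion_volume(m, voxel_dims_mm = dims_mm, patient_id = id)
}

# cohort of n patients with random masks and given scores
random_mask_cohort <- function(n, dim = c(6L, 6L, 6L), p_lesion = 0.3,
                               hand = NULL, finger = NULL, seed = 1) {
  set.seed(seed)
  vols <- lapply(seq_len(n), function(i) {
    m <- array(as.integer(runif(prod(dim)) < p_lesion), dim)
    lesion_volume(m, patient_id = sprintf("P%02d", i))
  })
  if (is.null(hand)) hand <- sample(10:20, n, replace = TRUE)
  if (is.null(finger)) finger <- sample(10:20, n, replace = TRUE)
  cohort(data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                    hand_score = hand, finger_score = finger,
                    weeks_post_stroke = runif(n, 2, 30)), vols)
}

# scores-only cohort (no volumes) with the canonical 40/23/25/8 split
table1_cohort <- function() {
  score_of <- function(class) switch(class,
    none = c(19L, 19L), shared = c(12L, 12L),
    isolated_hand = c(15L, 19L), isolated_finger = c(19L, 13L))
  classes <- rep(c("none", "shared", "isolated_hand", "isolated_finger"),
                 times = c(40, 23, 25, 8))
  sc <- t(vapply(classes, score_of, integer(2)))
  cohort(data.frame(patient_id = sprintf("P%03d", seq_along(classes)),
                    hand_score = sc[, 1], finger_score = sc[, 2],
                    weeks_post_stroke = 10))
}

# a lesion_load_table straight from a numeric matrix
load_table_from_matrix <- function(X, min_patients = 1L) {
  if (is.null(colnames(X))) colnames(X) <- paste0("r", seq_len(ncol(X)))
  damaged <- colSums(X > 0)
  structure(list(loads = X, included = damaged >= min_patients,
                 damaged_count = damaged, min_patients = min_patients),
            class = "lesion_load_table")
}

# --- independent oracles -------------------------------------------------

# pooled two-sample t for a binary predictor
two_sample_t_oracle <- function(y, x) {
  a <- y[x == 1]; b <- y[x == 0]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Benjamini-Hochberg by its step-up definition
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) / m * q)
  rej <- logical(m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}

# t-statistic of the x-slope from explicit normal equations
ols_t_oracle <- function(y, x, Z = NULL) {
  X <- cbind(1, x, Z)
  b <- solve(t(X) %*% X) %*% t(X) %*% y
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  b[2] / se
}

# all permutations of seq_len(n), list form
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p + (p >= pos), pos, after = pos - 1L)
    }
  }
  out
}

# dense-grid JZS integral (trapezoid on g in log space), independent of
# the package quadrature
jzs_grid_oracle <- function(y, x, rscale = sqrt(2) / 2) {
  n <- length(y)
  r2 <- cor(y, x)^2
  a <- n * rscale^2 / 2
  g <- exp(seq(log(1e-8), log(1e10), length.out = 200000))
  f <- (1 + g)^((n - 2) / 2) * (1 + g * (1 - r2))^(-(n - 1) / 2) *
    sqrt(a / pi) * g^(-1.5) * exp(-a / g)
  sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
}

# truth spec used by the pipeline-level bias tests: shared-area
# mechanism with both isolated areas
bias_truth <- function(scenario = "shared_area") {
  ground_truth_spec(scenario = scenario)
}

# impaired-baseline cohort in which a genuinely protective area is
# identifiable: chronic severe cohort, lesions seeded partly inside the
# protective territory, partly anywhere
protective_fixture <- function(seed = 11, n_enriched = 30, n_other = 70) {
  truth <- ground_truth_spec(scenario = "co_damage",
    areas = default_effect_areas("co_damage", protective = TRUE),
    baseline_mean = 14, baseline_sd = 1)
  set.seed(seed)
  d <- truth$grid_dim
  pmaskarr <- array(FALSE, d); pmaskarr[17:23, 19:24, 8:15] <- TRUE
  seeds <- c(sample(which(pmaskarr), n_enriched, replace = TRUE),
             sample.int(prod(d), n_other, replace = TRUE))
  vols <- lapply(seq_along(seeds), function(i)
    grow_lesion(d, seeds[i], max(50, round(rnorm(1, 450, 150))),
                truth$voxel_dims_mm, patient_id = sprintf("S%03d", i)))
  sc <- t(sapply(vols, scores_from_lesion, truth = truth))
  co <- cohort(data.frame(patient_id = sprintf("S%03d", seq_along(seeds)),
                          hand_score = sc[, 1], finger_score = sc[, 2],
                          weeks_post_stroke = 10), vols)
  list(truth = truth, cohort = co)
}
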