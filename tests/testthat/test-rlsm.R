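test_that("the load table equals per-patient lesion_load and applies the inclusion rule", {
  co <- random_mask_cohort(8, seed = 31)
  labs <- array(0L, c(6, 6, 6))
  labs[1:40] <- 1L; labs[41:80] <- 2L; labs[100:110] <- 3L
  parc <- parcellation(labs, c(`1` = "A", `2` = "B", `3` = "C"))
  tab <- build_load_table(co, parc, min_patients = 1)
  for (i in c(1, 4, 8)) {
    expect_equal(tab$loads[i, ], lesion_load(co$volumes[[i]], parc))
  }
  # region damaged in 4 patients is excluded at min_patients = 5
  co2 <- random_mask_cohort(9, p_lesion = 0, seed = 32)
  for (i in 1:5) co2$volumes[[i]]$mask[1:40] <- 1L
  for (i in 1:4) co2$volumes[[i]]$mask[41:80] <- 1L
  tab2 <- build_load_table(co2, parc, min_patients = 5)
  expect_true(tab2$included[["A"]])
  expect_false(tab2$included[["B"]])
  # lesion covering exactly one parcel in every patient
  co3 <- random_mask_cohort(6, p_lesion = 0, seed = 33)
  for (i in 1:6) co3$volumes[[i]]$mask[1:40] <- 1L
  tab3 <- build_load_table(co3, parc, min_patients = 5)
  expect_true(all(tab3$loads[, "A"] == 1))
  expect_true(all(tab3$loads[, c("B", "C")] == 0))
})

test_that("max-statistic corrected p equals exhaustive enumeration at n = 5", {
  set.seed(41)
  X <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("A", "B")))
  y <- c(3, 9, 5, 7, 1)
  tab <- load_table_from_matrix(X)
  got <- run_rlsm_frequentist(tab, y, scheme = "exhaustive")
  # oracle: per-permutation max |t| over both regions via lm
  perms <- perms_oracle(5L)
  expect_length(perms, 120)
  maxt <- vapply(perms, function(pm) {
    yp <- y[pm]
    max(abs(vapply(1:2, function(j)
      summary(lm(yp ~ X[, j]))$coefficients[2, "t value"], numeric(1))))
  }, numeric(1))
  for (j in 1:2) {
    t_obs <- abs(summary(lm(y ~ X[, j]))$coefficients[2, "t value"])
    p_oracle <- (1 + sum(maxt >= t_obs - 1e-12)) / (1 + 120)
    expect_equal(got$p_corrected[j], p_oracle, tolerance = 1e-12)
  }
  # reported t carries the damage-worsens-positive convention
  expect_equal(got$t, -vapply(1:2, function(j)
    summary(lm(y ~ X[, j]))$coefficients[2, "t value"], numeric(1)),
    tolerance = 1e-10)
})

test_that("with a single region max-stat correction reduces to the plain permutation test", {
  set.seed(43)
  X <- matrix(runif(6), 6, 1, dimnames = list(NULL, "only"))
  y <- rnorm(6)
  tab <- load_table_from_matrix(X)
  got <- run_rlsm_frequentist(tab, y, scheme = "exhaustive")
  perms <- perms_oracle(6L)
  t_of <- function(yy) abs(summary(lm(yy ~ X[, 1]))$coefficients[2, "t value"])
  null_t <- vapply(perms, function(pm) t_of(y[pm]), numeric(1))
  p_plain <- (1 + sum(null_t >= t_of(y) - 1e-12)) / (1 + length(perms))
  expect_equal(got$p_corrected[1], p_plain, tolerance = 1e-12)
})

test_that("permutation p-values respect their floor and monotonicity in |t|", {
  set.seed(45)
  n <- 60
  X <- matrix(pmax(0, rnorm(n * 4, 0.3, 0.2)), n, 4)
  y <- 19 - 15 * X[, 1] + rnorm(n, 0, 0.3)   # overwhelming effect in region 1
  tab <- load_table_from_matrix(X)
  got <- run_rlsm_frequentist(tab, y, n_perm = 999, seed = 5)
  expect_equal(got$p_corrected[1], 1 / 1000)
  expect_true(all(got$p_corrected >= 1 / 1000 & got$p_corrected <= 1))
  expect_true(all(got$p_corrected >= got$p_uncorrected - 1e-12))
  ord <- order(-abs(got$t))
  expect_true(all(diff(got$p_corrected[ord]) >= -1e-12))
  expect_error(run_rlsm_frequentist(tab, rep(3, n)), "constant")
})

test_that("Freedman-Lane permutation with covariates controls the familywise error", {
  set.seed(47)
  n <- 40; fwe <- 0
  reps <- 120
  for (i in seq_len(reps)) {
    X <- matrix(pmax(0, rnorm(n * 5, 0.3, 0.25)), n, 5)
    Z <- matrix(rnorm(n), ncol = 1)
    y <- 2 * Z[, 1] + rnorm(n)     # covariate effect, no lesion effect
    tab <- load_table_from_matrix(X)
    got <- run_rlsm_frequentist(tab, y, covariates = Z, n_perm = 499,
                                alpha = 0.05, seed = i)
    fwe <- fwe + any(got$sig, na.rm = TRUE)
  }
  # familywise error near or below alpha = .05 (binomial tolerance)
  expect_lt(fwe / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("regionwise Bayesian mapping flags a planted region and stays quiet under the null", {
  set.seed(51)
  n <- 70
  X <- matrix(pmax(0, rnorm(n * 6, 0.35, 0.25)), n, 6,
              dimnames = list(NULL, paste0("r", 1:6)))
  y <- as.integer(round(pmin(20, pmax(0, 19 - 9 * X[, 3] + rnorm(n, 0, 0.8)))))
  tab <- load_table_from_matrix(X)
  bt <- run_rlsm_bayesian(tab, y)
  expect_true(bt$evidence[3])
  expect_false(any(bt$evidence[-3]))
  # shuffled scores: evidence should essentially never appear
  hits <- replicate(100, {
    any(run_rlsm_bayesian(tab, sample(y))$evidence)
  })
  expect_gte(mean(!hits), 0.95)
})

test_that("constant-load regions are untestable, not zero-evidence", {
  X <- cbind(r1 = runif(20), r2 = rep(0.5, 20))
  tab <- load_table_from_matrix(X)
  bt <- run_rlsm_bayesian(tab, rnorm(20))
  expect_true(is.na(bt$bf10[2]))
  expect_false(bt$evidence[2])
  ft <- run_rlsm_frequentist(tab, rnorm(20), n_perm = 99, seed = 1)
  expect_true(is.na(ft$p_corrected[2]))
})

test_that("region tables serialize with their permutation metadata", {
  X <- matrix(runif(40), 20, 2)
  tab <- load_table_from_matrix(X)
  ft <- run_rlsm_frequentist(tab, rnorm(20), n_perm = 199, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_region_table(ft, f)
  back <- read.csv(f)
  expect_equal(back$p_corrected, ft$p_corrected)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(meta$n_perm, 199)
  expect_equal(meta$seed, 9)
})
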