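test_that("grown lesions are connected, hit their target size, and are reproducible", {
  d <- c(20L, 20L, 20L)
  v1 <- grow_lesion(d, c(10, 10, 10), 1, rng_seed = 1)
  expect_equal(which(v1$mask == 1L), 10 + 9 * 20 + 9 * 400)
  v2 <- grow_lesion(d, c(10, 10, 10), 50, rng_seed = 5)
  v3 <- grow_lesion(d, c(10, 10, 10), 50, rng_seed = 5)
  expect_identical(v2$mask, v3$mask)
  expect_equal(sum(v2$mask), 50)
  # 6-connectivity: breadth-first flood fill from the seed reaches all voxels
  idx <- which(v2$mask == 1L)
  seen <- c(idx[match(10 + 9 * 20 + 9 * 400, idx)])
  frontier <- seen
  while (length(frontier)) {
    nbrs <- unique(unlist(lapply(frontier, lsmbias:::.neighbors6, d = d)))
    nbrs <- setdiff(intersect(nbrs, idx), seen)
    seen <- c(seen, nbrs)
    frontier <- nbrs
  }
  expect_setequal(seen, idx)
  expect_error(grow_lesion(d, c(10, 10, 10), prod(d) + 1), "exceeds")
  expect_error(grow_lesion(d, c(25, 10, 10), 5), "outside")
})

test_that("scores follow baseline plus area effects, clipped to the integer 0-20 scale", {
  truth <- ground_truth_spec(baseline_sd = 0, score_noise_sd = 0)
  d <- truth$grid_dim
  # empty lesion: baseline scores
  empty <- lesion_volume(array(0L, d), truth$voxel_dims_mm)
  expect_equal(scores_from_lesion(empty, truth), c(hand = 19L, finger = 19L))
  # full damage to the hand area only: hand drops by the full effect
  hand_area <- truth$areas[[1]]
  full_hand <- lesion_volume(
    {m <- array(0L, d); m[lsmbias:::.area_voxel_index(hand_area, d)] <- 1L; m},
    truth$voxel_dims_mm)
  expect_equal(scores_from_lesion(full_hand, truth),
               c(hand = 19L + as.integer(hand_area$effect_hand), finger = 19L))
  # protective areas add rather than subtract
  truth_p <- ground_truth_spec(baseline_sd = 0, score_noise_sd = 0,
    baseline_mean = 12,
    areas = default_effect_areas("shared_area", protective = TRUE))
  prot <- truth_p$areas[[length(truth_p$areas)]]
  expect_true(prot$protective)
  full_prot <- lesion_volume(
    {m <- array(0L, d); m[lsmbias:::.area_voxel_index(prot, d)] <- 1L; m},
    truth_p$voxel_dims_mm)
  expect_equal(scores_from_lesion(full_prot, truth_p)[["hand"]],
               12L - as.integer(prot$effect_hand))
  # scores are always integers within range
  set.seed(70)
  for (i in 1:20) {
    v <- grow_lesion(d, sample.int(prod(d), 1), 300, truth$voxel_dims_mm)
    sc <- scores_from_lesion(v, ground_truth_spec())
    expect_true(all(sc == as.integer(sc) & sc >= 0 & sc <= 20))
  }
})

test_that("area effects are recovered by regression from simulated patients", {
  truth <- ground_truth_spec(scenario = "shared_area")
  d <- truth$grid_dim
  set.seed(81)
  n <- 500
  loads <- matrix(0, n, length(truth$areas))
  hand <- integer(n)
  for (i in seq_len(n)) {
    v <- grow_lesion(d, sample.int(prod(d), 1),
                     max(50, round(rnorm(1, 500, 200))), truth$voxel_dims_mm)
    loads[i, ] <- area_loads(v, truth)
    hand[i] <- scores_from_lesion(v, truth)[["hand"]]
  }
  fit <- lm(hand ~ loads)
  co <- summary(fit)$coefficients
  true_hand_effects <- vapply(truth$areas, function(a)
    (if (a$protective) -1 else 1) * a$effect_hand, numeric(1))
  for (j in seq_along(truth$areas)) {
    if (true_hand_effects[j] == 0) next
    expect_lt(abs(co[j + 1, "Estimate"] - true_hand_effects[j]),
              2 * co[j + 1, "Std. Error"] + 0.5)  # rounding/clipping slack
  }
})

test_that("generated cohorts hit the 40/23/25/8 composition exactly and deterministically", {
  truth <- ground_truth_spec(scenario = "shared_area")
  sc <- generate_cohort(truth, master_seed = 42)
  tab <- table(sc$cohort$records$deficit_class)
  expect_equal(unname(tab[["none"]]), 40)
  expect_equal(unname(tab[["shared"]]), 23)
  expect_equal(unname(tab[["isolated_hand"]]), 25)
  expect_equal(unname(tab[["isolated_finger"]]), 8)
  # determinism: same master seed, bit-identical cohort
  sc2 <- generate_cohort(truth, master_seed = 42)
  expect_identical(sc$cohort$records, sc2$cohort$records)
  expect_identical(lapply(sc$cohort$volumes, `[[`, "mask"),
                   lapply(sc2$cohort$volumes, `[[`, "mask"))
  # lesion sizes recomputed from masks
  expect_equal(sc$cohort$records$lesion_size_mm3,
               unname(vapply(sc$cohort$volumes, lesion_size_mm3, numeric(1))))
  expect_true(all(sc$cohort$records$weeks_post_stroke > 0))
})

test_that("small targets and degenerate compositions are honoured", {
  truth <- ground_truth_spec(
    group_targets = c(none = 5L, isolated_hand = 0L, isolated_finger = 0L,
                      shared = 0L))
  sc <- generate_cohort(truth, master_seed = 3)
  expect_equal(cohort_size(sc$cohort), 5)
  expect_true(all(sc$cohort$records$hand_score >= 18))
  expect_true(all(sc$cohort$records$finger_score >= 17))
})

test_that("shared-deficit lesions respect the generating scenario", {
  tr_cd <- ground_truth_spec(scenario = "co_damage")
  sc_cd <- generate_cohort(tr_cd, master_seed = 9)
  shared_rows <- which(sc_cd$cohort$records$deficit_class == "shared")
  loads <- sc_cd$area_loads[shared_rows, , drop = FALSE]
  expect_true(all(loads[, "hand_area"] > 0))
  expect_true(all(loads[, "finger_area"] > 0))
  tr_sa <- ground_truth_spec(scenario = "shared_area")
  sc_sa <- generate_cohort(tr_sa, master_seed = 9)
  shared_rows2 <- which(sc_sa$cohort$records$deficit_class == "shared")
  expect_true(all(sc_sa$area_loads[shared_rows2, "shared_area"] > 0))
})

test_that("truth-aligned parcellations cover the effect areas and tile the rest", {
  truth <- ground_truth_spec(scenario = "shared_area")
  parc <- parcellation_from_truth(truth)
  d <- truth$grid_dim
  for (a in truth$areas) {
    lab <- which(unname(parc$names) == a$name)
    expect_length(lab, 1)
    expect_setequal(which(parc$labels == lab),
                    lsmbias:::.area_voxel_index(a, d))
  }
  expect_gt(length(parc$names), length(truth$areas))
})

test_that("a cohort bundle roundtrips through NIfTI + CSV on disk", {
  truth <- ground_truth_spec(
    group_targets = c(none = 3L, isolated_hand = 2L, isolated_finger = 0L,
                      shared = 0L))
  sc <- generate_cohort(truth, master_seed = 5)
  dir <- file.path(tempdir(), "bundle")
  write_cohort_bundle(sc, dir)
  back <- read_cohort_csv(file.path(dir, "behaviour.csv"), read_masks = TRUE)
  expect_equal(cohort_size(back), 5)
  expect_identical(back$volumes[[1]]$mask, sc$cohort$volumes[[1]]$mask)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$scenario, truth$scenario)
})
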