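#' Ground-truth effect area for the simulator
#'
#' An axis-aligned box (or explicit voxel set) whose lesion load shifts
#' the behavioural scores: `effect_hand` / `effect_finger` are points
#' lost per unit load (<= 0); a `protective` area contributes with the
#' opposite sign, so its damage *improves* the score.
#'
#' @param name area name.
#' @param box list with `lo` and `hi`, length-3 inclusive voxel index
#'   bounds; or `NULL` if `voxels` is given.
#' @param voxels explicit linear voxel indices (alternative to `box`).
#' @param effect_hand,effect_finger points per unit load, `<= 0`.
#' @param protective flip the effect sign?
#' @return Object of class `effect_area`.
#' @export
effect_area <- function(name, box = NULL, voxels = NULL,
                        effect_hand = 0, effect_finger = 0,
                        protective = FALSE) {
  if (is.null(box) && is.null(voxels)) stop("give `box` or `voxels`")
  if (effect_hand > 0 || effect_finger > 0)
    stop("effects are points lost per unit load and must be <= 0; ",
         "use `protective = TRUE` for beneficial areas")
  structure(list(name = name, box = box, voxels = voxels,
                 effect_hand = effect_hand, effect_finger = effect_finger,
                 protective = protective),
            class = "effect_area")
}

# linear voxel indices of an area on a given grid
.area_voxel_index <- function(area, grid_dim) {
  if (!is.null(area$voxels)) {
    v <- as.integer(area$voxels)
    if (any(v < 1L | v > prod(grid_dim))) stop("area voxels outside grid")
    return(v)
  }
  lo <- area$box$lo; hi <- area$box$hi
  if (any(lo < 1L) || any(hi > grid_dim) || any(lo > hi))
    stop("area box outside grid: ", area$name)
  i <- lo[1]:hi[1]; j <- lo[2]:hi[2]; k <- lo[3]:hi[3]
  nx <- grid_dim[1]; ny <- grid_dim[2]
  as.integer(outer(outer(i, (j - 1L) * nx, "+"),
                   (k - 1L) * nx * ny, "+"))
}

#' Default anterior/posterior effect areas
#'
#' A posterior "hand" area and an anterior "finger" area on the
#' default 24 x 28 x 24 grid (the second axis running
#' posterior-to-anterior), each costing 8 points at full damage.
#' Under the `shared_area` scenario a third area between them carries
#' both effects; under `co_damage` no shared area exists and shared
#' deficits arise from lesions covering both isolated areas.
#' Optionally adds a protective area stacked above the hand area whose
#' damage *improves* the hand score.
#'
#' @param scenario `"shared_area"` or `"co_damage"`.
#' @param protective include the protective area?
#' @return List of [effect_area()]s.
#' @export
default_effect_areas <- function(scenario = c("shared_area", "co_damage"),
                                 protective = FALSE) {
  scenario <- match.arg(scenario)
  areas <- list(
    effect_area("hand_area",
                box = list(lo = c(7, 4, 8), hi = c(14, 9, 15)),
                effect_hand = -10),
    effect_area("finger_area",
                box = list(lo = c(7, 19, 8), hi = c(14, 24, 15)),
                effect_finger = -10))
  if (scenario == "shared_area")
    areas <- c(areas, list(
      effect_area("shared_area",
                  box = list(lo = c(7, 12, 8), hi = c(14, 17, 15)),
                  effect_hand = -10, effect_finger = -10)))
  if (protective)
    areas <- c(areas, list(
      effect_area("protective_area",
                  box = list(lo = c(17, 19, 8), hi = c(23, 24, 15)),
                  effect_hand = -8, protective = TRUE)))
  areas
}

#' Ground-truth specification for a synthetic stroke cohort
#'
#' Fixes the voxel grid, the causal effect areas, the behavioural
#' noise model, the group composition (default 40 no deficit / 23
#' shared / 25 isolated hand / 8 isolated finger), per-group lesion
#' sizes and weeks-post-stroke distributions, and the mechanism by
#' which shared deficits arise: a designated `shared_area` carrying
#' both effects, or `co_damage` of both isolated areas by one
#' patient's lesion.
#'
#' @param grid_dim length-3 integer grid shape.
#' @param voxel_dims_mm physical voxel size in mm.
#' @param areas list of [effect_area()]s.
#' @param baseline_mean,baseline_sd latent per-patient ability (points),
#'   shared between the hand and finger tests.
#' @param score_noise_sd additive test noise (points) before rounding
#'   and clipping to `[0, 20]`.
#' @param group_targets named integer vector over [deficit_classes()].
#' @param lesion_voxels named list of `c(mean, sd)` lesion sizes in
#'   voxels per group.
#' @param weeks_post_stroke named list of `c(mean, sd)` per group
#'   (gamma-distributed; the shared group is tested earliest).
#' @param scenario `"shared_area"` or `"co_damage"`.
#' @return Object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(grid_dim = c(24L, 28L, 24L),
                              voxel_dims_mm = c(2, 2, 2),
                              scenario = c("shared_area", "co_damage"),
                              areas = default_effect_areas(scenario),
                              baseline_mean = 19, baseline_sd = 0.8,
                              score_noise_sd = 0.5,
                              group_targets = c(none = 40L, isolated_hand = 25L,
                                                isolated_finger = 8L,
                                                shared = 23L),
                              lesion_voxels = list(
                                none = c(260, 80), isolated_hand = c(420, 160),
                                isolated_finger = c(420, 160),
                                shared = if (match.arg(scenario) == "co_damage")
                                  c(800, 200) else c(500, 150)),
                              weeks_post_stroke = list(
                                none = c(12.8, 19), isolated_hand = c(18.1, 18.8),
                                isolated_finger = c(19.3, 17.2),
                                shared = c(7, 4.1))) {
  scenario <- match.arg(scenario)
  stopifnot(all(group_targets >= 0), score_noise_sd >= 0, baseline_sd >= 0)
  if (!all(names(group_targets) %in% deficit_classes()))
    stop("group_targets must be named by deficit class")
  for (a in areas) {
    if (length(.area_voxel_index(a, grid_dim)) == 0L)
      stop("empty effect area: ", a$name)
  }
  structure(list(grid_dim = as.integer(grid_dim),
                 voxel_dims_mm = as.numeric(voxel_dims_mm),
                 areas = areas, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, score_noise_sd = score_noise_sd,
                 group_targets = group_targets,
                 lesion_voxels = lesion_voxels,
                 weeks_post_stroke = weeks_post_stroke,
                 scenario = scenario),
            class = "ground_truth_spec")
}

# 6-connected neighbours of linear index v on grid d, as linear indices
.neighbors6 <- function(v, d) {
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  v0 <- v - 1L
  i <- v0 %% nx
  j <- (v0 %/% nx) %% ny
  k <- v0 %/% (nx * ny)
  out <- integer(0)
  if (i > 0L) out <- c(out, v - 1L)
  if (i < nx - 1L) out <- c(out, v + 1L)
  if (j > 0L) out <- c(out, v - nx)
  if (j < ny - 1L) out <- c(out, v + nx)
  if (k > 0L) out <- c(out, v - nx * ny)
  if (k < nz - 1L) out <- c(out, v + nx * ny)
  out
}

#' Grow a connected synthetic lesion
#'
#' Stochastic boundary accretion: starting from a seed voxel, voxels
#' are added one at a time, drawn uniformly from the 6-connected
#' boundary of the current mask, until the target size is reached.
#' Produces compact but irregular connected masks.
#'
#' @param grid_dim length-3 grid shape.
#' @param seed_voxel linear voxel index (or length-3 i,j,k vector).
#' @param target_voxels lesion size in voxels (>= 1).
#' @param voxel_dims_mm voxel size for the resulting volume.
#' @param rng_seed optional integer; when given, growth is reproducible
#'   and the caller's RNG stream is left untouched.
#' @param patient_id optional id for the volume.
#' @return A [lesion_volume()].
#' @export
grow_lesion <- function(grid_dim, seed_voxel, target_voxels,
                        voxel_dims_mm = c(1, 1, 1), rng_seed = NULL,
                        patient_id = NULL) {
  grid_dim <- as.integer(grid_dim)
  if (length(seed_voxel) == 3L) {
    if (any(seed_voxel < 1L) || any(seed_voxel > grid_dim))
      stop("seed voxel outside grid")
    seed_voxel <- seed_voxel[1] + (seed_voxel[2] - 1L) * grid_dim[1] +
      (seed_voxel[3] - 1L) * grid_dim[1] * grid_dim[2]
  }
  seed_voxel <- as.integer(seed_voxel)
  if (seed_voxel < 1L || seed_voxel > prod(grid_dim))
    stop("seed voxel outside grid")
  if (target_voxels < 1L) stop("target_voxels must be >= 1")
  if (target_voxels > prod(grid_dim))
    stop("target_voxels exceeds the grid size")
  run <- function() .grow_lesion_impl(grid_dim, seed_voxel, target_voxels)
  mask_idx <- if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
  mask <- array(0L, grid_dim)
  mask[mask_idx] <- 1L
  lesion_volume(mask, voxel_dims_mm = voxel_dims_mm, patient_id = patient_id)
}

.grow_lesion_impl <- function(d, seed, target) {
  n <- prod(d)
  in_mask <- logical(n)
  in_cand <- logical(n)
  in_mask[seed] <- TRUE
  cand <- .neighbors6(seed, d)
  in_cand[cand] <- TRUE
  size <- 1L
  while (size < target) {
    pick_at <- sample.int(length(cand), 1L)
    v <- cand[pick_at]
    cand[pick_at] <- cand[length(cand)]
    cand <- cand[-length(cand)]
    in_cand[v] <- FALSE
    in_mask[v] <- TRUE
    size <- size + 1L
    for (nb in .neighbors6(v, d)) {
      if (!in_mask[nb] && !in_cand[nb]) {
        cand <- c(cand, nb)
        in_cand[nb] <- TRUE
      }
    }
  }
  which(in_mask)
}

#' Per-area lesion loads of a volume
#'
#' @param vol a [lesion_volume()].
#' @param truth a [ground_truth_spec()] on the same grid.
#' @return Named numeric vector, fraction of each effect area lesioned.
#' @export
area_loads <- function(vol, truth) {
  if (!identical(dim(vol$mask), as.integer(truth$grid_dim)))
    stop("volume grid does not match the ground truth")
  vapply(truth$areas, function(a) {
    idx <- .area_voxel_index(a, truth$grid_dim)
    mean(vol$mask[idx])
  }, numeric(1)) |> stats::setNames(vapply(truth$areas, `[[`, "", "name"))
}

#' Behavioural scores implied by a lesion
#'
#' Each test score is the latent patient baseline plus the summed area
#' effects (points-per-unit-load times realized load, sign flipped for
#' protective areas) plus Gaussian test noise, rounded and clipped to
#' the 0-20 scale.  Integer scores, as produced by a 10-item test
#' scored 2/1/0 per item.
#'
#' @param vol a [lesion_volume()].
#' @param truth a [ground_truth_spec()].
#' @param rng_seed optional seed for the noise draws.
#' @return Named integer vector `c(hand = , finger = )`.
#' @export
scores_from_lesion <- function(vol, truth, rng_seed = NULL) {
  loads <- area_loads(vol, truth)
  run <- function() {
    base <- stats::rnorm(1, truth$baseline_mean, truth$baseline_sd)
    eff_h <- eff_f <- 0
    for (i in seq_along(truth$areas)) {
      a <- truth$areas[[i]]
      s <- if (a$protective) -1 else 1
      eff_h <- eff_h + s * a$effect_hand * loads[i]
      eff_f <- eff_f + s * a$effect_finger * loads[i]
    }
    noise <- stats::rnorm(2, 0, truth$score_noise_sd)
    c(hand = .clip_score(base + eff_h + noise[1]),
      finger = .clip_score(base + eff_f + noise[2]))
  }
  if (is.null(rng_seed)) run() else with_seed(rng_seed, run())
}

.clip_score <- function(x) as.integer(pmin(20, pmax(0, round(x))))

# draw a seed voxel for a patient of the given class
.draw_seed_voxel <- function(class, truth) {
  d <- truth$grid_dim
  areas <- truth$areas
  by_name <- stats::setNames(areas, vapply(areas, `[[`, "", "name"))
  inside <- function(a) {
    idx <- .area_voxel_index(a, d)
    idx[sample.int(length(idx), 1L)]
  }
  if (class == "isolated_hand") return(inside(by_name[["hand_area"]]))
  if (class == "isolated_finger") return(inside(by_name[["finger_area"]]))
  if (class == "shared") {
    if (truth$scenario == "shared_area") return(inside(by_name[["shared_area"]]))
    stop("co_damage shared lesions are drawn pairwise")  # handled by caller
  }
  # none: uniform over voxels outside every effect area
  all_area <- unique(unlist(lapply(areas, .area_voxel_index, grid_dim = d)))
  repeat {
    v <- sample.int(prod(d), 1L)
    if (!(v %in% all_area)) return(v)
  }
}

#' Generate a synthetic lesion cohort with known ground truth
#'
#' Draws lesions group by group -- seed locations steer each patient
#' toward the intended deficit class, lesion sizes follow the
#' per-group distributions -- then scores each lesion with
#' [scores_from_lesion()] and *verifies* the resulting class against
#' the behavioural cut-offs, redrawing until the realized composition
#' matches `group_targets` exactly.  Class membership is therefore
#' always defined by scores, never by construction.  Under the
#' `co_damage` scenario a shared-deficit patient's mask is the union
#' of two growths, one seeded in each isolated area.
#'
#' @param truth a [ground_truth_spec()].
#' @param master_seed integer; the single seed for all randomness.
#' @param max_tries redraw budget per patient before failing.
#' @return Object of class `synthetic_cohort`: `cohort` (a
#'   [cohort()] with volumes), `truth`, and `area_loads` (matrix of
#'   realized per-patient loads, patients x areas).
#' @export
generate_cohort <- function(truth, master_seed = 1L, max_tries = 500L) {
  stopifnot(inherits(truth, "ground_truth_spec"))
  with_seed(master_seed, .generate_cohort_impl(truth, max_tries))
}

.generate_cohort_impl <- function(truth, max_tries) {
  d <- truth$grid_dim
  targets <- truth$group_targets[truth$group_targets > 0]
  vols <- list(); rows <- list(); loads_list <- list()
  pid <- 0L
  for (class in names(targets)) {
    lv <- truth$lesion_voxels[[class]]
    wk <- truth$weeks_post_stroke[[class]]
    for (i in seq_len(targets[[class]])) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        size <- max(20L, as.integer(round(stats::rnorm(1, lv[1], lv[2]))))
        size <- min(size, prod(d) %/% 2L)
        if (class == "shared" && truth$scenario == "co_damage") {
          areas <- stats::setNames(truth$areas,
                                   vapply(truth$areas, `[[`, "", "name"))
          s1 <- .area_voxel_index(areas[["hand_area"]], d)
          s2 <- .area_voxel_index(areas[["finger_area"]], d)
          n1 <- max(20L, as.integer(round(0.55 * size)))
          v1 <- grow_lesion(d, s1[sample.int(length(s1), 1L)], n1,
                            truth$voxel_dims_mm)
          v2 <- grow_lesion(d, s2[sample.int(length(s2), 1L)],
                            max(20L, size - n1), truth$voxel_dims_mm)
          mask <- pmax(v1$mask, v2$mask)
          vol <- lesion_volume(mask, truth$voxel_dims_mm, patient_id = id)
        } else {
          seed_v <- .draw_seed_voxel(class, truth)
          vol <- grow_lesion(d, seed_v, size, truth$voxel_dims_mm,
                             patient_id = id)
        }
        sc <- scores_from_lesion(vol, truth)
        realized <- as.character(classify_deficit(sc["hand"], sc["finger"]))
        if (realized == class) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not realize class '", class, "' for patient ", pid,
             " within ", max_tries, " tries; check effect sizes vs cut-offs")
      vols[[pid]] <- vol
      loads_list[[pid]] <- area_loads(vol, truth)
      shape <- (wk[1] / wk[2])^2
      rows[[pid]] <- data.frame(
        patient_id = id, hand_score = sc[["hand"]],
        finger_score = sc[["finger"]],
        weeks_post_stroke = stats::rgamma(1, shape = shape,
                                          rate = shape / wk[1]))
    }
  }
  records <- do.call(rbind, rows)
  co <- cohort(records, vols)
  realized <- table(factor(co$records$deficit_class,
                           levels = names(truth$group_targets)))
  stopifnot(all(realized == truth$group_targets))
  structure(list(cohort = co, truth = truth,
                 area_loads = do.call(rbind, loads_list)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> scenario:", x$truth$scenario, "\n")
  print(x$cohort)
  invisible(x)
}

#' Parcellation aligned with a ground-truth spec
#'
#' Builds an atlas on the simulator grid: each effect area is one
#' parcel, and the remaining brain is tiled into rectangular null
#' parcels, so regionwise analyses of synthetic cohorts have both true
#' and false regions to find.
#'
#' @param truth a [ground_truth_spec()].
#' @param tile length-3 block size (voxels) for the null parcels.
#' @return A [parcellation()].
#' @export
parcellation_from_truth <- function(truth, tile = c(8L, 7L, 8L)) {
  d <- truth$grid_dim
  labels <- array(0L, d)
  nm <- character(0)
  lab <- 0L
  for (a in truth$areas) {
    lab <- lab + 1L
    labels[.area_voxel_index(a, d)] <- lab
    nm[lab] <- a$name
  }
  starts <- function(n, t) seq(1L, n, by = t)
  for (i0 in starts(d[1], tile[1])) for (j0 in starts(d[2], tile[2]))
    for (k0 in starts(d[3], tile[3])) {
      box <- list(lo = c(i0, j0, k0),
                  hi = pmin(c(i0 + tile[1] - 1L, j0 + tile[2] - 1L,
                              k0 + tile[3] - 1L), d))
      idx <- .area_voxel_index(list(box = box, voxels = NULL, name = "tile"), d)
      idx <- idx[labels[idx] == 0L]
      if (length(idx) >= 10L) {
        lab <- lab + 1L
        labels[idx] <- lab
        nm[lab] <- sprintf("bg_%02d", lab)
      }
    }
  parcellation(labels, stats::setNames(nm, seq_along(nm)),
               voxel_dims_mm = truth$voxel_dims_mm)
}

#' Write a full synthetic cohort bundle to disk
#'
#' NIfTI masks per patient, the behavioural CSV (with mask paths), and
#' a ground-truth JSON for audit.
#'
#' @param x a [generate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(x, dir) {
  dir.create(file.path(dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  rec <- x$cohort$records
  rec$mask_path <- file.path("masks", paste0(rec$patient_id, ".nii.gz"))
  for (i in seq_len(nrow(rec)))
    write_lesion_mask(x$cohort$volumes[[i]], file.path(dir, rec$mask_path[i]))
  utils::write.csv(rec, file.path(dir, "behaviour.csv"), row.names = FALSE)
  truth <- x$truth
  jsonlite::write_json(
    list(grid_dim = truth$grid_dim, voxel_dims_mm = truth$voxel_dims_mm,
         scenario = truth$scenario,
         baseline_mean = truth$baseline_mean,
         baseline_sd = truth$baseline_sd,
         score_noise_sd = truth$score_noise_sd,
         group_targets = as.list(truth$group_targets),
         areas = lapply(truth$areas, function(a)
           list(name = a$name, box = a$box, effect_hand = a$effect_hand,
                effect_finger = a$effect_finger, protective = a$protective))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
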