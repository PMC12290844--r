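#' Clinical cut-offs for imitation deficits
#'
#' A score strictly below the cut-off is pathological: below 18 of 20
#' for hand imitation, below 17 of 20 for finger imitation.
#'
#' @param hand_cutoff,finger_cutoff integers in (0, 20].
#' @return An object of class `deficit_cutoffs`.
#' @export
deficit_cutoffs <- function(hand_cutoff = 18L, finger_cutoff = 17L) {
  hand_cutoff <- as.integer(hand_cutoff)
  finger_cutoff <- as.integer(finger_cutoff)
  if (hand_cutoff <= 0L || hand_cutoff > 20L ||
      finger_cutoff <= 0L || finger_cutoff > 20L)
    stop("cut-offs must lie in (0, 20]")
  structure(list(hand_cutoff = hand_cutoff, finger_cutoff = finger_cutoff),
            class = "deficit_cutoffs")
}

#' The four deficit classes
#' @return Character vector of class labels in canonical order.
#' @export
deficit_classes <- function() c("none", "isolated_hand", "isolated_finger", "shared")

#' Classify a patient's deficit from hand and finger imitation scores
#'
#' Both scores below their cut-offs give a shared deficit; one gives
#' the corresponding isolated deficit; neither gives `"none"`.
#' Inequalities are strict, so a score exactly at the cut-off is
#' non-pathological.  Vectorized over scores.
#'
#' @param hand,finger integer scores in `[0, 20]`.
#' @param cutoffs a [deficit_cutoffs()].
#' @return Factor with levels [deficit_classes()].
#' @export
classify_deficit <- function(hand, finger, cutoffs = deficit_cutoffs()) {
  if (any(hand < 0 | hand > 20 | finger < 0 | finger > 20, na.rm = FALSE))
    stop("scores must lie in [0, 20]")
  hd <- hand < cutoffs$hand_cutoff
  fd <- finger < cutoffs$finger_cutoff
  cls <- ifelse(hd & fd, "shared",
         ifelse(hd, "isolated_hand",
         ifelse(fd, "isolated_finger", "none")))
  factor(cls, levels = deficit_classes())
}

#' Assemble a lesion-behaviour cohort
#'
#' Binds the behavioural table to the per-patient lesion volumes,
#' checks grid compatibility, and derives each patient's deficit
#' class from the cut-offs.
#'
#' @param records data.frame with columns `patient_id`, `hand_score`,
#'   `finger_score`, `weeks_post_stroke` and optionally
#'   `lesion_size_mm3` (recomputed from the masks when volumes are
#'   supplied) plus any metadata.
#' @param volumes list of [lesion_volume()], one per record, aligned by
#'   position; names are checked against `patient_id` when present.
#' @param cutoffs a [deficit_cutoffs()].
#' @return An object of class `cohort` with elements `records`
#'   (including a `deficit_class` column), `volumes`, `cutoffs`.
#' @export
cohort <- function(records, volumes = NULL, cutoffs = deficit_cutoffs()) {
  records <- as.data.frame(records)
  need <- c("patient_id", "hand_score", "finger_score")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient ids")
  if (!is.null(volumes)) {
    if (length(volumes) != nrow(records))
      stop("need one lesion volume per record")
    ref <- volumes[[1]]
    for (v in volumes) {
      if (!inherits(v, "lesion_volume")) stop("volumes must be lesion_volume objects")
      if (!identical(dim(v$mask), dim(ref$mask)) ||
          !isTRUE(all.equal(v$voxel_dims_mm, ref$voxel_dims_mm)) ||
          !isTRUE(all.equal(v$affine, ref$affine)))
        stop("all volumes must share grid shape, voxel dims and affine")
    }
    records$lesion_size_mm3 <- vapply(volumes, lesion_size_mm3, numeric(1))
    names(volumes) <- records$patient_id
  }
  records$deficit_class <- classify_deficit(records$hand_score,
                                            records$finger_score, cutoffs)
  structure(list(records = records, volumes = volumes, cutoffs = cutoffs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$records$deficit_class)
  cat(sprintf("<cohort> %d patients (%s)%s\n", nrow(x$records),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              if (is.null(x$volumes)) ", no volumes" else ""))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a [cohort()].
#' @return Integer count.
#' @export
cohort_size <- function(x) nrow(x$records)

#' Sub-sample specification
#'
#' The four analysis samples: `full` keeps everyone; `shared_hand`
#' drops patients with an isolated hand deficit; `shared_finger` drops
#' isolated finger deficits; `isolated` drops shared deficits.
#'
#' @param name one of `"full"`, `"shared_hand"`, `"shared_finger"`,
#'   `"isolated"`.
#' @return List with `name` and `excluded_classes`.
#' @export
subsample_spec <- function(name = c("full", "shared_hand", "shared_finger",
                                    "isolated")) {
  name <- match.arg(name)
  excluded <- switch(name,
    full = character(0),
    shared_hand = "isolated_hand",
    shared_finger = "isolated_finger",
    isolated = "shared")
  structure(list(name = name, excluded_classes = excluded),
            class = "subsample_spec")
}

#' Build one of the analysis sub-samples
#'
#' Retains exactly the patients whose deficit class is not excluded by
#' the spec, preserving order.  Idempotent.
#'
#' @param x a classified [cohort()].
#' @param spec a [subsample_spec()] or its name.
#' @return A [cohort()].
#' @export
build_subsample <- function(x, spec = "full") {
  stopifnot(inherits(x, "cohort"))
  if (is.character(spec)) spec <- subsample_spec(spec)
  keep <- !(as.character(x$records$deficit_class) %in% spec$excluded_classes)
  if (!any(keep)) stop("sub-sample '", spec$name, "' would be empty")
  subset_cohort(x, which(keep))
}

# positional subset preserving class structure
subset_cohort <- function(x, idx) {
  structure(list(records = x$records[idx, , drop = FALSE],
                 volumes = if (is.null(x$volumes)) NULL else x$volumes[idx],
                 cutoffs = x$cutoffs),
            class = "cohort")
}

#' Resampling plan equalizing a deficit group's size
#'
#' Control design for small deficit groups: each draw keeps every
#' patient *not* of the target class and a uniform random subset of
#' exactly `keep` target-class patients, drawn without replacement.
#' Used to ask whether a finding from a small group (e.g. 8 isolated
#' finger deficits) could equally have arisen from a size-matched
#' random subset of a larger group.
#'
#' @param x a classified [cohort()].
#' @param target_class one of [deficit_classes()].
#' @param keep how many target-class patients each draw retains.
#' @param n_iter number of draws.
#' @param seed integer seed; same seed gives identical draws.
#' @return Object of class `resample_plan`: `draws` is an
#'   `n_iter`-list of kept row indices into `x$records` (sorted,
#'   all non-target rows plus `keep` target rows).  Materialize draw
#'   `i` with [resample_cohort()].
#' @export
resample_isolated_control <- function(x, target_class = "isolated_hand",
                                      keep = 8L, n_iter = 10000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  target_class <- match.arg(target_class, deficit_classes())
  in_class <- which(x$records$deficit_class == target_class)
  others <- which(x$records$deficit_class != target_class)
  if (keep > length(in_class))
    stop("keep = ", keep, " exceeds the ", length(in_class),
         " patients of class ", target_class)
  draws <- with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      sort(c(others, in_class[sample.int(length(in_class), keep)]))
    })
  })
  structure(list(draws = draws, cohort_ids = x$records$patient_id,
                 target_class = target_class, keep = keep, seed = seed),
            class = "resample_plan")
}

#' Materialize one draw of a resampling plan
#' @param x the [cohort()] the plan was built from.
#' @param plan a `resample_plan`.
#' @param i draw index.
#' @return A [cohort()].
#' @export
resample_cohort <- function(x, plan, i) {
  stopifnot(inherits(plan, "resample_plan"),
            identical(x$records$patient_id, plan$cohort_ids))
  subset_cohort(x, plan$draws[[i]])
}

#' Read / write the behavioural table
#'
#' CSV with columns `patient_id, hand_score, finger_score,
#' lesion_size_mm3, weeks_post_stroke` (plus optional metadata).
#' An optional `mask_path` column resolves lesion masks relative to
#' the CSV's directory.
#'
#' @param path CSV path.
#' @param read_masks load the masks named in `mask_path`?
#' @param cutoffs a [deficit_cutoffs()].
#' @return A [cohort()].
#' @export
read_cohort_csv <- function(path, read_masks = FALSE,
                            cutoffs = deficit_cutoffs()) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  vols <- NULL
  if (read_masks) {
    if (is.null(rec$mask_path)) stop("no mask_path column in ", path)
    vols <- lapply(seq_len(nrow(rec)), function(i) {
      read_lesion_mask(file.path(dirname(path), rec$mask_path[i]),
                       patient_id = rec$patient_id[i])
    })
  }
  cohort(rec, vols, cutoffs)
}

#' @rdname read_cohort_csv
#' @param x a [cohort()].
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x$records, path, row.names = FALSE)
  invisible(path)
}

# run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
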