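#' Binary lesion volume on a common voxel grid
#'
#' Container for one patient's binary damage mask.  All volumes analysed
#' together must share grid shape, voxel dimensions and affine; this is
#' enforced when a [cohort()] is assembled.
#'
#' @param mask 3D array coercible to integer 0/1.
#' @param voxel_dims_mm length-3 positive numeric, physical voxel size in mm.
#' @param patient_id optional identifier string.
#' @param affine 4x4 grid-to-world transform; defaults to a diagonal
#'   scaling by `voxel_dims_mm`.
#' @return An object of class `lesion_volume` with elements `mask`
#'   (integer 3D array of 0/1), `voxel_dims_mm`, `affine`, `patient_id`.
#' @export
lesion_volume <- function(mask, voxel_dims_mm = c(1, 1, 1), patient_id = NULL,
                          affine = NULL) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array, got ", length(dim(mask)), " dimensions")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1)))
    stop("mask is not binary: values outside {0,1} in range [",
         min(mask), ", ", max(mask), "]")
  voxel_dims_mm <- as.numeric(voxel_dims_mm)
  if (length(voxel_dims_mm) != 3L || any(voxel_dims_mm <= 0))
    stop("`voxel_dims_mm` must be 3 positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims_mm, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  mask <- array(as.integer(mask), dim = dim(mask))  # drop foreign attributes
  structure(
    list(mask = mask, voxel_dims_mm = voxel_dims_mm, affine = affine,
         patient_id = patient_id),
    class = "lesion_volume")
}

#' @export
print.lesion_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<lesion_volume> %s  grid %dx%dx%d  voxels %.3gx%.3gx%.3g mm  lesion %d voxels (%.1f mm^3)\n",
              if (is.null(x$patient_id)) "(unnamed)" else x$patient_id,
              d[1], d[2], d[3],
              x$voxel_dims_mm[1], x$voxel_dims_mm[2], x$voxel_dims_mm[3],
              sum(x$mask), lesion_size_mm3(x)))
  invisible(x)
}

#' Read a binary lesion mask from NIfTI
#'
#' Reads a 3D NIfTI volume and checks or enforces binarity.  In
#' `"strict"` mode any value other than 0/1 is an error; in
#' `"binarize"` mode values are thresholded (value >= `threshold`
#' becomes 1), the convention used when re-binarizing smoothed,
#' slice-reconstructed lesion maps at 0.45.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param mode `"strict"` or `"binarize"`.
#' @param threshold binarization threshold in (0,1); values `>=`
#'   threshold map to 1.  Default 0.45.
#' @param patient_id optional identifier; defaults to the file stem.
#' @return A [lesion_volume()].
#' @export
read_lesion_mask <- function(path, mode = c("strict", "binarize"),
                             threshold = 0.45, patient_id = NULL) {
  mode <- match.arg(mode)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), "D: ", path)
  vals_ok <- all(arr %in% c(0, 1))
  if (!vals_ok) {
    if (mode == "strict")
      stop(sprintf("non-binary values in %s: range [%g, %g]; use mode = \"binarize\"",
                   path, min(arr), max(arr)))
    if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)")
    arr <- (arr >= threshold) * 1L
  }
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_volume(arr,
                voxel_dims_mm = RNifti::pixdim(img)[1:3],
                patient_id = patient_id,
                affine = unclass(RNifti::xform(img)))
}

#' Write a lesion volume (or parcellation) to NIfTI
#'
#' @param vol a [lesion_volume()] or [parcellation()].
#' @param path destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_lesion_mask <- function(vol, path) {
  arr <- if (inherits(vol, "parcellation")) vol$labels else vol$mask
  .write_nifti_array(arr, vol$voxel_dims_mm, vol$affine, path)
}

.write_nifti_array <- function(arr, voxel_dims_mm, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_dims_mm
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Ordered stack of axial lesion slices
#'
#' Lesion drawings made on a small number of axial template slices,
#' to be expanded into a full volume by [reconstruct_from_slices()].
#'
#' @param slices list of 2D numeric arrays with values in `[0,1]`, all
#'   the same shape.
#' @param z_mm numeric vector of slice z-coordinates (mm), strictly
#'   increasing, one per slice.
#' @param inplane_dims_mm length-2 in-plane voxel size (mm).
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, z_mm, inplane_dims_mm = c(1, 1)) {
  if (length(slices) < 1L) stop("need at least one slice")
  if (length(z_mm) != length(slices)) stop("one z coordinate per slice")
  if (any(diff(z_mm) <= 0)) stop("`z_mm` must be strictly increasing")
  shp <- dim(slices[[1]])
  for (s in slices) {
    if (!identical(dim(s), shp)) stop("all slices must share a shape")
    if (min(s) < 0 || max(s) > 1) stop("slice values must lie in [0,1]")
  }
  structure(list(slices = slices, z_mm = as.numeric(z_mm),
                 inplane_dims_mm = as.numeric(inplane_dims_mm)),
            class = "slice_stack")
}

#' Read / write a slice stack as per-slice images plus a JSON manifest
#'
#' The manifest lists `inplane_dims_mm` and one entry per slice with its
#' `z_mm` coordinate and image `path` (relative to the manifest).  Slice
#' images may be PNG (grayscale; the first channel is used) or 2D NIfTI.
#'
#' @param manifest path to the JSON manifest.
#' @return A [slice_stack()].
#' @export
read_slice_stack <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  base <- dirname(manifest)
  ord <- order(m$slices$z_mm)
  slices <- lapply(m$slices$path[ord], function(p) {
    f <- file.path(base, p)
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    } else {
      a <- as.array(RNifti::readNifti(f))
      if (length(dim(a)) == 3L && dim(a)[3] == 1L) a <- a[, , 1]
      array(as.numeric(a), dim(a)[1:2])
    }
  })
  slice_stack(slices, m$slices$z_mm[ord],
              inplane_dims_mm = m$inplane_dims_mm)
}

#' @rdname read_slice_stack
#' @param stack a [slice_stack()].
#' @param dir output directory; slices are written as PNG plus
#'   `manifest.json`.
#' @return The manifest path, invisibly.
#' @export
write_slice_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("slice_%02d.png", seq_along(stack$slices))
  for (i in seq_along(stack$slices)) {
    png::writePNG(stack$slices[[i]], file.path(dir, paths[i]))
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(inplane_dims_mm = stack$inplane_dims_mm,
         slices = data.frame(z_mm = stack$z_mm, path = paths)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# separable Gaussian convolution along one array dimension, reflective
# boundaries; sd in voxels.  Kernel truncated at 4 sd.
.gauss_smooth_1d <- function(arr, sd_vox, along) {
  if (sd_vox <= 0) return(arr)
  r <- max(1L, ceiling(4 * sd_vox))
  k <- stats::dnorm(-r:r, sd = sd_vox)
  k <- k / sum(k)
  d <- dim(arr)
  n <- d[along]
  # reflective index: 1,2,...,n,n-1,... (mirror without repeating edge)
  idx <- seq_len(n + 2L * r) - r - 1L  # zero-based positions -r .. n-1+r
  period <- if (n > 1L) 2L * (n - 1L) else 1L
  m <- idx %% period
  m <- ifelse(m >= n, period - m, m) + 1L
  perm <- c(along, setdiff(1:3, along))
  a <- aperm(arr, perm)
  dp <- dim(a)
  a <- matrix(a, nrow = dp[1])
  ap <- a[m, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(a))
  for (j in seq_along(k)) {
    out <- out + k[j] * ap[j:(j + n - 1L), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

.gauss_smooth_3d <- function(arr, sd_vox) {
  for (ax in 1:3) arr <- .gauss_smooth_1d(arr, sd_vox[ax], ax)
  arr
}

#' Reconstruct a 3D lesion volume from axial slices
#'
#' Expands sparse axial slice drawings into a dense volume: each output
#' z-plane copies the nearest input slice (ties broken toward the lower
#' z), the stacked volume is smoothed with an isotropic Gaussian kernel,
#' and the result is re-binarized (value `>=` `threshold` becomes 1).
#' A kernel sd of half the inter-slice gap is a reasonable default for
#' slices drawn every 8 mm.
#'
#' @param stack a [slice_stack()].
#' @param out_spacing_mm output z spacing in mm (> 0).
#' @param kernel_sd_mm isotropic Gaussian sd in mm; 0 skips smoothing.
#' @param threshold binarization threshold in (0,1), default 0.45.
#' @param patient_id optional identifier for the result.
#' @return A [lesion_volume()] spanning the z-range of the stack.
#' @export
reconstruct_from_slices <- function(stack, out_spacing_mm = 1,
                                    kernel_sd_mm = 4, threshold = 0.45,
                                    patient_id = NULL) {
  stopifnot(inherits(stack, "slice_stack"))
  if (out_spacing_mm <= 0) stop("`out_spacing_mm` must be positive")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0,1)")
  z_in <- stack$z_mm
  z_out <- seq(z_in[1], z_in[length(z_in)], by = out_spacing_mm)
  if (length(z_out) == 0L) z_out <- z_in[1]
  # nearest input slice per output plane; ties -> lower z
  pick <- vapply(z_out, function(z) {
    d <- abs(z_in - z)
    which(d == min(d))[1]
  }, integer(1))
  shp <- dim(stack$slices[[1]])
  vol <- array(0, dim = c(shp, length(z_out)))
  for (i in seq_along(z_out)) vol[, , i] <- stack$slices[[pick[i]]]
  dims <- c(stack$inplane_dims_mm, out_spacing_mm)
  if (kernel_sd_mm > 0 && all(dim(vol) > 1L)) {
    vol <- .gauss_smooth_3d(vol, kernel_sd_mm / dims)
  } else if (kernel_sd_mm > 0) {
    message("grid too small to smooth; binarizing unsmoothed volume")
  }
  affine <- diag(c(dims, 1))
  affine[3, 4] <- z_out[1]
  lesion_volume((vol >= threshold) * 1L, voxel_dims_mm = dims,
                patient_id = patient_id, affine = affine)
}

#' Lesion size in cubic millimetres
#'
#' @param vol a [lesion_volume()].
#' @return Number of lesioned voxels times the voxel volume.
#' @export
lesion_size_mm3 <- function(vol) {
  stopifnot(inherits(vol, "lesion_volume"))
  sum(vol$mask) * prod(vol$voxel_dims_mm)
}

#' Integer-labelled brain parcellation
#'
#' @param labels 3D integer array; 0 is background.
#' @param names named character vector or data.frame(label, name)
#'   mapping every nonzero label to a region name.
#' @param voxel_dims_mm,affine grid geometry, as for [lesion_volume()].
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, names, voxel_dims_mm = c(1, 1, 1),
                         affine = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (is.data.frame(names)) {
    nm <- as.character(names[[2]])
    names(nm) <- as.character(names[[1]])
    names <- nm
  }
  present <- sort(unique(labels[labels != 0L]))
  missing <- setdiff(as.character(present), base::names(names))
  if (length(missing))
    stop("labels without a region name: ", paste(missing, collapse = ", "))
  if (is.null(affine)) affine <- diag(c(voxel_dims_mm, 1))
  structure(list(labels = labels, names = names,
                 voxel_dims_mm = as.numeric(voxel_dims_mm),
                 affine = unname(as.matrix(affine))),
            class = "parcellation")
}

#' Read a parcellation volume and its label table
#'
#' @param path NIfTI volume of integer labels.
#' @param names_tsv 2-column TSV (label, name), no header required.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, names_tsv) {
  img <- RNifti::readNifti(path)
  tab <- utils::read.table(names_tsv, sep = "\t", header = FALSE,
                           col.names = c("label", "name"),
                           colClasses = c("integer", "character"))
  parcellation(round(as.array(img)), tab,
               voxel_dims_mm = RNifti::pixdim(img)[1:3],
               affine = unclass(RNifti::xform(img)))
}

#' Per-region lesion load
#'
#' Fraction of each parcel's voxels overlapped by the lesion, in
#' `[0,1]`.  Parcels with zero voxels are dropped with a warning.
#'
#' @param vol a [lesion_volume()].
#' @param parc a [parcellation()] on the same grid.
#' @return Named numeric vector, one entry per region.
#' @export
lesion_load <- function(vol, parc) {
  stopifnot(inherits(vol, "lesion_volume"), inherits(parc, "parcellation"))
  if (!identical(dim(vol$mask), dim(parc$labels)))
    stop("lesion and parcellation grids differ")
  labs <- parc$labels
  all_labels <- as.integer(base::names(parc$names))
  sizes <- tabulate(labs, nbins = max(all_labels))[all_labels]
  hits <- tabulate(labs[vol$mask == 1L], nbins = max(all_labels))[all_labels]
  empty <- sizes == 0L
  if (any(empty)) {
    warning("dropping empty parcels: ",
            paste(parc$names[empty], collapse = ", "))
  }
  load <- hits[!empty] / sizes[!empty]
  names(load) <- unname(parc$names[!empty])
  load
}
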