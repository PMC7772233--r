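#' Construct a labeled volume
#'
#' The unit of I/O and evaluation: a 3-D intensity array with the slice axis
#' first, voxel spacing in mm, a modality tag, and an optional voxel-aligned
#' binary ventricle mask. The thick/thin domain tag is always derived from
#' the slice spacing: spacing above 3 mm is thick, otherwise thin.
#'
#' @param intensity Numeric array `(slices, rows, cols)`.
#' @param mask Optional binary array of identical shape (0 = background,
#'   1 = ventricle), or `NULL`.
#' @param spacing Numeric triple `(slice, row, col)` in mm.
#' @param modality `"CT"` or `"MR_T1"`.
#' @param volume_id Identifier string.
#' @return An object of class `labeled_volume` with fields `intensity`,
#'   `mask`, `spacing`, `modality`, `domain`, `volume_id`.
#' @export
labeled_volume <- function(intensity, mask = NULL, spacing, modality,
                           volume_id = "volume") {
  if (length(dim(intensity)) != 3L)
    stopf("intensity must be a 3-D array (slices x rows x cols)")
  if (!is.null(mask)) {
    mask <- array(as.integer(mask != 0), dim(mask))
    if (!identical(dim(mask), dim(intensity)))
      stopf("mask shape %s does not match intensity shape %s",
            paste(dim(mask), collapse = "x"),
            paste(dim(intensity), collapse = "x"))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be three positive lengths (mm)")
  structure(list(
    intensity = intensity,
    mask = mask,
    spacing = spacing,
    modality = match_modality(modality),
    domain = if (spacing[1] > 3) "thick" else "thin",
    volume_id = as.character(volume_id)
  ), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<labeled_volume '%s'> %s %s, %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm%s\n",
              x$volume_id, x$modality, x$domain, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              if (is.null(x$mask)) ", unlabeled" else ", with mask"))
  invisible(x)
}

nifti_from_array <- function(arr, spacing) {
  # internal array order is (slice, row, col); NIfTI stores (x, y, z)
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- c(spacing[3], spacing[2], spacing[1])
  img
}

write_mask_nifti <- function(mask, spacing, path) {
  RNifti::writeNifti(nifti_from_array(mask, spacing), path, datatype = "uint8")
  invisible(path)
}

#' Write a volume (and optionally its mask) as NIfTI
#'
#' @param volume A [labeled_volume()].
#' @param path Output `.nii` / `.nii.gz` path for the intensity image.
#' @param mask_path Optional path for the mask image; requires the volume to
#'   carry a mask.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, mask_path = NULL) {
  RNifti::writeNifti(nifti_from_array(volume$intensity, volume$spacing), path,
                     datatype = "double")
  if (!is.null(mask_path)) {
    if (is.null(volume$mask))
      stopf("volume '%s' has no mask to write", volume$volume_id)
    write_mask_nifti(volume$mask, volume$spacing, mask_path)
  }
  invisible(path)
}

#' Read a NIfTI volume as a labeled volume
#'
#' The thick/thin domain tag is derived from the slice spacing stored in the
#' header (> 3 mm is thick). Modality is not a NIfTI concept, so it is
#' supplied by the caller (cohort manifests record it).
#'
#' @param path NIfTI file with 3-D data.
#' @param mask_path Optional NIfTI mask of identical shape.
#' @param modality `"CT"` or `"MR_T1"`.
#' @param volume_id Identifier; defaults to the file stem.
#' @return A [labeled_volume()].
#' @export
read_volume <- function(path, mask_path = NULL, modality = "CT",
                        volume_id = NULL) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stopf("'%s' is not a 3-D volume (found %d dimensions)",
          path, length(dim(img)))
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stopf("'%s' has no usable voxel spacing in its header", path)
  arr <- aperm(as.array(img), c(3, 2, 1))
  mask <- NULL
  if (!is.null(mask_path) && nzchar(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- aperm(as.array(m), c(3, 2, 1))
  }
  if (is.null(volume_id))
    volume_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  labeled_volume(arr, mask = mask, spacing = c(pd[3], pd[2], pd[1]),
                 modality = modality, volume_id = volume_id)
}

#' Read a cohort manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [make_cohort()].
#' @return The manifest `data.frame`; file paths are kept relative, with the
#'   manifest directory in attribute `"dir"`.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) stopf("no such file: '%s'", manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  needed <- c("volume_id", "path", "mask_path", "modality", "domain", "split")
  missing <- setdiff(needed, names(m))
  if (length(missing))
    stopf("manifest '%s' lacks column(s): %s", manifest_path,
          paste(missing, collapse = ", "))
  attr(m, "dir") <- dirname(normalizePath(manifest_path))
  m
}

# Read the i-th manifest row as a labeled_volume.
manifest_volume <- function(manifest, i, with_mask = TRUE) {
  d <- attr(manifest, "dir")
  mp <- manifest$mask_path[i]
  read_volume(file.path(d, manifest$path[i]),
              mask_path = if (with_mask && nzchar(mp)) file.path(d, mp),
              modality = manifest$modality[i],
              volume_id = manifest$volume_id[i])
}

# Head region used for normalization: voxels not equal to a dominant constant
# background value (makes z-scoring invariant under affine remaps a*x + b).
head_region <- function(x) {
  xs <- x[seq(1, length(x), length.out = min(length(x), 50000L))]
  ux <- unique(xs)
  cnt <- tabulate(match(xs, ux))
  modal <- ux[which.max(cnt)]
  if (max(cnt) > 0.05 * length(xs)) x != modal else rep(TRUE, length(x))
}

#' Z-score a volume over its head region
#'
#' Mean and standard deviation are estimated over the head region (voxels
#' differing from the dominant constant background value) and the resulting
#' affine map is applied to every voxel. The output therefore has zero mean
#' and unit variance over the head, the result is invariant under affine
#' intensity remaps `a * x + b` (a > 0), re-normalizing is the identity up
#' to floating-point error, and the transform is invertible via the stored
#' statistics.
#'
#' @param volume A [labeled_volume()].
#' @return The volume with normalized intensities and a `norm = c(mean, sd)`
#'   field.
#' @export
normalize_volume <- function(volume) {
  x <- volume$intensity
  reg <- head_region(as.vector(x))
  v <- as.vector(x)[reg]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stopf("volume '%s' has constant intensity; cannot normalize",
          volume$volume_id)
  m <- mean(v)
  volume$intensity <- (x - m) / s   # one affine map for the whole volume
  volume$norm <- c(mean = m, sd = s)
  volume
}

#' Decompose a volume into 2-D slice samples
#'
#' Each axial slice becomes one training/inference sample: the grayscale
#' slice replicated onto 3 identical channels (the network's expected input
#' layout), plus its label plane when the volume carries a mask.
#'
#' @param volume A (typically normalized) [labeled_volume()].
#' @return A list of `slice_sample` objects in slice order, each with fields
#'   `image` (H x W x 3), `label` (H x W integer matrix or `NULL`), `domain`,
#'   `modality`, `volume_id`, and 0-based `slice_index`.
#' @export
volume_to_samples <- function(volume) {
  d <- dim(volume$intensity)
  lapply(seq_len(d[1]), function(i) {
    sl <- volume$intensity[i, , ]
    structure(list(
      image = array(sl, c(d[2], d[3], 3L)),
      label = if (!is.null(volume$mask))
        matrix(as.integer(volume$mask[i, , ]), d[2], d[3]),
      domain = volume$domain,
      modality = volume$modality,
      volume_id = volume$volume_id,
      slice_index = i - 1L
    ), class = "slice_sample")
  })
}

# Restack per-slice label planes (list of H x W matrices) into a mask array.
stack_slices <- function(planes) {
  d <- dim(planes[[1]])
  out <- array(0L, c(length(planes), d[1], d[2]))
  for (i in seq_along(planes)) out[i, , ] <- planes[[i]]
  out
}
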