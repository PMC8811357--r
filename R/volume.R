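#' 3-D volume with physical geometry
#'
#' A `volume_image` bundles a 3-D scalar voxel grid with its physical voxel
#' dimensions (mm) and anatomical axis labels. Axis labels follow the
#' neuroimaging convention where, e.g., `"LR"` means the axis runs from left
#' to right as the index increases; the canonical order used throughout the
#' package is `c("LR", "PA", "IS")` (RAS-like).
#'
#' @param voxels numeric 3-D array of voxel intensities.
#' @param voxel_size_mm positive numeric triple, voxel pitch in mm.
#' @param axis_labels character triple of axis direction labels.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_size_mm = c(1, 1, 1),
                         axis_labels = c("LR", "PA", "IS")) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive numeric triple")
  axis_labels <- as.character(axis_labels)
  valid <- c("LR", "RL", "PA", "AP", "IS", "SI")
  if (length(axis_labels) != 3L || !all(axis_labels %in% valid))
    stop("'axis_labels' must be three of ", paste(valid, collapse = ", "))
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm,
                 axis_labels = axis_labels),
            class = "volume_image")
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s voxels, %s mm, axes %s\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(signif(x$voxel_size_mm, 3), collapse = " x "),
              paste(x$axis_labels, collapse = "/")))
  invisible(x)
}

as_volume <- function(x) {
  if (inherits(x, "volume_image")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(volume_image(x))
  stop("cannot interpret input as a volume_image")
}

# world direction unit vector (RAS) for an axis label
.label_dir <- function(lab) {
  switch(lab,
         LR = c(1, 0, 0), RL = c(-1, 0, 0),
         PA = c(0, 1, 0), AP = c(0, -1, 0),
         IS = c(0, 0, 1), SI = c(0, 0, -1),
         stop("bad axis label"))
}

.orientation_to_labels <- function(orient) {
  map <- c(R = "LR", L = "RL", A = "PA", P = "AP", S = "IS", I = "SI")
  ch <- strsplit(orient, "")[[1]]
  unname(map[ch])
}

#' Read a 3-D NIfTI volume
#'
#' Loads a NIfTI-1/2 file into a [volume_image], taking voxel dimensions and
#' axis orientation from the header. No resampling or intensity scaling is
#' applied beyond what the NIfTI scl slope/intercept mandate.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(d)))
  pd <- RNifti::pixdim(img)[seq_len(3)]
  xf <- RNifti::xform(img)
  labels <- c("LR", "PA", "IS")
  if (!is.null(xf) && any(abs(xf[1:3, 1:3]) > 0)) {
    rot <- xf[1:3, 1:3]
    cs <- apply(rot, 2, function(v) max(abs(v)) / sqrt(sum(v^2)))
    if (any(cs < 0.999))
      warning("oblique orientation; using nearest axis permutation")
    labels <- .orientation_to_labels(RNifti::orientation(img))
  }
  volume_image(array(as.numeric(img), dim = d), pd, labels)
}

#' Write a volume to NIfTI
#'
#' Writes the voxel grid with a diagonal (axis-aligned) affine consistent with
#' the image's axis labels and voxel sizes, at double precision so that
#' write/read round trips are voxel-identical.
#'
#' @param img a [volume_image] (or logical/integer array mask aligned to one).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param reference optional [volume_image] providing geometry when `img` is a
#'   bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path, reference = NULL) {
  if (!inherits(img, "volume_image")) {
    if (is.null(reference))
      stop("need a volume_image or a reference geometry")
    img <- volume_image(array(as.numeric(img), dim = dim(reference$voxels)),
                        reference$voxel_size_mm, reference$axis_labels)
  }
  aff <- matrix(0, 4, 4)
  for (i in 1:3)
    aff[1:3, i] <- .label_dir(img$axis_labels[i]) * img$voxel_size_mm[i]
  aff[4, 4] <- 1
  nii <- RNifti::asNifti(img$voxels)
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(aff, code = 2L))
  RNifti::pixdim(nii) <- img$voxel_size_mm
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Reorient a volume to canonical axis labels
#'
#' Permutes and flips the voxel grid so that its axes match the canonical
#' `LR/PA/IS` order, exactly as done when matching axis labels of a standard
#' template by swapping axes. Only axis permutations and flips are applied:
#' the multiset of voxel intensities is unchanged and voxel sizes are permuted
#' consistently.
#'
#' @param img a [volume_image].
#' @return The reoriented [volume_image]; an identity operation if the image
#'   is already canonical.
#' @export
reorient_canonical <- function(img) {
  img <- as_volume(img)
  canonical <- c("LR", "PA", "IS")
  if (identical(img$axis_labels, canonical)) return(img)
  axis_of <- function(lab) {
    f <- substr(lab, 1, 1)
    if (f %in% c("L", "R")) 1L else if (f %in% c("P", "A")) 2L else 3L
  }
  src_axis <- vapply(img$axis_labels, axis_of, integer(1))
  if (anyDuplicated(src_axis))
    stop("axis labels do not span three distinct anatomical axes")
  perm <- match(1:3, src_axis)           # source index for each target axis
  vox <- aperm(img$voxels, perm)
  sizes <- img$voxel_size_mm[perm]
  labs <- img$axis_labels[perm]
  for (i in 1:3) {
    if (labs[i] != canonical[i]) {       # reversed: flip that axis
      idx <- rev(seq_len(dim(vox)[i]))
      if (i == 1L) vox <- vox[idx, , , drop = FALSE]
      if (i == 2L) vox <- vox[, idx, , drop = FALSE]
      if (i == 3L) vox <- vox[, , idx, drop = FALSE]
    }
  }
  volume_image(vox, sizes, canonical)
}

# Global Otsu threshold of a numeric vector (256 levels).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  th <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)),
                      range = rng, levels = 256L)
  as.numeric(th)
}

#' Compute (or validate) a brain mask
#'
#' If a mask is supplied it is validated and passed through unchanged.
#' Otherwise a simple fallback segmentation is used: global Otsu threshold,
#' largest 26-connected component, slice-wise morphological closing and hole
#' filling. The fallback targets synthetic or skull-stripped inputs; for raw
#' clinical acquisitions a dedicated brain-extraction mask should be supplied.
#'
#' @param img a [volume_image].
#' @param mask optional logical/0-1 array of the same shape; returned verbatim.
#' @return A logical 3-D array (`TRUE` = brain).
#' @export
compute_brain_mask <- function(img, mask = NULL) {
  img <- as_volume(img)
  if (!is.null(mask)) {
    if (inherits(mask, "volume_image")) mask <- mask$voxels
    if (!all(dim(mask) == dim(img$voxels)))
      stop("supplied mask shape does not match the image")
    m <- array(as.logical(mask), dim = dim(mask))
    if (!any(m)) stop("supplied mask is empty")
    return(m)
  }
  v <- as.numeric(img$voxels)
  if (diff(range(v)) == 0) stop("cannot derive a brain mask from a constant image")
  th <- otsu_threshold(v)
  m <- img$voxels > th
  if (!any(m)) stop("fallback brain mask is empty")
  lab <- cpp_label_26(m, dim(m))
  tab <- tabulate(lab[lab > 0L])
  m <- array(lab == which.max(tab), dim = dim(m))
  brush <- EBImage::makeBrush(5L, shape = "disc")
  for (k in seq_len(dim(m)[3])) {
    sl <- EBImage::closing(m[, , k] * 1, brush)
    sl <- EBImage::fillHull(sl)
    m[, , k] <- sl > 0.5
  }
  if (!any(m)) stop("fallback brain mask is empty")
  m
}

#' Standardize intensities within a brain mask
#'
#' Subtracts the mean intensity within the mask and divides by the (population)
#' standard deviation within the mask; voxels outside the mask are set to 0.
#'
#' @param img a [volume_image].
#' @param mask logical array of the same shape, non-empty.
#' @return A [volume_image] with within-mask mean 0 and sd 1.
#' @export
standardize_intensity <- function(img, mask) {
  img <- as_volume(img)
  if (!all(dim(mask) == dim(img$voxels))) stop("mask shape mismatch")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  v <- img$voxels[mask]
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) stop("within-mask standard deviation is zero")
  out <- array(0, dim = dim(img$voxels))
  out[mask] <- (v - mu) / sdv
  volume_image(out, img$voxel_size_mm, img$axis_labels)
}
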