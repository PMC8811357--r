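#' Frangi filter parameters
#'
#' Controls the multiscale Hessian vesselness used to detect elongated dark
#' structures. `beta1` penalizes blob-like (non-line) structure — set high
#' (default 0.9) so microbleeds are deliberately suppressed during vessel
#' detection — and `beta2` controls suppression of low-contrast background
#' response (default 20). Scales are Gaussian sigmas in voxels; filtering is
#' slice-wise 2-D with dark-on-bright polarity.
#'
#' @param beta1 line-vs-blob discrimination parameter, in (0, 1].
#' @param beta2 background-noise suppression parameter, > 0.
#' @param scales_vox positive Gaussian scales (voxels).
#' @return An object of class `frangi_params`.
#' @export
frangi_params <- function(beta1 = 0.9, beta2 = 20, scales_vox = c(1, 2, 3)) {
  if (beta1 <= 0 || beta1 > 1) stop("'beta1' must be in (0, 1]")
  if (beta2 <= 0) stop("'beta2' must be positive")
  if (length(scales_vox) < 1L || any(scales_vox <= 0))
    stop("'scales_vox' must be a nonempty set of positive scales")
  structure(list(beta1 = beta1, beta2 = beta2,
                 scales_vox = as.numeric(scales_vox)),
            class = "frangi_params")
}

# 2-D Hessian vesselness of one slice at one scale (bright structures).
.frangi_slice <- function(sl, sigma, beta1, beta2) {
  g0 <- gauss_kernel(sigma, 0L)
  g2 <- gauss_kernel(sigma, 2L)
  g1 <- gauss_kernel(sigma, 1L)
  s2 <- sigma^2                     # gamma = 2 scale normalization
  hxx <- s2 * conv_sep2d(sl, g2, g0)
  hyy <- s2 * conv_sep2d(sl, g0, g2)
  hxy <- s2 * conv_sep2d(sl, g1, g1)
  tmp <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  m <- (hxx + hyy) / 2
  e1 <- m + tmp
  e2 <- m - tmp
  # order by absolute value: |l1| <= |l2|
  swap <- abs(e1) > abs(e2)
  l1 <- ifelse(swap, e2, e1)
  l2 <- ifelse(swap, e1, e2)
  rb2 <- (l1 / l2)^2
  rb2[l2 == 0] <- 0
  s2n <- e1^2 + e2^2
  v <- exp(-rb2 / (2 * beta1^2)) * (1 - exp(-s2n / (2 * beta2^2)))
  v[l2 >= 0] <- 0                    # keep ridges of the (inverted) image
  v
}

#' Multiscale Frangi vesselness map
#'
#' Computes slice-wise 2-D vesselness of dark tubular structures: each axial
#' slice is intensity-inverted, filtered with a sigma^2-normalized Gaussian
#' Hessian at every scale, and the per-voxel maximum over scales is returned.
#' The response is nonnegative, high on dark elongated structures, low on
#' blob-like ones, and zero outside the brain mask.
#'
#' @param img a [volume_image] (raw or standardized).
#' @param mask logical brain mask.
#' @param params a [frangi_params].
#' @return Numeric 3-D array of vesselness values.
#' @export
frangi_vesselness <- function(img, mask, params = frangi_params()) {
  img <- as_volume(img)
  stopifnot(inherits(params, "frangi_params"))
  d <- dim(img$voxels)
  out <- array(0, dim = d)
  scales <- params$scales_vox
  ksizes <- vapply(scales, function(s) 2 * max(1, ceiling(3.5 * s)) + 1,
                   numeric(1))
  usable <- ksizes <= min(d[1], d[2])
  if (!all(usable)) {
    warning("skipping Frangi scale(s) larger than the slice: ",
            paste(scales[!usable], collapse = ", "))
    scales <- scales[usable]
  }
  for (k in seq_len(d[3])) {
    sl <- -img$voxels[, , k]        # dark-on-bright polarity
    best <- matrix(0, d[1], d[2])
    for (s in scales)
      best <- pmax(best, .frangi_slice(sl, s, params$beta1, params$beta2))
    out[, , k] <- best
  }
  out[!mask] <- 0
  out
}

#' Structure-tensor eigenvalue features
#'
#' Computes, per axial slice, the 2-D structure tensor (Gaussian-window
#' smoothed outer product of Gaussian-derivative gradients), its ordered
#' eigenvalues lambda1 >= lambda2 >= 0 and the linearity measure
#' `l = |lambda1 - lambda2| / 2`, which is large on edges/lines and near zero
#' on isotropic structure.
#'
#' @param img a [volume_image].
#' @param sigma_grad gradient (derivative) scale in voxels.
#' @param sigma_window tensor smoothing window scale in voxels.
#' @return List of class `structure_tensor_features` with 3-D arrays
#'   `lambda1` and `linearity`, plus the scales used.
#' @export
structure_tensor_features <- function(img, sigma_grad = 1, sigma_window = 1.5) {
  img <- as_volume(img)
  if (sigma_grad <= 0 || sigma_window <= 0) stop("scales must be positive")
  d <- dim(img$voxels)
  lam1 <- array(0, dim = d)
  lin <- array(0, dim = d)
  g0 <- gauss_kernel(sigma_grad, 0L)
  g1 <- gauss_kernel(sigma_grad, 1L)
  w <- gauss_kernel(sigma_window, 0L)
  for (k in seq_len(d[3])) {
    sl <- img$voxels[, , k]
    gx <- conv_sep2d(sl, g1, g0)
    gy <- conv_sep2d(sl, g0, g1)
    jxx <- conv_sep2d(gx * gx, w, w)
    jyy <- conv_sep2d(gy * gy, w, w)
    jxy <- conv_sep2d(gx * gy, w, w)
    tmp <- sqrt(((jxx - jyy) / 2)^2 + jxy^2)
    m <- (jxx + jyy) / 2
    lam1[, , k] <- m + tmp
    lin[, , k] <- abs((m + tmp) - (m - tmp)) / 2
  }
  structure(list(lambda1 = lam1, linearity = lin,
                 sigma_grad = sigma_grad, sigma_window = sigma_window),
            class = "structure_tensor_features")
}

#' Classify vessel/sulci voxels by unsupervised clustering
#'
#' Clusters voxels into 2 groups (vessel vs background) on the feature
#' triple (Frangi vesselness, lambda1, linearity), features scaled to unit
#' variance beforehand. The cluster centers are estimated on the eroded mask
#' interior — the brain/air boundary carries the strongest edges in a
#' skull-stripped volume and would otherwise dominate the structure cluster —
#' and every in-mask voxel (surface sulci included) is then assigned to its
#' nearest center. The cluster with the higher mean Frangi response is
#' labeled vessel. Degenerate (constant) features yield an empty mask with a
#' warning. Deterministic for a given seed.
#'
#' @param frangi_map array from [frangi_vesselness()].
#' @param st a [structure_tensor_features] object.
#' @param mask logical brain mask.
#' @param seed integer seed for the clustering restarts.
#' @return Logical 3-D array (`TRUE` = vessel/sulcus), a subset of `mask`.
#' @export
classify_vessel_voxels <- function(frangi_map, st, mask, seed = 42L) {
  stopifnot(inherits(st, "structure_tensor_features"))
  x <- cbind(frangi = frangi_map[mask],
             lambda1 = st$lambda1[mask],
             linearity = st$linearity[mask])
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) {
    warning("degenerate features: no elongated structure detected")
    return(array(FALSE, dim = dim(mask)))
  }
  keep <- sds > 0
  xs <- scale(x[, keep, drop = FALSE])
  # estimate centers away from the brain boundary
  er <- mask
  brush <- EBImage::makeBrush(7L, shape = "disc")
  for (k in seq_len(dim(mask)[3]))
    er[, , k] <- EBImage::erode(mask[, , k] * 1, brush) > 0.5
  sel <- er[mask]
  if (sum(sel) < 100L) sel <- rep(TRUE, nrow(xs))
  km <- with_seed(seed, kmeans(xs[sel, , drop = FALSE], centers = 2L,
                               nstart = 10L, iter.max = 100L))
  d1 <- colSums((t(xs) - km$centers[1, ])^2)
  d2 <- colSums((t(xs) - km$centers[2, ])^2)
  cl <- ifelse(d1 <= d2, 1L, 2L)
  mf <- tapply(x[, "frangi"], cl, mean)
  vessel_cluster <- as.integer(names(mf)[which.max(mf)])
  if (length(mf) < 2L) {
    warning("clustering collapsed to a single group; empty vessel mask")
    return(array(FALSE, dim = dim(mask)))
  }
  out <- array(FALSE, dim = dim(mask))
  out[mask] <- cl == vessel_cluster
  out
}

#' Inpaint masked voxels from their nearest unmasked neighbours
#'
#' Replaces every masked voxel by the mean of its 3 nearest (physical
#' in-plane distance) non-masked voxels. Masked voxels are processed
#' shell-by-shell in order of distance to the unmasked set (onion-peel), each
#' filled voxel immediately becoming available as a source, so thick masked
#' regions fill inward. Unmasked voxels are returned bit-identical. A slice
#' that is entirely masked is filled with the mean of its neighbouring
#' slices, with a warning.
#'
#' @param img a [volume_image].
#' @param vmask logical array of voxels to replace.
#' @return The inpainted [volume_image].
#' @export
inpaint <- function(img, vmask) {
  img <- as_volume(img)
  d <- dim(img$voxels)
  if (!all(dim(vmask) == d)) stop("vessel mask shape mismatch")
  vmask <- array(as.logical(vmask), dim = d)
  out <- img$voxels
  dx <- img$voxel_size_mm[1]; dy <- img$voxel_size_mm[2]
  full <- which(apply(vmask, 3, all))
  for (k in seq_len(d[3])) {
    if (k %in% full) next
    if (!any(vmask[, , k])) next
    out[, , k] <- cpp_inpaint_slice(out[, , k], vmask[, , k], dx, dy)
  }
  if (length(full) > 0L) {
    warning("slice(s) entirely masked; filled with neighbouring-slice mean: ",
            paste(full, collapse = ", "))
    for (k in full) {
      nb <- intersect(c(k - 1L, k + 1L), setdiff(seq_len(d[3]), full))
      if (length(nb) == 0L) nb <- setdiff(seq_len(d[3]), full)
      out[, , k] <- mean(out[, , nb])
    }
  }
  volume_image(out, img$voxel_size_mm, img$axis_labels)
}

#' Remove vessels and sulci from a volume
#'
#' Stage 1 of the preselection pipeline: computes Frangi vesselness and
#' structure-tensor features, classifies elongated dark voxels by 2-class
#' clustering, and inpaints them from their unmasked neighbourhood.
#'
#' @param img a [volume_image] (typically standardized).
#' @param mask logical brain mask.
#' @param params a [frangi_params].
#' @param sigma_grad,sigma_window structure-tensor scales (voxels).
#' @param seed clustering seed.
#' @return List with `image` (vessel-removed [volume_image]), `vessel_mask`,
#'   `frangi` and `st` (the feature maps, for QC).
#' @export
remove_vessels <- function(img, mask, params = frangi_params(),
                           sigma_grad = 1, sigma_window = 1.5, seed = 42L) {
  img <- as_volume(img)
  fr <- frangi_vesselness(img, mask, params)
  st <- structure_tensor_features(img, sigma_grad, sigma_window)
  vm <- classify_vessel_voxels(fr, st, mask, seed = seed)
  list(image = inpaint(img, vm), vessel_mask = vm, frangi = fr, st = st)
}
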