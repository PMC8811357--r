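#' Configuration of the voxel-level candidate features
#'
#' Parameters for the seven per-voxel features used by the candidate
#' classifier: raw intensity, exponential of the standardized intensity
#' (`exp(p * intensity)`, p = 1), slice-wise CLAHE (clip limit 0.01), mean
#' fast radial symmetry transform over radii \{2, 3, 4, 6\} voxels, principal
#' structure-tensor eigenvalue, blobness (image minus Gaussian smooth at
#' sigma = 1.5 voxels) and Laplacian-of-Gaussian (sigma = 1.5 voxels), plus
#' the probability threshold `th_prob` (default 0.8) applied to the
#' classifier's probability map.
#'
#' @param p exponential gain on the standardized intensity.
#' @param clahe_clip CLAHE clip limit (normalized, as a fraction of the
#'   per-tile histogram).
#' @param frst_radii_vox positive integer radii (voxels) for the FRST.
#' @param sigma_blob_vox Gaussian scale (voxels) for the blobness feature.
#' @param sigma_log_vox Gaussian scale (voxels) for the LoG feature.
#' @param th_prob candidate probability threshold in [0, 1].
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(p = 1, clahe_clip = 0.01,
                           frst_radii_vox = c(2L, 3L, 4L, 6L),
                           sigma_blob_vox = 1.5, sigma_log_vox = 1.5,
                           th_prob = 0.8) {
  if (th_prob < 0 || th_prob > 1) stop("'th_prob' must be in [0, 1]")
  if (any(frst_radii_vox <= 0)) stop("FRST radii must be positive")
  if (sigma_blob_vox <= 0 || sigma_log_vox <= 0 || clahe_clip <= 0)
    stop("scales and clip limit must be positive")
  structure(list(p = p, clahe_clip = clahe_clip,
                 frst_radii_vox = as.integer(frst_radii_vox),
                 sigma_blob_vox = sigma_blob_vox,
                 sigma_log_vox = sigma_log_vox, th_prob = th_prob),
            class = "feature_config")
}

#' Slice-wise CLAHE map
#'
#' Min-max rescales the volume to [0, 1] (within-volume range) and applies
#' contrast limited adaptive histogram equalization to each axial slice on an
#' 8 x 8 tile grid. Slices are replicate-padded to a tile multiple and
#' cropped back. Constant slices pass through unchanged with a warning.
#'
#' @param img a [volume_image].
#' @param mask logical brain mask (output is zeroed outside it).
#' @param clip clip limit (fraction of per-tile histogram; default 0.01).
#' @return Numeric 3-D array in [0, 1].
#' @export
clahe_map <- function(img, mask, clip = 0.01) {
  img <- as_volume(img)
  if (clip <= 0) stop("'clip' must be positive")
  d <- dim(img$voxels)
  rng <- range(img$voxels)
  out <- array(0, dim = d)
  if (diff(rng) == 0) {
    warning("constant volume: CLAHE returned unchanged (zero) map")
    return(out)
  }
  v01 <- (img$voxels - rng[1]) / diff(rng)
  ntile <- 8L
  had_const <- FALSE
  for (k in seq_len(d[3])) {
    sl <- v01[, , k]
    if (diff(range(sl)) == 0) {
      if (any(mask[, , k])) had_const <- TRUE
      out[, , k] <- sl
      next
    }
    nx <- ceiling(d[1] / ntile) * ntile
    ny <- ceiling(d[2] / ntile) * ntile
    pad <- sl[c(seq_len(d[1]), rep(d[1], nx - d[1])),
              c(seq_len(d[2]), rep(d[2], ny - d[2]))]
    eq <- EBImage::clahe(pad, nx = ntile, ny = ntile, bins = 256L,
                         limit = clip * 256)
    out[, , k] <- pmin(pmax(eq[seq_len(d[1]), seq_len(d[2])], 0), 1)
  }
  if (had_const) warning("constant slice(s): CLAHE left them unchanged")
  out[!mask] <- 0
  out
}

#' Exponential intensity feature
#'
#' Voxel-wise `exp(p * value)` of a standardized image (within-mask mean 0,
#' sd 1). Arguments with `|p * value| > 50` are clipped, with a warning, to
#' avoid overflow.
#'
#' @param std_img a standardized [volume_image].
#' @param p exponential gain (default 1).
#' @return Numeric 3-D array.
#' @export
exp_intensity <- function(std_img, p = 1) {
  std_img <- as_volume(std_img)
  a <- p * std_img$voxels
  if (any(abs(a) > 50)) {
    warning("exponential argument clipped at |p x intensity| = 50")
    a <- pmin(pmax(a, -50), 50)
  }
  exp(a)
}

# one slice of the dark fast radial symmetry transform
.frst_slice <- function(sl, radii, alpha = 2, kappa = 9.9) {
  nx <- nrow(sl); ny <- ncol(sl)
  sob1 <- c(-1, 0, 1) / 2
  sob0 <- c(1, 2, 1) / 4
  gx <- conv_sep2d(sl, sob1, sob0)
  gy <- conv_sep2d(sl, sob0, sob1)
  gmag <- sqrt(gx^2 + gy^2)
  pos <- gmag > 0
  if (!any(pos)) return(matrix(0, nx, ny))
  floor_g <- quantile(gmag[pos], 0.05, names = FALSE)
  sel <- which(gmag > floor_g)
  if (length(sel) == 0L) return(matrix(0, nx, ny))
  ij <- arrayInd(sel, c(nx, ny))
  ux <- gx[sel] / gmag[sel]
  uy <- gy[sel] / gmag[sel]
  acc <- matrix(0, nx, ny)
  for (r in radii) {
    # negatively-affected pixels: step against the gradient (towards dark)
    pi_ <- ij[, 1] - round(r * ux)
    pj <- ij[, 2] - round(r * uy)
    ok <- pi_ >= 1 & pi_ <= nx & pj >= 1 & pj <= ny
    if (!any(ok)) next
    lin <- pi_[ok] + (pj[ok] - 1L) * nx
    o_map <- numeric(nx * ny)
    m_map <- numeric(nx * ny)
    cnt <- tabulate(lin, nbins = nx * ny)
    o_map <- cnt
    ms <- rowsum(gmag[sel][ok], group = lin)
    m_map[as.integer(rownames(ms))] <- ms
    o_t <- pmin(o_map, kappa) / kappa
    f <- (o_t^alpha) * (m_map / kappa)
    fmat <- matrix(f, nx, ny)
    g <- gauss_kernel(max(0.5, r / 2), 0L)
    acc <- acc + conv_sep2d(fmat, g, g)
  }
  acc / length(radii)
}

#' Fast radial symmetry transform map
#'
#' Slice-wise FRST restricted to dark radial symmetry: image gradients vote
#' at the pixel one radius step against the gradient direction (the dark side)
#' and orientation/magnitude votes are combined with radial-strictness
#' exponent alpha = 2, a gradient floor at the 5th percentile of per-slice
#' gradient magnitudes, and Gaussian spreading at sigma = r/2. Outputs for
#' all radii are averaged; large positive values mean strong dark radial
#' symmetry. Radii that do not fit in the slice are skipped with a warning.
#'
#' @param img a [volume_image].
#' @param mask logical brain mask (output zeroed outside).
#' @param radii positive integer radii in voxels.
#' @return Numeric 3-D array.
#' @export
frst_map <- function(img, mask, radii = c(2L, 3L, 4L, 6L)) {
  img <- as_volume(img)
  if (length(radii) == 0L) stop("need at least one radius")
  d <- dim(img$voxels)
  usable <- radii < min(d[1], d[2])
  if (!all(usable)) {
    warning("skipping FRST radius/radii not fitting the slice: ",
            paste(radii[!usable], collapse = ", "))
    radii <- radii[usable]
  }
  out <- array(0, dim = d)
  for (k in seq_len(d[3]))
    out[, , k] <- .frst_slice(img$voxels[, , k], radii)
  out[!mask] <- 0
  out
}

#' Blobness map (difference-from-smooth)
#'
#' Per-slice `I - GaussianSmooth(I, sigma)`: a high-pass residual that
#' removes slowly varying background and highlights sharp objects. Dark blobs
#' of size comparable to sigma give strongly negative values at their center.
#'
#' @param img a [volume_image].
#' @param sigma Gaussian scale in voxels.
#' @return Numeric 3-D array.
#' @export
blobness_map <- function(img, sigma = 1.5) {
  img <- as_volume(img)
  if (sigma <= 0) stop("'sigma' must be positive")
  g <- gauss_kernel(sigma, 0L)
  apply_slices(img$voxels, function(sl) sl - conv_sep2d(sl, g, g))
}

#' Laplacian-of-Gaussian map
#'
#' Per-slice sigma^2-normalized LoG response, a second-derivative filter that
#' highlights well-defined edges and blobs at the chosen scale.
#'
#' @param img a [volume_image].
#' @param sigma Gaussian scale in voxels.
#' @return Numeric 3-D array.
#' @export
log_map <- function(img, sigma = 1.5) {
  img <- as_volume(img)
  if (sigma <= 0) stop("'sigma' must be positive")
  g0 <- gauss_kernel(sigma, 0L)
  g2 <- gauss_kernel(sigma, 2L)
  s2 <- sigma^2
  apply_slices(img$voxels, function(sl)
    s2 * (conv_sep2d(sl, g2, g0) + conv_sep2d(sl, g0, g2)))
}

#' Assemble the 7-feature voxel stack
#'
#' Computes the seven candidate-detection feature maps on the vessel-removed
#' image and normalizes each by its per-image maximum absolute value (a map
#' that is identically zero stays zero). The exponential feature is computed
#' on a standardized copy of the input; the intensity feature is the input
#' itself. All maps are zeroed outside the brain mask before normalization.
#'
#' @param vessel_removed the vessel-removed [volume_image].
#' @param mask logical brain mask.
#' @param cfg a [feature_config].
#' @param clahe_source optional [volume_image] on which CLAHE is computed
#'   (defaults to `vessel_removed`; supply the original image to switch).
#' @return Object of class `voxel_feature_stack`: list with `features` (named
#'   list of 7 arrays), `mask`, `voxel_size_mm` and `cfg`.
#' @export
assemble_features <- function(vessel_removed, mask, cfg = feature_config(),
                              clahe_source = NULL) {
  img <- as_volume(vessel_removed)
  stopifnot(inherits(cfg, "feature_config"))
  if (is.null(clahe_source)) clahe_source <- img
  std <- standardize_intensity(img, mask)
  maps <- list(
    intensity = img$voxels,
    exp_intensity = exp_intensity(std, cfg$p),
    clahe = clahe_map(as_volume(clahe_source), mask, cfg$clahe_clip),
    frst_mean = frst_map(std, mask, cfg$frst_radii_vox),
    st_lambda1 = structure_tensor_features(std)$lambda1,
    blobness = blobness_map(std, cfg$sigma_blob_vox),
    log = log_map(std, cfg$sigma_log_vox))
  for (nm in names(maps)) {
    m <- maps[[nm]]
    m[!mask] <- 0
    if (any(!is.finite(m)))
      stop("non-finite values in feature '", nm, "'")
    mx <- max(abs(m))
    if (mx > 0) m <- m / mx
    maps[[nm]] <- m
  }
  structure(list(features = maps, mask = mask,
                 voxel_size_mm = img$voxel_size_mm, cfg = cfg),
            class = "voxel_feature_stack")
}

#' @export
print.voxel_feature_stack <- function(x, ...) {
  cat(sprintf("voxel_feature_stack: %d features over %d in-mask voxels\n",
              length(x$features), sum(x$mask)))
  invisible(x)
}

# in-mask feature matrix (n x 7) in a fixed column order
stack_matrix <- function(stack, voxels = NULL) {
  idx <- if (is.null(voxels)) which(stack$mask) else voxels
  out <- vapply(stack$features, function(m) m[idx], numeric(length(idx)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(idx))
  colnames(out) <- names(stack$features)
  out
}

#' Sample voxel-level training data from a feature stack
#'
#' Keeps every positive (true microbleed) voxel and samples negatives
#' uniformly from the remaining in-mask voxels at `neg_pos_ratio` per
#' positive, deterministically for a given seed.
#'
#' @param stack a [assemble_features()] stack.
#' @param truth integer-labeled truth array (0 = background).
#' @param neg_pos_ratio negatives per positive (default 10).
#' @param seed sampling seed.
#' @return List with feature matrix `x`, 0/1 labels `y`, and the sampled
#'   voxel indices.
#' @export
sample_training_voxels <- function(stack, truth, neg_pos_ratio = 10, seed = 1L) {
  stopifnot(inherits(stack, "voxel_feature_stack"))
  pos <- which(stack$mask & truth > 0)
  if (length(pos) == 0L) stop("no positive voxels in the truth mask")
  negpool <- which(stack$mask & truth == 0)
  n_neg <- min(length(negpool), round(neg_pos_ratio * length(pos)))
  neg <- with_seed(seed, sample(negpool, n_neg))
  idx <- c(pos, neg)
  list(x = stack_matrix(stack, idx),
       y = rep(c(1L, 0L), c(length(pos), n_neg)),
       voxels = idx)
}
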