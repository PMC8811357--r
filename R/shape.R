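#' Shape criteria for candidate filtering
#'
#' A candidate component is kept as a microbleed only if all four physical
#' shape criteria hold: volume strictly inside `vol_range_mm3` (open
#' interval, default (5, 120) mm^3), ellipticity strictly below
#' `ellipticity_max` (default 0.2), solidity at or above `solidity_min`
#' (lower threshold, default 0.6), and diameter strictly inside
#' `diameter_range_mm` (open interval, default (2, 10) mm).
#'
#' @param vol_range_mm3 open volume interval in mm^3.
#' @param ellipticity_max strict upper bound on ellipticity, in [0, 1].
#' @param solidity_min inclusive lower bound on solidity, in [0, 1].
#' @param diameter_range_mm open diameter interval in mm.
#' @return An object of class `shape_criteria`.
#' @export
shape_criteria <- function(vol_range_mm3 = c(5, 120), ellipticity_max = 0.2,
                           solidity_min = 0.6, diameter_range_mm = c(2, 10)) {
  ok <- function(r) length(r) == 2L && r[2] > r[1]
  if (!ok(vol_range_mm3) || !ok(diameter_range_mm))
    stop("ranges must be nonempty intervals")
  if (ellipticity_max < 0 || ellipticity_max > 1 ||
      solidity_min < 0 || solidity_min > 1)
    stop("ellipticity/solidity thresholds must lie in [0, 1]")
  structure(list(vol_range_mm3 = as.numeric(vol_range_mm3),
                 ellipticity_max = ellipticity_max,
                 solidity_min = solidity_min,
                 diameter_range_mm = as.numeric(diameter_range_mm)),
            class = "shape_criteria")
}

#' Label 26-connected components of a candidate mask
#'
#' Finds maximal 26-connected clusters (voxels sharing a face, edge or
#' corner belong together). Labels are assigned deterministically in
#' column-major scan order.
#'
#' @param cmask logical 3-D candidate mask.
#' @return List of components, each a list with `id` and `voxels` (an n x 3
#'   integer matrix of 1-based voxel indices); the integer label array is
#'   attached as attribute `labels`. An empty mask gives an empty list.
#' @export
label_components <- function(cmask) {
  cmask <- array(as.logical(cmask), dim = dim(cmask))
  lab <- cpp_label_26(cmask, dim(cmask))
  n <- attr(lab, "n_components")
  comps <- vector("list", n)
  if (n > 0L) {
    idx <- which(lab > 0L)
    ord <- order(lab[idx])
    idx <- idx[ord]
    grp <- lab[idx]
    coords <- arrayInd(idx, dim(cmask))
    splits <- split(seq_along(idx), grp)
    for (i in seq_len(n))
      comps[[i]] <- list(id = i,
                         voxels = coords[splits[[as.character(i)]], , drop = FALSE])
  }
  attr(comps, "labels") <- lab
  comps
}

# 2-D (maximal-area slice) solidity fallback: convex-hull area ratio by
# rasterized hull membership
.solidity_2d <- function(vox_slice, dx, dy) {
  x <- (vox_slice[, 1] - 1) * dx
  y <- (vox_slice[, 2] - 1) * dy
  n <- length(x)
  if (n <= 2L) return(1)
  h <- grDevices::chull(x, y)
  if (length(h) <= 2L) return(1)     # collinear: trivially convex
  xr <- range(vox_slice[, 1]); yr <- range(vox_slice[, 2])
  gi <- seq.int(xr[1], xr[2]); gj <- seq.int(yr[1], yr[2])
  qx <- rep((gi - 1) * dx, times = length(gj))
  qy <- rep((gj - 1) * dy, each = length(gi))
  inp <- pracma::inpolygon(qx, qy, x[h], y[h], boundary = TRUE)
  n / max(sum(inp), n)
}

#' Compute physical shape attributes of a component
#'
#' Fills in the candidate's physical shape descriptors:
#' \describe{
#'   \item{volume_mm3}{voxel count times voxel volume.}
#'   \item{diameter_mm}{longest line through the candidate: the exact maximum
#'     pairwise distance between voxel centers in physical coordinates
#'     (bounded below by the in-plane voxel pitch).}
#'   \item{ellipticity}{1 minus the minor/major principal-axis ratio from
#'     second moments of the component's maximal-area axial slice, voxels
#'     treated as uniform squares (their own second moment is included); 0
#'     for a sphere/disc, approaching 1 for elongated shapes.}
#'   \item{solidity}{component volume divided by its convex volume, where the
#'     convex volume counts voxel centers inside the 3-D convex hull of the
#'     component's voxel centers (so a filled convex lattice shape scores
#'     exactly 1). Single-slice or otherwise degenerate components fall back
#'     to the 2-D convex area ratio on the maximal-area slice.}
#' }
#' Components larger than 4000 voxels (far beyond any plausible microbleed)
#' get a bounding-box-diagonal diameter and `NA` solidity; they are rejected
#' by the volume criterion regardless.
#'
#' @param comp a component from [label_components()].
#' @param voxel_size_mm voxel pitch triple (mm).
#' @return The component with attribute fields added.
#' @export
compute_shape_attributes <- function(comp, voxel_size_mm) {
  vox <- comp$voxels
  if (is.null(vox) || nrow(vox) == 0L) stop("empty component")
  vs <- as.numeric(voxel_size_mm)
  n <- nrow(vox)
  pts <- sweep(vox - 1, 2, vs, `*`)
  comp$n_vox <- n
  comp$centroid_mm <- colMeans(pts)
  comp$volume_mm3 <- n * prod(vs)

  big <- n > 4000L
  if (big) {
    comp$diameter_mm <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
    comp$solidity <- NA_real_
  } else {
    comp$diameter_mm <- max(cpp_max_pairwise_dist(pts), max(vs[1:2]))
  }

  # ellipticity from second moments on the maximal-area axial slice
  slice_tab <- table(vox[, 3])
  kmax <- as.integer(names(slice_tab)[which.max(slice_tab)])
  sl <- vox[vox[, 3] == kmax, , drop = FALSE]
  if (nrow(sl) < 2L) {
    comp$ellipticity <- 0
  } else {
    xy <- cbind((sl[, 1] - 1) * vs[1], (sl[, 2] - 1) * vs[2])
    cc <- sweep(xy, 2, colMeans(xy))
    # voxel-extent correction: voxels are uniform squares, not points
    covm <- crossprod(cc) / nrow(cc) + diag(vs[1:2]^2) / 12
    ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
    comp$ellipticity <- if (ev[1] <= 0) 0 else
      1 - sqrt(max(ev[2], 0) / ev[1])
  }

  if (!big) {
    nz <- length(unique(vox[, 3]))
    rank3 <- if (n >= 4L) {
      svv <- svd(sweep(pts, 2, colMeans(pts)))$d
      sum(svv > 1e-9 * max(svv, 1))
    } else 0L
    if (nz < 2L || rank3 < 3L) {
      comp$solidity <- .solidity_2d(sl, vs[1], vs[2])
    } else {
      bb_lo <- apply(vox, 2, min); bb_hi <- apply(vox, 2, max)
      gi <- seq.int(bb_lo[1], bb_hi[1])
      gj <- seq.int(bb_lo[2], bb_hi[2])
      gk <- seq.int(bb_lo[3], bb_hi[3])
      q <- as.matrix(expand.grid(gi, gj, gk))
      qpts <- sweep(q - 1, 2, vs, `*`)
      h <- cpp_hull3d_inside(pts, qpts, tol = 1e-7 * max(vs))
      comp$solidity <- min(1, n / max(sum(h$inside), n))
    }
  }
  comp$diameter_mm <- max(comp$diameter_mm, max(vs[1:2]))
  comp
}

#' Filter candidate components by shape criteria
#'
#' Applies the four shape criteria conjunctively; a component survives only
#' if every criterion passes. Per-criterion pass flags are recorded on each
#' component for QC. Components lacking attributes are measured first using
#' `voxel_size_mm`.
#'
#' @param components list from [label_components()].
#' @param criteria a [shape_criteria].
#' @param voxel_size_mm voxel pitch (needed if attributes are not yet set).
#' @return List with `components` (all, annotated), `surviving` (the subset
#'   passing all criteria) and `report` (one row per component).
#' @export
filter_candidates <- function(components, criteria = shape_criteria(),
                              voxel_size_mm = NULL) {
  stopifnot(inherits(criteria, "shape_criteria"))
  components <- lapply(components, function(cp) {
    if (is.null(cp$volume_mm3)) {
      if (is.null(voxel_size_mm))
        stop("components lack attributes and no 'voxel_size_mm' given")
      cp <- compute_shape_attributes(cp, voxel_size_mm)
    }
    cp$pass_volume <- cp$volume_mm3 > criteria$vol_range_mm3[1] &&
      cp$volume_mm3 < criteria$vol_range_mm3[2]
    cp$pass_ellipticity <- cp$ellipticity < criteria$ellipticity_max
    cp$pass_solidity <- !is.na(cp$solidity) &&
      cp$solidity >= criteria$solidity_min
    cp$pass_diameter <- cp$diameter_mm > criteria$diameter_range_mm[1] &&
      cp$diameter_mm < criteria$diameter_range_mm[2]
    cp$passes <- cp$pass_volume && cp$pass_ellipticity &&
      cp$pass_solidity && cp$pass_diameter
    cp
  })
  surviving <- Filter(function(cp) cp$passes, components)
  report <- if (length(components) == 0L) {
    data.frame(id = integer(0), n_vox = integer(0), volume_mm3 = numeric(0),
               ellipticity = numeric(0), solidity = numeric(0),
               diameter_mm = numeric(0), pass_volume = logical(0),
               pass_ellipticity = logical(0), pass_solidity = logical(0),
               pass_diameter = logical(0), passes = logical(0))
  } else {
    do.call(rbind, lapply(components, function(cp)
      data.frame(id = cp$id, n_vox = cp$n_vox, volume_mm3 = cp$volume_mm3,
                 ellipticity = cp$ellipticity, solidity = cp$solidity,
                 diameter_mm = cp$diameter_mm, pass_volume = cp$pass_volume,
                 pass_ellipticity = cp$pass_ellipticity,
                 pass_solidity = cp$pass_solidity,
                 pass_diameter = cp$pass_diameter, passes = cp$passes)))
  }
  list(components = components, surviving = surviving, report = report)
}

# labeled array containing only the given components
components_to_labels <- function(components, dims) {
  lab <- array(0L, dim = dims)
  for (cp in components)
    lab[cp$voxels] <- cp$id
  lab
}
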