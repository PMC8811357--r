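#' Specification for a synthetic SWI-like phantom
#'
#' Defines the geometry, object content and noise of one synthetic subject:
#' an ellipsoidal "brain" filled at `background_level`, containing dark
#' quasi-spherical microbleeds, dark curved vessel tubes, dark surface ribbons
#' emulating sulci, and optionally one large haemorrhage blob, with additive
#' Gaussian noise. All randomness derives from `seed`, so identical specs give
#' voxel-identical phantoms.
#'
#' Defaults emulate a desk-scale SWI acquisition: 0.8 x 0.8 x 3 mm voxels and
#' microbleed diameters of 2.5-6 mm, the size range that dominates observed
#' CMB volume distributions (a sphere above ~6 mm already exceeds the 120 mm^3
#' volume ceiling used by the shape filter). Object darkening is
#' multiplicative: an object voxel takes intensity
#' `background_level * (1 - contrast)`.
#'
#' @param grid_shape integer triple of voxel counts, at least (32, 32, 8).
#' @param voxel_size_mm positive voxel pitch triple in mm.
#' @param background_level background intensity inside the brain mask.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param n_cmbs number of microbleeds to place.
#' @param cmb_diameter_range_mm microbleed diameter interval, within [2, 10].
#' @param cmb_contrast fractional darkening of microbleeds, in (0, 1].
#' @param n_vessels number of vessel tubes.
#' @param vessel_radius_range_mm vessel radius interval in mm.
#' @param vessel_contrast fractional darkening of vessels/sulci, in (0, 1];
#'   darker than microbleeds by default, reflecting the near-signal-void
#'   blooming of veins and flow voids on susceptibility-weighted contrasts.
#' @param sulci_density nonnegative; expected number of surface ribbons is
#'   `round(8 * sulci_density)`.
#' @param haemorrhage logical; add one large dark blob.
#' @param haemorrhage_diameter_mm diameter of the haemorrhage blob.
#' @param seed integer seed controlling all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 24L),
                         voxel_size_mm = c(0.8, 0.8, 3),
                         background_level = 100,
                         noise_sd = 5,
                         n_cmbs = 4L,
                         cmb_diameter_range_mm = c(2.5, 6),
                         cmb_contrast = 0.5,
                         n_vessels = 6L,
                         vessel_radius_range_mm = c(0.4, 1.2),
                         vessel_contrast = 0.8,
                         sulci_density = 0.5,
                         haemorrhage = FALSE,
                         haemorrhage_diameter_mm = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < c(32L, 32L, 8L)))
    stop("'grid_shape' must be an integer triple of at least (32, 32, 8)")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be a positive triple")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (n_cmbs < 0 || n_vessels < 0) stop("object counts must be nonnegative")
  rng_ok <- function(r) length(r) == 2L && r[1] > 0 && r[2] >= r[1]
  if (!rng_ok(cmb_diameter_range_mm) ||
      cmb_diameter_range_mm[1] < 2 || cmb_diameter_range_mm[2] > 10)
    stop("'cmb_diameter_range_mm' must be a nonempty interval within [2, 10]")
  if (!rng_ok(vessel_radius_range_mm))
    stop("'vessel_radius_range_mm' must be a nonempty positive interval")
  if (cmb_contrast <= 0 || cmb_contrast > 1 ||
      vessel_contrast <= 0 || vessel_contrast > 1)
    stop("contrasts must lie in (0, 1]")
  if (sulci_density < 0) stop("'sulci_density' must be nonnegative")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 background_level = background_level, noise_sd = noise_sd,
                 n_cmbs = as.integer(n_cmbs),
                 cmb_diameter_range_mm = as.numeric(cmb_diameter_range_mm),
                 cmb_contrast = cmb_contrast,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius_range_mm = as.numeric(vessel_radius_range_mm),
                 vessel_contrast = vessel_contrast,
                 sulci_density = sulci_density,
                 haemorrhage = isTRUE(haemorrhage),
                 haemorrhage_diameter_mm = haemorrhage_diameter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinates of voxel centers along each axis (voxel i at (i-1)*d)
.grid_coords <- function(grid, voxel_size_mm) {
  lapply(1:3, function(a) (seq_len(grid[a]) - 1) * voxel_size_mm[a])
}

#' Rasterize an ellipsoid onto a voxel grid
#'
#' A voxel belongs to the mask iff its center lies inside (or on) the
#' ellipsoid in physical coordinates. An ellipsoid entirely outside the grid
#' yields an empty mask.
#'
#' @param center_mm physical center (mm), length 3.
#' @param semi_axes_mm positive semi-axis lengths (mm), length 3.
#' @param grid integer triple of voxel counts.
#' @param voxel_size_mm voxel pitch triple (mm).
#' @return Logical 3-D array.
#' @export
rasterize_ellipsoid <- function(center_mm, semi_axes_mm, grid, voxel_size_mm) {
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive")
  co <- .grid_coords(grid, voxel_size_mm)
  q <- lapply(1:3, function(a) ((co[[a]] - center_mm[a]) / semi_axes_mm[a])^2)
  s <- outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+")
  array(s <= 1, dim = grid)
}

#' Rasterize a tube around a polyline
#'
#' A voxel belongs to the mask iff its center is within `radius_mm` of the
#' polyline (in physical coordinates). A degenerate (zero-length) path gives a
#' sphere; a path entirely outside the grid gives an empty mask.
#'
#' @param path_points_mm numeric matrix (n >= 2 rows, 3 columns) of polyline
#'   vertices in mm.
#' @param radius_mm tube radius in mm.
#' @param grid integer triple of voxel counts.
#' @param voxel_size_mm voxel pitch triple (mm).
#' @return Logical 3-D array.
#' @export
rasterize_tube <- function(path_points_mm, radius_mm, grid, voxel_size_mm) {
  pts <- as.matrix(path_points_mm)
  if (nrow(pts) < 2L) stop("need at least 2 path points")
  co <- .grid_coords(grid, voxel_size_mm)
  lo <- apply(pts, 2, min) - radius_mm
  hi <- apply(pts, 2, max) + radius_mm
  idx <- lapply(1:3, function(a) which(co[[a]] >= lo[a] & co[[a]] <= hi[a]))
  out <- array(FALSE, dim = grid)
  if (any(vapply(idx, length, 1L) == 0L)) return(out)
  gx <- co[[1]][idx[[1]]]; gy <- co[[2]][idx[[2]]]; gz <- co[[3]][idx[[3]]]
  nb <- c(length(gx), length(gy), length(gz))
  px <- rep(gx, times = nb[2] * nb[3])
  py <- rep(rep(gy, each = nb[1]), times = nb[3])
  pz <- rep(gz, each = nb[1] * nb[2])
  mind2 <- rep(Inf, length(px))
  r2 <- radius_mm^2
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (px - a[1])^2 + (py - a[2])^2 + (pz - a[3])^2
    } else {
      t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2 +
        (pz - (a[3] + t * ab[3]))^2
    }
    mind2 <- pmin(mind2, d2)
  }
  sub <- array(mind2 <= r2, dim = nb)
  out[idx[[1]], idx[[2]], idx[[3]]] <- sub
  out
}

# smooth mostly-in-plane random polyline inside the brain mask (mm coords)
.random_vessel_path <- function(mask_fun, extent_mm, z_range_mm,
                                step_mm = 2, max_steps = 30L) {
  for (try in 1:50) {
    p <- c(runif(1, 0.2, 0.8) * extent_mm[1],
           runif(1, 0.2, 0.8) * extent_mm[2],
           runif(1, z_range_mm[1], z_range_mm[2]))
    if (!mask_fun(p)) next
    ang <- runif(1, 0, 2 * pi)
    drift_z <- runif(1, -0.15, 0.15)
    path <- matrix(p, ncol = 3)
    for (s in seq_len(max_steps)) {
      ang <- ang + runif(1, -0.5, 0.5)
      q <- path[nrow(path), ] +
        step_mm * c(cos(ang), sin(ang), drift_z)
      if (!mask_fun(q)) break
      path <- rbind(path, q)
    }
    if (nrow(path) >= 5L) return(path)
  }
  NULL
}

#' Generate one synthetic phantom subject
#'
#' Builds the volume described by a [phantom_spec]: ellipsoidal brain mask,
#' flat background, dark vessels and surface sulci ribbons, optionally one
#' large haemorrhage blob, and `n_cmbs` dark spheres placed inside the brain
#' without overlapping each other or any mimic, followed by additive Gaussian
#' noise. The returned truth mask labels the voxels of the k-th microbleed
#' with integer k.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_subject`: list with elements `image`
#'   ([volume_image]), `brain_mask` (logical array), `cmb_truth` (integer
#'   array), `has_cmb`, `placed_cmb_count`, and the generating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    grid <- spec$grid_shape
    vs <- spec$voxel_size_mm
    extent <- (grid - 1) * vs
    center <- extent / 2
    semi <- c(0.45 * extent[1], 0.45 * extent[2], 0.44 * extent[3])
    brain <- rasterize_ellipsoid(center, semi, grid, vs)
    in_brain <- function(p, margin = 0) {
      all(p >= 0) && all(p <= extent) &&
        sum(((p - center) / (semi - margin))^2) <= 1
    }
    img <- array(0, dim = grid)
    img[brain] <- spec$background_level

    mimic <- array(FALSE, dim = grid)
    # vessels: smooth, predominantly in-plane random polylines
    if (spec$n_vessels > 0L) {
      for (v in seq_len(spec$n_vessels)) {
        path <- .random_vessel_path(function(p) in_brain(p, margin = 1),
                                    extent, c(0.15, 0.85) * extent[3])
        if (is.null(path))
          stop("vessel placement failed: could not fit a vessel path")
        r <- runif(1, spec$vessel_radius_range_mm[1],
                   spec$vessel_radius_range_mm[2])
        mimic <- mimic | rasterize_tube(path, r, grid, vs)
      }
    }
    # sulci: thin ribbons hugging the brain surface (within ~2 voxels)
    n_sulci <- round(8 * spec$sulci_density)
    if (n_sulci > 0L) {
      shell_in <- rasterize_ellipsoid(center, semi * 0.88, grid, vs)
      for (s in seq_len(n_sulci)) {
        th <- runif(1, 0, 2 * pi)
        phi <- runif(1, -0.25 * pi, 0.25 * pi)
        u <- c(cos(phi) * cos(th), cos(phi) * sin(th), sin(phi))
        surf <- center + 0.94 * semi * u
        tang <- c(-sin(th), cos(th), 0)
        len <- runif(1, 8, 18)
        tpts <- seq(-len / 2, len / 2, by = 2)
        path <- t(vapply(tpts, function(t) {
          p <- surf + t * tang
          # re-project towards the surface shell
          d <- (p - center) / semi
          nd <- sqrt(sum(d^2))
          if (nd > 0) p <- center + 0.94 * semi * d / nd
          p
        }, numeric(3)))
        rib <- rasterize_tube(path, 0.7, grid, vs)
        mimic <- mimic | (rib & brain & !shell_in)
      }
    }
    if (spec$haemorrhage) {
      for (try in 1:100) {
        p <- center + runif(3, -0.4, 0.4) * semi
        if (in_brain(p, margin = spec$haemorrhage_diameter_mm / 2)) break
        if (try == 100) stop("haemorrhage placement failed")
      }
      mimic <- mimic | rasterize_ellipsoid(p, rep(spec$haemorrhage_diameter_mm / 2, 3),
                                           grid, vs)
    }
    mimic <- mimic & brain
    img[mimic] <- spec$background_level * (1 - spec$vessel_contrast)

    # microbleeds: dark spheres, centers snapped to slice planes, no overlap
    truth <- array(0L, dim = grid)
    zs <- .grid_coords(grid, vs)[[3]]
    placed <- 0L
    centers <- matrix(numeric(0), ncol = 4) # x, y, z, radius
    if (spec$n_cmbs > 0L) {
      for (k in seq_len(spec$n_cmbs)) {
        ok <- FALSE
        for (try in 1:200) {
          d <- runif(1, spec$cmb_diameter_range_mm[1],
                     spec$cmb_diameter_range_mm[2])
          p <- center + runif(3, -0.9, 0.9) * semi
          p[3] <- zs[which.min(abs(zs - p[3]))]  # snap to slice center
          if (!in_brain(p, margin = d / 2 + 1)) next
          if (nrow(centers) > 0) {
            dd <- sqrt(rowSums(sweep(centers[, 1:3, drop = FALSE], 2, p)^2))
            if (any(dd < centers[, 4] + d / 2 + 2)) next
          }
          sph <- rasterize_ellipsoid(p, rep(d / 2, 3), grid, vs)
          if (!any(sph)) next
          if (any(sph & mimic)) next
          truth[sph] <- k
          img[sph] <- spec$background_level * (1 - spec$cmb_contrast)
          centers <- rbind(centers, c(p, d / 2))
          ok <- TRUE
          break
        }
        if (!ok)
          stop("CMB placement failed: could not fit microbleed ", k)
        placed <- placed + 1L
      }
    }
    if (spec$noise_sd > 0)
      img <- img + array(rnorm(prod(grid), 0, spec$noise_sd), dim = grid)

    structure(list(image = volume_image(img, vs),
                   brain_mask = brain,
                   cmb_truth = truth,
                   has_cmb = placed > 0L,
                   placed_cmb_count = placed,
                   spec = spec),
              class = "phantom_subject")
  })
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf("phantom_subject: %s voxels, %d CMB(s), has_cmb = %s\n",
              paste(dim(x$image$voxels), collapse = " x "),
              x$placed_cmb_count, x$has_cmb))
  invisible(x)
}

#' Generate a cohort of phantom subjects
#'
#' Creates `n_subjects` phantoms from a common template spec. A seeded random
#' subset of `round(prevalence * n_subjects)` subjects receives a microbleed
#' count drawn uniformly from `n_cmbs_range`; the remainder get none.
#' Per-subject seeds are derived deterministically from `seed`, so the cohort
#' is fully reproducible.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param prevalence fraction of CMB-positive subjects, in [0, 1].
#' @param spec_template a [phantom_spec] used for all subjects.
#' @param seed integer cohort seed.
#' @param n_cmbs_range integer interval for per-positive-subject CMB counts.
#' @return A list of `phantom_subject`s with a `manifest` attribute
#'   (data.frame: subject_id, has_cmb, n_cmbs, seed).
#' @export
generate_cohort <- function(n_subjects, prevalence,
                            spec_template = phantom_spec(), seed = 1L,
                            n_cmbs_range = c(2L, 6L)) {
  if (n_subjects < 1L) stop("'n_subjects' must be at least 1")
  if (prevalence < 0 || prevalence > 1) stop("'prevalence' must be in [0, 1]")
  n_pos <- round(prevalence * n_subjects)
  with_seed(seed, {
    pos <- if (n_pos > 0) sample(n_subjects, n_pos) else integer(0)
    counts <- integer(n_subjects)
    counts[pos] <- sample(seq.int(n_cmbs_range[1], n_cmbs_range[2]),
                          n_pos, replace = TRUE)
    seeds <- vapply(seq_len(n_subjects), function(i) derive_seed(seed, i),
                    integer(1))
    subjects <- lapply(seq_len(n_subjects), function(i) {
      sp <- spec_template
      sp$n_cmbs <- counts[i]
      sp$seed <- seeds[i]
      generate_phantom(sp)
    })
    names(subjects) <- sprintf("subj%03d", seq_len(n_subjects))
    attr(subjects, "manifest") <- data.frame(
      subject_id = names(subjects),
      has_cmb = counts > 0L,
      n_cmbs = counts,
      seed = seeds,
      stringsAsFactors = FALSE)
    subjects
  })
}

#' Write a phantom subject to NIfTI files
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory (created if needed).
#' @param id subject identifier used as file prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_phantom <- function(subject, dir, id = "subj001") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(id, "_swi.nii.gz")),
             mask = file.path(dir, paste0(id, "_mask.nii.gz")),
             truth = file.path(dir, paste0(id, "_truth.nii.gz")))
  write_volume(subject$image, paths["image"])
  write_volume(subject$brain_mask * 1, paths["mask"], reference = subject$image)
  write_volume(subject$cmb_truth, paths["truth"], reference = subject$image)
  invisible(paths)
}

#' Write a phantom cohort with manifest and spec
#'
#' Writes each subject's image/mask/truth as NIfTI, a `manifest.csv`
#' (subject_id, has_cmb, n_cmbs, seed, paths) and the template spec as
#' `spec.yaml`.
#'
#' @param subjects result of [generate_cohort()].
#' @param dir output directory.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- attr(subjects, "manifest")
  if (is.null(man))
    man <- data.frame(subject_id = sprintf("subj%03d", seq_along(subjects)),
                      has_cmb = vapply(subjects, `[[`, TRUE, "has_cmb"),
                      n_cmbs = vapply(subjects, `[[`, 1L, "placed_cmb_count"),
                      seed = vapply(subjects, function(s) s$spec$seed, 1L))
  files <- t(vapply(seq_along(subjects), function(i)
    write_phantom(subjects[[i]], dir, man$subject_id[i]), character(3)))
  man$image_path <- files[, 1]
  man$mask_path <- files[, 2]
  man$truth_path <- files[, 3]
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(subjects[[1]]$spec), file.path(dir, "spec.yaml"))
  invisible(man)
}
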