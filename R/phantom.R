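#' Specification for a synthetic nasal-like voxel phantom
#'
#' The phantom is a desk-scale stand-in for a head CT: a tissue block with
#' an anterior exterior air slab, a protruding "nasal tip", two tube-like
#' air channels swept along a smooth anterior-superior-posterior arc that
#' merge into a posterior cavity (the oropharynx analogue).  One side may
#' carry a parametric constriction that multiplies the channel radius at
#' a configurable site, emulating a septal deviation.
#'
#' @param grid_shape integer length-3, voxels per axis (LR, AP, IS).
#' @param spacing_mm isotropic voxel edge length in mm.
#' @param channel_radius_mm nominal channel radius in mm.
#' @param radius_profile optional function of arc position `t` in `[0, 1]`
#'   returning the radius in mm (overrides `channel_radius_mm`).
#' @param constriction_side `"left"`, `"right"` or `"none"`.
#' @param constriction_factor multiplies the radius at the constriction
#'   site; in `(0, 1]` (1 = no constriction).
#' @param constriction_site,constriction_width arc position and Gaussian
#'   half-width of the constriction, as fractions of the channel length.
#' @param hu_air,hu_tissue Hounsfield values assigned to lumen and wall;
#'   must straddle the -460 HU segmentation threshold.
#' @param jitter_mm amplitude of the seeded sinusoidal centerline jitter.
#' @param seed integer seed for the jitter.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L), spacing_mm = 0.4,
                         channel_radius_mm = 1.2, radius_profile = NULL,
                         constriction_side = c("none", "left", "right"),
                         constriction_factor = 1,
                         constriction_site = 0.55, constriction_width = 0.12,
                         hu_air = -1000, hu_tissue = 40,
                         jitter_mm = 0.15, seed = 1L) {
  constriction_side <- match.arg(constriction_side)
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be three axis lengths of at least 8 voxels")
  if (!is.finite(spacing_mm) || spacing_mm <= 0) stop("spacing must be > 0")
  if (!is.finite(constriction_factor) ||
      constriction_factor <= 0 || constriction_factor > 1)
    stop("constriction_factor must lie in (0, 1]")
  if (!(hu_air < -460 && -460 < hu_tissue))
    stop("hu_air must be below and hu_tissue above the -460 HU threshold")
  if (channel_radius_mm <= 0) stop("channel_radius_mm must be > 0")
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 channel_radius_mm = channel_radius_mm,
                 radius_profile = radius_profile,
                 constriction_side = constriction_side,
                 constriction_factor = constriction_factor,
                 constriction_site = constriction_site,
                 constriction_width = constriction_width,
                 hu_air = hu_air, hu_tissue = hu_tissue,
                 jitter_mm = jitter_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# fractional layout of the phantom inside its grid; shared with the
# probe-scale defaults so the inlet sphere always fits anterior of the tip
.phantom_layout <- function(spec) {
  g <- spec$grid_shape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  list(
    cx = (nx + 1) / 2,
    tip_j = round(0.20 * ny), tip_k = round(0.28 * nz),
    face_j = round(0.265 * ny),
    nostril_k = round(0.28 * nz), nostril_off = max(4L, round(0.0625 * nx)),
    chan_end_j = round(0.84 * ny), chan_end_k = round(0.34 * nz),
    arch = 0.19 * nz,
    cavity = list(i = round(c(0.33, 0.67) * nx),
                  j = c(round(0.75 * ny), ny - 2L),
                  k = round(c(0.125, 0.39) * nz))
  )
}

#' Build a voxel phantom volume
#'
#' Constructs the Hounsfield volume described by a [phantom_spec()].  The
#' returned volume carries a `truth` attribute with the constructed lumen
#' masks, tip voxel and cavity box, which downstream tests use as the
#' segmentation oracle.
#'
#' @param spec a [phantom_spec()].
#' @return An [hu_volume()] with attribute `truth`, a list holding
#'   `lumen`, `lumen_left`, `lumen_right`, `exterior` (logical arrays),
#'   `tip_vox`, `face_j`, `nostril_centers` and `cavity_box`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  L <- .phantom_layout(spec)
  r0_vox <- spec$channel_radius_mm / spec$spacing_mm

  # sizing checks: the cavity must admit the phantom-scale probe cuboid
  # and the tip must sit at least one sphere radius inside the grid
  if (diff(L$cavity$i) < 2 * r0_vox + 4)
    stop("grid too small on the LR axis to contain the outlet cavity")
  if (L$cavity$j[2] - L$cavity$j[1] < 4)
    stop("grid too small on the AP axis to contain the outlet cavity")
  if (L$tip_j < 3)
    stop("grid too small on the AP axis to place the inlet sphere")

  vol <- array(spec$hu_tissue, dim = g)
  air <- array(FALSE, dim = g)

  # anterior exterior air slab
  air[, seq_len(L$face_j - 1L), ] <- TRUE

  # nasal tip: a slim midline tissue ridge protruding into the exterior
  # slab, narrow enough not to shadow the nostril apertures
  for (j in L$tip_j:(L$face_j - 1L)) {
    xh <- 1 + 0.35 * (j - L$tip_j)
    zh <- 1 + 0.9 * (j - L$tip_j)
    ii <- which(abs(seq_len(nx) - L$cx) <= xh)
    kk <- which(abs(seq_len(nz) - L$tip_k) <= zh)
    air[ii, j, kk] <- FALSE
  }
  tip_vox <- c(round(L$cx), L$tip_j, L$tip_k)

  # swept channels
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(spec$seed)
  phase <- runif(4, 0, 2 * pi)
  jit_vox <- spec$jitter_mm / spec$spacing_mm

  lumen_side <- list()
  nostril_centers <- list()
  for (s in c("right", "left")) {
    sg <- if (s == "left") 1 else -1
    side_air <- array(FALSE, dim = g)
    nt <- max(200L, 4L * (L$chan_end_j - L$face_j))
    tt <- seq(0, 1, length.out = nt)
    merge_w <- pmin(1, pmax(0, (tt - 0.75) / 0.22))^2
    xoff <- sg * (L$nostril_off * (1 - merge_w) + 1.5 * merge_w)
    xc <- L$cx + xoff +
      jit_vox * sin(3 * pi * tt + phase[1 + (s == "left")])
    yc <- L$face_j + (L$chan_end_j - L$face_j) * tt
    zc <- L$nostril_k + (L$chan_end_k - L$nostril_k) * tt +
      L$arch * sin(pi * tt) +
      jit_vox * sin(2.5 * pi * tt + phase[3 + (s == "left")])
    r_mm <- if (is.null(spec$radius_profile)) {
      rep(spec$channel_radius_mm, nt)
    } else {
      vapply(tt, spec$radius_profile, numeric(1))
    }
    if (spec$constriction_side == s && spec$constriction_factor < 1) {
      dip <- exp(-((tt - spec$constriction_site) /
                     spec$constriction_width)^2)
      r_mm <- r_mm * (1 - (1 - spec$constriction_factor) * dip)
    }
    r_vox <- r_mm / spec$spacing_mm
    for (p in seq_len(nt)) {
      r <- r_vox[p]
      ii <- max(1L, floor(xc[p] - r)):min(nx, ceiling(xc[p] + r))
      jj <- max(1L, floor(yc[p] - r)):min(ny, ceiling(yc[p] + r))
      kk <- max(1L, floor(zc[p] - r)):min(nz, ceiling(zc[p] + r))
      dx2 <- (ii - xc[p])^2
      dy2 <- (jj - yc[p])^2
      dz2 <- (kk - zc[p])^2
      ball <- outer(dx2, dy2, "+")
      ball <- outer(ball, dz2, "+") <= r^2
      blk <- side_air[ii, jj, kk, drop = FALSE]
      blk[ball] <- TRUE
      side_air[ii, jj, kk] <- blk
    }
    lumen_side[[s]] <- side_air
    nostril_centers[[s]] <- c(L$cx + sg * L$nostril_off, L$face_j,
                              L$nostril_k)
  }

  # posterior outlet cavity (oropharynx analogue)
  cav <- L$cavity
  cavity <- array(FALSE, dim = g)
  cavity[cav$i[1]:cav$i[2], cav$j[1]:cav$j[2], cav$k[1]:cav$k[2]] <- TRUE

  exterior <- air # anterior slab minus the tip bump
  lumen <- (lumen_side$left | lumen_side$right | cavity) & !exterior
  # channels must not open onto the anterior slab inside tissue rows only:
  # lumen is everything carved posterior of the slab
  air <- exterior | lumen
  vol[air] <- spec$hu_air

  out <- hu_volume(vol, spacing = spec$spacing_mm)
  attr(out, "truth") <- list(
    lumen = lumen,
    lumen_left = lumen_side$left & !exterior & !cavity,
    lumen_right = lumen_side$right & !exterior & !cavity,
    cavity = cavity & !exterior,
    exterior = exterior,
    tip_vox = tip_vox, face_j = L$face_j,
    nostril_centers = nostril_centers,
    cavity_box = cav)
  attr(out, "phantom_spec") <- spec
  out
}

#' Phantom-scale probe defaults
#'
#' Patient-scale probes are a 70 mm inlet sphere and a 60 x 40 x 30 mm
#' oropharynx cuboid.  At phantom scale both shrink with the geometry:
#' the sphere diameter is computed from the phantom layout as the
#' smallest tip-centered sphere that fully encloses both nostril
#' apertures (plus half a millimetre of margin), mirroring how the
#' patient-scale 70 mm sphere swallows the whole anterior nose; the
#' cuboid scales with the head extent.
#'
#' @param spec a [phantom_spec()].
#' @return list with `sphere_diam_mm` and `cuboid_dims_mm`.
#' @export
phantom_probe_defaults <- function(spec) {
  L <- .phantom_layout(spec)
  r0 <- spec$channel_radius_mm / spec$spacing_mm
  reach_vox <- sqrt((L$nostril_off + r0 + 1)^2 +
                    (L$face_j - L$tip_j)^2 + (r0 + 1)^2)
  sphere_diam <- 2 * (reach_vox * spec$spacing_mm + 0.5)
  list(sphere_diam_mm = sphere_diam,
       cuboid_dims_mm = c(6, 4, 3) * (spec$spacing_mm / 0.4) *
         (spec$grid_shape[2] / 64))
}

# RNG bookkeeping so seeded generators do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
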