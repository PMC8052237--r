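#' Threshold a CT volume into an air mask
#'
#' Voxels at or below the Hounsfield cut are air (1), all others wall
#' (0).  The default cut of -460 HU separates the nasal lumen from soft
#' tissue; the boundary is inclusive, so a voxel at exactly -460 HU
#' counts as air.
#'
#' @param vol an [hu_volume()].
#' @param hu_cut Hounsfield threshold (inclusive), default -460.
#' @return logical array with the volume's `spacing` attribute.
#' @export
threshold_air <- function(vol, hu_cut = -460) {
  nbad <- sum(!is.finite(vol))
  if (nbad > 0)
    stop(nbad, " non-finite voxel value(s) in volume")
  out <- array(as.vector(vol) <= hu_cut, dim = dim(vol))
  attr(out, "spacing") <- voxel_spacing(vol)
  out
}

# 6-neighbourhood dilation of a logical 3D array
.dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Detect the nasal tip on an air mask
#'
#' Scans anterior to posterior and returns the first tissue voxel that
#' touches air, restricted to a central band of the left-right axis (the
#' protruding tip).  Ties are broken towards the midline, then towards
#' superior.
#'
#' @param air logical air mask (package axis convention: LR, AP, IS).
#' @param band_frac half-width of the central LR band as a fraction of
#'   the axis, default 0.25.
#' @return integer voxel coordinate `c(i, j, k)` of the tip.
#' @export
detect_tip <- function(air, band_frac = 0.25) {
  d <- dim(air)
  if (!any(!air)) stop("no tissue found: volume is all air")
  cx <- (d[1] + 1) / 2
  band <- abs(seq_len(d[1]) - cx) <= band_frac * d[1]
  near_air <- .dilate6(air)
  for (j in seq_len(d[2])) {
    cand <- (!air[, j, , drop = TRUE]) & near_air[, j, , drop = TRUE] &
      matrix(band, d[1], d[3])
    if (any(cand)) {
      ik <- which(cand, arr.ind = TRUE)
      ord <- order(abs(ik[, 1] - cx), -ik[, 2])
      best <- ik[ord[1], ]
      return(as.integer(c(best[1], j, best[2])))
    }
  }
  stop("no tissue adjacent to air found in the central band")
}

# voxel index set of a sphere given center (voxel coords) and radius (mm)
.sphere_voxels <- function(dim, spacing, center, radius_mm) {
  r_vox <- radius_mm / spacing
  lo <- floor(center - r_vox); hi <- ceiling(center + r_vox)
  for (ax in 1:3) {
    nm <- c("LR", "AP", "IS")[ax]
    if (lo[ax] < 1 || hi[ax] > dim[ax])
      stop("sphere exceeds grid bounds on the ", nm, " axis")
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- ((ii - center[1]) * spacing[1])^2
  dy2 <- ((jj - center[2]) * spacing[2])^2
  dz2 <- ((kk - center[3]) * spacing[3])^2
  ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_mm^2
  sel <- which(ball, arr.ind = TRUE)
  .grid_index(dim, ii[sel[, 1]], jj[sel[, 2]], kk[sel[, 3]])
}

.cuboid_voxels <- function(dim, spacing, center, dims_mm) {
  half_vox <- dims_mm / (2 * spacing)
  lo <- ceiling(center - half_vox); hi <- floor(center + half_vox)
  for (ax in 1:3) {
    nm <- c("LR", "AP", "IS")[ax]
    if (lo[ax] < 1 || hi[ax] > dim[ax])
      stop("cuboid exceeds grid bounds on the ", nm, " axis")
  }
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  gg <- expand.grid(i = ii, j = jj, k = kk)
  .grid_index(dim, gg$i, gg$j, gg$k)
}

#' Place the inlet sphere and oropharynx cuboid probe regions
#'
#' The sphere is centered at the detected nasal tip (patient-scale
#' default diameter 70 mm).  The cuboid (patient-scale default
#' 60 x 40 x 30 mm) is centered on the centroid of the most inferior
#' connected air slab posterior to the channel junction, the oropharynx
#' analogue.
#'
#' @param air logical air mask with a `spacing` attribute (mm).
#' @param tip tip voxel coordinate from [detect_tip()].
#' @param sphere_diam_mm inlet sphere diameter in mm.
#' @param cuboid_dims_mm cuboid edge lengths (LR, AP, IS) in mm.
#' @param posterior_frac fraction of the tip-to-posterior extent behind
#'   which the oropharynx is sought.
#' @param slab_thickness thickness (voxels) of the inferior air slab used
#'   for the cuboid centroid.
#' @return a `probe_set`: list with `sphere` (center, diameter_mm,
#'   voxels) and `cuboid` (center, dims_mm, voxels).
#' @export
place_probes <- function(air, tip, sphere_diam_mm = 70,
                         cuboid_dims_mm = c(60, 40, 30),
                         posterior_frac = 0.6, slab_thickness = 3L) {
  d <- dim(air)
  spacing <- attr(air, "spacing")
  if (is.null(spacing)) stop("air mask has no spacing attribute")
  sph_vox <- .sphere_voxels(d, spacing, tip, sphere_diam_mm / 2)

  j_post <- ceiling(tip[2] + posterior_frac * (d[2] - tip[2]))
  post <- array(FALSE, d)
  post[, j_post:d[2], ] <- TRUE
  cand <- air & post
  if (!any(cand)) stop("no air found posterior to the channel junction")
  kk <- which(apply(cand, 3, any))
  k_lo <- min(kk)
  slab <- cand
  slab[, , -(k_lo:min(d[3], k_lo + slab_thickness - 1L))] <- FALSE
  # most inferior connected slab: component containing the lowest voxel
  seed <- which(slab)[1]
  comp <- flood26_cpp(as.vector(slab), d, seed)
  ijk <- .index_to_ijk(d, which(comp))
  center <- colMeans(ijk)
  cub_vox <- .cuboid_voxels(d, spacing, center, cuboid_dims_mm)
  if (!any(air[cub_vox]))
    stop("cuboid does not overlap the air mask")

  structure(list(
    sphere = list(center = tip, diameter_mm = sphere_diam_mm,
                  voxels = sph_vox),
    cuboid = list(center = center, dims_mm = cuboid_dims_mm,
                  voxels = cub_vox)),
    class = "probe_set")
}

#' Region-grow the nasal airway from the oropharynx
#'
#' Keeps exactly the 26-connected air component containing a seed inside
#' the cuboid.  Exterior air outside the inlet sphere is first excluded
#' (flood fill from the anterior face restricted to outside-sphere
#' voxels), so the grown component is the nasal lumen plus the exterior
#' air inside the sphere.  The fluid voxels adjacent to the removed
#' exterior form the open (ambient pressure) boundary on the sphere
#' surface.
#'
#' @param air logical air mask with `spacing` attribute.
#' @param probes a `probe_set` from [place_probes()].
#' @return an `airspace_domain`: list with `air_mask`, `tip`, `sphere`,
#'   `cuboid`, `open_cells`, `face_j`, `blocked_side`, `plug_voxels`,
#'   `spacing`.
#' @export
grow_airway <- function(air, probes) {
  d <- dim(air)
  spacing <- attr(air, "spacing")
  sphere_mask <- array(FALSE, d)
  sphere_mask[probes$sphere$voxels] <- TRUE

  # exterior air outside the sphere, reached from the anterior face
  face_idx <- which(air[, 1, , drop = TRUE] & !sphere_mask[, 1, , drop = TRUE])
  ext <- array(FALSE, d)
  if (length(face_idx) > 0) {
    ik <- arrayInd(face_idx, d[c(1, 3)])
    seeds <- .grid_index(d, ik[, 1], 1L, ik[, 2])
    allowed <- air & !sphere_mask
    ext <- flood26_cpp(as.vector(allowed), d, seeds)
  }

  domain <- air & !ext
  seed_cands <- probes$cuboid$voxels[air[probes$cuboid$voxels]]
  if (length(seed_cands) == 0)
    stop("region-growing seed is not air: cuboid contains no air voxels")
  comp <- flood26_cpp(as.vector(domain), d, seed_cands[1])
  comp <- array(comp, d)

  # open boundary: component voxels 6-adjacent to removed exterior air;
  # when the input mask was already clipped to the sphere (no exterior
  # left) the boundary falls back to the component's sphere-surface shell
  open_cells <- which(comp & .dilate6(array(ext, d)) & !ext)
  if (length(open_cells) == 0) {
    r_mm <- probes$sphere$diameter_mm / 2
    shell <- .sphere_voxels(d, spacing, probes$sphere$center, r_mm)
    ijk <- .index_to_ijk(d, shell)
    dist <- sqrt(colSums((t(ijk) - probes$sphere$center)^2)) * spacing[1]
    open_cells <- shell[dist > r_mm - 1.5 * spacing[1] & comp[shell]]
  }
  if (length(open_cells) == 0 || !any(comp[probes$sphere$voxels]))
    stop("no airway path: grown component does not reach the sphere surface")

  # anterior tissue face: first AP slab that is mostly tissue in the
  # ungrown mask (used later to locate the nostril apertures)
  frac <- apply(air, 2, mean)
  face_j <- which(frac < 0.5)[1]
  if (is.na(face_j)) face_j <- 1L

  attr(comp, "spacing") <- spacing
  structure(list(air_mask = comp, tip = probes$sphere$center,
                 sphere = probes$sphere, cuboid = probes$cuboid,
                 open_cells = open_cells, face_j = face_j,
                 blocked_side = "none", plug_voxels = integer(0),
                 spacing = spacing),
            class = "airspace_domain")
}

#' @export
print.airspace_domain <- function(x, ...) {
  cat(sprintf(
    "<airspace_domain> %s voxels air, %d open-boundary cells, blocked: %s\n",
    format(sum(x$air_mask)), length(x$open_cells), x$blocked_side))
  invisible(x)
}

#' Block one nostril of an extracted airway
#'
#' Converts a plug of air voxels at the side's nostril aperture (the most
#' anterior air slabs of that side, just behind the tissue face) to wall,
#' then re-grows connectivity from the cuboid.  The remaining open side
#' must still connect the sphere surface to the cuboid.  A user-supplied
#' `plug_mask` overrides the automatic aperture search.
#'
#' @param domain an `airspace_domain`.
#' @param side `"left"`, `"right"` or `"none"` (identity).
#' @param thickness plug depth in voxels along the AP axis.
#' @param plug_mask optional logical array marking the plug voxels.
#' @return the modified `airspace_domain`.
#' @export
block_nostril <- function(domain, side = c("none", "left", "right"),
                          thickness = 3L, plug_mask = NULL) {
  side <- match.arg(side)
  if (side == "none") return(domain)
  d <- dim(domain$air_mask)
  cx <- (d[1] + 1) / 2
  if (is.null(plug_mask)) {
    side_sel <- array(FALSE, d)
    if (side == "left") side_sel[seq_len(d[1]) > cx, , ] <- TRUE
    else side_sel[seq_len(d[1]) < cx, , ] <- TRUE
    jr <- domain$face_j:min(d[2], domain$face_j + thickness - 1L)
    plug_mask <- array(FALSE, d)
    plug_mask[, jr, ] <- TRUE
    plug_mask <- plug_mask & side_sel & domain$air_mask
  } else {
    plug_mask <- plug_mask & domain$air_mask
  }
  if (!any(plug_mask))
    stop("no aperture voxels found for side ", side)

  new_air <- domain$air_mask & !plug_mask
  seed_cands <- domain$cuboid$voxels[new_air[domain$cuboid$voxels]]
  if (length(seed_cands) == 0)
    stop("no airway path: cuboid contains no air after blocking")
  comp <- array(flood26_cpp(as.vector(new_air), d, seed_cands[1]), d)
  open_keep <- domain$open_cells[comp[domain$open_cells]]
  if (length(open_keep) == 0)
    stop("no airway path: blocking disconnected the sphere from the cuboid")

  attr(comp, "spacing") <- domain$spacing
  domain$air_mask <- comp
  domain$open_cells <- open_keep
  domain$blocked_side <- side
  domain$plug_voxels <- which(plug_mask)
  domain
}

#' Full automatic air-space extraction
#'
#' Thresholding, tip detection, probe placement and region growing in
#' one call.
#'
#' @param vol an [hu_volume()].
#' @param hu_cut Hounsfield threshold, default -460.
#' @param sphere_diam_mm,cuboid_dims_mm probe sizes in mm; defaults are
#'   patient scale (70 mm; 60 x 40 x 30 mm).  For phantoms use
#'   [phantom_probe_defaults()].
#' @param block nostril to block (`"none"`, `"left"`, `"right"`).
#' @param ... passed to [place_probes()].
#' @return an `airspace_domain`.
#' @export
extract_airspace <- function(vol, hu_cut = -460, sphere_diam_mm = 70,
                             cuboid_dims_mm = c(60, 40, 30),
                             block = "none", ...) {
  air <- threshold_air(vol, hu_cut)
  tip <- detect_tip(air)
  probes <- place_probes(air, tip, sphere_diam_mm, cuboid_dims_mm, ...)
  domain <- grow_airway(air, probes)
  block_nostril(domain, block)
}
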