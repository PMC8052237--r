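#' The four-curve rhinomanometry plot palette
#'
#' RGB triples used to draw (and later threshold out) the four AAR curves
#' of a two-sided congested/decongested examination.  These are the
#' standard plot colors the digitizer separates with a +/-10 per-channel
#' tolerance; they are pairwise more than 10 counts apart in at least one
#' channel, so the tolerance boxes never overlap.
#'
#' @return named list of integer RGB triples.
#' @export
aar_palette <- function() {
  list(congested_right   = c(255L, 223L, 204L),
       congested_left    = c(103L, 148L, 198L),
       decongested_right = c(232L, 138L, 135L),
       decongested_left  = c(193L, 218L, 242L))
}

#' Render AAR curves to an RGB raster with axis calibration
#'
#' Draws each curve in a flat (non-anti-aliased) color on a white
#' background, so every non-background curve pixel carries exactly the
#' assigned RGB triple.  The calibration metadata records two pixel/data
#' reference points per axis, which [calibrate_points()] inverts.
#'
#' @param curves an `aar_curve` (possibly several side/state groups).
#' @param palette named list of RGB triples; names must match the
#'   curve groups as `"<state>_<side>"`.  Defaults to [aar_palette()].
#' @param width,height image size in pixels (the reference digitization
#'   worked at 847 x 757).
#' @param dpi nominal raster density recorded in the metadata.
#' @param mode `"line"` connects points with a stroked polyline;
#'   `"points"` stamps a disc per sample (recording-style scatter).
#' @param linewidth stroke width in pixels for `mode = "line"`.
#' @param marker_radius disc radius in pixels for `mode = "points"`.
#' @param xlim,ylim data limits (flow ml/s, pressure Pa); default spans
#'   the data symmetrically.
#' @param margin_px margin around the plotting area.
#' @return An `aar_plot`: list with `image` (integer array
#'   height x width x 3, 0-255), `calibration` (two reference points per
#'   axis), `palette`, `dpi`.
#' @export
render_aar_plot <- function(curves, palette = aar_palette(),
                            width = 847L, height = 757L, dpi = 200,
                            mode = c("line", "points"),
                            linewidth = 3L, marker_radius = 4L,
                            xlim = NULL, ylim = NULL, margin_px = 60L) {
  mode <- match.arg(mode)
  if (nrow(curves) > 0) curves <- aar_curve(curves)

  # palette ambiguity guard: tolerance boxes (+/-10) must not overlap
  labs <- names(palette)
  if (length(labs) >= 2) {
    for (a in seq_along(labs)) for (b in seq_along(labs)) {
      if (a < b && all(abs(palette[[a]] - palette[[b]]) <= 20))
        stop("palette colors '", labs[a], "' and '", labs[b],
             "' are within the +/-10 tolerance of each other")
    }
  }

  if (is.null(xlim)) {
    mx <- if (nrow(curves)) max(abs(curves$flow_ml_s), 1) else 625
    xlim <- c(-mx, mx) * 1.05
  }
  if (is.null(ylim)) {
    my <- if (nrow(curves)) max(abs(curves$pressure_pa), 1) else 600
    ylim <- c(-my, my) * 1.05
  }

  img <- array(255L, dim = c(height, width, 3L))
  x_px <- function(v) margin_px + (v - xlim[1]) / diff(xlim) *
    (width - 2 * margin_px)
  y_px <- function(v) height - margin_px - (v - ylim[1]) / diff(ylim) *
    (height - 2 * margin_px)

  stamp <- function(px, py, rgb, rad) {
    px <- round(px); py <- round(py)
    for (dx in -rad:rad) for (dy in -rad:rad) {
      if (dx * dx + dy * dy > rad * rad) next
      cx <- px + dx; cy <- py + dy
      ok <- cx >= 1 & cx <= width & cy >= 1 & cy <= height
      if (any(ok)) {
        idx <- cbind(cy[ok], cx[ok])
        img[cbind(idx, 1L)] <<- rgb[1]
        img[cbind(idx, 2L)] <<- rgb[2]
        img[cbind(idx, 3L)] <<- rgb[3]
      }
    }
  }

  # axes in black through the data origin
  img[round(y_px(0)), margin_px:(width - margin_px), ] <- 0L
  img[margin_px:(height - margin_px), round(x_px(0)), ] <- 0L

  if (nrow(curves)) {
    groups <- split(curves, paste(curves$state, curves$side, sep = "_"))
    for (gname in names(groups)) {
      rgb <- palette[[gname]]
      if (is.null(rgb))
        stop("no palette color assigned to curve group '", gname, "'")
      gc <- groups[[gname]]
      if (mode == "points") {
        stamp(x_px(gc$flow_ml_s), y_px(gc$pressure_pa), rgb,
              marker_radius)
      } else {
        gc <- gc[order(gc$flow_ml_s), ]
        px <- x_px(gc$flow_ml_s); py <- y_px(gc$pressure_pa)
        rad <- max(0L, floor(linewidth / 2))
        for (i in seq_len(nrow(gc) - 1)) {
          n <- max(2, ceiling(max(abs(px[i + 1] - px[i]),
                                  abs(py[i + 1] - py[i]))) + 1)
          stamp(seq(px[i], px[i + 1], length.out = n),
                seq(py[i], py[i + 1], length.out = n), rgb, rad)
        }
        if (nrow(gc) == 1) stamp(px, py, rgb, rad)
      }
    }
  }

  calib <- list(
    x = data.frame(px = c(x_px(xlim[1]), x_px(xlim[2])),
                   value = c(xlim[1], xlim[2])),
    y = data.frame(py = c(y_px(ylim[1]), y_px(ylim[2])),
                   value = c(ylim[1], ylim[2])))
  structure(list(image = img, calibration = calib, palette = palette,
                 dpi = dpi), class = "aar_plot")
}

#' Write an AAR plot as PNG with a JSON calibration sidecar
#'
#' @param plot an `aar_plot` from [render_aar_plot()].
#' @param path PNG output path; the calibration is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_aar_plot_png <- function(plot, path) {
  stopifnot(inherits(plot, "aar_plot"))
  png::writePNG(plot$image / 255, path, dpi = plot$dpi)
  jsonlite::write_json(
    list(calibration = plot$calibration,
         palette = plot$palette, dpi = plot$dpi),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plot PNG (plus optional calibration sidecar)
#' @param path PNG path written by [write_aar_plot_png()] or any 8-bit
#'   RGB image.
#' @return An `aar_plot` (calibration present only if the sidecar is
#'   found).
#' @export
read_aar_plot_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3L))
  img <- array(as.integer(round(arr[, , 1:3] * 255)), dim = c(dim(arr)[1:2], 3L))
  side <- paste0(path, ".json")
  calib <- NULL
  palette <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    calib <- list(x = as.data.frame(meta$calibration$x),
                  y = as.data.frame(meta$calibration$y))
    palette <- lapply(meta$palette, as.integer)
  }
  structure(list(image = img, calibration = calib, palette = palette,
                 dpi = NA_real_), class = "aar_plot")
}
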