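#' Digitizer configuration
#'
#' @param color_specs named list of RGB triples (labels to extract), e.g.
#'   [aar_palette()].
#' @param tolerance per-channel color tolerance (inclusive), default 10.
#' @param window discretization window edge in pixels, default 5.
#' @param calibration list with elements `x` (data frame `px`, `value`)
#'   and `y` (`py`, `value`), two reference points each.
#' @return a `digitizer_config`.
#' @export
digitizer_config <- function(color_specs = aar_palette(), tolerance = 10,
                             window = 5L, calibration = NULL) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  if (window < 1) stop("window must be >= 1")
  if (!is.null(calibration)) .check_calibration(calibration)
  structure(list(color_specs = color_specs, tolerance = tolerance,
                 window = as.integer(window), calibration = calibration),
            class = "digitizer_config")
}

.check_calibration <- function(calibration) {
  for (ax in c("x", "y")) {
    ref <- calibration[[ax]]
    if (is.null(ref) || nrow(ref) != 2)
      stop("calibration needs two reference points per axis")
    pcol <- if (ax == "x") "px" else "py"
    if (ref[[pcol]][1] == ref[[pcol]][2] || ref$value[1] == ref$value[2])
      stop("degenerate calibration on the ", ax,
           " axis: reference points coincide")
  }
  invisible(TRUE)
}

#' Threshold an image on one curve color
#'
#' A pixel is kept iff every channel lies within `tolerance` (inclusive)
#' of the spec triple.
#'
#' @param image an `aar_plot`, or an integer array height x width x 3
#'   with values 0-255.
#' @param rgb integer RGB triple.
#' @param tolerance per-channel tolerance, inclusive.
#' @return logical matrix (height x width).
#' @export
mask_color <- function(image, rgb, tolerance = 10) {
  img <- if (inherits(image, "aar_plot")) image$image else image
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3)
  abs(img[, , 1] - rgb[1]) <= tolerance &
    abs(img[, , 2] - rgb[2]) <= tolerance &
    abs(img[, , 3] - rgb[3]) <= tolerance
}

#' Reduce a pixel mask to one centroid per discretization window
#'
#' Tiles the mask into `window` x `window` cells; every cell containing
#' at least one kept pixel emits the centroid of its kept pixels.
#'
#' @param mask logical matrix (height x width), e.g. from
#'   [mask_color()].
#' @param window cell edge in pixels.
#' @return data frame with columns `px`, `py` (pixel coordinates,
#'   x = column, y = row), ordered by `px`.
#' @export
discretize_mask <- function(mask, window = 5L) {
  if (window < 1) stop("window must be >= 1")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(px = numeric(0), py = numeric(0)))
  cell <- paste((idx[, 1] - 1L) %/% window, (idx[, 2] - 1L) %/% window)
  px <- tapply(idx[, 2], cell, mean)
  py <- tapply(idx[, 1], cell, mean)
  out <- data.frame(px = as.numeric(px), py = as.numeric(py))
  out[order(out$px, out$py), , drop = FALSE]
}

#' Map pixel centroids to data coordinates
#'
#' Affine map per axis fixed by two reference points (pixel, value).
#'
#' @param centroids data frame with `px`, `py` from [discretize_mask()].
#' @param calibration list with `x` (`px`, `value`) and `y`
#'   (`py`, `value`) reference data frames, two rows each.
#' @return data frame with columns `flow_ml_s`, `pressure_pa`.
#' @export
calibrate_points <- function(centroids, calibration) {
  .check_calibration(calibration)
  cx <- calibration$x
  cy <- calibration$y
  sx <- (cx$value[2] - cx$value[1]) / (cx$px[2] - cx$px[1])
  sy <- (cy$value[2] - cy$value[1]) / (cy$py[2] - cy$py[1])
  data.frame(
    flow_ml_s = cx$value[1] + (centroids$px - cx$px[1]) * sx,
    pressure_pa = cy$value[1] + (centroids$py - cy$py[1]) * sy)
}

#' Digitize all configured curves from a plot image
#'
#' Runs [mask_color()], [discretize_mask()] and [calibrate_points()] for
#' every color spec in the configuration.
#'
#' @param image an `aar_plot` (e.g. from [read_aar_plot_png()]); its
#'   embedded calibration is used unless the config provides one.
#' @param config a [digitizer_config()].
#' @return data frame with columns `label`, `flow_ml_s`, `pressure_pa`.
#' @export
digitize_plot <- function(image, config = digitizer_config()) {
  calib <- config$calibration
  if (is.null(calib) && inherits(image, "aar_plot"))
    calib <- image$calibration
  if (is.null(calib)) stop("no axis calibration available")
  out <- lapply(names(config$color_specs), function(lab) {
    m <- mask_color(image, config$color_specs[[lab]], config$tolerance)
    cen <- discretize_mask(m, config$window)
    if (nrow(cen) == 0)
      return(data.frame(label = character(0), flow_ml_s = numeric(0),
                        pressure_pa = numeric(0)))
    cbind(label = lab, calibrate_points(cen, calib))
  })
  do.call(rbind, out)
}
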