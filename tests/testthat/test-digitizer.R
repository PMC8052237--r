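test_that("mask_color applies an inclusive per-channel tolerance", {
  img <- array(0L, dim = c(1, 3, 3))
  img[1, 1, ] <- c(103L, 148L, 198L) # exact palette color
  img[1, 2, ] <- c(103L, 148L, 209L) # blue off by 11
  img[1, 3, ] <- c(113L, 158L, 208L) # all channels off by exactly 10
  m <- mask_color(img, c(103, 148, 198), tolerance = 10)
  expect_equal(as.vector(m), c(TRUE, FALSE, TRUE))
})

test_that("discretize_mask emits one centroid per occupied window", {
  m <- matrix(FALSE, 20, 60)
  m[7, 13] <- TRUE
  one <- discretize_mask(m, 5)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$px, one$py), c(13, 7))
  # a 50-pixel horizontal line tiled by 5x5 windows gives 10 centroids
  m2 <- matrix(FALSE, 20, 60)
  m2[10, 1:50] <- TRUE
  ten <- discretize_mask(m2, 5)
  expect_equal(nrow(ten), 10)
  expect_equal(ten$py, rep(10, 10))
  # empty mask: empty result
  expect_equal(nrow(discretize_mask(matrix(FALSE, 5, 5), 5)), 0)
})

test_that("calibrate_points applies the affine axis maps", {
  calib <- list(x = data.frame(px = c(0, 100), value = c(0, 100)),
                y = data.frame(py = c(0, 100), value = c(0, 100)))
  pts <- calibrate_points(data.frame(px = 50, py = 25), calib)
  expect_equal(pts$flow_ml_s, 50)
  expect_equal(pts$pressure_pa, 25)
  # degenerate reference points
  bad <- list(x = data.frame(px = c(10, 10), value = c(0, 100)),
              y = calib$y)
  expect_error(calibrate_points(data.frame(px = 1, py = 1), bad),
               "degenerate")
})

test_that("the four-curve palette colors are pairwise separable at +/-10", {
  pal <- aar_palette()
  for (a in seq_along(pal)) for (b in seq_along(pal)) {
    if (a < b) expect_true(any(abs(pal[[a]] - pal[[b]]) > 20))
  }
})

test_that("rendering refuses ambiguous palette assignments", {
  cur <- synth_aar(rohrer_model(0.3, 0), 100)
  pal <- list(congested_left = c(100L, 100L, 100L),
              congested_right = c(105L, 105L, 105L))
  expect_error(render_aar_plot(cur, palette = pal), "tolerance")
})

test_that("rendered curve pixels carry exactly the assigned RGB", {
  m <- rohrer_model(k1 = 0.3, k2 = 5e-4, noise_sd = 0)
  cur <- synth_aar(m, seq(-600, 600, by = 10))
  pl <- render_aar_plot(cur, palette = aar_palette()["congested_left"])
  mk <- mask_color(pl, aar_palette()$congested_left, tolerance = 0)
  mk10 <- mask_color(pl, aar_palette()$congested_left, tolerance = 10)
  expect_gt(sum(mk), 500)
  expect_equal(sum(mk), sum(mk10)) # no anti-aliased halo
  # empty curve set gives a background-only image
  pl0 <- render_aar_plot(cur[0, ], palette = aar_palette())
  for (col in aar_palette())
    expect_equal(sum(mask_color(pl0, col)), 0)
})

test_that("render-digitize round trip recovers the curve within one window", {
  m <- rohrer_model(k1 = 0.25, k2 = 1 / 1200, noise_sd = 0)
  cur <- synth_aar(m, seq(-600, 600, by = 5))
  for (lab in names(aar_palette())) {
    parts <- strsplit(lab, "_")[[1]]
    cur2 <- cur
    cur2$state <- parts[1]; cur2$side <- parts[2]
    pl <- render_aar_plot(cur2, palette = aar_palette()[lab])
    path <- withr::local_tempfile(fileext = ".png")
    write_aar_plot_png(pl, path)
    rt <- read_aar_plot_png(path)
    expect_identical(rt$image, pl$image)
    pts <- digitize_plot(rt, digitizer_config(
      color_specs = aar_palette()[lab]))
    expect_gt(nrow(pts), 100)
    win_pa <- 5 * abs(diff(pl$calibration$y$value) /
                        diff(pl$calibration$y$py))
    win_ml <- 5 * abs(diff(pl$calibration$x$value) /
                        diff(pl$calibration$x$px))
    truth <- rohrer_pressure(0.25, 1 / 1200, pts$flow_ml_s)
    expect_lt(max(abs(pts$pressure_pa - truth)), win_pa + 1e-9)
    # flow spacing between adjacent points stays near one window too
    expect_lt(max(diff(sort(pts$flow_ml_s))), 3 * win_ml)
  }
})
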