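test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(constriction_factor = 0), "constriction_factor")
  expect_error(phantom_spec(constriction_factor = 1.2), "constriction_factor")
  expect_error(phantom_spec(spacing_mm = -1), "spacing")
  expect_error(phantom_spec(hu_air = -400), "threshold")
  expect_error(phantom_spec(hu_tissue = -500), "threshold")
})

test_that("symmetric phantom has balanced channels", {
  tr <- attr(default_phantom(), "truth")
  nl <- sum(tr$lumen_left)
  nr <- sum(tr$lumen_right)
  expect_lt(abs(nl - nr) / max(nl, nr), 0.02)
})

test_that("constriction scales the minimum cross-section area like factor^2", {
  # finer phantom so the discrete area ratio is meaningful
  base <- phantom_spec(grid_shape = c(96L, 96L, 96L), spacing_mm = 0.4,
                       channel_radius_mm = 2.4, jitter_mm = 0)
  con <- phantom_spec(grid_shape = c(96L, 96L, 96L), spacing_mm = 0.4,
                      channel_radius_mm = 2.4, jitter_mm = 0,
                      constriction_side = "right",
                      constriction_factor = 0.5)
  min_area <- function(spec, side) {
    tr <- attr(build_phantom(spec), "truth")
    m <- if (side == "right") tr$lumen_right else tr$lumen_left
    counts <- apply(m, 2, sum)
    jr <- which(counts > 0)
    jr <- jr[jr > quantile(jr, 0.2) & jr < quantile(jr, 0.8)]
    min(counts[jr])
  }
  ratio <- min_area(con, "right") / min_area(base, "right")
  expect_lt(abs(ratio - 0.25), 0.08)
  # untouched side unchanged
  expect_equal(min_area(con, "left"), min_area(base, "left"))
})

test_that("thresholding at -460 recovers the constructed lumen exactly", {
  vol <- default_phantom()
  tr <- attr(vol, "truth")
  air <- threshold_air(vol, -460)
  expect_true(all(air == (tr$lumen | tr$exterior)))
})

test_that("phantom construction is bit-identical under a fixed seed", {
  s <- phantom_spec(seed = 42L)
  v1 <- build_phantom(s)
  v2 <- build_phantom(s)
  expect_identical(as.vector(v1), as.vector(v2))
  v3 <- build_phantom(phantom_spec(seed = 43L))
  expect_false(all(as.vector(v1) == as.vector(v3)))
})

test_that("phantom sizing errors name the limiting dimension", {
  expect_error(phantom_spec(grid_shape = c(4L, 64L, 64L)), "at least 8")
  expect_error(build_phantom(phantom_spec(grid_shape = c(12L, 64L, 64L),
                                          channel_radius_mm = 3)),
               "LR")
})

test_that("Rohrer generator reproduces the closed-form pressures", {
  m <- rohrer_model(k1 = 0.5, k2 = 0, noise_sd = 0)
  expect_equal(synth_aar(m, 300)$pressure_pa, 150)
  m2 <- rohrer_model(k1 = 0, k2 = 0.001, noise_sd = 0)
  expect_equal(synth_aar(m2, 300)$pressure_pa, 90)
  # expiration quadrant: negative flow gives negative pressure
  expect_equal(synth_aar(m2, -300)$pressure_pa, -90)
})

test_that("Rohrer generator is deterministic under a fixed seed", {
  m <- rohrer_model(k1 = 0.3, k2 = 5e-4, noise_sd = 5, seed = 11L)
  a <- synth_aar(m, seq(-600, 600, by = 50))
  b <- synth_aar(m, seq(-600, 600, by = 50))
  expect_identical(a, b)
  rec1 <- synth_aar_recording(m)
  rec2 <- synth_aar_recording(m)
  expect_identical(rec1, rec2)
})

test_that("noise-free Rohrer pressure is strictly increasing in |flow|", {
  for (k in list(c(0.5, 0), c(0, 1e-3), c(0.2, 5e-4))) {
    q <- seq(0, 625, by = 25)
    p <- rohrer_pressure(k[1], k[2], q)
    expect_true(all(diff(p) > 0))
  }
})

test_that("synth_aar validates its inputs", {
  m <- rohrer_model(k1 = 0.5, k2 = 0)
  expect_error(synth_aar(m, numeric(0)), "empty")
  expect_error(synth_aar(m, 700), "625")
  expect_error(rohrer_model(k1 = 0, k2 = 0), "both")
  expect_error(rohrer_model(k1 = -1, k2 = 0), "non-negative")
  expect_error(rohrer_model(k1 = c(0.2, 0.4), k2 = 0,
                            state = c("congested", "decongested")),
               "congested")
})

test_that("rohrer_flow_at inverts the pressure law", {
  expect_equal(rohrer_flow_at(0.5, 0, 150), 300)
  q <- rohrer_flow_at(0.25, 1 / 1200, 150)
  expect_equal(rohrer_pressure(0.25, 1 / 1200, q), 150)
})
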