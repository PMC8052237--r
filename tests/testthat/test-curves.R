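mk_curve <- function(flow, pressure, subject = "S", side = "left",
                     state = "simulated") {
  aar_curve(data.frame(subject = subject, side = side, state = state,
                       flow_ml_s = flow, pressure_pa = pressure,
                       stringsAsFactors = FALSE))
}

test_that("bin_curve groups flows into half-open 50 ml/s bins", {
  b <- bin_curve(mk_curve(c(30, 60), c(100, 100)))
  expect_equal(b$bin_flow_ml_s, 50)
  expect_equal(b$n, 2)
  # negative flows mirror
  b2 <- bin_curve(mk_curve(-30, -80))
  expect_equal(b2$bin_flow_ml_s, -50)
  expect_equal(b2$phase, "expiration")
  # boundary value 25 joins the upper bin
  b3 <- bin_curve(mk_curve(c(25, 24.999), c(50, 50)))
  expect_equal(sort(b3$bin_flow_ml_s), c(0, 50))
})

test_that("bin aggregation takes means, then absolute values", {
  b <- bin_curve(mk_curve(c(40, 45, 55), c(100, 100, 100)))
  expect_equal(b$mean_pressure_pa, 100)
  expect_equal(b$sd, 0)
  expect_equal(b$n, 3)
  bneg <- bin_curve(mk_curve(c(-40, -45), c(-120, -100)))
  expect_equal(bneg$mean_pressure_pa, -110)
  expect_equal(bneg$abs_pressure_pa, 110)
})

test_that("binning conserves points", {
  set.seed(2)
  q <- runif(200, -620, 620)
  b <- bin_curve(mk_curve(q, 0.4 * q))
  expect_equal(sum(b$n), 200)
})

test_that("drop_nearzero removes only the near-zero pressure band", {
  b <- bin_curve(mk_curve(c(0, 50, 100), c(0, 30, 20)))
  kept <- drop_nearzero(b)
  # 0 Pa and 20 Pa fall inside (-25, 25); 30 Pa survives
  expect_equal(kept$bin_flow_ml_s, 50)
  expect_equal(kept$abs_pressure_pa, 30)
})

test_that("resistance150 follows the labelled-numerator rule", {
  r <- resistance150(mk_curve(300, 150))
  expect_equal(r$resistance_spa_ml, 0.5)
  r2 <- resistance150(mk_curve(c(200, 250), c(130, 170)))
  expect_equal(r2$mean_flow_ml_s, 225)
  expect_equal(r2$resistance_spa_ml, 150 / 225)
  # the actual-pressure variant divides the observed mean instead
  r3 <- resistance150(mk_curve(c(200, 250), c(130, 170)),
                      numerator = "actual")
  expect_equal(r3$resistance_spa_ml, 150 / 225) # mean(130,170) = 150
})

test_that("resistance150 analyzes inspiration only and handles gaps", {
  # expiration-only points in band: no inspiration record
  r <- resistance150(mk_curve(c(-300, 100), c(-150, 40)))
  expect_true(is.na(r$resistance_spa_ml))
  expect_equal(r$n_points, 0)
  # points outside [125, 175] never qualify
  r2 <- resistance150(mk_curve(c(300, 400), c(124.9, 175.1)))
  expect_true(is.na(r2$resistance_spa_ml))
})

test_that("resistance150 recovers 150/Q* from a noise-free Rohrer curve", {
  k1 <- 0.25; k2 <- 1 / 1200
  m <- rohrer_model(k1 = k1, k2 = k2, noise_sd = 0)
  cur <- synth_aar(m, seq(5, 620, by = 5))
  b <- bin_curve(cur)
  r <- resistance150(b)
  qstar <- rohrer_flow_at(k1, k2, 150)
  expect_lt(abs(r$resistance_spa_ml - 150 / qstar) / (150 / qstar),
            50 / qstar) # within one bin width of flow
})

test_that("choose_clinical_state picks the smaller log distance", {
  sim <- drop_nearzero(bin_curve(mk_curve(seq(50, 600, 50),
                                          0.5 * seq(50, 600, 50))))
  con <- sim; con$abs_pressure_pa <- 2.0 * sim$abs_pressure_pa
  dec <- sim; dec$abs_pressure_pa <- 1.1 * sim$abs_pressure_pa
  expect_equal(choose_clinical_state(con, dec, sim), "decongested")
  # identical decongested wins outright
  expect_equal(choose_clinical_state(con, sim, sim), "decongested")
  # exact tie goes to congested, with a message
  expect_message(st <- choose_clinical_state(dec, dec, sim), "tie")
  expect_equal(st, "congested")
})

test_that("choose_clinical_state needs at least three common bins", {
  sim <- drop_nearzero(bin_curve(mk_curve(c(100, 200), c(60, 120))))
  con <- drop_nearzero(bin_curve(mk_curve(c(100, 200), c(70, 130))))
  dec <- drop_nearzero(bin_curve(mk_curve(c(300, 400), c(70, 130))))
  expect_error(choose_clinical_state(con, dec, sim), "common bins")
})

test_that("extract_dp averages the probe regions", {
  dom <- default_domain()
  d <- dim(dom$air_mask)
  fld <- list(pressure = array(5, d),
              lattice = list(dx_m = 4e-4))
  class(fld) <- "pressure_field"
  expect_equal(extract_dp(fld, dom), 0) # uniform field
  # sphere high, cuboid low
  p <- array(NA_real_, d)
  p[dom$sphere$voxels] <- 10
  p[dom$cuboid$voxels] <- 2
  fld$pressure <- p
  expect_equal(extract_dp(fld, dom), 8)
  fld$pressure <- array(NA_real_, d)
  expect_error(extract_dp(fld, dom), "no fluid")
})
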