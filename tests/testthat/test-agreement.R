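mk_pairs <- function(rhino, sim, ...) {
  paired_measurements(data.frame(rhino_value = rhino, sim_value = sim, ...))
}

test_that("logdiff is the exact log10 ratio, row-wise", {
  p <- logdiff(mk_pairs(c(5, 50, 182), c(5, 5, 100)))
  expect_equal(p$logdiff, c(0, 1, log10(1.82)))
  expect_equal(10^p$logdiff, p$rhino_value / p$sim_value)
  expect_error(logdiff(mk_pairs(-1, 2)), "non-positive")
  expect_error(mk_pairs(0, 2), "non-positive")
})

test_that("bland_altman back-transforms mean and half-width to ratios", {
  # perfect agreement: mean 0, width 0, both ratios 1
  set.seed(1)
  v <- runif(20, 10, 500)
  ba <- bland_altman(mk_pairs(v, v), strata = character(0))
  expect_equal(ba$mean_logdiff, 0)
  expect_equal(ba$half_width, 0)
  expect_equal(ba$ratio_mean, 1)
  expect_equal(ba$ratio_half_width, 1)
  # the ratio columns are exactly 10^(log columns)
  set.seed(2)
  rh <- v * exp(rnorm(20, 0.1, 0.3))
  ba2 <- bland_altman(mk_pairs(rh, v), strata = character(0))
  expect_equal(ba2$ratio_mean, 10^ba2$mean_logdiff)
  expect_equal(ba2$ratio_half_width, 10^ba2$half_width)
  d <- log10(rh) - log10(v)
  expect_equal(ba2$mean_logdiff, mean(d))
  expect_equal(ba2$half_width, 1.96 * sd(d))
})

test_that("the printed agreement factors follow from the log deviations", {
  # 2% +/- 47% in log10 units corresponds to factors 1.05 and 2.95
  expect_equal(round(ratio_from_logdiff(0.02), 2), 1.05)
  expect_equal(round(ratio_from_logdiff(0.47), 2), 2.95)
  # 26% +/- 40% corresponds to 1.82 and 2.51
  expect_equal(round(ratio_from_logdiff(0.26), 2), 1.82)
  expect_equal(round(ratio_from_logdiff(0.40), 2), 2.51)
})

test_that("bland_altman strata partition the rows", {
  set.seed(3)
  n <- 40
  df <- mk_pairs(runif(n, 50, 400), runif(n, 50, 400),
                 side = sample(c("left", "right"), n, TRUE),
                 phase = sample(c("inspiration", "expiration"), n, TRUE))
  ba <- bland_altman(df)
  expect_equal(sum(ba$n), n)
  pts <- attr(ba, "points")
  expect_equal(nrow(pts), n)
  # under-filled strata are skipped with a warning
  df2 <- mk_pairs(c(100, 120, 90, 80), c(100, 100, 100, 100),
                  side = c("left", "left", "left", "right"))
  expect_warning(ba2 <- bland_altman(df2, strata = "side"), "skipped")
  expect_equal(ba2$side, "left")
})

test_that("adjusted_correlation reduces to plain Pearson for constant factors", {
  set.seed(4)
  lr <- runif(30, 30, 300)
  ls <- lr * exp(rnorm(30, 0, 0.2))
  df <- mk_pairs(lr, ls, subject = "A", side = "left",
                 phase = "inspiration")
  ac <- adjusted_correlation(df)
  expect_equal(ac$r, cor(log10(lr), log10(ls)), tolerance = 1e-12)
})

test_that("adjusted_correlation removes per-subject scale factors", {
  set.seed(5)
  sim <- runif(60, 20, 500)
  subject <- rep(c("A", "B", "C"), each = 20)
  cfac <- c(A = 0.7, B = 1.4, C = 2.9)[subject]
  df <- mk_pairs(cfac * sim, sim, subject = subject)
  ac <- adjusted_correlation(df, factors = "subject")
  expect_equal(ac$r, 1, tolerance = 1e-10)
  # invariance: rescaling one subject's clinical values changes nothing
  df2 <- df; sel <- df2$subject == "B"
  df2$rhino_value[sel] <- df2$rhino_value[sel] * 5
  ac2 <- adjusted_correlation(df2, factors = "subject")
  expect_equal(ac2$r, ac$r, tolerance = 1e-10)
})

test_that("adjusted_correlation stays near zero under independence", {
  set.seed(6)
  n <- 200
  df <- mk_pairs(exp(rnorm(n, 4, 0.5)), exp(rnorm(n, 4, 0.5)),
                 subject = sample(letters[1:5], n, TRUE),
                 side = sample(c("left", "right"), n, TRUE),
                 phase = sample(c("i", "e"), n, TRUE))
  ac <- adjusted_correlation(df)
  expect_lt(abs(ac$r), 0.2)
  expect_gt(ac$p, 1e-4)
})

test_that("pearson_corr matches the product-moment formula and categories", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 3, 2, 4, 5)
  pc <- pearson_corr(x, y)
  # brute-force formula as the oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r, r_oracle, tolerance = 1e-12)
  expect_equal(pearson_corr(x, 2 * x)$r, 1)
  expect_equal(pearson_corr(x, 2 * x)$category, "strong")
  # category boundaries assigned upward
  mk_r <- function(target) {
    set.seed(7)
    repeat {
      yy <- target * scale(x)[, 1] + sqrt(1 - target^2) * rnorm(6)
      if (abs(cor(x, yy) - target) < 0.02) return(yy)
    }
  }
  expect_equal(pearson_corr(x, mk_r(0.65))$category, "moderate")
  expect_error(pearson_corr(x, rep(1, 6)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("paired_ttest handles regular and degenerate inputs", {
  x <- c(0.5, 0.7, 0.6, 0.9, 0.4)
  same <- paired_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(inf <- paired_ttest(x + 1, x), "infinite")
  expect_equal(inf$t, Inf)
  # against the closed-form paired t as the oracle
  set.seed(8)
  a <- rnorm(10, 1, 0.3); b <- rnorm(10, 0.8, 0.3)
  res <- paired_ttest(a, b)
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(10))
  p_oracle <- 2 * pt(-abs(t_oracle), 9)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$mean_rhino, mean(a))
  expect_equal(res$sd_sim, sd(b))
  expect_error(paired_ttest(1, 1), "at least 2")
})
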