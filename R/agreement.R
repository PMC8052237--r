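#' Paired clinical/simulated measurements
#'
#' Validates a paired table for the agreement analysis: one row per key,
#' strictly positive values (the analysis works on log10 scale).
#'
#' @param df data frame with at least `rhino_value` and `sim_value`
#'   columns (pressures in Pa or resistances in sPa/ml), plus any
#'   stratum columns such as `subject`, `side`, `phase`, `bin_flow`.
#' @return the validated data frame, class `paired_measurements`.
#' @export
paired_measurements <- function(df) {
  need <- c("rhino_value", "sim_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing paired columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$rhino_value > 0 & df$sim_value > 0))
  if (length(bad))
    stop("non-positive value(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": log transform requires positive values")
  class(df) <- c("paired_measurements", "data.frame")
  df
}

#' Per-row log10 ratio of clinical to simulated values
#'
#' d = log10(rhino) - log10(sim); back-transforming gives the raw ratio
#' exactly, 10^d = rhino/sim.
#'
#' @param pairs a [paired_measurements()] table (or coercible).
#' @return the table with a `logdiff` column added.
#' @export
logdiff <- function(pairs) {
  pairs <- paired_measurements(as.data.frame(pairs))
  pairs$logdiff <- log10(pairs$rhino_value) - log10(pairs$sim_value)
  pairs
}

#' Back-transform a log10 deviation to a ratio factor
#' @param x mean (or half-width) of log10 differences.
#' @return 10^x, the proportional deviation factor.
#' @export
ratio_from_logdiff <- function(x) 10^x

#' Log-scale Bland-Altman agreement per stratum
#'
#' For each stratum the mean log10 ratio d and a dispersion half-width
#' `multiplier * sd(d)` are computed and back-transformed to ratio
#' factors: `10^mean` is the typical clinical/simulated ratio and
#' `10^half_width` its dispersion factor.  The per-row x-coordinate for
#' Bland-Altman plots (mean of the two log values) is attached as
#' attribute `points`.
#'
#' @param pairs a [paired_measurements()] table.
#' @param strata character vector of stratum columns, default side and
#'   respiration phase.
#' @param multiplier half-width multiplier on the log-difference
#'   standard deviation (sample sd, n-1); default 1.96.
#' @param min_n strata with fewer rows are skipped with a warning.
#' @return an `agreement_summary` data frame: stratum columns, `n`,
#'   `mean_logdiff`, `half_width`, `ratio_mean`, `ratio_half_width`.
#' @export
bland_altman <- function(pairs, strata = c("side", "phase"),
                         multiplier = 1.96, min_n = 3L) {
  pairs <- logdiff(pairs)
  strata <- intersect(strata, names(pairs))
  key <- if (length(strata))
    interaction(pairs[strata], drop = TRUE, sep = ":")
  else factor(rep("all", nrow(pairs)))
  groups <- split(pairs, key)
  rows <- list(); pts <- list()
  for (g in groups) {
    lab <- g[1, strata, drop = FALSE]
    rownames(lab) <- NULL
    if (nrow(g) < min_n) {
      warning("stratum ", paste(unlist(lab), collapse = "/"),
              " has fewer than ", min_n, " rows; skipped")
      next
    }
    m <- mean(g$logdiff)
    hw <- multiplier * stats::sd(g$logdiff)
    rows[[length(rows) + 1L]] <- cbind(
      lab, data.frame(n = nrow(g), mean_logdiff = m, half_width = hw,
                      ratio_mean = ratio_from_logdiff(m),
                      ratio_half_width = ratio_from_logdiff(hw)))
    lab_rep <- lab[rep(1L, nrow(g)), , drop = FALSE]
    rownames(lab_rep) <- NULL
    pts[[length(pts) + 1L]] <- cbind(
      lab_rep, data.frame(
        x = (log10(g$rhino_value) + log10(g$sim_value)) / 2,
        d = g$logdiff))
  }
  if (length(rows) == 0) {
    out <- data.frame(n = integer(0), mean_logdiff = numeric(0),
                      half_width = numeric(0), ratio_mean = numeric(0),
                      ratio_half_width = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "points") <- do.call(rbind, pts)
  }
  class(out) <- c("agreement_summary", "data.frame")
  out
}

#' Correlation after removing categorical factor variation
#'
#' Residualizes log10(rhino) and log10(sim) each on an additive model of
#' the given categorical factors (least squares on indicator variables)
#' and returns the Pearson correlation of the residuals, i.e. the
#' clinical/simulated correlation after removing variation due to
#' subjects, nasal sides and respiration phases.  The p-value uses the t
#' transform with `n - (estimated coefficients) - 1` degrees of freedom.
#'
#' @param pairs a [paired_measurements()] table.
#' @param factors categorical adjustment columns present in `pairs`;
#'   constant factors drop out (the result then equals the plain Pearson
#'   correlation of the logs).
#' @return list with `r`, `p`, `df`, `n`.
#' @export
adjusted_correlation <- function(pairs,
                                 factors = c("subject", "side", "phase")) {
  pairs <- paired_measurements(as.data.frame(pairs))
  factors <- intersect(factors, names(pairs))
  lr <- log10(pairs$rhino_value)
  ls <- log10(pairs$sim_value)
  keep <- vapply(factors, function(f) length(unique(pairs[[f]])) > 1,
                 logical(1))
  factors <- factors[keep]
  if (length(factors)) {
    fml <- stats::as.formula(paste(
      "y ~", paste(sprintf("factor(%s)", factors), collapse = " + ")))
    dat <- pairs[factors]
    fit_r <- stats::lm(fml, data = cbind(y = lr, dat))
    fit_s <- stats::lm(fml, data = cbind(y = ls, dat))
    if (fit_r$rank < length(stats::coef(fit_r)))
      stop("rank-deficient factor design")
    rr <- stats::resid(fit_r); rs <- stats::resid(fit_s)
    p_used <- fit_r$rank
  } else {
    rr <- lr - mean(lr); rs <- ls - mean(ls)
    p_used <- 1
  }
  n <- length(rr)
  dfree <- n - p_used - 1
  if (dfree < 1) stop("not enough rows for the factor adjustment")
  if (stats::sd(rr) == 0 || stats::sd(rs) == 0)
    stop("zero residual variance: correlation undefined")
  r <- stats::cor(rr, rs)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(dfree / (1 - r^2))
    2 * stats::pt(-abs(tval), dfree)
  }
  list(r = r, p = p, df = dfree, n = n)
}

#' Pearson correlation with clinical strength category
#'
#' Standard product-moment correlation with a two-sided p-value, plus
#' the conventional strength category: strong (r >= 0.8), moderate
#' (0.6 <= r < 0.8), weak (r < 0.6); boundaries assigned upward.
#'
#' @param x,y numeric vectors, length at least 3.
#' @return list with `r`, `p`, `category`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  cat_lab <- if (r >= 0.8) "strong" else if (r >= 0.6) "moderate" else "weak"
  list(r = r, p = ct$p.value, category = cat_lab, n = length(x))
}

#' Paired t-test with per-method summaries
#'
#' Paired t on the differences, reporting each vector's mean and sd
#' ("mean +/- sd" style).  Degenerate inputs are handled explicitly:
#' identical vectors give t = 0, p = 1; constant non-zero differences
#' give infinite t with a warning.
#'
#' @param rhino,sim equal-length paired vectors (n >= 2); NA pairs are
#'   dropped.
#' @return list with `t`, `p`, `df`, `mean_rhino`, `sd_rhino`,
#'   `mean_sim`, `sd_sim`, `mean_diff`, `n`.
#' @export
paired_ttest <- function(rhino, sim) {
  if (length(rhino) != length(sim)) stop("vectors must have equal length")
  ok <- stats::complete.cases(rhino, sim)
  rhino <- rhino[ok]; sim <- sim[ok]
  n <- length(rhino)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- rhino - sim
  base <- list(mean_rhino = mean(rhino), sd_rhino = stats::sd(rhino),
               mean_sim = mean(sim), sd_sim = stats::sd(sim),
               mean_diff = mean(d), n = n)
  if (stats::sd(d) <= 1e-9 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12)
      return(c(list(t = 0, p = 1, df = n - 1), base))
    warning("all differences identical and non-zero: t is infinite")
    return(c(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1), base))
  }
  tt <- stats::t.test(rhino, sim, paired = TRUE)
  c(list(t = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter)), base)
}
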