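#' Rohrer model for synthetic rhinomanometry curves
#'
#' The Rohrer equation Dp = k1*Q + k2*Q*|Q| is the classical empirical
#' pressure-flow law for airway resistance and serves here as the
#' generator of synthetic clinical AAR data.  Coefficients are stored per
#' side and congestion state; Gaussian noise of standard deviation
#' `noise_sd` (Pa) is added to pressure only, flow being the controlled
#' variable.
#'
#' @param k1 linear coefficient(s), Pa per (ml/s); recycled against
#'   `side`/`state`.
#' @param k2 quadratic coefficient(s), Pa per (ml/s)^2.
#' @param side,state character vectors labelling each coefficient row.
#' @param noise_sd pressure noise standard deviation in Pa.
#' @param seed integer seed; generation is deterministic given the model.
#' @return A `rohrer_model` with a `coefs` data frame.
#' @export
rohrer_model <- function(k1, k2, side = "left", state = "congested",
                         noise_sd = 0, seed = 1L) {
  coefs <- data.frame(side = side, state = state, k1 = k1, k2 = k2,
                      stringsAsFactors = FALSE)
  if (any(coefs$k1 < 0) || any(coefs$k2 < 0))
    stop("Rohrer coefficients must be non-negative")
  if (any(coefs$k1 + coefs$k2 == 0))
    stop("k1 and k2 must not both be zero")
  # the congested state of a side must be at least as resistive as its
  # decongested state
  for (s in unique(coefs$side)) {
    con <- coefs[coefs$side == s & coefs$state == "congested", ]
    dec <- coefs[coefs$side == s & coefs$state == "decongested", ]
    if (nrow(con) == 1 && nrow(dec) == 1 &&
        (con$k1 < dec$k1 || con$k2 < dec$k2))
      stop("congested coefficients must be >= decongested for side ", s)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(coefs = coefs, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "rohrer_model")
}

#' Evaluate the noise-free Rohrer pressure at given flows
#' @param k1,k2 Rohrer coefficients.
#' @param flow flow rate(s) in ml/s (signed; inspiration positive).
#' @return pressure drop in Pa, same sign convention as the flow.
#' @export
rohrer_pressure <- function(k1, k2, flow) k1 * flow + k2 * flow * abs(flow)

#' Flow at which a Rohrer curve reaches a given pressure drop
#' @param k1,k2 Rohrer coefficients.
#' @param pressure_pa target pressure drop (Pa), default the clinical
#'   150 Pa evaluation point.
#' @return the positive flow `Q*` in ml/s solving `k1 Q + k2 Q^2 = p`.
#' @export
rohrer_flow_at <- function(k1, k2, pressure_pa = 150) {
  if (k2 == 0) return(pressure_pa / k1)
  (-k1 + sqrt(k1^2 + 4 * k2 * pressure_pa)) / (2 * k2)
}

#' Generate synthetic AAR curves from a Rohrer model
#'
#' Produces one curve per coefficient row (side x state) at the requested
#' flows.  Inspiration (positive flow) and expiration (negative flow)
#' occupy opposite quadrants, as on a clinical rhinomanometry plot.
#'
#' @param model a [rohrer_model()].
#' @param flows flow rates in ml/s; must lie within +/-625 ml/s, the
#'   analyzed flow span.
#' @param subject subject label attached to the output.
#' @return An `aar_curve` data frame with columns `subject`, `side`,
#'   `state`, `flow_ml_s`, `pressure_pa`.
#' @export
synth_aar <- function(model, flows, subject = "synthetic") {
  stopifnot(inherits(model, "rohrer_model"))
  if (length(flows) == 0) stop("flow list must not be empty")
  if (any(abs(flows) > 625))
    stop("flows must lie within +/-625 ml/s")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(model$seed)
  out <- do.call(rbind, lapply(seq_len(nrow(model$coefs)), function(i) {
    co <- model$coefs[i, ]
    dp <- rohrer_pressure(co$k1, co$k2, flows)
    if (model$noise_sd > 0)
      dp <- dp + rnorm(length(flows), 0, model$noise_sd)
    data.frame(subject = subject, side = co$side, state = co$state,
               flow_ml_s = flows, pressure_pa = dp,
               stringsAsFactors = FALSE)
  }))
  aar_curve(out)
}

#' Emulate a full AAR recording for one side and state
#'
#' Clinical rhinomanometry traces are time series over several breathing
#' cycles, so a plotted curve is a dense scatter band rather than a thin
#' line.  This sampler sweeps the flow sinusoidally over `n_cycles`
#' breaths with a small per-cycle mucosal gain drift and a pressure
#' phase lag (the inertance/compliance loop visible in clinical
#' traces), giving rendered plots a realistic trace density.
#'
#' @param model a [rohrer_model()] (its first coefficient row is used
#'   unless `side`/`state` select another).
#' @param side,state coefficient row selector.
#' @param flow_max peak flow in ml/s.
#' @param n_cycles breathing cycles recorded.
#' @param samples_per_cycle samples per breathing cycle.
#' @param cycle_drift_sd relative per-cycle drift of the pressure gain.
#' @param phase_lag pressure lag behind flow, as a fraction of one
#'   breathing cycle; opens the inspiration/expiration loop.
#' @param subject subject label.
#' @return An `aar_curve` data frame.
#' @export
synth_aar_recording <- function(model, side = NULL, state = NULL,
                                flow_max = 600, n_cycles = 3,
                                samples_per_cycle = 1000,
                                cycle_drift_sd = 0.06, phase_lag = 0.07,
                                subject = "synthetic") {
  stopifnot(inherits(model, "rohrer_model"))
  co <- model$coefs
  if (!is.null(side)) co <- co[co$side == side, ]
  if (!is.null(state)) co <- co[co$state == state, ]
  if (nrow(co) == 0) stop("no coefficient row matches side/state")
  co <- co[1, ]
  if (flow_max > 625) stop("flow_max must lie within 625 ml/s")
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(model$seed)
  tt <- seq(0, n_cycles, length.out = n_cycles * samples_per_cycle)
  q <- flow_max * sin(2 * pi * tt)
  q_lag <- flow_max * sin(2 * pi * (tt - phase_lag))
  gain <- 1 + rep(rnorm(n_cycles, 0, cycle_drift_sd),
                  each = samples_per_cycle)
  dp <- gain * rohrer_pressure(co$k1, co$k2, q_lag) +
    rnorm(length(q), 0, model$noise_sd)
  aar_curve(data.frame(subject = subject, side = co$side, state = co$state,
                       flow_ml_s = q, pressure_pa = dp,
                       stringsAsFactors = FALSE))
}

#' AAR curve container
#'
#' Ordered (flow, pressure) points for one or more side/state groups.
#'
#' @param df data frame with columns `subject`, `side`, `state`,
#'   `flow_ml_s`, `pressure_pa`.
#' @return the validated data frame with class `aar_curve`.
#' @export
aar_curve <- function(df) {
  need <- c("subject", "side", "state", "flow_ml_s", "pressure_pa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing AAR curve columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$flow_ml_s)) || any(!is.finite(df$pressure_pa)))
    stop("AAR curve points must be finite")
  class(df) <- c("aar_curve", "data.frame")
  df
}

#' Write / read AAR curves as CSV
#' @param curve an `aar_curve`.
#' @param path CSV path.
#' @return `read_aar_csv` returns an `aar_curve`; the writer returns
#'   `path` invisibly.
#' @export
write_aar_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aar_csv
#' @export
read_aar_csv <- function(path) aar_curve(utils::read.csv(path))
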