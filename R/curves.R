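#' Extract the sphere-to-oropharynx pressure drop
#'
#' Dp = p1 - p2 with p1 the mean pressure over the inlet-sphere fluid
#' voxels (nasal entrance, ambient) and p2 the mean over the cuboid
#' fluid voxels (oropharynx).
#'
#' @param field a `pressure_field` from [run_to_stationary()].
#' @param domain the `airspace_domain` the field was computed on.
#' @return Dp in Pa (positive during inspiration).
#' @export
extract_dp <- function(field, domain) {
  p1v <- field$pressure[domain$sphere$voxels]
  p2v <- field$pressure[domain$cuboid$voxels]
  if (all(is.na(p1v)) || all(is.na(p2v)))
    stop("probe region contains no fluid voxels")
  mean(p1v, na.rm = TRUE) - mean(p2v, na.rm = TRUE)
}

#' Simulate the AAR curve of one nasal side
#'
#' Runs the standard sweep (0 to 600 ml/s in steps of 50, inspiration
#' and expiration; 25 conditions per side counting the shared zero) on a
#' domain whose other nostril is blocked, and returns the simulated AAR
#' curve.  Runs are warm-started from the previous flow of the same
#' phase.  Desk-scale phantoms run at `flow_scale` times the nominal
#' flow; in the viscous regime the pressure drop is proportional to the
#' flow, so the recorded pressure is rescaled by `1/flow_scale`
#' (`pressure_scale`) to the nominal-flow equivalent.
#'
#' @param domain an `airspace_domain`.
#' @param cfg a [lattice_config()]; if `dt_s` is `NULL` one time step is
#'   chosen for the whole sweep from the largest flow.
#' @param side the open nasal side (the opposite nostril is blocked if
#'   the domain is still unblocked).
#' @param subject subject label.
#' @param flows non-negative sweep magnitudes in ml/s.
#' @param flow_scale nominal-to-physical flow factor (see above).
#' @param pressure_scale recorded-pressure factor, default
#'   `1/flow_scale`.
#' @return an `aar_curve` with `state = "simulated"` and a `converged`
#'   column; non-stationary points carry `converged = FALSE` and are
#'   excluded by the binning stage with a warning.
#' @export
build_sim_curve <- function(domain, cfg = lattice_config(), side,
                            subject = "phantom",
                            flows = seq(0, 600, by = 50),
                            flow_scale = 0.001,
                            pressure_scale = 1 / flow_scale) {
  stopifnot(all(flows >= 0))
  other <- if (side == "left") "right" else "left"
  if (domain$blocked_side == "none") {
    domain <- block_nostril(domain, other)
  } else if (domain$blocked_side != other) {
    stop("domain is blocked on side ", domain$blocked_side,
         " but the open side requested is ", side)
  }
  if (is.null(cfg$dt_s))
    cfg$dt_s <- .auto_dt(domain, cfg, max(flows) * 1e-6 * flow_scale)

  flows <- sort(unique(flows))
  rows <- list()
  for (phase in c("inspiration", "expiration")) {
    fset <- if (phase == "inspiration") flows else setdiff(flows, 0)
    warm <- NULL
    for (q in fset) {
      fld <- run_to_stationary(domain, flow_condition(q, phase, side),
                               cfg, flow_scale = flow_scale,
                               init_f = warm)
      warm <- fld$f
      dp <- extract_dp(fld, domain)
      sgn <- if (phase == "inspiration") 1 else -1
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, side = side, state = "simulated",
        flow_ml_s = sgn * q, pressure_pa = dp * pressure_scale,
        converged = fld$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$flow_ml_s), ]
  rownames(out) <- NULL
  class(out) <- c("aar_curve", "data.frame")
  out
}

#' Bin an AAR curve into 50 ml/s flow groups
#'
#' Points are grouped by flow in steps of 50 ml/s around the centers 0,
#' +/-50, +/-100, ... (half-open bins `[center - 25, center + 25)`, so a
#' boundary value joins the upper bin), and pressures aggregated as the
#' per-bin mean; absolute values are taken after aggregation.  Points
#' flagged non-stationary are excluded with a warning.
#'
#' @param curve an `aar_curve`.
#' @return a `binned_curve` data frame: `subject`, `side`, `state`,
#'   `phase`, `bin_flow_ml_s`, `mean_pressure_pa` (signed),
#'   `abs_pressure_pa`, `n`, `sd`.
#' @export
bin_curve <- function(curve) {
  if (nrow(curve) == 0)
    return(structure(data.frame(subject = character(0), side = character(0),
                                state = character(0), phase = character(0),
                                bin_flow_ml_s = numeric(0),
                                mean_pressure_pa = numeric(0),
                                abs_pressure_pa = numeric(0),
                                n = integer(0), sd = numeric(0)),
                     class = c("binned_curve", "data.frame")))
  curve <- as.data.frame(curve)
  if (!is.null(curve$converged) && any(!curve$converged)) {
    warning(sum(!curve$converged),
            " non-stationary point(s) excluded from binning")
    curve <- curve[curve$converged, ]
  }
  bin <- 50 * floor(curve$flow_ml_s / 50 + 0.5)
  key <- interaction(curve$subject, curve$side, curve$state, bin,
                     drop = TRUE)
  agg <- lapply(split(seq_len(nrow(curve)), key), function(ix) {
    p <- curve$pressure_pa[ix]
    data.frame(subject = curve$subject[ix[1]], side = curve$side[ix[1]],
               state = curve$state[ix[1]], bin_flow_ml_s = bin[ix[1]],
               mean_pressure_pa = mean(p), n = length(ix),
               sd = if (length(ix) > 1) stats::sd(p) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out$abs_pressure_pa <- abs(out$mean_pressure_pa)
  out$phase <- ifelse(out$bin_flow_ml_s > 0, "inspiration",
                      ifelse(out$bin_flow_ml_s < 0, "expiration", "zero"))
  out <- out[order(out$subject, out$side, out$bin_flow_ml_s),
             c("subject", "side", "state", "phase", "bin_flow_ml_s",
               "mean_pressure_pa", "abs_pressure_pa", "n", "sd")]
  rownames(out) <- NULL
  class(out) <- c("binned_curve", "data.frame")
  out
}

#' Remove near-zero pressure bins
#'
#' Bins whose aggregated (signed) pressure lies in the open interval
#' (-25, 25) Pa are removed: around zero the respiration phase cannot be
#' told apart.  In practice this removes the zero-flow bin.
#'
#' @param binned a `binned_curve`.
#' @return the filtered `binned_curve`.
#' @export
drop_nearzero <- function(binned) {
  keep <- !(binned$mean_pressure_pa > -25 & binned$mean_pressure_pa < 25)
  out <- binned[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nasal resistance at the 150 Pa pressure drop
#'
#' Points whose absolute pressure drop lies in [125, 175] Pa are
#' labelled 150 Pa; their (absolute) flows are averaged, and resistance
#' is the labelled 150 Pa divided by that mean flow (sPa/ml).  Only
#' inspiration is analyzed.  With `numerator = "actual"` the mean
#' observed pressure replaces the 150 Pa label.
#'
#' @param data an `aar_curve` (column `pressure_pa`) or `binned_curve`
#'   (column `mean_pressure_pa`); may contain several subject/side
#'   groups.
#' @param phase respiration phase analyzed, default inspiration.
#' @param source `"clinical"` or `"simulated"` label for the record.
#' @param numerator `"label"` (150 Pa) or `"actual"`.
#' @return data frame with one `ResistanceRecord` per subject and side:
#'   `subject`, `side`, `phase`, `source`, `resistance_spa_ml`,
#'   `mean_flow_ml_s`, `n_points`.  Groups with no qualifying point get
#'   `NA` resistance.
#' @export
resistance150 <- function(data, phase = "inspiration",
                          source = "simulated",
                          numerator = c("label", "actual")) {
  numerator <- match.arg(numerator)
  df <- as.data.frame(data)
  pcol <- if ("mean_pressure_pa" %in% names(df)) "mean_pressure_pa"
          else "pressure_pa"
  fcol <- if ("bin_flow_ml_s" %in% names(df)) "bin_flow_ml_s"
          else "flow_ml_s"
  if (!is.null(df$converged)) df <- df[df$converged, ]
  want_insp <- phase == "inspiration"
  groups <- split(df, list(df$subject, df$side), drop = TRUE)
  out <- lapply(groups, function(g) {
    sel <- if (want_insp) g[[fcol]] > 0 else g[[fcol]] < 0
    sel <- sel & abs(g[[pcol]]) >= 125 & abs(g[[pcol]]) <= 175
    rec <- data.frame(subject = g$subject[1], side = g$side[1],
                      phase = phase, source = source,
                      resistance_spa_ml = NA_real_,
                      mean_flow_ml_s = NA_real_,
                      n_points = sum(sel), stringsAsFactors = FALSE)
    if (any(sel)) {
      mq <- mean(abs(g[[fcol]][sel]))
      num <- if (numerator == "label") 150 else mean(abs(g[[pcol]][sel]))
      rec$mean_flow_ml_s <- mq
      rec$resistance_spa_ml <- num / mq
    }
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Choose the clinical state matching the simulation
#'
#' Of the congested and decongested binned AARs, returns the state whose
#' pressures better match the simulated AAR: the smaller mean absolute
#' log10 pressure ratio over the bins common to all three curves.  Ties
#' go to congested (and are messaged).
#'
#' @param congested,decongested,simulated `binned_curve`s of one subject
#'   and side, after [drop_nearzero()].
#' @return `"congested"` or `"decongested"`.
#' @export
choose_clinical_state <- function(congested, decongested, simulated) {
  common <- Reduce(intersect, list(congested$bin_flow_ml_s,
                                   decongested$bin_flow_ml_s,
                                   simulated$bin_flow_ml_s))
  if (length(common) < 3)
    stop("fewer than 3 common bins between clinical and simulated curves")
  dist_to_sim <- function(clin) {
    ci <- match(common, clin$bin_flow_ml_s)
    si <- match(common, simulated$bin_flow_ml_s)
    mean(abs(log10(clin$abs_pressure_pa[ci]) -
             log10(simulated$abs_pressure_pa[si])))
  }
  dc <- dist_to_sim(congested)
  dd <- dist_to_sim(decongested)
  if (dc == dd) {
    message("congested/decongested tie; choosing congested")
    return("congested")
  }
  if (dc < dd) "congested" else "decongested"
}
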