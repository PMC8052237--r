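#' Build the default synthetic study cohort
#'
#' Five phantom subjects emulating the pilot-study conditions: four with
#' a right-sided constriction (septal deviation analogue) and one with a
#' left-sided one, with mild subject-to-subject variation in the
#' constriction factor and seeded centerline jitter.  The channel radius
#' is sized so that every side's unilateral resistance lies between
#' roughly 0.5 and 1.0 sPa/ml, the clinical range in which the 50 ml/s
#' sweep crosses the 150 Pa evaluation band.
#'
#' @param n_subjects number of subjects (default 5).
#' @param seed cohort seed; subject seeds derive from it.
#' @param grid_shape,spacing_mm,channel_radius_mm phantom geometry
#'   shared by the cohort.
#' @return list of [phantom_spec()]s.
#' @export
cohort_specs <- function(n_subjects = 5L, seed = 1L,
                         grid_shape = c(64L, 64L, 64L),
                         spacing_mm = 0.4, channel_radius_mm = 1.2) {
  sides <- rep(c("right", "right", "right", "right", "left"),
               length.out = n_subjects)
  factors <- rep(c(0.88, 0.84, 0.92, 0.86, 0.90),
                 length.out = n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 channel_radius_mm = channel_radius_mm,
                 constriction_side = sides[i],
                 constriction_factor = factors[i],
                 seed = seed * 1000L + i)
  })
}

#' Pipeline run configuration
#'
#' @param phantom_specs list of [phantom_spec()]s; default the
#'   five-subject cohort from [cohort_specs()].
#' @param lattice a [lattice_config()].
#' @param flows sweep magnitudes in ml/s.
#' @param flow_scale nominal-to-physical flow factor for desk-scale
#'   phantoms (see [build_sim_curve()]).
#' @param clinical `"rohrer"` generates synthetic clinical AAR curves
#'   from per-side Rohrer fits (congested/decongested states);
#'   `"null"` sets the clinical curves exactly equal to the simulated
#'   ones (end-to-end null).
#' @param noise_sd clinical pressure noise in Pa.
#' @param congested_gain,decongested_gain multipliers applied to the
#'   fitted Rohrer coefficients for the two mucosal states.
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return a `run_config`.
#' @export
run_config <- function(phantom_specs = NULL, lattice = lattice_config(),
                       flows = seq(0, 600, by = 50), flow_scale = 0.001,
                       clinical = c("rohrer", "null"), noise_sd = 5,
                       congested_gain = 1.4, decongested_gain = 0.95,
                       seed = 1L, out_dir = NULL) {
  clinical <- match.arg(clinical)
  if (is.null(phantom_specs)) phantom_specs <- cohort_specs(seed = seed)
  structure(list(phantom_specs = phantom_specs, lattice = lattice,
                 flows = flows, flow_scale = flow_scale,
                 clinical = clinical, noise_sd = noise_sd,
                 congested_gain = congested_gain,
                 decongested_gain = decongested_gain,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# least-squares Rohrer fit |dp| = k1 |q| + k2 q^2 through the origin
.fit_rohrer <- function(curve) {
  q <- abs(curve$flow_ml_s)
  p <- abs(curve$pressure_pa)
  keep <- q > 0
  fit <- stats::lm(p[keep] ~ 0 + q[keep] + I(q[keep]^2))
  k <- pmax(0, unname(stats::coef(fit)))
  if (sum(k) == 0) k[1] <- 1e-6
  list(k1 = k[1], k2 = k[2])
}

#' Run the full phantom-to-agreement pipeline
#'
#' For every subject: build the phantom, segment the air space, simulate
#' both sides' AAR sweeps (other nostril blocked), generate or copy the
#' clinical curves, bin everything, apply the near-zero exclusion,
#' choose the clinical state matching the simulation, extract 150 Pa
#' resistances, and run the agreement statistics.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return a `rhinoflow_run`: list with `sim_curves`, `sim_binned`
#'   (retained), `clinical_binned` (chosen state, retained),
#'   `paired_pressure`, `resistance`, `pressure_stats`,
#'   `resistance_stats` and a `manifest` of counts and seeds.
#' @export
run_pipeline <- function(cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message(...)
  sim_all <- list(); clin_all <- list()
  chosen_states <- list()

  for (i in seq_along(cfg$phantom_specs)) {
    spec <- cfg$phantom_specs[[i]]
    subj <- sprintf("S%02d", i)
    say("subject ", subj, ": building phantom and segmenting")
    vol <- build_phantom(spec)
    pd <- phantom_probe_defaults(spec)
    domain <- extract_airspace(vol, sphere_diam_mm = pd$sphere_diam_mm,
                               cuboid_dims_mm = pd$cuboid_dims_mm)
    for (side in c("left", "right")) {
      say("subject ", subj, ": simulating ", side, " side")
      sim <- build_sim_curve(domain, cfg$lattice, side, subject = subj,
                             flows = cfg$flows,
                             flow_scale = cfg$flow_scale)
      sim_all[[paste(subj, side)]] <- sim

      if (cfg$clinical == "rohrer") {
        k <- .fit_rohrer(sim)
        model <- rohrer_model(
          k1 = k$k1 * c(cfg$congested_gain, cfg$decongested_gain),
          k2 = k$k2 * c(cfg$congested_gain, cfg$decongested_gain),
          side = side, state = c("congested", "decongested"),
          noise_sd = cfg$noise_sd,
          seed = cfg$seed * 10000L + i * 10L +
            (side == "right"))
        clin <- synth_aar(model, flows = seq(-600, 600, by = 10),
                          subject = subj)
        clin_all[[paste(subj, side)]] <- clin
      }
    }
  }

  sim_curves <- do.call(rbind, sim_all)
  rownames(sim_curves) <- NULL
  sim_binned <- drop_nearzero(bin_curve(sim_curves))

  # clinical side: generate, bin, choose state
  clinical_binned <- NULL
  if (cfg$clinical == "null") {
    clinical_binned <- sim_binned
    clinical_binned$state <- "clinical"
  } else {
    clin_curves <- do.call(rbind, clin_all)
    clin_binned <- drop_nearzero(bin_curve(clin_curves))
    pick <- list()
    for (key in unique(paste(sim_binned$subject, sim_binned$side))) {
      ks <- strsplit(key, " ")[[1]]
      con <- clin_binned[clin_binned$subject == ks[1] &
                           clin_binned$side == ks[2] &
                           clin_binned$state == "congested", ]
      dec <- clin_binned[clin_binned$subject == ks[1] &
                           clin_binned$side == ks[2] &
                           clin_binned$state == "decongested", ]
      simb <- sim_binned[sim_binned$subject == ks[1] &
                           sim_binned$side == ks[2], ]
      st <- choose_clinical_state(con, dec, simb)
      chosen_states[[key]] <- st
      pick[[key]] <- if (st == "congested") con else dec
    }
    clinical_binned <- do.call(rbind, pick)
    rownames(clinical_binned) <- NULL
  }

  # paired pressure table over common retained bins
  key_sim <- paste(sim_binned$subject, sim_binned$side,
                   sim_binned$bin_flow_ml_s)
  key_cli <- paste(clinical_binned$subject, clinical_binned$side,
                   clinical_binned$bin_flow_ml_s)
  common <- intersect(key_sim, key_cli)
  si <- match(common, key_sim); ci <- match(common, key_cli)
  paired_pressure <- paired_measurements(data.frame(
    subject = sim_binned$subject[si], side = sim_binned$side[si],
    phase = sim_binned$phase[si],
    bin_flow = sim_binned$bin_flow_ml_s[si],
    rhino_value = clinical_binned$abs_pressure_pa[ci],
    sim_value = sim_binned$abs_pressure_pa[si],
    stringsAsFactors = FALSE))

  # 150 Pa resistances during inspiration
  sim_res <- resistance150(sim_binned, source = "simulated")
  cli_res <- resistance150(clinical_binned, source = "clinical")
  res_key <- paste(sim_res$subject, sim_res$side)
  cli_ix <- match(res_key, paste(cli_res$subject, cli_res$side))
  resistance <- data.frame(
    subject = sim_res$subject, side = sim_res$side,
    rhino_res150 = cli_res$resistance_spa_ml[cli_ix],
    sim_res150 = sim_res$resistance_spa_ml,
    stringsAsFactors = FALSE)

  pressure_stats <- list(
    adjusted = adjusted_correlation(paired_pressure),
    bland_altman = bland_altman(paired_pressure))
  res_ok <- stats::complete.cases(resistance$rhino_res150,
                                  resistance$sim_res150)
  res_pairs <- resistance[res_ok, ]
  resistance_stats <- list(
    pearson = tryCatch(
      pearson_corr(res_pairs$rhino_res150, res_pairs$sim_res150),
      error = function(e) list(r = NA_real_, p = NA_real_,
                               category = NA_character_,
                               n = nrow(res_pairs),
                               note = conditionMessage(e))),
    ttest = paired_ttest(res_pairs$rhino_res150, res_pairs$sim_res150),
    bland_altman = suppressWarnings(bland_altman(
      paired_measurements(data.frame(rhino_value = res_pairs$rhino_res150,
                                     sim_value = res_pairs$sim_res150)),
      strata = character(0), min_n = min(3L, nrow(res_pairs)))))

  per_side_n <- vapply(sim_all, nrow, integer(1))
  manifest <- list(
    n_subjects = length(cfg$phantom_specs),
    dp_evaluations_per_side = unname(per_side_n),
    dp_evaluations_total = sum(per_side_n),
    sim_press_retained = nrow(sim_binned),
    rhino_press_retained = nrow(clinical_binned),
    paired_pressure_n = nrow(paired_pressure),
    sim_res150_n = sum(!is.na(resistance$sim_res150)),
    rhino_res150_n = sum(!is.na(resistance$rhino_res150)),
    chosen_states = unlist(chosen_states),
    seed = cfg$seed, clinical = cfg$clinical,
    flow_scale = cfg$flow_scale)

  out <- structure(list(sim_curves = sim_curves, sim_binned = sim_binned,
                        clinical_binned = clinical_binned,
                        paired_pressure = paired_pressure,
                        resistance = resistance,
                        pressure_stats = pressure_stats,
                        resistance_stats = resistance_stats,
                        manifest = manifest),
                   class = "rhinoflow_run")
  if (!is.null(cfg$out_dir)) .write_run(out, cfg$out_dir)
  out
}

.write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(run$sim_curves),
                   file.path(dir, "sim_curves.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$sim_binned),
                   file.path(dir, "sim_binned.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$clinical_binned),
                   file.path(dir, "clinical_binned.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$paired_pressure),
                   file.path(dir, "paired_pressure.csv"), row.names = FALSE)
  utils::write.csv(run$resistance,
                   file.path(dir, "resistance.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.rhinoflow_run <- function(x, ...) {
  m <- x$manifest
  cat("<rhinoflow_run>\n")
  cat(sprintf("  %d subjects, %d dp evaluations (%s per side)\n",
              m$n_subjects, m$dp_evaluations_total,
              paste(unique(m$dp_evaluations_per_side), collapse = "/")))
  cat(sprintf("  retained SimPress %d, RhinoPress %d; SimRes150 %d, RhinoRes150 %d\n",
              m$sim_press_retained, m$rhino_press_retained,
              m$sim_res150_n, m$rhino_res150_n))
  cat(sprintf("  adjusted pressure r = %.3f; resistance r = %.3f\n",
              x$pressure_stats$adjusted$r, x$resistance_stats$pearson$r))
  invisible(x)
}

#' Load a paired clinical/simulated study table from CSV
#'
#' @param path CSV with columns `subject`, `side`, `phase`, `bin_flow`,
#'   `rhino_value`, `sim_value`.
#' @return a [paired_measurements()] table.
#' @export
load_study_tables <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "side", "phase", "bin_flow",
            "rhino_value", "sim_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("study table is missing column(s): ",
         paste(miss, collapse = ", "))
  paired_measurements(df)
}
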