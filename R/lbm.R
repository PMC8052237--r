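#' Lattice Boltzmann solver configuration
#'
#' Physical and numerical parameters of the D3Q19 solver.  Lattice units
#' follow the usual diffusive scaling: `u_lat = u * dt/dx`,
#' `nu_lat = nu * dt/dx^2`, relaxation time `tau = 3 nu_lat + 0.5`, and
#' pressure converts back as `p = (rho_lat - 1)/3 * rho_phys * (dx/dt)^2`
#' (lattice sound speed squared 1/3).
#'
#' @param dx_m grid resolution in metres.
#' @param dt_s time step in seconds, or `NULL` to choose automatically
#'   from the target lattice velocity and the narrowest passage.
#' @param nu_phys kinematic viscosity of air at 20 C, m^2/s.
#' @param rho_phys air density at 20 C, kg/m^3.
#' @param smagorinsky_cs Smagorinsky constant for the LES closure; 0
#'   disables the closure (desk-scale default, laminar regimes), 0.14 is
#'   the reference value for under-resolved turbulent runs.
#' @param max_steps iteration cap.
#' @param stationarity_tol the run is stationary once the peak-to-peak
#'   fluctuation of the sphere-cuboid pressure drop over
#'   `monitor_window` steps falls below this fraction (+/-3% default) of
#'   its running mean.
#' @param monitor_window fluctuation window in time steps.
#' @param check_every pressure-drop sampling stride in steps.
#' @param p_floor_pa absolute pressure-drop floor (Pa) below which a run
#'   counts as stationary regardless of relative fluctuation (zero-flow
#'   runs).
#' @param u_lat_target target peak lattice velocity for automatic time
#'   step choice; keeps the lattice Mach number low.
#' @return a `lattice_config`.
#' @export
lattice_config <- function(dx_m = 0.4e-3, dt_s = NULL,
                           nu_phys = 1.516e-5, rho_phys = 1.204,
                           smagorinsky_cs = 0, max_steps = 20000L,
                           stationarity_tol = 0.03,
                           monitor_window = 500L, check_every = 10L,
                           p_floor_pa = 0.02, u_lat_target = 0.025) {
  if (dx_m <= 0 || (!is.null(dt_s) && dt_s <= 0))
    stop("dx and dt must be positive")
  if (stationarity_tol <= 0) stop("stationarity_tol must be > 0")
  structure(list(dx_m = dx_m, dt_s = dt_s, nu_phys = nu_phys,
                 rho_phys = rho_phys, smagorinsky_cs = smagorinsky_cs,
                 max_steps = as.integer(max_steps),
                 stationarity_tol = stationarity_tol,
                 monitor_window = as.integer(monitor_window),
                 check_every = as.integer(check_every),
                 p_floor_pa = p_floor_pa, u_lat_target = u_lat_target),
            class = "lattice_config")
}

#' Reference full-resolution configuration
#'
#' The patient-scale configuration: 0.234 mm grid, 1.8e-6 s time step,
#' Smagorinsky LES with c_s = 0.14, 13605-step cap.  At this resolution
#' runs belong on a GPU or cluster; it is provided for unit conversion
#' and documentation.
#' @return a `lattice_config`.
#' @export
paper_scale_config <- function() {
  lattice_config(dx_m = 0.234e-3, dt_s = 1.8e-6, smagorinsky_cs = 0.14,
                 max_steps = 13605L)
}

#' Convert between physical and lattice units
#'
#' @param cfg a [lattice_config()] with `dt_s` set.
#' @param velocity physical velocity (m/s) to convert, or `NULL`.
#' @param viscosity physical kinematic viscosity (m^2/s), or `NULL`.
#' @return list with any of `velocity_lat`, `nu_lat`, plus `tau` and the
#'   lattice speed `dx/dt` (m/s).
#' @export
to_lattice_units <- function(cfg, velocity = NULL, viscosity = NULL) {
  if (is.null(cfg$dt_s)) stop("dt is not set in this configuration")
  out <- list(lattice_speed = cfg$dx_m / cfg$dt_s)
  nu <- if (is.null(viscosity)) cfg$nu_phys else viscosity
  out$nu_lat <- nu * cfg$dt_s / cfg$dx_m^2
  out$tau <- 3 * out$nu_lat + 0.5
  if (out$tau < 0.505 && cfg$smagorinsky_cs <= 0)
    stop("relaxation time tau is too close to 0.5 and unstable without ",
         "the LES closure; increase dt or decrease dx")
  if (!is.null(velocity)) out$velocity_lat <- velocity * cfg$dt_s / cfg$dx_m
  out
}

#' Convert a lattice density deviation to physical pressure
#' @param cfg a [lattice_config()] with `dt_s` set.
#' @param rho_lat lattice density (reference density 1).
#' @return pressure in Pa.
#' @export
pressure_from_lattice <- function(cfg, rho_lat) {
  (rho_lat - 1) / 3 * cfg$rho_phys * (cfg$dx_m / cfg$dt_s)^2
}

#' A single simulated flow condition
#' @param flow_rate_ml_s nominal flow rate in ml/s (magnitude at most
#'   625, the analyzed span).
#' @param phase `"inspiration"` (flow into the nostril) or
#'   `"expiration"`.
#' @param side nasal side the open nostril belongs to.
#' @return a `flow_condition`.
#' @export
flow_condition <- function(flow_rate_ml_s,
                           phase = c("inspiration", "expiration"),
                           side = "left") {
  phase <- match.arg(phase)
  if (abs(flow_rate_ml_s) > 625)
    stop("flow rate must lie within +/-625 ml/s")
  structure(list(flow_rate_ml_s = abs(flow_rate_ml_s), phase = phase,
                 side = side), class = "flow_condition")
}

# flag array and boundary cell sets for one domain
.domain_flags <- function(domain) {
  d <- dim(domain$air_mask)
  flags <- array(0L, d)
  flags[domain$air_mask] <- 1L
  cub <- domain$cuboid$voxels[domain$air_mask[domain$cuboid$voxels]]
  if (length(cub) == 0) stop("open outlet area zero: no fluid in cuboid")
  kk <- .index_to_ijk(d, cub)[, 3]
  outlet <- cub[kk == min(kk)]
  flags[outlet] <- 2L
  flags[domain$open_cells] <- 3L
  list(flags = flags, outlet = outlet)
}

# narrowest flowing cross-section (m^2) between the tissue face and the
# cuboid, used by the automatic time step
.narrowest_area <- function(domain) {
  d <- dim(domain$air_mask)
  spacing_m <- domain$spacing[1] * 1e-3
  cub_j <- .index_to_ijk(d, domain$cuboid$voxels)[, 2]
  j_hi <- max(domain$face_j + 1L, min(cub_j) - 2L)
  jr <- domain$face_j:j_hi
  m <- domain$air_mask
  if (domain$blocked_side != "none") {
    cx <- (d[1] + 1) / 2
    keep <- if (domain$blocked_side == "left") seq_len(d[1]) < cx
            else seq_len(d[1]) > cx
    m <- m & array(keep, d)
  }
  counts <- vapply(jr, function(j) sum(m[, j, ]), numeric(1))
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("no open cross-section found")
  min(counts) * spacing_m^2
}

# automatic dt: peak lattice velocity u_lat_target at flow Q (m^3/s)
.auto_dt <- function(domain, cfg, q_max_m3s) {
  if (q_max_m3s <= 0) {
    # no flow: any stable dt; pick tau = 0.8
    return(0.1 * cfg$dx_m^2 / cfg$nu_phys)
  }
  a_min <- .narrowest_area(domain)
  u_est <- q_max_m3s / a_min
  cfg$u_lat_target * cfg$dx_m / u_est
}

#' Run the solver to a stationary pressure drop
#'
#' Iterates collide-stream steps from a zero-velocity initialization (or
#' a warm-start state) until the sphere-cuboid pressure drop is
#' stationary: peak-to-peak fluctuation over the monitor window below
#' the tolerance fraction of its running mean (or below the absolute
#' floor).  Non-convergence within `max_steps` is flagged on the result,
#' not raised.
#'
#' @param domain an `airspace_domain` (one nostril typically blocked).
#' @param cond a [flow_condition()].
#' @param cfg a [lattice_config()]; `dx_m` must equal the domain voxel
#'   spacing.
#' @param flow_scale factor converting the nominal flow (ml/s) to the
#'   solver's physical flow; desk-scale phantoms run at reduced flow for
#'   dynamic similarity (see the package vignette).
#' @param init_f optional distribution state from a previous run on the
#'   identical domain (warm start).
#' @return a `pressure_field`: pressure (Pa) and velocity (m/s) arrays
#'   over the fluid domain, `converged`, `steps`, `dp_pa`, and the
#'   distribution state `f` for warm starts.
#' @export
run_to_stationary <- function(domain, cond, cfg = lattice_config(),
                              flow_scale = 1, init_f = NULL) {
  d <- dim(domain$air_mask)
  fl <- .domain_flags(domain)
  q_phys <- cond$flow_rate_ml_s * 1e-6 * flow_scale
  dt <- cfg$dt_s
  if (is.null(dt)) dt <- .auto_dt(domain, cfg, q_phys)
  cfg$dt_s <- dt
  lat <- to_lattice_units(cfg)
  a_open <- length(fl$outlet) * cfg$dx_m^2
  u_phys <- q_phys / a_open
  u_lat <- u_phys * dt / cfg$dx_m
  # outlet normal is inferior (-IS); inspiration draws air down it
  sgn <- if (cond$phase == "inspiration") -1 else 1
  u_bc <- c(0, 0, sgn * u_lat)

  p_scale <- cfg$rho_phys * (cfg$dx_m / dt)^2 # Pa per (lattice dp)
  res <- lbm_run_cpp(as.integer(fl$flags), dim(fl$flags), u_bc,
                     lat$tau, cfg$smagorinsky_cs, cfg$max_steps,
                     cfg$check_every, cfg$monitor_window,
                     cfg$stationarity_tol, cfg$p_floor_pa / p_scale,
                     domain$sphere$voxels, domain$cuboid$voxels,
                     c(0L, 0L, 1L), init_f)
  if (res$diverged)
    stop("solver diverged (non-finite pressure) at step ", res$steps)

  press <- array(NA_real_, d)
  press[res$fluid_idx] <- (res$rho - 1) / 3 * p_scale
  vel_scale <- cfg$dx_m / dt
  mk <- function(v) { a <- array(NA_real_, d); a[res$fluid_idx] <- v * vel_scale; a }
  dp_pa <- if (length(res$dp_history)) utils::tail(res$dp_history, 1) * p_scale
           else NA_real_
  structure(list(pressure = press, ux = mk(res$ux), uy = mk(res$uy),
                 uz = mk(res$uz), converged = res$converged,
                 steps = res$steps, dp_pa = dp_pa,
                 dp_history_pa = res$dp_history * p_scale,
                 f = res$f, fluid_idx = res$fluid_idx,
                 cond = cond,
                 lattice = list(dx_m = cfg$dx_m, dt_s = dt,
                                tau = lat$tau, nu_lat = lat$nu_lat,
                                u_lat = u_lat, flow_scale = flow_scale)),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf(
    "<pressure_field> %s @ %g ml/s: dp = %.4g Pa, %s in %d steps\n",
    x$cond$phase, x$cond$flow_rate_ml_s, x$dp_pa,
    if (x$converged) "stationary" else "NOT stationary", x$steps))
  invisible(x)
}

#' Volume flux through an AP cross-section
#'
#' Integrates the anterior-posterior velocity component over the fluid
#' voxels of one AP slab (optionally one lateral half), in m^3/s.
#' Useful for checking that a blocked-nostril run carries the full
#' outlet flux through the open channel.
#'
#' @param field a `pressure_field`.
#' @param j AP slab index.
#' @param side `"left"`, `"right"` or `NULL` for the full slab.
#' @return signed flux in m^3/s (positive towards posterior).
#' @export
slab_flux <- function(field, j, side = NULL) {
  uy <- field$uy[, j, ]
  d <- dim(field$pressure)
  if (!is.null(side)) {
    cx <- (d[1] + 1) / 2
    keep <- if (side == "left") seq_len(d[1]) > cx else seq_len(d[1]) < cx
    uy <- uy[keep, , drop = FALSE]
  }
  dx <- field$lattice$dx_m
  sum(uy, na.rm = TRUE) * dx^2
}

#' Hagen-Poiseuille duct benchmark
#'
#' Runs the solver on a circular duct (axis along AP) with an ambient
#' pressure inlet and a plug-velocity outlet, and compares the pressure
#' gradient in the developed region against the analytic
#' `8 nu rho L Q / (pi R^4)`.  Fluid voxels are those whose center lies
#' within `R` of the axis; on a staircased cylinder with half-way
#' bounce-back the measured effective hydraulic radius then agrees with
#' the nominal `R` to about one percent.
#'
#' @param radius_vox nominal duct radius in voxels.
#' @param length_vox duct length in voxels (default 8 radii).
#' @param tau lattice relaxation time (viscosity `(tau - 0.5)/3`).
#' @param u_plug outlet plug velocity in lattice units.
#' @param smagorinsky_cs Smagorinsky constant; 0 (default) disables the
#'   LES closure, appropriate at duct Reynolds numbers.
#' @param probe_frac positions of the two pressure probe planes as
#'   fractions of the duct length.
#' @param max_steps,window_steps,tol solver controls.
#' @return list with `dp_sim`, `dp_analytic` (lattice units), `rel_err`,
#'   `q_lat` (measured mid-plane flux), `re` (Reynolds number),
#'   `converged`.
#' @export
duct_benchmark <- function(radius_vox = 12, length_vox = NULL,
                           tau = 0.8, u_plug = 0.04,
                           smagorinsky_cs = 0,
                           probe_frac = c(0.3, 0.7),
                           max_steps = 20000L, window_steps = 400L,
                           tol = 1e-6) {
  r <- radius_vox
  ny <- if (is.null(length_vox)) as.integer(8 * r) else as.integer(length_vox)
  nx <- as.integer(2 * ceiling(r) + 3)
  cx <- (nx + 1) / 2
  d <- c(nx, ny, nx)
  xx <- seq_len(nx) - cx
  disc <- outer(xx^2, xx^2, "+") <= r^2
  flags <- array(0L, d)
  for (j in seq_len(ny)) flags[, j, ][disc] <- 1L
  flags[, 1, ][disc] <- 3L    # ambient pressure inlet
  flags[, ny, ][disc] <- 2L   # plug velocity outlet

  j1 <- round(probe_frac[1] * ny); j2 <- round(probe_frac[2] * ny)
  slab_idx <- function(j) {
    ik <- which(disc, arr.ind = TRUE)
    .grid_index(d, ik[, 1], j, ik[, 2])
  }
  res <- lbm_run_cpp(as.integer(flags), d, c(0, u_plug, 0), tau,
                     smagorinsky_cs, as.integer(max_steps), 10L,
                     as.integer(window_steps), tol, 1e-12,
                     slab_idx(j1), slab_idx(j2), c(0L, -1L, 0L))
  if (res$diverged) stop("duct benchmark diverged")

  rho <- array(NA_real_, d); rho[res$fluid_idx] <- res$rho
  uy <- array(NA_real_, d); uy[res$fluid_idx] <- res$uy
  jm <- round(ny / 2)
  q_lat <- sum(uy[, jm, ], na.rm = TRUE)
  dp_sim <- (mean(rho[, j1, ], na.rm = TRUE) -
             mean(rho[, j2, ], na.rm = TRUE)) / 3
  nu_lat <- (tau - 0.5) / 3
  dp_an <- 8 * nu_lat * (j2 - j1) * q_lat / (pi * r^4)
  list(dp_sim = dp_sim, dp_analytic = dp_an,
       rel_err = abs(dp_sim - dp_an) / abs(dp_an),
       q_lat = q_lat, re = abs(q_lat) / (pi * r^2) * 2 * r / nu_lat,
       converged = res$converged, steps = res$steps)
}
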