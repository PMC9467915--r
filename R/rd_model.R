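# Radially symmetric reaction-diffusion model of antibody penetration into
# an antigen-bearing cylinder. Free antibody [Ab] diffuses (cylindrical
# Laplacian, reduced diffusivity inside the cylinder) and binds immobile
# antigen [Ag] reversibly to form the immobile complex [Ab-Ag]:
#
#   d[Ab]/dt    = D_eff (1/r) d/dr (r d[Ab]/dr) + k_off [Ab-Ag] - k_on [Ab][Ag]
#   d[Ag]/dt    =                                 k_off [Ab-Ag] - k_on [Ab][Ag]
#   d[Ab-Ag]/dt =                               - k_off [Ab-Ag] + k_on [Ab][Ag]
#
# All quantities are dimensionless. Kinetic parameter sets are labeled by
# temperature and assigned to time phases by a piecewise schedule.

#' Temperature-labeled kinetic/diffusion parameter set
#'
#' @param label short label, e.g. `"22C"`.
#' @param D_out diffusion coefficient of free antibody outside the cylinder.
#' @param k_on association rate constant.
#' @param k_off dissociation rate constant.
#' @param D_in_factor ratio of inside- to outside-cylinder diffusivity;
#'   default 1/7 (hindered diffusion in dense tissue).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(label, D_out, k_on, k_off, D_in_factor = 1 / 7) {
  stopifnot(D_out > 0, D_in_factor > 0, D_in_factor <= 1,
            k_on >= 0, k_off >= 0)
  structure(list(label = label, D_out = D_out, D_in_factor = D_in_factor,
                 k_on = k_on, k_off = k_off),
            class = "kinetic_params")
}

#' @rdname kinetic_params
#' @details `kinetic_params_22c()` and `kinetic_params_55c()` return the
#'   canonical room-temperature and heated parameter sets: at 22 C,
#'   `D_out = 1`, `k_on = 1`, `k_off = 1`; at 55 C, `D_out = 1.11`
#'   (Stokes-Einstein scaling of the 22 C value), `k_on = 2`,
#'   `k_off = 60.75`. The heated set shifts the association equilibrium
#'   strongly toward free antibody (K_a drops from 1 to about 0.033),
#'   which is what lets antibody escape the surface "binding trap" and
#'   reach depth.
#' @export
kinetic_params_22c <- function() kinetic_params("22C", 1, 1, 1)

#' @rdname kinetic_params
#' @param elevated_diffusion if `FALSE`, keep `D_out` at the 22 C value
#'   so that the kinetic effect can be isolated from the diffusivity
#'   effect.
#' @export
kinetic_params_55c <- function(elevated_diffusion = TRUE) {
  kinetic_params(if (elevated_diffusion) "55C" else "55C_kinetics_only",
                 D_out = if (elevated_diffusion)
                   round(stokes_einstein_ratio(22, 55), 2) else 1,
                 k_on = 2, k_off = 60.75)
}

#' Association constant of a parameter set
#' @param params a `kinetic_params` object.
#' @return `k_on / k_off`.
#' @export
association_constant <- function(params) params$k_on / params$k_off

#' Stokes-Einstein diffusivity scaling between two temperatures
#'
#' Under the Stokes-Einstein relation with solvent viscosity and
#' hydrodynamic radius held constant, the diffusion coefficient scales
#' with absolute temperature, so D(T2)/D(T1) is the ratio of absolute
#' temperatures.
#'
#' @param T1_celsius,T2_celsius temperatures in degrees Celsius.
#' @return the scalar ratio D(T2)/D(T1).
#' @examples
#' stokes_einstein_ratio(22, 55) # ~1.11
#' @export
stokes_einstein_ratio <- function(T1_celsius, T2_celsius) {
  if (T1_celsius <= -273.15 || T2_celsius <= -273.15) {
    stop("temperatures must be above absolute zero (-273.15 C)")
  }
  (T2_celsius + 273.15) / (T1_celsius + 273.15)
}

#' Piecewise-in-time assignment of kinetic parameter sets
#'
#' @param phases list of phases, each a list with elements `start`
#'   (dimensionless time) and `params` (a [kinetic_params()] object).
#'   Starts must be strictly increasing, the first must be 0, and all
#'   must lie below `t_end`.
#' @param t_end end of the simulated interval.
#' @return object of class `rd_schedule`.
#' @export
rd_schedule <- function(phases, t_end = 1) {
  starts <- vapply(phases, function(p) p$start, numeric(1))
  stopifnot(length(phases) >= 1,
            starts[1] == 0,
            all(diff(starts) > 0),
            all(starts < t_end))
  for (p in phases) stopifnot(inherits(p$params, "kinetic_params"))
  structure(list(phases = phases, t_end = t_end), class = "rd_schedule")
}

#' @rdname rd_schedule
#' @param first,second parameter sets for the two phases.
#' @param t_switch time of the temperature change (default 0.95).
#' @export
two_phase_schedule <- function(first, second, t_switch = 0.95, t_end = 1) {
  rd_schedule(list(list(start = 0, params = first),
                   list(start = t_switch, params = second)),
              t_end = t_end)
}

#' Parameter set active at a given time
#'
#' Phases occupy half-open intervals `[start, next_start)`; the final
#' phase is closed at `t_end`.
#'
#' @param schedule an [rd_schedule()].
#' @param t dimensionless time in `[0, t_end]`.
#' @return the active `kinetic_params`.
#' @export
params_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "rd_schedule"))
  if (t < 0 || t > schedule$t_end) {
    stop("t = ", t, " outside the schedule range [0, ", schedule$t_end, "]")
  }
  starts <- vapply(schedule$phases, function(p) p$start, numeric(1))
  i <- findInterval(t, starts)
  schedule$phases[[i]]$params
}

#' Simulation configuration
#'
#' Defaults reproduce the canonical setup: domain radius 2, cylinder
#' radius 1, 1,000 radial and 500 temporal grid points, initial free
#' antibody 50 outside the cylinder and 0 inside, initial antigen 50
#' inside, complex 0 everywhere, and a fixed antibody reservoir of 50 at
#' the outer boundary.
#'
#' @param r_max outer radius of the domain.
#' @param cylinder_radius radius of the antigen-bearing cylinder.
#' @param n_r,n_t number of (evenly spaced) radial and temporal points.
#' @param ab_boundary fixed free-antibody value at `r = r_max`.
#' @param ab_init_out initial free antibody outside the cylinder.
#' @param ag_init_in initial antigen inside the cylinder.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(r_max = 2, cylinder_radius = 1, n_r = 1000,
                       n_t = 500, ab_boundary = 50, ab_init_out = 50,
                       ag_init_in = 50) {
  stopifnot(cylinder_radius > 0, cylinder_radius < r_max,
            n_r >= 3, n_t >= 2,
            ab_boundary >= 0, ab_init_out >= 0, ag_init_in >= 0)
  structure(list(r_max = r_max, cylinder_radius = cylinder_radius,
                 n_r = as.integer(n_r), n_t = as.integer(n_t),
                 ab_boundary = ab_boundary, ab_init_out = ab_init_out,
                 ag_init_in = ag_init_in),
            class = "sim_config")
}

# Right-hand side of the method-of-lines system. Finite-volume radial
# diffusion with harmonic-mean interface diffusivity (conserves flux
# across the step change at the cylinder wall); the r = 0 cell uses the
# symmetric limit 4 D (ab[2] - ab[1]) / dr^2; the outer node is held at
# the Dirichlet value (zero time derivative).
rd_rhs <- function(t, y, p) {
  n <- p$n
  ab <- y[seq_len(n)]
  ag <- y[n + seq_len(n)]
  cx <- y[2L * n + seq_len(n)]
  react <- p$k_on * ab * ag - p$k_off * cx
  flux <- p$D_iface * (ab[-1L] - ab[-n]) / p$dr
  div <- numeric(n)
  div[1L] <- 4 * p$D_iface[1L] * (ab[2L] - ab[1L]) / p$dr^2
  j <- 2:(n - 1L)
  div[j] <- (p$r_half[j] * flux[j] - p$r_half[j - 1L] * flux[j - 1L]) /
    (p$r[j] * p$dr)
  dab <- div - react
  dab[n] <- 0
  list(c(dab, -react, react))
}

#' Solve the reaction-diffusion system
#'
#' Method of lines on the fixed radial grid with a stiff implicit time
#' integrator (banded Jacobian via [deSolve::ode.1D()]). The integrator
#' is restarted at every phase boundary so parameter switches are
#' applied exactly, not smeared by step control.
#'
#' @param config a [sim_config()].
#' @param schedule an [rd_schedule()].
#' @param rtol,atol integrator tolerances.
#' @return object of class `rd_solution`: list with `r` (radii), `t`
#'   (times), and `n_r x n_t` matrices `ab`, `ag`, `ab_ag`.
#' @export
solve_rd <- function(config, schedule, rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(config, "sim_config"), inherits(schedule, "rd_schedule"))
  n <- config$n_r
  r <- seq(0, config$r_max, length.out = n)
  dr <- r[2] - r[1]
  inside <- r <= config$cylinder_radius + 1e-12
  t_grid <- seq(0, schedule$t_end, length.out = config$n_t)

  ab0 <- ifelse(inside, 0, config$ab_init_out)
  ab0[n] <- config$ab_boundary
  ag0 <- ifelse(inside, config$ag_init_in, 0)
  y <- c(ab0, ag0, numeric(n))

  starts <- vapply(schedule$phases, function(p) p$start, numeric(1))
  ends <- c(starts[-1], schedule$t_end)
  out_ab <- matrix(NA_real_, n, config$n_t)
  out_ag <- matrix(NA_real_, n, config$n_t)
  out_cx <- matrix(NA_real_, n, config$n_t)

  for (i in seq_along(schedule$phases)) {
    kp <- schedule$phases[[i]]$params
    D_node <- kp$D_out * ifelse(inside, kp$D_in_factor, 1)
    parms <- list(n = n, dr = dr, r = r,
                  r_half = (r[-1] + r[-n]) / 2,
                  D_iface = 2 * D_node[-1] * D_node[-n] /
                    (D_node[-1] + D_node[-n]),
                  k_on = kp$k_on, k_off = kp$k_off)
    keep <- which(if (i < length(schedule$phases))
      t_grid >= starts[i] & t_grid < ends[i]
      else t_grid >= starts[i])
    times <- sort(unique(c(starts[i], t_grid[keep], ends[i])))
    # collapse grid times that coincide with a phase boundary up to
    # floating-point noise (the integrator rejects near-duplicate times)
    times <- times[c(TRUE, diff(times) > 1e-12)]
    sol <- deSolve::ode.1D(y = y, times = times, func = rd_rhs,
                           parms = parms, nspec = 3, dimens = n,
                           method = "lsoda", rtol = rtol, atol = atol)
    istate <- attributes(sol)$istate[1]
    if (is.null(istate) || istate < 0 || nrow(sol) < length(times)) {
      stop("reaction-diffusion integration failed in phase ", i,
           " near t = ", sol[nrow(sol), 1])
    }
    rows <- vapply(t_grid[keep],
                   function(tt) which.min(abs(sol[, 1] - tt)), integer(1))
    out_ab[, keep] <- t(sol[rows, 1 + seq_len(n), drop = FALSE])
    out_ag[, keep] <- t(sol[rows, 1 + n + seq_len(n), drop = FALSE])
    out_cx[, keep] <- t(sol[rows, 1 + 2 * n + seq_len(n), drop = FALSE])
    y <- as.numeric(sol[nrow(sol), -1])
  }
  # final grid time belongs to the last phase's closed end
  neg_tol <- 1e-8 * max(config$ab_boundary, config$ab_init_out,
                        config$ag_init_in, 1)
  low <- min(out_ab, out_ag, out_cx)
  if (low < -neg_tol) {
    stop("negative concentrations beyond tolerance: min = ", low)
  }
  structure(list(r = r, t = t_grid, ab = out_ab, ag = out_ag,
                 ab_ag = out_cx, inside = inside, config = config,
                 schedule = schedule),
            class = "rd_solution")
}

#' Radial concentration profile at a fixed time
#'
#' @param solution an [solve_rd()] result.
#' @param t requested time; the nearest stored time point is used
#'   (no interpolation).
#' @param species one of `"ab"`, `"ag"`, `"ab_ag"`.
#' @return object of class `radial_profile`: list with `r`, `value`,
#'   `inside` (inside-cylinder indicator) and `t_actual`.
#' @export
profile_at <- function(solution, t, species = c("ab_ag", "ab", "ag")) {
  stopifnot(inherits(solution, "rd_solution"))
  species <- match.arg(species)
  if (t < min(solution$t) || t > max(solution$t)) {
    stop("t outside the stored time range")
  }
  it <- which.min(abs(solution$t - t))
  structure(list(r = solution$r, value = solution[[species]][, it],
                 inside = solution$inside, t_actual = solution$t[it],
                 species = species),
            class = "radial_profile")
}

#' Penetration and homogeneity metrics of a radial profile
#'
#' Summarizes how deep and how uniform the bound-complex profile is
#' inside the cylinder: mean, standard deviation and coefficient of
#' variation over inside-cylinder points, and the ratio of the value at
#' the cylinder center to the value at the cylinder boundary. A
#' homogeneously stained cylinder has low `cv_in` and a
#' `center_edge_ratio` near 1; surface-trapped staining has a high CV
#' and a ratio near 0.
#'
#' @param profile a [profile_at()] result (>= 2 inside-cylinder points).
#' @return list with `mean_in`, `sd_in`, `cv_in`, `center_edge_ratio`.
#'   Degenerate all-zero profiles give `cv_in = 0` and ratio 1; a zero
#'   edge with nonzero center gives ratio `Inf`.
#' @export
penetration_metrics <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  v <- profile$value[profile$inside]
  r <- profile$r[profile$inside]
  if (length(v) < 2) stop("need at least 2 inside-cylinder points")
  m <- mean(v)
  s <- sd(v)
  center <- v[which.min(r)]
  edge <- v[which.max(r)]
  ratio <- if (center == 0 && edge == 0) 1
           else if (edge == 0) Inf
           else center / edge
  list(mean_in = m, sd_in = s,
       cv_in = if (m == 0) 0 else s / m,
       center_edge_ratio = ratio)
}

#' Canonical staining scenarios
#'
#' Runs the four combinations of binding kinetics (room temperature
#' throughout versus heated kinetics during the long first phase with a
#' return to room temperature at `t_switch`) and diffusivity (baseline
#' versus Stokes-Einstein-elevated), and summarizes the final
#' bound-complex profile of each.
#'
#' @param config a [sim_config()]; smaller grids are fine for relative
#'   comparisons.
#' @param t_switch time of the temperature change.
#' @return data.frame with one row per scenario: label, kinetic and
#'   diffusion settings, and the [penetration_metrics()] of the final
#'   bound-complex profile.
#' @export
rd_scenarios <- function(config = sim_config(), t_switch = 0.95) {
  p22 <- kinetic_params_22c()
  d_hi <- round(stokes_einstein_ratio(22, 55), 2)
  scen <- list(
    conventional = rd_schedule(list(list(start = 0, params = p22)),
                               t_end = 1),
    diffusion_only = rd_schedule(list(list(
      start = 0, params = kinetic_params("22C_highD", d_hi, 1, 1))),
      t_end = 1),
    kinetics_only = two_phase_schedule(
      kinetic_params_55c(elevated_diffusion = FALSE), p22,
      t_switch = t_switch),
    heated = two_phase_schedule(
      kinetic_params_55c(elevated_diffusion = TRUE), p22,
      t_switch = t_switch)
  )
  rows <- lapply(names(scen), function(nm) {
    sol <- solve_rd(config, scen[[nm]])
    pm <- penetration_metrics(profile_at(sol, max(sol$t), "ab_ag"))
    kp <- scen[[nm]]$phases[[1]]$params
    data.frame(scenario = nm, first_phase = kp$label, D_out = kp$D_out,
               k_on = kp$k_on, k_off = kp$k_off,
               mean_in = pm$mean_in, sd_in = pm$sd_in, cv_in = pm$cv_in,
               center_edge_ratio = pm$center_edge_ratio)
  })
  do.call(rbind, rows)
}
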