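#' Radial discretization of the chamber annulus
#'
#' Uniform node-centred grid from `r_inner` to `r_outer`.  The requested
#' spacing is adjusted (never enlarged) so that the outer wall falls
#' exactly on the last node.
#'
#' @param geom A [chamber_geometry()].
#' @param spacing Target node spacing, um (default 10).
#' @return An object of class `radial_grid` with `nodes` (um) and the
#'   actual `spacing` (um).
#' @export
radial_grid <- function(geom = chamber_geometry(), spacing = 10) {
  stopifnot(inherits(geom, "chamber_geometry"))
  check_scalar(spacing, "spacing")
  span <- geom$r_outer - geom$r_inner
  n_int <- max(ceiling(span / spacing), 15L)
  nodes <- seq(geom$r_inner, geom$r_outer, length.out = n_int + 1L)
  structure(list(nodes = nodes, spacing = span / n_int),
            class = "radial_grid")
}

#' Radial concentration profile
#'
#' A concentration profile C(r) at one time point on a [radial_grid()].
#'
#' @param grid A [radial_grid()].
#' @param C Concentrations at the grid nodes, uM.
#' @param time Time stamp, s.
#' @param species Species label.
#' @param c_ref Reference (boundary/bulk) concentration, uM; used to
#'   validate front thresholds.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(grid, C, time = NA_real_,
                                  species = "species", c_ref = max(C)) {
  stopifnot(inherits(grid, "radial_grid"))
  if (length(C) != length(grid$nodes))
    stop_reec("'C' must have one value per grid node")
  if (any(!is.finite(C)) || any(C < 0))
    stop_reec("concentrations must be finite and >= 0")
  structure(list(grid = grid, C = as.numeric(C), time = time,
                 species = species, c_ref = c_ref),
            class = "concentration_profile")
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("%s profile at t = %g s: %d nodes, %g-%g um, C in [%.4g, %.4g] uM\n",
              x$species, x$time, length(x$C), min(x$grid$nodes),
              max(x$grid$nodes), min(x$C), max(x$C)))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(species = x$species, time_s = x$time, r_um = x$grid$nodes,
             C_uM = x$C)
}

#' @export
plot.concentration_profile <- function(x, ...) {
  graphics::plot(x$grid$nodes, x$C, type = "l", xlab = "r (um)",
                 ylab = paste0("[", x$species, "] (uM)"), ...)
  invisible(x)
}

#' Simulation settings
#'
#' @param t_end Simulated horizon, s (default 172800 = 48 h).
#' @param inspection_interval Cadence at which profiles are stored and the
#'   steady-state criterion is evaluated, s (default 60).
#' @param rms_tol Convergence tolerance: relative RMS change between
#'   successive inspected profiles, normalized by `C_bulk` (default 0.001,
#'   i.e. 0.1%).
#' @param spacing Grid spacing, um (default 10).
#' @param linear_consumption If `TRUE`, replace the saturating uptake
#'   response by its dilute limit `f(C) = C`, for which the steady state
#'   has a modified-Bessel closed form ([steady_linear_annulus()]).
#' @param initial_uM Initial condition, uM: `NULL` (default) for the
#'   uniform bulk concentration that holds the moment the chamber top is
#'   placed, or a scalar/per-node vector.
#' @param rtol,atol_rel Relative tolerance and relative absolute tolerance
#'   (times `C_bulk`) passed to the stiff integrator.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(t_end = 172800, inspection_interval = 60,
                              rms_tol = 0.001, spacing = 10,
                              linear_consumption = FALSE,
                              initial_uM = NULL,
                              rtol = 1e-8, atol_rel = 1e-8) {
  check_scalar(t_end, "t_end")
  check_scalar(inspection_interval, "inspection_interval")
  check_scalar(rms_tol, "rms_tol")
  if (rms_tol >= 1) stop_reec("'rms_tol' must be in (0, 1)")
  check_scalar(spacing, "spacing")
  structure(list(t_end = t_end, inspection_interval = inspection_interval,
                 rms_tol = rms_tol, spacing = spacing,
                 linear_consumption = isTRUE(linear_consumption),
                 initial_uM = initial_uM, rtol = rtol, atol_rel = atol_rel),
            class = "simulation_config")
}

#' Transient solution of the radial diffusion-consumption equation
#'
#' Solves
#' \deqn{\partial C/\partial t = (1/r)\,\partial/\partial r\,(r D\,
#'   \partial C/\partial r) - n\,k\,f(C)}
#' on the chamber annulus with a fixed concentration `C_bulk` at the
#' aperture radius (the opening acts as a constant source), zero flux at
#' the outer wall, and a uniform initial condition `C_bulk` (the moment
#' the chamber top is placed).  `f` is the saturating uptake response
#' (see [consumption_term()]), or `f(C) = C` in linear mode.
#'
#' Discretization is conservative finite volumes on a uniform radial grid;
#' time integration is `deSolve`'s stiff `lsoda` method-of-lines solver
#' with a banded Jacobian, which is unconditionally stable against the
#' fast consumption timescale (~1/(n k), minutes) relative to the 48 h
#' horizon.  Snapshots are stored at every inspection interval.
#'
#' @param species A [transport_params()].
#' @param consumers A [consumer_field()].
#' @param geom A [chamber_geometry()].
#' @param config A [simulation_config()].
#' @return An object of class `simulation_result`: a list with `times`
#'   (s), `C` (snapshot matrix, one row per time, one column per node,
#'   inner Dirichlet node included), `grid`, `rms_history` (relative RMS
#'   change between successive snapshots, normalized by `C_bulk`),
#'   `converged`, `convergence_time` (s, `NA` if never converged) and the
#'   inputs.
#' @examples
#' \donttest{
#' res <- simulate_transient(oxygen_params(), consumer_field(),
#'                           config = simulation_config(t_end = 7200))
#' res
#' }
#' @export
simulate_transient <- function(species, consumers = consumer_field(),
                               geom = chamber_geometry(),
                               config = simulation_config()) {
  stopifnot(inherits(species, "transport_params"),
            inherits(consumers, "consumer_field"),
            inherits(geom, "chamber_geometry"),
            inherits(config, "simulation_config"))

  grid <- radial_grid(geom, config$spacing)
  r <- grid$nodes
  N <- length(r)
  h <- grid$spacing
  D <- species$D
  Cb <- species$C_bulk
  Km <- species$half_saturation
  nk <- consumers$volumetric_density * per_cell_rate(species)

  if (nk > 0) {
    lam <- sqrt(D / nk)
    if (h > lam / 10)
      warning(sprintf(paste0("grid spacing %.3g um does not resolve the ",
                             "characteristic length %.3g um (want <= lambda/10)"),
                      h, lam))
  }

  r_half <- (r[-1] + r[-N]) / 2   # interface radii
  linear <- config$linear_consumption

  rhs <- function(t, y, parms) {
    C <- c(Cb, y)                              # Dirichlet inner node
    flux <- r_half * D * diff(C) / h           # r D dC/dr at interfaces
    div <- (c(flux[-1], 0) - flux) / (r[-1] * h)  # outer wall: zero flux
    Cpos <- pmax(C[-1], 0)
    cons <- if (linear) nk * Cpos else
      nk * saturating_response(Cpos, Cb, Km)
    list(div - cons)
  }

  y0 <- if (is.null(config$initial_uM)) rep(Cb, N - 1L) else {
    init <- config$initial_uM
    if (length(init) == 1L) rep(init, N - 1L)
    else if (length(init) == N) init[-1L]
    else stop_reec("'initial_uM' must be a scalar or one value per node")
  }

  times <- seq(0, config$t_end, by = config$inspection_interval)
  if (times[length(times)] < config$t_end) times <- c(times, config$t_end)

  out <- deSolve::ode.1D(y = y0, times = times, func = rhs, parms = NULL,
                         nspec = 1L, dimens = N - 1L, method = "lsoda",
                         rtol = config$rtol, atol = config$atol_rel * Cb)
  C <- cbind(Cb, unname(out[, -1, drop = FALSE]))

  if (any(!is.finite(C)))
    stop_reec("solver instability: non-finite concentrations ",
              "(grid spacing ", format(h), " um); tighten tolerances")
  neg_floor <- -1e-9 * Cb
  if (min(C) < neg_floor)
    stop_reec("solver instability: concentration ", format(min(C)),
              " uM below round-off floor (grid spacing ", format(h), " um)")
  C[C < 0] <- 0                          # round-off only, |C| < 1e-9 C_bulk
  C[C > Cb] <- pmin(C[C > Cb], Cb * (1 + 1e-9))
  C[C > Cb] <- Cb                        # maximum-principle round-off

  dC <- diff(C)
  rms_history <- sqrt(rowMeans(dC^2)) / Cb
  conv_idx <- which(rms_history < config$rms_tol)[1]
  converged <- !is.na(conv_idx)

  structure(list(
    times = times, C = C, grid = grid,
    rms_history = rms_history,
    converged = converged,
    convergence_time = if (converged) times[conv_idx + 1L] else NA_real_,
    species = species, consumers = consumers, geom = geom, config = config
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("%s diffusion-consumption run: %d snapshots to t = %g h, %d nodes\n",
              x$species$name, length(x$times), max(x$times) / 3600,
              length(x$grid$nodes)))
  if (x$converged)
    cat(sprintf("converged (relative RMS change < %g) at t = %g s (%.2f h)\n",
                x$config$rms_tol, x$convergence_time,
                x$convergence_time / 3600))
  else cat("did not converge within the horizon\n")
  invisible(x)
}

#' Extract the snapshot closest to a requested time
#'
#' @param result A [simulate_transient()] result.
#' @param time Requested time, s.
#' @return A [concentration_profile()].
#' @export
profile_at <- function(result, time) {
  stopifnot(inherits(result, "simulation_result"))
  i <- which.min(abs(result$times - time))
  concentration_profile(result$grid, result$C[i, ], time = result$times[i],
                        species = result$species$name,
                        c_ref = result$species$C_bulk)
}

#' Steady-state concentration profile
#'
#' Time-marches the transient model and declares convergence at the first
#' inspection interval whose profile differs from its predecessor by a
#' relative RMS change (normalized by `C_bulk`) below `rms_tol` (default
#' 0.1%).  The returned profile is the final snapshot of the horizon,
#' which at that point is stationary to well within the tolerance; the
#' first-crossing time is reported as `convergence_time`.
#'
#' @inheritParams simulate_transient
#' @return A list of class `steady_state`: `profile` (a
#'   [concentration_profile()]), `converged`, `convergence_time` (s) and
#'   `rms_history`.  Failure to converge within the horizon flags
#'   `converged = FALSE`; it is not an error.
#' @export
solve_steady_state <- function(species, consumers = consumer_field(),
                               geom = chamber_geometry(),
                               config = simulation_config()) {
  res <- simulate_transient(species, consumers, geom, config)
  prof <- profile_at(res, max(res$times))
  if (!all(diff(prof$C) <= 1e-6 * species$C_bulk))
    warning("steady profile is not monotone non-increasing in r")
  structure(list(profile = prof, converged = res$converged,
                 convergence_time = res$convergence_time,
                 rms_history = res$rms_history),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady state (", if (x$converged) "converged" else "NOT converged",
      if (x$converged) sprintf(" at %.2f h", x$convergence_time / 3600),
      ")\n", sep = "")
  print(x$profile)
  invisible(x)
}

#' Closed-form steady state for linear consumption
#'
#' With the dilute-limit response `f(C) = C` the steady transport equation
#' on the annulus is a modified Bessel equation; with a fixed
#' concentration at `r_inner` and zero flux at `r_outer` the solution is
#' \deqn{C(r) = C_b \frac{I_0(r/\lambda) K_1(r_2/\lambda) +
#'   K_0(r/\lambda) I_1(r_2/\lambda)}{I_0(r_1/\lambda) K_1(r_2/\lambda) +
#'   K_0(r_1/\lambda) I_1(r_2/\lambda)}}
#' with \eqn{\lambda = \sqrt{D/(nk)}}.  Evaluated with exponentially
#' scaled Bessel functions so the expression stays finite for small
#' \eqn{\lambda}.
#'
#' @param r Radii at which to evaluate, um.
#' @param lambda Characteristic length, um (see
#'   [characteristic_length()]).
#' @param r_inner,r_outer Annulus radii, um.
#' @param C_bulk Source concentration, uM.
#' @return Concentrations at `r`, uM.
#' @export
steady_linear_annulus <- function(r, lambda, r_inner = 350, r_outer = 6000,
                                  C_bulk = 171) {
  check_scalar(lambda, "lambda")
  a <- r / lambda
  a1 <- r_inner / lambda
  a2 <- r_outer / lambda
  # I0(a)K1(a2) + K0(a)I1(a2), scaled: In~ = I e^-x, Kn~ = K e^x
  num <- besselK(a, 0, TRUE) * besselI(a2, 1, TRUE) +
    exp(2 * (a - a2)) * besselI(a, 0, TRUE) * besselK(a2, 1, TRUE)
  den <- besselK(a1, 0, TRUE) * besselI(a2, 1, TRUE) +
    exp(2 * (a1 - a2)) * besselI(a1, 0, TRUE) * besselK(a2, 1, TRUE)
  C_bulk * exp(a1 - a) * num / den
}

#' Concentration front position
#'
#' Distance from the opening edge at which the concentration first falls
#' to a threshold, scanning outward: the smallest r with C(r) <= threshold,
#' linearly interpolated between grid nodes, reported as `r - r_inner`.
#' This is the model-side analog of the reporter-derived hypoxic front
#' (see [hypoxic_front()]): dissolved oxygen below the reporter-activation
#' threshold marks cells as hypoxic.
#'
#' @param profile A [concentration_profile()].
#' @param threshold Threshold concentration, uM; must lie strictly between
#'   0 and the profile's reference concentration.
#' @return Distance from the opening edge, um, or `NA` if the profile
#'   never crosses the threshold.
#' @export
front_from_concentration <- function(profile, threshold) {
  stopifnot(inherits(profile, "concentration_profile"))
  check_scalar(threshold, "threshold")
  if (threshold >= profile$c_ref)
    stop_reec("'threshold' must be below the reference concentration ",
              format(profile$c_ref), " uM")
  C <- profile$C
  r <- profile$grid$nodes
  if (any(diff(C) > 1e-6 * max(profile$c_ref, 1)))
    warning("profile is not monotone non-increasing; using first crossing")
  i <- which(C <= threshold)[1]
  if (is.na(i)) return(NA_real_)
  r_cross <- if (i == 1L) r[1] else
    r[i - 1] + (C[i - 1] - threshold) / (C[i - 1] - C[i]) * (r[i] - r[i - 1])
  r_cross - r[1]
}
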