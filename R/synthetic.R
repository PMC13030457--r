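## Synthetic trapped-particle data: overdamped Brownian motion in a harmonic
## trap with a slowly growing drag (ligand monolayer) and a phenomenological
## quadrant-photodiode detector model producing X, Y and SUM channels.

#' Stokes drag of a sphere
#'
#' \eqn{\gamma = 6 \pi \eta a} for a sphere of radius `radius` in a fluid of
#' dynamic viscosity `viscosity`.
#'
#' @param radius Sphere radius, m (non-negative).
#' @param viscosity Dynamic viscosity, Pa s (positive).
#' @return Friction coefficient, N s/m. Vectorised over `radius`.
#' @examples
#' stokes_drag(2.4e-6, 8.9e-4)  # ~4.03e-8 N s/m
#' @export
stokes_drag <- function(radius, viscosity) {
  if (!is.numeric(radius) || any(!is.finite(radius)) || any(radius < 0))
    stop("'radius' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(viscosity) || length(viscosity) != 1 ||
      !is.finite(viscosity) || viscosity <= 0)
    stop("'viscosity' must be a single positive number", call. = FALSE)
  6 * pi * viscosity * radius
}

#' Bound fraction of surface sites at time t
#'
#' Pseudo-first-order association: the fraction of the maximal
#' ligand-receptor complex formed by time `t` is
#' \eqn{1 - \exp(-K_{obs} \max(0, t - t_0))} with
#' \eqn{K_{obs} = k_{off} + k_{on}[L]}.
#'
#' @param schedule A [binding_schedule()].
#' @param t Time(s), s; must be non-negative.
#' @return Fraction in `[0, 1]`, same length as `t`.
#' @export
bound_fraction <- function(schedule, t) {
  stopifnot(inherits(schedule, "binding_schedule"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  kobs <- observed_rate(schedule)
  1 - exp(-kobs * pmax(0, t - schedule$start_time))
}

#' Drag schedule during monolayer formation
#'
#' Composes Stokes' law with the binding model: the effective radius grows
#' from `bare_radius` to `bare_radius + layer_thickness` as the monolayer
#' forms, so
#' \eqn{\gamma(t) = 6\pi\eta\,(a_0 + h\,\phi(t))} with \eqn{\phi} the
#' [bound_fraction()].
#'
#' @param trap A [trap_config()].
#' @param schedule A [binding_schedule()].
#' @param times Non-empty, non-decreasing time grid, s.
#' @return Numeric vector of friction coefficients, N s/m.
#' @export
gamma_schedule <- function(trap, schedule, times) {
  stopifnot(inherits(trap, "trap_config"), inherits(schedule, "binding_schedule"))
  if (length(times) == 0) stop("'times' must be non-empty", call. = FALSE)
  if (is.unsorted(times)) stop("'times' must be non-decreasing", call. = FALSE)
  radius <- trap$bare_radius +
    schedule$layer_thickness * bound_fraction(schedule, times)
  stokes_drag(radius, trap$viscosity)
}

## deterministic substream seeds below 2^31, exact in double arithmetic
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% m
  as.integer(((master %% m) * 48271 + h * 16807) %% m)
}

#' Simulate a trapped-particle trajectory
#'
#' Integrates per-axis overdamped Ornstein-Uhlenbeck dynamics
#' \eqn{\gamma(t)\dot x = -k x + \sqrt{2 k_B T \gamma(t)}\,W(t)}
#' with the instantaneous drag from [gamma_schedule()]. The default
#' integrator uses the exact one-step OU update (drag frozen within each
#' step -- the binding time scale exceeds the trap relaxation time by >= 1e4),
#' so there is no discretisation bias and no step-size restriction;
#' `"euler_maruyama"` is available as a cross-check and refuses steps with
#' `stiffness * dt / gamma >= 1`. Each axis consumes an independent RNG
#' substream derived from `sim$seed`; identical configurations reproduce
#' bit-identical trajectories.
#'
#' @param trap A [trap_config()].
#' @param schedule A [binding_schedule()].
#' @param sim A [sim_config()].
#' @param x0,y0 Optional initial displacements, m. Default: a draw from the
#'   stationary distribution `N(0, kB T / k)` so the record is stationary
#'   from the first sample (zero when `temperature` is at the zero-noise
#'   test hook, see `zero_temperature`).
#' @param zero_temperature Test hook: suppress thermal forcing (noiseless
#'   relaxation) while keeping the configured temperature for bookkeeping.
#' @return An object of class `trajectory`: list with `times`, `x`, `y`,
#'   `gamma_true`, `sampling_rate` and the three configuration objects.
#' @examples
#' tr <- simulate_trajectory(trap_config(), binding_schedule(),
#'                           sim_config(duration = 2, seed = 7))
#' var(tr$x)  # ~ kB T / kx
#' @export
simulate_trajectory <- function(trap, schedule, sim, x0 = NULL, y0 = NULL,
                                zero_temperature = FALSE) {
  stopifnot(inherits(trap, "trap_config"),
            inherits(schedule, "binding_schedule"),
            inherits(sim, "sim_config"))
  fs <- sim$sampling_rate
  dt <- 1 / fs
  n <- round(sim$duration * fs)
  if (n < 2) stop("duration too short for the sampling rate", call. = FALSE)
  times <- (0:(n - 1)) * dt
  gam <- gamma_schedule(trap, schedule, times)
  kT <- if (zero_temperature) 0 else .kB * trap$temperature

  one_axis <- function(k, label, init) {
    set.seed(derive_seed(sim$seed, label))
    sigma2 <- kT / k
    start <- if (is.null(init)) rnorm(1, 0, sqrt(sigma2)) else init
    ## drag frozen at the value at the start of each step (quasi-static)
    g <- gam[-n]
    if (sim$integrator == "overdamped_exact") {
      a <- exp(-k * dt / g)
      b <- sqrt(sigma2 * (1 - a^2))
    } else {
      r <- k * dt / g
      if (max(r) >= 1)
        stop(sprintf(
          "euler_maruyama unstable: stiffness*dt/gamma = %.3g >= 1; %s",
          max(r), "reduce dt or use integrator = 'overdamped_exact'"),
          call. = FALSE)
      a <- 1 - r
      b <- sqrt(2 * kT * dt / g)
    }
    eps <- rnorm(n - 1)
    c(start, .linear_recursion(a, b, eps, start))
  }

  structure(list(times = times,
                 x = one_axis(trap$stiffness_x, "axis_x", x0),
                 y = one_axis(trap$stiffness_y, "axis_y", y0),
                 gamma_true = gam, sampling_rate = fs,
                 trap = trap, schedule = schedule, sim = sim),
            class = "trajectory")
}

#' Render detector channels from a trajectory
#'
#' Phenomenological quadrant-photodiode model: `X = gain_x * x + noise`,
#' `Y = gain_y * y + noise`, and
#' `SUM = sum_baseline * (1 + sum_coupling * bound_fraction(t)) + noise`.
#' The coverage-coupled SUM embodies the detection-gain shift caused by the
#' growing surface layer: downstream analysis works on X/SUM and Y/SUM, so a
#' SUM increase scales the apparent diffusion down and the effective
#' friction coefficient up, on top of the (much smaller) hydrodynamic drag
#' change. Additive channel noise is white with one-sided PSD `noise_floor`
#' in normalized units (scaled by `sum_baseline` into detector units).
#'
#' @param traj A `trajectory` from [simulate_trajectory()].
#' @param sim,schedule Defaults taken from the trajectory.
#' @param particle_id Identifier stored with the record.
#' @return A [qpd_record()].
#' @export
render_qpd <- function(traj, sim = traj$sim, schedule = traj$schedule,
                       particle_id = "P1") {
  stopifnot(inherits(traj, "trajectory"), inherits(sim, "sim_config"),
            inherits(schedule, "binding_schedule"))
  n <- length(traj$times)
  fs <- traj$sampling_rate
  phi <- bound_fraction(schedule, traj$times)
  noise_sd <- sqrt(sim$noise_floor * fs / 2) * sim$sum_baseline

  channel_noise <- function(label) {
    if (noise_sd == 0) return(0)
    set.seed(derive_seed(sim$seed, label))
    rnorm(n, 0, noise_sd)
  }
  X <- sim$gain_x * traj$x + channel_noise("detector_x")
  Y <- sim$gain_y * traj$y + channel_noise("detector_y")
  SUM <- sim$sum_baseline * (1 + sim$sum_coupling * phi) +
    channel_noise("detector_sum")
  if (any(SUM <= 0))
    stop("detector configuration produced non-positive SUM samples",
         call. = FALSE)
  qpd_record(times = traj$times, X = X, Y = Y, SUM = SUM,
             sampling_rate = fs, particle_id = particle_id)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trapped-particle trajectory: %d samples at %g Hz (%.1f s)\n",
              length(x$times), x$sampling_rate,
              length(x$times) / x$sampling_rate))
  cat(sprintf("  gamma(t): %.4g -> %.4g N s/m\n",
              x$gamma_true[1], x$gamma_true[length(x$gamma_true)]))
  invisible(x)
}
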