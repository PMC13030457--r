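## Configuration objects for the trapped-particle simulator and the
## spectral analysis chain. All constructors validate eagerly so that a bad
## parameter fails at construction, not deep inside a simulation loop.

.check_positive <- function(x, name, strict = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("'%s' must be finite", name), call. = FALSE)
  if (strict && x <= 0)
    stop(sprintf("'%s' must be strictly positive (got %g)", name, x), call. = FALSE)
  if (!strict && x < 0)
    stop(sprintf("'%s' must be non-negative (got %g)", name, x), call. = FALSE)
  invisible(x)
}

#' Optical trap and medium parameters
#'
#' Physical constants of the trap and the immersion medium used both by the
#' simulator and by the friction-coefficient convention \eqn{\gamma^* =
#' k_B T / D}. Defaults describe a 4.8 um bead in water at 25 C held in a
#' trap of stiffness 1e-5 N/m per axis.
#'
#' @param temperature Medium temperature in kelvin. Must lie in the
#'   [273, 373] K sanity band.
#' @param viscosity Dynamic viscosity of the medium, Pa s.
#' @param stiffness_x,stiffness_y Trap stiffness per axis, N/m.
#' @param bare_radius Radius of the uncoated particle, m.
#' @return An object of class `trap_config`.
#' @examples
#' trap_config()
#' trap_config(temperature = 300, stiffness_x = 2e-5)
#' @export
trap_config <- function(temperature = 298.15, viscosity = 8.9e-4,
                        stiffness_x = 1e-5, stiffness_y = 1e-5,
                        bare_radius = 2.4e-6) {
  .check_positive(temperature, "temperature")
  if (temperature < 273 || temperature > 373)
    stop("'temperature' outside the [273, 373] K sanity band; supply kelvin",
         call. = FALSE)
  .check_positive(viscosity, "viscosity")
  .check_positive(stiffness_x, "stiffness_x")
  .check_positive(stiffness_y, "stiffness_y")
  .check_positive(bare_radius, "bare_radius")
  structure(list(temperature = temperature, viscosity = viscosity,
                 stiffness_x = stiffness_x, stiffness_y = stiffness_y,
                 bare_radius = bare_radius, boltzmann_constant = .kB),
            class = "trap_config")
}

#' Ligand-binding schedule for monolayer growth
#'
#' Describes pseudo-first-order association of a ligand onto the particle
#' surface. The bound fraction follows
#' \eqn{1 - \exp(-K_{obs} (t - t_0))} with the observed rate
#' \eqn{K_{obs} = k_{off} + k_{on} [L]}, and the effective particle radius
#' grows by `layer_thickness` times the bound fraction. Defaults state the
#' streptavidin-biotin demonstration system: kon = 1e6 /M/s, koff ~ 0
#' (ultra-high affinity), [L] = 5 nM, a 7 nm protein monolayer starting at
#' t = 0.
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param ligand_conc Ligand concentration, mol/L.
#' @param layer_thickness Full-monolayer thickness, m.
#' @param start_time Time at which ligand is introduced, s.
#' @return An object of class `binding_schedule`.
#' @seealso [bound_fraction()], [observed_rate()]
#' @export
binding_schedule <- function(kon = 1e6, koff = 0, ligand_conc = 5e-9,
                             layer_thickness = 7e-9, start_time = 0) {
  .check_positive(kon, "kon", strict = FALSE)
  .check_positive(koff, "koff", strict = FALSE)
  .check_positive(ligand_conc, "ligand_conc", strict = FALSE)
  .check_positive(layer_thickness, "layer_thickness", strict = FALSE)
  if (!is.numeric(start_time) || length(start_time) != 1 || !is.finite(start_time))
    stop("'start_time' must be a single finite number", call. = FALSE)
  structure(list(kon = kon, koff = koff, ligand_conc = ligand_conc,
                 layer_thickness = layer_thickness, start_time = start_time),
            class = "binding_schedule")
}

#' Observed pseudo-first-order rate constant
#'
#' @param schedule A [binding_schedule()].
#' @return `koff + kon * ligand_conc`, in 1/s.
#' @export
observed_rate <- function(schedule) {
  stopifnot(inherits(schedule, "binding_schedule"))
  schedule$koff + schedule$kon * schedule$ligand_conc
}

#' Acquisition and detector model settings
#'
#' Parameters of the synthetic acquisition: sampling, integrator choice,
#' detector gains and the phenomenological coupling between monolayer
#' coverage and total detected intensity (SUM). The acquisition rate is a
#' declared default (10 kHz), well above corner frequencies of tens of Hz.
#' `sum_coupling` is the fractional SUM change at full monolayer; it is the
#' free parameter that converts surface coverage into a detection-gain
#' shift, the effect that dominates the effective friction coefficient.
#'
#' @param sampling_rate Samples per second, Hz.
#' @param duration Record length, s.
#' @param seed Integer seed; one substream per axis and per detector channel
#'   is derived from it so axes are uncorrelated.
#' @param integrator `"overdamped_exact"` (closed-form one-step update, no
#'   step-size restriction) or `"euler_maruyama"` (cross-check; requires
#'   `stiffness * dt / gamma < 1`).
#' @param gain_x,gain_y Detector gain per axis, detector units per metre.
#' @param sum_baseline Baseline SUM level, detector units (> 0).
#' @param sum_coupling Fractional SUM change at full monolayer coverage.
#' @param noise_floor One-sided PSD level of additive detector noise in
#'   SUM-normalized units^2/Hz. Default 1e-22 models shot-noise-limited
#'   detection far below the in-band motion spectrum (about 1% of the
#'   Lorentzian tail at a quarter of the sampling rate for the default
#'   trap).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1e4, duration = 600, seed = 1L,
                       integrator = c("overdamped_exact", "euler_maruyama"),
                       gain_x = 1, gain_y = 1, sum_baseline = 1,
                       sum_coupling = 0.25, noise_floor = 1e-22) {
  integrator <- match.arg(integrator)
  .check_positive(sampling_rate, "sampling_rate")
  .check_positive(duration, "duration")
  .check_positive(gain_x, "gain_x")
  .check_positive(gain_y, "gain_y")
  .check_positive(sum_baseline, "sum_baseline")
  .check_positive(sum_coupling, "sum_coupling", strict = FALSE)
  .check_positive(noise_floor, "noise_floor", strict = FALSE)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != trunc(seed) || abs(seed) >= 2^31)
    stop("'seed' must be a single integer below 2^31", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed), integrator = integrator,
                 gain_x = gain_x, gain_y = gain_y,
                 sum_baseline = sum_baseline, sum_coupling = sum_coupling,
                 noise_floor = noise_floor),
            class = "sim_config")
}

#' Spectral-analysis settings
#'
#' Controls the friction-coefficient estimation chain: SUM-normalization,
#' discard of the unstable initial transient, 1-s segmentation, PSD
#' estimation and Lorentzian fitting.
#'
#' @param segment_length Segment duration, s (default 1 s).
#' @param discard_initial Seconds discarded from the start of each record
#'   (default 30 s, covering the post-trapping transient).
#' @param fit_band Two-element numeric `c(f_lo, f_hi)` in Hz. `f_hi = NA`
#'   resolves to `sampling_rate / 8` at fit time, keeping aliasing
#'   distortion of the sampled spectrum around the percent level; `f_lo`
#'   defaults to 5 Hz, excluding low-frequency drift.
#' @param psd_averaging `"single_periodogram"` (maximal frequency
#'   resolution, default) or `"welch_subblocks"`.
#' @param fit_space `"log_least_squares"` (default; least squares on the log
#'   periodogram with the Euler-Mascheroni/digamma bias correction) or
#'   `"weighted_linear"` (cross-check: weighted regression of 1/PSD on f^2
#'   after block-averaging).
#' @param temperature Temperature (K) entering \eqn{\gamma^* = k_B T / D};
#'   constant over a run.
#' @param bias_correction Apply the known bias correction for the expected
#'   log of exponential-distributed periodogram ordinates. Disable when
#'   fitting noiseless model curves.
#' @param welch_n Number of non-overlapping sub-blocks when
#'   `psd_averaging = "welch_subblocks"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(segment_length = 1, discard_initial = 30,
                            fit_band = c(5, NA),
                            psd_averaging = c("single_periodogram",
                                              "welch_subblocks"),
                            fit_space = c("log_least_squares",
                                          "weighted_linear"),
                            temperature = 298.15, bias_correction = TRUE,
                            welch_n = 4L) {
  psd_averaging <- match.arg(psd_averaging)
  fit_space <- match.arg(fit_space)
  .check_positive(segment_length, "segment_length")
  .check_positive(discard_initial, "discard_initial", strict = FALSE)
  .check_positive(temperature, "temperature")
  if (length(fit_band) != 2 || !is.numeric(fit_band))
    stop("'fit_band' must be numeric of length 2", call. = FALSE)
  if (is.na(fit_band[1]) || fit_band[1] <= 0)
    stop("'fit_band[1]' (f_lo) must be a positive frequency", call. = FALSE)
  if (!is.na(fit_band[2]) && fit_band[2] <= fit_band[1])
    stop("'fit_band[2]' must exceed 'fit_band[1]'", call. = FALSE)
  welch_n <- as.integer(welch_n)
  if (welch_n < 2) stop("'welch_n' must be at least 2", call. = FALSE)
  structure(list(segment_length = segment_length,
                 discard_initial = discard_initial, fit_band = fit_band,
                 psd_averaging = psd_averaging, fit_space = fit_space,
                 temperature = temperature, bias_correction = bias_correction,
                 welch_n = welch_n),
            class = "spectral_config")
}

#' @export
print.trap_config <- function(x, ...) {
  cat("Optical trap configuration\n")
  cat(sprintf("  temperature : %g K\n", x$temperature))
  cat(sprintf("  viscosity   : %g Pa s\n", x$viscosity))
  cat(sprintf("  stiffness   : kx = %g, ky = %g N/m\n",
              x$stiffness_x, x$stiffness_y))
  cat(sprintf("  bare radius : %g m\n", x$bare_radius))
  invisible(x)
}

#' @export
print.binding_schedule <- function(x, ...) {
  cat("Binding schedule (pseudo-first-order association)\n")
  cat(sprintf("  kon  = %g /M/s, koff = %g /s, [L] = %g M\n",
              x$kon, x$koff, x$ligand_conc))
  cat(sprintf("  Kobs = %g /s, layer = %g m, start = %g s\n",
              observed_rate(x), x$layer_thickness, x$start_time))
  invisible(x)
}
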