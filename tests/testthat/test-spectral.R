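make_qpd <- function(n, fs, X = NULL, Y = NULL, SUM = NULL, id = "t") {
  qpd_record(times = (0:(n - 1)) / fs,
             X = X %||% rep(0, n), Y = Y %||% rep(0, n),
             SUM = SUM %||% rep(1, n), sampling_rate = fs, particle_id = id)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("preprocess normalizes to SUM and drops the transient", {
  fs <- 100
  n <- 600 * fs
  set.seed(1)
  sm <- runif(n, 0.5, 2)
  rec <- make_qpd(n, fs, X = sm, Y = rnorm(n), SUM = sm)
  pre <- preprocess(rec, spectral_config(discard_initial = 30))
  expect_equal(pre$x, rep(1, (600 - 30) * fs))    # X == SUM -> constant 1
  expect_length(pre$y, (600 - 30) * fs)
  ## 570 one-second segments from a 10-min record after the 30-s discard
  expect_identical(ncol(segment(pre$x, spectral_config(), fs)), 570L)
})

test_that("preprocess rejects bad SUM and too-short records", {
  rec <- make_qpd(1000, 100)
  rec$SUM[501] <- 0  # bypass constructor validation on purpose
  err <- expect_error(preprocess(rec, spectral_config()), "sample 501")
  short <- make_qpd(1000, 100)  # 10 s < 30 s discard
  expect_error(preprocess(short, spectral_config()), "not longer")
})

test_that("segment partitions the channel and drops the tail", {
  fs <- 1000
  ch <- rnorm(5.5 * fs)
  cfg <- spectral_config()
  b <- segment(ch, cfg, fs)
  expect_identical(dim(b), c(1000L, 5L))
  expect_identical(as.vector(b), ch[1:5000])  # partition property
  expect_identical(ncol(segment(rnorm(fs), cfg, fs)), 1L)
  expect_error(segment(rnorm(10), cfg, fs), "shorter than one segment")
})

test_that("compute_psd satisfies Parseval and basic spectral shapes", {
  fs <- 1000
  cfg <- spectral_config()
  set.seed(2)
  w <- rnorm(fs)
  psd <- compute_psd(w, fs, cfg)
  df <- diff(psd$frequencies[1:2])
  vpop <- mean((w - mean(w))^2)
  expect_equal(sum(psd$power) * df, vpop, tolerance = 1e-12)  # exact
  ## white noise: flat one-sided level 2 sigma^2 / fs
  expect_equal(mean(psd$power), 2 * var(w) / fs, tolerance = 0.01)
  ## pure sinusoid: single dominant bin at 100 Hz
  s <- sin(2 * pi * 100 * (0:(fs - 1)) / fs)
  ps <- compute_psd(s, fs, cfg)
  expect_equal(ps$frequencies[which.max(ps$power)], 100)
  expect_gt(max(ps$power) / sum(ps$power), 0.999)
  ## zero signal
  expect_true(all(compute_psd(rep(0, 100), fs, cfg)$power == 0))
  expect_error(compute_psd(w, fs, cfg, times = cumsum(runif(fs))),
               "non-uniform")
})

test_that("welch averaging reduces variance on a coarser grid", {
  fs <- 2000
  cfg <- spectral_config(psd_averaging = "welch_subblocks", welch_n = 4)
  set.seed(3)
  w <- rnorm(2 * fs)
  pw <- compute_psd(w, fs, cfg)
  p1 <- compute_psd(w, fs, spectral_config())
  expect_identical(pw$n_averages, 4L)
  expect_length(pw$frequencies, 2 * fs / 4 / 2)
  expect_lt(sd(pw$power) / mean(pw$power), sd(p1$power) / mean(p1$power))
})

test_that("fit_lorentzian recovers exact model samples to >= 6 digits", {
  fs <- 10000
  f <- 1:5000
  D <- 1e-3; fc <- 40
  psd <- structure(list(frequencies = f, power = lorentzian_psd(f, D, fc),
                        n_averages = 1L, sampling_rate = fs),
                   class = "psd_estimate")
  cfg <- spectral_config(bias_correction = FALSE, temperature = 298.15)
  fit <- fit_lorentzian(psd, cfg)
  expect_true(fit$converged)
  expect_equal(fit$corner_frequency, fc, tolerance = 1e-7)
  expect_equal(fit$diffusion_scale, D, tolerance = 1e-7)
  expect_equal(fit$gamma_star, kB_test * 298.15 / fit$diffusion_scale)
  ## half-power point of the model: P(fc) is half the zero-frequency level
  expect_equal(lorentzian_psd(fc, D, fc), lorentzian_psd(0, D, fc) / 2)
})

test_that("fit_lorentzian agrees with a brute-force grid search", {
  fs <- 10000
  f <- 1:5000
  D <- 2e-4; fc <- 55
  set.seed(4)
  p <- lorentzian_psd(f, D, fc) * rexp(length(f))  # periodogram noise
  psd <- structure(list(frequencies = f, power = p, n_averages = 1L,
                        sampling_rate = fs), class = "psd_estimate")
  cfg <- spectral_config()
  fit <- fit_lorentzian(psd, cfg)
  ## independent oracle: exhaustive 2-D grid minimisation of the same
  ## bias-corrected log-residual criterion
  band <- c(5, fs / 8)
  sel <- f >= band[1] & f <= band[2]
  y <- log(p[sel]) + 0.57721566490153286  # Euler-Mascheroni
  fgrid <- exp(seq(log(band[1]), log(band[2]), length.out = 900))
  dgrid <- D * exp(seq(-0.7, 0.7, length.out = 400))
  sse <- outer(seq_along(dgrid), seq_along(fgrid),
               function(i, j) vapply(seq_along(i), function(k) {
                 sum((y - log(lorentzian_psd(f[sel], dgrid[i[k]],
                                             fgrid[j[k]])))^2)
               }, 0))
  idx <- arrayInd(which.min(sse), dim(sse))
  ## agreement to the oracle's grid resolution (one log-step)
  expect_equal(fit$corner_frequency, fgrid[idx[2]],
               tolerance = diff(log(fgrid[1:2])))
  expect_equal(fit$diffusion_scale, dgrid[idx[1]],
               tolerance = diff(log(dgrid[1:2])))
})

test_that("per-segment corner frequencies concentrate on the true value", {
  g <- control_gamma_135()
  gx <- g[g$converged, ]
  expect_gt(nrow(gx), 100)
  ## single-segment scatter is large but bounded
  expect_lt(sd(gx$corner_frequency) / mean(gx$corner_frequency), 0.25)
  ## medians concentrate: within 5% of kx / (2 pi gamma)
  expect_equal(median(gx$corner_frequency), fc_theory(), tolerance = 0.05)
})

test_that("gamma* estimates are consistent: error shrinks like 1/sqrt(n)", {
  g <- control_gamma_135()
  gs <- g$gamma_star[g$converged]
  expect_equal(median(gs), gamma_bare(), tolerance = 0.03)
  ## sd of disjoint group means shrinks ~2x when group size grows 4x
  g10 <- vapply(split(gs[1:100], rep(1:10, each = 10)), mean, 0)
  g40 <- vapply(split(gs[1:80], rep(1:2, each = 40)), mean, 0)
  expect_lt(abs(mean(gs) - gamma_bare()) / gamma_bare(), 0.03)
  expect_lt(sd(g10) / mean(g10), 0.25 / sqrt(10) * 3)
})

test_that("weighted_linear cross-check lands near the log-space fit", {
  rec <- control_sim_135()$rec
  cfgw <- spectral_config(fit_space = "weighted_linear")
  pre <- preprocess(rec, cfgw)
  blocks <- segment(pre$x, cfgw, rec$sampling_rate)
  fcw <- vapply(1:40, function(j) {
    fit_lorentzian(compute_psd(blocks[, j], rec$sampling_rate, cfgw),
                   cfgw)$corner_frequency
  }, 0)
  ## a cross-check route: coarser than the log-space fit, occasionally
  ## non-converged on single segments, but in the right neighbourhood
  expect_lt(mean(is.na(fcw)), 0.2)
  expect_equal(median(fcw, na.rm = TRUE), fc_theory(), tolerance = 0.15)
})

test_that("gamma trajectories have the contracted shape and scaling", {
  g <- control_gamma_135()
  expect_s3_class(g, "gamma_trajectory")
  expect_identical(nrow(g), 105L)                    # (135 - 30) segments
  expect_true(!is.unsorted(g$t_mid))
  expect_equal(g$t_mid[1], 30.5)
  ## scale invariance: scaling X and SUM together changes nothing
  rec <- control_sim_135()$rec
  rec2 <- qpd_record(rec$times, 3.7 * rec$X, rec$Y, 3.7 * rec$SUM,
                     rec$sampling_rate, rec$particle_id)
  g2 <- gamma_trajectory(rec2, axes = "x")
  expect_identical(g2$converged, g$converged)
  ok <- g$converged
  expect_equal(g2$gamma_star[ok], g$gamma_star[ok], tolerance = 1e-6)
  ## no-trap white noise: every fit lands on the band edge -> hard error
  set.seed(5)
  noise <- make_qpd(8 * 2000, 2000, X = rnorm(16000), Y = rnorm(16000))
  expect_error(
    gamma_trajectory(noise, spectral_config(discard_initial = 0),
                     axes = "x"),
    "no segment")
})

test_that("binding records yield rising gamma* trends; controls do not", {
  g <- gamma_trajectory(binding_sim_fast()$rec,
                        spectral_config(discard_initial = 10), axes = "x")
  d <- g[g$converged, ]
  slope <- lm(gamma_star ~ t_mid, data = d)
  p_bind <- summary(slope)$coefficients["t_mid", c(1, 4)]
  expect_gt(p_bind[1], 0)
  expect_lt(p_bind[2], 1e-6)
  ctrl <- control_gamma_135()
  dc <- ctrl[ctrl$converged, ]
  sc <- summary(lm(gamma_star ~ t_mid, data = dc))$coefficients
  expect_gt(sc["t_mid", 4], 0.05)  # no significant trend at this seed
})
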