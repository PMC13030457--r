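## small synthetic trajectory builder (no simulation needed here)
fake_traj <- function(values, times = seq_along(values) - 0.5, axis = "x",
                      converged = TRUE, normalized = FALSE) {
  n <- length(values)
  structure(
    data.frame(t_mid = times, axis = axis,
               diffusion_scale = 1 / values, corner_frequency = 40,
               gamma_star = values, fit_residual = 0.1,
               converged = rep_len(converged, n)),
    class = c("gamma_trajectory", "data.frame"),
    particle_id = "fake", normalized = normalized,
    temperature = 298.15, segment_length = 1)
}

test_that("normalize_to_max scales each axis by its converged maximum", {
  tr <- fake_traj(c(2, 4, 8, 6))
  norm <- normalize_to_max(tr)
  expect_equal(norm$gamma_star, c(0.25, 0.5, 1, 0.75))
  expect_true(attr(norm, "normalized"))
  expect_equal(max(norm$gamma_star[norm$converged]), 1)
  ## idempotent
  expect_equal(normalize_to_max(norm)$gamma_star, norm$gamma_star)
  ## non-converged entries do not set the scale
  tr2 <- fake_traj(c(2, 100, 4), converged = c(TRUE, FALSE, TRUE))
  expect_equal(normalize_to_max(tr2)$gamma_star, c(0.5, 25, 1))
  expect_error(normalize_to_max(fake_traj(1:3, converged = FALSE)),
               "no converged")
})

test_that("moving_average matches a brute-force oracle", {
  set.seed(10)
  x <- rnorm(57)
  w <- 20
  ma <- moving_average(x, w)
  brute_m <- vapply(1:(57 - w + 1), function(i) mean(x[i:(i + w - 1)]), 0)
  brute_s <- vapply(1:(57 - w + 1), function(i) sd(x[i:(i + w - 1)]), 0)
  expect_equal(ma$mean, brute_m, tolerance = 1e-12)
  expect_equal(ma$sd, brute_s, tolerance = 1e-10)
  expect_length(ma$mean, 57 - w + 1)
  ## constant input -> constant mean, zero dispersion
  cm <- moving_average(rep(3, 25), w)
  expect_equal(cm$mean, rep(3, 6))
  expect_equal(cm$sd, rep(0, 6))
  expect_error(moving_average(rnorm(10), 20), "shorter than window")
})

test_that("moving average of a monotone series is monotone", {
  x <- cumsum(abs(rnorm(100)))
  expect_true(all(diff(moving_average(x, 20)$mean) >= 0))
})

test_that("trajectory moving averages use converged segments only", {
  v <- c(1:10, 100, 11:30)  # spike marked non-converged
  conv <- rep(TRUE, 31); conv[11] <- FALSE
  ma <- moving_average(fake_traj(v, converged = conv), window = 10)
  expect_s3_class(ma, "gamma_ma")
  expect_equal(nrow(ma), 30 - 10 + 1)
  expect_true(all(ma$mean <= 30))  # spike excluded
})

test_that("kde_summary returns normalized per-window densities", {
  set.seed(11)
  tr <- fake_traj(rnorm(2000), times = seq(0, 1999.5, length.out = 2000))
  kde <- kde_summary(tr, window_duration = 2000)
  expect_length(kde, 1)
  d <- kde[[1]]$density
  integral <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$y)]), 0.3)  # peak near 0 for N(0,1)
  ## two separated clusters -> bimodal density
  tr2 <- fake_traj(c(rnorm(300), rnorm(300) + 10),
                   times = seq(0.5, 600, 1))
  kb <- kde_summary(tr2, window_duration = 600)[[1]]$density
  peaks <- which(diff(sign(diff(kb$y))) == -2)
  expect_gte(length(peaks), 2)
  ## default windows: thirds of the record
  kd3 <- kde_summary(tr)
  expect_length(kd3, 3)
  ## sparse windows raise warnings and are skipped
  tr3 <- fake_traj(c(rnorm(50), 1), times = c(seq(0.5, 50, 1), 1000))
  w <- capture_warnings(kde3 <- kde_summary(tr3, window_duration = 300))
  expect_gte(length(w), 1)
  expect_true(all(grepl("skipped", w)))
  expect_length(kde3, 1)
})

test_that("binding_curve follows the association kinetics closed form", {
  expect_equal(binding_curve(2, 1e6, 0, 5e-9, 0), 0)
  expect_equal(binding_curve(2, 1e6, 0, 5e-9, 1e9), 2)
  expect_equal(binding_curve(1, 1e6, 0, 5e-9, 1 / 5e-3), 1 - exp(-1),
               tolerance = 1e-12)
  ## Kobs combines kon[L] with koff
  expect_equal(binding_curve(1, 1e6, 2e-3, 5e-9, 100),
               1 - exp(-(5e-3 + 2e-3) * 100))
})

test_that("sigmoid and association fits recover noiseless parameters", {
  tt <- seq(30.5, 599.5, 1)
  ## association model self-fit (default)
  va <- 0.9 * (1 - exp(-5e-3 * (tt - 20)))
  fa <- suppressWarnings(fit_binding_sigmoid(tt, va))
  expect_equal(fa$Kobs, 5e-3, tolerance = 1e-6)
  expect_equal(fa$t0, 20, tolerance = 1e-5)
  expect_equal(fa$b, 0.9, tolerance = 1e-6)
  expect_true(fa$identifiable)
  ## logistic self-fit
  vl <- binding_sigmoid(tt, 5e-3, 150, 2, 1)
  fl <- suppressWarnings(fit_binding_sigmoid(tt, vl, model = "logistic"))
  expect_equal(fl$Kobs, 5e-3, tolerance = 1e-6)
  expect_equal(fl$t0, 150, tolerance = 1e-4)
  expect_equal(fl$r_squared, 1, tolerance = 1e-9)
})

test_that("Kobs is invariant under rescaling of the series", {
  set.seed(12)
  tt <- seq(30.5, 599.5, 1)
  v <- (1 - 0.4 * exp(-5e-3 * tt)) + rnorm(570, 0, 0.02)
  f1 <- suppressWarnings(fit_binding_sigmoid(tt, v))
  f2 <- suppressWarnings(fit_binding_sigmoid(tt, 37 * v))
  expect_equal(f2$Kobs, f1$Kobs, tolerance = 1e-6)
  expect_equal(f2$b / f1$b, 37, tolerance = 1e-4)
})

test_that("noisy model series are recovered within a few percent", {
  ## scaled-down Monte Carlo (acceptance runs the full 100 replicates)
  tt <- seq(30.5, 599.5, 1)
  truth <- 5e-3
  model <- 1 - 0.45 * exp(-truth * (tt - 0))
  set.seed(13)
  ratios <- vapply(1:15, function(i) {
    v <- model + rnorm(570, 0, 0.05)
    sm <- moving_average(v, 20)
    ts <- moving_average(tt, 20)$mean
    f <- suppressWarnings(fit_binding_sigmoid(ts, sm$mean))
    f$Kobs / truth
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.05)
})

test_that("flat series are flagged non-identifiable", {
  set.seed(14)
  tt <- seq(30.5, 329.5, 1)
  f <- suppressWarnings(fit_binding_sigmoid(tt, 1 + rnorm(300, 0, 0.03)))
  expect_false(f$identifiable)
  expect_gt(f$Kobs_se, f$Kobs)
})

test_that("logistic and its expansion agree when the exponential is small", {
  ## second-order consistency: relative deviation < 1e-3 when exp < 0.01 c
  for (cc in c(0.5, 1, 5, 20)) {
    b <- 2.4
    u <- cc * c(1e-4, 1e-3, 0.01)
    logistic <- b / (cc + u)
    expansion <- (b / cc) * (1 - u / cc)
    expect_lt(max(abs(logistic - expansion) / logistic), 1e-3)
  }
})

test_that("fit covariance respects the c gauge and reports uncertainty", {
  set.seed(15)
  tt <- seq(30.5, 599.5, 1)
  v <- (1 - 0.4 * exp(-5e-3 * tt)) + rnorm(570, 0, 0.01)
  f <- suppressWarnings(fit_binding_sigmoid(tt, v))
  expect_identical(dim(f$covariance), c(4L, 4L))
  expect_true(all(f$covariance["c", ] == 0))
  expect_equal(sqrt(f$covariance["Kobs", "Kobs"]), f$Kobs_se)
  ## truth within ~3 SE
  expect_lt(abs(f$Kobs - 5e-3), 4 * f$Kobs_se)
})

test_that("association_rate applies the high-affinity shortcut correctly", {
  r <- association_rate(4.8e-3, 5e-9, assume_high_affinity = TRUE)
  expect_equal(r$kon, 9.6e5)
  expect_true(is.na(r$KD_implied))
  expect_equal(association_rate(0, 5e-9, assume_high_affinity = TRUE)$kon, 0)
  expect_equal(association_rate(1e-2, 1e-8,
                                assume_high_affinity = TRUE)$kon, 1e6)
  ## supplied koff is subtracted and yields an implied KD
  r2 <- association_rate(6e-3, 5e-9, koff = 1e-3)
  expect_equal(r2$kon, 1e6)
  expect_equal(r2$KD_implied, 1e-3 / 1e6)
  expect_error(association_rate(5e-3, 0, assume_high_affinity = TRUE),
               "positive")
  expect_error(association_rate(5e-3, 5e-9), "assume_high_affinity")
  expect_error(association_rate(1e-3, 5e-9, koff = 2e-3), "negative")
})

test_that("the full kinetic chain works on a fast-binding simulation", {
  g <- gamma_trajectory(binding_sim_fast()$rec,
                        spectral_config(discard_initial = 10), axes = "x")
  fit <- suppressWarnings(fit_binding_sigmoid(g, axis = "x", window = 10))
  expect_true(fit$identifiable)
  ## Kobs = 0.05 /s in this fixture; loose bound for an 80-s record
  expect_equal(fit$Kobs, 0.05, tolerance = 0.35)
  expect_gt(fit$r_squared, 0.9)
})
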