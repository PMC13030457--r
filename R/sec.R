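## Size-exclusion chromatography calibration: log10(hydrodynamic radius)
## is linear in elution for globular protein standards, so an unknown's Rh
## follows from its retention by interpolation on the fitted line.

#' Validate a table of SEC calibration standards
#'
#' @param name Standard names.
#' @param rh Hydrodynamic radii, nm (> 0).
#' @param elution Elution abscissa (retention time in min, or relative
#'   elution volume; > 0). Retention time and relative volume are
#'   proportional at constant flow rate, so either works -- declare which in
#'   [fit_sec_calibration()].
#' @return A validated data frame with columns `name`, `rh`, `elution`.
#' @export
sec_standards <- function(name, rh, elution) {
  n <- length(name)
  if (length(rh) != n || length(elution) != n)
    stop("name, rh and elution must have equal length", call. = FALSE)
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh <= 0))
    stop("'rh' must be positive (nm)", call. = FALSE)
  if (!is.numeric(elution) || any(!is.finite(elution)) || any(elution <= 0))
    stop("'elution' must be positive", call. = FALSE)
  data.frame(name = as.character(name), rh = rh, elution = elution)
}

#' Read SEC standards from a delimited file
#'
#' Expects a header `name,rh,elution`.
#'
#' @param path File path.
#' @return A validated standards data frame.
#' @export
read_sec_standards <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path),
                               call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  miss <- setdiff(c("name", "rh", "elution"), names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  sec_standards(df$name, df$rh, df$elution)
}

#' Fit an SEC calibration line
#'
#' Ordinary least squares of `log10(rh)` on the elution abscissa. A valid
#' size-exclusion column elutes larger molecules earlier, so the slope
#' should be negative; a non-negative slope triggers a warning.
#'
#' @param standards Data frame from [sec_standards()] (>= 3 standards with
#'   distinct elution values).
#' @param abscissa What the elution column holds; retention time (min) and
#'   relative elution volume are proportional at constant flow.
#' @return Object of class `sec_calibration`: `slope`, `intercept`,
#'   `r_squared`, `n_standards`, `elution_range`, `abscissa`.
#' @export
fit_sec_calibration <- function(standards,
                                abscissa = c("relative_volume",
                                             "retention_time")) {
  abscissa <- match.arg(abscissa)
  standards <- sec_standards(standards$name, standards$rh, standards$elution)
  if (nrow(standards) < 3)
    stop("need at least 3 standards", call. = FALSE)
  if (length(unique(standards$elution)) < 3)
    stop("elution values are degenerate (fewer than 3 distinct)",
         call. = FALSE)
  fit <- lm(log10(rh) ~ elution, data = standards)
  b <- coef(fit)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((log10(standards$rh) - mean(log10(standards$rh)))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (b[[2]] >= 0)
    warning("calibration slope is non-negative; not a valid SEC column",
            call. = FALSE)
  structure(list(slope = b[[2]], intercept = b[[1]], r_squared = r2,
                 n_standards = nrow(standards),
                 elution_range = range(standards$elution),
                 abscissa = abscissa),
            class = "sec_calibration")
}

#' Estimate a hydrodynamic radius from elution
#'
#' `rh = 10^(intercept + slope * elution)`; entries outside the standards'
#' elution range are flagged as extrapolated.
#'
#' @param cal A [fit_sec_calibration()] result.
#' @param elution Elution value(s) on the calibration's abscissa.
#' @return Data frame with columns `elution`, `rh` (nm), `extrapolated`.
#' @export
estimate_rh <- function(cal, elution) {
  stopifnot(inherits(cal, "sec_calibration"))
  if (!is.numeric(elution) || any(!is.finite(elution)))
    stop("'elution' must be finite numeric", call. = FALSE)
  data.frame(elution = elution,
             rh = 10^(cal$intercept + cal$slope * elution),
             extrapolated = elution < cal$elution_range[1] |
               elution > cal$elution_range[2])
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "SEC calibration (%s): log10(rh) = %.4g %+.4g * elution, r^2 = %.4f (n = %d)\n",
    x$abscissa, x$intercept, x$slope, x$r_squared, x$n_standards))
  invisible(x)
}
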