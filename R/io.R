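## Time-series containers and readers/writers. Delimited text is the
## interchange default (human-inspectable, '#'-prefixed provenance header);
## an uncompressed platform-native binary container is available for long
## records. Every writer stamps seed and config hash into the header.

#' Quadrant-photodiode record
#'
#' The raw observable of the pipeline: detector channels X, Y and SUM
#' sampled on a uniform grid.
#'
#' @param times Sample times, s; strictly increasing uniform grid.
#' @param X,Y,SUM Channel values; `SUM` must be strictly positive.
#' @param sampling_rate Hz; inferred from `times` when `NULL`.
#' @param particle_id Identifier string.
#' @return An object of class `qpd_record`.
#' @export
qpd_record <- function(times, X, Y, SUM, sampling_rate = NULL,
                       particle_id = "P1") {
  n <- length(times)
  if (n < 2) stop("a QPD record needs at least 2 samples", call. = FALSE)
  if (length(X) != n || length(Y) != n || length(SUM) != n)
    stop("times, X, Y and SUM must have equal length", call. = FALSE)
  bad <- which(SUM <= 0)
  if (length(bad))
    stop(sprintf("SUM must be strictly positive; first violation at sample %d",
                 bad[1]), call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("'times' must be strictly increasing", call. = FALSE)
  mdt <- mean(dt)
  if (max(abs(dt - mdt)) > 1e-6 * mdt)
    stop("'times' is not a uniform grid (tolerance 1 part in 1e6)",
         call. = FALSE)
  if (is.null(sampling_rate)) sampling_rate <- 1 / mdt
  structure(list(times = times, X = X, Y = Y, SUM = SUM,
                 sampling_rate = sampling_rate,
                 particle_id = as.character(particle_id)),
            class = "qpd_record")
}

#' @export
print.qpd_record <- function(x, ...) {
  cat(sprintf("QPD record '%s': %d samples at %g Hz (%.1f s)\n",
              x$particle_id, length(x$times), x$sampling_rate,
              length(x$times) / x$sampling_rate))
  invisible(x)
}

.header_lines <- function(meta) {
  vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]), "")
}

.read_header <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  meta <- character(); n <- 0L
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln) || !startsWith(ln, "#")) break
    n <- n + 1L
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[substr(kv, 1, eq - 1)] <- substring(kv, eq + 1)
  }
  list(meta = as.list(meta), skip = n)
}

#' Write a QPD record to disk
#'
#' @param qpd A [qpd_record()].
#' @param path Output file.
#' @param format `"text"`: delimited text with a `#` provenance header and
#'   columns `time,X,Y,SUM`. `"binary"`: uncompressed native binary
#'   container (magic `OTK1`) storing the uniform grid parametrically; exact
#'   round-trip, much smaller for long records.
#' @param meta Named character vector merged into the header (e.g. seed,
#'   config hash).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(qpd, path, format = c("text", "binary"),
                             meta = character()) {
  stopifnot(inherits(qpd, "qpd_record"))
  format <- match.arg(format)
  base <- c(particle_id = qpd$particle_id,
            sampling_rate = sprintf("%.17g", qpd$sampling_rate))
  meta <- c(base, meta)
  if (format == "text") {
    writeLines(c(.header_lines(meta), "time,X,Y,SUM"), path)
    data.table::fwrite(
      data.table::data.table(time = qpd$times, X = qpd$X, Y = qpd$Y,
                             SUM = qpd$SUM),
      path, append = TRUE, col.names = FALSE)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeChar("OTK1", con, nchars = 4, eos = NULL)
    id <- charToRaw(qpd$particle_id)
    writeBin(length(id), con, size = 4)
    writeBin(id, con)
    writeBin(length(qpd$times), con, size = 4)
    writeBin(qpd$sampling_rate, con, size = 8)
    writeBin(c(qpd$times, qpd$X, qpd$Y, qpd$SUM), con, size = 8)
  }
  invisible(path)
}

#' Read a QPD record
#'
#' Accepts either format written by [write_timeseries()] (auto-detected by
#' magic bytes) or any delimited text file with columns `time,X,Y,SUM`.
#' Validates the schema, the uniformity of the time grid (1 part in 1e6) and
#' SUM positivity, with descriptive errors.
#'
#' @param path Input file.
#' @return A [qpd_record()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path),
                               call. = FALSE)
  magic <- readBin(path, "raw", n = 4)
  if (length(magic) == 4 && rawToChar(magic) == "OTK1") {
    con <- file(path, "rb"); on.exit(close(con))
    readChar(con, 4, useBytes = TRUE)
    idlen <- readBin(con, "integer", size = 4)
    id <- rawToChar(readBin(con, "raw", n = idlen))
    n <- readBin(con, "integer", size = 4)
    sr <- readBin(con, "double", n = 1, size = 8)
    v <- readBin(con, "double", n = 4 * n, size = 8)
    return(qpd_record(v[1:n], v[(n + 1):(2 * n)], v[(2 * n + 1):(3 * n)],
                      v[(3 * n + 1):(4 * n)],
                      sampling_rate = sr, particle_id = id))
  }
  hdr <- .read_header(path)
  dt <- data.table::fread(path, skip = hdr$skip, header = TRUE)
  need <- c("time", "X", "Y", "SUM")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  sr <- if (!is.null(hdr$meta$sampling_rate))
    as.numeric(hdr$meta$sampling_rate) else NULL
  id <- if (!is.null(hdr$meta$particle_id)) hdr$meta$particle_id else "P1"
  qpd_record(dt$time, dt$X, dt$Y, dt$SUM, sampling_rate = sr,
             particle_id = id)
}

#' Write / read a per-segment friction-coefficient table
#'
#' Delimited text with columns `t_mid, axis, diffusion_scale,
#' corner_frequency, gamma_star, fit_residual, converged` and a `#` header
#' carrying particle id, temperature, segment length and the normalization
#' flag, so a table round-trips into an identical `gamma_trajectory`.
#'
#' @param traj A `gamma_trajectory` (see [gamma_trajectory()]).
#' @param path File path.
#' @param meta Extra named header entries.
#' @return `path` (write) or a `gamma_trajectory` (read).
#' @export
write_gamma_table <- function(traj, path, meta = character()) {
  stopifnot(inherits(traj, "gamma_trajectory"))
  base <- c(particle_id = attr(traj, "particle_id"),
            temperature = sprintf("%.17g", attr(traj, "temperature")),
            segment_length = sprintf("%.17g", attr(traj, "segment_length")),
            normalized = tolower(as.character(attr(traj, "normalized"))))
  writeLines(.header_lines(c(base, meta)), path)
  data.table::fwrite(as.data.frame(traj), path, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_gamma_table
#' @export
read_gamma_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path),
                               call. = FALSE)
  hdr <- .read_header(path)
  df <- as.data.frame(data.table::fread(path, skip = hdr$skip, header = TRUE))
  need <- c("t_mid", "axis", "diffusion_scale", "corner_frequency",
            "gamma_star", "fit_residual", "converged")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  df$converged <- as.logical(df$converged)
  structure(df, class = c("gamma_trajectory", "data.frame"),
            particle_id = hdr$meta$particle_id %||% "P1",
            temperature = as.numeric(hdr$meta$temperature %||% "298.15"),
            segment_length = as.numeric(hdr$meta$segment_length %||% "1"),
            normalized = identical(hdr$meta$normalized, "true"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
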