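## Run configuration and the end-to-end pipeline driver:
## simulate (or read) -> friction trajectory -> normalize / moving average
## -> sigmoid fit -> association rate -> report. One master seed fans out
## into named substreams; every output file carries the config hash and
## seed so stages can be re-run in isolation.

#' Assemble a run configuration
#'
#' @param trap A [trap_config()].
#' @param schedule A [binding_schedule()].
#' @param sim A [sim_config()].
#' @param spectral A [spectral_config()].
#' @param paths List with optional `input` (an existing record to analyse
#'   instead of simulating), `outdir`, and `write_record` (store the raw
#'   simulated record; off by default since records run to millions of
#'   rows).
#' @param master_seed Integer master seed; stage seeds are derived from it.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(trap = trap_config(), schedule = binding_schedule(),
                       sim = sim_config(), spectral = spectral_config(),
                       paths = list(input = NA_character_, outdir = ".",
                                    write_record = FALSE),
                       master_seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(trap, "trap_config"),
            inherits(schedule, "binding_schedule"),
            inherits(sim, "sim_config"),
            inherits(spectral, "spectral_config"))
  if (!is.numeric(master_seed) || length(master_seed) != 1 ||
      master_seed != trunc(master_seed) || abs(master_seed) >= 2^31)
    stop("'master_seed' must be a single integer below 2^31", call. = FALSE)
  paths <- modifyList(list(input = NA_character_, outdir = ".",
                           write_record = FALSE), as.list(paths))
  structure(list(trap = trap, schedule = schedule, sim = sim,
                 spectral = spectral, paths = paths,
                 master_seed = as.integer(master_seed),
                 log_level = log_level),
            class = "run_config")
}

.fmt_value <- function(v) {
  if (is.character(v)) return(v)
  if (is.logical(v)) return(tolower(as.character(v)))
  if (is.na(v)) return("NA")
  sprintf("%.17g", v)
}

.flat_config <- function(cfg) {
  out <- character()
  add <- function(prefix, lst) {
    for (nm in names(lst)) {
      v <- lst[[nm]]
      if (length(v) > 1) {
        for (i in seq_along(v))
          out[[sprintf("%s.%s%d", prefix, nm, i)]] <<- .fmt_value(v[i])
      } else out[[sprintf("%s.%s", prefix, nm)]] <<- .fmt_value(v)
    }
  }
  add("trap", cfg$trap[setdiff(names(cfg$trap), "boltzmann_constant")])
  add("schedule", cfg$schedule)
  add("sim", cfg$sim)
  add("spectral", cfg$spectral)
  add("paths", cfg$paths)
  out[["master_seed"]] <- .fmt_value(cfg$master_seed)
  out[["log_level"]] <- cfg$log_level
  out
}

#' Write / read a run configuration
#'
#' Human-readable flat `section.key = value` format; numeric values are
#' stored with 17 significant digits so a configuration round-trips through
#' serialization losslessly.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `path` (write) or a validated [run_config()] (read).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  kv <- .flat_config(cfg)
  writeLines(c("# otkinetics run configuration",
               sprintf("%s = %s", names(kv), unlist(kv))), path)
  invisible(path)
}

.parse_value <- function(s) {
  if (s == "NA") return(NA_real_)
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) num else s
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed config line: '%s'", ln),
                     call. = FALSE)
    kv[[trimws(substr(ln, 1, eq - 1))]] <-
      .parse_value(trimws(substring(ln, eq + 1)))
  }
  section <- function(prefix) {
    keys <- grep(paste0("^", prefix, "\\."), names(kv), value = TRUE)
    setNames(kv[keys], sub(paste0("^", prefix, "\\."), "", keys))
  }
  sp <- section("spectral")
  fit_band <- c(sp$fit_band1, sp$fit_band2)
  sp <- sp[setdiff(names(sp), c("fit_band1", "fit_band2"))]
  pa <- section("paths")
  if (is.numeric(pa$input) && is.na(pa$input)) pa$input <- NA_character_
  run_config(trap = do.call(trap_config, section("trap")),
             schedule = do.call(binding_schedule, section("schedule")),
             sim = do.call(sim_config, section("sim")),
             spectral = do.call(spectral_config,
                                c(sp, list(fit_band = fit_band))),
             paths = pa,
             master_seed = kv$master_seed,
             log_level = kv$log_level %||% "info")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical flat serialization; stamped into every output file
#' header for provenance.
#'
#' @param cfg A [run_config()].
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".cfg")
  on.exit(unlink(tf))
  write_run_config(cfg, tf)
  unname(tools::md5sum(tf))
}

.log <- function(cfg, fmt, ...) {
  if (!identical(cfg$log_level, "quiet")) message(sprintf(fmt, ...))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or reads `paths$input`) -> [gamma_trajectory()] ->
#' [normalize_to_max()] -> [moving_average()] -> [fit_binding_sigmoid()] ->
#' [association_rate()], writing the per-segment table, the smoothed series
#' and a report (plain-text key-value plus JSON) under `outdir`. Identical
#' configuration and master seed reproduce identical outputs. Any stage
#' failure aborts with the stage name and cause. When the kinetic fit is
#' not identifiable (no transition in the series), the report flags it and
#' no association rate is computed.
#'
#' @param config A [run_config()].
#' @param outdir Output directory; defaults to `config$paths$outdir`.
#' @return Invisibly, a list with the trajectory, moving average, kinetic
#'   fit, rate result (or `NULL`), and output paths.
#' @export
run_pipeline <- function(config, outdir = config$paths$outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  meta <- c(config_hash = hash,
            master_seed = as.character(config$master_seed))

  qpd <- .stage("simulate", {
    if (!is.na(config$paths$input) && nzchar(config$paths$input)) {
      .log(config, "reading record from %s", config$paths$input)
      read_timeseries(config$paths$input)
    } else {
      sim <- config$sim
      sim$seed <- derive_seed(config$master_seed, "simulate")
      .log(config, "simulating %g s at %g Hz (seed %d)",
           sim$duration, sim$sampling_rate, sim$seed)
      traj <- simulate_trajectory(config$trap, config$schedule, sim)
      rec <- render_qpd(traj, sim, config$schedule)
      if (isTRUE(config$paths$write_record))
        write_timeseries(rec, file.path(outdir, "record.csv"), meta = meta)
      rec
    }
  })

  traj <- .stage("analyze", gamma_trajectory(qpd, config$spectral))
  .stage("write-segments",
         write_gamma_table(traj, file.path(outdir, "segments.csv"),
                           meta = meta))

  norm <- .stage("normalize", normalize_to_max(traj))
  ma <- .stage("smooth", moving_average(norm, 20))
  .stage("write-smoothed", {
    writeLines(.header_lines(meta), file.path(outdir, "moving_average.csv"))
    data.table::fwrite(as.data.frame(ma),
                       file.path(outdir, "moving_average.csv"),
                       append = TRUE, col.names = TRUE)
  })

  fit <- .stage("fit", fit_binding_sigmoid(ma, axis = "x"))
  rate <- if (fit$identifiable) {
    .stage("rate", association_rate(
      fit, config$schedule$ligand_conc,
      koff = if (config$schedule$koff > 0) config$schedule$koff else NULL,
      assume_high_affinity = config$schedule$koff == 0))
  } else NULL

  report <- list(
    config_hash = hash, master_seed = config$master_seed,
    particle_id = attr(traj, "particle_id"),
    n_segments = nrow(traj), n_converged = sum(traj$converged),
    Kobs = fit$Kobs, Kobs_se = fit$Kobs_se, t0 = fit$t0, b = fit$b,
    c = fit$c, r_squared = fit$r_squared, rmse = fit$rmse,
    identifiable = fit$identifiable,
    kon = if (!is.null(rate)) rate$kon else NA_real_,
    koff_assumed = if (!is.null(rate)) rate$koff_assumed else NA_real_,
    ligand_conc = config$schedule$ligand_conc,
    assumption = if (!is.null(rate)) rate$assumption
                 else "kinetic fit not identifiable; no rate derived")
  .stage("report", {
    txt <- vapply(names(report), function(k)
      sprintf("%s = %s", k, .fmt_value(report[[k]])), "")
    writeLines(c(sprintf("# config_hash=%s", hash),
                 sprintf("# master_seed=%d", config$master_seed), txt),
               file.path(outdir, "report.txt"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  .log(config, "pipeline done: Kobs = %.4g /s (identifiable: %s)",
       fit$Kobs, fit$identifiable)
  invisible(list(qpd = qpd, trajectory = traj, moving_average = ma,
                 fit = fit, rate = rate, report = report,
                 paths = file.path(outdir, c("segments.csv",
                                             "moving_average.csv",
                                             "report.txt", "report.json"))))
}
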