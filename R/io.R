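# Readers and writers for the package's plain-text CSV dialects.
#
# Dialects (all with mandatory headers):
#   time series: time_h, well, frequency_hz, channel, value
#                (channel: resistance_ohm | capacitance_nf)
#   scans:       well, frequency_hz, z_real_ohm, z_imag_ohm, state
#   RTC:         t_s, well, resistance_ohm        (one frequency per file)
#   plate:       well, substrate, rfu_experimental, rfu_negative, rfu_positive

read_dialect <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) stop(what, " file ", path, " contains no records", call. = FALSE)
  df
}

#' Read a time-series CSV
#'
#' Reads the time-series dialect (`time_h, well, frequency_hz, channel,
#' value`), sorts each trace by time and validates that, within each
#' (well, frequency, channel) trace, times are strictly increasing after
#' sorting (duplicate time points are reported with their row numbers).
#'
#' @param path CSV file path.
#' @return A tibble sorted by well, channel, frequency and time.
#' @export
read_timeseries <- function(path) {
  df <- read_dialect(path, c("time_h", "well", "frequency_hz", "channel", "value"),
                     "time-series")
  bad_ch <- setdiff(unique(df$channel), c("resistance_ohm", "capacitance_nf"))
  if (length(bad_ch)) {
    stop("unknown channel(s): ", paste(bad_ch, collapse = ", "),
         "; expected resistance_ohm or capacitance_nf", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$well, .data$channel, .data$frequency_hz,
                       .data$time_h)
  dup <- df |>
    dplyr::group_by(.data$well, .data$channel, .data$frequency_hz) |>
    dplyr::mutate(.dup = duplicated(.data$time_h)) |>
    dplyr::ungroup()
  if (any(dup$.dup)) {
    stop("non-monotone time: duplicate time points at sorted row(s) ",
         paste(utils::head(which(dup$.dup), 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a frequency-scan CSV
#'
#' Dialect `well, frequency_hz, z_real_ohm, z_imag_ohm, state`, one row per
#' frequency; rows are sorted by well, state and frequency.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_scan <- function(path) {
  df <- read_dialect(path, c("well", "frequency_hz", "z_real_ohm",
                             "z_imag_ohm", "state"), "frequency-scan")
  bad <- setdiff(unique(df$state), c("cell_free", "cell_covered"))
  if (length(bad)) {
    stop("unknown scan state(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(df, .data$well, .data$state, .data$frequency_hz)
}

#' Read a rapid-time-collection CSV
#'
#' Dialect `t_s, well, resistance_ohm` (a single acquisition frequency per
#' file); rows are sorted by well and time.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_rtc <- function(path) {
  df <- read_dialect(path, c("t_s", "well", "resistance_ohm"), "RTC")
  dplyr::arrange(df, .data$well, .data$t_s)
}

#' Read a plate-reader CSV
#'
#' Dialect `well, substrate, rfu_experimental, rfu_negative, rfu_positive`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_plate <- function(path) {
  read_dialect(path, c("well", "substrate", "rfu_experimental",
                       "rfu_negative", "rfu_positive"), "plate")
}

#' Write a simulated experiment to a directory
#'
#' Emits the time-series, RTC and scan CSV dialects plus `wells.csv` and a
#' YAML run manifest recording the configuration, seed and dialect version.
#'
#' @param sim An `ecis_sim` from [simulate_experiment()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ecis_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  if (!is.null(sim$timeseries)) {
    readr::write_csv(sim$timeseries[, c("time_h", "well", "frequency_hz",
                                        "channel", "value")], p("timeseries.csv"))
  }
  if (!is.null(sim$rtc)) {
    readr::write_csv(sim$rtc[, c("t_s", "well", "resistance_ohm")], p("rtc.csv"))
  }
  if (!is.null(sim$scans)) {
    readr::write_csv(sim$scans[, c("well", "frequency_hz", "z_real_ohm",
                                   "z_imag_ohm", "state")], p("scans.csv"))
  }
  readr::write_csv(sim$wells, p("wells.csv"))
  cfg <- sim$config
  manifest <- list(
    dialect_version = "1",
    generator = paste0("ecisfence ", as.character(utils::packageVersion("ecisfence"))),
    array_type = cfg$array_type,
    substrates = cfg$substrates,
    n_wells = cfg$n_wells,
    seed = cfg$seed,
    noise_sd = cfg$noise_sd,
    scan_noise_sd = cfg$scan_noise_sd,
    attach_interval_h = cfg$attach_interval_h,
    migr_interval_h = cfg$migr_interval_h,
    attach_duration_h = cfg$attach_duration_h,
    migration_mode = cfg$migration_mode,
    fence = unclass(cfg$fence),
    include = cfg$include
  )
  yaml::write_yaml(manifest, p("manifest.yml"))
  invisible(dir)
}

#' Read a run configuration from YAML
#'
#' Accepts exactly the fields of [ecis_config()] (plus a nested `fence`
#' block with the fields of [fence_schedule()]); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return An `ecis_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fence <- NULL
  if (!is.null(raw$fence)) {
    fk <- setdiff(names(raw$fence), c("array_type", "fence_off_h"))
    if (length(fk)) {
      stop("unknown fence key(s) in ", path, ": ", paste(fk, collapse = ", "),
           call. = FALSE)
    }
    fence <- fence_schedule(raw$fence$array_type %||% raw$array_type %||% "8W1E",
                            raw$fence$fence_off_h %||% 10)
    raw$fence <- NULL
  }
  known <- setdiff(names(formals(ecis_config)), "fence")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw$substrates <- unlist(raw$substrates %||% formals(ecis_config)$substrates)
  raw$include <- unlist(raw$include) %||% NULL
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(ecis_config, c(raw, if (!is.null(fence)) list(fence = fence)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
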