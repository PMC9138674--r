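# End-to-end analysis of a simulated or imported experiment: per-well
# kinetics, micromotion and scan fits, summarized per substrate as
# mean +/- SEM.

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Analyse every well of an experiment
#'
#' Runs the full readout chain on an `ecis_sim` (or an equivalently shaped
#' list of tables): attachment slope Sc and T50 from the capacitance traces,
#' migration slope Sr and T50 from the fence-release resistance traces,
#' Var32 from the RTC series, and (optionally) the cell-electrode model fit
#' (Rb, h, Cm) from each well's scan pair. A failing stage is logged for
#' that well and the run continues.
#'
#' @param sim An `ecis_sim` from [simulate_experiment()], or a list with any
#'   of `timeseries`, `rtc`, `scans`, plus `wells` and `config`.
#' @param fit_scans Fit the cell-electrode model to the scans (the slowest
#'   stage).
#' @param n_starts Multi-start count for the scan fits.
#' @param cap_thresholds Capacitance window for Sc; `NULL` selects (3, 1.5)
#'   for 8W1E and (30, 10) for 8W10E.
#' @return An object of class `ecis_report`: `per_well` (one row per well
#'   with every metric), `summary` (per substrate x metric: mean, sem, n),
#'   `log` (tibble of per-well stage failures), `config`.
#' @examples
#' sim <- simulate_experiment(ecis_config(n_wells = 2, seed = 7,
#'                                        include = c("attachment", "migration")))
#' rep <- run_pipeline(sim)
#' rep$summary
#' @export
run_pipeline <- function(sim, fit_scans = TRUE, n_starts = 4,
                         cap_thresholds = NULL) {
  cfg <- sim$config
  array_type <- cfg$array_type %||% "8W1E"
  if (is.null(cap_thresholds)) {
    cap_thresholds <- if (array_type == "8W10E") c(30, 10) else c(3, 1.5)
  }
  wells <- sim$wells
  logs <- list()
  note <- function(well, stage, e) {
    logs[[length(logs) + 1]] <<- tibble::tibble(
      well = well, stage = stage, error = conditionMessage(e))
    NULL
  }

  rows <- purrr::map(seq_len(nrow(wells)), function(r) {
    wl <- wells$well[r]
    out <- tibble::tibble(well = wl, substrate = wells$substrate[r])
    if (!is.null(sim$timeseries)) {
      att <- dplyr::filter(sim$timeseries, .data$well == wl,
                           .data$channel == "capacitance_nf")
      if (nrow(att)) {
        res <- tryCatch({
          s <- capacitance_slope(att, cap_thresholds[1], cap_thresholds[2])
          t5 <- trace_t50(att)
          tibble::tibble(sc_nf_h = s$slope, sc_r2 = s$r_squared,
                         t50_attach_h = t5$t50_h)
        }, error = function(e) note(wl, "attachment", e))
        if (!is.null(res)) out <- dplyr::bind_cols(out, res)
      }
      mig <- dplyr::filter(sim$timeseries, .data$well == wl,
                           .data$channel == "resistance_ohm")
      if (nrow(mig)) {
        res <- tryCatch({
          t0 <- if ("fence_off_h" %in% names(mig)) mig$fence_off_h[1] else
            cfg$fence$fence_off_h %||% mig$time_h[1]
          s <- resistance_slope(mig)
          t5 <- trace_t50(mig, t0 = t0)
          tibble::tibble(sr_ohm_h = s$slope, sr_r2 = s$r_squared,
                         t50_migr_h = t5$t50_h)
        }, error = function(e) note(wl, "migration", e))
        if (!is.null(res)) out <- dplyr::bind_cols(out, res)
      }
    }
    if (!is.null(sim$rtc)) {
      rt <- dplyr::filter(sim$rtc, .data$well == wl)
      if (nrow(rt)) {
        res <- tryCatch(tibble::tibble(var32 = var32(rt)$var32),
                        error = function(e) note(wl, "micromotion", e))
        if (!is.null(res)) out <- dplyr::bind_cols(out, res)
      }
    }
    if (fit_scans && !is.null(sim$scans)) {
      sc <- dplyr::filter(sim$scans, .data$well == wl)
      if (nrow(sc)) {
        res <- tryCatch({
          covered <- dplyr::filter(sc, .data$state == "cell_covered")
          free <- dplyr::filter(sc, .data$state == "cell_free")
          if (!nrow(covered) || !nrow(free)) stop("missing scan pair")
          m <- substrate_morphology()
          rc <- m$rc_um[match(wells$substrate[r], m$substrate)]
          if (is.na(rc)) rc <- 11.72
          fit <- fit_cell_params(covered, free, electrode_spec(array_type),
                                 rc_um = rc, n_starts = n_starts,
                                 seed = (cfg$seed %||% 1) + r)
          tibble::tibble(rb_ohm_cm2 = fit$params$rb_ohm_cm2,
                         h_nm = fit$params$h_nm,
                         cm_uf_cm2 = fit$params$cm_uf_cm2,
                         fit_residual = fit$residual)
        }, error = function(e) note(wl, "scan_fit", e))
        if (!is.null(res)) out <- dplyr::bind_cols(out, res)
      }
    }
    out
  })
  per_well <- dplyr::bind_rows(rows)

  metrics <- intersect(c("sc_nf_h", "t50_attach_h", "sr_ohm_h", "t50_migr_h",
                         "var32", "rb_ohm_cm2", "h_nm", "cm_uf_cm2"),
                       names(per_well))
  summary <- per_well |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$substrate, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value[is.finite(.data$value)]),
                     sem = sem(.data$value),
                     n = sum(is.finite(.data$value)), .groups = "drop")

  structure(
    list(per_well = per_well, summary = summary,
         log = if (length(logs)) dplyr::bind_rows(logs) else
           tibble::tibble(well = character(), stage = character(),
                          error = character()),
         config = cfg),
    class = "ecis_report"
  )
}

#' @export
print.ecis_report <- function(x, ...) {
  cat("<ecis_report> ", nrow(x$per_well), " wells; ",
      nrow(x$log), " stage failure(s)\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write an analysis report to a directory
#'
#' Emits `per_well.csv`, `summary.csv` and a human-readable `report.txt`
#' with all floating output at a fixed 6 significant digits (diffable).
#'
#' @param report An `ecis_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ecis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    ~ signif(.x, 6)))
  }
  readr::write_csv(fmt(report$per_well), file.path(dir, "per_well.csv"))
  readr::write_csv(fmt(report$summary), file.path(dir, "summary.csv"))
  con <- file(file.path(dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines("ECIS electric-fence analysis report", con)
  writeLines(paste0("wells: ", nrow(report$per_well), "; failures: ",
                    nrow(report$log)), con)
  writeLines("", con)
  s <- report$summary
  for (m in unique(s$metric)) {
    writeLines(paste0("  ", m, ":"), con)
    sub <- s[s$metric == m, ]
    for (i in seq_len(nrow(sub))) {
      writeLines(sprintf("    %-10s %s +/- %s (n=%d)", sub$substrate[i],
                         signif(sub$mean[i], 6),
                         ifelse(is.na(sub$sem[i]), "NA", signif(sub$sem[i], 6)),
                         sub$n[i]), con)
    }
  }
  if (nrow(report$log)) {
    writeLines("", con)
    writeLines("stage failures:", con)
    for (i in seq_len(nrow(report$log))) {
      writeLines(sprintf("  %s/%s: %s", report$log$well[i],
                         report$log$stage[i], report$log$error[i]), con)
    }
  }
  invisible(dir)
}
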