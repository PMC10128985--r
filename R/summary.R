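#' Time to recovery
#'
#' First tick at which the fibril count regains (or exceeds) the initial
#' fibril count of the run's own geometry; `NA` if the count never recovers
#' within the recorded window. An undamaged constant series recovers at
#' tick 0.
#'
#' @param series a run (or ensemble-mean) series data frame with columns
#'   `tick` and `fibril`, or a numeric vector of fibril counts (then ticks
#'   are taken as `0, 1, ...`).
#' @param initial_count the initial fibril count to recover to.
#' @return Integer tick, or `NA_integer_`.
#' @export
time_to_recovery <- function(series, initial_count) {
  if (is.data.frame(series)) {
    ticks <- series$tick
    fib <- series$fibril
  } else {
    fib <- as.numeric(series)
    ticks <- seq_along(fib) - 1
  }
  dip <- which(fib < initial_count)
  if (length(dip) == 0L) return(0L) # never damaged below the initial count
  hit <- which(fib >= initial_count & seq_along(fib) > dip[1L])
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(ticks[hit[1L]])
}

#' Peak of a series
#'
#' Maximum value and the first tick at which it is attained.
#'
#' @param series numeric vector, or data frame with `tick` plus the column
#'   named by `what`.
#' @param what column name when `series` is a data frame.
#' @return Named numeric vector `c(amplitude, tick)`.
#' @export
peak <- function(series, what = NULL) {
  if (is.data.frame(series)) {
    ticks <- series$tick
    v <- series[[what]]
  } else {
    v <- as.numeric(series)
    ticks <- seq_along(v) - 1
  }
  if (length(v) == 0L) stop("empty series")
  i <- which.max(v)
  c(amplitude = v[i], tick = ticks[i])
}

#' Summarise a run or ensemble
#'
#' Derived statistics of a repair cycle: time to recovery of the initial
#' fibril count, damage clearance time (first tick with no damaged fibrils),
#' per-population peak amplitude and timing, endpoint counts, ECM percent
#' change from initial, and the cumulative number of satellite-cell
#' activations. For a `muscle_ensemble` the statistics are computed on the
#' ensemble-mean series.
#'
#' @param x a `muscle_sim` or `muscle_ensemble`.
#' @return A `run_summary` list.
#' @export
run_summary <- function(x) {
  if (inherits(x, "muscle_ensemble")) {
    series <- x$mean
    initial <- x$initial
  } else if (inherits(x, "muscle_sim")) {
    series <- x$series
    initial <- x$initial
  } else stop("x must be a muscle_sim or muscle_ensemble")
  n <- nrow(series)
  clear <- which(series$damaged_fibril == 0)
  # clearance measured after the damage event at tick 0
  clear <- clear[series$tick[clear] > 0 | series$damaged_fibril[1L] == 0]
  pops <- c("neutrophils", "macrophages", "sc_active", "myoblasts",
            "fibroblasts")
  peaks <- lapply(pops, function(p) peak(series, p))
  names(peaks) <- pops
  out <- list(
    time_to_recovery = time_to_recovery(series, initial[["fibril"]]),
    damage_clearance_time =
      if (length(clear) > 0L) as.integer(series$tick[clear[1L]]) else NA_integer_,
    peaks = peaks,
    endpoint = c(fibril = series$fibril[n], ecm = series$ecm[n],
                 sc_active = series$sc_active[n],
                 fibroblasts = series$fibroblasts[n]),
    initial = initial,
    ecm_pct_change = 100 * (series$ecm[n] - initial[["ecm"]]) / initial[["ecm"]],
    sc_activated_total = series$cum_sc_activated[n],
    duration = as.integer(series$tick[n])
  )
  class(out) <- "run_summary"
  out
}

#' @export
print.run_summary <- function(x, ...) {
  fmt_t <- function(t) if (is.na(t)) "never" else sprintf("%d h", t)
  cat("run_summary\n")
  cat(sprintf("  time to recovery:   %s\n", fmt_t(x$time_to_recovery)))
  cat(sprintf("  damage clearance:   %s\n", fmt_t(x$damage_clearance_time)))
  cat(sprintf("  neutrophil peak:    %.1f at %d h\n",
              x$peaks$neutrophils[["amplitude"]],
              as.integer(x$peaks$neutrophils[["tick"]])))
  cat(sprintf("  macrophage peak:    %.1f at %d h\n",
              x$peaks$macrophages[["amplitude"]],
              as.integer(x$peaks$macrophages[["tick"]])))
  cat(sprintf("  SC activated total: %.1f\n", x$sc_activated_total))
  cat(sprintf("  endpoint fibrils:   %.1f (initial %d)\n",
              x$endpoint[["fibril"]], as.integer(x$initial[["fibril"]])))
  cat(sprintf("  endpoint ECM:       %.1f (initial %d, %+.2f%%)\n",
              x$endpoint[["ecm"]], as.integer(x$initial[["ecm"]]),
              x$ecm_pct_change))
  invisible(x)
}

#' Compare localised and widespread summaries
#'
#' Signed differences (widespread minus localised) and orderings for the
#' headline statistics of two condition summaries at the same damage
#' fraction: clearance and recovery times, neutrophil and macrophage peak
#' amplitude/timing, satellite-cell activation totals, and endpoint fibril
#' and ECM counts.
#'
#' @param summary_localised,summary_widespread [run_summary()] objects.
#' @return A `condition_comparison` data frame with columns `metric`,
#'   `localised`, `widespread`, `difference`.
#' @export
compare_conditions <- function(summary_localised, summary_widespread) {
  sl <- summary_localised
  sw <- summary_widespread
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  metrics <- list(
    time_to_recovery = c(num(sl$time_to_recovery), num(sw$time_to_recovery)),
    damage_clearance_time = c(num(sl$damage_clearance_time),
                              num(sw$damage_clearance_time)),
    neutrophil_peak_amplitude = c(sl$peaks$neutrophils[["amplitude"]],
                                  sw$peaks$neutrophils[["amplitude"]]),
    neutrophil_peak_tick = c(sl$peaks$neutrophils[["tick"]],
                             sw$peaks$neutrophils[["tick"]]),
    macrophage_peak_amplitude = c(sl$peaks$macrophages[["amplitude"]],
                                  sw$peaks$macrophages[["amplitude"]]),
    macrophage_peak_tick = c(sl$peaks$macrophages[["tick"]],
                             sw$peaks$macrophages[["tick"]]),
    sc_activated_total = c(num(sl$sc_activated_total),
                           num(sw$sc_activated_total)),
    endpoint_fibril = c(sl$endpoint[["fibril"]], sw$endpoint[["fibril"]]),
    endpoint_ecm = c(sl$endpoint[["ecm"]], sw$endpoint[["ecm"]]))
  out <- data.frame(
    metric = names(metrics),
    localised = vapply(metrics, `[`, numeric(1), 1L),
    widespread = vapply(metrics, `[`, numeric(1), 2L),
    row.names = NULL)
  out$difference <- out$widespread - out$localised
  class(out) <- c("condition_comparison", class(out))
  out
}

#' Write / read a condition comparison as JSON
#'
#' @param comparison a [compare_conditions()] result.
#' @param path JSON path.
#' @export
save_comparison <- function(comparison, path) {
  jsonlite::write_json(as.data.frame(unclass(comparison)), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname save_comparison
#' @export
load_comparison <- function(path) {
  out <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(out) <- c("condition_comparison", class(out))
  out
}
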