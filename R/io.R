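#' Read and write the package's columnar text formats
#'
#' Photometry sessions, event logs, trajectories, sweeps, and tracing
#' counts all travel as plain CSV with fixed column schemas; processed
#' traces as two-column CSV (`t_s`, `z`); pipeline diagnostics as JSON.
#'
#' @param path File path.
#' @param session A `photometry_session`.
#' @name photopeth-io
NULL

#' @rdname photopeth-io
#' @export
write_photometry_csv <- function(session, path) {
  utils::write.csv(as.data.frame(unclass(session))[,
    c("frame_index", "t_s", "channel", "roi_signal", "roi_control")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname photopeth-io
#' @param rate_hz Per-channel multiplex rate (10 or 15 Hz).
#' @export
read_photometry_csv <- function(path, rate_hz) {
  frames <- utils::read.csv(path, colClasses = c(channel = "character"))
  photometry_session(frames, rate_hz = rate_hz)
}

#' @rdname photopeth-io
#' @param trace A `processed_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname photopeth-io
#' @param sample_rate_hz Sampling rate of the stored trace; inferred from
#'   the timestamps when `NULL`.
#' @export
read_trace_csv <- function(path, sample_rate_hz = NULL) {
  df <- utils::read.csv(path)
  processed_trace(df$t_s, df$z, sample_rate_hz)
}

#' @rdname photopeth-io
#' @param log An `event_log` data frame.
#' @export
write_event_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(unclass(log))[,
    c("t_s", "label", "trial_index", "light_flag")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname photopeth-io
#' @param schedule Optional schedule name attached to the returned log.
#' @export
read_event_log_csv <- function(path, schedule = NULL) {
  df <- utils::read.csv(path, colClasses = c(label = "character"))
  structure(df, class = c("event_log", "data.frame"), schedule = schedule)
}

#' @rdname photopeth-io
#' @param sweep A `current_clamp_sweep`.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- data.frame(t_s = sweep$t_s, vm_mv = sweep$vm_mv, i_pa = sweep$i_pa)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname photopeth-io
#' @param step Step descriptor (`onset_s`, `offset_s`, `amplitude_pa`);
#'   when `NULL` it is inferred from the `i_pa` column.
#' @export
read_sweep_csv <- function(path, step = NULL) {
  df <- utils::read.csv(path)
  if (is.null(step)) {
    on_idx <- which(df$i_pa != 0)
    if (length(on_idx) == 0L) stop("sweep has no current step; supply `step`")
    dt <- df$t_s[2L] - df$t_s[1L]
    step <- list(onset_s = df$t_s[min(on_idx)],
                 offset_s = df$t_s[max(on_idx)] + dt,
                 amplitude_pa = df$i_pa[min(on_idx)])
  }
  current_clamp_sweep(df$t_s, df$vm_mv, df$i_pa, step)
}

#' @rdname photopeth-io
#' @param counts A `tracing_counts` table.
#' @export
write_tracing_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(unclass(counts)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname photopeth-io
#' @export
read_tracing_csv <- function(path) {
  tracing_counts(utils::read.csv(path,
                                 colClasses = c(region = "character")))
}

#' @rdname photopeth-io
#' @export
write_diagnostics_json <- function(trace, path) {
  stopifnot(inherits(trace, "processed_trace"))
  jsonlite::write_json(trace$diagnostics, path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
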