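# File formats: BIDS-style events TSV, signal CSV, results TSV/JSON.
# All writers use tab/comma-delimited UTF-8, '.' decimal, and fixed
# 6-significant-digit floats so identical config + seed gives identical bytes.

stim_duration_s <- function(trial_type, soa_ms) {
  # pulse 40 ms, prepulse 20 ms; a PPI trial spans prepulse onset to pulse end
  ifelse(trial_type == "pulse", 0.040,
         ifelse(trial_type == "prepulse", 0.020, soa_ms / 1000 + 0.040))
}

#' Write a run schedule as a BIDS-style events.tsv
#'
#' Columns: onset (s), duration (s), trial_type, soa_ms (empty for non-PPI
#' trials). Tab-delimited, period decimal separator.
#'
#' @param run_schedule a [build_run_schedule()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(run_schedule, path) {
  s <- run_schedule
  df <- data.frame(onset = fmt_num(s$onset),
                   duration = fmt_num(stim_duration_s(s$trial_type, s$soa_ms)),
                   trial_type = s$trial_type,
                   soa_ms = ifelse(is.na(s$soa_ms), "", fmt_num(s$soa_ms)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events.tsv
#'
#' @param path tab-delimited file with header onset, duration, trial_type
#'   (and optionally soa_ms).
#' @return data.frame with onset (s), duration (s), trial_type, soa_ms,
#'   index_in_run.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    df$soa_ms <- numeric(0); df$index_in_run <- integer(0)
    return(df)
  }
  bad <- which(!df$trial_type %in% trial_type_levels())
  if (length(bad))
    stop("unknown trial_type in row(s) ", paste(bad, collapse = ", "), ": ",
         paste(unique(df$trial_type[bad]), collapse = ", "))
  if (any(!is.finite(df$onset)) || is.unsorted(df$onset, strictly = TRUE))
    stop("onsets must be finite and strictly increasing")
  if (is.null(df$soa_ms)) df$soa_ms <- soa_of(df$trial_type)
  df$soa_ms <- as.numeric(df$soa_ms)
  df$index_in_run <- seq_len(nrow(df))
  df
}

#' Write a continuous EMG signal as CSV
#'
#' Two columns, `time_s` and `emg_mv`; a comment line declaring units and
#' sampling rate precedes the header.
#'
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# emg signal; units: s, mV; fs = %g Hz; channel = %s",
                     rec$fs, rec$channel), con)
  t <- rec$start_time + (seq_along(rec$samples) - 1) / rec$fs
  writeLines("time_s,emg_mv", con)
  writeLines(paste(sprintf("%.6f", t), fmt_num(rec$samples), sep = ","), con)
  invisible(path)
}

#' Read a continuous EMG signal from CSV
#'
#' Expects columns `time_s`, `emg_mv` with uniform sampling; the sampling rate
#' is inferred from the timestamps (each step must match the median step
#' within 0.1%). Gaps, non-uniform steps, or non-finite samples are errors.
#'
#' @param path CSV file path.
#' @return an [emg_recording()].
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "emg_mv") %in% names(df)))
    stop("signal file must have columns time_s, emg_mv")
  if (nrow(df) < 2) stop("signal too short")
  if (any(!is.finite(df$emg_mv)))
    stop("non-finite samples at indices: ",
         paste(utils::head(which(!is.finite(df$emg_mv)), 5), collapse = ", "))
  dt <- diff(df$time_s)
  dt0 <- stats::median(dt)
  bad <- which(abs(dt - dt0) > 0.001 * dt0)
  if (length(bad))
    stop("non-uniform sampling at indices: ",
         paste(utils::head(bad, 5), collapse = ", "))
  emg_recording(df$emg_mv, fs = 1 / dt0, start_time = df$time_s[1])
}

# tab-delimited writer with a units comment line and fixed float formatting
write_tsv_units <- function(df, path, units_comment) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", units_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
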