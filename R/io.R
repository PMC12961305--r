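#' Read a stimulation event list from TSV
#'
#' Expects tab-separated columns `onset_ms`, `finger`, `block`. Malformed
#' rows (non-numeric onset, missing fields) are rejected with their line
#' numbers; non-monotone onsets are an error naming the offending line.
#'
#' @param path TSV file path.
#' @return a `stim_train`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_ms", "finger", "block")
  if (!all(need %in% names(df)))
    stop("events TSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(suppressWarnings(as.numeric(df$onset_ms))) |
                 is.na(df$finger) | df$finger == "" |
                 is.na(suppressWarnings(as.integer(df$block))))
  if (length(bad) > 0)
    stop("malformed event rows at lines: ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  on <- as.numeric(df$onset_ms)
  nm <- which(diff(on) <= 0)
  if (length(nm) > 0)
    stop("non-monotone onsets at line ", nm[1] + 2L)
  structure(list(onsets = on, finger = df$finger[1],
                 block = as.integer(df$block), seed = NA_integer_),
            class = "stim_train")
}

#' Write a stimulation train to TSV
#' @param train a `stim_train`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(train, path) {
  stopifnot(inherits(train, "stim_train"))
  df <- data.frame(onset_ms = train$onsets,
                   finger = train$finger,
                   block = rep(train$block,
                               length.out = length(train$onsets)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a recording to the plain-text container
#'
#' The container is a pair of files: `<path>` holds the channel x sample
#' matrix as TSV (one column per channel, full `%.17g` precision, so the
#' round-trip is lossless), and `<path>.json` holds sampling rate, channel
#' labels, events and metadata.
#'
#' @param rec an `eeg_recording`.
#' @param path data file path (the JSON sidecar gets `.json` appended).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  cols <- lapply(seq_len(nrow(rec$data)), function(i)
    sprintf("%.17g", rec$data[i, ]))     # %.17g: doubles survive exactly
  con <- file(path, "w")
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  close(con)
  jsonlite::write_json(
    list(srate = rec$srate, channel_labels = rec$channel_labels,
         unit = "uV",
         events = list(onsets = rec$events$onsets,
                       finger = rec$events$finger,
                       block = rec$events$block,
                       seed = rec$events$seed),
         meta = rec$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recording
#'
#' Reads the plain-text container written by [write_recording()]. An
#' external events TSV, when given, takes precedence over the events
#' embedded in the container (a message notes the override).
#'
#' @param path data file path.
#' @param events_tsv optional path to an events TSV overriding embedded
#'   events.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, events_tsv = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.(vhdr|vmrk|eeg|edf)$", path, ignore.case = TRUE))
    stop("unsupported format; supported: the package's TSV+JSON container ",
         "(write_recording) with an events TSV")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing metadata sidecar ", meta_path,
         "; supported: the package's TSV+JSON container")
  js <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  train <- structure(list(onsets = as.numeric(js$events$onsets),
                          finger = js$events$finger,
                          block = as.integer(js$events$block),
                          seed = if (is.null(js$events$seed)) NA_integer_
                                 else as.integer(js$events$seed)),
                     class = "stim_train")
  if (!is.null(events_tsv)) {
    message("external events TSV overrides embedded events")
    train <- read_events(events_tsv)
  }
  structure(list(data = t(as.matrix(df)), srate = as.numeric(js$srate),
                 channel_labels = js$channel_labels,
                 events = train,
                 meta = as.list(js$meta)),
            class = "eeg_recording")
}

#' Write a JIERP tensor to TSV
#'
#' One row per bin (row, col, then one column per latency); invalid bins
#' are written as NA. Trial counts go into a `<path>.counts.tsv` sidecar.
#'
#' @param jierp a `jierp`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_jierp_tsv <- function(jierp, path) {
  stopifnot(inherits(jierp, "jierp"))
  b <- jierp$grid$n_bins
  flat <- matrix(jierp$amplitude, b * b, length(jierp$time_ms))
  df <- cbind(expand.grid(row = seq_len(b), col = seq_len(b)),
              stats::setNames(as.data.frame(flat),
                              paste0("t", jierp$time_ms)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cnt <- cbind(expand.grid(row = seq_len(b), col = seq_len(b)),
               trial_count = as.vector(jierp$trial_count))
  utils::write.table(cnt, paste0(path, ".counts.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a JIERP tensor written by [write_jierp_tsv()]
#'
#' @param path TSV path.
#' @param min_trials validity threshold re-applied from the counts
#'   sidecar (default 10); without a sidecar, validity is inferred from
#'   non-NA amplitudes.
#' @return a `jierp`.
#' @export
read_jierp_tsv <- function(path, min_trials = 10) {
  df <- utils::read.delim(path, check.names = FALSE)
  tcols <- grep("^t-?\\d+$", names(df))
  time_ms <- as.integer(sub("^t", "", names(df)[tcols]))
  b <- as.integer(sqrt(nrow(df)))
  stopifnot(b * b == nrow(df))
  amp <- array(as.matrix(df[, tcols]), dim = c(b, b, length(tcols)))
  cpath <- paste0(path, ".counts.tsv")
  if (file.exists(cpath)) {
    cnt <- matrix(utils::read.delim(cpath)$trial_count, b, b)
    valid <- cnt >= min_trials
  } else {
    cnt <- matrix(NA_integer_, b, b)
    valid <- !apply(is.na(amp), c(1, 2), all)
  }
  grid <- bin_grid()
  if (b != grid$n_bins) grid <- bin_grid(seq_len(b))
  structure(list(amplitude = amp, trial_count = cnt, valid = valid,
                 time_ms = time_ms, grid = grid, counts = list(),
                 meta = list(source = path)),
            class = "jierp")
}
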