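# shared fixtures, all generated in code

# a small epoch_set built directly (bypasses filtering) for unit tests
make_epochs <- function(data, time_ms = -200:299, event_index = NULL,
                        events = NULL) {
  n <- dim(data)[1]
  structure(list(data = data, time_ms = time_ms,
                 event_index = if (is.null(event_index)) seq_len(n)
                               else event_index,
                 rejected = rep(FALSE, n),
                 n_dropped_edge = 0L,
                 channel_labels = paste0("CH", seq_len(dim(data)[2])),
                 events = events,
                 meta = list()),
            class = "epoch_set")
}

# manufacture a stim_train from explicit onsets (ms)
make_train <- function(onsets, finger = "index") {
  structure(list(onsets = onsets, finger = finger,
                 block = rep(1L, length(onsets)), seed = 0L),
            class = "stim_train")
}

# a zjierp with given z array and validity (defaults all valid)
make_zjierp <- function(z, valid = NULL, grid = jierp::bin_grid()) {
  b <- dim(z)[1]
  structure(list(z = z,
                 valid = if (is.null(valid)) matrix(TRUE, b, b) else valid,
                 time_ms = seq_len(dim(z)[3]),
                 constant_latency = rep(FALSE, dim(z)[3]),
                 grid = grid, meta = list()),
            class = "zjierp")
}

# one fully preprocessed synthetic subject; memoised per parameter set
quick_subject <- local({
  cache <- list()
  function(seed = 1, n_events = 600, preset = "none", noise_sd = 0,
           n_channels = 4) {
    key <- paste(seed, n_events, preset, noise_sd, n_channels)
    if (!is.null(cache[[key]])) return(cache[[key]])
    tr <- jierp::generate_train(n_events, seed = seed)
    rec <- jierp::synthesize_recording(
      tr, jierp::erp_template(), jierp::modulation_spec(preset),
      n_channels = n_channels, noise_sd = noise_sd, seed = seed + 500)
    ep <- jierp::preprocess(rec)
    out <- list(train = tr, rec = rec, epochs = ep,
                triads = jierp::compute_triads(rec$events))
    cache[[key]] <<- out
    out
  }
})
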