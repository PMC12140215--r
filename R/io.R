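#' Read and write trial tables
#'
#' Trial tables are plain CSV with the documented header (`participant`,
#' `session`, `condition`, `block`, `stimulus`, `stim`, `gap_time`,
#' `fm_phase`, `tacs_phase`, `tacs_lag`, `response_time`, `accuracy`);
#' phases are serialized in radians.
#'
#' @param table A trial table.
#' @param path File path.
#' @return `read_trial_table` returns a `trial_table` data frame.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$condition <- as.character(d$condition)
  need <- c("participant", "condition", "gap_time", "accuracy")
  if (!all(need %in% names(d)))
    stop("read_trial_table: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  structure(d, class = c("trial_table", "data.frame"))
}

#' Write / read an epoch set
#'
#' Epoch data are stored as a whitespace-delimited sample matrix (one row
#' per trial x channel, trials varying slowest) next to a JSON sidecar
#' holding the sampling rate, condition, channel labels and onset phase.
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory to write `epochs.txt` and `epochs.json` into
#'   (created if needed).
#' @return `read_epochs` returns an `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  utils::write.table(flat, file.path(dir, "epochs.txt"),
                     row.names = FALSE, col.names = FALSE)
  meta <- list(fs = epochs$fs, condition = epochs$condition,
               channel_labels = epochs$channel_labels,
               onset_phase = epochs$onset_phase,
               n_trials = d[1], n_channels = d[2], n_samples = d[3])
  jsonlite::write_json(meta, file.path(dir, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(dir, "epochs.txt")))
  dat <- array(NA_real_,
               dim = c(meta$n_trials, meta$n_channels, meta$n_samples))
  r <- 1L
  for (tr in seq_len(meta$n_trials)) for (ch in seq_len(meta$n_channels)) {
    dat[tr, ch, ] <- flat[r, ]
    r <- r + 1L
  }
  structure(list(data = dat, fs = meta$fs, condition = meta$condition,
                 channel_labels = meta$channel_labels,
                 onset_phase = meta$onset_phase),
            class = "epoch_set")
}
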