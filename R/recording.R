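#' Construct a continuous EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs, channel_labels) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0,
            length(channel_labels) == nrow(data))
  if (!all(is.finite(data))) stop("recording contains non-finite values")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct a set of cue-aligned trials
#'
#' @param data numeric array, trials x channels x samples, microvolts.
#' @param labels per-trial class, factor or character; levels drawn from
#'   `mi_classes()`.
#' @param fs sampling rate (Hz).
#' @param cue_sample 1-based index of the cue within each epoch.
#' @param round_id integer per-trial experimental round in 1..10.
#' @param channel_labels optional channel labels.
#' @return an object of class `eeg_epochs`.
#' @export
new_epochs <- function(data, labels, fs, cue_sample, round_id,
                       channel_labels = NULL) {
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[1]
  labels <- factor(as.character(labels), levels = mi_classes())
  if (anyNA(labels)) stop("labels must be drawn from: ",
                          paste(mi_classes(), collapse = ", "))
  stopifnot(length(labels) == n, length(round_id) == n,
            cue_sample >= 1, cue_sample <= dim(data)[3])
  if (is.null(channel_labels)) channel_labels <- as.character(seq_len(dim(data)[2]))
  structure(list(data = data, labels = labels, fs = as.numeric(fs),
                 cue_sample = as.integer(cue_sample),
                 round_id = as.integer(round_id),
                 channel_labels = as.character(channel_labels)),
            class = "eeg_epochs")
}

#' The four motor-imagery class labels
#' @return character vector of class names in canonical order.
#' @export
mi_classes <- function() c("left_hand", "right_hand", "tongue", "foot")

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, cue at %d\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$cue_sample))
  print(table(x$labels))
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

subset_epochs <- function(epochs, trials) {
  new_epochs(epochs$data[trials, , , drop = FALSE], epochs$labels[trials],
             epochs$fs, epochs$cue_sample, epochs$round_id[trials],
             epochs$channel_labels)
}

select_channels <- function(epochs, idx) {
  new_epochs(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
             epochs$cue_sample, epochs$round_id, epochs$channel_labels[idx])
}

#' Read / write a recording as a CSV matrix
#'
#' Rows are channels; the first column (`channel`) carries the label, the
#' remaining columns the samples. A leading comment line `# fs: <Hz>`
#' records the sampling rate.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @return `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", rec$fs), con)
  df <- data.frame(channel = rec$channel_labels, rec$data,
                   check.names = FALSE)
  colnames(df) <- c("channel", paste0("s", seq_len(ncol(rec$data))))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# fs:", first)) stop("missing '# fs:' header line")
  fs <- as.numeric(sub("^# fs:\\s*", "", first))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  new_recording(as.matrix(df[, -1, drop = FALSE]), fs, df[[1]])
}

#' Write / read an epoch set as a directory of per-trial CSVs
#'
#' `manifest.csv` lists one row per trial (`trial`, `label`, `round_id`,
#' `cue_sample`, `fs`, `file`); each trial file is a channels x samples CSV
#' in the recording dialect.
#'
#' @param epochs an `eeg_epochs`.
#' @param dir directory to create/fill.
#' @return `read_epochs_dir` returns an `eeg_epochs`.
#' @export
write_epochs_dir <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_trials(epochs)
  files <- sprintf("trial_%03d.csv", seq_len(n))
  for (i in seq_len(n)) {
    write_recording_csv(
      new_recording(epochs$data[i, , ], epochs$fs, epochs$channel_labels),
      file.path(dir, files[i]))
  }
  manifest <- data.frame(trial = seq_len(n),
                         label = as.character(epochs$labels),
                         round_id = epochs$round_id,
                         cue_sample = epochs$cue_sample,
                         fs = epochs$fs, file = files)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs_dir
#' @export
read_epochs_dir <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(file.path(dir, manifest$file), read_recording_csv)
  nch <- nrow(recs[[1]]$data); ns <- ncol(recs[[1]]$data)
  arr <- array(NA_real_, c(nrow(manifest), nch, ns))
  for (i in seq_along(recs)) arr[i, , ] <- recs[[i]]$data
  new_epochs(arr, manifest$label, manifest$fs[1], manifest$cue_sample[1],
             manifest$round_id, recs[[1]]$channel_labels)
}
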