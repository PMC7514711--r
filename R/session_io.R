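SESSION_FORMAT_VERSION <- 1L

#' Write a session container
#'
#' Serializes a `bci_recording` into a plain-text directory container:
#' `meta.json` (format version, sampling rate, channel labels, subject id
#' and the provenance block), `characters.csv`, `events.csv` and
#' `signal.csv` (samples x channels, one column per channel).  Signal
#' values are written with 17 significant digits, so the round trip
#' through [read_session()] is lossless.
#'
#' @param recording A valid `bci_recording`.
#' @param path Directory to create (must not already contain a session
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, path, overwrite = FALSE) {
  validate_recording(recording)
  if (file.exists(file.path(path, "meta.json")) && !isTRUE(overwrite))
    stop("session already exists at ", path, call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  meta <- list(
    format = "asyncbci-session",
    format_version = SESSION_FORMAT_VERSION,
    fs = recording$fs,
    channel_labels = recording$channel_labels,
    n_samples = ncol(recording$signal),
    subject_id = recording$subject_id,
    provenance = recording$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  chars <- data.frame(
    character_index = seq_along(recording$characters),
    label = vapply(recording$characters, `[[`, "", "label"),
    state = vapply(recording$characters, `[[`, "", "state"),
    start_sample = vapply(recording$characters, `[[`, 0L, "start_sample"))
  data.table::fwrite(chars, file.path(path, "characters.csv"))
  events <- do.call(rbind, lapply(seq_along(recording$characters),
    function(ci) {
      ev <- recording$characters[[ci]]$events
      cbind(character_index = ci, ev)
    }))
  data.table::fwrite(events, file.path(path, "events.csv"))
  # signal: %.17g guarantees exact double round-trip through text
  sig <- t(recording$signal)
  lines <- c(paste(recording$channel_labels, collapse = ","),
             do.call(paste,
                     c(lapply(seq_len(ncol(sig)),
                              function(j) sprintf("%.17g", sig[, j])),
                       sep = ",")))
  writeLines(lines, file.path(path, "signal.csv"))
  invisible(path)
}

#' Read a session container
#'
#' Reads and fully validates a session directory written by
#' [write_session()].  Schema violations (unsupported version, mismatched
#' channel labels, events outside the recorded range, unknown states)
#' raise descriptive errors naming the failing field.
#'
#' @param path Session directory.
#' @return A `bci_recording`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf))
    stop("not a session container (missing meta.json): ", path,
         call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version > SESSION_FORMAT_VERSION)
    stop(sprintf("unsupported session format version: %s",
                 as.character(meta$format_version)), call. = FALSE)
  sig_dt <- data.table::fread(file.path(path, "signal.csv"),
                              header = TRUE, sep = ",")
  if (!identical(names(sig_dt), as.character(meta$channel_labels)))
    stop("invalid session: field `channel_labels` does not match ",
         "the signal columns", call. = FALSE)
  signal <- t(as.matrix(sig_dt))
  dimnames(signal) <- NULL
  chars <- data.table::fread(file.path(path, "characters.csv"),
                             data.table = FALSE)
  events <- data.table::fread(file.path(path, "events.csv"),
                              data.table = FALSE)
  characters <- lapply(seq_len(nrow(chars)), function(i) {
    ev <- events[events$character_index == chars$character_index[i],
                 c("onset_sample", "stimulus_id", "is_target",
                   "sequence_index")]
    rownames(ev) <- NULL
    list(label = as.character(chars$label[i]), state = chars$state[i],
         start_sample = chars$start_sample[i], events = ev)
  })
  prov <- meta$provenance
  rec <- structure(list(
    signal = signal, fs = as.numeric(meta$fs),
    channel_labels = as.character(meta$channel_labels),
    characters = characters, subject_id = meta$subject_id,
    provenance = prov), class = "bci_recording")
  validate_recording(rec)
  rec
}
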