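#' Zero-phase band-pass filtering of a multichannel signal
#'
#' Applies a Butterworth band-pass per channel, forward and backward
#' (zero net phase).  For numerical robustness with very low high-pass
#' edges the band-pass is realized as a cascade of a 2nd-order high-pass
#' and a 4th-order low-pass, each run through `filtfilt`.
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_filter <- function(signal, fs, low = 0.1, high = 30) {
  signal <- as_signal_matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!(low > 0 && high > low && high < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  out <- signal
  for (ch in seq_len(nrow(signal))) {
    y <- signal::filtfilt(hp, signal[ch, ])
    out[ch, ] <- signal::filtfilt(lp, y)
  }
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels from
#' each channel, so the across-channel mean of the output is zero
#' everywhere.
#'
#' @param signal Numeric matrix, channels x samples (at least 2 channels).
#' @return Re-referenced matrix of the same shape.
#' @export
common_average_reference <- function(signal) {
  signal <- as_signal_matrix(signal)
  if (nrow(signal) < 2L)
    stop("common average reference needs at least 2 channels", call. = FALSE)
  sweep(signal, 2L, colMeans(signal), "-")
}

#' Preprocess a recording (band-pass + common average reference)
#'
#' Standard continuous-session preprocessing applied before trial
#' extraction: per-channel zero-phase band-pass followed by a common
#' average reference.  Filtering the continuous recording (rather than the
#' extracted trials) avoids per-trial filter edge artifacts.
#'
#' @param recording A `bci_recording` (see [generate_session()] /
#'   [read_session()]).
#' @param low,high Band edges in Hz; set `low = NULL` (or `high = NULL`)
#'   to skip the band-pass entirely.
#' @param car Logical, apply the common average reference (default `TRUE`).
#' @return The recording with its `signal` replaced.
#' @export
preprocess_recording <- function(recording, low = 0.1, high = 30,
                                 car = TRUE) {
  validate_recording(recording)
  sig <- recording$signal
  if (!is.null(low) && !is.null(high))
    sig <- bandpass_filter(sig, recording$fs, low, high)
  if (isTRUE(car)) sig <- common_average_reference(sig)
  recording$signal <- sig
  recording
}

#' Extract cumulative trials for one character
#'
#' For a spelled character of `k` stimulation sequences, trial `i` is the
#' cumulative segment running from the character's first recorded sample up
#' to (excluding) the onset sample of the last flash of sequence `i`.
#' Trials are therefore nested: each contains the previous one as a prefix,
#' and lengths increase strictly with the sequence index.
#'
#' @param recording A `bci_recording`.
#' @param character One element of `recording$characters`.
#' @return A list of trials, each a list with `sequence_index`, `segment`
#'   (channels x samples), `n` (length in samples) and `state`.
#' @export
extract_trials <- function(recording, character) {
  validate_recording(recording)
  ev <- character$events
  n_seq <- max(ev$sequence_index)
  start <- character$start_sample  # 0-based
  trials <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    on_i <- ev$onset_sample[ev$sequence_index == i]
    if (length(on_i) != 12L)
      stop(sprintf("incomplete sequence %d: expected 12 flashes, got %d",
                   i, length(on_i)), call. = FALSE)
    end0 <- max(on_i)  # 0-based, exclusive
    if (end0 > ncol(recording$signal))
      stop("event onset beyond recorded signal", call. = FALSE)
    segment <- recording$signal[, (start + 1L):end0, drop = FALSE]
    trials[[i]] <- list(sequence_index = i, segment = segment,
                        n = end0 - start, state = character$state)
  }
  trials
}

#' Balanced optimization/validation split
#'
#' Randomly assigns characters to an optimization and a validation set at
#' the given ratio, independently for each subject and each state, so
#' that both sets stay balanced (equal control and non-control counts)
#' within every subject.
#'
#' @param info A data frame with columns `subject`, `character_index` and
#'   `state` (values `"control"` / `"non-control"`), one row per character.
#' @param ratio Fraction assigned to the optimization set (default 0.3).
#' @param seed Optional integer seed making the split reproducible without
#'   disturbing the global RNG state.
#' @return `info` with an added factor column `set`
#'   (`"optimization"`/`"validation"`).
#' @export
split_dataset <- function(info, ratio = 0.3, seed = NULL) {
  req <- c("subject", "character_index", "state")
  if (!is.data.frame(info) || !all(req %in% names(info)))
    stop("`info` must have columns subject, character_index, state",
         call. = FALSE)
  if (!all(info$state %in% c("control", "non-control")))
    stop("`state` must be 'control' or 'non-control'", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("`ratio` must be in (0, 1)")
  with_local_seed(seed, {
    info$set <- factor(rep("validation", nrow(info)),
                       levels = c("optimization", "validation"))
    for (subj in unique(info$subject)) {
      rows <- which(info$subject == subj)
      st <- info$state[rows]
      n_c <- sum(st == "control"); n_n <- sum(st == "non-control")
      if (n_c != n_n)
        stop(sprintf(
          "subject %s unbalanced: %d control vs %d non-control characters",
          subj, n_c, n_n), call. = FALSE)
      for (state in c("control", "non-control")) {
        srows <- rows[st == state]
        k <- round(ratio * length(srows))
        pick <- sample(srows, k)
        info$set[pick] <- "optimization"
      }
    }
    info
  })
}

# coerce/validate a channels x samples numeric matrix
as_signal_matrix <- function(signal) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix (channels x samples)",
         call. = FALSE)
  signal
}

# evaluate `code` under a temporary RNG seed, restoring the global state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
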