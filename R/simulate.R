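#' Standard 16-channel montage of the recording protocol
#'
#' Channel labels (International 10-20 system) in the fixed order used
#' throughout the pipeline.
#' @export
bci_channels <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "CPz", "Pz",
                  "P3", "P4", "POz", "PO3", "PO4", "PO7", "PO8", "Oz")

#' Configuration for the synthetic oddball generator
#'
#' Bundles and validates the parameters of [generate_session()].  The
#' defaults reproduce the acquisition protocol the pipeline is designed
#' for: a 6x6 row-column speller flashing for 75 ms with a 100 ms
#' inter-stimulus interval, 15 sequences of 12 flashes per character, 120
#' characters per subject (half control, half non-control) and 16 channels
#' sampled at 256 Hz.
#'
#' @param n_subjects Number of subjects the dataset comprises.
#' @param n_characters Characters per subject (even; half per state).
#' @param fs Sampling rate in Hz.
#' @param flash_ms,isi_ms Flash duration and inter-stimulus interval (ms).
#' @param n_sequences Stimulation sequences per character.
#' @param n_channels Number of EEG channels.
#' @param regularity_gap Dimensionless in `[0, 1]`: scales every
#'   state-dependent signal component, so `0` makes control and
#'   non-control characters statistically identical and larger values give
#'   control characters increasingly higher sample entropy.
#' @param erp_amplitude Peak amplitude (uV) of the P300-like deflection
#'   added 300 ms after target flashes of control characters (scaled by
#'   `regularity_gap`).
#' @param alpha_power Amplitude (uV) of the 10 Hz rhythm added to
#'   non-control characters (scaled by `regularity_gap`); a strong regular
#'   oscillation lowers sample entropy, emulating an idle/reading state.
#' @param gapnoise_amplitude Amplitude (uV, as standard deviation) of the
#'   band-limited noise added to control characters (scaled by
#'   `regularity_gap`).  The band sits between one third and one half of
#'   Nyquist, so the extra irregularity survives decimation by 2 but is
#'   largely removed from scale 3 onward - the gap is concentrated at
#'   scale 2.
#' @param mask_amplitude Amplitude (uV, sd) of a shared high-band noise
#'   (above half Nyquist, present in both states) that masks the gap at
#'   scale 1 and is filtered out at scale 2.
#' @param noise_ar AR coefficients of the 1/f-like background process.
#' @param noise_sd Background standard deviation (uV).
#' @param gap_channel_weights Optional per-channel weights (length
#'   `n_channels`) for the state-dependent components.  Default: for the
#'   standard 16-channel montage, weight 1 on frontal and occipital
#'   channels and 0.3 elsewhere; uniform 1 otherwise.
#' @param inter_char_gap_ms Pause between consecutive characters (ms).
#' @param seed Integer seed; sessions are bit-identical for identical
#'   config + seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10L, n_characters = 120L, fs = 256,
                         flash_ms = 75, isi_ms = 100, n_sequences = 15L,
                         n_channels = 16L, regularity_gap = 0.5,
                         erp_amplitude = 5, alpha_power = 6,
                         gapnoise_amplitude = 14, mask_amplitude = 8,
                         noise_ar = c(1.6, -0.64), noise_sd = 5,
                         gap_channel_weights = NULL,
                         inter_char_gap_ms = 500, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_characters = as.integer(n_characters), fs = fs,
              flash_ms = flash_ms, isi_ms = isi_ms,
              n_sequences = as.integer(n_sequences),
              n_channels = as.integer(n_channels),
              regularity_gap = regularity_gap,
              erp_amplitude = erp_amplitude, alpha_power = alpha_power,
              gapnoise_amplitude = gapnoise_amplitude,
              mask_amplitude = mask_amplitude, noise_ar = noise_ar,
              noise_sd = noise_sd,
              gap_channel_weights = gap_channel_weights,
              inter_char_gap_ms = inter_char_gap_ms,
              seed = as.integer(seed))
  if (cfg$flash_ms + cfg$isi_ms <= 0)
    stop("invalid timing: flash_ms + isi_ms must be positive", call. = FALSE)
  if (cfg$n_characters < 2L || cfg$n_characters %% 2L != 0L)
    stop("`n_characters` must be even (balanced states)", call. = FALSE)
  if (cfg$n_channels < 2L) stop("need at least 2 channels", call. = FALSE)
  if (cfg$n_sequences < 1L) stop("need at least 1 sequence", call. = FALSE)
  if (cfg$regularity_gap < 0 || cfg$regularity_gap > 1)
    stop("`regularity_gap` must be in [0, 1]", call. = FALSE)
  if (!is.null(cfg$gap_channel_weights) &&
      length(cfg$gap_channel_weights) != cfg$n_channels)
    stop("`gap_channel_weights` must have length n_channels", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' P300-like waveform template
#'
#' Smooth unimodal deflection peaking 300 ms after stimulus onset with
#' support on 200-500 ms (zero outside), realized as two raised-cosine
#' half-lobes.  The amplitude scales the waveform linearly.
#'
#' @param t Time since stimulus onset, in seconds (vectorized).
#' @param amplitude Peak amplitude (uV), non-negative.
#' @return Deflection values, same length as `t`.
#' @export
erp_template <- function(t, amplitude = 1) {
  if (amplitude < 0) stop("`amplitude` must be non-negative", call. = FALSE)
  w <- numeric(length(t))
  rise <- t >= 0.2 & t < 0.3
  fall <- t >= 0.3 & t <= 0.5
  w[rise] <- 0.5 * (1 - cos(pi * (t[rise] - 0.2) / 0.1))
  w[fall] <- 0.5 * (1 + cos(pi * (t[fall] - 0.3) / 0.2))
  amplitude * w
}

# default spatial weighting of the state-dependent components:
# strongest over frontal and occipital sites, as the channel-wise
# statistics of the pipeline are expected to highlight those regions
default_gap_weights <- function(n_channels) {
  if (n_channels == 16L) {
    w <- rep(0.3, 16L)
    names(w) <- bci_channels
    w[c("Fz", "F3", "F4", "POz", "PO3", "PO4", "PO7", "PO8", "Oz")] <- 1
    unname(w)
  } else rep(1, n_channels)
}

# band-limited Gaussian noise with unit standard deviation
bandnoise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, stats::rnorm(n + 512L))[-(1:512)]
  y / stats::sd(y)
}

#' Generate one synthetic oddball session
#'
#' Simulates a multichannel EEG recording of a row-column speller session
#' with per-character state labels and a full stimulus event log.  All
#' characters share a 1/f-like AR(2) background plus a common high-band
#' noise component.  State-dependent components, all scaled by
#' `regularity_gap`, make control characters more irregular than
#' non-control ones: control characters receive band-limited broadband
#' noise (raising sample entropy) and P300-like transients after target
#' flashes, while non-control characters receive a strong amplitude
#' modulated 10 Hz rhythm (lowering sample entropy).  See [synth_config()]
#' for how the component bands localize the entropy gap at scale 2.
#'
#' @param config A [synth_config()].
#' @param subject Subject index in `1..config$n_subjects`; each subject
#'   uses an independent RNG substream derived from `config$seed`.
#' @return A `bci_recording`: list with `signal` (channels x samples, uV),
#'   `fs`, `channel_labels`, `characters` (each with `label`, `state`,
#'   `start_sample` and an `events` data frame), `subject_id` and a
#'   `provenance` block recording the generator configuration.
#' @export
generate_session <- function(config = synth_config(), subject = 1L) {
  stopifnot(inherits(config, "synth_config"))
  subject <- as.integer(subject)
  if (subject < 1L || subject > config$n_subjects)
    stop("`subject` out of range", call. = FALSE)
  with_local_seed(config$seed + 7919L * (subject - 1L), {
    fs <- config$fs
    n_seq <- config$n_sequences
    n_char <- config$n_characters
    n_ch <- config$n_channels
    soa <- (config$flash_ms + config$isi_ms) / 1000
    n_flash <- 12L * n_seq
    # character window: last flash onset + flash + 650 ms tail for the ERP
    char_n <- floor((n_flash - 1) * soa * fs) +
      round((config$flash_ms / 1000 + 0.65) * fs)
    gap_n <- round(config$inter_char_gap_ms / 1000 * fs)
    N <- n_char * (char_n + gap_n)
    w <- config$gap_channel_weights
    if (is.null(w)) w <- default_gap_weights(n_ch)
    gap <- config$regularity_gap

    # shared background: AR(2) 1/f-like + high-band mask noise
    burn <- 500L
    sig <- matrix(0, n_ch, N)
    for (ch in seq_len(n_ch)) {
      bg <- stats::filter(stats::rnorm(N + burn), config$noise_ar,
                          method = "recursive")[-(1:burn)]
      bg <- config$noise_sd * bg / stats::sd(bg)
      mask <- config$mask_amplitude *
        bandnoise(N, c(0.52, 0.92) * fs / 2, fs)
      sig[ch, ] <- bg + mask
    }

    # balanced, shuffled state sequence and spelled symbols
    states <- sample(rep(c("control", "non-control"), n_char / 2L))
    symbols <- c(LETTERS, 0:9)
    cells <- sample(0:35, n_char, replace = TRUE)

    characters <- vector("list", n_char)
    for (ci in seq_len(n_char)) {
      start <- as.integer((ci - 1L) * (char_n + gap_n))  # 0-based
      cell <- cells[ci]
      row_id <- cell %/% 6L
      col_id <- 6L + cell %% 6L
      is_control <- states[ci] == "control"
      ev <- data.frame(
        onset_sample = integer(n_flash), stimulus_id = integer(n_flash),
        is_target = logical(n_flash), sequence_index = integer(n_flash))
      for (si in seq_len(n_seq)) {
        perm <- sample(0:11)
        k <- (si - 1L) * 12L + 0:11
        rows <- k + 1L
        ev$onset_sample[rows] <- as.integer(start + floor(k * soa * fs))
        ev$stimulus_id[rows] <- perm
        ev$sequence_index[rows] <- si
        ev$is_target[rows] <- is_control & perm %in% c(row_id, col_id)
      }
      idx <- (start + 1L):(start + char_n)
      tloc <- (seq_len(char_n) - 1L) / fs
      # state components are channel-specific (independent noise, per-channel
      # oscillation phase): a purely common-mode component would be removed
      # by the common average reference downstream
      if (is_control) {
        for (ch in seq_len(n_ch)) {
          extra <- gap * config$gapnoise_amplitude *
            bandnoise(char_n, c(0.35, 0.48) * fs / 2, fs)
          sig[ch, idx] <- sig[ch, idx] + w[ch] * extra
        }
        if (gap * config$erp_amplitude > 0) {
          erp <- numeric(char_n)
          for (on in ev$onset_sample[ev$is_target]) {
            rel <- on - start  # 0-based offset within character
            span <- (rel + 1L):min(rel + round(0.55 * fs), char_n)
            erp[span] <- erp[span] +
              erp_template(tloc[span] - rel / fs, gap * config$erp_amplitude)
          }
          for (ch in seq_len(n_ch))
            sig[ch, idx] <- sig[ch, idx] +
              w[ch] * stats::runif(1, 0.8, 1.2) * erp
        }
      } else {
        env <- 1 + 0.25 * sin(2 * pi * 0.3 * tloc + stats::runif(1, 0, 2 * pi))
        for (ch in seq_len(n_ch)) {
          phase <- stats::runif(1, 0, 2 * pi)
          alpha <- gap * config$alpha_power * env *
            sin(2 * pi * 10 * tloc + phase)
          sig[ch, idx] <- sig[ch, idx] + w[ch] * alpha
        }
      }
      characters[[ci]] <- list(label = symbols[cell + 1L],
                               state = states[ci],
                               start_sample = start, events = ev)
    }

    labels <- if (n_ch == 16L) bci_channels else
      sprintf("CH%02d", seq_len(n_ch))
    rec <- list(
      signal = sig, fs = fs, channel_labels = labels,
      characters = characters,
      subject_id = sprintf("S%02d", subject),
      provenance = list(
        generator = "asyncbci::generate_session",
        package_version = as.character(utils::packageVersion("asyncbci")),
        seed = config$seed, subject = subject,
        config = unclass(config)))
    class(rec) <- "bci_recording"
    validate_recording(rec)
    rec
  })
}

#' Validate the structure of a recording
#'
#' Checks the structural invariants of a `bci_recording`: matching channel
#' and label counts, event onsets inside the recorded range and
#' non-decreasing within each character, and known state labels.  Called
#' by the functions that consume recordings; errors name the failing
#' field.
#'
#' @param recording Object to validate.
#' @return The recording, invisibly.
#' @export
validate_recording <- function(recording) {
  if (!inherits(recording, "bci_recording"))
    stop("not a bci_recording object", call. = FALSE)
  fail <- function(field, why)
    stop(sprintf("invalid recording: field `%s` %s", field, why),
         call. = FALSE)
  if (!is.matrix(recording$signal) || !is.numeric(recording$signal))
    fail("signal", "must be a numeric channels x samples matrix")
  if (length(recording$channel_labels) != nrow(recording$signal))
    fail("channel_labels", "length must equal the number of signal rows")
  if (!is.numeric(recording$fs) || recording$fs <= 0)
    fail("fs", "must be a positive sampling rate")
  ns <- ncol(recording$signal)
  for (ch in recording$characters) {
    if (!ch$state %in% c("control", "non-control"))
      fail("state", sprintf("has unknown value '%s'", ch$state))
    ev <- ch$events
    if (any(ev$onset_sample < ch$start_sample) || any(ev$onset_sample > ns))
      fail("events", "onset_sample outside the recorded character range")
    if (is.unsorted(ev$onset_sample))
      fail("events", "onset_sample must be non-decreasing")
    if (!all(ev$stimulus_id %in% 0:11))
      fail("events", "stimulus_id must be in 0..11")
  }
  invisible(recording)
}

#' @export
print.bci_recording <- function(x, ...) {
  st <- vapply(x$characters, `[[`, "", "state")
  cat(sprintf(
    "<bci_recording> subject %s: %d channels x %d samples at %g Hz\n",
    x$subject_id, nrow(x$signal), ncol(x$signal), x$fs))
  cat(sprintf("  %d characters (%d control / %d non-control)\n",
              length(x$characters), sum(st == "control"),
              sum(st == "non-control")))
  invisible(x)
}

#' Character metadata table of a set of recordings
#'
#' Convenience accessor building the per-character table consumed by
#' [split_dataset()] from one or more recordings.
#'
#' @param recordings A `bci_recording` or a list of them.
#' @return Data frame with columns `subject`, `character_index`, `state`.
#' @export
character_info <- function(recordings) {
  if (inherits(recordings, "bci_recording")) recordings <- list(recordings)
  do.call(rbind, lapply(recordings, function(r) {
    data.frame(subject = r$subject_id,
               character_index = seq_along(r$characters),
               state = vapply(r$characters, `[[`, "", "state"),
               stringsAsFactors = FALSE)
  }))
}
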