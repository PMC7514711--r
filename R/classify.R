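# Two-class linear discriminant with pooled covariance and equal priors.
# A small ridge (1e-6 x mean diagonal) is added only when the pooled
# covariance cannot be inverted; if the covariance is identically zero the
# discriminant degenerates to the nearest-mean direction.
lda_fit <- function(x, y) {
  x <- as.matrix(x)
  y <- as.logical(y)
  x1 <- x[y, , drop = FALSE]
  x0 <- x[!y, , drop = FALSE]
  if (nrow(x0) < 1L || nrow(x1) < 1L)
    stop("both classes must be present", call. = FALSE)
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  p <- ncol(x)
  cv <- function(z) if (nrow(z) > 1L) crossprod(sweep(z, 2L, colMeans(z))) else
    matrix(0, p, p)
  df <- nrow(x) - 2L
  S <- (cv(x0) + cv(x1)) / max(df, 1L)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w)) {
    tr <- mean(diag(S))
    if (tr > 0) {
      w <- tryCatch(solve(S + 1e-6 * tr * diag(p), mu1 - mu0),
                    error = function(e) NULL)
    }
    if (is.null(w)) w <- mu1 - mu0  # zero covariance: nearest mean
  }
  list(w = w, threshold = sum(w * (mu0 + mu1)) / 2)
}

lda_predict <- function(fit, x) {
  as.matrix(x) %*% fit$w > fit$threshold
}

#' Leave-one-out LDA accuracy
#'
#' Estimates control vs non-control classification accuracy by
#' leave-one-out cross-validation: each observation is classified by a
#' two-class linear discriminant (pooled covariance, equal priors) trained
#' on all remaining observations.  The procedure is deterministic.
#'
#' @param features Numeric matrix (observations x features) or a feature
#'   matrix as returned by [trial_features()] (its `state` labels are then
#'   used).
#' @param labels Class labels, one per row: logical, or anything with two
#'   levels (the second sorted level is the positive class).  Ignored when
#'   `features` carries its own labels.
#' @return Fraction of correctly classified observations.
#' @export
loo_accuracy <- function(features, labels = NULL) {
  if (inherits(features, "bci_features")) {
    labels <- features$state == "control"
    features <- features$x
  }
  x <- as.matrix(features)
  y <- as_binary_labels(labels, nrow(x))
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 observations per class", call. = FALSE)
  correct <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    fit <- lda_fit(x[-i, , drop = FALSE], y[-i])
    correct[i] <- lda_predict(fit, x[i, , drop = FALSE]) == y[i]
  }
  mean(correct)
}

as_binary_labels <- function(labels, n) {
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  if (length(labels) != n)
    stop("`labels` must match the number of rows", call. = FALSE)
  if (is.logical(labels)) return(labels)
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop("`labels` must have exactly two classes", call. = FALSE)
  f == levels(f)[2L]
}

#' Per-channel sample-entropy features for a set of trials
#'
#' Builds the characters x channels feature matrix of the pipeline: each
#' trial's channels are decimated to scale `tau` and summarized by their
#' sample entropy at the given `m` and `r`.  Rows whose decimated length
#' violates the reliability criterion, or that contain a degenerate
#' channel, are flagged (feature values `NA`) rather than silently kept.
#'
#' @param trials List of trials (elements with `segment` and `state`, as
#'   produced by [extract_trials()]), one per character, all at the same
#'   sequence count.
#' @param m,r Sample-entropy hyperparameters (see [sample_entropy()]).
#' @param tau Decimation scale (`>= 1`).
#' @param estimator,strict,sigma Passed to the entropy computation; see
#'   [sample_entropy()] and [mse_profile()].
#' @return An object of class `bci_features`: list with `x` (numeric
#'   matrix), `state` (character vector), `ok` (logical per row) and
#'   `reason` (per-row string, `""` when computed).
#' @export
trial_features <- function(trials, m, r, tau = 1L,
                           estimator = c("corrected", "canonical"),
                           strict = TRUE, sigma = c("per-scale", "original")) {
  estimator <- match.arg(estimator)
  sigma <- match.arg(sigma)
  n_ch <- nrow(trials[[1L]]$segment)
  if (!all(vapply(trials, function(t) nrow(t$segment), 0L) == n_ch))
    stop("all trials must share the channel count", call. = FALSE)
  n <- length(trials)
  x <- matrix(NA_real_, n, n_ch)
  ok <- rep(TRUE, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    seg <- trials[[i]]$segment
    n_dec <- ceiling(ncol(seg) / tau)
    if (!is_reliable(n_dec, m)) {
      ok[i] <- FALSE
      reason[i] <- "unreliable-length"
      next
    }
    for (ch in seq_len(n_ch)) {
      v <- tryCatch({
        xc <- seg[ch, ]
        sd1 <- if (sigma == "original") stats::sd(xc) else NULL
        sample_entropy(decimate_signal(xc, tau), m, r,
                       estimator = estimator, strict = strict, sd_x = sd1)
      }, error = function(e) e)
      if (inherits(v, "error")) {
        ok[i] <- FALSE
        reason[i] <- if (grepl("degenerate", conditionMessage(v)))
          "degenerate-channel" else "no-matches"
        break
      }
      x[i, ch] <- v
    }
  }
  structure(list(x = x, state = vapply(trials, `[[`, "", "state"),
                 ok = ok, reason = reason),
            class = "bci_features")
}

# Entropy "cube" shared by the grid search: sample entropy for every
# (character, channel, sequence, tau, m, r) in a single O(N^2) counting
# pass per decimated channel segment (all template lengths and tolerances
# at once).  `char_trials` is a list over characters, each with elements
# `trials` (list of cumulative trials) and `state`.
entropy_cube <- function(char_trials, ms, rs, taus,
                         estimator = "corrected", strict = TRUE,
                         sigma = "per-scale") {
  n_char <- length(char_trials)
  n_ch <- nrow(char_trials[[1L]]$trials[[1L]]$segment)
  n_seq <- length(char_trials[[1L]]$trials)
  rs <- sort(rs)
  lmax <- max(ms) + 1L
  cube <- array(NA_real_,
                dim = c(n_char, n_ch, n_seq, length(taus), length(ms),
                        length(rs)),
                dimnames = list(NULL, NULL, NULL, taus, ms, rs))
  for (ci in seq_len(n_char)) {
    trials <- char_trials[[ci]]$trials
    for (si in seq_len(n_seq)) {
      seg <- trials[[si]]$segment
      for (ti in seq_along(taus)) {
        tau <- taus[ti]
        n_dec <- ceiling(ncol(seg) / tau)
        m_ok <- is_reliable(n_dec, ms)
        if (!any(m_ok)) next
        for (ch in seq_len(n_ch)) {
          xd <- decimate_signal(seg[ch, ], tau)
          sdx <- if (sigma == "original") stats::sd(seg[ch, ]) else
            stats::sd(xd)
          if (!is.finite(sdx) || sdx <= 0) next
          cnt <- cpp_count_multi(xd, lmax, rs * sdx, strict)
          N <- length(xd)
          for (mi in seq_along(ms)) {
            if (!m_ok[mi]) next
            m <- ms[mi]
            A <- cnt[m + 1L, ]; B <- cnt[m, ]
            val <- ifelse(A > 0 & B > 0,
                          if (estimator == "corrected")
                            -log((N - m + 1) / (N - m - 1) * A / B)
                          else -log(A / B),
                          NA_real_)
            cube[ci, ch, si, ti, mi, ] <- val
          }
        }
      }
    }
  }
  cube
}

#' Hyperparameter grid optimization
#'
#' Searches the `(m, r, tau)` grid for the combination that best separates
#' control from non-control characters.  For every grid point, per-channel
#' sample-entropy features are computed at each cumulative sequence count,
#' classified with leave-one-out LDA, and the accuracies over the sequence
#' counts are averaged into one score; `(sequence, tau)` pairs whose
#' decimated length violates the reliability criterion are excluded from
#' the average.  The maximum-accuracy combination is selected, breaking
#' ties toward the smallest `tau`, then the smallest `m`, then the largest
#' `r` (cheapest computation, loosest tolerance).
#'
#' @param char_trials List over characters (pooled over subjects), each a
#'   list with `trials` (cumulative trials from [extract_trials()]) and
#'   `state`; see [collect_char_trials()].
#' @param ms,rs,taus Grid values for the embedding dimension, tolerance
#'   factor and scale.  Defaults span the standard physiological ranges:
#'   `m` in 1:2, `r` from 0.10 to 0.30 in steps of 0.05, `tau` in 1..25.
#' @param estimator,strict,sigma See [sample_entropy()] / [mse_profile()].
#' @return An object of class `grid_result`: list with `table` (data frame
#'   of `m`, `r`, `tau`, `accuracy`, `n_seq_used`) and `best` (named list
#'   `m`, `r`, `tau`, `accuracy`).
#' @export
grid_optimize <- function(char_trials, ms = 1:2,
                          rs = seq(0.10, 0.30, by = 0.05), taus = 1:25,
                          estimator = c("corrected", "canonical"),
                          strict = TRUE, sigma = c("per-scale", "original")) {
  estimator <- match.arg(estimator)
  sigma <- match.arg(sigma)
  if (length(ms) < 1L || length(rs) < 1L || length(taus) < 1L)
    stop("empty hyperparameter grid", call. = FALSE)
  states <- vapply(char_trials, `[[`, "", "state")
  y <- states == "control"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 characters per state", call. = FALSE)
  rs <- sort(rs)
  cube <- entropy_cube(char_trials, ms, rs, taus, estimator, strict, sigma)
  n_seq <- dim(cube)[3L]
  tab <- expand.grid(m = ms, r = rs, tau = taus,
                     KEEP.OUT.ATTRS = FALSE)
  tab$accuracy <- NA_real_
  tab$n_seq_used <- 0L
  for (k in seq_len(nrow(tab))) {
    mi <- match(tab$m[k], ms); ri <- match(tab$r[k], rs)
    ti <- match(tab$tau[k], taus)
    accs <- rep(NA_real_, n_seq)
    for (si in seq_len(n_seq)) {
      X <- cube[, , si, ti, mi, ri, drop = TRUE]
      X <- matrix(X, nrow = dim(cube)[1L])
      if (anyNA(X)) next  # unreliable or undefined at this (sequence, tau)
      accs[si] <- loo_accuracy(X, y)
    }
    used <- which(!is.na(accs))
    tab$n_seq_used[k] <- length(used)
    if (length(used) > 0L) tab$accuracy[k] <- mean(accs[used])
  }
  best <- select_best(tab)
  structure(list(table = tab, best = best), class = "grid_result")
}

# deterministic argmax with the tie-break contract:
# highest accuracy, then smallest tau, then smallest m, then largest r
select_best <- function(tab) {
  ok <- which(!is.na(tab$accuracy))
  if (length(ok) == 0L)
    stop("no grid point produced a reliable accuracy", call. = FALSE)
  o <- ok[order(-tab$accuracy[ok], tab$tau[ok], tab$m[ok], -tab$r[ok])][1L]
  list(m = tab$m[o], r = tab$r[o], tau = tab$tau[o],
       accuracy = tab$accuracy[o])
}

#' @export
print.grid_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(
    "<grid_result> %d combinations; best: m = %d, r = %.2f, tau = %d (accuracy %.3f)\n",
    nrow(x$table), b$m, b$r, b$tau, b$accuracy))
  invisible(x)
}

#' Per-subject validation curve at fixed hyperparameters
#'
#' Applies the fixed optimal `(m, r, tau)` to one subject's characters:
#' for every cumulative sequence count, trials are decimated to scale
#' `tau`, summarized by per-channel sample entropy and classified with
#' leave-one-out LDA, yielding the subject's accuracy as a function of the
#' number of sequences.
#'
#' @param char_trials One subject's characters, as for [grid_optimize()].
#' @param m,r,tau Fixed hyperparameters (e.g. `grid_result$best`).
#' @param estimator,strict,sigma See [sample_entropy()].
#' @return An object of class `validation_curve`: data frame with columns
#'   `ns` (sequence count), `accuracy` (`NA` where the reliability
#'   criterion fails) and `n_characters`.
#' @export
validate_subject <- function(char_trials, m, r, tau,
                             estimator = c("corrected", "canonical"),
                             strict = TRUE,
                             sigma = c("per-scale", "original")) {
  estimator <- match.arg(estimator)
  sigma <- match.arg(sigma)
  states <- vapply(char_trials, `[[`, "", "state")
  y <- states == "control"
  if (sum(y) < 2L || sum(!y) < 2L)
    stop("need at least 2 characters per state", call. = FALSE)
  n_seq <- length(char_trials[[1L]]$trials)
  acc <- rep(NA_real_, n_seq)
  for (si in seq_len(n_seq)) {
    trials <- lapply(char_trials, function(ct) ct$trials[[si]])
    fm <- trial_features(trials, m, r, tau, estimator = estimator,
                         strict = strict, sigma = sigma)
    if (all(fm$ok)) acc[si] <- loo_accuracy(fm)
  }
  structure(data.frame(ns = seq_len(n_seq), accuracy = acc,
                       n_characters = length(char_trials)),
            class = c("validation_curve", "data.frame"))
}

#' Collect per-character cumulative trials from recordings
#'
#' Extracts, for each selected character of each recording, the list of
#' cumulative trials plus its state and subject - the pooled structure
#' consumed by [grid_optimize()] and [validate_subject()].
#'
#' @param recordings A `bci_recording` or list of them (already
#'   preprocessed, see [preprocess_recording()]).
#' @param selection Optional data frame with columns `subject` and
#'   `character_index` restricting which characters are collected (e.g.
#'   one `set` of [split_dataset()]).
#' @return List over characters with elements `trials`, `state`,
#'   `subject`.
#' @export
collect_char_trials <- function(recordings, selection = NULL) {
  if (inherits(recordings, "bci_recording")) recordings <- list(recordings)
  out <- list()
  for (rec in recordings) {
    idx <- seq_along(rec$characters)
    if (!is.null(selection))
      idx <- selection$character_index[selection$subject == rec$subject_id]
    for (ci in idx) {
      trials <- extract_trials(rec, rec$characters[[ci]])
      out[[length(out) + 1L]] <- list(trials = trials,
                                      state = rec$characters[[ci]]$state,
                                      subject = rec$subject_id)
    }
  }
  out
}
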