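#' Count template matches for sample entropy
#'
#' Counts the unordered pairs of templates (subsequences) of `x` whose
#' Chebyshev distance lies within an absolute tolerance `R`, for template
#' lengths `m` (count `B`) and `m + 1` (count `A`).  These are the raw
#' counts from which sample entropy is formed: `A/B` estimates the
#' conditional probability that two sequences matching over `m` samples
#' still match over `m + 1`.
#'
#' Self-pairs (`i == j`) are excluded; every unordered pair is counted once.
#' Matching is strict (`distance < R`) by default; set `strict = FALSE` for
#' the non-strict (`<=`) convention used by some implementations.
#'
#' @param x Numeric vector, the one-dimensional signal.
#' @param m Embedding dimension (positive integer): template length in
#'   samples for `B`; `A` uses templates of length `m + 1`.
#' @param R Absolute tolerance (non-negative), on the scale of `x`.
#' @param strict Logical; `TRUE` counts `distance < R`, `FALSE` counts
#'   `distance <= R`.
#' @return A list with elements `A`, `B` (pair counts) and `N` (signal
#'   length).
#' @examples
#' count_template_matches(rep(0, 6), m = 1, R = 0.1)  # A = 10, B = 15
#' @seealso [sample_entropy()]
#' @export
count_template_matches <- function(x, m, R, strict = TRUE) {
  x <- as.numeric(x)
  m <- check_embedding(m)
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R < 0)
    stop("`R` must be a single non-negative number", call. = FALSE)
  if (anyNA(x)) stop("`x` contains missing values", call. = FALSE)
  if (length(x) < m + 2L)
    stop(sprintf("signal too short: need at least m + 2 = %d samples, got %d",
                 m + 2L, length(x)), call. = FALSE)
  cnt <- cpp_count_multi(x, m + 1L, R, strict)
  list(A = cnt[m + 1L, 1L], B = cnt[m, 1L], N = length(x))
}

#' Sample entropy of a one-dimensional signal
#'
#' Sample entropy (SampEn) quantifies the irregularity of a time series as
#' the negative log of the conditional probability that template pairs
#' matching over `m` samples (within tolerance `R = r * sd(x)`, Chebyshev
#' distance) still match over `m + 1` samples.  Higher values indicate a
#' less predictable signal.
#'
#' Two estimators are provided.  `"corrected"` (the default) applies the finite
#' sample normalization `-log((N - m + 1)/(N - m - 1) * A/B)`;
#' `"canonical"` is the plain conditional-probability estimate
#' `-log(A/B)`, the form against which published SampEn values are usually
#' reported.  The two differ by exactly `log((N - m + 1)/(N - m - 1))`.
#'
#' @inheritParams count_template_matches
#' @param r Tolerance factor (positive): the absolute tolerance is
#'   `r * sd(x)`, so the statistic is invariant to affine rescaling of `x`.
#' @param estimator `"corrected"` or `"canonical"`, see Details.
#' @param sd_x Optional: standard deviation used to form the absolute
#'   tolerance.  Defaults to `sd(x)`; pass an externally fixed value, e.g.
#'   the standard deviation of an undecimated signal, to decouple the
#'   tolerance from the analyzed segment.
#' @return Entropy value in nats (single numeric).
#' @section Errors:
#' A constant signal (`sd(x) == 0`, unless `sd_x` is supplied) makes the
#' tolerance degenerate and raises an error, as does the absence of any
#' template match (`A == 0` or `B == 0`), which leaves the statistic
#' undefined.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500), m = 1, r = 0.3, estimator = "canonical")
#' @export
sample_entropy <- function(x, m, r, estimator = c("corrected", "canonical"),
                           strict = TRUE, sd_x = NULL) {
  estimator <- match.arg(estimator)
  x <- as.numeric(x)
  m <- check_embedding(m)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a single positive number", call. = FALSE)
  sdx <- if (is.null(sd_x)) stats::sd(x) else sd_x
  if (!is.finite(sdx) || sdx <= 0)
    stop("degenerate tolerance: signal has zero standard deviation",
         call. = FALSE)
  cc <- count_template_matches(x, m, r * sdx, strict = strict)
  if (cc$B == 0 || cc$A == 0)
    stop("sample entropy undefined: no template matches found ",
         sprintf("(A = %g, B = %g)", cc$A, cc$B), call. = FALSE)
  N <- cc$N
  ratio <- cc$A / cc$B
  switch(estimator,
    canonical = -log(ratio),
    corrected = -log((N - m + 1) / (N - m - 1) * ratio)
  )
}

#' Reliability of a sample-entropy estimate
#'
#' The variance of the SampEn estimator grows as the signal shortens; the
#' usual rule of thumb deems the estimate reliable when the signal holds at
#' least `10^m` samples.
#'
#' @param n Signal length in samples (after any decimation).
#' @param m Embedding dimension.  Both arguments are vectorized.
#' @return Logical: `TRUE` iff `n >= 10^m`.
#' @examples
#' is_reliable(100, 2)  # TRUE
#' is_reliable(99, 2)   # FALSE
#' @export
is_reliable <- function(n, m) {
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 1) ||
      any(m != round(m)))
    stop("`m` must be integer(s) >= 1", call. = FALSE)
  if (!is.numeric(n) || any(n < 0)) stop("`n` must be non-negative")
  n >= 10^m
}

#' Least-squares linear-phase FIR filter design
#'
#' Designs an even-order (type I) linear-phase FIR filter whose amplitude
#' response minimizes the integrated squared error against a piecewise
#' constant desired response over the given frequency bands.  With adjacent
#' bands covering the whole axis the solution reduces to the truncated ideal
#' impulse response; transition ("don't care") gaps between bands are
#' supported.  The taps are normalized to unit DC gain when the desired
#' response at 0 is 1.
#'
#' @param order Filter order (even); the filter has `order + 1` taps.
#' @param bands Numeric vector of band edges in `[0, 1]` (1 = Nyquist),
#'   as consecutive pairs: `c(b1_lo, b1_hi, b2_lo, b2_hi, ...)`.
#' @param desired Desired amplitude (one constant per band).
#' @return Numeric vector of `order + 1` symmetric filter coefficients.
#' @keywords internal
fir_ls <- function(order, bands, desired) {
  if (order %% 2 != 0) stop("`order` must be even")
  nb <- length(bands) / 2L
  if (length(desired) != nb || nb < 1 || any(bands < 0) || any(bands > 1))
    stop("malformed band specification")
  M <- order / 2L
  # amplitude H(f) = a0 + sum_{k=1..M} a_k cos(pi k f), f in [0, 1]
  icc <- function(k, l, f1, f2) {
    # integral of cos(pi k f) cos(pi l f) over [f1, f2]
    if (k == 0 && l == 0) return(f2 - f1)
    s <- function(q, f) if (q == 0) f else sin(pi * q * f) / (pi * q)
    0.5 * ((s(k - l, f2) - s(k - l, f1)) + (s(k + l, f2) - s(k + l, f1)))
  }
  Q <- matrix(0, M + 1L, M + 1L)
  b <- numeric(M + 1L)
  for (bi in seq_len(nb)) {
    f1 <- bands[2L * bi - 1L]; f2 <- bands[2L * bi]
    d <- desired[bi]
    for (k in 0:M) {
      b[k + 1L] <- b[k + 1L] + d * icc(k, 0, f1, f2)
      for (l in k:M) {
        v <- icc(k, l, f1, f2)
        Q[k + 1L, l + 1L] <- Q[k + 1L, l + 1L] + v
        if (l > k) Q[l + 1L, k + 1L] <- Q[l + 1L, k + 1L] + v
      }
    }
  }
  a <- solve(Q, b)
  h <- c(rev(a[-1L]) / 2, a[1L], a[-1L] / 2)
  if (desired[1L] == 1 && bands[1L] == 0) h <- h / sum(h)
  h
}

#' Anti-aliased decimation (coarse-graining) of a signal
#'
#' Coarse-grains `x` for multiscale entropy by low-pass filtering with a
#' least-squares linear-phase FIR filter (cutoff at `1/tau` of Nyquist)
#' and keeping every `tau`-th sample, starting at the first.  Filtering is
#' delay-compensated (zero net phase) and the signal is reflected at both
#' ends to suppress edge transients.  `tau = 1` returns `x` unchanged.
#'
#' Unlike averaging over non-overlapping blocks, filtered decimation does
#' not alias high-frequency power into the retained band.
#'
#' @param x Numeric vector.
#' @param tau Integer scale factor `>= 1`.
#' @param order FIR filter order used for `tau > 1` (default 30).
#' @return Numeric vector of length `ceiling(length(x)/tau)`.
#' @examples
#' length(decimate_signal(sin(1:100), 4))  # 25
#' @export
decimate_signal <- function(x, tau, order = 30L) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau < 1 || tau != round(tau))
    stop("`tau` must be a single integer >= 1", call. = FALSE)
  tau <- as.integer(tau)
  x <- as.numeric(x)
  if (tau == 1L) return(x)
  n <- length(x)
  if (n <= order)
    stop(sprintf("signal too short to decimate: need > %d samples", order),
         call. = FALSE)
  h <- decimation_filter(tau, order)
  np <- order
  xp <- c(x[(np + 1L):2L], x, x[(n - 1L):(n - np)])
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  y <- as.numeric(y)[(np + 1L):(np + n)]
  y[seq.int(1L, n, by = tau)]
}

#' Multiscale entropy profile
#'
#' Computes sample entropy of `x` at scales `tau = 1..max_tau`, where each
#' scale is obtained by anti-aliased decimation ([decimate_signal()]).
#' Scales whose decimated length violates the reliability criterion
#' `N >= 10^m` ([is_reliable()]) are not computed and are flagged in the
#' output; scale 1 equals the sample entropy of the unmodified signal.
#'
#' @inheritParams sample_entropy
#' @param max_tau Largest scale to evaluate (integer `>= 1`).
#' @param sigma `"per-scale"` recomputes the tolerance standard deviation on
#'   each decimated signal (default); `"original"` fixes it at the scale-1
#'   value.
#' @return A data frame with one row per scale: `scale`, `n` (decimated
#'   length), `reliable`, `value` (entropy in nats, `NA` where not
#'   computed) and `reason` (`""`, `"unreliable-length"`, `"degenerate"`,
#'   `"short-signal"` or `"no-matches"`).
#' @examples
#' set.seed(1)
#' mse_profile(rnorm(600), m = 1, r = 0.2, max_tau = 5)
#' @export
mse_profile <- function(x, m, r, max_tau = 25L,
                        estimator = c("corrected", "canonical"),
                        strict = TRUE, sigma = c("per-scale", "original")) {
  estimator <- match.arg(estimator)
  sigma <- match.arg(sigma)
  if (!is.numeric(max_tau) || length(max_tau) != 1L || max_tau < 1)
    stop("`max_tau` must be a single integer >= 1", call. = FALSE)
  x <- as.numeric(x)
  m <- check_embedding(m)
  sd1 <- stats::sd(x)
  taus <- seq_len(max_tau)
  n_dec <- ceiling(length(x) / taus)
  value <- rep(NA_real_, max_tau)
  reason <- character(max_tau)
  reliable <- is_reliable(n_dec, m)
  for (tau in taus) {
    if (!reliable[tau]) {
      reason[tau] <- "unreliable-length"
      next
    }
    res <- tryCatch({
      xd <- decimate_signal(x, tau)
      sample_entropy(xd, m, r, estimator = estimator, strict = strict,
                     sd_x = if (sigma == "original") sd1 else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      reason[tau] <- if (grepl("degenerate", msg)) "degenerate"
        else if (grepl("too short", msg)) "short-signal"
        else "no-matches"
    } else {
      value[tau] <- res
    }
  }
  data.frame(scale = taus, n = as.integer(n_dec), reliable = reliable,
             value = value, reason = reason, stringsAsFactors = FALSE)
}

# decimation filters depend only on (tau, order): cache the designs
.fir_cache <- new.env(parent = emptyenv())
decimation_filter <- function(tau, order) {
  key <- paste0(order, ":", tau)
  h <- .fir_cache[[key]]
  if (is.null(h)) {
    h <- fir_ls(order, c(0, 1 / tau, 1 / tau, 1), c(1, 0))
    .fir_cache[[key]] <- h
  }
  h
}

# shared argument check: positive integer embedding dimension
check_embedding <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) ||
      m < 1 || m != round(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  as.integer(m)
}
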