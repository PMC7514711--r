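# Independent brute-force oracles used to pin down the optimized
# implementations.  They deliberately take a different computational route
# (dense outer/pmax distance matrices, explicit enumeration).

# all-pairs Chebyshev template-match counts, dense matrix route
oracle_counts <- function(x, m, R, strict = TRUE) {
  N <- length(x)
  count_len <- function(L) {
    n_t <- N - L + 1
    D <- matrix(0, n_t, n_t)
    for (k in 0:(L - 1)) {
      v <- x[(1 + k):(n_t + k)]
      D <- pmax(D, abs(outer(v, v, "-")))
    }
    up <- D[upper.tri(D)]
    # counts as doubles, matching the package convention (avoids integer
    # overflow for very long signals)
    as.numeric(if (strict) sum(up < R) else sum(up <= R))
  }
  list(A = count_len(m + 1), B = count_len(m), N = N)
}

# exact two-sided signed-rank p-value by full enumeration of sign patterns
# (no zeros or tied absolute values allowed; n must be small)
oracle_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)), length(d) <= 12)
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# small synthetic session, CAR-referenced but not band-passed (the
# state-dependent components of the generator live above the narrow
# study band; see the methods vignette)
make_test_session <- function(n_characters = 12, n_sequences = 3,
                              n_channels = 4, gap = 0.5, seed = 1,
                              ...) {
  cfg <- synth_config(n_subjects = 1, n_characters = n_characters,
                      n_sequences = n_sequences, n_channels = n_channels,
                      regularity_gap = gap, seed = seed, ...)
  rec <- generate_session(cfg)
  preprocess_recording(rec, low = NULL, high = NULL, car = TRUE)
}
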