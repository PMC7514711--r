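test_that("template counting matches closed-form counts on a constant signal", {
  cc <- count_template_matches(rep(0, 6), m = 1, R = 0.1)
  # 6 length-1 templates -> C(6,2) = 15 pairs; 5 length-2 -> C(5,2) = 10
  expect_equal(cc$B, 15)
  expect_equal(cc$A, 10)
  expect_equal(cc$N, 6)
})

test_that("template counting equals the brute-force oracle on random signals", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(20:300, 1)
    m <- sample(1:2, 1)
    x <- rnorm(n)
    R <- runif(1, 0.05, 0.5) * sd(x)
    strict <- i %% 2 == 0
    got <- count_template_matches(x, m, R, strict = strict)
    want <- oracle_counts(x, m, R, strict = strict)
    expect_identical(got$A, want$A)
    expect_identical(got$B, want$B)
  }
})

test_that("A never exceeds B and counts respect the strictness convention", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(100)
    cc <- count_template_matches(x, 2, 0.2 * sd(x))
    expect_lte(cc$A, cc$B)
  }
  # ties: repeated values at distance exactly R
  x <- c(0, 1, 0, 1, 0, 1)
  s <- count_template_matches(x, 1, R = 1, strict = TRUE)
  ns <- count_template_matches(x, 1, R = 1, strict = FALSE)
  expect_lt(s$B, ns$B)  # the |0-1| = R pairs count only when non-strict
})

test_that("alternating signal is nearly perfectly predictable", {
  x <- rep(c(1, -1), 100)
  cc <- count_template_matches(x, 1, 0.2)
  # same-parity positions match: C(100,2)*2 pairs of length-1 templates,
  # C(100,2)+C(99,2) of length 2
  expect_equal(cc$B, 2 * choose(100, 2))
  expect_equal(cc$A, choose(100, 2) + choose(99, 2))
  expect_lt(sample_entropy(x, 1, 0.2, estimator = "canonical"), 0.02)
})

test_that("canonical SampEn of iid Gaussian noise approaches the analytic limit", {
  set.seed(42)
  x <- rnorm(5000)
  limit <- -log(2 * pnorm(0.3 / sqrt(2)) - 1)
  for (m in 1:2)
    expect_lt(abs(sample_entropy(x, m, 0.3, estimator = "canonical") - limit),
              0.05)
})

test_that("sample entropy is invariant to affine transformations", {
  set.seed(8)
  x <- rnorm(400)
  for (est in c("corrected", "canonical")) {
    h <- sample_entropy(x, 2, 0.2, estimator = est)
    expect_equal(sample_entropy(5 * x - 3, 2, 0.2, estimator = est), h)
    expect_equal(sample_entropy(-0.1 * x + 7, 2, 0.2, estimator = est), h)
  }
})

test_that("paper and canonical estimators differ by the finite-size factor", {
  set.seed(9)
  for (m in 1:2) {
    x <- rnorm(300)
    d <- sample_entropy(x, m, 0.25, estimator = "canonical") -
      sample_entropy(x, m, 0.25, estimator = "corrected")
    expect_equal(d, log((300 - m + 1) / (300 - m - 1)), tolerance = 1e-12)
  }
})

test_that("degenerate inputs raise informative errors", {
  expect_error(sample_entropy(rep(1, 50), 1, 0.2), "degenerate")
  expect_error(count_template_matches(rnorm(3), 2, 0.1), "too short")
  # far-apart samples: no matches at all
  expect_error(sample_entropy(c(0, 100, -300, 1000, -2000, 5000), 1, 1e-6),
               "no template matches")
  expect_error(sample_entropy(rnorm(50), 0, 0.2), "`m`")
  expect_error(sample_entropy(rnorm(50), 1, -0.2), "`r`")
})

test_that("reliability criterion is N >= 10^m with exact boundaries", {
  expect_true(is_reliable(100, 2))
  expect_false(is_reliable(99, 2))
  expect_true(is_reliable(10, 1))
  expect_false(is_reliable(9, 1))
  # one-sequence trial of the standard protocol: 492 samples
  expect_false(is_reliable(ceiling(492 / 5), 2))  # 99 after decimation by 5
  expect_true(is_reliable(ceiling(492 / 4), 2))   # 123 after decimation by 4
})

test_that("decimation is the identity at scale 1 and preserves constants", {
  x <- rnorm(200)
  expect_identical(decimate_signal(x, 1), x)
  expect_equal(decimate_signal(rep(3, 200), 4), rep(3, 50), tolerance = 1e-9)
  expect_length(decimate_signal(rnorm(492), 5), 99)
  expect_length(decimate_signal(rnorm(492), 4), 123)
  expect_error(decimate_signal(x, 0), "tau")
  expect_error(decimate_signal(rnorm(20), 2), "too short")
})

test_that("decimation attenuates tones above the new Nyquist", {
  fs <- 256
  t <- (0:2047) / fs
  tone <- sin(2 * pi * 96 * t)  # above 64 Hz, the post-decimation Nyquist
  y <- decimate_signal(tone, 2)
  expect_lt(mean(y^2), 0.05 * mean(tone^2))
  keep <- sin(2 * pi * 20 * t)  # well inside the retained band
  yk <- decimate_signal(keep, 2)
  expect_equal(mean(yk^2), mean(keep^2), tolerance = 0.05)
})

test_that("mse profile reproduces scale-1 SampEn and masks unreliable scales", {
  set.seed(10)
  x <- rnorm(492)
  p <- mse_profile(x, m = 2, r = 0.2, max_tau = 25)
  expect_equal(p$value[1], sample_entropy(x, 2, 0.2))
  # reliability masking: values only where the criterion holds
  expect_identical(is.na(p$value), !p$reliable)
  expect_identical(p$reliable, ceiling(492 / p$scale) >= 100)
  expect_equal(sum(p$reliable), 4)
  expect_true(all(p$reason[!p$reliable] == "unreliable-length"))
})

test_that("mse profile of white noise shows no rising trend across scales", {
  set.seed(11)
  vals <- replicate(5, {
    p <- mse_profile(rnorm(4000), m = 1, r = 0.2, max_tau = 8,
                     estimator = "canonical")
    p$value
  })
  mv <- rowMeans(vals)
  # decimated white noise stays near-white at reduced bandwidth: the curve
  # must not increase beyond sampling noise
  expect_true(all(diff(mv) < 0.05))
  expect_lt(mv[8], mv[1] + 0.05)
})

test_that("tolerance convention can be fixed at the undecimated scale", {
  set.seed(12)
  x <- rnorm(1500)
  p1 <- mse_profile(x, 1, 0.2, max_tau = 4, sigma = "per-scale")
  p2 <- mse_profile(x, 1, 0.2, max_tau = 4, sigma = "original")
  expect_equal(p1$value[1], p2$value[1])  # same signal, same sd at scale 1
  # decimation removes power, so the per-scale tolerance shrinks and
  # entropies differ from scale 2 on
  expect_false(any(p1$value[-1] == p2$value[-1]))
})

test_that("least-squares FIR design has unit DC gain and symmetric taps", {
  for (tau in c(2, 5, 10)) {
    h <- asyncbci:::fir_ls(30, c(0, 1 / tau, 1 / tau, 1), c(1, 0))
    expect_length(h, 31)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_equal(h, rev(h), tolerance = 1e-12)
  }
})
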