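test_that("default configuration encodes the acquisition protocol", {
  cfg <- synth_config()
  expect_identical(cfg$n_characters, 120L)
  expect_identical(cfg$n_sequences, 15L)
  expect_identical(cfg$n_channels, 16L)
  expect_equal(cfg$fs, 256)
  expect_equal(cfg$flash_ms + cfg$isi_ms, 175)  # 175 ms SOA
  expect_identical(length(bci_channels), 16L)
  expect_error(synth_config(n_characters = 7), "even")
  expect_error(synth_config(regularity_gap = 1.5), "regularity_gap")
  expect_error(synth_config(n_channels = 4,
                            gap_channel_weights = rep(1, 3)),
               "length n_channels")
})

test_that("the ERP template is a unimodal deflection peaking at 300 ms", {
  t <- seq(-0.2, 0.8, by = 0.001)
  w <- erp_template(t, amplitude = 2)
  expect_equal(max(w), 2)
  expect_equal(t[which.max(w)], 0.3)
  expect_true(all(w[t < 0.2 | t > 0.5] == 0))
  expect_true(all(w >= 0))
  # linear in amplitude
  expect_equal(erp_template(t, 5), 2.5 * w)
  expect_error(erp_template(t, -1), "non-negative")
})

test_that("event logs satisfy the row-column protocol invariants", {
  cfg <- synth_config(n_subjects = 1, n_characters = 6, n_sequences = 4,
                      n_channels = 4, seed = 40)
  rec <- generate_session(cfg)
  st <- vapply(rec$characters, `[[`, "", "state")
  expect_identical(sum(st == "control"), 3L)
  expect_identical(sum(st == "non-control"), 3L)
  for (ch in rec$characters) {
    ev <- ch$events
    expect_identical(nrow(ev), 48L)
    expect_true(is.integer(ev$onset_sample))
    for (si in 1:4) {
      sev <- ev[ev$sequence_index == si, ]
      # each sequence flashes every row and column exactly once
      expect_setequal(sev$stimulus_id, 0:11)
      # in control, exactly the spelled row + column are targets
      expect_identical(sum(sev$is_target),
                       if (ch$state == "control") 2L else 0L)
    }
    # onsets follow the SOA grid relative to the character start
    k <- 0:47
    expect_identical(ev$onset_sample,
                     as.integer(ch$start_sample + floor(k * 0.175 * 256)))
  }
})

test_that("generation is deterministic and subject streams are independent", {
  cfg <- synth_config(n_subjects = 2, n_characters = 4, n_sequences = 2,
                      n_channels = 3, seed = 41)
  a <- generate_session(cfg, subject = 1)
  b <- generate_session(cfg, subject = 1)
  expect_identical(a, b)
  c2 <- generate_session(cfg, subject = 2)
  expect_false(identical(a$signal, c2$signal))
  expect_identical(c2$subject_id, "S02")
  expect_error(generate_session(cfg, subject = 3), "out of range")
  # generation must not disturb the global RNG stream
  set.seed(77)
  before <- .Random.seed
  invisible(generate_session(cfg))
  expect_identical(.Random.seed, before)
})

test_that("the entropy contrast between states is created by the gap", {
  contrast <- function(gap) {
    mean(vapply(1:8, function(s) {
      rec <- make_test_session(n_characters = 6, n_sequences = 2,
                               gap = gap, seed = 700 + s)
      trials <- lapply(collect_char_trials(rec), function(x) x$trials[[2]])
      st <- vapply(trials, `[[`, "", "state")
      fm <- trial_features(trials, m = 1, r = 0.3, tau = 2)
      mean(fm$x[st == "control", ]) - mean(fm$x[st == "non-control", ])
    }, numeric(1)))
  }
  # with gap = 0 every state-dependent amplitude is exactly zero: the
  # average contrast over seeds is pure sampling noise
  c0 <- contrast(0)
  c1 <- contrast(0.1)
  c2 <- contrast(0.2)
  expect_lt(abs(c0), 0.1)
  expect_gt(c1, c0 + 0.2)
  expect_gt(c2, c1 + 0.1)
  # the contrast saturates above ~0.3 (a very strong narrow-band component
  # is itself quasi-regular), but it must stay clearly positive
  expect_gt(contrast(0.5), 0.3)
  expect_gt(contrast(1), 0.3)
})

test_that("a full default-protocol session has the documented structure", {
  cfg <- synth_config(n_subjects = 1, seed = 43)
  rec <- generate_session(cfg)
  expect_s3_class(rec, "bci_recording")
  expect_identical(nrow(rec$signal), 16L)
  expect_identical(rec$channel_labels, bci_channels)
  expect_length(rec$characters, 120)
  st <- vapply(rec$characters, `[[`, "", "state")
  expect_identical(sum(st == "control"), 60L)
  expect_true(all(vapply(rec$characters,
                         function(ch) nrow(ch$events), 0L) == 180L))
  # first-trial window of every character is 492 samples
  tr <- extract_trials(rec, rec$characters[[50]])
  expect_length(tr, 15)
  expect_identical(tr[[1]]$n, 492L)
  expect_output(print(rec), "120 characters \\(60 control / 60 non-control\\)")
})

test_that("recording validation catches corrupted structures", {
  rec <- make_test_session(n_characters = 2, n_sequences = 1, seed = 44)
  bad <- rec
  bad$characters[[1]]$state <- "idle"
  expect_error(validate_recording(bad), "state")
  bad2 <- rec
  bad2$characters[[1]]$events$stimulus_id[1] <- 12L
  expect_error(validate_recording(bad2), "stimulus_id")
  bad3 <- rec
  bad3$characters[[2]]$events$onset_sample[2] <- 0L  # before character start
  expect_error(validate_recording(bad3), "onset_sample")
  bad4 <- rec
  bad4$channel_labels <- bad4$channel_labels[-1]
  expect_error(validate_recording(bad4), "channel_labels")
  expect_error(validate_recording(list()), "not a bci_recording")
})

test_that("character_info summarizes states across recordings", {
  cfg <- synth_config(n_subjects = 2, n_characters = 4, n_sequences = 1,
                      n_channels = 3, seed = 45)
  recs <- lapply(1:2, function(s) generate_session(cfg, s))
  info <- character_info(recs)
  expect_identical(nrow(info), 8L)
  expect_identical(unique(info$subject), c("S01", "S02"))
  expect_identical(info$character_index, rep(1:4, 2))
  expect_true(all(table(info$subject, info$state) == 2L))
})
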