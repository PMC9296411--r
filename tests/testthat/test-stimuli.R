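test_that("glide contours span the requested excursion, geometrically centred", {
  up <- make_glide_contour(500, 6, "up", 0.6)
  expect_equal(up$f0[1], 500 * 2^(-3 / 12), tolerance = 1e-6)
  expect_equal(up$f0[length(up$f0)], 500 * 2^(3 / 12), tolerance = 1e-6)
  expect_equal(max(up$times), 0.6)

  flat <- make_glide_contour(500, 0, "up", 0.6)
  expect_true(all(flat$f0 == 500))

  down <- make_glide_contour(500, 6, "down", 0.6)
  expect_equal(down$f0, rev(up$f0), tolerance = 1e-9)
})

test_that("triplets have one odd tone in a uniformly random slot", {
  set.seed(21)
  tr <- make_triplet("up", 6)
  expect_length(tr$contours, 3)
  durs <- vapply(tr$contours, function(c) max(c$times), numeric(1))
  expect_true(all(durs == durs[1]))
  rising <- vapply(tr$contours,
                   function(c) c$f0[length(c$f0)] > c$f0[1], logical(1))
  expect_equal(sum(!rising), 1)
  expect_equal(which(!rising), tr$odd_index)

  set.seed(22)
  idx <- replicate(3000, make_triplet("up", 6)$odd_index)
  expect_gt(stats::chisq.test(table(factor(idx, levels = 1:3)))$p.value,
            0.01)

  degenerate <- make_triplet("up", 0)
  expect_equal(degenerate$contours[[1]]$f0, degenerate$contours[[2]]$f0)
  expect_true(degenerate$odd_index %in% 1:3)
})

test_that("statement and question contours share the stem exactly", {
  st <- utterance_spec("statement", -50, stem_start_f0 = 220,
                       pair_id = "p1")
  qu <- utterance_spec("question", 50, stem_start_f0 = 220, pair_id = "p1")
  cs <- make_utterance_contour(st)
  cq <- make_utterance_contour(qu)
  stem_end <- cs$final_word_interval[1]
  stem_idx <- cs$times <= stem_end
  expect_identical(cs$f0[stem_idx], cq$f0[stem_idx])

  # final word ends at stem-final F0 + glide
  stem_f0_end <- 220 - 10 * stem_end
  expect_equal(cq$f0[length(cq$f0)], stem_f0_end + 50, tolerance = 1e-9)
  expect_equal(cs$f0[length(cs$f0)], stem_f0_end - 50, tolerance = 1e-9)

  flat <- utterance_spec("question", 1e-9, declination = 0)
  cf <- make_utterance_contour(flat)
  expect_lt(diff(range(cf$f0)), 1e-6)

  crash <- utterance_spec("statement", -300, stem_start_f0 = 200)
  expect_error(make_utterance_contour(crash), "0 Hz")
})

test_that("utterance-spec sign conventions are enforced", {
  expect_error(utterance_spec("statement", 50), "negative")
  expect_error(utterance_spec("question", -50), "positive")
  expect_error(utterance_spec("statement", -50, declination = 5),
               "declination")
})

test_that("speech proxy has harmonic spectrum and silent gaps", {
  ct <- f0_contour(c(0, 1), c(200, 200),
                   syllable_intervals = matrix(c(0.1, 0.9), ncol = 2))
  au <- render_speech_proxy(ct)
  spec <- spectrum_db(au)
  for (h in c(1, 2, 3, 5, 10, 15))
    expect_gt(level_at(spec, 200 * h), -60)
  # silence outside the syllable interval
  fs <- au$sample_rate
  expect_equal(max(abs(au$samples[1:round(0.08 * fs)])), 0)
  expect_lt(max(abs(au$samples)), 1 + 1e-9)
})

test_that("F0 round-trips through rendering and extraction within 2 Hz", {
  ct <- make_glide_contour(250, 4, "up", 0.8)
  au <- render_speech_proxy(ct)
  est <- extract_f0(au)
  voiced <- est$f0 > 0
  truth <- stats::approx(ct$times, ct$f0, xout = est$times[voiced],
                         rule = 2)$y
  inner <- est$times[voiced] > 0.05 & est$times[voiced] < 0.75
  expect_gt(sum(voiced), 50)
  expect_lt(max(abs(est$f0[voiced][inner] - truth[inner])), 2)
})

test_that("musical analogues contain the fundamental plus seven odd harmonics only", {
  ct <- f0_contour(c(0, 1), c(200, 200),
                   syllable_intervals = matrix(c(0, 1), ncol = 2))
  au <- render_musical_analogue(ct)
  spec <- spectrum_db(au)
  odd <- 200 * seq(1, 15, 2)
  for (f in odd) expect_gt(level_at(spec, f), -40)
  expect_equal(count_peaks_above(spec, fmin_hz = 300, floor_db = -35), 7)
  # even harmonics at least 40 dB below the fundamental
  fund <- level_at(spec, 200)
  for (f in 200 * c(2, 4, 6, 8)) expect_lt(level_at(spec, f), fund - 40)
})

test_that("nyquist violations are rejected", {
  hot <- f0_contour(c(0, 0.2), c(900, 900),
                    syllable_intervals = matrix(c(0, 0.2), ncol = 2))
  expect_error(render_speech_proxy(hot, sample_rate = 22050), "Nyquist")
})

test_that("peak normalization matches the reference and preserves shape", {
  ct <- f0_contour(c(0, 0.5), c(200, 200),
                   syllable_intervals = matrix(c(0, 0.5), ncol = 2))
  ref <- render_speech_proxy(ct, peak = 0.5)
  x <- render_musical_analogue(ct, peak = 0.9)
  y <- normalize_peak(x, ref)
  expect_equal(max(abs(y$samples)), 0.5, tolerance = 1e-6)
  expect_equal(normalize_peak(y, ref)$samples, y$samples,
               tolerance = 1e-6)
  sx <- spectrum_db(x); sy <- spectrum_db(y)
  expect_equal(sx$db, sy$db, tolerance = 1e-6)   # dB relative to own max
  silent <- audio_buffer(numeric(100), 22050)
  expect_error(normalize_peak(x, silent), "silent")
})

test_that("discrimination lists have balanced same/different trials", {
  set.seed(31)
  pairs <- make_utterance_pairs(18)
  tl <- build_discrimination_trials(pairs, "speech")
  expect_equal(nrow(tl$trials), 36)
  expect_equal(sum(tl$trials$truth == "same"), 18)
  expect_equal(sum(tl$trials$truth == "different"), 18)
  expect_equal(tl$isi_ms, 750)
  expect_equal(tl$iti_ms, 2000)
  # balanced same-trial composition: 9 statement-same, 9 question-same
  same <- tl$trials[tl$trials$truth == "same", ]
  expect_equal(sum(same$stim_a == "statement"), 9)
  # every pair contributes exactly two trials
  expect_true(all(table(tl$trials$pair_id) == 2))

  one <- build_discrimination_trials(pairs[1], "speech")
  expect_equal(nrow(one$trials), 2)
  expect_error(build_discrimination_trials(pairs[1:3], "speech",
                                           strict_balance = TRUE),
               "even")

  set.seed(77); a <- build_discrimination_trials(pairs, "music")
  set.seed(77); b <- build_discrimination_trials(pairs, "music")
  expect_identical(a$trials, b$trials)
})

test_that("identification lists are balanced and permutation-complete", {
  set.seed(32)
  pairs <- make_utterance_pairs(18)
  tl <- build_identification_trials(pairs)
  expect_equal(nrow(tl$trials), 36)
  expect_equal(sum(tl$trials$truth == "statement"), 18)
  expect_equal(sum(tl$trials$truth == "question"), 18)
  per_pair <- table(tl$trials$pair_id, tl$trials$truth)
  expect_true(all(per_pair == 1))
})

test_that("WAV files round-trip in PCM16 and float32", {
  ct <- make_glide_contour(300, 2, "up", 0.3)
  au <- render_speech_proxy(ct)
  p16 <- tempfile(fileext = ".wav")
  write_wav(au, p16)
  back <- read_wav(p16)
  expect_equal(back$sample_rate, au$sample_rate)
  expect_lt(max(abs(back$samples - au$samples)), 2^-15)

  pf <- tempfile(fileext = ".wav")
  write_wav(au, pf, format = "float32")
  backf <- read_wav(pf)
  expect_lt(max(abs(backf$samples - au$samples)), 1e-6)

  bad <- tempfile(fileext = ".wav")
  writeLines("definitely not audio", bad)
  expect_error(read_wav(bad), "RIFF")
})
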