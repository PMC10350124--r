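test_that("envelope extraction recovers a known AM modulator", {
  st <- synth_stimulus(f0 = 1000, n_harmonics = 1, am_rate = 10, am_depth = 1,
                       dur = 1, fs = FS)
  band <- split_bands(st$audio, band_edges(c(500, 2000)))[[1]]
  env <- extract_envelopes(list(band), env_cutoff = 50)
  expect_gte(lag_corr(env$values[1, ], st$envelope), 0.95)
})

test_that("a constant-amplitude tone yields a near-constant envelope", {
  st <- synth_stimulus(f0 = 1000, n_harmonics = 1, am_depth = 0, dur = 1)
  band <- split_bands(st$audio, band_edges(c(500, 2000)))[[1]]
  env <- extract_envelopes(list(band), env_cutoff = 50)
  v <- env$values[1, -(1:(0.1 * FS))]
  expect_lt(stats::sd(v) / mean(v), 0.05)
})

test_that("envelope extraction degenerate cases", {
  zero <- audio_signal(numeric(1000), FS)
  env <- extract_envelopes(list(zero), 100)
  expect_true(all(env$values == 0))
  expect_true(all(extract_envelopes(list(pure_tone(300, 0.1)), 100)$values >= 0))
  expect_error(extract_envelopes(list(pure_tone(300, 0.1)), 9000), "Nyquist")
  expect_error(extract_envelopes(list(), 100), "no channels")
})

test_that("dynamic-range limiting zeroes values below the global floor", {
  e <- envelope_matrix(matrix(c(1.0, 0.1, 0.001), 1), FS)
  out <- limit_dynamic_range(e, 40) # floor = 10^(-40/20) = 0.01
  expect_equal(out$values, matrix(c(1.0, 0.1, 0), 1))
  # "full" is the identity
  expect_equal(limit_dynamic_range(e, "full")$values, e$values)
  # the maximum is global across channels: a uniformly weak channel dies
  two <- envelope_matrix(rbind(c(1.0, 0.5), c(0.005, 0.005)), FS)
  out2 <- limit_dynamic_range(two, 40)
  expect_true(all(out2$values[2, ] == 0))
  expect_equal(out2$values[1, ], c(1.0, 0.5))
  expect_error(envelope_matrix(matrix(numeric(0), 0, 0), FS), "empty")
})

test_that("dynamic-range limiting is monotone in dr_db", {
  set.seed(7)
  v <- matrix(stats::runif(60)^3, 3)
  e <- envelope_matrix(v, FS)
  for (i in 1:10) {
    dr_small <- stats::runif(1, 5, 50)
    dr_large <- dr_small + stats::runif(1, 0, 60)
    kept_small <- limit_dynamic_range(e, dr_small)$values > 0
    kept_large <- limit_dynamic_range(e, dr_large)$values > 0
    expect_true(all(kept_large[kept_small]))
  }
})

test_that("quantization rounds to the nearest dB level and is idempotent", {
  # M = 1, dr = 40 dB, 2 steps -> levels {1, 0.01}; 0.5 (-6 dB) is nearer 0 dB
  e <- envelope_matrix(matrix(c(1, 0.5, 0.02), 1), FS)
  q <- quantize_envelopes(e, 2, 40)
  expect_equal(q$values, matrix(c(1, 1, 0.01), 1))
  # identity cases
  expect_equal(quantize_envelopes(e, "infinite")$values, e$values)
  ez <- envelope_matrix(matrix(c(1, 0, 0.3), 1), FS)
  expect_equal(quantize_envelopes(ez, 5, 40)$values[1, 2], 0)
  # idempotence and level-set membership
  set.seed(3)
  big <- envelope_matrix(matrix(stats::runif(200), 4), FS)
  q1 <- quantize_envelopes(big, 7, 60)
  q2 <- quantize_envelopes(q1, 7, 60)
  expect_equal(q1$values, q2$values)
  levels <- 10^(vocsim:::quant_levels_db(20 * log10(max(big$values)), 60, 7) / 20)
  expect_true(all(vapply(as.vector(q1$values), function(v) {
    v == 0 || min(abs(v - levels)) < 1e-12
  }, logical(1))))
  # single level collapses everything retained to the maximum
  q_one <- quantize_envelopes(e, 1, 40)
  expect_true(all(q_one$values %in% c(0, 1)))
  # an equal-dB grid over an unbounded range is undefined
  expect_error(quantize_envelopes(e, 4, "full"), "finite")
  expect_error(quantize_envelopes(e, 0, 40), ">= 1")
})

test_that("synthesis confines energy to the channel band and is deterministic", {
  e <- envelope_matrix(matrix(1, 1, FS), FS)
  eb <- band_edges(c(500, 2000))
  out <- synthesize(e, eb, seed = 3)
  expect_gte(band_energy_fraction(out, 400, 2500), 0.9)
  out2 <- synthesize(e, eb, seed = 3)
  expect_identical(out$samples, out2$samples)
  # all-zero envelopes give silence
  ez <- envelope_matrix(matrix(0, 1, 1000), FS)
  expect_true(all(synthesize(ez, eb, seed = 1)$samples == 0))
  expect_error(synthesize(e, equal_octave_edges(200, 7900, 4), seed = 1),
               "channels")
})

test_that("the full vocoder chain preserves duration and RMS", {
  st <- synth_stimulus(f0 = 1000, n_harmonics = 1, am_rate = 8, dur = 0.5)
  p <- vocoder_params(n_channels = 8, carrier_seed = 5)
  v <- vocode(st$audio, p)
  expect_equal(length(v), length(st$audio))
  expect_equal(rms(v), rms(st$audio), tolerance = 1e-6)
})

test_that("vocoded tone energy stays in the channel band containing it", {
  st <- synth_stimulus(f0 = 1000, n_harmonics = 1, am_rate = 8, dur = 1)
  for (nch in c(6, 8)) {
    v <- vocode(st$audio, vocoder_params(n_channels = nch))
    e <- equal_octave_edges(200, 7900, nch)$edges
    lo <- max(e[e <= 1000])
    hi <- min(e[e > 1000])
    expect_gte(band_energy_fraction(v, lo, hi), 0.8)
  }
})

test_that("identity degradations reproduce the classic noise vocoder", {
  st <- synth_stimulus(f0 = 500, n_harmonics = 4, am_rate = 6, dur = 0.4)
  p_id <- vocoder_params(n_channels = 6, dynamic_range_db = "full",
                         quant_steps = "infinite", carrier_seed = 9)
  # identical to the manually composed classic chain
  edges <- equal_octave_edges(200, 7900, 6)
  env <- extract_envelopes(split_bands(st$audio, edges), 100)
  manual <- synthesize(env, edges, seed = 9)
  manual$samples <- manual$samples * rms(st$audio) / rms(manual)
  expect_equal(vocode(st$audio, p_id)$samples, manual$samples,
               tolerance = 1e-12)
})

test_that("vocoder parameter validation enforces study ranges and fs floor", {
  expect_error(vocoder_params(n_channels = 5), "4, 6, 8")
  expect_silent(vocoder_params(n_channels = 5, paper_mode = FALSE))
  expect_error(vocoder_params(env_cutoff = -1), "env_cutoff")
  expect_error(vocoder_params(dynamic_range_db = 0), "dynamic_range_db")
  low_fs <- audio_signal(sin(2 * pi * 440 * (0:7999) / 8000), 8000)
  expect_error(vocode(low_fs, vocoder_params()), "16000")
})
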