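test_that("temporal average and centering behave as arithmetic means", {
  expect_equal(temporal_average(lsfg_series(c(1, 2, 3), c(0, 1, 2))), 2)
  expect_equal(temporal_average(lsfg_series(rep(5, 118), lsfg_times())), 5)
  # integer number of periods: the sinusoid averages out exactly
  s <- tone_series(m = 30, a = 3, f = 1.5)
  expect_equal(temporal_average(s), 30, tolerance = 1e-9)

  expect_equal(center_series(lsfg_series(c(1, 2, 3), c(0, 1, 2)))$y,
               c(-1, 0, 1))
  expect_equal(center_series(lsfg_series(rep(7, 10), 1:10))$y, rep(0, 10))
  set.seed(42)
  r <- lsfg_series(runif(50, 10, 40), sort(runif(50, 0, 4)))
  expect_lt(abs(mean(center_series(r)$y)), 1e-12)
})

test_that("series constructor validates its invariants", {
  expect_error(lsfg_series(1:3, 1:2), "same length")
  expect_error(lsfg_series(1:3, c(0, 2, 2)), "strictly increasing")
  expect_error(temporal_average(lsfg_series(numeric(0), numeric(0))),
               "empty")
  df <- data.frame(time = c(0, 1), value = c(3, 5))
  expect_equal(as_lsfg_series(df)$y, c(3, 5))
})

test_that("sparse spectrum fit recovers single tones against the
           per-frequency least-squares oracle", {
  t <- lsfg_times()
  # zero series: empty spectrum
  sp0 <- fit_spectrum(lsfg_series(rep(0, 118), t))
  expect_true(all(sp0$p == 0))

  # a 3-4-5 coefficient pair at an exact-period grid frequency
  y <- 3 * sin(2 * pi * 1.5 * t) + 4 * cos(2 * pi * 1.5 * t)
  sp <- fit_spectrum(lsfg_series(y - mean(y), t))
  i <- which.min(abs(sp$freqs - 1.5))
  expect_equal(sp$p[i], 5, tolerance = 1e-9)

  # on-grid tone: peak equals the oracle amplitude, off-peak is clean
  y <- 3 * sin(2 * pi * 1.0 * t)
  yc <- y - mean(y)
  sp <- fit_spectrum(lsfg_series(yc, t))
  i <- which.min(abs(sp$freqs - 1.0))
  expect_equal(sp$p[i], ls_amplitude_oracle(yc, t, 1.0), tolerance = 1e-6)
  expect_equal(sp$p[i], 3, tolerance = 1e-6)
  away <- abs(sp$freqs - 1.0) >= 0.5
  expect_true(all(sp$p[away] < 0.1 * 3))
})

test_that("dense ridge estimator is available and guards the singular case", {
  t <- lsfg_times()
  y <- 3 * sin(2 * pi * 1.0 * t)
  s <- lsfg_series(y - mean(y), t)
  # 2M = 200 unknowns vs 118 samples: the unpenalized problem is singular
  expect_error(fit_spectrum(s, estimator = "ridge", ridge = 0), "ridge > 0")
  sp <- fit_spectrum(s, estimator = "ridge")
  expect_length(sp$p, 100)
  expect_true(all(sp$p >= 0))
  expect_equal(sp$p, sqrt(sp$a^2 + sp$b^2))
})

test_that("beat strength takes the scaled in-band maximum with
           low-frequency tie-breaking", {
  grid <- spectrum_grid()
  mk <- function(p) structure(list(freqs = grid$freqs, a = p, b = 0 * p,
                                   p = p, atoms = NULL, estimator = "omp"),
                              class = "lsfg_spectrum")
  expect_equal(beat_strength(mk(rep(0, 100)))$bs, 0)
  p <- rep(0, 100)
  p[12] <- 0.5  # 1.2 Hz
  expect_equal(beat_strength(mk(p), C = 2)$bs, 1.0)
  # global max outside the band must be ignored
  p <- rep(0, 100)
  p[50] <- 9   # 5.0 Hz
  p[12] <- 4   # 1.2 Hz
  bsr <- beat_strength(mk(p), band = c(0.5, 3.0), C = 2)
  expect_equal(bsr$bs, 8)
  expect_equal(bsr$peak_freq_hz, 1.2)
  # equal maxima: the lower frequency wins
  p <- rep(0, 100)
  p[c(10, 20)] <- 2
  expect_equal(beat_strength(mk(p))$peak_freq_hz, 1.0)
  expect_error(beat_strength(mk(p), band = c(10.5, 11)), "no grid frequency")
})

test_that("bom composes the pipeline and matches the closed form", {
  t <- lsfg_times()
  expect_equal(bom(lsfg_series(rep(30, 118), t))$bom, 0)
  w <- bom(tone_series(m = 20, a = 2, f = 1.25), C = 2)
  expect_equal(w$bom, 0.2, tolerance = 0.01 * 0.2)
  expect_equal(w$bom, w$bs / w$mbr_avg)
  expect_error(bom(lsfg_series(rep(0, 118), t)), "positive")
})

test_that("bom is scale invariant and decreases under an added offset", {
  s <- tone_series(m = 25, a = 4, f = 1.2, phase = 0.7)
  b0 <- bom(s)$bom
  for (k in c(0.1, 3, 40)) {
    expect_equal(bom(lsfg_series(k * s$y, s$t))$bom, b0, tolerance = 1e-9)
  }
  b_shift <- bom(lsfg_series(s$y + 10, s$t))$bom
  expect_lt(b_shift, b0)
})

test_that("bos follows the per-beat blowout formula", {
  t <- lsfg_times()
  expect_equal(bos(lsfg_series(rep(5, 10), 1:10), list(c(1, 10))), 100)
  y <- c(10, 20, 30, 20, 10)
  expect_equal(bos(lsfg_series(y, 1:5), list(c(1, 5))), 100 * 20 / 40)
  # sinusoid mean 20 amplitude 2 -> 100 * 36 / 40
  s <- tone_series(m = 20, a = 2, f = 1.0)
  expect_equal(bos(s, beat_windows(s, 1.0)), 90, tolerance = 0.2)
  expect_error(bos(lsfg_series(1:10, 1:10), list(c(1, 2))), "fewer than 3")
  expect_error(bos(lsfg_series(c(1, -1, 2, 3), 1:4), list(c(1, 4))),
               "non-positive")
})

test_that("beat windows split integer periods of the known frequency", {
  s <- tone_series(f = 1.0)
  w <- beat_windows(s, 1.0)
  expect_length(w, 4)  # 4 seconds at 1 Hz
  expect_true(all(vapply(w, function(x) diff(x) + 1, numeric(1)) >= 29))
})

test_that("bos and bom are negatively related across a resistivity sweep", {
  ratios <- seq(0.05, 1.0, length.out = 12)
  res <- vapply(ratios, function(pr) {
    s <- tone_series(m = 30, a = 30 * pr / 2, f = 1.5)
    c(bom = bom(s)$bom, bos = bos(s, beat_windows(s, 1.5)))
  }, numeric(2))
  expect_lt(cor(res["bom", ], res["bos", ], method = "spearman"), 0)
})
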