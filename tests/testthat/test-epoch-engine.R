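test_that("high-pass filter removes DC and preserves supra-cutoff content", {
  rate <- 32
  n <- 30 * rate
  t <- (seq_len(n) - 1) / rate
  interior <- (5 * rate):(n - 5 * rate)  # skip edge transients

  # constant offset -> ~0 everywhere
  const <- raw_signal(rep(987, n), rep(-500, n), rep(1000, n))
  f <- highpass_filter(const)
  expect_lt(max(abs(f$axes[interior, ])), 1e-6 * 1000)

  # 5 Hz unit sinusoid: amplitude preserved within 5%
  s5 <- raw_signal(sin(2 * pi * 5 * t), rep(0, n), rep(0, n))
  f5 <- highpass_filter(s5)
  amp5 <- max(abs(f5$axes[interior, 1]))
  expect_gt(amp5, 0.95)
  expect_lt(amp5, 1.05)

  # 0.1 Hz unit sinusoid: attenuated by > 90%
  s01 <- raw_signal(sin(2 * pi * 0.1 * t), rep(0, n), rep(0, n))
  f01 <- highpass_filter(s01)
  expect_lt(max(abs(f01$axes[interior, 1])), 0.1)
})

test_that("filter rejects cutoffs outside the Nyquist range", {
  s <- raw_signal(rnorm(64), rnorm(64), rnorm(64))
  expect_error(highpass_filter(s, cutoff = 16), "Nyquist|rate")
  expect_error(highpass_filter(s, cutoff = 0), "rate")
})

test_that("all-zero signal stays exactly zero through the filter", {
  s <- raw_signal(rep(0, 640), rep(0, 640), rep(0, 640))
  f <- highpass_filter(s)
  expect_identical(f$axes, s$axes)
})

test_that("epochize computes per-axis mean-absolute norms and drops partials", {
  rate <- 32
  # all-zero signal -> (0, 0) and raw_zero
  z <- raw_signal(rep(0, 640), rep(0, 640), rep(0, 640))
  ep <- epochize(z, z, epoch_s = 10)
  expect_equal(nrow(ep), 2L)
  expect_true(all(ep$ac_fil == 0 & ep$ac_unfil == 0 & ep$raw_zero))

  # 320 samples at 32 Hz with 10-s epochs -> exactly 1 epoch
  s1 <- raw_signal(rnorm(320), rnorm(320), rnorm(320))
  expect_equal(nrow(epochize(s1, s1)), 1L)
  # 321 samples: still 1 (partial dropped); 639: 1; 640: 2
  mk <- function(n) raw_signal(rnorm(n), rnorm(n), rnorm(n))
  expect_equal(nrow(epochize(mk(639), mk(639))), 1L)
  expect_equal(nrow(epochize(mk(640), mk(640))), 2L)

  # synthesized magnitude = Euclidean norm of per-axis mean |values|:
  # filtered path holding (3, 4, 0) constant in absolute value -> 5
  n <- 320
  alt <- rep(c(1, -1), n / 2)  # zero-mean so the unfiltered DC removal
  filt <- raw_signal(3 * alt, 4 * alt, rep(0, n))
  raw <- raw_signal(12 * alt, rep(0, n), rep(0, n))
  ep2 <- epochize(raw, filt)
  expect_equal(ep2$ac_fil, 5)
  # unfiltered: single axis at +/-12 around a zero epoch mean -> 12
  expect_equal(ep2$ac_unfil, 12)

  # gravity handling: a large constant offset does not leak into ac_unfil
  raw_g <- raw_signal(12 * alt + 1000, rep(0, n), rep(500, n))
  expect_equal(epochize(raw_g, filt)$ac_unfil, 12)

  expect_error(epochize(raw, raw_signal(rnorm(64), rnorm(64), rnorm(64))),
               "misaligned")
})

test_that("epoch magnitudes are scale-equivariant and ordered by frequency", {
  rate <- 32
  n <- 60 * rate
  t <- (seq_len(n) - 1) / rate
  set.seed(42)
  mk <- function(k) {
    s <- raw_signal(k * (sin(2 * pi * 2 * t) * 100 + rnorm(n, 0, 5)),
                    k * rnorm(n, 0, 5), k * rnorm(n, 0, 5))
    epochize(s, highpass_filter(s))
  }
  set.seed(42); a <- mk(1)
  set.seed(42); b <- mk(3)
  expect_equal(b$ac_fil, 3 * a$ac_fil, tolerance = 1e-12)
  expect_equal(b$ac_unfil, 3 * a$ac_unfil, tolerance = 1e-12)

  # sub-cutoff content is suppressed relative to supra-cutoff content
  lo <- raw_signal(100 * sin(2 * pi * 0.2 * t), rep(0, n), rep(0, n))
  hi <- raw_signal(100 * sin(2 * pi * 2 * t), rep(0, n), rep(0, n))
  ep_lo <- epochize(lo, highpass_filter(lo))
  ep_hi <- epochize(hi, highpass_filter(hi))
  expect_true(all(ep_lo$ac_fil < ep_hi$ac_fil))
})

test_that("epoch count equals floor(samples / (epoch_s * rate))", {
  for (n in c(0, 100, 320, 500, 3200, 3519)) {
    s <- raw_signal(rnorm(n), rnorm(n), rnorm(n))
    expect_equal(nrow(epochize(s, s)), n %/% 320)
  }
})
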