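test_that("both coefficient sets are stable and consistent with each other", {
  full <- count_filter("full")
  rnd <- count_filter("rounded")
  expect_identical(full$a[1], 1)
  expect_identical(rnd$a[1], 1)
  expect_true(is_stable(full))
  expect_true(is_stable(rnd))
  # the rounded set is exactly the full set rounded to 3 significant digits
  expect_identical(signif(full$b, 3), rnd$b)
  expect_identical(signif(full$a, 3), rnd$a)
  expect_identical(rnd$b[4], 0.0442)
  # injected custom coefficients are accepted; unstable ones are not
  expect_s3_class(count_filter(b = rnd$b, a = rnd$a), "count_filter")
  expect_error(count_filter(b = c(1, 0), a = c(1, -1.5)), "unstable")
  expect_error(count_filter(b = c(1, 0), a = c(2, 0)), "a\\[1\\]")
})

test_that("steady-state initialization is homogeneous and yields constant output", {
  f <- count_filter()
  expect_identical(steady_state_init(f, 0), rep(0, 7))
  expect_equal(steady_state_init(f, 2.5), 2.5 * steady_state_init(f, 1),
               tolerance = 1e-15)
  # constant input c from the initialized state stays at c * H(1) from sample 0
  h1 <- sum(f$b) / sum(f$a)
  for (c0 in c(1, -0.6, 9)) {
    y <- apply_bandpass(data.frame(x = rep(c0, 200)), f)$x
    expect_equal(y, rep(c0 * h1, 200), tolerance = 1e-9)
  }
})

test_that("filtering a zero or empty series returns zeros or empties", {
  f <- count_filter()
  expect_identical(apply_bandpass(data.frame(x = rep(0, 30)), f)$x, rep(0, 30))
  empty <- apply_bandpass(data.frame(x = double(0)), f)
  expect_identical(nrow(empty), 0L)
  # length-1 input: the steady-state output for that constant (H(1) is ~1e-11,
  # so the comparison is on the absolute scale)
  y1 <- apply_bandpass(data.frame(x = 3), f)$x
  expect_lt(abs(y1 - 3 * sum(f$b) / sum(f$a)), 1e-12)
})

test_that("recursive filtering matches independent oracles", {
  f <- count_filter()
  set.seed(41)
  # naive difference-equation loop with the same steady-state pre-history
  for (n in c(5, 100, 500)) {
    x <- rnorm(n) + 0.3
    got <- apply_bandpass(data.frame(x = x), f)$x
    expect_equal(got, naive_bandpass(f, x), tolerance = 1e-9)
  }
  # signal::filter with zero initial conditions, on a signal starting at 0
  # (steady-state init for a first sample of 0 is the zero state)
  x <- c(0, rnorm(300))
  got <- apply_bandpass(data.frame(x = x), f)$x
  ref <- as.numeric(signal::filter(f$b, f$a, x))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("filtering is invariant to prepending the constant first sample", {
  # with steady-state initialization, a longer constant lead-in changes
  # nothing: the state already encodes an infinite constant history
  f <- count_filter()
  set.seed(42)
  s <- rnorm(100)
  x1 <- c(0.8, s)
  x2 <- c(rep(0.8, 50), s)
  y1 <- apply_bandpass(data.frame(x = x1), f)$x
  y2 <- apply_bandpass(data.frame(x = x2), f)$x
  expect_equal(tail(y1, 100), tail(y2, 100), tolerance = 1e-9)
})

test_that("steady-state sinusoid amplitude matches the transfer function", {
  f <- count_filter()
  for (freq in c(0.5, 1, 3)) {
    sig <- generate_sinusoid(freq = freq, amplitude = 1, sample_rate = 30,
                             duration = 120)
    y <- apply_bandpass(sig, f)$x
    # amplitude from the RMS of the last 30 s (a whole number of cycles),
    # immune to the peak falling between samples
    amp <- sqrt(2 * mean(tail(y, 30 * 30)^2))
    expect_equal(amp, gain_at(f, freq), tolerance = 1e-3)
  }
})

test_that("the magnitude response approaches |H(1)| at DC and refines consistently", {
  f <- count_filter()
  fr <- frequency_response(f, fs = 30, n_grid = 30000)
  expect_equal(fr$gain[1], abs(sum(f$b) / sum(f$a)), tolerance = 1e-4)
  # grid refinement: shared frequencies give identical values
  coarse <- frequency_response(f, fs = 30, n_grid = 3000)
  fine <- frequency_response(f, fs = 30, n_grid = 15000)
  expect_equal(coarse$gain, fine$gain[seq(5, 15000, by = 5)], tolerance = 1e-12)
  # and each grid value equals the direct transfer-function evaluation
  idx <- c(100, 759, 2000)
  expect_equal(fine$gain[idx], sapply(fine$freq[idx], gain_at, filter = f),
               tolerance = 1e-12)
})

test_that("response landmarks recover the band edges of the counts band-pass", {
  lm <- response_landmarks(frequency_response(count_filter(), 30, 15000))
  expect_equal(lm$peak_freq, 0.759, tolerance = 0.001)
  expect_equal(lm$lower_halfgain, 0.212, tolerance = 0.001)
  expect_equal(lm$upper_halfgain, 2.116, tolerance = 0.001)
})

test_that("landmarks of a symmetric ideal curve are symmetric about its peak", {
  freq <- seq(0.01, 10, by = 0.01)
  gain <- exp(-(freq - 5)^2)   # Gaussian bump centered at 5 Hz
  curve <- tibble::tibble(freq = freq, gain = gain,
                          gain_db = 20 * log10(gain))
  lm <- response_landmarks(curve)
  expect_equal(lm$peak_freq, 5, tolerance = 0.01)
  expect_equal(lm$peak_freq - lm$lower_halfgain,
               lm$upper_halfgain - lm$peak_freq, tolerance = 1e-6)
  # a monotone curve has no bracketing crossings
  mono <- tibble::tibble(freq = freq, gain = freq, gain_db = 20 * log10(freq))
  expect_error(response_landmarks(mono), "band-pass")
})

test_that("filter accessors tidy and glance report coefficients and landmarks", {
  f <- count_filter()
  td <- tidy(f)
  expect_identical(td$term[1], "b0")
  expect_identical(nrow(td), 16L)
  gl <- glance(f)
  expect_true(gl$stable)
  expect_equal(gl$peak_freq, 0.759, tolerance = 0.001)
})
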