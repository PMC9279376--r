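#' Generate Gaussian white noise raw acceleration
#'
#' Simulated white noise is the validation workhorse for the counts chain:
#' it is broad-band, so every stage of the band-pass, thresholding and
#' decimation logic is exercised at once. With the default `sd` of 1 g the
#' rescaled filtered signal straddles both the deadband and the ceiling of
#' the quantizer.
#'
#' @param duration Length of the recording in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param n_axes 1 or 3 axis columns.
#' @param sd Noise standard deviation in g.
#' @param seed Optional integer; when given, the signal is reproducible and
#'   the caller's RNG state is untouched.
#' @return Tibble of axis columns (`x` or `x`, `y`, `z`) with
#'   `duration * sample_rate` rows.
#' @export
#' @examples
#' generate_white_noise(duration = 1, sample_rate = 30, seed = 1)
generate_white_noise <- function(duration = 60, sample_rate = 30, n_axes = 1,
                                 sd = 1, seed = NULL) {
  stopifnot(duration > 0, n_axes %in% c(1, 3), sd >= 0)
  n <- as.integer(round(duration * sample_rate))
  draw <- function() {
    cols <- purrr::map(seq_len(n_axes), ~ stats::rnorm(n, mean = 0, sd = sd))
    names(cols) <- c("x", "y", "z")[seq_len(n_axes)]
    tibble::as_tibble(cols)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw)
}

# run code under a given seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a sinusoidal raw acceleration signal
#'
#' A single-frequency probe for the spectral behaviour of the counts chain:
#' counts depend not only on amplitude but on spectral content, so a
#' sinusoid at the band-pass peak (0.759 Hz) yields far more counts than an
#' equal-amplitude sinusoid outside the band.
#'
#' @param freq Sinusoid frequency in Hz; must be below `sample_rate / 2`.
#' @param amplitude Amplitude in g.
#' @param sample_rate Sampling rate in Hz.
#' @param duration Length in seconds.
#' @param n_axes 1 or 3 (all axes identical).
#' @return Tibble of axis columns.
#' @export
#' @examples
#' generate_sinusoid(freq = 0.759, amplitude = 1, sample_rate = 30,
#'                   duration = 10)
generate_sinusoid <- function(freq, amplitude, sample_rate, duration,
                              n_axes = 1) {
  stopifnot(n_axes %in% c(1, 3))
  if (!is.numeric(freq) || freq < 0 || freq >= sample_rate / 2) {
    stop("`freq` must satisfy 0 <= freq < sample_rate/2 (Nyquist); got ",
         format(freq), " at ", format(sample_rate), " Hz.", call. = FALSE)
  }
  n <- as.integer(round(duration * sample_rate))
  t <- (seq_len(n) - 1) / sample_rate
  x <- amplitude * sin(2 * pi * freq * t)
  cols <- purrr::map(seq_len(n_axes), ~x)
  names(cols) <- c("x", "y", "z")[seq_len(n_axes)]
  tibble::as_tibble(cols)
}

# ---------------------------------------------------------------------------
# Independent scalar-loop reference implementation. Deliberately written as
# naive per-sample loops with no code shared with the vectorized pipeline,
# so that agreement between the two is meaningful differential evidence.
# The band-pass runs as a direct-form I difference equation whose pre-history
# is the constant steady-state extension (x[j<0] = x0, y[j<0] = x0*H(1)) --
# an independent route to the same steady-state initialization.
# ---------------------------------------------------------------------------

oracle_axis <- function(x, sample_rate, device, epoch, b, a) {
  # --- stage 0/1/2: bring to 30 Hz ---
  if (device == "cpiw") {
    n <- length(x)
    if (n < 2) {
      x30 <- x
    } else {
      t_last <- (n - 1) / sample_rate
      n_out <- length(seq(0, t_last, by = 1 / 30))
      x30 <- double(n_out)
      for (j in seq_len(n_out)) {
        t_idx <- (j - 1) / 30 * sample_rate    # zero-based fractional index
        lo <- floor(t_idx)
        if (lo >= n - 1L) {
          x30[j] <- x[n]
        } else {
          frac <- t_idx - lo
          x30[j] <- (1 - frac) * x[lo + 1L] + frac * x[lo + 2L]
        }
      }
    }
  } else if (sample_rate == 30) {
    x30 <- x
  } else if (sample_rate %% 30 == 0) {
    m <- sample_rate / 30
    x30 <- double(0)
    j <- 1L
    for (i in seq_along(x)) {
      if ((i - 1) %% m == 0) {
        x30[j] <- x[i]
        j <- j + 1L
      }
    }
  } else {
    n <- length(x)
    v <- double(3L * n)
    for (i in seq_len(n)) v[3L * (i - 1L) + 1L] <- x[i]
    b0 <- 3 * pi / (pi + 3 * 2)
    c1 <- (2 * 3 - pi) / (pi + 2 * 3)
    w <- double(3L * n)
    vprev <- 0
    wprev <- 0
    for (i in seq_along(v)) {
      w[i] <- b0 * v[i] + b0 * vprev + c1 * wprev
      vprev <- v[i]
      wprev <- w[i]
    }
    m <- (3 * sample_rate) / 30
    x30 <- double(0)
    j <- 1L
    for (i in seq_along(w)) {
      if ((i - 1) %% m == 0) {
        x30[j] <- w[i]
        j <- j + 1L
      }
    }
  }
  # --- stage 3: band-pass, direct-form I with steady-state pre-history ---
  n <- length(x30)
  y <- double(n)
  if (n > 0) {
    h1 <- sum(b) / sum(a)
    x0 <- x30[1]
    ord <- length(a) - 1L
    for (i in seq_len(n)) {
      acc <- 0
      for (k in 0:ord) {
        xk <- if (i - k >= 1) x30[i - k] else x0
        acc <- acc + b[k + 1L] * xk
      }
      for (k in 1:ord) {
        yk <- if (i - k >= 1) y[i - k] else x0 * h1
        acc <- acc - a[k + 1L] * yk
      }
      y[i] <- acc
    }
  }
  # --- stages 4-6: rescale, rectify, threshold ---
  sf <- (3.0 / 4096.0) / (2.6 / 256.0) * 237.5
  q <- integer(n)
  for (i in seq_len(n)) {
    v <- abs(y[i] * sf)
    q[i] <- if (v > 128) 128L else if (v >= 4) as.integer(floor(v)) else 0L
  }
  # --- stage 7: 10 Hz by non-overlapping 3-sample average ---
  n10 <- n %/% 3L
  d <- integer(n10)
  for (j in seq_len(n10)) {
    i <- 3L * (j - 1L) + 1L
    d[j] <- (q[i] + q[i + 1L] + q[i + 2L]) %/% 3L
  }
  # --- stage 8: epoch sums ---
  block <- 10L * epoch
  n_ep <- n10 %/% block
  cts <- integer(n_ep)
  for (e in seq_len(n_ep)) {
    s <- 0L
    for (j in ((e - 1L) * block + 1L):(e * block)) s <- s + d[j]
    cts[e] <- s
  }
  cts
}

#' Reference scalar-loop implementation of the counts chain
#'
#' An independent, unoptimized per-sample implementation of all eight
#' processing steps, sharing no stage code with [activity_counts()]. Its
#' purpose is differential testing: on any input, its integer counts must
#' match the vectorized pipeline exactly. See [cross_validate()].
#'
#' @inheritParams activity_counts
#' @return Tibble with columns `epoch` and one integer counts column per
#'   axis (same layout as [activity_counts()] minus the `time` column).
#' @export
oracle_counts <- function(data, sample_rate, epoch = 10,
                          device = c("standard", "cpiw"),
                          filter = count_filter()) {
  device <- match.arg(device)
  epoch <- check_epoch_len(epoch)
  sample_rate <- validate_rate(sample_rate, device)
  data <- check_signal_frame(data)
  cts <- purrr::map(data, oracle_axis, sample_rate = sample_rate,
                    device = device, epoch = epoch,
                    b = filter$b, a = filter$a)
  tibble::tibble(epoch = seq_along(cts[[1L]]), !!!cts)
}

#' Define the simulation cases of the validation design
#'
#' @param sample_rate,epoch Vectors recycled against each other (use
#'   [default_cases()] for the standard four-case grid).
#' @param n_sims Simulations per case.
#' @param duration Trial length in seconds.
#' @param sd Noise standard deviation in g.
#' @param n_axes Axes per simulated signal.
#' @param device Device path.
#' @return Tibble with one row per case.
#' @export
simulation_cases <- function(sample_rate, epoch, n_sims = 100, duration = 60,
                             sd = 1, n_axes = 1, device = "standard") {
  tibble::tibble(sample_rate = sample_rate, epoch = epoch, n_sims = n_sims,
                 duration = duration, sd = sd, n_axes = n_axes,
                 device = device)
}

#' The four-case white-noise validation grid
#'
#' Gaussian white noise at 30 or 40 Hz summarized into 10 or 30 s epochs:
#' the two sampling rates exercise both the identity and the
#' up-sample-then-decimate resampling paths, and the two epoch lengths
#' exercise the epoch bookkeeping.
#'
#' @inheritParams simulation_cases
#' @return Tibble with four rows.
#' @export
default_cases <- function(n_sims = 100, duration = 60, sd = 1) {
  grid <- expand.grid(sample_rate = c(30, 40), epoch = c(10, 30))
  simulation_cases(grid$sample_rate, grid$epoch, n_sims = n_sims,
                   duration = duration, sd = sd)
}

#' Differential validation of the counts pipeline
#'
#' For every simulation of every case, generates seeded Gaussian white
#' noise, computes counts with both [activity_counts()] and the independent
#' scalar-loop [oracle_counts()], and tallies epoch values that differ. A
#' nonzero mismatch count is a reported result, not an error.
#'
#' @param cases Tibble of cases as from [simulation_cases()] or
#'   [default_cases()].
#' @param seed Integer master seed; per-simulation seeds are derived from it
#'   so the whole report is reproducible.
#' @param filter Band-pass to use in both implementations.
#' @return Tibble of class `counts_validation`: one row per case with
#'   `n_sims`, `n_epochs_compared` and `n_mismatched`.
#' @export
#' @examples
#' cross_validate(default_cases(n_sims = 2, duration = 30), seed = 1)
cross_validate <- function(cases = default_cases(), seed = 1,
                           filter = count_filter()) {
  res <- purrr::map(seq_len(nrow(cases)), function(ci) {
    cs <- cases[ci, ]
    n_ep <- 0L
    n_mis <- 0L
    for (s in seq_len(cs$n_sims)) {
      sim_seed <- (seed * 10000L + ci * 1000L + s) %% .Machine$integer.max
      raw <- generate_white_noise(duration = cs$duration,
                                  sample_rate = cs$sample_rate,
                                  n_axes = cs$n_axes, sd = cs$sd,
                                  seed = sim_seed)
      got <- activity_counts(raw, cs$sample_rate, cs$epoch,
                             device = cs$device, filter = filter)
      ref <- oracle_counts(raw, cs$sample_rate, cs$epoch,
                           device = cs$device, filter = filter)
      axes <- setdiff(names(ref), "epoch")
      for (ax in axes) {
        n_ep <- n_ep + nrow(ref)
        n_mis <- n_mis + sum(got[[ax]] != ref[[ax]])
      }
    }
    tibble::tibble(sample_rate = cs$sample_rate, epoch = cs$epoch,
                   n_sims = cs$n_sims, n_epochs_compared = n_ep,
                   n_mismatched = n_mis)
  })
  structure(dplyr::bind_rows(res), seed = seed,
            class = c("counts_validation", class(tibble::tibble())))
}

#' @importFrom generics tidy
#' @export
tidy.counts_validation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @importFrom generics glance
#' @export
glance.counts_validation <- function(x, ...) {
  tibble::tibble(
    n_cases = nrow(x),
    n_sims = sum(x$n_sims),
    n_epochs_compared = sum(x$n_epochs_compared),
    n_mismatched = sum(x$n_mismatched),
    identical = sum(x$n_mismatched) == 0L
  )
}
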