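# Full-precision coefficients of the ActiLife 7th-order IIR band-pass, as
# distributed in ActiGraph's open-source implementation of the algorithm.
# The "rounded" variant is the same set rounded to 3 significant digits, the
# form in which the coefficients are usually quoted in print. The rounding
# matters: with poles at |z| ~ 0.96-0.99, 3-digit coefficients shift the
# response peak from 0.759 Hz to ~0.99 Hz, so the full set is the default.
.count_filter_sets <- list(
  full = list(
    b = c(-0.009341062898525, -0.025470289659360, -0.004235264826105,
           0.044152415456420,  0.036493718347760, -0.011893961934740,
          -0.022917390623150, -0.006788163862310),
    a = c( 1.00000000000000,  -3.63367395910510,   5.03689812757486,
          -3.09612247819666,   0.50620507633883,   0.32421701566682,
          -0.15685485875559,   0.01949130205890)
  ),
  rounded = list(
    b = c(-0.00934, -0.0255, -0.00424, 0.0442, 0.0365, -0.0119, -0.0229,
          -0.00679),
    a = c(1, -3.63, 5.04, -3.10, 0.506, 0.324, -0.157, 0.0195)
  )
)

#' The band-pass filter of the counts algorithm
#'
#' Builds the 7th-order IIR band-pass filter that isolates the ~0.2-2.5 Hz
#' band compatible with human movement, rejecting the DC component (gravity
#' and orientation) and high-frequency artifact. Its magnitude response at
#' 30 Hz sampling peaks at 0.759 Hz and falls to half gain (-6 dB) near
#' 0.212 and 2.15 Hz.
#'
#' @param coefficients `"full"` (default) for the full-precision set used by
#'   the ActiLife software, or `"rounded"` for the 3-significant-digit
#'   rendering of the same set. Ignored when `b` and `a` are given.
#' @param b,a Optional numeric vectors of 8 numerator and 8 denominator
#'   coefficients (`a[1]` must be 1) to inject a custom set.
#' @return An object of class `count_filter`: a list with elements `b`, `a`
#'   and `coefficients` (the set label).
#' @export
#' @examples
#' count_filter()$a[1]
#' count_filter("rounded")$b[4]
count_filter <- function(coefficients = c("full", "rounded"), b = NULL, a = NULL) {
  if (is.null(b) != is.null(a)) {
    stop("Supply both `b` and `a`, or neither.", call. = FALSE)
  }
  if (is.null(b)) {
    coefficients <- match.arg(coefficients)
    set <- .count_filter_sets[[coefficients]]
    b <- set$b
    a <- set$a
  } else {
    coefficients <- "custom"
    if (length(b) != length(a)) {
      stop("`b` and `a` must have equal length.", call. = FALSE)
    }
  }
  if (a[1] != 1) stop("`a[1]` must equal 1.", call. = FALSE)
  if (!is_stable(list(a = a))) {
    stop("Filter is unstable: a pole lies on or outside the unit circle.",
         call. = FALSE)
  }
  structure(list(b = as.double(b), a = as.double(a), coefficients = coefficients),
            class = "count_filter")
}

#' @export
print.count_filter <- function(x, ...) {
  cat(sprintf("<count_filter> order %d, coefficient set \"%s\"\n",
              length(x$a) - 1L, x$coefficients))
  cat("b:", format(x$b, digits = 6), "\n")
  cat("a:", format(x$a, digits = 6), "\n")
  invisible(x)
}

#' Is a filter stable?
#'
#' @param filter A `count_filter` (or any list with element `a`).
#' @return `TRUE` if all poles of the transfer function lie strictly inside
#'   the unit circle.
#' @export
is_stable <- function(filter) {
  a <- filter$a
  # roots of a0 z^m + a1 z^(m-1) + ... + am
  poles <- polyroot(rev(a))
  all(Mod(poles) < 1)
}

# Transposed direct-form II difference-equation runner: the workhorse of the
# band-pass stage. zi is the vector of m = length(a)-1 delay registers.
iir_df2t <- function(b, a, x, zi = NULL) {
  m <- length(a) - 1L
  if (is.null(zi)) zi <- double(m)
  stopifnot(length(zi) == m, length(b) == length(a))
  n <- length(x)
  y <- double(n)
  if (n == 0L) return(y)
  b0 <- b[1L]
  bt <- b[-1L]
  at <- a[-1L]
  z <- as.double(zi)
  if (m == 1L) {
    for (i in seq_len(n)) {
      xi <- x[i]
      yi <- b0 * xi + z
      z <- bt * xi - at * yi
      y[i] <- yi
    }
  } else {
    for (i in seq_len(n)) {
      xi <- x[i]
      yi <- b0 * xi + z[1L]
      z[-m] <- z[-1L] + bt[-m] * xi - at[-m] * yi
      z[m] <- bt[m] * xi - at[m] * yi
      y[i] <- yi
    }
  }
  y
}

#' Steady-state initial filter state for a step input
#'
#' Solves for the transposed direct-form II delay-register contents such that
#' filtering a constant input equal to `first_sample` produces a constant
#' output (the step response's steady-state value, `first_sample * H(1)`)
#' from the very first sample. Starting the band-pass from this state removes
#' the startup transient that zero initial conditions would inject at the
#' recording's first sample, where the signal level is dominated by the
#' gravity component.
#'
#' The state is the solution of the linear fixed-point equations of the
#' state update under unit input, scaled by `first_sample`.
#'
#' @param filter A [count_filter()].
#' @param first_sample The signal's first sample value.
#' @return Numeric vector of length `length(filter$a) - 1` (the filter
#'   order).
#' @export
#' @examples
#' steady_state_init(count_filter(), 1)
steady_state_init <- function(filter, first_sample = 1) {
  b <- filter$b
  a <- filter$a
  m <- length(a) - 1L
  # Fixed point under unit input: y = b0 + z1;
  #   z_k = z_{k+1} + b_{k+1} - a_{k+1} y   (k < m, with z_{m+1} = 0)
  # Substituting y gives M z = r with unknowns z_1..z_m.
  M <- diag(m)
  for (k in seq_len(m - 1L)) M[k, k + 1L] <- -1
  M[, 1L] <- M[, 1L] + a[-1L]
  r <- b[-1L] - a[-1L] * b[1L]
  zi <- solve(M, r)
  as.double(first_sample) * zi
}

#' Band-pass filter a 30 Hz signal
#'
#' Applies the counts band-pass to every axis column with the steady-state
#' initial condition of [steady_state_init()] computed from that column's
#' first sample, so each axis starts transient-free.
#'
#' @param data Data frame of axis columns at 30 Hz.
#' @param filter A [count_filter()].
#' @return Tibble of filtered axis columns, same dimensions.
#' @export
apply_bandpass <- function(data, filter = count_filter()) {
  data <- check_signal_frame(data)
  if (nrow(data) == 0L) return(data)
  dplyr::mutate(data, dplyr::across(dplyr::everything(), function(x) {
    iir_df2t(filter$b, filter$a, x, zi = steady_state_init(filter, x[1L]))
  }))
}

#' Magnitude response of a filter
#'
#' Evaluates the transfer-function magnitude `|H(e^{i 2 pi f / fs})|` on a
#' uniform frequency grid over `(0, fs/2]`.
#'
#' @param filter A [count_filter()].
#' @param fs Sampling rate in Hz the response is referred to.
#' @param n_grid Number of grid points; the grid is `(1:n_grid) * fs/2 /
#'   n_grid`, so `n_grid = 15000` at `fs = 30` gives 0.001 Hz spacing.
#' @return A tibble of class `filter_response` with columns `freq` (Hz),
#'   `gain` (linear) and `gain_db`.
#' @export
#' @examples
#' fr <- frequency_response(count_filter(), fs = 30, n_grid = 3000)
#' fr[which.max(fr$gain), ]
frequency_response <- function(filter, fs = 30, n_grid = 15000L) {
  stopifnot(fs > 0, n_grid >= 2)
  freq <- seq_len(n_grid) * (fs / 2) / n_grid
  z1 <- exp(-1i * 2 * pi * freq / fs)
  num <- 0i
  den <- 0i
  zp <- rep(1 + 0i, n_grid)
  for (k in seq_along(filter$b)) {
    num <- num + filter$b[k] * zp
    den <- den + filter$a[k] * zp
    zp <- zp * z1
  }
  gain <- Mod(num / den)
  structure(
    tibble::tibble(freq = freq, gain = gain, gain_db = 20 * log10(gain)),
    fs = fs, class = c("filter_response", class(tibble::tibble()))
  )
}

#' Locate the peak and half-gain frequencies of a magnitude response
#'
#' Finds the gain maximum and, on each side of it, the frequency at which the
#' gain first falls to half the peak value (-6 dB), locating the crossings by
#' linear interpolation of the linear gain between the bracketing grid
#' points. The grid must be fine enough to bracket both crossings.
#'
#' @param response A `filter_response` tibble from [frequency_response()].
#' @return One-row tibble with `peak_freq`, `peak_gain`, `lower_halfgain`
#'   and `upper_halfgain` (Hz).
#' @export
#' @examples
#' response_landmarks(frequency_response(count_filter()))
response_landmarks <- function(response) {
  f <- response$freq
  g <- response$gain
  pk <- which.max(g)
  half <- g[pk] / 2
  cross_at <- function(i) {
    f[i] + (half - g[i]) / (g[i + 1L] - g[i]) * (f[i + 1L] - f[i])
  }
  below_lo <- which(g[seq_len(pk)] < half)
  below_hi <- which(g[pk:length(g)] < half)
  if (length(below_lo) == 0L || length(below_hi) == 0L) {
    stop("No half-gain crossing on one side of the peak: the response is ",
         "not band-pass shaped on this grid.", call. = FALSE)
  }
  lo <- max(below_lo)               # last grid point below half, left of peak
  hi <- pk - 1L + min(below_hi)     # first grid point below half, right of peak
  tibble::tibble(
    peak_freq = f[pk],
    peak_gain = g[pk],
    lower_halfgain = cross_at(lo),
    upper_halfgain = cross_at(hi - 1L)
  )
}

#' @importFrom generics glance
#' @export
glance.count_filter <- function(x, fs = 30, n_grid = 15000L, ...) {
  lm <- response_landmarks(frequency_response(x, fs = fs, n_grid = n_grid))
  tibble::tibble(
    coefficients = x$coefficients,
    order = length(x$a) - 1L,
    stable = is_stable(x),
    dc_gain = sum(x$b) / sum(x$a),
    peak_freq = lm$peak_freq,
    lower_halfgain = lm$lower_halfgain,
    upper_halfgain = lm$upper_halfgain
  )
}

#' @importFrom generics tidy
#' @export
tidy.count_filter <- function(x, ...) {
  m <- length(x$b)
  tibble::tibble(
    term = c(paste0("b", 0:(m - 1L)), paste0("a", 0:(m - 1L))),
    coefficient = c(x$b, x$a)
  )
}
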