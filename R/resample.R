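#' Coefficients of the x3 up-sampling low-pass recursion
#'
#' Rates that are multiples of 10 Hz but not of 30 Hz (40, 50, 70, 80,
#' 100 Hz) are brought to a multiple of 30 Hz by inserting two zeros between
#' consecutive samples and running the first-order recursion
#' `w[i] = b0*v[i] + b0*v[i-1] + a1*w[i-1]` with
#' `b0 = 3*pi/(pi + 6)` and `a1 = (6 - pi)/(pi + 6)`.
#' Its DC gain `2*b0/(1 - a1) = 6*pi/(2*pi)` is exactly 3, compensating the
#' 1/3 duty cycle of zero insertion so constants pass through unchanged.
#'
#' @return Named list with elements `b0`, `b1`, `a1`.
#' @export
upsample_coefficients <- function() {
  list(b0 = 3 * pi / (pi + 6), b1 = 3 * pi / (pi + 6), a1 = (6 - pi) / (pi + 6))
}

# zero-stuff by 3 then run the first-order low-pass recursion, zero state
upsample_axis_x3 <- function(x) {
  n <- length(x)
  if (n == 0L) return(double(0))
  v <- double(3L * n)
  v[seq(1L, 3L * n, by = 3L)] <- x
  cf <- upsample_coefficients()
  # w[i] = b0 v[i] + b1 v[i-1] + a1 w[i-1], v[0] = w[0] = 0
  # first-order IIR: use the package's own difference-equation runner
  iir_df2t(c(cf$b0, cf$b1), c(1, -cf$a1), v, zi = 0)
}

#' Up-sample axis columns by a factor of three
#'
#' Inserts two zeros between consecutive samples of every axis column and
#' applies the first-order low-pass recursion of
#' [upsample_coefficients()], turning a signal at `f` Hz into one at
#' `3*f` Hz. Initial conditions are zero (`v[-1] = w[-1] = 0`).
#'
#' @param data Data frame of numeric axis columns.
#' @return Tibble with the same columns and three times the rows.
#' @export
#' @examples
#' upsample_x3(data.frame(x = c(1, 0, 0)))
upsample_x3 <- function(data) {
  data <- check_signal_frame(data)
  tibble::as_tibble(purrr::map(data, upsample_axis_x3))
}

#' Decimate by keeping every m-th sample
#'
#' @param data Data frame of axis columns at an exact multiple of the target
#'   rate.
#' @param m Positive integer decimation factor; the first sample (phase 0) is
#'   always kept, so `out[i] = in[m*i]` in zero-based indexing.
#' @return Tibble with `ceiling(nrow(data)/m)` rows.
#' @export
#' @examples
#' decimate_every(data.frame(x = 1:6), m = 3)
decimate_every <- function(data, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer decimation factor.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  data[seq(1L, nrow(data), by = as.integer(m)), , drop = FALSE]
}

#' Resample a CPIW recording to 30 Hz
#'
#' The CentrePoint Insight Watch records at 32, 64, 128 or 256 Hz (behind an
#' anti-aliasing low-pass in the accelerometer itself) and is resampled to
#' 30 Hz before the common counts chain. The resampling strategy here is
#' linear interpolation onto the exact 30 Hz time grid; it is a documented,
#' swappable stand-in, as the cloud service's exact resampler is not public.
#'
#' @param data Data frame of axis columns.
#' @param sample_rate Input rate in Hz; must be 32, 64, 128 or 256.
#' @return Tibble of the same columns sampled at 30 Hz over the same time
#'   span.
#' @export
resample_cpiw_to_30 <- function(data, sample_rate) {
  sample_rate <- validate_rate(sample_rate, "cpiw")
  data <- check_signal_frame(data)
  n <- nrow(data)
  if (n < 2L) return(data[seq_len(min(n, 1L)), , drop = FALSE])
  t_in <- (seq_len(n) - 1) / sample_rate
  t_out <- seq(0, t_in[n], by = 1 / 30)
  tibble::as_tibble(purrr::map(
    data, ~ stats::approx(t_in, .x, xout = t_out, method = "linear")$y
  ))
}

#' Bring a raw signal to the 30 Hz pipeline rate
#'
#' Dispatches on the device path and rate: CPIW rates are linearly resampled;
#' 30 Hz passes through; 60 and 90 Hz are directly decimated (they are
#' already multiples of 30, so the up-sampling recursion is bypassed); 40,
#' 50, 70, 80 and 100 Hz are up-sampled by 3 with the low-pass recursion and
#' then decimated by `3*rate/30`.
#'
#' @param data Data frame of axis columns.
#' @param sample_rate Input rate in Hz.
#' @param device `"standard"` or `"cpiw"`.
#' @return Tibble of the same columns at 30 Hz.
#' @export
to_30hz <- function(data, sample_rate, device = c("standard", "cpiw")) {
  device <- match.arg(device)
  sample_rate <- validate_rate(sample_rate, device)
  data <- check_signal_frame(data)
  if (device == "cpiw") {
    return(resample_cpiw_to_30(data, sample_rate))
  }
  if (sample_rate == 30) {
    data
  } else if (sample_rate %% 30 == 0) {
    decimate_every(data, m = sample_rate / 30)
  } else {
    decimate_every(upsample_x3(data), m = sample_rate / 10)
  }
}
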