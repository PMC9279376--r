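#' Rescale a filtered signal to the legacy counts range
#'
#' Multiplies every sample by [count_scale_factor()] (~17.127404) so that the
#' band-pass output occupies the dynamic range of the original AM7164
#' device's 8-bit quantizer, on which the deadband and ceiling of
#' [threshold_floor()] are defined.
#'
#' @param data Data frame of filtered axis columns.
#' @return Tibble, same dimensions.
#' @export
rescale_counts <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, dplyr::across(dplyr::everything(), ~ .x * count_scale_factor()))
}

#' Rectify a signal
#'
#' Elementwise absolute value; counts accumulate movement magnitude
#' regardless of direction.
#'
#' @param data Data frame of axis columns.
#' @return Tibble, same dimensions.
#' @export
rectify <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, dplyr::across(dplyr::everything(), abs))
}

threshold_axis <- function(x, deadband, ceiling) {
  if (any(x < 0)) {
    stop("threshold_floor() requires nonnegative input; rectify first.",
         call. = FALSE)
  }
  out <- integer(length(x))
  out[x > ceiling] <- as.integer(ceiling)
  mid <- x >= deadband & x <= ceiling
  out[mid] <- as.integer(floor(x[mid]))
  out
}

#' Quantize a rectified signal with deadband and saturation
#'
#' Applies the piecewise rule of the counts quantizer to every sample:
#' values above the ceiling (128) clip to the ceiling, values from the
#' deadband (4) up to the ceiling are floored to integers, and values below
#' the deadband map to 0. Outputs are exact integers in `{0} U [4, 128]`.
#'
#' @param data Data frame of nonnegative axis columns (or a bare numeric
#'   vector, returned as a vector).
#' @param deadband,ceiling Quantizer limits; defaults from
#'   [count_thresholds()].
#' @return Tibble of integer columns (or an integer vector).
#' @export
#' @examples
#' threshold_floor(c(3.999, 4, 10.7, 200))
threshold_floor <- function(data, deadband = 4, ceiling = 128) {
  stopifnot(deadband < ceiling)
  if (is.numeric(data) && is.null(dim(data))) {
    return(threshold_axis(data, deadband, ceiling))
  }
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, dplyr::across(dplyr::everything(),
                                    ~ threshold_axis(.x, deadband, ceiling)))
}

avg3_axis <- function(x) {
  n3 <- length(x) %/% 3L
  if (n3 == 0L) return(integer(0))
  x <- as.integer(x[seq_len(3L * n3)])
  i <- seq(1L, by = 3L, length.out = n3)
  (x[i] + x[i + 1L] + x[i + 2L]) %/% 3L
}

#' Decimate a 30 Hz integer signal to 10 Hz by block averages
#'
#' Replaces each non-overlapping block of three consecutive samples by the
#' floor of its mean. A trailing remainder of one or two samples is dropped.
#' Because the input is integer-valued in `[0, 128]`, the output is too, and
#' the computation is carried out in exact integer arithmetic.
#'
#' @param data Data frame of integer axis columns at 30 Hz.
#' @return Tibble of integer axis columns at 10 Hz.
#' @export
#' @examples
#' decimate_avg_to_10hz(data.frame(x = c(3L, 4L, 5L, 5L, 5L, 6L)))
decimate_avg_to_10hz <- function(data) {
  data <- tibble::as_tibble(data)
  tibble::as_tibble(purrr::map(data, avg3_axis))
}

#' Sum a 10 Hz integer signal into epochs
#'
#' Sums consecutive half-open blocks of `10 * epoch` samples per axis; an
#' incomplete final epoch is dropped rather than padded. Each epoch total is
#' bounded by `128 * 10 * epoch` per axis.
#'
#' @param data Data frame of integer axis columns at 10 Hz.
#' @param epoch Epoch length in seconds (positive integer).
#' @return Tibble with an `epoch` index column (1-based) followed by one
#'   integer column of counts per axis; zero rows if the series is shorter
#'   than one epoch.
#' @export
#' @examples
#' sum_epochs(data.frame(x = rep(1L, 25)), epoch = 1)
sum_epochs <- function(data, epoch) {
  epoch <- check_epoch_len(epoch)
  data <- tibble::as_tibble(data)
  block <- 10L * epoch
  n_ep <- nrow(data) %/% block
  sums <- purrr::map(data, function(x) {
    if (n_ep == 0L) return(integer(0))
    x <- as.integer(x[seq_len(n_ep * block)])
    as.integer(rowsum(x, rep(seq_len(n_ep), each = block))[, 1L])
  })
  tibble::tibble(epoch = seq_len(n_ep), !!!sums)
}

#' Compute activity counts from raw acceleration
#'
#' Runs the full raw-to-counts chain on a recording: bring the signal to
#' 30 Hz ([to_30hz()]), band-pass filter with steady-state initialization
#' ([apply_bandpass()]), rescale to the legacy range ([rescale_counts()]),
#' rectify, quantize with deadband 4 and ceiling 128 ([threshold_floor()]),
#' decimate to 10 Hz by non-overlapping three-sample averages
#' ([decimate_avg_to_10hz()]), and sum within non-overlapping epochs
#' ([sum_epochs()]). Axes are processed fully independently; counts are
#' reported per axis in input column order.
#'
#' @param data Data frame with 1 or 3 numeric axis columns of acceleration
#'   in g units.
#' @param sample_rate Sampling rate in Hz (30-100 in steps of 10 for the
#'   standard path; 32/64/128/256 for `device = "cpiw"`).
#' @param epoch Epoch length in seconds (positive integer); 10-60 s are
#'   typical.
#' @param device `"standard"` or `"cpiw"`.
#' @param filter The band-pass to use; defaults to [count_filter()].
#' @return A tibble of class `activity_counts` with columns `epoch`, `time`
#'   (epoch start, seconds) and one nonnegative-integer counts column per
#'   axis. The epoch length and configuration are carried as attributes.
#' @export
#' @examples
#' raw <- generate_sinusoid(freq = 1, amplitude = 0.5, sample_rate = 30,
#'                          duration = 30)
#' activity_counts(raw, sample_rate = 30, epoch = 10)
activity_counts <- function(data, sample_rate, epoch = 10,
                            device = c("standard", "cpiw"),
                            filter = count_filter()) {
  device <- match.arg(device)
  epoch <- check_epoch_len(epoch)
  counts <- check_signal_frame(data) |>
    to_30hz(sample_rate, device) |>
    apply_bandpass(filter) |>
    rescale_counts() |>
    rectify() |>
    threshold_floor() |>
    decimate_avg_to_10hz() |>
    sum_epochs(epoch)
  out <- tibble::add_column(counts,
                            time = (counts$epoch - 1L) * as.double(epoch),
                            .after = "epoch")
  structure(out,
            epoch_len = epoch, sample_rate = sample_rate, device = device,
            coefficients = filter$coefficients,
            class = c("activity_counts", class(tibble::tibble())))
}

#' Per-stage walkthrough of the counts pipeline
#'
#' Runs the same chain as [activity_counts()] but returns every intermediate
#' series in long form, for inspection and plotting of what each stage does
#' to a waveform.
#'
#' @inheritParams activity_counts
#' @return A tibble with columns `stage` (ordered factor: `raw`,
#'   `resampled30`, `filtered`, `rescaled`, `rectified`, `thresholded`,
#'   `decimated10`), `rate` (Hz), `time` (s), `axis` and `value`.
#' @export
count_stages <- function(data, sample_rate, epoch = 10,
                         device = c("standard", "cpiw"),
                         filter = count_filter()) {
  device <- match.arg(device)
  sample_rate <- validate_rate(sample_rate, device)
  raw <- check_signal_frame(data)
  s30 <- to_30hz(raw, sample_rate, device)
  fil <- apply_bandpass(s30, filter)
  res <- rescale_counts(fil)
  rec <- rectify(res)
  thr <- threshold_floor(rec)
  dec <- decimate_avg_to_10hz(thr)
  stages <- list(
    raw = list(raw, sample_rate), resampled30 = list(s30, 30),
    filtered = list(fil, 30), rescaled = list(res, 30),
    rectified = list(rec, 30), thresholded = list(thr, 30),
    decimated10 = list(dec, 10)
  )
  out <- purrr::imap(stages, function(st, nm) {
    d <- tibble::as_tibble(st[[1L]])
    d$time <- (seq_len(nrow(d)) - 1) / st[[2L]]
    d <- tidyr::pivot_longer(d, cols = -"time", names_to = "axis",
                             values_to = "value",
                             values_transform = as.double)
    tibble::add_column(d, stage = nm, rate = st[[2L]], .before = 1L)
  })
  out <- dplyr::bind_rows(out)
  out$stage <- factor(out$stage, levels = names(stages), ordered = TRUE)
  out
}

#' @importFrom generics tidy
#' @export
tidy.activity_counts <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), cols = -c("epoch", "time"),
                      names_to = "axis", values_to = "counts")
}

#' @importFrom generics glance
#' @export
glance.activity_counts <- function(x, ...) {
  epoch_len <- attr(x, "epoch_len")
  long <- tidy.activity_counts(x)
  tibble::tibble(
    n_epochs = nrow(x),
    epoch_len = epoch_len,
    n_axes = ncol(x) - 2L,
    sample_rate = attr(x, "sample_rate"),
    device = attr(x, "device"),
    total_counts = sum(long$counts),
    max_count = if (nrow(long)) max(long$counts) else NA_integer_,
    count_ceiling = 128L * 10L * epoch_len
  )
}
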