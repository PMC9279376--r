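#' Admissible sampling rates
#'
#' The counts pipeline only accepts the sampling rates the target devices can
#' record at. Standard devices (wGT3X-BT, GT9X) record between 30 and 100 Hz
#' in multiples of 10 Hz; the CentrePoint Insight Watch (CPIW) records at
#' 32, 64, 128 or 256 Hz and is resampled to 30 Hz before the common chain.
#'
#' @param device `"standard"` or `"cpiw"`.
#' @return Integer vector of admissible rates in Hz.
#' @export
#' @examples
#' admissible_rates("standard")
#' admissible_rates("cpiw")
admissible_rates <- function(device = c("standard", "cpiw")) {
  device <- match.arg(device)
  switch(device,
    standard = seq(30L, 100L, by = 10L),
    cpiw = c(32L, 64L, 128L, 256L)
  )
}

#' Validate a sampling rate for a device path
#'
#' @param rate Sampling rate in Hz.
#' @param device `"standard"` or `"cpiw"`.
#' @return The rate, unchanged, if admissible; otherwise an error naming the
#'   admissible set.
#' @export
#' @examples
#' validate_rate(40, "standard")
#' validate_rate(64, "cpiw")
validate_rate <- function(rate, device = c("standard", "cpiw")) {
  device <- match.arg(device)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number, not ",
         deparse(substitute(rate)), call. = FALSE)
  }
  ok <- admissible_rates(device)
  if (!rate %in% ok) {
    stop(sprintf(
      "Sampling rate %s Hz is not admissible for the %s device path; admissible rates are {%s} Hz.",
      format(rate), device, paste(ok, collapse = ", ")
    ), call. = FALSE)
  }
  rate
}

# Check a raw-signal data frame: 1 or 3 numeric axis columns, finite values.
# Returns the data as a plain tibble of doubles.
check_signal_frame <- function(data, arg = "data") {
  if (!is.data.frame(data)) {
    stop("`", arg, "` must be a data frame of axis columns.", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!ncol(data) %in% c(1L, 3L)) {
    stop("`", arg, "` must have 1 or 3 axis columns, not ", ncol(data), ".",
         call. = FALSE)
  }
  for (nm in names(data)) {
    col <- data[[nm]]
    if (!is.numeric(col)) {
      stop("Axis column `", nm, "` is not numeric.", call. = FALSE)
    }
    if (anyNA(col) || any(!is.finite(col))) {
      bad <- which(!is.finite(col))[1L]
      stop("Axis column `", nm, "` contains a non-finite value at sample ",
           bad, "; raw acceleration must be finite.", call. = FALSE)
    }
    data[[nm]] <- as.double(col)
  }
  data
}

check_epoch_len <- function(epoch) {
  if (!is.numeric(epoch) || length(epoch) != 1L || !is.finite(epoch) ||
      epoch < 1 || epoch != round(epoch)) {
    stop("`epoch` must be a positive whole number of seconds (the 10 Hz ",
         "stage makes an epoch a whole number of 10-sample blocks).",
         call. = FALSE)
  }
  as.integer(epoch)
}

#' Scale factor applied to the band-pass filtered signal
#'
#' The filtered 30 Hz signal is multiplied by
#' `(3.0/4096.0) / (2.6/256.0) * 237.5` (about 17.127404) so that its dynamic
#' range replicates that of the legacy AM7164 device, whose 8-bit quantizer
#' defined the original counts scale.
#'
#' @return The scale factor, computed in full double precision.
#' @export
#' @examples
#' round(count_scale_factor(), 6)
count_scale_factor <- function() {
  (3.0 / 4096.0) / (2.6 / 256.0) * 237.5
}

#' Deadband and saturation limits of the counts quantizer
#'
#' Rectified, rescaled samples below the deadband (4) contribute nothing,
#' suppressing accumulation of the noise floor; samples above the ceiling
#' (128) are clipped, bounding each epoch at `128 * 10 * epoch` counts per
#' axis.
#'
#' @return Named list with elements `deadband` and `ceiling`.
#' @export
count_thresholds <- function() {
  list(deadband = 4L, ceiling = 128L)
}
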