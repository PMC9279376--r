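#' Read a raw acceleration CSV
#'
#' Reads a plain CSV of per-sample acceleration in g units, one column per
#' axis (1 or 3 columns). The sampling rate is never inferred from
#' timestamps: it is supplied explicitly via `sample_rate`, or read from a
#' leading comment line of the form `# sample_rate: 30` if present.
#'
#' @param path Path to the CSV file.
#' @param sample_rate Sampling rate in Hz; may be omitted if the file
#'   carries a `# sample_rate:` comment line.
#' @param header Whether the file has a header row of axis names.
#' @param col_names Axis names to use when `header = FALSE` (defaults to
#'   `x` or `x`,`y`,`z` by column count).
#' @param delim Field delimiter.
#' @return Tibble of axis columns with attribute `sample_rate`.
#' @export
read_raw_csv <- function(path, sample_rate = NULL, header = TRUE,
                         col_names = NULL, delim = ",") {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  n_comment <- if (all(startsWith(head_lines, "#"))) length(head_lines) else
    which(!startsWith(head_lines, "#"))[1L] - 1L
  comment_rate <- grep("^#\\s*sample_rate\\s*[:=]", head_lines, value = TRUE)
  if (is.null(sample_rate)) {
    if (length(comment_rate) == 0L) {
      stop("No `sample_rate` given and no `# sample_rate:` comment line in ",
           path, "; the rate must be stated explicitly.", call. = FALSE)
    }
    sample_rate <- as.numeric(sub("^#\\s*sample_rate\\s*[:=]\\s*", "",
                                  comment_rate[1L]))
  }
  dat <- suppressWarnings(readr::read_delim(
    path, delim = delim, comment = "#",
    col_names = if (header) TRUE else col_names %||%
      c("x", "y", "z")[seq_len(count_csv_fields(path, delim))],
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0L) {
    p <- probs[1L, ]
    stop(sprintf(
      "Malformed value in %s at line %d, column %d: expected %s, got \"%s\".",
      path, p$row + n_comment, p$col, p$expected, p$actual
    ), call. = FALSE)
  }
  out <- check_signal_frame(dat, arg = "file")
  attr(out, "sample_rate") <- sample_rate
  out
}

count_csv_fields <- function(path, delim) {
  ln <- readLines(path, n = 20L, warn = FALSE)
  ln <- ln[!startsWith(ln, "#")]
  if (length(ln) == 0L) return(1L)
  length(strsplit(ln[1L], delim, fixed = TRUE)[[1L]])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write an activity-counts table to CSV
#'
#' Writes one row per complete epoch with header
#' `epoch_index,<axis names...>`; all values are integers.
#'
#' @param counts An `activity_counts` tibble (or any tibble with an `epoch`
#'   column and integer axis columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  out <- tibble::as_tibble(counts)
  out$time <- NULL
  names(out)[names(out) == "epoch"] <- "epoch_index"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read counts written by [write_counts_csv()]
#'
#' @param path Path to the counts CSV.
#' @return Tibble with an `epoch` column and integer axis columns.
#' @export
read_counts_csv <- function(path) {
  dat <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_integer()),
                         progress = FALSE, show_col_types = FALSE)
  names(dat)[names(dat) == "epoch_index"] <- "epoch"
  dat
}
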