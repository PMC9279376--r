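# Small independent oracles used across the test files.

# direct evaluation of |H(e^{i 2 pi f / fs})| from the coefficient vectors
gain_at <- function(filter, freq, fs = 30) {
  z <- exp(-1i * 2 * pi * freq / fs)
  k <- 0:(length(filter$b) - 1L)
  Mod(sum(filter$b * z^k) / sum(filter$a * z^k))
}

# naive scalar recursion for the x3 up-sampler: zero-stuff then
# w[i] = b0 v[i] + b0 v[i-1] + c w[i-1]
naive_upsample_x3 <- function(x) {
  v <- double(3 * length(x))
  v[seq(1, length(v), by = 3)] <- x
  b0 <- 3 * pi / (pi + 6)
  cc <- (6 - pi) / (pi + 6)
  w <- double(length(v))
  for (i in seq_along(v)) {
    w[i] <- b0 * v[i] + b0 * (if (i > 1) v[i - 1] else 0) +
      cc * (if (i > 1) w[i - 1] else 0)
  }
  w
}

# naive difference-equation band-pass with steady-state constant pre-history
naive_bandpass <- function(filter, x) {
  b <- filter$b
  a <- filter$a
  h1 <- sum(b) / sum(a)
  n <- length(x)
  y <- double(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in 0:(length(b) - 1L)) {
      acc <- acc + b[k + 1] * (if (i - k >= 1) x[i - k] else x[1])
    }
    for (k in 1:(length(a) - 1L)) {
      acc <- acc - a[k + 1] * (if (i - k >= 1) y[i - k] else x[1] * h1)
    }
    y[i] <- acc
  }
  y
}
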