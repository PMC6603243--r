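# Internal helpers shared across modules.

# DFT bin frequencies in cycles per unit, standard FFT order
# (0, 1, ..., n/2-1, -n/2, ..., -1) / (n * d).
fft_freq <- function(n, d = 1) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2)):-1)
  k / (n * d)
}

# Reorder a matrix from FFT order to DC-centered order and back.
fftshift2 <- function(m) {
  i <- shift_index(nrow(m))
  j <- shift_index(ncol(m))
  m[i, j, drop = FALSE]
}

ifftshift2 <- function(m) {
  i <- order(shift_index(nrow(m)))
  j <- order(shift_index(ncol(m)))
  m[i, j, drop = FALSE]
}

shift_index <- function(n) {
  h <- ceiling(n / 2)
  c((h + 1):n, 1:h)
}

# Centered frequency axis matching fftshift2 output rows/cols.
centered_freq <- function(n, d = 1) {
  sort_idx <- shift_index(n)
  fft_freq(n, d)[sort_idx]
}

# Run code with a temporary RNG seed; NULL seed uses the current stream.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, force(code))
}

# Random signs: +1 with probability p, else -1.
rand_sign <- function(n, p) {
  ifelse(stats::runif(n) < p, 1, -1)
}

# Normalize an in-plane pixel size to length-2 (row mm, col mm).
as_pixel_mm <- function(pixel_mm) {
  stopifnot(is.numeric(pixel_mm), length(pixel_mm) %in% c(1L, 2L),
            all(is.finite(pixel_mm)), all(pixel_mm > 0))
  if (length(pixel_mm) == 1L) rep(pixel_mm, 2L) else as.numeric(pixel_mm)
}

is_binary_pm1 <- function(m) {
  is.numeric(m) && all(m %in% c(-1, 1))
}
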