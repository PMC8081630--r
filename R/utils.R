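# Internal numeric helpers shared across the transform, filters and fixtures.
# All spatial filtering in the package is done in the FFT domain with periodic
# (circular) boundary handling, so shift-invariance contracts are exact.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @keywords internal
re_ifft2 <- function(x) Re(ifft2(x))

# Circular shift: positive s moves content down/right (row/col).
circshift <- function(x, s) {
  s <- as.integer(s)
  d <- dim(x)
  i <- ((seq_len(d[1]) - 1L - (s[1] %% d[1])) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L - (s[2] %% d[2])) %% d[2]) + 1L
  x[i, j, drop = FALSE]
}

# Signed FFT frequency index grid for an n-point axis: 0, 1, ..., n/2, -(n/2-1), ..., -1
fft_freqs <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n %/% 2, k, k - n)
}

# Exact circular Gaussian blur via its frequency response.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  wu <- 2 * pi * fft_freqs(d[1]) / d[1]
  wv <- 2 * pi * fft_freqs(d[2]) / d[2]
  h <- exp(-0.5 * sigma^2 * outer(wu^2, wv^2, "+"))
  re_ifft2(h * fft2(x))
}

# Sum of x over the (2r+1)x(2r+1) window centred at each pixel, truncated at
# the borders (zero outside). O(HW) via 2-D cumulative sums.
boxsum <- function(x, r) {
  d <- dim(x); h <- d[1]; w <- d[2]
  cs <- apply(apply(x, 2L, cumsum), 1L, cumsum)  # cs is t(cumsum2): dims w x h
  cs <- t(cs)                                    # back to h x w, cs[i,j] = sum x[1:i,1:j]
  cs <- rbind(0, cbind(0, cs))                   # pad so cs[i+1,j+1] = sum x[1:i,1:j]
  i2 <- pmin(seq_len(h) + r, h) + 1L
  i1 <- pmax(seq_len(h) - r - 1L, 0L) + 1L
  j2 <- pmin(seq_len(w) + r, w) + 1L
  j1 <- pmax(seq_len(w) - r - 1L, 0L) + 1L
  cs[i2, j2] - cs[i1, j2] - cs[i2, j1] + cs[i1, j1]
}

# Number of in-image pixels in each truncated box window (denominator for
# border-corrected box means).
boxcount <- function(dim2, r) {
  boxsum(matrix(1, dim2[1], dim2[2]), r)
}

boxmean <- function(x, r, n = NULL) {
  if (is.null(n)) n <- boxcount(dim(x), r)
  boxsum(x, r) / n
}

# Sum of img over the p x p window whose bottom-right corner is each pixel
# (i.e. out[i,j] = sum img[(i-p+1):i, (j-p+1):j], zero outside the image).
# Used to average sliding-window scores over every window covering a pixel.
cover_sum <- function(img, p) {
  d <- dim(img); h <- d[1]; w <- d[2]
  cs <- t(apply(apply(img, 2L, cumsum), 1L, cumsum))
  cs <- rbind(0, cbind(0, cs))
  i2 <- seq_len(h) + 1L
  i1 <- pmax(seq_len(h) - p, 0L) + 1L
  j2 <- seq_len(w) + 1L
  j1 <- pmax(seq_len(w) - p, 0L) + 1L
  cs[i2, j2] - cs[i1, j2] - cs[i2, j1] + cs[i1, j1]
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

next_pow2 <- function(n) as.integer(2^ceiling(log2(n)))

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# Reflect-pad a matrix on the bottom/right up to size (h, w).
reflect_pad <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  stopifnot(h >= d[1], w >= d[2], h - d[1] < d[1], w - d[2] < d[2])
  ri <- c(seq_len(d[1]), rev(seq_len(d[1])))[seq_len(h)]
  ci <- c(seq_len(d[2]), rev(seq_len(d[2])))[seq_len(w)]
  x[ri, ci, drop = FALSE]
}

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_matrix_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_invalid(name, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) stop_invalid(name, " contains non-finite values")
  invisible(x)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop_invalid(what, " must have identical dimensions (got ",
                 paste(dim(a), collapse = "x"), " vs ",
                 paste(dim(b), collapse = "x"), ")")
  }
  invisible(NULL)
}
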