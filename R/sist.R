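#' Configuration for the shift-invariant shearlet transform
#'
#' The transform decomposes an image with a non-subsampled (a-trous) pyramid
#' into `levels` scales, then splits each scale's high-pass plane into
#' directional subbands with frequency-domain shearing windows. All planes keep
#' the input's full resolution, so the transform commutes with circular
#' translation of the input.
#'
#' @param levels Number of pyramid scales `M` (default 4). Level 1 is the
#'   finest scale, level `M` the coarsest.
#' @param directions Integer vector of length `levels`: number of directional
#'   subbands per level, each a power of two. Default `c(32, 32, 16, 16)`,
#'   finest to coarsest.
#' @param pyramid_filter Name of the pyramid low-pass kernel. Only
#'   `"maxflat"` (a maximally-flat binomial half-band kernel) is provided.
#' @param maxflat_order Half-order of the binomial kernel; the 1-D kernel is
#'   `choose(2m, 0:2m) / 4^m` with `m = maxflat_order` (default 2, the
#'   classic 1-4-6-4-1 kernel).
#' @return An object of class `sist_config`.
#' @export
sist_config <- function(levels = 4L,
                        directions = c(32L, 32L, 16L, 16L),
                        pyramid_filter = "maxflat",
                        maxflat_order = 2L) {
  levels <- as.integer(levels)
  directions <- as.integer(directions)
  if (levels < 1L) stop_invalid("levels must be >= 1")
  if (length(directions) != levels) {
    stop_invalid("directions must have one entry per level")
  }
  if (!all(vapply(directions, is_pow2, logical(1))) || any(directions < 2L)) {
    stop_invalid("each directions count must be a power of two >= 2")
  }
  if (!identical(pyramid_filter, "maxflat")) {
    stop_invalid("unknown pyramid filter: ", pyramid_filter)
  }
  structure(
    list(levels = levels, directions = directions,
         pyramid_filter = pyramid_filter,
         maxflat_order = as.integer(maxflat_order)),
    class = "sist_config"
  )
}

# 1-D maximally flat (binomial) low-pass kernel, unit DC gain.
maxflat_kernel <- function(order = 2L) {
  m <- as.integer(order)
  choose(2L * m, 0:(2L * m)) / 4^m
}

# Frequency response (real, zero phase) on an n-point circular axis of the
# symmetric kernel h (odd length), dilated a-trous style by `dilation`
# (zeros inserted between taps).
kernel_response_1d <- function(h, n, dilation = 1L) {
  half <- (length(h) - 1L) %/% 2L
  taps <- (-half:half) * dilation
  w <- 2 * pi * fft_freqs(n) / n
  # symmetric kernel: response = sum h_k cos(k w)
  resp <- rep(0, n)
  for (k in seq_along(h)) resp <- resp + h[k] * cos(taps[k] * w)
  resp
}

# Separable 2-D low-pass transfer functions for each a-trous level.
nsp_transfer <- function(dim2, levels, order) {
  h <- maxflat_kernel(order)
  lapply(seq_len(levels), function(j) {
    ru <- kernel_response_1d(h, dim2[1], dilation = 2L^(j - 1L))
    rv <- kernel_response_1d(h, dim2[2], dilation = 2L^(j - 1L))
    outer(ru, rv)
  })
}

#' Non-subsampled pyramid decomposition
#'
#' Undecimated (a-trous) multiscale decomposition with a maximally-flat
#' binomial low-pass kernel dilated by `2^(j-1)` at level `j`. High-pass
#' planes are additive details `g^j = f^(j-1) - f^j`, so
#' `lowpass + sum(highpass)` reconstructs the input exactly. Filtering is
#' FFT-domain with circular boundaries.
#'
#' @param image Numeric matrix (any finite values).
#' @param levels Number of scales.
#' @param filter_name Pyramid kernel name (only `"maxflat"`).
#' @param maxflat_order Kernel half-order, see [sist_config()].
#' @return A list with `lowpass` (matrix) and `highpass` (list of `levels`
#'   matrices, finest first).
#' @export
nsp_decompose <- function(image, levels, filter_name = "maxflat",
                          maxflat_order = 2L) {
  assert_matrix_image(image)
  levels <- as.integer(levels)
  if (levels < 1L) stop_invalid("levels must be >= 1")
  if (!identical(filter_name, "maxflat")) {
    stop_invalid("unknown pyramid filter: ", filter_name)
  }
  transfers <- nsp_transfer(dim(image), levels, maxflat_order)
  f <- image
  highpass <- vector("list", levels)
  for (j in seq_len(levels)) {
    f_next <- re_ifft2(transfers[[j]] * fft2(f))
    highpass[[j]] <- f - f_next
    f <- f_next
  }
  list(lowpass = f, highpass = highpass)
}

#' Build directional shearing filter windows
#'
#' Constructs `n_directions` real, nonnegative frequency-domain windows from
#' smooth Meyer-type angular bumps laid out on the pseudo-polar grid (the
#' angle variable is piecewise linear in the shear `xi2/xi1` on the horizontal
#' frequency cone and `xi1/xi2` on the vertical cone) and evaluated on the
#' Cartesian FFT grid. The squared windows form an exact partition of unity:
#' `sum_k |W_k|^2 = 1` at every frequency bin, so a tight-frame reconstruction
#' by plain summation is possible.
#'
#' @param size Integer `(H, W)` of the frequency grid.
#' @param n_directions Power of two `>= 2`.
#' @return List of `n_directions` `H x W` matrices (unshifted FFT layout).
#' @export
build_shearing_filters <- function(size, n_directions) {
  n_directions <- as.integer(n_directions)
  if (!is_pow2(n_directions) || n_directions < 2L) {
    stop_invalid("n_directions must be a power of two >= 2")
  }
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 32L || w < 32L) {
    stop_invalid("frequency grid too small for directional windows (need >= 32)")
  }
  if (min(h, w) < n_directions) {
    stop_invalid("grid of ", h, "x", w, " too small for ", n_directions,
                 " directions")
  }
  xu <- matrix(fft_freqs(h), h, w)        # row frequency
  xv <- matrix(fft_freqs(w), h, w, byrow = TRUE)  # column frequency
  phi <- pseudo_polar_angle(xu, xv)
  spacing <- pi / n_directions
  lapply(seq_len(n_directions), function(k) {
    centre <- (k - 1L) * spacing
    delta <- phi - centre
    delta <- delta - pi * round(delta / pi)   # wrap to (-pi/2, pi/2]
    win2 <- ifelse(abs(delta) < spacing, cos(pi * delta / (2 * spacing))^2, 0)
    win2[1, 1] <- 1 / n_directions            # DC shared equally
    sqrt(win2)
  })
}

# Pseudo-polar angle in [0, pi): piecewise linear in the shear variable on
# each frequency cone; equals the true angle on the cone boundaries.
pseudo_polar_angle <- function(xu, xv) {
  # treat xv as the horizontal axis (xi1), xu as vertical (xi2)
  horiz <- abs(xv) >= abs(xu)
  phi <- matrix(0, nrow(xu), ncol(xu))
  phi[horiz] <- (pi / 4) * (xu[horiz] / xv[horiz])
  phi[!horiz] <- pi / 2 - (pi / 4) * (xv[!horiz] / xu[!horiz])
  phi[1, 1] <- 0
  phi %% pi
}

#' Shift-invariant shearlet decomposition
#'
#' Runs the non-subsampled pyramid, then splits each level's high-pass plane
#' into directional subbands by multiplying its FFT with the squared shearing
#' windows (the analysis and synthesis halves of the tight frame folded
#' together). Consequently the directional planes of a level sum exactly to
#' that level's pyramid high-pass plane, and reconstruction is plain
#' summation.
#'
#' @param image Numeric matrix with power-of-two dimensions.
#' @param config A [sist_config()].
#' @return An object of class `shearlet_pyramid`: list with `lowpass`,
#'   `highpass` (list per level of lists of directional planes, finest level
#'   first) and `config`.
#' @export
sist_decompose <- function(image, config = sist_config()) {
  assert_matrix_image(image)
  d <- dim(image)
  if (!is_pow2(d[1]) || !is_pow2(d[2])) {
    stop_invalid("image dimensions must be powers of two; pad first ",
                 "(see fuse_pair for automatic padding)")
  }
  pyr <- nsp_decompose(image, config$levels, config$pyramid_filter,
                       config$maxflat_order)
  highpass <- vector("list", config$levels)
  for (j in seq_len(config$levels)) {
    wins <- build_shearing_filters(d, config$directions[j])
    gf <- fft2(pyr$highpass[[j]])
    highpass[[j]] <- lapply(wins, function(w) re_ifft2((w * w) * gf))
  }
  structure(list(lowpass = pyr$lowpass, highpass = highpass, config = config),
            class = "shearlet_pyramid")
}

#' Inverse shift-invariant shearlet transform
#'
#' Exact inverse of [sist_decompose()]: sums every directional plane and the
#' low-pass plane. Validates the pyramid structure against `config`.
#'
#' @param pyramid A `shearlet_pyramid`.
#' @param config A [sist_config()]; defaults to the pyramid's own.
#' @return The reconstructed image matrix.
#' @export
sist_reconstruct <- function(pyramid, config = pyramid$config) {
  if (!inherits(pyramid, "shearlet_pyramid")) {
    stop_invalid("pyramid must be a shearlet_pyramid")
  }
  if (length(pyramid$highpass) != config$levels) {
    stop_invalid("pyramid has ", length(pyramid$highpass),
                 " levels but config expects ", config$levels)
  }
  out <- pyramid$lowpass
  d <- dim(out)
  for (j in seq_len(config$levels)) {
    planes <- pyramid$highpass[[j]]
    if (length(planes) != config$directions[j]) {
      stop_invalid("level ", j, " has ", length(planes),
                   " directional planes but config expects ",
                   config$directions[j])
    }
    for (p in planes) {
      if (!identical(dim(p), d)) stop_invalid("plane shape mismatch at level ", j)
      out <- out + p
    }
  }
  out
}

#' Save / load a shearlet pyramid
#'
#' Serializes the pyramid to a single RDS archive with named planes
#' (`low`, `hp_L{j}_D{k}`) for debugging and fixtures.
#'
#' @param pyramid A `shearlet_pyramid`.
#' @param path File path.
#' @return `save_pyramid` the path invisibly; `load_pyramid` the pyramid.
#' @export
save_pyramid <- function(pyramid, path) {
  planes <- list(low = pyramid$lowpass)
  for (j in seq_along(pyramid$highpass)) {
    for (k in seq_along(pyramid$highpass[[j]])) {
      planes[[sprintf("hp_L%d_D%d", j, k)]] <- pyramid$highpass[[j]][[k]]
    }
  }
  saveRDS(list(planes = planes, config = pyramid$config), path)
  invisible(path)
}

#' @rdname save_pyramid
#' @export
load_pyramid <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  highpass <- lapply(seq_len(cfg$levels), function(j) {
    lapply(seq_len(cfg$directions[j]), function(k) {
      obj$planes[[sprintf("hp_L%d_D%d", j, k)]]
    })
  })
  structure(list(lowpass = obj$planes$low, highpass = highpass, config = cfg),
            class = "shearlet_pyramid")
}
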