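#' Specification for a synthetic phantom pair
#'
#' Describes a seeded, fully reproducible synthetic input for the fusion
#' pipeline. Three scenarios are provided: `"complementary_blur"` (a textured
#' ground truth with opposite halves degraded in each source, so the sharp
#' composite is known), `"modality_phantom"` (shared anatomy rendered with
#' CT-like boundary contrast in one image and MRI-like soft-tissue contrast in
#' the other) and `"shifted_pair"` (an image and its circular translation, for
#' keypoint colocation checks).
#'
#' @param size Integer `(H, W)`, default `c(256, 256)` matching the standard
#'   preprocessing size for the clinical slices this emulates.
#' @param seed Integer RNG seed; every generator is a pure function of the
#'   spec.
#' @param scenario One of `"complementary_blur"`, `"modality_phantom"`,
#'   `"shifted_pair"`.
#' @param blur_sigma Gaussian degradation width in pixels (default 3).
#' @param n_structures Number of internal geometric structures (default 6).
#' @param shift Integer `(dy, dx)` used by `"shifted_pair"` (default
#'   `c(10, 10)`).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L), seed = 1L,
                         scenario = c("complementary_blur",
                                      "modality_phantom", "shifted_pair"),
                         blur_sigma = 3, n_structures = 6L,
                         shift = c(10L, 10L)) {
  scenario <- match.arg(scenario)
  size <- as.integer(size)
  if (any(size < 32L)) stop_invalid("phantom size must be at least 32x32")
  structure(list(size = size, seed = as.integer(seed), scenario = scenario,
                 blur_sigma = blur_sigma, n_structures = as.integer(n_structures),
                 shift = as.integer(shift)),
            class = "phantom_spec")
}

# Band-limited seeded noise: white noise restricted to an annulus of
# normalized frequency, giving texture with energy where SIFT and the CNN
# sharpness cue operate. The default band mixes blob-scale energy (which
# survives the SIFT base blur, feeding the keypoint detector) with finer
# detail (which feeds the CNN sharpness cue).
bandlimited_noise <- function(h, w, f_lo = 0.008, f_hi = 0.25) {
  z <- matrix(stats::rnorm(h * w), h, w)
  fu <- fft_freqs(h) / h
  fv <- fft_freqs(w) / w
  rad <- sqrt(outer(fu^2, fv^2, "+"))
  # 1/f amplitude weighting inside the band so coarse blobs dominate while
  # fine detail is still present
  mask <- (rad >= f_lo & rad <= f_hi) / (rad + f_lo)
  x <- re_ifft2(mask * fft2(z))
  rng <- range(x)
  (x - rng[1]) / (rng[2] - rng[1])
}

# Render n random soft-edged ellipses; returns intensity canvas and the union
# mask plus each structure's mask.
render_structures <- function(h, w, n, intensities = NULL) {
  canvas <- matrix(0, h, w)
  masks <- vector("list", n)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 0.25 * h, 0.75 * h)
    cx <- stats::runif(1, 0.25 * w, 0.75 * w)
    ry <- stats::runif(1, 0.04 * h, 0.12 * h)
    rx <- stats::runif(1, 0.04 * w, 0.12 * w)
    th <- stats::runif(1, 0, pi)
    u <- (yy - cy) * cos(th) + (xx - cx) * sin(th)
    v <- -(yy - cy) * sin(th) + (xx - cx) * cos(th)
    d2 <- (u / ry)^2 + (v / rx)^2
    m <- d2 <= 1
    masks[[i]] <- m
    val <- if (is.null(intensities)) stats::runif(1, 0.3, 1) else intensities[i]
    canvas[m] <- val
  }
  list(canvas = canvas, masks = masks)
}

#' Generate a complementary-blur phantom pair with known ground truth
#'
#' Builds a textured ground-truth image `G` (band-limited noise plus soft
#' ellipses), then degrades the right half of source A and the left half of
#' source B with a Gaussian blur of width `spec$blur_sigma`. The untouched
#' halves equal `G` exactly, so the ideal fusion is `G` itself.
#'
#' @param spec A [phantom_spec()].
#' @return List with matrices `a`, `b`, `truth` (all in `[0, 1]`) and the spec.
#' @export
make_complementary_blur_pair <- function(spec = phantom_spec()) {
  h <- spec$size[1]; w <- spec$size[2]
  set.seed(spec$seed)
  tex <- bandlimited_noise(h, w)
  st <- render_structures(h, w, spec$n_structures)
  truth <- clamp01(0.55 * tex + 0.45 * st$canvas)
  blurred <- clamp01(gaussian_blur(truth, spec$blur_sigma))
  half <- w %/% 2L
  a <- truth; a[, (half + 1L):w] <- blurred[, (half + 1L):w]
  b <- truth; b[, seq_len(half)] <- blurred[, seq_len(half)]
  list(a = a, b = b, truth = truth, spec = spec)
}

#' Generate a two-modality phantom pair with shared geometry
#'
#' Shared anatomy (an elliptical "skull" ring plus internal structures) is
#' rendered with disjoint contrast assignments: image A emulates CT (bright
#' bone-like boundaries, dark low-texture interior), image B emulates MRI
#' (soft interior gradients, faint boundaries). The per-structure masks are
#' returned so tests can assert the shared geometry and the decorrelated
#' intensities.
#'
#' @param spec A [phantom_spec()].
#' @return List with `a`, `b`, `masks` (list of logical matrices, first the
#'   skull ring), and the spec.
#' @export
make_modality_phantom_pair <- function(spec = phantom_spec(scenario = "modality_phantom")) {
  h <- spec$size[1]; w <- spec$size[2]
  set.seed(spec$seed)
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- ((yy - h / 2) / (0.42 * h))^2 + ((xx - w / 2) / (0.42 * w))^2
  skull <- d2 <= 1 & d2 >= 0.82
  interior <- d2 < 0.82
  st <- render_structures(h, w, spec$n_structures)
  union_mask <- Reduce(`|`, st$masks)
  edge <- structure_edges(union_mask)

  noise_a <- bandlimited_noise(h, w); noise_b <- bandlimited_noise(h, w)
  # CT-like: very bright skull, bright structure boundaries, dark interior
  a <- matrix(0.05, h, w)
  a[interior] <- 0.12 + 0.05 * noise_a[interior]
  a[union_mask] <- 0.1
  a[edge] <- 0.9
  a[skull] <- 0.95
  # MRI-like: dark skull, textured interior, structures filled with soft values
  b <- matrix(0.05, h, w)
  b[interior] <- 0.45 + 0.25 * noise_b[interior]
  for (m in st$masks) b[m] <- stats::runif(1, 0.55, 0.95)
  b[skull] <- 0.1
  b <- gaussian_blur(b, 1)
  list(a = clamp01(a), b = clamp01(b),
       masks = c(list(skull), st$masks), spec = spec)
}

# Boundary pixels of a logical mask (mask pixels with a non-mask 4-neighbour).
structure_edges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !inner
}

#' Generate an image and its known circular shift
#'
#' @param spec A [phantom_spec()] whose `shift` is the `(dy, dx)` translation.
#' @return List with `image`, `shifted`, `shift` and the spec.
#' @export
make_shifted_pair <- function(spec = phantom_spec(scenario = "shifted_pair")) {
  h <- spec$size[1]; w <- spec$size[2]
  if (any(abs(spec$shift) >= spec$size)) {
    stop_invalid("shift must be smaller than the image")
  }
  set.seed(spec$seed)
  tex <- bandlimited_noise(h, w)
  st <- render_structures(h, w, spec$n_structures)
  img <- clamp01(0.5 * tex + 0.5 * st$canvas)
  list(image = img, shifted = circshift(img, spec$shift),
       shift = spec$shift, spec = spec)
}
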