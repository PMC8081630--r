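#' SIFT detector parameters
#'
#' Constants of the scale-invariant feature transform detector/descriptor:
#' difference-of-Gaussians scale space, 3 scales per octave with base width
#' 1.6 px, contrast and edge-response rejection, 36-bin orientation
#' assignment and the standard 4 x 4 x 8 gradient-orientation-histogram
#' descriptor (128 dimensions, unit L2 norm, 0.2 clipping).
#'
#' @param n_scales Scales per octave (default 3).
#' @param sigma0 Base blur of each octave in pixels (default 1.6).
#' @param init_sigma Assumed blur of the input (default 0.5).
#' @param contrast_thresh Minimum interpolated |DoG| response. The default
#'   `0.04 / n_scales` follows the common convention of spreading the 0.04
#'   peak-contrast threshold over the scales of an octave.
#' @param edge_thresh Principal-curvature ratio bound (default 10).
#' @param max_octaves Cap on the number of octaves (default 4).
#' @param ori_bins,ori_sigma_factor,ori_peak_ratio Orientation histogram
#'   constants.
#' @param desc_width,desc_ori_bins,desc_bin_scale,desc_clip Descriptor grid
#'   constants (4 x 4 spatial bins of width `3 * sigma`, 8 orientation bins,
#'   0.2 normalization clip).
#' @return Object of class `sift_params`.
#' @export
sift_params <- function(n_scales = 3L, sigma0 = 1.6, init_sigma = 0.5,
                        contrast_thresh = 0.04 / n_scales, edge_thresh = 10,
                        max_octaves = 4L, ori_bins = 36L,
                        ori_sigma_factor = 1.5, ori_peak_ratio = 0.8,
                        desc_width = 4L, desc_ori_bins = 8L,
                        desc_bin_scale = 3, desc_clip = 0.2) {
  structure(list(n_scales = as.integer(n_scales), sigma0 = sigma0,
                 init_sigma = init_sigma, contrast_thresh = contrast_thresh,
                 edge_thresh = edge_thresh, max_octaves = as.integer(max_octaves),
                 ori_bins = as.integer(ori_bins),
                 ori_sigma_factor = ori_sigma_factor,
                 ori_peak_ratio = ori_peak_ratio,
                 desc_width = as.integer(desc_width),
                 desc_ori_bins = as.integer(desc_ori_bins),
                 desc_bin_scale = desc_bin_scale, desc_clip = desc_clip),
            class = "sift_params")
}

empty_sift <- function() {
  structure(list(
    keypoints = data.frame(x = numeric(0), y = numeric(0),
                           scale = numeric(0), orientation = numeric(0)),
    descriptors = matrix(0, 0L, 128L)), class = "sift_descriptors")
}

#' Detect SIFT keypoints and descriptors
#'
#' Full SIFT pipeline on one plane: Gaussian scale-space pyramid,
#' difference-of-Gaussians extrema with subpixel refinement, low-contrast and
#' edge-response rejection, orientation assignment (multiple peaks allowed)
#' and 128-dimensional unit-normalized descriptors. Deterministic for a fixed
#' input; a constant plane yields an empty set.
#'
#' @param lowpass Matrix in `[0, 1]` (typically a low-pass subband).
#' @param params A [sift_params()].
#' @return Object of class `sift_descriptors`: `keypoints` data frame
#'   (`x`, `y` subpixel image coordinates with `x` along columns, `scale`,
#'   `orientation` in radians) and a matching `descriptors` matrix (one row
#'   per keypoint, 128 columns).
#' @export
detect_sift <- function(lowpass, params = sift_params()) {
  assert_matrix_image(lowpass, "lowpass plane")
  if (diff(range(lowpass)) < 1e-12) return(empty_sift())
  h <- nrow(lowpass); w <- ncol(lowpass)
  n_oct <- max(1L, min(params$max_octaves,
                       floor(log2(min(h, w) / 32)) + 1L))
  s <- params$n_scales
  k <- 2^(1 / s)
  sig <- params$sigma0 * k^(0:(s + 2L))

  base <- lowpass
  d0 <- sqrt(max(params$sigma0^2 - params$init_sigma^2, 0.01))
  base <- gaussian_blur(base, d0)

  kps <- list(); descs <- list()
  for (o in seq_len(n_oct)) {
    gauss <- vector("list", s + 3L)
    gauss[[1]] <- base
    for (i in 2:(s + 3L)) {
      inc <- sqrt(sig[i]^2 - sig[i - 1L]^2)
      gauss[[i]] <- gaussian_blur(gauss[[i - 1L]], inc)
    }
    dog <- lapply(1:(s + 2L), function(i) gauss[[i + 1L]] - gauss[[i]])
    grads <- lapply(gauss, image_gradients)
    found <- octave_keypoints(dog, params)
    if (nrow(found) > 0L) {
      res <- describe_keypoints(found, gauss, grads, sig, o, params)
      kps[[o]] <- res$keypoints
      descs[[o]] <- res$descriptors
    }
    # next octave: scale-2*sigma0 image subsampled by 2
    nxt <- gauss[[s + 1L]][seq(1L, nrow(base), by = 2L),
                           seq(1L, ncol(base), by = 2L), drop = FALSE]
    base <- nxt
  }
  if (length(kps) == 0L) return(empty_sift())
  keypoints <- do.call(rbind, kps)
  descriptors <- do.call(rbind, descs)
  if (is.null(keypoints) || nrow(keypoints) == 0L) return(empty_sift())
  # clip to the image domain
  keep <- keypoints$x >= 0 & keypoints$x < w & keypoints$y >= 0 & keypoints$y < h
  structure(list(keypoints = keypoints[keep, , drop = FALSE],
                 descriptors = descriptors[keep, , drop = FALSE]),
            class = "sift_descriptors")
}

image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
  ri <- 2:(h + 1L); ci <- 2:(w + 1L)
  gx <- (pad[ri, ci + 1L] - pad[ri, ci - 1L]) / 2
  gy <- (pad[ri + 1L, ci] - pad[ri - 1L, ci]) / 2
  list(mag = sqrt(gx^2 + gy^2), ang = atan2(gy, gx))
}

# Integer-located scale-space extrema of one octave with subpixel refinement
# and contrast/edge rejection. Returns a data frame in octave coordinates.
octave_keypoints <- function(dog, params) {
  h <- nrow(dog[[1]]); w <- ncol(dog[[1]])
  out <- list()
  pre_thresh <- 0.8 * params$contrast_thresh
  for (i in 2:(length(dog) - 1L)) {
    centre <- dog[[i]][2:(h - 1L), 2:(w - 1L)]
    strong <- abs(centre) > pre_thresh
    if (!any(strong)) next
    is_max <- strong & centre > 0
    is_min <- strong & centre < 0
    for (ds in -1:1) {
      plane <- dog[[i + ds]]
      for (di in -1:1) {
        for (dj in -1:1) {
          if (ds == 0L && di == 0L && dj == 0L) next
          nb <- plane[(2 + di):(h - 1L + di), (2 + dj):(w - 1L + dj)]
          is_max <- is_max & centre > nb
          is_min <- is_min & centre < nb
          if (!any(is_max) && !any(is_min)) break
        }
      }
    }
    cand <- which(is_max | is_min, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    for (r in seq_len(nrow(cand))) {
      iy <- cand[r, 1L] + 1L; ix <- cand[r, 2L] + 1L
      ref <- refine_extremum(dog, i, iy, ix, params)
      if (!is.null(ref)) out[[length(out) + 1L]] <- ref
    }
  }
  if (length(out) == 0L) {
    return(data.frame(y = numeric(0), x = numeric(0), scale_idx = numeric(0)))
  }
  do.call(rbind, out)
}

# Quadratic (Newton) refinement of one extremum; up to 3 relocations.
refine_extremum <- function(dog, i, iy, ix, params) {
  h <- nrow(dog[[1]]); w <- ncol(dog[[1]])
  for (iter in 1:3) {
    d <- dog[[i]]
    dm <- dog[[i - 1L]]; dp <- dog[[i + 1L]]
    g <- c((d[iy, ix + 1L] - d[iy, ix - 1L]) / 2,
           (d[iy + 1L, ix] - d[iy - 1L, ix]) / 2,
           (dp[iy, ix] - dm[iy, ix]) / 2)
    dxx <- d[iy, ix + 1L] + d[iy, ix - 1L] - 2 * d[iy, ix]
    dyy <- d[iy + 1L, ix] + d[iy - 1L, ix] - 2 * d[iy, ix]
    dss <- dp[iy, ix] + dm[iy, ix] - 2 * d[iy, ix]
    dxy <- (d[iy + 1L, ix + 1L] - d[iy + 1L, ix - 1L] -
            d[iy - 1L, ix + 1L] + d[iy - 1L, ix - 1L]) / 4
    dxs <- (dp[iy, ix + 1L] - dp[iy, ix - 1L] -
            dm[iy, ix + 1L] + dm[iy, ix - 1L]) / 4
    dys <- (dp[iy + 1L, ix] - dp[iy - 1L, ix] -
            dm[iy + 1L, ix] + dm[iy - 1L, ix]) / 4
    hess <- matrix(c(dxx, dxy, dxs,
                     dxy, dyy, dys,
                     dxs, dys, dss), 3L, 3L)
    off <- tryCatch(-solve(hess, g), error = function(e) NULL)
    if (is.null(off) || any(!is.finite(off))) return(NULL)
    if (all(abs(off) <= 0.5)) {
      val <- d[iy, ix] + 0.5 * sum(g * off)
      if (abs(val) < params$contrast_thresh) return(NULL)
      # edge response on the spatial 2x2 Hessian
      tr <- dxx + dyy; det <- dxx * dyy - dxy^2
      et <- params$edge_thresh
      if (det <= 0 || tr^2 / det >= (et + 1)^2 / et) return(NULL)
      return(data.frame(y = iy + off[2L], x = ix + off[1L],
                        scale_idx = i + off[3L]))
    }
    ix <- ix + as.integer(round(max(min(off[1L], 1), -1)))
    iy <- iy + as.integer(round(max(min(off[2L], 1), -1)))
    i <- i + as.integer(round(max(min(off[3L], 1), -1)))
    if (i < 2L || i > length(dog) - 1L ||
        iy < 2L || iy > h - 1L || ix < 2L || ix > w - 1L) return(NULL)
  }
  NULL
}

# Orientation assignment + descriptor extraction for one octave's keypoints.
describe_keypoints <- function(found, gauss, grads, sig, octave, params) {
  kp_rows <- list(); desc_rows <- list()
  fac <- 2^(octave - 1L)
  h <- nrow(gauss[[1]]); w <- ncol(gauss[[1]])
  for (r in seq_len(nrow(found))) {
    si <- max(1L, min(length(gauss), as.integer(round(found$scale_idx[r]))))
    sigma_oct <- params$sigma0 * 2^((found$scale_idx[r] - 1) / params$n_scales)
    gr <- grads[[si]]
    oris <- assign_orientations(gr, found$y[r], found$x[r], sigma_oct, params)
    for (th in oris) {
      v <- sift_descriptor(gr, found$y[r], found$x[r], sigma_oct, th, params)
      if (is.null(v)) next
      kp_rows[[length(kp_rows) + 1L]] <- data.frame(
        x = (found$x[r] - 1) * fac,
        y = (found$y[r] - 1) * fac,
        scale = sigma_oct * fac,
        orientation = th)
      desc_rows[[length(desc_rows) + 1L]] <- v
    }
  }
  if (length(kp_rows) == 0L) {
    return(list(keypoints = NULL, descriptors = NULL))
  }
  list(keypoints = do.call(rbind, kp_rows),
       descriptors = do.call(rbind, desc_rows))
}

assign_orientations <- function(gr, y, x, sigma_oct, params) {
  h <- nrow(gr$mag); w <- ncol(gr$mag)
  sw <- params$ori_sigma_factor * sigma_oct
  rad <- max(2L, as.integer(ceiling(3 * sw)))
  cy <- as.integer(round(y)); cx <- as.integer(round(x))
  ri <- max(1L, cy - rad):min(h, cy + rad)
  ci <- max(1L, cx - rad):min(w, cx + rad)
  dy <- ri - y; dx <- ci - x
  wgt <- exp(-outer(dy^2, dx^2, "+") / (2 * sw^2))
  m <- gr$mag[ri, ci] * wgt
  a <- gr$ang[ri, ci] %% (2 * pi)
  nb <- params$ori_bins
  bin <- (as.integer(floor(a / (2 * pi) * nb)) %% nb) + 1L
  hist <- numeric(nb)
  agg <- tapply(as.vector(m), bin, sum)
  hist[as.integer(names(agg))] <- agg
  for (pass in 1:2) {
    hist <- (hist + c(hist[-1], hist[1]) + c(hist[nb], hist[-nb])) / 3
  }
  peak <- max(hist)
  if (peak <= 0) return(numeric(0))
  out <- numeric(0)
  for (b in seq_len(nb)) {
    l <- hist[if (b == 1L) nb else b - 1L]
    rr <- hist[if (b == nb) 1L else b + 1L]
    if (hist[b] >= params$ori_peak_ratio * peak && hist[b] > l && hist[b] > rr) {
      denom <- l - 2 * hist[b] + rr
      dbin <- if (abs(denom) > 1e-12) 0.5 * (l - rr) / denom else 0
      out <- c(out, ((b - 1 + dbin + 0.5) / nb * 2 * pi) %% (2 * pi))
    }
  }
  out
}

# 4x4x8 gradient histogram descriptor, trilinear interpolation, unit norm with
# 0.2 clipping.
sift_descriptor <- function(gr, y, x, sigma_oct, theta, params) {
  d <- params$desc_width; nb <- params$desc_ori_bins
  binw <- params$desc_bin_scale * sigma_oct
  radius <- as.integer(ceiling(binw * sqrt(2) * (d + 1) / 2))
  h <- nrow(gr$mag); w <- ncol(gr$mag)
  cy <- as.integer(round(y)); cx <- as.integer(round(x))
  ri <- max(1L, cy - radius):min(h, cy + radius)
  ci <- max(1L, cx - radius):min(w, cx + radius)
  if (length(ri) < 4L || length(ci) < 4L) return(NULL)
  dy <- matrix(ri - y, length(ri), length(ci))
  dx <- matrix(ci - x, length(ri), length(ci), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  u <- (ct * dx + st * dy) / binw          # rotated row coord in bin units
  v <- (-st * dx + ct * dy) / binw
  ubin <- u + d / 2 - 0.5
  vbin <- v + d / 2 - 0.5
  ang <- (gr$ang[ri, ci] - theta) %% (2 * pi)
  obin <- ang / (2 * pi) * nb
  wgt <- gr$mag[ri, ci] * exp(-(u^2 + v^2) / (2 * (d / 2)^2))

  keep <- ubin > -1 & ubin < d & vbin > -1 & vbin < d
  if (!any(keep)) return(NULL)
  ub <- ubin[keep]; vb <- vbin[keep]; ob <- obin[keep]; wk <- wgt[keep]
  u0 <- floor(ub); v0 <- floor(vb); o0 <- floor(ob)
  fu <- ub - u0; fv <- vb - v0; fo <- ob - o0
  acc <- numeric(d * d * nb)
  for (du in 0:1) {
    uu <- u0 + du
    wu <- if (du == 0) 1 - fu else fu
    ok_u <- uu >= 0 & uu < d
    for (dv in 0:1) {
      vv <- v0 + dv
      wv <- if (dv == 0) 1 - fv else fv
      ok <- ok_u & vv >= 0 & vv < d
      if (!any(ok)) next
      for (do_ in 0:1) {
        oo <- (o0 + do_) %% nb
        wo <- if (do_ == 0) 1 - fo else fo
        idx <- (uu[ok] * d + vv[ok]) * nb + oo[ok] + 1
        contrib <- wk[ok] * wu[ok] * wv[ok] * wo[ok]
        acc_part <- tapply(contrib, idx, sum)
        ii <- as.integer(names(acc_part))
        acc[ii] <- acc[ii] + acc_part
      }
    }
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-12) return(NULL)
  acc <- pmin(acc / nrm, params$desc_clip)
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-12) return(NULL)
  acc / nrm
}
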