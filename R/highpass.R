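#' Guided filter parameters
#'
#' @param r Local window radius in pixels (default 8).
#' @param eps Ridge regularization of the per-window linear regression
#'   (default 0.1).
#' @return Object of class `guided_filter_params`.
#' @export
guided_filter_params <- function(r = 8L, eps = 0.1) {
  r <- as.integer(r)
  if (r < 1L) stop_invalid("guided filter radius must be >= 1")
  if (eps <= 0) stop_invalid("guided filter eps must be > 0")
  structure(list(r = r, eps = eps), class = "guided_filter_params")
}

#' Edge-preserving guided filter
#'
#' Standard guided image filter: in every `(2r+1) x (2r+1)` window the input
#' is regressed linearly on the guide with ridge `eps`; the per-window
#' coefficients are then averaged over all windows covering each pixel and the
#' output is `mean(a) * guide + mean(b)`. Windows are truncated at the image
#' border (means divide by the in-image pixel count), which matches a direct
#' per-window implementation exactly.
#'
#' @param guide Guidance image (matrix).
#' @param input_map Input to be filtered (matrix, same shape).
#' @param params A [guided_filter_params()].
#' @return Filtered matrix.
#' @export
guided_filter <- function(guide, input_map, params = guided_filter_params()) {
  assert_matrix_image(guide, "guide")
  assert_matrix_image(input_map, "input_map")
  assert_same_shape(guide, input_map, "guide and input")
  r <- params$r
  n <- boxcount(dim(guide), r)
  mean_i <- boxsum(guide, r) / n
  mean_p <- boxsum(input_map, r) / n
  corr_ip <- boxsum(guide * input_map, r) / n
  corr_ii <- boxsum(guide * guide, r) / n
  var_i <- corr_ii - mean_i^2
  cov_ip <- corr_ip - mean_i * mean_p
  a <- cov_ip / (var_i + params$eps)
  b <- mean_p - a * mean_i
  mean_a <- boxsum(a, r) / n
  mean_b <- boxsum(b, r) / n
  mean_a * guide + mean_b
}

#' Sliding-window score map over a pair of high-pass planes
#'
#' Extracts every `patch_size x patch_size` window at the given stride from
#' both planes, affinely normalizes each window pair to `[0, 1]` with their
#' joint min/max (the network was trained on `[0, 1]` intensity patches while
#' subband coefficients are signed), and scores each pair with the siamese
#' network. Scores near 1 mean the window's feature is carried by `a_h`.
#'
#' @param model Trained `sist_cnn`.
#' @param a_h,b_h Same-shape planes.
#' @param stride Window stride in pixels (default 2).
#' @return Object of class `score_map`: list with `values` (score grid),
#'   `origins_y`, `origins_x`, `stride`, `patch_size`, `shape`.
#' @export
compute_score_map <- function(model, a_h, b_h, stride = 2L) {
  assert_matrix_image(a_h, "a_h"); assert_matrix_image(b_h, "b_h")
  assert_same_shape(a_h, b_h, "high-pass planes")
  ps <- model$config$patch_size
  d <- dim(a_h)
  if (d[1] < ps || d[2] < ps) {
    stop_invalid("plane smaller than the ", ps, "x", ps, " scoring patch")
  }
  stride <- as.integer(stride)
  oy <- seq.int(1L, d[1] - ps + 1L, by = stride)
  ox <- seq.int(1L, d[2] - ps + 1L, by = stride)
  n <- length(oy) * length(ox)

  pa <- extract_patches(a_h, oy, ox, ps)
  pb <- extract_patches(b_h, oy, ox, ps)
  # joint per-pair affine normalization to [0, 1]
  lo <- pmin(apply_rows_min(pa), apply_rows_min(pb))
  hi <- pmax(apply_rows_max(pa), apply_rows_max(pb))
  scale <- hi - lo
  scale[scale == 0] <- 1
  pa <- (pa - lo) / scale
  pb <- (pb - lo) / scale
  dim(pa) <- c(n, ps, ps); dim(pb) <- c(n, ps, ps)
  sc <- predict_scores(model, pa, pb)
  structure(list(values = matrix(sc, length(oy), length(ox)),
                 origins_y = oy, origins_x = ox,
                 stride = stride, patch_size = ps, shape = d),
            class = "score_map")
}

# Stack of patches as an (n, ps*ps) matrix; rows ordered with origin-y fastest
# to match matrix(sc, length(oy), length(ox)).
extract_patches <- function(img, oy, ox, ps) {
  n <- length(oy) * length(ox)
  out <- matrix(0, n, ps * ps)
  col <- 1L
  for (dj in seq_len(ps) - 1L) {
    for (di in seq_len(ps) - 1L) {
      out[, col] <- img[outer(oy + di, ox + dj, function(i, j) i + (j - 1L) * nrow(img))]
      col <- col + 1L
    }
  }
  out
}

apply_rows_min <- function(m) as.numeric(do.call(pmin, asplit(m, 2L)))
apply_rows_max <- function(m) as.numeric(do.call(pmax, asplit(m, 2L)))

#' Expand a score map into a per-pixel feature map
#'
#' Each pixel of the feature map `M` is the arithmetic mean of the scores of
#' every sliding window covering it. Border pixels not covered by any window
#' (possible when `stride > 1`) take the value of the nearest covered pixel.
#'
#' @param score_map A `score_map` from [compute_score_map()].
#' @param shape Optional `(H, W)`; defaults to the map's recorded shape.
#' @return Matrix `H x W` with values in `[0, 1]`.
#' @export
score_to_feature_map <- function(score_map, shape = score_map$shape) {
  if (!inherits(score_map, "score_map")) stop_invalid("need a score_map")
  h <- shape[1]; w <- shape[2]
  ps <- score_map$patch_size
  oy <- score_map$origins_y; ox <- score_map$origins_x
  if (max(oy) + ps - 1L > h || max(ox) + ps - 1L > w) {
    stop_invalid("score map geometry inconsistent with requested shape")
  }
  s_img <- matrix(0, h, w); c_img <- matrix(0, h, w)
  # a window with origin o covers pixels o..o+ps-1, so the windows covering
  # pixel x are those with origins in [x-ps+1, x]: exactly the trailing
  # ps-window sum that cover_sum computes over origin-indexed impulses
  s_img[oy, ox] <- score_map$values
  c_img[oy, ox] <- 1
  sums <- cover_sum(s_img, ps)
  counts <- cover_sum(c_img, ps)
  m <- matrix(0, h, w)
  covered <- counts > 0
  m[covered] <- sums[covered] / counts[covered]
  if (!all(covered)) m <- fill_nearest(m, covered)
  pmin(pmax(m, 0), 1)
}

# Fill uncovered pixels with the nearest covered value (row-wise then
# column-wise nearest; uncovered regions are border bands).
fill_nearest <- function(m, covered) {
  h <- nrow(m); w <- ncol(m)
  for (j in seq_len(w)) {
    ci <- which(covered[, j])
    if (length(ci) == 0L) next
    mi <- which(!covered[, j])
    nearest <- ci[pmax(1L, findInterval(mi, ci))]
    # findInterval gives the last covered index <= mi; compare with next
    nxt <- ci[pmin(length(ci), findInterval(mi, ci) + 1L)]
    use_next <- abs(nxt - mi) < abs(nearest - mi)
    nearest[use_next] <- nxt[use_next]
    m[mi, j] <- m[nearest, j]
    covered[mi, j] <- TRUE
  }
  for (i in seq_len(h)) {
    ci <- which(covered[i, ])
    if (length(ci) == 0L || length(ci) == w) next
    mi <- which(!covered[i, ])
    pos <- pmax(1L, findInterval(mi, ci))
    nearest <- ci[pos]
    nxt <- ci[pmin(length(ci), pos + 1L)]
    use_next <- abs(nxt - mi) < abs(nearest - mi)
    nearest[use_next] <- nxt[use_next]
    m[i, mi] <- m[i, nearest]
  }
  m
}

#' Threshold a feature map into a binary map
#'
#' `T(x, y) = 1` iff `M(x, y) > tau` (strict inequality), else 0. The default
#' threshold 0.5 works well for medical pairs; 0.4-0.7 is the suggested range
#' for other multi-modal imagery.
#'
#' @param m Feature map matrix in `[0, 1]`.
#' @param tau Threshold in `(0, 1)` (default 0.5).
#' @return Binary matrix of 0/1.
#' @export
binarize <- function(m, tau = 0.5) {
  assert_matrix_image(m, "feature map")
  if (!is.finite(tau) || tau <= 0 || tau >= 1) {
    stop_invalid("tau must lie strictly inside (0, 1)")
  }
  (m > tau) * 1
}

#' Consistency verification of a binary map
#'
#' Refines the binary segmentation into a soft decision map by edge-preserving
#' guided filtering (guide = the corresponding source plane), clamped to
#' `[0, 1]`. This removes isolated misclassified pixels while following true
#' edges, replacing the traditional small-region-removal step.
#'
#' @param t Binary map matrix.
#' @param guide Guidance plane (same shape).
#' @param params A [guided_filter_params()].
#' @return Decision map matrix in `[0, 1]`.
#' @export
refine_decision <- function(t, guide, params = guided_filter_params()) {
  clamp01(guided_filter(guide, t, params))
}

#' Pixel-weighted high-pass fusion
#'
#' `F_H(x, y) = D(x, y) A_H(x, y) + (1 - D(x, y)) B_H(x, y)`: an exact
#' per-pixel convex combination of the two subbands driven by the decision
#' map.
#'
#' @param a_h,b_h Same-shape subband planes.
#' @param d Decision map in `[0, 1]`.
#' @return Fused plane.
#' @export
fuse_highpass <- function(a_h, b_h, d) {
  assert_same_shape(a_h, b_h, "subband planes")
  assert_same_shape(a_h, d, "subband planes and decision map")
  if (min(d) < 0 || max(d) > 1) stop_invalid("decision map must lie in [0, 1]")
  d * a_h + (1 - d) * b_h
}

# Full high-pass rule over two pyramids: one decision map per level computed
# from the aggregate (root-sum-square) directional energy, applied to every
# direction of that level.
fuse_highpass_pyramids <- function(pyr_a, pyr_b, model, stride = 2L,
                                   tau = 0.5, gf = guided_filter_params()) {
  levels <- pyr_a$config$levels
  fused <- vector("list", levels)
  decisions <- vector("list", levels)
  for (j in seq_len(levels)) {
    ea <- sqrt(Reduce(`+`, lapply(pyr_a$highpass[[j]], function(p) p^2)))
    eb <- sqrt(Reduce(`+`, lapply(pyr_b$highpass[[j]], function(p) p^2)))
    sm <- compute_score_map(model, ea, eb, stride = stride)
    m <- score_to_feature_map(sm)
    t <- binarize(m, tau)
    d <- refine_decision(t, (ea + eb) / 2, gf)
    decisions[[j]] <- d
    fused[[j]] <- mapply(function(pa, pb) fuse_highpass(pa, pb, d),
                         pyr_a$highpass[[j]], pyr_b$highpass[[j]],
                         SIMPLIFY = FALSE)
  }
  list(highpass = fused, decisions = decisions)
}
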