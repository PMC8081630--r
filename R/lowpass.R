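#' Match SIFT descriptors between two sets
#'
#' For each descriptor `i` of `set1`, the Euclidean distances to every
#' descriptor of `set2` are computed and sorted; the nearest neighbour `j` is
#' the match candidate. Two acceptance criteria are available:
#'
#' * `"ratio"` (default): Lowe's ratio test - accepted iff the nearest
#'   distance is below `ratio` times the second-nearest distance.
#' * `"second_largest"`: accepted iff the nearest distance is strictly below the
#'   second-largest of all sorted distances for that query. This literal
#'   second-largest criterion accepts nearly every query when `set2` is
#'   large; it is kept selectable for fidelity, but the ratio test is the
#'   default.
#'
#' Queries with fewer than two candidates produce no match (the criteria are
#' undefined there).
#'
#' @param set1,set2 `sift_descriptors` objects or plain descriptor matrices
#'   (rows = descriptors).
#' @param mode `"ratio"` or `"second_largest"`.
#' @param ratio Ratio-test threshold (default 0.75).
#' @return Data frame with columns `i`, `j`, `distance`.
#' @export
match_descriptors <- function(set1, set2, mode = c("ratio", "second_largest"),
                              ratio = 0.75) {
  mode <- match.arg(mode)
  d1 <- descriptor_matrix(set1); d2 <- descriptor_matrix(set2)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (nrow(d1) == 0L || nrow(d2) < 2L) return(empty)
  # pairwise Euclidean distances via the Gram matrix
  n1 <- rowSums(d1^2); n2 <- rowSums(d2^2)
  dist2 <- outer(n1, n2, "+") - 2 * tcrossprod(d1, d2)
  dist2[dist2 < 0] <- 0
  dist <- sqrt(dist2)
  out <- vector("list", nrow(d1))
  for (i in seq_len(nrow(d1))) {
    di <- dist[i, ]
    j <- which.min(di)
    nearest <- di[j]
    accepted <- if (mode == "second_largest") {
      # an identical descriptor (zero distance) always matches; otherwise the
      # literal second-largest criterion (which with exactly two candidates
      # compares the nearest distance against itself and so never fires)
      second_largest <- sort(di, decreasing = TRUE)[2L]
      nearest == 0 || nearest < second_largest
    } else {
      second_nearest <- sort(di, partial = 2L)[2L]
      nearest < ratio * second_nearest
    }
    if (accepted) {
      out[[i]] <- data.frame(i = i, j = j, distance = nearest)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty else res
}

descriptor_matrix <- function(x) {
  if (inherits(x, "sift_descriptors")) x$descriptors
  else if (is.matrix(x)) x
  else stop_invalid("expected a sift_descriptors object or a matrix")
}

keypoint_frame <- function(x) {
  if (!inherits(x, "sift_descriptors")) {
    stop_invalid("keypoint coordinates require sift_descriptors objects")
  }
  x$keypoints
}

#' Keep only colocated matches
#'
#' A matched descriptor pair is colocated when its two keypoints occupy the
#' same position: Euclidean distance at most `tol_px` pixels (boundary
#' inclusive). Matched-and-colocated regions carry the same content at the
#' same place in both low-pass subbands.
#'
#' @param matches Data frame from [match_descriptors()].
#' @param set1,set2 The `sift_descriptors` the match indices refer to.
#' @param tol_px Colocation tolerance in pixels (default 2; exact equality of
#'   subpixel coordinates would never fire).
#' @return The matches data frame with a `colocated` column, filtered to the
#'   colocated rows.
#' @export
filter_colocated <- function(matches, set1, set2, tol_px = 2) {
  if (tol_px < 0) stop_invalid("tol_px must be >= 0")
  k1 <- keypoint_frame(set1); k2 <- keypoint_frame(set2)
  if (nrow(matches) == 0L) {
    return(cbind(matches, colocated = logical(0)))
  }
  dx <- k1$x[matches$i] - k2$x[matches$j]
  dy <- k1$y[matches$i] - k2$y[matches$j]
  matches$colocated <- sqrt(dx^2 + dy^2) <= tol_px
  matches[matches$colocated, , drop = FALSE]
}

#' Rasterize colocated matches into a dense matching-degree map
#'
#' Starts from an all-zero map; for every surviving match a disk of radius
#' `support_radius_mult * scale` around the `set1` keypoint is set to 1 (the
#' descriptor support of a SIFT keypoint spans roughly six times its scale).
#' The result is binary, the union of all match disks.
#'
#' @param matches Filtered matches (data frame with column `i`).
#' @param set1 `sift_descriptors` of the first low-pass subband.
#' @param shape `(H, W)` of the low-pass planes.
#' @param support_radius_mult Disk radius per unit keypoint scale (default 6).
#' @return Binary `H x W` matrix.
#' @export
build_match_map <- function(matches, set1, shape, support_radius_mult = 6) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  map <- matrix(0, h, w)
  if (nrow(matches) == 0L) return(map)
  k1 <- keypoint_frame(set1)
  for (row in seq_len(nrow(matches))) {
    kp <- k1[matches$i[row], ]
    rad <- support_radius_mult * kp$scale
    cy <- kp$y + 1; cx <- kp$x + 1   # keypoints are 0-indexed coordinates
    ri <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
    ci <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
    d2 <- outer((ri - cy)^2, (ci - cx)^2, "+")
    sub <- map[ri, ci, drop = FALSE]
    sub[d2 <= rad^2] <- 1
    map[ri, ci] <- sub
  }
  map
}

#' Matching-degree low-pass fusion
#'
#' `F_L(x, y) = match_map(x, y) A_L(x, y) + (1 - match_map(x, y)) B_L(x, y)`:
#' the first subband is selected where content is matched and colocated, the
#' second elsewhere (the complement weighting reading of the matching-degree
#' combination).
#'
#' @param a_l,b_l Low-pass subband planes.
#' @param match_map Binary matrix from [build_match_map()].
#' @return Fused low-pass plane.
#' @export
fuse_lowpass <- function(a_l, b_l, match_map) {
  assert_same_shape(a_l, b_l, "low-pass planes")
  assert_same_shape(a_l, match_map, "low-pass planes and match map")
  if (!all(match_map %in% c(0, 1))) {
    stop_invalid("match_map must be binary")
  }
  match_map * a_l + (1 - match_map) * b_l
}

# Full low-pass rule: normalize the two planes with one joint affine map,
# detect SIFT on both, match, keep colocated matches, rasterize, fuse.
fuse_lowpass_planes <- function(a_l, b_l, match_mode = "ratio", tol_px = 2,
                                support_radius_mult = 6,
                                fallback = c("b", "mean"),
                                sift = sift_params()) {
  fallback <- match.arg(fallback)
  lo <- min(a_l, b_l); hi <- max(a_l, b_l)
  scale <- if (hi > lo) hi - lo else 1
  s1 <- detect_sift((a_l - lo) / scale, sift)
  s2 <- detect_sift((b_l - lo) / scale, sift)
  if (nrow(s1$keypoints) == 0L || nrow(s2$keypoints) == 0L) {
    warning("no SIFT descriptors on at least one low-pass subband; ",
            if (fallback == "mean") "falling back to per-pixel averaging"
            else "selecting the second subband everywhere")
    if (fallback == "mean") {
      return(list(fused = (a_l + b_l) / 2, match_map = matrix(0, nrow(a_l), ncol(a_l)),
                  n_matches = 0L))
    }
    return(list(fused = b_l, match_map = matrix(0, nrow(a_l), ncol(a_l)),
                n_matches = 0L))
  }
  m0 <- match_descriptors(s1, s2, mode = match_mode)
  m <- filter_colocated(m0, s1, s2, tol_px = tol_px)
  mm <- build_match_map(m, s1, dim(a_l), support_radius_mult)
  kp <- s1$keypoints
  kp$matched <- seq_len(nrow(kp)) %in% m0$i
  kp$colocated <- seq_len(nrow(kp)) %in% m$i
  list(fused = fuse_lowpass(a_l, b_l, mm), match_map = mm,
       n_matches = nrow(m), keypoints = kp)
}
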