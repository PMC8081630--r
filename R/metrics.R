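#' Objective fusion quality metrics
#'
#' Four standard objective measurements of a fused image against its two
#' sources: standard deviation (contrast), Shannon entropy (information
#' content), fusion mutual information `I(A;F) + I(B;F)` (information
#' transferred from the sources) and the Xydeas-Petrovic edge-preservation
#' measure `Q^AB/F`. Inputs are matrices in `[0, 1]`; SD, entropy and MI are
#' reported on the 8-bit intensity scale (values 0..255, histograms with 256
#' bins).
#'
#' @name metrics
NULL

as_8bit <- function(img) {
  assert_matrix_image(img)
  round(pmin(pmax(img, 0), 1) * 255)
}

#' Standard deviation of an image
#'
#' Population standard deviation of pixel intensities on the 8-bit scale.
#'
#' @param img Matrix in `[0, 1]`.
#' @return Nonnegative scalar.
#' @export
std_dev <- function(img) {
  assert_matrix_image(img)
  if (length(img) == 0L) stop_invalid("empty image")
  v <- as.vector(img) * 255
  sqrt(mean((v - mean(v))^2))
}

#' Shannon entropy of an image in bits
#'
#' Entropy of the `n_bins`-bin intensity histogram, with `0 log 0 := 0`.
#' Bounded by `log2(n_bins)` (8 bits for the default 256 bins).
#'
#' @param img Matrix in `[0, 1]`.
#' @param n_bins Number of histogram bins (default 256).
#' @return Entropy in bits.
#' @export
img_entropy <- function(img, n_bins = 256L) {
  assert_matrix_image(img)
  if (length(img) == 0L) stop_invalid("empty image")
  # quantization matches as_8bit at the default 256 bins, so entropy and the
  # mutual-information terms share one discretization
  lv <- round(pmin(pmax(img, 0), 1) * (n_bins - 1L))
  p <- tabulate(as.integer(lv) + 1L, nbins = n_bins) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Mutual information between two 8-bit images from the 256x256 joint
# histogram, in bits.
mi_pair <- function(x, y) {
  n <- length(x)
  joint <- tabulate(as.integer(x) * 256L + as.integer(y) + 1L,
                    nbins = 256L * 256L) / n
  dim(joint) <- c(256L, 256L)
  px <- colSums(joint)  # marginal over x index (first factor varies slowly)
  py <- rowSums(joint)
  # joint[i, j] = P(y = i-1, x = j-1)
  outer_p <- outer(py, px)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Fusion mutual information
#'
#' `MI = I(A; F) + I(B; F)`, each term computed from the 256 x 256 joint
#' intensity histogram of the 8-bit quantized images.
#'
#' @param a,b Source images in `[0, 1]`.
#' @param f Fused image in `[0, 1]`.
#' @return Mutual information in bits (nonnegative).
#' @export
mutual_information_fusion <- function(a, b, f) {
  assert_same_shape(a, f, "source and fused images")
  assert_same_shape(b, f, "source and fused images")
  qa <- as_8bit(a); qb <- as_8bit(b); qf <- as_8bit(f)
  mi_pair(qa, qf) + mi_pair(qb, qf)
}

#' Parameters of the Q^AB/F edge-preservation measure
#'
#' The sigmoid constants of the Xydeas-Petrovic model for edge-strength and
#' orientation preservation. `normalize = TRUE` rescales both preservation
#' factors by their value at perfect preservation (strength ratio 1,
#' orientation difference 0), so that a fused image identical to both sources
#' scores exactly 1.
#'
#' @param gamma_g,kappa_g,sigma_g Strength-preservation sigmoid constants.
#' @param gamma_a,kappa_a,sigma_a Orientation-preservation sigmoid constants.
#' @param L Exponent of the edge-strength importance weights.
#' @param normalize Scale so perfect preservation scores 1 (default TRUE).
#' @return List of constants.
#' @export
qabf_params <- function(gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                        gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8,
                        L = 1, normalize = TRUE) {
  list(gamma_g = gamma_g, kappa_g = kappa_g, sigma_g = sigma_g,
       gamma_a = gamma_a, kappa_a = kappa_a, sigma_a = sigma_a,
       L = L, normalize = normalize)
}

# Sobel gradients with circular borders (consistent with the package's
# periodic boundary convention, making the measure exactly invariant to joint
# circular shifts); returns strength g and orientation alpha in [0, pi)
# (gradient orientation is only defined modulo pi here).
sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(h, seq_len(h), 1L), c(w, seq_len(w), 1L)]
  ri <- 2:(h + 1L); ci <- 2:(w + 1L)
  gx <- (pad[ri - 1L, ci + 1L] + 2 * pad[ri, ci + 1L] + pad[ri + 1L, ci + 1L]) -
        (pad[ri - 1L, ci - 1L] + 2 * pad[ri, ci - 1L] + pad[ri + 1L, ci - 1L])
  gy <- (pad[ri + 1L, ci - 1L] + 2 * pad[ri + 1L, ci] + pad[ri + 1L, ci + 1L]) -
        (pad[ri - 1L, ci - 1L] + 2 * pad[ri - 1L, ci] + pad[ri - 1L, ci + 1L])
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan2(gy, gx) %% pi
  alpha[g == 0] <- 0
  list(g = g, alpha = alpha)
}

sigmoid_pres <- function(x, gamma, kappa, sigma) {
  gamma / (1 + exp(kappa * (x - sigma)))
}

#' Q^AB/F edge information preservation measure
#'
#' Edge strength and orientation are estimated per pixel with the Sobel
#' operator. For each source, a strength-preservation factor (sigmoid of the
#' min/max gradient ratio) and an orientation-preservation factor (sigmoid of
#' the orientation agreement, differences wrapped modulo pi) are multiplied
#' into a per-pixel preservation estimate, then averaged over both sources
#' weighted by source edge strength.
#'
#' @param a,b Source images in `[0, 1]`.
#' @param f Fused image in `[0, 1]`.
#' @param params Constants from [qabf_params()].
#' @return Scalar in `[0, 1]`. If both sources have zero gradient everywhere
#'   the measure is defined as 0 (with a warning).
#' @export
q_abf <- function(a, b, f, params = qabf_params()) {
  assert_same_shape(a, f, "source and fused images")
  assert_same_shape(b, f, "source and fused images")
  ga <- sobel_gradients(a); gb <- sobel_gradients(b); gf <- sobel_gradients(f)
  qaf <- edge_preservation(ga, gf, params)
  qbf <- edge_preservation(gb, gf, params)
  wa <- ga$g^params$L; wb <- gb$g^params$L
  denom <- sum(wa + wb)
  if (denom == 0) {
    warning("both sources have zero gradient everywhere; Q^AB/F defined as 0")
    return(0)
  }
  sum(qaf * wa + qbf * wb) / denom
}

edge_preservation <- function(gs, gf, params) {
  # strength ratio min/max in [0,1]; both-zero pixels treated as preserved
  # (their weight is zero anyway)
  hi <- pmax(gs$g, gf$g)
  ratio <- ifelse(hi > 0, pmin(gs$g, gf$g) / pmax(hi, .Machine$double.xmin), 1)
  dalpha <- abs(gs$alpha - gf$alpha)
  dalpha <- pmin(dalpha, pi - dalpha)          # orientation is modulo pi
  aa <- 1 - dalpha / (pi / 2)
  qg <- sigmoid_pres(ratio, params$gamma_g, params$kappa_g, params$sigma_g)
  qa <- sigmoid_pres(aa, params$gamma_a, params$kappa_a, params$sigma_a)
  q <- qg * qa
  if (isTRUE(params$normalize)) {
    q <- q / (sigmoid_pres(1, params$gamma_g, params$kappa_g, params$sigma_g) *
              sigmoid_pres(1, params$gamma_a, params$kappa_a, params$sigma_a))
  }
  q
}

#' Quality report for a fused image
#'
#' Computes all four objective measurements for one fused result against its
#' two sources.
#'
#' @param a,b Source images in `[0, 1]` (luma for color inputs).
#' @param f Fused image in `[0, 1]`.
#' @param params Constants for [q_abf()].
#' @return Object of class `quality_report`: list with `sd`, `en`, `mi`,
#'   `q_abf`.
#' @export
quality_report <- function(a, b, f, params = qabf_params()) {
  structure(list(sd = std_dev(f), en = img_entropy(f),
                 mi = mutual_information_fusion(a, b, f),
                 q_abf = q_abf(a, b, f, params)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("Fusion quality: SD = %.2f  En = %.3f bits  MI = %.3f bits  Q^AB/F = %.4f\n",
              x$sd, x$en, x$mi, x$q_abf))
  invisible(x)
}
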