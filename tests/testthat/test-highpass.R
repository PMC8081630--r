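# High-pass fusion chain: score map, feature map, threshold, guided filter,
# decision refinement and the pixel-weighted combination.

# Independent brute-force guided filter: explicit per-window regression, then
# averaging the coefficients of every window covering each pixel.
guided_filter_oracle <- function(guide, input, r, eps) {
  h <- nrow(guide); w <- ncol(guide)
  a_acc <- matrix(0, h, w); b_acc <- matrix(0, h, w); n_acc <- matrix(0, h, w)
  for (ci in seq_len(h)) {
    for (cj in seq_len(w)) {
      ri <- max(1, ci - r):min(h, ci + r)
      rj <- max(1, cj - r):min(w, cj + r)
      gi <- guide[ri, rj]; pi_ <- input[ri, rj]
      mg <- mean(gi); mp <- mean(pi_)
      a <- (mean(gi * pi_) - mg * mp) / (mean(gi^2) - mg^2 + eps)
      b <- mp - a * mg
      a_acc[ri, rj] <- a_acc[ri, rj] + a
      b_acc[ri, rj] <- b_acc[ri, rj] + b
      n_acc[ri, rj] <- n_acc[ri, rj] + 1
    }
  }
  (a_acc / n_acc) * guide + b_acc / n_acc
}

test_that("guided filter matches the brute-force per-window oracle", {
  set.seed(31)
  for (r in c(2L, 3L, 4L)) {
    guide <- matrix(runif(32 * 32), 32, 32)
    input <- matrix(runif(32 * 32), 32, 32)
    got <- guided_filter(guide, input, guided_filter_params(r = r, eps = 0.1))
    want <- guided_filter_oracle(guide, input, r, 0.1)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("guided filter limits: constant input and huge regularization", {
  set.seed(8)
  guide <- matrix(runif(32 * 32), 32, 32)
  const <- matrix(0.42, 32, 32)
  out <- guided_filter(guide, const, guided_filter_params(r = 4, eps = 0.1))
  expect_lt(max(abs(out - 0.42)), 1e-10)
  # eps >> var(guide): a -> 0, b -> window mean, output -> double box mean
  input <- matrix(runif(32 * 32), 32, 32)
  out <- guided_filter(guide, input, guided_filter_params(r = 3, eps = 1e6))
  n <- sistfuse:::boxcount(dim(input), 3L)
  dbl <- sistfuse:::boxsum(sistfuse:::boxsum(input, 3L) / n, 3L) / n
  expect_lt(max(abs(out - dbl)), 1e-4)
  expect_error(guided_filter(guide, matrix(0, 16, 16)), "dimensions")
  expect_error(guided_filter_params(r = 0), ">= 1")
  expect_error(guided_filter_params(eps = 0), "> 0")
})

test_that("score map geometry and the identical-input fence", {
  model <- test_model()
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  sm <- compute_score_map(model, img, img, stride = 2)
  expect_identical(dim(sm$values), c(25L, 25L))  # (64-16)/2 + 1
  expect_true(all(abs(sm$values - 0.5) < 1e-12))
  expect_error(compute_score_map(model, img, matrix(0, 32, 32)), "dimensions")
  expect_error(compute_score_map(model, matrix(0, 8, 8), matrix(0, 8, 8)),
               "smaller")
})

test_that("score map separates a sharp-left/sharp-right pair", {
  model <- test_model()
  cb <- make_complementary_blur_pair(phantom_spec(size = c(128, 128), seed = 6))
  sm <- compute_score_map(model, cb$a, cb$b, stride = 4)
  half <- ncol(sm$values) %/% 2
  left <- mean(sm$values[, 1:half])
  right <- mean(sm$values[, (half + 1):ncol(sm$values)])
  expect_gt(left, right)
})

test_that("feature map averages the scores of all covering windows", {
  # single window: every pixel takes its score
  sm <- structure(list(values = matrix(0.7, 1, 1), origins_y = 1L,
                       origins_x = 1L, stride = 1L, patch_size = 16L,
                       shape = c(16L, 16L)), class = "score_map")
  m <- score_to_feature_map(sm)
  expect_true(all(m == 0.7))
  # two windows overlapping by 8 columns with scores 0.2 / 0.8
  sm2 <- structure(list(values = matrix(c(0.2, 0.8), 1, 2), origins_y = 1L,
                        origins_x = c(1L, 9L), stride = 8L, patch_size = 16L,
                        shape = c(16L, 24L)), class = "score_map")
  m2 <- score_to_feature_map(sm2)
  expect_true(all(abs(m2[, 1:8] - 0.2) < 1e-12))
  expect_true(all(abs(m2[, 9:16] - 0.5) < 1e-12))
  expect_true(all(abs(m2[, 17:24] - 0.8) < 1e-12))
  # constant score map stays constant through the expansion
  model <- test_model()
  img <- matrix(0.3, 32, 32)
  smc <- compute_score_map(model, img, img, stride = 2)
  expect_true(all(abs(score_to_feature_map(smc) - 0.5) < 1e-12))
  expect_error(score_to_feature_map(sm2, shape = c(10L, 10L)), "inconsistent")
})

test_that("feature map covers border pixels when the stride skips them", {
  model <- test_model()
  set.seed(12)
  a <- matrix(runif(37 * 41), 37, 41)   # (37-16) not divisible by 3
  b <- matrix(runif(37 * 41), 37, 41)
  sm <- compute_score_map(model, a, b, stride = 3)
  m <- score_to_feature_map(sm, shape = c(37L, 41L))
  expect_true(all(is.finite(m)))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("binarization is a strict threshold", {
  m <- matrix(c(0.6, 0.5, 0.4999, 0.0), 2, 2)
  t <- binarize(m, 0.5)
  expect_identical(as.vector(t), c(1, 0, 0, 0))
  expect_true(all(binarize(matrix(0, 4, 4)) == 0))
  expect_error(binarize(m, 0), "inside")
  expect_error(binarize(m, 1.2), "inside")
})

test_that("decision refinement keeps endpoints and softens boundaries", {
  guide <- matrix(0.5, 32, 32)
  ones <- matrix(1, 32, 32)
  zeros <- matrix(0, 32, 32)
  p <- guided_filter_params(r = 4, eps = 0.1)
  expect_lt(max(abs(refine_decision(ones, guide, p) - 1)), 1e-10)
  expect_lt(max(abs(refine_decision(zeros, guide, p))), 1e-10)
  checker <- outer(1:32, 1:32, function(i, j) (i + j) %% 2)
  d <- refine_decision(checker, guide, p)
  expect_true(all(d >= 0 & d <= 1))
  interior <- d[8:24, 8:24]
  expect_true(all(interior > 0 & interior < 1))
})

test_that("pixel-weighted fusion is an exact convex combination", {
  set.seed(19)
  a <- matrix(rnorm(32 * 32), 32, 32)
  b <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(fuse_highpass(a, b, matrix(1, 32, 32)), a)
  expect_identical(fuse_highpass(a, b, matrix(0, 32, 32)), b)
  f <- fuse_highpass(matrix(2, 4, 4), matrix(4, 4, 4), matrix(0.5, 4, 4))
  expect_true(all(f == 3))
  d <- matrix(runif(32 * 32), 32, 32)
  f <- fuse_highpass(a, b, d)
  expect_true(all(f >= pmin(a, b) - 1e-12 & f <= pmax(a, b) + 1e-12))
  # swapping the inputs and complementing the map changes nothing
  expect_lt(max(abs(fuse_highpass(b, a, 1 - d) - f)), 1e-12)
  # identical subbands are a fixed point for any decision map
  expect_lt(max(abs(fuse_highpass(a, a, d) - a)), 1e-12)
  expect_error(fuse_highpass(a, b, d * 2), "\\[0, 1\\]")
})
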