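# SIFT detection, descriptor matching, colocation filtering, match-map
# rasterization and the low-pass combination.

test_that("SIFT on degenerate and duplicated planes", {
  expect_identical(nrow(detect_sift(matrix(0.5, 64, 64))$keypoints), 0L)
  sp <- make_shifted_pair(phantom_spec(size = c(128, 128),
                                       scenario = "shifted_pair", seed = 2))
  s1 <- detect_sift(sp$image)
  s2 <- detect_sift(sp$image)
  expect_identical(s1, s2)
  expect_gte(nrow(s1$keypoints), 10L)
  # descriptors are unit-normalized, nonnegative, 128-dimensional
  expect_identical(ncol(s1$descriptors), 128L)
  expect_true(all(s1$descriptors >= 0))
  expect_lt(max(abs(sqrt(rowSums(s1$descriptors^2)) - 1)), 1e-6)
  # keypoints stay inside the image domain
  expect_true(all(s1$keypoints$x >= 0 & s1$keypoints$x < 128))
  expect_true(all(s1$keypoints$y >= 0 & s1$keypoints$y < 128))
})

test_that("matched keypoints track a known translation", {
  sp <- make_shifted_pair(phantom_spec(scenario = "shifted_pair", seed = 4,
                                       shift = c(10L, 10L)))
  s1 <- detect_sift(sp$image)
  s2 <- detect_sift(sp$shifted)
  m <- match_descriptors(s1, s2, mode = "ratio")
  expect_gt(nrow(m), 5L)
  dy <- s2$keypoints$y[m$j] - s1$keypoints$y[m$i]
  dx <- s2$keypoints$x[m$j] - s1$keypoints$x[m$i]
  good <- abs(dy - 10) <= 1 & abs(dx - 10) <= 1
  expect_gte(mean(good), 0.8)
  # colocation filtering at tol 2 removes nearly every shifted match
  surv <- filter_colocated(m, s1, s2, tol_px = 2)
  expect_gte(1 - nrow(surv) / nrow(m), 0.9)
})

test_that("matching criteria behave as specified on constructed sets", {
  q <- matrix(0, 1, 4); q[1, 1] <- 1                      # unit basis vector
  dup <- q
  decoy <- matrix(0, 1, 4); decoy[1, 2] <- 1              # orthogonal
  set2 <- rbind(dup, decoy)
  for (mode in c("ratio", "second_largest")) {
    m <- match_descriptors(q, set2, mode = mode)
    expect_identical(m$j, 1L)
    expect_equal(m$distance, 0)
  }
  # distances {0.3, 0.5, 0.9}: criterion compares 0.3 < 0.5 (second largest)
  base <- diag(4)[1, , drop = FALSE]
  mk <- function(d) {
    # unit vector at Euclidean distance d from e1: |e1 - v|^2 = 2 - 2 v1
    v1 <- 1 - d^2 / 2
    matrix(c(v1, sqrt(1 - v1^2), 0, 0), 1, 4)
  }
  set2 <- rbind(mk(0.3), mk(0.5), mk(0.9))
  m <- match_descriptors(base, set2, mode = "second_largest")
  expect_identical(nrow(m), 1L)
  expect_equal(m$distance, 0.3, tolerance = 1e-9)
  # distances {0.5, 0.52, 0.9}: ratio test fails since 0.5 >= 0.75 * 0.52
  set2 <- rbind(mk(0.5), mk(0.52), mk(0.9))
  expect_identical(nrow(match_descriptors(base, set2, mode = "ratio")), 0L)
  # fewer than two candidates: criterion undefined, no match
  expect_identical(nrow(match_descriptors(base, mk(0.1), mode = "ratio")), 0L)
})

test_that("colocation tolerance boundary is inclusive", {
  fake_set <- function(x, y) {
    structure(list(keypoints = data.frame(x = x, y = y, scale = 1,
                                          orientation = 0),
                   descriptors = matrix(1, length(x), 128) / sqrt(128)),
              class = "sift_descriptors")
  }
  m <- data.frame(i = 1L, j = 1L, distance = 0)
  expect_identical(nrow(filter_colocated(m, fake_set(5, 5), fake_set(5, 5), 2)), 1L)
  expect_identical(nrow(filter_colocated(m, fake_set(0, 0), fake_set(10, 0), 2)), 0L)
  expect_identical(nrow(filter_colocated(m, fake_set(0, 0), fake_set(2, 0), 2)), 1L)
  expect_error(filter_colocated(m, fake_set(0, 0), fake_set(0, 0), -1), ">= 0")
})

test_that("match map rasterizes disks around surviving matches", {
  shape <- c(64L, 64L)
  empty <- build_match_map(data.frame(i = integer(0)), NULL, shape)
  expect_true(all(empty == 0))
  centre_set <- structure(
    list(keypoints = data.frame(x = 31, y = 31, scale = 1, orientation = 0),
         descriptors = matrix(1, 1, 128) / sqrt(128)),
    class = "sift_descriptors")
  m <- data.frame(i = 1L, j = 1L, distance = 0)
  map <- build_match_map(m, centre_set, shape, support_radius_mult = 5)
  # brute-force disk membership oracle (keypoint is 0-indexed at (31, 31))
  oracle <- outer(seq_len(64) - 32, seq_len(64) - 32,
                  function(r, c) (r^2 + c^2 <= 25) * 1)
  expect_identical(map, oracle)
  # two disjoint matches: union of both disks
  two_set <- structure(
    list(keypoints = data.frame(x = c(9, 49), y = c(9, 49), scale = c(1, 1),
                                orientation = 0),
         descriptors = matrix(1, 2, 128) / sqrt(128)),
    class = "sift_descriptors")
  m2 <- data.frame(i = c(1L, 2L), j = c(1L, 2L), distance = 0)
  map2 <- build_match_map(m2, two_set, shape, support_radius_mult = 3)
  expect_identical(sort(unique(as.vector(map2))), c(0, 1))
  expect_identical(map2[10, 10], 1)
  expect_identical(map2[50, 50], 1)
  expect_identical(map2[30, 30], 0)
})

test_that("low-pass combination selects by the match map", {
  set.seed(23)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_identical(fuse_lowpass(a, b, matrix(1, 32, 32)), a)
  expect_identical(fuse_lowpass(a, b, matrix(0, 32, 32)), b)
  mm <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
  f <- fuse_lowpass(a, b, mm)
  expect_true(all(f >= pmin(a, b) & f <= pmax(a, b)))
  expect_identical(fuse_lowpass(a, a, mm), a)
  expect_error(fuse_lowpass(a, b, mm * 0.5), "binary")
  expect_error(fuse_lowpass(a, matrix(0, 16, 16), mm), "dimensions")
})

test_that("the full low-pass rule is deterministic and self-consistent", {
  cb <- make_complementary_blur_pair(phantom_spec(size = c(128, 128), seed = 9))
  pyr <- sist_decompose(cb$a, sist_config(levels = 2, directions = c(8, 8)))
  pyr_b <- sist_decompose(cb$b, sist_config(levels = 2, directions = c(8, 8)))
  r1 <- sistfuse:::fuse_lowpass_planes(pyr$lowpass, pyr_b$lowpass)
  r2 <- sistfuse:::fuse_lowpass_planes(pyr$lowpass, pyr_b$lowpass)
  expect_identical(r1, r2)
  # fusing a plane with itself returns it exactly
  rs <- sistfuse:::fuse_lowpass_planes(pyr$lowpass, pyr$lowpass)
  expect_identical(rs$fused, pyr$lowpass)
})
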