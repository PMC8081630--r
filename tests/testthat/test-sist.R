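# Shift-invariant shearlet transform: filter construction, pyramid,
# decomposition and exact inversion.

test_that("shearing filter windows tile the frequency plane", {
  for (nd in c(2L, 8L, 16L)) {
    ws <- build_shearing_filters(c(64L, 64L), nd)
    expect_length(ws, nd)
    s2 <- Reduce(`+`, lapply(ws, function(w) w * w))
    expect_lt(max(abs(s2 - 1)), 1e-6)
    expect_true(all(vapply(ws, function(w) all(w >= 0), logical(1))))
  }
})

test_that("two-direction windows are mirror images under 90-degree rotation", {
  n <- 64L
  ws <- build_shearing_filters(c(n, n), 2L)
  fu <- sistfuse:::fft_freqs(n)
  idx <- function(f) ((f %% n) + 1L)
  rot <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # W2(u, v) must equal W1 evaluated at the rotated frequency (v, -u)
    rot[i, ] <- ws[[1]][cbind(idx(fu), rep(idx(-fu[i]), n))]
  }
  expect_lt(max(abs(ws[[2]] - rot)), 1e-12)
})

test_that("invalid filter configurations are rejected", {
  expect_error(build_shearing_filters(c(64L, 64L), 3L), "power of two")
  expect_error(build_shearing_filters(c(16L, 16L), 4L), "small")
  expect_error(build_shearing_filters(c(64L, 64L), 128L), "small")
  expect_error(sist_config(directions = c(32, 32, 16)), "per level")
  expect_error(sist_config(pyramid_filter = "haar"), "unknown")
  expect_error(nsp_decompose(matrix(0, 32, 32), 2, "boxcar"), "unknown")
})

test_that("non-subsampled pyramid is additive and kills constants", {
  const <- matrix(0.37, 64, 64)
  p <- nsp_decompose(const, 3)
  expect_lt(max(abs(p$lowpass - 0.37)), 1e-8)
  for (g in p$highpass) expect_lt(max(abs(g)), 1e-8)

  set.seed(11)
  x <- matrix(rnorm(64 * 64), 64, 64)
  p <- nsp_decompose(x, 4)
  recon <- p$lowpass + Reduce(`+`, p$highpass)
  expect_lt(max(abs(recon - x)), 1e-8)
  expect_true(all(vapply(p$highpass, function(g) all(dim(g) == c(64, 64)),
                         logical(1))))
})

test_that("pyramid subbands are exactly shift-invariant", {
  set.seed(3)
  x <- matrix(rnorm(64 * 64), 64, 64)
  cs <- sistfuse:::circshift
  p1 <- nsp_decompose(x, 3)
  p2 <- nsp_decompose(cs(x, c(5, 3)), 3)
  expect_lt(max(abs(p2$lowpass - cs(p1$lowpass, c(5, 3)))), 1e-8)
  for (j in 1:3) {
    expect_lt(max(abs(p2$highpass[[j]] - cs(p1$highpass[[j]], c(5, 3)))), 1e-8)
  }
})

test_that("default decomposition yields 4 levels with 32/32/16/16 directions", {
  set.seed(9)
  img <- matrix(runif(256 * 256), 256, 256)
  pyr <- sist_decompose(img, sist_config())
  expect_length(pyr$highpass, 4L)
  expect_identical(vapply(pyr$highpass, length, integer(1)),
                   c(32L, 32L, 16L, 16L))
  expect_true(all(vapply(pyr$highpass[[1]],
                         function(p) identical(dim(p), c(256L, 256L)),
                         logical(1))))
})

test_that("directional planes of a level sum to the pyramid high-pass plane", {
  set.seed(5)
  x <- matrix(rnorm(64 * 64), 64, 64)
  cfg <- sist_config(levels = 2, directions = c(8, 4))
  pyr <- sist_decompose(x, cfg)
  nsp <- nsp_decompose(x, 2)
  for (j in 1:2) {
    expect_lt(max(abs(Reduce(`+`, pyr$highpass[[j]]) - nsp$highpass[[j]])), 1e-6)
  }
  # constant image: every directional plane vanishes
  pyr0 <- sist_decompose(matrix(0.5, 64, 64), cfg)
  for (j in 1:2) {
    for (p in pyr0$highpass[[j]]) expect_lt(max(abs(p)), 1e-8)
  }
})

test_that("round trip reconstructs exactly at several sizes", {
  for (n in c(64L, 128L, 256L)) {
    set.seed(n)
    x <- matrix(rnorm(n * n), n, n)
    cfg <- if (n >= 128) sist_config() else sist_config(levels = 3,
                                                        directions = c(8, 8, 4))
    pyr <- sist_decompose(x, cfg)
    expect_lt(max(abs(sist_reconstruct(pyr) - x)), 1e-6)
  }
  # all-zeros input round trips to all zeros
  z <- matrix(0, 64, 64)
  pyr <- sist_decompose(z, sist_config(levels = 2, directions = c(4, 4)))
  expect_true(all(sist_reconstruct(pyr) == 0))
})

test_that("zeroing the high-pass planes reconstructs the low-pass plane", {
  set.seed(2)
  x <- matrix(rnorm(64 * 64), 64, 64)
  cfg <- sist_config(levels = 2, directions = c(8, 4))
  pyr <- sist_decompose(x, cfg)
  pyr$highpass <- lapply(pyr$highpass, function(lv) {
    lapply(lv, function(p) p * 0)
  })
  expect_lt(max(abs(sist_reconstruct(pyr) - pyr$lowpass)), 1e-8)
})

test_that("decomposition is linear and shift-invariant plane by plane", {
  set.seed(7)
  x <- matrix(rnorm(64 * 64), 64, 64)
  y <- matrix(rnorm(64 * 64), 64, 64)
  cfg <- sist_config(levels = 2, directions = c(8, 4))
  pa <- sist_decompose(2 * x - 3 * y, cfg)
  px <- sist_decompose(x, cfg)
  py <- sist_decompose(y, cfg)
  expect_lt(max(abs(pa$lowpass - (2 * px$lowpass - 3 * py$lowpass))), 1e-8)
  for (j in 1:2) for (k in seq_along(pa$highpass[[j]])) {
    expect_lt(max(abs(pa$highpass[[j]][[k]] -
                        (2 * px$highpass[[j]][[k]] - 3 * py$highpass[[j]][[k]]))),
              1e-8)
  }
  cs <- sistfuse:::circshift
  ps <- sist_decompose(cs(x, c(5, 3)), cfg)
  for (j in 1:2) for (k in seq_along(ps$highpass[[j]])) {
    expect_lt(max(abs(ps$highpass[[j]][[k]] -
                        cs(px$highpass[[j]][[k]], c(5, 3)))), 1e-8)
  }
})

test_that("impulse subbands translate with a circularly shifted impulse", {
  imp <- matrix(0, 64, 64); imp[20, 30] <- 1
  cs <- sistfuse:::circshift
  p1 <- nsp_decompose(imp, 3)
  p2 <- nsp_decompose(cs(imp, c(5, 3)), 3)
  for (j in 1:3) {
    expect_lt(max(abs(p2$highpass[[j]] - cs(p1$highpass[[j]], c(5, 3)))), 1e-8)
  }
})

test_that("pyramid serialization round trips", {
  set.seed(13)
  x <- matrix(rnorm(64 * 64), 64, 64)
  cfg <- sist_config(levels = 2, directions = c(4, 4))
  pyr <- sist_decompose(x, cfg)
  path <- tempfile(fileext = ".rds")
  save_pyramid(pyr, path)
  back <- load_pyramid(path)
  expect_equal(back$lowpass, pyr$lowpass)
  expect_equal(back$highpass[[2]][[3]], pyr$highpass[[2]][[3]])
  unlink(path)
})

test_that("structural mismatches are rejected at reconstruction", {
  set.seed(1)
  x <- matrix(rnorm(64 * 64), 64, 64)
  pyr <- sist_decompose(x, sist_config(levels = 2, directions = c(4, 4)))
  expect_error(sist_reconstruct(pyr, sist_config(levels = 3,
                                                 directions = c(4, 4, 4))),
               "levels")
  pyr$highpass[[1]] <- pyr$highpass[[1]][1:3]
  expect_error(sist_reconstruct(pyr), "directional planes")
  expect_error(sist_decompose(matrix(0, 60, 64)), "powers of two")
})
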