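#' Configuration of the siamese scoring network
#'
#' A small two-branch convolutional network that scores which of two 16 x 16
#' patches carries the salient feature. Each branch has three 3 x 3
#' convolution layers (stride 1, valid padding, ReLU) followed by one 2 x 2
#' max-pooling layer with span 2. The two branch feature vectors are combined
#' antisymmetrically: the head maps the difference `f_A - f_B` through a
#' bias-free linear layer and a sigmoid, so `score(A, B) + score(B, A) = 1`
#' exactly and identical patches score exactly 0.5.
#'
#' @param patch_size Input block side (default 16).
#' @param kernel_size Convolution kernel side (default 3).
#' @param conv_stride Convolution stride (default 1).
#' @param pool_size,pool_stride Max-pooling window and span (default 2, 2).
#' @param channels Feature channels of the three conv layers
#'   (default `c(16, 32, 64)`).
#' @param seed Integer seed for parameter initialization.
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(patch_size = 16L, kernel_size = 3L, conv_stride = 1L,
                       pool_size = 2L, pool_stride = 2L,
                       channels = c(16L, 32L, 64L), seed = 1L,
                       learning_rate = 1e-3, batch_size = 64L) {
  cfg <- list(patch_size = as.integer(patch_size),
              kernel_size = as.integer(kernel_size),
              conv_stride = as.integer(conv_stride),
              pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              channels = as.integer(channels),
              seed = as.integer(seed),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size))
  if (cfg$conv_stride != 1L) stop_invalid("only conv_stride 1 is supported")
  side <- cfg$patch_size - length(cfg$channels) * (cfg$kernel_size - 1L)
  if (side < cfg$pool_size) {
    stop_invalid("patch_size incompatible with conv/pool arithmetic")
  }
  if ((side - cfg$pool_size) %% cfg$pool_stride != 0L) {
    stop_invalid("patch_size incompatible with pooling arithmetic: ",
                 "post-conv side ", side, " does not pool evenly")
  }
  structure(cfg, class = "cnn_config")
}

#' Build an untrained scoring model
#'
#' He-normal parameter initialization, deterministic in `config$seed`. The
#' convolutional branch parameters are shared between the two inputs (a
#' siamese pair of identical branches).
#'
#' @param config A [cnn_config()].
#' @return Object of class `sist_cnn` with `params`, `config` and `meta`.
#' @export
build_model <- function(config = cnn_config()) {
  k2 <- config$kernel_size^2
  ch <- c(1L, config$channels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- list()
  for (l in seq_along(config$channels)) {
    fan_in <- k2 * ch[l]
    params[[paste0("W", l)]] <- matrix(
      stats::rnorm(fan_in * ch[l + 1L], sd = sqrt(2 / fan_in)),
      fan_in, ch[l + 1L])
    params[[paste0("b", l)]] <- rep(0, ch[l + 1L])
  }
  side <- config$patch_size - length(config$channels) * (config$kernel_size - 1L)
  pooled <- (side - config$pool_size) %/% config$pool_stride + 1L
  n_feat <- pooled^2 * utils::tail(config$channels, 1L)
  params$w_head <- stats::rnorm(n_feat, sd = sqrt(1 / n_feat))
  structure(list(params = params, config = config,
                 meta = list(trained = FALSE, epochs = 0L,
                             heldout_accuracy = NA_real_, seed = config$seed)),
            class = "sist_cnn")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- activation plumbing ------------------------------------------------
# Activations are flat matrices (N, H*W*C) with column layout
# i + (j-1)*H + (c-1)*H*W (column-major spatial planes per channel).
# Convolutions gather their receptive fields through precomputed column
# indices, so everything reduces to indexed copies plus one BLAS multiply.

# Gather-index matrix (P x k^2*C) for a valid k x k convolution on an H x W x C
# activation; column order is offset-major (di fastest, then dj), channel
# within offset, matching the weight row layout.
make_conv_idx <- function(h, w, cin, k) {
  ho <- h - k + 1L; wo <- w - k + 1L
  p0 <- as.vector(outer(seq_len(ho), (seq_len(wo) - 1L) * h, "+"))  # offset (0,0)
  cols <- matrix(0L, ho * wo, k * k * cin)
  o <- 0L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      base <- p0 + di + dj * h
      for (cc in 0:(cin - 1L)) {
        cols[, o * cin + cc + 1L] <- base + cc * h * w
      }
      o <- o + 1L
    }
  }
  list(cols = cols, ho = ho, wo = wo, p = ho * wo, k2 = k * k, cin = cin)
}

conv_forward <- function(x, geom, W, b) {
  n <- nrow(x)
  m <- x[, as.vector(geom$cols), drop = FALSE]
  dim(m) <- c(n * geom$p, geom$k2 * geom$cin)
  y <- m %*% W
  for (cc in seq_along(b)) y[, cc] <- y[, cc] + b[cc]
  dim(y) <- c(n, geom$p * length(b))
  list(y = y, col = m)
}

conv_backward <- function(dy, cache, geom, W, in_cols) {
  nn <- nrow(dy)
  cout <- ncol(W)
  dim(dy) <- c(nn * geom$p, cout)
  dW <- crossprod(cache$col, dy)
  db <- colSums(dy)
  dm <- dy %*% t(W)                       # (n*P, K)
  dim(dm) <- c(nn, geom$p * geom$k2 * geom$cin)
  dx <- matrix(0, nn, in_cols)
  for (o in seq_len(geom$k2)) {
    kcols <- ((o - 1L) * geom$cin + 1L):(o * geom$cin)
    src <- as.vector(outer(seq_len(geom$p), (kcols - 1L) * geom$p, "+"))
    tgt <- as.vector(geom$cols[, kcols])
    dx[, tgt] <- dx[, tgt, drop = FALSE] + dm[, src, drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# Disjoint-window max pooling on the flat layout; offsets never overlap for
# pool size == stride, so the backward scatter is a plain masked assignment.
make_pool_idx <- function(ho, wo, cc, pool, stride) {
  po_h <- (ho - pool) %/% stride + 1L
  po_w <- (wo - pool) %/% stride + 1L
  p_in <- ho * wo
  sets <- list()
  o <- 1L
  for (dj in 0:(pool - 1L)) {
    for (di in 0:(pool - 1L)) {
      sp <- as.vector(outer(seq.int(1L + di, by = stride, length.out = po_h),
                            (seq.int(1L + dj, by = stride, length.out = po_w) - 1L) * ho,
                            "+"))
      sets[[o]] <- as.vector(outer(sp, (0:(cc - 1L)) * p_in, "+"))
      o <- o + 1L
    }
  }
  list(sets = sets, out_cols = po_h * po_w * cc)
}

maxpool_forward <- function(x, pidx) {
  y <- x[, pidx$sets[[1L]], drop = FALSE]
  arg <- matrix(1L, nrow(y), ncol(y))
  for (o in seq_along(pidx$sets)[-1L]) {
    slab <- x[, pidx$sets[[o]], drop = FALSE]
    upd <- slab > y
    y[upd] <- slab[upd]
    arg[upd] <- o
  }
  list(y = y, arg = arg, in_cols = ncol(x))
}

maxpool_backward <- function(dy, cache, pidx) {
  dx <- matrix(0, nrow(dy), cache$in_cols)
  for (o in seq_along(pidx$sets)) {
    g <- matrix(0, nrow(dy), ncol(dy))
    mask <- cache$arg == o
    g[mask] <- dy[mask]
    dx[, pidx$sets[[o]]] <- g
  }
  dx
}

# Per-layer gather geometry for a model configuration (cheap; rebuilt per
# forward call batch).
branch_geometry <- function(cfg) {
  ch <- c(1L, cfg$channels)
  h <- cfg$patch_size
  geoms <- vector("list", length(cfg$channels))
  for (l in seq_along(cfg$channels)) {
    geoms[[l]] <- make_conv_idx(h, h, ch[l], cfg$kernel_size)
    geoms[[l]]$in_cols <- h * h * ch[l]
    h <- h - cfg$kernel_size + 1L
  }
  pool <- make_pool_idx(h, h, utils::tail(cfg$channels, 1L),
                        cfg$pool_size, cfg$pool_stride)
  list(conv = geoms, pool = pool)
}

# Forward pass of one branch on a stack of patches (N, ps, ps).
# Returns features (N, n_feat); with cache = TRUE also the layer caches.
branch_forward <- function(model, patches, cache = FALSE, geom = NULL) {
  cfg <- model$config
  if (is.null(geom)) geom <- branch_geometry(cfg)
  n <- dim(patches)[1]
  x <- patches
  dim(x) <- c(n, cfg$patch_size^2)
  caches <- list()
  for (l in seq_along(cfg$channels)) {
    cf <- conv_forward(x, geom$conv[[l]], model$params[[paste0("W", l)]],
                       model$params[[paste0("b", l)]])
    relu_mask <- cf$y > 0
    x <- cf$y * relu_mask
    if (cache) caches[[l]] <- list(conv = cf, relu = relu_mask)
  }
  pf <- maxpool_forward(x, geom$pool)
  if (cache) list(feat = pf$y, caches = caches, pool = pf, geom = geom)
  else list(feat = pf$y)
}

# Backward pass through one branch; returns parameter gradients (list).
branch_backward <- function(model, dfeat, fw) {
  cfg <- model$config
  geom <- fw$geom
  dx <- maxpool_backward(dfeat, fw$pool, geom$pool)
  grads <- list()
  for (l in rev(seq_along(cfg$channels))) {
    dx <- dx * fw$caches[[l]]$relu
    cb <- conv_backward(dx, fw$caches[[l]]$conv, geom$conv[[l]],
                        model$params[[paste0("W", l)]],
                        geom$conv[[l]]$in_cols)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- cb$db
    dx <- cb$dx
  }
  grads
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Vectorized pair scoring: a, b are (N, ps, ps) stacks.
predict_scores <- function(model, a, b, batch_size = 512L) {
  n <- dim(a)[1]
  out <- numeric(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fa <- branch_forward(model, a[idx, , , drop = FALSE])$feat
    fb <- branch_forward(model, b[idx, , , drop = FALSE])$feat
    out[idx] <- sigmoid((fa - fb) %*% model$params$w_head)
  }
  out
}

#' Score one pair of patches
#'
#' Returns the feature degree of the pair: a scalar in `[0, 1]`, close to 1
#' when the salient feature is carried by `patch_a` and close to 0 when it is
#' carried by `patch_b`.
#'
#' @param model A `sist_cnn` (see [build_model()], [train_model()]).
#' @param patch_a,patch_b Numeric `patch_size x patch_size` matrices.
#' @return Scalar in `[0, 1]`.
#' @export
score_pair <- function(model, patch_a, patch_b) {
  ps <- model$config$patch_size
  if (!is.matrix(patch_a) || !identical(dim(patch_a), c(ps, ps)) ||
      !is.matrix(patch_b) || !identical(dim(patch_b), c(ps, ps))) {
    stop_invalid("patches must be ", ps, "x", ps, " matrices")
  }
  a <- array(patch_a, c(1L, ps, ps))
  b <- array(patch_b, c(1L, ps, ps))
  predict_scores(model, a, b)
}

#' Generate labeled synthetic training patch pairs
#'
#' Procedurally textured 16 x 16 patches: each pair couples a sharp patch with
#' a Gaussian-degraded copy (blur width drawn uniformly from
#' `blur_sigma_range`). Label 1 means `patch_a` is the sharp member. Classes
#' are balanced to within one pair, and the whole set is a pure function of
#' `(n, seed)`.
#'
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @param blur_sigma_range `(lo, hi)` of the degradation width in pixels.
#' @param patch_size Patch side (default 16).
#' @return List of `n` pair objects, each with `patch_a`, `patch_b`, `label`.
#' @export
make_training_pairs <- function(n, seed = 1L, blur_sigma_range = c(0.75, 3),
                                patch_size = 16L) {
  n <- as.integer(n)
  if (n < 1L) stop_invalid("n must be >= 1")
  if (blur_sigma_range[2] <= 0 || blur_sigma_range[2] < blur_sigma_range[1]) {
    stop_invalid("degenerate blur_sigma_range")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  big <- 2L * patch_size
  ctr <- (patch_size %/% 2L + 1L):(patch_size %/% 2L + patch_size)
  labels <- rep(c(1, 0), length.out = n)
  lapply(seq_len(n), function(i) {
    # textured base: band-limited noise, occasionally with a step edge
    base <- bandlimited_noise(big, big, f_lo = 0.03, f_hi = 0.35)
    if (stats::runif(1) < 0.5) {
      th <- stats::runif(1, 0, pi); off <- stats::runif(1, -3, 3)
      yy <- matrix(seq_len(big) - big / 2, big, big)
      xx <- matrix(seq_len(big) - big / 2, big, big, byrow = TRUE)
      base <- clamp01(base * 0.7 +
                        0.3 * (cos(th) * yy + sin(th) * xx > off))
    }
    sigma <- stats::runif(1, blur_sigma_range[1], blur_sigma_range[2])
    blur <- gaussian_blur(base, sigma)
    sharp <- base[ctr, ctr]; soft <- blur[ctr, ctr]
    if (labels[i] == 1) {
      list(patch_a = sharp, patch_b = soft, label = 1)
    } else {
      list(patch_a = soft, patch_b = sharp, label = 0)
    }
  })
}

pairs_to_arrays <- function(pairs, patch_size) {
  n <- length(pairs)
  a <- array(0, c(n, patch_size, patch_size))
  b <- array(0, c(n, patch_size, patch_size))
  y <- numeric(n)
  for (i in seq_len(n)) {
    a[i, , ] <- pairs[[i]]$patch_a
    b[i, , ] <- pairs[[i]]$patch_b
    y[i] <- pairs[[i]]$label
  }
  list(a = a, b = b, y = y)
}

#' Train the scoring model
#'
#' Binary cross-entropy on the pair labels, optimized with Adam; 20% of the
#' pairs are held out (seeded split) and the final held-out accuracy is stored
#' in the model metadata. Training is reproducible given the seed.
#'
#' @param model A `sist_cnn` from [build_model()].
#' @param pairs List of pair objects from [make_training_pairs()].
#' @param epochs Number of passes over the training split (default 12).
#' @param seed Integer seed for the split, shuffling and Adam.
#' @return The trained model with updated `meta`.
#' @export
train_model <- function(model, pairs, epochs = 12L, seed = 1L) {
  if (length(pairs) == 0L) stop_invalid("empty training pair list")
  if (length(pairs) < 100L && epochs > 0L) {
    stop_invalid("need at least 100 pairs to train")
  }
  cfg <- model$config
  arr <- pairs_to_arrays(pairs, cfg$patch_size)
  if (as.integer(epochs) == 0L) return(model)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(arr$y)
  n_hold <- max(1L, floor(0.2 * n))
  hold <- sample.int(n, n_hold)
  tr <- setdiff(seq_len(n), hold)

  # Adam state
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- lapply(model$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8
  step <- 0L
  lr <- cfg$learning_rate

  for (ep in seq_len(as.integer(epochs))) {
    ord <- sample(tr)
    for (start in seq.int(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      m <- length(idx)
      fa <- branch_forward(model, arr$a[idx, , , drop = FALSE], cache = TRUE)
      fb <- branch_forward(model, arr$b[idx, , , drop = FALSE], cache = TRUE)
      diff <- fa$feat - fb$feat
      p <- sigmoid(as.vector(diff %*% model$params$w_head))
      dz <- (p - arr$y[idx]) / m                       # BCE + sigmoid
      grads <- list(w_head = as.vector(crossprod(diff, dz)))
      dfeat <- outer(dz, model$params$w_head)
      ga <- branch_backward(model, dfeat, fa)
      gb <- branch_backward(model, -dfeat, fb)
      for (nm in names(ga)) grads[[nm]] <- ga[[nm]] + gb[[nm]]
      step <- step + 1L
      for (nm in names(grads)) {
        g <- grads[[nm]]
        mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
        vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
        mhat <- mstate[[nm]] / (1 - beta1^step)
        vhat <- vstate[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] -
          lr * mhat / (sqrt(vhat) + epsadam)
      }
    }
  }
  ph <- predict_scores(model, arr$a[hold, , , drop = FALSE],
                       arr$b[hold, , , drop = FALSE])
  acc <- mean((ph > 0.5) == (arr$y[hold] > 0.5))
  model$meta <- list(trained = TRUE, epochs = as.integer(epochs),
                     heldout_accuracy = acc, seed = as.integer(seed))
  model
}

#' Save / load a scoring model checkpoint
#'
#' @param model A `sist_cnn`.
#' @param path Checkpoint file path (RDS archive of named parameter arrays,
#'   config and metadata).
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_invalid("model checkpoint not found: ", path)
  structure(readRDS(path), class = "sist_cnn")
}

#' @export
print.sist_cnn <- function(x, ...) {
  cat(sprintf("Siamese scoring CNN: %d conv layers (%s channels), patch %dx%d\n",
              length(x$config$channels),
              paste(x$config$channels, collapse = "-"),
              x$config$patch_size, x$config$patch_size))
  if (isTRUE(x$meta$trained)) {
    cat(sprintf("  trained %d epochs, held-out accuracy %.3f\n",
                x$meta$epochs, x$meta$heldout_accuracy))
  } else cat("  untrained\n")
  invisible(x)
}
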