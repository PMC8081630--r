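#' Fusion pipeline configuration
#'
#' Bundles every tunable of the fusion chain with the defaults used
#' throughout: 4-level SIST with 32/32/16/16 directional subbands and maxflat
#' pyramid filters, feature-map threshold 0.5, guided filter `r = 8`,
#' `eps = 0.1`, sliding-window stride 2 and the ratio matching mode.
#'
#' @param sist A [sist_config()].
#' @param tau Feature-map threshold in `(0, 1)`.
#' @param guided A [guided_filter_params()].
#' @param stride Score-map window stride.
#' @param match_mode `"ratio"` or `"second_largest"` (see [match_descriptors()]).
#' @param coloc_tol_px Keypoint colocation tolerance in pixels.
#' @param support_radius_mult Match-map disk radius per unit keypoint scale.
#' @param lowpass_fallback `"b"` (select the second subband) or `"mean"`
#'   (per-pixel average) when either descriptor set is empty.
#' @param seed Integer seed recorded in results.
#' @return Object of class `fusion_config`.
#' @export
fusion_config <- function(sist = sist_config(), tau = 0.5,
                          guided = guided_filter_params(),
                          stride = 2L, match_mode = c("ratio", "second_largest"),
                          coloc_tol_px = 2, support_radius_mult = 6,
                          lowpass_fallback = c("b", "mean"), seed = 1L) {
  if (!is.finite(tau) || tau <= 0 || tau >= 1) {
    stop_invalid("tau must lie strictly inside (0, 1)")
  }
  structure(list(sist = sist, tau = tau, guided = guided,
                 stride = as.integer(stride),
                 match_mode = match.arg(match_mode),
                 coloc_tol_px = coloc_tol_px,
                 support_radius_mult = support_radius_mult,
                 lowpass_fallback = match.arg(lowpass_fallback),
                 seed = as.integer(seed)),
            class = "fusion_config")
}

#' Fuse a pair of co-registered grayscale images
#'
#' The complete fusion chain: both images are decomposed with the
#' shift-invariant shearlet transform; each level's high-pass subbands are
#' fused through a CNN-scored, guided-filter-refined decision map; the
#' low-pass subbands are fused through the colocated-SIFT matching-degree
#' map; the fused pyramid is inverted and clamped to `[0, 1]`. Non-dyadic
#' inputs are reflect-padded to the next power of two and cropped back after
#' reconstruction. Deterministic given the configuration and model.
#'
#' @param image_a,image_b Matrices in `[0, 1]`, identical shape,
#'   co-registered.
#' @param model A trained `sist_cnn` (or a checkpoint path).
#' @param config A [fusion_config()].
#' @return Object of class `fusion_result`: `fused` matrix, `decision_maps`
#'   (per level), `match_map`, `quality` ([quality_report()]), `details`.
#' @export
fuse_pair <- function(image_a, image_b, model, config = fusion_config()) {
  assert_matrix_image(image_a, "image_a")
  assert_matrix_image(image_b, "image_b")
  assert_same_shape(image_a, image_b, "images to fuse")
  if (is.character(model)) model <- load_model(model)
  if (!inherits(model, "sist_cnn")) stop_invalid("model must be a sist_cnn")

  d0 <- dim(image_a)
  hp <- next_pow2(d0[1]); wp <- next_pow2(d0[2])
  a <- reflect_pad(image_a, hp, wp)
  b <- reflect_pad(image_b, hp, wp)

  pyr_a <- sist_decompose(a, config$sist)
  pyr_b <- sist_decompose(b, config$sist)

  hi <- fuse_highpass_pyramids(pyr_a, pyr_b, model,
                               stride = config$stride, tau = config$tau,
                               gf = config$guided)
  lo <- fuse_lowpass_planes(pyr_a$lowpass, pyr_b$lowpass,
                            match_mode = config$match_mode,
                            tol_px = config$coloc_tol_px,
                            support_radius_mult = config$support_radius_mult,
                            fallback = config$lowpass_fallback)

  fused_pyr <- structure(list(lowpass = lo$fused, highpass = hi$highpass,
                              config = config$sist),
                         class = "shearlet_pyramid")
  fused <- clamp01(sist_reconstruct(fused_pyr))
  fused <- fused[seq_len(d0[1]), seq_len(d0[2]), drop = FALSE]

  quality <- quality_report(image_a, image_b, fused)
  structure(list(fused = fused,
                 decision_maps = hi$decisions,
                 match_map = lo$match_map,
                 quality = quality,
                 details = list(config = config,
                                model_meta = model$meta,
                                n_lowpass_matches = lo$n_matches,
                                lowpass_keypoints = lo$keypoints,
                                padded_to = c(hp, wp))),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("Fusion result: %d x %d image, %d colocated low-pass matches\n",
              nrow(x$fused), ncol(x$fused), x$details$n_lowpass_matches))
  print(x$quality)
  invisible(x)
}

# BT.601 luma/chroma conversions used for anatomical-functional color fusion.
rgb_to_ycbcr <- function(rgb) {
  y <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  cb <- (rgb[, , 3] - y) * 0.564 + 0.5
  cr <- (rgb[, , 1] - y) * 0.713 + 0.5
  list(y = y, cb = cb, cr = cr)
}

ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + (cr - 0.5) / 0.713
  b <- y + (cb - 0.5) / 0.564
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(nrow(y), ncol(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clamp01(out)
}

#' Fuse a grayscale anatomical image with a color functional image
#'
#' The color image (e.g. a PET pseudo-color map) is converted to luma/chroma;
#' its luma is fused with the grayscale source by [fuse_pair()] and the
#' chroma channels are carried over unchanged, so the functional color coding
#' survives fusion while the anatomical detail enters through the luma.
#'
#' @param gray_anatomical Matrix in `[0, 1]`.
#' @param color_functional `H x W x 3` RGB array in `[0, 1]`.
#' @param model A trained `sist_cnn` (or checkpoint path).
#' @param config A [fusion_config()].
#' @return A `fusion_result` whose `fused` is an RGB array; the grayscale
#'   luma fusion is available as `fused_luma`.
#' @export
fuse_color_pair <- function(gray_anatomical, color_functional, model,
                            config = fusion_config()) {
  if (length(dim(color_functional)) != 3L || dim(color_functional)[3] < 3L) {
    stop_invalid("color_functional must be an H x W x 3 RGB array")
  }
  ycc <- rgb_to_ycbcr(color_functional[, , 1:3, drop = FALSE])
  assert_same_shape(gray_anatomical, ycc$y, "gray and color images")
  res <- fuse_pair(gray_anatomical, ycc$y, model, config)
  rgb <- ycbcr_to_rgb(res$fused, ycc$cb, ycc$cr)
  res$fused_luma <- res$fused
  res$fused <- rgb
  res
}

#' Read and write images
#'
#' PNG and TIFF, 8- or 16-bit, 1 or 3 channels. Reading normalizes to
#' `[0, 1]` doubles (grayscale as a matrix, RGB as an `H x W x 3` array; an
#' alpha channel is dropped). Writing denormalizes to the file bit depth;
#' 8-bit data round-trips losslessly.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image`: matrix or 3-d array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_invalid("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop_invalid("cannot read PNG '", path,
                                                    "': ", conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop_invalid("cannot read TIFF '", path,
                                                     "': ", conditionMessage(e))),
    stop_invalid("unsupported image format '.", ext, "' (PNG or TIFF only)")
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1]
    else if (dim(img)[3] == 2L) img <- img[, , 1]      # gray + alpha
    else img <- img[, , 1:3, drop = FALSE]             # drop alpha if present
  }
  img
}

#' @rdname read_image
#' @param image Matrix or `H x W x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  if (any(!is.finite(image))) stop_invalid("image contains non-finite values")
  image <- clamp01(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
    stop_invalid("unsupported image format '.", ext, "' (PNG or TIFF only)")
  )
  invisible(path)
}

#' Convert an RGB array to grayscale luma
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @return Matrix in `[0, 1]`.
#' @export
rgb_to_gray <- function(rgb) {
  if (length(dim(rgb)) != 3L) stop_invalid("expected an H x W x 3 array")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}
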