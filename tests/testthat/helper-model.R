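# Shared small trained model and fixtures, built once per test run.

.sistfuse_test_cache <- new.env(parent = emptyenv())

# trained at the default desk scale (2000 pairs) so the scoring properties
# the suite asserts reflect the intended operating point
test_model <- function() {
  if (is.null(.sistfuse_test_cache$model)) {
    pairs <- make_training_pairs(2000, seed = 21)
    .sistfuse_test_cache$model <- train_model(
      build_model(cnn_config(seed = 5)), pairs, epochs = 12, seed = 9)
  }
  .sistfuse_test_cache$model
}

test_pairs <- function() {
  if (is.null(.sistfuse_test_cache$pairs)) {
    .sistfuse_test_cache$pairs <- make_training_pairs(400, seed = 33)
  }
  .sistfuse_test_cache$pairs
}

rmse <- function(x, y) sqrt(mean((x - y)^2))

# mean finite-difference gradient magnitude, a simple sharpness proxy
mean_grad <- function(img) {
  gy <- diff(img)
  gx <- t(diff(t(img)))
  (sum(abs(gy)) + sum(abs(gx))) / length(img)
}
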