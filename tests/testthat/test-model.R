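test_that("receptive field covers the 9-epoch window and matches the formula", {
  cfg <- model_config()
  rf <- receptive_field(cfg)
  # independent recursion: rf = 1 + sum (k-1) * d * jump over all convs
  k <- cfg$kernel_size
  expected <- 1 + (k - 1) * 1 + (k - 1) * 5 +
    sum(2 * (k - 1) * cfg$dilations * 25)
  expect_equal(rf, expected)
  expect_gte(rf, 6750)
  expect_error(model_config(n_blocks = 2, dilations = c(1, 2)),
               "receptive field")
})

test_that("forward outputs satisfy simplex and probability contracts", {
  m <- build_model(model_config(spatial_dropout_rate = 0), seed = 3)
  set.seed(4)
  x <- matrix(rnorm(2 * 6750), 2)
  out <- predict_window(m, x)
  expect_equal(sum(out$state_probs), 1, tolerance = 1e-5)
  expect_true(all(out$state_probs >= 0 & out$state_probs <= 1))
  expect_length(out$arousal_probs, 30)
  expect_true(all(out$arousal_probs >= 0 & out$arousal_probs <= 1))

  out2 <- predict_window(m, x)
  expect_identical(out, out2)   # eval mode is deterministic

  expect_error(predict_window(m, matrix(0, 2, 100)), "6750")
})

test_that("batches are row-independent in eval mode", {
  m <- build_model(model_config(), seed = 5)
  set.seed(6)
  x1 <- array(rnorm(2 * 6750), dim = c(2, 6750, 1))
  x2 <- array(rnorm(2 * 6750), dim = c(2, 6750, 1))
  xb <- array(c(x1, x2), dim = c(2, 6750, 2))
  f1 <- ripsleep:::nbs_forward(m, x1)
  f2 <- ripsleep:::nbs_forward(m, x2)
  fb <- ripsleep:::nbs_forward(m, xb)
  expect_equal(fb$state_logits[, 1], f1$state_logits[, 1], tolerance = 1e-10)
  expect_equal(fb$state_logits[, 2], f2$state_logits[, 1], tolerance = 1e-10)
  expect_equal(fb$ar_logits[, 2], f2$ar_logits[, 1], tolerance = 1e-10)
})

test_that("zero-weight heads give uniform states and 0.5 arousal", {
  m <- build_model(model_config(), seed = 7)
  m$params[["state.W"]][] <- 0
  m$params[["state.b"]][] <- 0
  m$params[["ar.W"]][] <- 0
  m$params[["ar.b"]] <- 0
  out <- predict_window(m, matrix(rnorm(2 * 6750), 2))
  expect_equal(unname(out$state_probs), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(out$arousal_probs, rep(0.5, 30), tolerance = 1e-12)
})

test_that("compiled convolution kernels equal the pure-R reference", {
  set.seed(8)
  for (i in 1:5) {
    ci <- sample(2:4, 1); co <- sample(2:5, 1); kk <- sample(c(3, 5, 7), 1)
    s <- sample(c(1L, 5L), 1); dl <- sample(1:4, 1)
    p <- (kk - 1) * dl %/% 2
    x <- array(rnorm(ci * 50 * 3), dim = c(ci, 50, 3))
    W <- array(rnorm(co * ci * kk), dim = c(co, ci, kk))
    b <- rnorm(co)
    f_cpp <- ripsleep:::conv1d_fwd(x, W, b, s, dl, p)
    f_ref <- ripsleep:::conv1d_fwd_ref(x, W, b, s, dl, p)
    expect_equal(f_cpp$out, f_ref$out, tolerance = 1e-12)
    dy <- array(rnorm(length(f_ref$out)), dim = dim(f_ref$out))
    b_cpp <- ripsleep:::conv1d_bwd(dy, f_cpp$cache)
    b_ref <- ripsleep:::conv1d_bwd_ref(dy, f_ref$cache)
    expect_equal(b_cpp$dx, b_ref$dx, tolerance = 1e-10)
    expect_equal(b_cpp$dW, b_ref$dW, tolerance = 1e-10)
    expect_equal(b_cpp$db, b_ref$db, tolerance = 1e-10)
  }
})

test_that("backpropagated gradients match finite differences", {
  cfg <- model_config(n_blocks = 2, kernel_size = 3, dilations = c(32, 64),
                      channels = 4, enc_channels = 3,
                      spatial_dropout_rate = 0)
  m <- build_model(cfg, seed = 2)
  set.seed(3)
  nb <- 2
  x <- array(rnorm(2 * 6750 * nb), dim = c(2, 6750, nb))
  st <- c(1L, 3L)
  ar <- matrix(rbinom(nb * 30, 1, 0.3), nb, 30)
  bl <- ripsleep:::batch_loss(m, x, st, ar, lambda = 0.7, training = TRUE)
  fd <- function(nm, i) {
    eps <- 1e-5
    m2 <- m
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    l1 <- ripsleep:::batch_loss(m2, x, st, ar, 0.7, TRUE,
                                want_grads = FALSE)$loss
    m2$params[[nm]][i] <- m2$params[[nm]][i] - 2 * eps
    l0 <- ripsleep:::batch_loss(m2, x, st, ar, 0.7, TRUE,
                                want_grads = FALSE)$loss
    (l1 - l0) / (2 * eps)
  }
  for (nm in c("enc1.W", "blk1.W1", "blk2.W2", "blk1.bn1.gamma",
               "blk2.bn2.beta", "state.W", "ar.W")) {
    i <- 1 + length(m$params[[nm]]) %/% 2
    g <- fd(nm, i)
    expect_equal(bl$grads[[nm]][i], g, tolerance = 1e-5 * max(1, abs(g)))
  }
})

test_that("lambda = 0 silences the arousal head gradients exactly", {
  cfg <- model_config(n_blocks = 2, kernel_size = 3, dilations = c(32, 64),
                      channels = 4, enc_channels = 3,
                      spatial_dropout_rate = 0)
  m <- build_model(cfg, seed = 4)
  set.seed(5)
  x <- array(rnorm(2 * 6750 * 2), dim = c(2, 6750, 2))
  bl <- ripsleep:::batch_loss(m, x, c(1L, 2L),
                              matrix(1L, 2, 30), lambda = 0, training = TRUE)
  expect_true(all(bl$grads[["ar.W"]] == 0))
  expect_equal(bl$grads[["ar.b"]], 0)
})

test_that("a small model overfits a small window pool", {
  st <- tiny_window_set(seed = 51, hours = 0.5)
  cfg <- model_config(spatial_dropout_rate = 0)
  m <- build_model(cfg, seed = 6)
  tc <- train_config(steps = 150, batch_size = 16, lr = 3e-3,
                     eval_every = 75, patience = 50, seed = 6,
                     augment = NULL)
  fit <- train_nbs(m, st$ws, st$ws, tc)
  h <- fit$history
  early <- mean(h$train_loss[1:10])
  late <- mean(tail(h$train_loss, 10))
  expect_lt(late, 0.5 * early)
  # balanced sampler engaged: positive fraction near one half
  expect_lt(abs(mean(h$pos_fraction) - 0.5), 0.05)
})

test_that("recording prediction emits matched-length tracks deterministically", {
  st <- tiny_window_set(seed = 52, hours = 1)
  m <- build_model(model_config(), seed = 9)
  pr <- predict_recording(m, st$ws)
  expect_equal(nrow(pr$hypnodensity), 120)
  expect_length(pr$arousal_probs, 3600)
  expect_true(all(abs(rowSums(as.matrix(
    pr$hypnodensity[, c("WAKE", "NREM", "REM")])) - 1) < 1e-5))
  pr2 <- predict_recording(m, st$ws)
  expect_identical(pr$arousal_probs, pr2$arousal_probs)
})

test_that("a 1-s input shift moves per-second outputs consistently", {
  st <- tiny_window_set(seed = 53, hours = 0.5)
  m <- build_model(model_config(), seed = 10)
  sig <- st$ws$signal
  w1 <- sig[, 1:6750]
  w2 <- sig[, (1 + 25):(6750 + 25)]
  a1 <- predict_window(m, w1)$arousal_probs
  a2 <- predict_window(m, w2)$arousal_probs
  # same absolute seconds: a1[2..30] vs a2[1..29]; bounded discrepancy
  expect_lt(max(abs(a1[2:30] - a2[1:29])), 0.2)
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(model_config(n_blocks = 2, kernel_size = 3,
                                dilations = c(32, 64), channels = 4,
                                enc_channels = 3), seed = 11)
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  x <- matrix(rnorm(2 * 6750), 2)
  expect_equal(predict_window(m, x), predict_window(m2, x),
               tolerance = 1e-12)
})
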