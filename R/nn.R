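# Minimal 1-D convolutional network engine.
#
# Tensors are numeric arrays (channels, time, batch). Convolutions are
# evaluated as one BLAS matrix product per kernel tap on the flattened
# (channels, time*batch) view, which keeps training fast enough for
# desk-scale models without compiled code. Backward passes are written
# by hand and verified against finite differences in the test suite.

nn_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2L * p, d[3]))
  out[, (p + 1L):(p + d[2]), ] <- x
  out
}

conv_out_len <- function(t_in, k, stride, dil, pad) {
  span <- (k - 1L) * dil + 1L
  as.integer((t_in + 2L * pad - span) %/% stride) + 1L
}

# tap index vectors into the flattened padded input, one per kernel tap
conv_tap_idx <- function(t_pad, t_out, k, stride, dil, batch) {
  offs <- (seq_len(batch) - 1L) * t_pad
  lapply(seq_len(k), function(kk) {
    v <- (0:(t_out - 1L)) * stride + (kk - 1L) * dil + 1L
    as.integer(outer(v, offs, `+`))
  })
}

conv1d_fwd <- function(x, W, b, stride, dil, pad) {
  y <- conv1d_forward_cpp(x, W, as.numeric(b), stride, dil, pad)
  list(out = y,
       cache = list(x = x, W = W, stride = stride, dil = dil, pad = pad))
}

conv1d_bwd <- function(dy, cache) {
  r <- conv1d_backward_cpp(dy, cache$x, cache$W, cache$stride, cache$dil,
                           cache$pad)
  r$db <- as.numeric(r$db)
  r
}

# Pure-R reference implementation (used as the oracle for the compiled
# kernels in the test suite).
conv1d_fwd_ref <- function(x, W, b, stride, dil, pad) {
  d <- dim(x); k <- dim(W)[3]
  xp <- nn_pad(x, pad)
  t_pad <- d[2] + 2L * pad
  t_out <- conv_out_len(d[2], k, stride, dil, pad)
  idx <- conv_tap_idx(t_pad, t_out, k, stride, dil, d[3])
  xf <- matrix(xp, nrow = d[1])
  c_out <- dim(W)[1]
  y <- matrix(0, nrow = c_out, ncol = t_out * d[3])
  for (kk in seq_len(k)) {
    y <- y + matrix(W[, , kk], nrow = c_out) %*% xf[, idx[[kk]], drop = FALSE]
  }
  y <- y + b
  list(out = array(y, dim = c(c_out, t_out, d[3])),
       cache = list(xf = xf, idx = idx, dims = d, t_pad = t_pad,
                    t_out = t_out, pad = pad, W = W))
}

conv1d_bwd_ref <- function(dy, cache) {
  d <- cache$dims; W <- cache$W
  k <- dim(W)[3]; c_out <- dim(W)[1]; c_in <- dim(W)[2]
  dyf <- matrix(dy, nrow = c_out)
  dW <- array(0, dim = dim(W))
  dxf <- matrix(0, nrow = c_in, ncol = cache$t_pad * d[3])
  for (kk in seq_len(k)) {
    xk <- cache$xf[, cache$idx[[kk]], drop = FALSE]
    dW[, , kk] <- dyf %*% t(xk)
    dxf[, cache$idx[[kk]]] <- dxf[, cache$idx[[kk]], drop = FALSE] +
      crossprod(matrix(W[, , kk], nrow = c_out), dyf)
  }
  db <- rowSums(dyf)
  dxp <- array(dxf, dim = c(c_in, cache$t_pad, d[3]))
  p <- cache$pad
  dx <- if (p > 0L) dxp[, (p + 1L):(p + d[2]), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  r <- bn_forward_cpp(matrix(x, nrow = d[1]), gamma, beta,
                      run_mean, run_var, training, momentum, eps)
  list(out = array(r$y, dim = d),
       cache = list(xhat = r$xhat, inv_sd = as.numeric(r$inv_sd),
                    gamma = gamma, dims = d, training = training),
       run_mean = as.numeric(r$run_mean), run_var = as.numeric(r$run_var))
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  r <- bn_backward_cpp(matrix(dy, nrow = d[1]), cache$xhat, cache$inv_sd,
                       cache$gamma, cache$training)
  list(dx = array(r$dx, dim = d), dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

relu_fwd <- function(x) {
  y <- relu_cpp(x)
  list(out = y, cache = y)
}
relu_bwd <- function(dy, cache) relu_grad_cpp(dy, cache)

# spatial dropout: zero whole channels per sample
sdrop_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  d <- dim(x)
  mask <- matrix(rbinom(d[1] * d[3], 1L, 1 - rate) / (1 - rate),
                 d[1], d[3])
  list(out = channel_scale_cpp(x, mask), cache = mask)
}
sdrop_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else channel_scale_cpp(dy, cache)
}

softmax_cols <- function(z) {
  z <- z - apply(z, 2, max)[col(z)]
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

adamw_step <- function(params, grads, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    # decouple weight decay: convolution/linear weights only, never
    # biases or batch-norm affine parameters
    decay <- if (grepl("\\.W[0-9]*$", nm)) opt$weight_decay else 0
    params[[nm]] <- params[[nm]] -
      opt$lr * (mhat / (sqrt(vhat) + opt$eps) + decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

adamw_init <- function(params, lr = 3e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  # moment buffers mirror each parameter's exact shape (plain vectors
  # stay dimensionless so updates never attach spurious dim attributes)
  zeros <- lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
  list(m = zeros, v = zeros, t = 0L, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, weight_decay = weight_decay)
}
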