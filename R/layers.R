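# Low-level neural network layer operations.
#
# Tensors are base-R arrays in (H, W, C, N) layout; fully-connected
# activations are (units, N) matrices.  Convolution is computed as an im2col
# gather followed by one BLAS matrix multiply; the gather/scatter, pooling
# and group-normalization passes are compiled kernels (src/kernels.cpp)
# because they are memory-bound and dominate training time otherwise.

conv_out_hw <- function(H, W, k, stride, pad) {
  outH <- (H + 2L * pad - k) %/% stride + 1L
  outW <- (W + 2L * pad - k) %/% stride + 1L
  if (outH < 1L || outW < 1L) config_error("kernel larger than (padded) input")
  c(outH, outW)
}

conv_forward <- function(x, layer, params) {
  N <- dim(x)[4]
  col <- im2col_cpp(x, layer$inH, layer$inW, layer$in_ch, N,
                    layer$k, layer$stride, layer$pad)
  out <- crossprod(params[[layer$W]], col) + params[[layer$b]]
  arr <- conv_out_to_array_cpp(out, layer$outH, layer$outW, layer$out_ch, N)
  list(out = arr, cache = list(col = col, N = N))
}

conv_backward <- function(dout, layer, params, cache) {
  N <- cache$N
  g <- conv_array_to_mat_cpp(dout, layer$outH, layer$outW, layer$out_ch, N)
  dW <- cache$col %*% t(g)
  db <- rowSums(g)
  gcol <- params[[layer$W]] %*% g
  dx <- col2im_cpp(gcol, layer$inH, layer$inW, layer$in_ch, N,
                   layer$k, layer$stride, layer$pad)
  list(dx = dx, grads = stats::setNames(list(dW, db), c(layer$W, layer$b)))
}

# Group normalization; per image and group the pre-affine output has mean 0
# and variance 1 (up to eps).  Works on (H, W, C, N) arrays and (units, N)
# matrices alike (spatial = 1 for the latter); channels are grouped as
# consecutive blocks.
gn_forward <- function(x, layer, params, eps = 1e-5) {
  d <- dim(x)
  spatial <- if (length(d) == 4L) d[1] * d[2] else 1L
  C <- if (length(d) == 4L) d[3] else d[1]
  N <- d[length(d)]
  res <- gn_fwd_cpp(x, spatial, C, N, layer$groups,
                    params[[layer$gamma]], params[[layer$beta]], eps)
  list(out = res$out,
       cache = list(xhat = res$xhat, s = res$s, spatial = spatial, C = C, N = N))
}

gn_backward <- function(dout, layer, params, cache) {
  res <- gn_bwd_cpp(dout, cache$xhat, cache$s, cache$spatial, cache$C,
                    cache$N, layer$groups, params[[layer$gamma]])
  list(dx = res$dx,
       grads = stats::setNames(list(res$dgamma, res$dbeta),
                               c(layer$gamma, layer$beta)))
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

# Max pooling (no padding); ties are routed to the first (lowest-index)
# window entry, pinned for determinism.
pool_forward <- function(x, layer) {
  d <- dim(x)
  res <- pool_fwd_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$stride)
  list(out = res$out, cache = list(arg = res$arg, dims = d))
}

pool_backward <- function(dout, layer, cache) {
  d <- cache$dims
  pool_bwd_cpp(dout, cache$arg, d[1], d[2], d[3], d[4])
}

# Flatten to the pinned unit order (channel-major, spatial row-major).
flatten_forward <- function(x) {
  d <- dim(x)
  out <- aperm(x, c(2, 1, 3, 4))
  dim(out) <- c(d[1] * d[2] * d[3], d[4])
  list(out = out, cache = d)
}

flatten_backward <- function(dout, cache) {
  d <- cache
  dim(dout) <- c(d[2], d[1], d[3], d[4])
  aperm(dout, c(2, 1, 3, 4))
}

fc_forward <- function(x, layer, params) {
  out <- crossprod(params[[layer$W]], x) + params[[layer$b]]
  list(out = out, cache = x)
}

fc_backward <- function(dout, layer, params, cache) {
  list(dx = params[[layer$W]] %*% dout,
       grads = stats::setNames(
         list(cache %*% t(dout), rowSums(dout)), c(layer$W, layer$b)))
}

l2norm_forward <- function(x, tol = 1e-12) {
  nrm <- sqrt(colSums(x * x))
  if (any(nrm < tol)) numeric_error("zero-norm vector at the L2 projection head")
  z <- x / rep(nrm, each = nrow(x))
  list(out = z, cache = list(z = z, nrm = nrm))
}

l2norm_backward <- function(dout, cache) {
  z <- cache$z
  (dout - z * rep(colSums(z * dout), each = nrow(z))) /
    rep(cache$nrm, each = nrow(z))
}
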