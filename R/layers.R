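# Layer primitives. A layer is a plain list carrying its learnable arrays
# and hyperparameters; forward functions in training mode return the updated
# layer (batch-norm running statistics) plus whatever the backward pass
# needs. Convolutions carry no bias: every one is followed by batch norm,
# whose shift makes a bias redundant.

.convLayer <- function(k, cin, cout, stride, groups) {
  if (cin %% groups != 0L) {
    stop("input channels (", cin, ") not divisible by group count ", groups)
  }
  if (cout %% groups != 0L) {
    stop("output channels (", cout, ") not divisible by group count ", groups)
  }
  cing <- cin %/% groups
  fanin <- k * k * cing
  w <- array(stats::rnorm(k * k * cing * cout, sd = sqrt(2 / fanin)),
             dim = c(k, k, cing, cout))
  list(type = "conv", w = w, k = k, cin = cin, cout = cout,
       stride = stride, groups = groups)
}

.bnLayer <- function(c, eps, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c), eps = eps, momentum = momentum)
}

.fcLayer <- function(cin, n) {
  lim <- sqrt(1 / cin)
  list(type = "fc",
       w = matrix(stats::runif(cin * n, -lim, lim), nrow = cin, ncol = n),
       b = rep(0, n))
}

.convForward <- function(layer, x) {
  cpp_conv2d_forward(x, layer$w, layer$stride, layer$groups)
}

.convBackward <- function(layer, x, dout) {
  cpp_conv2d_backward(x, layer$w, dout, layer$stride, layer$groups)
}

# Forward through batch norm. In training mode normalizes with batch
# statistics and updates the running ones (momentum 0.1, unbiased variance
# in the running estimate); in inference mode uses the running statistics.
.bnForward <- function(layer, x, training = FALSE) {
  if (training) {
    st <- cpp_bn_stats(x)
    scale <- layer$gamma / sqrt(st$var + layer$eps)
    shift <- layer$beta - st$mean * scale
    out <- cpp_channel_affine(x, scale, shift)
    d <- dim(x)
    m <- prod(d[c(1L, 2L, 4L)])
    unb <- if (m > 1) st$var * m / (m - 1) else st$var
    mom <- layer$momentum
    layer$rmean <- (1 - mom) * layer$rmean + mom * st$mean
    layer$rvar <- (1 - mom) * layer$rvar + mom * unb
    list(out = out, layer = layer, mean = st$mean, var = st$var)
  } else {
    scale <- layer$gamma / sqrt(layer$rvar + layer$eps)
    shift <- layer$beta - layer$rmean * scale
    list(out = cpp_channel_affine(x, scale, shift), layer = layer)
  }
}

.bnBackward <- function(layer, x, cache, dout) {
  cpp_bn_backward(x, dout, cache$mean, cache$var, layer$gamma, layer$eps)
}

# Exact (error-function) GELU and its derivative.
.gelu <- function(x) x * stats::pnorm(x)
.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
.relu <- function(x) {
  x[x < 0] <- 0
  x
}
.reluGrad <- function(x) (x > 0) * 1

# Global average pooling: H x W x C x N -> C x N matrix.
.gap <- function(x) {
  d <- dim(x)
  m <- matrix(.colMeans(matrix(x, d[1] * d[2], d[3] * d[4]),
                        d[1] * d[2], d[3] * d[4]),
              nrow = d[3], ncol = d[4])
  m
}

.gapBackward <- function(dm, d) {
  hw <- d[1] * d[2]
  dx <- array(rep(as.numeric(dm), each = hw) / hw, dim = d)
  dx
}

.softmax <- function(z) {
  # z: n x N logits
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}
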