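# Minimal neural-network engine used by the dual-branch fusion classifier.
#
# Layers are plain lists tagged with $kind; parameters live inside the
# layer. Convolution is implemented as im2col + BLAS matrix product, which
# is where essentially all the training time goes. Image batches are 4-D
# arrays N x H x W x C (sample-first, channel-last); vector batches are
# N x p matrices.
#
# Forward functions return list(out, cache); backward functions take the
# cache and the upstream gradient and return list(dx, grads), grads named
# like the layer's parameters.

new_dense <- function(n_in, n_out, act = TRUE) {
  if (n_in < 1L) abort_spec("dense layer requires a positive input width")
  list(kind = "dense",
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out), act = act)
}

new_conv <- function(c_in, c_out) {
  if (c_in < 1L) abort_spec("conv layer requires at least one input channel")
  fan_in <- 9L * c_in
  list(kind = "conv",
       W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = numeric(c_out))
}

new_bn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c),
       momentum = momentum, eps = eps)
}

new_relu    <- function() list(kind = "relu")
new_pool    <- function() list(kind = "pool")
new_flatten <- function() list(kind = "flatten")
new_dropout <- function(rate) list(kind = "dropout", rate = rate)

# ---- forward passes ------------------------------------------------------
# The convolution (im2col + GEMM), batch-norm, ReLU and max-pool kernels
# live in src/conv_ops.cpp; the dense layers ride BLAS from R directly.

# column-wise broadcast helpers; rep(each) avoids sweep()'s aperm copies
.addc <- function(x, v) x + rep(v, each = nrow(x))
.mulc <- function(x, v) x * rep(v, each = nrow(x))

fwd_dense <- function(l, x, training) {
  z <- x %*% l$W
  z <- .addc(z, l$b)
  if (l$act) {
    out <- z * (z > 0)
    list(out = out, cache = list(x = x, z = z))
  } else {
    list(out = z, cache = list(x = x))
  }
}

fwd_conv <- function(l, x, training) {
  list(out = cpp_conv_fwd(x, l$W, l$b), cache = list(x = x))
}

fwd_bn <- function(l, x, training) {
  r <- cpp_bn_fwd(x, l$gamma, l$beta, l$eps, training, l$rmean, l$rvar)
  state <- if (training)
    list(rmean = l$momentum * l$rmean + (1 - l$momentum) * r$mu,
         rvar = l$momentum * l$rvar + (1 - l$momentum) * r$var)
  list(out = r$out,
       cache = list(x = x, mu = r$mu, istd = r$istd, state = state))
}

fwd_relu <- function(l, x, training) {
  list(out = cpp_relu_fwd(x), cache = list(x = x))
}

fwd_pool <- function(l, x, training) {
  r <- cpp_pool_fwd(x)
  list(out = r$out, cache = list(idx = r$idx, dims = dim(x)))
}

fwd_flatten <- function(l, x, training) {
  d <- dim(x)
  list(out = matrix(x, nrow = d[1]), cache = list(dims = d))
}

fwd_dropout <- function(l, x, training) {
  if (!training || l$rate <= 0) return(list(out = x, cache = NULL))
  mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
  if (is.matrix(x)) mask <- matrix(mask, nrow(x), ncol(x))
  else mask <- array(mask, dim(x))
  list(out = x * mask, cache = list(mask = mask))
}

layer_forward <- function(l, x, training) {
  switch(l$kind,
    dense = fwd_dense(l, x, training),
    conv = fwd_conv(l, x, training),
    bn = fwd_bn(l, x, training),
    relu = fwd_relu(l, x, training),
    pool = fwd_pool(l, x, training),
    flatten = fwd_flatten(l, x, training),
    dropout = fwd_dropout(l, x, training),
    abort_spec(sprintf("unknown layer kind '%s'", l$kind)))
}

# ---- backward passes -----------------------------------------------------

bwd_dense <- function(l, cache, dy) {
  if (l$act) dy <- dy * (cache$z > 0)
  list(dx = dy %*% t(l$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

bwd_conv <- function(l, cache, dy) {
  r <- cpp_conv_bwd(cache$x, l$W, dy)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

bwd_bn <- function(l, cache, dy) {
  r <- cpp_bn_bwd(cache$x, dy, cache$mu, cache$istd, l$gamma)
  list(dx = r$dx, grads = list(gamma = as.numeric(r$dgamma),
                               beta = as.numeric(r$dbeta)))
}

bwd_relu <- function(l, cache, dy)
  list(dx = cpp_relu_bwd(cache$x, dy), grads = NULL)

bwd_pool <- function(l, cache, dy)
  list(dx = cpp_pool_bwd(cache$idx, dy, cache$dims), grads = NULL)

bwd_flatten <- function(l, cache, dy)
  list(dx = array(dy, cache$dims), grads = NULL)

bwd_dropout <- function(l, cache, dy) {
  if (is.null(cache)) return(list(dx = dy, grads = NULL))
  list(dx = dy * cache$mask, grads = NULL)
}

layer_backward <- function(l, cache, dy) {
  switch(l$kind,
    dense = bwd_dense(l, cache, dy),
    conv = bwd_conv(l, cache, dy),
    bn = bwd_bn(l, cache, dy),
    relu = bwd_relu(l, cache, dy),
    pool = bwd_pool(l, cache, dy),
    flatten = bwd_flatten(l, cache, dy),
    dropout = bwd_dropout(l, cache, dy))
}

# ---- branch (layer list) plumbing ----------------------------------------

branch_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

branch_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots for parameter-free layers
  }
  list(dx = dy, grads = grads)
}

# commit batch-norm running statistics recorded during a training forward
branch_update_state <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$kind == "bn" && !is.null(caches[[i]]$state)) {
      layers[[i]]$rmean <- caches[[i]]$state$rmean
      layers[[i]]$rvar <- caches[[i]]$state$rvar
    }
  }
  layers
}

.trainable <- c("W", "b", "gamma", "beta")

branch_param_count <- function(layers) {
  # trainable weights plus batch-norm moving statistics (4 per channel),
  # matching the convention of standard framework summaries
  sum(vapply(layers, function(l) {
    nm <- intersect(names(l), c(.trainable, "rmean", "rvar"))
    sum(vapply(nm, function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
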