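# Backward-pass correctness of the network engine, pinned by central finite
# differences through the full fused network (dropout off so the forward
# pass is deterministic).

grad_setup <- function() {
  set.seed(42)
  spec <- fccnn_spec(spectral_input_len = 7, image_rows = 32, image_cols = 32,
                     image_channels = 2, spectral_units = c(5, 6, 5, 4),
                     conv_filters = c(3, 4, 4, 3, 2), n_classes = 3,
                     dropout_spectral = 0, dropout_head = 0)
  net <- build_fccnn(spec)
  n <- 4
  list(net = net,
       x_spec = matrix(rnorm(n * 7), n, 7),
       x_img = array(rnorm(n * 32 * 32 * 2), c(n, 32, 32, 2)),
       tgt = specfuse:::one_hot(c(1, 2, 3, 1), 3))
}

analytic_grads <- function(s) {
  fw <- specfuse:::network_forward(s$net, s$x_spec, s$x_img, training = TRUE)
  dlogits <- specfuse:::mae_softmax_grad(fw$probs, s$tgt)
  bh <- specfuse:::branch_backward(s$net$head$layers, fw$rh$caches, dlogits)
  w_s <- s$net$spectral$out_len
  bs <- specfuse:::branch_backward(s$net$spectral$layers, fw$rs$caches,
                                   bh$dx[, 1:w_s, drop = FALSE])
  bi <- specfuse:::branch_backward(s$net$image$layers, fw$ri$caches,
                                   bh$dx[, w_s + seq_len(s$net$image$out_len),
                                         drop = FALSE])
  list(head = bh$grads, spectral = bs$grads, image = bi$grads)
}

numeric_grad <- function(s, branch, li, pname, i, eps = 1e-6) {
  f <- function(shift) {
    net2 <- s$net
    net2[[branch]]$layers[[li]][[pname]][i] <-
      net2[[branch]]$layers[[li]][[pname]][i] + shift
    fw <- specfuse:::network_forward(net2, s$x_spec, s$x_img, training = TRUE)
    mean(abs(fw$probs - s$tgt))
  }
  (f(eps) - f(-eps)) / (2 * eps)
}

test_that("backprop matches finite differences for every layer kind", {
  s <- grad_setup()
  an <- analytic_grads(s)
  cases <- list(
    list("image", 1L, "W", 1:8),        # conv
    list("image", 2L, "gamma", 1:3),    # batch-norm scale
    list("image", 2L, "beta", 1:3),     # batch-norm shift
    list("image", 5L, "W", 1:8),        # deeper conv (through pool + relu)
    list("image", 23L, "W", 1:8),       # post-flatten dense
    list("spectral", 1L, "W", 1:8),
    list("spectral", 1L, "b", 1:4),
    list("spectral", 7L, "W", 1:8),     # last spectral dense
    list("head", 2L, "W", 1:8),
    list("head", 2L, "b", 1:3))
  for (cs in cases) {
    g_an <- an[[cs[[1]]]][[cs[[2]]]][[cs[[3]]]]
    for (i in cs[[4]]) {
      g_num <- numeric_grad(s, cs[[1]], cs[[2]], cs[[3]], i)
      expect_equal(g_an[i], g_num, tolerance = 1e-4,
                   label = sprintf("%s[%d]$%s[%d]", cs[[1]], cs[[2]], cs[[3]], i))
    }
  }
  # conv bias feeds straight into batch-norm, so its gradient is exactly
  # the mean-shift that normalization removes: zero
  expect_lt(max(abs(an$image[[1L]]$b)), 1e-12)
})

test_that("gradient descent on one fixed example drives the loss to zero", {
  set.seed(7)
  spec <- fccnn_spec(spectral_input_len = 12, image_channels = 0,
                     spectral_units = c(16, 16, 16, 8), n_classes = 3,
                     dropout_spectral = 0, dropout_head = 0)
  net <- build_fccnn(spec)
  # the zero-initialized head starts at the uniform softmax and ramps the
  # logits at the optimizer's step size, so give the single example a
  # large step size and enough steps to saturate
  fit <- train_fccnn(net, matrix(rnorm(12), 1, 12), NULL, y = 2L,
                     iterations = 400, batch_size = 1, lr = 1e-2)
  expect_lt(fit$loss[400], 0.02)
  expect_lt(fit$loss[400], fit$loss[1] / 10)
  # trend is monotone in the large: late average far below early average
  expect_lt(mean(fit$loss[351:400]), mean(fit$loss[1:25]) / 2)
})

test_that("training is deterministic under a fixed seed", {
  run <- function() {
    set.seed(123)
    spec <- fccnn_spec(spectral_input_len = 6, image_rows = 32,
                       image_cols = 32, image_channels = 1,
                       spectral_units = c(4, 4, 4, 4),
                       conv_filters = c(2, 2, 2, 2, 2), n_classes = 2)
    net <- build_fccnn(spec)
    x_s <- matrix(rnorm(8 * 6), 8, 6)
    x_i <- array(rnorm(8 * 32 * 32), c(8, 32, 32, 1))
    train_fccnn(net, x_s, x_i, rep(1:2, 4), iterations = 6, batch_size = 4)
  }
  a <- run(); b <- run()
  expect_identical(a$loss, b$loss)
  expect_identical(a$net$head$layers[[2]]$W, b$net$head$layers[[2]]$W)
  expect_identical(a$net$image$layers[[1]]$W, b$net$image$layers[[1]]$W)
})

test_that("batch-norm switches between batch and moving statistics", {
  set.seed(5)
  l <- specfuse:::new_bn(3)
  x <- array(rnorm(40 * 3, mean = 2, sd = 4), c(10, 2, 2, 3))
  r <- specfuse:::fwd_bn(l, x, training = TRUE)
  ym <- matrix(r$out, ncol = 3)
  expect_equal(colMeans(ym), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(ym, 2, sd) * sqrt(39 / 40), rep(1, 3), tolerance = 1e-3)
  # inference with warmed-up moving stats reproduces the training map
  l2 <- l
  l2$rmean <- r$cache$x |> matrix(ncol = 3) |> colMeans()
  l2$rvar <- apply(matrix(r$cache$x, ncol = 3), 2,
                   function(v) mean((v - mean(v))^2))
  r2 <- specfuse:::fwd_bn(l2, x, training = FALSE)
  expect_equal(r2$out, r$out, tolerance = 1e-10)
})

test_that("max-pool halves dimensions and routes gradients to the argmax", {
  x <- array(0, c(1, 4, 4, 1))
  x[1, , , 1] <- matrix(1:16, 4, 4)
  r <- specfuse:::fwd_pool(NULL, x, TRUE)
  expect_identical(dim(r$out), c(1L, 2L, 2L, 1L))
  expect_equal(r$out[1, , , 1], matrix(c(6, 8, 14, 16), 2, 2))
  dy <- r$out; dy[] <- 1
  dx <- specfuse:::bwd_pool(NULL, r$cache, dy)$dx
  expect_equal(sum(dx), 4)
  expect_equal(dx[1, 2, 2, 1], 1)   # at the max positions
  expect_equal(dx[1, 1, 1, 1], 0)
})
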