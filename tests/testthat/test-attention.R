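set.seed(100)

test_that("the channel gate is sigmoid(local 1D conv of the pooled descriptor)", {
  C <- 12
  cfg <- seca_config(C, channel_kernel = 3)
  x <- array(rnorm(C * 5 * 4), c(C, 5, 4))
  expect_equal(channel_gate(x, cfg, numeric(3)), rep(0.5, C))

  w <- rnorm(3)
  g <- channel_gate(x, cfg, w)
  # spatial permutation invariance
  perm <- sample(20)
  xp <- array(0, dim(x))
  flat <- matrix(x, C, 20)
  xp[] <- array(flat[, perm], c(C, 5, 4))
  expect_equal(channel_gate(xp, cfg, w), g)
  # brute force: explicit means and sliding dot product
  s <- sapply(1:C, function(c) mean(x[c, , ]))
  manual <- sapply(1:C, function(c) {
    acc <- 0
    for (j in -1:1) if (c + j >= 1 && c + j <= C)
      acc <- acc + w[j + 2] * s[c + j]
    1 / (1 + exp(-acc))
  })
  expect_equal(g, manual, tolerance = 1e-12)
  expect_true(all(g > 0 & g < 1))
  expect_error(seca_config(C, channel_kernel = 4), "odd")
})

test_that("the spatial gate matches dense evaluation of its two convolutions", {
  C <- 8; H <- 4; W <- 4
  cfg <- seca_config(C, spatial_ratio = 4, min_width = 2)
  C4 <- max(cfg$min_width, ceiling(C / 4))
  k <- cfg$spatial_kernel
  zero_w <- list(w1 = matrix(0, C * k^2, C4), b1 = numeric(C4),
                 w2 = matrix(0, C4 * k^2, 1), b2 = 0)
  x <- array(rnorm(C * H * W), c(C, H, W))
  m0 <- spatial_gate(x, cfg, zero_w)
  expect_equal(dim(m0), c(1L, H, W))
  expect_true(all(m0 == 0.5))

  wts <- list(w1 = matrix(rnorm(C * k^2 * C4, 0, 0.2), C * k^2, C4),
              b1 = rnorm(C4, 0, 0.1),
              w2 = matrix(rnorm(C4 * k^2, 0, 0.2), C4 * k^2, 1),
              b2 = rnorm(1, 0, 0.1))
  m <- spatial_gate(x, cfg, wts)
  xm <- slenet:::fm_to_mat(x)
  h1 <- naive_conv_mat(xm, wts$w1, wts$b1, 1, H, W, k, 1, (k - 1) %/% 2)
  h1 <- h1 / (1 + exp(-h1))
  h2 <- naive_conv_mat(h1, wts$w2, wts$b2, 1, H, W, k, 1, (k - 1) %/% 2)
  manual <- 1 / (1 + exp(-t(matrix(h2, W, H))))
  expect_lt(max(abs(m[1, , ] - manual)), 1e-5)
  expect_true(all(m > 0 & m < 1))
})

test_that("joint channel-spatial gating composes the two gates and never amplifies", {
  C <- 8; H <- 4; W <- 4
  cfg <- seca_config(C, channel_kernel = 3, min_width = 2)
  C4 <- max(cfg$min_width, ceiling(C / 4))
  k <- cfg$spatial_kernel
  zero_w <- list(channel = numeric(3),
                 spatial = list(w1 = matrix(0, C * k^2, C4), b1 = numeric(C4),
                                w2 = matrix(0, C4 * k^2, 1), b2 = 0))
  x <- array(rnorm(C * H * W), c(C, H, W))
  expect_equal(seca_apply(array(0, c(C, H, W)), cfg, zero_w),
               array(0, c(C, H, W)))
  expect_equal(seca_apply(x, cfg, zero_w), 0.25 * x, tolerance = 1e-12)

  wts <- list(channel = rnorm(3),
              spatial = list(w1 = matrix(rnorm(C * k^2 * C4, 0, 0.3),
                                         C * k^2, C4),
                             b1 = rnorm(C4, 0, 0.1),
                             w2 = matrix(rnorm(C4 * k^2, 0, 0.3), C4 * k^2, 1),
                             b2 = 0.2))
  y <- seca_apply(x, cfg, wts)
  expect_true(all(abs(y) <= abs(x)))
})

test_that("the attention-block parameter count matches closed-form arithmetic", {
  for (C in c(16, 40, 112)) {
    sg <- slenet:::mod_spatial_gate(C, 7L, 7L)
    C4 <- max(8, ceiling(C / 4))
    expect_equal(sum(vapply(sg$params, function(p) length(p$value), numeric(1))),
                 49 * C * C4 + C4 + 49 * C4 + 1)
  }
  cg <- slenet:::mod_channel_gate_bottleneck(96L, 4L, 5L, 5L)
  expect_equal(sum(vapply(cg$params, function(p) length(p$value), numeric(1))),
               96 * 4 + 4 + 4 * 96 + 96)
})

test_that("scaled attention matches the explicit softmax oracle", {
  C <- 3; dk <- 2
  p <- nonlocal_params(C, dk, residual = FALSE, seed = 7)
  # single position: softmax of one logit is 1, output is x Wv
  x1 <- matrix(rnorm(C), 1, C)
  expect_equal(scaled_attention(x1, p), x1 %*% p$Wv, tolerance = 1e-12)
  # identical rows attend uniformly and reproduce the common value row
  xid <- matrix(rep(rnorm(C), each = 5), 5, C)
  oid <- scaled_attention(xid, p)
  expect_equal(oid, xid %*% p$Wv, tolerance = 1e-10)
  # random case vs brute force
  X <- matrix(rnorm(4 * C), 4, C)
  expect_lt(max(abs(scaled_attention(X, p) -
                      naive_attention(X, p$Wq, p$Wk, p$Wv, dk))), 1e-6)
  # rows of the attention matrix sum to one
  at <- slenet:::attention_forward(X, p$Wq, p$Wk, p$Wv, dk)
  expect_lt(max(abs(rowSums(at$A) - 1)), 1e-9)
  expect_error(scaled_attention(matrix(c(1, NA), 1), p), "non-finite")
})

test_that("the non-local block is identity at init and permutation-equivariant", {
  C <- 8; H <- 3; W <- 3
  x <- array(rnorm(C * H * W), c(C, H, W))
  p0 <- nonlocal_params(C, seed = 3)       # Wz = 0, residual on
  expect_equal(nonlocal_block(x, p0), x, tolerance = 1e-12)

  p <- nonlocal_params(C, seed = 3, Wz = matrix(rnorm(C * C, 0, 0.2), C, C))
  y <- nonlocal_block(x, p)
  # brute force: flatten, oracle attention, project, residual
  X <- slenet:::fm_to_mat(x)
  manual <- naive_attention(X, p$Wq, p$Wk, p$Wv, p$dk) %*% p$Wz + X
  expect_lt(max(abs(slenet:::fm_to_mat(y) - manual)), 1e-5)

  # permuting spatial positions permutes the output identically
  perm <- sample(H * W)
  Xp <- X[perm, ]
  yp <- nonlocal_block(slenet:::mat_to_fm(Xp, H, W), p)
  expect_equal(slenet:::fm_to_mat(yp), slenet:::fm_to_mat(y)[perm, ],
               tolerance = 1e-10)
  expect_true(all(is.finite(y)))
})

test_that("network gate modules agree with the functional definitions", {
  C <- 10; H <- 4; W <- 3
  x <- array(rnorm(C * H * W), c(C, H, W))
  xm <- slenet:::fm_to_mat(x)

  eca <- slenet:::mod_channel_gate_local(C, 3L, H, W)
  cfg <- seca_config(C, channel_kernel = 3)
  g <- channel_gate(x, cfg, eca$params$w$value)
  expect_equal(eca$forward(xm, 1L, FALSE), xm * rep(g, each = H * W),
               tolerance = 1e-12)

  nl <- slenet:::mod_nonlocal(C, H, W, dk = C)
  p <- nonlocal_params(C, Wq = nl$params$Wq$value, Wk = nl$params$Wk$value,
                       Wv = nl$params$Wv$value,
                       Wz = matrix(rnorm(C * C, 0, 0.2), C, C))
  nl$params$Wz$value <- p$Wz
  expect_equal(nl$forward(xm, 1L, FALSE),
               slenet:::fm_to_mat(nonlocal_block(x, p)), tolerance = 1e-10)
})
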