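test_that("compound scaling returns the stated multipliers and checks the constraint", {
  expect_equal(unname(compound_scale(scaling_config(phi = 0))), c(1, 1, 1))
  s <- scaling_config(phi = 1, alpha = 1.2, beta = 1.1, gamma = 1.15)
  expect_equal(unname(compound_scale(s)), c(1.2, 1.1, 1.15))
  expect_equal(s$alpha * s$beta^2 * s$gamma^2, 1.92, tolerance = 1e-3)
  expect_warning(compound_scale(scaling_config(phi = 1, alpha = 2, beta = 2,
                                               gamma = 1)),
                 "outside")
  expect_error(compound_scale(scaling_config(phi = -1)), "nonnegative")
  expect_silent(compound_scale(s))
})

test_that("parameter counting is exact on closed-form cases", {
  conv <- slenet:::mod_conv(3L, 8L, 3L, 1L, 8L, 8L, bias = TRUE)
  m <- list(modules = list(conv))
  expect_equal(count_parameters(m), 3 * 8 * 9 + 8)
  lin <- slenet:::mod_linear(7L, 5L)
  expect_equal(count_parameters(list(modules = list(lin))), 7 * 5 + 5)
})

test_that("operation counting follows the documented convention", {
  conv <- slenet:::mod_conv(4L, 6L, 1L, 1L, 10L, 12L)
  expect_equal(count_flops(list(modules = list(conv))),
               2 * 4 * 6 * 10 * 12)
  lin <- slenet:::mod_linear(9L, 4L)
  expect_equal(count_flops(list(modules = list(lin))), 2 * 9 * 4 + 4)
  dw <- slenet:::mod_depthwise(5L, 3L, 1L, 6L, 6L)
  expect_equal(count_flops(list(modules = list(dw))), 2 * 9 * 5 * 6 * 6)
  nl <- slenet:::mod_nonlocal(4L, 2L, 2L, dk = 3L)
  N <- 4
  expect_equal(count_flops(list(modules = list(nl))),
               2 * (3 * N * 4 * 3 + 2 * N^2 * 3 + N * 3 * 4))
})

test_that("convolutional cost scales quadratically with input resolution", {
  f64 <- count_flops(build_model(model_config("se", input_size = 64L,
                                              width_mult = 0.25), seed = 1))
  f128 <- count_flops(build_model(model_config("se", input_size = 128L,
                                               width_mult = 0.25), seed = 1))
  expect_gt(f128 / f64, 3.8)
  expect_lte(f128 / f64, 4.0)
})

test_that("built networks produce finite logits of the right shape", {
  for (attn in c("se", "seca", "none")) {
    cfg <- model_config(attn, use_nonlocal = attn == "seca",
                        width_mult = 0.25, input_size = 64L)
    m <- build_model(cfg, seed = 2)
    x <- matrix(rnorm(2 * 64 * 64 * 3, 0, 0.5), 2 * 64 * 64, 3)
    logits <- network_forward(m, x, 2L, training = FALSE)
    expect_equal(dim(logits), c(2L, 4L))
    expect_true(all(is.finite(logits)))
    # evaluation mode is deterministic
    expect_identical(network_forward(m, x, 2L, training = FALSE), logits)
  }
})

test_that("the zero-initialized non-local head leaves logits unchanged", {
  cfg <- model_config("seca", use_nonlocal = TRUE, width_mult = 0.25,
                      input_size = 64L)
  m <- build_model(cfg, seed = 4)
  x <- matrix(rnorm(64 * 64 * 3, 0, 0.5), 64 * 64, 3)
  with_nl <- network_forward(m, x, 1L, training = FALSE)
  keep <- !vapply(m$modules, function(mm) mm$type == "nonlocal", logical(1))
  m$modules <- m$modules[keep]
  without_nl <- network_forward(m, x, 1L, training = FALSE)
  expect_equal(with_nl, without_nl, tolerance = 1e-12)
})

test_that("model building is seed-reproducible", {
  cfg <- model_config("seca", use_nonlocal = TRUE, width_mult = 0.25,
                      input_size = 64L)
  p1 <- slenet:::snapshot_params(build_model(cfg, seed = 7))
  p2 <- slenet:::snapshot_params(build_model(cfg, seed = 7))
  expect_identical(p1, p2)
  p3 <- slenet:::snapshot_params(build_model(cfg, seed = 8))
  expect_false(identical(p1, p3))
})

test_that("the analytic network gradient matches finite differences", {
  cfg <- model_config("seca", use_nonlocal = TRUE, width_mult = 0.25,
                      input_size = 32L, dropout = 0)
  m <- build_model(cfg, seed = 3)
  ps <- slenet:::collect_params(m)
  set.seed(4)
  x <- matrix(rnorm(2 * 32 * 32 * 3, 0, 0.5), 2 * 1024, 3)
  yid <- c(1L, 3L)
  loss_of <- function() {
    lg <- network_forward(m, x, 2L, training = TRUE)
    slenet:::softmax_xent(lg, yid)$loss
  }
  lg <- network_forward(m, x, 2L, training = TRUE)
  ls <- slenet:::softmax_xent(lg, yid)
  slenet:::zero_grads(ps)
  slenet:::network_backward(m, ls$grad)
  set.seed(9)
  eps <- 1e-6
  for (trial in 1:10) {
    i <- sample(length(ps), 1)
    p <- ps[[i]]
    j <- sample(length(p$value), 1)
    old <- p$value[j]
    p$value[j] <- old + eps; lp <- loss_of()
    p$value[j] <- old - eps; lm <- loss_of()
    p$value[j] <- old
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - p$grad[j]) / max(1, abs(num), abs(p$grad[j])), 5e-3)
  }
})
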