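# Minimal feed-forward network framework with hand-derived backpropagation.
# There is no deep-learning runtime in the dependency stack, and the network
# itself is the subject of this package, so layers are implemented directly:
# each module is a closure-backed list with forward(x, B, training) and
# backward(dy), exchanging feature maps as (B*H*W) x C matrices (row index
# b*H*W + h*W + w) and caching whatever the backward pass needs. Spatial sizes
# are fixed at construction time from the model's input resolution.

new_param <- function(value, decay = TRUE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$decay <- decay
  e
}

conv_init <- function(cin, cout, k) {
  matrix(rnorm(cin * k * k * cout, 0, sqrt(2 / (k * k * cout))),
         cin * k * k, cout)
}

silu <- function(x) x / (1 + exp(-x))
silu_grad <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }
sigmoid <- function(x) 1 / (1 + exp(-x))

# Standard 2D convolution (no bias by default; batch norm follows).
mod_conv <- function(cin, cout, k, stride, H, W, bias = FALSE,
                     pad = (k - 1L) %/% 2L, zero_init = FALSE) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  Wp <- new_param(if (zero_init) matrix(0, cin * k * k, cout)
                  else conv_init(cin, cout, k))
  bp <- if (bias) new_param(numeric(cout), decay = FALSE) else NULL
  cache <- new.env(parent = emptyenv())
  m <- list(
    type = "conv", cin = cin, cout = cout, k = k, stride = stride, pad = pad,
    H = H, W = W, Ho = Ho, Wo = Wo, bias = bias,
    params = c(list(W = Wp), if (bias) list(b = bp)),
    forward = function(x, B, training) {
      if (training) cache$x <- x
      cache$B <- B
      .conv2d_fwd(x, Wp$value, if (bias) bp$value else NULL,
                  B, H, W, k, stride, pad)
    },
    backward = function(dy) {
      g <- .conv2d_bwd(cache$x, Wp$value, dy, bias, cache$B, H, W, k, stride, pad)
      Wp$grad <- g$dw
      if (bias) bp$grad <- g$db
      g$dx
    })
  m
}

mod_depthwise <- function(ch, k, stride, H, W, pad = (k - 1L) %/% 2L) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  Wp <- new_param(matrix(rnorm(k * k * ch, 0, sqrt(2 / (k * k))), k * k, ch))
  cache <- new.env(parent = emptyenv())
  list(
    type = "depthwise", cin = ch, cout = ch, k = k, stride = stride, pad = pad,
    H = H, W = W, Ho = Ho, Wo = Wo,
    params = list(W = Wp),
    forward = function(x, B, training) {
      if (training) cache$x <- x
      cache$B <- B
      .depthwise_fwd(x, Wp$value, B, H, W, k, stride, pad)
    },
    backward = function(dy) {
      g <- .depthwise_bwd(cache$x, Wp$value, dy, cache$B, H, W, k, stride, pad)
      Wp$grad <- g$dw
      g$dx
    })
}

mod_bn <- function(C, H, W, eps = 1e-3, momentum = 0.1) {
  gamma <- new_param(rep(1, C), decay = FALSE)
  beta <- new_param(numeric(C), decay = FALSE)
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  cache <- new.env(parent = emptyenv())
  list(
    type = "bn", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    params = list(gamma = gamma, beta = beta), state = st,
    forward = function(x, B, training) {
      if (training) {
        r <- .bn_fwd_train(x, gamma$value, beta$value, eps)
        st$running_mean <- (1 - momentum) * st$running_mean + momentum * r$mean
        st$running_var <- (1 - momentum) * st$running_var + momentum * r$var
        cache$xhat <- r$xhat
        cache$invstd <- r$invstd
        r$y
      } else {
        scale <- gamma$value / sqrt(st$running_var + eps)
        shift <- beta$value - st$running_mean * scale
        .scale_shift_cols(x, scale, shift)
      }
    },
    backward = function(dy) {
      g <- .bn_bwd(cache$xhat, cache$invstd, gamma$value, dy)
      gamma$grad <- g$dgamma
      beta$grad <- g$dbeta
      g$dx
    })
}

mod_silu <- function(C, H, W) {
  cache <- new.env(parent = emptyenv())
  list(
    type = "act", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    params = list(),
    forward = function(x, B, training) {
      if (training) cache$x <- x
      .silu_fwd(x)
    },
    backward = function(dy) .silu_bwd(cache$x, dy))
}

# Fused batch norm + SiLU (the backbone's standard conv -> norm -> activation
# tail); mathematically identical to mod_bn followed by mod_silu.
mod_bn_silu <- function(C, H, W, eps = 1e-3, momentum = 0.1) {
  gamma <- new_param(rep(1, C), decay = FALSE)
  beta <- new_param(numeric(C), decay = FALSE)
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  cache <- new.env(parent = emptyenv())
  list(
    type = "bn_silu", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    params = list(gamma = gamma, beta = beta), state = st,
    forward = function(x, B, training) {
      if (training) {
        r <- .bn_silu_fwd_train(x, gamma$value, beta$value, eps)
        st$running_mean <- (1 - momentum) * st$running_mean + momentum * r$mean
        st$running_var <- (1 - momentum) * st$running_var + momentum * r$var
        cache$xhat <- r$xhat
        cache$invstd <- r$invstd
        r$z
      } else {
        scale <- gamma$value / sqrt(st$running_var + eps)
        shift <- beta$value - st$running_mean * scale
        .silu_fwd(.scale_shift_cols(x, scale, shift))
      }
    },
    backward = function(dy) {
      g <- .bn_silu_bwd(cache$xhat, cache$invstd, gamma$value, beta$value, dy)
      gamma$grad <- g$dgamma
      beta$grad <- g$dbeta
      g$dx
    })
}

# Global average pool: (B*H*W) x C -> B x C.
mod_gap <- function(C, H, W) {
  hw <- H * W
  cache <- new.env(parent = emptyenv())
  list(
    type = "gap", cin = C, cout = C, H = H, W = W, Ho = 1L, Wo = 1L,
    params = list(),
    forward = function(x, B, training) {
      cache$B <- B
      grp <- rep(seq_len(B), each = hw)
      rowsum(x, grp, reorder = FALSE) / hw
    },
    backward = function(dy) .block_expand(dy / hw, hw))
}

mod_dropout <- function(C, p) {
  cache <- new.env(parent = emptyenv())
  list(
    type = "dropout", cin = C, cout = C, H = 1L, W = 1L, Ho = 1L, Wo = 1L,
    params = list(),
    forward = function(x, B, training) {
      if (!training || p == 0) {
        cache$mask <- NULL
        return(x)
      }
      mask <- matrix((runif(length(x)) >= p) / (1 - p), nrow(x), ncol(x))
      cache$mask <- mask
      x * mask
    },
    backward = function(dy) if (is.null(cache$mask)) dy else dy * cache$mask)
}

mod_linear <- function(cin, cout) {
  Wp <- new_param(matrix(rnorm(cin * cout, 0, 0.01), cin, cout))
  bp <- new_param(numeric(cout), decay = FALSE)
  cache <- new.env(parent = emptyenv())
  list(
    type = "linear", cin = cin, cout = cout, H = 1L, W = 1L, Ho = 1L, Wo = 1L,
    params = list(W = Wp, b = bp),
    forward = function(x, B, training) {
      if (training) cache$x <- x
      sweep(x %*% Wp$value, 2, bp$value, `+`)
    },
    backward = function(dy) {
      Wp$grad <- crossprod(cache$x, dy)
      bp$grad <- colSums(dy)
      dy %*% t(Wp$value)
    })
}

# Squeeze-excite style bottleneck gate over pooled channel descriptors. Used
# both as the SE block of the baseline and, in its 1D-convolution reading, as
# the channel branch of the joint channel-spatial attention block.
mod_channel_gate_bottleneck <- function(C, squeeze, H, W) {
  W1 <- new_param(matrix(rnorm(C * squeeze, 0, sqrt(2 / C)), C, squeeze))
  b1 <- new_param(numeric(squeeze), decay = FALSE)
  W2 <- new_param(matrix(rnorm(squeeze * C, 0, sqrt(2 / squeeze)), squeeze, C))
  b2 <- new_param(numeric(C), decay = FALSE)
  hw <- H * W
  cache <- new.env(parent = emptyenv())
  list(
    type = "channel_gate", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    squeeze = squeeze,
    params = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
    forward = function(x, B, training) {
      grp <- rep(seq_len(B), each = hw)
      S <- rowsum(x, grp, reorder = FALSE) / hw
      h1 <- sweep(S %*% W1$value, 2, b1$value, `+`)
      a1 <- silu(h1)
      z <- sigmoid(sweep(a1 %*% W2$value, 2, b2$value, `+`))
      if (training) {
        cache$x <- x; cache$S <- S; cache$h1 <- h1; cache$a1 <- a1
        cache$z <- z; cache$B <- B
      }
      .block_scale(x, z, hw)
    },
    backward = function(dy) {
      z <- cache$z
      dz <- .block_dot(dy, cache$x, hw)
      dpre2 <- dz * z * (1 - z)
      W2$grad <- crossprod(cache$a1, dpre2)
      b2$grad <- colSums(dpre2)
      da1 <- dpre2 %*% t(W2$value)
      dh1 <- da1 * silu_grad(cache$h1)
      W1$grad <- crossprod(cache$S, dh1)
      b1$grad <- colSums(dh1)
      dS <- dh1 %*% t(W1$value)
      .block_scale_add(dy, z, dS / hw, hw)
    })
}

# Local 1D cross-channel gate: a single k-wide convolution slid along the
# pooled channel descriptor (zero-padded), followed by a sigmoid.
mod_channel_gate_local <- function(C, k, H, W) {
  if (k %% 2 == 0) stop("channel kernel must be odd")
  wk <- new_param(numeric(k), decay = FALSE)
  wk$value <- rnorm(k, 0, sqrt(1 / k))
  hw <- H * W
  off <- (k - 1L) / 2L
  cache <- new.env(parent = emptyenv())
  conv_chan <- function(S, w) {
    out <- matrix(0, nrow(S), ncol(S))
    for (j in seq_len(length(w))) {
      sh <- j - 1L - off
      src <- seq_len(C) + sh
      keep <- src >= 1 & src <= C
      out[, which(keep)] <- out[, which(keep), drop = FALSE] +
        w[j] * S[, src[keep], drop = FALSE]
    }
    out
  }
  list(
    type = "channel_gate_local", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    k = k,
    params = list(w = wk),
    forward = function(x, B, training) {
      grp <- rep(seq_len(B), each = hw)
      S <- rowsum(x, grp, reorder = FALSE) / hw
      z <- sigmoid(conv_chan(S, wk$value))
      if (training) { cache$x <- x; cache$S <- S; cache$z <- z; cache$B <- B }
      .block_scale(x, z, hw)
    },
    backward = function(dy) {
      z <- cache$z
      dz <- .block_dot(dy, cache$x, hw)
      dt <- dz * z * (1 - z)
      gw <- numeric(length(wk$value))
      S <- cache$S
      for (j in seq_along(gw)) {
        sh <- j - 1L - off
        src <- seq_len(C) + sh
        keep <- src >= 1 & src <= C
        gw[j] <- sum(dt[, which(keep), drop = FALSE] * S[, src[keep], drop = FALSE])
      }
      wk$grad <- gw
      dS <- conv_chan(dt, rev(wk$value))
      .block_scale_add(dy, z, dS / hw, hw)
    })
}

# Spatial gate: 7x7 conv to a reduced width, nonlinearity, 7x7 conv to a
# single map, sigmoid; the input is multiplied by the resulting H x W map.
# The output conv is zero-initialized so every gate starts flat at 0.5:
# randomly initialized gates are patchy near-binary masks that repeatedly
# blank spatial positions across the stacked blocks and stall optimization
# (the same neutral-start convention as the non-local output projection).
mod_spatial_gate <- function(C, H, W, ratio = 4L, kernel = 7L, min_width = 8L) {
  C4 <- max(min_width, as.integer(ceiling(C / ratio)))
  conv1 <- mod_conv(C, C4, kernel, 1L, H, W, bias = TRUE)
  act <- mod_silu(C4, H, W)
  conv2 <- mod_conv(C4, 1L, kernel, 1L, H, W, bias = TRUE, zero_init = TRUE)
  cache <- new.env(parent = emptyenv())
  list(
    type = "spatial_gate", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    reduced = C4, kernel = kernel,
    params = c(conv1$params, act$params, conv2$params),
    submodules = list(conv1, act, conv2),
    forward = function(x, B, training) {
      m <- sigmoid(conv2$forward(act$forward(conv1$forward(x, B, training),
                                             B, training), B, training))
      if (training) { cache$x <- x; cache$m <- m }
      x * as.vector(m)
    },
    backward = function(dy) {
      m <- cache$m
      dm <- rowSums(dy * cache$x)
      dpre <- dm * m * (1 - m)
      dxg <- conv1$backward(act$backward(conv2$backward(
        matrix(dpre, ncol = 1))))
      dy * as.vector(m) + dxg
    })
}

# Non-local self-attention over all spatial positions of the head feature map:
# per image, softmax(Q K' / sqrt(dk)) V with linear projections, an output
# projection initialized at zero, and a residual connection (identity at
# initialization).
mod_nonlocal <- function(C, H, W, dk = C, residual = TRUE) {
  Wq <- new_param(matrix(rnorm(C * dk, 0, sqrt(1 / C)), C, dk))
  Wk <- new_param(matrix(rnorm(C * dk, 0, sqrt(1 / C)), C, dk))
  Wv <- new_param(matrix(rnorm(C * dk, 0, sqrt(1 / C)), C, dk))
  Wz <- new_param(matrix(0, dk, C))
  hw <- H * W
  cache <- new.env(parent = emptyenv())
  list(
    type = "nonlocal", cin = C, cout = C, H = H, W = W, Ho = H, Wo = W,
    dk = dk, residual = residual,
    params = list(Wq = Wq, Wk = Wk, Wv = Wv, Wz = Wz),
    forward = function(x, B, training) {
      y <- matrix(0, nrow(x), C)
      if (training) {
        cache$B <- B; cache$x <- x
        cache$per <- vector("list", B)
      }
      for (b in seq_len(B)) {
        rows <- ((b - 1) * hw + 1):(b * hw)
        Xb <- x[rows, , drop = FALSE]
        at <- attention_forward(Xb, Wq$value, Wk$value, Wv$value, dk)
        Yb <- at$O %*% Wz$value
        if (residual) Yb <- Yb + Xb
        if (training) cache$per[[b]] <- at
        y[rows, ] <- Yb
      }
      y
    },
    backward = function(dy) {
      B <- cache$B
      dx <- matrix(0, nrow(dy), C)
      gWq <- matrix(0, C, dk); gWk <- matrix(0, C, dk)
      gWv <- matrix(0, C, dk); gWz <- matrix(0, dk, C)
      for (b in seq_len(B)) {
        rows <- ((b - 1) * hw + 1):(b * hw)
        dYb <- dy[rows, , drop = FALSE]
        Xb <- cache$x[rows, , drop = FALSE]
        at <- cache$per[[b]]
        gWz <- gWz + crossprod(at$O, dYb)
        dO <- dYb %*% t(Wz$value)
        dA <- dO %*% t(at$V)
        dV <- crossprod(at$A, dO)
        dL <- at$A * (dA - rowSums(dA * at$A))
        dQ <- dL %*% at$K / sqrt(dk)
        dK <- crossprod(dL, at$Q) / sqrt(dk)
        gWq <- gWq + crossprod(Xb, dQ)
        gWk <- gWk + crossprod(Xb, dK)
        gWv <- gWv + crossprod(Xb, dV)
        dXb <- dQ %*% t(Wq$value) + dK %*% t(Wk$value) + dV %*% t(Wv$value)
        if (residual) dXb <- dXb + dYb
        dx[rows, ] <- dXb
      }
      Wq$grad <- gWq; Wk$grad <- gWk; Wv$grad <- gWv; Wz$grad <- gWz
      dx
    })
}

# Shared forward for scaled dot-product attention with max-subtraction
# stabilized row softmax. Returns intermediates needed by backprop.
attention_forward <- function(Xb, Wq, Wk, Wv, dk) {
  Q <- Xb %*% Wq
  K <- Xb %*% Wk
  V <- Xb %*% Wv
  L <- tcrossprod(Q, K) / sqrt(dk)
  L <- L - apply(L, 1, max)
  E <- exp(L)
  A <- E / rowSums(E)
  list(Q = Q, K = K, V = V, A = A, O = A %*% V)
}

# Sequential container; also propagates the residual bookkeeping of MBConv.
mod_sequential <- function(mods) {
  list(
    type = "sequential",
    params = do.call(c, lapply(mods, function(m) m$params)),
    submodules = mods,
    forward = function(x, B, training) {
      for (m in mods) x <- m$forward(x, B, training)
      x
    },
    backward = function(dy) {
      for (m in rev(mods)) dy <- m$backward(dy)
      dy
    })
}

# Mobile inverted-bottleneck block: 1x1 expansion, depthwise conv, attention
# at the squeeze-excite position, 1x1 projection; for the joint
# channel-spatial variant a spatial gate follows the projection; residual
# connection when the block preserves shape.
mod_mbconv <- function(cin, cout, k, expansion, stride, H, W,
                       attention = c("se", "seca", "none"),
                       seca = list(ratio = 4L, kernel = 7L, min_width = 8L,
                                   channel = "bottleneck", channel_kernel = NULL)) {
  attention <- match.arg(attention)
  E <- cin * expansion
  mods <- list()
  Hc <- H; Wc <- W
  if (expansion != 1L) {
    mods <- c(mods, list(mod_conv(cin, E, 1L, 1L, Hc, Wc),
                         mod_bn_silu(E, Hc, Wc)))
  }
  dw <- mod_depthwise(E, k, stride, Hc, Wc)
  Hc <- dw$Ho; Wc <- dw$Wo
  mods <- c(mods, list(dw, mod_bn_silu(E, Hc, Wc)))
  if (attention == "se") {
    mods <- c(mods, list(mod_channel_gate_bottleneck(E, max(1L, cin %/% 4L),
                                                     Hc, Wc)))
  } else if (attention == "seca") {
    ch <- if (identical(seca$channel, "local")) {
      kk <- seca$channel_kernel %||% adaptive_channel_kernel(E)
      mod_channel_gate_local(E, kk, Hc, Wc)
    } else {
      mod_channel_gate_bottleneck(E, max(1L, cin %/% 4L), Hc, Wc)
    }
    mods <- c(mods, list(ch))
  }
  mods <- c(mods, list(mod_conv(E, cout, 1L, 1L, Hc, Wc),
                       mod_bn(cout, Hc, Wc)))
  if (attention == "seca") {
    mods <- c(mods, list(mod_spatial_gate(cout, Hc, Wc, seca$ratio,
                                          seca$kernel, seca$min_width)))
  }
  body <- mod_sequential(mods)
  use_res <- stride == 1L && cin == cout
  cache <- new.env(parent = emptyenv())
  list(
    type = "mbconv", cin = cin, cout = cout, k = k, stride = stride,
    H = H, W = W, Ho = Hc, Wo = Wc, expansion = expansion,
    attention = attention, use_res = use_res,
    params = body$params, submodules = body$submodules,
    forward = function(x, B, training) {
      y <- body$forward(x, B, training)
      if (use_res) y + x else y
    },
    backward = function(dy) {
      dx <- body$backward(dy)
      if (use_res) dx + dy else dx
    })
}

# Nearest odd integer to log2(C)/2 + 1/2, clamped to >= 3: the adaptive local
# cross-channel kernel rule.
adaptive_channel_kernel <- function(C) {
  k <- round(log2(C) / 2 + 0.5)
  if (k %% 2 == 0) k <- k + 1
  max(3L, as.integer(k))
}

collect_params <- function(net) do.call(c, lapply(net$modules, `[[`, "params"))

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Decoupled weight-decay Adam (AdamW). Decay is applied only to parameters
# flagged for it (conv/linear weights; not biases, norms or gate kernels).
adamw_state <- function(params) {
  lapply(params, function(p) {
    list(m = array(0, dim = dim(p$value) %||% length(p$value)),
         v = array(0, dim = dim(p$value) %||% length(p$value)))
  })
}

adamw_step <- function(params, st, t, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    st[[i]]$m <- beta1 * st[[i]]$m + (1 - beta1) * g
    st[[i]]$v <- beta2 * st[[i]]$v + (1 - beta2) * g * g
    mhat <- st[[i]]$m / (1 - beta1^t)
    vhat <- st[[i]]$v / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (p$decay && weight_decay > 0) upd <- upd + weight_decay * p$value
    p$value <- p$value - lr * upd
  }
  st
}

# Cross-entropy over softmax logits; returns loss and gradient wrt logits.
softmax_xent <- function(logits, y_idx) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y_idx)], 1e-12)))
  grad <- probs
  grad[cbind(seq_len(n), y_idx)] <- grad[cbind(seq_len(n), y_idx)] - 1
  list(loss = loss, grad = grad / n, probs = probs)
}
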