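# Independent brute-force oracles used by the tests. These are deliberately
# written as plain loops over the defining formulas, sharing no code with the
# package's computational paths.

# Dense 2D convolution on the (B*H*W) x C feature layout, zero padding.
naive_conv_mat <- function(x, w, bias = NULL, B, H, W, k, stride, pad) {
  C <- ncol(x)
  Co <- ncol(w)
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- matrix(0, B * Ho * Wo, Co)
  for (b in 1:B) for (ho in 1:Ho) for (wo in 1:Wo) for (co in 1:Co) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (c in 1:C) for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
      h <- (ho - 1) * stride - pad + di + 1
      wc <- (wo - 1) * stride - pad + dj + 1
      if (h >= 1 && h <= H && wc >= 1 && wc <= W)
        acc <- acc + x[(b - 1) * H * W + (h - 1) * W + wc, c] *
          w[(c - 1) * k * k + di * k + dj + 1, co]
    }
    y[(b - 1) * Ho * Wo + (ho - 1) * Wo + wo, co] <- acc
  }
  y
}

# Direct evaluation of the bicubic resampling double sum at every output
# pixel: half-pixel centers, clamp-to-edge neighbours, clamp to [0, 255].
naive_bicubic <- function(img, Ho, Wo, a = -0.5) {
  kernel <- function(x) {
    ax <- abs(x)
    if (ax <= 1) (a + 2) * ax^3 - (a + 3) * ax^2 + 1
    else if (ax < 2) a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a
    else 0
  }
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- array(0, c(Ho, Wo, C))
  for (ch in 1:C) for (i in 1:Ho) for (j in 1:Wo) {
    sy <- (i - 0.5) * H / Ho + 0.5   # 1-based source position
    sx <- (j - 0.5) * W / Wo + 0.5
    fy <- floor(sy); fx <- floor(sx)
    acc <- 0
    for (m in -1:2) for (n in -1:2) {
      yy <- min(max(fy + m, 1), H)
      xx <- min(max(fx + n, 1), W)
      acc <- acc + kernel(sy - (fy + m)) * kernel(sx - (fx + n)) *
        img[yy, xx, ch]
    }
    out[i, j, ch] <- min(max(acc, 0), 255)
  }
  out
}

# Pairwise (Mann-Whitney) AUC: fraction of positive/negative pairs ranked
# correctly, ties counted one half.
mw_auc <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Explicit softmax attention: loops, exponentials and row normalization.
naive_attention <- function(X, Wq, Wk, Wv, dk) {
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  N <- nrow(X)
  out <- matrix(0, N, ncol(Wv))
  for (i in 1:N) {
    logits <- numeric(N)
    for (j in 1:N) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in 1:N) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

# A tiny rendered dataset shared by training tests (built once per test run).
tiny_imageset <- function(n_per_class = 2, size = 64, seed = 11) {
  stages <- rep(stage_levels(), each = n_per_class)
  hw <- size^2
  x <- matrix(0, length(stages) * hw, 3)
  for (i in seq_along(stages)) {
    sc <- sample_scene(stages[i], seed = seed + i, canvas = size)
    img <- render_scene(sc, c(size, size))
    x[((i - 1) * hw + 1):(i * hw), ] <- slenet:::chw_rows(img)
  }
  list(x = x, y = factor(stages, levels = stage_levels()), size = size)
}
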