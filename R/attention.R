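# Functional forms of the attention operations, defined on C x H x W feature
# arrays with explicit weights. These are the reference surface for the two
# attention mechanisms; the network modules in nn_core.R implement the same
# mathematics in the batched layout with backprop.

#' Configuration of the joint channel-spatial attention block
#'
#' @param channels Number of input channels C.
#' @param channel_kernel Odd width of the local 1D cross-channel convolution;
#'   `NULL` selects the adaptive rule (nearest odd integer to
#'   `log2(C)/2 + 1/2`, at least 3).
#' @param spatial_ratio Channel reduction ratio of the spatial branch
#'   (default 4).
#' @param spatial_kernel Kernel size of the two spatial convolutions
#'   (default 7).
#' @param min_width Lower bound on the reduced width of the spatial branch.
#' @return A `seca_config` list.
#' @export
seca_config <- function(channels, channel_kernel = NULL, spatial_ratio = 4L,
                        spatial_kernel = 7L, min_width = 8L) {
  if (is.null(channel_kernel)) channel_kernel <- adaptive_channel_kernel(channels)
  if (channel_kernel %% 2 == 0)
    stop("channel_kernel must be odd")
  stopifnot(channels > 0, spatial_ratio >= 1)
  structure(list(channels = as.integer(channels),
                 channel_kernel = as.integer(channel_kernel),
                 spatial_ratio = as.integer(spatial_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 min_width = as.integer(min_width)),
            class = "seca_config")
}

# C x H x W array -> (H*W) x C matrix with row index (h-1)*W + w.
fm_to_mat <- function(x) {
  d <- dim(x)
  chw_rows(aperm(x, c(2, 3, 1)))
}

mat_to_fm <- function(m, H, W) {
  aperm(rows_chw(m, H, W), c(3, 1, 2))
}

#' Channel gate: local 1D convolution over the pooled channel descriptor
#'
#' Spatially average-pools the feature map to a length-C descriptor, slides a
#' zero-padded 1D convolution of width `cfg$channel_kernel` along the channel
#' axis, and applies a sigmoid. The gains are invariant to any permutation of
#' spatial positions and lie strictly inside (0, 1).
#'
#' @param x `C x H x W` numeric array.
#' @param cfg A [seca_config()].
#' @param weights Numeric vector of length `cfg$channel_kernel` (the 1D
#'   kernel), or a list with element `w`.
#' @return Numeric vector of C per-channel gains.
#' @export
channel_gate <- function(x, cfg, weights) {
  w <- if (is.list(weights)) weights$w else weights
  if (length(w) != cfg$channel_kernel)
    stop("weights must have length channel_kernel = ", cfg$channel_kernel)
  C <- dim(x)[1]
  s <- apply(x, 1, mean)
  off <- (length(w) - 1) / 2
  t <- vapply(seq_len(C), function(c) {
    idx <- c + (seq_along(w) - 1) - off
    keep <- idx >= 1 & idx <= C
    sum(w[keep] * s[idx[keep]])
  }, numeric(1))
  sigmoid(t)
}

#' Spatial gate: two 7x7 convolutions to a sigmoid spatial map
#'
#' Reduces C channels to `max(min_width, ceiling(C/ratio))` with a 7x7
#' convolution, applies the backbone nonlinearity, maps to a single channel
#' with a second 7x7 convolution, and applies a sigmoid. Padding keeps the
#' spatial size unchanged.
#'
#' @param x `C x H x W` numeric array.
#' @param cfg A [seca_config()].
#' @param weights List with `w1` (`(C*k^2) x C4` matrix), `b1` (length C4),
#'   `w2` (`(C4*k^2) x 1`), `b2` (length 1), in the row layout
#'   `c*k^2 + di*k + dj`.
#' @return `1 x H x W` array of gate values in (0, 1).
#' @export
spatial_gate <- function(x, cfg, weights) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  k <- cfg$spatial_kernel
  C4 <- max(cfg$min_width, ceiling(C / cfg$spatial_ratio))
  m <- fm_to_mat(x)
  h1 <- .conv2d_fwd(m, weights$w1, weights$b1, 1L, H, W, k, 1L, (k - 1L) %/% 2L)
  h2 <- .conv2d_fwd(silu(h1), weights$w2, weights$b2, 1L, H, W, k, 1L,
                    (k - 1L) %/% 2L)
  array(sigmoid(t(matrix(h2, W, H))), c(1L, H, W))
}

#' Apply joint channel-spatial attention to a feature map
#'
#' `y = x (.) channel_gate(x); z = y (.) spatial_gate(y)` -- the channel gate
#' first, then the spatial gate on the channel-gated map. Both gates lie in
#' (0, 1), so gating never increases elementwise magnitude.
#'
#' @param x `C x H x W` numeric array.
#' @param cfg A [seca_config()].
#' @param weights List with elements `channel` (see [channel_gate()]) and
#'   `spatial` (see [spatial_gate()]).
#' @return Gated `C x H x W` array.
#' @export
seca_apply <- function(x, cfg, weights) {
  g <- channel_gate(x, cfg, weights$channel)
  y <- x * g
  m <- spatial_gate(y, cfg, weights$spatial)
  y * rep(m[1, , ], each = dim(x)[1])
}

#' Parameters of the non-local self-attention block
#'
#' @param channels Number of channels C of the head feature map.
#' @param dk Key/query/value projection width (defaults to C, square
#'   projections).
#' @param Wq,Wk,Wv `C x dk` projection matrices; random normal if omitted.
#' @param Wz `dk x C` output projection; zero by default so the block is the
#'   identity at initialization.
#' @param residual Add the input back to the projected attention output.
#' @param seed Seed for the default random projections.
#' @return A `nonlocal_params` list.
#' @export
nonlocal_params <- function(channels, dk = channels, Wq = NULL, Wk = NULL,
                            Wv = NULL, Wz = NULL, residual = TRUE, seed = 1L) {
  stopifnot(dk > 0)
  init <- function(m) with_seed(seed + m, matrix(rnorm(channels * dk, 0,
                                                       sqrt(1 / channels)),
                                                 channels, dk))
  p <- list(channels = as.integer(channels), dk = as.integer(dk),
            Wq = Wq %||% init(1), Wk = Wk %||% init(2), Wv = Wv %||% init(3),
            Wz = Wz %||% matrix(0, dk, channels), residual = residual)
  if (!all(vapply(p[c("Wq", "Wk", "Wv", "Wz")],
                  function(m) all(is.finite(m)), logical(1))))
    stop("projection matrices must be finite")
  structure(p, class = "nonlocal_params")
}

#' Scaled dot-product self-attention over spatial positions
#'
#' Computes `softmax(Q K' / sqrt(dk)) V` with `Q = X Wq`, `K = X Wk`,
#' `V = X Wv` and a row-wise softmax (max-subtraction stabilized), so every
#' attention row is a convex combination of the value rows.
#'
#' @param X `N x C` matrix of flattened spatial positions.
#' @param p A [nonlocal_params()].
#' @return `N x dk` matrix of attended values.
#' @export
scaled_attention <- function(X, p) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in attention input")
  attention_forward(X, p$Wq, p$Wk, p$Wv, p$dk)$O
}

#' Non-local attention block on a head feature map
#'
#' Flattens `C x H x W` to `N x C` positions, applies [scaled_attention()],
#' projects back with `Wz`, reshapes, and adds the input when `residual` is
#' set. With `Wz = 0` and the residual on, the block is exactly the identity.
#'
#' @param x `C x H x W` numeric array.
#' @param p A [nonlocal_params()].
#' @return `C x H x W` array.
#' @export
nonlocal_block <- function(x, p) {
  d <- dim(x)
  X <- fm_to_mat(x)
  Y <- scaled_attention(X, p) %*% p$Wz
  if (isTRUE(p$residual)) Y <- Y + X
  mat_to_fm(Y, d[2], d[3])
}
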