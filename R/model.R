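# Network assembly: compound-scaled MBConv backbone (16 blocks at scale
# exponent zero), either squeeze-excite (baseline) or joint channel-spatial
# attention in every block, optional non-local head block, global average
# pooling, dropout and a linear classifier. Also the analytic parameter and
# floating-point-operation accounting.

#' Compound-scaling configuration
#'
#' @param phi Compound scaling exponent (0 = the unscaled base network).
#' @param alpha,beta,gamma Depth, width and resolution bases; the constraint
#'   `alpha * beta^2 * gamma^2` should be close to 2 so each increment of
#'   `phi` roughly doubles the computational cost.
#' @return A `scaling_config` list.
#' @export
scaling_config <- function(phi = 0, alpha = 1.2, beta = 1.1, gamma = 1.15) {
  structure(list(phi = phi, alpha = alpha, beta = beta, gamma = gamma),
            class = "scaling_config")
}

#' Depth/width/resolution multipliers from a compound-scaling exponent
#'
#' Returns `(alpha^phi, beta^phi, gamma^phi)` and checks the constraint
#' `alpha * beta^2 * gamma^2` (approximately 2); a value outside `[1.8, 2.2]`
#' raises a warning.
#'
#' @param s A [scaling_config()].
#' @return Named numeric vector with elements `depth`, `width`, `resolution`.
#' @export
compound_scale <- function(s) {
  stopifnot(inherits(s, "scaling_config"))
  if (s$phi < 0) stop("compound exponent phi must be nonnegative")
  if (any(c(s$alpha, s$beta, s$gamma) < 1))
    stop("scaling bases must be at least 1")
  cv <- s$alpha * s$beta^2 * s$gamma^2
  if (cv < 1.8 || cv > 2.2)
    warning(sprintf(
      "compound constraint alpha*beta^2*gamma^2 = %.3g outside [1.8, 2.2]", cv))
  c(depth = s$alpha^s$phi, width = s$beta^s$phi, resolution = s$gamma^s$phi)
}

# The canonical base layout: 16 MBConv blocks in 7 stages, expansion 1 then 6.
base_blocks <- function() {
  data.frame(
    kernel = c(3L, 3L, 5L, 3L, 5L, 5L, 3L),
    expansion = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    out_ch = c(16L, 24L, 40L, 80L, 112L, 192L, 320L),
    stride = c(1L, 2L, 2L, 2L, 1L, 2L, 1L),
    repeats = c(1L, 2L, 2L, 3L, 3L, 4L, 1L)
  )
}

# Width scaling with the usual divisor-8 rounding.
round_filters <- function(f, width_mult, divisor = 8L) {
  f <- f * width_mult
  new <- max(divisor, as.integer(f + divisor / 2) %/% divisor * divisor)
  if (new < 0.9 * f) new <- new + divisor
  as.integer(new)
}

round_repeats <- function(r, depth_mult) as.integer(ceiling(r * depth_mult))

#' Model configuration
#'
#' @param attention Attention inside each MBConv block: `"se"`
#'   (squeeze-excite; the baseline), `"seca"` (joint channel-spatial
#'   attention) or `"none"`.
#' @param use_nonlocal Insert the non-local self-attention block between the
#'   head convolution and the pooling layer.
#' @param num_classes Number of output classes (4 estrous stages).
#' @param dropout Dropout rate before the classifier, in `[0, 1)`.
#' @param scaling A [scaling_config()]; its `phi` sets the compound scale.
#' @param width_mult,depth_mult Extra multipliers applied on top of the
#'   compound scale (used for reduced desk-scale models, e.g. 0.5 width).
#' @param input_size Input resolution in pixels (square).
#' @param seca_channel Channel-branch form of the joint attention block:
#'   `"bottleneck"` (two pointwise 1D convolutions with reduction ratio 4
#'   across the pooled descriptor, the configuration that reproduces the
#'   published parameter budget) or `"local"` (a single k-wide sliding 1D
#'   convolution with the adaptive kernel rule).
#' @param seca_ratio,seca_kernel,seca_min_width Spatial-branch geometry: its
#'   reduction ratio, convolution kernel and minimum reduced width.
#' @param nonlocal_dk Projection width of the non-local block; `NULL` means
#'   square projections (`dk` = head channels).
#' @return A `model_config` list with the resolved per-block layout.
#' @export
model_config <- function(attention = c("se", "seca", "none"),
                         use_nonlocal = FALSE, num_classes = 4L,
                         dropout = 0.2, scaling = scaling_config(),
                         width_mult = 1, depth_mult = 1,
                         input_size = 224L,
                         seca_channel = c("bottleneck", "local"),
                         seca_ratio = 4L, seca_kernel = 7L,
                         seca_min_width = 8L, nonlocal_dk = NULL) {
  attention <- match.arg(attention)
  seca_channel <- match.arg(seca_channel)
  stopifnot(dropout >= 0, dropout < 1, num_classes >= 2)
  mult <- compound_scale(scaling)
  wm <- mult[["width"]] * width_mult
  dm <- mult[["depth"]] * depth_mult
  bl <- base_blocks()
  bl$out_ch <- vapply(bl$out_ch, round_filters, integer(1), width_mult = wm)
  bl$repeats <- vapply(bl$repeats, round_repeats, integer(1), depth_mult = dm)
  structure(list(
    attention = attention, use_nonlocal = use_nonlocal,
    num_classes = as.integer(num_classes), dropout = dropout,
    scaling = scaling, width_mult = width_mult, depth_mult = depth_mult,
    blocks = bl,
    stem_ch = round_filters(32L, wm),
    head_channels = round_filters(1280L, wm),
    input_size = as.integer(input_size),
    seca = list(ratio = as.integer(seca_ratio),
                kernel = as.integer(seca_kernel),
                min_width = as.integer(seca_min_width),
                channel = seca_channel, channel_kernel = NULL),
    nonlocal_dk = nonlocal_dk
  ), class = "model_config")
}

#' Build the classification network
#'
#' Assembles stem convolution, the MBConv stages with the configured
#' attention, the 1x1 head convolution, the optional non-local block, global
#' average pooling, dropout and the linear classifier. All parameters are
#' initialized from the given seed, so two builds with the same seed have
#' identical initial weights; the non-local output projection starts at zero,
#' making that block the identity at initialization.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `slenet_model` list with the module graph and parameter set.
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    mods <- list()
    Hc <- cfg$input_size; Wc <- cfg$input_size
    stem <- mod_conv(3L, cfg$stem_ch, 3L, 2L, Hc, Wc)
    Hc <- stem$Ho; Wc <- stem$Wo
    mods <- c(mods, list(stem, mod_bn_silu(cfg$stem_ch, Hc, Wc)))
    cin <- cfg$stem_ch
    for (i in seq_len(nrow(cfg$blocks))) {
      b <- cfg$blocks[i, ]
      for (j in seq_len(b$repeats)) {
        stride <- if (j == 1L) b$stride else 1L
        blk <- mod_mbconv(cin, b$out_ch, b$kernel, b$expansion, stride,
                          Hc, Wc, attention = cfg$attention, seca = cfg$seca)
        Hc <- blk$Ho; Wc <- blk$Wo
        cin <- b$out_ch
        mods <- c(mods, list(blk))
      }
    }
    head <- mod_conv(cin, cfg$head_channels, 1L, 1L, Hc, Wc)
    mods <- c(mods, list(head, mod_bn_silu(cfg$head_channels, Hc, Wc)))
    if (cfg$use_nonlocal) {
      dk <- cfg$nonlocal_dk %||% cfg$head_channels
      mods <- c(mods, list(mod_nonlocal(cfg$head_channels, Hc, Wc, dk = dk)))
    }
    mods <- c(mods, list(mod_gap(cfg$head_channels, Hc, Wc),
                         mod_dropout(cfg$head_channels, cfg$dropout),
                         mod_linear(cfg$head_channels, cfg$num_classes)))
    structure(list(config = cfg, modules = mods, seed = as.integer(seed)),
              class = "slenet_model")
  })
}

#' @export
print.slenet_model <- function(x, ...) {
  cfg <- x$config
  cat("<slenet_model>", cfg$attention, "attention,",
      if (cfg$use_nonlocal) "with" else "no", "non-local head\n")
  cat("  input", cfg$input_size, "x", cfg$input_size,
      "| head", cfg$head_channels, "| classes", cfg$num_classes, "\n")
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Forward pass of a built network
#'
#' @param model A `slenet_model`.
#' @param x Input batch as a `(B * S * S) x 3` matrix (see [load_images()]),
#'   already normalized to the network input range.
#' @param B Batch size.
#' @param training Logical; enables batch statistics, dropout and caching for
#'   backprop.
#' @return `B x num_classes` logit matrix.
#' @export
network_forward <- function(model, x, B, training = FALSE) {
  for (m in model$modules) x <- m$forward(x, B, training)
  x
}

network_backward <- function(model, dlogits) {
  dy <- dlogits
  for (m in rev(model$modules)) dy <- m$backward(dy)
  dy
}

#' Count trainable parameters
#'
#' @param model A `slenet_model` (or any module list).
#' @return Integer number of trainable scalars.
#' @export
count_parameters <- function(model) {
  ps <- collect_params(model)
  sum(vapply(ps, function(p) length(p$value), numeric(1)))
}

flatten_leaf_modules <- function(mods) {
  out <- list()
  for (m in mods) {
    if (!is.null(m$submodules) && m$type %in% c("sequential", "mbconv",
                                                "spatial_gate")) {
      out <- c(out, flatten_leaf_modules(m$submodules))
    } else {
      out <- c(out, list(m))
    }
  }
  out
}

#' Analytic floating-point operation count per forward pass
#'
#' Layer-wise closed-form counting: convolutions and linear layers contribute
#' `ops_per_mac * (kernel * kernel * C_in) * C_out * H_out * W_out` (plus one
#' add per output element when a bias is present), attention matrix products
#' contribute their full multiply-accumulate counts (projections,
#' query-key products and value aggregation), channel gates contribute their
#' pooled-descriptor products. Normalization, activations, pooling and
#' elementwise gating multiplies are excluded. The default convention counts
#' multiply and add separately (`ops_per_mac = 2`).
#'
#' @param model A built `slenet_model`.
#' @param ops_per_mac Operations counted per multiply-accumulate (2 counts
#'   multiply and add separately; 1 counts fused MACs).
#' @return Total operation count (numeric, single forward pass, batch 1).
#' @export
count_flops <- function(model, ops_per_mac = 2) {
  leaves <- flatten_leaf_modules(model$modules)
  total <- 0
  for (m in leaves) {
    total <- total + switch(m$type,
      conv = ops_per_mac * m$k^2 * m$cin * m$cout * m$Ho * m$Wo +
        (if (isTRUE(m$bias)) m$Ho * m$Wo * m$cout else 0),
      depthwise = ops_per_mac * m$k^2 * m$cin * m$Ho * m$Wo,
      linear = ops_per_mac * m$cin * m$cout + m$cout,
      channel_gate = ops_per_mac * 2 * m$cin * m$squeeze,
      channel_gate_local = ops_per_mac * m$k * m$cin,
      nonlocal = {
        N <- m$H * m$W
        ops_per_mac * (3 * N * m$cin * m$dk + 2 * N^2 * m$dk +
                         N * m$dk * m$cin)
      },
      bn = 0, bn_silu = 0, act = 0, gap = 0, dropout = 0,
      stop("unsupported layer type in FLOP accounting: ", m$type))
  }
  total
}

#' Calibrated complexity comparison of two models
#'
#' The published complexity table for this architecture family reports
#' operation counts far above any single standard analytic convention, so the
#' convention here is explicitly a calibration: raw analytic counts (see
#' [count_flops()]) are rescaled by a single constant chosen so that the
#' baseline model reproduces the reference figure `anchor_gflops`. The
#' baseline's calibrated value is therefore the anchor by construction; the
#' full model's calibrated value, and the ratio between the two, carry the
#' information.
#'
#' @param baseline,full Built `slenet_model` objects.
#' @param anchor_gflops Reference figure (in GFLOPs) the baseline is anchored
#'   to.
#' @param ops_per_mac Passed to [count_flops()].
#' @return List with raw counts, the calibration scale, calibrated GFLOPs for
#'   both models, and their ratio.
#' @export
flops_report <- function(baseline, full, anchor_gflops = 6.58,
                         ops_per_mac = 2) {
  raw_base <- count_flops(baseline, ops_per_mac)
  raw_full <- count_flops(full, ops_per_mac)
  scale <- anchor_gflops * 1e9 / raw_base
  list(raw_base = raw_base, raw_full = raw_full, calibration_scale = scale,
       base_gflops = raw_base * scale / 1e9,
       full_gflops = raw_full * scale / 1e9,
       ratio = raw_full / raw_base)
}

#' Parameter, FLOP and timing report for one configuration
#'
#' @param cfg A [model_config()].
#' @param seed Build seed.
#' @param time_runs Number of timed single-image forward passes to average
#'   (informational only; wall-clock milliseconds are hardware-dependent).
#' @return List with `parameter_count`, `flop_count` (raw analytic count) and
#'   `inference_ms`.
#' @export
complexity_report <- function(cfg, seed = 0L, time_runs = 5L) {
  model <- build_model(cfg, seed)
  x <- matrix(0.1, cfg$input_size^2, 3L)
  ms <- vapply(seq_len(time_runs), function(i) {
    t0 <- proc.time()[["elapsed"]]
    network_forward(model, x, 1L, training = FALSE)
    (proc.time()[["elapsed"]] - t0) * 1000
  }, numeric(1))
  list(parameter_count = count_parameters(model),
       flop_count = count_flops(model),
       inference_ms = mean(ms))
}
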