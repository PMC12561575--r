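# Synthetic vaginal-smear simulator. Stage-specific mixtures of leukocytes,
# nucleated epithelial cells and cornified (anucleated, keratinized) cells are
# drawn onto a methylene-blue-like background with a low-frequency illumination
# field and pixel noise, so the classification pipeline can be exercised with
# labeled images generated entirely in code.

#' Cell kinds present in vaginal smears
#'
#' @return Character vector of the three cell kinds: small round leukocytes,
#'   round/oval nucleated epithelial cells, and anucleated cornified
#'   (keratinized) epithelial cells.
#' @export
cell_kinds <- function() c("leukocyte", "nucleated_epithelial", "cornified")

#' Default per-stage cell composition for the simulator
#'
#' Mean cell counts per kind and stage used by [sample_scene()]. The
#' qualitative composition rules are cytological: diestrus (D) is dominated by
#' leukocytes with few nucleated cells and no cornified cells; proestrus (P)
#' by nucleated epithelial cells with a small number of cornified cells and no
#' leukocytes; estrus (E) contains only cornified cells; metestrus (M) is a
#' mixture of all three. The numeric means are simulator choices (not
#' biological measurements) picked with wide margins so that Poisson draws
#' satisfy the qualitative rules with overwhelming probability.
#'
#' @return A data frame with columns `stage`, `kind` and `mean_count`.
#' @export
sim_params <- function() {
  data.frame(
    stage = c("D", "D", "P", "P", "E", "M", "M", "M"),
    kind = c("leukocyte", "nucleated_epithelial",
             "nucleated_epithelial", "cornified",
             "cornified",
             "leukocyte", "nucleated_epithelial", "cornified"),
    mean_count = c(120, 8, 60, 6, 70, 30, 25, 40),
    stringsAsFactors = FALSE
  )
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  code
}

stage_rule_counts <- function(n_leu, n_nuc, n_cor) {
  ok <- character(0)
  if (n_cor >= 1 && n_leu == 0 && n_nuc == 0) ok <- c(ok, "E")
  if (n_leu == 0 && n_nuc > n_cor && n_nuc > 0) ok <- c(ok, "P")
  if (n_cor == 0 && n_leu > n_nuc && n_leu > 0) ok <- c(ok, "D")
  if (n_leu >= 1 && n_nuc >= 1 && n_cor >= 1) ok <- c(ok, "M")
  ok
}

#' Sample the ground-truth description of one synthetic smear
#'
#' Draws per-kind cell counts from Poisson distributions with the stage's mean
#' composition, rejecting and resampling any draw that violates the stage's
#' qualitative composition rule, then places cells with randomized geometry
#' (position, size, elongation, orientation, stain intensity, and polygon
#' irregularity for cornified cells). Leukocytes are the smallest cells and
#' always nucleated; cornified cells are anucleated.
#'
#' @param stage One of `"P"`, `"E"`, `"M"`, `"D"`.
#' @param params Composition table as returned by [sim_params()].
#' @param seed Integer seed; identical seeds give identical scenes.
#' @param canvas Canvas side length in pixels the coordinates refer to.
#' @return An object of class `scene_spec`: a list with the stage, a data
#'   frame of cell records, background/illumination/noise parameters and the
#'   seed.
#' @export
sample_scene <- function(stage, params = sim_params(), seed = 0L,
                         canvas = 448L) {
  if (length(stage) != 1L || !stage %in% STAGES)
    stop("unknown stage '", paste(stage, collapse = ","),
         "'; must be one of ", paste(STAGES, collapse = ", "))
  pp <- params[params$stage == stage, , drop = FALSE]
  means <- setNames(numeric(3), cell_kinds())
  means[pp$kind] <- pp$mean_count
  with_seed(seed, {
    repeat {
      n <- setNames(rpois(3, means), cell_kinds())
      ok <- stage_rule_counts(n["leukocyte"], n["nucleated_epithelial"],
                              n["cornified"])
      if (identical(ok, stage)) break
    }
    cells <- do.call(rbind, lapply(cell_kinds(), function(kind) {
      m <- n[[kind]]
      if (m == 0) return(NULL)
      radius <- switch(kind,
        leukocyte = runif(m, 3, 6),
        nucleated_epithelial = runif(m, 10, 18),
        cornified = runif(m, 18, 30))
      data.frame(
        kind = kind,
        x = runif(m, 1, canvas), y = runif(m, 1, canvas),
        radius = radius,
        elongation = switch(kind,
          leukocyte = rep(1, m),
          nucleated_epithelial = runif(m, 1, 1.3),
          cornified = runif(m, 1, 1.6)),
        orientation = runif(m, 0, 2 * pi),
        stain_intensity = switch(kind,
          leukocyte = runif(m, 0.75, 0.95),
          nucleated_epithelial = runif(m, 0.5, 0.75),
          cornified = runif(m, 0.25, 0.5)),
        has_nucleus = kind != "cornified",
        vertex_jitter = if (kind == "cornified") runif(m, 0.1, 0.35) else rep(0, m),
        stringsAsFactors = FALSE)
    }))
    if (is.null(cells)) cells <- empty_cells()
    # cornified first so small dark cells overlap large pale ones (back-to-front)
    cells <- cells[order(match(cells$kind, rev(cell_kinds()))), , drop = FALSE]
    rownames(cells) <- NULL
    structure(list(
      stage = stage, cells = cells, canvas = as.integer(canvas),
      background_level = runif(1, 0.88, 0.96),
      illumination = list(amp = runif(1, 0.05, 0.15),
                          fx = runif(1, 0.5, 1.5), fy = runif(1, 0.5, 1.5),
                          phx = runif(1), phy = runif(1)),
      noise_sd = runif(1, 1.5, 3.5),
      rng_seed = as.integer(seed)
    ), class = "scene_spec")
  })
}

empty_cells <- function() {
  data.frame(kind = character(0), x = numeric(0), y = numeric(0),
             radius = numeric(0), elongation = numeric(0),
             orientation = numeric(0), stain_intensity = numeric(0),
             has_nucleus = logical(0), vertex_jitter = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec> stage", x$stage, "with", nrow(x$cells), "cells (",
      paste(names(table(x$cells$kind)), table(x$cells$kind),
            collapse = ", "), ")\n")
  invisible(x)
}

# Deep stain colors (0-255 RGB) at stain_intensity 1; rendering interpolates
# toward white as intensity decreases (methylene blue: blue/violet hues).
cell_base_color <- function(kind) {
  switch(kind,
    leukocyte = c(60, 50, 140),
    nucleated_epithelial = c(120, 130, 205),
    cornified = c(150, 160, 215),
    nucleus = c(55, 45, 135))
}

# Anti-aliased alpha mask for one cell on the (sub)grid given rotated
# coordinates; cornified cells are star-shaped polygons with per-vertex radial
# wobble, other kinds are (elongated) discs.
cell_alpha <- function(u, v, cell, wobble, edge = 1.25) {
  d <- sqrt((u / cell$elongation)^2 + v^2)
  if (cell$kind == "cornified") {
    nv <- length(wobble)
    th <- atan2(v, u / cell$elongation) %% (2 * pi)
    pos <- th / (2 * pi) * nv
    k0 <- floor(pos) %% nv
    t <- pos - floor(pos)
    rv <- cell$radius * (1 + cell$vertex_jitter * wobble)
    rb <- rv[k0 + 1] * (1 - t) + rv[(k0 + 1) %% nv + 1] * t
    pmin(pmax((rb - d) / edge, 0), 1)
  } else {
    pmin(pmax((cell$radius - d) / edge, 0), 1)
  }
}

# Rasterize one cell: linear pixel indices within the H x W canvas and the
# anti-aliased coverage at those pixels. Works on the cell's bounding box
# only; returns NULL when the cell misses the canvas.
cell_patch <- function(cell, scale, H, W, radius_frac = 1, wobble = NULL) {
  cx <- cell$x * scale
  cy <- cell$y * scale
  r <- cell$radius * scale * cell$elongation * 1.6 + 2
  if (cx + r < 1 || cx - r > W || cy + r < 1 || cy - r > H) return(NULL)
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  nx <- length(xs); ny <- length(ys)
  dx <- rep(xs - cx, each = ny)
  dy <- rep(ys - cy, times = nx)
  u <- dx * cos(cell$orientation) + dy * sin(cell$orientation)
  v <- -dx * sin(cell$orientation) + dy * cos(cell$orientation)
  cs <- cell
  cs$radius <- cell$radius * scale * radius_frac
  alpha <- cell_alpha(u, v, cs, wobble)
  hit <- which(alpha > 0)
  if (!length(hit)) return(NULL)
  list(li = (rep.int(ys, nx) + (rep(xs, each = ny) - 1L) * H)[hit],
       a = alpha[hit])
}

#' Render a synthetic smear image from its scene description
#'
#' Deterministic given the scene: polygon wobble and pixel noise are drawn
#' from the scene's own seed. Cells are painted back-to-front (large pale
#' cornified polygons first, small dark leukocytes last) with anti-aliased
#' edges, over an off-white background modulated by a low-frequency
#' multiplicative illumination field; Gaussian luminance noise is added last
#' and the result clamped to [0, 255].
#'
#' @param scene A `scene_spec`.
#' @param size Integer vector `c(H, W)`, both at least 64.
#' @return An `H x W x 3` numeric array with values in [0, 255].
#' @export
render_scene <- function(scene, size = c(448L, 448L)) {
  stopifnot(inherits(scene, "scene_spec"))
  if (length(size) != 2L || any(size < 64))
    stop("render size must give H and W of at least 64 pixels")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  scale <- H / scene$canvas
  with_seed(scene$rng_seed * 2654435761 %% 2147483647 + 1, {
    il <- scene$illumination
    gx <- (seq_len(W) - 0.5) / W
    gy <- (seq_len(H) - 0.5) / H
    field <- 1 + il$amp *
      outer(sin(2 * pi * (il$fy * gy + il$phy)),
            sin(2 * pi * (il$fx * gx + il$phx)))
    bg <- 255 * scene$background_level * c(0.96, 0.97, 1.00)
    m1 <- bg[1] * field
    m2 <- bg[2] * field
    m3 <- bg[3] * field
    cells <- scene$cells
    if (nrow(cells) > 0) {
      cols <- lapply(cells, identity)
      for (i in seq_len(nrow(cells))) {
        cell <- lapply(cols, `[`, i)
        wobble <- if (cell$kind == "cornified") runif(8, -1, 1) else NULL
        col3 <- cell_base_color(cell$kind)
        s <- cell$stain_intensity
        p <- cell_patch(cell, scale, H, W, wobble = wobble)
        if (!is.null(p)) {
          keep <- 1 - p$a
          m1[p$li] <- m1[p$li] * keep + (255 * (1 - s) + col3[1] * s) * p$a
          m2[p$li] <- m2[p$li] * keep + (255 * (1 - s) + col3[2] * s) * p$a
          m3[p$li] <- m3[p$li] * keep + (255 * (1 - s) + col3[3] * s) * p$a
        }
        if (isTRUE(cell$has_nucleus) && cell$kind == "nucleated_epithelial") {
          sn <- min(1, s + 0.3)
          coln <- cell_base_color("nucleus")
          p <- cell_patch(cell, scale, H, W, radius_frac = 0.35)
          if (!is.null(p)) {
            keep <- 1 - p$a
            m1[p$li] <- m1[p$li] * keep + (255 * (1 - sn) + coln[1] * sn) * p$a
            m2[p$li] <- m2[p$li] * keep + (255 * (1 - sn) + coln[2] * sn) * p$a
            m3[p$li] <- m3[p$li] * keep + (255 * (1 - sn) + coln[3] * sn) * p$a
          }
        }
      }
    }
    noise <- matrix(rnorm(H * W, 0, scene$noise_sd), H, W)
    img <- array(0, dim = c(H, W, 3))
    img[, , 1] <- m1 + noise
    img[, , 2] <- m2 + noise
    img[, , 3] <- m3 + noise
    img[img < 0] <- 0
    img[img > 255] <- 255
    img
  })
}

#' Infer the stage of a scene from its ground-truth cell counts
#'
#' Applies the cytological composition rules (estrus: only cornified cells;
#' proestrus: nucleated cells outnumbering cornified, no leukocytes; diestrus:
#' leukocytes outnumbering nucleated cells, no cornified; metestrus: all three
#' kinds present) to the scene's cell list. Used as an oracle for checking
#' that sampled scenes are separable by composition alone.
#'
#' @param scene A `scene_spec` (or any list with a `cells` data frame).
#' @return A stage code, or `"ambiguous"` if no rule (or more than one rule)
#'   matches.
#' @export
rule_based_stager <- function(scene) {
  if (is.null(scene$cells)) stop("scene has no ground-truth cell list")
  n <- table(factor(scene$cells$kind, levels = cell_kinds()))
  ok <- stage_rule_counts(n[["leukocyte"]], n[["nucleated_epithelial"]],
                          n[["cornified"]])
  if (length(ok) == 1L) ok else "ambiguous"
}

#' Generate a labeled synthetic smear dataset on disk
#'
#' Writes one image per requested record and returns the dataset manifest.
#' Generation is bit-reproducible given `counts` and `seed`: each record's
#' scene seed is derived deterministically from the generator seed.
#'
#' @param counts Named integer vector of per-stage image counts, e.g.
#'   `c(P = 646, E = 672, M = 670, D = 667)`.
#' @param outdir Output directory (created if missing).
#' @param seed Integer generator seed.
#' @param format `"png"` (lossless, default) or `"jpg"` (quality 95; requires
#'   the EBImage package).
#' @param size Rendered image side length in pixels (square canvas).
#' @param params Composition table, see [sim_params()].
#' @return A `dataset_manifest`: data frame with columns `path`, `stage`,
#'   `split` (all `"unassigned"`), with attributes `class_counts` and
#'   `generator_seed`.
#' @export
generate_dataset <- function(counts, outdir, seed = 0L, format = c("png", "jpg"),
                             size = 448L, params = sim_params()) {
  format <- match.arg(format)
  if (is.null(names(counts)) || !all(names(counts) %in% STAGES))
    stop("counts must be a named vector with names among P, E, M, D")
  counts <- counts[STAGES[STAGES %in% names(counts)]]
  if (any(counts < 0)) stop("negative image count requested")
  if (any(counts != floor(counts))) stop("counts must be whole numbers")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory ", outdir)
  }
  if (format == "jpg" && !requireNamespace("EBImage", quietly = TRUE))
    stop("JPG output requires the EBImage package; use format = 'png'")
  recs <- list()
  idx <- 0L
  for (stage in names(counts)) {
    for (i in seq_len(counts[[stage]])) {
      idx <- idx + 1L
      scene_seed <- (as.double(seed) * 7919 + idx * 104729) %% 2147483629
      scene <- sample_scene(stage, params, seed = scene_seed, canvas = size)
      img <- render_scene(scene, c(size, size))
      path <- file.path(outdir, sprintf("%s_%05d.%s", stage, idx, format))
      if (format == "png") {
        png::writePNG(img / 255, path)
      } else {
        EBImage::writeImage(EBImage::Image(aperm(img / 255, c(2, 1, 3)),
                                           colormode = "Color"),
                            path, quality = 95)
      }
      recs[[idx]] <- data.frame(path = path, stage = stage,
                                split = "unassigned", stringsAsFactors = FALSE)
    }
  }
  man <- if (length(recs)) do.call(rbind, recs) else
    data.frame(path = character(0), stage = character(0), split = character(0),
               stringsAsFactors = FALSE)
  as_manifest(man, generator_seed = as.integer(seed))
}

as_manifest <- function(df, generator_seed = NA_integer_) {
  stopifnot(all(c("path", "stage", "split") %in% names(df)))
  if (anyDuplicated(df$path)) stop("manifest paths must be unique")
  cc <- table(factor(df$stage, levels = STAGES))
  structure(df, class = c("dataset_manifest", "data.frame"),
            class_counts = setNames(as.integer(cc), STAGES),
            generator_seed = generator_seed)
}

#' Class counts of a dataset manifest
#' @param manifest A `dataset_manifest`.
#' @return Named integer vector of per-stage record counts.
#' @export
class_counts <- function(manifest) attr(manifest, "class_counts")

#' Write / read a dataset manifest as CSV
#'
#' The on-disk dialect has a `path,stage,split` header; `stage` is one of
#' P, E, M, D and `split` one of train, val, test, unassigned.
#'
#' @param manifest A `dataset_manifest`.
#' @param file CSV file path.
#' @return `write_manifest` returns `file` invisibly; `read_manifest` returns
#'   a `dataset_manifest`.
#' @export
write_manifest <- function(manifest, file) {
  write.csv(as.data.frame(manifest)[, c("path", "stage", "split")], file,
            row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$stage), STAGES)
  if (length(bad)) stop("unknown stage label(s) in manifest: ",
                        paste(bad, collapse = ", "))
  as_manifest(df)
}
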