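test_that("sampled scenes satisfy the stage composition rules", {
  for (stage in stage_levels()) {
    for (seed in 1:8) {
      sc <- sample_scene(stage, seed = seed)
      n <- table(factor(sc$cells$kind, levels = cell_kinds()))
      leu <- n[["leukocyte"]]; nuc <- n[["nucleated_epithelial"]]
      cor <- n[["cornified"]]
      switch(stage,
        E = { expect_equal(leu, 0L); expect_equal(nuc, 0L)
              expect_gt(cor, 0L) },
        P = { expect_equal(leu, 0L); expect_gt(nuc, cor) },
        D = { expect_gt(leu, nuc); expect_equal(cor, 0L) },
        M = { expect_gte(min(leu, nuc, cor), 1L) })
      # leukocytes are always nucleated and smaller than epithelial cells
      isleu <- sc$cells$kind == "leukocyte"
      if (any(isleu)) {
        expect_true(all(sc$cells$has_nucleus[isleu]))
        if (any(sc$cells$kind == "nucleated_epithelial"))
          expect_lt(max(sc$cells$radius[isleu]),
                    min(sc$cells$radius[sc$cells$kind == "nucleated_epithelial"]))
      }
      expect_false(any(sc$cells$has_nucleus[sc$cells$kind == "cornified"]))
    }
  }
})

test_that("scene sampling is seed-deterministic and rejects unknown stages", {
  a <- sample_scene("D", seed = 3)
  b <- sample_scene("D", seed = 3)
  expect_identical(a$cells, b$cells)
  expect_identical(a$background_level, b$background_level)
  expect_error(sample_scene("X", seed = 1), "unknown stage")
})

test_that("rendering is deterministic, bounded, and empty scenes are pure background", {
  sc <- sample_scene("M", seed = 5)
  img1 <- render_scene(sc, c(128, 128))
  img2 <- render_scene(sc, c(128, 128))
  expect_identical(img1, img2)
  expect_true(all(is.finite(img1)))
  expect_gte(min(img1), 0)
  expect_lte(max(img1), 255)

  empty <- sc
  empty$cells <- empty$cells[0, ]
  bg <- render_scene(empty, c(128, 128))
  # background + illumination + noise only: reconstruct it directly
  il <- sc$illumination
  gx <- (seq_len(128) - 0.5) / 128
  field <- 1 + il$amp * outer(sin(2 * pi * (il$fy * gx + il$phy)),
                              sin(2 * pi * (il$fx * gx + il$phx)))
  base <- 255 * sc$background_level * 0.96 * field
  # channel 1 must equal base + noise; noise has small sd, so deviations from
  # the noise-free field stay within a few sigmas everywhere
  expect_lt(max(abs(bg[, , 1] - base)), 6 * sc$noise_sd)
  expect_error(render_scene(sc, c(32, 32)), "at least 64")
})

test_that("a rendered leukocyte is darker than the surrounding background", {
  sc <- sample_scene("E", seed = 2, canvas = 128)
  sc$cells <- data.frame(kind = "leukocyte", x = 64, y = 64, radius = 10,
                         elongation = 1, orientation = 0,
                         stain_intensity = 0.9, has_nucleus = TRUE,
                         vertex_jitter = 0, stringsAsFactors = FALSE)
  img <- render_scene(sc, c(128, 128))
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  yy <- rep(1:128, times = 128)
  xx <- rep(1:128, each = 128)
  d <- sqrt((yy - 64)^2 + (xx - 64)^2)
  expect_lt(mean(lum[d <= 8]), mean(lum[d >= 20]))
})

test_that("the rule-based stager recovers stages and flags ambiguity", {
  mkscene <- function(kinds) {
    structure(list(cells = data.frame(kind = kinds, stringsAsFactors = FALSE)),
              class = "scene_spec")
  }
  expect_equal(rule_based_stager(mkscene(rep("cornified", 50))), "E")
  expect_equal(rule_based_stager(
    mkscene(c(rep("leukocyte", 100), rep("nucleated_epithelial", 5)))), "D")
  expect_equal(rule_based_stager(mkscene(character(0))), "ambiguous")
  expect_error(rule_based_stager(list()), "no ground-truth")
  # composition oracle agrees with the generating stage for sampled scenes
  for (stage in stage_levels()) {
    agree <- vapply(1:100, function(s)
      rule_based_stager(sample_scene(stage, seed = s)) == stage, logical(1))
    expect_true(all(agree))
  }
})

test_that("dataset generation writes reproducible files and a valid manifest", {
  d1 <- file.path(tempdir(), "cyt1")
  d2 <- file.path(tempdir(), "cyt2")
  counts <- c(P = 2L, E = 2L, M = 2L, D = 2L)
  m1 <- generate_dataset(counts, d1, seed = 42, size = 96)
  m2 <- generate_dataset(counts, d2, seed = 42, size = 96)
  expect_equal(nrow(m1), 8L)
  expect_equal(unname(class_counts(m1)), rep(2L, 4))
  expect_true(all(m1$split == "unassigned"))
  expect_false(anyDuplicated(m1$path) > 0)
  h1 <- tools::md5sum(m1$path)
  h2 <- tools::md5sum(m2$path)
  expect_identical(unname(h1), unname(h2))

  empty <- generate_dataset(c(P = 0L, E = 0L, M = 0L, D = 0L),
                            file.path(tempdir(), "cyt0"), seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(generate_dataset(c(P = -1), tempdir(), 1), "negative")

  csv <- tempfile(fileext = ".csv")
  write_manifest(m1, csv)
  back <- read_manifest(csv)
  expect_equal(back$path, m1$path)
  expect_equal(back$stage, m1$stage)
  expect_equal(class_counts(back), class_counts(m1))
  unlink(c(d1, d2), recursive = TRUE)
})
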