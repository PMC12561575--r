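test_that("the cubic-convolution kernel matches hand-evaluated values", {
  expect_equal(bicubic_weight(0), 1)
  expect_equal(bicubic_weight(1, a = -0.5), 0)
  expect_equal(bicubic_weight(1.5, a = -0.5), -0.0625)
  expect_equal(bicubic_weight(2.5), 0)
  expect_equal(bicubic_weight(-1.5, a = -0.5), -0.0625)
  # branch arithmetic at a = 1
  expect_equal(bicubic_weight(1.5, a = 1), 1 * 1.5^3 - 5 * 1.5^2 + 8 * 1.5 - 4)
})

test_that("the four-neighbour weights are a partition of unity", {
  t <- seq(0, 0.999, length.out = 101)
  for (ti in t) {
    s <- sum(bicubic_weight(ti - (-1:2), a = -0.5))
    expect_lt(abs(s - 1), 1e-12)
  }
})

test_that("bicubic resizing reproduces constants, identity, and the brute-force sum", {
  const <- array(137.5, c(12, 12, 3))
  out <- resize_bicubic(const, c(6, 6))
  expect_equal(max(abs(out - 137.5)), 0, tolerance = 1e-12)

  set.seed(21)
  img <- array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3))
  expect_equal(resize_bicubic(img, c(10, 10)), img, tolerance = 1e-12)

  img16 <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  for (a in c(-0.5, 1)) {
    fast <- resize_bicubic(img16, c(8, 8), a = a)
    slow <- naive_bicubic(img16, 8, 8, a = a)
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
  # upscale goes through the same formula
  up <- resize_bicubic(img16, c(24, 24))
  expect_lt(max(abs(up - naive_bicubic(img16, 24, 24))), 1e-6)
  expect_error(resize_bicubic(array(0, c(3, 3, 3))), "at least 4")
})

test_that("augmentation follows the stated brightness/contrast arithmetic", {
  img <- array(100, c(8, 8, 3))
  cfg <- augment_config()
  id_draw <- list(brightness_factor = 1, contrast_factor = 1,
                  hflip = FALSE, vflip = FALSE, rotation = 0)
  expect_equal(augment_image(img, cfg, draws = id_draw), img)

  br <- augment_image(img, cfg, draws = modifyList(id_draw,
                                                   list(brightness_factor = 1.15)))
  expect_equal(max(abs(br - 115)), 0, tolerance = 1e-12)

  ct <- augment_image(img, cfg, draws = modifyList(id_draw,
                                                   list(contrast_factor = 1.37)))
  expect_equal(ct, img)  # (p - mean) = 0 on constants

  set.seed(5)
  rimg <- array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3))
  r90 <- augment_image(rimg, cfg, draws = modifyList(id_draw,
                                                     list(rotation = 90)))
  r360 <- r90
  for (i in 1:3) r360 <- augment_image(r360, cfg,
                                       draws = modifyList(id_draw,
                                                          list(rotation = 90)))
  expect_equal(r360, rimg)
  hf <- augment_image(rimg, cfg, draws = modifyList(id_draw,
                                                    list(hflip = TRUE)))
  expect_equal(hf[, 8:1, ], rimg)

  set.seed(6)
  out <- augment_image(rimg * 1.9, cfg)
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
})

test_that("6:2:2 splitting reproduces the published sizes and is well-behaved", {
  fake <- function(n) slenet:::as_manifest(
    data.frame(path = sprintf("img%05d.png", seq_len(n)),
               stage = rep(stage_levels(), length.out = n),
               split = "unassigned", stringsAsFactors = FALSE))
  big <- split_manifest(fake(2655), seed = 1)
  expect_equal(as.vector(table(factor(big$split,
                                      c("train", "val", "test")))),
               c(1593L, 531L, 531L))
  ten <- split_manifest(fake(10), seed = 1)
  expect_equal(as.vector(table(factor(ten$split, c("train", "val", "test")))),
               c(6L, 2L, 2L))
  all_train <- split_manifest(fake(7), ratios = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))

  a <- split_manifest(fake(101), seed = 9)
  b <- split_manifest(fake(101), seed = 9)
  expect_identical(a$split, b$split)
  cc <- split_manifest(fake(101), seed = 10)
  expect_false(identical(a$split, cc$split))
  expect_true(all(a$split %in% c("train", "val", "test")))

  expect_error(split_manifest(fake(10), ratios = c(0.6, 0.2, 0.1)), "sum to 1")
  expect_error(split_manifest(a, seed = 2), "already")
})
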