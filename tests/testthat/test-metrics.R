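test_that("confusion matrices tally predictions by true class", {
  cm <- confusion(c("E", "E", "M"), c("E", "M", "M"),
                  class_order = c("E", "M", "D", "P"))
  expect_equal(cm["E", "E"], 1L)
  expect_equal(cm["E", "M"], 1L)
  expect_equal(cm["M", "M"], 1L)
  expect_equal(sum(cm), 3L)

  perfect <- confusion(rep(stage_levels(), 5), rep(stage_levels(), 5))
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  expect_equal(sum(diag(perfect)), 20L)

  empty <- confusion(character(0), character(0))
  expect_true(all(empty == 0))
  expect_error(confusion("E", "Q"), "outside")
  expect_error(confusion(c("E", "M"), "E"), "equal length")
})

test_that("precision, recall, F1 and accuracy reproduce the worked example", {
  # binary one-vs-rest with TP=50, FP=10, FN=10, TN=30
  cm <- structure(matrix(c(50L, 10L, 10L, 30L), 2, 2, byrow = TRUE,
                         dimnames = list(true = c("pos", "neg"),
                                         predicted = c("pos", "neg"))),
                  class = c("confusion_matrix", "matrix"))
  r <- classification_metrics(cm)
  pos <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.8333, tolerance = 1e-4)
  expect_equal(pos$recall, 0.8333, tolerance = 1e-4)
  expect_equal(pos$f1, 0.8333, tolerance = 1e-4)
  expect_equal(r$accuracy, 0.8)

  diagcm <- confusion(rep(stage_levels(), 3), rep(stage_levels(), 3))
  rd <- classification_metrics(diagcm)
  expect_equal(rd$accuracy, 1)
  expect_true(all(rd$per_class$f1 == 1))

  # class never predicted and never present: flagged, metrics 0
  cm0 <- confusion(c("E", "E", "M"), c("E", "E", "M"))
  r0 <- classification_metrics(cm0)
  expect_true(r0$per_class$undefined[r0$per_class$class == "D"])
  expect_equal(r0$per_class$f1[r0$per_class$class == "D"], 0)
})

test_that("derived metrics stay within bounds on random confusion matrices", {
  set.seed(33)
  for (i in 1:20) {
    cm <- confusion(sample(stage_levels(), 40, TRUE),
                    sample(stage_levels(), 40, TRUE))
    r <- classification_metrics(cm)
    vals <- c(r$accuracy, r$per_class$precision, r$per_class$recall,
              r$per_class$f1, r$macro_f1)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(r$accuracy, sum(diag(cm)) / sum(cm))
    expect_gte(r$macro_f1, min(r$per_class$f1))
    expect_lte(r$macro_f1, max(r$per_class$f1))
    expect_equal(r$per_class$f1,
                 ifelse(r$per_class$precision + r$per_class$recall > 0,
                        2 * r$per_class$precision * r$per_class$recall /
                          (r$per_class$precision + r$per_class$recall), 0))
  }
})

test_that("one-vs-rest AUC equals the pairwise oracle and AP behaves at the ends", {
  set.seed(44)
  y <- sample(stage_levels(), 30, TRUE)
  sc <- matrix(runif(30 * 4), 30, 4, dimnames = list(NULL, stage_levels()))
  sc <- sc / rowSums(sc)
  res <- roc_pr_ovr(y, sc)
  for (k in seq_len(4)) {
    lab <- y == stage_levels()[k]
    expect_equal(res$auc[k], mw_auc(lab, sc[, k]), tolerance = 1e-12)
  }
  # scores with heavy ties still match the pairwise-with-ties oracle
  sc2 <- round(sc, 1)
  sc2 <- sc2 / rowSums(sc2)
  res2 <- roc_pr_ovr(y, sc2)
  for (k in seq_len(4)) {
    lab <- y == stage_levels()[k]
    expect_equal(res2$auc[k], mw_auc(lab, sc2[, k]), tolerance = 1e-12)
  }

  # perfect separation
  yb <- c(rep("E", 3), rep("M", 3))
  sp <- cbind(E = c(.9, .8, .7, .2, .1, .3), M = c(.1, .2, .3, .8, .9, .7))
  rp <- roc_pr_ovr(yb, sp, class_order = c("E", "M"))
  expect_equal(rp$auc, c(1, 1))
  expect_equal(rp$ap, c(1, 1))
  # no ranking information
  su <- cbind(E = rep(0.5, 6), M = rep(0.5, 6))
  ru <- roc_pr_ovr(yb, su, class_order = c("E", "M"))
  expect_equal(ru$auc, c(0.5, 0.5))
  # absent class is flagged
  ra <- roc_pr_ovr(rep("E", 4), cbind(E = rep(0.6, 4), M = rep(0.4, 4)),
                   class_order = c("E", "M"))
  expect_true(ra$undefined[ra$class == "M"])
  expect_true(is.na(ra$auc[ra$class == "M"]))
  expect_error(roc_pr_ovr(yb, sp * 2), "sum to 1")
})

test_that("multi-seed summaries reproduce the Student-t interval example", {
  mk <- function(acc) {
    cm <- confusion(rep(stage_levels(), 10), rep(stage_levels(), 10))
    r <- classification_metrics(cm)
    r$accuracy <- acc
    r
  }
  reps <- lapply(c(90, 92, 94, 96, 98), mk)
  s <- multi_seed_summary(reps)
  acc_row <- s$summary[s$summary$metric == "accuracy", ]
  expect_equal(acc_row$mean, 94)
  expect_equal(acc_row$ci_half_width, 2.776445 * sqrt(10) / sqrt(5),
               tolerance = 1e-6)
  expect_equal(acc_row$ci_half_width, 3.926, tolerance = 1e-3)

  same <- multi_seed_summary(lapply(rep(90, 5), mk))
  expect_equal(same$summary$ci_half_width[same$summary$metric == "accuracy"], 0)
  expect_error(multi_seed_summary(reps[1]), "at least 2")
})

test_that("paired F1 tests match t.test and flag degenerate pairs", {
  mkf1 <- function(f1s) {
    cm <- confusion(rep(stage_levels(), 2), rep(stage_levels(), 2))
    r <- classification_metrics(cm)
    r$per_class$f1 <- f1s
    r
  }
  a <- list(mkf1(c(.90, .80, .70, .60)), mkf1(c(.92, .82, .72, .62)),
            mkf1(c(.91, .81, .71, .61)))
  b <- list(mkf1(c(.85, .80, .65, .55)), mkf1(c(.86, .82, .66, .56)),
            mkf1(c(.84, .81, .64, .54)))
  s <- multi_seed_summary(a, comparator = b)
  av <- vapply(a, function(r) r$per_class$f1[1], numeric(1))
  bv <- vapply(b, function(r) r$per_class$f1[1], numeric(1))
  expect_equal(s$p_per_class$p[1], t.test(av, bv, paired = TRUE)$p.value)
  # class 2 has identical pairs in every run -> degenerate, p = 1
  expect_true(s$p_per_class$degenerate[2])
  expect_equal(s$p_per_class$p[2], 1)
  expect_equal(s$p_avg, mean(s$p_per_class$p))
})
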