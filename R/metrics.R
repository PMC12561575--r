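# Multiclass evaluation statistics: confusion matrices, one-vs-rest
# precision/recall/F1, ROC/AUC and precision-recall/AP, and multi-seed
# summaries with Student-t confidence intervals and paired tests.

#' Confusion matrix
#'
#' @param y_true,y_pred Vectors of class labels (character or factor).
#' @param class_order Display order of the classes (rows = true class,
#'   columns = predicted class); defaults to E, M, D, P.
#' @return Integer `K x K` matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, class_order = stage_levels(display = TRUE)) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  bad <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(bad))
    stop("label(s) outside class order: ", paste(bad, collapse = ", "))
  cm <- table(factor(y_true, levels = class_order),
              factor(y_pred, levels = class_order))
  cm <- matrix(as.integer(cm), nrow = length(class_order),
               dimnames = list(true = class_order, predicted = class_order))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest per class: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 the harmonic mean of the two; accuracy is the trace over the total.
#' A zero denominator yields 0 with the class flagged as undefined rather
#' than NaN.
#'
#' @param cm A [confusion()] matrix.
#' @return A `metrics_report` list: `accuracy`, a `per_class` data frame
#'   (precision, recall, f1, undefined flag), and macro averages.
#' @export
classification_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  undefined <- (tp + fp == 0) | (tp + fn == 0)
  per_class <- data.frame(class = classes, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          undefined = as.logical(undefined),
                          stringsAsFactors = FALSE)
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 macro_precision = mean(per_class$precision),
                 macro_recall = mean(per_class$recall),
                 macro_f1 = mean(per_class$f1),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f macro-F1 %.4f\n",
              x$accuracy, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# Binary AUC by threshold-grouped trapezoidal integration of the ROC curve;
# identical to the pairwise (Mann-Whitney) statistic with ties counted 1/2.
binary_auc <- function(labels, scores) {
  pos <- sum(labels)
  neg <- sum(!labels)
  if (pos == 0 || neg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- c(which(diff(sc) != 0), length(sc))
  tps <- cumsum(lab)[grp_end]
  fps <- cumsum(!lab)[grp_end]
  tpr <- c(0, tps / pos)
  fpr <- c(0, fps / neg)
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

# Average precision by stepwise summation over score thresholds
# (sum over thresholds of recall increment times precision at threshold).
binary_ap <- function(labels, scores) {
  pos <- sum(labels)
  if (pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- c(which(diff(sc) != 0), length(sc))
  tps <- cumsum(lab)[grp_end]
  fps <- cumsum(!lab)[grp_end]
  recall <- tps / pos
  precision <- tps / (tps + fps)
  sum(diff(c(0, recall)) * precision)
}

#' One-vs-rest ROC/AUC and precision-recall/AP per class
#'
#' @param y_true Vector of true class labels.
#' @param scores `N x K` matrix of class probabilities; rows must sum to 1
#'   within `1e-6` and column names (if present) give the class order.
#' @param class_order Class order of the score columns when the matrix has no
#'   column names.
#' @return Data frame with one row per class: `auc`, `ap`, and `undefined`
#'   (no positive or no negative samples for that class).
#' @export
roc_pr_ovr <- function(y_true, scores,
                       class_order = colnames(scores) %||% stage_levels()) {
  scores <- as.matrix(scores)
  if (max(abs(rowSums(scores) - 1)) > 1e-6)
    stop("score rows must sum to 1")
  y_true <- as.character(y_true)
  res <- lapply(seq_along(class_order), function(k) {
    lab <- y_true == class_order[k]
    data.frame(class = class_order[k],
               auc = binary_auc(lab, scores[, k]),
               ap = binary_ap(lab, scores[, k]),
               undefined = sum(lab) == 0 || sum(!lab) == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Multi-seed summary: means, 95 percent confidence intervals, paired tests
#'
#' Per metric, reports the mean over runs and the Student-t 95 percent
#' confidence half-width `t(0.975, n-1) * s / sqrt(n)`. When comparator
#' reports (paired by seed) are supplied, a paired t-test on each class's F1
#' is performed and the per-class p-values are reported together with their
#' average (the averaged p-value is an unconventional summary and the
#' per-class values are always listed alongside). Pairs with identical
#' values in every run yield p = 1 with a degeneracy flag.
#'
#' @param reports List (length >= 2) of [classification_metrics()] reports
#'   from repeated runs of one model.
#' @param comparator Optional list of reports of a second model, same length
#'   and seed order.
#' @return A `multi_run_summary` list.
#' @export
multi_seed_summary <- function(reports, comparator = NULL) {
  n <- length(reports)
  if (n < 2) stop("need at least 2 runs for a confidence interval")
  metric_matrix <- function(reps) {
    cls <- reps[[1]]$per_class$class
    m <- cbind(accuracy = vapply(reps, `[[`, numeric(1), "accuracy"),
               macro_f1 = vapply(reps, `[[`, numeric(1), "macro_f1"))
    f1 <- vapply(reps, function(r) r$per_class$f1, numeric(length(cls)))
    f1 <- matrix(f1, ncol = n, dimnames = list(paste0("f1_", cls), NULL))
    cbind(m, t(f1))
  }
  mm <- metric_matrix(reports)
  tcrit <- qt(0.975, n - 1)
  summ <- data.frame(metric = colnames(mm),
                     mean = colMeans(mm),
                     ci_half_width = tcrit * apply(mm, 2, sd) / sqrt(n),
                     row.names = NULL, stringsAsFactors = FALSE)
  out <- list(n_runs = n, summary = summ)
  if (!is.null(comparator)) {
    if (length(comparator) != n)
      stop("comparator must have the same number of runs")
    cls <- reports[[1]]$per_class$class
    ptab <- data.frame(class = cls, p = NA_real_, degenerate = FALSE,
                       stringsAsFactors = FALSE)
    for (i in seq_along(cls)) {
      a <- vapply(reports, function(r) r$per_class$f1[i], numeric(1))
      b <- vapply(comparator, function(r) r$per_class$f1[i], numeric(1))
      d <- a - b
      if (sd(d) < 1e-12) {
        ptab$degenerate[i] <- TRUE
        ptab$p[i] <- if (max(abs(d)) < 1e-12) 1 else 0
      } else {
        ptab$p[i] <- stats::t.test(a, b, paired = TRUE)$p.value
      }
    }
    out$p_per_class <- ptab
    out$p_avg <- mean(ptab$p)
  }
  structure(out, class = "multi_run_summary")
}

#' @export
print.multi_run_summary <- function(x, ...) {
  cat("<multi_run_summary>", x$n_runs, "runs\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$p_per_class)) {
    cat("paired F1 p-values (vs comparator), average",
        format(x$p_avg, digits = 3), "\n")
    print(x$p_per_class, row.names = FALSE)
  }
  invisible(x)
}
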