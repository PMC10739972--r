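#' Confusion counts
#'
#' Counts with positive class 1 (death): `tp` true positives, `fp` false
#' positives, `fn` false negatives, `tn` true negatives.
#'
#' @param y_true,y_pred Equal-length vectors of labels in `{0, 1}`.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ", call. = FALSE)
  }
  stopifnot(all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  tibble::tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    fn = sum(y_true == 1 & y_pred == 0),
    tn = sum(y_true == 0 & y_pred == 0)
  )
}

#' Classification metrics
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 (harmonic mean of precision and recall) and, when
#' positive-class scores are supplied, AUC as the trapezoidal area under
#' the ROC curve built from the score thresholds (identical scores for
#' all samples yield 0.5). Ratios with zero denominators return 0 with a
#' warning.
#'
#' @param counts A one-row tibble from [confusion_counts()].
#' @param scores Optional per-sample positive-class probabilities in
#'   `[0, 1]`.
#' @param y_true Labels aligned to `scores` (required with `scores`).
#' @return A one-row tibble `accuracy`, `precision`, `recall`, `f1`,
#'   `auc` (`NA` when no scores given).
#' @examples
#' classification_metrics(tibble::tibble(tp = 50, fp = 10, fn = 5, tn = 35))
#' @export
classification_metrics <- function(counts, scores = NULL, y_true = NULL) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0",
              call. = FALSE)
      return(0)
    }
    num / den
  }
  accuracy <- safe_ratio(tp + tn, tp + fp + tn + fn, "accuracy")
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (precision + recall == 0) {
    warning("f1 undefined (zero denominator); returning 0", call. = FALSE)
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true required with scores", call. = FALSE)
    if (any(scores < 0 | scores > 1)) {
      stop("scores outside [0, 1]", call. = FALSE)
    }
    if (length(scores) != (tp + fp + tn + fn)) {
      stop("counts inconsistent with y_true length", call. = FALSE)
    }
    auc <- roc_auc(y_true, scores)
  }
  tibble::tibble(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, auc = auc)
}

# trapezoidal area under the ROC built by sweeping the unique score
# thresholds (predict positive when score >= threshold)
roc_auc <- function(y_true, scores) {
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined with a single class; returning 0", call. = FALSE)
    return(0)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & y_true == 1),
                     numeric(1)) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & y_true == 0),
                     numeric(1)) / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate a model factory over a multi-split plan
#'
#' Trains a fresh model per split of the plan, computes the metric set on
#' each held-out side, and reports both the per-split values and their
#' arithmetic mean. Wall time per fit and a serialized-size estimate are
#' captured as informational profiling.
#'
#' @param factory A function `function(train)` returning a fitted object
#'   supporting `predict(fit, newdata, type = "prob"|"label")`.
#' @param data A `clinical_tbl`.
#' @param plan A [split_plan()].
#' @return An `eval_summary`: list with `per_split` (tibble of fraction,
#'   metrics, `fit_time_s`, `model_bytes`) and `mean` (averaged metrics).
#' @export
evaluate_over_splits <- function(factory, data, plan = split_plan()) {
  splits <- make_splits(data, plan)
  per_split <- purrr::pmap_dfr(splits, function(fraction, train, test) {
    stopifnot(length(intersect(train$sample_id, test$sample_id)) == 0)
    t0 <- proc.time()["elapsed"]
    fit <- factory(train)
    fit_time <- proc.time()["elapsed"] - t0
    y_test <- clinical_labels(test)
    pred <- predict(fit, test, type = "label")
    prob <- predict(fit, test, type = "prob")[, "1"]
    m <- classification_metrics(confusion_counts(y_test, pred),
                                scores = prob, y_true = y_test)
    dplyr::bind_cols(
      tibble::tibble(fraction = fraction),
      m,
      tibble::tibble(fit_time_s = unname(fit_time),
                     model_bytes = as.numeric(utils::object.size(fit)))
    )
  })
  means <- dplyr::summarise(
    per_split,
    dplyr::across(c("accuracy", "precision", "recall", "f1", "auc"), mean)
  )
  structure(list(per_split = per_split, mean = means),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Multi-split evaluation (", nrow(x$per_split), " splits)\n", sep = "")
  print(x$per_split)
  cat("mean:\n")
  print(x$mean)
  invisible(x)
}

#' @export
tidy.eval_summary <- function(x, ...) x$per_split

#' @export
glance.eval_summary <- function(x, ...) x$mean

#' Plot a multi-split evaluation
#'
#' @param object An `eval_summary`.
#' @param ... Unused.
#' @return A ggplot of metric values by training fraction.
#' @export
autoplot.eval_summary <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_split,
                            c("accuracy", "precision", "recall", "f1", "auc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "training fraction", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Paired differences `d = a - b` are taken, zeros dropped, absolute
#' differences ranked with midranks for ties, and the test statistic is
#' `TS = min(W+, W-)`, the smaller of the two signed rank sums. The
#' two-sided p-value is exact for `n_effective <= 25` (computed from the
#' full null distribution of the rank-sum under independent random
#' signs) and uses the normal approximation with continuity and tie
#' corrections above that.
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @param sl Significance level (default 0.05).
#' @return A one-row tibble: `statistic` (TS), `w_plus`, `w_minus`,
#'   `p_value`, `n_effective`, `significant`, `method`, `degenerate`.
#' @examples
#' wsrt(c(3, 4, 6, 8, 9), c(1, 5, 3, 12, 4))
#' @export
wsrt <- function(a, b, sl = 0.05) {
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = 0, w_plus = 0, w_minus = 0,
                          p_value = 1, n_effective = 0L,
                          significant = FALSE, method = "degenerate",
                          degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  ts <- min(w_plus, w_minus)
  s_total <- n * (n + 1) / 2
  if (n <= 25) {
    dist2 <- signed_rank_null_counts(r)  # counts over 2*W+ grid
    total <- 2^n
    p_low <- sum(dist2[seq_len(round(2 * ts) + 1)]) / total
    hi_cut <- round(2 * (s_total - ts))
    p_high <- sum(dist2[seq(hi_cut + 1, length(dist2))]) / total
    p <- min(1, p_low + p_high)
    method <- "exact"
  } else {
    mu <- s_total / 2
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (ts - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal-approx"
  }
  tibble::tibble(statistic = ts, w_plus = w_plus, w_minus = w_minus,
                 p_value = p, n_effective = as.integer(n),
                 significant = p < sl, method = method, degenerate = FALSE)
}

# exact null distribution of W+ via the characteristic polynomial
# prod_i (1 + x^{2 r_i}); midranks double to integers, so counts are
# indexed by 2*W+ = 0 .. 2*sum(r)
signed_rank_null_counts <- function(r) {
  r2 <- round(2 * r)
  counts <- numeric(sum(r2) + 1)
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  counts
}

#' Pairwise signed-rank comparisons between classifiers
#'
#' Runs [wsrt()] on every unordered pair of classifiers, pairing their
#' per-split metric values; with a `feature_set` column, pairs are
#' compared within each feature set.
#'
#' @param data A tibble with columns `classifier`, `split`, `accuracy`
#'   and optionally `feature_set`.
#' @param sl Significance level (default 0.05).
#' @return A tibble with one row per pair (per feature set).
#' @export
compare_all_pairs <- function(data, sl = 0.05) {
  stopifnot(all(c("classifier", "split", "accuracy") %in% names(data)))
  has_fs <- "feature_set" %in% names(data)
  groups <- if (has_fs) unique(data$feature_set) else NA_character_
  purrr::map_dfr(groups, function(fs) {
    sub <- if (has_fs) data[data$feature_set == fs, ] else data
    cls <- unique(sub$classifier)
    if (length(cls) < 2) stop("need at least 2 classifiers", call. = FALSE)
    pairs <- utils::combn(cls, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- sub$accuracy[sub$classifier == pr[1]][order(sub$split[sub$classifier == pr[1]])]
      b <- sub$accuracy[sub$classifier == pr[2]][order(sub$split[sub$classifier == pr[2]])]
      res <- wsrt(a, b, sl)
      dplyr::bind_cols(
        tibble::tibble(classifier_a = pr[1], classifier_b = pr[2],
                       feature_set = fs),
        res
      )
    })
  })
}
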