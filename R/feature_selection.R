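#' Information gain of a feature with respect to the outcome
#'
#' `IG(D, f) = I(D) - sum_j (N_j / N) * I(D_j)` where `I` is the Shannon
#' entropy (base 2) of the label distribution and the sum runs over the
#' partition of the table induced by the feature. Continuous features
#' are discretised into equal-frequency bins, which makes the score
#' invariant under strictly monotone transformations; features with at
#' most `bins` distinct values are used as categories directly.
#' Constant features score 0.
#'
#' @param data A `clinical_tbl`.
#' @param feature Feature name.
#' @param bins Number of equal-frequency bins for continuous features
#'   (default 10).
#' @return A non-negative scalar, at most the label entropy, in bits.
#' @examples
#' tbl <- simulate_hf(hf_generator_config(seed = 2))
#' information_gain(tbl, "time")
#' @export
information_gain <- function(data, feature, bins = 10L) {
  if (!feature %in% names(data)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  y <- clinical_labels(data)
  if (!length(y)) return(0)
  v <- data[[feature]]
  g <- discretize_equal_freq(v, bins)
  parent <- shannon_entropy(y)
  child <- tapply(y, g, shannon_entropy)
  wts <- tapply(y, g, length) / length(y)
  max(0, parent - sum(wts * child))
}

shannon_entropy <- function(y) {
  p <- tabulate(factor(y)) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

discretize_equal_freq <- function(v, bins) {
  u <- unique(v)
  if (length(u) <= bins) return(factor(v))
  brk <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1),
                                type = 7))
  if (length(brk) < 2) return(factor(rep(1, length(v))))
  cut(v, breaks = brk, include.lowest = TRUE)
}

#' Rank features by information gain
#'
#' @inheritParams information_gain
#' @return A `feature_ranking` tibble with columns `feature` and `score`,
#'   sorted by score descending (ties broken alphabetically), and a
#'   `method` attribute `"IG"`.
#' @export
rank_information_gain <- function(data, bins = 10L) {
  feats <- setdiff((attr(data, "schema") %||% hf_schema())$name, "death_event")
  feats <- intersect(feats, names(data))
  if (!length(feats)) stop("no features to rank", call. = FALSE)
  scores <- vapply(feats, function(f) information_gain(data, f, bins),
                   numeric(1))
  new_feature_ranking(feats, scores, method = "IG")
}

#' Rank features by tree-ensemble impurity importance
#'
#' Fits a random forest and ranks features by mean impurity decrease,
#' normalised to sum to one. Deterministic under the given seed.
#'
#' @param data A `clinical_tbl` with `n >= 10` and both classes.
#' @param forest_size Number of trees (default 500).
#' @param seed Integer RNG seed.
#' @return A `feature_ranking` tibble (`method` attribute `"FI"`).
#' @export
rank_impurity_importance <- function(data, forest_size = 500L, seed = 1L) {
  y <- clinical_labels(data)
  if (nrow(data) < 10) stop("need at least 10 samples", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  df <- as.data.frame(clinical_features(data))
  df$.y <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    .y ~ ., data = df, num.trees = forest_size, importance = "impurity",
    seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  new_feature_ranking(names(imp), unname(imp), method = "FI")
}

new_feature_ranking <- function(features, scores, method) {
  ord <- order(-scores, features)
  out <- tibble::tibble(feature = features[ord],
                        score = unname(scores[ord]))
  structure(out, method = method,
            class = c("feature_ranking", class(out)))
}

#' Top-k features of a ranking
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of features to keep (default 10, the subset size the
#'   downstream comparisons use).
#' @return A character vector of the `k` best-ranked feature names.
#' @export
top_features <- function(ranking, k = 10L) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (k < 1 || k > nrow(ranking)) {
    stop("k must be between 1 and ", nrow(ranking), call. = FALSE)
  }
  ranking$feature[seq_len(k)]
}

#' Plot a feature ranking
#'
#' @param object A `feature_ranking`.
#' @param ... Unused.
#' @return A ggplot bar chart of scores, best feature on top.
#' @export
autoplot.feature_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste0("importance (", attr(object, "method") %||% "score", ")"),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
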