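#' Boosting configuration for minority emphasis weights
#'
#' @param T_rounds Number of boosting rounds (default 10).
#' @param weak_learner_depth Depth of the weak tree learner (default 1,
#'   a decision stump).
#' @param learning_rate Positive multiplier on the stage weight
#'   (default 1).
#' @return A `boost_config` list.
#' @export
boost_config <- function(T_rounds = 10L, weak_learner_depth = 1L,
                         learning_rate = 1) {
  stopifnot(T_rounds >= 1, weak_learner_depth >= 1, learning_rate >= 0)
  structure(list(T_rounds = as.integer(T_rounds),
                 weak_learner_depth = as.integer(weak_learner_depth),
                 learning_rate = learning_rate),
            class = "boost_config")
}

#' SMOTE configuration
#'
#' @param k Number of minority nearest neighbors (default 5; lowered with
#'   a warning when the minority class is smaller than `k + 1`).
#' @param target_ratio Desired minority/majority count ratio after
#'   synthesis, in (0, 1] (default 1 = full balance).
#' @param seed Integer RNG seed for seed-row and neighbor draws.
#' @return A `smote_config` list.
#' @export
smote_config <- function(k = 5L, target_ratio = 1, seed = 1L) {
  stopifnot(k >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k = as.integer(k), target_ratio = target_ratio,
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Adaptive minority-emphasis sample weights
#'
#' Runs `T_rounds` of adaptive reweighting in the AdaBoost style: a
#' shallow tree weak learner is fitted on the current case weights, its
#' weighted error `eps` computed, the stage weight
#' `alpha = lr * 0.5 * log((1 - eps)/eps)` applied multiplicatively to
#' the misclassified cases, and the weights renormalised to sum to one.
#' Because the underrepresented class is misclassified most often, its
#' cases accumulate weight — these weights later bias which minority
#' rows seed synthetic samples.
#'
#' Degenerate rounds: `eps = 0` (a perfect weak learner) stops early and
#' returns the current weights; `eps >= 0.5` resets that round's weights
#' to uniform and continues.
#'
#' @param data A `clinical_tbl` with both classes present.
#' @param config A [boost_config()].
#' @return A tibble with columns `sample_id`, `weight` (positive, summing
#'   to 1) and `rounds_run`.
#' @export
boost_weights <- function(data, config = boost_config()) {
  stopifnot(inherits(config, "boost_config"))
  y <- clinical_labels(data)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  X <- as.data.frame(clinical_features(data))
  n <- nrow(X)
  df <- X
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  rounds <- 0L
  for (t in seq_len(config$T_rounds)) {
    fit <- rpart::rpart(
      .y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = config$weak_learner_depth,
                                     minsplit = 2, minbucket = 1, cp = -1,
                                     xval = 0, maxsurrogate = 0,
                                     maxcompete = 0)
    )
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    mis <- pred != y
    eps <- sum(w[mis])
    if (eps <= 0) {
      rounds <- t
      break
    }
    if (eps >= 0.5) {
      w <- rep(1 / n, n)
      rounds <- t
      next
    }
    alpha <- config$learning_rate * 0.5 * log((1 - eps) / eps)
    w[mis] <- w[mis] * exp(alpha)
    w <- w / sum(w)
    rounds <- t
  }
  tibble::tibble(sample_id = data$sample_id, weight = w, rounds_run = rounds)
}

#' Weight-biased SMOTE oversampling
#'
#' Synthesises minority-class records by linear interpolation:
#' `ceiling(target_ratio * n_majority) - n_minority` new samples, each
#' grown from a minority seed row `xi` drawn with probability
#' proportional to its boost weight, towards a neighbor `xj` drawn
#' uniformly from `xi`'s `k` nearest minority neighbors (Euclidean),
#' as `xs = xi + r * (xj - xi)` with `r` drawn uniformly from (0, 1]. Binary
#' features copy the nearer endpoint (`r` at most 0.5 takes the seed, else the
#' neighbor) so flags stay in `{0, 1}`.
#'
#' @param data A `clinical_tbl`, ideally min-max scaled.
#' @param weights A tibble from [boost_weights()] aligned to `data`'s
#'   rows (`NULL` for uniform seeding).
#' @param config A [smote_config()].
#' @return A list with `augmented` (the table with synthetic rows
#'   appended, synthetic `sample_id`s prefixed `"syn"`) and `records`
#'   (a tibble of provenance: `synth_id`, `seed_index`,
#'   `neighbor_index`, `r`).
#' @export
weighted_smote <- function(data, weights = NULL, config = smote_config()) {
  stopifnot(inherits(config, "smote_config"))
  y <- clinical_labels(data)
  min_lab <- minority_label(y)
  min_idx <- which(y == min_lab)
  n_min <- length(min_idx)
  n_maj <- length(y) - n_min
  if (n_min < 2) {
    stop("minority class has fewer than 2 members; cannot interpolate",
         call. = FALSE)
  }
  n_syn <- ceiling(config$target_ratio * n_maj) - n_min
  empty_rec <- tibble::tibble(synth_id = character(), seed_index = integer(),
                              neighbor_index = integer(), r = numeric())
  if (n_syn <= 0) {
    return(list(augmented = data, records = empty_rec))
  }
  k <- config$k
  if (k > n_min - 1) {
    warning("k lowered from ", k, " to ", n_min - 1,
            " (minority size)", call. = FALSE)
    k <- n_min - 1
  }
  sch <- attr(data, "schema") %||% hf_schema()
  feats <- setdiff(sch$name, "death_event")
  binary_feats <- sch$name[sch$kind == "binary" & sch$name != "death_event"]
  X <- clinical_features(data, feats)
  Xmin <- X[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Xmin))
  diag(D) <- Inf
  # k nearest minority neighbors of each minority row, ties by lowest index
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i) {
    order(D[i, ], seq_len(n_min))[seq_len(k)]
  }))

  w <- if (is.null(weights)) rep(1 / n_min, n_min) else {
    stopifnot(nrow(weights) == length(y))
    wv <- weights$weight[min_idx]
    wv / sum(wv)
  }
  syn <- matrix(NA_real_, n_syn, ncol(X), dimnames = list(NULL, colnames(X)))
  rec <- vector("list", n_syn)
  withr::with_seed(config$seed, {
    seed_pick <- sample.int(n_min, n_syn, replace = TRUE, prob = w)
    nbr_pick <- vapply(seed_pick, function(s) nn[s, sample.int(k, 1)], integer(1))
    r <- stats::runif(n_syn)
    r[r == 0] <- 1
    for (s in seq_len(n_syn)) {
      xi <- Xmin[seed_pick[s], ]
      xj <- Xmin[nbr_pick[s], ]
      xs <- xi + r[s] * (xj - xi)
      xs[binary_feats] <- if (r[s] <= 0.5) xi[binary_feats] else xj[binary_feats]
      syn[s, ] <- xs
    }
  })
  records <- tibble::tibble(
    synth_id = paste0("syn", seq_len(n_syn)),
    seed_index = min_idx[seed_pick],
    neighbor_index = min_idx[nbr_pick],
    r = r
  )
  syn_df <- tibble::as_tibble(as.data.frame(syn))
  syn_df$death_event <- min_lab
  syn_df$sample_id <- records$synth_id
  aug <- dplyr::bind_rows(tibble::as_tibble(as.data.frame(data)), syn_df)
  aug <- structure(aug, schema = sch, scaled = attr(data, "scaled"),
                   class = class(data))
  list(augmented = aug, records = records)
}

#' Tomek links
#'
#' Finds every cross-class pair of mutual nearest neighbors under
#' Euclidean distance on the feature columns. Such pairs sit on (or
#' across) the class boundary; removing the majority member of each pair
#' sharpens the boundary and discards ambiguous or noisy samples.
#' Nearest-neighbor ties are broken by lowest row index.
#'
#' @param data A `clinical_tbl` with both classes present.
#' @return A tibble with columns `index_a`, `index_b` (`index_a <
#'   index_b`), `label_a`, `label_b` and `distance`.
#' @export
find_tomek_links <- function(data) {
  y <- clinical_labels(data)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  X <- clinical_features(data)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- vapply(seq_len(n), function(i) which.min(D[i, ]), integer(1))
  out <- list()
  for (i in seq_len(n)) {
    j <- nn[i]
    if (j > i && nn[j] == i && y[i] != y[j]) {
      out[[length(out) + 1]] <- tibble::tibble(
        index_a = i, index_b = j,
        label_a = y[i], label_b = y[j], distance = D[i, j]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(index_a = integer(), index_b = integer(),
                          label_a = integer(), label_b = integer(),
                          distance = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Remove the majority member of each Tomek pair
#'
#' @param data The `clinical_tbl` on which `pairs` were computed.
#' @param pairs A tibble from [find_tomek_links()].
#' @param minority Label of the protected minority class; defaults to
#'   the less frequent class of `data`. Inside [boo_st()] this is the
#'   minority class of the table *before* oversampling, so synthetic
#'   minority rows are never dropped even once counts are balanced.
#' @return The table with each pair's majority-class member dropped;
#'   minority members (including synthetic rows) are never dropped.
#' @export
remove_tomek_majority <- function(data, pairs, minority = NULL) {
  if (nrow(pairs) == 0) return(data)
  y <- clinical_labels(data)
  n <- nrow(data)
  if (any(c(pairs$index_a, pairs$index_b) > n) ||
      any(c(pairs$index_a, pairs$index_b) < 1)) {
    stop("pair indices out of range for this table", call. = FALSE)
  }
  maj_lab <- 1L - (minority %||% minority_label(y))
  drop <- unique(c(pairs$index_a[pairs$label_a == maj_lab],
                   pairs$index_b[pairs$label_b == maj_lab]))
  if (!length(drop)) return(data)
  subset_clinical(data, setdiff(seq_len(n), drop))
}

#' Hybrid boosting-SMOTE-Tomek resampling
#'
#' Balances an imbalanced clinical table in three stages:
#' (1) [boost_weights()] concentrates emphasis on the hard-to-classify
#' minority cases; (2) [weighted_smote()] synthesises minority samples,
#' seeding preferentially from the high-weight rows; (3) Tomek-link
#' cleaning ([find_tomek_links()] + [remove_tomek_majority()]) deletes
#' the majority member of every cross-class mutual-nearest-neighbor
#' pair in the augmented table. Features should be on comparable scales
#' (see [fit_minmax()]); a warning is issued otherwise.
#'
#' @param data A `clinical_tbl` with both classes present.
#' @param boost_cfg A [boost_config()].
#' @param smote_cfg A [smote_config()].
#' @param iterate_tomek Logical; repeat the cleaning pass until no links
#'   remain (default `FALSE`: a single pass).
#' @return A list of class `boo_st_result`: `balanced` (the resampled
#'   table) and `report` (a `boo_st_report` reconciling all counts).
#' @examples
#' tbl <- simulate_hf(hf_generator_config(n_samples = 120, seed = 3))
#' tbl <- apply_minmax(tbl, fit_minmax(tbl))
#' res <- boo_st(tbl)
#' tidy(res$report)
#' @export
boo_st <- function(data, boost_cfg = boost_config(),
                   smote_cfg = smote_config(), iterate_tomek = FALSE) {
  y <- clinical_labels(data)
  check_comparable_scales(data)
  counts_before <- class_counts(y)
  w <- boost_weights(data, boost_cfg)
  sm <- weighted_smote(data, w, smote_cfg)
  aug <- sm$augmented
  removed <- c(`0` = 0L, `1` = 0L)
  removed_ids <- character()
  repeat {
    pairs <- find_tomek_links(aug)
    if (nrow(pairs) == 0) break
    before_ids <- aug$sample_id
    cleaned <- remove_tomek_majority(aug, pairs, minority = minority_label(y))
    gone <- setdiff(before_ids, cleaned$sample_id)
    gone_labels <- clinical_labels(aug)[match(gone, aug$sample_id)]
    removed <- removed + class_counts(gone_labels)
    removed_ids <- c(removed_ids, gone)
    aug <- cleaned
    if (!iterate_tomek) break
  }
  counts_after <- class_counts(clinical_labels(aug))
  min_lab <- as.character(minority_label(y))
  synthesized <- c(`0` = 0L, `1` = 0L)
  synthesized[min_lab] <- nrow(sm$records)
  ratio <- counts_after[min_lab] / counts_after[setdiff(c("0", "1"), min_lab)]
  if (smote_cfg$target_ratio == 1 && (ratio < 0.8 || ratio > 1.25)) {
    message("post-resampling class ratio ", round(ratio, 3),
            " outside [0.8, 1.25]")
  }
  report <- structure(list(
    counts_before = counts_before,
    synthesized = synthesized,
    removed = removed,
    counts_after = counts_after,
    synthetic_records = sm$records,
    removed_ids = removed_ids,
    boost_weights = w,
    minority_label = minority_label(y)
  ), class = "boo_st_report")
  structure(list(balanced = aug, report = report), class = "boo_st_result")
}

class_counts <- function(y) {
  c(`0` = sum(y == 0L), `1` = sum(y == 1L))
}

check_comparable_scales <- function(data) {
  if (isTRUE(attr(data, "scaled"))) return(invisible(TRUE))
  X <- clinical_features(data)
  if (!nrow(X)) return(invisible(TRUE))
  spans <- apply(X, 2, function(v) diff(range(v)))
  if (any(spans > 10)) {
    warning("features span widely different ranges; min-max scale before ",
            "distance-based resampling (see fit_minmax)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.boo_st_report <- function(x, ...) {
  cat("Hybrid resampling report\n")
  cat("  before:      ", format_counts(x$counts_before), "\n")
  cat("  synthesized: ", format_counts(x$synthesized), "\n")
  cat("  removed:     ", format_counts(x$removed), "\n")
  cat("  after:       ", format_counts(x$counts_after), "\n")
  invisible(x)
}

format_counts <- function(cc) {
  paste0("class0=", cc[["0"]], " class1=", cc[["1"]])
}

#' Tidy a resampling report
#'
#' @param x A `boo_st_report`.
#' @param ... Unused.
#' @return One row per class with before/synthesized/removed/after counts.
#' @export
tidy.boo_st_report <- function(x, ...) {
  tibble::tibble(
    class = c(0L, 1L),
    before = as.integer(x$counts_before),
    synthesized = as.integer(x$synthesized),
    removed = as.integer(x$removed),
    after = as.integer(x$counts_after)
  )
}

#' @rdname tidy.boo_st_report
#' @export
glance.boo_st_report <- function(x, ...) {
  tibble::tibble(
    n_before = sum(x$counts_before),
    n_synthesized = sum(x$synthesized),
    n_removed = sum(x$removed),
    n_after = sum(x$counts_after),
    minority_label = x$minority_label,
    balance_ratio = min(x$counts_after) / max(x$counts_after)
  )
}
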