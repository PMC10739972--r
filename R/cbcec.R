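#' Select the best-performing conventional classifier
#'
#' Trains one learner per family on the training table, scores each by
#' accuracy on the validation table, and returns the argmax. Ties are
#' broken by the fixed family order DT, GB, SVM, ET.
#'
#' @param train,validation `clinical_tbl`s; validation must be nonempty.
#' @param families List of [base_learner()] specs (default: one per
#'   family, seed 10).
#' @param features Optional feature subset.
#' @return A `selection_result`: tibble of per-family accuracies plus
#'   attributes `chosen` (family name) and `chosen_spec`.
#' @export
select_best <- function(train, validation,
                        families = default_families(), features = NULL) {
  stopifnot(length(families) >= 2, nrow(validation) >= 1)
  fams <- vapply(families, function(s) s$family, character(1))
  ord <- order(match(fams, learner_families()))
  families <- families[ord]
  fams <- fams[ord]
  y_val <- clinical_labels(validation)
  acc <- vapply(families, function(spec) {
    fit <- train_base(spec, train, features)
    mean(predict(fit, validation, type = "label") == y_val)
  }, numeric(1))
  scores <- tibble::tibble(family = fams, accuracy = acc)
  best <- which.max(acc)  # first max = fixed-order tie-break
  structure(scores,
            chosen = fams[best],
            chosen_spec = families[[best]],
            class = c("selection_result", class(scores)))
}

#' @rdname select_best
#' @param seed Seed applied to every family spec.
#' @export
default_families <- function(seed = 10L) {
  lapply(learner_families(), base_learner, seed = seed)
}

#' Bagged ensemble of one base learner
#'
#' Draws `B` bootstrap resamples (size `n`, with replacement), fits one
#' member per resample and aggregates by the arithmetic mean of member
#' class-probability vectors. A resample that misses a class is redrawn
#' (at most 10 attempts, counted).
#'
#' @param spec A [base_learner()].
#' @param data Training `clinical_tbl`.
#' @param B Bag count (default 10).
#' @param seed Integer RNG seed fixing the bootstrap index sets.
#' @param features Optional feature subset.
#' @return An `hf_bagged` with `predict(fit, newdata, type)`.
#' @export
fit_bagged <- function(spec, data, B = 10L, seed = 10L, features = NULL) {
  stopifnot(B >= 1)
  n <- nrow(data)
  y <- clinical_labels(data)
  boot_idx <- withr::with_seed(seed, {
    lapply(seq_len(B), function(b) {
      for (attempt in 1:10) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) {
          attr(idx, "redraws") <- attempt - 1L
          return(idx)
        }
      }
      stop("bootstrap resample kept missing a class after 10 attempts",
           call. = FALSE)
    })
  })
  members <- lapply(boot_idx, function(idx) {
    train_base(spec, subset_clinical(data, idx), features)
  })
  structure(list(spec = spec, B = as.integer(B), members = members,
                 boot_idx = lapply(boot_idx, as.integer),
                 redraws = sum(vapply(boot_idx, attr, integer(1), "redraws")),
                 features = members[[1]]$features),
            class = "hf_bagged")
}

#' @export
predict.hf_bagged <- function(object, newdata, type = c("prob", "label"),
                              ...) {
  type <- match.arg(type)
  probs <- lapply(object$members, predict, newdata = newdata, type = "prob")
  prob <- Reduce(`+`, probs) / length(probs)
  if (type == "prob") prob else as.integer(prob[, "1"] >= 0.5)
}

#' Fit the hybrid best-classifier-plus-bagging voting ensemble
#'
#' The hybrid classifier: (1) empirically select the best conventional
#' family ([select_best()]); (2) refit that family on the full training
#' table; (3) bag it ([fit_bagged()]); (4) combine the single fit and
#' the bag by voting. Soft voting (the default) averages the two
#' class-probability vectors and takes the argmax; hard voting takes the
#' agreed label, falling back to the first member (the single best
#' classifier) on disagreement; weighted voting averages with the given
#' weights.
#'
#' Selection is scored on an internal stratified validation fold (20 %
#' of `train`) by default, so the final test split never informs model
#' choice. `paper_faithful = TRUE` scores selection on the supplied
#' `validation` table instead, reproducing protocols that select on the
#' test split.
#'
#' @param train Training `clinical_tbl`.
#' @param validation Validation table (required when
#'   `paper_faithful = TRUE`; otherwise unused).
#' @param B Bag count (default 10).
#' @param voting `"soft"`, `"hard"` or `"weighted"`.
#' @param weights Two nonnegative member weights for weighted voting
#'   (default `c(0.5, 0.5)`).
#' @param seed Integer RNG seed (also the learners' random state;
#'   default 10).
#' @param features Optional feature subset.
#' @param families Candidate [base_learner()] specs.
#' @param base_family Optional family name to use directly, skipping
#'   selection (used by the ablation grids).
#' @param paper_faithful Logical; select on `validation` instead of an
#'   internal fold.
#' @return An `hf_cbcec` with `predict(fit, newdata, type)`.
#' @examples
#' tbl <- simulate_hf(hf_generator_config(n_samples = 150, seed = 4))
#' sp <- make_splits(tbl, split_plan(0.8, seed = 4))
#' fit <- fit_cbcec(sp$train[[1]], B = 5, seed = 10)
#' glance(fit)
#' @export
fit_cbcec <- function(train, validation = NULL, B = 10L,
                      voting = c("soft", "hard", "weighted"),
                      weights = c(0.5, 0.5), seed = 10L, features = NULL,
                      families = default_families(seed),
                      base_family = NULL, paper_faithful = FALSE) {
  voting <- match.arg(voting)
  stopifnot(length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  if (!is.null(base_family)) {
    base_family <- match.arg(base_family, learner_families())
    selection <- NULL
    spec <- base_learner(base_family, seed = seed)
  } else if (paper_faithful) {
    if (is.null(validation)) {
      stop("paper_faithful selection needs a validation table", call. = FALSE)
    }
    selection <- select_best(train, validation, families, features)
    spec <- attr(selection, "chosen_spec")
  } else {
    inner <- make_splits(train, split_plan(0.8, seed = seed))
    selection <- select_best(inner$train[[1]], inner$test[[1]],
                             families, features)
    spec <- attr(selection, "chosen_spec")
  }
  bp_c <- train_base(spec, train, features)
  b_bg <- fit_bagged(spec, train, B = B, seed = seed, features = features)
  structure(list(selection = selection, family = spec$family,
                 bp_c = bp_c, b_bg = b_bg, voting = voting,
                 weights = weights / sum(weights), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "hf_cbcec")
}

#' @export
predict.hf_cbcec <- function(object, newdata, type = c("prob", "label"),
                             ...) {
  type <- match.arg(type)
  p1 <- predict(object$bp_c, newdata, type = "prob")
  p2 <- predict(object$b_bg, newdata, type = "prob")
  prob <- switch(
    object$voting,
    soft = (p1 + p2) / 2,
    weighted = object$weights[1] * p1 + object$weights[2] * p2,
    hard = {
      l1 <- as.integer(p1[, "1"] >= 0.5)
      l2 <- as.integer(p2[, "1"] >= 0.5)
      lab <- ifelse(l1 == l2, l1, l1)  # disagreement -> first member
      v1 <- (l1 + l2) / 2
      cbind(`0` = 1 - v1, `1` = v1)
    }
  )
  if (type == "prob") return(prob)
  if (object$voting == "hard") {
    l1 <- as.integer(p1[, "1"] >= 0.5)
    l2 <- as.integer(p2[, "1"] >= 0.5)
    return(ifelse(l1 == l2, l1, l1))
  }
  as.integer(prob[, "1"] >= 0.5)
}

#' @export
print.hf_cbcec <- function(x, ...) {
  cat("<hf_cbcec> base =", x$family, "| B =", x$B, "| voting =",
      x$voting, "\n")
  invisible(x)
}

#' Tidy/glance methods for the hybrid ensemble
#'
#' `tidy()` returns the per-family selection accuracies (empty when
#' selection was skipped); `glance()` returns a one-row summary.
#'
#' @param x An `hf_cbcec`.
#' @param ... Unused.
#' @export
tidy.hf_cbcec <- function(x, ...) {
  if (is.null(x$selection)) {
    return(tibble::tibble(family = character(), accuracy = numeric()))
  }
  tibble::as_tibble(x$selection)
}

#' @rdname tidy.hf_cbcec
#' @export
glance.hf_cbcec <- function(x, ...) {
  tibble::tibble(base_family = x$family, B = x$B, voting = x$voting,
                 seed = x$seed)
}

#' Ablation grids for the hybrid ensemble
#'
#' Full factorial over base-estimator families, random states and voting
#' types, crossed with feature sets; each cell is the hybrid ensemble's
#' validation accuracy. The setting (estimator, random state, voting)
#' with the best mean accuracy across feature sets is flagged
#' `accepted`, mirroring the check-mark convention of ablation tables.
#'
#' @param train,validation `clinical_tbl`s.
#' @param estimators Character vector of families (default all four).
#' @param random_states Integer vector of seeds (default 10).
#' @param voting_types Subset of `c("hard", "weighted", "soft")`.
#' @param feature_sets Named list of feature-name vectors (e.g. `ALL`,
#'   `FI`, `IG`); `NULL` for a single all-features set.
#' @param B Bag count.
#' @return A tibble: `estimator`, `random_state`, `voting`,
#'   `feature_set`, `accuracy`, `accepted`.
#' @export
run_ablation <- function(train, validation,
                         estimators = learner_families(),
                         random_states = 10L,
                         voting_types = "soft",
                         feature_sets = NULL, B = 10L) {
  stopifnot(length(estimators) >= 1, length(random_states) >= 1,
            length(voting_types) >= 1)
  feature_sets <- feature_sets %||% list(ALL = NULL)
  grid <- tidyr::expand_grid(
    estimator = estimators,
    random_state = as.integer(random_states),
    voting = voting_types,
    feature_set = names(feature_sets)
  )
  y_val <- clinical_labels(validation)
  grid$accuracy <- purrr::pmap_dbl(grid, function(estimator, random_state,
                                                  voting, feature_set) {
    fit <- fit_cbcec(train, B = B, voting = voting, seed = random_state,
                     features = feature_sets[[feature_set]],
                     base_family = estimator)
    mean(predict(fit, validation, type = "label") == y_val)
  })
  setting_mean <- grid |>
    dplyr::group_by(.data$estimator, .data$random_state, .data$voting) |>
    dplyr::summarise(mean_acc = mean(.data$accuracy), .groups = "drop")
  best <- setting_mean[which.max(setting_mean$mean_acc), ]
  grid$accepted <- grid$estimator == best$estimator &
    grid$random_state == best$random_state &
    grid$voting == best$voting
  grid
}
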