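test_that("confusion counts match hand tallies", {
  cc <- confusion_counts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unlist(cc), c(tp = 2, fp = 1, fn = 1, tn = 1))
  same <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(same$fp + same$fn, 0)
  inv <- confusion_counts(c(1, 0, 1), c(0, 1, 0))
  expect_equal(inv$tp + inv$tn, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths differ")
})

test_that("metric formulas reproduce the hand-computed values", {
  m <- classification_metrics(tibble::tibble(tp = 50, fp = 10, fn = 5,
                                             tn = 35))
  expect_equal(m$accuracy, 0.85)
  expect_equal(round(m$precision, 4), 0.8333)
  expect_equal(round(m$recall, 4), 0.9091)
  expect_equal(round(m$f1, 4), 0.8696)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
})

test_that("zero denominators warn and return 0", {
  w <- capture_warnings(
    m <- classification_metrics(tibble::tibble(tp = 0, fp = 0, fn = 3,
                                               tn = 7))
  )
  expect_match(w, "precision", all = FALSE)
  expect_match(w, "f1", all = FALSE)
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
})

test_that("AUC is trapezoidal, tie-aware and monotone-invariant", {
  y <- c(0, 0, 1, 1)
  m <- classification_metrics(confusion_counts(y, y),
                              scores = c(0.1, 0.2, 0.8, 0.9), y_true = y)
  expect_equal(m$auc, 1)
  m2 <- classification_metrics(confusion_counts(y, rep(1, 4)),
                               scores = rep(0.5, 4), y_true = y)
  expect_equal(m2$auc, 0.5)
  withr::local_seed(1)
  yr <- rbinom(60, 1, 0.5)
  sc <- runif(60)
  auc1 <- classification_metrics(confusion_counts(yr, as.integer(sc >= .5)),
                                 scores = sc, y_true = yr)$auc
  # strictly monotone transform leaves AUC unchanged
  sc2 <- stats::plogis(5 * sc - 2)
  auc2 <- classification_metrics(confusion_counts(yr, as.integer(sc >= .5)),
                                 scores = sc2, y_true = yr)$auc
  expect_equal(auc1, auc2)
  # independent reference implementation agrees
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(yr, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc1, ref, tolerance = 1e-9)
  expect_error(classification_metrics(confusion_counts(yr, yr),
                                      scores = sc * 2, y_true = yr),
               "outside")
})

test_that("multi-split evaluation averages fresh fits per split", {
  tbl <- scaled_hf_table(n = 120, seed = 22)
  # constant predictor: accuracy equals the majority share of each split
  factory <- function(train) stub_model(1)
  ev <- suppressWarnings(
    evaluate_over_splits(factory, tbl, split_plan(c(0.7, 0.8), seed = 5))
  )
  splits <- make_splits(tbl, split_plan(c(0.7, 0.8), seed = 5))
  shares <- vapply(splits$test, function(te) mean(te$death_event == 1),
                   numeric(1))
  expect_equal(ev$per_split$accuracy, shares)
  # single split: the mean is the split value
  ev1 <- suppressWarnings(
    evaluate_over_splits(factory, tbl, split_plan(0.8, seed = 5))
  )
  expect_equal(ev1$mean$accuracy, ev1$per_split$accuracy)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
})

test_that("signed-rank statistic follows the rank arithmetic", {
  # all-positive differences: W- = 0, TS = 0
  r <- wsrt(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r$w_minus, 0)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 32)

  # differences {2,-1,3,-4,5}: ranks (2,1,3,4,5), W+ = 10, W- = 5
  r2 <- wsrt(c(2, -1, 3, -4, 5), rep(0, 5))
  expect_equal(r2$w_plus, 10)
  expect_equal(r2$w_minus, 5)
  expect_equal(r2$statistic, 5)

  # all differences zero: degenerate
  r3 <- wsrt(c(1, 1), c(1, 1))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$statistic, 0)
})

test_that("exact p-values agree with full sign enumeration", {
  withr::local_seed(33)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    a <- round(runif(n), 2)
    b <- round(runif(n), 2)  # rounding induces occasional ties/zeros
    if (all(a == b)) next
    got <- wsrt(a, b)
    oracle <- wsrt_enum(a, b)
    expect_equal(got$statistic, oracle$statistic)
    expect_equal(got$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("exact path matches wilcox.test when no ties are present", {
  withr::local_seed(8)
  a <- rnorm(12); b <- rnorm(12)
  got <- wsrt(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("large-sample path uses the normal approximation", {
  withr::local_seed(9)
  a <- rnorm(40); b <- rnorm(40)
  got <- wsrt(a, b)
  expect_equal(got$method, "normal-approx")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("all-pairs comparison covers every unordered pair", {
  withr::local_seed(10)
  df <- tidyr::expand_grid(classifier = LETTERS[1:5], split = 1:6)
  df$accuracy <- runif(nrow(df))
  res <- compare_all_pairs(df)
  expect_equal(nrow(res), choose(5, 2))
  # a classifier against itself is degenerate
  self <- compare_all_pairs(
    tibble::tibble(classifier = rep(c("A", "B"), each = 3),
                   split = rep(1:3, 2),
                   accuracy = rep(c(.7, .8, .9), 2))
  )
  expect_true(all(self$degenerate))
  # feature_set column groups the comparisons
  df$feature_set <- "FI"
  df2 <- df; df2$feature_set <- "IG"
  res2 <- compare_all_pairs(dplyr::bind_rows(df, df2))
  expect_equal(nrow(res2), 2 * choose(5, 2))
})
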