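test_that("information gain matches hand-worked entropies", {
  # 8 rows, labels half/half, feature splitting 4/4 with 3-1 purity:
  # IG = 1 - [0.5*H(3/4) + 0.5*H(1/4)] = 0.18872...
  tbl <- make_tbl(matrix(c(1, 1, 1, 0, 1, 0, 0, 0), ncol = 1),
                  c(1, 1, 1, 1, 0, 0, 0, 0), binary = "f1")
  h <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(information_gain(tbl, "f1"), 1 - h(3 / 4), tolerance = 1e-12)
  expect_equal(round(information_gain(tbl, "f1"), 4), 0.1887)

  # perfect split recovers the full parent entropy (1 bit at 50/50)
  tbl2 <- make_tbl(matrix(c(1, 1, 0, 0), ncol = 1), c(1, 1, 0, 0),
                   binary = "f1")
  expect_equal(information_gain(tbl2, "f1"), 1)

  # feature independent of the label gains nothing
  tbl3 <- make_tbl(matrix(c(1, 0, 1, 0), ncol = 1), c(1, 1, 0, 0),
                   binary = "f1")
  expect_equal(information_gain(tbl3, "f1"), 0)

  # constant feature gains nothing
  tbl4 <- make_tbl(matrix(rep(3, 6), ncol = 1), c(1, 1, 1, 0, 0, 0))
  expect_equal(information_gain(tbl4, "f1"), 0)

  expect_error(information_gain(tbl4, "nope"), "unknown feature")
})

test_that("IG is bounded by the label entropy and invariant to monotone maps", {
  withr::local_seed(3)
  tbl <- scaled_hf_table(n = 200, seed = 3)
  parent <- -mean(tbl$death_event) * log2(mean(tbl$death_event)) -
    (1 - mean(tbl$death_event)) * log2(1 - mean(tbl$death_event))
  for (f in hf_feature_names()) {
    ig <- information_gain(tbl, f)
    expect_gte(ig, 0)
    expect_lte(ig, parent + 1e-12)
  }
  # equal-frequency bins see only the order, so exp() changes nothing
  df <- as.data.frame(tbl)
  base_ig <- information_gain(tbl, "serum_creatinine")
  df$serum_creatinine <- exp(3 * df$serum_creatinine)
  expect_equal(information_gain(clinical_table(df, attr(tbl, "schema"),
                                               check_range = FALSE),
                                "serum_creatinine"),
               base_ig)
})

test_that("IG ranking is ordered, deterministic, and duplicates tie", {
  tbl <- scaled_hf_table(n = 150, seed = 6)
  rk <- rank_information_gain(tbl)
  expect_s3_class(rk, "feature_ranking")
  expect_equal(sort(rk$feature), sort(hf_feature_names()))
  expect_true(all(diff(rk$score) <= 1e-12))
  # a duplicated top feature receives the identical score
  df <- as.data.frame(tbl)
  sch <- attr(tbl, "schema")
  df$age2 <- df$age
  sch2 <- dplyr::bind_rows(sch, tibble::tibble(name = "age2",
                                               kind = "continuous",
                                               unit = "years", low = 40,
                                               high = 95))
  tbl2 <- clinical_table(df, sch2, check_range = FALSE)
  rk2 <- rank_information_gain(tbl2)
  expect_equal(rk2$score[rk2$feature == "age"],
               rk2$score[rk2$feature == "age2"])
})

test_that("impurity importance finds a label-copy feature", {
  withr::local_seed(14)
  ok <- vapply(1:10, function(seed) {
    y <- rbinom(60, 1, 0.5)
    X <- cbind(y, matrix(runif(60 * 4), ncol = 4))
    colnames(X) <- paste0("f", 1:5)
    rk <- rank_impurity_importance(make_tbl(X, y), forest_size = 100,
                                   seed = seed)
    rk$feature[1] == "f1"
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("all-noise features get near-uniform importance shares", {
  withr::local_seed(15)
  maxima <- vapply(1:10, function(seed) {
    X <- matrix(runif(80 * 6), ncol = 6)
    colnames(X) <- paste0("f", 1:6)
    rk <- rank_impurity_importance(make_tbl(X, rbinom(80, 1, 0.5)),
                                   forest_size = 100, seed = seed)
    max(rk$score)
  }, numeric(1))
  expect_lt(mean(maxima), 3 / 6)
})

test_that("impurity ranking is deterministic under seed and validates input", {
  tbl <- scaled_hf_table(n = 100, seed = 8)
  r1 <- rank_impurity_importance(tbl, forest_size = 100, seed = 5)
  r2 <- rank_impurity_importance(tbl, forest_size = 100, seed = 5)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  one_class <- make_tbl(matrix(runif(24), ncol = 2), rep(1, 12))
  expect_error(rank_impurity_importance(one_class), "both classes")
})

test_that("top_features cuts the ordered list correctly", {
  tbl <- scaled_hf_table(n = 100, seed = 9)
  rk <- rank_information_gain(tbl)
  expect_equal(top_features(rk, nrow(rk)), rk$feature)
  expect_equal(top_features(rk, 1), rk$feature[1])
  expect_length(top_features(rk, 10), 10)
  expect_error(top_features(rk, 0))
  expect_error(top_features(rk, 99))
})

test_that("both rankings recover planted signal features", {
  hits_fi <- hits_ig <- logical(8)
  for (seed in 1:8) {
    tbl <- scaled_hf_table(n = 1000, seed = seed)
    planted <- c("time", "serum_creatinine", "ejection_fraction", "age")
    hits_fi[seed] <- all(planted %in%
                           top_features(rank_impurity_importance(tbl,
                                                                 forest_size = 300,
                                                                 seed = seed), 5))
    hits_ig[seed] <- all(planted %in%
                           top_features(rank_information_gain(tbl), 5))
  }
  expect_gte(mean(hits_fi), 0.9)
  expect_gte(mean(hits_ig), 0.9)
})
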