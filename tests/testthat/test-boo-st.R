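test_that("boost weights stay uniform on separable data and zero lr", {
  X <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
  tbl <- make_tbl(X, c(0, 0, 0, 0, 1))
  w <- boost_weights(tbl, boost_config(T_rounds = 5))
  expect_equal(w$weight, rep(0.2, 5))  # stump separates perfectly: early stop

  w0 <- boost_weights(tbl, boost_config(T_rounds = 1, learning_rate = 0))
  expect_equal(w0$weight, rep(0.2, 5))
})

test_that("misclassified samples gain weight over boosting rounds", {
  # XOR-ish layout a depth-1 stump cannot separate
  X <- matrix(c(0, 0, 1, 1, 0.5, 0.5,
                0, 1, 0, 1, 0.5, 0.6), ncol = 2)
  y <- c(0, 1, 1, 0, 0, 1)
  tbl <- make_tbl(X, y)
  w <- boost_weights(tbl, boost_config(T_rounds = 3))
  expect_equal(sum(w$weight), 1)
  expect_true(all(w$weight > 0))
  expect_gt(max(w$weight), min(w$weight))  # some emphasis accumulated
})

test_that("minority class accumulates more mean weight on imbalanced data", {
  tbl <- scaled_hf_table(n = 200, seed = 21, minority_fraction = 0.2)
  w <- boost_weights(tbl)
  y <- tbl$death_event
  minority <- as.integer(names(which.min(table(y))))
  expect_gte(mean(w$weight[y == minority]), mean(w$weight[y != minority]))
})

test_that("synthetic records obey the interpolation formula exactly", {
  withr::local_seed(5)
  for (rep in 1:20) {
    tbl <- random_tbl(n = sample(12:50, 1), d = 3, p_minority = 0.3)
    cfg <- smote_config(k = 3, seed = rep)
    out <- weighted_smote(tbl, config = cfg)
    rec <- out$records
    expect_gt(nrow(rec), 0)
    X <- as.matrix(as.data.frame(tbl)[, c("f1", "f2", "f3")])
    aug <- as.matrix(as.data.frame(out$augmented)[, c("f1", "f2", "f3")])
    syn_rows <- aug[startsWith(out$augmented$sample_id, "syn"), , drop = FALSE]
    for (s in seq_len(nrow(rec))) {
      xi <- X[rec$seed_index[s], ]
      xj <- X[rec$neighbor_index[s], ]
      expect_identical(unname(syn_rows[s, ]),
                       unname(xi + rec$r[s] * (xj - xi)))
      # convexity: each coordinate between seed and neighbor
      expect_true(all(syn_rows[s, ] >= pmin(xi, xj) - 1e-12))
      expect_true(all(syn_rows[s, ] <= pmax(xi, xj) + 1e-12))
    }
    # neighbor is among the k nearest minority neighbors of the seed
    min_idx <- which(tbl$death_event == minority_of(tbl))
    D <- as.matrix(dist(X[min_idx, , drop = FALSE]))
    diag(D) <- Inf
    k_eff <- min(3, length(min_idx) - 1)
    for (s in seq_len(nrow(rec))) {
      i <- match(rec$seed_index[s], min_idx)
      j <- match(rec$neighbor_index[s], min_idx)
      expect_lte(D[i, j], sort(D[i, ])[k_eff] + 1e-12)
    }
  }
})

test_that("binary features come from an endpoint, not interpolation", {
  withr::local_seed(8)
  X <- cbind(stats::runif(30), stats::rbinom(30, 1, 0.5))
  colnames(X) <- c("f1", "f2")
  tbl <- make_tbl(X, rep(c(1, 0), c(22, 8)), binary = "f2")
  out <- weighted_smote(tbl, config = smote_config(k = 3, seed = 2))
  syn <- out$augmented[startsWith(out$augmented$sample_id, "syn"), ]
  expect_true(all(syn$f2 %in% c(0, 1)))
  rec <- out$records
  expected <- ifelse(rec$r <= 0.5,
                     tbl$f2[rec$seed_index], tbl$f2[rec$neighbor_index])
  expect_equal(syn$f2, expected)
})

test_that("already balanced tables pass through SMOTE unchanged", {
  tbl <- random_tbl(20, p_minority = 0.5)
  out <- weighted_smote(tbl, config = smote_config())
  expect_identical(as.data.frame(out$augmented), as.data.frame(tbl))
  expect_equal(nrow(out$records), 0)
})

test_that("single-member minority and oversized k are handled", {
  tbl <- make_tbl(matrix(runif(10), ncol = 1), c(rep(1, 9), 0))
  expect_error(weighted_smote(tbl), "fewer than 2")
  tbl2 <- make_tbl(matrix(runif(12), ncol = 1), c(rep(1, 9), 0, 0, 0))
  expect_warning(out <- weighted_smote(tbl2, config = smote_config(k = 5)),
                 "lowered")
  expect_gt(nrow(out$records), 0)
})

test_that("Tomek links match hand-worked geometry", {
  # 1-D: class0 at 0.0, class1 at {0.1, 5.0} -> single pair (1, 2)
  tbl <- make_tbl(matrix(c(0, 0.1, 5)), c(0, 1, 1))
  pairs <- find_tomek_links(tbl)
  expect_equal(nrow(pairs), 1)
  expect_equal(c(pairs$index_a, pairs$index_b), c(1, 2))
  expect_equal(pairs$distance, 0.1)

  # well-separated clusters: no cross-class mutual NN
  X <- rbind(matrix(runif(20, 0, 0.1), ncol = 2),
             matrix(runif(20, 10, 10.1), ncol = 2))
  tbl2 <- make_tbl(X, rep(c(0, 1), each = 10))
  expect_equal(nrow(find_tomek_links(tbl2)), 0)

  # exact duplicates in opposite classes pair at distance zero
  tbl3 <- make_tbl(matrix(c(0.5, 0.5, 9), ncol = 1), c(0, 1, 1))
  pairs3 <- find_tomek_links(tbl3)
  expect_equal(nrow(pairs3), 1)
  expect_equal(pairs3$distance, 0)
})

test_that("Tomek finder agrees with the brute-force oracle", {
  withr::local_seed(42)
  for (rep in 1:40) {
    tbl <- random_tbl(sample(8:60, 1), d = sample(2:4, 1))
    got <- find_tomek_links(tbl)
    oracle <- brute_tomek(tbl)
    expect_equal(nrow(got), length(oracle))
    if (length(oracle)) {
      expect_equal(Map(c, got$index_a, got$index_b), unname(oracle))
    }
  }
})

test_that("majority members of pairs are removed, minority kept", {
  tbl <- make_tbl(matrix(c(0, 0.1, 5)), c(0, 1, 1))
  pairs <- find_tomek_links(tbl)
  cleaned <- remove_tomek_majority(tbl, pairs)
  expect_equal(nrow(cleaned), 2)
  expect_equal(sort(cleaned$death_event), c(0, 1))
  expect_false("s2" %in% cleaned$sample_id)  # the 0.1 majority point

  expect_identical(remove_tomek_majority(tbl, pairs[0, ]), tbl)
  bad <- pairs; bad$index_b <- 99
  expect_error(remove_tomek_majority(tbl, bad), "out of range")
})

test_that("the composite resampler reconciles its counts exactly", {
  tbl <- scaled_hf_table(n = 200, seed = 31, minority_fraction = 0.2)
  res <- boo_st(tbl, smote_cfg = smote_config(seed = 31))
  rep_tbl <- tidy(res$report)
  expect_equal(rep_tbl$after, rep_tbl$before + rep_tbl$synthesized -
                 rep_tbl$removed)
  expect_equal(sum(rep_tbl$after), nrow(res$balanced))
  # synthetic rows only ever belong to the minority class
  min_lab <- res$report$minority_label
  syn <- res$balanced[startsWith(res$balanced$sample_id, "syn"), ]
  expect_true(all(syn$death_event == min_lab))
  # determinism of the whole composite
  res2 <- boo_st(tbl, smote_cfg = smote_config(seed = 31))
  expect_identical(as.data.frame(res$balanced), as.data.frame(res2$balanced))
})

test_that("balanced well-separated input passes through unchanged", {
  X <- rbind(matrix(runif(20, 0, 0.1), ncol = 2),
             matrix(runif(20, 5, 5.1), ncol = 2))
  tbl <- make_tbl(X, rep(c(0, 1), each = 10))
  res <- boo_st(tbl)
  expect_identical(as.data.frame(res$balanced), as.data.frame(tbl))
})

test_that("seed-selection frequency tracks boost weights (emphasis)", {
  tbl <- scaled_hf_table(n = 150, seed = 13, minority_fraction = 0.2)
  w <- boost_weights(tbl)
  min_idx <- which(tbl$death_event == minority_of(tbl))
  counts <- numeric(length(min_idx))
  for (seed in 1:20) {
    rec <- weighted_smote(tbl, w, smote_config(seed = seed))$records
    counts <- counts + tabulate(match(rec$seed_index, min_idx),
                                nbins = length(min_idx))
  }
  rho <- suppressWarnings(
    cor(counts, w$weight[min_idx], method = "spearman")
  )
  expect_gt(rho, 0)
})
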