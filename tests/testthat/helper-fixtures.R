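# build a clinical_tbl around an arbitrary feature matrix (geometric
# fixtures for the resampling / PDP oracles)
make_tbl <- function(X, y, binary = character()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  sch <- tibble::tibble(
    name = c(colnames(X), "death_event"),
    kind = c(ifelse(colnames(X) %in% binary, "binary", "continuous"),
             "binary"),
    unit = "",
    low = c(ifelse(colnames(X) %in% binary, 0, -1e9), 0),
    high = c(ifelse(colnames(X) %in% binary, 1, 1e9), 1)
  )
  df <- tibble::as_tibble(as.data.frame(X))
  df$death_event <- as.integer(y)
  clinical_table(df, schema = sch, check_range = FALSE)
}

# random imbalanced table for the oracle sweeps
random_tbl <- function(n, d = 3, p_minority = 0.3) {
  y <- c(rep(1L, max(2, round(n * (1 - p_minority)))),
         rep(0L, max(2, n - round(n * (1 - p_minority)))))
  X <- matrix(stats::runif(length(y) * d), ncol = d)
  make_tbl(X, y)
}

# O(n^2) brute-force Tomek oracle: enumerate every cross-class pair and
# keep the mutual nearest neighbors
brute_tomek <- function(tbl) {
  X <- as.matrix(as.data.frame(tbl)[, setdiff(attr(tbl, "schema")$name,
                                              "death_event"), drop = FALSE])
  y <- tbl$death_event
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (y[i] == y[j]) next
      if (which.min(D[i, ]) == j && which.min(D[j, ]) == i) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  pairs
}

# full 2^n enumeration oracle for the signed-rank test
wsrt_enum <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  s <- sum(r)
  ts <- min(w_plus, s - w_plus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- mean(w_all <= ts + 1e-9 | w_all >= s - ts - 1e-9)
  list(statistic = ts, p_value = min(1, p))
}

# per-row substitution PDP oracle
brute_pdp <- function(model, tbl, feature, grid) {
  vapply(grid, function(v) {
    acc <- 0
    for (i in seq_len(nrow(tbl))) {
      row <- tbl
      row[[feature]][i] <- v
      acc <- acc + predict(model, row, type = "prob")[i, "1"]
    }
    acc / nrow(tbl)
  }, numeric(1))
}

minority_of <- function(tbl) {
  y <- tbl$death_event
  if (sum(y == 1) <= sum(y == 0)) 1L else 0L
}

# stub model with a fixed positive-class probability vector
stub_model <- function(p1) {
  structure(list(p1 = p1), class = "hf_stub_model")
}
predict.hf_stub_model <- function(object, newdata, type = c("prob", "label"),
                                  ...) {
  type <- match.arg(type)
  p1 <- rep(object$p1, length.out = nrow(newdata))
  prob <- cbind(`0` = 1 - p1, `1` = p1)
  if (type == "prob") prob else as.integer(p1 >= 0.5)
}
registerS3method("predict", "hf_stub_model", predict.hf_stub_model,
                 envir = asNamespace("stats"))

# model whose probability is the logistic of one standardized feature
sigmoid_model <- function(feature, center, scale) {
  structure(list(feature = feature, center = center, scale = scale),
            class = "hf_sigmoid_model")
}
predict.hf_sigmoid_model <- function(object, newdata,
                                     type = c("prob", "label"), ...) {
  type <- match.arg(type)
  z <- (newdata[[object$feature]] - object$center) / object$scale
  p1 <- stats::plogis(z)
  prob <- cbind(`0` = 1 - p1, `1` = p1)
  if (type == "prob") prob else as.integer(p1 >= 0.5)
}
registerS3method("predict", "hf_sigmoid_model", predict.hf_sigmoid_model,
                 envir = asNamespace("stats"))

scaled_hf_table <- function(n = 150, seed = 1, ...) {
  tbl <- simulate_hf(hf_generator_config(n_samples = n, seed = seed, ...))
  apply_minmax(tbl, fit_minmax(tbl))
}
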