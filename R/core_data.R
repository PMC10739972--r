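#' Read a clinical-records CSV
#'
#' Reads a comma-separated file whose header matches the schema (order
#' insensitive; display-name and shorthand aliases such as
#' `"Ejection fraction"` or `"Se_cr"` are accepted). Unknown columns and
#' schema violations are reported by column and row.
#'
#' @param path Path to a CSV file.
#' @inheritParams clinical_table
#' @return A [clinical_table()].
#' @export
read_clinical_csv <- function(path, schema = hf_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  aliases <- hf_aliases()
  nm <- names(raw)
  canonical <- ifelse(nm %in% names(aliases), aliases[nm], nm)
  names(raw) <- canonical
  unknown <- setdiff(canonical, c(schema$name, "sample_id"))
  if (length(unknown)) {
    stop("unknown column(s) not in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(schema$name, canonical)
  if (length(missing_cols)) {
    stop("missing schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    warning("empty table: header only, zero records", call. = FALSE)
    for (nm in intersect(schema$name, names(raw))) raw[[nm]] <- numeric(0)
  }
  non_num <- canonical[canonical %in% schema$name &
                         !vapply(raw, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric cell(s) in column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  }
  clinical_table(raw, schema = schema)
}

#' @rdname read_clinical_csv
#' @param data A `clinical_tbl` to write.
#' @export
write_clinical_csv <- function(data, path) {
  out <- as.data.frame(data)[, c("sample_id", attr(data, "schema")$name %||% hf_schema()$name)]
  readr::write_csv(out, path)
  invisible(path)
}

#' Min-max scaling
#'
#' `fit_minmax()` learns per-column (min, max) pairs from a table;
#' `apply_minmax()` maps each fitted column `x` to `(x - min)/(max - min)`.
#' Zero-range columns map to 0 and values outside the fitted range are
#' clipped to `[0, 1]`, so distance-based downstream steps always see
#' bounded inputs. By default only non-binary features are scaled
#' (binary flags are already in `{0, 1}`).
#'
#' To avoid information leaking from test to train, fit the scaler on the
#' training side only and apply it to both sides; fitting on the full
#' table before splitting is available for faithful reproduction of
#' published single-table protocols via [run_pipeline()]'s
#' `paper_faithful` flag.
#'
#' @param data A `clinical_tbl` or data frame of clinical records.
#' @param columns Character vector of columns to scale; defaults to all
#'   non-binary features of the schema.
#' @return `fit_minmax()` returns a `minmax_scaler`; `apply_minmax()`
#'   returns the rescaled table (same class as the input).
#' @examples
#' tbl <- simulate_hf(hf_generator_config(n_samples = 50, seed = 1))
#' sc <- fit_minmax(tbl)
#' range(apply_minmax(tbl, sc)$age)
#' @export
fit_minmax <- function(data, columns = NULL) {
  sch <- attr(data, "schema") %||% hf_schema()
  columns <- columns %||% sch$name[sch$kind != "binary" & sch$name != "death_event"]
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols)) {
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ranges <- purrr::map_dfr(columns, function(cl) {
    v <- data[[cl]]
    tibble::tibble(column = cl,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_)
  })
  structure(ranges, class = c("minmax_scaler", class(ranges)))
}

#' @rdname fit_minmax
#' @param scaler A `minmax_scaler` from `fit_minmax()`.
#' @export
apply_minmax <- function(data, scaler) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  absent <- setdiff(scaler$column, names(data))
  if (length(absent)) {
    stop("scaler column(s) absent from table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(scaler))) {
    cl <- scaler$column[i]
    lo <- scaler$min[i]; hi <- scaler$max[i]
    v <- data[[cl]]
    if (!length(v)) next
    if (is.na(lo) || hi == lo) {
      data[[cl]] <- rep(0, length(v))
    } else {
      data[[cl]] <- pmin(pmax((v - lo) / (hi - lo), 0), 1)
    }
  }
  attr(data, "scaled") <- TRUE
  data
}

#' Multi-split evaluation plan
#'
#' Defines the repeated train/test partitions used by the evaluation
#' protocol: one stratified split per training fraction (defaults 70, 80
#' and 90 % train). The test count is `round(n * (1 - fraction))`,
#' allocated across classes by largest remainder so the per-side class
#' proportions stay within one sample of the global proportions.
#'
#' @param train_fractions Numeric vector of training fractions in (0, 1).
#' @param seed Integer RNG seed making index draws reproducible.
#' @param stratified Logical; stratify by label (default `TRUE`).
#' @return A `split_plan` list.
#' @export
split_plan <- function(train_fractions = c(0.7, 0.8, 0.9), seed = 1L,
                       stratified = TRUE) {
  stopifnot(all(train_fractions > 0), all(train_fractions < 1))
  structure(list(train_fractions = train_fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_plan")
}

#' Stratified train/test splits
#'
#' Materialises the splits of a [split_plan()]: for each fraction, a
#' disjoint and exhaustive train/test partition, stratified by
#' `death_event`, reproducible under the plan's seed.
#'
#' @param data A `clinical_tbl` with both classes present and `n >= 10`.
#' @param plan A [split_plan()].
#' @return A tibble with columns `fraction`, `train` and `test`
#'   (list-columns of `clinical_tbl`s).
#' @export
make_splits <- function(data, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  y <- clinical_labels(data)
  n <- length(y)
  if (n < 10) stop("need at least 10 samples to split", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  withr::with_seed(plan$seed, {
    purrr::map_dfr(plan$train_fractions, function(f) {
      test_idx <- draw_test_indices(y, f, stratified = plan$stratified)
      train_idx <- setdiff(seq_len(n), test_idx)
      if (plan$stratified &&
          (length(unique(y[train_idx])) < 2 || length(unique(y[test_idx])) < 2)) {
        stop("a class is absent from one side of the ", f, " split",
             call. = FALSE)
      }
      tibble::tibble(
        fraction = f,
        train = list(subset_clinical(data, train_idx)),
        test = list(subset_clinical(data, test_idx))
      )
    })
  })
}

# largest-remainder per-class allocation of the test set
draw_test_indices <- function(y, fraction, stratified = TRUE) {
  n <- length(y)
  n_test <- round(n * (1 - fraction))
  n_test <- max(1L, min(n - 1L, n_test))
  if (!stratified) {
    return(sort(sample(n, n_test)))
  }
  classes <- sort(unique(y))
  ideal <- vapply(classes, function(cl) sum(y == cl) * n_test / n, numeric(1))
  alloc <- floor(ideal)
  rem <- n_test - sum(alloc)
  if (rem > 0) {
    frac_order <- order(ideal - alloc, -ideal, decreasing = TRUE)
    alloc[frac_order[seq_len(rem)]] <- alloc[frac_order[seq_len(rem)]] + 1
  }
  idx <- unlist(lapply(seq_along(classes), function(j) {
    pool <- which(y == classes[j])
    sample(pool, min(alloc[j], length(pool)))
  }))
  sort(idx)
}

subset_clinical <- function(data, idx) {
  out <- tibble::as_tibble(as.data.frame(data)[idx, , drop = FALSE])
  structure(out, schema = attr(data, "schema"),
            scaled = attr(data, "scaled"),
            class = class(data))
}
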