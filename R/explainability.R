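#' Partial dependence of the predicted death probability on one feature
#'
#' Sweeps the feature over a grid — 20 equal-frequency quantiles of the
#' observed values for non-binary features, `{0, 1}` for binary flags —
#' substituting each grid value into every row while all other features
#' keep their observed values, and averages the model's positive-class
#' probability over the rows (the true partial-dependence estimate).
#'
#' @param model A fitted object supporting
#'   `predict(model, newdata, type = "prob")`.
#' @param data A `clinical_tbl` providing the background rows.
#' @param feature Feature name.
#' @param grid_size Number of quantile grid points (default 20).
#' @return A `pdp_curve` tibble with columns `grid` (strictly
#'   increasing) and `pd` (averaged probability, in `[0, 1]`), plus a
#'   `feature` attribute.
#' @examples
#' tbl <- simulate_hf(hf_generator_config(n_samples = 120, seed = 6))
#' fit <- train_base(base_learner("DT"), tbl)
#' pdp(fit, tbl, "serum_creatinine")
#' @export
pdp <- function(model, data, feature, grid_size = 20L) {
  if (!feature %in% names(data)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  sch <- attr(data, "schema") %||% hf_schema()
  kind <- sch$kind[match(feature, sch$name)]
  grid <- if (!is.na(kind) && kind == "binary") {
    c(0, 1)
  } else {
    sort(unique(stats::quantile(data[[feature]],
                                probs = seq(0, 1, length.out = grid_size),
                                type = 7, names = FALSE)))
  }
  pd <- vapply(grid, function(v) {
    sub <- data
    sub[[feature]] <- rep(v, nrow(sub))
    mean(predict(model, sub, type = "prob")[, "1"])
  }, numeric(1))
  out <- tibble::tibble(grid = grid, pd = pd)
  structure(out, feature = feature,
            class = c("pdp_curve", class(out)))
}

#' Extract high-risk value ranges from a partial-dependence curve
#'
#' Flags the contiguous grid intervals where the partial dependence
#' exceeds a threshold — by default `mean(pd) + 0.5 * sd(pd)`, i.e.
#' regions where the averaged death probability is clearly above the
#' feature's typical level. Adjacent flagged grid points merge into one
#' range; ranges are disjoint and sorted.
#'
#' @param curve A [pdp()] curve.
#' @param threshold Numeric cut on `pd`; default
#'   `mean(pd) + 0.5 * sd(pd)`.
#' @return A tibble with columns `feature`, `low`, `high`, `peak_pd`,
#'   `threshold` (zero rows when nothing exceeds the cut).
#' @export
risk_ranges <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "pdp_curve"), nrow(curve) >= 1)
  thr <- threshold %||%
    (mean(curve$pd) + 0.5 * stats::sd(curve$pd))
  if (is.na(thr)) thr <- Inf  # single-point curve has sd NA: nothing exceeds
  above <- curve$pd > thr
  if (!any(above)) {
    return(tibble::tibble(feature = character(), low = numeric(),
                          high = numeric(), peak_pd = numeric(),
                          threshold = numeric()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  purrr::map_dfr(keep, function(i) {
    idx <- starts[i]:ends[i]
    tibble::tibble(
      feature = attr(curve, "feature"),
      low = curve$grid[starts[i]],
      high = curve$grid[ends[i]],
      peak_pd = max(curve$pd[idx]),
      threshold = thr
    )
  })
}

#' Plot a partial-dependence curve
#'
#' @param object A `pdp_curve`.
#' @param ... Unused.
#' @return A ggplot line plot of averaged death probability over the
#'   feature grid.
#' @export
autoplot.pdp_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$grid, y = .data$pd)) +
    ggplot2::geom_line(colour = "limegreen", linewidth = 0.8) +
    ggplot2::geom_rug(sides = "b") +
    ggplot2::labs(x = attr(object, "feature"),
                  y = "partial dependence (P(death))") +
    ggplot2::theme_minimal()
}
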