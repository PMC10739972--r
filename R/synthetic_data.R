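#' Synthetic clinical-records generator configuration
#'
#' Defaults emulate the heart-failure clinical-records table the package
#' targets: 299 patients, 96 minority-class cases (the survivors — the
#' published composition reports 203 deaths against 96 survivals), and a
#' planted dependence of mortality on follow-up time, serum creatinine,
#' ejection fraction and age, in that order of strength, matching the
#' published feature-importance rank order. Signs follow clinical
#' direction: shorter follow-up, higher creatinine, lower ejection
#' fraction and higher age all push towards death.
#'
#' @param n_samples Number of records (default 299).
#' @param minority_fraction Share of the minority class in (0, 0.5]
#'   (default 96/299).
#' @param minority_is_death Logical; is the minority class the death
#'   class? Default `FALSE` (deaths are the majority, as published).
#' @param signal_features Named numeric vector of effect weights on the
#'   latent log-odds of death, per standardized feature.
#' @param noise_sd Standard deviation of the latent-score noise.
#' @param overlap Non-negative scalar; larger values shrink the signal
#'   relative to the noise, increasing class overlap.
#' @param seed Integer RNG seed.
#' @return An `hf_generator_config` list.
#' @export
hf_generator_config <- function(n_samples = 299,
                                minority_fraction = 96 / 299,
                                minority_is_death = FALSE,
                                signal_features = c(
                                  time = -1.4,
                                  serum_creatinine = 1.0,
                                  ejection_fraction = -0.8,
                                  age = 0.6
                                ),
                                noise_sd = 1,
                                overlap = 0,
                                seed = 1L) {
  stopifnot(n_samples >= 4,
            minority_fraction > 0, minority_fraction <= 0.5,
            minority_fraction * n_samples >= 2,
            noise_sd >= 0, overlap >= 0)
  bad <- setdiff(names(signal_features), hf_feature_names())
  if (length(bad)) {
    stop("unknown signal feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 minority_fraction = minority_fraction,
                 minority_is_death = isTRUE(minority_is_death),
                 signal_features = signal_features,
                 noise_sd = noise_sd, overlap = overlap,
                 seed = as.integer(seed)),
            class = "hf_generator_config")
}

#' Simulate a heart-failure-style clinical table
#'
#' Draws features within the schema's valid ranges — right-skewed labs
#' (creatinine phosphokinase, platelets, serum creatinine) from range-
#' truncated log-normals, other non-binary features uniformly, binary
#' flags from Bernoulli draws with realistic prevalences — then assigns
#' labels from a logistic latent score
#' `z = sum(w_j * standardized(x_j)) / (1 + overlap) + noise`,
#' with the intercept solved by bisection so the expected minority share
#' matches the configuration, and finally trims to the exact class
#' counts by flipping the labels of the most boundary-ambiguous records.
#' Fully reproducible under the configured seed.
#'
#' @param config An [hf_generator_config()].
#' @return A [clinical_table()] with exact class counts
#'   `round(n * minority_fraction)` vs the rest.
#' @examples
#' tbl <- simulate_hf(hf_generator_config(seed = 7))
#' table(tbl$death_event)
#' @export
simulate_hf <- function(config = hf_generator_config()) {
  stopifnot(inherits(config, "hf_generator_config"))
  n <- config$n_samples
  n_min <- round(n * config$minority_fraction)
  if (n_min < 2 || n - n_min < 2) {
    stop("infeasible minority_fraction for n_samples", call. = FALSE)
  }
  sch <- hf_schema()
  withr::with_seed(config$seed, {
    X <- draw_features(n, sch)
    y <- draw_labels(X, config, n_min)
  })
  df <- tibble::as_tibble(as.data.frame(X))
  df$death_event <- y
  clinical_table(df, schema = sch)
}

# skewed labs are log-normal truncated to the schema range; remaining
# non-binary features uniform; binaries Bernoulli at plausible prevalences
draw_features <- function(n, sch) {
  lognormal_cols <- c(
    creatinine_phosphokinase = NA, platelets = NA, serum_creatinine = NA
  )
  lognormal_pars <- list(
    creatinine_phosphokinase = c(meanlog = log(250), sdlog = 1.1),
    platelets = c(meanlog = log(260), sdlog = 0.4),
    serum_creatinine = c(meanlog = log(1.1), sdlog = 0.45)
  )
  bern_p <- c(anaemia = 0.43, high_blood_pressure = 0.35, diabetes = 0.42,
              sex = 0.65, smoking = 0.32)
  cols <- lapply(seq_len(nrow(sch)), function(i) {
    nm <- sch$name[i]
    if (nm == "death_event") return(NULL)
    lo <- sch$low[i]; hi <- sch$high[i]
    v <- if (sch$kind[i] == "binary") {
      stats::rbinom(n, 1, bern_p[[nm]])
    } else if (nm %in% names(lognormal_pars)) {
      p <- lognormal_pars[[nm]]
      rlnorm_trunc(n, p["meanlog"], p["sdlog"], lo, hi)
    } else {
      stats::runif(n, lo, hi)
    }
    if (sch$kind[i] == "integer") v <- round(v)
    pmin(pmax(v, lo), hi)
  })
  names(cols) <- sch$name
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}

# inverse-CDF truncated log-normal draw
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, p_lo, p_hi), meanlog, sdlog)
}

draw_labels <- function(X, config, n_min) {
  n <- nrow(X)
  w <- config$signal_features
  z <- rep(0, n)
  if (length(w)) {
    Xs <- scale(X[, names(w), drop = FALSE])
    Xs[is.nan(Xs)] <- 0
    z <- drop(Xs %*% w) / (1 + config$overlap)
  }
  z <- z + stats::rnorm(n, 0, config$noise_sd)
  # minority share of the DEATH class
  target_death <- if (config$minority_is_death) {
    config$minority_fraction
  } else {
    1 - config$minority_fraction
  }
  b <- solve_intercept(z, target_death)
  p <- stats::plogis(z + b)
  y <- stats::rbinom(n, 1, p)
  n_death <- if (config$minority_is_death) n_min else n - n_min
  trim_to_count(y, p, n_death)
}

# bisection on the intercept so mean(sigmoid(z + b)) hits the target rate
solve_intercept <- function(z, target) {
  f <- function(b) mean(stats::plogis(z + b)) - target
  lo <- -50; hi <- 50
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# flip the labels of the records nearest the decision boundary until the
# death count is exact; deterministic (ties by row index)
trim_to_count <- function(y, p, n_death) {
  excess <- sum(y) - n_death
  if (excess > 0) {
    cand <- which(y == 1)
    flip <- cand[order(p[cand], cand)][seq_len(excess)]
    y[flip] <- 0L
  } else if (excess < 0) {
    cand <- which(y == 0)
    flip <- cand[order(-p[cand], cand)][seq_len(-excess)]
    y[flip] <- 1L
  }
  as.integer(y)
}

#' Summarise a clinical table
#'
#' Per-feature minimum, maximum and mean together with class counts;
#' mirrors the schema's range column so tests can assert conformity.
#'
#' @param data A `clinical_tbl`.
#' @return A tibble with one row per schema column plus attributes
#'   `n` and `class_counts`.
#' @export
describe_clinical <- function(data) {
  sch <- attr(data, "schema") %||% hf_schema()
  out <- purrr::map_dfr(sch$name, function(nm) {
    v <- data[[nm]]
    tibble::tibble(
      feature = nm,
      kind = sch$kind[match(nm, sch$name)],
      min = if (length(v)) min(v) else NA_real_,
      max = if (length(v)) max(v) else NA_real_,
      mean = if (length(v)) mean(v) else NA_real_
    )
  })
  y <- clinical_labels(data)
  attr(out, "n") <- nrow(data)
  attr(out, "class_counts") <- c(survived = sum(y == 0), died = sum(y == 1))
  out
}
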