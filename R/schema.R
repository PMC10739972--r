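#' Clinical-records feature schema
#'
#' The column schema of a heart-failure clinical-records table: twelve
#' predictors (a mix of binary flags, integer counts and continuous labs)
#' plus the binary target `death_event` (1 = died during follow-up,
#' 0 = survived). Each feature carries its measurement unit and the valid
#' value range used for validation and by the synthetic generator.
#'
#' @return A tibble with columns `name`, `kind` (one of `"binary"`,
#'   `"integer"`, `"continuous"`), `unit`, `low`, `high`.
#' @examples
#' hf_schema()
#' @export
hf_schema <- function() {
  tibble::tribble(
    ~name,                       ~kind,        ~unit,                ~low,   ~high,
    "age",                       "continuous", "years",              40,     95,
    "anaemia",                   "binary",     "flag",               0,      1,
    "high_blood_pressure",       "binary",     "flag",               0,      1,
    "creatinine_phosphokinase",  "integer",    "mcg/L",              23,     7861,
    "diabetes",                  "binary",     "flag",               0,      1,
    "ejection_fraction",         "integer",    "percent",            14,     80,
    "sex",                       "binary",     "flag",               0,      1,
    "platelets",                 "continuous", "kiloplatelets/mL",   25.01,  850,
    "serum_creatinine",          "continuous", "mg/dL",              0.5,    9.4,
    "serum_sodium",              "integer",    "mEq/L",              114,    148,
    "smoking",                   "binary",     "flag",               0,      1,
    "time",                      "integer",    "days",               4,      285,
    "death_event",               "binary",     "flag",               0,      1
  )
}

#' @rdname hf_schema
#' @export
hf_feature_names <- function() {
  setdiff(hf_schema()$name, "death_event")
}

#' Header aliases accepted when reading clinical CSV files
#'
#' Maps common header spellings (display names with spaces, shorthand
#' column names) onto the canonical snake_case schema names.
#'
#' @return A named character vector: `alias -> canonical`.
#' @keywords internal
hf_aliases <- function() {
  c(
    "Age" = "age",
    "Anaemia" = "anaemia",
    "High blood pressure" = "high_blood_pressure",
    "H_b_p" = "high_blood_pressure",
    "Creatinine phosphokinase" = "creatinine_phosphokinase",
    "Cr_ph" = "creatinine_phosphokinase",
    "Diabetes" = "diabetes",
    "Ejection fraction" = "ejection_fraction",
    "Ej_fr" = "ejection_fraction",
    "Ej_fa" = "ejection_fraction",
    "Sex" = "sex",
    "Platelets" = "platelets",
    "Serum creatinine" = "serum_creatinine",
    "Se_cr" = "serum_creatinine",
    "Serum sodium" = "serum_sodium",
    "Se_so" = "serum_sodium",
    "Smoking" = "smoking",
    "Time" = "time",
    "DEATH_EVENT" = "death_event"
  )
}

#' Construct a validated clinical table
#'
#' Wraps a data frame of clinical records into a `clinical_tbl`: a tibble
#' with one row per patient, the schema's feature columns, a binary
#' `death_event` target and an opaque `sample_id`. Validation checks
#' column presence, numeric type, missingness and binary {0,1} coding;
#' out-of-range values in non-binary columns are reported as warnings
#' with their row indices (ranges describe raw, unscaled data).
#'
#' @param data A data frame holding the schema columns (canonical names).
#'   A `sample_id` character column is added when absent.
#' @param schema Feature schema, see [hf_schema()].
#' @param validate Logical; run invariant checks (default `TRUE`).
#' @param check_range Logical; warn on out-of-range raw values
#'   (default `TRUE`; set `FALSE` for scaled or resampled tables).
#' @return A `clinical_tbl` (subclass of tibble) with a `schema` attribute.
#' @export
clinical_table <- function(data, schema = hf_schema(), validate = TRUE,
                           check_range = TRUE) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    data$sample_id <- if (nrow(data)) paste0("s", seq_len(nrow(data))) else character()
  }
  data$sample_id <- as.character(data$sample_id)
  data <- data[, c("sample_id", intersect(schema$name, names(data))), drop = FALSE]
  if (validate) {
    validate_clinical(data, schema, check_range = check_range)
  }
  structure(
    data,
    schema = schema,
    class = c("clinical_tbl", class(tibble::tibble()))
  )
}

#' @rdname clinical_table
#' @export
is_clinical_tbl <- function(data) inherits(data, "clinical_tbl")

validate_clinical <- function(data, schema = hf_schema(), check_range = TRUE) {
  missing_cols <- setdiff(schema$name, names(data))
  if (length(missing_cols)) {
    stop("missing schema column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- data[[nm]]
    if (!is.numeric(v)) {
      stop("column '", nm, "' is not numeric", call. = FALSE)
    }
    if (anyNA(v)) {
      stop("column '", nm, "' has missing values at row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           call. = FALSE)
    }
    if (schema$kind[i] == "binary" && length(v) && !all(v %in% c(0, 1))) {
      stop("binary column '", nm, "' holds values outside {0, 1} at row(s) ",
           paste(utils::head(which(!v %in% c(0, 1)), 5), collapse = ", "),
           call. = FALSE)
    }
    if (check_range && schema$kind[i] != "binary" && length(v)) {
      bad <- which(v < schema$low[i] | v > schema$high[i])
      if (length(bad)) {
        warning("column '", nm, "' outside its valid range [", schema$low[i],
                ", ", schema$high[i], "] at row(s) ",
                paste(utils::head(bad, 5), collapse = ", "),
                if (length(bad) > 5) " ..." else "",
                call. = FALSE)
      }
    }
  }
  invisible(data)
}

# feature matrix / label accessors used throughout
clinical_features <- function(data, features = NULL) {
  sch <- attr(data, "schema")
  if (is.null(sch)) sch <- hf_schema()
  features <- features %||% setdiff(sch$name, "death_event")
  as.matrix(as.data.frame(data)[, features, drop = FALSE])
}

clinical_labels <- function(data) as.integer(data[["death_event"]])

# label value of the minority (less frequent) class; ties -> 1 (the
# positive / death class) so downstream emphasis lands on deaths
minority_label <- function(y) {
  tab <- c(`0` = sum(y == 0), `1` = sum(y == 1))
  if (tab["1"] <= tab["0"]) 1L else 0L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
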