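#' sepsiskit: utility scoring, Sepsis-3 labeling, and synthetic ICU cohorts
#'
#' Evaluation and data machinery for hourly sepsis prediction in the ICU:
#' a time-dependent clinical utility score for sequential predictions, a
#' Sepsis-3 onset labeler, pipe-separated patient-record I/O with cohort
#' inclusion rules, a seeded multi-hospital synthetic cohort generator, and a
#' Weibull proportional-hazards baseline predictor.
#'
#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble is_tibble new_tibble
#' @importFrom stats median optim rnorm runif rbinom quantile sd var cor
#'   setNames IQR
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

# Fixed 40-variable schema: 8 vitals, 26 laboratory values, 6 demographics.
.VITALS <- c("HR", "O2Sat", "Temp", "SBP", "MAP", "DBP", "Resp", "EtCO2")

.LABS <- c(
  "BaseExcess", "HCO3", "FiO2", "pH", "PaCO2", "SaO2", "AST", "BUN",
  "Alkalinephos", "Calcium", "Chloride", "Creatinine", "Bilirubin_direct",
  "Glucose", "Lactate", "Magnesium", "Phosphate", "Potassium",
  "Bilirubin_total", "TroponinI", "Hct", "Hgb", "PTT", "WBC",
  "Fibrinogen", "Platelets"
)

.DEMOGRAPHICS <- c("Age", "Gender", "Unit1", "Unit2", "HospAdmTime", "ICULOS")

#' The hourly patient-record variable schema
#'
#' Forty clinical variables in fixed column order: eight vital signs, 26
#' laboratory values, and six demographic variables. All record I/O, the
#' synthetic generator, and the measurement-density and distribution-shift
#' reports use this order.
#'
#' @param group One of `"all"`, `"vitals"`, `"labs"`, `"demographics"`, or
#'   `"clinical"` (vitals + labs, the 34 time-varying variables).
#' @return Character vector of variable names.
#' @examples
#' length(sepsis_vars())          # 40
#' sepsis_vars("vitals")
#' @export
sepsis_vars <- function(group = c("all", "vitals", "labs", "demographics",
                                  "clinical")) {
  group <- match.arg(group)
  switch(group,
    all = c(.VITALS, .LABS, .DEMOGRAPHICS),
    vitals = .VITALS,
    labs = .LABS,
    demographics = .DEMOGRAPHICS,
    clinical = c(.VITALS, .LABS)
  )
}

#' Default source-variable aliasing map
#'
#' Raw EMR extracts may report the same clinical parameter under several
#' source names (e.g. serum and arterial hemoglobin); aliased names are merged
#' into one schema column before hourly binning. The default map covers the
#' hemoglobin merge; extend it by passing a named character vector
#' (`c(source_name = schema_name)`) to [condense_hourly()].
#'
#' @return Named character vector mapping source variable names to schema
#'   names.
#' @export
default_alias_map <- function() {
  c(Hgb_serum = "Hgb", Hgb_arterial = "Hgb")
}

#' Construct an hourly patient record
#'
#' A patient record is a tibble with one row per ICU hour (hour 0 first),
#' exactly the 40 schema columns in fixed order, and optionally a trailing
#' `SepsisLabel` column of 0/1 labels. The patient and hospital identifiers
#' travel as attributes so the tabular part round-trips through the
#' pipe-separated file format unchanged.
#'
#' @param values A data frame with the 40 schema columns (missing entries
#'   `NA`). Extra columns other than `SepsisLabel` are an error.
#' @param labels Optional integer vector of per-hour 0/1 sepsis labels; must
#'   be non-decreasing. Overrides any `SepsisLabel` column in `values`.
#' @param patient_id,hospital_id Opaque identifier strings.
#' @param validate Check record invariants (default `TRUE`).
#' @return A `patient_record` tibble.
#' @examples
#' rec <- patient_record(empty_record_values(3), patient_id = "p1")
#' n_hours(rec)
#' @export
patient_record <- function(values, labels = NULL, patient_id = "unknown",
                           hospital_id = "A", validate = TRUE) {
  values <- as_tibble(values)
  if ("SepsisLabel" %in% names(values)) {
    if (is.null(labels)) labels <- as.integer(values$SepsisLabel)
    values$SepsisLabel <- NULL
  }
  schema <- sepsis_vars()
  missing_cols <- setdiff(schema, names(values))
  if (length(missing_cols) > 0) {
    abort(paste0("record is missing schema columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "sepsiskit_schema_error")
  }
  extra <- setdiff(names(values), schema)
  if (length(extra) > 0) {
    abort(paste0("unknown columns in record: ", paste(extra, collapse = ", ")),
          class = "sepsiskit_schema_error")
  }
  values <- values[schema]
  values[] <- lapply(values, as.double)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    values$SepsisLabel <- labels
  }
  rec <- new_tibble(values, class = "patient_record")
  attr(rec, "patient_id") <- as.character(patient_id)
  attr(rec, "hospital_id") <- as.character(hospital_id)
  if (validate) validate_patient_record(rec)
  rec
}

#' @rdname patient_record
#' @param x An object.
#' @export
is_patient_record <- function(x) inherits(x, "patient_record")

#' @rdname patient_record
#' @param record A `patient_record`.
#' @export
n_hours <- function(record) nrow(record)

#' @rdname patient_record
#' @export
patient_id <- function(record) attr(record, "patient_id")

#' @rdname patient_record
#' @export
hospital_id <- function(record) attr(record, "hospital_id")

#' @rdname patient_record
#' @export
record_labels <- function(record) {
  if ("SepsisLabel" %in% names(record)) as.integer(record$SepsisLabel) else NULL
}

#' @rdname patient_record
#' @param hours Number of hourly rows.
#' @export
empty_record_values <- function(hours) {
  stopifnot(hours >= 1)
  vals <- as_tibble(setNames(
    rep(list(rep(NA_real_, hours)), 40), sepsis_vars()
  ))
  vals$ICULOS <- as.double(seq_len(hours))
  vals
}

validate_patient_record <- function(record) {
  if (nrow(record) < 1) {
    abort("patient record must contain at least one hourly row",
          class = "sepsiskit_empty_record_error")
  }
  lab <- record_labels(record)
  if (!is.null(lab)) {
    if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
      abort("SepsisLabel must be 0/1 with no missing entries",
            class = "sepsiskit_schema_error")
    }
    if (any(diff(lab) < 0)) {
      abort("SepsisLabel must be non-decreasing over time",
            class = "sepsiskit_schema_error")
    }
  }
  # demographic columns constant within the record, except ICULOS (+1/row)
  for (v in setdiff(.DEMOGRAPHICS, "ICULOS")) {
    col <- record[[v]]
    obs <- col[!is.na(col)]
    if (length(obs) > 1 && max(obs) - min(obs) > 1e-9) {
      abort(paste0("demographic column ", v, " varies within a record"),
            class = "sepsiskit_schema_error")
    }
  }
  iculos <- record$ICULOS
  if (!anyNA(iculos) && nrow(record) > 1 &&
      any(abs(diff(iculos) - 1) > 1e-9)) {
    abort("ICULOS must increment by 1 per hourly row",
          class = "sepsiskit_schema_error")
  }
  invisible(record)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s | hospital %s | %d h%s>\n",
              patient_id(x), hospital_id(x), nrow(x),
              if (!is.null(record_labels(x))) " | labeled" else ""))
  NextMethod()
}

# tibble subsetting drops custom attrs; keep identity on [ when possible
#' @export
`[.patient_record` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "patient_id") <- attr(x, "patient_id")
    attr(out, "hospital_id") <- attr(x, "hospital_id")
  }
  out
}
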