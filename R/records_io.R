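#' Read an hourly patient record from pipe-separated text
#'
#' Parses the pipe-separated-value (PSV) patient-record layout: a header row
#' of column names followed by one row per ICU hour, missing entries encoded
#' as the literal token `NaN` (case-sensitive), no quoting, Unix newlines. A
#' trailing `SepsisLabel` column, when present, populates the record's
#' per-hour labels.
#'
#' @param file Path to a `.psv` file, or a length-1 character string of PSV
#'   text (distinguished by containing a newline or pipe), or a character
#'   vector of lines.
#' @param patient_id Identifier for the record; defaults to the file's base
#'   name without extension when reading from a path.
#' @param hospital_id Hospital system identifier attached to the record.
#' @return A [patient_record()].
#' @examples
#' txt <- write_psv(patient_record(empty_record_values(2), patient_id = "p"))
#' rec <- read_psv(txt)
#' @export
read_psv <- function(file, patient_id = NULL, hospital_id = "A") {
  if (length(file) == 1 && !grepl("[|\n]", file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(patient_id)) {
      patient_id <- sub("\\.[^.]*$", "", basename(file))
    }
  } else {
    lines <- unlist(strsplit(file, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    abort("empty PSV input: no header row", class = "sepsiskit_parse_error")
  }
  header <- strsplit(lines[[1]], "|", fixed = TRUE)[[1]]
  known <- c(sepsis_vars(), "SepsisLabel")
  bad <- setdiff(header, known)
  if (length(bad) > 0) {
    abort(paste0("unknown column name(s) in PSV header: ",
                 paste(bad, collapse = ", ")),
          class = "sepsiskit_schema_error")
  }
  if (anyDuplicated(header)) {
    abort("duplicate column names in PSV header",
          class = "sepsiskit_schema_error")
  }
  body <- lines[-1]
  if (length(body) == 0) {
    abort("PSV record has a header but no hourly rows",
          class = "sepsiskit_empty_record_error")
  }
  cells <- strsplit(body, "|", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != length(header))) {
    abort(sprintf("PSV row %d has %d fields; header has %d",
                  which(nfield != length(header))[1],
                  nfield[nfield != length(header)][1], length(header)),
          class = "sepsiskit_parse_error")
  }
  mat <- matrix(unlist(cells), nrow = length(body), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad_cell <- which(is.na(num) & mat != "NaN", arr.ind = TRUE)
  if (nrow(bad_cell) > 0) {
    abort(sprintf("non-numeric cell '%s' at row %d, column %s",
                  mat[bad_cell[1, 1], bad_cell[1, 2]], bad_cell[1, 1],
                  header[bad_cell[1, 2]]),
          class = "sepsiskit_parse_error")
  }
  num[mat == "NaN"] <- NA_real_
  vals <- as_tibble(setNames(as.data.frame(num), header))
  # columns absent from the file are missing throughout
  for (v in setdiff(sepsis_vars(), header)) vals[[v]] <- NA_real_
  patient_record(vals, patient_id = patient_id %||% "unknown",
                 hospital_id = hospital_id)
}

#' Write a patient record as pipe-separated text
#'
#' Inverse of [read_psv()]: header then one row per hour, missing entries as
#' `NaN`, `SepsisLabel` emitted last when the record carries labels.
#'
#' @param record A [patient_record()].
#' @param file Optional path; when given the text is written there and the
#'   path returned invisibly, otherwise the PSV text is returned as a single
#'   string.
#' @return PSV text (single string) or, with `file`, the path invisibly.
#' @export
write_psv <- function(record, file = NULL) {
  stopifnot(is_patient_record(record))
  cols <- names(record)
  fmt_col <- function(x, is_label) {
    if (is_label) return(as.character(as.integer(x)))
    vapply(x, function(v) {
      if (is.na(v)) "NaN" else format(v, digits = 15, scientific = FALSE,
                                      trim = TRUE)
    }, character(1))
  }
  body_cols <- lapply(cols, function(cn) {
    fmt_col(record[[cn]], identical(cn, "SepsisLabel"))
  })
  rows <- do.call(paste, c(body_cols, sep = "|"))
  text <- paste0(paste(c(paste(cols, collapse = "|"), rows), collapse = "\n"),
                 "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", text), file)
    return(invisible(file))
  }
  text
}

#' Condense raw timestamped observations into hourly bins
#'
#' Collapses irregular raw observations into the hourly record grid: the cell
#' for variable `v` at ICU hour `h` is the median of all observations of `v`
#' with timestamp in `[h, h + 1)`; hours with no observation stay missing.
#' Source variables that alias the same clinical parameter (e.g. serum and
#' arterial hemoglobin) are merged into one schema column before binning.
#'
#' @param observations A data frame with columns `variable` (name), `time`
#'   (hours since ICU admission, real-valued, must be `>= 0`), and `value`.
#' @param hours Number of hourly rows in the output record.
#' @param aliases Named character vector mapping source names to schema
#'   names; defaults to [default_alias_map()].
#' @return A tibble of record values (the 40 schema columns, `hours` rows)
#'   suitable for [patient_record()].
#' @examples
#' obs <- tibble::tibble(variable = "HR", time = c(3.1, 3.5, 3.9),
#'                       value = c(80, 84, 90))
#' condense_hourly(obs, hours = 5)$HR[4]  # median 84 at hour 3
#' @export
condense_hourly <- function(observations, hours,
                            aliases = default_alias_map()) {
  stopifnot(hours >= 1)
  obs <- as_tibble(observations)
  req <- c("variable", "time", "value")
  if (!all(req %in% names(obs))) {
    abort("observations need columns variable, time, value",
          class = "sepsiskit_schema_error")
  }
  if (nrow(obs) > 0 && any(obs$time < 0)) {
    abort("observation timestamps must be >= 0 (hours since ICU admission)",
          class = "sepsiskit_validation_error")
  }
  obs$variable <- dplyr::recode(as.character(obs$variable), !!!as.list(aliases))
  unknown <- setdiff(unique(obs$variable), sepsis_vars())
  if (length(unknown) > 0) {
    abort(paste0("observations of unknown variable(s): ",
                 paste(unknown, collapse = ", ")),
          class = "sepsiskit_schema_error")
  }
  vals <- empty_record_values(hours)
  if (nrow(obs) > 0) {
    binned <- obs |>
      dplyr::mutate(hour = floor(.data$time)) |>
      dplyr::filter(.data$hour < hours) |>
      dplyr::group_by(.data$variable, .data$hour) |>
      dplyr::summarise(value = median(.data$value), .groups = "drop")
    for (i in seq_len(nrow(binned))) {
      vals[[binned$variable[i]]][binned$hour[i] + 1L] <- binned$value[i]
    }
  }
  vals
}

#' Apply the cohort inclusion and truncation rules
#'
#' Enforces the study's cohort filters: records with fewer than 8 hourly
#' windows are excluded; septic records with onset earlier than 4 hours after
#' ICU admission are excluded; records longer than 2 weeks (336 hourly
#' windows) are truncated to the first 336 hours. Truncation never alters
#' retained cell values, and the filter is idempotent.
#'
#' @param records A list of [patient_record()]s.
#' @param annotations A sepsis annotation tibble (one row per record, in the
#'   same order) as produced by [annotate_cohort()] or
#'   [generate_cohort()]; needs columns `patient_id`, `is_septic`,
#'   `t_sepsis`. `NULL` skips the early-onset rule.
#' @param min_hours,max_hours,min_onset Filter constants; defaults 8, 336
#'   (14 days), and 4 hours.
#' @return A list with `records` (the retained, possibly truncated records),
#'   `annotations` (matching rows), and `exclusions`, a tibble of
#'   `patient_id`, `reason` (`"min-length"` or `"early-onset"`), and the
#'   offending value.
#' @export
apply_cohort_filters <- function(records, annotations = NULL,
                                 min_hours = 8L, max_hours = 336L,
                                 min_onset = 4) {
  stopifnot(is.list(records))
  ids <- vapply(records, patient_id, character(1))
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    if (nrow(annotations) != length(records) ||
        !identical(as.character(annotations$patient_id), ids)) {
      abort("annotations must pair 1:1 (same order) with records",
            class = "sepsiskit_pairing_error")
    }
  }
  hours <- vapply(records, n_hours, integer(1))
  excl <- tibble(patient_id = character(), reason = character(),
                 value = double())
  keep <- rep(TRUE, length(records))

  short <- hours < min_hours
  if (any(short)) {
    excl <- dplyr::bind_rows(excl, tibble(
      patient_id = ids[short], reason = "min-length",
      value = as.double(hours[short])
    ))
    keep[short] <- FALSE
  }
  if (!is.null(annotations)) {
    early <- keep & annotations$is_septic &
      !is.na(annotations$t_sepsis) & annotations$t_sepsis < min_onset
    if (any(early)) {
      excl <- dplyr::bind_rows(excl, tibble(
        patient_id = ids[early], reason = "early-onset",
        value = annotations$t_sepsis[early]
      ))
      keep[early] <- FALSE
    }
  }
  out <- lapply(records[keep], function(r) {
    if (nrow(r) > max_hours) r[seq_len(max_hours), ] else r
  })
  list(
    records = out,
    annotations = if (is.null(annotations)) NULL else annotations[keep, ],
    exclusions = excl
  )
}

#' Per-variable measurement density
#'
#' Fraction of non-missing hourly cells for each of the 34 time-varying
#' (vital sign and laboratory) variables, pooled over the cohort and, in the
#' `per_record` component, per patient record. Most vitals are measured
#' roughly hourly (density near 1) and most laboratory values roughly daily
#' (density near 1/24).
#'
#' @param records A non-empty list of [patient_record()]s.
#' @return A list with `overall` (tibble: `variable`, `group`, `density`) and
#'   `per_record` (tibble: `patient_id`, `variable`, `density`).
#' @export
measurement_density <- function(records) {
  if (!is.list(records) || length(records) == 0) {
    abort("measurement_density needs a non-empty cohort",
          class = "sepsiskit_validation_error")
  }
  vars <- sepsis_vars("clinical")
  per <- purrr::map_dfr(records, function(r) {
    tibble(
      patient_id = patient_id(r),
      variable = vars,
      density = vapply(vars, function(v) mean(!is.na(r[[v]])), double(1))
    )
  })
  pooled_n <- sum(vapply(records, n_hours, integer(1)))
  overall <- purrr::map_dfr(vars, function(v) {
    filled <- sum(vapply(records, function(r) sum(!is.na(r[[v]])), double(1)))
    tibble(
      variable = v,
      group = if (v %in% sepsis_vars("vitals")) "vital" else "lab",
      density = filled / pooled_n
    )
  })
  overall$variable <- factor(overall$variable, levels = vars)
  list(overall = overall, per_record = per)
}

#' Read or write a directory of PSV patient records
#'
#' One file per patient, `<patient_id>.psv`. Files are read in lexicographic
#' order of their names.
#'
#' @param dir Directory path.
#' @param hospital_id Hospital identifier attached to every record read.
#' @return `read_psv_dir()`: a list of records; `write_psv_dir()`: the
#'   directory path, invisibly.
#' @export
read_psv_dir <- function(dir, hospital_id = "A") {
  files <- sort(list.files(dir, pattern = "\\.psv$", full.names = TRUE))
  if (length(files) == 0) {
    abort(paste0("no .psv files in ", dir), class = "sepsiskit_io_error")
  }
  lapply(files, read_psv, hospital_id = hospital_id)
}

#' @rdname read_psv_dir
#' @param records List of [patient_record()]s.
#' @export
write_psv_dir <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in records) {
    write_psv(r, file.path(dir, paste0(patient_id(r), ".psv")))
  }
  invisible(dir)
}
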