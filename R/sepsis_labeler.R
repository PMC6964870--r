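#' Default SOFA component scoring table
#'
#' Threshold tables for the six organ-system subscores of the Sequential
#' Organ Failure Assessment (SOFA) score, each graded 0-4. Respiration is
#' scored on PaO2/FiO2 (mm Hg); the ventilation requirement for subscores 3-4
#' is not modeled (any ratio below the threshold scores). Cardiovascular
#' scoring uses MAP plus a binary vasopressor flag in place of dose tiers:
#' MAP < 70 scores 1, any vasopressor support scores 2. Renal scoring uses
#' creatinine only (no urine output).
#'
#' Each component entry is a list with `breaks` (decreasing or increasing
#' cutpoints) and `direction` (`"low"`: lower values are worse; `"high"`:
#' higher values are worse). The table is configurable: pass a modified copy
#' to [sofa_total()].
#'
#' @return Named list of component threshold definitions.
#' @export
default_sofa_table <- function() {
  list(
    # PaO2/FiO2 (mm Hg): >=400 -> 0, <400 -> 1, <300 -> 2, <200 -> 3, <100 -> 4
    respiration   = list(breaks = c(400, 300, 200, 100), direction = "low"),
    # platelets (x10^3/uL): >=150 -> 0, <150 -> 1, <100 -> 2, <50 -> 3, <20 -> 4
    coagulation   = list(breaks = c(150, 100, 50, 20), direction = "low"),
    # bilirubin (mg/dL): <1.2 -> 0, >=1.2 -> 1, >=2.0 -> 2, >=6.0 -> 3, >=12 -> 4
    liver         = list(breaks = c(1.2, 2.0, 6.0, 12.0), direction = "high"),
    # cardiovascular handled specially: MAP < 70 -> 1, vasopressors -> 2
    cardiovascular = list(map_cut = 70),
    # Glasgow Coma Scale: 15 -> 0, 13-14 -> 1, 10-12 -> 2, 6-9 -> 3, <6 -> 4
    cns           = list(breaks = c(15, 13, 10, 6), direction = "low_gcs"),
    # creatinine (mg/dL): <1.2 -> 0, >=1.2 -> 1, >=2.0 -> 2, >=3.5 -> 3, >=5 -> 4
    renal         = list(breaks = c(1.2, 2.0, 3.5, 5.0), direction = "high")
  )
}

score_component <- function(value, spec) {
  if (is.na(value)) return(NA_integer_)
  b <- spec$breaks
  switch(spec$direction,
    low = sum(value < b),
    high = sum(value >= b),
    low_gcs = {
      # GCS cutpoints are inclusive lower bounds of the better bands
      if (value >= 15) 0L
      else if (value >= 13) 1L
      else if (value >= 10) 2L
      else if (value >= 6) 3L
      else 4L
    }
  )
}

#' Hourly SOFA totals from component measurements
#'
#' Computes the per-hour SOFA total (0-24) from hourly component
#' measurements. A component missing at an hour carries forward its last
#' known subscore; a component never observed contributes 0 (the
#' `carry_forward = FALSE` switch instead treats every missing component as
#' normal).
#'
#' @param components A data frame with one row per hour and any subset of the
#'   columns `pao2_fio2`, `platelets`, `bilirubin`, `map`, `vasopressor`
#'   (0/1), `gcs`, `creatinine`. Missing cells are `NA`.
#' @param table A SOFA threshold table, see [default_sofa_table()].
#' @param carry_forward Carry each component's last observed subscore across
#'   missing hours (default `TRUE`).
#' @return Integer vector of hourly SOFA totals.
#' @examples
#' sofa_total(tibble::tibble(platelets = c(200, 90)))  # 0, 2
#' @export
sofa_total <- function(components, table = default_sofa_table(),
                       carry_forward = TRUE) {
  comp <- as_tibble(components)
  n <- nrow(comp)
  if (n == 0) return(integer(0))
  col <- function(nm) if (nm %in% names(comp)) comp[[nm]] else rep(NA_real_, n)

  pf <- col("pao2_fio2"); plt <- col("platelets"); bili <- col("bilirubin")
  map <- col("map"); vaso <- col("vasopressor"); gcs <- col("gcs")
  crea <- col("creatinine")
  if (any(plt < 0, na.rm = TRUE) || any(bili < 0, na.rm = TRUE) ||
      any(crea < 0, na.rm = TRUE) || any(pf < 0, na.rm = TRUE)) {
    abort("negative physiologic values are not valid SOFA inputs",
          class = "sepsiskit_validation_error")
  }

  sub <- matrix(NA_integer_, nrow = n, ncol = 6)
  for (h in seq_len(n)) {
    sub[h, 1] <- score_component(pf[h], table$respiration)
    sub[h, 2] <- score_component(plt[h], table$coagulation)
    sub[h, 3] <- score_component(bili[h], table$liver)
    # cardiovascular: vasopressor support dominates MAP
    sub[h, 4] <- if (!is.na(vaso[h]) && vaso[h] > 0) 2L
      else if (!is.na(map[h])) (if (map[h] < table$cardiovascular$map_cut) 1L else 0L)
      else NA_integer_
    sub[h, 5] <- score_component(gcs[h], table$cns)
    sub[h, 6] <- score_component(crea[h], table$renal)
  }
  if (carry_forward) {
    for (j in 1:6) {
      last <- 0L
      for (h in seq_len(n)) {
        if (is.na(sub[h, j])) sub[h, j] <- last else last <- sub[h, j]
      }
    }
  } else {
    sub[is.na(sub)] <- 0L
  }
  as.integer(rowSums(sub))
}

#' Time of clinical suspicion of infection
#'
#' The suspicion time is the earlier member of the earliest qualifying
#' (IV antibiotic, blood culture) pair. A pair qualifies when either the
#' culture was obtained within 24 hours after the antibiotic start, or the
#' antibiotic was started within 72 hours after the culture; in both cases
#' the antibiotic course must last at least 72 consecutive hours.
#'
#' @param events A data frame of treatment events with columns `event_type`
#'   (`"abx"` or `"culture"`), `start_hour` (may be negative for pre-ICU
#'   events), and `duration_hours` (antibiotic course length; ignored and may
#'   be `NA` for cultures).
#' @param abx_first_window Hours allowed from antibiotic start to culture
#'   (default 24).
#' @param culture_first_window Hours allowed from culture to antibiotic start
#'   (default 72).
#' @param min_abx_duration Minimum consecutive antibiotic duration in hours
#'   (default 72).
#' @return The suspicion hour, or `NA` if no pair qualifies.
#' @examples
#' ev <- tibble::tibble(event_type = c("abx", "culture"),
#'                      start_hour = c(10, 20), duration_hours = c(80, NA))
#' find_t_suspicion(ev)  # 10
#' @export
find_t_suspicion <- function(events, abx_first_window = 24,
                             culture_first_window = 72,
                             min_abx_duration = 72) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0) return(NA_real_)
  if (!all(c("event_type", "start_hour") %in% names(ev))) {
    abort("events need columns event_type, start_hour",
          class = "sepsiskit_schema_error")
  }
  if (!"duration_hours" %in% names(ev)) ev$duration_hours <- NA_real_
  abx <- ev[ev$event_type == "abx", ]
  cul <- ev[ev$event_type == "culture", ]
  abx <- abx[!is.na(abx$duration_hours) &
               abx$duration_hours >= min_abx_duration, ]
  if (nrow(abx) == 0 || nrow(cul) == 0) return(NA_real_)
  best <- Inf
  for (a in abx$start_hour) {
    for (cu in cul$start_hour) {
      qualifies <- (cu >= a && cu - a <= abx_first_window) ||
        (a >= cu && a - cu <= culture_first_window)
      if (qualifies) best <- min(best, min(a, cu))
    }
  }
  if (is.finite(best)) best else NA_real_
}

#' Time of SOFA-defined organ failure
#'
#' The earliest hour `t` at which the SOFA total exceeds its minimum over the
#' trailing 24-hour window (`[t - window, t]`) by at least two points.
#'
#' @param sofa Integer vector of hourly SOFA totals (hour 0 first), or a data
#'   frame with columns `hour` and `sofa`.
#' @param window Lookback window in hours (default 24).
#' @param rise Required increase (default 2).
#' @return The hour of the first qualifying rise, or `NA` if none.
#' @examples
#' find_t_sofa(c(2, 2, 2, 4, 4))  # 3
#' @export
find_t_sofa <- function(sofa, window = 24, rise = 2) {
  if (is.data.frame(sofa)) {
    sofa <- sofa$sofa[order(sofa$hour)]
  }
  n <- length(sofa)
  if (n == 0) return(NA_real_)
  for (t in seq_len(n) - 1L) {
    lo <- max(0L, t - as.integer(window))
    if (sofa[t + 1L] - min(sofa[(lo + 1L):(t + 1L)]) >= rise) {
      return(as.double(t))
    }
  }
  NA_real_
}

#' Sepsis onset time from suspicion and organ-failure times
#'
#' Sepsis onset is the earlier of the suspicion and SOFA times, provided the
#' SOFA time falls no more than 24 hours before and no more than 12 hours
#' after the suspicion time; otherwise the patient is not labeled septic.
#'
#' @param t_suspicion,t_sofa Hours, or `NA` when the respective criterion was
#'   never met.
#' @param before_window,after_window Compatibility window bounds in hours
#'   (defaults 24 before, 12 after suspicion).
#' @return The onset hour, or `NA`.
#' @examples
#' find_t_sepsis(30, 20)  # 20
#' find_t_sepsis(10, 50)  # NA: organ failure too long after suspicion
#' @export
find_t_sepsis <- function(t_suspicion, t_sofa, before_window = 24,
                          after_window = 12) {
  if (is.na(t_suspicion) || is.na(t_sofa)) return(NA_real_)
  if (t_sofa >= t_suspicion - before_window &&
      t_sofa <= t_suspicion + after_window) {
    min(t_suspicion, t_sofa)
  } else {
    NA_real_
  }
}

#' Annotate one patient with the three Sepsis-3 time points
#'
#' @param events Treatment events for one patient, see [find_t_suspicion()].
#' @param sofa Hourly SOFA totals, see [find_t_sofa()].
#' @param patient_id Identifier copied into the annotation row.
#' @param ... Passed on to [find_t_suspicion()] and [find_t_sofa()].
#' @return One-row tibble: `patient_id`, `t_suspicion`, `t_sofa`, `t_sepsis`,
#'   `is_septic`.
#' @export
annotate_patient <- function(events, sofa, patient_id = "unknown", ...) {
  ts <- find_t_suspicion(events)
  tf <- find_t_sofa(sofa)
  tsep <- find_t_sepsis(ts, tf)
  tibble(
    patient_id = as.character(patient_id),
    t_suspicion = ts, t_sofa = tf, t_sepsis = tsep,
    is_septic = !is.na(tsep)
  )
}

#' Annotate a cohort
#'
#' @param events_tbl Long event table with a `patient_id` column plus the
#'   [find_t_suspicion()] columns, covering all patients (patients with no
#'   events may be absent).
#' @param sofa_tbl Long SOFA table with columns `patient_id`, `hour`, `sofa`.
#' @param patient_ids Character vector fixing the output order; defaults to
#'   the union of ids seen in the two tables.
#' @return Annotation tibble, one row per patient.
#' @export
annotate_cohort <- function(events_tbl, sofa_tbl, patient_ids = NULL) {
  events_tbl <- as_tibble(events_tbl)
  sofa_tbl <- as_tibble(sofa_tbl)
  ids <- patient_ids %||%
    sort(union(unique(events_tbl$patient_id), unique(sofa_tbl$patient_id)))
  purrr::map_dfr(ids, function(id) {
    annotate_patient(
      events_tbl[events_tbl$patient_id == id, , drop = FALSE],
      sofa_tbl[sofa_tbl$patient_id == id, , drop = FALSE],
      patient_id = id
    )
  })
}

#' Emit hourly sepsis labels for one record
#'
#' Nonseptic patients receive all-zero labels. Septic patients are labeled 1
#' from `lead` hours before onset onward (clamped at admission), matching the
#' convention that positive labels begin at the earliest optimally-rewarded
#' prediction time.
#'
#' @param hours Record length in hourly windows.
#' @param t_sepsis Onset hour, or `NA` for a nonseptic patient.
#' @param lead Label lead time in hours before onset (default 6).
#' @return Integer 0/1 vector of length `hours`, non-decreasing. When the
#'   onset lies at or beyond the record end (e.g. after truncation) the labels
#'   are all zero and carry attribute `truncated_onset = TRUE`.
#' @examples
#' table(emit_labels(60, t_sepsis = 48))  # 42 zeros then 18 ones
#' @export
emit_labels <- function(hours, t_sepsis, lead = 6) {
  stopifnot(hours >= 1)
  if (is.na(t_sepsis)) return(rep(0L, hours))
  first_pos <- max(0, t_sepsis - lead)
  if (first_pos >= hours) {
    out <- rep(0L, hours)
    attr(out, "truncated_onset") <- TRUE
    warn(sprintf(
      "t_sepsis - lead (%.0f) is at or beyond the record end (%d h); all-zero labels",
      first_pos, hours))
    return(out)
  }
  as.integer(seq_len(hours) - 1L >= first_pos)
}
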