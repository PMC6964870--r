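#' Parameters of the clinical utility score
#'
#' The utility of a single hourly prediction is a piecewise-linear function
#' of time relative to sepsis onset. For septic patients, positive
#' predictions earn a reward that ramps from 0 at `dt_early` hours relative
#' to onset up to `u_tp_max` at `dt_optimal`, then declines to 0 at
#' `dt_late`; positive predictions earlier than `dt_early` incur the constant
#' false-alarm penalty `u_fp`. Negative predictions in septic patients score
#' 0 through `dt_optimal` and then are increasingly penalized, reaching
#' `u_fn_min` at `dt_late`. In nonseptic patients every positive prediction
#' scores `u_fp` and every negative scores `u_tn`. Beyond `dt_late` both
#' choices score 0 in septic patients, so all weight lies on the decision
#' window around onset.
#'
#' The default time points (-12, -6, +3 hours) reward predictions at least
#' 12 hours before and at most 3 hours after onset, with the maximum reward 6
#' hours before onset. The default levels (`u_tp_max = 1`, `u_fp = -0.05`,
#' `u_fn_min = -2`, `u_tn = 0`) are the conventional choices shipped with the
#' public scoring code for this metric; all values are configurable to encode
#' a particular hospital's preferences.
#'
#' @param dt_early,dt_optimal,dt_late Breakpoints in hours relative to onset;
#'   must satisfy `dt_early < dt_optimal < dt_late`.
#' @param u_tp_max Reward apex (>= 0).
#' @param u_fp False-positive penalty (< 0).
#' @param u_fn_min Worst missed-prediction penalty (< 0).
#' @param u_tn True-negative utility (default 0).
#' @return A `utility_params` list.
#' @examples
#' p <- utility_params()
#' prediction_utility(TRUE, 48, 42, 1, p)  # apex reward
#' @export
utility_params <- function(dt_early = -12, dt_optimal = -6, dt_late = 3,
                           u_tp_max = 1, u_fp = -0.05, u_fn_min = -2,
                           u_tn = 0) {
  if (!(dt_early < dt_optimal && dt_optimal < dt_late)) {
    abort("breakpoints must satisfy dt_early < dt_optimal < dt_late",
          class = "sepsiskit_config_error")
  }
  if (!(u_fp < 0 && u_tp_max >= 0 && u_fn_min < 0)) {
    abort("utility levels must satisfy u_fp < 0 <= u_tp_max and u_fn_min < 0",
          class = "sepsiskit_config_error")
  }
  structure(
    list(dt_early = dt_early, dt_optimal = dt_optimal, dt_late = dt_late,
         u_tp_max = u_tp_max, u_fp = u_fp, u_fn_min = u_fn_min, u_tn = u_tn),
    class = "utility_params"
  )
}

#' @export
print.utility_params <- function(x, ...) {
  cat(sprintf(
    "<utility_params: window [%g, %g] h, apex %g at %g h; u_fp=%g, u_fn_min=%g, u_tn=%g>\n",
    x$dt_early, x$dt_late, x$u_tp_max, x$dt_optimal, x$u_fp, x$u_fn_min,
    x$u_tn))
  invisible(x)
}

#' Utility of single hourly predictions
#'
#' Vectorized over `hour` and `prediction`; see [utility_params()] for the
#' piecewise definition.
#'
#' @param is_septic Logical scalar: does this patient ever reach sepsis
#'   onset?
#' @param t_sepsis Onset hour (required when `is_septic`); ignored otherwise.
#' @param hour Hour(s) of the prediction(s), 0-based.
#' @param prediction 0/1 prediction(s).
#' @param params A [utility_params()] object.
#' @return Numeric utility per prediction.
#' @export
prediction_utility <- function(is_septic, t_sepsis, hour, prediction,
                               params = utility_params()) {
  stopifnot(inherits(params, "utility_params"))
  hour <- as.double(hour)
  pos <- as.logical(prediction > 0)
  n <- max(length(hour), length(pos))
  hour <- rep_len(hour, n); pos <- rep_len(pos, n)
  if (!is_septic) {
    return(ifelse(pos, params$u_fp, params$u_tn))
  }
  if (is.na(t_sepsis)) {
    abort("t_sepsis must be supplied for a septic patient",
          class = "sepsiskit_validation_error")
  }
  dt <- hour - t_sepsis
  u <- numeric(n)
  # positive predictions
  ramp_up <- pos & dt >= params$dt_early & dt <= params$dt_optimal
  ramp_dn <- pos & dt > params$dt_optimal & dt <= params$dt_late
  too_early <- pos & dt < params$dt_early
  u[too_early] <- params$u_fp
  u[ramp_up] <- params$u_tp_max *
    (dt[ramp_up] - params$dt_early) / (params$dt_optimal - params$dt_early)
  u[ramp_dn] <- params$u_tp_max *
    (params$dt_late - dt[ramp_dn]) / (params$dt_late - params$dt_optimal)
  # positives after dt_late: late true positives with zero value (u stays 0)
  # negative predictions: 0 through dt_optimal, ramp to u_fn_min at dt_late,
  # 0 after dt_late (all weight lies inside the decision window)
  fn_ramp <- !pos & dt > params$dt_optimal & dt <= params$dt_late
  u[fn_ramp] <- params$u_fn_min *
    (dt[fn_ramp] - params$dt_optimal) / (params$dt_late - params$dt_optimal)
  u
}

check_prediction_coverage <- function(annotations, predictions) {
  annotations <- as_tibble(annotations)
  predictions <- as_tibble(predictions)
  need <- c("patient_id", "hour", "prediction")
  if (!all(need %in% names(predictions))) {
    abort("predictions need columns patient_id, hour, prediction",
          class = "sepsiskit_schema_error")
  }
  if (!all(c("patient_id", "is_septic", "hours") %in% names(annotations))) {
    abort("annotations need columns patient_id, is_septic, t_sepsis, hours",
          class = "sepsiskit_schema_error")
  }
  cov <- predictions |>
    dplyr::count(.data$patient_id, name = "n_pred")
  joined <- dplyr::left_join(annotations, cov, by = "patient_id")
  miss <- is.na(joined$n_pred) | joined$n_pred != joined$hours
  if (any(miss)) {
    abort(paste0("predictions do not cover every hourly window for: ",
                 paste(head(joined$patient_id[miss], 5), collapse = ", ")),
          class = "sepsiskit_coverage_error")
  }
  invisible(TRUE)
}

per_patient_utility <- function(annotations, predictions, params) {
  annotations <- as_tibble(annotations)
  predictions <- as_tibble(predictions)
  purrr::map_dbl(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    p <- predictions[predictions$patient_id == a$patient_id, ]
    sum(prediction_utility(a$is_septic, a$t_sepsis, p$hour, p$prediction,
                           params))
  })
}

#' Total utility of a prediction set over a cohort
#'
#' Sums the per-window utilities over all hourly windows of all patient
#' records. Every window of every record must carry a prediction; partial
#' coverage is an error, never silently defaulted.
#'
#' @param annotations Cohort annotation tibble with columns `patient_id`,
#'   `is_septic`, `t_sepsis`, `hours`.
#' @param predictions Long tibble with columns `patient_id`, `hour` (0-based),
#'   `prediction` (0/1), and optionally `risk`.
#' @param params A [utility_params()].
#' @return Total utility (scalar).
#' @export
total_utility <- function(annotations, predictions,
                          params = utility_params()) {
  check_prediction_coverage(annotations, predictions)
  sum(per_patient_utility(annotations, predictions, params))
}

#' Reference predictors: per-window optimal and all-negative (inaction)
#'
#' The optimal predictor chooses, at every hourly window, whichever of the
#' positive and negative predictions has the higher utility; the inaction
#' predictor outputs a negative prediction everywhere.
#'
#' @inheritParams total_utility
#' @return A prediction tibble (`patient_id`, `hour`, `prediction`).
#' @export
optimal_predictions <- function(annotations, params = utility_params()) {
  annotations <- as_tibble(annotations)
  purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    h <- seq_len(a$hours) - 1L
    up <- prediction_utility(a$is_septic, a$t_sepsis, h, 1L, params)
    un <- prediction_utility(a$is_septic, a$t_sepsis, h, 0L, params)
    tibble(patient_id = a$patient_id, hour = h,
           prediction = as.integer(up > un))
  })
}

#' @rdname optimal_predictions
#' @export
inaction_predictions <- function(annotations) {
  annotations <- as_tibble(annotations)
  purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    tibble(patient_id = annotations$patient_id[i],
           hour = seq_len(annotations$hours[i]) - 1L, prediction = 0L)
  })
}

#' Normalized clinical utility
#'
#' Rescales the total utility so that the optimal predictor scores 1 and the
#' inaction (all-negative) predictor scores 0:
#' `(S_observed - S_inaction) / (S_optimal - S_inaction)`. Undefined on
#' cohorts without septic patients, where optimal and inaction coincide.
#'
#' @inheritParams total_utility
#' @return Normalized utility (scalar, at most 1; negative when the
#'   predictions do worse than inaction).
#' @export
normalized_utility <- function(annotations, predictions,
                               params = utility_params()) {
  s_obs <- total_utility(annotations, predictions, params)
  s_opt <- total_utility(annotations, optimal_predictions(annotations, params),
                         params)
  s_in <- total_utility(annotations, inaction_predictions(annotations), params)
  if (abs(s_opt - s_in) < .Machine$double.eps * 100) {
    abort("normalized utility undefined: optimal equals inaction (no septic patients?)",
          class = "sepsiskit_undefined_score_error")
  }
  (s_obs - s_in) / (s_opt - s_in)
}

#' Recover cohort annotations from labeled records
#'
#' Reconstructs the scoring inputs from records that carry `SepsisLabel`
#' columns: a patient is septic when any label is positive, and the onset is
#' taken as the first positive hour plus the label lead (labels start `lead`
#' hours before onset, see [emit_labels()]).
#'
#' @param records List of labeled [patient_record()]s.
#' @param lead Label lead in hours (default 6).
#' @return Annotation tibble (`patient_id`, `hospital_id`, `hours`,
#'   `t_sepsis`, `is_septic`).
#' @export
annotations_from_labels <- function(records, lead = 6) {
  purrr::map_dfr(records, function(r) {
    lab <- record_labels(r)
    if (is.null(lab)) {
      abort(paste0("record ", patient_id(r), " carries no SepsisLabel column"),
            class = "sepsiskit_schema_error")
    }
    septic <- any(lab == 1L)
    tibble(
      patient_id = patient_id(r), hospital_id = hospital_id(r),
      hours = length(lab),
      t_sepsis = if (septic) which.max(lab) - 1 + lead else NA_real_,
      is_septic = septic
    )
  })
}

#' Pooled per-window classification metrics
#'
#' Complements the utility score with threshold-free (AUROC by the mid-rank
#' Mann-Whitney statistic, AUPRC by precision-recall step integration) and
#' thresholded (accuracy, F-measure) metrics over all hourly windows pooled
#' across the cohort.
#'
#' @param labels 0/1 per-window labels, pooled.
#' @param risks Real-valued per-window risks (for AUROC/AUPRC); may be `NULL`
#'   when only thresholded metrics are wanted.
#' @param predictions 0/1 per-window predictions (for accuracy/F-measure);
#'   may be `NULL`.
#' @return One-row tibble: `auroc`, `auprc`, `accuracy`, `f_measure` (`NA`
#'   where the needed input is absent).
#' @export
binary_metrics <- function(labels, risks = NULL, predictions = NULL) {
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2 && !is.null(risks)) {
    abort("AUROC undefined: labels contain a single class",
          class = "sepsiskit_undefined_score_error")
  }
  auroc <- auprc <- accuracy <- f_measure <- NA_real_
  if (!is.null(risks)) {
    stopifnot(length(risks) == length(y), all(is.finite(risks)))
    auroc <- auroc_rank(y, risks)
    auprc <- auprc_step(y, risks)
  }
  if (!is.null(predictions)) {
    p <- as.integer(predictions)
    stopifnot(length(p) == length(y))
    tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
    fn <- sum(p == 0 & y == 1)
    accuracy <- mean(p == y)
    f_measure <- if (2 * tp + fp + fn == 0) NA_real_ else
      2 * tp / (2 * tp + fp + fn)
  }
  tibble(auroc = auroc, auprc = auprc, accuracy = accuracy,
         f_measure = f_measure)
}

# Mann-Whitney AUROC with mid-rank tie correction
auroc_rank <- function(y, s) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(s)  # mid-ranks on ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# AUPRC by step integration of the tie-grouped precision-recall curve
auprc_step <- function(y, s) {
  n1 <- sum(y == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  # cumulative counts at the end of each tie group of descending scores
  ends <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[ends]
  n_pred <- ends
  recall <- tp / n1
  precision <- tp / n_pred
  sum(diff(c(0, recall)) * precision)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties); used to compare
#' algorithm rankings across evaluation metrics and hospital systems.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (var(rank(x)) == 0 || var(rank(y)) == 0) {
    abort("Spearman correlation undefined: zero rank variance",
          class = "sepsiskit_undefined_score_error")
  }
  cor(x, y, method = "spearman")
}

#' Full score report for a prediction set
#'
#' @inheritParams total_utility
#' @param labels Long tibble of true per-window labels (`patient_id`, `hour`,
#'   `label`); when `NULL`, labels are reconstructed from the annotations via
#'   [emit_labels()].
#' @param lead Label lead used when reconstructing labels (hours).
#' @return One-row tibble: `total`, `normalized`, `optimal`, `inaction`,
#'   `auroc`, `auprc`, `accuracy`, `f_measure`, `n_patients`, `n_windows`.
#' @export
score_report <- function(annotations, predictions,
                         params = utility_params(), labels = NULL, lead = 6) {
  annotations <- as_tibble(annotations)
  predictions <- as_tibble(predictions)
  check_prediction_coverage(annotations, predictions)
  s_obs <- total_utility(annotations, predictions, params)
  s_opt <- total_utility(annotations,
                         optimal_predictions(annotations, params), params)
  s_in <- total_utility(annotations, inaction_predictions(annotations),
                        params)
  normalized <- if (abs(s_opt - s_in) < .Machine$double.eps * 100) NA_real_
    else (s_obs - s_in) / (s_opt - s_in)

  if (is.null(labels)) {
    labels <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
      a <- annotations[i, ]
      lab <- suppressWarnings(
        emit_labels(a$hours, if (a$is_septic) a$t_sepsis else NA_real_, lead))
      tibble(patient_id = a$patient_id, hour = seq_len(a$hours) - 1L,
             label = as.integer(lab))
    })
  }
  joined <- dplyr::inner_join(labels, predictions,
                              by = c("patient_id", "hour"))
  risks <- if ("risk" %in% names(joined)) joined$risk else NULL
  metr <- if (length(unique(joined$label)) < 2) {
    tibble(auroc = NA_real_, auprc = NA_real_,
           accuracy = mean(joined$prediction == joined$label),
           f_measure = NA_real_)
  } else {
    binary_metrics(joined$label, risks, joined$prediction)
  }
  dplyr::bind_cols(
    tibble(total = s_obs, normalized = normalized, optimal = s_opt,
           inaction = s_in),
    metr,
    tibble(n_patients = nrow(annotations), n_windows = nrow(joined))
  )
}
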