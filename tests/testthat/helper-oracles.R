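# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each quantity from its definition by direct
# enumeration, sharing no code with the package internals.

# median by explicit sort (even count -> mean of the middle pair)
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# earliest t with sofa[t] - sofa[s] >= rise for some s in [t - window, t]
oracle_t_sofa <- function(sofa, window = 24, rise = 2) {
  n <- length(sofa)
  for (t in seq_len(n) - 1L) {
    for (s in seq_len(n) - 1L) {
      if (s <= t && s >= t - window && sofa[t + 1] - sofa[s + 1] >= rise) {
        return(as.double(t))
      }
    }
  }
  NA_real_
}

# minimum over all qualifying (abx, culture) pairs, by full enumeration
oracle_t_suspicion <- function(events, abx_window = 24, cul_window = 72,
                               min_dur = 72) {
  abx <- events[events$event_type == "abx", ]
  cul <- events[events$event_type == "culture", ]
  best <- Inf
  for (i in seq_len(nrow(abx))) {
    if (is.na(abx$duration_hours[i]) || abx$duration_hours[i] < min_dur) next
    for (j in seq_len(nrow(cul))) {
      a <- abx$start_hour[i]; cu <- cul$start_hour[j]
      ok <- (cu >= a && cu - a <= abx_window) ||
        (a >= cu && a - cu <= cul_window)
      if (ok) best <- min(best, min(a, cu))
    }
  }
  if (is.finite(best)) best else NA_real_
}

# single-prediction utility written as an explicit if-chain over the pieces
oracle_prediction_utility <- function(is_septic, t_sepsis, hour, pred,
                                      p = utility_params()) {
  if (!is_septic) {
    if (pred == 1) return(p$u_fp) else return(p$u_tn)
  }
  dt <- hour - t_sepsis
  if (pred == 1) {
    if (dt < p$dt_early) return(p$u_fp)
    if (dt <= p$dt_optimal) {
      return(p$u_tp_max * (dt - p$dt_early) / (p$dt_optimal - p$dt_early))
    }
    if (dt <= p$dt_late) {
      return(p$u_tp_max * (p$dt_late - dt) / (p$dt_late - p$dt_optimal))
    }
    return(0)
  }
  if (dt <= p$dt_optimal) return(0)
  if (dt <= p$dt_late) {
    return(p$u_fn_min * (dt - p$dt_optimal) / (p$dt_late - p$dt_optimal))
  }
  0
}

# one-line brute-force cohort sum
oracle_total_utility <- function(annotations, predictions,
                                 p = utility_params()) {
  tot <- 0
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    pp <- predictions[predictions$patient_id == a$patient_id, ]
    for (j in seq_len(nrow(pp))) {
      tot <- tot + oracle_prediction_utility(a$is_septic, a$t_sepsis,
                                             pp$hour[j], pp$prediction[j], p)
    }
  }
  tot
}

# AUROC as the concordant-pair fraction (ties count half)
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  num <- 0
  for (a in pos) for (b in neg) {
    num <- num + (a > b) + 0.5 * (a == b)
  }
  num / (length(pos) * length(neg))
}

# small deterministic annotation table for utility tests
toy_annotations <- function() {
  tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e"),
    hours = c(30L, 40L, 25L, 50L, 60L),
    t_sepsis = c(20, NA, NA, 30, NA),
    is_septic = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

random_predictions <- function(annotations) {
  purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    tibble::tibble(
      patient_id = annotations$patient_id[i],
      hour = seq_len(annotations$hours[i]) - 1L,
      prediction = sample(0:1, annotations$hours[i], replace = TRUE)
    )
  })
}
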