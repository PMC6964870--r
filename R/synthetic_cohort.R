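#' Default marginal distributions for the 34 clinical variables
#'
#' Per-variable truncated-normal parameters (mean, SD, plausible clamp range)
#' used by the synthetic generator. The values are conventional adult-ICU
#' magnitudes in the schema's units; they give the generator first-order
#' realism (plausible locations and spreads) and are fully overridable via
#' [cohort_config()].
#'
#' @return Tibble with columns `variable`, `mean`, `sd`, `lo`, `hi`.
#' @export
default_variable_marginals <- function() {
  tibble::tribble(
    ~variable,          ~mean, ~sd,  ~lo,   ~hi,
    "HR",                85,   17,   30,    200,
    "O2Sat",             97,   2.5,  60,    100,
    "Temp",              37,   0.7,  33,    42,
    "SBP",               120,  20,   60,    230,
    "MAP",               82,   14,   40,    180,
    "DBP",               64,   12,   30,    150,
    "Resp",              18,   5,    4,     50,
    "EtCO2",             33,   6,    15,    60,
    "BaseExcess",        0,    4,   -20,    20,
    "HCO3",              24,   4,    5,     45,
    "FiO2",              0.5,  0.15, 0.21,  1,
    "pH",                7.38, 0.06, 6.9,   7.7,
    "PaCO2",             40,   8,    15,    90,
    "SaO2",              96,   3,    60,    100,
    "AST",               60,   40,   5,     500,
    "BUN",               22,   14,   2,     150,
    "Alkalinephos",      90,   40,   10,    500,
    "Calcium",           8.5,  0.7,  5,     12,
    "Chloride",          104,  5,    80,    130,
    "Creatinine",        1.2,  0.8,  0.2,   10,
    "Bilirubin_direct",  0.4,  0.4,  0,     10,
    "Glucose",           130,  35,   40,    500,
    "Lactate",           1.8,  1.0,  0.3,   15,
    "Magnesium",         2.0,  0.3,  1,     4,
    "Phosphate",         3.5,  1.0,  1,     10,
    "Potassium",         4.1,  0.5,  2,     7,
    "Bilirubin_total",   0.9,  0.6,  0.1,   15,
    "TroponinI",         0.3,  0.5,  0,     20,
    "Hct",               31,   5,    15,    55,
    "Hgb",               10.5, 1.7,  5,     18,
    "PTT",               35,   10,   15,    150,
    "WBC",               11,   5,    0.5,   50,
    "Fibrinogen",        300,  100,  50,    800,
    "Platelets",         200,  80,   10,    800
  )
}

#' Default per-variable measurement densities
#'
#' Vitals are measured roughly hourly (density near 0.9, except end-tidal CO2,
#' which is recorded only in ventilated patients), laboratory values roughly
#' daily (density near 1/24). Lab measurements are additionally clustered at
#' one per-patient daily draw hour, mimicking the banded missingness of real
#' hourly EHR extracts.
#'
#' @return Named numeric vector over the 34 clinical variables.
#' @export
default_densities <- function() {
  d <- c(
    setNames(rep(0.9, 8), sepsis_vars("vitals")),
    setNames(rep(1 / 24, 26), sepsis_vars("labs"))
  )
  d["EtCO2"] <- 0.15
  # blood-gas panel slightly rarer than daily; chemistries close to daily
  d[c("BaseExcess", "FiO2", "pH", "PaCO2", "SaO2")] <- 0.7 / 24
  d[c("Bilirubin_direct", "TroponinI", "Fibrinogen")] <- 0.4 / 24
  d
}

#' Default pre-onset physiology drift
#'
#' Total change, in each variable's units, applied linearly over the 12 hours
#' preceding a planted sepsis onset and held afterwards: tachycardia, fever,
#' hypotension, tachypnea, rising lactate/creatinine/WBC, falling
#' oxygenation — the canonical early-sepsis signature. An artifact convention
#' that makes baseline-model performance nontrivial, not a calibrated
#' physiologic claim.
#'
#' @return Named numeric vector of drift magnitudes.
#' @export
default_sepsis_effect <- function() {
  c(HR = 15, Temp = 1.2, MAP = -12, SBP = -15, Resp = 6, O2Sat = -4,
    Lactate = 1.8, WBC = 5, Creatinine = 0.8)
}

#' Configuration for the synthetic multi-hospital cohort generator
#'
#' @param n_patients Cohort size.
#' @param prevalence Fraction of patients with a planted sepsis onset.
#' @param hospital_id Hospital system label stamped on every record.
#' @param stay_meanlog,stay_sdlog Log-normal ICU stay-length parameters
#'   (hours); draws are clamped to `[min_stay, max_stay]`.
#' @param min_stay,max_stay Stay bounds in hours; defaults 8 and 336 so every
#'   generated record passes the cohort filters unchanged.
#' @param densities Named per-variable measurement-density targets in (0, 1];
#'   see [default_densities()].
#' @param marginals Per-variable truncated-normal parameters; see
#'   [default_variable_marginals()].
#' @param sepsis_effect Named drift magnitudes over the 12 h before onset;
#'   see [default_sepsis_effect()].
#' @param shift_loc,shift_scale Named per-variable location offsets (units)
#'   and scale multipliers expressing this hospital system's distribution
#'   shift relative to the defaults.
#' @param lead Label lead in hours (see [emit_labels()]).
#' @param seed Integer seed fixing all generator randomness.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 100, prevalence = 0.1,
                          hospital_id = "A",
                          stay_meanlog = log(38), stay_sdlog = 0.6,
                          min_stay = 8L, max_stay = 336L,
                          densities = default_densities(),
                          marginals = default_variable_marginals(),
                          sepsis_effect = default_sepsis_effect(),
                          shift_loc = NULL, shift_scale = NULL,
                          lead = 6, seed = 1L) {
  if (prevalence < 0 || prevalence > 1) {
    abort("prevalence must lie in [0, 1]", class = "sepsiskit_config_error")
  }
  if (any(densities <= 0 | densities > 1)) {
    abort("densities must lie in (0, 1]", class = "sepsiskit_config_error")
  }
  if (min_stay < 8) {
    abort("min_stay below 8 h conflicts with the cohort inclusion rule",
          class = "sepsiskit_config_error")
  }
  if (prevalence > 0 && max_stay < 5) {
    abort("infeasible config: septic onsets need stays of at least 5 h",
          class = "sepsiskit_config_error")
  }
  structure(
    list(n_patients = n_patients, prevalence = prevalence,
         hospital_id = hospital_id, stay_meanlog = stay_meanlog,
         stay_sdlog = stay_sdlog, min_stay = as.integer(min_stay),
         max_stay = as.integer(max_stay), densities = densities,
         marginals = marginals, sepsis_effect = sepsis_effect,
         shift_loc = shift_loc, shift_scale = shift_scale,
         lead = lead, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

with_preserved_seed <- function(code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Generate a synthetic multi-hospital ICU cohort
#'
#' Draws `n_patients` hourly records with the structure of real shared sepsis
#' datasets: near-hourly vitals, roughly daily labs clustered at a per-patient
#' draw hour, constant demographics, planted sepsis onsets with a 12-hour
#' pre-onset physiologic drift, and treatment-event/SOFA ground truth built so
#' that the Sepsis-3 labeler recovers each planted onset exactly. All records
#' satisfy the cohort inclusion rules by construction. The generator is fully
#' determined by `config$seed` and leaves the caller's RNG state untouched.
#'
#' @param config A [cohort_config()].
#' @return A list:
#'   * `records`: list of [patient_record()]s with `SepsisLabel` columns,
#'   * `annotations`: tibble `patient_id`, `hospital_id`, `hours`,
#'     `t_suspicion`, `t_sofa`, `t_sepsis`, `is_septic`,
#'   * `events`: long treatment-event tibble (`patient_id`, `event_type`,
#'     `start_hour`, `duration_hours`),
#'   * `sofa`: long hourly SOFA tibble (`patient_id`, `hour`, `sofa`),
#'   * `config`: the input configuration.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' coh$annotations
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_preserved_seed({
    set.seed(config$seed)
    generate_cohort_impl(config)
  })
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  marg <- config$marginals
  dens <- config$densities
  ids <- sprintf("p%05d", seq_len(n))
  septic <- runif(n) < config$prevalence
  hours <- pmin(pmax(round(exp(rnorm(n, config$stay_meanlog,
                                     config$stay_sdlog))),
                     config$min_stay), config$max_stay)

  records <- vector("list", n)
  ann <- vector("list", n)
  ev <- vector("list", n)
  sofa_l <- vector("list", n)

  for (i in seq_len(n)) {
    h <- hours[i]
    t_sep <- NA_real_
    if (septic[i]) {
      # onset at least 4 h after admission (inclusion rule) and inside stay
      t_sep <- as.double(sample(4:(h - 1), 1))
    }
    gt <- plant_ground_truth(ids[i], h, t_sep)
    vals <- draw_record_values(h, t_sep, config)
    labels <- emit_labels(h, t_sep, config$lead)
    records[[i]] <- patient_record(vals, labels = labels,
                                   patient_id = ids[i],
                                   hospital_id = config$hospital_id)
    ann[[i]] <- tibble(
      patient_id = ids[i], hospital_id = config$hospital_id,
      hours = as.integer(h), t_suspicion = gt$t_suspicion,
      t_sofa = gt$t_sofa, t_sepsis = t_sep, is_septic = septic[i]
    )
    ev[[i]] <- gt$events
    sofa_l[[i]] <- tibble(patient_id = ids[i], hour = seq_len(h) - 1L,
                          sofa = gt$sofa)
  }
  list(
    records = records,
    annotations = dplyr::bind_rows(ann),
    events = dplyr::bind_rows(ev),
    sofa = dplyr::bind_rows(sofa_l),
    config = config
  )
}

# Build events and a SOFA trajectory that the labeler maps back to t_sepsis.
plant_ground_truth <- function(id, hours, t_sepsis) {
  base_sofa <- sample(0:3, 1)
  sofa <- rep(base_sofa, hours)
  events <- tibble(patient_id = character(), event_type = character(),
                   start_hour = double(), duration_hours = double())
  t_susp <- NA_real_
  t_sofa <- NA_real_
  if (!is.na(t_sepsis)) {
    if (runif(1) < 0.5) {
      # organ failure first: t_sofa = onset, suspicion within the next 24 h
      t_sofa <- t_sepsis
      t_susp <- t_sepsis + sample(0:24, 1)
    } else {
      # suspicion first: SOFA rise within the following 12 h (inside stay)
      t_susp <- t_sepsis
      t_sofa <- t_sepsis + sample(0:min(12, hours - 1 - t_sepsis), 1)
    }
    if (t_sofa <= hours - 1) {
      sofa[(t_sofa + 1):hours] <- base_sofa + 2L
    }
    abx_delay <- sample(0:48, 1)
    events <- tibble(
      patient_id = id,
      event_type = c("culture", "abx"),
      start_hour = c(t_susp, t_susp + abx_delay),
      duration_hours = c(NA_real_, 72 + round(runif(1, 0, 96)))
    )
  } else {
    # occasional non-qualifying treatment activity in nonseptic patients
    if (runif(1) < 0.3) {
      t0 <- round(runif(1, 0, max(1, hours - 1)))
      events <- tibble(
        patient_id = id, event_type = c("culture", "abx"),
        start_hour = c(t0, t0 + 2),
        duration_hours = c(NA_real_, round(runif(1, 6, 48)))  # < 72 h course
      )
    }
    # mild wiggle that never constitutes a 2-point rise
    wiggle <- as.integer(runif(hours) < 0.1)
    sofa <- pmin(base_sofa + wiggle, base_sofa + 1L)
  }
  list(events = events, sofa = as.integer(sofa),
       t_suspicion = t_susp, t_sofa = t_sofa)
}

draw_record_values <- function(hours, t_sepsis, config) {
  marg <- config$marginals
  dens <- config$densities
  vals <- empty_record_values(hours)
  t <- seq_len(hours) - 1L
  drift_frac <- if (is.na(t_sepsis)) rep(0, hours) else {
    pmin(pmax((t - (t_sepsis - 12)) / 12, 0), 1)
  }
  draw_offset <- sample(0:23, 1)  # per-patient daily lab draw hour

  for (v in sepsis_vars("clinical")) {
    m <- marg[marg$variable == v, ]
    mu <- m$mean; s <- m$sd
    if (!is.null(config$shift_loc) && v %in% names(config$shift_loc)) {
      mu <- mu + config$shift_loc[[v]]
    }
    if (!is.null(config$shift_scale) && v %in% names(config$shift_scale)) {
      s <- s * config$shift_scale[[v]]
    }
    patient_intercept <- rnorm(1, 0, 0.5 * s)
    x <- mu + patient_intercept + rnorm(hours, 0, s)
    if (v %in% names(config$sepsis_effect)) {
      x <- x + drift_frac * config$sepsis_effect[[v]]
    }
    x <- pmin(pmax(x, m$lo), m$hi)
    p <- dens[[v]]
    observed <- if (v %in% sepsis_vars("vitals")) {
      runif(hours) < p
    } else {
      # labs cluster at the daily draw hour; per-draw inclusion keeps the
      # overall per-cell density at the target p (= p * 24 per draw hour)
      (t %% 24 == draw_offset) & (runif(hours) < min(1, p * 24))
    }
    x[!observed] <- NA_real_
    vals[[v]] <- x
  }

  vals$Age <- rep(round(rtruncnorm1(1, 62, 16, 18, 100)), hours)
  vals$Gender <- rep(rbinom(1, 1, 0.55), hours)
  u1 <- rbinom(1, 1, 0.5)
  vals$Unit1 <- rep(u1, hours)
  vals$Unit2 <- rep(1 - u1, hours)
  vals$HospAdmTime <- rep(-round(runif(1, 0, 120), 2), hours)
  vals$ICULOS <- as.double(seq_len(hours))
  vals
}

#' Jensen-Shannon divergence between two univariate samples
#'
#' Bins both samples on a shared grid (Freedman-Diaconis width on the pooled
#' sample, at least `min_bins` bins) and computes
#' `JSD(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q) / 2` and base-2
#' entropies, so the result lies in `[0, 1]`: 0 for identical distributions,
#' 1 for disjoint supports.
#'
#' @param sample_a,sample_b Non-empty numeric vectors (`NA`s dropped).
#' @param bins Either `NULL` (automatic binning), an integer bin count, or a
#'   vector of break points spanning both samples.
#' @param min_bins Lower bound on the automatic bin count (default 10).
#' @return Divergence in `[0, 1]`.
#' @examples
#' jensen_shannon_divergence(rnorm(500), rnorm(500) + 5) # near 1
#' @export
jensen_shannon_divergence <- function(sample_a, sample_b, bins = NULL,
                                      min_bins = 10) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty", class = "sepsiskit_validation_error")
  }
  pooled <- c(a, b)
  if (is.null(bins) || length(bins) == 1) {
    rng <- range(pooled)
    if (rng[1] == rng[2]) return(0)
    if (is.null(bins)) {
      bw <- 2 * IQR(pooled) / length(pooled)^(1 / 3)  # Freedman-Diaconis
      nb <- if (bw <= 0) min_bins else
        max(min_bins, ceiling(diff(rng) / bw))
    } else {
      nb <- max(2, as.integer(bins))
    }
    breaks <- seq(rng[1], rng[2], length.out = nb + 1)
  } else {
    breaks <- bins
  }
  breaks[1] <- breaks[1] - 1e-9
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  p <- tabulate(cut(a, breaks, labels = FALSE), nbins = length(breaks) - 1)
  q <- tabulate(cut(b, breaks, labels = FALSE), nbins = length(breaks) - 1)
  jsd_discrete(p / sum(p), q / sum(q))
}

# JSD of two discrete distributions on a shared support, base-2 entropy
jsd_discrete <- function(p, q) {
  m <- (p + q) / 2
  h <- function(w) {
    w <- w[w > 0]
    -sum(w * log2(w))
  }
  max(0, min(1, h(m) - (h(p) + h(q)) / 2))
}

#' Per-variable distribution shift between two cohorts
#'
#' Pools the non-missing hourly values of each clinical variable in each
#' cohort and reports their Jensen-Shannon divergence, quantifying the
#' distribution shift between hospital systems. Symmetric in its arguments.
#'
#' @param cohort_a,cohort_b Lists of [patient_record()]s sharing the schema.
#' @param bins Binning rule passed to [jensen_shannon_divergence()].
#' @return Tibble with `variable`, `group` (vital/lab), `jsd`, and `flagged`
#'   (`TRUE` when a variable has no observed values in one cohort and is left
#'   unscored).
#' @export
shift_report <- function(cohort_a, cohort_b, bins = NULL) {
  vars <- sepsis_vars("clinical")
  pool <- function(cohort, v) {
    unlist(lapply(cohort, function(r) r[[v]][!is.na(r[[v]])]),
           use.names = FALSE)
  }
  purrr::map_dfr(vars, function(v) {
    a <- pool(cohort_a, v)
    b <- pool(cohort_b, v)
    if (length(a) == 0 || length(b) == 0) {
      tibble(variable = v,
             group = if (v %in% sepsis_vars("vitals")) "vital" else "lab",
             jsd = NA_real_, flagged = TRUE)
    } else {
      tibble(variable = v,
             group = if (v %in% sepsis_vars("vitals")) "vital" else "lab",
             jsd = jensen_shannon_divergence(a, b, bins = bins),
             flagged = FALSE)
    }
  })
}
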