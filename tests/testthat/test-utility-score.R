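test_that("the piecewise utility hits its endpoints and midpoints", {
  p <- utility_params()
  ts <- 48
  # positive predictions in a septic patient
  expect_equal(prediction_utility(TRUE, ts, ts - 12, 1, p), 0)    # ramp start
  expect_equal(prediction_utility(TRUE, ts, ts - 9, 1, p), 0.5)   # midpoint
  expect_equal(prediction_utility(TRUE, ts, ts - 6, 1, p), 1)     # apex
  expect_equal(prediction_utility(TRUE, ts, ts - 1.5, 1, p), 0.5) # decline mid
  expect_equal(prediction_utility(TRUE, ts, ts + 3, 1, p), 0)     # late end
  expect_equal(prediction_utility(TRUE, ts, ts - 13, 1, p), -0.05) # too early
  # negative predictions in a septic patient
  expect_equal(prediction_utility(TRUE, ts, ts - 6, 0, p), 0)
  expect_equal(prediction_utility(TRUE, ts, ts - 1.5, 0, p), -1)  # midpoint
  expect_equal(prediction_utility(TRUE, ts, ts + 3, 0, p), -2)    # worst miss
  # nonseptic patients
  expect_equal(prediction_utility(FALSE, NA, 10, 0, p), 0)
  expect_equal(prediction_utility(FALSE, NA, 10, 1, p), -0.05)
})

test_that("utility pieces match the closed-form line equations everywhere", {
  p <- utility_params()
  ts <- 100
  for (h in seq(80, 110, by = 0.5)) {
    expect_equal(prediction_utility(TRUE, ts, h, 1, p),
                 oracle_prediction_utility(TRUE, ts, h, 1, p))
    expect_equal(prediction_utility(TRUE, ts, h, 0, p),
                 oracle_prediction_utility(TRUE, ts, h, 0, p))
  }
})

test_that("the ramp-start discontinuity for too-early positives is as designed", {
  p <- utility_params()
  eps <- 1e-9
  expect_equal(prediction_utility(TRUE, 48, 36, 1, p), 0)
  expect_equal(prediction_utility(TRUE, 48, 36 - eps, 1, p), p$u_fp)
  # the other junctions are continuous
  expect_equal(prediction_utility(TRUE, 48, 42 - eps, 1, p),
               prediction_utility(TRUE, 48, 42, 1, p), tolerance = 1e-6)
  expect_equal(prediction_utility(TRUE, 48, 42 + eps, 0, p),
               prediction_utility(TRUE, 48, 42, 0, p), tolerance = 1e-6)
})

test_that("invalid parameter orderings are rejected", {
  expect_error(utility_params(dt_early = -3, dt_optimal = -6),
               class = "sepsiskit_config_error")
  expect_error(utility_params(u_fp = 0.1), class = "sepsiskit_config_error")
})

test_that("total utility sums per-window scores and is additive over patients", {
  p <- utility_params()
  one <- tibble::tibble(patient_id = "x", hours = 10L, t_sepsis = NA_real_,
                        is_septic = FALSE)
  all_neg <- tibble::tibble(patient_id = "x", hour = 0:9, prediction = 0L)
  all_pos <- dplyr::mutate(all_neg, prediction = 1L)
  expect_equal(total_utility(one, all_neg, p), 0)
  expect_equal(total_utility(one, all_pos, p), 10 * p$u_fp)

  ann <- toy_annotations()
  set.seed(41)
  preds <- random_predictions(ann)
  per_patient <- vapply(ann$patient_id, function(id) {
    total_utility(ann[ann$patient_id == id, ],
                  preds[preds$patient_id == id, ], p)
  }, double(1))
  expect_equal(total_utility(ann, preds, p), sum(per_patient))
})

test_that("total utility equals the brute-force sum and ignores patient order", {
  p <- utility_params()
  ann <- toy_annotations()
  set.seed(42)
  for (i in 1:10) {
    preds <- random_predictions(ann)
    expect_equal(total_utility(ann, preds, p), oracle_total_utility(ann, preds, p))
    shuffled <- ann[sample(nrow(ann)), ]
    expect_equal(total_utility(shuffled, preds, p),
                 total_utility(ann, preds, p))
  }
})

test_that("missing per-window predictions are a coverage error", {
  ann <- toy_annotations()
  preds <- random_predictions(ann)
  expect_error(total_utility(ann, preds[-1, ]),
               class = "sepsiskit_coverage_error")
  expect_error(total_utility(ann, preds[preds$patient_id != "a", ]),
               class = "sepsiskit_coverage_error")
})

test_that("normalization anchors hold on random cohorts", {
  p <- utility_params()
  set.seed(43)
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(n_patients = 25,
                                         prevalence = 0.3, seed = seed))
    ann <- coh$annotations
    if (!any(ann$is_septic)) next
    expect_equal(normalized_utility(ann, optimal_predictions(ann, p), p), 1,
                 tolerance = 1e-12)
    expect_equal(normalized_utility(ann, inaction_predictions(ann), p), 0,
                 tolerance = 1e-12)
  }
})

test_that("normalized utility is undefined without septic patients", {
  ann <- tibble::tibble(patient_id = c("a", "b"), hours = c(10L, 12L),
                        t_sepsis = c(NA_real_, NA_real_),
                        is_septic = c(FALSE, FALSE))
  expect_error(normalized_utility(ann, inaction_predictions(ann)),
               class = "sepsiskit_undefined_score_error")
})

test_that("all-positive predictions on a heavily nonseptic cohort score below 0", {
  # one short septic stay against four long nonseptic stays: the accumulated
  # false-alarm penalty outweighs the single patient's early-detection reward
  ann <- tibble::tibble(
    patient_id = c("s", "n1", "n2", "n3", "n4"),
    hours = c(12L, 300L, 300L, 300L, 300L),
    t_sepsis = c(8, NA, NA, NA, NA),
    is_septic = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  all_pos <- dplyr::mutate(inaction_predictions(ann), prediction = 1L)
  val <- normalized_utility(ann, all_pos)
  expect_lt(val, 0)
  # cross-check the three sums by direct summation
  p <- utility_params()
  s_obs <- oracle_total_utility(ann, all_pos, p)
  s_in <- oracle_total_utility(ann, inaction_predictions(ann), p)
  opt <- optimal_predictions(ann, p)
  s_opt <- oracle_total_utility(ann, opt, p)
  expect_equal(val, (s_obs - s_in) / (s_opt - s_in))
})

test_that("flipping any window to its utility-maximizing choice never lowers the total", {
  p <- utility_params()
  ann <- toy_annotations()
  set.seed(44)
  preds <- random_predictions(ann)
  base <- total_utility(ann, preds, p)
  opt <- optimal_predictions(ann, p)
  key <- paste(opt$patient_id, opt$hour)
  for (j in sample(nrow(preds), 40)) {
    flipped <- preds
    best <- opt$prediction[match(paste(preds$patient_id[j], preds$hour[j]),
                                 key)]
    flipped$prediction[j] <- best
    expect_gte(total_utility(ann, flipped, p), base - 1e-12)
  }
})

test_that("AUROC uses mid-rank tie correction and matches brute force", {
  expect_equal(binary_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auroc, 1)
  expect_equal(binary_metrics(c(0, 1, 0, 1), c(0.5, 0.5, 0.5, 0.5))$auroc, 0.5)
  expect_equal(binary_metrics(c(0, 0, 1, 1), c(0.1, 0.8, 0.4, 0.9))$auroc,
               0.75)
  set.seed(45)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n, 0, 1), 2))  # coarse grid forces ties
    expect_equal(binary_metrics(y, s)$auroc, oracle_auroc(y, s))
  }
  expect_error(binary_metrics(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               class = "sepsiskit_undefined_score_error")
})

test_that("AUROC and AUPRC agree with the pROC reference on a random case", {
  set.seed(46)
  y <- rbinom(300, 1, 0.3)
  s <- rnorm(300) + y
  m <- binary_metrics(y, s)
  ref <- suppressMessages(as.numeric(pROC::auc(y, s)))
  expect_equal(m$auroc, ref, tolerance = 1e-12)
  # AUPRC sanity: perfect separation -> 1; random scores near prevalence
  expect_equal(binary_metrics(c(0, 0, 1), c(1, 2, 3))$auprc, 1)
  expect_gt(m$auprc, mean(y))
})

test_that("thresholded metrics count errors correctly", {
  m <- binary_metrics(c(0, 0, 1, 1), risks = NULL,
                      predictions = c(0, 1, 1, 1))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f_measure, 2 * 2 / (2 * 2 + 1 + 0))
})

test_that("Spearman correlation is the mid-rank Pearson correlation", {
  x <- c(3, 1, 4, 15, 9, 2)
  expect_equal(spearman_rho(x, exp(x)), 1)            # monotone transform
  expect_equal(spearman_rho(x, -x), -1)               # reversal
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # tie handling: mid-ranks, cross-checked against the rank-difference formula
  set.seed(47)
  a <- rnorm(30); b <- rnorm(30)
  d <- rank(a) - rank(b)
  expect_equal(spearman_rho(a, b), 1 - 6 * sum(d^2) / (30 * (30^2 - 1)))
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "sepsiskit_undefined_score_error")
})

test_that("score_report assembles utility and classification metrics", {
  coh <- generate_cohort(cohort_config(n_patients = 30, prevalence = 0.3,
                                       seed = 12))
  ann <- coh$annotations
  opt <- optimal_predictions(ann, utility_params())
  rep <- score_report(ann, opt)
  expect_equal(rep$normalized, 1, tolerance = 1e-12)
  expect_equal(rep$n_patients, 30)
  expect_equal(rep$n_windows, sum(ann$hours))
  expect_true(rep$accuracy > 0 && rep$accuracy <= 1)
})
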