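test_that("imputation forward-fills, mean-fills, and z-scores cleanly", {
  v1 <- empty_record_values(4)
  v1$HR <- c(80, NA, NA, 90)
  v1$Lactate <- c(NA, NA, NA, NA)
  v2 <- empty_record_values(4)
  v2$HR <- c(60, 70, NA, NA)
  v2$Lactate <- c(2, NA, NA, 4)
  recs <- list(patient_record(v1, patient_id = "a"),
               patient_record(v2, patient_id = "b"))
  state <- fit_feature_state(recs, features = c("HR", "Lactate"))

  # forward fill before scaling
  raw <- state$scale["HR"] * impute_and_normalize(recs[[1]], state)$HR +
    state$center["HR"]
  expect_equal(unname(raw), c(80, 80, 80, 90))
  # never-observed feature becomes the training-mean constant column
  raw_lac <- state$scale["Lactate"] *
    impute_and_normalize(recs[[1]], state)$Lactate + state$center["Lactate"]
  expect_equal(unname(raw_lac), rep(mean(c(2, 4)), 4))

  # pooled z-scored training matrix has mean 0, sd 1 per feature
  pooled <- do.call(rbind, lapply(recs, function(r) {
    as.matrix(impute_and_normalize(r, state))
  }))
  expect_equal(unname(colMeans(pooled)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(pooled, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_false(anyNA(pooled))
  expect_error(impute_and_normalize(recs[[1]], "not fitted"),
               class = "sepsiskit_validation_error")
})

test_that("the MLE recovers planted parameters from simulated survival data", {
  # averaging over replicates shrinks the Monte-Carlo error so this checks
  # the estimator is centred on the truth, not just one lucky draw
  truth <- c(1.5, 100, 0.8, -0.5)
  set.seed(61)
  ests <- replicate(3, {
    sim <- simulate_weibull_cox(2000, shape = 1.5, scale = 100,
                                beta = c(0.8, -0.5))
    fit <- weibull_cox_mle(sim$time, sim$status,
                           as.matrix(sim[c("x1", "x2")]))
    expect_equal(fit$convergence, 0)
    c(fit$shape, fit$scale, unname(fit$beta))
  })
  expect_true(all(abs(rowMeans(ests) / truth - 1) < 0.10))
})

test_that("the MLE agrees with the survreg Weibull-PH reparameterization", {
  set.seed(62)
  sim <- simulate_weibull_cox(500, shape = 1.2, scale = 80, beta = c(0.6))
  fit <- weibull_cox_mle(sim$time, sim$status, as.matrix(sim["x1"]),
                         ridge = 0)
  sr <- survival::survreg(survival::Surv(time, status) ~ x1, data = sim,
                          dist = "weibull")
  # AFT -> PH: k = 1/scale, lambda = exp(intercept), beta_PH = -beta_AFT * k
  expect_equal(fit$shape, 1 / sr$scale, tolerance = 1e-4)
  expect_equal(fit$scale, unname(exp(coef(sr)[1])), tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(-coef(sr)[2] / sr$scale),
               tolerance = 1e-4)
})

test_that("with no covariates the fit reduces to a plain Weibull MLE", {
  set.seed(63)
  sim <- simulate_weibull_cox(800, shape = 2, scale = 50, beta = numeric(0),
                              censor_time = Inf)
  fit <- weibull_cox_mle(sim$time, sim$status)
  # direct two-parameter Weibull MLE via optim on the density
  nll <- function(par) -sum(stats::dweibull(sim$time, exp(par[1]),
                                            exp(par[2]), log = TRUE))
  ref <- optim(c(0, log(mean(sim$time))), nll)
  expect_equal(fit$shape, exp(ref$par[1]), tolerance = 1e-3)
  expect_equal(fit$scale, exp(ref$par[2]), tolerance = 1e-3)
})

test_that("fitting is invariant to patient order and needs both classes", {
  coh <- generate_cohort(cohort_config(n_patients = 40, prevalence = 0.3,
                                       seed = 64))
  ann <- coh$annotations
  feats <- c("HR", "Temp", "MAP", "Lactate", "WBC")
  m1 <- fit_weibull_cox(coh$records, ann, features = feats, threshold = 0.5)
  perm <- sample(length(coh$records))
  m2 <- fit_weibull_cox(coh$records[perm], ann[perm, ], features = feats,
                        threshold = 0.5)
  expect_equal(m1$shape, m2$shape, tolerance = 1e-5)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-4)

  nonseptic <- ann$is_septic == FALSE
  expect_error(fit_weibull_cox(coh$records[nonseptic], ann[nonseptic, ]),
               class = "sepsiskit_fit_error")
})

test_that("hourly risks are probabilities, monotone in the linear predictor", {
  coh <- generate_cohort(cohort_config(n_patients = 30, prevalence = 0.3,
                                       seed = 65))
  model <- fit_weibull_cox(coh$records, coh$annotations, threshold = 0.5)
  preds <- predict_cohort_risk(model, coh$records)
  expect_true(all(preds$risk >= 0 & preds$risk <= 1))
  expect_true(all(preds$prediction %in% 0:1))
  expect_equal(nrow(preds), sum(coh$annotations$hours))

  # closed forms: k = 1 gives a time-independent exponential risk, and
  # eta -> -Inf gives risk -> 0
  st <- model$state
  toy <- model
  toy$shape <- 1; toy$scale <- 50
  toy$beta <- setNames(rep(0, length(toy$beta)), names(toy$beta))
  r <- predict_hourly_risk(toy, coh$records[[1]])
  expect_equal(r$risk, rep(1 - exp(-(6 / 50)), nrow(r)), tolerance = 1e-12)
  h0 <- function(t, m) (t / m$scale)^m$shape
  eta <- -30
  expect_equal(1 - exp(-(h0(10 + 6, toy) - h0(10, toy)) * exp(eta)), 0,
               tolerance = 1e-9)
})

test_that("the log-likelihood increases from init to optimum", {
  set.seed(66)
  sim <- simulate_weibull_cox(300, shape = 1.4, scale = 60, beta = c(0.5))
  x <- as.matrix(sim["x1"])
  init <- c(0, log(mean(sim$time) / max(mean(sim$status), 1e-3)), 0)
  ll_init <- sepsiskit:::weibull_cox_loglik(init, sim$time, sim$status, x,
                                            1e-4)
  fit <- weibull_cox_mle(sim$time, sim$status, x)
  expect_gt(fit$loglik, ll_init)
})

test_that("models round-trip through flat JSON", {
  coh <- generate_cohort(cohort_config(n_patients = 25, prevalence = 0.3,
                                       seed = 67))
  model <- fit_weibull_cox(coh$records, coh$annotations,
                           features = c("HR", "MAP", "Lactate"),
                           threshold = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  write_weibull_cox(model, path)
  back <- read_weibull_cox(path)
  expect_equal(back$shape, model$shape)
  expect_equal(back$beta, model$beta)
  p1 <- predict_hourly_risk(model, coh$records[[1]])
  p2 <- predict_hourly_risk(back, coh$records[[1]])
  expect_equal(p1, p2)
})

test_that("tidy and glance summarize the fit", {
  coh <- generate_cohort(cohort_config(n_patients = 25, prevalence = 0.3,
                                       seed = 68))
  model <- fit_weibull_cox(coh$records, coh$annotations,
                           features = c("HR", "MAP"), threshold = 0.5)
  td <- tidy(model)
  expect_setequal(td$term, c("shape", "scale", "HR", "MAP"))
  gl <- glance(model)
  expect_equal(gl$n, 25)
  expect_true(gl$converged)
})

test_that("the baseline beats inaction and all-positive on drifted cohorts", {
  p <- utility_params()
  coh <- generate_cohort(cohort_config(n_patients = 150, prevalence = 0.25,
                                       seed = 69))
  ann <- coh$annotations
  model <- fit_weibull_cox(coh$records, ann, params = p)
  preds <- predict_cohort_risk(model, coh$records)
  u_base <- normalized_utility(ann, preds, p)
  all_pos <- dplyr::mutate(inaction_predictions(ann), prediction = 1L)
  expect_gt(u_base, 0)  # inaction scores exactly 0
  expect_gt(u_base, normalized_utility(ann, all_pos, p))
})
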