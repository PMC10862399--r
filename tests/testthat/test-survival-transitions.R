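# simulate censored single-cause data with known truth
sim_surv_data <- function(n, family, pars, censor = 7, seed = 1) {
  set.seed(seed)
  t_true <- rsurvtime(n, family, pars)
  cens <- runif(n, censor / 2, censor)
  data.frame(
    time = pmax(pmin(t_true, cens), 1e-9), status = as.integer(t_true <= cens),
    age_band = factor(sample(age_bands(), n, TRUE), levels = age_bands()),
    sex = factor(sample(sexes(), n, TRUE), levels = sexes()),
    baseline_history = sample(c(TRUE, FALSE), n, TRUE)
  )
}

test_that("exponential rate recovery matches the closed-form MLE oracle", {
  dat <- sim_surv_data(10000, "exponential", list(rate = 0.10), seed = 21)
  fit <- fit_parametric_survival(dat, c("NTRD", "death"), "exponential",
                                 adjust = FALSE)
  lambda_mle <- sum(dat$status) / sum(dat$time)   # independent closed form
  lambda_fit <- fit_params(fit, "10-24|female|nohx")$rate
  expect_equal(lambda_fit, lambda_mle, tolerance = 1e-5)
  ci <- fit$model$res["rate", c("L95%", "U95%")]
  expect_gt(0.10, ci[1])
  expect_lt(0.10, ci[2])
})

test_that("zero events raise an estimation error advising the zero override", {
  dat <- sim_surv_data(200, "exponential", list(rate = 0.1), seed = 2)
  dat$status <- 0L
  expect_error(
    fit_parametric_survival(dat, c("NTRD", "TRD"), "weibull"),
    "zero events.*zero_transition_fit"
  )
})

test_that("AIC/BIC identities hold and the true family attains the lowest AIC and BIC", {
  dat <- sim_surv_data(10000, "weibull", list(shape = 0.7, scale = 10),
                       seed = 33)
  fits <- lapply(survival_families(), function(f) {
    fit_parametric_survival(dat, c("NTRD", "TRD"), f, adjust = FALSE)
  })
  for (f in fits) {
    expect_equal(f$aic, 2 * f$npars - 2 * f$loglik, tolerance = 1e-9)
    expect_equal(f$bic, f$npars * log(f$n) - 2 * f$loglik, tolerance = 1e-9)
  }
  aic <- vapply(fits, function(f) f$aic, 0)
  bic <- vapply(fits, function(f) f$bic, 0)
  expect_equal(survival_families()[which.min(aic)], "weibull")
  expect_equal(survival_families()[which.min(bic)], "weibull")
  sel <- select_best_family(fits, quiet = TRUE)
  expect_equal(sel$family, "weibull")
})

test_that("selection returns lowest AIC, breaks exact ties by family order, and requires five fits", {
  fits <- lapply(seq_along(survival_families()), function(i) {
    f <- synthetic_fit(survival_families()[i], switch(survival_families()[i],
      exponential = list(rate = 0.1), weibull = list(shape = 1, scale = 10),
      lognormal = list(meanlog = 2, sdlog = 1),
      loglogistic = list(shape = 1, scale = 10),
      gompertz = list(shape = 0.1, rate = 0.1)))
    f$aic <- c(100, 90, 95, 99, 98)[i]
    f$bic <- f$aic + 2
    f
  })
  expect_equal(select_best_family(fits, quiet = TRUE)$family, "weibull")
  # exact AIC tie between exponential and weibull: exponential is first
  fits2 <- fits
  fits2[[1]]$aic <- 90; fits2[[1]]$bic <- 92
  expect_equal(select_best_family(fits2, quiet = TRUE)$family, "exponential")
  # AIC/BIC disagreement is flagged
  fits3 <- fits
  fits3[[3]]$bic <- 1
  expect_message(select_best_family(fits3), "BIC prefers")
  sel <- suppressMessages(select_best_family(fits3))
  expect_true(sel$bic_disagrees)
  expect_error(select_best_family(fits[1:4]), "missing")
})

test_that("cycle probabilities follow 1 - S(t)/S(t-1) with the quadrature oracle", {
  g <- "41-65|female|nohx"
  # exponential: constant q = 1 - exp(-rate)
  fe <- synthetic_fit("exponential", list(rate = 0.0513))
  q <- survival_to_cycle_probs(fe, g)
  expect_equal(q, rep(1 - exp(-0.0513), 10), tolerance = 1e-12)
  expect_equal(q[1], 0.05, tolerance = 1e-3)
  # Weibull shape 0.7 with S(1) = 0.938: q declines from 0.062
  scale <- (-log(0.938))^(-1 / 0.7)
  fw <- synthetic_fit("weibull", list(shape = 0.7, scale = scale))
  qw <- survival_to_cycle_probs(fw, g)
  expect_equal(qw[1], 0.062, tolerance = 1e-9)
  expect_lt(qw[2], qw[1])
  expect_lt(qw[3], qw[2])
  # quadrature oracle across families
  cases <- list(
    list(family = "lognormal", pars = list(meanlog = 2, sdlog = 1.2)),
    list(family = "loglogistic", pars = list(shape = 1.4, scale = 9)),
    list(family = "gompertz", pars = list(shape = -0.3, rate = 0.07))
  )
  for (cs in cases) {
    f <- synthetic_fit(cs$family, cs$pars)
    expect_equal(survival_to_cycle_probs(f, g),
                 quadrature_q(cs$family, cs$pars, 1:10), tolerance = 1e-9)
  }
  # exhausted support raises an error
  fz <- synthetic_fit("weibull", list(shape = 8, scale = 0.1))
  expect_error(survival_to_cycle_probs(fz, g), "support exhausted")
})

test_that("covariate-adjusted per-subgroup survival agrees with flexsurv's own predictions", {
  co <- test_cohort()
  fit <- fit_parametric_survival(co, c("NTRD", "TRD"), "gompertz")
  for (g in c("10-24|female|nohx", ">65|male|hx", "41-65|female|hx")) {
    prof <- subgroup_table()[subgroup_table()$subgroup == g, ]
    nd <- data.frame(
      age_band = factor(prof$age_band, levels = age_bands()),
      sex = factor(prof$sex, levels = sexes()),
      baseline_history = prof$baseline_history
    )
    sf <- summary(fit$model, newdata = nd, t = 1:5, type = "survival",
                  ci = FALSE, tidy = TRUE)
    mine <- survival_at("gompertz", fit_params(fit, g), 1:5)
    expect_equal(mine, sf$est, tolerance = 1e-8)
  }
})

test_that("schedules are row-stochastic with absorbing rows and complement stay probability", {
  fits <- list(
    "NTRD->TRD" = synthetic_fit("exponential", list(rate = -log(1 - 0.06))),
    "NTRD->NTRD_comorbid" = synthetic_fit("exponential", list(rate = -log(1 - 0.05))),
    "NTRD->low_intensity" = synthetic_fit("exponential", list(rate = -log(1 - 0.10))),
    "NTRD->death" = synthetic_fit("exponential", list(rate = -log(1 - 0.02))),
    "TRD->TRD_comorbid" = zero_transition_fit(c("TRD", "TRD_comorbid")),
    "TRD->low_intensity" = zero_transition_fit(c("TRD", "low_intensity")),
    "TRD->death" = zero_transition_fit(c("TRD", "death")),
    "NTRD_comorbid->low_intensity" = zero_transition_fit(c("NTRD_comorbid", "low_intensity")),
    "NTRD_comorbid->death" = zero_transition_fit(c("NTRD_comorbid", "death")),
    "TRD_comorbid->low_intensity" = zero_transition_fit(c("TRD_comorbid", "low_intensity")),
    "TRD_comorbid->death" = zero_transition_fit(c("TRD_comorbid", "death"))
  )
  sch <- assemble_schedule(fits, "25-40|male|hx")
  m <- sch$prob[1, , ]
  expect_equal(m["NTRD", "NTRD"], 0.77, tolerance = 1e-12)
  expect_equal(unname(rowSums(m)), rep(1, 6), tolerance = 1e-12)
  for (s in absorbing_states()) expect_equal(unname(m[s, s]), 1)
  # all-zero fits give identity matrices
  zfits <- lapply(fits, function(f) zero_transition_fit(f$transition))
  names(zfits) <- names(fits)
  schz <- assemble_schedule(zfits, "25-40|male|hx")
  for (t in 1:10) expect_equal(unname(schz$prob[t, , ]), diag(6))
  # missing edge is named
  expect_error(assemble_schedule(fits[-1], "25-40|male|hx"), "NTRD->TRD")
  # row sums hold under random probability vectors (property)
  set.seed(14)
  for (i in 1:25) {
    qs <- runif(4, 0, 0.5)
    rf <- fits
    edges <- c("NTRD->TRD", "NTRD->NTRD_comorbid", "NTRD->low_intensity",
               "NTRD->death")
    for (j in 1:4) {
      rf[[edges[j]]] <- synthetic_fit("exponential",
                                      list(rate = -log(1 - qs[j])))
    }
    suppressWarnings({
      s1 <- assemble_schedule(rf, "10-24|female|nohx")
      s2 <- assemble_schedule(rf, "10-24|female|nohx", method = "hazard")
    })
    for (t in 1:10) {
      expect_equal(unname(rowSums(s1$prob[t, , ])), rep(1, 6),
                   tolerance = 1e-12)
      expect_equal(unname(rowSums(s2$prob[t, , ])), rep(1, 6),
                   tolerance = 1e-12)
    }
  }
})

test_that("over-unity competing probabilities are rescaled proportionally with a warning", {
  fits <- list(
    "NTRD->TRD" = synthetic_fit("exponential", list(rate = -log(1 - 0.6))),
    "NTRD->NTRD_comorbid" = synthetic_fit("exponential", list(rate = -log(1 - 0.6))),
    "NTRD->low_intensity" = zero_transition_fit(c("NTRD", "low_intensity")),
    "NTRD->death" = zero_transition_fit(c("NTRD", "death")),
    "TRD->TRD_comorbid" = zero_transition_fit(c("TRD", "TRD_comorbid")),
    "TRD->low_intensity" = zero_transition_fit(c("TRD", "low_intensity")),
    "TRD->death" = zero_transition_fit(c("TRD", "death")),
    "NTRD_comorbid->low_intensity" = zero_transition_fit(c("NTRD_comorbid", "low_intensity")),
    "NTRD_comorbid->death" = zero_transition_fit(c("NTRD_comorbid", "death")),
    "TRD_comorbid->low_intensity" = zero_transition_fit(c("TRD_comorbid", "low_intensity")),
    "TRD_comorbid->death" = zero_transition_fit(c("TRD_comorbid", "death"))
  )
  expect_warning(sch <- assemble_schedule(fits, "10-24|female|nohx",
                                          cycles = 1),
                 "rescaling")
  m <- sch$prob[1, , ]
  expect_equal(unname(m["NTRD", "TRD"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(m["NTRD", "NTRD"]), 0, tolerance = 1e-12)
})

test_that("hazard-combination schedules match a latent competing-risks simulation", {
  # two competing exponential causes with rates 0.4 each
  fits <- list(
    "NTRD->TRD" = synthetic_fit("exponential", list(rate = 0.4)),
    "NTRD->NTRD_comorbid" = synthetic_fit("exponential", list(rate = 0.4)),
    "NTRD->low_intensity" = zero_transition_fit(c("NTRD", "low_intensity")),
    "NTRD->death" = zero_transition_fit(c("NTRD", "death")),
    "TRD->TRD_comorbid" = zero_transition_fit(c("TRD", "TRD_comorbid")),
    "TRD->low_intensity" = zero_transition_fit(c("TRD", "low_intensity")),
    "TRD->death" = zero_transition_fit(c("TRD", "death")),
    "NTRD_comorbid->low_intensity" = zero_transition_fit(c("NTRD_comorbid", "low_intensity")),
    "NTRD_comorbid->death" = zero_transition_fit(c("NTRD_comorbid", "death")),
    "TRD_comorbid->low_intensity" = zero_transition_fit(c("TRD_comorbid", "low_intensity")),
    "TRD_comorbid->death" = zero_transition_fit(c("TRD_comorbid", "death"))
  )
  sch <- assemble_schedule(fits, "10-24|female|nohx", method = "hazard")
  set.seed(123)
  nsim <- 1e6
  t1 <- rexp(nsim, 0.4); t2 <- rexp(nsim, 0.4)
  p_sim <- mean(t1 < t2 & t1 <= 1)
  p_mod <- sch$prob[1, "NTRD", "TRD"]
  se <- sqrt(p_sim * (1 - p_sim) / nsim)
  expect_lt(abs(p_mod - p_sim), 3 * se)
  # and the analytic value (lambda1/lambda) * (1 - exp(-lambda))
  expect_equal(unname(p_mod), 0.5 * (1 - exp(-0.8)), tolerance = 1e-12)
})

test_that("MAPE is the mean absolute percentage error with guarded inputs", {
  expect_equal(validate_mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(validate_mape(c(110, 90), c(100, 100)), 10)
  expect_error(validate_mape(1:3, 1:2), "equal length")
  expect_error(validate_mape(c(1, 2), c(1, 0)), "undefined")
})

test_that("fitted schedules forecast the cohort's own cycle-4 outcomes closely", {
  pipe <- test_pipeline()
  v <- validate_schedule_fit(pipe$cohort, pipe$schedules, cycle = 4)
  expect_lt(v$mape, 5)
})
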