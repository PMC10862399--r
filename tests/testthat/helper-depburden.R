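# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

# medium synthetic cohort under the default study conditions
test_cohort <- function() {
  if (is.null(.cache$cohort)) {
    .cache$cohort <- generate_cohort(generator_config(n_patients = 4000,
                                                      seed = 424242))
  }
  .cache$cohort
}

# selected fits + schedules + state inputs for the medium cohort
test_pipeline <- function() {
  if (is.null(.cache$pipe)) {
    co <- test_cohort()
    fits <- fit_transition_models(co)
    .cache$pipe <- list(
      cohort = co, fits = fits,
      schedules = build_schedules(fits),
      state_inputs = derive_state_inputs(co)
    )
  }
  .cache$pipe
}

# a survival_fit with known natural parameters, bypassing estimation
synthetic_fit <- function(family, pars, transition = c("NTRD", "TRD")) {
  cf <- switch(family,
    exponential = c(rate = log(pars$rate)),
    weibull = c(shape = log(pars$shape), scale = log(pars$scale)),
    lognormal = c(meanlog = pars$meanlog, sdlog = log(pars$sdlog)),
    loglogistic = c(shape = log(pars$shape), scale = log(pars$scale)),
    gompertz = c(shape = pars$shape, rate = log(pars$rate))
  )
  structure(
    list(transition = transition, family = family, model = NULL,
         coefficients = cf, adjust = FALSE, loglik = NA_real_,
         aic = NA_real_, bic = NA_real_, npars = length(cf), n = 0L,
         n_events = 0L, n_at_risk = 0L, qq_dev = NA_real_),
    class = "survival_fit"
  )
}

# constant per-cycle probability schedule for a single subgroup
constant_schedule <- function(q_edges, cycles = 10,
                              subgroup = "41-65|female|nohx") {
  states <- model_states()
  prob <- array(0, dim = c(cycles, 6, 6),
                dimnames = list(NULL, states, states))
  for (t in seq_len(cycles)) {
    m <- diag(6)
    dimnames(m) <- list(states, states)
    for (edge in names(q_edges)) {
      ft <- strsplit(edge, "->", fixed = TRUE)[[1]]
      m[ft[1], ft[2]] <- q_edges[[edge]]
    }
    for (s in setdiff(states, absorbing_states())) {
      m[s, s] <- 1 - sum(m[s, -match(s, states)])
    }
    prob[t, , ] <- m
  }
  structure(list(subgroup = subgroup, cycles = cycles, prob = prob),
            class = "transition_schedule")
}

# state inputs for a single subgroup with given costs/utilities
simple_state_inputs <- function(subgroup = "41-65|female|nohx",
                                cost_allcause = c(NTRD = 1000, TRD = 2000,
                                                  NTRD_comorbid = 3000,
                                                  TRD_comorbid = 4000,
                                                  low_intensity = 0, death = 0),
                                cost_psychiatric = cost_allcause * 0.2,
                                utility = c(NTRD = 0.8, TRD = 0.6,
                                            NTRD_comorbid = 0.664,
                                            TRD_comorbid = 0.498,
                                            low_intensity = 0.85, death = 0)) {
  do.call(rbind, lapply(subgroup, function(g) {
    data.frame(state = model_states(), subgroup = g,
               cost_allcause = cost_allcause[model_states()],
               cost_psychiatric = cost_psychiatric[model_states()],
               utility = utility[model_states()], row.names = NULL)
  }))
}

# numerical-quadrature oracle: q(t) from integrating the flexsurv hazard
quadrature_q <- function(family, pars, t, accel = 1) {
  h <- function(u) {
    u <- u / accel
    val <- switch(family,
      exponential = rep_len(pars$rate, length(u)),
      weibull = flexsurv::hweibull(u, pars$shape, pars$scale),
      lognormal = flexsurv::hlnorm(u, pars$meanlog, pars$sdlog),
      loglogistic = flexsurv::hllogis(u, shape = pars$shape,
                                      scale = pars$scale),
      gompertz = flexsurv::hgompertz(u, shape = pars$shape, rate = pars$rate)
    )
    val / accel
  }
  vapply(t, function(tt) {
    H <- stats::integrate(h, tt - 1, tt, rel.tol = 1e-13,
                          abs.tol = 1e-14)$value
    1 - exp(-H)
  }, 0)
}
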