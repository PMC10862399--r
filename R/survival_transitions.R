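#' Build a time-to-event dataset for one transition
#'
#' Extracts, from a cohort, the subjects who entered `from`, with time
#' measured from entry into `from` until entry into `to` (event) or until a
#' competing transition or administrative censoring (right-censored),
#' whichever comes first.
#'
#' @param cohort A `depression_cohort`.
#' @param from,to States defining the transition.
#' @return Data frame with columns `time`, `status`, `age_band`, `sex`,
#'   `baseline_history`.
#' @export
transition_data <- function(cohort, from, to) {
  entry <- event_matrix(cohort)
  idx <- which(is.finite(entry[, from]))
  if (!length(idx)) stop("no subjects ever entered state ", from)
  t0 <- entry[idx, from]
  exit <- exit_time_from(entry, from)[idx]
  end <- pmin(exit, cohort$patients$censor_time[idx])
  status <- as.integer(is.finite(entry[idx, to]) & entry[idx, to] <= end &
                         entry[idx, to] == exit)
  time <- pmax(end - t0, 1e-9)
  p <- cohort$patients[idx, ]
  data.frame(
    time = time, status = status,
    age_band = factor(p$age_band, levels = age_bands()),
    sex = factor(p$sex, levels = sexes()),
    baseline_history = p$baseline_history
  )
}

# mapping to flexsurv distribution codes
flexsurv_dist <- function(family) {
  switch(match.arg(family, survival_families()),
    exponential = "exp", weibull = "weibull", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz"
  )
}

#' Fit a parametric survival model for one transition
#'
#' Maximum-likelihood fit of one of the five supported families to the
#' time-to-event data of a transition, adjusted for age band, sex and
#' baseline medical history.  Covariates act on the location parameter of
#' the family (the accelerated-failure-time form for the Weibull, lognormal
#' and log-logistic families; the rate for the exponential and Gompertz).
#'
#' @param data Either a `depression_cohort` (with `transition` giving the
#'   edge) or a data frame from [transition_data()].
#' @param transition Character vector `c(from, to)`; required when `data` is
#'   a cohort, used as metadata otherwise.
#' @param family One of [survival_families()].
#' @param adjust Adjust for covariates (default `TRUE`); with `FALSE` an
#'   intercept-only model is fitted.
#' @return Object of class `survival_fit` carrying the fitted `flexsurvreg`
#'   model, the family, log-likelihood, AIC and BIC (`k * log(n)` with `n`
#'   the number of subjects), event and at-risk counts, and a
#'   quantile-deviation statistic `qq_dev` comparing fitted and
#'   Kaplan-Meier survival.
#' @export
fit_parametric_survival <- function(data, transition, family,
                                    adjust = TRUE) {
  if (inherits(data, "depression_cohort")) {
    stopifnot(length(transition) == 2L)
    data <- transition_data(data, transition[1], transition[2])
  }
  family <- match.arg(family, survival_families())
  if (sum(data$status) == 0L) {
    stop("zero events for transition ",
         paste(transition, collapse = "->"),
         ": no model can be estimated; use zero_transition_fit() to force ",
         "a zero-probability edge")
  }
  fml <- if (adjust) {
    survival::Surv(time, status) ~ age_band + sex + baseline_history
  } else {
    survival::Surv(time, status) ~ 1
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(fml, data = data, dist = flexsurv_dist(family)),
    error = function(e) {
      # sparse-event edges can defeat the default initial values; retry
      # from moment-based starting points with covariate effects at zero
      flexsurv::flexsurvreg(fml, data = data, dist = flexsurv_dist(family),
                            inits = moment_inits(family, data, adjust))
    }
  )
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0) {
    stop("optimiser failed to converge for family '", family, "' (code ",
         fit$opt$convergence, "): ", fit$opt$message)
  }
  k <- fit$npars
  n <- nrow(data)
  structure(
    list(
      transition = transition, family = family, model = fit,
      coefficients = stats::setNames(fit$res.t[, "est"],
                                     rownames(fit$res.t)),
      adjust = adjust,
      loglik = fit$loglik, aic = 2 * k - 2 * fit$loglik,
      bic = k * log(n) - 2 * fit$loglik, npars = k, n = n,
      n_events = sum(data$status), n_at_risk = n,
      qq_dev = qq_deviation(fit, data)
    ),
    class = "survival_fit"
  )
}

# crude natural-scale starting values from the event-time moments
moment_inits <- function(family, data, adjust) {
  ev <- data$time[data$status == 1]
  rate <- sum(data$status) / sum(data$time)
  base <- switch(family,
    exponential = rate,
    weibull = c(1, mean(ev)),
    lognormal = c(mean(log(ev)), max(stats::sd(log(ev)), 0.5)),
    loglogistic = c(1, stats::median(ev)),
    gompertz = c(1e-3, rate)
  )
  n_cov <- if (adjust) 5L else 0L
  c(base, rep(0, n_cov))
}

# mean absolute deviation between Kaplan-Meier and mean fitted survival at
# the deciles of observed event times; the automated stand-in for visual
# curve inspection
qq_deviation <- function(fit, data) {
  km <- survival::survfit(survival::Surv(time, status) ~ 1, data = data)
  tq <- stats::quantile(data$time[data$status == 1], probs = seq(0.1, 0.9, 0.1),
                        names = FALSE)
  km_s <- stats::approx(km$time, km$surv, xout = tq, method = "constant",
                        yleft = 1, rule = 2)$y
  sm <- summary(fit, t = tq, type = "survival", ci = FALSE, tidy = TRUE)
  mod_s <- tapply(sm$est, sm$time, mean)[as.character(tq)]
  mean(abs(km_s - as.numeric(mod_s)))
}

#' @rdname fit_parametric_survival
#' @export
print.survival_fit <- function(x, ...) {
  cat("Parametric transition fit: ",
      paste(x$transition, collapse = " -> "), "\n", sep = "")
  cat("  family:", x$family, " events:", x$n_events, "/", x$n_at_risk, "\n")
  cat(sprintf("  loglik: %.2f  AIC: %.2f  BIC: %.2f  qq_dev: %.4f\n",
              x$loglik, x$aic, x$bic, x$qq_dev))
  invisible(x)
}

#' A forced zero-probability transition
#'
#' Stand-in for edges with no observed events: the per-cycle transition
#' probability is identically zero.
#'
#' @param transition Character vector `c(from, to)`.
#' @return A `survival_fit` of family `"zero"`.
#' @export
zero_transition_fit <- function(transition) {
  structure(
    list(transition = transition, family = "zero", model = NULL,
         coefficients = numeric(), loglik = NA_real_, aic = Inf, bic = Inf,
         npars = 0L, n = 0L, n_events = 0L, n_at_risk = 0L, qq_dev = NA_real_),
    class = "survival_fit"
  )
}

#' Select the best-fitting family by information criteria
#'
#' Returns the fit with the lowest AIC among the five candidate families.
#' Exact ties are broken by the fixed family order of
#' [survival_families()].  When the BIC ranking disagrees with the AIC
#' choice, a message is emitted and the selected fit is flagged
#' (`bic_disagrees`).
#'
#' @param fits List of five `survival_fit` objects for the same transition.
#' @param quiet Suppress the BIC-disagreement message.
#' @return The selected `survival_fit`.
#' @export
select_best_family <- function(fits, quiet = FALSE) {
  fams <- vapply(fits, function(f) f$family, "")
  missing <- setdiff(survival_families(), fams)
  if (length(missing)) {
    stop("select_best_family() needs one fit per family; missing: ",
         paste(missing, collapse = ", "))
  }
  fits <- fits[match(survival_families(), fams)]
  aic <- vapply(fits, function(f) f$aic, 0)
  bic <- vapply(fits, function(f) f$bic, 0)
  best <- which(aic == min(aic))[1]   # first in family order on exact ties
  best_bic <- which(bic == min(bic))[1]
  sel <- fits[[best]]
  sel$bic_disagrees <- best_bic != best
  if (sel$bic_disagrees && !quiet) {
    message("AIC selects '", sel$family, "' but BIC prefers '",
            fits[[best_bic]]$family, "' for transition ",
            paste(sel$transition, collapse = "->"), "; AIC wins")
  }
  sel
}

#' Natural-scale parameters of a fit for one subgroup
#'
#' Combines the fitted intercept and covariate effects into the natural
#' parameters of the family for a given subgroup profile.
#'
#' @param fit A `survival_fit`.
#' @param subgroup A subgroup id from [subgroup_table()].
#' @return Named list of natural-scale parameters.
#' @export
fit_params <- function(fit, subgroup) {
  stopifnot(inherits(fit, "survival_fit"))
  if (fit$family == "zero") return(list())
  prof <- parse_subgroup(subgroup)
  cf <- fit$coefficients
  loc_name <- switch(fit$family,
    exponential = "rate", weibull = "scale", lognormal = "meanlog",
    loglogistic = "scale", gompertz = "rate"
  )
  lp <- cf[[loc_name]]
  if (fit$adjust) {
    if (prof$age_band != "10-24") {
      lp <- lp + cf[[paste0("age_band", prof$age_band)]]
    }
    if (prof$sex == "male") lp <- lp + cf[["sexmale"]]
    if (prof$baseline_history) lp <- lp + cf[["baseline_historyTRUE"]]
  }
  loc <- if (fit$family == "lognormal") lp else exp(lp)
  switch(fit$family,
    exponential = list(rate = loc),
    weibull = list(shape = exp(cf[["shape"]]), scale = loc),
    lognormal = list(meanlog = loc, sdlog = exp(cf[["sdlog"]])),
    loglogistic = list(shape = exp(cf[["shape"]]), scale = loc),
    gompertz = list(shape = cf[["shape"]], rate = loc)
  )
}

#' Convert a survival fit to per-cycle conditional transition probabilities
#'
#' For yearly cycles `t = 1..cycles`, the conditional probability of the
#' event during cycle `t` given event-free survival to `t - 1` is
#' `q(t) = 1 - S(t) / S(t - 1)`, with `S` the covariate-adjusted survival
#' function of the fitted family.  For an exponential fit, `q(t)` is
#' constant at `1 - exp(-rate)`.
#'
#' @param fit A `survival_fit` (or zero fit).
#' @param subgroup Subgroup id.
#' @param cycles Number of yearly cycles (default 10).
#' @return Numeric vector `q[1..cycles]`, each in `[0, 1]`.
#' @export
survival_to_cycle_probs <- function(fit, subgroup, cycles = 10) {
  if (fit$family == "zero") return(rep(0, cycles))
  pars <- fit_params(fit, subgroup)
  s <- survival_at(fit$family, pars, 0:cycles)
  if (any(s[seq_len(cycles)] <= 0)) {
    stop("survival support exhausted before cycle ", cycles,
         " for subgroup ", subgroup)
  }
  q <- 1 - s[-1] / s[-length(s)]
  pmin(pmax(q, 0), 1)
}

#' Fit all transitions and select families
#'
#' Fits the five candidate families to every edge of the model topology and
#' selects the best by AIC.  Edges without any observed event are replaced
#' by [zero_transition_fit()] with a message.
#'
#' @param cohort A `depression_cohort`.
#' @param families Families to try (default all five).
#' @param include_comorbid_trd Include the optional
#'   `NTRD_comorbid -> TRD_comorbid` edge.
#' @param quiet Suppress selection messages.
#' @return Named list (by `"from->to"`) of selected `survival_fit` objects.
#' @export
fit_transition_models <- function(cohort, families = survival_families(),
                                  include_comorbid_trd = FALSE,
                                  quiet = TRUE) {
  topo <- model_topology(include_comorbid_trd)
  out <- list()
  for (i in seq_len(nrow(topo))) {
    tr <- c(topo$from[i], topo$to[i])
    dat <- transition_data(cohort, tr[1], tr[2])
    if (sum(dat$status) == 0L) {
      message("no events on edge ", topo$edge[i], "; forcing zero probability")
      out[[topo$edge[i]]] <- zero_transition_fit(tr)
      next
    }
    fits <- lapply(families, function(f) {
      fit_parametric_survival(dat, tr, f)
    })
    out[[topo$edge[i]]] <- if (length(fits) == 5L) {
      select_best_family(fits, quiet = quiet)
    } else {
      fits[[which.min(vapply(fits, function(f) f$aic, 0))]]
    }
  }
  out
}

#' Assemble a per-subgroup transition schedule
#'
#' Combines the cause-specific per-cycle probabilities of all edges into
#' row-stochastic transition matrices for one subgroup over the horizon.
#' Two combination conventions are available.  `"sum"` (the default) uses
#' the cause-specific cycle probabilities directly, with the stay
#' probability as their complement; if they sum beyond 1 in a cycle they
#' are rescaled proportionally (with a warning, since this signals
#' implausible inputs).  `"hazard"` converts each probability back to a
#' cycle hazard increment and allocates the total exit probability
#' `1 - exp(-sum(dH))` proportionally to the increments, which reproduces a
#' latent competing-risks simulation exactly for constant hazards; the two
#' conventions agree to first order when probabilities are small.
#' Absorbing states keep probability 1 of remaining.
#'
#' @param fits Named list of selected `survival_fit` objects (names
#'   `"from->to"`), e.g. from [fit_transition_models()].
#' @param subgroup Subgroup id.
#' @param cycles Number of yearly cycles.
#' @param include_comorbid_trd Include the optional comorbid-to-TRD edge.
#' @param method `"sum"` or `"hazard"` competing-cause combination.
#' @return Object of class `transition_schedule`: list with `subgroup`,
#'   `cycles` and `prob`, an array `[cycle, from, to]`.
#' @export
assemble_schedule <- function(fits, subgroup, cycles = 10,
                              include_comorbid_trd = FALSE,
                              method = c("sum", "hazard")) {
  method <- match.arg(method)
  topo <- model_topology(include_comorbid_trd)
  missing <- setdiff(topo$edge, names(fits))
  if (length(missing)) {
    stop("missing transition fit for edge(s): ", paste(missing, collapse = ", "))
  }
  q <- sapply(topo$edge, function(e) {
    survival_to_cycle_probs(fits[[e]], subgroup, cycles)
  })
  q <- matrix(q, nrow = cycles, dimnames = list(NULL, topo$edge))
  states <- model_states()
  prob <- array(0, dim = c(cycles, 6, 6), dimnames = list(NULL, states, states))
  for (t in seq_len(cycles)) {
    m <- diag(6)
    dimnames(m) <- list(states, states)
    for (from in setdiff(states, absorbing_states())) {
      edges <- topo[topo$from == from, ]
      qs <- q[t, edges$edge]
      if (method == "hazard") {
        qs <- combine_competing_hazard(qs)
      } else {
        tot <- sum(qs)
        if (tot > 1) {
          warning("competing probabilities from ", from, " sum to ",
                  signif(tot, 4), " in cycle ", t, " for subgroup ", subgroup,
                  "; rescaling proportionally")
          qs <- qs / tot
        }
      }
      m[from, ] <- 0
      m[from, edges$to] <- qs
      m[from, from] <- 1 - sum(qs)
    }
    prob[t, , ] <- m
  }
  structure(list(subgroup = subgroup, cycles = cycles, prob = prob),
            class = "transition_schedule")
}

# allocate the joint exit probability 1 - exp(-sum(dH)) across causes in
# proportion to their cycle hazard increments dH_c = -log(1 - q_c)
combine_competing_hazard <- function(qs) {
  if (any(qs >= 1)) stop("cause-specific probability of 1 is not compatible ",
                         "with the hazard combination method")
  dh <- -log1p(-qs)
  tot <- sum(dh)
  if (tot == 0) return(qs * 0)
  dh / tot * (1 - exp(-tot))
}

#' @rdname assemble_schedule
#' @param subgroups Subgroup ids (default all 16).
#' @return `build_schedules`: named list of `transition_schedule`, one per
#'   subgroup.
#' @export
build_schedules <- function(fits, subgroups = subgroup_table()$subgroup,
                            cycles = 10, include_comorbid_trd = FALSE,
                            method = c("sum", "hazard")) {
  method <- match.arg(method)
  stats::setNames(
    lapply(subgroups, assemble_schedule, fits = fits, cycles = cycles,
           include_comorbid_trd = include_comorbid_trd, method = method),
    subgroups
  )
}

#' Transition schedule from known hazard specifications
#'
#' Builds the schedule implied directly by a generator configuration's
#' cause-specific hazards (the simulation truth), bypassing estimation.
#' Useful for engine studies with known parameters and for validating
#' fitted schedules.
#'
#' @param config A [generator_config()].
#' @param subgroup Subgroup id.
#' @param cycles Number of yearly cycles.
#' @return A `transition_schedule`.
#' @export
schedule_from_hazards <- function(config, subgroup, cycles = 10,
                                  method = c("sum", "hazard")) {
  method <- match.arg(method)
  prof <- parse_subgroup(subgroup)
  topo <- model_topology(config$include_comorbid_trd)
  states <- model_states()
  prob <- array(0, dim = c(cycles, 6, 6), dimnames = list(NULL, states, states))
  qmat <- sapply(topo$edge, function(e) {
    hz <- config$hazards[[e]]
    accel <- exp(covariate_lp(hz$beta, prof$age_band, prof$sex,
                              prof$baseline_history))
    H <- cum_hazard(hz$family, hz$pars, 0:cycles, accel = accel)
    1 - exp(-diff(H))
  })
  qmat <- matrix(qmat, nrow = cycles, dimnames = list(NULL, topo$edge))
  for (t in seq_len(cycles)) {
    m <- diag(6)
    dimnames(m) <- list(states, states)
    for (from in setdiff(states, absorbing_states())) {
      edges <- topo[topo$from == from, ]
      qs <- qmat[t, edges$edge]
      if (method == "hazard") {
        qs <- combine_competing_hazard(qs)
      } else if (sum(qs) > 1) {
        qs <- qs / sum(qs)
      }
      m[from, ] <- 0
      m[from, edges$to] <- qs
      m[from, from] <- 1 - sum(qs)
    }
    prob[t, , ] <- m
  }
  structure(list(subgroup = subgroup, cycles = cycles, prob = prob),
            class = "transition_schedule")
}

#' Mean absolute percentage error
#'
#' Internal-validation metric comparing modelled against observed
#' quantities: the mean over items of `|modelled - observed| / observed`,
#' in percent.
#'
#' @param modelled,observed Equal-length numeric vectors; `observed` must be
#'   strictly positive.
#' @return The MAPE in percent.
#' @export
validate_mape <- function(modelled, observed) {
  if (length(modelled) != length(observed)) {
    stop("modelled and observed must have equal length")
  }
  if (any(observed == 0)) {
    stop("observed values contain 0: percentage error undefined")
  }
  mean(abs(modelled - observed) / abs(observed)) * 100
}
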