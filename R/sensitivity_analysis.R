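#' Model specification bundle for sensitivity analyses
#'
#' Collects everything one closed-cohort run needs, so that sensitivity
#' analyses can perturb inputs and re-run the model mechanically.
#'
#' @param schedules Per-subgroup `transition_schedule` list.
#' @param state_inputs State-input table from [derive_state_inputs()].
#' @param entrants Named entrants vector per subgroup.
#' @param horizon Cycles (default 10).
#' @param discount_rate Annual discount rate (default 0).
#' @return A `model_spec` list.
#' @export
model_spec <- function(schedules, state_inputs, entrants, horizon = 10,
                       discount_rate = 0) {
  structure(list(schedules = schedules, state_inputs = state_inputs,
                 entrants = entrants, horizon = horizon,
                 discount_rate = discount_rate),
            class = "model_spec")
}

#' @rdname model_spec
#' @param ms A `model_spec`.
#' @return `run_model_spec`: a `cohort_trace`.
#' @export
run_model_spec <- function(ms) {
  run_closed_cohort(ms$schedules, ms$state_inputs, ms$entrants,
                    horizon = ms$horizon, discount_rate = ms$discount_rate)
}

# default outcome selector: cumulative undiscounted costs
outcome_costs <- function(trace) {
  c(cost_allcause = sum(trace$outcomes$cost_allcause),
    cost_psychiatric = sum(trace$outcomes$cost_psychiatric))
}

# multiply the per-cycle probability of one edge in every schedule and
# re-complement the stay probability (rescaling proportionally if the
# perturbed row exceeds 1)
perturb_schedule_edge <- function(schedules, from, to, factor) {
  for (g in names(schedules)) {
    pr <- schedules[[g]]$prob
    for (t in seq_len(dim(pr)[1])) {
      row <- pr[t, from, ]
      row[to] <- row[to] * factor
      row[from] <- 0
      tot <- sum(row)
      if (tot > 1) row <- row / tot else row[from] <- 1 - tot
      pr[t, from, ] <- row
    }
    schedules[[g]]$prob <- pr
  }
  schedules
}

#' Default parameter registry for sensitivity analyses
#'
#' One entry per uncertain input: the number of entrants, the per-cycle
#' probabilities of the four transitions leaving the NTRD state, the two
#' cost scopes and the base state utilities.  Multiplicative parameters
#' (scales) have base 1; bounds default to a relative variation of
#' `rel` (20%), standing in for 95% confidence limits where none are
#' carried.  Assigned probabilistic distributions follow health-economic
#' convention: beta for utilities, gamma for cost scales and probability
#' scales, truncated normal for entrants.
#'
#' @param ms A [model_spec()].
#' @param rel Relative half-width of the bounds (default 0.20).
#' @return A `parameter_registry`: named list of entries with `id`, `base`,
#'   `lower`, `upper`, `dist` and an `apply(ms, value)` function.
#' @export
default_parameter_registry <- function(ms, rel = 0.20) {
  entries <- list()
  add <- function(id, base, lower, upper, dist, apply) {
    if (!(lower <= base && base <= upper)) {
      stop("registry bounds must satisfy lower <= base <= upper for ", id)
    }
    entries[[id]] <<- list(id = id, base = base, lower = lower,
                           upper = upper, dist = dist, apply = apply)
  }
  add("entrants", 1, 1 - rel, 1 + rel, list(family = "normal_pos"),
      function(ms, v) { ms$entrants <- ms$entrants * v; ms })
  for (to in c("TRD", "NTRD_comorbid", "low_intensity", "death")) {
    local({
      to_ <- to
      add(paste0("prob_NTRD_", to_), 1, 1 - rel, 1 + rel,
          list(family = "gamma"),
          function(ms, v) {
            ms$schedules <- perturb_schedule_edge(ms$schedules, "NTRD", to_, v)
            ms
          })
    })
  }
  add("cost_allcause", 1, 1 - rel, 1 + rel, list(family = "gamma"),
      function(ms, v) {
        ms$state_inputs$cost_allcause <- ms$state_inputs$cost_allcause * v
        ms
      })
  add("cost_psychiatric", 1, 1 - rel, 1 + rel, list(family = "gamma"),
      function(ms, v) {
        ms$state_inputs$cost_psychiatric <- ms$state_inputs$cost_psychiatric * v
        ms
      })
  for (st in c("NTRD", "TRD")) {
    local({
      st_ <- st
      u <- max(ms$state_inputs$utility[ms$state_inputs$state == st_])
      add(paste0("utility_", st_), u, max(0, u * (1 - rel)),
          min(1, u * (1 + rel)), list(family = "beta"),
          function(ms, v) {
            sel <- ms$state_inputs$state == st_
            selc <- ms$state_inputs$state == paste0(st_, "_comorbid")
            ratio <- v / ms$state_inputs$utility[sel][1]
            ms$state_inputs$utility[sel] <- v
            ms$state_inputs$utility[selc] <-
              ms$state_inputs$utility[selc] * ratio
            ms
          })
    })
  }
  structure(entries, class = "parameter_registry")
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the model with each parameter at its lower and upper bound in
#' turn, all other parameters at base, and reports the outcome swing per
#' parameter in tornado order (largest absolute swing first).
#'
#' @param registry A `parameter_registry`.
#' @param ms The base [model_spec()].
#' @param outcome Function `trace -> named numeric` of outcomes (default:
#'   cumulative all-cause and psychiatric cost).
#' @param runner Function `model_spec -> cohort_trace`.
#' @return Object of class `dsa_result`: data frame with, per parameter and
#'   outcome, the value at the lower and upper bound and the `swing`
#'   (upper minus lower), sorted by absolute swing of the first outcome.
#' @export
run_dsa <- function(registry, ms, outcome = outcome_costs,
                    runner = run_model_spec) {
  base_out <- outcome(runner(ms))
  rows <- lapply(registry, function(e) {
    lo <- outcome(runner(e$apply(ms, e$lower)))
    hi <- outcome(runner(e$apply(ms, e$upper)))
    data.frame(parameter = e$id, outcome = names(base_out),
               base = as.numeric(base_out), at_lower = as.numeric(lo),
               at_upper = as.numeric(hi),
               swing = as.numeric(hi) - as.numeric(lo),
               row.names = NULL)
  })
  res <- do.call(rbind, rows)
  first <- names(base_out)[1]
  # tornado order; near-ties (floating-point noise) fall back to registry order
  ord <- order(-signif(abs(res$swing[res$outcome == first]), 8))
  res$rank <- NA_integer_
  for (o in names(base_out)) {
    res$rank[res$outcome == o] <- match(seq_along(registry), ord)
  }
  res <- res[order(res$outcome != first, res$rank), ]
  rownames(res) <- NULL
  structure(res, class = c("dsa_result", "data.frame"))
}

# draw one value for a registry entry, moment-matched to (base, sd) where
# sd is implied by the bounds as a 95% interval
draw_parameter <- function(e) {
  m <- e$base
  s <- (e$upper - e$lower) / (2 * 1.96)
  if (s == 0 || identical(e$dist$family, "degenerate")) return(m)
  switch(e$dist$family,
    beta = {
      v <- m * (1 - m) / s^2 - 1
      if (v <= 0) stop("invalid beta hyperparameters for ", e$id,
                       ": variance too large for mean ", m)
      stats::rbeta(1, m * v, (1 - m) * v)
    },
    gamma = stats::rgamma(1, shape = m^2 / s^2, rate = m / s^2),
    normal_pos = {
      repeat {
        x <- stats::rnorm(1, m, s)
        if (x >= 0) return(x)
      }
    },
    stop("unknown distribution family '", e$dist$family, "' for ", e$id)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Samples all registry parameters jointly from their assigned
#' distributions, re-runs the model once per iteration, and summarises the
#' outcome distribution.  Identical seeds give identical results.
#'
#' @inheritParams run_dsa
#' @param n_iter Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `psa_result`: list with `draws` (sampled
#'   parameter values per iteration), `outcomes` (per iteration) and
#'   `summary` (mean and SD per outcome).
#' @export
run_psa <- function(registry, ms, n_iter = 1000, seed = 1L,
                    outcome = outcome_costs, runner = run_model_spec) {
  stopifnot(n_iter >= 1)
  set.seed(seed)
  draws <- matrix(NA_real_, n_iter, length(registry),
                  dimnames = list(NULL, names(registry)))
  outs <- NULL
  for (i in seq_len(n_iter)) {
    ms_i <- ms
    for (j in seq_along(registry)) {
      e <- registry[[j]]
      v <- draw_parameter(e)
      draws[i, j] <- v
      ms_i <- e$apply(ms_i, v)
    }
    o <- outcome(runner(ms_i))
    if (is.null(outs)) {
      outs <- matrix(NA_real_, n_iter, length(o),
                     dimnames = list(NULL, names(o)))
    }
    outs[i, ] <- o
  }
  summ <- data.frame(outcome = colnames(outs),
                     mean = colMeans(outs),
                     sd = apply(outs, 2, stats::sd),
                     row.names = NULL)
  structure(list(n_iter = n_iter, seed = seed,
                 draws = as.data.frame(draws),
                 outcomes = as.data.frame(outs), summary = summ),
            class = "psa_result")
}
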