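#' Accrue one cycle of outcomes for one subgroup
#'
#' State membership is measured at cycle start; a cycle contributes
#' `occupancy x annual cost` for the two cost scopes (absorbing states are
#' cost-free), one life-year per person alive (active states and the
#' low-intensity state), and `occupancy x utility` QALYs.  Attribution
#' splits restrict the sums to the TRD-family states (`TRD`,
#' `TRD_comorbid`) or the comorbid-family states (`NTRD_comorbid`,
#' `TRD_comorbid`).  Discounted values divide by `(1 + r)^(cycle - 1)`, so
#' the first cycle is undiscounted.
#'
#' @param occupancy Named numeric vector over [model_states()] (expected
#'   persons at cycle start).
#' @param inputs `state_inputs` rows for this subgroup (see
#'   [derive_state_inputs()]): columns `state`, `cost_allcause`,
#'   `cost_psychiatric`, `utility`.
#' @param cycle Cycle index (1-based).
#' @param discount_rate Annual discount rate (fraction, default 0).
#' @return One-row data frame of cycle outcomes.
#' @export
accrue_outcomes <- function(occupancy, inputs, cycle, discount_rate = 0) {
  states <- model_states()
  stopifnot(setequal(names(occupancy), states), discount_rate >= 0)
  if (any(occupancy < -1e-9)) stop("integrity error: negative occupancy")
  occupancy <- pmax(occupancy[states], 0)
  ii <- inputs[match(states, inputs$state), ]
  cost_ac <- occupancy * ii$cost_allcause
  cost_ps <- occupancy * ii$cost_psychiatric
  alive <- setdiff(states, "death")
  ly <- occupancy[alive]
  qaly <- occupancy * ii$utility
  trd <- trd_family_states()
  com <- comorbid_family_states()
  disc <- 1 / (1 + discount_rate)^(cycle - 1)
  data.frame(
    cycle = cycle,
    cost_allcause = sum(cost_ac), cost_psychiatric = sum(cost_ps),
    life_years = sum(ly), qalys = sum(qaly),
    cost_allcause_trd = sum(cost_ac[trd]),
    cost_psychiatric_trd = sum(cost_ps[trd]),
    life_years_trd = sum(occupancy[trd]), qalys_trd = sum(qaly[trd]),
    cost_allcause_comorbid = sum(cost_ac[com]),
    cost_psychiatric_comorbid = sum(cost_ps[com]),
    life_years_comorbid = sum(occupancy[com]), qalys_comorbid = sum(qaly[com]),
    cost_allcause_disc = sum(cost_ac) * disc,
    cost_psychiatric_disc = sum(cost_ps) * disc,
    qalys_disc = sum(qaly) * disc
  )
}

#' Run the closed-cohort Markov model
#'
#' Follows a single incident cohort (everyone starting in `NTRD`) for
#' `horizon` yearly cycles under per-subgroup, per-cycle transition
#' matrices.  Outcomes accrue on start-of-cycle occupancy; transitions
#' apply at cycle end.
#'
#' @param schedules Named list of `transition_schedule` objects per
#'   subgroup (see [build_schedules()]).
#' @param state_inputs Data frame from [derive_state_inputs()].
#' @param entrants Named numeric vector of cohort entrants per subgroup.
#' @param horizon Number of cycles (default 10).
#' @param discount_rate Annual discount rate (default 0; main results are
#'   undiscounted).
#' @return Object of class `cohort_trace`: list with `mode`, `occupancy`
#'   (start-of-cycle expected persons: `cycle`, `subgroup`, `state`,
#'   `occupancy`), `occupancy_end` (after the final transition), `outcomes`
#'   (per cycle and subgroup, including incident `deaths`), `entrants`,
#'   `horizon`, `discount_rate`.
#' @export
run_closed_cohort <- function(schedules, state_inputs, entrants,
                              horizon = 10, discount_rate = 0) {
  stopifnot(horizon >= 1, all(entrants >= 0))
  subgroups <- names(entrants)
  if (is.null(subgroups)) stop("entrants must be a named vector of subgroups")
  missing <- setdiff(subgroups, names(schedules))
  if (length(missing)) {
    stop("no transition schedule for subgroup(s): ",
         paste(missing, collapse = ", "))
  }
  missing_si <- setdiff(subgroups, unique(state_inputs$subgroup))
  if (length(missing_si)) {
    stop("no state inputs for subgroup(s): ", paste(missing_si, collapse = ", "))
  }
  states <- model_states()
  occ_rows <- list(); out_rows <- list(); end_rows <- list()
  for (g in subgroups) {
    sch <- schedules[[g]]
    if (sch$cycles < horizon) {
      stop("schedule for subgroup ", g, " covers ", sch$cycles,
           " cycles; horizon is ", horizon)
    }
    ii <- state_inputs[state_inputs$subgroup == g, ]
    occ <- stats::setNames(numeric(6), states)
    occ["NTRD"] <- entrants[[g]]
    for (t in seq_len(horizon)) {
      rec <- accrue_outcomes(occ, ii, t, discount_rate)
      occ_new <- stats::setNames(as.numeric(occ %*% sch$prob[t, , ]), states)
      rec$deaths <- occ_new["death"] - occ["death"]
      rec$subgroup <- g
      occ_rows[[length(occ_rows) + 1L]] <- data.frame(
        cycle = t, subgroup = g, state = states, occupancy = as.numeric(occ),
        row.names = NULL
      )
      out_rows[[length(out_rows) + 1L]] <- rec
      occ <- occ_new
    }
    end_rows[[length(end_rows) + 1L]] <- data.frame(
      cycle = horizon + 1L, subgroup = g, state = states,
      occupancy = as.numeric(occ), row.names = NULL
    )
  }
  structure(
    list(mode = "closed",
         occupancy = do.call(rbind, occ_rows),
         occupancy_end = do.call(rbind, end_rows),
         outcomes = do.call(rbind, out_rows),
         entrants = entrants, horizon = horizon,
         discount_rate = discount_rate),
    class = "cohort_trace"
  )
}

#' Run the open-cohort Markov model
#'
#' Introduces one incident cohort per calendar year of the incidence plan;
#' every cohort is simulated for at most `horizon` cycles, so calendar-year
#' outputs aggregate the cohorts diagnosed within the previous `horizon`
#' years (the prevalent cases).  A cohort entering year `Y` contributes its
#' first-cycle outcomes to calendar year `Y`.  Output equals the
#' superposition of independently run closed cohorts at the matching cycle
#' offsets.
#'
#' @param plan Incidence plan data frame with columns `year`, `subgroup`,
#'   `new_patients` (see [build_incidence_plan()]).
#' @param end_year Last simulated calendar year (default: the plan's last
#'   entry year, mirroring a projection that stops with the final incident
#'   cohort's first cycle; extend it to follow late cohorts to completion).
#' @inheritParams run_closed_cohort
#' @return A `cohort_trace` with `mode = "open"`; `occupancy` and
#'   `outcomes` are keyed by calendar `year` (plus per-cohort `cycle`
#'   aggregation already applied), and `entrants` is per calendar year and
#'   subgroup.
#' @export
run_open_cohort <- function(schedules, state_inputs, plan,
                            horizon = 10, discount_rate = 0,
                            end_year = NULL) {
  need <- c("year", "subgroup", "new_patients")
  stopifnot(all(need %in% names(plan)))
  years <- sort(unique(plan$year))
  if (!identical(years, seq(min(years), max(years)))) {
    gap <- setdiff(seq(min(years), max(years)), years)
    stop("incidence plan has a gap at year ", gap[1])
  }
  if (is.null(end_year)) end_year <- max(years)
  subgroups <- sort(unique(plan$subgroup))
  states <- model_states()
  cohorts <- list()   # per entry year: subgroup x state occupancy matrix
  occ_rows <- list(); out_rows <- list()
  for (y in seq(min(years), end_year)) {
    if (y %in% years) {
      newc <- matrix(0, length(subgroups), 6,
                     dimnames = list(subgroups, states))
      py <- plan[plan$year == y, ]
      newc[match(py$subgroup, subgroups), "NTRD"] <- py$new_patients
      cohorts[[as.character(y)]] <- newc
    }
    keep <- as.integer(names(cohorts)) > y - horizon
    cohorts <- cohorts[keep]
    # start-of-year prevalence and accrual, then one transition per cohort
    for (ey in names(cohorts)) {
      cyc <- y - as.integer(ey) + 1L
      occm <- cohorts[[ey]]
      for (g in subgroups) {
        occ <- stats::setNames(occm[g, ], states)
        if (sum(occ) == 0) next
        ii <- state_inputs[state_inputs$subgroup == g, ]
        rec <- accrue_outcomes(occ, ii, cyc, discount_rate)
        sch <- schedules[[g]]
        occ_new <- stats::setNames(as.numeric(occ %*% sch$prob[cyc, , ]), states)
        rec$deaths <- occ_new["death"] - occ["death"]
        rec$year <- y
        rec$subgroup <- g
        out_rows[[length(out_rows) + 1L]] <- rec
        occ_rows[[length(occ_rows) + 1L]] <- data.frame(
          year = y, subgroup = g, state = states, occupancy = as.numeric(occ),
          row.names = NULL
        )
        cohorts[[ey]][g, ] <- occ_new
      }
    }
  }
  occupancy <- do.call(rbind, occ_rows)
  occupancy <- stats::aggregate(occupancy ~ year + subgroup + state,
                                occupancy, sum)
  outcomes <- do.call(rbind, out_rows)
  num <- setdiff(names(outcomes), c("year", "subgroup", "cycle"))
  outcomes <- stats::aggregate(outcomes[num],
                               outcomes[c("year", "subgroup")], sum)
  entrants <- stats::aggregate(new_patients ~ year + subgroup, plan, sum)
  structure(
    list(mode = "open", occupancy = occupancy, occupancy_end = NULL,
         outcomes = outcomes, entrants = entrants, horizon = horizon,
         discount_rate = discount_rate),
    class = "cohort_trace"
  )
}

#' Compound annual growth rate
#'
#' `(v_last / v_first)^(1 / (n_cycles - 1)) - 1` for an annual output
#' series spanning `n_cycles` cycles.
#'
#' @param v_first,v_last First and last annual values.
#' @param n_cycles Number of cycles spanned.
#' @return The CAGR as a fraction.
#' @export
cagr <- function(v_first, v_last, n_cycles) {
  if (v_first == 0) stop("CAGR undefined: first value is 0")
  (v_last / v_first)^(1 / (n_cycles - 1)) - 1
}

#' Summarise a cohort trace
#'
#' Headline statistics of a completed run: cumulative costs (both scopes,
#' with TRD/comorbid attribution), cumulative deaths and case fatality,
#' life-years and QALYs, cost CAGRs over the annual series, and a
#' per-subgroup table of cumulative burden and per-patient-year burden
#' (cumulative burden divided by the subgroup's life-years).
#'
#' @param object A `cohort_trace`.
#' @param ... Unused.
#' @return List of class `burden_summary` with elements `totals`, `annual`,
#'   `by_subgroup`, `case_fatality`, `cagr_allcause`, `cagr_psychiatric`.
#' @export
summary.cohort_trace <- function(object, ...) {
  out <- object$outcomes
  key <- if (object$mode == "open") "year" else "cycle"
  num <- setdiff(names(out), c("cycle", "year", "subgroup"))
  annual <- stats::aggregate(out[num], out[key], sum)
  annual <- annual[order(annual[[key]]), ]
  totals <- colSums(out[num])
  entrants_total <- if (object$mode == "open") {
    sum(object$entrants$new_patients)
  } else {
    sum(object$entrants)
  }
  by_sub <- stats::aggregate(out[num], out["subgroup"], sum)
  by_sub$cost_allcause_per_py <- by_sub$cost_allcause / by_sub$life_years
  by_sub$cost_psychiatric_per_py <- by_sub$cost_psychiatric / by_sub$life_years
  by_sub$deaths_per_100py <- 100 * by_sub$deaths / by_sub$life_years
  n_ann <- nrow(annual)
  structure(
    list(
      mode = object$mode, totals = as.list(totals), annual = annual,
      by_subgroup = by_sub, entrants = entrants_total,
      cumulative_deaths = totals[["deaths"]],
      case_fatality = totals[["deaths"]] / entrants_total,
      cagr_allcause = cagr(annual$cost_allcause[1],
                           annual$cost_allcause[n_ann], n_ann),
      cagr_psychiatric = cagr(annual$cost_psychiatric[1],
                              annual$cost_psychiatric[n_ann], n_ann)
    ),
    class = "burden_summary"
  )
}

#' @rdname summary.cohort_trace
#' @param x A `burden_summary`.
#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("%s-cohort burden summary (%d entrants)\n",
              x$mode, round(x$entrants)))
  cat(sprintf("  cumulative all-cause cost:   US$%.1f million\n",
              x$totals$cost_allcause / 1e6))
  cat(sprintf("  cumulative psychiatric cost: US$%.1f million (%.0f%% share)\n",
              x$totals$cost_psychiatric / 1e6,
              100 * x$totals$cost_psychiatric / x$totals$cost_allcause))
  cat(sprintf("  deaths: %.0f (case fatality %.1f%%)\n",
              x$cumulative_deaths, 100 * x$case_fatality))
  cat(sprintf("  life-years: %.0f   QALYs: %.0f\n",
              x$totals$life_years, x$totals$qalys))
  cat(sprintf("  cost CAGR: all-cause %.1f%%, psychiatric %.1f%%\n",
              100 * x$cagr_allcause, 100 * x$cagr_psychiatric))
  invisible(x)
}

#' Internal validation of fitted schedules against the cohort
#'
#' Compares modelled cumulative deaths and low-intensity service users at a
#' given cycle with the observed counts in the (synthetic) cohort among
#' patients followed at least that long, and reports the mean absolute
#' percentage error.
#'
#' @param cohort A `depression_cohort`.
#' @param schedules Per-subgroup schedules to validate.
#' @param cycle Cycle at which to compare (default 4).
#' @return List with the comparison table and `mape`.
#' @export
validate_schedule_fit <- function(cohort, schedules, cycle = 4) {
  p <- cohort$patients
  keep <- p$censor_time >= cycle
  entry <- event_matrix(cohort)[keep, , drop = FALSE]
  obs <- c(
    deaths = sum(entry[, "death"] <= cycle),
    low_intensity = sum(entry[, "low_intensity"] <= cycle)
  )
  entrants <- table(factor(p$subgroup[keep], levels = names(schedules)))
  entrants <- stats::setNames(as.numeric(entrants), names(schedules))
  si <- neutral_state_inputs()
  tr <- run_closed_cohort(schedules, si, entrants, horizon = cycle)
  endo <- tr$occupancy_end
  mod <- c(
    deaths = sum(endo$occupancy[endo$state == "death"]),
    low_intensity = sum(endo$occupancy[endo$state == "low_intensity"])
  )
  tab <- data.frame(measure = names(obs), observed = as.numeric(obs),
                    modelled = as.numeric(mod))
  list(table = tab, mape = validate_mape(tab$modelled, tab$observed))
}

# zero-cost, unit-utility state inputs for runs that only need occupancy
neutral_state_inputs <- function() {
  tab <- expand.grid(state = model_states(),
                     subgroup = subgroup_table()$subgroup,
                     stringsAsFactors = FALSE)
  tab$cost_allcause <- 0
  tab$cost_psychiatric <- 0
  tab$utility <- ifelse(tab$state == "death", 0, 1)
  tab
}
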