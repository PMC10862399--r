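#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration of [generate_cohort()].  The
#' generator emulates the statistical structure of a territory-wide
#' electronic-medical-record extract of newly diagnosed depression: four age
#' bands crossed with sex and baseline medical history (16 subgroups),
#' cause-specific parametric event-time hazards with accelerated-failure-time
#' covariate effects, administrative censoring at the end of a calendar
#' year, and negative-binomially distributed annual service-use counts per
#' care setting, split into all-cause and psychiatric scopes.
#'
#' The default hazards are calibrated so that the crude annual probability
#' of developing TRD from the NTRD state declines over follow-up years 1-3
#' as roughly 6.2%, 4.4% and 3.0%, and the ten-year case fatality of the
#' simulated cohort is close to 9.8%.
#'
#' @param n_patients Number of patients to simulate.
#' @param subgroup_mix Named probability vector over the 16 subgroup ids of
#'   [subgroup_table()]; must sum to 1 (tolerance `1e-9`).
#' @param hazards Named list of per-edge hazard specifications, one per edge
#'   of [model_topology()]; each is a list with `family`, `pars` (natural
#'   scale) and `beta` (log time-acceleration factors: `age_band` vector of
#'   4, `male`, `history`).  See [default_hazards()].
#' @param service_model Service-use count model; see [default_service_model()].
#' @param diagnosis_years Calendar years of diagnosis to sample uniformly.
#' @param censor_year Administrative censoring at 31 December of this year.
#' @param max_followup Maximum follow-up in years.
#' @param include_comorbid_trd Include the `NTRD_comorbid -> TRD_comorbid`
#'   edge (off by default).
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 25190,
                             subgroup_mix = default_subgroup_mix(),
                             hazards = default_hazards(),
                             service_model = default_service_model(),
                             diagnosis_years = 2014:2016,
                             censor_year = 2020,
                             max_followup = 7,
                             include_comorbid_trd = FALSE,
                             seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1 ||
      n_patients != round(n_patients)) {
    stop("configuration error in 'n_patients': must be a positive integer")
  }
  ids <- subgroup_table()$subgroup
  if (!setequal(names(subgroup_mix), ids)) {
    stop("configuration error in 'subgroup_mix': must be named by the 16 subgroup ids")
  }
  subgroup_mix <- subgroup_mix[ids]
  if (any(subgroup_mix < 0) || abs(sum(subgroup_mix) - 1) > 1e-9) {
    stop("configuration error in 'subgroup_mix': probabilities must be >= 0 and sum to 1")
  }
  topo <- model_topology(include_comorbid_trd)
  missing <- setdiff(topo$edge, names(hazards))
  if (length(missing)) {
    stop("configuration error in 'hazards': missing edge(s) ",
         paste(missing, collapse = ", "))
  }
  for (e in topo$edge) {
    hz <- hazards[[e]]
    check_family_pars(hz$family, hz$pars)
    if (length(hz$beta$age_band) != 4L) {
      stop("configuration error in 'hazards': beta$age_band of ", e,
           " must have 4 elements")
    }
  }
  for (st in names(service_model$states)) {
    for (se in names(service_model$states[[st]])) {
      m <- service_model$states[[st]][[se]]
      if (m$mean_allcause < 0 || m$mean_psychiatric < 0 ||
          m$mean_psychiatric > m$mean_allcause) {
        stop("configuration error in 'service_model': require 0 <= psychiatric ",
             "mean <= all-cause mean for ", st, "/", se)
      }
      if (m$dispersion <= 0) {
        stop("configuration error in 'service_model': dispersion must be > 0 for ",
             st, "/", se)
      }
    }
  }
  if (max(diagnosis_years) > censor_year) {
    stop("configuration error in 'diagnosis_years': must not exceed censor_year")
  }
  structure(
    list(n_patients = as.integer(n_patients), subgroup_mix = subgroup_mix,
         hazards = hazards, service_model = service_model,
         diagnosis_years = as.integer(diagnosis_years),
         censor_year = as.integer(censor_year), max_followup = max_followup,
         include_comorbid_trd = include_comorbid_trd, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_subgroup_mix <- function() {
  # marginal shares of the reference incident cohort: age-band mix with a
  # 10.6% child/adolescent share, 74.8% women, 28.1% with baseline history
  p_age <- c("10-24" = 0.106, "25-40" = 0.200, "41-65" = 0.556, ">65" = 0.138)
  p_sex <- c(female = 0.748, male = 0.252)
  p_his <- c(nohx = 0.719, hx = 0.281)
  tab <- subgroup_table()
  mix <- p_age[tab$age_band] * p_sex[tab$sex] *
    ifelse(tab$baseline_history, p_his["hx"], p_his["nohx"])
  stats::setNames(as.numeric(mix), tab$subgroup)
}

#' @rdname generator_config
#' @export
default_hazards <- function() {
  # log time-acceleration factors shared per destination type; positive
  # values delay the event for that covariate level
  beta_trd <- list(age_band = c(0, -0.05, 0, 0.18), male = 0.10, history = -0.22)
  beta_com <- list(age_band = c(0.3, 0.15, 0, -0.5), male = -0.10, history = -0.5)
  beta_low <- list(age_band = c(0.1, 0.05, 0, -0.1), male = 0, history = 0.15)
  beta_dea <- list(age_band = c(1.5, 1.2, 0.6, -1.2), male = -0.25, history = -0.6)
  exp_edge <- function(rate, beta) {
    list(family = "exponential", pars = list(rate = rate), beta = beta)
  }
  list(
    # Gompertz with negative shape: near-geometric decline of the annual
    # TRD risk, calibrated to the 6.2/4.4/3.0% crude sequence
    "NTRD->TRD" = list(family = "gompertz",
                       pars = list(shape = -0.3539749, rate = 0.08020936),
                       beta = beta_trd),
    # Weibull shape < 1: early-peaking comorbidity onset
    "NTRD->NTRD_comorbid" = list(family = "weibull",
                                 pars = list(shape = 0.75,
                                             scale = 0.040^(-1 / 0.75)),
                                 beta = beta_com),
    "NTRD->low_intensity" = exp_edge(0.105, beta_low),
    "NTRD->death" = exp_edge(0.008, beta_dea),
    "TRD->TRD_comorbid" = exp_edge(0.100, beta_com),
    "TRD->low_intensity" = exp_edge(0.065, beta_low),
    "TRD->death" = exp_edge(0.013, beta_dea),
    "NTRD_comorbid->low_intensity" = exp_edge(0.080, beta_low),
    "NTRD_comorbid->death" = exp_edge(0.058, beta_dea),
    "NTRD_comorbid->TRD_comorbid" = exp_edge(0.030, beta_trd),
    "TRD_comorbid->low_intensity" = exp_edge(0.050, beta_low),
    "TRD_comorbid->death" = exp_edge(0.072, beta_dea)
  )
}

#' @rdname generator_config
#' @export
service_settings <- function() c("outpatient", "emergency", "inpatient")

#' @rdname generator_config
#' @export
default_service_model <- function() {
  # annual mean visit / attendance / bed-day counts per active state at the
  # reference covariate profile, all-cause and psychiatric scope
  st <- function(op_ac, op_ps, ed_ac, ed_ps, ip_ac, ip_ps, theta = 1.5) {
    list(
      outpatient = list(mean_allcause = op_ac, mean_psychiatric = op_ps, dispersion = theta),
      emergency = list(mean_allcause = ed_ac, mean_psychiatric = ed_ps, dispersion = theta),
      inpatient = list(mean_allcause = ip_ac, mean_psychiatric = ip_ps, dispersion = theta)
    )
  }
  list(
    states = list(
      NTRD = st(14, 3.0, 0.8, 0.12, 2.0, 0.30),
      TRD = st(20, 6.0, 1.0, 0.20, 3.5, 1.00),
      NTRD_comorbid = st(24, 4.0, 1.8, 0.25, 6.0, 0.80),
      TRD_comorbid = st(28, 7.0, 2.0, 0.40, 8.0, 1.50)
    ),
    # log multipliers on count means
    beta = list(age_band = c(-0.10, -0.05, 0, 0.45), male = 0.05, history = 0.35)
  )
}

# linear predictor of log acceleration / count multipliers for covariates
covariate_lp <- function(beta, age_band, sex, baseline_history) {
  idx <- match(age_band, age_bands())
  beta$age_band[idx] + (sex == "male") * beta$male +
    baseline_history * beta$history
}

#' Generate a synthetic patient-level cohort
#'
#' Simulates `n_patients` records by competing cause-specific event-time
#' draws: in each state, one event time is drawn per outgoing edge and the
#' earliest realised event (if before administrative censoring) determines
#' the next state.  Every patient starts in `NTRD` at diagnosis (time 0).
#' Annual service-use counts are drawn per patient-year in an active state,
#' with exposure equal to the fraction of the year spent before censoring or
#' entry into an absorbing state; psychiatric counts are a binomial thinning
#' of all-cause counts, so they are never larger and remain negative
#' binomial with the same dispersion.
#'
#' @param config A [generator_config()].
#' @return Object of class `depression_cohort`: a list with data frames
#'   `patients` (one row per patient), `events` (one row per state entry,
#'   including `NTRD` at time 0), `counts` (one row per patient-year at
#'   risk, with per-setting all-cause and psychiatric counts and the
#'   `exposure` fraction), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  tab <- subgroup_table()

  sg <- sample(names(config$subgroup_mix), n, replace = TRUE,
               prob = config$subgroup_mix)
  cov <- tab[match(sg, tab$subgroup), ]
  diag_year <- sample(config$diagnosis_years, n, replace = TRUE)
  diag_frac <- stats::runif(n)
  censor_time <- pmin(config$censor_year + 1 - (diag_year + diag_frac),
                      config$max_followup)

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    subgroup = sg, age_band = cov$age_band, sex = cov$sex,
    baseline_history = cov$baseline_history, diagnosis_year = diag_year,
    censor_time = censor_time, stringsAsFactors = FALSE
  )

  draw_edge <- function(edge, idx) {
    hz <- config$hazards[[edge]]
    accel <- exp(covariate_lp(hz$beta, patients$age_band[idx],
                              patients$sex[idx], patients$baseline_history[idx]))
    rsurvtime(length(idx), hz$family, hz$pars) * accel
  }

  # competing draws out of `from` for patients idx entering at `entry`;
  # returns realised next state ("" if censored first) and its entry time
  step_state <- function(from, idx, entry) {
    edges <- model_topology(config$include_comorbid_trd)
    out <- edges[edges$from == from, ]
    tm <- matrix(Inf, length(idx), nrow(out))
    for (j in seq_len(nrow(out))) tm[, j] <- draw_edge(out$edge[j], idx)
    jmin <- max.col(-tm, ties.method = "first")
    tmin <- tm[cbind(seq_along(idx), jmin)]
    abs_time <- entry + tmin
    realised <- abs_time <= censor_time[idx]
    list(state = ifelse(realised, out$to[jmin], ""),
         time = ifelse(realised, abs_time, Inf))
  }

  # entry times per state (Inf = never entered)
  entry <- matrix(Inf, n, 6, dimnames = list(NULL, model_states()))
  entry[, "NTRD"] <- 0
  s1 <- step_state("NTRD", seq_len(n), rep(0, n))
  for (stt in unique(s1$state)) {
    if (stt != "") entry[s1$state == stt, stt] <- s1$time[s1$state == stt]
  }
  in_trd <- which(is.finite(entry[, "TRD"]))
  if (length(in_trd)) {
    s2 <- step_state("TRD", in_trd, entry[in_trd, "TRD"])
    for (stt in unique(s2$state)) {
      if (stt != "") entry[in_trd[s2$state == stt], stt] <- s2$time[s2$state == stt]
    }
  }
  in_nc <- which(is.finite(entry[, "NTRD_comorbid"]))
  if (length(in_nc)) {
    s3 <- step_state("NTRD_comorbid", in_nc, entry[in_nc, "NTRD_comorbid"])
    for (stt in unique(s3$state)) {
      if (stt != "") entry[in_nc[s3$state == stt], stt] <- s3$time[s3$state == stt]
    }
  }
  in_tc <- which(is.finite(entry[, "TRD_comorbid"]))
  if (length(in_tc)) {
    s4 <- step_state("TRD_comorbid", in_tc, entry[in_tc, "TRD_comorbid"])
    for (stt in unique(s4$state)) {
      if (stt != "") entry[in_tc[s4$state == stt], stt] <- s4$time[s4$state == stt]
    }
  }

  ev <- data.frame(
    patient_id = rep(patients$patient_id, each = 6L),
    state = rep(model_states(), n),
    entry_time = as.numeric(t(entry)), stringsAsFactors = FALSE
  )
  events <- ev[is.finite(ev$entry_time), ]
  events <- events[order(events$patient_id, events$entry_time), ]
  rownames(events) <- NULL

  counts <- draw_service_counts(patients, entry, config)
  structure(list(patients = patients, events = events, counts = counts,
                 config = config),
            class = "depression_cohort")
}

draw_service_counts <- function(patients, entry, config) {
  n <- nrow(patients)
  t_abs <- pmin(entry[, "low_intensity"], entry[, "death"])
  end_active <- pmin(patients$censor_time, t_abs)
  n_years <- pmax(ceiling(end_active - 1e-12), 0L)

  idx <- rep(seq_len(n), n_years)
  year <- sequence(n_years)
  exposure <- pmin(year, end_active[idx]) - (year - 1)
  keep <- exposure > 1e-12
  idx <- idx[keep]; year <- year[keep]; exposure <- exposure[keep]

  st <- rep("NTRD", length(idx))
  for (s in c("TRD", "NTRD_comorbid", "TRD_comorbid")) {
    st[entry[idx, s] <= (year - 1)] <- s
  }

  sm <- config$service_model
  mult <- exp(covariate_lp(sm$beta, patients$age_band[idx], patients$sex[idx],
                           patients$baseline_history[idx]))
  out <- data.frame(
    patient_id = patients$patient_id[idx], year = year, state = st,
    exposure = exposure, stringsAsFactors = FALSE
  )
  for (se in service_settings()) {
    m_ac <- vapply(st, function(s) sm$states[[s]][[se]]$mean_allcause, 0)
    m_ps <- vapply(st, function(s) sm$states[[s]][[se]]$mean_psychiatric, 0)
    theta <- vapply(st, function(s) sm$states[[s]][[se]]$dispersion, 0)
    mu <- m_ac * mult * exposure
    ac <- stats::rnbinom(length(idx), size = theta, mu = mu)
    ps <- stats::rbinom(length(idx), size = ac,
                        prob = ifelse(m_ac > 0, m_ps / m_ac, 0))
    out[[paste0(se, "_allcause")]] <- ac
    out[[paste0(se, "_psychiatric")]] <- ps
  }
  rownames(out) <- NULL
  out
}

#' Crude annual transition probabilities from a cohort
#'
#' Empirical annual probabilities of moving from `from` to `to`: among
#' patients occupying `from` at the start of follow-up year `t` whose
#' censoring time covers the full year, the fraction entering `to` during
#' that year.
#'
#' @param cohort A `depression_cohort`.
#' @param from,to State names.
#' @param years Follow-up years to evaluate.
#' @return Named numeric vector of probabilities.
#' @export
crude_transition_probs <- function(cohort, from = "NTRD", to = "TRD",
                                   years = 1:3) {
  entry <- event_matrix(cohort)
  exit_from <- exit_time_from(entry, from)
  out <- numeric(length(years))
  for (i in seq_along(years)) {
    t <- years[i]
    at_risk <- entry[, from] <= (t - 1) & exit_from > (t - 1) &
      cohort$patients$censor_time >= t
    event <- at_risk & entry[, to] > (t - 1) & entry[, to] <= t
    if (!any(at_risk)) stop("no patients at risk in ", from, " at year ", t)
    out[i] <- sum(event) / sum(at_risk)
  }
  stats::setNames(out, paste0("year", years))
}

# entry-time matrix (patients x states, Inf = never) from the events table
event_matrix <- function(cohort) {
  p <- cohort$patients
  m <- matrix(Inf, nrow(p), 6, dimnames = list(p$patient_id, model_states()))
  ev <- cohort$events
  m[cbind(match(ev$patient_id, p$patient_id), match(ev$state, model_states()))] <-
    ev$entry_time
  m
}

# time of first departure from `from` (Inf if never observed to leave)
exit_time_from <- function(entry, from) {
  succ <- model_topology(TRUE)
  succ <- succ$to[succ$from == from]
  ex <- rep(Inf, nrow(entry))
  for (s in succ) ex <- pmin(ex, ifelse(entry[, s] > entry[, from],
                                        entry[, s], Inf))
  ex
}
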