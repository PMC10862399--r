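#' Packaged incidence and population tables
#'
#' Small plain-text fixtures standing in for the official inputs: mean
#' age-specific annual incidence of diagnosed depression per five-year age
#' group (assumed constant over the projection), government population
#' projections per five-year age group for 2014-2032, observed annual
#' numbers of newly diagnosed patients 2014-2018, and the pandemic uplift
#' profile.  The population table is reverse-engineered so that the 2023
#' baseline projection equals 9,147 new patients (15.0 per 10,000
#' population aged 10+) and is labelled synthetic.
#'
#' @return Data frames (or a list, for the uplift profile).
#' @export
default_incidence_rates <- function() {
  utils::read.csv(system.file("extdata", "incidence_rates.csv",
                              package = "depburden", mustWork = TRUE))
}

#' @rdname default_incidence_rates
#' @export
default_population_projection <- function() {
  utils::read.csv(system.file("extdata", "population_projection.csv",
                              package = "depburden", mustWork = TRUE))
}

#' @rdname default_incidence_rates
#' @export
default_observed_new_patients <- function() {
  utils::read.csv(system.file("extdata", "observed_new_patients.csv",
                              package = "depburden", mustWork = TRUE))
}

#' @rdname default_incidence_rates
#' @export
default_pandemic_uplift <- function() {
  jsonlite::read_json(system.file("extdata", "pandemic_uplift.json",
                                  package = "depburden", mustWork = TRUE),
                      simplifyVector = TRUE)
}

# five-year age group -> model age band
age_group_band <- function(age_group) {
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", age_group)))
  if (any(is.na(lower))) stop("unrecognised age group: ",
                              age_group[is.na(lower)][1])
  cut(lower, breaks = c(9, 24, 39, 64, Inf), labels = age_bands())
}

# sex/history mix conditional on age band, from a subgroup mix
conditional_sex_history_mix <- function(subgroup_mix = default_subgroup_mix()) {
  tab <- subgroup_table()
  tab$p <- subgroup_mix[tab$subgroup]
  split_p <- split(tab, tab$age_band)
  lapply(split_p, function(d) {
    stats::setNames(d$p / sum(d$p), d$subgroup)
  })
}

#' Project new patients for one year
#'
#' Expected number of newly diagnosed patients: the sum over five-year age
#' groups of the mean age-specific incidence rate times the projected
#' population, apportioned to the 16 subgroups using the age distribution
#' implied by the projection and the reference cohort's sex and
#' medical-history mix within each age band.
#'
#' @param year Calendar year.
#' @param rates Incidence table (`age_group`, `rate_per_10000`).
#' @param population Population projection (`year`, `age_group`,
#'   `population`).
#' @param subgroup_mix Reference subgroup mix supplying the sex/history
#'   split within age bands (default [default_subgroup_mix()]).  When
#'   `apportion = "mix"` the full 16-way mix replaces the population-based
#'   age distribution (the demographic-shift check).
#' @param apportion `"population"` (default) or `"mix"`.
#' @return Data frame `subgroup`, `new_patients`; the total is the sum.
#' @export
project_new_patients <- function(year, rates = default_incidence_rates(),
                                 population = default_population_projection(),
                                 subgroup_mix = default_subgroup_mix(),
                                 apportion = c("population", "mix")) {
  apportion <- match.arg(apportion)
  pop <- population[population$year == year, ]
  if (!nrow(pop)) stop("no population projection for year ", year)
  missing <- setdiff(rates$age_group, pop$age_group)
  if (length(missing)) {
    stop("missing population for age group ", missing[1], " in year ", year)
  }
  m <- merge(rates, pop, by = "age_group")
  m$count <- m$rate_per_10000 / 1e4 * m$population
  total <- sum(m$count)
  tab <- subgroup_table()
  if (apportion == "mix") {
    p <- subgroup_mix[tab$subgroup] / sum(subgroup_mix)
    out <- data.frame(subgroup = tab$subgroup,
                      new_patients = total * as.numeric(p))
  } else {
    m$band <- age_group_band(m$age_group)
    band_tot <- tapply(m$count, m$band, sum)
    shmix <- conditional_sex_history_mix(subgroup_mix)
    rows <- lapply(age_bands(), function(b) {
      p <- shmix[[b]]
      data.frame(subgroup = names(p),
                 new_patients = as.numeric(band_tot[[b]] * p))
    })
    out <- do.call(rbind, rows)
  }
  out$year <- year
  rownames(out) <- NULL
  out[, c("year", "subgroup", "new_patients")]
}

#' Build an incidence plan
#'
#' Annual numbers of newly diagnosed patients per subgroup.  In closed
#' mode the plan holds the single 2023 entry cohort; in open mode it covers
#' the 19 entry years 2014-2032, using recorded annual counts for
#' 2014-2018 (apportioned by the reference mix) and the constant-incidence
#' projection thereafter.  The pandemic scenario applies
#' [apply_pandemic_uplift()].
#'
#' @param mode `"closed"` or `"open"`.
#' @param scenario `"baseline"` or `"pandemic"`.
#' @param uplift_profile `"age_specific"` (default) or `"uniform"` 2023
#'   uplift.
#' @inheritParams project_new_patients
#' @param observed Observed 2014-2018 totals (`year`, `new_patients`).
#' @param uplift Pandemic uplift configuration
#'   (default [default_pandemic_uplift()]).
#' @return Plan data frame: `year`, `subgroup`, `new_patients`, `source`
#'   (`"observed"`/`"projected"`), `scenario`.
#' @export
build_incidence_plan <- function(mode = c("closed", "open"),
                                 scenario = c("baseline", "pandemic"),
                                 uplift_profile = c("age_specific", "uniform"),
                                 rates = default_incidence_rates(),
                                 population = default_population_projection(),
                                 observed = default_observed_new_patients(),
                                 subgroup_mix = default_subgroup_mix(),
                                 uplift = default_pandemic_uplift()) {
  mode <- match.arg(mode)
  scenario <- match.arg(scenario)
  uplift_profile <- match.arg(uplift_profile)
  years <- if (mode == "closed") 2023L else 2014:2032
  rows <- lapply(years, function(y) {
    if (y %in% observed$year) {
      tot <- observed$new_patients[observed$year == y]
      tab <- subgroup_table()
      p <- subgroup_mix[tab$subgroup] / sum(subgroup_mix)
      d <- data.frame(year = y, subgroup = tab$subgroup,
                      new_patients = tot * as.numeric(p))
      d$source <- "observed"
    } else {
      d <- project_new_patients(y, rates, population, subgroup_mix)
      d$source <- "projected"
    }
    d
  })
  plan <- do.call(rbind, rows)
  plan$scenario <- "baseline"
  if (scenario == "pandemic") {
    plan <- apply_pandemic_uplift(plan, "pandemic", mode, uplift_profile,
                                  uplift)
  }
  rownames(plan) <- NULL
  plan
}

#' Apply the pandemic incidence uplift to a plan
#'
#' In the closed-cohort pandemic scenario only the 2023 entrants are
#' scaled: uniformly by +25%, or by the age-band-specific profile (whose
#' mixture over the baseline age distribution reproduces 11,397 entrants).
#' In the open-cohort pandemic scenario, 2019-2022 entrants are scaled by
#' +33% (social unrest and pandemic years) and 2023 as in closed mode;
#' other years are unchanged.
#'
#' @param plan A plan from [build_incidence_plan()].
#' @param scenario `"baseline"` (identity) or `"pandemic"`.
#' @param mode `"closed"` or `"open"`.
#' @param uplift_profile `"age_specific"` or `"uniform"` for 2023.
#' @param uplift Uplift configuration list.
#' @return The modified plan.
#' @export
apply_pandemic_uplift <- function(plan, scenario, mode = c("closed", "open"),
                                  uplift_profile = c("age_specific", "uniform"),
                                  uplift = default_pandemic_uplift()) {
  mode <- match.arg(mode)
  uplift_profile <- match.arg(uplift_profile)
  if (identical(scenario, "baseline")) return(plan)
  if (!identical(scenario, "pandemic")) {
    stop("unknown scenario label: ", scenario)
  }
  f2023 <- if (uplift_profile == "uniform") {
    stats::setNames(rep(uplift$uniform_2023, 4), age_bands())
  } else {
    unlist(uplift$age_specific_2023)[age_bands()]
  }
  band <- parse_subgroup(plan$subgroup)$age_band
  is23 <- plan$year == 2023
  plan$new_patients[is23] <- plan$new_patients[is23] * f2023[band[is23]]
  if (mode == "open") {
    isp <- plan$year %in% 2019:2022
    plan$new_patients[isp] <- plan$new_patients[isp] * uplift$open_2019_2022
  }
  plan$scenario <- "pandemic"
  plan
}

#' @rdname project_new_patients
#' @export
reference_mix_2018 <- function() {
  # demographic-shift check: the child/adolescent share rises to 17.0%
  p_age <- c("10-24" = 0.170, "25-40" = 0.208, "41-65" = 0.505, ">65" = 0.117)
  p_sex <- c(female = 0.748, male = 0.252)
  p_his <- c(nohx = 0.719, hx = 0.281)
  tab <- subgroup_table()
  mix <- p_age[tab$age_band] * p_sex[tab$sex] *
    ifelse(tab$baseline_history, p_his["hx"], p_his["nohx"])
  stats::setNames(as.numeric(mix), tab$subgroup)
}
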