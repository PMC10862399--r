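#' Unit costs and utility tables
#'
#' `default_unit_costs()` reads the packaged unit-cost table (2023 US$ per
#' outpatient visit, emergency attendance and inpatient bed-day, converted
#' at 7.85 Hong Kong dollars per US dollar); `read_unit_costs()` reads a
#' user-supplied JSON file of the same shape.  `default_utilities()` reads
#' the packaged state utility weights; these are synthetic placeholder
#' values, not literature estimates, and real values can be slotted in via
#' `read_utilities()`.
#'
#' @param path Path to a JSON file.
#' @return `*_unit_costs`: named numeric vector over
#'   [service_settings()].  `*_utilities`: list with `NTRD`, `TRD`,
#'   `low_intensity` base utilities and the `comorbid_decrement`.
#' @export
read_unit_costs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  uc <- unlist(x[service_settings()])
  if (any(is.na(uc)) || any(uc <= 0)) {
    stop("unit costs must be positive for all of: ",
         paste(service_settings(), collapse = ", "))
  }
  uc
}

#' @rdname read_unit_costs
#' @export
default_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.json",
                              package = "depburden", mustWork = TRUE))
}

#' @rdname read_unit_costs
#' @export
read_utilities <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("NTRD", "TRD", "low_intensity", "comorbid_decrement")) {
    if (is.null(x[[f]])) stop("utilities file is missing field '", f, "'")
  }
  x
}

#' @rdname read_unit_costs
#' @export
default_utilities <- function() {
  read_utilities(system.file("extdata", "utilities.json",
                             package = "depburden", mustWork = TRUE))
}

#' Expand base utilities into the full state utility set
#'
#' Comorbid-state utilities carry a fixed relative decrement (default 17%)
#' against the corresponding non-comorbid state, so
#' `u(NTRD_comorbid) = (1 - decrement) * u(NTRD)` and likewise for TRD.
#' Death has utility 0; the low-intensity utility is taken as supplied.
#'
#' @param base Named list or vector with `NTRD`, `TRD` and `low_intensity`
#'   utilities, each in `(0, 1]`.
#' @param decrement Relative comorbidity decrement in `[0, 1)`.
#' @return Named numeric vector of utilities over [model_states()].
#' @export
apply_utility_decrement <- function(base, decrement = 0.17) {
  if (!is.numeric(decrement) || length(decrement) != 1L ||
      decrement < 0 || decrement >= 1) {
    stop("configuration error: decrement must be in [0, 1)")
  }
  for (f in c("NTRD", "TRD", "low_intensity")) {
    u <- base[[f]]
    if (is.null(u) || u <= 0 || u > 1) {
      stop("configuration error: base utility '", f, "' must be in (0, 1]")
    }
  }
  c(NTRD = base[["NTRD"]], TRD = base[["TRD"]],
    NTRD_comorbid = (1 - decrement) * base[["NTRD"]],
    TRD_comorbid = (1 - decrement) * base[["TRD"]],
    low_intensity = base[["low_intensity"]], death = 0)
}

#' Negative-binomial service-use count model
#'
#' Fits an annual service-use count model for one care setting and scope
#' (all-cause or psychiatric) on patient-year data, adjusted for age band,
#' sex, baseline medical history and the TRD / comorbidity onset status
#' implied by the state occupied in that year, with the fraction of the
#' year at risk as exposure offset.  The negative-binomial variance
#' follows `mu + mu^2 / theta`.
#'
#' @param cohort A `depression_cohort` (its `counts` and `patients` tables
#'   are joined), or a prejoined patient-year data frame with columns
#'   `age_band`, `sex`, `baseline_history`, `state`, `exposure` and the
#'   count column.
#' @param setting One of [service_settings()].
#' @param scope `"allcause"` or `"psychiatric"`.
#' @return Object of class `nb_count_fit` wrapping the `glm.nb` model.
#' @export
fit_nb_count_model <- function(cohort, setting = service_settings(),
                               scope = c("allcause", "psychiatric")) {
  setting <- match.arg(setting)
  scope <- match.arg(scope)
  dat <- if (inherits(cohort, "depression_cohort")) {
    count_model_frame(cohort)
  } else {
    cohort
  }
  ycol <- paste0(setting, "_", scope)
  if (!ycol %in% names(dat)) stop("no count column '", ycol, "' in data")
  dat$y <- dat[[ycol]]
  if (all(dat$y == 0)) {
    stop("degenerate fit: all ", ycol, " counts are zero; ",
         "use a zero-cost override for this setting")
  }
  dat$trd <- dat$state %in% trd_family_states()
  dat$comorbid <- dat$state %in% comorbid_family_states()
  # keep only covariates that vary in the data (stratified inputs may hold
  # some of them fixed)
  terms <- c("age_band", "sex", "baseline_history", "trd", "comorbid")
  terms <- terms[vapply(terms, function(v) {
    length(unique(dat[[v]])) >= 2L
  }, TRUE)]
  rhs <- paste(c(terms, "offset(log(exposure))"), collapse = " + ")
  model <- suppressWarnings(MASS::glm.nb(
    stats::as.formula(paste("y ~", if (length(terms)) rhs else
      "1 + offset(log(exposure))")),
    data = dat
  ))
  if (!model$converged) {
    stop("negative-binomial fit for ", ycol, " did not converge after ",
         model$iter, " iterations")
  }
  structure(list(model = model, setting = setting, scope = scope),
            class = "nb_count_fit")
}

# patient-year frame: counts joined to covariates
count_model_frame <- function(cohort) {
  m <- merge(cohort$counts,
             cohort$patients[c("patient_id", "age_band", "sex",
                               "baseline_history")],
             by = "patient_id")
  m$age_band <- factor(m$age_band, levels = age_bands())
  m$sex <- factor(m$sex, levels = sexes())
  m
}

#' Predicted annual mean count per state and subgroup
#'
#' Evaluates a fitted count model at the indicator profile of a state
#' (TRD on/off, comorbidity on/off) and subgroup, with one full year of
#' exposure.
#'
#' @param fit An `nb_count_fit`.
#' @param state An active model state.
#' @param subgroup Subgroup id.
#' @return Predicted mean annual count.
#' @export
predict_state_count <- function(fit, state, subgroup) {
  stopifnot(inherits(fit, "nb_count_fit"))
  state <- match.arg(state, active_states())
  prof <- parse_subgroup(subgroup)
  nd <- data.frame(
    age_band = factor(prof$age_band, levels = age_bands()),
    sex = factor(prof$sex, levels = sexes()),
    baseline_history = prof$baseline_history,
    trd = state %in% trd_family_states(),
    comorbid = state %in% comorbid_family_states(),
    exposure = 1
  )
  as.numeric(stats::predict(fit$model, newdata = nd, type = "response"))
}

#' Combine predicted counts with unit costs
#'
#' Annual cost is the sum over care settings of predicted mean count times
#' the setting's unit cost.
#'
#' @param counts Named numeric vector of mean annual counts per setting.
#' @param unit_costs Named numeric vector of unit costs per setting.
#' @return Annual cost (same currency as `unit_costs`).
#' @export
counts_to_costs <- function(counts, unit_costs) {
  missing <- setdiff(service_settings(), names(counts))
  if (length(missing)) {
    stop("missing count prediction for setting(s): ",
         paste(missing, collapse = ", "))
  }
  sum(counts[service_settings()] * unit_costs[service_settings()])
}

#' Derive per-state, per-subgroup annual costs and utilities
#'
#' Fits one negative-binomial count model per care setting and scope on
#' the cohort's patient-year data, predicts mean annual counts at every
#' active state x subgroup profile, prices them with the unit-cost table,
#' and attaches state utilities.  The low-intensity and death states carry
#' zero cost in both scopes (their care is not depression-related by
#' definition).
#'
#' @param cohort A `depression_cohort`.
#' @param unit_costs Named unit-cost vector (default
#'   [default_unit_costs()]).
#' @param utilities Utility configuration (default [default_utilities()]).
#' @return Data frame `state_inputs` with columns `state`, `subgroup`,
#'   `cost_allcause`, `cost_psychiatric`, `utility`.
#' @export
derive_state_inputs <- function(cohort, unit_costs = default_unit_costs(),
                                utilities = default_utilities()) {
  dat <- count_model_frame(cohort)
  fits <- list()
  for (se in service_settings()) {
    for (sc in c("allcause", "psychiatric")) {
      fits[[paste0(se, "_", sc)]] <- fit_nb_count_model(dat, se, sc)
    }
  }
  u <- apply_utility_decrement(utilities, utilities$comorbid_decrement)
  grid <- expand.grid(state = model_states(),
                      subgroup = subgroup_table()$subgroup,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cost_allcause <- 0
  grid$cost_psychiatric <- 0
  grid$utility <- u[grid$state]
  for (i in which(grid$state %in% active_states())) {
    for (sc in c("allcause", "psychiatric")) {
      counts <- vapply(service_settings(), function(se) {
        predict_state_count(fits[[paste0(se, "_", sc)]],
                            grid$state[i], grid$subgroup[i])
      }, 0)
      grid[[paste0("cost_", sc)]][i] <- counts_to_costs(counts, unit_costs)
    }
  }
  grid
}
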