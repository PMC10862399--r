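#' Parametric time-to-event families
#'
#' The five survival families used throughout the package, in the fixed
#' order that also breaks information-criterion ties:
#' exponential, Weibull, lognormal, log-logistic, Gompertz.
#'
#' @return Character vector of family names.
#' @export
survival_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz")
}

# parameter names on the natural scale, per family
family_par_names <- function(family) {
  switch(match.arg(family, survival_families()),
    exponential = "rate",
    weibull = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    loglogistic = c("shape", "scale"),
    gompertz = c("shape", "rate")
  )
}

check_family_pars <- function(family, pars) {
  need <- family_par_names(family)
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    stop("family '", family, "' requires parameter(s): ",
         paste(missing, collapse = ", "))
  }
  positive <- setdiff(need, c("meanlog", "shape"[family == "gompertz"]))
  for (p in positive) {
    if (!is.finite(pars[[p]]) || pars[[p]] <= 0) {
      stop("parameter '", p, "' of family '", family, "' must be positive")
    }
  }
  invisible(pars)
}

#' Cumulative hazard, hazard, survival and random draws for a family
#'
#' Closed-form evaluation of H(t), h(t) and S(t) = exp(-H(t)), and event-time
#' sampling, for one of the five supported families.  `accel` is a time
#' acceleration factor: the event time is multiplied by `accel`, i.e.
#' S(t) = S0(t / accel), the accelerated-failure-time convention used for
#' covariate effects.
#'
#' @param family One of [survival_families()].
#' @param pars Named list of natural-scale parameters (`rate`; `shape`,
#'   `scale`; `meanlog`, `sdlog`; `shape`, `rate` for Gompertz).
#' @param t Time points (years), non-negative.
#' @param n Number of random draws.
#' @param accel Positive time acceleration factor (default 1).
#' @return `cum_hazard`/`hazard`/`survival`: numeric vector along `t`;
#'   `rsurvtime`: `n` event times (possibly `Inf` for defective
#'   distributions such as Gompertz with negative shape).
#' @export
cum_hazard <- function(family, pars, t, accel = 1) {
  check_family_pars(family, pars)
  stopifnot(accel > 0, all(t >= 0))
  u <- t / accel
  switch(family,
    exponential = pars$rate * u,
    weibull = (u / pars$scale)^pars$shape,
    lognormal = -stats::plnorm(u, pars$meanlog, pars$sdlog,
                               lower.tail = FALSE, log.p = TRUE),
    loglogistic = log1p((u / pars$scale)^pars$shape),
    gompertz = flexsurv::Hgompertz(u, shape = pars$shape, rate = pars$rate)
  )
}

#' @rdname cum_hazard
#' @export
hazard <- function(family, pars, t, accel = 1) {
  check_family_pars(family, pars)
  stopifnot(accel > 0)
  u <- t / accel
  h <- switch(family,
    exponential = rep_len(pars$rate, length(u)),
    weibull = flexsurv::hweibull(u, pars$shape, pars$scale),
    lognormal = flexsurv::hlnorm(u, pars$meanlog, pars$sdlog),
    loglogistic = flexsurv::hllogis(u, shape = pars$shape, scale = pars$scale),
    gompertz = flexsurv::hgompertz(u, shape = pars$shape, rate = pars$rate)
  )
  h / accel
}

#' @rdname cum_hazard
#' @export
survival_at <- function(family, pars, t, accel = 1) {
  exp(-cum_hazard(family, pars, t, accel = accel))
}

#' @rdname cum_hazard
#' @export
rsurvtime <- function(n, family, pars, accel = 1) {
  check_family_pars(family, pars)
  stopifnot(accel > 0)
  x <- switch(family,
    exponential = stats::rexp(n, pars$rate),
    weibull = stats::rweibull(n, pars$shape, pars$scale),
    lognormal = stats::rlnorm(n, pars$meanlog, pars$sdlog),
    loglogistic = flexsurv::rllogis(n, shape = pars$shape, scale = pars$scale),
    gompertz = flexsurv::rgompertz(n, shape = pars$shape, rate = pars$rate)
  )
  x * accel
}
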