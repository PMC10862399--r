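#' Health states of the depression burden model
#'
#' The model tracks six mutually exclusive health states: non-treatment-
#' resistant depression (`NTRD`, the initial state for every newly diagnosed
#' patient), treatment-resistant depression (`TRD`), new-onset comorbidity
#' states entered before (`NTRD_comorbid`) or after (`TRD_comorbid`) TRD
#' onset, and two absorbing states: `low_intensity` (a low-intensity service
#' user, the model's proxy for recovery) and all-cause `death`.
#'
#' @return Character vector of the six state names, in canonical order.
#' @export
model_states <- function() {
  c("NTRD", "TRD", "NTRD_comorbid", "TRD_comorbid", "low_intensity", "death")
}

#' @rdname model_states
#' @export
absorbing_states <- function() c("low_intensity", "death")

#' @rdname model_states
#' @export
active_states <- function() c("NTRD", "TRD", "NTRD_comorbid", "TRD_comorbid")

# states counted as "TRD states" / "comorbid states" in attribution splits
trd_family_states <- function() c("TRD", "TRD_comorbid")
comorbid_family_states <- function() c("NTRD_comorbid", "TRD_comorbid")

#' Permitted transitions of the model
#'
#' Directed edges of the state-transition diagram.  All patients start in
#' `NTRD`; comorbidity states are split before/after TRD onset so that the
#' memoryless cohort model can carry different transition intensities per
#' disease stage.  The `NTRD_comorbid -> TRD_comorbid` edge (TRD onset after
#' a pre-TRD comorbidity) is optional and excluded by default.
#'
#' @param include_comorbid_trd Logical; include the
#'   `NTRD_comorbid -> TRD_comorbid` edge.
#' @return Data frame with columns `from` and `to`.
#' @export
model_topology <- function(include_comorbid_trd = FALSE) {
  edges <- rbind(
    data.frame(from = "NTRD", to = c("TRD", "NTRD_comorbid", "low_intensity", "death")),
    data.frame(from = "TRD", to = c("TRD_comorbid", "low_intensity", "death")),
    data.frame(from = "NTRD_comorbid", to = c("low_intensity", "death")),
    data.frame(from = "TRD_comorbid", to = c("low_intensity", "death"))
  )
  if (include_comorbid_trd) {
    edges <- rbind(edges, data.frame(from = "NTRD_comorbid", to = "TRD_comorbid"))
  }
  edges$edge <- paste(edges$from, edges$to, sep = "->")
  edges
}

#' Patient subgroups
#'
#' Outcomes are stratified into 16 subgroups formed by four age bands at
#' diagnosis (10-24, 25-40, 41-65, >65 years), sex, and presence of baseline
#' medical history.
#'
#' @return Data frame with one row per subgroup: `subgroup` (identifier),
#'   `age_band`, `sex`, `baseline_history`.
#' @export
subgroup_table <- function() {
  g <- expand.grid(
    age_band = age_bands(), sex = sexes(), baseline_history = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$subgroup <- subgroup_id(g$age_band, g$sex, g$baseline_history)
  g[, c("subgroup", "age_band", "sex", "baseline_history")]
}

#' @rdname subgroup_table
#' @export
age_bands <- function() c("10-24", "25-40", "41-65", ">65")

#' @rdname subgroup_table
#' @export
sexes <- function() c("female", "male")

#' @rdname subgroup_table
#' @param age_band,sex,baseline_history Vectors of covariate values.
#' @export
subgroup_id <- function(age_band, sex, baseline_history) {
  stopifnot(all(age_band %in% age_bands()), all(sex %in% sexes()))
  paste(age_band, sex, ifelse(baseline_history, "hx", "nohx"), sep = "|")
}

# split "41-65|female|nohx" back into covariates
parse_subgroup <- function(subgroup) {
  parts <- strsplit(subgroup, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) stop("malformed subgroup id: ", subgroup[bad][1])
  data.frame(
    subgroup = subgroup,
    age_band = vapply(parts, `[`, "", 1L),
    sex = vapply(parts, `[`, "", 2L),
    baseline_history = vapply(parts, `[`, "", 3L) == "hx",
    stringsAsFactors = FALSE
  )
}
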