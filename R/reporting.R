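#' Published reference projection figures
#'
#' Headline estimates reported by the published Hong Kong depression burden
#' projection (cumulative costs, deaths, life-years, QALYs, entrant
#' counts), packaged as benchmark inputs for the derived-ratio checks.
#'
#' @return Nested list of reference values.
#' @export
reference_projections <- function() {
  jsonlite::read_json(system.file("extdata", "reference_projections.json",
                                  package = "depburden", mustWork = TRUE),
                      simplifyVector = TRUE)
}

#' Derived burden ratios
#'
#' Ratios fully determined by a set of headline figures: the case fatality
#' rate (cumulative deaths over entrants), the psychiatric share of
#' all-cause cost, quality-of-life reductions per attribution group
#' (`(1 - QALY/LY) x 100`), and the pandemic entrant fold (pandemic over
#' baseline entrants).  Each ratio is returned raw and at the reporting
#' rounding (one decimal for percentages, two decimals for folds).
#'
#' @param deaths Cumulative deaths.
#' @param entrants Baseline cohort entrants.
#' @param cost_allcause,cost_psychiatric Cumulative costs (same units).
#' @param life_years,qalys Named vectors (or lists) with elements `all`,
#'   `trd`, `comorbid`.
#' @param entrants_pandemic Pandemic-scenario entrants.
#' @return List with `case_fatality_pct`, `psychiatric_share_pct`,
#'   `qol_reduction_pct` (named vector), `pandemic_fold`, plus a `rounded`
#'   sub-list.
#' @export
derived_ratios <- function(deaths, entrants, cost_allcause, cost_psychiatric,
                           life_years, qalys, entrants_pandemic = NULL) {
  if (entrants == 0) stop("zero denominator in ratio: entrants")
  if (cost_allcause == 0) stop("zero denominator in ratio: cost_allcause")
  ly <- unlist(life_years)
  qa <- unlist(qalys)
  groups <- intersect(names(ly), names(qa))
  if (any(ly[groups] == 0)) {
    stop("zero denominator in ratio: life_years[",
         groups[ly[groups] == 0][1], "]")
  }
  qol <- (1 - qa[groups] / ly[groups]) * 100
  out <- list(
    case_fatality_pct = deaths / entrants * 100,
    psychiatric_share_pct = cost_psychiatric / cost_allcause * 100,
    qol_reduction_pct = qol,
    pandemic_fold = if (is.null(entrants_pandemic)) NA_real_ else
      entrants_pandemic / entrants
  )
  out$rounded <- list(
    case_fatality_pct = round(out$case_fatality_pct, 1),
    psychiatric_share_pct = round(out$psychiatric_share_pct),
    qol_reduction_pct = round(out$qol_reduction_pct, 1),
    pandemic_fold = round(out$pandemic_fold, 2)
  )
  out
}

#' @rdname derived_ratios
#' @param trace A closed-cohort `cohort_trace`.
#' @param trace_pandemic Optional pandemic-scenario trace.
#' @return `derived_ratios_from_trace`: same structure as
#'   [derived_ratios()], computed from model runs.
#' @export
derived_ratios_from_trace <- function(trace, trace_pandemic = NULL) {
  s <- summary(trace)
  ly <- c(all = s$totals$life_years, trd = s$totals$life_years_trd,
          comorbid = s$totals$life_years_comorbid)
  qa <- c(all = s$totals$qalys, trd = s$totals$qalys_trd,
          comorbid = s$totals$qalys_comorbid)
  keep <- ly > 0    # attribution groups never occupied carry no ratio
  derived_ratios(
    deaths = s$cumulative_deaths, entrants = s$entrants,
    cost_allcause = s$totals$cost_allcause,
    cost_psychiatric = s$totals$cost_psychiatric,
    life_years = ly[keep], qalys = qa[keep],
    entrants_pandemic = if (is.null(trace_pandemic)) NULL else
      summary(trace_pandemic)$entrants
  )
}

#' Build a burden report
#'
#' Writes the standard outputs of one or more scenario runs to a
#' directory: tidy per-cycle occupancy and outcome tables, a 16-subgroup
#' cumulative and per-patient-year table, and a JSON summary with the
#' headline figures, derived ratios, configuration echo and software
#' fingerprint.  Rounding is applied only in the printed summary; the
#' persisted tables carry full precision.
#'
#' @param traces Named list of `cohort_trace` objects (names are scenario
#'   labels; the first is treated as the base case).
#' @param out_dir Output directory (created if needed).
#' @param validation Optional result of [validate_schedule_fit()] to embed.
#' @return Invisibly, the list of file paths written.
#' @export
build_report <- function(traces, out_dir, validation = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1, !is.null(names(traces)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  summaries <- list()
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    s <- summary(tr)
    occ_path <- file.path(out_dir, paste0(nm, "_occupancy.csv"))
    out_path <- file.path(out_dir, paste0(nm, "_outcomes.csv"))
    sub_path <- file.path(out_dir, paste0(nm, "_subgroups.csv"))
    utils::write.csv(tr$occupancy, occ_path, row.names = FALSE)
    utils::write.csv(tr$outcomes, out_path, row.names = FALSE)
    utils::write.csv(s$by_subgroup, sub_path, row.names = FALSE)
    files <- c(files, occ_path, out_path, sub_path)
    summaries[[nm]] <- list(
      mode = s$mode, entrants = s$entrants,
      cumulative = s$totals, cumulative_deaths = s$cumulative_deaths,
      case_fatality_pct = 100 * s$case_fatality,
      cagr_allcause_pct = 100 * s$cagr_allcause,
      cagr_psychiatric_pct = 100 * s$cagr_psychiatric
    )
  }
  base <- traces[[1]]
  ratios <- derived_ratios_from_trace(base)
  summary_doc <- list(
    scenarios = summaries,
    derived_ratios = ratios[setdiff(names(ratios), "rounded")],
    derived_ratios_rounded = ratios$rounded,
    validation = if (is.null(validation)) NULL else
      list(table = validation$table, mape_pct = validation$mape),
    fingerprint = list(
      package = "depburden",
      version = as.character(utils::packageVersion("depburden")),
      r_version = R.version.string
    )
  )
  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_doc, json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- c(files, json_path)
  invisible(files)
}
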