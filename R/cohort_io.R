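#' Write and read a cohort as delimited text
#'
#' A cohort is persisted as a directory of tab-delimited files
#' (`patients.tsv`, `events.tsv`, `counts.tsv`) plus a JSON sidecar
#' (`config.json`) holding the generator configuration.  Numeric columns are
#' written with 17 significant digits so that `read_cohort(write_cohort(x))`
#' reproduces every field exactly.
#'
#' @param cohort A `depression_cohort`.
#' @param dir Directory to write to (created if absent).
#' @return `write_cohort`: the directory, invisibly.  `read_cohort`: a
#'   `depression_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "depression_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_exact(cohort$patients, file.path(dir, "patients.tsv"))
  write_tsv_exact(cohort$events, file.path(dir, "events.tsv"))
  write_tsv_exact(cohort$counts, file.path(dir, "counts.tsv"))
  cfg <- unclass(cohort$config)
  cfg$subgroup_mix <- as.list(cfg$subgroup_mix)   # keep names in JSON
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  for (f in c("patients.tsv", "events.tsv", "counts.tsv", "config.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing cohort file: ", file.path(dir, f))
    }
  }
  patients <- read_tsv_checked(file.path(dir, "patients.tsv"))
  events <- read_tsv_checked(file.path(dir, "events.tsv"))
  counts <- read_tsv_checked(file.path(dir, "counts.tsv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- restore_generator_config(cfg)
  if (nrow(events)) events$state <- as.character(events$state)
  structure(list(patients = patients, events = events, counts = counts,
                 config = config),
            class = "depression_cohort")
}

# rebuild the nested list structure (and class) from parsed JSON
restore_generator_config <- function(cfg) {
  hazards <- lapply(cfg$hazards, function(h) {
    list(family = h$family, pars = as.list(h$pars),
         beta = list(age_band = as.numeric(h$beta$age_band),
                     male = h$beta$male, history = h$beta$history))
  })
  sm <- list(
    states = lapply(cfg$service_model$states, function(stt) {
      lapply(stt, function(se) as.list(se))
    }),
    beta = list(age_band = as.numeric(cfg$service_model$beta$age_band),
                male = cfg$service_model$beta$male,
                history = cfg$service_model$beta$history)
  )
  generator_config(
    n_patients = cfg$n_patients,
    subgroup_mix = unlist(cfg$subgroup_mix),
    hazards = hazards, service_model = sm,
    diagnosis_years = cfg$diagnosis_years, censor_year = cfg$censor_year,
    max_followup = cfg$max_followup,
    include_comorbid_trd = cfg$include_comorbid_trd, seed = cfg$seed
  )
}

write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.finite(out[[j]]), sprintf("%.17g", out[[j]]),
                         as.character(out[[j]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_tsv_checked <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  n_fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(n_fields)) > 1L) {
    bad <- which(n_fields != n_fields[1])[1]
    stop("parse error in ", path, " at line ", bad,
         ": inconsistent number of fields")
  }
  df
}
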