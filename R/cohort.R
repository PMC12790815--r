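#' Construct a longitudinal cohort object
#'
#' Holds the three per-person tables the pipeline consumes: dated ICD-10
#' diagnoses, dated RxNorm prescriptions, and a wide covariate table with
#' one row per person. Persons without follow-up are kept here and removed
#' at analysis time by [apply_temporal_validity()].
#'
#' @param diagnoses data frame with columns \code{person_id}, \code{icd10},
#'   \code{date} (ISO-8601 or \code{Date}).
#' @param prescriptions data frame with columns \code{person_id},
#'   \code{rxnorm}, \code{date}.
#' @param covariates data frame with a \code{person_id} column plus
#'   demographic/lifestyle columns (e.g. \code{sex}, \code{age},
#'   \code{ethnicity}, \code{bmi}); one row per person.
#' @param followup optional data frame \code{person_id}, \code{has_followup}
#'   (logical). Persons absent from it are assumed followed up.
#' @return object of class \code{cohort}.
#' @export
cohort <- function(diagnoses, prescriptions, covariates, followup = NULL) {
  stopifnot(all(c("person_id", "icd10", "date") %in% names(diagnoses)),
            all(c("person_id", "rxnorm", "date") %in% names(prescriptions)),
            "person_id" %in% names(covariates))
  to_date <- function(x) {
    d <- tryCatch(as.Date(x), error = function(e) NA)
    if (anyNA(d)) {
      stop("invalid calendar date in diagnoses or prescriptions",
           call. = FALSE)
    }
    d
  }
  diagnoses$date <- to_date(diagnoses$date)
  prescriptions$date <- to_date(prescriptions$date)
  covariates$person_id <- as.character(covariates$person_id)
  if (anyDuplicated(covariates$person_id)) {
    stop("covariates must have one row per person", call. = FALSE)
  }
  diagnoses$person_id <- as.character(diagnoses$person_id)
  prescriptions$person_id <- as.character(prescriptions$person_id)
  diagnoses$icd10 <- normalize_icd10(diagnoses$icd10)
  missing_ids <- setdiff(c(diagnoses$person_id, prescriptions$person_id),
                         covariates$person_id)
  if (length(missing_ids) > 0L) {
    stop("event records for person(s) absent from covariates: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  if (is.null(followup)) {
    followup <- data.frame(person_id = covariates$person_id,
                           has_followup = rep(TRUE, nrow(covariates)),
                           stringsAsFactors = FALSE)
  }
  followup$person_id <- as.character(followup$person_id)
  structure(list(diagnoses = diagnoses, prescriptions = prescriptions,
                 covariates = covariates, followup = followup),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Longitudinal cohort: %d persons, %d diagnoses (%d codes), %d prescriptions (%d drugs)\n",
    nrow(x$covariates), nrow(x$diagnoses), length(unique(x$diagnoses$icd10)),
    nrow(x$prescriptions), length(unique(x$prescriptions$rxnorm))))
  invisible(x)
}

#' Read a cohort from a directory of TSV tables
#'
#' Expects \code{diagnoses.tsv} (\code{person_id}, \code{icd10},
#' \code{date}), \code{prescriptions.tsv} (\code{person_id}, \code{rxnorm},
#' \code{date}), \code{covariates.tsv} (wide per-person), and optionally
#' \code{followup.tsv} (\code{person_id}, \code{has_followup}).
#'
#' @param dir directory containing the tables.
#' @return a [cohort] object.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      stringsAsFactors = FALSE)
  fu <- NULL
  if (file.exists(file.path(dir, "followup.tsv"))) {
    fu <- rd("followup.tsv")
    fu$has_followup <- as.logical(fu$has_followup)
  }
  cohort(rd("diagnoses.tsv"), rd("prescriptions.tsv"), rd("covariates.tsv"), fu)
}

#' Write a cohort to a directory of TSV tables
#' @param x a [cohort] object.
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wr(x$diagnoses, "diagnoses.tsv")
  wr(x$prescriptions, "prescriptions.tsv")
  wr(x$covariates, "covariates.tsv")
  wr(x$followup, "followup.tsv")
  invisible(dir)
}

#' Per-person disease-severity proxies
#'
#' Severity is not directly observed in claims-style records; the pipeline
#' uses two standard proxies: the number of distinct 3-character ICD-10
#' categories a person was ever diagnosed with (\code{comorbidity_count})
#' and the number of distinct drugs ever prescribed
#' (\code{prescription_count}).
#'
#' @param cohort a [cohort] object.
#' @return data frame \code{person_id}, \code{comorbidity_count},
#'   \code{prescription_count}, one row per cohort person.
#' @export
severity_proxies <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- cohort$covariates$person_id
  cats <- unique(data.frame(person_id = cohort$diagnoses$person_id,
                            cat = icd10_category(cohort$diagnoses$icd10)))
  cc <- table(factor(cats$person_id, levels = ids))
  drugs <- unique(cohort$prescriptions[, c("person_id", "rxnorm")])
  pc <- table(factor(drugs$person_id, levels = ids))
  data.frame(person_id = ids,
             comorbidity_count = as.integer(cc[ids]),
             prescription_count = as.integer(pc[ids]),
             stringsAsFactors = FALSE)
}

first_event_date <- function(events, id_col, code_col, codes, normalize = FALSE) {
  code_vals <- events[[code_col]]
  if (normalize) code_vals <- normalize_icd10(code_vals)
  sel <- events[code_vals %in% codes, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(data.frame(person_id = character(0), first = as.Date(character(0)),
                      last = as.Date(character(0))))
  }
  agg_min <- tapply(sel$date, sel[[id_col]], min)
  agg_max <- tapply(sel$date, sel[[id_col]], max)
  data.frame(person_id = names(agg_min),
             first = as.Date(as.numeric(agg_min), origin = "1970-01-01"),
             last = as.Date(as.numeric(agg_max), origin = "1970-01-01"),
             stringsAsFactors = FALSE)
}

#' Encode a cohort into a binary analysis table for one hypothesis
#'
#' Builds the per-person table mediation analysis runs on: \code{T}
#' (indication ever diagnosed), \code{M} (drug ever taken), \code{Y}
#' (outcome ever diagnosed), with temporal-validity sample selection
#' enforced first:
#' \itemize{
#'   \item persons without follow-up are excluded;
#'   \item persons whose outcome preceded the indication or the drug are
#'     excluded;
#'   \item persons whose drug use occurred only before the indication
#'     diagnosis are excluded (same-day events count as valid order).
#' }
#' Diagnoses of the indication/outcome include their \code{is_a}
#' descendants when a graph is supplied, mirroring the subsumption closure
#' of the population assignment.
#'
#' @param cohort a [cohort] object.
#' @param hypothesis list/row with \code{indication}, \code{drug},
#'   \code{outcome}.
#' @param graph optional [ckg]; when given, disease membership uses the
#'   \code{is_a}-closed code sets.
#' @param severity logical; attach severity-proxy columns (default TRUE).
#' @return an object of class \code{analysis_table}: a data frame with
#'   columns \code{person_id}, \code{T}, \code{M}, \code{Y} and the cohort
#'   covariates, plus attributes \code{excluded} (counts by reason) and
#'   \code{testable} (at least one person with T=M=Y=1).
#' @export
apply_temporal_validity <- function(cohort, hypothesis, graph = NULL,
                                    severity = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  ind <- normalize_icd10(hypothesis$indication)
  out <- normalize_icd10(hypothesis$outcome)
  drug <- as.character(hypothesis$drug)

  ind_codes <- ind
  out_codes <- out
  if (!is.null(graph)) {
    desc <- isa_children_map(graph)
    ind_codes <- unique(c(ind, desc[[ind]]))
    out_codes <- unique(c(out, desc[[out]]))
  }

  dx <- cohort$diagnoses
  t_dates <- first_event_date(dx, "person_id", "icd10", ind_codes)
  y_dates <- first_event_date(dx, "person_id", "icd10", out_codes)
  m_dates <- first_event_date(cohort$prescriptions, "person_id", "rxnorm", drug)

  ids <- cohort$covariates$person_id
  fu <- cohort$followup$has_followup[match(ids, cohort$followup$person_id)]
  fu[is.na(fu)] <- TRUE

  t_first <- as.Date(rep(NA, length(ids)))
  t_first[match(t_dates$person_id, ids)] <- t_dates$first
  y_first <- as.Date(rep(NA, length(ids)))
  y_first[match(y_dates$person_id, ids)] <- y_dates$first
  m_first <- as.Date(rep(NA, length(ids)))
  m_first[match(m_dates$person_id, ids)] <- m_dates$first
  m_last <- as.Date(rep(NA, length(ids)))
  m_last[match(m_dates$person_id, ids)] <- m_dates$last

  no_follow <- !fu
  # outcome strictly before indication or before drug use
  out_before <- (!is.na(y_first) & !is.na(t_first) & y_first < t_first) |
    (!is.na(y_first) & !is.na(m_first) & y_first < m_first)
  # drug taken only before the indication was ever diagnosed
  drug_only_before <- !is.na(m_last) & !is.na(t_first) & m_last < t_first

  keep <- !(no_follow | out_before | drug_only_before)
  excluded <- c(no_followup = sum(no_follow),
                outcome_before = sum(out_before & !no_follow),
                drug_only_before_indication =
                  sum(drug_only_before & !no_follow & !out_before))

  tab <- cohort$covariates[keep, , drop = FALSE]
  tab$T <- as.integer(!is.na(t_first[keep]))
  tab$M <- as.integer(!is.na(m_first[keep]))
  tab$Y <- as.integer(!is.na(y_first[keep]))
  if (severity) {
    sp <- severity_proxies(cohort)
    tab$comorbidity_count <- sp$comorbidity_count[match(tab$person_id,
                                                        sp$person_id)]
    tab$prescription_count <- sp$prescription_count[match(tab$person_id,
                                                          sp$person_id)]
  }
  rownames(tab) <- NULL
  first <- c("person_id", "T", "M", "Y")
  tab <- tab[, c(first, setdiff(names(tab), first)), drop = FALSE]
  structure(tab, class = c("analysis_table", "data.frame"),
            excluded = excluded,
            testable = any(tab$T == 1L & tab$M == 1L & tab$Y == 1L))
}
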