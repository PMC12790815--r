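#' Attach graph-node covariate columns to an analysis table
#'
#' Adjustment sets identified on the causal subgraph contain disease and
#' drug nodes; modeling needs them as per-person binary columns. Disease
#' nodes become ever-diagnosed indicators (with \code{is_a} closure), drug
#' nodes ever-prescribed indicators.
#'
#' @param table an \code{analysis_table}.
#' @param cohort the [cohort] the table came from.
#' @param graph the [ckg].
#' @param nodes character vector of graph node ids.
#' @return the table with one extra 0/1 column per node.
#' @export
attach_graph_covariates <- function(table, cohort, graph, nodes) {
  if (length(nodes) == 0L) return(table)
  desc <- isa_children_map(graph)
  kinds <- setNames(graph$nodes$kind, graph$nodes$id)
  dx_by_person <- split(cohort$diagnoses$icd10, cohort$diagnoses$person_id)
  rx_by_person <- split(as.character(cohort$prescriptions$rxnorm),
                        cohort$prescriptions$person_id)
  for (v in nodes) {
    if (identical(kinds[[v]], "drug")) {
      members <- names(rx_by_person)[vapply(rx_by_person, function(s)
        v %in% s, TRUE)]
    } else {
      codes <- c(v, desc[[v]])
      members <- names(dx_by_person)[vapply(dx_by_person, function(s)
        any(codes %in% s), TRUE)]
    }
    table[[v]] <- as.integer(table$person_id %in% members)
  }
  table
}

stage_log <- function(log, stage, hypothesis, event, detail = "") {
  c(log, sprintf("%s | %s | %s | %s", stage, hypothesis, event, detail))
}

hyp_id <- function(h) paste(h$indication, h$drug, h$outcome, sep = ":")

#' Run the full drug-mediation discovery pipeline
#'
#' Orchestrates every stage on one graph/cohort pair: hypothesis
#' generation (from progression edges, cohort comorbidity statistics, or
#' both), contradiction and support filtering, temporal-validity encoding,
#' adjustment-set identification on the hypothesis-augmented causal
#' subgraph, optional LASSO shrinkage of the graph-derived covariates
#' (demographics and severity proxies are always retained unpenalized),
#' quasi-Bayesian ACME estimation, and Benjamini-Hochberg correction.
#' All randomness flows from \code{seed} via per-hypothesis derived seeds,
#' so reruns are byte-identical.
#'
#' @param graph a [ckg].
#' @param cohort a [cohort].
#' @param source hypothesis source: \code{"causal"}, \code{"comorbidity"}
#'   or \code{"both"}.
#' @param criterion \code{"backdoor"} or \code{"disjunctive"}.
#' @param lasso logical; shrink graph-derived adjustment sets by
#'   cross-validated LASSO.
#' @param sims coefficient draws per hypothesis (default 1000).
#' @param alpha BH level (default 0.05).
#' @param seed integer master seed (mandatory).
#' @param demographics covariate columns always adjusted for when present
#'   in the cohort table.
#' @param severity include the comorbidity/prescription-count severity
#'   proxies as unconditional covariates.
#' @param reference optional side-effect reference (\code{drug},
#'   \code{outcome}) for precision/recall evaluation of the significant
#'   positive predictions.
#' @param outdir optional directory; when given, writes
#'   \code{hypotheses.tsv}, \code{adjustment_sets.tsv},
#'   \code{results.tsv}, \code{summary.tsv} and \code{log.txt}.
#' @return list of class \code{ckgmed_run}: \code{hypotheses},
#'   \code{results} (one row per hypothesis), \code{summary} (category
#'   counts), \code{evaluation} (when a reference was given), \code{log}.
#' @export
run_pipeline <- function(graph, cohort, source = c("causal", "comorbidity",
                                                   "both"),
                         criterion = c("backdoor", "disjunctive"),
                         lasso = TRUE, sims = 1000L, alpha = 0.05, seed,
                         demographics = c("sex", "age", "bmi"),
                         severity = TRUE, reference = NULL, outdir = NULL) {
  source <- match.arg(source)
  criterion <- match.arg(criterion)
  stopifnot(inherits(graph, "ckg"), inherits(cohort, "cohort"))
  if (missing(seed)) stop("seed is required")
  stopifnot(alpha > 0, alpha < 1)
  log <- character(0)

  pairs <- NULL
  if (source %in% c("causal", "both")) {
    pairs <- extract_causal_pairs(graph)
  }
  if (source %in% c("comorbidity", "both")) {
    cp <- compute_comorbidity_pairs(cohort, alpha = alpha)$pairs
    pairs <- rbind(pairs, cp)
  }
  log <- stage_log(log, "pairs", "-", "extracted", nrow(pairs))

  hyp <- generate_hypotheses(pairs, graph)
  hyp <- filter_contradicted(hyp, graph)
  hyp <- filter_by_support(hyp, cohort, graph)
  for (i in which(hyp$status != "testable")) {
    log <- stage_log(log, "filter", hyp_id(hyp[i, ]), "removed",
                     hyp$status[i])
  }

  csg <- causal_subgraph(graph)
  demo <- intersect(demographics, names(cohort$covariates))
  sev_cols <- if (severity) c("comorbidity_count", "prescription_count")
              else character(0)

  n_hyp <- nrow(hyp)
  results <- vector("list", n_hyp)
  adj_rows <- vector("list", n_hyp)
  for (i in seq_len(n_hyp)) {
    h <- hyp[i, ]
    if (h$status != "testable") {
      results[[i]] <- list(status = h$status)
      next
    }
    dag <- tryCatch(add_hypothesis_edge(csg, h$drug, h$outcome),
                    ckgmed_cycle_error = function(e) NULL)
    if (is.null(dag)) {
      results[[i]] <- list(status = "NA_cycle")
      log <- stage_log(log, "adjust", hyp_id(h), "cycle", "untestable")
      next
    }
    aset <- if (criterion == "backdoor") {
      suppressWarnings(backdoor_set(dag, h$indication, h$outcome,
                                    forbidden = h$drug))
    } else {
      disjunctive_cause_set(dag, h$indication, h$outcome, mediator = h$drug)
    }
    if (is.null(aset)) {
      results[[i]] <- list(status = "NA_no_adjustment")
      log <- stage_log(log, "adjust", hyp_id(h), "no_set", "untestable")
      next
    }
    aset <- prune_hierarchy(aset, graph)
    graph_covs <- setdiff(aset$covariates, c(h$indication, h$outcome, h$drug))
    adj_rows[[i]] <- data.frame(indication = h$indication, drug = h$drug,
                                outcome = h$outcome, criterion = criterion,
                                covariates = paste(graph_covs, collapse = ","),
                                stringsAsFactors = FALSE)

    tab <- apply_temporal_validity(cohort, h, graph = graph,
                                   severity = severity)
    tab <- attach_graph_covariates(tab, cohort, graph, graph_covs)

    if (lasso && length(graph_covs) > 0L) {
      sel_t <- select_covariates(tab, "indication", graph_covs,
                                 seed = seed + 500000L + i)
      sel_y <- select_covariates(tab, "outcome", graph_covs,
                                 seed = seed + 600000L + i)
      graph_covs <- union_selection(sel_t, sel_y)
      log <- stage_log(log, "lasso", hyp_id(h), "selected",
                       paste(graph_covs, collapse = ","))
    }
    covs <- c(demo, sev_cols, graph_covs)
    res <- mediate_hypothesis(tab, covs, sims = sims, seed = seed + i)
    res$covariates <- covs
    results[[i]] <- res
    log <- stage_log(log, "mediate", hyp_id(h), "status", res$status)
  }

  res_df <- data.frame(
    indication = hyp$indication, drug = hyp$drug, outcome = hyp$outcome,
    source = hyp$source,
    n = vapply(results, function(r) r$n %||% NA_integer_, 0L),
    acme = vapply(results, function(r) r$acme %||% NA_real_, 0.0),
    ci_low = vapply(results, function(r) (r$acme_ci %||% c(NA_real_, NA_real_))[1], 0.0),
    ci_high = vapply(results, function(r) (r$acme_ci %||% c(NA_real_, NA_real_))[2], 0.0),
    p_value = vapply(results, function(r) r$p_value %||% NA_real_, 0.0),
    ade = vapply(results, function(r) r$ade %||% NA_real_, 0.0),
    total = vapply(results, function(r) r$total_effect %||% NA_real_, 0.0),
    prop_mediated = vapply(results, function(r) r$prop_mediated %||% NA_real_, 0.0),
    interaction = vapply(results, function(r)
      isTRUE(r$interaction_included), TRUE),
    sims = sims, seed = seed,
    status = vapply(results, function(r) r$status, ""),
    stringsAsFactors = FALSE)

  bh <- bh_correct(res_df, alpha = alpha)
  res_df$q_value <- bh$q_value
  res_df$category <- bh$category

  summary_df <- data.frame(
    n_hypotheses = n_hyp,
    n_na = sum(res_df$category == "N/A"),
    n_insignificant = sum(res_df$category == "insignificant"),
    n_positive = sum(res_df$category == "positive"),
    n_negative = sum(res_df$category == "negative"))

  evaluation <- NULL
  if (!is.null(reference)) {
    preds <- res_df[res_df$category == "positive", c("drug", "outcome")]
    uni <- res_df[res_df$status == "ok", c("drug", "outcome")]
    evaluation <- match_reference(preds, reference, universe = uni)
    summary_df$precision <- evaluation$precision
    summary_df$recall <- evaluation$recall
    summary_df$f1 <- evaluation$f1
  }

  out <- structure(list(hypotheses = hyp, results = res_df,
                        summary = summary_df, evaluation = evaluation,
                        adjustment_sets = do.call(rbind, adj_rows),
                        log = log, seed = seed, criterion = criterion,
                        lasso = lasso),
                   class = "ckgmed_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    if (!is.null(df)) utils::write.table(df, file.path(outdir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  }
  wr(as.data.frame(run$hypotheses), "hypotheses.tsv")
  wr(run$adjustment_sets, "adjustment_sets.tsv")
  wr(run$results, "results.tsv")
  wr(run$summary, "summary.tsv")
  writeLines(run$log, file.path(outdir, "log.txt"))
  invisible(outdir)
}

#' @export
print.ckgmed_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Mediation pipeline run (%s%s): %d hypotheses | N/A %d, insignificant %d, +ACME %d, -ACME %d\n",
    x$criterion, if (x$lasso) " + LASSO" else "", s$n_hypotheses, s$n_na,
    s$n_insignificant, s$n_positive, s$n_negative))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
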