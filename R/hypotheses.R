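#' Extract directed disease pairs from the progression edges
#'
#' The graph-driven source of candidate disease-to-disease relations:
#' exactly the progression edges, as ordered pairs.
#'
#' @param graph a [ckg] object.
#' @return data frame \code{from}, \code{to}, \code{source} (\code{"causal"}).
#' @export
extract_causal_pairs <- function(graph) {
  stopifnot(inherits(graph, "ckg"))
  e <- graph$edges[graph$edges$relation == "progression", , drop = FALSE]
  data.frame(from = e$source, to = e$target,
             source = rep("causal", nrow(e)), stringsAsFactors = FALSE)
}

#' Significant, temporally oriented comorbidity pairs
#'
#' The cohort-driven source of candidate relations. For every unordered
#' pair of diseases co-occurring in at least one person, the relative risk
#' is \eqn{RR = (n_{both} \cdot n_{total}) / (n_a \cdot n_b)} with lifetime
#' (ever/ever) person counts; enrichment is tested by a one-sided Fisher
#' exact test on the person-level 2x2 table and corrected across all tested
#' pairs by Benjamini-Hochberg. Significant pairs are oriented by first
#' diagnosis dates: \code{a} before \code{b} in a strict majority of
#' co-occurring persons gives direction \code{a -> b}; exact ties drop the
#' pair.
#'
#' @param cohort a [cohort] object.
#' @param alpha BH significance level (default 0.05).
#' @param min_count minimum co-occurrence count for a pair to be tested
#'   (default 1).
#' @return list with \code{pairs} (oriented significant pairs: \code{from},
#'   \code{to}, \code{source="comorbidity"}) and \code{stats} (all tested
#'   pairs with \code{rr}, \code{p_value}, \code{q_value}, counts).
#' @export
compute_comorbidity_pairs <- function(cohort, alpha = 0.05, min_count = 1L) {
  stopifnot(inherits(cohort, "cohort"), alpha > 0, alpha < 1)
  dx <- unique(data.frame(person_id = cohort$diagnoses$person_id,
                          code = cohort$diagnoses$icd10,
                          stringsAsFactors = FALSE))
  n_total <- nrow(cohort$covariates)
  persons_by_code <- split(dx$person_id, dx$code)
  codes <- names(persons_by_code)
  if (length(codes) < 2L) {
    stop("need at least two distinct disease codes", call. = FALSE)
  }

  # co-occurrence counts via person-level incidence crossprod
  inc <- table(factor(dx$person_id), factor(dx$code, levels = codes))
  inc <- (unclass(inc) > 0) * 1L
  co <- crossprod(inc)
  n_per <- diag(co)

  idx <- which(upper.tri(co) & co >= min_count, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(pairs = data.frame(from = character(0), to = character(0),
                                   source = character(0)),
                stats = data.frame()))
  }
  a <- codes[idx[, 1L]]; b <- codes[idx[, 2L]]
  n_both <- co[idx]
  n_a <- n_per[idx[, 1L]]; n_b <- n_per[idx[, 2L]]
  keep <- n_a > 0L & n_b > 0L
  a <- a[keep]; b <- b[keep]
  n_both <- n_both[keep]; n_a <- n_a[keep]; n_b <- n_b[keep]

  rr <- (n_both * n_total) / (n_a * n_b)
  p <- vapply(seq_along(a), function(i) {
    tab <- matrix(c(n_both[i], n_a[i] - n_both[i],
                    n_b[i] - n_both[i],
                    n_total - n_a[i] - n_b[i] + n_both[i]), 2L, 2L)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, 0.0)
  q <- stats::p.adjust(p, method = "BH")

  stats_df <- data.frame(disease_a = a, disease_b = b, rr = rr,
                         p_value = p, q_value = q,
                         n_both = n_both, n_a = n_a, n_b = n_b,
                         n_total = n_total, stringsAsFactors = FALSE)

  sig <- which(q <= alpha)
  first_dx <- tapply(cohort$diagnoses$date,
                     list(cohort$diagnoses$person_id, cohort$diagnoses$icd10),
                     min)
  orient <- lapply(sig, function(i) {
    shared <- intersect(persons_by_code[[a[i]]], persons_by_code[[b[i]]])
    da <- first_dx[cbind(shared, a[i])]
    db <- first_dx[cbind(shared, b[i])]
    a_first <- sum(da < db); b_first <- sum(db < da)
    if (a_first > b_first) c(a[i], b[i])
    else if (b_first > a_first) c(b[i], a[i])
    else NULL  # no strict majority
  })
  orient <- orient[!vapply(orient, is.null, TRUE)]
  pairs <- if (length(orient) > 0L) {
    data.frame(from = vapply(orient, `[`, "", 1L),
               to = vapply(orient, `[`, "", 2L),
               source = "comorbidity", stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), source = character(0))
  }
  list(pairs = pairs, stats = stats_df)
}

drugs_indicated_for <- function(graph, disease) {
  e <- graph$edges
  unique(e$source[e$relation == "indication" & e$target == disease])
}

#' Generate drug-mediation hypotheses from oriented disease pairs
#'
#' For each directed disease pair (x, y) and each drug indicated for the
#' source disease x in the graph, emits one candidate hypothesis
#' "x (indication) -> drug -> y (candidate adverse effect)".
#'
#' @param pairs data frame \code{from}, \code{to}, \code{source} as produced
#'   by [extract_causal_pairs()] or [compute_comorbidity_pairs()].
#' @param graph a [ckg] object.
#' @return a \code{hypothesis_set}: data frame \code{indication},
#'   \code{drug}, \code{outcome}, \code{source}, \code{status}
#'   (\code{"candidate"}).
#' @export
generate_hypotheses <- function(pairs, graph) {
  stopifnot(inherits(graph, "ckg"),
            all(c("from", "to") %in% names(pairs)))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    drugs <- drugs_indicated_for(graph, pairs$from[i])
    if (length(drugs) == 0L) return(NULL)
    data.frame(indication = pairs$from[i], drug = drugs,
               outcome = pairs$to[i],
               source = if ("source" %in% names(pairs)) pairs$source[i] else "causal",
               stringsAsFactors = FALSE)
  })
  hyp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(hyp)) {
    hyp <- data.frame(indication = character(0), drug = character(0),
                      outcome = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  }
  hyp <- hyp[!duplicated(hyp[, c("indication", "drug", "outcome")]), ,
             drop = FALSE]
  hyp$status <- rep("candidate", nrow(hyp))
  rownames(hyp) <- NULL
  class(hyp) <- c("hypothesis_set", "data.frame")
  hyp
}

#' Filter hypotheses contradicted by graph knowledge
#'
#' Marks \code{filtered_contradicted} any hypothesis for which the graph
#' already offers a non-mediation explanation:
#' \enumerate{
#'   \item the drug is indicated for \emph{both} the indication and the
#'     outcome (treatment overlap, not mediation);
#'   \item some single drug lists \emph{both} diseases as side effects
#'     (a common downstream effect, not a directed chain).
#' }
#'
#' @param hypotheses a \code{hypothesis_set}.
#' @param graph a [ckg] object.
#' @return the hypothesis set with updated \code{status}.
#' @export
filter_contradicted <- function(hypotheses, graph) {
  stopifnot(inherits(graph, "ckg"))
  e <- graph$edges
  ind <- e[e$relation == "indication", c("source", "target")]
  se <- e[e$relation == "side_effect", c("source", "target")]
  ind_key <- paste(ind$source, ind$target)
  se_by_drug <- split(se$target, se$source)

  for (i in seq_len(nrow(hypotheses))) {
    if (hypotheses$status[i] %in% c("filtered_contradicted", "filtered_support"))
      next
    h <- hypotheses[i, ]
    both_ind <- (paste(h$drug, h$indication) %in% ind_key) &&
      (paste(h$drug, h$outcome) %in% ind_key)
    both_se <- any(vapply(se_by_drug, function(eff) {
      h$indication %in% eff && h$outcome %in% eff
    }, TRUE))
    if (both_ind || both_se) hypotheses$status[i] <- "filtered_contradicted"
  }
  hypotheses
}

#' Filter hypotheses without cohort support
#'
#' Marks \code{filtered_support} any hypothesis whose drug or either
#' disease never appears in the cohort, or for which no person carries all
#' three components (indication = 1, drug = 1, outcome = 1) after
#' temporal-validity encoding.
#'
#' @param hypotheses a \code{hypothesis_set}.
#' @param cohort a [cohort] object.
#' @param graph optional [ckg] for \code{is_a}-closed disease membership.
#' @return the hypothesis set with updated \code{status}; survivors of both
#'   filters are marked \code{testable}.
#' @export
filter_by_support <- function(hypotheses, cohort, graph = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  codes <- unique(cohort$diagnoses$icd10)
  drugs <- unique(as.character(cohort$prescriptions$rxnorm))
  desc <- if (!is.null(graph)) isa_children_map(graph) else list()
  seen_disease <- function(d) {
    any(c(d, desc[[d]]) %in% codes)
  }
  for (i in seq_len(nrow(hypotheses))) {
    if (hypotheses$status[i] %in% c("filtered_contradicted", "filtered_support"))
      next
    h <- hypotheses[i, ]
    if (!seen_disease(h$indication) || !seen_disease(h$outcome) ||
        !(h$drug %in% drugs)) {
      hypotheses$status[i] <- "filtered_support"
      next
    }
    tab <- apply_temporal_validity(cohort, h, graph = graph, severity = FALSE)
    if (!attr(tab, "testable")) {
      hypotheses$status[i] <- "filtered_support"
    } else {
      hypotheses$status[i] <- "testable"
    }
  }
  hypotheses
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat(sprintf("Hypothesis set: %d hypotheses\n", nrow(x)))
  print(table(x$status))
  invisible(x)
}
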