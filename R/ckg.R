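#' @importFrom stats coef median model.matrix p.adjust pnorm quantile rbinom
#'   rnorm runif sd setNames binomial gaussian glm plogis predict fisher.test
#'   var wilcox.test as.formula vcov complete.cases
#' @importFrom utils read.delim write.table combn head modifyList
NULL

CKG_RELATIONS <- c("progression", "indication", "side_effect", "is_a")

#' Normalize an ICD-10 code to its internal form
#'
#' Internal disease identifiers strip the dot and uppercase the code
#' (\code{"E11.9"} becomes \code{"E119"}), which makes codes from different
#' cohort dialects comparable. The 3-character category of a code is its
#' first three characters.
#'
#' @param code character vector of ICD-10 codes in any dialect.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd10(c("E11.9", "i10"))
#' @export
normalize_icd10 <- function(code) {
  toupper(gsub(".", "", as.character(code), fixed = TRUE))
}

#' 3-character ICD-10 category of a (normalized) code
#' @param code character vector of ICD-10 codes.
#' @return character vector of 3-character categories.
#' @export
icd10_category <- function(code) {
  substr(normalize_icd10(code), 1L, 3L)
}

node_kind_for_edges <- function(edges) {
  # drugs are sources of indication/side_effect edges; every other endpoint
  # is a disease
  drug <- unique(edges$source[edges$relation %in% c("indication", "side_effect")])
  disease <- unique(c(
    edges$target,
    edges$source[edges$relation %in% c("progression", "is_a")]
  ))
  clash <- intersect(drug, disease)
  if (length(clash) > 0L) {
    stop("node(s) used both as drug and disease: ",
         paste(utils::head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(
    id = c(disease, drug),
    kind = rep(c("disease", "drug"), c(length(disease), length(drug))),
    stringsAsFactors = FALSE
  )
}

find_directed_cycle <- function(edges_df) {
  # returns NULL when acyclic, else the node ids of one offending cycle
  if (nrow(edges_df) == 0L) return(NULL)
  g <- igraph::graph_from_data_frame(edges_df[, c("source", "target")],
                                     directed = TRUE)
  if (igraph::is_dag(g)) return(NULL)
  comp <- igraph::components(g, mode = "strong")
  big <- which(comp$csize > 1L)
  if (length(big) > 0L) {
    return(sort(names(comp$membership)[comp$membership == big[1L]]))
  }
  loops <- igraph::which_loop(g)
  ends <- igraph::ends(g, igraph::E(g)[loops][1L])
  ends[1L, 1L]
}

#' Construct a causal knowledge graph
#'
#' A \code{ckg} is a typed directed multigraph over disease and drug nodes
#' with four relation types: \code{progression} (disease to disease),
#' \code{indication} (drug to its indicated disease), \code{side_effect}
#' (drug to a documented adverse-event disease) and \code{is_a} (disease code
#' to a more general code). The causal relation subset consists of the
#' progression edges together with the \emph{inverse} of the indication
#' edges (a diagnosis leads to the prescription of a drug); this causal
#' subgraph must be acyclic, as must the \code{is_a} hierarchy.
#'
#' @param edges data frame with columns \code{source}, \code{relation},
#'   \code{target} and optionally \code{provenance} (source dataset name,
#'   kept for audit only). Duplicate triples are removed.
#' @return an object of class \code{ckg} with components \code{nodes}
#'   (data frame \code{id}, \code{kind}) and \code{edges}.
#' @seealso [load_graph()], [causal_subgraph()], [assign_population()]
#' @export
ckg <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("source", "relation", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$relation <- as.character(edges$relation)
  if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_
  bad <- setdiff(unique(edges$relation), CKG_RELATIONS)
  if (length(bad) > 0L) {
    stop("unknown relation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(edges$source)) || any(!nzchar(edges$target))) {
    stop("node ids must be non-empty strings", call. = FALSE)
  }
  edges <- edges[!duplicated(edges[, c("source", "relation", "target")]), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  nodes <- node_kind_for_edges(edges)

  isa <- edges[edges$relation == "is_a", , drop = FALSE]
  cyc <- find_directed_cycle(isa)
  if (!is.null(cyc)) {
    stop("is_a hierarchy contains a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  causal <- causal_edge_table(edges)
  cyc <- find_directed_cycle(causal)
  if (!is.null(cyc)) {
    stop("causal subgraph contains a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }

  structure(list(nodes = nodes, edges = edges), class = "ckg")
}

causal_edge_table <- function(edges) {
  prog <- edges[edges$relation == "progression", c("source", "target")]
  ind <- edges[edges$relation == "indication", c("target", "source")]
  names(ind) <- c("source", "target")
  out <- rbind(prog, ind)
  rownames(out) <- NULL
  out
}

#' @export
print.ckg <- function(x, ...) {
  cat("Causal knowledge graph\n")
  cat(sprintf("  nodes: %d (%d diseases, %d drugs)\n",
              nrow(x$nodes), sum(x$nodes$kind == "disease"),
              sum(x$nodes$kind == "drug")))
  tab <- table(factor(x$edges$relation, levels = CKG_RELATIONS))
  for (r in CKG_RELATIONS) cat(sprintf("  %-12s %d edges\n", r, tab[[r]]))
  invisible(x)
}

#' Load a causal knowledge graph from per-relation edge tables
#'
#' Each file is a tab-separated table with one header line and columns
#' \code{source} and \code{target}; the file's role (which relation it
#' contributes) is declared by the name of the list element.
#'
#' @param files named list/vector mapping a relation name (one of
#'   \code{progression}, \code{indication}, \code{side_effect},
#'   \code{is_a}) to a TSV path. Names may repeat to merge several sources
#'   of the same relation.
#' @param provenance optional character vector, parallel to \code{files},
#'   recording where each table came from; defaults to the file name.
#' @return a validated [ckg] object.
#' @export
load_graph <- function(files, provenance = NULL) {
  stopifnot(length(files) > 0L, !is.null(names(files)))
  if (is.null(provenance)) provenance <- basename(unlist(files))
  parts <- lapply(seq_along(files), function(i) {
    rel <- names(files)[i]
    if (!rel %in% CKG_RELATIONS) {
      stop("unknown relation label: ", rel, call. = FALSE)
    }
    tab <- utils::read.delim(files[[i]], header = TRUE,
                             colClasses = "character", sep = "\t")
    if (!all(c("source", "target") %in% names(tab))) {
      stop("edge table ", files[[i]],
           " must have columns source and target", call. = FALSE)
    }
    if (nrow(tab) == 0L) return(NULL)
    data.frame(source = tab$source, relation = rel, target = tab$target,
               provenance = provenance[i], stringsAsFactors = FALSE)
  })
  ckg(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Write a graph back to per-relation edge tables
#'
#' Inverse of [load_graph()]: writes one \code{<relation>.tsv} per relation
#' present, with sorted rows so output is reproducible byte-for-byte.
#'
#' @param graph a [ckg] object.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_graph_tables <- function(graph, dir) {
  stopifnot(inherits(graph, "ckg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rels <- intersect(CKG_RELATIONS, unique(graph$edges$relation))
  paths <- character(0)
  for (r in rels) {
    e <- graph$edges[graph$edges$relation == r, c("source", "target")]
    e <- e[order(e$source, e$target), , drop = FALSE]
    p <- file.path(dir, paste0(r, ".tsv"))
    utils::write.table(e, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[r] <- p
  }
  invisible(paths)
}

#' Causal subgraph of a CKG
#'
#' Returns the directed acyclic graph carrying the causal interpretation:
#' every progression edge, plus one disease-to-drug edge per indication edge
#' (the inverse of the indication, read as "the diagnosis leads to the
#' prescription"). \code{is_a} and \code{side_effect} edges never enter.
#'
#' @param graph a [ckg] object.
#' @return an \code{igraph} DAG whose vertices carry a \code{kind} attribute.
#' @export
causal_subgraph <- function(graph) {
  stopifnot(inherits(graph, "ckg"))
  ce <- causal_edge_table(graph$edges)
  ce <- ce[!duplicated(ce), , drop = FALSE]
  verts <- graph$nodes[graph$nodes$id %in% unique(c(ce$source, ce$target)), ,
                       drop = FALSE]
  g <- igraph::graph_from_data_frame(ce, directed = TRUE, vertices = verts)
  stopifnot(igraph::is_dag(g))
  g
}

isa_children_map <- function(graph) {
  # map: disease id -> ids of all is_a descendants (transitive), self excluded
  isa <- graph$edges[graph$edges$relation == "is_a", c("source", "target")]
  if (nrow(isa) == 0L) return(list())
  g <- igraph::graph_from_data_frame(isa, directed = TRUE)
  ids <- igraph::V(g)$name
  desc <- lapply(ids, function(v) {
    # is_a points child -> parent, so descendants reach v against edge flow
    setdiff(names(igraph::subcomponent(g, v, mode = "in")), v)
  })
  names(desc) <- ids
  desc
}

isa_ancestors_map <- function(graph) {
  isa <- graph$edges[graph$edges$relation == "is_a", c("source", "target")]
  if (nrow(isa) == 0L) return(list())
  g <- igraph::graph_from_data_frame(isa, directed = TRUE)
  ids <- igraph::V(g)$name
  anc <- lapply(ids, function(v) {
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v)
  })
  names(anc) <- ids
  anc
}

#' Assign the empirical population measure to a CKG
#'
#' Maps every graph node to the subset of the cohort it denotes: a disease
#' node collects the persons ever diagnosed with that code \emph{or any of
#' its \code{is_a} descendants} (subsumption closure), a drug node the
#' persons ever prescribed it. The probability measure is relative
#' frequency, \eqn{P(S) = |S| / |\Omega|}.
#'
#' Cohort codes absent from the graph are counted and skipped, never fatal.
#'
#' @param graph a [ckg] object.
#' @param cohort a [cohort] object.
#' @return an object of class \code{population_assignment} with components
#'   \code{population} (person ids), \code{membership} (named list of person
#'   subsets per node), \code{measure} (function: person subset to [0,1]),
#'   and \code{skipped} (counts of unmatched cohort codes).
#' @export
assign_population <- function(graph, cohort) {
  stopifnot(inherits(graph, "ckg"), inherits(cohort, "cohort"))
  omega <- unique(as.character(cohort$covariates$person_id))
  n_omega <- length(omega)

  diag_codes <- normalize_icd10(cohort$diagnoses$icd10)
  diseases <- graph$nodes$id[graph$nodes$kind == "disease"]
  drugs <- graph$nodes$id[graph$nodes$kind == "drug"]

  direct <- split(as.character(cohort$diagnoses$person_id), diag_codes)
  skipped_dx <- sum(!names(direct) %in% diseases)

  desc <- isa_children_map(graph)
  membership <- vector("list", nrow(graph$nodes))
  names(membership) <- graph$nodes$id
  for (v in diseases) {
    codes <- c(v, desc[[v]])
    membership[[v]] <- sort(unique(unlist(direct[intersect(codes, names(direct))],
                                          use.names = FALSE)))
  }
  rx <- split(as.character(cohort$prescriptions$person_id),
              as.character(cohort$prescriptions$rxnorm))
  skipped_rx <- sum(!names(rx) %in% drugs)
  for (m in drugs) {
    membership[[m]] <- sort(unique(rx[[m]]))
  }
  membership <- lapply(membership, function(s) if (is.null(s)) character(0) else s)

  measure <- function(subset) {
    if (n_omega == 0L) return(0)
    length(unique(subset)) / n_omega
  }

  structure(list(population = omega, membership = membership,
                 measure = measure,
                 skipped = c(diagnoses = skipped_dx, prescriptions = skipped_rx)),
            class = "population_assignment")
}

#' @export
print.population_assignment <- function(x, ...) {
  cat(sprintf("Population assignment: |Omega| = %d, %d mapped nodes\n",
              length(x$population), length(x$membership)))
  invisible(x)
}

#' Export a CKG as RDF N-Triples
#'
#' Serializes every edge as one triple with a per-relation predicate IRI.
#' Triples are emitted sorted, so the export is bit-stable: the same graph
#' always produces the same bytes, and the contradiction filters can be run
#' as queries against any external triple store loaded from the file.
#'
#' @param graph a [ckg] object.
#' @param path output file.
#' @param base IRI prefix for entities and relations.
#' @return invisibly, the path.
#' @export
export_ntriples <- function(graph, path, base = "http://example.org/ckg/") {
  stopifnot(inherits(graph, "ckg"))
  esc <- function(x) utils::URLencode(x, reserved = TRUE)
  lines <- sprintf("<%sentity/%s> <%srelation/%s> <%sentity/%s> .",
                   base, vapply(graph$edges$source, esc, ""),
                   base, graph$edges$relation,
                   base, vapply(graph$edges$target, esc, ""))
  writeLines(sort(lines), path)
  invisible(path)
}

#' Read a CKG back from an N-Triples export
#'
#' Counterpart of [export_ntriples()] used to check that graph-side filters
#' give identical answers when run over the serialized triple store.
#'
#' @param path N-Triples file written by [export_ntriples()].
#' @param base IRI prefix used at export time.
#' @return a validated [ckg] object.
#' @export
read_ntriples <- function(path, base = "http://example.org/ckg/") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  pat <- "^<(.+)> <(.+)> <(.+)> \\.$"
  m <- regmatches(lines, regexec(pat, lines))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed N-Triples line(s)", call. = FALSE)
  strip <- function(iri, kind) {
    pre <- paste0(base, kind, "/")
    utils::URLdecode(sub(pre, "", iri, fixed = TRUE))
  }
  ckg(data.frame(
    source = vapply(m, function(x) strip(x[2], "entity"), ""),
    relation = vapply(m, function(x) strip(x[3], "relation"), ""),
    target = vapply(m, function(x) strip(x[4], "entity"), ""),
    stringsAsFactors = FALSE
  ))
}
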