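as_adjacency <- function(dag) {
  if (is.matrix(dag)) {
    storage.mode(dag) <- "logical"
    stopifnot(!is.null(rownames(dag)), identical(rownames(dag), colnames(dag)))
    return(dag)
  }
  stopifnot(igraph::is_igraph(dag))
  m <- as.matrix(igraph::as_adjacency_matrix(dag, sparse = FALSE)) > 0
  m
}

# reachability closure: out[i, j] TRUE iff a directed path i -> ... -> j
# (including i == j) exists; Warshall on the small matrices used here
reach_closure <- function(adj) {
  n <- nrow(adj)
  r <- adj | diag(TRUE, n)
  for (k in seq_len(n)) {
    r <- r | outer(r[, k], r[k, ], `&`)
  }
  dimnames(r) <- dimnames(adj)
  r
}

#' Test d-separation in a DAG
#'
#' Standard d-separation: every path between \code{A} and \code{B} must be
#' blocked by \code{Z} (chains and forks are blocked when the middle node is
#' in \code{Z}; colliders block unless the collider or one of its
#' descendants is in \code{Z}). Implemented by the moralized-ancestral-graph
#' reduction: restrict to the ancestors of \code{A}, \code{B}, \code{Z},
#' moralize, delete \code{Z}, and test undirected separation.
#'
#' @param dag an \code{igraph} DAG or a named logical adjacency matrix.
#' @param A,B,Z character vectors of node names; must be pairwise disjoint.
#' @param closure optional reachability matrix from a previous call on the
#'   same DAG (a speed-up for repeated queries; computed when missing).
#' @return \code{TRUE} iff \code{A} and \code{B} are d-separated given
#'   \code{Z}.
#' @export
d_separated <- function(dag, A, B, Z = character(0), closure = NULL) {
  adj <- as_adjacency(dag)
  nodes <- rownames(adj)
  A <- as.character(A); B <- as.character(B); Z <- as.character(Z)
  miss <- setdiff(c(A, B, Z), nodes)
  if (length(miss) > 0L) {
    stop("node(s) not in dag: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(A, B)) || length(intersect(A, Z)) ||
      length(intersect(B, Z))) {
    stop("A, B, Z must be disjoint", call. = FALSE)
  }
  if (is.null(closure)) closure <- reach_closure(adj)

  targets <- c(A, B, Z)
  anc <- nodes[rowSums(closure[, targets, drop = FALSE]) > 0]
  sub <- adj[anc, anc, drop = FALSE]

  und <- sub | t(sub)
  # moralize: marry parents of every common child
  for (child in seq_len(ncol(sub))) {
    pa <- which(sub[, child])
    if (length(pa) > 1L) und[pa, pa] <- TRUE
  }
  diag(und) <- FALSE
  keep <- setdiff(anc, Z)
  und <- und[keep, keep, drop = FALSE]

  # BFS from A over the pruned moral graph
  frontier <- intersect(A, keep)
  seen <- frontier
  while (length(frontier) > 0L) {
    nxt <- keep[colSums(und[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  !any(B %in% seen)
}

#' Add the hypothesized drug-to-outcome edge to a causal subgraph
#'
#' Each mediation hypothesis is analyzed on the causal subgraph augmented
#' with a single edge from the drug to the candidate outcome disease. The
#' input graph is never modified; adding an edge already present is a
#' no-op.
#'
#' @param dag \code{igraph} causal subgraph.
#' @param drug,outcome node names (outcome vertex added if absent).
#' @return the augmented \code{igraph} DAG.
#' @section Errors: if the new edge would close a directed cycle the
#'   hypothesis is untestable; a condition of class
#'   \code{ckgmed_cycle_error} is signalled.
#' @export
add_hypothesis_edge <- function(dag, drug, outcome) {
  stopifnot(igraph::is_igraph(dag))
  if (!outcome %in% igraph::V(dag)$name) {
    dag <- igraph::add_vertices(dag, 1L, name = outcome, kind = "disease")
  }
  if (!drug %in% igraph::V(dag)$name) {
    dag <- igraph::add_vertices(dag, 1L, name = drug, kind = "drug")
  }
  if (igraph::are_adjacent(dag, drug, outcome)) {
    return(dag)
  }
  # a directed path outcome -> drug would be closed into a cycle
  reach <- names(igraph::subcomponent(dag, outcome, mode = "out"))
  if (drug %in% reach) {
    stop(structure(class = c("ckgmed_cycle_error", "error", "condition"),
                   list(message = sprintf(
                     "edge %s -> %s would create a cycle", drug, outcome),
                     call = NULL)))
  }
  g2 <- igraph::add_edges(dag, c(drug, outcome))
  stopifnot(igraph::is_dag(g2))
  g2
}

subsets_in_order <- function(items, k) {
  # columns of combn are already in lexicographic order for sorted input
  if (k == 0L) return(list(character(0)))
  if (length(items) < k) return(list())
  cols <- utils::combn(items, k, simplify = FALSE)
  cols
}

#' Backdoor adjustment set with enumeration cap
#'
#' Enumerates candidate covariate sets \code{Z} over the DAG's nodes
#' (excluding the treatment, the outcome, descendants of the treatment and
#' any \code{forbidden} nodes) in a deterministic order — increasing
#' cardinality, then lexicographic — and returns the first set satisfying
#' the backdoor criterion: \code{Z} d-separates treatment and outcome in
#' the graph with the treatment's outgoing edges removed. Because of the
#' enumeration order this is a minimum-cardinality valid set, with ties
#' broken by first encounter. Enumeration stops after \code{cap} candidate
#' sets.
#'
#' @param dag \code{igraph} DAG (typically the hypothesis-augmented causal
#'   subgraph).
#' @param treatment,outcome node names.
#' @param forbidden nodes never admitted into a set (e.g. the mediator
#'   drug).
#' @param cap maximum number of candidate sets examined (default 1000).
#' @return an \code{adjustment_set} (criterion \code{"backdoor"}), or
#'   \code{NULL} with a warning when no valid set is found within the cap.
#' @export
backdoor_set <- function(dag, treatment, outcome, forbidden = character(0),
                         cap = 1000L) {
  adj <- as_adjacency(dag)
  nodes <- rownames(adj)
  stopifnot(treatment %in% nodes, outcome %in% nodes)
  closure <- reach_closure(adj)
  desc_t <- nodes[closure[treatment, ]]  # includes treatment itself

  # proper backdoor test graph: treatment's outgoing edges removed
  adj_bd <- adj
  adj_bd[treatment, ] <- FALSE
  closure_bd <- reach_closure(adj_bd)
  # minimal d-separators of (treatment, outcome) lie within their ancestors,
  # so enumeration can be restricted to them without changing the chosen
  # minimum-cardinality set; this keeps the cap from binding on large graphs
  anc_ty <- nodes[closure_bd[, treatment] | closure_bd[, outcome]]
  eligible <- sort(setdiff(intersect(anc_ty, nodes),
                           c(desc_t, outcome, forbidden)))

  examined <- 0L
  for (k in 0:length(eligible)) {
    for (Z in subsets_in_order(eligible, k)) {
      examined <- examined + 1L
      if (examined > cap) {
        warning("no valid backdoor set within the enumeration cap")
        return(NULL)
      }
      if (d_separated(adj_bd, treatment, outcome, Z, closure = closure_bd)) {
        return(structure(list(covariates = Z, criterion = "backdoor",
                              treatment = treatment, outcome = outcome,
                              pruned = FALSE, examined = examined),
                         class = "adjustment_set"))
      }
    }
  }
  warning("no valid backdoor set exists for this pair")
  NULL
}

#' Disjunctive-cause adjustment set
#'
#' Selects the direct causes of the treatment, of the outcome, or of both:
#' the union of the DAG parents of treatment and outcome, excluding the
#' treatment, the outcome and the mediator drug.
#'
#' @param dag \code{igraph} DAG.
#' @param treatment,outcome node names.
#' @param mediator optional mediator node, always excluded.
#' @return an \code{adjustment_set} (criterion \code{"disjunctive"}).
#' @export
disjunctive_cause_set <- function(dag, treatment, outcome, mediator = NULL) {
  adj <- as_adjacency(dag)
  nodes <- rownames(adj)
  stopifnot(treatment %in% nodes, outcome %in% nodes)
  pa <- unique(c(nodes[adj[, treatment]], nodes[adj[, outcome]]))
  pa <- sort(setdiff(pa, c(treatment, outcome, mediator)))
  structure(list(covariates = pa, criterion = "disjunctive",
                 treatment = treatment, outcome = outcome, pruned = FALSE),
            class = "adjustment_set")
}

#' Prune hierarchically redundant covariates from an adjustment set
#'
#' When a set contains both a disease and one of its \code{is_a} ancestors,
#' adjusting for both is redundant: the more specific (descendant) code is
#' removed, keeping only the parent. Applied transitively, so a chain
#' \code{A.1.1 is_a A.1 is_a A} collapses to \code{A}.
#'
#' @param adjustment an \code{adjustment_set}.
#' @param graph the [ckg] supplying the \code{is_a} hierarchy.
#' @return the pruned \code{adjustment_set} (\code{pruned = TRUE}).
#' @export
prune_hierarchy <- function(adjustment, graph) {
  stopifnot(inherits(adjustment, "adjustment_set"), inherits(graph, "ckg"))
  anc <- isa_ancestors_map(graph)
  s <- adjustment$covariates
  keep <- vapply(s, function(v) !any(anc[[v]] %in% s), TRUE)
  adjustment$covariates <- s[keep]
  adjustment$pruned <- TRUE
  adjustment
}

#' @export
print.adjustment_set <- function(x, ...) {
  cat(sprintf("Adjustment set (%s%s) for %s ~ %s: {%s}\n",
              x$criterion, if (isTRUE(x$pruned)) ", pruned" else "",
              x$treatment, x$outcome,
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}
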