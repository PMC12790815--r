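# Shared fixtures and independent oracles used across the suite.

# --- tiny hand-built graph -------------------------------------------------

toy_graph_edges <- function() {
  rbind(
    data.frame(source = "A01", relation = "progression", target = "B01"),
    data.frame(source = "B01", relation = "progression", target = "C01"),
    data.frame(source = "RX1", relation = "indication", target = "A01"),
    data.frame(source = "RX2", relation = "indication", target = "A01"),
    data.frame(source = "RX1", relation = "side_effect", target = "C01"),
    data.frame(source = "C011", relation = "is_a", target = "C01")
  )
}

toy_graph <- function() ckg(toy_graph_edges())

# cohort with hand-chosen dates; person ids p1..p12
toy_cohort <- function() {
  dx <- data.frame(
    person_id = c("p1", "p1", "p2", "p2", "p3", "p4", "p5", "p6", "p6",
                  "p8", "p9", "p9", "p10", "p11"),
    icd10 = c("A01", "C01", "A01", "C01", "A01", "C01", "A01", "A01", "C01",
              "A01", "A01", "C011", "A01", "C01"),
    date = as.Date(c("2001-01-01", "2005-01-01",   # p1 valid order
                     "2004-01-01", "2002-01-01",   # p2 outcome before T
                     "2001-06-01",                 # p3 T only
                     "2003-01-01",                 # p4 Y only
                     "2002-01-01",                 # p5 T only
                     "2001-01-01", "2003-06-01",   # p6 valid T..Y
                     "2001-01-01",                 # p8 (no follow-up)
                     "2002-01-01", "2006-01-01",   # p9 child code outcome
                     "2001-01-01",                 # p10 drug only before T
                     "2004-01-01")),               # p11 Y before drug
    stringsAsFactors = FALSE)
  rx <- data.frame(
    person_id = c("p1", "p6", "p9", "p10", "p11", "p12"),
    rxnorm = c("RX1", "RX1", "RX1", "RX1", "RX1", "RX1"),
    date = as.Date(c("2002-01-01", "2001-01-01", "2003-01-01",
                     "2000-01-01",                # p10: only before T
                     "2005-01-01",                # p11: after their Y
                     "2001-01-01")),
    stringsAsFactors = FALSE)
  cov <- data.frame(person_id = sprintf("p%d", 1:12),
                    sex = rep(c(0, 1), 6), age = seq(40, 62, 2),
                    bmi = seq(22, 33, 1), stringsAsFactors = FALSE)
  fu <- data.frame(person_id = sprintf("p%d", 1:12),
                   has_followup = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                    TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  cohort(dx, rx, cov, fu)
}

# --- random DAGs -----------------------------------------------------------

random_dag <- function(n_nodes, p_edge = 0.3) {
  adj <- matrix(FALSE, n_nodes, n_nodes,
                dimnames = list(LETTERS[1:n_nodes], LETTERS[1:n_nodes]))
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (runif(1) < p_edge) adj[i, j] <- TRUE
    }
  }
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# --- brute-force d-separation oracle: enumerate all simple paths and apply
# the chain/fork/collider blocking rules --------------------------------------

oracle_descendants <- function(adj, v) {
  nodes <- rownames(adj)
  seen <- v
  frontier <- v
  while (length(frontier) > 0L) {
    nxt <- nodes[colSums(adj[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

oracle_d_separated <- function(adj, a, b, Z) {
  nodes <- rownames(adj)
  sk <- adj | t(adj)
  desc <- lapply(setNames(nodes, nodes), function(v) oracle_descendants(adj, v))

  path_open <- function(path) {
    if (length(path) > 2L) {
      for (k in 2:(length(path) - 1L)) {
        prev <- path[k - 1L]; v <- path[k]; nxt <- path[k + 1L]
        collider <- adj[prev, v] && adj[nxt, v]
        if (collider) {
          if (!any(desc[[v]] %in% Z)) return(FALSE)   # blocked collider
        } else {
          if (v %in% Z) return(FALSE)                  # blocked chain/fork
        }
      }
    }
    TRUE
  }
  found_open <- FALSE
  dfs <- function(path) {
    if (found_open) return()
    v <- path[length(path)]
    if (v == b) {
      if (path_open(path)) found_open <<- TRUE
      return()
    }
    for (w in nodes[sk[v, ]]) {
      if (!w %in% path) dfs(c(path, w))
    }
  }
  dfs(a)
  !found_open
}

# all subsets of a character vector, increasing cardinality then lexicographic
all_subsets <- function(items) {
  out <- list(character(0))
  items <- sort(items)
  for (k in seq_along(items)) {
    if (length(items) >= k) {
      out <- c(out, utils::combn(items, k, simplify = FALSE))
    }
  }
  out
}

# brute-force valid backdoor sets: Z has no descendant of t and d-separates
# t from y in the graph with t's outgoing edges removed (oracle d-sep)
oracle_backdoor_valid <- function(adj, t, y, Z) {
  desc_t <- oracle_descendants(adj, t)
  if (any(Z %in% desc_t)) return(FALSE)
  adj2 <- adj
  adj2[t, ] <- FALSE
  oracle_d_separated(adj2, t, y, Z)
}

sample_confounders_test <- function(n) {
  data.frame(sex = rbinom(n, 1, 0.5), age_z = rnorm(n), bmi_z = rnorm(n))
}

# --- brute-force BH step-up -------------------------------------------------

oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  kmax <- 0L
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k / m * alpha) kmax <- k
  }
  if (kmax > 0L) flags[ord[seq_len(kmax)]] <- TRUE
  flags
}
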