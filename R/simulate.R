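#' Structural-equation parameters for one binary mediation block
#'
#' One hypothesis block follows the logistic structural causal model
#' \deqn{T ~ Bern(expit(t0 + g_T C)),\quad
#'       M ~ Bern(expit(m0 + a T + g_M C)),\quad
#'       Y ~ Bern(expit(y0 + b M + c T + g_Y C))}
#' with person-level confounders \eqn{C} = (sex, standardized age,
#' standardized BMI). Defaults give an indication prevalence around 0.15,
#' a strong indication-to-prescription path and a moderate planted
#' drug-to-outcome effect — the regime in which drug-mediated
#' adverse-effect signals are realistically detectable in a cohort of ten
#' thousand.
#'
#' @param a treatment-to-mediator log-odds coefficient.
#' @param b mediator-to-outcome log-odds coefficient (0 for a null block).
#' @param c_direct direct treatment-to-outcome log-odds coefficient.
#' @param t0,m0,y0 intercepts.
#' @param conf_t,conf_m,conf_y length-3 confounder coefficients
#'   (sex, age_z, bmi_z) for each equation.
#' @param n_z number of binary comorbidity-confounder diseases: conditions
#'   that raise the probability of both the indication and the outcome,
#'   giving the companion graph genuine backdoor paths.
#' @param z_t,z_y log-odds effect of each such disease on indication and
#'   outcome.
#' @param z_prev prevalence of each confounder disease.
#' @return a parameter list of class \code{binary_params}.
#' @export
binary_params <- function(a = 2.0, b = 1.2, c_direct = 0.3,
                          t0 = -1.8, m0 = -2.2, y0 = -2.5,
                          conf_t = c(0.3, 0.4, 0.3),
                          conf_m = c(0.1, 0.2, 0.1),
                          conf_y = c(0.2, 0.3, 0.2),
                          n_z = 0L, z_t = 0.8, z_y = 0.8, z_prev = 0.3) {
  p <- list(a = a, b = b, c_direct = c_direct, t0 = t0, m0 = m0, y0 = y0,
            conf_t = conf_t, conf_m = conf_m, conf_y = conf_y,
            n_z = as.integer(n_z), z_t = z_t, z_y = z_y, z_prev = z_prev)
  stopifnot(all(is.finite(unlist(p))))
  structure(p, class = "binary_params")
}

sample_confounders <- function(n) {
  data.frame(sex = stats::rbinom(n, 1L, 0.5),
             age_z = stats::rnorm(n),
             bmi_z = stats::rnorm(n))
}

sample_z <- function(n, p) {
  if (p$n_z == 0L) return(matrix(0, n, 0))
  matrix(stats::rbinom(n * p$n_z, 1L, p$z_prev), n, p$n_z)
}

sample_block <- function(C, p, Z = NULL) {
  n <- nrow(C)
  Cm <- as.matrix(C)
  if (is.null(Z)) Z <- sample_z(n, p)
  zsum <- if (ncol(Z) > 0L) rowSums(Z) else numeric(n)
  Tt <- stats::rbinom(n, 1L, stats::plogis(p$t0 + drop(Cm %*% p$conf_t) +
                                             p$z_t * zsum))
  M <- stats::rbinom(n, 1L, stats::plogis(p$m0 + p$a * Tt + drop(Cm %*% p$conf_m)))
  Y <- stats::rbinom(n, 1L, stats::plogis(p$y0 + p$b * M + p$c_direct * Tt +
                                            p$z_y * zsum + drop(Cm %*% p$conf_y)))
  data.frame(T = Tt, M = M, Y = Y)
}

#' Simulate a single binary analysis table
#'
#' Draws one hypothesis block from the logistic structural model of
#' [binary_params()] together with its confounders, already in the binary
#' \code{T}/\code{M}/\code{Y} encoding the mediation models consume.
#'
#' @param n number of persons.
#' @param params a [binary_params()] list.
#' @param seed integer seed.
#' @return data frame \code{T}, \code{M}, \code{Y}, \code{sex},
#'   \code{age_z}, \code{bmi_z}.
#' @export
simulate_binary_dataset <- function(n, params = binary_params(), seed) {
  set.seed(seed)
  C <- sample_confounders(n)
  Z <- sample_z(n, params)
  out <- cbind(sample_block(C, params, Z), C)
  if (ncol(Z) > 0L) {
    colnames(Z) <- sprintf("z%d", seq_len(ncol(Z)))
    out <- cbind(out, as.data.frame(Z))
  }
  out
}

#' Monte-Carlo oracle for the true natural indirect effect
#'
#' Evaluates \eqn{E[Y(0, M(1)) - Y(0, M(0))]} from the \emph{known}
#' structural equations: confounders are simulated, and the inner
#' expectation over the binary mediator and outcome is computed exactly per
#' draw, so the only Monte-Carlo error comes from the confounder average.
#'
#' @param params a [binary_params()] list.
#' @param mc_n number of confounder draws (default 1e6).
#' @param seed integer seed.
#' @return numeric oracle NIE with attributes \code{mc_se} (Monte-Carlo
#'   standard error) and \code{mc_n}.
#' @export
true_nie <- function(params, mc_n = 1e6, seed = 1L) {
  stopifnot(inherits(params, "binary_params"))
  set.seed(seed)
  C <- as.matrix(sample_confounders(mc_n))
  Z <- sample_z(mc_n, params)
  zsum <- if (ncol(Z) > 0L) rowSums(Z) else numeric(mc_n)
  pm1 <- stats::plogis(params$m0 + params$a + drop(C %*% params$conf_m))
  pm0 <- stats::plogis(params$m0 + drop(C %*% params$conf_m))
  lpy <- params$y0 + drop(C %*% params$conf_y) + params$z_y * zsum  # T = 0
  contrib <- (stats::plogis(lpy + params$b) - stats::plogis(lpy)) * (pm1 - pm0)
  est <- mean(contrib)
  structure(est, mc_se = stats::sd(contrib) / sqrt(mc_n), mc_n = mc_n)
}

#' Simulate a linear-Gaussian mediation dataset
#'
#' The identity-link benchmark: \eqn{T ~ Bern(0.5)},
#' \eqn{M = aT + e_1}, \eqn{Y = bM + cT + e_2} with standard normal
#' errors. Under this model the true natural indirect effect is exactly
#' the product \eqn{a b}.
#'
#' @param n number of rows.
#' @param a,b,c_direct structural coefficients.
#' @param seed integer seed.
#' @return data frame \code{T}, \code{M}, \code{Y}.
#' @export
simulate_linear_dataset <- function(n, a = 0.5, b = 0.4, c_direct = 0.2,
                                    seed) {
  set.seed(seed)
  Tt <- stats::rbinom(n, 1L, 0.5)
  M <- a * Tt + stats::rnorm(n)
  Y <- b * M + c_direct * Tt + stats::rnorm(n)
  data.frame(T = Tt, M = M, Y = Y)
}

#' Configuration for a full synthetic cohort with companion CKG
#'
#' Describes the study conditions of a planted-truth experiment: how many
#' persons, how many hypothesis blocks of each kind, and the structural
#' coefficients shared by the blocks. Block kinds:
#' \describe{
#'   \item{planted}{true adverse effect, \code{b = b_planted > 0};}
#'   \item{null}{drug taken but no drug-to-outcome effect (\code{b = 0});}
#'   \item{contradicted_indication}{null block whose drug is additionally
#'     indicated for the outcome (the treatment-overlap decoy the first
#'     contradiction rule must remove);}
#'   \item{contradicted_side_effect}{null block where a further drug lists
#'     both diseases as side effects (the common-downstream decoy for the
#'     second rule);}
#'   \item{unsupported}{progression and indication edges exist but the drug
#'     is never prescribed in the cohort (removed by the support filter).}
#' }
#' Every block writes its progression edge (indication to outcome),
#' indication edge (drug to indication) and \code{is_a} edges (each dotted
#' code to its 3-character category) into the companion graph, so the graph
#' contains the planted hypotheses as testable candidates plus one decoy
#' class per filter rule. Event dates respect indication before (or equal
#' to) prescription before outcome, drawn uniformly in ordered windows
#' within the study period.
#'
#' @param n_persons cohort size (default 10000).
#' @param n_planted,n_null,n_contradicted,n_common_se,n_unsupported block
#'   counts.
#' @param params shared [binary_params()]; \code{b} is overridden to
#'   \code{b_planted} for planted blocks and 0 elsewhere.
#' @param b_planted planted drug-to-outcome coefficient.
#' @param date_start,date_end study window.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_persons = 10000L, n_planted = 5L, n_null = 20L,
                       n_contradicted = 2L, n_common_se = 2L,
                       n_unsupported = 2L,
                       params = binary_params(n_z = 2L), b_planted = 1.2,
                       date_start = as.Date("2000-01-01"),
                       date_end = as.Date("2015-12-31")) {
  stopifnot(n_persons > 0, inherits(params, "binary_params"))
  types <- rep(c("planted", "null", "contradicted_indication",
                 "contradicted_side_effect", "unsupported"),
               c(n_planted, n_null, n_contradicted, n_common_se,
                 n_unsupported))
  k <- length(types)
  hyp <- data.frame(
    indication = sprintf("A%02d.1", seq_len(k)),
    drug = sprintf("RX%03d", seq_len(k)),
    outcome = sprintf("B%02d.1", seq_len(k)),
    type = types,
    b = ifelse(types == "planted", b_planted, 0),
    stringsAsFactors = FALSE)
  structure(list(n_persons = n_persons, hypotheses = hyp, params = params,
                 date_start = date_start, date_end = date_end),
            class = "sim_config")
}

params_for_block <- function(config, i) {
  p <- config$params
  p$b <- config$hypotheses$b[i]
  p
}

rdate <- function(n, lo, hi) {
  # uniform dates in [lo, hi], elementwise bounds
  lo_n <- as.numeric(lo); hi_n <- as.numeric(hi)
  as.Date(round(lo_n + stats::runif(n) * pmax(hi_n - lo_n, 0)),
          origin = "1970-01-01")
}

#' Generate a synthetic cohort, companion CKG and ground truth
#'
#' Samples confounders once per person, then each hypothesis block
#' independently from its structural equations; emits dated diagnosis and
#' prescription records in valid indication-to-drug-to-outcome order, the
#' companion graph edge tables, and a ground-truth table with the oracle
#' NIE of every block (Monte-Carlo, exact inner expectation).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory; same seed, identical output).
#' @param oracle_mc_n confounder draws for the per-block oracle NIE.
#' @return list with \code{cohort} ([cohort]), \code{graph} ([ckg]) and
#'   \code{ground_truth} (data frame: hypothesis triple, \code{type},
#'   \code{b}, \code{true_nie}, \code{true_nie_se}).
#' @export
simulate_cohort <- function(config, seed, oracle_mc_n = 2e5) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  n <- config$n_persons
  ids <- sprintf("P%06d", seq_len(n))
  C <- sample_confounders(n)
  covariates <- data.frame(person_id = ids,
                           sex = C$sex,
                           age = round(58 + 8 * C$age_z, 1),
                           bmi = round(27 + 4.5 * C$bmi_z, 1),
                           stringsAsFactors = FALSE)

  hyp <- config$hypotheses
  d0 <- config$date_start
  d1 <- config$date_end
  span <- as.numeric(d1 - d0)
  dx_list <- list()
  rx_list <- list()

  # shared comorbidity-confounder diseases, diagnosed before the blocks
  Z <- sample_z(n, config$params)
  for (k in seq_len(ncol(Z))) {
    zi <- Z[, k] == 1L
    dx_list[[length(dx_list) + 1L]] <- data.frame(
      person_id = ids[zi], icd10 = rep(sprintf("Z%02d.1", k), sum(zi)),
      date = rdate(sum(zi), d0, d0 + span / 20), stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(hyp))) {
    blk <- sample_block(C, params_for_block(config, i), Z)
    t_date <- rdate(n, d0, d0 + span / 3)
    m_lo <- ifelse(blk$T == 1L, as.numeric(t_date), as.numeric(d0))
    m_date <- rdate(n, as.Date(m_lo, origin = "1970-01-01"), d0 + 2 * span / 3)
    y_lo <- pmax(ifelse(blk$T == 1L, as.numeric(t_date), as.numeric(d0)),
                 ifelse(blk$M == 1L, as.numeric(m_date), as.numeric(d0)))
    y_date <- rdate(n, as.Date(y_lo, origin = "1970-01-01"), d1)

    ti <- blk$T == 1L
    yi <- blk$Y == 1L
    dx_list[[length(dx_list) + 1L]] <- data.frame(
      person_id = c(ids[ti], ids[yi]),
      icd10 = c(rep(hyp$indication[i], sum(ti)), rep(hyp$outcome[i], sum(yi))),
      date = c(t_date[ti], y_date[yi]), stringsAsFactors = FALSE)
    if (hyp$type[i] != "unsupported") {
      mi <- blk$M == 1L
      rx_list[[length(rx_list) + 1L]] <- data.frame(
        person_id = ids[mi], rxnorm = rep(hyp$drug[i], sum(mi)),
        date = m_date[mi], stringsAsFactors = FALSE)
    }
  }
  diagnoses <- do.call(rbind, dx_list)
  prescriptions <- do.call(rbind, rx_list)
  coh <- cohort(diagnoses, prescriptions, covariates)

  graph <- companion_graph(config)

  oracle <- lapply(seq_len(nrow(hyp)), function(i) {
    true_nie(params_for_block(config, i), mc_n = oracle_mc_n,
             seed = seed + i)
  })
  gt <- hyp
  gt$indication <- normalize_icd10(gt$indication)
  gt$outcome <- normalize_icd10(gt$outcome)
  gt$true_nie <- vapply(oracle, as.numeric, 0.0)
  gt$true_nie_se <- vapply(oracle, attr, 0.0, "mc_se")

  list(cohort = coh, graph = graph, ground_truth = gt)
}

companion_graph <- function(config) {
  hyp <- config$hypotheses
  ind <- normalize_icd10(hyp$indication)
  out <- normalize_icd10(hyp$outcome)
  e <- list(
    data.frame(source = ind, relation = "progression", target = out),
    data.frame(source = hyp$drug, relation = "indication", target = ind),
    data.frame(source = c(ind, out), relation = "is_a",
               target = icd10_category(c(ind, out))),
    # benign documented side effects (never both diseases of one pair)
    data.frame(source = hyp$drug, relation = "side_effect", target = out)
  )
  n_z <- config$params$n_z
  if (n_z > 0L) {
    zc <- normalize_icd10(sprintf("Z%02d.1", seq_len(n_z)))
    e <- c(e, list(
      data.frame(source = rep(zc, each = 2L * nrow(hyp)),
                 relation = "progression",
                 target = rep(c(ind, out), n_z)),
      data.frame(source = zc, relation = "is_a", target = icd10_category(zc))))
  }
  ci <- hyp$type == "contradicted_indication"
  if (any(ci)) {
    e <- c(e, list(data.frame(source = hyp$drug[ci], relation = "indication",
                              target = out[ci])))
  }
  cs <- which(hyp$type == "contradicted_side_effect")
  if (length(cs) > 0L) {
    extra <- sprintf("RXSE%02d", seq_along(cs))
    e <- c(e, list(
      data.frame(source = rep(extra, 2L), relation = "side_effect",
                 target = c(ind[cs], out[cs]))))
  }
  edges <- do.call(rbind, e)
  edges$provenance <- "synthetic"
  ckg(edges)
}

#' Simulate a severity-confounded cohort block
#'
#' Reproduces the classic pharmacovigilance false-positive pattern: a
#' latent severity variable drives both the prescription of the drug and
#' the outcome, while the drug itself has no effect (\code{b = 0}).
#' Severity also inflates the person's number of recorded comorbid
#' conditions and prescriptions, so the observable severity proxies carry
#' the confounder signal: adjusting for them shrinks the spurious mediated
#' effect.
#'
#' @param n number of persons.
#' @param s_m,s_y severity log-odds effects on prescription and outcome.
#' @param params baseline [binary_params()] (its \code{b} is forced to 0).
#' @param seed integer seed.
#' @return data frame \code{T}, \code{M}, \code{Y}, confounders,
#'   \code{comorbidity_count}, \code{prescription_count} and the latent
#'   \code{severity}.
#' @export
simulate_severity_block <- function(n, s_m = 1.2, s_y = 1.2,
                                    params = binary_params(), seed) {
  set.seed(seed)
  p <- params
  p$b <- 0
  C <- sample_confounders(n)
  Cm <- as.matrix(C)
  S <- stats::rnorm(n)
  Tt <- stats::rbinom(n, 1L, stats::plogis(p$t0 + drop(Cm %*% p$conf_t)))
  M <- stats::rbinom(n, 1L, stats::plogis(p$m0 + p$a * Tt + s_m * S +
                                            drop(Cm %*% p$conf_m)))
  Y <- stats::rbinom(n, 1L, stats::plogis(p$y0 + p$c_direct * Tt + s_y * S +
                                            drop(Cm %*% p$conf_y)))
  cc <- stats::rpois(n, exp(1.0 + 0.8 * S))
  pc <- stats::rpois(n, exp(0.7 + 0.8 * S))
  cbind(data.frame(T = Tt, M = M, Y = Y), C,
        data.frame(comorbidity_count = cc, prescription_count = pc,
                   severity = S))
}
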