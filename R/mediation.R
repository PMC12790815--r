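#' @importFrom stats delete.response terms
NULL

family_for <- function(y) {
  if (is_binary(y)) stats::binomial() else stats::gaussian()
}

robust_vcov <- function(fit) {
  # sandwich warns on hat values near 1; non-finite results are handled
  # explicitly below (hypothesis flagged untestable), so the warning is
  # redundant here
  v <- suppressWarnings(sandwich::vcovHC(fit, type = "HC3"))
  if (any(!is.finite(v))) return(NULL)
  # symmetrize tiny numerical asymmetry
  (v + t(v)) / 2
}

model_matrix_at <- function(fit, data) {
  tt <- stats::delete.response(stats::terms(fit))
  stats::model.matrix(tt, data, xlev = fit$xlevels)
}

fit_ok <- function(fit) {
  isTRUE(fit$converged) && !anyNA(stats::coef(fit)) &&
    all(abs(stats::coef(fit)) < 20 | fit$family$family != "binomial")
}

untestable <- function(reason) {
  structure(list(status = reason), class = "fitted_models")
}

#' Fit the mediator and outcome regressions for one hypothesis
#'
#' Fits a mediator model \code{M ~ T + X} and an outcome model
#' \code{Y ~ T + M (+ T:M) + X} with a logistic link for binary responses
#' (identity/Gaussian otherwise), storing HC3
#' heteroskedasticity-consistent coefficient covariances. The
#' treatment-by-mediator interaction is screened: it is kept only when its
#' robust Wald p-value is below \code{interaction_alpha}, otherwise the
#' outcome model is refitted without it.
#'
#' @param table an \code{analysis_table} with columns \code{T}, \code{M},
#'   \code{Y}.
#' @param covariates character vector of covariate columns to adjust for.
#' @param interaction_alpha screening level for the interaction term
#'   (default 0.05).
#' @return object of class \code{fitted_models} with components
#'   \code{mediator}, \code{outcome}, \code{vcov_m}, \code{vcov_y},
#'   \code{interaction_included}, \code{status}. Degenerate inputs
#'   (constant T/M/Y, non-convergence, separation) give
#'   \code{status != "ok"} instead of an error.
#' @export
fit_models <- function(table, covariates = character(0),
                       interaction_alpha = 0.05) {
  stopifnot(all(c("T", "M", "Y") %in% names(table)))
  covariates <- setdiff(covariates, c("T", "M", "Y", "person_id"))
  stopifnot(all(covariates %in% names(table)))
  df <- as.data.frame(table)
  df <- df[stats::complete.cases(df[, c("T", "M", "Y", covariates),
                                    drop = FALSE]), , drop = FALSE]
  for (v in c("T", "M", "Y")) {
    if (length(unique(df[[v]])) < 2L) return(untestable("NA_degenerate"))
  }
  covs <- if (length(covariates) > 0L) paste("+", paste(covariates, collapse = " + ")) else ""
  f_m <- stats::as.formula(paste("M ~ T", covs))
  fam_m <- family_for(df$M)
  fam_y <- family_for(df$Y)

  fit_m <- tryCatch(
    suppressWarnings(stats::glm(f_m, family = fam_m, data = df)),
    error = function(e) NULL)
  if (is.null(fit_m) || !fit_ok(fit_m)) return(untestable("NA_separation"))

  f_y_int <- stats::as.formula(paste("Y ~ T * M", covs))
  fit_y <- tryCatch(
    suppressWarnings(stats::glm(f_y_int, family = fam_y, data = df)),
    error = function(e) NULL)

  interaction_included <- FALSE
  if (!is.null(fit_y) && fit_ok(fit_y)) {
    vy <- robust_vcov(fit_y)
    if (!is.null(vy)) {
      b <- stats::coef(fit_y)["T:M"]
      se <- sqrt(vy["T:M", "T:M"])
      p_int <- 2 * stats::pnorm(-abs(b / se))
      interaction_included <- is.finite(p_int) && p_int < interaction_alpha
    }
  }
  if (!interaction_included) {
    f_y <- stats::as.formula(paste("Y ~ T + M", covs))
    fit_y <- tryCatch(
      suppressWarnings(stats::glm(f_y, family = fam_y, data = df)),
      error = function(e) NULL)
  }
  if (is.null(fit_y) || !fit_ok(fit_y)) return(untestable("NA_separation"))

  vm <- robust_vcov(fit_m)
  vy <- robust_vcov(fit_y)
  if (is.null(vm) || is.null(vy)) return(untestable("NA_separation"))

  structure(list(mediator = fit_m, outcome = fit_y,
                 vcov_m = vm, vcov_y = vy,
                 interaction_included = interaction_included,
                 data = df, status = "ok"),
            class = "fitted_models")
}

linkinv_mat <- function(fam, lp) {
  # logistic inverse link, written out: measurably faster than plogis on
  # the large n-by-sims matrices used here
  if (fam$family == "binomial") 1 / (1 + exp(-lp)) else lp
}

#' Quasi-Bayesian estimation of the average causal mediation effect
#'
#' Estimates the natural indirect effect
#' \eqn{E[Y(0, M(1)) - Y(0, M(0))]} — the average causal mediation effect
#' (ACME) — by parametric simulation: \code{sims} coefficient vectors are
#' drawn from the asymptotic normal approximation (mean = point estimates,
#' covariance = HC3 robust covariance) for both regressions; for each draw
#' and each observed covariate row, the mediator distribution under
#' \eqn{T=0} and \eqn{T=1} and the potential-outcome expectations
#' \eqn{E[Y(t, M(t'))]} are computed by exact summation over the binary
#' mediator (no mediator resampling — the coefficient draw is the only
#' stochastic element). The average direct effect (ADE, at \eqn{t=1}) and
#' the total effect are computed analogously; per draw the identity
#' total = ACME(0) + ADE(1) holds exactly.
#'
#' For a continuous (Gaussian, identity-link) mediator the summation is
#' replaced by the plug-in mean, valid because the outcome model is then
#' required to be linear in the mediator.
#'
#' @param models a \code{fitted_models} object with \code{status == "ok"}.
#' @param sims number of coefficient draws (default 1000, minimum 100).
#' @param seed integer seed (required; the draw sequence is fully
#'   reproducible from it).
#' @return object of class \code{mediation_result}: \code{acme},
#'   \code{acme_ci} (2.5/97.5 percentile), \code{p_value} (two-sided
#'   simulation tail probability, floored at \code{1/sims}), \code{ade},
#'   \code{total_effect}, \code{prop_mediated} (draw-median of
#'   ACME/total), \code{interaction_included}, \code{n}, \code{sims},
#'   \code{seed}, \code{draws}.
#' @export
estimate_acme <- function(models, sims = 1000L, seed) {
  stopifnot(inherits(models, "fitted_models"))
  if (!identical(models$status, "ok")) {
    return(structure(list(status = models$status, acme = NA_real_,
                          p_value = NA_real_),
                     class = "mediation_result"))
  }
  if (missing(seed)) stop("seed is required for reproducibility")
  stopifnot(sims >= 100L)
  df <- models$data
  n <- nrow(df)
  fam_m <- models$mediator$family
  fam_y <- models$outcome$family
  binary_m <- fam_m$family == "binomial"
  if (!binary_m && fam_y$family == "binomial") {
    stop("continuous mediator with binary outcome is not supported")
  }

  set.seed(seed)
  bm <- MASS::mvrnorm(sims, stats::coef(models$mediator), models$vcov_m)
  by <- MASS::mvrnorm(sims, stats::coef(models$outcome), models$vcov_y)

  at <- function(fit, Tval, Mval) {
    nd <- df
    nd$T <- Tval
    nd$M <- Mval
    model_matrix_at(fit, nd)
  }
  # mediator distribution under each treatment arm: n x sims
  pm0 <- linkinv_mat(fam_m, at(models$mediator, 0, df$M) %*% t(bm))
  pm1 <- linkinv_mat(fam_m, at(models$mediator, 1, df$M) %*% t(bm))

  # outcome linear predictor is linear in M given T: lp(t, m) = A_t + m B_t
  lp <- function(t, m) at(models$outcome, t, m) %*% t(by)
  if (binary_m) {
    py00 <- linkinv_mat(fam_y, lp(0, 0))
    py01 <- linkinv_mat(fam_y, lp(0, 1))
    py10 <- linkinv_mat(fam_y, lp(1, 0))
    py11 <- linkinv_mat(fam_y, lp(1, 1))
    ey00 <- colMeans(py01 * pm0 + py00 * (1 - pm0))
    ey01 <- colMeans(py01 * pm1 + py00 * (1 - pm1))
    ey11 <- colMeans(py11 * pm1 + py10 * (1 - pm1))
  } else {
    l00 <- lp(0, 0); l01 <- lp(0, 1)
    l10 <- lp(1, 0); l11 <- lp(1, 1)
    ey00 <- colMeans(l00 + pm0 * (l01 - l00))
    ey01 <- colMeans(l00 + pm1 * (l01 - l00))
    ey11 <- colMeans(l10 + pm1 * (l11 - l10))
  }

  acme_d <- ey01 - ey00          # ACME at t = 0
  ade_d <- ey11 - ey01           # ADE at t = 1
  tot_d <- ey11 - ey00
  if (any(!is.finite(c(acme_d, ade_d)))) {
    stop("non-finite effect draws; check model fits")
  }

  pval <- function(d) {
    max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / length(d))
  }
  structure(list(
    acme = mean(acme_d),
    acme_ci = stats::quantile(acme_d, c(0.025, 0.975), names = FALSE),
    p_value = min(pval(acme_d), 1),
    ade = mean(ade_d),
    total_effect = mean(tot_d),
    total_ci = stats::quantile(tot_d, c(0.025, 0.975), names = FALSE),
    prop_mediated = stats::median(acme_d / tot_d),
    interaction_included = models$interaction_included,
    n = n, sims = sims, seed = seed,
    draws = list(acme = acme_d, ade = ade_d, total = tot_d),
    status = "ok"
  ), class = "mediation_result")
}

#' Fit and estimate in one step
#'
#' Convenience wrapper: [fit_models()] then [estimate_acme()], propagating
#' untestable statuses as a result row rather than an error.
#'
#' @inheritParams fit_models
#' @inheritParams estimate_acme
#' @return a \code{mediation_result}.
#' @export
mediate_hypothesis <- function(table, covariates = character(0),
                               sims = 1000L, seed,
                               interaction_alpha = 0.05) {
  m <- fit_models(table, covariates, interaction_alpha)
  estimate_acme(m, sims = sims, seed = seed)
}

#' @export
print.mediation_result <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat("Mediation result: untestable (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "ACME = %.5f [%.5f, %.5f], p = %.4g (n = %d, sims = %d)\n",
    x$acme, x$acme_ci[1], x$acme_ci[2], x$p_value, x$n, x$sims))
  cat(sprintf("ADE = %.5f, total = %.5f, prop. mediated = %.3f%s\n",
              x$ade, x$total_effect, x$prop_mediated,
              if (x$interaction_included) " (T:M interaction)" else ""))
  invisible(x)
}

#' Benjamini-Hochberg correction across mediation results
#'
#' Applies the step-up BH procedure once over all testable hypotheses in a
#' run and classifies each result the way pharmacovigilance summaries
#' tabulate them: untestable (\code{"N/A"}), \code{"insignificant"},
#' \code{"positive"} (significant ACME > 0, the adverse-effect signal) or
#' \code{"negative"} (significant ACME < 0, a protective signal).
#'
#' @param results list of \code{mediation_result} objects, or a data frame
#'   with columns \code{p_value}, \code{acme}, \code{status}.
#' @param alpha FDR level (default 0.05).
#' @return data frame with \code{p_value}, \code{q_value},
#'   \code{significant}, \code{category}.
#' @export
bh_correct <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) {
    df <- results
  } else {
    df <- data.frame(
      p_value = vapply(results, function(r) r$p_value %||% NA_real_, 0.0),
      acme = vapply(results, function(r) r$acme %||% NA_real_, 0.0),
      status = vapply(results, function(r) r$status, ""),
      stringsAsFactors = FALSE)
  }
  ok <- df$status == "ok" & !is.na(df$p_value)
  df$q_value <- NA_real_
  df$q_value[ok] <- stats::p.adjust(df$p_value[ok], method = "BH")
  df$significant <- !is.na(df$q_value) & df$q_value <= alpha
  df$category <- ifelse(!ok, "N/A",
                        ifelse(!df$significant, "insignificant",
                               ifelse(df$acme > 0, "positive", "negative")))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
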