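is_binary <- function(x) all(x %in% c(0, 1))

#' LASSO covariate selection for one model
#'
#' Shrinks a graph-derived candidate adjustment set by L1-penalized
#' regression of the indication (\code{T}) or the outcome (\code{Y}) on the
#' candidate covariates. Binary targets use logistic loss; the
#' regularization strength is chosen to minimize k-fold cross-validation
#' error (deviance), with fold assignment fully determined by \code{seed}.
#' Covariates are standardized to unit variance before penalization and
#' reported on the original scale. Covariates with non-zero coefficients at
#' the chosen lambda are selected.
#'
#' @param table an \code{analysis_table} (or data frame with the needed
#'   columns).
#' @param target \code{"indication"} (regress \code{T}) or
#'   \code{"outcome"} (regress \code{Y}).
#' @param candidates character vector of candidate covariate columns.
#' @param folds number of CV folds (default 10; reduced with a warning when
#'   the table has fewer rows).
#' @param seed integer seed for fold assignment.
#' @param lambda optional fixed penalty; when supplied CV is skipped (used
#'   for limit checks).
#' @return object of class \code{lasso_selection}: \code{target},
#'   \code{lambda}, \code{selected}, \code{coefficients},
#'   \code{cv_error_curve}.
#' @export
select_covariates <- function(table, target = c("indication", "outcome"),
                              candidates, folds = 10L, seed = 1L,
                              lambda = NULL) {
  target <- match.arg(target)
  ycol <- if (target == "indication") "T" else "Y"
  stopifnot(ycol %in% names(table), all(candidates %in% names(table)))
  y <- table[[ycol]]
  if (length(candidates) == 0L || length(unique(y)) < 2L) {
    if (length(unique(y)) < 2L) warning("constant target column; empty selection")
    return(structure(list(target = target, lambda = NA_real_,
                          selected = character(0),
                          coefficients = numeric(0),
                          cv_error_curve = data.frame(lambda = numeric(0),
                                                      error = numeric(0))),
                     class = "lasso_selection"))
  }
  X <- as.matrix(table[, candidates, drop = FALSE])
  storage.mode(X) <- "double"
  if (ncol(X) == 1L) {
    # glmnet needs >= 2 columns; a constant dummy never gets selected
    X <- cbind(X, `.dummy` = 0)
  }
  fam <- if (is_binary(y)) "binomial" else "gaussian"

  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(X, y, family = fam, lambda = lambda,
                          standardize = TRUE)
    cvc <- data.frame(lambda = lambda, error = NA_real_)
    lam <- lambda
  } else {
    nf <- folds
    if (nrow(X) < folds) {
      nf <- max(3L, nrow(X) %/% 2L)
      warning(sprintf("fewer rows than folds; using %d folds", nf))
    }
    old <- .Random.seed_exists()
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nf), nrow(X)))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    cv <- glmnet::cv.glmnet(X, y, family = fam, foldid = foldid,
                            standardize = TRUE)
    fit <- cv$glmnet.fit
    cvc <- data.frame(lambda = cv$lambda, error = cv$cvm)
    lam <- cv$lambda.min
  }
  beta <- as.matrix(coef(fit, s = lam))[, 1L]
  beta <- beta[setdiff(names(beta), c("(Intercept)", ".dummy"))]
  sel <- names(beta)[beta != 0]
  structure(list(target = target, lambda = lam,
                 selected = sort(intersect(sel, candidates)),
                 coefficients = beta,
                 cv_error_curve = cvc),
            class = "lasso_selection")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' Union of the covariates selected for the indication and outcome models
#'
#' Two separate penalized models are fitted (one per target); the variables
#' selected in either are used for adjustment.
#'
#' @param sel_T,sel_Y \code{lasso_selection} objects over the same
#'   candidate pool.
#' @return sorted character vector of covariate ids.
#' @export
union_selection <- function(sel_T, sel_Y) {
  stopifnot(inherits(sel_T, "lasso_selection"),
            inherits(sel_Y, "lasso_selection"))
  sort(union(sel_T$selected, sel_Y$selected))
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("LASSO selection (%s): lambda = %.4g, %d selected\n",
              x$target, x$lambda, length(x$selected)))
  invisible(x)
}
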