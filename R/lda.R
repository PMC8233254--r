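#' Fit a two-class LDA on ERP features
#'
#' Three variants differing only in the covariance estimate:
#' \describe{
#'   \item{`"p-cov"`}{pooled class-centered covariance with analytic
#'     Ledoit-Wolf shrinkage — the standard shrinkage LDA.}
#'   \item{`"c-covs"`}{per-class covariances averaged (weights proportional
#'     to `n_class - 1`), then shrunk.}
#'   \item{`"imp-p-cov"`}{the time-decoupled estimator of
#'     [time_decoupled_covariance()].}
#' }
#' Weights solve `Sigma w = mu1 - mu0` through a Cholesky factorization
#' (never an explicit inverse); the bias centers the decision score at the
#' class-mean midpoint, and the orientation is fixed so that a higher score
#' means target. There is no class-prior term in the bias: class imbalance
#' is handled by threshold-free AUC scoring downstream.
#'
#' @param fm A [feature_matrix()] with both classes present.
#' @param variant `"p-cov"`, `"c-covs"`, or `"imp-p-cov"`.
#' @param gamma Optional fixed shrinkage intensity overriding the analytic
#'   Ledoit-Wolf value (for `"p-cov"`/`"c-covs"`).
#' @param ... Further arguments to [time_decoupled_covariance()] for the
#'   `"imp-p-cov"` variant (e.g. `psd_policy`).
#' @return An object of class `tdlda_model` with fields `w`, `b`, `means`,
#'   `covariance`, `variant`.
#' @export
lda_fit <- function(fm, variant = c("p-cov", "c-covs", "imp-p-cov"),
                    gamma = NULL, ...) {
  variant <- match.arg(variant)
  stopifnot(inherits(fm, "feature_matrix"))
  means <- class_means(fm)
  cov_est <- switch(variant,
    "p-cov" = {
      sig_hat <- pooled_sample_covariance(fm, means)
      g <- if (is.null(gamma)) ledoit_wolf_gamma(center_classwise(fm, means))
           else gamma
      shrink_covariance(sig_hat, g)
    },
    "c-covs" = {
      if (is.null(gamma)) classwise_average_covariance(fm)
      else shrink_covariance(classwise_average_covariance(fm, shrink = FALSE),
                             gamma)
    },
    "imp-p-cov" = time_decoupled_covariance(fm, ...))

  d <- means$mu1 - means$mu0
  ch <- tryCatch(chol(cov_est$matrix), error = function(e) NULL)
  if (is.null(ch)) {
    kap <- tryCatch(kappa(cov_est$matrix, exact = FALSE),
                    error = function(e) NA_real_)
    stop(sprintf("covariance for variant '%s' is singular after regularization (condition estimate %.3e)",
                 variant, kap))
  }
  w <- backsolve(ch, forwardsolve(t(ch), d))
  b <- -0.5 * sum(w * (means$mu0 + means$mu1))
  structure(list(w = as.numeric(w), b = b, means = means,
                 covariance = cov_est, variant = variant),
            class = "tdlda_model")
}

#' @export
print.tdlda_model <- function(x, ...) {
  cat(sprintf("<tdlda_model> variant = %s, D = %d, covariance kind = %s",
              x$variant, length(x$w), x$covariance$kind))
  if (!is.null(x$covariance$gamma))
    cat(sprintf(", gamma = %.4f", x$covariance$gamma))
  cat("\n")
  invisible(x)
}

#' Linear decision scores
#'
#' `score = w' x + b`; positive scores favor the target class and the score
#' is exactly zero at the midpoint of the class means.
#'
#' @param model A fitted `tdlda_model`.
#' @param X A [feature_matrix()], or a `D x N` matrix / length-`D` vector of
#'   features.
#' @return Numeric vector of per-epoch scores.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "tdlda_model"))
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != length(model$w))
    stop(sprintf("feature dimensionality %d does not match model dimension %d",
                 nrow(X), length(model$w)))
  as.numeric(crossprod(X, model$w)) + model$b
}

#' @export
predict.tdlda_model <- function(object, newdata, ...) {
  decision_scores(object, newdata)
}
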