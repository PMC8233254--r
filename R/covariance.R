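#' Covariance estimate container
#'
#' A symmetric matrix with provenance: its estimator kind, the block layout
#' `(C, K)` of the channel-by-interval feature stacking, the shrinkage
#' intensity used (if any), the shrinkage target level (the mean of the
#' diagonal), and a log of positive-definiteness repairs.
#'
#' @param matrix Symmetric numeric matrix.
#' @param kind One of `"sample"`, `"shrunk"`, `"channel"`,
#'   `"time_decoupled"`, `"population"`.
#' @param layout Optional integer pair `(C, K)`.
#' @param gamma Optional shrinkage intensity in `[0, 1]`.
#' @param diag_mean Optional mean of the diagonal of the unshrunk matrix.
#' @param psd_log Optional character vector of PSD-repair events.
#' @return An object of class `cov_estimate`.
#' @export
cov_estimate <- function(matrix, kind, layout = NULL, gamma = NULL,
                         diag_mean = NULL, psd_log = character()) {
  kind <- match.arg(kind, c("sample", "shrunk", "channel",
                            "time_decoupled", "population"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("matrix must be square")
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix))))
    stop("matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  if (!is.null(layout) && prod(layout) != nrow(matrix) && kind != "channel")
    stop("layout (C, K) inconsistent with matrix dimension")
  structure(list(matrix = matrix, kind = kind, layout = layout,
                 gamma = gamma, diag_mean = diag_mean, psd_log = psd_log),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf("<cov_estimate> %d x %d, kind = %s", nrow(x$matrix),
              ncol(x$matrix), x$kind))
  if (!is.null(x$layout))
    cat(sprintf(", layout = %d channels x %d intervals", x$layout[1],
                x$layout[2]))
  if (!is.null(x$gamma)) cat(sprintf(", gamma = %.4f", x$gamma))
  cat("\n")
  if (length(x$psd_log))
    cat("  PSD repairs:", paste(x$psd_log, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize / load a covariance estimate
#'
#' Writes `metadata.json` (kind, layout, gamma, diagonal mean, PSD-repair
#' log) plus `matrix.csv` into a directory so that benchmark runs remain
#' auditable.
#'
#' @param x A [cov_estimate()].
#' @param path Directory.
#' @export
write_cov_estimate <- function(x, path) {
  stopifnot(inherits(x, "cov_estimate"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(kind = x$kind, layout = x$layout, gamma = x$gamma,
         diag_mean = x$diag_mean, psd_log = x$psd_log, dim = nrow(x$matrix)),
    file.path(path, "metadata.json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(x$matrix, file.path(path, "matrix.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cov_estimate
#' @export
read_cov_estimate <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(path, "matrix.csv"), sep = ","))
  dimnames(m) <- NULL
  cov_estimate((m + t(m)) / 2, kind = meta$kind, layout = meta$layout,
               gamma = meta$gamma, diag_mean = meta$diag_mean,
               psd_log = if (length(meta$psd_log)) meta$psd_log else character())
}

#' Class-wise feature means
#'
#' @param fm A [feature_matrix()] with both classes present.
#' @return List with `mu0` (non-target) and `mu1` (target) length-`D` means.
#' @export
class_means <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!any(fm$labels == 0L) || !any(fm$labels == 1L))
    stop("both classes must be present")
  list(mu0 = rowMeans(fm$X[, fm$labels == 0L, drop = FALSE]),
       mu1 = rowMeans(fm$X[, fm$labels == 1L, drop = FALSE]))
}

# Class-wise mean-free data matrix (each column minus its class mean).
center_classwise <- function(fm, means = class_means(fm)) {
  M <- matrix(0, nrow(fm$X), ncol(fm$X))
  M[, fm$labels == 0L] <- means$mu0
  M[, fm$labels == 1L] <- means$mu1
  fm$X - M
}

#' Pooled sample covariance of class-centered features
#'
#' Removes the class-wise means, pools both classes and computes the sample
#' covariance `S = Xt %*% t(Xt) / (N - 1)`. With `N - 2 < D` the result is
#' rank deficient (two means are subtracted) and cannot be inverted — the
#' situation the shrinkage and time-decoupled estimators address.
#'
#' @param fm A [feature_matrix()] with `N >= 2`.
#' @param means Optional precomputed [class_means()].
#' @return A [cov_estimate()] of kind `"sample"`.
#' @export
pooled_sample_covariance <- function(fm, means = class_means(fm)) {
  if (ncol(fm$X) < 2) stop("need at least 2 epochs")
  Xt <- center_classwise(fm, means)
  S <- Xt %*% t(Xt) / (ncol(Xt) - 1)
  cov_estimate(S, kind = "sample", layout = c(fm$n_channels, fm$n_intervals))
}

#' Class-wise averaged covariance
#'
#' Estimates one sample covariance per class and combines them into a common
#' matrix, by default weighted proportionally to `n_class - 1` (the pooled
#' within-class scatter convention used by standard toolbox LDA
#' implementations); an unweighted average is available since either reading
#' of "averaging the class matrices" is defensible. Optionally
#' shrinkage-regularized like the pooled variant.
#'
#' @param fm A [feature_matrix()] with at least 2 epochs per class.
#' @param weighted Weight classes by `n_class - 1` (default) or equally.
#' @param shrink Apply Ledoit-Wolf shrinkage to the averaged matrix.
#' @return A [cov_estimate()] (kind `"shrunk"` if `shrink`, else `"sample"`).
#' @export
classwise_average_covariance <- function(fm, weighted = TRUE, shrink = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  counts <- table(factor(fm$labels, levels = c(0L, 1L)))
  if (any(counts < 2)) stop("need at least 2 epochs per class")
  covs <- lapply(c(0L, 1L), function(cls) {
    Xc <- fm$X[, fm$labels == cls, drop = FALSE]
    Xc <- Xc - rowMeans(Xc)
    Xc %*% t(Xc) / (ncol(Xc) - 1)
  })
  wts <- if (weighted) (as.numeric(counts) - 1) / sum(as.numeric(counts) - 1)
         else c(0.5, 0.5)
  S <- wts[1] * covs[[1]] + wts[2] * covs[[2]]
  out <- cov_estimate(S, kind = "sample",
                      layout = c(fm$n_channels, fm$n_intervals))
  if (!shrink) return(out)
  g <- ledoit_wolf_gamma(center_classwise(fm))
  shrink_covariance(out, g)
}

#' Analytic Ledoit-Wolf shrinkage intensity
#'
#' Optimal intensity for shrinking a sample covariance toward the scaled
#' identity target `mean(diag) * I`, after Ledoit & Wolf (2004), computed on
#' already mean-free data with `1/N` internal scaling (the convention of the
#' reference implementation in scikit-learn with `assume_centered = TRUE`).
#' Clipped to `[0, 1]`; defined as 1 for zero-variance data.
#'
#' @param Xtilde `D x N` mean-free data matrix (columns = observations).
#' @return Shrinkage intensity in `[0, 1]`.
#' @export
ledoit_wolf_gamma <- function(Xtilde) {
  Xtilde <- as.matrix(Xtilde)
  D <- nrow(Xtilde); N <- ncol(Xtilde)
  if (N < 2) return(1)
  S <- Xtilde %*% t(Xtilde) / N
  mu <- mean(diag(S))
  d2 <- (sum(S^2) - 2 * mu * sum(diag(S)) + D * mu^2) / D
  if (d2 <= .Machine$double.eps * mu^2) return(1)
  # (1/N^2) * sum_i ||x_i x_i' - S||_F^2 / D  ==  (sum_i (x_i'x_i)^2 / N^2 - ||S||_F^2 / N) / D
  sq_norms <- colSums(Xtilde^2)
  b2 <- (sum(sq_norms^2) / N^2 - sum(S^2) / N) / D
  min(max(min(b2, d2) / d2, 0), 1)
}

#' Shrink a covariance matrix toward the scaled identity
#'
#' `S_shrunk = (1 - gamma) * S + gamma * mean(diag(S)) * I`. The trace is
#' preserved for every `gamma`; for `gamma > 0` the result is strictly
#' positive definite whenever `S` is PSD with a positive diagonal mean.
#'
#' @param sigma_hat A [cov_estimate()] or plain symmetric matrix.
#' @param gamma Shrinkage intensity in `[0, 1]`.
#' @return A [cov_estimate()] of kind `"shrunk"`.
#' @export
shrink_covariance <- function(sigma_hat, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  layout <- NULL
  if (inherits(sigma_hat, "cov_estimate")) {
    layout <- sigma_hat$layout
    sigma_hat <- sigma_hat$matrix
  }
  nu_bar <- mean(diag(sigma_hat))
  S <- (1 - gamma) * sigma_hat
  diag(S) <- diag(S) + gamma * nu_bar
  cov_estimate(S, kind = "shrunk", layout = layout, gamma = gamma,
               diag_mean = nu_bar)
}

#' Rearrange class-centered features into the channel-sample matrix
#'
#' Treats each epoch's per-interval channel vector as an independent
#' observation of the between-channel structure, yielding a `C x (N * K)`
#' matrix with `N * K` columns instead of `N` — the sample-size gain that
#' makes the decoupled channel covariance estimable from tiny epoch counts.
#' When interval widths `|T_m|` differ, interval `m`'s columns are multiplied
#' by `sqrt(|T_m|)` to equalize the variance of the interval means before
#' pooling (averaging white noise over `|T_m|` samples divides its variance
#' by `|T_m|`).
#'
#' @param Xtilde `D x N` class-wise mean-free feature matrix (means removed
#'   in feature space first, then scaled).
#' @param n_channels,n_intervals Layout `(C, K)`.
#' @param widths Per-interval sample counts `|T_m|`.
#' @return A `C x (N * K)` matrix, columns grouped by interval.
#' @export
rearrange_channel_matrix <- function(Xtilde, n_channels, n_intervals,
                                     widths) {
  Xtilde <- as.matrix(Xtilde)
  if (nrow(Xtilde) != n_channels * n_intervals)
    stop("feature layout mismatch: nrow(Xtilde) != n_channels * n_intervals")
  if (length(widths) != n_intervals)
    stop("need one width per interval")
  blocks <- lapply(seq_len(n_intervals), function(m) {
    rows <- (m - 1L) * n_channels + seq_len(n_channels)
    sqrt(widths[m]) * Xtilde[rows, , drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Between-channel covariance from the rearranged channel matrix
#'
#' Sample covariance over the `N * K` channel observations (columns assumed
#' mean-free: class means are removed in feature space before
#' rearrangement). Shrinkage is applied only in the degenerate case where
#' the channel count exceeds the number of channel samples — with more
#' observations than channels the raw estimate is preferred.
#'
#' @param XC `C x (N * K)` matrix from [rearrange_channel_matrix()].
#' @return A [cov_estimate()] of kind `"channel"`.
#' @export
channel_covariance <- function(XC) {
  XC <- as.matrix(XC)
  if (ncol(XC) < 2) stop("need at least 2 channel samples")
  S <- XC %*% t(XC) / (ncol(XC) - 1)
  gamma <- NULL
  if (nrow(XC) > ncol(XC)) {
    gamma <- ledoit_wolf_gamma(XC)
    nu_bar <- mean(diag(S))
    S <- (1 - gamma) * S
    diag(S) <- diag(S) + gamma * nu_bar
  }
  cov_estimate(S, kind = "channel", gamma = gamma)
}

# Log-determinant via Cholesky; NULL if the matrix is not positive definite.
# Never goes through the plain determinant: det of a 31 x 31 covariance in
# microvolt^2 units routinely under/overflows double precision.
chol_logdet <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  2 * sum(log(diag(ch)))
}

#' Rescale the channel covariance to match a block's determinant
#'
#' `S_m = (det(B_m) / det(S_C))^(1/C) * S_C`, computed via log-determinants,
#' so that `det(S_m) = det(B_m)`: the overall spread described by the
#' rescaled channel covariance equals the spread described by the block it
#' will replace.
#'
#' @param sigma_C `C x C` channel covariance ([cov_estimate()] or matrix).
#' @param block `C x C` diagonal block `B_m` of the full feature covariance.
#' @return `C x C` rescaled matrix.
#' @export
rescale_to_block <- function(sigma_C, block) {
  if (inherits(sigma_C, "cov_estimate")) sigma_C <- sigma_C$matrix
  if (inherits(block, "cov_estimate")) block <- block$matrix
  if (!all(dim(sigma_C) == dim(block)))
    stop("channel covariance and block must have identical dimensions")
  C <- nrow(sigma_C)
  ld_C <- chol_logdet(sigma_C)
  if (is.null(ld_C))
    stop("channel covariance has a non-positive determinant; cannot rescale")
  ld_B <- chol_logdet(block)
  if (is.null(ld_B))
    stop("target block has a non-positive determinant; cannot rescale")
  exp((ld_B - ld_C) / C) * sigma_C
}

#' Enforce positive definiteness of a covariance estimate
#'
#' Block substitution can leave the assembled matrix with non-positive
#' eigenvalues (a failure mode observed in practice on real ERP data). Three
#' policies: `"reject"` errors; `"clip"` (default elsewhere) floors all
#' eigenvalues at `eps * lambda_max` and reconstitutes the matrix, leaving
#' the remaining eigenpairs unchanged and logging the event; `"fallback"`
#' signals the caller (condition class `tdlda_psd_fallback`) to use the
#' plain shrunk matrix instead.
#'
#' @param sigma A [cov_estimate()] or symmetric matrix.
#' @param policy `"reject"`, `"clip"`, or `"fallback"`.
#' @param eps Relative eigenvalue floor for `"clip"` (times the largest
#'   eigenvalue).
#' @param floor Optional absolute eigenvalue floor for `"clip"`, overriding
#'   `eps` (used by [time_decoupled_covariance()] to clip at the shrinkage
#'   ridge level).
#' @return The (possibly repaired) input, same type; repairs are appended to
#'   the `psd_log` of a `cov_estimate` input.
#' @export
assert_psd <- function(sigma, policy = c("reject", "clip", "fallback"),
                       eps = 1e-10, floor = NULL) {
  policy <- match.arg(policy)
  is_est <- inherits(sigma, "cov_estimate")
  m <- if (is_est) sigma$matrix else sigma
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lmin <- min(e$values)
  if (lmin > 0 && (is.null(floor) || lmin >= floor)) return(sigma)
  msg <- sprintf("smallest eigenvalue %.3e is below the positivity floor",
                 lmin)
  if (policy == "reject")
    stop("covariance matrix is not positive definite: ", msg)
  if (policy == "fallback")
    stop(structure(class = c("tdlda_psd_fallback", "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  lmax <- max(e$values)
  if (lmax <= 0)
    stop("cannot repair a matrix with no positive eigenvalue")
  lo <- if (is.null(floor)) eps * lmax else floor
  vals <- pmax(e$values, lo)
  repaired <- e$vectors %*% (vals * t(e$vectors))
  repaired <- (repaired + t(repaired)) / 2
  event <- sprintf("clipped %d eigenvalue(s); %s; floor %.3e",
                   sum(e$values < lo), msg, lo)
  message("PSD repair: ", event)
  if (is_est) {
    sigma$matrix <- repaired
    sigma$psd_log <- c(sigma$psd_log, event)
    sigma
  } else {
    repaired
  }
}

#' Time-decoupled covariance estimator
#'
#' The package's central estimator. Pipeline: (1) class-wise mean removal
#' and pooled sample covariance; (2) Ledoit-Wolf shrinkage of the full
#' `D x D` matrix; (3) read the `K` within-interval diagonal blocks
#' `B_1 ... B_K`; (4) estimate one `C x C` between-channel covariance from
#' the rearranged, `sqrt(|T_m|)`-scaled channel matrix (all `N * K` interval
#' observations jointly); (5) rescale it to match each block's determinant;
#' (6) substitute the diagonal blocks, leaving all between-interval blocks
#' untouched. Valid when the noise is homoscedastic across the epoch (not
#' time-locked to the stimulus); under that assumption the substituted
#' blocks are estimated from `K` times more observations than the blocks
#' they replace.
#'
#' The determinant targets are read from the *sample* covariance blocks
#' (the unshrunk `B_m`): shrinkage inflates every block's determinant by
#' design — that is what makes the matrix invertible — so matching the
#' channel covariance to a shrunk block's determinant would systematically
#' overscale it. If a sample block is itself not positive definite (possible
#' when the per-block sample count is below `C`), that block's target falls
#' back to the shrunk block's determinant, and the event is logged. The
#' substituted blocks are placed into the *shrunk* matrix by default, so the
#' result differs from the plain shrinkage estimator only in the diagonal
#' blocks; `substitute_into = "sample"` substitutes into the raw pooled
#' covariance instead.
#'
#' Because the substituted blocks carry less shrinkage than the blocks they
#' replace, the assembled matrix routinely has a few small or negative
#' eigenvalues. The default repair clips all eigenvalues at the shrinkage
#' ridge level `gamma * nu_bar` — the variance the shrinkage target assigns
#' to any direction — which keeps the subsequent LDA solve well conditioned
#' and vanishes as the sample size grows (`gamma -> 0`), so the estimator
#' converges to the plain pooled covariance.
#'
#' @param fm A [feature_matrix()] with both classes present and `C >= 2`.
#' @param substitute_into `"shrunk"` (default) or `"sample"`.
#' @param block_det_from `"sample"` (default) or `"shrunk"`: which matrix's
#'   diagonal blocks provide the determinant targets of the rescaling.
#' @param psd_policy Policy for [assert_psd()] on the assembled matrix:
#'   `"clip"` (default), `"reject"`, or `"fallback"` (return the plain
#'   shrunk matrix, with a warning).
#' @param eps Relative eigenvalue floor passed to [assert_psd()] when the
#'   ridge-level floor is unavailable (`gamma = 0`).
#' @return A [cov_estimate()] of kind `"time_decoupled"` (or kind
#'   `"shrunk"` after a fallback).
#' @export
time_decoupled_covariance <- function(fm,
                                      substitute_into = c("shrunk", "sample"),
                                      block_det_from = c("sample", "shrunk"),
                                      psd_policy = c("clip", "reject",
                                                     "fallback"),
                                      eps = 1e-10) {
  substitute_into <- match.arg(substitute_into)
  block_det_from <- match.arg(block_det_from)
  psd_policy <- match.arg(psd_policy)
  stopifnot(inherits(fm, "feature_matrix"), fm$n_channels >= 2)
  C <- fm$n_channels; K <- fm$n_intervals
  means <- class_means(fm)
  Xt <- center_classwise(fm, means)
  sig_hat <- pooled_sample_covariance(fm, means)
  gamma <- ledoit_wolf_gamma(Xt)
  sig_til <- shrink_covariance(sig_hat, gamma)
  base <- if (substitute_into == "shrunk") sig_til$matrix else sig_hat$matrix
  det_src <- if (block_det_from == "sample") sig_hat$matrix else sig_til$matrix

  XC <- rearrange_channel_matrix(Xt, C, K, fm$widths)
  sig_C <- channel_covariance(XC)

  out <- base
  ok <- TRUE
  log <- character()
  for (m in seq_len(K)) {
    rows <- (m - 1L) * C + seq_len(C)
    B_m <- det_src[rows, rows]
    if (block_det_from == "sample" && is.null(chol_logdet(B_m))) {
      log <- c(log, sprintf(
        "block %d: sample block not PD, determinant target taken from the shrunk block", m))
      B_m <- sig_til$matrix[rows, rows]
    }
    sub <- tryCatch(rescale_to_block(sig_C, B_m), error = function(e) e)
    if (inherits(sub, "error")) {
      warning(sprintf("block %d substitution failed (%s); falling back to the shrunk covariance",
                      m, conditionMessage(sub)))
      ok <- FALSE
      break
    }
    out[rows, rows] <- sub
  }
  if (!ok) return(sig_til)
  out <- (out + t(out)) / 2
  est <- cov_estimate(out, kind = "time_decoupled", layout = c(C, K),
                      gamma = gamma, diag_mean = sig_til$diag_mean,
                      psd_log = log)
  if (psd_policy == "fallback") {
    res <- tryCatch(assert_psd(est, "fallback"),
                    tdlda_psd_fallback = function(e) {
                      warning("time-decoupled matrix not PD (",
                              conditionMessage(e),
                              "); falling back to the shrunk covariance")
                      sig_til
                    })
    return(res)
  }
  ridge <- gamma * sig_til$diag_mean
  suppressMessages(assert_psd(est, psd_policy, eps = eps,
                              floor = if (psd_policy == "clip" && ridge > 0)
                                ridge else NULL))
}
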