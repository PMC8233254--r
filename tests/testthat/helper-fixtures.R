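# Shared fixtures and independent oracles for the test suite.

# Small, fast simulation configuration used across tests.
tiny_config <- function(..., seed = 1) {
  sim_config(n_channels = 4, epoch_window = c(0, 0.6),
             n_target = 10, n_nontarget = 40, seed = seed, ...)
}

tiny_intervals <- interval_set(c(0.10, 0.20, 0.30, 0.40))

# AUC by exhaustive pair enumeration (ties count one half) — independent of
# the rank-based implementation.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Construct a feature_matrix directly from a plain matrix.
fm_from_matrix <- function(X, labels, n_channels = nrow(X), n_intervals = 1,
                           widths = rep(1L, n_intervals)) {
  feature_matrix(X, labels, n_channels, n_intervals, widths)
}

# Class-wise mean-free version of a feature matrix (test-side helper).
center_fm <- function(fm) {
  mu0 <- rowMeans(fm$X[, fm$labels == 0, drop = FALSE])
  mu1 <- rowMeans(fm$X[, fm$labels == 1, drop = FALSE])
  M <- matrix(0, nrow(fm$X), ncol(fm$X))
  M[, fm$labels == 0] <- mu0
  M[, fm$labels == 1] <- mu1
  fm$X - M
}

log_det <- function(m) 2 * sum(log(diag(chol(m))))
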