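test_that("class means match hand-computed values and ignore label order", {
  X <- cbind(c(1, 2), c(3, 4), c(5, 6), c(7, 10))
  fm <- fm_from_matrix(X, c(0, 0, 1, 1), n_channels = 2)
  m <- class_means(fm)
  expect_equal(m$mu0, c(2, 3))
  expect_equal(m$mu1, c(6, 8))
  perm <- c(3, 1, 4, 2)
  m2 <- class_means(fm_from_matrix(X[, perm], c(0, 0, 1, 1)[perm],
                                   n_channels = 2))
  expect_equal(m2, m)
  # all columns identical
  fm3 <- fm_from_matrix(matrix(4, 2, 4), c(0, 1, 0, 1), n_channels = 2)
  expect_equal(class_means(fm3), list(mu0 = c(4, 4), mu1 = c(4, 4)))
  expect_error(class_means(fm_from_matrix(X, c(0, 0, 0, 0), n_channels = 2)),
               "both classes")
})

test_that("pooled covariance equals brute-force summation and handles degenerate input", {
  set.seed(3)
  X <- matrix(rnorm(2 * 4), 2, 4)
  y <- c(0, 1, 0, 1)
  fm <- fm_from_matrix(X, y, n_channels = 2)
  est <- pooled_sample_covariance(fm)
  # brute force per definition: class-centered outer-product sum / (N-1)
  mu <- class_means(fm)
  acc <- matrix(0, 2, 2)
  for (i in 1:4) {
    d <- X[, i] - if (y[i] == 1) mu$mu1 else mu$mu0
    acc <- acc + d %*% t(d)
  }
  expect_equal(est$matrix, acc / 3, tolerance = 1e-12)
  expect_equal(est$kind, "sample")
  # every epoch equal to its class mean -> zero matrix
  Xz <- cbind(c(1, 1), c(1, 1), c(5, 2), c(5, 2))
  fz <- fm_from_matrix(Xz, c(0, 0, 1, 1), n_channels = 2)
  expect_equal(pooled_sample_covariance(fz)$matrix, matrix(0, 2, 2))
})

test_that("155-dimensional covariance from 90 epochs is rank deficient", {
  cfg <- sim_config(seed = 1)   # defaults: 31 channels, 90 epochs
  fm <- extract_features(generate_epochs(cfg), default_intervals("visual", 5))
  S <- pooled_sample_covariance(fm)$matrix
  expect_equal(dim(S), c(155, 155))
  r <- qr(S)$rank
  expect_lte(r, 88)   # N - 2 after removing two class means
  expect_lt(r, 155)
})

test_that("class-wise averaged covariance matches a hand-rolled weighted average", {
  set.seed(4)
  X <- matrix(rnorm(3 * 9), 3, 9)
  y <- c(rep(0, 6), rep(1, 3))
  fm <- fm_from_matrix(X, y, n_channels = 3)
  est <- classwise_average_covariance(fm, shrink = FALSE)
  c0 <- stats::cov(t(X[, y == 0]))
  c1 <- stats::cov(t(X[, y == 1]))
  expect_equal(est$matrix, (5 * c0 + 2 * c1) / 7, tolerance = 1e-12)
  est_u <- classwise_average_covariance(fm, weighted = FALSE, shrink = FALSE)
  expect_equal(est_u$matrix, (c0 + c1) / 2, tolerance = 1e-12)
  # one constant class contributes a zero matrix
  Xc <- X; Xc[, y == 1] <- 2
  fc <- fm_from_matrix(Xc, y, n_channels = 3)
  expect_equal(classwise_average_covariance(fc, weighted = FALSE,
                                            shrink = FALSE)$matrix,
               c0 / 2, tolerance = 1e-12)
  expect_error(classwise_average_covariance(
    fm_from_matrix(X[, 1:7], c(rep(0, 6), 1), n_channels = 3)),
    "at least 2")
})

test_that("Ledoit-Wolf gamma reproduces the reference implementation", {
  # frozen oracle values from scikit-learn's ledoit_wolf_shrinkage
  # (assume_centered) on the identical fixtures
  set.seed(42); X1 <- matrix(rnorm(5 * 40), 5, 40)
  expect_equal(ledoit_wolf_gamma(X1), 0.741551311350148, tolerance = 1e-8)
  set.seed(7); X2 <- matrix(rnorm(10 * 2), 10, 2)
  expect_equal(ledoit_wolf_gamma(X2), 0.5131690633304875, tolerance = 1e-8)
  set.seed(11); X3 <- matrix(rnorm(10 * 2000), 10, 2000)
  expect_equal(ledoit_wolf_gamma(X3), 1.0, tolerance = 1e-8)
  set.seed(13); A <- matrix(rnorm(100), 10, 10)
  L <- t(chol(A %*% t(A) + diag(10)))
  X4 <- L %*% matrix(rnorm(10 * 50), 10, 50)
  expect_equal(ledoit_wolf_gamma(X4), 0.2315100829254084, tolerance = 1e-8)
  # clipping contract and degenerate input
  for (s in 1:10) {
    set.seed(100 + s)
    g <- ledoit_wolf_gamma(matrix(rnorm(6 * 12), 6, 12))
    expect_gte(g, 0); expect_lte(g, 1)
  }
  expect_equal(ledoit_wolf_gamma(matrix(0, 4, 8)), 1)
})

test_that("shrinkage interpolates to the scaled identity and preserves the trace", {
  set.seed(5)
  A <- matrix(rnorm(16), 4, 4); S <- A %*% t(A)
  est <- cov_estimate(S, "sample")
  expect_equal(shrink_covariance(est, 0)$matrix, S, tolerance = 1e-12)
  expect_equal(shrink_covariance(est, 1)$matrix, mean(diag(S)) * diag(4),
               tolerance = 1e-12)
  for (g in c(0.25, 0.7))
    expect_equal(sum(diag(shrink_covariance(est, g)$matrix)), sum(diag(S)),
                 tolerance = 1e-12)
})

test_that("channel-matrix rearrangement has shape C x (N*K) with sqrt-width scaling", {
  cfg <- sim_config(seed = 2)   # 31 channels, 90 epochs
  fm <- extract_features(generate_epochs(cfg), default_intervals("visual", 5))
  XC <- rearrange_channel_matrix(center_fm(fm), 31, 5, fm$widths)
  expect_equal(dim(XC), c(31, 90 * 5))
  # K = 1 keeps column order, scaled by sqrt(width)
  X <- matrix(1:12, 3, 4)
  expect_equal(rearrange_channel_matrix(X, 3, 1, 4L), 2 * X)
  expect_error(rearrange_channel_matrix(X, 2, 2, c(1L, 1L)), "layout")
})

test_that("channel covariance recovers Sigma_spatial and shrinks only when starved", {
  cfg <- sim_config(n_channels = 4, epoch_window = c(0, 0.6),
                    n_target = 400, n_nontarget = 1600, snr = 0,
                    temporal_color = 0, seed = 11)
  fm <- extract_features(generate_epochs(cfg), tiny_intervals)
  XC <- rearrange_channel_matrix(center_fm(fm), 4, 3, fm$widths)
  est <- channel_covariance(XC)
  expect_null(est$gamma)                     # C << N*K: no shrinkage
  expect_lt(norm(est$matrix - cfg$spatial_cov, "F") /
              norm(cfg$spatial_cov, "F"), 0.1)
  # C > number of channel samples triggers shrinkage
  set.seed(1)
  starved <- channel_covariance(matrix(rnorm(8 * 3), 8, 3))
  expect_false(is.null(starved$gamma))
  # degenerate all-zero input gives the zero matrix
  expect_equal(channel_covariance(matrix(0, 3, 10))$matrix, matrix(0, 3, 3))
})

test_that("determinant-matched rescaling hits the target log-determinant", {
  expect_equal(rescale_to_block(diag(31), 3 * diag(31)), 3 * diag(31),
               tolerance = 1e-10)
  set.seed(21)
  A <- random_spd(8, cond = 50)
  expect_equal(rescale_to_block(A, A), A, tolerance = 1e-12)
  B <- random_spd(8, cond = 200, scale = 5)
  out <- rescale_to_block(A, B)
  expect_lt(abs(log_det(out) - log_det(B)), 1e-8)
  # non-PD inputs rejected with a diagnostic naming the culprit
  ind <- diag(c(1, -1))
  expect_error(rescale_to_block(ind, diag(2)), "channel covariance")
  expect_error(rescale_to_block(diag(2), ind), "target block")
})

test_that("PSD assertion repairs, rejects, or signals fallback per policy", {
  pd <- random_spd(4)
  expect_identical(assert_psd(pd, "reject"), pd)
  expect_identical(assert_psd(pd, "clip"), pd)
  # symmetric indefinite fixture with known eigenpairs
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  m <- q %*% diag(c(1, 0.5, 0.2, -0.1)) %*% t(q)
  m <- (m + t(m)) / 2
  expect_error(assert_psd(m, "reject"), "not positive definite")
  expect_error(assert_psd(m, "fallback"), class = "tdlda_psd_fallback")
  expect_message(rep_m <- assert_psd(m, "clip", eps = 1e-4), "PSD repair")
  ev <- eigen(rep_m, symmetric = TRUE)
  expect_equal(min(ev$values), 1e-4, tolerance = 1e-8)
  expect_equal(sort(ev$values, decreasing = TRUE)[1:3], c(1, 0.5, 0.2),
               tolerance = 1e-8)
  # absolute floor override
  expect_message(rep2 <- assert_psd(m, "clip", floor = 0.3))
  expect_equal(min(eigen(rep2, symmetric = TRUE)$values), 0.3,
               tolerance = 1e-10)
})

test_that("time-decoupled estimator preserves off-diagonal blocks and block shape", {
  # well-posed case (N >> D) that needs no PSD repair, so structural
  # invariants hold exactly
  cfg <- sim_config(n_channels = 4, epoch_window = c(0, 0.6),
                    n_target = 150, n_nontarget = 600, seed = 12)
  fm <- extract_features(generate_epochs(cfg), tiny_intervals)
  dot <- time_decoupled_covariance(fm, psd_policy = "reject")
  expect_equal(dot$kind, "time_decoupled")
  mu <- class_means(fm)
  til <- shrink_covariance(pooled_sample_covariance(fm),
                           ledoit_wolf_gamma(center_fm(fm)))
  C <- 4
  for (m1 in 1:3) for (m2 in 1:3) {
    r1 <- (m1 - 1) * C + 1:C; r2 <- (m2 - 1) * C + 1:C
    if (m1 != m2)
      expect_identical(dot$matrix[r1, r2], til$matrix[r1, r2])
  }
  # diagonal blocks share eigenstructure: det-normalized blocks identical
  norm_block <- function(S, m) {
    r <- (m - 1) * C + 1:C
    B <- S[r, r]
    B / exp(log_det(B) / C)
  }
  b1 <- norm_block(dot$matrix, 1)
  for (m in 2:3)
    expect_equal(norm_block(dot$matrix, m), b1, tolerance = 1e-8)
  # determinant equality against the sample-block targets
  hat <- pooled_sample_covariance(fm)$matrix
  for (m in 1:3) {
    r <- (m - 1) * C + 1:C
    expect_lt(abs(log_det(dot$matrix[r, r]) - log_det(hat[r, r])), 1e-8)
  }
})

test_that("K = 1 substitution rescales the channel covariance to the full determinant", {
  cfg <- sim_config(n_channels = 4, epoch_window = c(0, 0.3),
                    n_target = 100, n_nontarget = 400, seed = 13)
  fm <- extract_features(generate_epochs(cfg), interval_set(c(0, 0.3)))
  dot <- time_decoupled_covariance(fm, psd_policy = "reject")
  hat <- pooled_sample_covariance(fm)$matrix
  expect_lt(abs(log_det(dot$matrix) - log_det(hat)), 1e-8)
  XC <- rearrange_channel_matrix(center_fm(fm), 4, 1, fm$widths)
  SC <- channel_covariance(XC)$matrix
  expect_equal(dot$matrix / SC, matrix((dot$matrix / SC)[1], 4, 4),
               tolerance = 1e-8)              # proportional to Sigma_hat^C
})

test_that("final estimate is invariant to a global interval-width rescaling", {
  cfg <- sim_config(n_channels = 4, epoch_window = c(0, 0.6),
                    n_target = 100, n_nontarget = 400, seed = 14)
  fm <- extract_features(generate_epochs(cfg), tiny_intervals)
  a <- time_decoupled_covariance(fm, psd_policy = "reject")
  fm2 <- fm; fm2$widths <- fm$widths * 4L     # global factor 2 on X^C
  b <- time_decoupled_covariance(fm2, psd_policy = "reject")
  expect_equal(a$matrix, b$matrix, tolerance = 1e-10)
})

test_that("estimators converge to the true covariance as N grows", {
  iv <- tiny_intervals
  err <- sapply(c(60, 400, 3000), function(n) {
    cfg <- sim_config(n_channels = 4, epoch_window = c(0, 0.6),
                      n_target = n / 5, n_nontarget = 4 * n / 5, snr = 0,
                      seed = 15)
    fm <- extract_features(generate_epochs(cfg), iv)
    tru <- true_feature_covariance(cfg, iv)$matrix
    mu <- class_means(fm)
    g <- ledoit_wolf_gamma(center_fm(fm))
    c(hat = norm(pooled_sample_covariance(fm)$matrix - tru, "F"),
      til = norm(shrink_covariance(pooled_sample_covariance(fm), g)$matrix -
                   tru, "F"),
      dot = norm(time_decoupled_covariance(fm)$matrix - tru, "F"))
  })
  for (i in 1:3) expect_true(all(diff(err[i, ]) < 0))
})

test_that("PSD repairs on ill-posed fits are recorded in the estimate's log", {
  cfg <- sim_config(seed = 16)   # N = 90 << D = 155: repair expected
  fm <- extract_features(generate_epochs(cfg), default_intervals("visual", 5))
  dot <- time_decoupled_covariance(fm)
  expect_gt(min(eigen(dot$matrix, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_equal(dot$layout, c(31, 5))
})

test_that("covariance estimates round-trip through serialization", {
  cfg <- tiny_config(seed = 17)
  fm <- extract_features(generate_epochs(cfg), tiny_intervals)
  est <- time_decoupled_covariance(fm)
  dir <- withr::local_tempdir()
  write_cov_estimate(est, dir)
  back <- read_cov_estimate(dir)
  expect_equal(back$matrix, est$matrix, tolerance = 1e-10)
  expect_identical(back$kind, est$kind)
  expect_equal(back$gamma, est$gamma, tolerance = 1e-12)
  expect_equal(back$layout, est$layout)
})
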