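test_that("minimum-norm inverse matches the normal-equations solve", {
  set.seed(41)
  n1 <- 8; p <- 20; T_len <- 15
  At <- matrix(rnorm(n1 * p), n1, p)
  Y <- matrix(rnorm(n1 * T_len), n1, T_len)
  lam <- 0.3
  inv <- mne_inverse(At, Y, lambda = lam)
  S_direct <- t(At) %*% solve(At %*% t(At) + lam * diag(n1), Y)
  expect_equal(inv$S_hat, S_direct, tolerance = 1e-10)
  # zero data and ridge shrinkage limits
  expect_equal(mne_inverse(At, Y * 0, lambda = 1)$S_hat,
               matrix(0, p, T_len))
  expect_lt(max(abs(mne_inverse(At, Y, lambda = 1e9)$S_hat)), 1e-5)
  expect_error(mne_inverse(At, Y, lambda = 0), "lambda")
  # L-curve search returns a grid member and the curve itself
  auto <- mne_inverse(At, Y)
  expect_true(auto$lambda %in% auto$lcurve$lambda)
})

test_that("knee point follows the distance-to-origin rule", {
  scores <- c(1, 1, 0.05, rep(0.04, 7))
  # direct evaluation of d_q = s_q^2 + (q/p)^2 over all q
  d <- sort(scores, decreasing = TRUE)^2 + (seq_along(scores) / 10)^2
  expect_equal(knee_point(scores), which.min(d))
  expect_equal(knee_point(scores), 3L)
  # constant curve: the index term is strictly increasing
  expect_equal(knee_point(rep(0.5, 20)), 1L)
  # ties resolve to the lowest index
  expect_equal(knee_point(c(sqrt(3) / 10, sqrt(3) / 10)), 1L)
  expect_error(knee_point(numeric(0)), "empty")
})

test_that("MUSIC contribution is the normalized noise-space projection", {
  set.seed(42)
  n1 <- 10; p <- 14
  At <- matrix(rnorm(n1 * p), n1, p)
  # rank-2 signal: sources orthogonal to the signal subspace score 1
  U <- qr.Q(qr(matrix(rnorm(n1 * 2), n1, 2)))
  Y <- U %*% matrix(rnorm(2 * 500), 2, 500)
  b <- contribution_values(music_contribution(At, Y, rho = 99.99))
  P_perp <- diag(n1) - U %*% t(U)
  oracle <- colSums((P_perp %*% At)^2) / colSums(At^2)
  expect_equal(b, oracle, tolerance = 1e-6)
  expect_true(all(b >= 0 & b <= 1))
  # a lead-field column inside the signal subspace scores ~0
  At2 <- At
  At2[, 1] <- U[, 1]
  b2 <- contribution_values(music_contribution(At2, Y, rho = 99.99))
  expect_lt(b2[1], 1e-6)
  # a column orthogonal to the signal subspace scores 1
  v <- P_perp %*% rnorm(n1)
  At2[, 2] <- v
  b3 <- contribution_values(music_contribution(At2, Y, rho = 99.99))
  expect_equal(b3[2], 1, tolerance = 1e-6)
  # rho capturing the full energy of a full-rank recording leaves no
  # noise space
  Yfull <- matrix(rnorm(n1 * 500), n1, 500)
  expect_equal(contribution_values(music_contribution(At, Yfull,
    rho = 100)), rep(0, p), tolerance = 1e-6)
  # rank-0 recording: every source is "silent"
  expect_equal(contribution_values(music_contribution(At, Y * 0, 95)),
               rep(1, p))
})

test_that("sLORETA standardization matches its closed form", {
  set.seed(43)
  n1 <- 6; p <- 12
  At <- qr.Q(qr(matrix(rnorm(p * n1), p, n1)))  # orthonormal columns
  At <- t(At)                                   # orthonormal rows
  Y <- matrix(rnorm(n1 * 30), n1, 30)
  st <- sloreta_standardize(At, Y, lambda = 1e-9)
  # with orthonormal rows, C = At' At / (1 + lambda): diag = ||a_i||^2
  expect_equal(st$diag_C, colSums(At^2), tolerance = 1e-6)
  expect_equal(sloreta_standardize(At, Y * 0, lambda = 1)$S2,
               matrix(0, p, 30))
  # standardization reduces the deep-vs-shallow gain bias of plain MNE
  a_shallow <- c(1, 0); a_deep <- c(0, 0.1)
  At2 <- cbind(a_shallow, a_deep)
  S_true <- rbind(0, rnorm(100))            # only the deep source active
  Y2 <- At2 %*% S_true
  mne_pow <- rowMeans(mne_inverse(At2, Y2, lambda = 1e-6)$S_hat^2)
  sl_pow <- rowMeans(sloreta_standardize(At2, Y2, lambda = 1e-6)$S2)
  expect_gt(sl_pow[2] / max(sl_pow[1], 1e-12),
            mne_pow[2] / max(mne_pow[1], 1e-12))
})

test_that("modified localizers return contiguous regions of sane size", {
  b <- tiny_bench
  sim <- simulate_recording(b$grids$high, b$leadfields$high, tiny_scheme,
                            k = 10, snr_db = 9, T_len = 4000, seed = 51)
  grids <- b$grids
  for (m in c("mne", "music", "sloreta")) {
    res <- switch(m,
      mne = modified_mne_localize(tiny_At_low, tiny_At_high,
                                  sim$recording, grids),
      music = modified_music_localize(tiny_At_low, tiny_At_high,
                                      sim$recording, grids),
      sloreta = modified_sloreta_localize(tiny_At_low, tiny_At_high,
                                          sim$recording, grids))
    expect_length(res$silent_set, res$k_hat)
    expect_true(all(res$silent_set >= 1 & res$silent_set <= grids$high$p))
    # final set is the k_hat-NN of the pass's center-of-mass: contiguous
    d <- rowSums(sweep(grids$high$positions, 2, res$com)^2)
    expect_setequal(res$silent_set,
                    order(d, seq_len(grids$high$p))[seq_len(res$k_hat)])
    # metrics consume the result directly
    ev <- evaluate_silence(res$silent_set, sim$truth, grids$high)
    expect_true(is.finite(ev$delta_com))
  }
})

test_that("rank histogram concentrates on truly quiet sources", {
  set.seed(52)
  p <- 30; T_len <- 200
  S2 <- matrix(runif(p * T_len, 0.5, 1), p, T_len)
  quiet <- c(4, 9, 17)
  S2[quiet, ] <- runif(3 * T_len, 0, 0.05)
  h <- silencemapr:::rank_histogram(S2, k0 = 3)
  expect_equal(which(h == 1), quiet)
  expect_true(all(h[-quiet] < 0.2))
  # T = 1 degenerate input still yields a single valid ranking
  h1 <- silencemapr:::rank_histogram(S2[, 1, drop = FALSE], k0 = 3)
  expect_equal(sort(order(-h1)[1:3]), quiet)
})
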