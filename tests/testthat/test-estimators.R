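# explicit-loop oracle for Var(mu_qt) under the uncorrelated source model:
# sum_{i notin S} (a_q' a_i)^2 sigma_s^2 + a_q' C~_z a_q
var_mu_uncorrelated <- function(A_tilde, silent, sigma_s2, C_z_tilde) {
  p <- ncol(A_tilde)
  vapply(seq_len(p), function(q) {
    aq <- A_tilde[, q]
    sig <- 0
    for (i in setdiff(seq_len(p), silent))
      sig <- sig + sum(aq * A_tilde[, i])^2 * sigma_s2
    sig + as.numeric(t(aq) %*% C_z_tilde %*% aq)
  }, 0)
}

test_that("channel statistics match closed forms and degenerate inputs", {
  set.seed(21)
  n <- 6; p <- 9; T_len <- 400
  A <- matrix(rnorm(n * p), n, p)
  M <- make_reference_scheme(n, n)$M
  At <- M %*% A
  C_z <- diag(runif(n, 0.1, 0.5))
  # zero recording -> zero statistics
  st0 <- estimate_channel_stats(matrix(0, n - 1, T_len), At, C_z, M)
  expect_equal(st0$var_y, rep(0, n - 1))
  expect_equal(st0$var_mu, rep(0, p))
  # exact stats reproduce the uncorrelated-model oracle
  silent <- c(2, 5)
  Cs <- diag(p); Cs[silent, silent] <- 0
  st <- exact_channel_stats(At, Cs, M %*% C_z %*% t(M))
  expect_equal(st$var_mu, var_mu_uncorrelated(At, silent, 1,
                                              M %*% C_z %*% t(M)),
               tolerance = 1e-10)
  expect_equal(st$var_y, diag(At %*% Cs %*% t(At) + M %*% C_z %*% t(M)),
               tolerance = 1e-12)
})

test_that("sample statistics converge to the exact ones", {
  b <- tiny_bench
  sim <- simulate_recording(b$grids$high, b$leadfields$high, tiny_scheme,
                            k = 8, T_len = 3e4, seed = 31)
  At <- tiny_At_high
  st <- estimate_channel_stats(sim$recording, At, sim$noise_model,
                               tiny_scheme)
  ex <- exact_channel_stats(At, sim$source_model$C_s,
                            tiny_scheme$M %*% sim$noise_model$C_z %*%
                              t(tiny_scheme$M))
  expect_equal(st$var_y, ex$var_y, tolerance = 0.1)
  rel <- sqrt(mean((st$var_mu / ex$var_mu - 1)^2))
  expect_lt(rel, 0.1)
})

test_that("Welch band-integrated variance agrees with the sample variance", {
  set.seed(7)
  n <- 4; T_len <- 2e4; fs <- 256
  Y <- matrix(rnorm(n * T_len, sd = 2), n, T_len)
  At <- matrix(rnorm(n * 6), n, 6)
  M <- make_reference_scheme(n + 1, n + 1)$M
  stw <- estimate_channel_stats(Y, At, diag(n + 1), M, method = "welch",
                                band = c(0, fs / 2), fs = fs)
  expect_equal(stw$var_y, rep(4, n), tolerance = 0.05)
  sts <- estimate_channel_stats(Y, At, diag(n + 1), M)
  expect_equal(stw$var_y, sts$var_y, tolerance = 0.05)
  expect_error(estimate_channel_stats(Y[, 1:100], At, diag(n + 1), M,
                                      method = "welch", fs = fs),
               "insufficient")
})

test_that("low-resolution contribution attains its documented bounds", {
  set.seed(22)
  n <- 5; p <- 7
  A <- matrix(rnorm(n * p), n, p)
  M <- make_reference_scheme(n, n)$M
  At <- M %*% A
  Cz_t <- 0.05 * diag(n - 1)
  # all sources silent -> beta = 0
  st_all <- exact_channel_stats(At, matrix(0, p, p), Cz_t)
  expect_equal(contribution_values(contribution_lowres(st_all, At)),
               rep(0, p))
  # no silence, uncorrelated unit-variance sources -> beta = sigma_s^2
  for (s2 in c(1, 2.5)) {
    st_full <- exact_channel_stats(At, s2 * diag(p), Cz_t)
    expect_equal(contribution_values(contribution_lowres(st_full, At)),
                 rep(s2, p), tolerance = 1e-10)
  }
  # one silent source: matches the explicit-loop oracle
  silent <- 4
  Cs <- diag(p); Cs[silent, silent] <- 0
  st <- exact_channel_stats(At, Cs, Cz_t)
  beta <- contribution_values(contribution_lowres(st, At))
  oracle_num <- var_mu_uncorrelated(At, silent, 1, Cz_t) -
    var_mu_uncorrelated(At, seq_len(p), 1, Cz_t)
  G <- crossprod(At)
  expect_equal(beta, pmax(oracle_num, 0) / rowSums(G^2),
               tolerance = 1e-10)
  # enlarging the silent set never increases any exact beta
  beta_small <- contribution_values(contribution_lowres(
    exact_channel_stats(At, {C <- diag(p); C[4, 4] <- 0; C}, Cz_t), At))
  beta_big <- contribution_values(contribution_lowres(
    exact_channel_stats(At, {C <- diag(p); C[c(2, 4), c(2, 4)] <- 0; C},
                        Cz_t), At))
  expect_true(all(beta_big <= beta_small + 1e-12))
})

test_that("high-resolution contribution is the ratio of quadratic forms", {
  set.seed(23)
  n <- 6; p <- 8
  A <- matrix(rnorm(n * p), n, p)
  M <- make_reference_scheme(n, n)$M
  At <- M %*% A
  pts <- matrix(rnorm(p * 3), p, 3) * 10
  Cfull <- build_source_covariance(pts, gamma = 0.01)$C_s_full
  Cz_t <- 0.02 * diag(n - 1)
  # no silence -> exactly 1; all silent -> 0
  st_full <- exact_channel_stats(At, Cfull, Cz_t)
  expect_equal(contribution_values(
    contribution_highres(st_full, At, Cfull)), rep(1, p),
    tolerance = 1e-10)
  st_none <- exact_channel_stats(At, matrix(0, p, p), Cz_t)
  expect_equal(contribution_values(
    contribution_highres(st_none, At, Cfull)), rep(0, p))
  # random silenced instance vs dense-matrix oracle
  silent <- c(1, 6)
  Cs <- Cfull; Cs[silent, ] <- 0; Cs[, silent] <- 0
  st <- exact_channel_stats(At, Cs, Cz_t)
  bh <- contribution_values(contribution_highres(st, At, Cfull))
  Sig_full <- At %*% Cfull %*% t(At)
  oracle <- vapply(seq_len(p), function(q) {
    aq <- At[, q]
    num <- as.numeric(t(aq) %*% (At %*% Cs %*% t(At)) %*% aq)
    den <- as.numeric(t(aq) %*% Sig_full %*% aq)
    min(max(num / den, 0), 1)
  }, 0)
  expect_equal(bh, oracle, tolerance = 1e-10)
})

test_that("hemispheric ratio flags one-sided silences and caps at 1", {
  g <- tiny_bench$grids$high
  At <- tiny_At_high
  Cz_t <- 1e-4 * diag(nrow(At))
  # symmetric field: ratio 1 everywhere
  m_full <- build_source_covariance(g, gamma = 0.12)
  st_full <- exact_channel_stats(At, m_full$C_s, Cz_t)
  b_full <- contribution_lowres(st_full, At)
  r_full <- hemispheric_ratio(b_full, g)
  expect_equal(contribution_values(r_full), rep(1, g$p),
               tolerance = 1e-8)
  # right-hemisphere patch: small ratio on patch, ~1 on its mirror
  patch <- tiny_truth
  expect_true(all(g$hemisphere[patch] == g$hemisphere[patch][1]))
  st <- exact_channel_stats(At, tiny_model$C_s, Cz_t)
  b <- contribution_lowres(st, At)
  r <- contribution_values(hemispheric_ratio(b, g))
  other_rh <- setdiff(which(g$hemisphere == g$hemisphere[patch[1]]),
                      patch)
  expect_true(all(r[patch] < 1))
  expect_lt(mean(r[patch]), mean(r[other_rh]))
  expect_equal(r[g$mirror_map[patch]], rep(1, length(patch)))
  expect_true(all(r >= 0 & r <= 1))
  # strip sources are exactly 1
  expect_equal(r[g$hemisphere == "strip"],
               rep(1, sum(g$hemisphere == "strip")))
  # explicit baseline variant: beta/beta_base capped at 1
  base <- contribution_values(b_full)
  r2 <- contribution_values(hemispheric_ratio(b, baseline = base))
  expect_true(all(r2 <= 1 & r2 >= 0))
  expect_lt(mean(r2[patch]), mean(r2[other_rh]))
  # doubly-silent mirrored pair: 0/0 counts as silent, not 1
  bb <- contribution_values(b)
  bb[c(patch, g$mirror_map[patch])] <- 0
  r3 <- contribution_values(hemispheric_ratio(
    silencemapr:::new_contribution(bb, "beta_low", c(0, Inf)), g))
  expect_equal(r3[patch], rep(0, length(patch)))
})

test_that("selected silent set is invariant to uniform data rescaling", {
  g <- tiny_bench$grids$high
  At <- tiny_At_high
  Cz_t <- 1e-3 * diag(nrow(At))
  st <- exact_channel_stats(At, tiny_model$C_s, Cz_t)
  b1 <- contribution_values(contribution_lowres(st, At))
  # rescale the data (and with it the noise covariance) by c^2
  st2 <- exact_channel_stats(At, 4 * tiny_model$C_s, 4 * Cz_t)
  b2 <- contribution_values(contribution_lowres(st2, At))
  expect_equal(b2, 4 * b1, tolerance = 1e-10)   # beta carries the scale
  r1 <- contribution_values(hemispheric_ratio(
    silencemapr:::new_contribution(b1, "beta_low", c(0, Inf)), g))
  r2 <- contribution_values(hemispheric_ratio(
    silencemapr:::new_contribution(b2, "beta_low", c(0, Inf)), g))
  expect_equal(r1, r2, tolerance = 1e-10)       # the ratio does not
})
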