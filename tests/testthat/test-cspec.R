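# independent QP oracle (active-set solver from pracma)
qp_oracle <- function(beta, L, k, lambda, ridge = 1e-9) {
  p <- length(beta)
  pracma::quadprog(2 * lambda * L + ridge * diag(p), -beta,
                   matrix(1, 1, p), p - k,
                   lb = rep(0, p), ub = rep(1, p))$xmin
}

path_laplacian <- function(p, w = 1) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  diag(rowSums(W)) - W
}

test_that("unconstrained and linear-program limits are exact", {
  p <- 6
  L <- path_laplacian(p)
  beta <- c(0, 0, 1, 1, 1, 1)
  # k = 0, lambda = 0: no reason to silence anything
  s0 <- solve_cspec(beta, L, k = 0, lambda = 0)
  expect_equal(s0$g, rep(1, p), tolerance = 1e-5)
  expect_equal(s0$objective_terms[["linear"]], 0, tolerance = 1e-6)
  expect_length(s0$silent_set, 0)
  # lambda = 0, k = 2: pure LP selects the two zero-beta coordinates
  s2 <- solve_cspec(beta, L, k = 2, lambda = 0)
  expect_equal(s2$silent_set, c(1L, 2L))
  expect_equal(s2$g[3:6], rep(1, 4), tolerance = 1e-5)
  expect_error(solve_cspec(beta, L, k = p, lambda = 0), "k must")
  expect_error(solve_cspec(beta, L, k = 1, lambda = -1), "lambda")
})

test_that("path-graph instance matches the exhaustive contiguous oracle", {
  p <- 8
  L <- path_laplacian(p)
  beta <- c(1, 0.9, 1.1, 0.05, 0.08, 1, 0.95, 1.05)
  lambda <- 0.3
  s <- solve_cspec(beta, L, k = 2, lambda = lambda)
  expect_equal(s$silent_set, c(4L, 5L))
  # brute force over all contiguous 2-subsets with binary indicators
  objs <- vapply(path_contiguous_subsets(p, 2), function(ss)
    cspec_binary_objective(beta, lambda * L, ss), 0)
  expect_equal(s$silent_set,
               path_contiguous_subsets(p, 2)[[which.min(objs)]])
})

test_that("solver matches an independent QP solver on random instances", {
  skip_if_not_installed("pracma")
  set.seed(33)
  for (i in 1:10) {
    p <- sample(10:40, 1)
    pts <- matrix(rnorm(p * 3), p, 3) * 15
    L <- build_graph(pts, z = 3)$L
    beta <- runif(p)
    k <- sample(1:(p %/% 3), 1)
    lambda <- 10^runif(1, -2, 1)
    s <- solve_cspec(beta, L, k, lambda)
    x0 <- qp_oracle(beta, L, k, lambda)
    obj <- function(g) sum(beta * (1 - g)) +
      lambda * as.numeric(crossprod(1 - g, L %*% (1 - g)))
    expect_lt(abs(obj(s$g) - obj(x0)), 1e-5 * max(1, abs(obj(x0))))
    expect_true(all(s$g >= -1e-6 & s$g <= 1 + 1e-6))
    expect_lte(sum(s$g), p - k + 1e-5)
  }
})

test_that("power constraints are enforced and never improve the objective", {
  set.seed(34)
  p <- 30
  pts <- matrix(rnorm(p * 3), p, 3) * 12
  L <- build_graph(pts, z = 4)$L
  beta <- runif(p)
  k <- 5
  lambda <- 0.5
  free <- solve_cspec(beta, L, k, lambda)
  # constraints built as in the pipeline: residual-sized allowances
  phi <- 4
  C_rows <- matrix(abs(rnorm(phi * p)), phi, p)
  g_ref <- free$g
  target <- as.numeric(C_rows %*% g_ref) + rnorm(phi, sd = 0.05)
  zeta <- (as.numeric(C_rows %*% rep(1, p)) - target)^2 + 0.1
  pc <- list(C_rows = C_rows, target = target, zeta = zeta)
  con <- solve_cspec(beta, L, k, lambda, power_constraints = pc)
  expect_true(con$feasible)
  viol <- abs(as.numeric(C_rows %*% con$g) - target) - sqrt(zeta)
  expect_true(all(viol <= 1e-4 * max(sqrt(zeta))))
  obj <- function(g) sum(beta * (1 - g)) +
    lambda * as.numeric(crossprod(1 - g, L %*% (1 - g)))
  expect_gte(obj(con$g), obj(free$g) - 1e-6)
  # unsatisfiable allowance is reported, not silently ignored
  pc_bad <- list(C_rows = C_rows,
                 target = as.numeric(C_rows %*% rep(1, p)) + 10,
                 zeta = rep(1e-8, phi))
  bad <- solve_cspec(beta, L, k, lambda, power_constraints = pc_bad)
  expect_false(bad$feasible)
})

test_that("thresholded relaxation recovers well-separated planted regions", {
  set.seed(35)
  hits <- 0
  n_draw <- 40
  for (i in seq_len(n_draw)) {
    p <- 12
    L <- path_laplacian(p)
    k <- sample(2:3, 1)
    start <- sample(seq_len(p - k + 1), 1)
    region <- start:(start + k - 1)
    beta <- runif(p, 0.6, 1)
    beta[region] <- runif(k, 0, 0.15)
    lambda <- 0.2
    s <- solve_cspec(beta, L, k, lambda)
    objs <- vapply(path_contiguous_subsets(p, k), function(ss)
      cspec_binary_objective(beta, lambda * L, ss), 0)
    comb <- path_contiguous_subsets(p, k)[[which.min(objs)]]
    if (identical(s$silent_set, as.integer(comb))) hits <- hits + 1
  }
  expect_gte(hits / n_draw, 0.95)
})

test_that("lambda tuning follows the normalized two-term criterion", {
  set.seed(36)
  p <- 20
  pts <- matrix(rnorm(p * 3), p, 3) * 12
  L <- build_graph(pts, z = 3)$L
  beta <- runif(p)
  beta[5:8] <- 0.02
  grid <- 10^seq(-3, 1, length.out = 6)
  tl <- tune_lambda(beta, L, k = 4, lambda_grid = grid)
  # independent recomputation from per-lambda oracle solutions
  t1 <- t2 <- numeric(length(grid))
  for (i in seq_along(grid)) {
    g <- qp_oracle(beta, L, 4, grid[i])
    t1[i] <- sum(beta * (1 - g))^2
    t2[i] <- as.numeric(crossprod(1 - g, L %*% (1 - g)))^2
  }
  score <- t1 / max(t1) + t2 / max(t2)
  expect_equal(tl$lambda_star, grid[which.min(score)])
  # a single-element grid returns that lambda
  expect_equal(tune_lambda(beta, L, 4, lambda_grid = 0.7)$lambda_star,
               0.7)
  # rescaling beta leaves the choice unchanged (both terms renormalize)
  tl2 <- tune_lambda(5 * beta, L, k = 4, lambda_grid = 5 * grid)
  expect_equal(tl2$lambda_star, 5 * tl$lambda_star)
})

test_that("size estimation recovers the generative region size", {
  # forward-consistent coarse instance: Var(y) generated exactly from a
  # size-k0 region under the uncorrelated source model
  g <- tiny_bench$grids$low
  At <- tiny_At_low
  k0 <- 5
  region <- sample_contiguous_region(g, k0, seed = 13)
  Cs <- diag(g$p)
  Cs[region, region] <- 0
  Cz_t <- 1e-6 * diag(nrow(At))
  st <- exact_channel_stats(At, Cs, Cz_t)
  beta <- contribution_values(contribution_lowres(st, At))
  L_for_k <- function(k) build_graph(g, z = max(k, 2))$L
  lam_grid <- default_lambda_grid(beta, L_for_k(k0), 6)
  est <- estimate_size(beta, L_for_k, At, st,
                       k_grid = c(2, k0, 2 * k0, 4 * k0),
                       lambda_grid = lam_grid)
  expect_equal(est$k_hat, k0)
  idx_k0 <- which(est$k_grid == k0)
  idx_2k0 <- which(est$k_grid == 2 * k0)
  expect_lte(est$costs[idx_k0], est$costs[idx_2k0])
  # degenerate single-candidate grid
  est1 <- estimate_size(beta, L_for_k, At, st, k_grid = k0,
                        lambda_grid = lam_grid)
  expect_equal(est1$k_hat, k0)
})

test_that("power mismatch is a normalized nonnegative score", {
  set.seed(37)
  n1 <- 10; p <- 15
  At <- matrix(rnorm(n1 * p), n1, p)
  pts <- matrix(rnorm(p * 3), p, 3) * 8
  Cs <- build_source_covariance(pts, gamma = 0.02)$C_s_full
  Cz_t <- 0.01 * diag(n1)
  st <- exact_channel_stats(At, Cs, Cz_t)
  # modeled power proportional to the measured one: mismatch 0
  expect_equal(power_mismatch(At, 3 * Cs, st), 0, tolerance = 1e-10)
  # random mismatch vs direct-summation oracle
  Cs2 <- Cs; Cs2[1:3, ] <- 0; Cs2[, 1:3] <- 0
  dp <- power_mismatch(At, Cs2, st)
  modeled <- diag(At %*% Cs2 %*% t(At))
  meas <- st$var_y - st$sigma_z2
  acc <- 0
  for (i in seq_len(n1))
    acc <- acc + (modeled[i] / max(modeled) - meas[i] / max(meas))^2
  expect_equal(dp, acc, tolerance = 1e-10)
  expect_gte(dp, 0)
  expect_error(power_mismatch(At, Cs * 0, st), "invalid model")
})
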