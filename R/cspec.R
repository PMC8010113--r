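#' @section CSpeC:
#' The convex spectral clustering program seeks a relaxed indicator
#' `g in [0,1]^p` (small entries mark silent sources) minimizing
#' `beta'(1-g) + lambda (1-g)' L (1-g)` subject to `||g||_1 <= p - k`, with
#' optional per-electrode power constraints
#' `(c_i' g + sigma_z_i^2 - Var(y_i))^2 <= zeta_i`. Because `L 1 = 0` the
#' Laplacian term equals `g' L g`, and with `g >= 0` the l1 bound is linear,
#' so the whole program is a convex QP with box and linear constraints. Each
#' squared power constraint is an interval constraint on an affine function
#' and contributes two linear inequalities.
#' @name cspec
NULL

# ---- internal operator-splitting QP solver -------------------------------
# min 0.5 x'Px + q'x  s.t.  l <= A x <= u
# ADMM with over-relaxation; the KKT factor depends on (P, rho, A) only, so
# it can be cached across solves that share lambda (P = 2 lambda L).
qp_admm <- function(P, q, A, l, u, rho = 1, sigma = 1e-6, alpha = 1.6,
                    max_iter = 20000, eps_abs = 1e-9, eps_rel = 1e-7,
                    warm = NULL, factor = NULL) {
  # A is structured: p box rows (identity), one scaled sum row, and
  # optionally phi dense power rows; products are applied blockwise.
  p <- length(q)
  m <- nrow(A)
  n_pow <- m - p - 1L
  srow <- A[p + 1L, 1L]                 # scaled sum-row entry (1/sqrt(p))
  Cp <- if (n_pow > 0) A[(p + 2L):m, , drop = FALSE] else NULL
  Amul <- function(x) c(x, sum(x) * srow,
                        if (n_pow > 0) as.numeric(Cp %*% x))
  Atmul <- function(v) {
    out <- v[seq_len(p)] + v[p + 1L] * srow
    if (n_pow > 0)
      out <- out + as.numeric(crossprod(Cp, v[(p + 2L):m]))
    out
  }
  refactor <- function(rho) {
    K <- P + rho * crossprod(A)
    diag(K) <- diag(K) + sigma
    chol2inv(chol(K))          # dense inverse: x-update is one gemv
  }
  if (is.null(factor)) factor <- refactor(rho)
  x <- if (!is.null(warm)) warm$x else numeric(p)
  z <- if (!is.null(warm)) warm$z else numeric(m)
  y <- if (!is.null(warm)) warm$y else numeric(m)
  converged <- FALSE
  n_adapt <- 0L
  best_res <- Inf
  last_improve <- 0L
  for (it in seq_len(max_iter)) {
    rhs <- sigma * x - q + Atmul(rho * z - y)
    xt <- as.numeric(factor %*% rhs)
    zt <- Amul(xt)
    x <- alpha * xt + (1 - alpha) * x
    zh <- alpha * zt + (1 - alpha) * z
    z_new <- pmin(pmax(zh + y / rho, l), u)
    y <- y + rho * (zh - z_new)
    z <- z_new
    if (it %% 50 == 0) {
      Ax <- Amul(x)
      Aty <- Atmul(y)
      Px <- as.numeric(P %*% x)
      sp <- max(max(abs(Ax)), max(abs(z)), 1e-12)
      sd_ <- max(max(abs(Px)), max(abs(q)), max(abs(Aty)), 1e-12)
      rp <- max(abs(Ax - z))
      rd <- max(abs(Px + q + Aty))
      if (rp < eps_abs + eps_rel * sp &&
          rd < eps_abs + eps_rel * sd_) { converged <- TRUE; break }
      # stall detection: stop when residuals no longer improve (the
      # iterate is then as good as this splitting will deliver)
      res_now <- rp / sp + rd / sd_
      if (res_now < 0.9 * best_res) {
        best_res <- res_now
        last_improve <- it
      } else if (it - last_improve >= 600) break
      # residual balancing: rescale rho when primal/dual progress diverges
      if (it %% 200 == 0 && n_adapt < 8L) {
        ratio <- (rp / sp) / max(rd / sd_, 1e-300)
        if (ratio > 10 || ratio < 0.1) {
          rho <- rho * max(min(sqrt(ratio), 100), 0.01)
          factor <- refactor(rho)
          n_adapt <- n_adapt + 1L
        }
      }
    }
  }
  list(x = x, z = z, y = y, iter = it, factor = factor, rho = rho,
       converged = converged)
}

#' Solver settings for the CSpeC program
#'
#' @param eps_rel Relative convergence tolerance of the internal
#'   operator-splitting solver.
#' @param max_iter Iteration cap per solve.
#' @param rho ADMM penalty parameter (problem rows are pre-scaled, so the
#'   default is rarely worth touching).
#' @return A list of control settings.
#' @export
cspec_control <- function(eps_rel = 1e-7, max_iter = 20000, rho = 1) {
  list(eps_rel = eps_rel, max_iter = max_iter, rho = rho)
}

# Assemble constraint matrix/bounds for the CSpeC program at size k.
# Rows: p box rows (identity), one cardinality row, 2-sided power rows.
cspec_constraints <- function(p, k, power = NULL) {
  # rows are equilibrated to comparable norms for the scalar-rho solver
  sum_scl <- sqrt(p)
  if (is.null(power)) {
    A <- rbind(diag(p), rep(1 / sum_scl, p))
    l <- c(rep(0, p), 0)
    u <- c(rep(1, p), (p - k) / sum_scl)
  } else {
    Crows <- power$C_rows
    scl <- pmax(abs(power$target), apply(abs(Crows), 1, max))
    scl[scl <= 0] <- 1
    Crows_s <- Crows / scl
    A <- rbind(diag(p), rep(1 / sum_scl, p), Crows_s)
    half <- sqrt(pmax(power$zeta, 0))
    l <- c(rep(0, p), 0, (power$target - half) / scl)
    u <- c(rep(1, p), (p - k) / sum_scl, (power$target + half) / scl)
  }
  list(A = A, l = l, u = u)
}

#' Solve the CSpeC program at fixed (lambda, k)
#'
#' Minimizes `beta'(1-g) + lambda (1-g)' L (1-g)` over `g in [0,1]^p` with
#' `||g||_1 <= p - k`, optionally subject to scalp power constraints
#' (high-resolution stage). The `k` silent sources are the `k` smallest
#' entries of the solution (ties broken by lowest index).
#'
#' @param beta A `contribution_vector` or numeric p-vector.
#' @param L p x p graph Laplacian (or a `neighbor_graph`).
#' @param k Region size, `0 <= k < p`.
#' @param lambda Contiguity regularization weight, >= 0.
#' @param power_constraints Optional list with `C_rows` (phi x p matrix whose
#'   row i is `a~_i * (C_s_full a~_i)`, the per-source power contribution at
#'   electrode i), `target` (phi-vector `Var(y_i) - sigma_z_i^2`), and `zeta`
#'   (phi-vector of squared residual allowances).
#' @param control See [cspec_control()].
#' @param warm,factor Internal warm-start state (solution of a related
#'   instance) and cached KKT factor.
#' @return An object of class `cspec_solution`: `g`, `lambda`, `k`,
#'   `silent_set`, `objective_terms` (linear and Laplacian parts),
#'   `feasible`, `iter`, plus the reusable `warm`/`factor` state.
#' @export
solve_cspec <- function(beta, L, k, lambda, power_constraints = NULL,
                        control = cspec_control(), warm = NULL,
                        factor = NULL) {
  b <- contribution_values(beta)
  if (inherits(L, "neighbor_graph")) L <- L$L
  p <- length(b)
  if (k < 0 || k >= p) stop("k must satisfy 0 <= k < p", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  bscale <- max(abs(b), 1e-300)
  con <- cspec_constraints(p, k, power_constraints)
  if (k == 0 && is.null(power_constraints) && all(b >= 0)) {
    # g = 1 zeroes both objective terms and satisfies all constraints:
    # the exact optimum, with ties resolved toward "no silence"
    return(structure(list(
      g = rep(1, p), lambda = lambda, k = 0L, silent_set = integer(0),
      objective_terms = c(linear = 0, laplacian = 0), feasible = TRUE,
      iter = 0L, max_violation = 0,
      warm = list(x = rep(1, p), z = NULL, y = NULL), factor = factor),
      class = "cspec_solution"))
  }
  if (is.null(warm) || is.null(warm$z)) {
    # start at the no-silence indicator: ties resolve toward g = 1
    x1 <- if (!is.null(warm)) warm$x else rep(1, p)
    warm <- list(x = x1, z = pmin(pmax(con$A %*% x1, con$l), con$u),
                 y = numeric(nrow(con$A)))
  }
  rho0 <- if (!is.null(factor)) attr(factor, "rho") else control$rho
  sol <- qp_admm(P = (2 * lambda / bscale) * L, q = -b / bscale,
                 A = con$A, l = con$l, u = con$u,
                 rho = rho0, max_iter = control$max_iter,
                 eps_rel = control$eps_rel, warm = warm, factor = factor)
  attr(sol$factor, "rho") <- sol$rho
  g <- pmin(pmax(sol$x, 0), 1)
  ord <- order(g, seq_len(p))
  silent <- if (k > 0) sort(ord[seq_len(k)]) else integer(0)
  slack <- con$A %*% g
  viol <- pmax(con$l - slack, slack - con$u, 0)
  feasible <- sol$converged && max(viol) <= 1e-5 * max(1, abs(con$u))
  structure(list(
    g = g, lambda = lambda, k = as.integer(k), silent_set = silent,
    objective_terms = c(linear = sum(b * (1 - g)),
                        laplacian = as.numeric(crossprod(1 - g, L %*%
                                                           (1 - g)))),
    feasible = feasible, iter = sol$iter, max_violation = max(viol),
    warm = sol[c("x", "z", "y")], factor = sol$factor),
    class = "cspec_solution")
}

# Solve the CSpeC program over a (lambda, k) grid, reusing factors across k
# (the KKT matrix depends on lambda only) and warm-starting neighbouring
# grid points. Returns a list indexed [[i_lambda]][[i_k]].
cspec_sweep <- function(beta, L_for_k, k_grid, lambda_grid,
                        power_for_k = NULL, control = cspec_control(),
                        state = NULL) {
  b <- contribution_values(beta)
  out <- vector("list", length(lambda_grid))
  prev_lambda_sol <- vector("list", length(k_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    out[[i]] <- vector("list", length(k_grid))
    factor_cache <- list()
    warm <- NULL
    for (j in seq_along(k_grid)) {
      k <- k_grid[j]
      L <- if (is.function(L_for_k)) L_for_k(k) else L_for_k
      pw <- if (is.function(power_for_k)) power_for_k(k) else power_for_k
      key <- if (is.function(L_for_k)) as.character(k) else "fixed"
      fac <- factor_cache[[key]]
      skey <- paste0("w_", i, "_", j)
      w <- if (!is.null(state)) state[[skey]] else NULL
      if (is.null(w)) w <- if (!is.null(warm)) warm else
        prev_lambda_sol[[j]]
      s <- solve_cspec(b, L, k, lam, power_constraints = pw,
                       control = control, warm = w, factor = fac)
      factor_cache[[key]] <- s$factor
      warm <- s$warm
      prev_lambda_sol[[j]] <- s$warm
      if (!is.null(state)) state[[skey]] <- s$warm
      s$warm <- NULL; s$factor <- NULL
      out[[i]][[j]] <- s
    }
  }
  out
}

#' Default logarithmic lambda grid
#'
#' Log-spaced weights spanning `[1e-4, 1e2]` scaled by the ratio of the
#' contribution scale to the Laplacian scale, so the two objective terms are
#' comparable across the grid.
#'
#' @param beta Contribution vector (values or `contribution_vector`).
#' @param L Graph Laplacian (or `neighbor_graph`).
#' @param length_out Number of grid points.
#' @return Numeric vector of lambda values.
#' @export
default_lambda_grid <- function(beta, L, length_out = 16) {
  b <- contribution_values(beta)
  if (inherits(L, "neighbor_graph")) L <- L$L
  scale <- max(abs(b), 1e-300) / max(mean(diag(L)), 1e-300)
  10^seq(-4, 2, length.out = length_out) * scale
}

#' Tune the contiguity weight lambda at fixed k
#'
#' Grid search minimizing the total normalized error: each of the squared
#' contribution term `(beta'(1-g*))^2` and squared contiguity term
#' `((1-g*)' L (1-g*))^2` is normalized by its maximum over the grid, and
#' `lambda*` minimizes their sum. Ties and the all-zero degenerate case
#' resolve to the smallest lambda.
#'
#' @param beta Contribution vector.
#' @param L Graph Laplacian (or `neighbor_graph`).
#' @param k Region size.
#' @param lambda_grid Candidate lambdas (default [default_lambda_grid()]).
#' @param power_constraints Optional power constraints (see
#'   [solve_cspec()]).
#' @param control See [cspec_control()].
#' @return List with `lambda_star`, `solution` (the `cspec_solution` at
#'   `lambda_star`), `scores`, `solutions`.
#' @export
tune_lambda <- function(beta, L, k, lambda_grid = NULL,
                        power_constraints = NULL,
                        control = cspec_control()) {
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(beta, L)
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  lambda_grid <- sort(lambda_grid)
  sols <- cspec_sweep(beta, L, k, lambda_grid,
                      power_for_k = power_constraints, control = control)
  sols <- lapply(sols, `[[`, 1)
  t1 <- vapply(sols, function(s) s$objective_terms[["linear"]]^2, 0)
  t2 <- vapply(sols, function(s) s$objective_terms[["laplacian"]]^2, 0)
  score <- t1 / max(t1, .Machine$double.xmin) +
    t2 / max(t2, .Machine$double.xmin)
  if (max(t1) == 0 && max(t2) == 0) score <- rep(0, length(score))
  i <- which.min(score)
  list(lambda_star = lambda_grid[i], solution = sols[[i]],
       scores = score, solutions = sols, lambda_grid = lambda_grid)
}

#' Default region-size grid
#'
#' Sizes spanning roughly 1% to 25% of the grid, log-spaced, always
#' including the bounds.
#'
#' @param p Number of sources.
#' @param length_out Number of grid points.
#' @param k_min,k_max_frac Lower bound and upper bound (fraction of p).
#' @return Integer vector of candidate sizes.
#' @export
default_k_grid <- function(p, length_out = 8, k_min = NULL,
                           k_max_frac = 0.25) {
  if (is.null(k_min)) k_min <- max(1L, round(0.01 * p))
  k_max <- max(k_min + 1L, floor(k_max_frac * p))
  ks <- unique(round(exp(seq(log(k_min), log(k_max),
                             length.out = length_out))))
  ks[ks >= 1 & ks < p]
}

#' Estimate the silence size k by scalp power matching
#'
#' For every candidate `k`, tunes `lambda*(k)`, takes the `k` smallest
#' entries of the solution as the candidate region, and scores the match
#' between the modeled scalp power under that region and the measured
#' (noise-corrected) channel powers. On the low-resolution grid the score is
#' the max-normalized squared mismatch of the uncorrelated-source powers
#' (`sum_j a~_ij^2` over non-silent j), which needs no source-variance
#' estimate; with `cs_builder` supplied (high-resolution stage) the raw
#' squared mismatch under the modeled covariance `C_s(k)` is used. Returns
#' the minimizing `k`.
#'
#' @param beta Contribution vector.
#' @param L_for_k Graph Laplacian, `neighbor_graph`, or a function
#'   `k -> Laplacian` (the contiguity graph conventionally uses `z = k`
#'   neighbors).
#' @param A_tilde (n-1) x p differential lead field.
#' @param stats A `channel_stats`.
#' @param k_grid Candidate sizes (default [default_k_grid()]).
#' @param lambda_grid Candidate lambdas per k.
#' @param cs_builder Optional function `silent_set -> C_s` for the
#'   high-resolution power model.
#' @param power_for_k Optional power constraints per k (function or fixed
#'   list), passed to the solver.
#' @param control See [cspec_control()].
#' @return List with `k_hat`, `lambda_star`, `solution`, `silent_set`,
#'   `costs`, `k_grid`.
#' @export
estimate_size <- function(beta, L_for_k, A_tilde, stats, k_grid = NULL,
                          lambda_grid = NULL, cs_builder = NULL,
                          power_for_k = NULL, control = cspec_control(),
                          state = NULL) {
  b <- contribution_values(beta)
  p <- length(b)
  if (is.null(k_grid)) k_grid <- default_k_grid(p)
  if (length(k_grid) == 0) stop("empty k grid", call. = FALSE)
  if (is.null(lambda_grid)) {
    L0 <- if (is.function(L_for_k)) L_for_k(k_grid[1]) else L_for_k
    lambda_grid <- default_lambda_grid(b, L0)
  }
  lambda_grid <- sort(lambda_grid)
  sweep <- cspec_sweep(b, L_for_k, k_grid, lambda_grid,
                       power_for_k = power_for_k, control = control,
                       state = state)
  best <- vector("list", length(k_grid))
  costs <- numeric(length(k_grid))
  for (j in seq_along(k_grid)) {
    t1 <- vapply(sweep, function(sl)
      sl[[j]]$objective_terms[["linear"]]^2, 0)
    t2 <- vapply(sweep, function(sl)
      sl[[j]]$objective_terms[["laplacian"]]^2, 0)
    score <- t1 / max(t1, .Machine$double.xmin) +
      t2 / max(t2, .Machine$double.xmin)
    i <- which.min(score)
    best[[j]] <- sweep[[i]][[j]]
    costs[j] <- power_match_cost(best[[j]]$silent_set, A_tilde, stats,
                                 cs_builder)
  }
  j_hat <- which.min(costs)
  list(k_hat = k_grid[j_hat], lambda_star = best[[j_hat]]$lambda,
       solution = best[[j_hat]], silent_set = best[[j_hat]]$silent_set,
       costs = costs, k_grid = k_grid)
}

# Scalp power-match cost of a candidate silent set.
# Low-resolution (cs_builder NULL): max-normalized mismatch between
# sum_{j notin S} a~_ij^2 and Var(y_i) - sigma_z_i^2.
# High-resolution: raw squared mismatch under the modeled covariance.
power_match_cost <- function(silent_set, A_tilde, stats,
                             cs_builder = NULL) {
  meas <- stats$var_y - stats$sigma_z2
  if (is.null(cs_builder)) {
    act <- setdiff(seq_len(ncol(A_tilde)), silent_set)
    modeled <- rowSums(A_tilde[, act, drop = FALSE]^2)
    mmax <- max(modeled)
    dmax <- max(meas)
    if (mmax <= 0) return(Inf)
    sum((modeled / mmax - meas / ifelse(dmax == 0, 1, dmax))^2)
  } else {
    Cs <- cs_builder(silent_set)
    modeled <- rowSums((A_tilde %*% Cs) * A_tilde)
    sum((modeled - meas)^2)
  }
}

#' Scalp power mismatch of a fitted silence model
#'
#' Total squared error between the max-normalized modeled scalp powers under
#' the estimated silenced covariance and the max-normalized measured
#' noise-corrected channel powers. Used to rank candidate reference
#' electrodes (smaller is better).
#'
#' @param A_tilde (n-1) x p differential lead field.
#' @param C_s_khat p x p silenced source covariance of the final estimate.
#' @param stats A `channel_stats`.
#' @return Nonnegative scalar mismatch.
#' @export
power_mismatch <- function(A_tilde, C_s_khat, stats) {
  modeled <- rowSums((A_tilde %*% C_s_khat) * A_tilde)
  meas <- stats$var_y - stats$sigma_z2
  mmax <- max(modeled)
  if (mmax <= 0) stop("invalid model: all-zero modeled scalp power",
                      call. = FALSE)
  dmax <- max(meas)
  sum((modeled / mmax - meas / ifelse(dmax == 0, 1, dmax))^2)
}
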