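#' Configuration for the silence localization pipeline
#'
#' @param use_baseline Use the hemispheric baseline ratio (mirror-source
#'   normalization) on both stages. Without it the raw contribution measures
#'   are used, which presumes identically distributed sources.
#' @param phi Number of least-affected electrodes used for covariance
#'   fitting and power constraints; default `ceiling((n-1)/4)`.
#' @param max_iter Maximum high-resolution iterations.
#' @param delta Convergence threshold (mm) on the center-of-mass
#'   displacement, required for two consecutive iterations; default one
#'   grid spacing (median nearest-neighbor distance) of the fine grid.
#' @param lambda_grid_length,k_grid_length Grid sizes for the lambda and k
#'   searches.
#' @param k_min,k_max_frac Bounds of the size grid (see [default_k_grid()]).
#' @param variance_method `"sample"` or `"welch"` (see
#'   [estimate_channel_stats()]).
#' @param band Welch integration band (Hz).
#' @param references Candidate reference electrode labels; default all
#'   midline labels present in the lead field's layout.
#' @param control CSpeC solver control, see [cspec_control()].
#' @return A `silencemap_config` list.
#' @export
silencemap_config <- function(use_baseline = TRUE, phi = NULL,
                              max_iter = 10, delta = NULL,
                              lambda_grid_length = 16, k_grid_length = 8,
                              k_min = NULL, k_max_frac = 0.25,
                              variance_method = c("sample", "welch"),
                              band = c(1, 100), references = NULL,
                              control = cspec_control()) {
  variance_method <- match.arg(variance_method)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (!is.null(delta) && delta <= 0) stop("delta must be > 0",
                                          call. = FALSE)
  structure(list(use_baseline = use_baseline, phi = phi,
                 max_iter = max_iter, delta = delta,
                 lambda_grid_length = lambda_grid_length,
                 k_grid_length = k_grid_length, k_min = k_min,
                 k_max_frac = k_max_frac,
                 variance_method = variance_method, band = band,
                 references = references, control = control),
            class = "silencemap_config")
}

#' Fit the source covariance parameters from least-affected electrodes
#'
#' Computes the per-electrode power ratio `h_i` (power under the current
#' silenced covariance over power under the no-silence covariance, both at
#' the previous parameter iterate), selects the `phi` electrodes with the
#' largest ratio — those least affected by the silence — and re-estimates
#' `(gamma, sigma_s)` by nonlinear least squares so that the modeled
#' no-silence powers plus noise match the measured channel variances on the
#' selected electrodes.
#'
#' @param stats A `channel_stats` for the fine grid.
#' @param A_tilde (n-1) x p differential lead field.
#' @param grid The fine `source_grid`.
#' @param silent_prev Current silent-set estimate (nonempty).
#' @param phi Electrode count (>= 2).
#' @param gamma_prev,sigma_s_prev Previous parameter iterate (also the
#'   optimizer start).
#' @return List with `gamma`, `sigma_s`, `S_elec` (selected electrode
#'   indices), `h` (power ratios), `converged` (optimizer status; on
#'   failure the previous iterate is kept and `converged` is `FALSE`).
#' @export
fit_covariance_params <- function(stats, A_tilde, grid, silent_prev, phi,
                                  gamma_prev = 1, sigma_s_prev = 1) {
  stopifnot(inherits(stats, "channel_stats"))
  if (length(silent_prev) < 1) stop("silent_prev must be nonempty",
                                    call. = FALSE)
  if (phi < 2) stop("phi must be >= 2", call. = FALSE)
  pos <- grid$positions
  d2 <- as.matrix(stats::dist(pos))^2
  Efun <- function(gamma) exp(-gamma * d2)
  C_full_prev <- sigma_s_prev^2 * Efun(gamma_prev)
  C_prev <- C_full_prev
  C_prev[silent_prev, ] <- 0
  C_prev[, silent_prev] <- 0
  pow_full <- rowSums((A_tilde %*% C_full_prev) * A_tilde)
  pow_sil <- rowSums((A_tilde %*% C_prev) * A_tilde)
  h <- pow_sil / pmax(pow_full, .Machine$double.xmin)
  S_elec <- order(-h, seq_along(h))[seq_len(min(phi, length(h)))]
  Asel <- A_tilde[S_elec, , drop = FALSE]
  meas <- stats$var_y[S_elec] - stats$sigma_z2[S_elec]
  resid_fn <- function(par) {
    V <- exp(-par[1] * d2)
    par[2]^2 * rowSums((Asel %*% V) * Asel) - meas
  }
  # the residual surface is multimodal in gamma (it flattens once the
  # decay length drops below the grid spacing): refine from the previous
  # iterate plus decade-spaced restarts, keep the best fit
  starts <- unique(c(gamma_prev, 0.01, 0.1, 1))
  best <- NULL
  for (g0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(g0, sigma_s_prev), fn = resid_fn,
                         lower = c(0, 0),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    return(list(gamma = gamma_prev, sigma_s = sigma_s_prev,
                S_elec = sort(S_elec), h = h, converged = FALSE))
  }
  list(gamma = best$par[1], sigma_s = best$par[2], S_elec = sort(S_elec),
       h = h, converged = TRUE)
}

#' Run the full silence localization pipeline
#'
#' Two-stage localization for each candidate reference electrode:
#' a coarse-grid pass under the uncorrelated-source model (contribution
#' measure, optional hemispheric ratio, CSpeC with tuned lambda and
#' power-matched size), whose region center-of-mass initializes an iterative
#' fine-grid pass that alternates covariance-parameter refitting,
#' high-resolution contribution computation, and power-constrained CSpeC,
#' until the center-of-mass displacement stays within `delta` for two
#' consecutive iterations. The reference whose final model has the smallest
#' scalp power mismatch is returned.
#'
#' @param recordings_by_ref Named list of `eeg_recording`s, one per
#'   candidate reference; names are electrode labels of the lead field.
#' @param leadfields List with elements `low` and `high`: `lead_field`s (or
#'   n x p matrices) for the coarse and fine grids, both in electrode space
#'   (n rows).
#' @param grids List with elements `low` and `high`: the matching
#'   `source_grid`s.
#' @param C_z n x n electrode noise covariance (matrix or `noise_model`).
#' @param config A [silencemap_config()].
#' @return A `silencemap_result`: `silent_set`, `k_hat`, `chosen_ref`,
#'   `delta_pow_by_ref`, `com_trajectory` (per-iteration fine-grid COM,
#'   first row is the initialization), `gamma_hat`, `sigma_s_hat` (per
#'   iteration), `converged`, `iterations_used`, `low_res` (coarse-stage
#'   details), `per_ref` (all per-reference results).
#' @export
run_silencemap <- function(recordings_by_ref, leadfields, grids, C_z,
                           config = silencemap_config()) {
  stopifnot(inherits(config, "silencemap_config"))
  A_low <- as_lead_matrix(leadfields$low)
  A_high <- as_lead_matrix(leadfields$high)
  n <- nrow(A_high)
  labels <- if (inherits(leadfields$high, "lead_field"))
    leadfields$high$electrode_names else paste0("E", seq_len(n))
  refs <- names(recordings_by_ref)
  if (is.null(refs) || any(!nzchar(refs)))
    stop("recordings_by_ref must be a named list of recordings",
         call. = FALSE)
  if (!is.null(config$references))
    refs <- intersect(refs, config$references)
  if (length(refs) == 0) stop("no candidate reference present",
                              call. = FALSE)
  if (inherits(C_z, "noise_model")) C_z <- C_z$C_z

  per_ref <- lapply(refs, function(rn) {
    ref_idx <- match(rn, labels)
    if (is.na(ref_idx))
      stop("reference label not in lead field: ", rn, call. = FALSE)
    scheme <- make_reference_scheme(n, ref_idx, labels)
    silencemap_one_ref(recordings_by_ref[[rn]], scheme, A_low, A_high,
                       grids, C_z, config)
  })
  names(per_ref) <- refs
  dpow <- vapply(per_ref, `[[`, 0, "delta_pow")
  conv <- vapply(per_ref, `[[`, TRUE, "converged")
  best <- if (any(conv)) refs[conv][which.min(dpow[conv])] else
    refs[which.min(dpow)]
  res <- per_ref[[best]]
  res$chosen_ref <- best
  res$delta_pow_by_ref <- dpow
  res$per_ref <- per_ref
  class(res) <- "silencemap_result"
  res
}

silencemap_one_ref <- function(recording, scheme, A_low, A_high, grids,
                               C_z, config) {
  M <- scheme$M
  At_low <- M %*% A_low
  At_high <- M %*% A_high
  grid_low <- grids$low
  grid_high <- grids$high
  n1 <- nrow(M)
  phi <- if (is.null(config$phi)) ceiling(n1 / 4) else config$phi
  delta <- if (is.null(config$delta)) grid_spacing(grid_high) else
    config$delta
  graph_cache <- new.env(parent = emptyenv())
  L_for <- function(grid) {
    force(grid)
    function(k) {
      key <- paste0(grid$resolution, "_", k)
      if (is.null(graph_cache[[key]]))
        graph_cache[[key]] <-
          build_graph(grid, z = max(1L, min(k, grid$p - 1L)))$L
      graph_cache[[key]]
    }
  }

  # ---- coarse stage: uncorrelated-source contribution -----------------
  stats_low <- estimate_channel_stats(recording, At_low, C_z, M,
                                      method = config$variance_method,
                                      band = config$band)
  beta_low <- contribution_lowres(stats_low, At_low)
  if (config$use_baseline)
    beta_low <- hemispheric_ratio(beta_low, grid_low)
  k_grid_low <- default_k_grid(grid_low$p, config$k_grid_length,
                               k_min = config$k_min,
                               k_max_frac = config$k_max_frac)
  lam_grid_low <- default_lambda_grid(beta_low, L_for(grid_low)(
    max(k_grid_low[1], 2L)), config$lambda_grid_length)
  est_low <- estimate_size(beta_low, L_for(grid_low), At_low, stats_low,
                           k_grid = k_grid_low,
                           lambda_grid = lam_grid_low,
                           control = config$control)
  f_com_low <- region_com(grid_low, est_low$silent_set)

  # ---- fine stage: iterative correlated-source localization -----------
  stats_high <- estimate_channel_stats(recording, At_high, C_z, M,
                                       method = config$variance_method,
                                       band = config$band)
  d2_high <- as.matrix(stats::dist(grid_high$positions))^2
  s0 <- which.min(rowSums(sweep(grid_high$positions, 2, f_com_low)^2))
  silent <- s0
  gamma <- 1
  sigma_s <- 1
  com_traj <- matrix(grid_high$positions[s0, ], 1, 3)
  gam_traj <- numeric(0)
  sig_traj <- numeric(0)
  converged <- FALSE
  k_grid_high <- default_k_grid(grid_high$p, config$k_grid_length,
                                k_min = config$k_min,
                                k_max_frac = config$k_max_frac)
  est <- NULL
  fit_ok <- TRUE
  sweep_state <- new.env(parent = emptyenv())
  r <- 0
  for (r in seq_len(config$max_iter)) {
    fit <- fit_covariance_params(stats_high, At_high, grid_high, silent,
                                 phi, gamma, sigma_s)
    gamma <- fit$gamma
    sigma_s <- fit$sigma_s
    fit_ok <- fit$converged
    gam_traj <- c(gam_traj, gamma)
    sig_traj <- c(sig_traj, sigma_s)
    C_full <- sigma_s^2 * exp(-gamma * d2_high)
    Asel <- At_high[fit$S_elec, , drop = FALSE]
    C_rows <- Asel * t(C_full %*% t(Asel))         # row i: a_i * (C a_i)
    modeled_full <- rowSums(C_rows)
    meas <- stats_high$var_y[fit$S_elec] - stats_high$sigma_z2[fit$S_elec]
    # allowance = fit residual widened by the sampling-error scale of a
    # variance estimate (sd ~ var * sqrt(2/T)); the pure squared residual
    # would put the constraint boundary exactly on the solution
    rel_se <- if (is.finite(stats_high$T_len))
      sqrt(2 / stats_high$T_len) else 0.01
    power <- list(C_rows = C_rows, target = meas,
                  zeta = (abs(modeled_full - meas) +
                            rel_se * abs(meas))^2)
    beta_high <- contribution_highres(stats_high, At_high, C_full)
    if (config$use_baseline)
      beta_high <- hemispheric_ratio(beta_high, grid_high)
    lam_grid <- default_lambda_grid(beta_high, L_for(grid_high)(
      max(k_grid_high[1], 2L)), config$lambda_grid_length)
    cs_builder <- function(S) {
      Cs <- C_full
      Cs[S, ] <- 0
      Cs[, S] <- 0
      Cs
    }
    est <- estimate_size(beta_high, L_for(grid_high), At_high, stats_high,
                         k_grid = k_grid_high, lambda_grid = lam_grid,
                         cs_builder = cs_builder, power_for_k = power,
                         control = config$control, state = sweep_state)
    silent <- est$silent_set
    com_traj <- rbind(com_traj, region_com(grid_high, silent))
    # displacement within delta for two consecutive iterations, r >= 2
    if (r >= 2) {
      d_last <- sqrt(sum((com_traj[r + 1, ] - com_traj[r, ])^2))
      d_prev <- sqrt(sum((com_traj[r, ] - com_traj[r - 1, ])^2))
      if (d_last <= delta && d_prev <= delta) { converged <- TRUE; break }
    }
  }
  C_final <- sigma_s^2 * exp(-gamma * d2_high)
  C_final[silent, ] <- 0
  C_final[, silent] <- 0
  dpow <- power_mismatch(At_high, C_final, stats_high)
  list(silent_set = silent, k_hat = length(silent),
       delta_pow = dpow, com_trajectory = com_traj,
       gamma_hat = gam_traj, sigma_s_hat = sig_traj,
       converged = converged && fit_ok, iterations_used = r,
       delta = delta, ref_name = scheme$ref_name,
       low_res = list(silent_set = est_low$silent_set,
                      k_hat = est_low$k_hat, f_com = f_com_low,
                      beta = beta_low),
       beta_high = if (!is.null(est)) est$solution$g else NULL)
}

# median nearest-neighbor distance: the grid's natural length scale
grid_spacing <- function(grid) {
  d <- as.matrix(stats::dist(grid$positions))
  diag(d) <- Inf
  stats::median(apply(d, 1, min))
}

#' @export
print.silencemap_result <- function(x, ...) {
  cat(sprintf(
    "<silencemap_result> k_hat = %d, ref = %s, converged = %s (%d iter)\n",
    x$k_hat, x$chosen_ref, x$converged, x$iterations_used))
  cat(sprintf("  delta_pow = %.4g; COM = (%.1f, %.1f, %.1f) mm\n",
              x$delta_pow,
              x$com_trajectory[nrow(x$com_trajectory), 1],
              x$com_trajectory[nrow(x$com_trajectory), 2],
              x$com_trajectory[nrow(x$com_trajectory), 3]))
  invisible(x)
}
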