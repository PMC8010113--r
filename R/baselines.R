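#' Minimum-norm inverse estimate
#'
#' Ridge-regularized minimum-norm source estimate
#' `S_hat = A~' (A~ A~' + lambda I)^-1 Y`, computed through the SVD of the
#' lead field. When `lambda` is not supplied it is chosen by the L-curve
#' method: the corner (maximum curvature) of the log residual-norm versus
#' log solution-norm curve over a logarithmic grid.
#'
#' @param A_tilde (n-1) x p differential lead field.
#' @param Y (n-1) x T differential recording (or `eeg_recording`).
#' @param lambda Regularization weight (> 0), or `NULL` for L-curve choice.
#' @param lambda_grid Candidate grid for the L-curve (default 20 log-spaced
#'   points scaled by the largest squared singular value).
#' @return List with `S_hat` (p x T), `lambda`, and (when searched)
#'   `lcurve` (residual and solution norms per candidate).
#' @export
mne_inverse <- function(A_tilde, Y, lambda = NULL, lambda_grid = NULL) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  sv <- svd(A_tilde)
  UtY <- crossprod(sv$u, Y)
  make_S <- function(lam)
    sv$v %*% (UtY * (sv$d / (sv$d^2 + lam)))
  if (is.null(lambda)) {
    if (is.null(lambda_grid))
      lambda_grid <- max(sv$d)^2 * 10^seq(-6, 0, length.out = 20)
    res <- vapply(lambda_grid, function(lam) {
      filt <- lam / (sv$d^2 + lam)           # residual factor
      sqrt(sum((UtY * filt)^2))
    }, 0)
    sol <- vapply(lambda_grid, function(lam) {
      filt <- sv$d / (sv$d^2 + lam)
      sqrt(sum((UtY * filt)^2))
    }, 0)
    lambda <- lambda_grid[lcurve_corner(res, sol)]
    out <- list(S_hat = make_S(lambda), lambda = lambda,
                lcurve = data.frame(lambda = lambda_grid, residual = res,
                                    solution = sol))
  } else {
    if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
    out <- list(S_hat = make_S(lambda), lambda = lambda)
  }
  out
}

# discrete maximum-curvature point of the log-log L-curve
lcurve_corner <- function(res, sol) {
  x <- log(pmax(res, .Machine$double.xmin))
  y <- log(pmax(sol, .Machine$double.xmin))
  if (length(x) < 3 || !any(is.finite(x + y))) return(1L)
  n <- length(x)
  dx <- diff(x); dy <- diff(y)
  ddx <- diff(dx); ddy <- diff(dy)
  x1 <- (dx[-1] + dx[-(n - 1)]) / 2
  y1 <- (dy[-1] + dy[-(n - 1)]) / 2
  curv <- abs(x1 * ddy - y1 * ddx) / (x1^2 + y1^2)^1.5
  curv[!is.finite(curv)] <- -Inf
  which.max(curv) + 1L
}

#' Knee point of a sorted score curve
#'
#' For scores sorted in descending order, the knee is the index minimizing
#' the squared distance `score_q^2 + (q/p)^2` to the origin of the
#' score-versus-normalized-index curve — the point of maximum curvature for
#' the typical L-shaped membership histogram. Ties resolve to the lowest
#' index. The input is sorted internally.
#'
#' @param scores Numeric vector of nonnegative scores (ideally in [0, 1]).
#' @return Integer knee index `k_hat`.
#' @export
knee_point <- function(scores) {
  if (length(scores) == 0) stop("empty scores", call. = FALSE)
  s <- sort(scores, decreasing = TRUE)
  p <- length(s)
  d <- s^2 + (seq_len(p) / p)^2
  which.min(d)
}

# membership histogram of the k0 lowest-power sources per time point,
# normalized to [0, 1] and usable as a silence score
rank_histogram <- function(power, k0) {
  p <- nrow(power)
  k0 <- max(1L, min(as.integer(k0), p))
  thr <- apply(power, 2, function(x) sort.int(x, partial = k0)[k0])
  counts <- rowSums(power <= rep(thr, each = p))
  counts / max(counts, 1)
}

# shared silence-selection tail (steps v-vi of the modified algorithms):
# knee-point size estimate, COM of the 2*k_hat top-scoring sources,
# final region = k_hat nearest grid sources to that COM (optionally to a
# COM supplied from the coarse pass)
silence_from_scores <- function(scores, grid, com = NULL) {
  p <- length(scores)
  k_hat <- knee_point(scores)
  top <- order(-scores, seq_len(p))[seq_len(min(2L * k_hat, p))]
  f_com <- if (is.null(com)) region_com(grid, top) else com
  d <- rowSums(sweep(grid$positions, 2, f_com)^2)
  est <- sort(order(d, seq_len(p))[seq_len(k_hat)])
  list(silent_set = est, k_hat = k_hat, com = f_com,
       com_top = region_com(grid, top))
}

#' Silence localization with the modified minimum-norm pipeline
#'
#' Two-pass adaptation of minimum-norm estimation to silence detection:
#' per-time-point ranking of squared source estimates, a membership
#' histogram of the lowest-power sources, knee-point size estimation, and a
#' center-of-mass neighborhood as the final contiguous region. The coarse
#' pass fixes the center-of-mass; the fine pass re-estimates the size.
#'
#' @param A_low,A_high Differential lead fields ((n-1) x p_low / p_high).
#' @param Y (n-1) x T differential recording (or `eeg_recording`).
#' @param grids List with `low` and `high` `source_grid`s.
#' @param k0 Initial ranking depth (defaults to 5% of the grid size).
#' @param lambda Optional ridge weight forwarded to [mne_inverse()].
#' @return List with `silent_set` (fine grid), `k_hat`, `com`, `scores`,
#'   `low` (coarse-pass details), `lambda`.
#' @export
modified_mne_localize <- function(A_low, A_high, Y, grids, k0 = NULL,
                                  lambda = NULL) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  low <- mne_silence_pass(A_low, Y, grids$low, k0, lambda, com = NULL)
  high <- mne_silence_pass(A_high, Y, grids$high, k0, lambda,
                           com = low$com)
  list(silent_set = high$silent_set, k_hat = high$k_hat, com = high$com,
       scores = high$scores, low = low, lambda = high$lambda)
}

mne_silence_pass <- function(A_tilde, Y, grid, k0, lambda, com) {
  if (is.null(k0)) k0 <- max(1L, round(0.05 * ncol(A_tilde)))
  inv <- mne_inverse(A_tilde, Y, lambda = lambda)
  scores <- rank_histogram(inv$S_hat^2, k0)
  out <- silence_from_scores(scores, grid, com = com)
  out$scores <- scores
  out$lambda <- inv$lambda
  out
}

#' MUSIC-style silence contribution
#'
#' Projects each lead-field column onto the orthogonal complement of the
#' signal subspace of the recording:
#' `beta_q = ||P_perp a~_q||^2 / ||a~_q||^2` with
#' `P_perp = I - U_s U_s'`, where `U_s` spans the left singular vectors
#' capturing `rho`% of the recording energy. A source with no contribution
#' to the recording scores 1; values lie in [0, 1].
#'
#' @param A_tilde (n-1) x p differential lead field.
#' @param Y (n-1) x T differential recording (or `eeg_recording`).
#' @param rho Retained signal-subspace energy, percent in (0, 100].
#' @return A `contribution_vector` with flavor `"beta_music"`.
#' @export
music_contribution <- function(A_tilde, Y, rho = 95) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  if (rho <= 0 || rho > 100) stop("rho must be in (0, 100]", call. = FALSE)
  sv <- svd(Y, nu = min(dim(Y)), nv = 0)
  energy <- sv$d^2
  if (sum(energy) == 0) {
    vals <- rep(1, ncol(A_tilde))
  } else {
    r <- which(cumsum(energy) / sum(energy) >= rho / 100 - 1e-12)[1]
    if (is.na(r)) r <- length(energy)
    Us <- sv$u[, seq_len(r), drop = FALSE]
    proj <- A_tilde - Us %*% crossprod(Us, A_tilde)
    vals <- colSums(proj^2) / colSums(A_tilde^2)
  }
  new_contribution(pmin(pmax(vals, 0), 1), "beta_music", c(0, 1))
}

#' Silence localization with the modified MUSIC pipeline
#'
#' Applies the knee-point and center-of-mass selection directly to the
#' MUSIC noise-space contribution (large values mark silent candidates),
#' coarse pass fixing the center-of-mass for the fine pass.
#'
#' @inheritParams modified_mne_localize
#' @param rho Signal-subspace energy percentage (see
#'   [music_contribution()]).
#' @return List with `silent_set`, `k_hat`, `com`, `scores`, `low`.
#' @export
modified_music_localize <- function(A_low, A_high, Y, grids, rho = 95) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  s_low <- contribution_values(music_contribution(A_low, Y, rho))
  low <- silence_from_scores(s_low, grids$low, com = NULL)
  s_high <- contribution_values(music_contribution(A_high, Y, rho))
  high <- silence_from_scores(s_high, grids$high, com = low$com)
  list(silent_set = high$silent_set, k_hat = high$k_hat, com = high$com,
       scores = s_high, low = low)
}

#' sLORETA standardized source power
#'
#' Standardizes the minimum-norm solution by the diagonal of the model
#' resolution covariance `C = A~' (A~ A~' + lambda I)^-1 A~` (radial,
#' known-orientation form), giving `s_hat_it^2 = s_tilde_it^2 / C_ii`. The
#' recording is referenced to a specific electrode, not average-referenced.
#'
#' @inheritParams mne_inverse
#' @return List with `S2` (p x T standardized powers), `lambda`, `diag_C`.
#' @export
sloreta_standardize <- function(A_tilde, Y, lambda = NULL,
                                lambda_grid = NULL) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  inv <- mne_inverse(A_tilde, Y, lambda = lambda,
                     lambda_grid = lambda_grid)
  sv <- svd(A_tilde)
  # diag of A~'(A~A~'+lam I)^-1 A~ = sum_j v_qj^2 d_j^2/(d_j^2+lam)
  w <- sv$d^2 / (sv$d^2 + inv$lambda)
  dC <- rowSums(sweep(sv$v^2, 2, w, "*"))
  bad <- dC <= 0
  if (any(bad)) {
    warning(sum(bad), " source(s) with zero resolution variance")
    dC[bad] <- Inf
  }
  list(S2 = inv$S_hat^2 / dC, lambda = inv$lambda, diag_C = dC)
}

#' Silence localization with the modified sLORETA pipeline
#'
#' Same two-pass ranking/histogram/knee/center-of-mass procedure as the
#' modified minimum-norm pipeline, applied to sLORETA-standardized source
#' powers.
#'
#' @inheritParams modified_mne_localize
#' @return List with `silent_set`, `k_hat`, `com`, `scores`, `low`.
#' @export
modified_sloreta_localize <- function(A_low, A_high, Y, grids, k0 = NULL,
                                      lambda = NULL) {
  if (inherits(Y, "eeg_recording")) Y <- Y$Y
  pass <- function(A_tilde, grid, com) {
    if (is.null(k0)) k0 <- max(1L, round(0.05 * ncol(A_tilde)))
    st <- sloreta_standardize(A_tilde, Y, lambda = lambda)
    scores <- rank_histogram(st$S2, k0)
    out <- silence_from_scores(scores, grid, com = com)
    out$scores <- scores
    out
  }
  low <- pass(A_low, grids$low, com = NULL)
  high <- pass(A_high, grids$high, com = low$com)
  list(silent_set = high$silent_set, k_hat = high$k_hat, com = high$com,
       scores = high$scores, low = low)
}
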