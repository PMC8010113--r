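#' Channel statistics for silence localization
#'
#' Computes the statistics the contribution measures are built from: the
#' per-channel variances `Var(y_i)` of the differential recording and the
#' variances of the per-source cross-correlation coefficients
#' `mu_qt = a~_q' y_t`. Because `mu_q` is a fixed linear functional of the
#' channels, `Var(mu_qt) = a~_q' Sigma_Y a~_q`, so only the (n-1) x (n-1)
#' channel covariance is ever estimated, by the plain sample covariance
#' (`method = "sample"`; exact for flat-PSD simulation) or by Welch-averaged
#' cross-spectra integrated over a frequency band (`method = "welch"`; Hann
#' windows, 50% overlap).
#'
#' The noise covariance is taken as known (simulation mode): supply the
#' electrode-space `C_z` together with the referencing matrix, and the
#' differential noise covariance `M C_z M'` is formed internally.
#'
#' @param recording An `eeg_recording` (or an (n-1) x T matrix).
#' @param A_tilde (n-1) x p differential lead field `M %*% A`.
#' @param C_z n x n electrode noise covariance (matrix or `noise_model`).
#' @param M (n-1) x n referencing matrix (matrix or `reference_scheme`).
#' @param method Covariance estimator, `"sample"` or `"welch"`.
#' @param band Integration band in Hz for `"welch"`.
#' @param seg_sec Welch segment length in seconds.
#' @param fs Sampling rate; defaults to the recording's.
#' @return An object of class `channel_stats`: list with `var_y` (n-1),
#'   `var_mu` (p), `Sigma_Y` ((n-1) x (n-1)), `C_z_tilde`, `sigma_z2`
#'   (its diagonal), `T_len`.
#' @export
estimate_channel_stats <- function(recording, A_tilde, C_z, M,
                                   method = c("sample", "welch"),
                                   band = c(1, 100), seg_sec = 2,
                                   fs = NULL) {
  method <- match.arg(method)
  Y <- if (inherits(recording, "eeg_recording")) recording$Y else
    as.matrix(recording)
  if (is.null(fs))
    fs <- if (inherits(recording, "eeg_recording")) recording$fs else 512
  if (inherits(C_z, "noise_model")) C_z <- C_z$C_z
  if (inherits(M, "reference_scheme")) M <- M$M
  if (nrow(Y) != nrow(A_tilde))
    stop("recording and A_tilde channel counts disagree", call. = FALSE)
  C_z_tilde <- M %*% C_z %*% t(M)
  if (method == "sample") {
    Sigma_Y <- tcrossprod(Y) / ncol(Y)
  } else {
    seg <- round(seg_sec * fs)
    if (ncol(Y) < 2 * seg)
      stop("insufficient data: need T >= 2 Welch segments", call. = FALSE)
    Sigma_Y <- welch_band_covariance(Y, fs, seg, band)
  }
  channel_stats_from_sigma(Sigma_Y, A_tilde, C_z_tilde, T_len = ncol(Y))
}

#' Exact channel statistics from model covariances
#'
#' Closed-form counterpart of [estimate_channel_stats()]: the statistics a
#' recording of infinite length would give, computed directly from the model
#' covariances. Used for analytic oracles and exact-statistics experiments.
#'
#' @param A_tilde (n-1) x p differential lead field.
#' @param C_s p x p source covariance (silenced).
#' @param C_z_tilde (n-1) x (n-1) differential noise covariance.
#' @return A `channel_stats` object.
#' @export
exact_channel_stats <- function(A_tilde, C_s, C_z_tilde) {
  Sigma_Y <- A_tilde %*% C_s %*% t(A_tilde) + C_z_tilde
  channel_stats_from_sigma(Sigma_Y, A_tilde, C_z_tilde, T_len = Inf)
}

channel_stats_from_sigma <- function(Sigma_Y, A_tilde, C_z_tilde, T_len) {
  var_y <- diag(Sigma_Y)
  var_mu <- colSums((Sigma_Y %*% A_tilde) * A_tilde)
  structure(list(var_y = var_y, var_mu = var_mu, Sigma_Y = Sigma_Y,
                 C_z_tilde = C_z_tilde, sigma_z2 = diag(C_z_tilde),
                 T_len = T_len),
            class = "channel_stats")
}

# Welch-averaged cross-spectral matrix integrated over a band.
# Hann window, 50% overlap; scaled so that integrating over [0, fs/2]
# recovers the sample covariance of a stationary series.
welch_band_covariance <- function(Y, fs, seg, band) {
  n <- nrow(Y)
  T_len <- ncol(Y)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))   # Hann
  step <- floor(seg / 2)
  starts <- seq(1, T_len - seg + 1, by = step)
  nfft <- seg
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  acc <- matrix(0 + 0i, n, n)
  # accumulate band-integrated cross-spectra segment by segment
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  scale <- 1 / (fs * sum(w^2))
  df <- fs / nfft
  for (s in starts) {
    seg_y <- Y[, s:(s + seg - 1), drop = FALSE] * rep(w, each = n)
    F <- t(stats::mvfft(t(seg_y)))
    Fk <- F[, keep, drop = FALSE]
    acc <- acc + (Fk %*% Conj(t(Fk))) * scale
  }
  acc <- acc / length(starts)
  # one-sided: double all retained bins (band excludes DC and Nyquist)
  Re(acc) * 2 * df
}

#' Per-source contribution measure on the low-resolution grid
#'
#' The low-resolution contribution of source `q`,
#' `beta_q = (Var(mu_qt) - a~_q' C~_z a~_q) / sum_j (a~_q' a~_j)^2`,
#' is the noise-corrected variance of the source's cross-correlation with the
#' recording, normalized by its value under the no-silence, unit-variance,
#' spatially uncorrelated source model. It ranges from 0 (all sources silent)
#' to `sigma_s^2` (no silence). Negative noise-over-subtracted values are
#' clipped to 0; sources invisible to the array (zero denominator) are set to
#' 0 with a warning.
#'
#' @param stats A `channel_stats`.
#' @param A_tilde (n-1) x p differential lead field.
#' @return A `contribution_vector` with flavor `"beta_low"`.
#' @export
contribution_lowres <- function(stats, A_tilde) {
  stopifnot(inherits(stats, "channel_stats"))
  G <- crossprod(A_tilde)                   # a~_q' a~_j
  denom <- rowSums(G^2)
  noise_q <- colSums((stats$C_z_tilde %*% A_tilde) * A_tilde)
  num <- stats$var_mu - noise_q
  bad <- denom <= 0
  if (any(bad)) {
    warning(sum(bad), " source(s) invisible to the array; contribution 0")
    denom[bad] <- 1
  }
  values <- pmax(num, 0) / denom
  values[bad] <- 0
  new_contribution(values, "beta_low", c(0, Inf))
}

#' Per-source contribution measure on the high-resolution grid
#'
#' The high-resolution contribution normalizes the noise-corrected
#' cross-correlation variance by its no-silence value under the current
#' correlated source model:
#' `beta_q^high = (Var(mu_qt) - a~_q' C~_z a~_q) /
#'                (a~_q' (A~ C_s_full A~') a~_q)`,
#' which lies in [0, 1] (0: all silent; 1: no silence). Values are clipped
#' to that interval.
#'
#' @param stats A `channel_stats`.
#' @param A_tilde (n-1) x p differential lead field.
#' @param C_s_full p x p no-silence source covariance.
#' @return A `contribution_vector` with flavor `"beta_high"`.
#' @export
contribution_highres <- function(stats, A_tilde, C_s_full) {
  stopifnot(inherits(stats, "channel_stats"))
  Sigma_full <- A_tilde %*% C_s_full %*% t(A_tilde)
  denom <- colSums((Sigma_full %*% A_tilde) * A_tilde)
  noise_q <- colSums((stats$C_z_tilde %*% A_tilde) * A_tilde)
  num <- stats$var_mu - noise_q
  bad <- denom <= 0
  if (any(bad)) {
    warning(sum(bad), " source(s) invisible to the array; contribution 0")
    denom[bad] <- 1
  }
  values <- pmin(pmax(num, 0) / denom, 1)
  values[bad] <- 0
  new_contribution(values, "beta_high", c(0, 1))
}

#' Baseline-relative contribution ratio
#'
#' Judges each source against a baseline contribution: with an explicit
#' baseline vector, `beta~_q = min(beta_q / beta_q_base, 1)`; with the
#' hemispheric baseline (default), the baseline of source `q` is the
#' contribution of its mirror partner `q_m`, and midline-strip sources
#' (which have no partner) are assigned 1. A silent patch in one hemisphere
#' then shows `beta~` near 0 while its healthy mirror is capped at 1.
#' Division is safeguarded by flooring the baseline at
#' `eps * max(contribution)`.
#'
#' @param beta A `contribution_vector` (low- or high-resolution flavor).
#' @param grid A `source_grid` with mirror pairing (hemispheric mode).
#' @param baseline Optional explicit baseline `contribution_vector` (same
#'   length); overrides the hemispheric pairing.
#' @param eps Relative division safeguard.
#' @return A `contribution_vector` with flavor `"beta_ratio"`, values in
#'   [0, 1].
#' @export
hemispheric_ratio <- function(beta, grid = NULL, baseline = NULL,
                              eps = 1e-6) {
  b <- contribution_values(beta)
  floor_val <- eps * max(b, 0)
  if (!is.null(baseline)) {
    base <- contribution_values(baseline)
    if (length(base) != length(b))
      stop("baseline length disagrees", call. = FALSE)
    vals <- pmin(b / pmax(base, floor_val, .Machine$double.xmin), 1)
    vals[b == 0] <- 0
    return(new_contribution(vals, "beta_ratio", c(0, 1)))
  }
  stopifnot(inherits(grid, "source_grid"))
  if (length(b) != grid$p) stop("beta length != grid p", call. = FALSE)
  vals <- rep(1, grid$p)
  paired <- which(!is.na(grid$mirror_map))
  bm <- b[grid$mirror_map[paired]]
  r <- b[paired] / pmax(bm, floor_val, .Machine$double.xmin)
  r[b[paired] == 0] <- 0          # 0/0 mirrored-silent pairs count as silent
  vals[paired] <- pmin(r, 1)
  new_contribution(vals, "beta_ratio", c(0, 1))
}

new_contribution <- function(values, flavor, bounds) {
  structure(list(values = as.numeric(values), flavor = flavor,
                 bounds = bounds),
            class = "contribution_vector")
}

#' Extract the numeric values of a contribution vector
#' @param x A `contribution_vector` (numeric vectors pass through).
#' @return Numeric vector of per-source contributions.
#' @export
contribution_values <- function(x) {
  if (inherits(x, "contribution_vector")) x$values else as.numeric(x)
}

#' @export
print.contribution_vector <- function(x, ...) {
  cat(sprintf("<contribution_vector> %s, p = %d, range [%.3g, %.3g]\n",
              x$flavor, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
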