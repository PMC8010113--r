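#' Source covariance with exponential spatial decay
#'
#' Builds the source covariance under the model
#' `c_ij = sigma_s^2 * exp(-gamma * ||f_i - f_j||^2)` for non-silent sources,
#' with rows and columns of the silent set zeroed (`C_s`), together with the
#' no-silence covariance (`C_s_full`). The Gaussian kernel makes `C_s_full`
#' symmetric positive definite for distinct source positions.
#'
#' @param grid A `source_grid` (or p x 3 position matrix).
#' @param gamma Spatial decay coefficient (mm^-2), >= 0. `gamma = 0` gives a
#'   rank-one (fully coherent) field; large `gamma` approaches independence.
#' @param sigma_s2 Common source variance (arbitrary units squared).
#' @param silent_set Integer indices of silent sources (possibly empty).
#' @return An object of class `source_model`: list with `C_s`, `C_s_full`,
#'   `silent_set`, `sigma_s2`, `gamma`, `p`.
#' @export
build_source_covariance <- function(grid, gamma, sigma_s2 = 1,
                                    silent_set = integer(0)) {
  pos <- if (inherits(grid, "source_grid")) grid$positions else
    as.matrix(grid)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  p <- nrow(pos)
  silent_set <- sort(unique(as.integer(silent_set)))
  if (length(silent_set) > 0 &&
      (min(silent_set) < 1 || max(silent_set) > p))
    stop("silent_set indices out of range", call. = FALSE)
  d2 <- unname(as.matrix(stats::dist(pos)))^2
  C_full <- sigma_s2 * exp(-gamma * d2)
  C_s <- C_full
  if (length(silent_set) > 0) {
    C_s[silent_set, ] <- 0
    C_s[, silent_set] <- 0
  }
  structure(list(C_s = C_s, C_s_full = C_full, silent_set = silent_set,
                 sigma_s2 = sigma_s2, gamma = gamma, p = p),
            class = "source_model")
}

#' FIR power-spectral-density shaper
#'
#' Linear-phase FIR filter whose magnitude response follows a `1/f` power
#' law (capped below `f_corner`), designed by frequency sampling. Convolving
#' temporally white sources with this filter yields signals whose PSD mimics
#' the broadband `1/f` shape of intracranial recordings while the zero-lag
#' spatial covariance is only scaled, by the filter energy `rho_h(0)`.
#'
#' @param order Filter order (number of taps minus one).
#' @param fs Sampling rate (Hz).
#' @param f_corner Corner frequency (Hz) below which the magnitude is flat.
#' @param exponent Spectral magnitude exponent; 1 gives `1/f` magnitude.
#' @return An object of class `psd_shaper`: list with `h` (taps), `rho`
#'   (autocorrelation, lags `0..order`), `fs`.
#' @export
fir_psd_shaper <- function(order = 128, fs = 512, f_corner = 2,
                           exponent = 1) {
  freqs <- seq(0, 1, length.out = 65)         # normalized to Nyquist
  f_hz <- pmax(freqs * fs / 2, 1e-6)
  mag <- (pmax(f_hz, f_corner) / f_corner)^(-exponent)
  mag[1] <- 0                                  # no DC
  h <- as.numeric(signal::fir2(order, freqs, mag))
  h <- h / sqrt(sum(h^2))                      # unit energy: rho_h(0) = 1
  rho <- vapply(0:order, function(l)
    sum(h[seq_len(length(h) - l)] * h[seq_len(length(h) - l) + l]),
    numeric(1))
  structure(list(h = h, rho = rho, fs = fs), class = "psd_shaper")
}

#' Autocorrelation of a shaper at a given lag
#' @param shaper A `psd_shaper`.
#' @param lag Nonnegative integer lag (0 returns the filter energy).
#' @return Autocorrelation value `rho_h(lag)` (0 beyond the filter support).
#' @export
shaper_rho <- function(shaper, lag = 0) {
  lag <- abs(as.integer(lag))
  if (lag >= length(shaper$rho)) return(0)
  shaper$rho[lag + 1]
}

#' Simulate spatially correlated Gaussian source signals
#'
#' Draws `T` time points of a zero-mean multivariate Gaussian field with the
#' model covariance; silent rows are identically zero. With a `psd_shaper`,
#' each row is convolved with the FIR taps and the first `length(h) - 1`
#' warm-up samples are discarded, so the output is stationary with zero-lag
#' covariance `rho_h(0) * C_s`.
#'
#' @param model A `source_model`.
#' @param T_len Number of output time points (>= 1).
#' @param seed Optional integer seed.
#' @param shaper Optional `psd_shaper` for non-flat PSD.
#' @return p x T matrix of source signals.
#' @export
simulate_sources <- function(model, T_len, seed = NULL, shaper = NULL) {
  stopifnot(inherits(model, "source_model"))
  if (T_len < 1) stop("T_len must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  active <- setdiff(seq_len(model$p), model$silent_set)
  n_raw <- T_len + if (!is.null(shaper)) length(shaper$h) - 1L else 0L
  S <- matrix(0, model$p, T_len)
  if (length(active) > 0) {
    Ca <- model$C_s[active, active, drop = FALSE]
    R <- tryCatch(chol(Ca), error = function(e)
      stop("source covariance is not numerically positive definite; ",
           "jitter the grid or reduce gamma", call. = FALSE))
    Z <- matrix(stats::rnorm(length(active) * n_raw), length(active), n_raw)
    Sa <- crossprod(R, Z)
    if (!is.null(shaper)) {
      h <- shaper$h
      Sa <- t(apply(Sa, 1, function(x)
        stats::filter(x, h, method = "convolution", sides = 1)))
      Sa <- Sa[, length(h):n_raw, drop = FALSE]   # drop warm-up
    }
    S[active, ] <- Sa
  }
  S
}

#' Calibrate the sensor-noise level to a target average SNR
#'
#' Finds the maximum noise variance `sigma_z_max` such that the average SNR
#' of the baseline (no-silence) recording,
#' `SNR_avg = 10 log10( mean_i (A~ C_s_full A~')_ii / sigma_z_max )`,
#' equals the requested target. Per-electrode noise variances are then drawn
#' uniformly on `[0, sigma_z_max]` by [draw_noise_model()].
#'
#' @param A n x p lead field (matrix or `lead_field`).
#' @param M (n-1) x n referencing matrix (matrix or `reference_scheme`).
#' @param C_s_full p x p no-silence source covariance.
#' @param target_snr_db Target average SNR in dB.
#' @return `sigma_z_max`, the maximum per-electrode noise variance.
#' @export
calibrate_noise <- function(A, M, C_s_full, target_snr_db) {
  A <- as_lead_matrix(A)
  if (inherits(M, "reference_scheme")) M <- M$M
  At <- M %*% A
  pow <- rowSums((At %*% C_s_full) * At)   # diag(At C At')
  mp <- mean(pow)
  if (mp <= 0) stop("zero signal power: SNR target unreachable",
                    call. = FALSE)
  mp / 10^(target_snr_db / 10)
}

#' Evaluate the average SNR for a given noise level
#' @inheritParams calibrate_noise
#' @param sigma_z_max Maximum per-electrode noise variance.
#' @return Average SNR in dB.
#' @export
snr_avg_db <- function(A, M, C_s_full, sigma_z_max) {
  A <- as_lead_matrix(A)
  if (inherits(M, "reference_scheme")) M <- M$M
  At <- M %*% A
  pow <- rowSums((At %*% C_s_full) * At)
  10 * log10(mean(pow / sigma_z_max))
}

#' Draw a diagonal spatially-white sensor noise model
#'
#' Per-electrode noise variances are drawn independently and uniformly on
#' `[0, sigma_z_max]`; the noise covariance is diagonal (spatially white).
#'
#' @param n Electrode count.
#' @param sigma_z_max Maximum noise variance.
#' @param seed Optional integer seed.
#' @return An object of class `noise_model`: list with `sigma_z2`
#'   (n-vector of variances) and `C_z` (diagonal n x n).
#' @export
draw_noise_model <- function(n, sigma_z_max, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  sigma_z2 <- stats::runif(n, 0, sigma_z_max)
  structure(list(sigma_z2 = sigma_z2, C_z = diag(sigma_z2, n)),
            class = "noise_model")
}

#' Simulate a complete differential EEG recording with a known silence
#'
#' Runs the full generative pipeline: sample a contiguous silent region,
#' build the silenced source covariance, draw source signals (optionally
#' PSD-shaped), draw SNR-calibrated sensor noise, and project to differential
#' scalp recordings. The infinite-reference sensor matrix `X = A S + E` is
#' returned so recordings under any candidate reference can be formed without
#' re-simulation.
#'
#' @param grid A `source_grid`.
#' @param leadfield A `lead_field` for `grid`.
#' @param refscheme A `reference_scheme` for the returned recording.
#' @param k Silent-region size (0 for no silence).
#' @param gamma,sigma_s2 Source covariance parameters (see
#'   [build_source_covariance()]); defaults are the standard simulation
#'   settings (`gamma = 0.12` mm^-2, unit variance).
#' @param snr_db Target average SNR in dB (default 9).
#' @param T_len Number of time points (default 1e5).
#' @param psd_mode `"flat"` (temporally white) or `"real"` (FIR-shaped).
#' @param seed Integer seed controlling region, sources and noise.
#' @param depth_limit Seed-depth restriction passed to
#'   [sample_contiguous_region()] (mm below the scalp).
#' @param fs Sampling rate (Hz).
#' @param keep_sources If `TRUE`, the p x T source matrix is kept on the
#'   result (memory-heavy at full T).
#' @return An object of class `sim_recording`: list with `recording`
#'   (`eeg_recording` under `refscheme`), `X` (n x T sensor matrix),
#'   `truth` (silent indices), `source_model`, `noise_model`, `shaper`,
#'   `sigma_z_max`, `seed`, and optionally `S`.
#' @export
simulate_recording <- function(grid, leadfield, refscheme, k,
                               gamma = 0.12, sigma_s2 = 1, snr_db = 9,
                               T_len = 1e5, psd_mode = c("flat", "real"),
                               seed = 1, depth_limit = 30, fs = 512,
                               keep_sources = FALSE) {
  psd_mode <- match.arg(psd_mode)
  stopifnot(inherits(grid, "source_grid"))
  A <- as_lead_matrix(leadfield)
  n <- nrow(A)
  truth <- if (k > 0)
    sample_contiguous_region(grid, k, seed = seed,
                             depth_limit = depth_limit) else integer(0)
  model <- build_source_covariance(grid, gamma, sigma_s2, truth)
  shaper <- if (psd_mode == "real") fir_psd_shaper(fs = fs) else NULL
  S <- simulate_sources(model, T_len, seed = seed + 1L, shaper = shaper)
  sigma_z_max <- calibrate_noise(A, refscheme, model$C_s_full, snr_db)
  noise <- draw_noise_model(n, sigma_z_max, seed = seed + 2L)
  old <- local_seed(seed + 3L)
  on.exit(restore_seed(old), add = TRUE)
  E <- matrix(stats::rnorm(n * T_len), n, T_len) * sqrt(noise$sigma_z2)
  X <- A %*% S + E
  rec <- new_recording(refscheme$M %*% X, fs = fs,
                       ref_name = refscheme$ref_name)
  out <- list(recording = rec, X = X, truth = truth, source_model = model,
              noise_model = noise, shaper = shaper,
              sigma_z_max = sigma_z_max, seed = seed)
  if (keep_sources) out$S <- S
  structure(out, class = "sim_recording")
}

#' Re-reference a simulated recording
#'
#' Forms the differential recording of a simulation under another reference
#' electrode from the stored sensor matrix `X`.
#'
#' @param sim A `sim_recording`.
#' @param refscheme A `reference_scheme`.
#' @return An `eeg_recording`.
#' @export
rereference <- function(sim, refscheme) {
  stopifnot(inherits(sim, "sim_recording"))
  new_recording(refscheme$M %*% sim$X, fs = sim$recording$fs,
                ref_name = refscheme$ref_name)
}
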