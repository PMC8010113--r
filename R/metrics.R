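#' Localization performance metrics
#'
#' Compares an estimated silent region against the ground truth on a common
#' source grid: center-of-mass distance
#' `DeltaCOM = || mean_i f_i (est) - mean_i f_i (truth) ||_2` (mm, unweighted
#' means over member sources), Jaccard index
#' `JI = |est & truth| / |est | truth|`, and relative size error
#' `Delta_k = |k - k_hat| / k`.
#'
#' @param est Integer indices of the estimated region (nonempty).
#' @param truth Integer indices of the true region (nonempty).
#' @param grid A `source_grid` (or p x 3 position matrix).
#' @param converged Optional convergence flag carried into the report.
#' @param meta Optional named list of per-run metadata columns.
#' @return A one-row `data.frame` with `delta_com`, `jaccard`, `delta_k`,
#'   `k`, `k_hat`, `converged`, plus any metadata.
#' @export
#' @examples
#' g <- build_symmetric_grid(80)
#' evaluate_silence(1:5, 1:5, g)   # perfect recovery
evaluate_silence <- function(est, truth, grid, converged = NA,
                             meta = NULL) {
  pos <- if (inherits(grid, "source_grid")) grid$positions else
    as.matrix(grid)
  if (length(truth) == 0) stop("truth must be nonempty", call. = FALSE)
  if (length(est) == 0)
    stop("estimated region is empty: DeltaCOM undefined", call. = FALSE)
  com_e <- colMeans(pos[est, , drop = FALSE])
  com_t <- colMeans(pos[truth, , drop = FALSE])
  out <- data.frame(
    delta_com = sqrt(sum((com_e - com_t)^2)),
    jaccard = length(intersect(est, truth)) / length(union(est, truth)),
    delta_k = abs(length(truth) - length(est)) / length(truth),
    k = length(truth), k_hat = length(est),
    converged = converged)
  if (!is.null(meta)) out <- cbind(out, as.data.frame(meta))
  out
}

#' Hemispheric power-asymmetry statistic (MAD)
#'
#' Mean absolute difference of channel power between mirror-paired scalp
#' electrodes, `MAD = 2/(n - n_mid) * sum_pairs |Var(y_R) - Var(y_L)|`,
#' excluding the midline electrodes (which have no mirror partner). A
#' healthy, roughly symmetric brain gives a small MAD; a unilateral silence
#' inflates it.
#'
#' @param var_y Per-electrode variances, in microvolts squared.
#' @param layout An `electrode_layout` with mirror pairing.
#' @param electrode_idx Indices into the layout for each entry of `var_y`
#'   (default `seq_along(var_y)`; use the kept indices of a reference
#'   scheme when `var_y` comes from differential channels).
#' @return The MAD statistic (same units as `var_y`).
#' @export
mad_symmetry <- function(var_y, layout, electrode_idx = NULL) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (is.null(electrode_idx)) electrode_idx <- seq_along(var_y)
  if (length(electrode_idx) != length(var_y))
    stop("electrode_idx and var_y lengths disagree", call. = FALSE)
  v <- rep(NA_real_, length(layout$labels))
  v[electrode_idx] <- var_y
  lateral <- which(!is.na(layout$mirror_map))
  right <- lateral[layout$positions[lateral, 1] > 0]
  if (length(right) == 0) stop("invalid montage: no mirror pairs",
                               call. = FALSE)
  lmate <- layout$mirror_map[right]
  have <- !is.na(v[right]) & !is.na(v[lmate])
  if (!all(have))
    stop("invalid montage: unpaired electrode(s): ",
         paste(layout$labels[c(right[!have], lmate[!have])],
               collapse = ", "), call. = FALSE)
  n_lat <- 2 * length(right)
  (2 / n_lat) * sum(abs(v[right] - v[lmate]))
}

#' Convergence rate across runs
#'
#' Fraction of runs whose pipeline converged (center-of-mass displacement
#' criterion met before the iteration cap).
#'
#' @param reports A `data.frame` with a logical `converged` column, or a
#'   logical vector.
#' @return Convergence rate in [0, 1].
#' @export
convergence_rate <- function(reports) {
  conv <- if (is.data.frame(reports)) reports$converged else
    as.logical(reports)
  if (length(conv) == 0) stop("no reports", call. = FALSE)
  mean(conv, na.rm = FALSE)
}

#' Build a synthetic localization test bench
#'
#' Constructs the fixed ingredients of a simulation study: a
#' mirror-symmetric fine source grid, its farthest-point-decimated coarse
#' copy, a symmetric electrode layout, and analytic lead fields for both
#' grids.
#'
#' @param p_high Fine-grid source count.
#' @param p_low Coarse-grid source count (default 15% of the fine grid).
#' @param n_elec Electrode count.
#' @param strip_width Midline strip width (mm).
#' @param radius,scalp_radius Source and scalp sphere radii (mm).
#' @return List with `grids` (low/high), `leadfields` (low/high),
#'   `layout`.
#' @export
make_test_bench <- function(p_high = 500, p_low = NULL, n_elec = 64,
                            strip_width = 10, radius = 75,
                            scalp_radius = 92) {
  if (is.null(p_low)) p_low <- max(20L, round(0.15 * p_high))
  grid_high <- build_symmetric_grid(p_high, resolution = "high",
                                    strip_width = strip_width,
                                    radius = radius,
                                    scalp_radius = scalp_radius)
  grid_low <- decimate_grid(grid_high, p_low)
  layout <- synth_electrode_layout(n_elec, scalp_radius = scalp_radius)
  lf_high <- synth_lead_field(grid_high, layout)
  lf_low <- synth_lead_field(grid_low, layout)
  list(grids = list(low = grid_low, high = grid_high),
       leadfields = list(low = lf_low, high = lf_high),
       layout = layout)
}

#' Benchmark silence localization methods on simulated regions
#'
#' Simulates `n_regions` random contiguous silent regions at a fixed SNR and
#' runs the localization pipeline and/or the modified source-localization
#' comparators on each, evaluating all of them against the known truth.
#'
#' @param n_regions Number of simulated regions.
#' @param bench A bench from [make_test_bench()] (built on demand if
#'   `NULL`).
#' @param k True region size.
#' @param snr_db Average SNR (dB) of the baseline recording.
#' @param T_len Time points per simulation.
#' @param psd_mode `"flat"` or `"real"` source PSD.
#' @param methods Subset of `c("silencemap", "mne", "music", "sloreta")`.
#' @param references Candidate reference labels for the pipeline (the
#'   comparators use the first).
#' @param config A [silencemap_config()]; the default is the desk-scale
#'   setting (5-point lambda and k grids, 5 refinement iterations, solver
#'   tolerance 3e-6) sized for a 500-source grid.
#' @param seed Base seed; region r uses `seed + r`.
#' @param gamma,sigma_s2 Source covariance parameters.
#' @param progress Print one line per region.
#' @return A `data.frame`, one row per (region, method), with the
#'   evaluation metrics and metadata.
#' @export
run_benchmark <- function(n_regions = 20, bench = NULL, k = 20,
                          snr_db = 9, T_len = 20000,
                          psd_mode = c("flat", "real"),
                          methods = c("silencemap", "mne", "music",
                                      "sloreta"),
                          references = "Cz",
                          config = silencemap_config(
                            lambda_grid_length = 5, k_grid_length = 5,
                            max_iter = 5, k_max_frac = 0.2,
                            control = cspec_control(eps_rel = 3e-6,
                                                    max_iter = 1500)),
                          seed = 1, gamma = 0.12, sigma_s2 = 1,
                          progress = FALSE) {
  psd_mode <- match.arg(psd_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(bench)) bench <- make_test_bench()
  labels <- bench$layout$labels
  n <- length(labels)
  refs <- intersect(references, labels)
  if (length(refs) == 0) stop("no valid reference label", call. = FALSE)
  ref_schemes <- lapply(refs, function(rn)
    make_reference_scheme(n, match(rn, labels), labels))
  names(ref_schemes) <- refs
  A_high <- bench$leadfields$high$A
  A_low <- bench$leadfields$low$A
  rows <- list()
  for (r in seq_len(n_regions)) {
    s <- seed + r
    sim <- simulate_recording(bench$grids$high, bench$leadfields$high,
                              ref_schemes[[1]], k = k, gamma = gamma,
                              sigma_s2 = sigma_s2, snr_db = snr_db,
                              T_len = T_len, psd_mode = psd_mode,
                              seed = s)
    meta <- list(seed = s, snr_db = snr_db, region = r)
    if ("silencemap" %in% methods) {
      recs <- lapply(ref_schemes, function(sc) rereference(sim, sc))
      fit <- run_silencemap(recs, bench$leadfields, bench$grids,
                            sim$noise_model, config)
      rows[[length(rows) + 1]] <- cbind(
        method = "silencemap",
        evaluate_silence(fit$silent_set, sim$truth, bench$grids$high,
                         converged = fit$converged, meta = meta))
    }
    comp <- setdiff(methods, "silencemap")
    if (length(comp) > 0) {
      M1 <- ref_schemes[[1]]$M
      Y <- sim$recording$Y
      At_low <- M1 %*% A_low
      At_high <- M1 %*% A_high
      for (m in comp) {
        res <- switch(m,
          mne = modified_mne_localize(At_low, At_high, Y, bench$grids),
          music = modified_music_localize(At_low, At_high, Y,
                                          bench$grids),
          sloreta = modified_sloreta_localize(At_low, At_high, Y,
                                              bench$grids))
        rows[[length(rows) + 1]] <- cbind(
          method = m,
          evaluate_silence(res$silent_set, sim$truth, bench$grids$high,
                           converged = NA, meta = meta))
      }
    }
    if (progress)
      message(sprintf("region %d/%d done", r, n_regions))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a benchmark table
#'
#' Per-method mean and standard error of each metric, the medians, and the
#' convergence rate where defined.
#'
#' @param results Output of [run_benchmark()].
#' @return A `data.frame`, one row per method.
#' @export
summarize_benchmark <- function(results) {
  split_res <- split(results, results$method)
  out <- lapply(split_res, function(d) {
    se <- function(x) stats::sd(x) / sqrt(length(x))
    data.frame(
      method = d$method[1], n = nrow(d),
      delta_com_mean = mean(d$delta_com), delta_com_se = se(d$delta_com),
      delta_com_median = stats::median(d$delta_com),
      jaccard_mean = mean(d$jaccard), jaccard_se = se(d$jaccard),
      jaccard_median = stats::median(d$jaccard),
      delta_k_mean = mean(d$delta_k), delta_k_se = se(d$delta_k),
      cr = if (all(is.na(d$converged))) NA_real_ else
        mean(d$converged, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
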