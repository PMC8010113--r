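#' Differential referencing matrix
#'
#' Builds the (n-1) x n matrix `M` that maps ideal infinite-reference scalp
#' potentials to differential recordings against one electrode. Each row has a
#' single +1 (the recorded electrode) and a single -1 (the reference), so the
#' common mode is rejected: `M %*% rep(1, n) == 0`. With the last electrode as
#' reference, `M = [I | -1]`; any other reference is the column-permuted form.
#'
#' @param n Number of electrodes (>= 2).
#' @param ref_index Index of the reference electrode, `1 <= ref_index <= n`.
#' @param labels Optional electrode labels of length `n`.
#' @return An object of class `reference_scheme`: list with `M` ((n-1) x n),
#'   `ref_index`, `ref_name`, `kept` (indices of the n-1 recorded electrodes).
#' @export
#' @examples
#' make_reference_scheme(3, 3)$M   # rbind(c(1,0,-1), c(0,1,-1))
make_reference_scheme <- function(n, ref_index, labels = NULL) {
  if (n < 2) stop("need at least 2 electrodes", call. = FALSE)
  if (ref_index < 1 || ref_index > n)
    stop("ref_index out of range", call. = FALSE)
  kept <- setdiff(seq_len(n), ref_index)
  M <- matrix(0, n - 1, n)
  M[cbind(seq_len(n - 1), kept)] <- 1
  M[, ref_index] <- -1
  ref_name <- if (!is.null(labels)) labels[ref_index] else
    paste0("E", ref_index)
  structure(list(M = M, ref_index = as.integer(ref_index),
                 ref_name = ref_name, kept = kept),
            class = "reference_scheme")
}

#' Synthetic scalp electrode layout
#'
#' Places `n` electrodes on the scalp sphere with the same symmetric cap
#' construction as the source grid: a midline arc at `x = 0` carrying the ten
#' standard longitudinal-fissure labels (Fpz, AFz, Fz, FCz, Cz, CPz, Pz, POz,
#' Oz, Iz — the reference candidates), plus mirror-paired lateral electrodes
#' labelled `E<i>L`/`E<i>R`.
#'
#' @param n Total electrode count (>= 12).
#' @param scalp_radius Scalp sphere radius (mm).
#' @param n_midline Number of midline electrodes (default 10, the standard
#'   reference-candidate arc).
#' @param cap_angle Cap half-angle in degrees for the lateral electrodes.
#' @return An object of class `electrode_layout`: list with `positions`
#'   (n x 3), `labels`, `mirror_map` (index of the mirror electrode, `NA` on
#'   the midline), `midline` (indices), `scalp_radius`.
#' @export
synth_electrode_layout <- function(n = 64, scalp_radius = 92,
                                   n_midline = 10, cap_angle = 95) {
  if (n < n_midline + 2) stop("n too small for the layout", call. = FALSE)
  midline_names <- c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz",
                     "Oz", "Iz")[seq_len(n_midline)]
  # midline arc in the y-z plane from front (+y) to back (-y)
  ang <- seq(80, -80, length.out = n_midline) * pi / 180
  mid <- cbind(x = 0, y = sin(ang), z = cos(ang)) * scalp_radius
  n_lat <- n - n_midline
  n_pair <- floor(n_lat / 2)
  # lateral electrodes: Fibonacci cap points mirrored in x
  pts <- fibonacci_cap(2 * n_pair + n_midline + 4, scalp_radius, cap_angle)
  pts <- pts[abs(pts[, 1]) > scalp_radius * 0.06, , drop = FALSE]
  pts <- pts[pts[, 1] > 0, , drop = FALSE][seq_len(n_pair), , drop = FALSE]
  lat_r <- pts
  lat_l <- pts
  lat_l[, 1] <- -lat_l[, 1]
  positions <- rbind(mid, lat_r, lat_l)
  labels <- c(midline_names,
              paste0("E", seq_len(n_pair), "R"),
              paste0("E", seq_len(n_pair), "L"))
  mirror_map <- c(rep(NA_integer_, n_midline),
                  n_midline + n_pair + seq_len(n_pair),
                  n_midline + seq_len(n_pair))
  structure(list(positions = positions, labels = labels,
                 mirror_map = as.integer(mirror_map),
                 midline = seq_len(n_midline),
                 scalp_radius = scalp_radius),
            class = "electrode_layout")
}

#' Analytic single-sphere lead field
#'
#' Computes scalp potentials of radially oriented current dipoles in a
#' homogeneous conducting sphere via the Legendre series solution
#' \deqn{V(\theta) = \frac{1}{4\pi\sigma R^2} \sum_{m \ge 1} (2m+1)
#'   (b/R)^{m-1} P_m(\cos\theta),}
#' where `b` is the source radius, `R` the scalp radius and `theta` the angle
#' between source and electrode. Dipoles are assumed normal to the (spherical)
#' cortical surface, i.e. radial. Gains are in arbitrary potential units per
#' unit source amplitude; only ratios enter the localization method.
#'
#' @param grid A `source_grid`.
#' @param layout An `electrode_layout` (or n x 3 matrix of positions).
#' @param conductivity Scalar conductivity (S/m). Acts as a pure gain; kept
#'   as a knob for conductivity-sensitivity experiments.
#' @param n_terms Legendre series truncation order.
#' @return An object of class `lead_field`: list with `A` (n x p),
#'   `electrode_names`, `electrode_positions`, `layout`.
#' @export
synth_lead_field <- function(grid, layout, conductivity = 0.33,
                             n_terms = 60) {
  stopifnot(inherits(grid, "source_grid"))
  epos <- if (inherits(layout, "electrode_layout")) layout$positions else
    as.matrix(layout)
  enames <- if (inherits(layout, "electrode_layout")) layout$labels else
    paste0("E", seq_len(nrow(epos)))
  spos <- grid$positions
  b <- sqrt(rowSums(spos^2))           # source radii
  R <- sqrt(rowSums(epos^2))           # electrode radii
  if (any(b >= min(R)))
    stop("invalid geometry: electrode inside the source sphere",
         call. = FALSE)
  Rm <- mean(R)
  # cos(theta) between each electrode and each source
  ct <- tcrossprod(epos / R, spos / b)
  ct <- pmin(pmax(ct, -1), 1)
  ratio <- b / Rm
  A <- matrix(0, nrow(epos), nrow(spos))
  # Legendre recurrence P_m(ct), accumulating (2m+1) (b/R)^(m-1) P_m
  Pm1 <- matrix(1, nrow(ct), ncol(ct))  # P_0
  Pm <- ct                              # P_1
  pow <- rep(1, length(ratio))          # (b/R)^(m-1)
  for (m in seq_len(n_terms)) {
    A <- A + sweep(Pm, 2, (2 * m + 1) * pow, "*")
    pow <- pow * ratio
    Pnext <- ((2 * m + 1) * ct * Pm - m * Pm1) / (m + 1)
    Pm1 <- Pm
    Pm <- Pnext
  }
  A <- A / (4 * pi * conductivity * Rm^2)
  if (any(colSums(abs(A)) == 0))
    stop("lead field has an all-zero column", call. = FALSE)
  structure(list(A = A, electrode_names = enames,
                 electrode_positions = epos,
                 layout = if (inherits(layout, "electrode_layout")) layout
                          else NULL),
            class = "lead_field")
}

#' Project sources and noise to a differential scalp recording
#'
#' Forms `Y = M (A S + E)`: sources map through the lead field, electrode
#' noise adds at the sensors, and the referencing matrix converts to
#' differential potentials.
#'
#' @param A n x p lead field (matrix or `lead_field`).
#' @param M (n-1) x n referencing matrix (matrix or `reference_scheme`).
#' @param S p x T source signal matrix.
#' @param E n x T electrode noise matrix (or `NULL` for noiseless).
#' @param fs Sampling rate in Hz, carried on the result.
#' @param ref_name Reference label, carried on the result.
#' @return An object of class `eeg_recording`: list with `Y` ((n-1) x T),
#'   `fs`, `ref_name`.
#' @export
project_scalp <- function(A, M, S, E = NULL, fs = 512, ref_name = NULL) {
  A <- as_lead_matrix(A)
  if (inherits(M, "reference_scheme")) {
    if (is.null(ref_name)) ref_name <- M$ref_name
    M <- M$M
  }
  if (ncol(A) != nrow(S)) stop("A and S shapes disagree", call. = FALSE)
  if (ncol(M) != nrow(A)) stop("M and A shapes disagree", call. = FALSE)
  X <- A %*% S
  if (!is.null(E)) {
    if (!all(dim(E) == dim(X))) stop("E shape disagrees", call. = FALSE)
    X <- X + E
  }
  new_recording(M %*% X, fs = fs, ref_name = ref_name)
}

new_recording <- function(Y, fs = 512, ref_name = NULL) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("recording needs T >= 2", call. = FALSE)
  structure(list(Y = Y, fs = fs,
                 ref_name = if (is.null(ref_name)) NA_character_ else
                   ref_name),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (ref %s)\n",
              nrow(x$Y), ncol(x$Y), x$fs, x$ref_name))
  invisible(x)
}

as_lead_matrix <- function(A) if (inherits(A, "lead_field")) A$A else
  as.matrix(A)
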