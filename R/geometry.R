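#' Build a mirror-symmetric synthetic source grid on a spherical cap
#'
#' Places approximately `p_target` sources quasi-uniformly (Fibonacci lattice)
#' on an upper spherical cap that stands in for a discretized cortical surface.
#' The grid is mirror-symmetric about the midsagittal plane `x = 0`: every
#' source with `|x|` larger than half the strip width has exactly one mirror
#' partner in the opposite hemisphere. Sources inside the midline strip (the
#' longitudinal-fissure stand-in) carry the label `"strip"` and have no mirror
#' partner.
#'
#' @param p_target Requested number of sources (>= 4). The realized count `p`
#'   can differ by a few sources because symmetry is enforced by construction.
#' @param resolution Tag `"low"` or `"high"`; carried on the object, not used
#'   in construction.
#' @param strip_width Width (mm) of the midline strip with no mirror partners.
#' @param radius Radius (mm) of the source sphere (cortical surface stand-in).
#' @param scalp_radius Radius (mm) of the outer (scalp) sphere; used for
#'   depth bookkeeping when sampling superficial regions.
#' @param cap_angle Half-opening angle of the cap in degrees, measured from
#'   the +z pole. Default 100 covers slightly more than a hemisphere of the
#'   sphere, mimicking cortex extending below the equator of the head.
#' @param jitter Standard deviation (mm) of tangential jitter applied
#'   symmetrically to mirrored pairs (breaks exact lattice ties). Default 0.
#' @param seed Optional integer seed controlling the jitter; the lattice
#'   itself is deterministic.
#'
#' @return An object of class `source_grid`: a list with `positions` (p x 3,
#'   mm; +x toward the right ear, midsagittal plane x = 0), `hemisphere`
#'   (character, `"L"`, `"R"` or `"strip"`), `mirror_map` (integer vector,
#'   `mirror_map[q]` is the index of the mirror partner of source `q`, `NA`
#'   for strip sources), `p`, `resolution`, `radius`, `scalp_radius`.
#' @export
#' @examples
#' g <- build_symmetric_grid(100, strip_width = 10)
#' table(g$hemisphere)
build_symmetric_grid <- function(p_target, resolution = c("high", "low"),
                                 strip_width = 0, radius = 75,
                                 scalp_radius = 92, cap_angle = 100,
                                 jitter = 0, seed = NULL) {
  resolution <- match.arg(resolution)
  if (!is.numeric(p_target) || p_target < 4)
    stop("p_target must be a number >= 4", call. = FALSE)
  if (strip_width < 0) stop("strip_width must be >= 0", call. = FALSE)

  pts <- fibonacci_cap(round(p_target), radius, cap_angle)
  half <- strip_width / 2
  right <- pts[pts[, 1] > half, , drop = FALSE]
  strip <- pts[abs(pts[, 1]) <= half, , drop = FALSE]
  if (nrow(right) < 1)
    stop("p_target too small to place at least one mirrored pair",
         call. = FALSE)

  if (jitter > 0) {
    if (!is.null(seed)) {
      old <- local_seed(seed)
      on.exit(restore_seed(old), add = TRUE)
    }
    right <- jitter_on_sphere(right, jitter, radius)
    if (nrow(strip) > 0) {
      # strip sources keep their x so they stay inside the strip
      strip_j <- jitter_on_sphere(strip, jitter, radius)
      strip_j[, 1] <- strip[, 1]
      strip <- strip_j
    }
  }

  left <- right
  left[, 1] <- -left[, 1]
  positions <- rbind(right, left, strip)
  nr <- nrow(right)
  ns <- nrow(strip)
  hemisphere <- c(rep("R", nr), rep("L", nr), rep("strip", ns))
  mirror_map <- c(seq_len(nr) + nr, seq_len(nr), rep(NA_integer_, ns))

  grid <- structure(
    list(positions = positions, hemisphere = hemisphere,
         mirror_map = as.integer(mirror_map), p = nrow(positions),
         resolution = resolution, radius = radius,
         scalp_radius = scalp_radius),
    class = "source_grid")
  validate_source_grid(grid)
  grid
}

# Fibonacci lattice on a spherical cap of half-angle cap_angle (deg)
fibonacci_cap <- function(m, radius, cap_angle) {
  i <- seq_len(m) - 0.5
  zmin <- cos(cap_angle * pi / 180)
  z <- 1 - (1 - zmin) * i / m          # cos(theta) in (zmin, 1)
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  r_xy <- sqrt(pmax(0, 1 - z^2))
  radius * cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
}

jitter_on_sphere <- function(pts, sd, radius) {
  pts <- pts + matrix(stats::rnorm(length(pts), sd = sd), nrow(pts), 3)
  pts * (radius / sqrt(rowSums(pts^2)))
}

#' Construct a source grid from explicit coordinates
#'
#' Builds a `source_grid` from externally supplied positions (e.g. a cortical
#' mesh exported from anatomical processing). Hemisphere labels are assigned
#' by the sign of `x` against the strip width, and mirror partners are found
#' as nearest neighbors after reflection across the midsagittal plane.
#'
#' @param positions p x 3 matrix of coordinates (mm), +x toward the right ear.
#' @param strip_width Width (mm) of the midline strip excluded from pairing.
#' @param resolution Tag `"low"` or `"high"`.
#' @param scalp_radius Outer-surface radius (mm); defaults to the largest
#'   source radius plus 15 mm.
#' @return A `source_grid`; see [build_symmetric_grid()].
#' @export
as_source_grid <- function(positions, strip_width = 0,
                           resolution = c("high", "low"),
                           scalp_radius = NULL) {
  resolution <- match.arg(resolution)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 2)
    stop("positions must be a p x 3 matrix with p >= 2", call. = FALSE)
  half <- strip_width / 2
  hemisphere <- ifelse(abs(positions[, 1]) <= half, "strip",
                       ifelse(positions[, 1] > 0, "R", "L"))
  mirror_map <- rep(NA_integer_, nrow(positions))
  reflected <- positions
  reflected[, 1] <- -reflected[, 1]
  for (h in c("L", "R")) {
    idx <- which(hemisphere == h)
    opp <- which(hemisphere == setdiff(c("L", "R"), h))
    if (length(idx) == 0 || length(opp) == 0) next
    # nearest opposite-hemisphere source to the reflected position
    d <- outer_dist(reflected[idx, , drop = FALSE],
                    positions[opp, , drop = FALSE])
    mirror_map[idx] <- opp[apply(d, 1, which.min)]
  }
  if (is.null(scalp_radius))
    scalp_radius <- max(sqrt(rowSums(positions^2))) + 15
  structure(
    list(positions = positions, hemisphere = hemisphere,
         mirror_map = as.integer(mirror_map), p = nrow(positions),
         resolution = resolution,
         radius = max(sqrt(rowSums(positions^2))),
         scalp_radius = scalp_radius),
    class = "source_grid")
}

validate_source_grid <- function(grid, tol = 1e-6) {
  stopifnot(inherits(grid, "source_grid"))
  p <- grid$p
  if (p < 2) stop("source grid needs p >= 2", call. = FALSE)
  paired <- which(!is.na(grid$mirror_map))
  mm <- grid$mirror_map
  if (length(paired) > 0) {
    if (!all(mm[mm[paired]] == paired))
      stop("mirror_map is not an involution", call. = FALSE)
    dx <- abs(abs(grid$positions[paired, 1]) -
              abs(grid$positions[mm[paired], 1]))
    if (max(dx) > tol)
      stop("mirrored pairs have unequal |x| offsets", call. = FALSE)
  }
  if (any(grid$hemisphere == "strip" & !is.na(mm)))
    stop("strip sources must have no mirror partner", call. = FALSE)
  invisible(grid)
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> p = %d (%s resolution), radius %.0f mm\n",
              x$p, x$resolution, x$radius))
  cat("  hemisphere:", paste(sprintf("%s=%d", names(table(x$hemisphere)),
                                     table(x$hemisphere)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Decimate a grid by farthest-point sampling
#'
#' Produces a coarse copy of a high-resolution grid, used as the
#' low-resolution stage of the localization pipeline. Mirror symmetry is
#' preserved by sampling on one hemisphere and mirroring the selection.
#'
#' @param grid A `source_grid`.
#' @param p_low Target number of sources in the coarse grid.
#' @return A `source_grid` with `resolution = "low"`.
#' @export
decimate_grid <- function(grid, p_low) {
  stopifnot(inherits(grid, "source_grid"))
  if (p_low >= grid$p) stop("p_low must be < p", call. = FALSE)
  right <- which(grid$hemisphere == "R")
  strip <- which(grid$hemisphere == "strip")
  n_r <- max(1L, floor((p_low - min(length(strip), 2)) / 2))
  sel_r <- farthest_point_sample(grid$positions[right, , drop = FALSE], n_r)
  keep <- c(right[sel_r], grid$mirror_map[right[sel_r]])
  if (length(strip) > 0) {
    n_s <- max(0L, p_low - length(keep))
    if (n_s > 0) {
      sel_s <- farthest_point_sample(grid$positions[strip, , drop = FALSE],
                                     min(n_s, length(strip)))
      keep <- c(keep, strip[sel_s])
    }
  }
  keep <- sort(keep)
  pos <- grid$positions[keep, , drop = FALSE]
  hemi <- grid$hemisphere[keep]
  remap <- match(grid$mirror_map[keep], keep)
  structure(
    list(positions = pos, hemisphere = hemi,
         mirror_map = as.integer(remap), p = length(keep),
         resolution = "low", radius = grid$radius,
         scalp_radius = grid$scalp_radius),
    class = "source_grid")
}

farthest_point_sample <- function(pts, m) {
  n <- nrow(pts)
  if (m >= n) return(seq_len(n))
  sel <- integer(m)
  # start from the point farthest from the centroid for determinism
  d0 <- rowSums(sweep(pts, 2, colMeans(pts))^2)
  sel[1] <- which.max(d0)
  mind <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  for (i in seq_len(m - 1L)) {
    sel[i + 1L] <- which.max(mind)
    d <- rowSums(sweep(pts, 2, pts[sel[i + 1L], ])^2)
    mind <- pmin(mind, d)
  }
  sort(sel)
}

#' Build the z-nearest-neighbor contiguity graph of a source grid
#'
#' Two sources are linked if either is among the `z` nearest neighbors of the
#' other; the link weight is a Gaussian kernel of their distance,
#' `w_ij = exp(-||f_i - f_j||^2 / (2 theta^2))`. The decay constant `theta` is
#' the standard deviation of all pairwise inter-source distances, which
#' normalizes distances by the grid's own scale. The graph Laplacian
#' `L = D - W` supplies the contiguity penalty of the CSpeC program.
#'
#' @param grid A `source_grid` (or a p x 3 position matrix).
#' @param z Neighbor count, `1 <= z < p`.
#' @param pair_subsample Above this many sources, `theta` is estimated from a
#'   seeded uniform subsample of pairs instead of all p(p-1)/2.
#' @return An object of class `neighbor_graph`: list with `W`, `D` (degree
#'   vector), `L`, `z`, `theta`.
#' @export
build_graph <- function(grid, z, pair_subsample = 3000) {
  pos <- if (inherits(grid, "source_grid")) grid$positions else as.matrix(grid)
  p <- nrow(pos)
  if (p < 3) stop("need p >= 3 sources", call. = FALSE)
  if (z < 1 || z >= p) stop("z must satisfy 1 <= z < p", call. = FALSE)
  dmat <- unname(as.matrix(stats::dist(pos)))
  theta <- pairwise_theta(dmat, pair_subsample)
  if (theta <= 0)
    stop("degenerate geometry: all sources coincident (theta = 0)",
         call. = FALSE)
  nn <- matrix(knn_indices(dmat, z), nrow = z)
  W <- matrix(0, p, p)
  for (j in seq_len(p)) W[nn[, j], j] <- 1
  W <- pmax(W, t(W))                    # OR rule: i in zNN(j) or j in zNN(i)
  W <- W * exp(-dmat^2 / (2 * theta^2))
  diag(W) <- 0
  D <- rowSums(W)
  L <- diag(D) - W
  structure(list(W = W, D = D, L = L, z = as.integer(z), theta = theta),
            class = "neighbor_graph")
}

# sample std-dev of pairwise distances; both mean and variance use 1/(N-1)
# with N = p(p-1)/2
pairwise_theta <- function(dmat, pair_subsample) {
  p <- nrow(dmat)
  d <- dmat[upper.tri(dmat)]
  if (p > pair_subsample) {
    n_pairs <- length(d)
    m <- pair_subsample * (pair_subsample - 1) / 2
    old <- local_seed(20231L)
    on.exit(restore_seed(old), add = TRUE)
    d <- d[sample.int(n_pairs, min(m, n_pairs))]
  }
  n <- length(d)
  dbar <- sum(d) / (n - 1)
  sqrt(sum((d - dbar)^2) / (n - 1))
}

# column q holds the z nearest neighbors of source q (ties: lowest index)
knn_indices <- function(dmat, z) {
  p <- nrow(dmat)
  vapply(seq_len(p), function(q) {
    d <- dmat[, q]
    d[q] <- Inf
    order(d, seq_len(p))[seq_len(z)]
  }, integer(z))
}

#' Sample a contiguous region on one hemisphere
#'
#' Picks a seed source uniformly at random (optionally restricted to sources
#' shallower than `depth_limit` below the scalp surface) and returns the seed
#' together with its `k - 1` nearest same-hemisphere neighbors — a contiguous
#' patch by construction. Strip sources are never chosen, and the region never
#' crosses the midline.
#'
#' @param grid A `source_grid`.
#' @param k Region size (number of sources), `1 <= k < p/2`.
#' @param seed Optional integer seed.
#' @param depth_limit Maximum depth (mm) of the seed source below the scalp
#'   surface, or `NULL` for no restriction. The conventional choice of 30 mm
#'   keeps regions within gray-matter reach of scalp electrodes.
#' @return Integer vector of `k` source indices.
#' @export
sample_contiguous_region <- function(grid, k, seed = NULL,
                                     depth_limit = NULL) {
  stopifnot(inherits(grid, "source_grid"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= grid$p / 2)
    stop("k must be < p/2 (silent region must be small)", call. = FALSE)
  eligible <- which(grid$hemisphere %in% c("L", "R"))
  if (!is.null(depth_limit)) {
    depth <- grid$scalp_radius - sqrt(rowSums(grid$positions^2))
    eligible <- eligible[depth[eligible] <= depth_limit]
  }
  # seed must have k-1 same-hemisphere companions
  hemi_n <- table(grid$hemisphere)
  eligible <- eligible[hemi_n[grid$hemisphere[eligible]] >= k]
  if (length(eligible) == 0)
    stop("no eligible seed source for the requested region", call. = FALSE)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  s <- eligible[sample.int(length(eligible), 1)]
  same <- which(grid$hemisphere == grid$hemisphere[s])
  d <- sqrt(rowSums(sweep(grid$positions[same, , drop = FALSE], 2,
                          grid$positions[s, ])^2))
  same[order(d, same)[seq_len(k)]]
}

region_com <- function(grid, idx) {
  colMeans(grid$positions[idx, , drop = FALSE])
}

outer_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# seed handling that restores the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
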