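#' Simulate a cortical CELSR1-like intensity profile
#'
#' Generates a synthetic per-cell cortical profile: a mixture of
#' von-Mises-shaped intensity bumps at the given domain centers on top
#' of a constant background with additive noise.  A polarized cell is
#' two opposing centers (e.g. `c(10, 190)`); an unpolarized cell is a
#' single center or none.
#'
#' @param centers Domain center angles in degrees.
#' @param kappa Concentration of each bump (larger = sharper).
#' @param n Number of samples around the circle (default 360).
#' @param amplitude Bump peak amplitude.
#' @param background Constant background level.
#' @param noise_sd Gaussian noise standard deviation.
#' @return A [cortical_profile()].
#' @export
sim_cortical_profile <- function(centers, kappa = 8, n = 360L,
                                 amplitude = 1, background = 0.1,
                                 noise_sd = 0.05) {
  theta <- seq(0, 360 - 360 / n, length.out = n)
  y <- rep(background, n)
  for (ct in centers) {
    d <- (theta - ct) * pi / 180
    y <- y + amplitude * exp(kappa * (cos(d) - 1))
  }
  y <- pmax(y + stats::rnorm(n, sd = noise_sd), 0)
  cortical_profile(theta, y)
}

#' Simulate a Voronoi cell label mask
#'
#' Scatters `n_cells` seed points uniformly and labels every pixel by
#' its nearest seed — a simple epithelial-sheet-like segmentation used
#' as test input for area/density measurements.
#'
#' @param n_cells Number of cells.
#' @param nrow,ncol Mask dimensions in pixels.
#' @param seed Optional RNG seed.
#' @return Integer label matrix with labels `1:n_cells`.
#' @export
sim_voronoi_mask <- function(n_cells, nrow = 64L, ncol = 64L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cells >= 1L)
  sr <- stats::runif(n_cells, 1, nrow)
  sc <- stats::runif(n_cells, 1, ncol)
  rr <- matrix(rep(seq_len(nrow), ncol), nrow)
  cc <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  best <- matrix(1L, nrow, ncol)
  bestd <- (rr - sr[1L])^2 + (cc - sc[1L])^2
  for (i in seq_len(n_cells)[-1L]) {
    d <- (rr - sr[i])^2 + (cc - sc[i])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  best
}

#' Simulate a binary focal-adhesion mask of elliptical objects
#'
#' Draws filled ellipses (axis lengths in pixels) at given centers on an
#' empty field; overlapping ellipses merge into one connected object.
#'
#' @param centers Two-column matrix of (row, col) centers.
#' @param semi_axes Two-column matrix of (a, b) semi-axis lengths in
#'   pixels, one row per ellipse.
#' @param angle_deg Rotation of each ellipse in degrees (recycled).
#' @param nrow,ncol Mask dimensions.
#' @return Logical matrix.
#' @export
sim_adhesion_mask <- function(centers, semi_axes, angle_deg = 0,
                              nrow = 64L, ncol = 64L) {
  centers <- matrix(centers, ncol = 2L)
  semi_axes <- matrix(semi_axes, ncol = 2L)
  stopifnot(nrow(centers) == nrow(semi_axes))
  angle_deg <- rep_len(angle_deg, nrow(centers))
  rr <- matrix(rep(seq_len(nrow), ncol), nrow)
  cc <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  bw <- matrix(FALSE, nrow, ncol)
  for (i in seq_len(nrow(centers))) {
    a <- angle_deg[i] * pi / 180
    dr <- rr - centers[i, 1L]
    dc <- cc - centers[i, 2L]
    u <- dr * cos(a) + dc * sin(a)
    v <- -dr * sin(a) + dc * cos(a)
    bw <- bw | (u / semi_axes[i, 1L])^2 + (v / semi_axes[i, 2L])^2 <= 1
  }
  bw
}
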