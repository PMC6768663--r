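#' Hair-follicle orientation histogram
#'
#' Frequency distribution of follicle orientation angles relative to the
#' anterior-posterior (A-P) axis; 0 degrees is perfect A-P alignment.
#' Angles live in (-180, 180]; bins are left-open right-closed so the
#' domain tiles exactly.
#'
#' @param angles Numeric vector of angles in degrees, each in
#'   (-180, 180].
#' @param bin_width Bin width in degrees; must divide 360.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `bin_mid`,
#'   `count`, `freq`; frequencies sum to 1.
#' @export
orientation_histogram <- function(angles, bin_width = 20) {
  if (!length(angles)) stop("empty angle sample")
  if (any(!is.finite(angles)) || any(angles <= -180 | angles > 180))
    stop("angles must be finite and in (-180, 180]")
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  breaks <- seq(-180, 180, by = bin_width)
  bin <- cut(angles, breaks = breaks, right = TRUE, include.lowest = FALSE)
  count <- as.integer(table(bin))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             bin_mid = (breaks[-length(breaks)] + breaks[-1L]) / 2,
             count = count, freq = count / sum(count))
}

#' Compare two angle distributions (Kolmogorov-Smirnov)
#'
#' @param a,b Numeric angle samples (degrees).
#' @return List with `statistic` (D, the maximum ECDF gap) and
#'   `p_value`.
#' @export
compare_angle_distributions <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty angle sample")
  ks <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Classify follicle growth direction
#'
#' A follicle is perpendicular if the angle between its growth axis and
#' the skin normal is at most `perpendicular_threshold` (inclusive);
#' otherwise it is angled.  Axes are treated as undirected.
#'
#' @param follicle_axis,skin_normal 3-D vectors (normalized internally).
#' @param perpendicular_threshold Threshold in degrees (default 15).
#' @return `"PERPENDICULAR"` or `"ANGLED"`.
#' @export
classify_follicle_growth <- function(follicle_axis, skin_normal,
                                     perpendicular_threshold = 15) {
  stopifnot(length(follicle_axis) == 3L, length(skin_normal) == 3L)
  na <- sqrt(sum(follicle_axis^2))
  nb <- sqrt(sum(skin_normal^2))
  if (na == 0 || nb == 0) stop("zero vector")
  cosang <- abs(sum(follicle_axis * skin_normal)) / (na * nb)
  ang <- acos(pmin(1, cosang)) * 180 / pi
  ## inclusive boundary, robust to acos rounding
  if (ang <= perpendicular_threshold + 1e-9) "PERPENDICULAR" else "ANGLED"
}

#' Bin a line-intensity profile into equal-width bins
#'
#' Normalizes for cell size by rescaling positions to the unit interval and
#' averaging intensity within `n_bins` equal-width bins (20 by default,
#' so profiles from cells of different sizes are comparable).
#'
#' @param position Ordered numeric positions along the line.
#' @param intensity Non-negative intensities, same length.
#' @param n_bins Number of bins (default 20).
#' @return Numeric vector of length `n_bins` of bin mean intensities.
#' @export
bin_intensity_profile <- function(position, intensity, n_bins = 20L) {
  stopifnot(length(position) == length(intensity), all(intensity >= 0))
  n <- length(position)
  if (n < n_bins) stop("need at least as many samples as bins")
  rng <- range(position)
  if (diff(rng) == 0) stop("degenerate profile: zero length line")
  u <- (position - rng[1L]) / diff(rng)
  bin <- pmin(floor(u * n_bins) + 1L, n_bins)
  as.numeric(tapply(intensity, factor(bin, levels = seq_len(n_bins)), mean))
}

#' Cortical intensity profile of one cell
#'
#' @param theta Cortical angles in degrees, covering [0, 360).
#' @param intensity Non-negative intensities.
#' @return An object of class `cortical_profile`.
#' @export
cortical_profile <- function(theta, intensity) {
  stopifnot(length(theta) == length(intensity), all(intensity >= 0),
            all(theta >= 0), all(theta < 360))
  o <- order(theta)
  structure(list(theta = theta[o], intensity = intensity[o]),
            class = "cortical_profile")
}

## circular moving-average smoothing
.circ_smooth <- function(y, half_window) {
  if (half_window < 1L) return(y)
  n <- length(y)
  k <- 2L * half_window + 1L
  ext <- c(y[(n - half_window + 1L):n], y, y[1:half_window])
  stats::filter(ext, rep(1 / k, k), sides = 2L)[(half_window + 1L):
                                                  (half_window + n)]
}

#' Classify a cell as planar-polarized from its cortical profile
#'
#' A cell is polarized when two opposing cortical domains are present:
#' after circular smoothing, the two strongest local maxima must each
#' rise above the background (the profile median, on a 0-1 normalized
#' scale) by at least `min_prominence`, and their angular separation
#' must be 180 +/- `opposition_tol` degrees.  The polarity axis is the
#' doubled-angle mean of the two refined peak directions, reported in
#' (-90, 90] with 0 meaning peaks on the A-P axis (theta = 0/180).
#'
#' @param profile A [cortical_profile()].
#' @param opposition_tol Allowed deviation from 180-degree opposition
#'   (default 30).
#' @param min_prominence Minimum peak height above background on the
#'   normalized scale (default 0.2).
#' @param smooth_halfwidth Smoothing half-window in samples (default:
#'   ~7.5 degrees of the profile).
#' @param refine_halfwidth Half-window (degrees) of the intensity-
#'   weighted circular mean used to refine each peak position
#'   (default 30).
#' @return List with `is_polarized`, `polarity_angle` (degrees, `NA`
#'   when not polarized) and `peaks` (the two candidate peak angles).
#' @export
classify_polarized_cell <- function(profile, opposition_tol = 30,
                                    min_prominence = 0.2,
                                    smooth_halfwidth = NULL,
                                    refine_halfwidth = 30) {
  stopifnot(inherits(profile, "cortical_profile"))
  th <- profile$theta
  y <- profile$intensity
  n <- length(y)
  if (n < 8L) stop("profile too sparse to classify")
  if (max(y) == min(y))
    return(list(is_polarized = FALSE, polarity_angle = NA_real_,
                peaks = c(NA_real_, NA_real_)))
  y01 <- (y - min(y)) / (max(y) - min(y))
  if (is.null(smooth_halfwidth))
    smooth_halfwidth <- max(1L, round(n * 7.5 / 360))
  ys <- as.numeric(.circ_smooth(y01, smooth_halfwidth))
  bg <- stats::median(ys)
  ## circular local maxima
  prv <- c(ys[n], ys[-n])
  nxt <- c(ys[-1L], ys[1L])
  is_max <- ys >= prv & ys > nxt
  cand <- which(is_max & ys >= bg + min_prominence)
  ## non-maximum suppression: one peak per cortical domain — greedily
  ## keep the highest maxima at least min_separation degrees apart, so
  ## noise twins on one domain do not masquerade as a second domain
  cand <- cand[order(ys[cand], decreasing = TRUE)]
  min_separation <- 60
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) ||
        all(abs(((th[i] - th[kept] + 180) %% 360) - 180) >= min_separation))
      kept <- c(kept, i)
  }
  if (length(kept) < 2L)
    return(list(is_polarized = FALSE, polarity_angle = NA_real_,
                peaks = c(NA_real_, NA_real_)))
  p1 <- kept[[1L]]
  p2 <- kept[[2L]]
  sep <- abs(((th[p1] - th[p2] + 180) %% 360) - 180)
  opposed <- abs(sep - 180) <= opposition_tol
  if (!opposed)
    return(list(is_polarized = FALSE, polarity_angle = NA_real_,
                peaks = th[c(p1, p2)]))
  a1 <- .refine_peak(th, y01, bg, th[p1], refine_halfwidth)
  a2 <- .refine_peak(th, y01, bg, th[p2], refine_halfwidth)
  ## axis via doubled angles: opposite peaks reinforce
  z <- exp(2i * a1 * pi / 180) + exp(2i * a2 * pi / 180)
  axis <- Arg(z) * 180 / pi / 2
  if (axis <= -90) axis <- axis + 180
  if (axis > 90) axis <- axis - 180
  list(is_polarized = TRUE, polarity_angle = axis, peaks = c(a1, a2))
}

## intensity-weighted circular mean of angles within +/- halfwidth of
## `center`, weights clamped at background
.refine_peak <- function(th, y, bg, center, halfwidth) {
  d <- abs(((th - center + 180) %% 360) - 180)
  sel <- d <= halfwidth
  w <- pmax(y[sel] - bg, 0)
  if (sum(w) == 0) return(center)
  z <- sum(w * exp(1i * th[sel] * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

#' Fraction of planar-polarized cells
#'
#' @param cells List of [cortical_profile()] objects.
#' @param ... Passed to [classify_polarized_cell()].
#' @return Fraction of cells classified as polarized.
#' @export
percent_polarized <- function(cells, ...) {
  if (!length(cells)) stop("no cells supplied")
  mean(vapply(cells, function(p)
    classify_polarized_cell(p, ...)$is_polarized, logical(1L)))
}

#' Cell areas and field density from a label mask
#'
#' @param mask Integer label matrix (0 = background, one positive label
#'   per cell).
#' @param pixel_size Pixel edge length in micrometers.
#' @return List with `cells` (data.frame `label`, `n_pixels`,
#'   `area_um2`) and `density_cells_per_um2` (labels per field area).
#' @export
cell_shape_metrics <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  if (all(mask == 0)) stop("empty mask")
  labels <- sort(unique(mask[mask > 0]))
  npx <- tabulate(match(mask[mask > 0], labels), nbins = length(labels))
  field_area <- length(mask) * pixel_size^2
  list(cells = data.frame(label = labels, n_pixels = npx,
                          area_um2 = npx * pixel_size^2),
       density_cells_per_um2 = length(labels) / field_area)
}

#' Cell height along a direction from a sagittal label mask
#'
#' Height is the extent of each labelled cell along the apical-basal
#' direction: the range of pixel-center projections plus one pixel.
#'
#' @param mask Integer label matrix.
#' @param pixel_size Micrometers per pixel.
#' @param direction Length-2 vector (row, col components) of the
#'   apical-basal axis; default is along rows.
#' @return data.frame with `label` and `height_um`.
#' @export
basal_cell_height <- function(mask, pixel_size, direction = c(1, 0)) {
  stopifnot(is.matrix(mask), pixel_size > 0, length(direction) == 2L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction vector")
  direction <- direction / nrm
  if (all(mask == 0)) stop("empty mask")
  labels <- sort(unique(mask[mask > 0]))
  h <- vapply(labels, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    proj <- idx[, 1L] * direction[1L] + idx[, 2L] * direction[2L]
    (max(proj) - min(proj) + 1) * pixel_size
  }, 0)
  data.frame(label = labels, height_um = h)
}

## 8-connected component labelling by flood fill (masks are small;
## a vectorized union-find would buy nothing here)
.label_components <- function(bw) {
  stopifnot(is.matrix(bw))
  nr <- nrow(bw)
  nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(bw)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      nr_ <- r + offs$dr
      nc_ <- c + offs$dc
      ok <- nr_ >= 1L & nr_ <= nr & nc_ >= 1L & nc_ <= nc
      nb <- (nc_[ok] - 1L) * nr + nr_[ok]
      nb <- nb[bw[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      stack <- c(stack, nb)
    }
  }
  lab
}

#' Focal-adhesion morphometry from a binary mask
#'
#' Labels 8-connected foreground components, measures each object's
#' area and major-axis length, and retains objects with area at least
#' `min_area` (inclusive bound; the reference size filter is
#' 0.3 um^2 and up).
#'
#' @param mask Logical or 0/1 matrix of thresholded adhesion staining.
#' @param pixel_size Micrometers per pixel.
#' @param min_area Minimum object area in um^2 (default 0.3, inclusive).
#' @return data.frame with `label`, `n_pixels`, `area_um2`,
#'   `major_axis_um` (projection extent along the principal axis);
#'   possibly zero rows.
#' @export
focal_adhesion_metrics <- function(mask, pixel_size, min_area = 0.3) {
  stopifnot(pixel_size > 0, min_area >= 0)
  bw <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- .label_components(bw)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), major_axis_um = numeric(0)))
  rows <- lapply(seq_len(n), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    npx <- nrow(idx)
    major <- if (npx == 1L) 1 else {
      xy <- sweep(idx, 2L, colMeans(idx))
      v <- eigen(crossprod(xy) / npx, symmetric = TRUE)$vectors[, 1L]
      proj <- xy %*% v
      max(proj) - min(proj) + 1
    }
    data.frame(label = l, n_pixels = npx, area_um2 = npx * pixel_size^2,
               major_axis_um = major * pixel_size)
  })
  out <- do.call(rbind, rows)
  out <- out[out$area_um2 >= min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}
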