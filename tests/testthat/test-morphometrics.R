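test_that("orientation histograms bin (-180, 180] exactly and sum to 1", {
  h <- orientation_histogram(rep(0, 5), bin_width = 20)
  expect_equal(sum(h$freq), 1)
  expect_equal(h$freq[h$bin_lo == -20 & h$bin_hi == 0], 1)

  h2 <- orientation_histogram(c(-170, 170), bin_width = 20)
  occ <- h2[h2$count > 0, ]
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$bin_lo, c(-180, 160))   # adjacent across the wrap

  angles <- seq(-179.5, 179.5, by = 1)
  h3 <- orientation_histogram(angles, bin_width = 20)
  expect_true(all(h3$count == 20L))
  expect_gt(chisq.test(h3$count)$p.value, 0.99)
  # order invariance
  expect_identical(orientation_histogram(rev(angles), 20), h3)

  expect_error(orientation_histogram(numeric(0)), "empty")
  expect_error(orientation_histogram(c(0, 181)), "-180")
  expect_error(orientation_histogram(0, bin_width = 7), "divide")
})

test_that("angle-distribution comparison equals the ECDF-gap oracle", {
  a <- c(1, 2, 3)
  same <- compare_angle_distributions(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  disjoint <- compare_angle_distributions(c(-90, -80, -70), c(10, 20, 30))
  expect_equal(disjoint$statistic, 1)

  set.seed(9)
  x <- rnorm(40, 0, 15)   # tight A-P-aligned orientations
  y <- rnorm(60, 40, 30)  # broad, offset orientations
  res <- compare_angle_distributions(x, y)
  grid <- sort(c(x, y))
  gap <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(res$statistic, gap)
})

test_that("follicle growth classification has an inclusive boundary", {
  expect_equal(classify_follicle_growth(c(0, 0, 1), c(0, 0, 1)), "PERPENDICULAR")
  expect_equal(classify_follicle_growth(c(0, 0, -1), c(0, 0, 1)), "PERPENDICULAR")
  expect_equal(classify_follicle_growth(c(1, 0, 0), c(0, 0, 1)), "ANGLED")
  th <- 15 * pi / 180
  at_threshold <- c(sin(th), 0, cos(th))
  expect_equal(classify_follicle_growth(at_threshold, c(0, 0, 1)),
               "PERPENDICULAR")
  just_past <- c(sin(th + 0.01), 0, cos(th + 0.01))
  expect_equal(classify_follicle_growth(just_past, c(0, 0, 1)), "ANGLED")
  expect_error(classify_follicle_growth(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("profile binning is 20 bins, mean-preserving and idempotent", {
  pos <- seq(0, 1, length.out = 200)
  const <- bin_intensity_profile(pos, rep(3.5, 200))
  expect_equal(length(const), 20L)
  expect_true(all(const == 3.5))

  ramp <- seq(0, 1, length.out = 200)
  b <- bin_intensity_profile(pos, ramp)
  expect_equal(b, seq(0.025, 0.975, by = 0.05), tolerance = 0.01)
  # overall mean preserved exactly for equally spaced samples
  expect_equal(mean(b), mean(ramp))

  y20 <- rexp(20)
  expect_equal(bin_intensity_profile(seq_len(20), y20), y20)
  expect_error(bin_intensity_profile(1:10, 1:10), "bins")
})

test_that("opposing cortical domains are detected and localized", {
  ap <- sim_cortical_profile(c(0, 180), kappa = 10, noise_sd = 0)
  res <- classify_polarized_cell(ap)
  expect_true(res$is_polarized)
  expect_lt(abs(res$polarity_angle), 2)

  dv <- sim_cortical_profile(c(90, 270), kappa = 10, noise_sd = 0)
  res_dv <- classify_polarized_cell(dv)
  expect_true(res_dv$is_polarized)
  expect_lt(abs(res_dv$polarity_angle - 90), 2)

  single <- sim_cortical_profile(45, kappa = 10, noise_sd = 0)
  expect_false(classify_polarized_cell(single)$is_polarized)

  flat <- cortical_profile(0:359, rep(1, 360))
  res_flat <- classify_polarized_cell(flat)
  expect_false(res_flat$is_polarized)
  expect_true(is.na(res_flat$polarity_angle))

  # two domains well short of opposition are rejected
  bent <- sim_cortical_profile(c(0, 90), kappa = 10, noise_sd = 0)
  expect_false(classify_polarized_cell(bent)$is_polarized)
})

test_that("noisy bimodal profiles are recovered near the planted axis", {
  set.seed(33)
  ok <- 0L
  for (i in 1:100) {
    pr <- sim_cortical_profile(c(10, 190), kappa = 8, noise_sd = 0.05)
    res <- classify_polarized_cell(pr)
    if (res$is_polarized && abs(res$polarity_angle - 10) <= 5)
      ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("polarity angles are rotation-covariant", {
  base <- sim_cortical_profile(c(20, 200), kappa = 10, noise_sd = 0)
  a0 <- classify_polarized_cell(base)$polarity_angle
  for (phi in c(40, 90, 130)) {
    # intensity at angle theta of the rotated cell = base at theta - phi
    rot <- cortical_profile(base$theta,
                            base$intensity[((0:359 - phi) %% 360) + 1])
    a1 <- classify_polarized_cell(rot)$polarity_angle
    d <- abs(((a1 - a0 - phi + 90) %% 180) - 90)
    expect_lt(d, 2)
  }
})

test_that("percent polarized counts planted mixtures correctly", {
  pol <- replicate(6, sim_cortical_profile(c(30, 210), kappa = 9,
                                           noise_sd = 0), simplify = FALSE)
  unpol <- replicate(4, sim_cortical_profile(120, kappa = 9, noise_sd = 0),
                     simplify = FALSE)
  expect_equal(percent_polarized(pol), 1)
  expect_equal(percent_polarized(unpol), 0)
  expect_equal(percent_polarized(c(pol, unpol)), 0.6)
})

test_that("label-mask areas, density and height match counting oracles", {
  mask <- matrix(0L, 20, 20)
  mask[6:15, 6:15] <- 1L
  met <- cell_shape_metrics(mask, pixel_size = 0.5)
  expect_equal(met$cells$area_um2, 25)

  mask4 <- matrix(0L, 20, 20)
  mask4[1:3, 1:3] <- 1L
  mask4[1:3, 10:12] <- 2L
  mask4[10:12, 1:3] <- 3L
  mask4[10:12, 10:12] <- 4L
  met4 <- cell_shape_metrics(mask4, pixel_size = 0.5)
  expect_equal(met4$density_cells_per_um2, 4 / 100)

  vor <- sim_voronoi_mask(12, nrow = 50, ncol = 50, seed = 2)
  mv <- cell_shape_metrics(vor, pixel_size = 0.4)
  oracle <- as.integer(table(factor(vor[vor > 0], levels = mv$cells$label)))
  expect_equal(mv$cells$n_pixels, oracle)
  expect_equal(mv$cells$area_um2, oracle * 0.16)

  tall <- matrix(0L, 30, 10)
  tall[5:14, 3:5] <- 1L
  h <- basal_cell_height(tall, pixel_size = 0.5, direction = c(1, 0))
  expect_equal(h$height_um, 5)       # 10 px extent * 0.5 um
  expect_error(cell_shape_metrics(matrix(0L, 4, 4), 1), "empty")
})

test_that("focal-adhesion filtering is inclusive at the area bound", {
  # single pixel at 0.45 um/px: 0.2025 um^2 < 0.3 -> removed
  m1 <- matrix(FALSE, 10, 10)
  m1[5, 5] <- TRUE
  expect_equal(nrow(focal_adhesion_metrics(m1, pixel_size = 0.45)), 0L)
  # 30 pixels at 0.1 um/px: exactly 0.3 um^2 -> retained (inclusive)
  m2 <- matrix(FALSE, 12, 12)
  m2[4:6, 1:10] <- TRUE
  fa2 <- focal_adhesion_metrics(m2, pixel_size = 0.1)
  expect_equal(nrow(fa2), 1L)
  expect_equal(fa2$area_um2, 0.3)
})

test_that("adhesion objects are 8-connected and areas match pixel counts", {
  diag2 <- matrix(FALSE, 6, 6)
  diag2[2, 2] <- TRUE
  diag2[3, 3] <- TRUE                 # touching only diagonally
  fa <- focal_adhesion_metrics(diag2, pixel_size = 1, min_area = 0)
  expect_equal(nrow(fa), 1L)
  expect_equal(fa$n_pixels, 2L)

  set.seed(14)
  centers <- cbind(c(10, 10, 30, 45, 50), c(10, 45, 30, 12, 50))
  axes <- cbind(c(1, 4, 6, 2, 1), c(1, 2, 3, 2, 1))
  mask <- sim_adhesion_mask(centers, axes, angle_deg = c(0, 30, 60, 0, 45),
                            nrow = 60, ncol = 60)
  all_objs <- focal_adhesion_metrics(mask, pixel_size = 0.2, min_area = 0)
  expect_equal(nrow(all_objs), 5L)
  expect_equal(sum(all_objs$n_pixels), sum(mask))
  # the two ~single-pixel-scale objects fall below 0.3 um^2 at 0.2 um/px
  kept <- focal_adhesion_metrics(mask, pixel_size = 0.2, min_area = 0.3)
  expect_equal(nrow(kept), 3L)
  # filter count is monotone non-increasing in the minimum area
  sizes <- vapply(c(0, 0.1, 0.3, 1, 5),
                  function(a) nrow(focal_adhesion_metrics(mask, 0.2, a)), 0L)
  expect_true(all(diff(sizes) <= 0))
})
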