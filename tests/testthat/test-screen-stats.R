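test_that("normalization is exactly invariant to global depth scaling", {
  m <- toy_manifest(genes = c("A1", "B1"), n_per_gene = 3, n_scr = 2)
  set.seed(21)
  base <- matrix(rpois(8 * 3, 50), ncol = 3)
  ct <- toy_count_table(m, base[, 1], base[, 2:3])
  fc <- normalize_log2fc(ct, m)
  scaled <- ct$counts
  scaled[, 2] <- scaled[, 2] * 7L          # one sample at 7x depth
  ct2 <- count_table(scaled, ct$samples)
  expect_identical(fc$log2fc, normalize_log2fc(ct2, m)$log2fc)
  # scaling t0 is also exactly absorbed
  scaled0 <- ct$counts
  scaled0[, 1] <- scaled0[, 1] * 13L
  ct3 <- count_table(scaled0, ct$samples)
  expect_identical(fc$log2fc, normalize_log2fc(ct3, m)$log2fc)
})

test_that("scrambled controls have exactly zero median after normalization", {
  m <- synthesize_manifest(library_composition(), seed = 99)
  ct <- simulate_screen(sim_params(), m, seed = 31)
  fc <- normalize_log2fc(ct, m)
  for (f in c("EPI", "HF")) for (r in 1:3) {
    scr <- fc$log2fc[fc$reg_class == "SCR" & fc$fraction == f &
                       fc$replicate == r]
    # with an even number of controls the median averages the two middle
    # values, exact up to floating-point rounding
    expect_equal(median(scr), 0, tolerance = 1e-12)
  }
})

test_that("a doubled proportion gives log2FC 1 when controls are steady", {
  m <- toy_manifest(genes = c("A1", "B1"), n_per_gene = 1, n_scr = 2)
  # 4 hairpins: test, filler, scr, scr; test doubles its share, the
  # filler absorbs it, SCR proportions unchanged
  t0  <- c(250000L, 250000L, 250000L, 250000L)
  epi <- c(500000L, 0L, 250000L, 250000L)
  ct <- toy_count_table(m, t0, matrix(epi, ncol = 1))
  fc <- normalize_log2fc(ct, m)
  expect_equal(fc$log2fc[1], 1, tolerance = 1e-5)
  expect_equal(fc$log2fc[3], 0, tolerance = 1e-9)
})

test_that("log2 fold changes match a hand-worked spreadsheet computation", {
  m <- toy_manifest(genes = c("A1", "B1"), n_per_gene = 2, n_scr = 1)
  t0 <- c(100L, 200L, 300L, 250L, 150L)
  s1 <- c(400L, 100L, 350L, 50L, 100L)
  ct <- toy_count_table(m, t0, matrix(s1, ncol = 1))
  fc <- normalize_log2fc(ct, m, pseudocount = 0.5)
  # independent arithmetic, spelled out step by step
  cpm0 <- t0 / sum(t0) * 1e6 + 0.5
  cpm1 <- s1 / sum(s1) * 1e6 + 0.5
  raw <- log2(cpm1 / cpm0)
  manual <- raw - median(raw[5])           # hairpin 5 is the only SCR
  expect_equal(fc$log2fc, manual)
})

test_that("replicate correlations equal a direct rank-based oracle", {
  ids <- sprintf("h%02d", 1:20)
  set.seed(4)
  v1 <- rnorm(20)
  fc_self <- toy_fc_table(rep(ids, 2), "G1", "EPI",
                          rep(1:2, each = 20), rep(v1, 2))
  r2 <- replicate_correlation(fc_self)$EPI
  expect_equal(r2["rep1", "rep2"], 1)

  fc_anti <- toy_fc_table(rep(ids, 2), "G1", "EPI",
                          rep(1:2, each = 20), c(v1, -v1))
  expect_equal(replicate_correlation(fc_anti)$EPI["rep1", "rep2"], 1)

  v2 <- rnorm(20)
  fc_two <- toy_fc_table(rep(ids, 2), "G1", "EPI",
                         rep(1:2, each = 20), c(v1, v2))
  got <- replicate_correlation(fc_two)$EPI["rep1", "rep2"]
  # oracle: squared Pearson correlation of the rank vectors
  oracle <- cor(rank(v1), rank(v2))^2
  expect_equal(got, oracle)
})

test_that("one-sample tests handle degenerate replicate sets", {
  fc <- toy_fc_table(rep(c("h1", "h2"), each = 3), rep(c("G1", "G2"), each = 3),
                     "HF", rep(1:3, 2), c(0, 0, 0, 1, 1, 1))
  expect_warning(res <- shrna_test(fc, variant = "one_sample"),
                 "zero replicate variance")
  expect_equal(res$p_value[res$shrna_id == "h1"], 1)
  expect_equal(res$q_value[res$shrna_id == "h1"], 1)
  expect_equal(res$p_value[res$shrna_id == "h2"], .Machine$double.xmin)
})

test_that("one-sample t and BH agree with stats::t.test and a step-up oracle", {
  set.seed(12)
  n_hp <- 10L
  ids <- sprintf("h%02d", 1:n_hp)
  vals <- rnorm(3 * n_hp, mean = rep(runif(n_hp, -2, 2), each = 3))
  fc <- toy_fc_table(rep(ids, each = 3), rep(sprintf("G%d", 1:n_hp), each = 3),
                     "HF", rep(1:3, n_hp), vals)
  res <- shrna_test(fc, variant = "one_sample")
  res <- res[match(ids, res$shrna_id), ]
  for (i in seq_len(n_hp)) {
    tt <- t.test(vals[(3 * i - 2):(3 * i)])
    expect_equal(res$p_value[i], tt$p.value)
  }
  # Benjamini-Hochberg step-up, written out from the definition
  p <- res$p_value
  o <- order(p)
  q_sorted <- p[o] * n_hp / seq_len(n_hp)
  q_sorted <- rev(cummin(rev(q_sorted)))
  oracle <- numeric(n_hp)
  oracle[o] <- pmin(q_sorted, 1)
  expect_equal(res$q_value, oracle)
})

test_that("the scrambled-reference test matches stats::t.test pooling", {
  m <- toy_manifest(genes = c("A1", "B1"), n_per_gene = 2, n_scr = 4)
  set.seed(77)
  vals <- rnorm(nrow(m) * 3, mean = rep(c(2, 2, 0, 0, 0, 0, 0, 0), 3))
  fc <- toy_fc_table(rep(m$shrna_id, 3), rep(m$gene, 3), "HF",
                     rep(1:3, each = nrow(m)), vals,
                     reg_class = rep(m$reg_class, 3))
  res <- shrna_test(fc, variant = "vs_scr")
  scr_vals <- fc$log2fc[fc$reg_class == "SCR"]
  h1_vals <- fc$log2fc[fc$shrna_id == "hp01"]
  tt <- t.test(h1_vals, scr_vals, var.equal = TRUE)
  expect_equal(res$p_value[res$shrna_id == "hp01"], tt$p.value)
  # a scrambled hairpin is compared against the other controls only
  s1_vals <- fc$log2fc[fc$shrna_id == "hp05"]
  ref <- fc$log2fc[fc$reg_class == "SCR" & fc$shrna_id != "hp05"]
  tt_scr <- t.test(s1_vals, ref, var.equal = TRUE)
  expect_equal(res$p_value[res$shrna_id == "hp05"], tt_scr$p.value)
})

test_that("gene calls follow the two-hairpin, no-opposition rule", {
  # >=2 significant >=2-fold hairpins, same direction -> ENRICHED
  t1 <- toy_tests("G1", c(1.5, 2.1, 0.2), sig = c(TRUE, TRUE, FALSE))
  c1 <- call_gene_hits(t1)
  expect_equal(c1$direction, "ENRICHED")
  expect_equal(c1$n_supporting, 2L)
  # opposing >=2-fold trends cancel the call
  t2 <- toy_tests("G1", c(2, -2), sig = c(TRUE, TRUE))
  expect_equal(call_gene_hits(t2)$direction, "NONE")
  # one supporting hairpin is not enough
  t3 <- toy_tests("G1", c(3, 0.1, -0.1), sig = c(TRUE, FALSE, FALSE))
  expect_equal(call_gene_hits(t3)$direction, "NONE")
  # significance is required even above threshold
  t4 <- toy_tests("G1", c(2.5, 2.5), sig = c(TRUE, FALSE))
  expect_equal(call_gene_hits(t4)$direction, "NONE")
  # an opposing hairpin below the fold threshold does not block
  t5 <- toy_tests("G1", c(1.2, 1.4, -0.9), sig = c(TRUE, TRUE, TRUE))
  expect_equal(call_gene_hits(t5)$direction, "ENRICHED")
  # depletion side mirrors enrichment
  t6 <- toy_tests("G1", c(-1.1, -2.3, 0.3), sig = c(TRUE, TRUE, FALSE))
  expect_equal(call_gene_hits(t6)$direction, "DEPLETED")
})

test_that("fraction classification assigns Venn classes and HF specificity", {
  tests <- rbind(toy_tests("G1", c(-2, -2.2), sig = TRUE, fraction = "HF"),
                 toy_tests("G1", c(0.1, -0.1), sig = FALSE, fraction = "EPI"))
  calls <- call_gene_hits(tests)
  cls <- classify_candidates(calls, tests)
  expect_equal(cls$venn_class, "HF_ONLY")
  expect_true(cls$hf_specific)
  expect_equal(cls$hf_direction, "DEPLETED")

  tests2 <- rbind(toy_tests("G1", c(2, 2.2), sig = TRUE, fraction = "HF"),
                  toy_tests("G1", c(2.4, 2.1), sig = TRUE, fraction = "EPI"))
  cls2 <- classify_candidates(call_gene_hits(tests2), tests2)
  expect_equal(cls2$venn_class, "BOTH")
  expect_false(cls2$hf_specific)
})

test_that("coverage arithmetic reproduces the printed design quantities", {
  expect_equal(hf_founders_per_embryo(120000, 0.10), 12000)
  expect_equal(hf_founders_per_embryo(12345, 0), 0)
  expect_equal(hf_founders_per_embryo(100, 0.5), 50)

  d <- coverage_design(library_size = 1000, target_coverage = 100,
                       progenitors_per_embryo = 120000,
                       hf_founder_fraction = 0.10, transduction_rate = 0.15)
  expect_equal(d$transduced_hf_founders_per_embryo, 1800)
  expect_equal(d$min_embryos, 56L)
  expect_lte(d$min_embryos, 60L)

  expect_equal(min_embryos_for_coverage(
    coverage_design(1000, 0, 120000, 0.10, 0.15)), 0L)
  expect_equal(min_embryos_for_coverage(
    coverage_design(1, 1, 1, 1, 1)), 1L)
  expect_error(min_embryos_for_coverage(
    coverage_design(1000, 100, 120000, 0, 0.15)), "zero")
})

test_that("minimum embryo counts are monotone in the design inputs", {
  base <- function(ls = 1000, cov = 100, founders_scale = 1)
    coverage_design(ls, cov, 120000 * founders_scale, 0.10, 0.15)$min_embryos
  for (i in 1:20) {
    set.seed(i)
    ls <- sample(100:5000, 2)
    expect_lte(base(ls = min(ls)), base(ls = max(ls)))
    cv <- sort(runif(2, 1, 500))
    expect_lte(base(cov = cv[1]), base(cov = cv[2]))
    fs <- sort(runif(2, 0.2, 5))
    expect_gte(base(founders_scale = fs[1]), base(founders_scale = fs[2]))
  }
})

test_that("competition ratios normalize to the starting mix", {
  expect_equal(competition_ratio(c(100, 100), c(100, 100)), 1)
  expect_equal(competition_ratio(c(100, 100), c(100, 50)), 0.5)
  expect_equal(competition_ratio(c(100, 200), c(50, 100)), 1)
  expect_warning(r <- competition_ratio(c(0, 100), c(10, 10)), "undefined")
  expect_true(is.na(r))
})

test_that("the normality dispatch takes the documented branches", {
  x <- c(1, 2, 3, 4, 5, 6)
  same <- normality_dispatch(x, x, design = "UNPAIRED")
  expect_equal(same$p_value, 1)

  set.seed(6)
  norm1 <- rnorm(30)
  norm2 <- rnorm(30, 0.2)
  res_t <- normality_dispatch(norm1, norm2, design = "UNPAIRED")
  expect_equal(res_t$branch, "t-test")
  # branch choice verified against directly computed Shapiro-Wilk p values
  expect_true(all(c(shapiro.test(norm1)$p.value,
                    shapiro.test(norm2)$p.value) > 0.05))

  expo <- rexp(40)
  expect_lt(shapiro.test(expo)$p.value, 0.05)
  res_mw <- normality_dispatch(expo, norm1, design = "UNPAIRED")
  expect_equal(res_mw$branch, "mann-whitney")

  a <- rnorm(25, 0, 20)
  b <- rnorm(35, 30, 25)
  res_ks <- normality_dispatch(a, b, design = "DISTRIBUTIONS")
  expect_equal(res_ks$branch, "ks")
  # oracle: maximum gap between empirical CDFs over all sample points
  grid <- sort(c(a, b))
  gap <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(res_ks$statistic, gap)

  expect_error(normality_dispatch(c(1, 2), c(1, 2, 3)), "n >= 3")
})
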