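#' Scrambled-normalized log2 fold changes versus t0
#'
#' Converts each sample to counts-per-million (so sequencing depth
#' cancels exactly), adds a prior `pseudocount` so that E18.5 dropouts
#' stay finite, takes the log2 ratio of each hairpin's abundance to its
#' t0 in vitro abundance, and centers each sample on its scrambled
#' controls by subtracting the median raw log2 fold change over the SCR
#' hairpins.  After normalization the median SCR log2FC is exactly 0 in
#' every sample, and a global multiplicative factor on any sample's
#' counts leaves all values unchanged (exactly: CPM is depth-invariant).
#'
#' @param ct A [count_table()] containing exactly one T0_INVITRO sample
#'   and at least one EPI or HF replicate.
#' @param manifest The `shrna_manifest` (provides gene and SCR labels).
#' @param pseudocount Prior added to each CPM value (default 0.5).
#' @return A data.frame of class `fc_table` with columns `shrna_id`,
#'   `gene`, `reg_class`, `fraction`, `replicate`, `log2fc`.
#' @export
normalize_log2fc <- function(ct, manifest, pseudocount = 0.5) {
  stopifnot(inherits(ct, "count_table"),
            inherits(manifest, "shrna_manifest"), pseudocount > 0)
  t0_col <- which(ct$samples$fraction == "T0_INVITRO")
  if (length(t0_col) != 1L)
    stop("count table must contain exactly one T0_INVITRO sample")
  idx <- match(rownames(ct$counts), manifest$shrna_id)
  if (anyNA(idx)) stop("count table rows missing from manifest")
  gene <- manifest$gene[idx]
  reg_class <- manifest$reg_class[idx]
  is_scr <- reg_class == "SCR"
  if (!any(is_scr)) stop("no scrambled (SCR) hairpins present")
  cpm <- function(x) {
    if (sum(x) == 0) stop("sample with zero total counts")
    x / sum(x) * 1e6 + pseudocount
  }
  p0 <- cpm(ct$counts[, t0_col])
  out <- list()
  for (s in which(ct$samples$fraction %in% c("EPI", "HF"))) {
    raw <- log2(cpm(ct$counts[, s]) / p0)
    norm <- raw - stats::median(raw[is_scr])
    out[[length(out) + 1L]] <- data.frame(
      shrna_id = rownames(ct$counts), gene = gene, reg_class = reg_class,
      fraction = ct$samples$fraction[s],
      replicate = ct$samples$replicate[s],
      log2fc = norm, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no EPI or HF samples present")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fc_table", "data.frame")
  res
}

#' Pairwise Spearman rank correlation between replicates
#'
#' @param fc An `fc_table` from [normalize_log2fc()].
#' @return Named list per fraction of symmetric matrices of squared
#'   Spearman correlations (R^2) between replicates.  A replicate with
#'   constant values yields `NA` entries with a warning.
#' @export
replicate_correlation <- function(fc) {
  stopifnot(inherits(fc, "fc_table"))
  out <- list()
  for (f in unique(fc$fraction)) {
    sub <- fc[fc$fraction == f, ]
    reps <- sort(unique(sub$replicate))
    if (length(reps) < 2L) stop("need >= 2 replicates in fraction ", f)
    mat <- sapply(reps, function(r)
      sub$log2fc[sub$replicate == r][order(sub$shrna_id[sub$replicate == r])])
    if (any(apply(mat, 2L, stats::sd) == 0))
      warning("constant replicate vector in fraction ", f,
              "; correlation undefined")
    r2 <- suppressWarnings(stats::cor(mat, method = "spearman"))^2
    dimnames(r2) <- list(paste0("rep", reps), paste0("rep", reps))
    out[[f]] <- r2
  }
  out
}

#' Per-hairpin replicate t tests with BH adjustment
#'
#' For every (hairpin, fraction), a two-tailed t test of the hairpin's
#' replicate normalized log2 fold changes; p values are adjusted by the
#' Benjamini-Hochberg step-up procedure across all hairpins within each
#' fraction.
#'
#' Two test structures are available.  The default, `"vs_scr"`, is a
#' two-sample pooled-variance t test of the hairpin's replicate values
#' against the pooled replicate values of all scrambled controls in the
#' same fraction (a scrambled hairpin is compared against the other
#' scrambled controls).  Pooling the 20 controls across replicates gives
#' the null distribution enough degrees of freedom for the
#' Benjamini-Hochberg step at 10% to be attainable with triplicate
#' screens; a one-sample test against 0 (`"one_sample"`) is capped at
#' n_replicates - 1 degrees of freedom and cannot reach the BH
#' thresholds however strong the effect.  Degenerate cases: zero pooled
#' variance gives p = 1 when the mean difference is 0 and the smallest
#' representable p (with a warning) otherwise.
#'
#' @param fc An `fc_table` with >= 2 replicates per fraction.
#' @param variant `"vs_scr"` (default) or `"one_sample"`, see Details.
#' @return A data.frame of class `shrna_tests` with columns `shrna_id`,
#'   `gene`, `fraction`, `mean_log2fc`, `p_value`, `q_value`, `n_reps`.
#' @export
shrna_test <- function(fc, variant = c("vs_scr", "one_sample")) {
  stopifnot(inherits(fc, "fc_table"))
  variant <- match.arg(variant)
  if (variant == "vs_scr" && !any(fc$reg_class == "SCR"))
    stop("variant \"vs_scr\" needs scrambled controls in the table")
  out <- list()
  for (f in unique(fc$fraction)) {
    sub <- fc[fc$fraction == f, ]
    sp <- split(sub$log2fc, sub$shrna_id)
    n <- lengths(sp)
    if (any(n < 2L)) stop("need >= 2 replicates per hairpin in ", f)
    m <- vapply(sp, mean, 0)
    s <- vapply(sp, stats::sd, 0)
    if (variant == "one_sample") {
      tt <- m / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tt), df = n - 1L)
      degen <- s == 0
    } else {
      scr_ids <- unique(sub$shrna_id[sub$reg_class == "SCR"])
      scr_all <- sub$log2fc[sub$reg_class == "SCR"]
      p <- numeric(length(sp))
      degen <- logical(length(sp))
      for (i in seq_along(sp)) {
        ref <- if (names(sp)[i] %in% scr_ids)
          sub$log2fc[sub$reg_class == "SCR" &
                       sub$shrna_id != names(sp)[i]]
        else scr_all
        n0 <- length(ref)
        sp2 <- ((n[i] - 1L) * s[i]^2 + (n0 - 1L) * stats::var(ref)) /
          (n[i] + n0 - 2L)
        if (sp2 == 0) {
          degen[i] <- TRUE
          p[i] <- if (m[i] - mean(ref) == 0) 1 else NA_real_
          next
        }
        tt <- (m[i] - mean(ref)) / sqrt(sp2 * (1 / n[i] + 1 / n0))
        p[i] <- 2 * stats::pt(-abs(tt), df = n[i] + n0 - 2L)
      }
    }
    if (variant == "one_sample") {
      if (any(degen & m != 0)) {
        warning("zero replicate variance with nonzero mean; ",
                "p set to smallest representable value")
        p[degen & m != 0] <- .Machine$double.xmin
      }
      p[degen & m == 0] <- 1
    } else if (anyNA(p)) {
      warning("zero pooled variance with nonzero mean difference; ",
              "p set to smallest representable value")
      p[is.na(p)] <- .Machine$double.xmin
    }
    q <- stats::p.adjust(p, method = "BH")
    gene <- sub$gene[match(names(sp), sub$shrna_id)]
    out[[f]] <- data.frame(shrna_id = names(sp), gene = gene, fraction = f,
                           mean_log2fc = unname(m), p_value = unname(p),
                           q_value = unname(q), n_reps = unname(n),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("shrna_tests", "data.frame")
  res
}

#' Gene-level hit calling
#'
#' A gene is called in a fraction if (a) at least `min_shrnas` of its
#' hairpins show a fold change of at least `fold_threshold` (i.e.
#' |mean log2FC| >= log2(threshold)) in the same direction, (b) each
#' supporting hairpin is statistically significant (raw p < `alpha` and
#' BH q < `fdr`), and (c) none of the gene's other hairpins crosses the
#' fold threshold in the opposite direction.  Scrambled controls are
#' never called.
#'
#' @param tests An `shrna_tests` table from [shrna_test()].
#' @param fold_threshold Fold-change threshold (default 2).
#' @param min_shrnas Minimum supporting hairpins (default 2).
#' @param alpha Raw p-value threshold (default 0.05).
#' @param fdr BH q-value threshold (default 0.10).
#' @return A data.frame of class `gene_calls` with columns `gene`,
#'   `fraction`, `direction` (ENRICHED / DEPLETED / NONE),
#'   `n_supporting` and `supporting` (comma-separated hairpin ids).
#' @export
call_gene_hits <- function(tests, fold_threshold = 2, min_shrnas = 2,
                           alpha = 0.05, fdr = 0.10) {
  stopifnot(inherits(tests, "shrna_tests"), fold_threshold > 1)
  lfc <- log2(fold_threshold)
  out <- list()
  for (f in unique(tests$fraction)) {
    sub <- tests[tests$fraction == f & tests$gene != "SCR", ]
    for (g in unique(sub$gene)) {
      gs <- sub[sub$gene == g, ]
      sig <- gs$p_value < alpha & gs$q_value < fdr
      up_sup <- gs$mean_log2fc >= lfc & sig
      dn_sup <- gs$mean_log2fc <= -lfc & sig
      any_up <- any(gs$mean_log2fc >= lfc)
      any_dn <- any(gs$mean_log2fc <= -lfc)
      direction <- "NONE"
      supporting <- character(0)
      if (sum(up_sup) >= min_shrnas && !any_dn) {
        direction <- "ENRICHED"
        supporting <- gs$shrna_id[up_sup]
      } else if (sum(dn_sup) >= min_shrnas && !any_up) {
        direction <- "DEPLETED"
        supporting <- gs$shrna_id[dn_sup]
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, fraction = f, direction = direction,
        n_supporting = length(supporting),
        supporting = paste(supporting, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("gene_calls", "data.frame")
  res
}

#' Classify candidates across fractions
#'
#' Assigns each gene a Venn class — called in the epidermal fraction
#' only, the HF fraction only, both, or neither — and flags HF-specific
#' candidates: genes called in the HF fraction whose transduced cells
#' were not strongly selected in the epidermis (gene-level mean
#' |log2FC| in EPI below `epi_neutrality_threshold`).
#'
#' @param calls A `gene_calls` table covering the EPI and HF fractions.
#' @param tests The `shrna_tests` table the calls came from (provides
#'   per-hairpin mean log2FCs for the epidermal neutrality screen).
#' @param epi_neutrality_threshold Gene mean |log2FC| in EPI below which
#'   the gene counts as epidermally neutral (default 1, i.e. < 2-fold).
#' @return A data.frame of class `gene_classes` with columns `gene`,
#'   `epi_direction`, `hf_direction`, `venn_class` (EPI_ONLY / HF_ONLY /
#'   BOTH / NONE), `epi_mean_abs_log2fc`, `hf_specific`.
#' @export
classify_candidates <- function(calls, tests, epi_neutrality_threshold = 1) {
  stopifnot(inherits(calls, "gene_calls"), inherits(tests, "shrna_tests"))
  genes <- unique(calls$gene)
  get_dir <- function(g, f) {
    d <- calls$direction[calls$gene == g & calls$fraction == f]
    if (length(d)) d[[1L]] else "NONE"
  }
  epi_abs <- vapply(genes, function(g) {
    v <- tests$mean_log2fc[tests$gene == g & tests$fraction == "EPI"]
    if (length(v)) mean(abs(v)) else NA_real_
  }, 0)
  epi_dir <- vapply(genes, get_dir, "", f = "EPI")
  hf_dir <- vapply(genes, get_dir, "", f = "HF")
  venn <- ifelse(epi_dir != "NONE" & hf_dir != "NONE", "BOTH",
          ifelse(epi_dir != "NONE", "EPI_ONLY",
          ifelse(hf_dir != "NONE", "HF_ONLY", "NONE")))
  res <- data.frame(
    gene = genes, epi_direction = epi_dir, hf_direction = hf_dir,
    venn_class = venn, epi_mean_abs_log2fc = epi_abs,
    hf_specific = hf_dir != "NONE" &
      !is.na(epi_abs) & epi_abs < epi_neutrality_threshold,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gene_classes", "data.frame")
  res
}

#' Transduced HF founders per embryo
#'
#' With ~120,000 E9.5 progenitors and ~10% of them fated to contribute
#' to hair follicles, ~12,000 future HF progenitors are present at the
#' time of injection.
#'
#' @param progenitors Progenitors per embryo.
#' @param hf_fraction Fraction contributing to HFs.
#' @return `round(progenitors * hf_fraction)`.
#' @examples
#' hf_founders_per_embryo(120000, 0.10)  # 12000
#' @export
hf_founders_per_embryo <- function(progenitors, hf_fraction) {
  stopifnot(progenitors > 0, hf_fraction >= 0, hf_fraction <= 1)
  round(progenitors * hf_fraction)
}

#' Screen coverage design
#'
#' Collects the quantities that determine how many embryos per replicate
#' are needed so that each library hairpin is carried by at least
#' `target_coverage` transduced HF founder cells.
#'
#' @param library_size Number of hairpins in the library.
#' @param target_coverage Desired founders per hairpin (fold coverage).
#' @param progenitors_per_embryo Progenitors per embryo.
#' @param hf_founder_fraction Fraction of transduced founders fated to HF.
#' @param transduction_rate Fraction of progenitors transduced.
#' @return An object of class `coverage_design` with derived fields
#'   `transduced_hf_founders_per_embryo` and `min_embryos`.
#' @export
coverage_design <- function(library_size, target_coverage,
                            progenitors_per_embryo, hf_founder_fraction,
                            transduction_rate) {
  stopifnot(library_size > 0, target_coverage >= 0,
            progenitors_per_embryo > 0,
            hf_founder_fraction >= 0, hf_founder_fraction <= 1,
            transduction_rate >= 0, transduction_rate <= 1)
  d <- list(library_size = library_size, target_coverage = target_coverage,
            progenitors_per_embryo = progenitors_per_embryo,
            hf_founder_fraction = hf_founder_fraction,
            transduction_rate = transduction_rate)
  d$transduced_hf_founders_per_embryo <-
    round(progenitors_per_embryo * hf_founder_fraction * transduction_rate)
  class(d) <- "coverage_design"
  d$min_embryos <- min_embryos_for_coverage(d)
  d
}

#' Minimum embryos per replicate for a coverage target
#'
#' `ceiling(library_size * target_coverage / (progenitors *
#' hf_fraction * transduction_rate))`.  For the reference design (1000
#' hairpins, 100-fold coverage, 120,000 progenitors, 10% HF fate, 15%
#' transduction) this is ceiling(100,000 / 1,800) = 56 embryos.
#'
#' @param design A [coverage_design()].
#' @return Integer number of embryos.
#' @export
min_embryos_for_coverage <- function(design) {
  stopifnot(inherits(design, "coverage_design"))
  founders <- design$progenitors_per_embryo * design$hf_founder_fraction *
    design$transduction_rate
  if (founders <= 0) stop("zero transduced HF founders per embryo")
  if (design$target_coverage == 0) return(0L)
  as.integer(ceiling(design$library_size * design$target_coverage / founders))
}

#' @export
print.coverage_design <- function(x, ...) {
  cat(sprintf(
    "coverage design: %d shRNAs at %gx coverage\n  %g transduced HF founders/embryo -> >= %d embryos per replicate\n",
    x$library_size, x$target_coverage,
    x$transduced_hf_founders_per_embryo, x$min_embryos))
  invisible(x)
}

#' Two-color competition ratio
#'
#' Normalized end-point ratio of the test (RFP) to control (GFP)
#' populations relative to the starting mix:
#' `(final RFP/GFP) / (initial RFP/GFP)`.  1 means neutral.
#'
#' @param initial,final Length-2 numeric vectors `c(gfp, rfp)` of cell
#'   counts at the start and end of the assay.
#' @return The normalized ratio; `NA` with a warning if a denominator is
#'   zero.
#' @export
competition_ratio <- function(initial, final) {
  stopifnot(length(initial) == 2L, length(final) == 2L,
            all(initial >= 0), all(final >= 0))
  if (initial[1L] == 0 || final[1L] == 0 || initial[2L] == 0) {
    warning("competition ratio undefined (zero denominator)")
    return(NA_real_)
  }
  (final[2L] / final[1L]) / (initial[2L] / initial[1L])
}

#' Normality-dispatched two-group comparison
#'
#' The decision tree used for all pairwise quantifications: normality of
#' each group is assessed by the Shapiro-Wilk test at 0.05; if both
#' groups pass, a parametric two-tailed t test (paired or unpaired per
#' `design`) is used, otherwise the non-parametric two-tailed
#' Mann-Whitney test.  For comparisons of whole distributions
#' (`design = "DISTRIBUTIONS"`), the two-sample Kolmogorov-Smirnov test
#' is applied directly.
#'
#' @param x,y Numeric samples (each n >= 3 so normality is testable).
#' @param design One of `"UNPAIRED"`, `"PAIRED"`, `"DISTRIBUTIONS"`.
#' @param shapiro_alpha Normality threshold (default 0.05).
#' @return List with `branch` (`"t-test"`, `"mann-whitney"` or `"ks"`),
#'   `method`, `statistic`, `p_value` and `shapiro_p` (length-2, `NA`
#'   for the KS branch).
#' @export
normality_dispatch <- function(x, y,
                               design = c("UNPAIRED", "PAIRED",
                                          "DISTRIBUTIONS"),
                               shapiro_alpha = 0.05) {
  design <- match.arg(design)
  if (length(x) < 3L || length(y) < 3L)
    stop("need n >= 3 per group to test normality")
  if (design == "DISTRIBUTIONS") {
    ks <- suppressWarnings(stats::ks.test(x, y))
    return(list(branch = "ks", method = ks$method,
                statistic = unname(ks$statistic),
                p_value = ks$p.value, shapiro_p = c(NA_real_, NA_real_)))
  }
  sw <- c(stats::shapiro.test(x)$p.value, stats::shapiro.test(y)$p.value)
  if (all(sw > shapiro_alpha)) {
    tt <- stats::t.test(x, y, paired = design == "PAIRED",
                        alternative = "two.sided")
    list(branch = "t-test", method = tt$method,
         statistic = unname(tt$statistic), p_value = tt$p.value,
         shapiro_p = sw)
  } else {
    mw <- suppressWarnings(
      stats::wilcox.test(x, y, paired = design == "PAIRED",
                         alternative = "two.sided",
                         exact = length(x) <= 8 && length(y) <= 8))
    list(branch = "mann-whitney", method = mw$method,
         statistic = unname(mw$statistic), p_value = mw$p.value,
         shapiro_p = sw)
  }
}
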