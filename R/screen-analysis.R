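#' Fit the full screen hit-calling analysis
#'
#' One call from a count table to gene-level candidates: drops hairpins
#' with zero reads in every sample, computes scrambled-normalized log2
#' fold changes versus t0 ([normalize_log2fc()]), runs per-hairpin
#' replicate t tests with Benjamini-Hochberg adjustment
#' ([shrna_test()]), calls gene-level hits per fraction
#' ([call_gene_hits()]) and classifies candidates across fractions
#' ([classify_candidates()]).
#'
#' @param ct A [count_table()] with one T0_INVITRO sample and replicated
#'   EPI / HF samples.
#' @param manifest The `shrna_manifest`.
#' @param pseudocount Prior count on the CPM scale (default 0.5).
#' @param fold_threshold,min_shrnas,alpha,fdr Hit-calling thresholds,
#'   see [call_gene_hits()].
#' @param epi_neutrality_threshold See [classify_candidates()].
#' @param test_variant Test structure passed to [shrna_test()].
#' @return An object of class `screen_analysis` with components `fc`,
#'   `tests`, `calls`, `genes`, `correlations`, `removed_shrnas` and
#'   `params`.
#' @examples
#' m <- synthesize_manifest(library_composition(), seed = 1)
#' eff <- effect_spec("Gef01", epi_effect = 1, hf_effect = 0.25)
#' ct <- simulate_screen(sim_params(), m, eff, seed = 1)
#' fit <- screen_analysis(ct, m)
#' fit
#' subset(coef(fit), gene == "Gef01")
#' @export
screen_analysis <- function(ct, manifest, pseudocount = 0.5,
                            fold_threshold = 2, min_shrnas = 2,
                            alpha = 0.05, fdr = 0.10,
                            epi_neutrality_threshold = 1,
                            test_variant = c("vs_scr", "one_sample")) {
  test_variant <- match.arg(test_variant)
  ct <- suppressMessages(filter_zero(ct))
  fc <- normalize_log2fc(ct, manifest, pseudocount = pseudocount)
  tests <- shrna_test(fc, variant = test_variant)
  calls <- call_gene_hits(tests, fold_threshold = fold_threshold,
                          min_shrnas = min_shrnas, alpha = alpha, fdr = fdr)
  genes <- classify_candidates(calls, tests,
                               epi_neutrality_threshold =
                                 epi_neutrality_threshold)
  structure(list(
    fc = fc, tests = tests, calls = calls, genes = genes,
    correlations = replicate_correlation(fc),
    removed_shrnas = attr(ct, "removed_shrnas"),
    params = list(pseudocount = pseudocount,
                  fold_threshold = fold_threshold,
                  min_shrnas = min_shrnas, alpha = alpha, fdr = fdr,
                  epi_neutrality_threshold = epi_neutrality_threshold)),
    class = "screen_analysis")
}

#' @export
print.screen_analysis <- function(x, ...) {
  hits <- x$genes[x$genes$venn_class != "NONE", ]
  cat(sprintf(
    "screen analysis: %d hairpins tested, %d genes\n",
    length(unique(x$tests$shrna_id)), nrow(x$genes)))
  cat(sprintf(
    "  candidates: %d total (EPI-only %d, HF-only %d, both %d); %d HF-specific\n",
    nrow(hits), sum(hits$venn_class == "EPI_ONLY"),
    sum(hits$venn_class == "HF_ONLY"), sum(hits$venn_class == "BOTH"),
    sum(x$genes$hf_specific)))
  invisible(x)
}

#' @export
summary.screen_analysis <- function(object, ...) {
  x <- object
  cat("Screen hit-calling analysis\n")
  cat(sprintf(
    "  thresholds: %g-fold, >=%d shRNAs, p < %g, BH q < %g\n",
    x$params$fold_threshold, x$params$min_shrnas, x$params$alpha,
    x$params$fdr))
  if (length(x$removed_shrnas))
    cat(sprintf("  %d hairpin(s) discarded by the zero-read filter\n",
                length(x$removed_shrnas)))
  for (f in names(x$correlations)) {
    r2 <- x$correlations[[f]]
    off <- r2[upper.tri(r2)]
    cat(sprintf("  %s replicate Spearman R^2: %s\n", f,
                paste(sprintf("%.4f", off), collapse = ", ")))
  }
  print.screen_analysis(x)
  hits <- x$genes[x$genes$venn_class != "NONE", ]
  if (nrow(hits)) {
    cat("\nCandidates:\n")
    print(hits, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn screen_analysis Per-hairpin mean normalized log2 fold
#'   changes, one column per fraction.
#' @param object,... S3 method arguments.
#' @export
coef.screen_analysis <- function(object, ...) {
  tests <- object$tests
  fracs <- unique(tests$fraction)
  ids <- sort(unique(tests$shrna_id))
  out <- data.frame(shrna_id = ids,
                    gene = tests$gene[match(ids, tests$shrna_id)],
                    stringsAsFactors = FALSE)
  for (f in fracs) {
    sub <- tests[tests$fraction == f, ]
    out[[paste0("log2fc_", f)]] <- sub$mean_log2fc[match(ids, sub$shrna_id)]
  }
  out
}

#' @export
plot.screen_analysis <- function(x, ...) {
  co <- coef(x)
  if (!all(c("log2fc_EPI", "log2fc_HF") %in% names(co)))
    stop("both EPI and HF fractions are needed for the default plot")
  hit_genes <- x$genes$gene[x$genes$venn_class != "NONE"]
  col <- ifelse(co$gene %in% hit_genes, "firebrick",
                ifelse(co$gene == "SCR", "dodgerblue", "grey50"))
  graphics::plot(co$log2fc_EPI, co$log2fc_HF, col = col, pch = 16,
                 cex = 0.6, xlab = "epidermal log2 fold change",
                 ylab = "hair-follicle log2 fold change", ...)
  graphics::abline(h = c(-1, 0, 1), v = c(-1, 0, 1), lty = 3,
                   col = "grey70")
  invisible(x)
}
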