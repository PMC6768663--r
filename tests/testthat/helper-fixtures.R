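# Shared fixtures, built in code at test time.

# tiny manifest with n_per_gene hairpins for each named gene + SCR controls
toy_manifest <- function(genes = c("Rhou", "Trio"), n_per_gene = 2L,
                         n_scr = 1L, hairpin_length = 21L, seed = 42L) {
  set.seed(seed)
  n <- length(genes) * n_per_gene + n_scr
  seqs <- character(0)
  while (length(unique(seqs)) < n)
    seqs <- unique(c(seqs, paste(
      sample(c("A", "C", "G", "T"), hairpin_length, replace = TRUE),
      collapse = "")))
  df <- data.frame(
    shrna_id = sprintf("hp%02d", seq_len(n)),
    gene = c(rep(genes, each = n_per_gene), rep("SCR", n_scr)),
    reg_class = c(rep("GTPASE", length(genes) * n_per_gene),
                  rep("SCR", n_scr)),
    hairpin_seq = seqs[seq_len(n)],
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_manifest(path, hairpin_length = hairpin_length)
}

# count table with one T0 plus per-fraction replicates from a base vector
toy_count_table <- function(manifest, t0, epi, hf = NULL) {
  counts <- cbind(T0 = t0)
  meta <- data.frame(label = "T0", fraction = "T0_INVITRO",
                     replicate = NA_integer_)
  add <- function(counts, meta, mat, fraction) {
    for (r in seq_len(ncol(mat))) {
      lab <- sprintf("%s_%d", fraction, r)
      counts <- cbind(counts, mat[, r])
      colnames(counts)[ncol(counts)] <- lab
      meta <- rbind(meta, data.frame(label = lab, fraction = fraction,
                                     replicate = r))
    }
    list(counts, meta)
  }
  res <- add(counts, meta, as.matrix(epi), "EPI")
  if (!is.null(hf)) res <- add(res[[1]], res[[2]], as.matrix(hf), "HF")
  rownames(res[[1]]) <- manifest$shrna_id
  count_table(res[[1]], res[[2]])
}

# hand-built fold-change table (bypasses normalization)
toy_fc_table <- function(shrna_id, gene, fraction, replicate, log2fc,
                         reg_class = ifelse(gene == "SCR", "SCR", "GTPASE")) {
  structure(data.frame(shrna_id = shrna_id, gene = gene,
                       reg_class = reg_class, fraction = fraction,
                       replicate = replicate, log2fc = log2fc,
                       stringsAsFactors = FALSE),
            class = c("fc_table", "data.frame"))
}

# hand-built per-hairpin test table for exercising the gene-call rules
toy_tests <- function(gene, mean_log2fc, sig, fraction = "HF") {
  n <- length(mean_log2fc)
  structure(data.frame(
    shrna_id = sprintf("hp%02d", seq_len(n)), gene = gene,
    fraction = fraction, mean_log2fc = mean_log2fc,
    p_value = ifelse(sig, 1e-4, 0.5), q_value = ifelse(sig, 1e-3, 0.6),
    n_reps = 3L, stringsAsFactors = FALSE),
    class = c("shrna_tests", "data.frame"))
}

# quick default simulation used by several suites (small but full-size lib)
default_sim_fit <- function(effects = NULL, seed = 1L, ...) {
  m <- synthesize_manifest(library_composition(), seed = 99L)
  ct <- simulate_screen(sim_params(), m, effects, seed = seed)
  list(manifest = m, counts = ct, fit = screen_analysis(ct, m, ...))
}
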