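#' Simulation parameters for the pooled screen
#'
#' Biological and technical parameters of the clonal founder-expansion
#' model.  Defaults encode the reference screen design: each E9.5 embryo
#' carries ~120,000 surface progenitors, of which ~15% are transduced at
#' MOI <= 1 (a single hairpin per founder); ~10% of transduced founders
#' contribute to hair follicles (HF), the rest remain epidermal (EPI);
#' each founder expands to ~40 cells by E18.5; 60 embryos are pooled per
#' biological replicate and the screen is run in triplicate.
#'
#' Clone sizes are overdispersed (negative-binomial with size
#' `expansion_dispersion` per founder); amplification adds a per-hairpin
#' multiplicative gamma factor with mean 1 and shape `pcr_noise_shape`
#' before multinomial sequencing to `reads_per_sample` reads.
#'
#' @param n_progenitors_per_embryo Epidermal progenitors per E9.5 embryo.
#' @param transduction_rate Fraction of progenitors transduced.
#' @param hf_founder_fraction Fraction of transduced founders fated to HF.
#' @param expansion_mean Mean cells per founder clone at E18.5.
#' @param expansion_dispersion Negative-binomial size parameter of a
#'   single founder clone (smaller = more overdispersed).
#' @param embryos_per_replicate Embryos pooled per biological replicate.
#' @param n_replicates Number of biological replicates.
#' @param reads_per_sample Sequencing depth per sample.
#' @param pcr_noise_shape Shape of the mean-1 gamma amplification noise
#'   (coefficient of variation = `1/sqrt(pcr_noise_shape)`).
#' @param seed Default master seed used when a simulation function is not
#'   given its own.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_progenitors_per_embryo = 120000,
                       transduction_rate = 0.15,
                       hf_founder_fraction = 0.10,
                       expansion_mean = 40,
                       expansion_dispersion = 2,
                       embryos_per_replicate = 60,
                       n_replicates = 3,
                       reads_per_sample = 1e6,
                       pcr_noise_shape = 100,
                       seed = 1L) {
  p <- list(n_progenitors_per_embryo = n_progenitors_per_embryo,
            transduction_rate = transduction_rate,
            hf_founder_fraction = hf_founder_fraction,
            expansion_mean = expansion_mean,
            expansion_dispersion = expansion_dispersion,
            embryos_per_replicate = embryos_per_replicate,
            n_replicates = n_replicates,
            reads_per_sample = reads_per_sample,
            pcr_noise_shape = pcr_noise_shape,
            seed = seed)
  with(p, {
    stopifnot(n_progenitors_per_embryo > 0, embryos_per_replicate > 0,
              n_replicates > 0, expansion_mean > 0,
              expansion_dispersion > 0, pcr_noise_shape > 0,
              transduction_rate >= 0, transduction_rate <= 1,
              hf_founder_fraction >= 0, hf_founder_fraction <= 1)
  })
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "screen simulation parameters:\n  %d progenitors/embryo, transduction %.0f%%, HF founder fate %.0f%%\n  expansion mean %g cells/founder (NB size %g), %d embryos x %d replicates\n  %g reads/sample, PCR gamma shape %g\n",
    x$n_progenitors_per_embryo, 100 * x$transduction_rate,
    100 * x$hf_founder_fraction, x$expansion_mean, x$expansion_dispersion,
    x$embryos_per_replicate, x$n_replicates, x$reads_per_sample,
    x$pcr_noise_shape))
  invisible(x)
}

#' Per-gene fitness effects (simulation ground truth)
#'
#' Multiplicative fitness effects applied to the mean clone expansion of
#' founders carrying a hairpin against the given gene, separately in the
#' epidermal and HF fractions.  Genes not listed (and all scrambled
#' controls) are neutral (effect 1).  An effect of 0.25 models a 4-fold
#' depletion; 4 models a 4-fold enrichment.
#'
#' @param gene Character vector of gene symbols.
#' @param epi_effect,hf_effect Numeric vectors (recycled) of
#'   multiplicative effects, all > 0 (0 allowed: complete loss).
#' @return An object of class `effect_spec` (data.frame).
#' @export
effect_spec <- function(gene = character(), epi_effect = numeric(),
                        hf_effect = numeric()) {
  if (length(gene)) {
    epi_effect <- rep_len(epi_effect, length(gene))
    hf_effect <- rep_len(hf_effect, length(gene))
  }
  stopifnot(all(epi_effect >= 0), all(hf_effect >= 0),
            !anyDuplicated(gene), !"SCR" %in% gene)
  structure(data.frame(gene = as.character(gene), epi_effect = epi_effect,
                       hf_effect = hf_effect, stringsAsFactors = FALSE),
            class = c("effect_spec", "data.frame"))
}

## Internal: per-shRNA effect matrix (n_shrna x 2, EPI / HF columns)
.effect_matrix <- function(manifest, effects) {
  e <- matrix(1, nrow(manifest), 2,
              dimnames = list(manifest$shrna_id, c("EPI", "HF")))
  if (!is.null(effects) && nrow(effects)) {
    idx <- match(manifest$gene, effects$gene)
    hit <- !is.na(idx)
    e[hit, "EPI"] <- effects$epi_effect[idx[hit]]
    e[hit, "HF"] <- effects$hf_effect[idx[hit]]
  }
  e
}

## Internal: total cells from k iid NB(size = disp, mean = mu1) clones.
## The sum is NB(size = k * disp, mean = k * mu1); drawn through
## qnbinom(runif()) so that, for a fixed RNG stream, the draw is
## monotone non-decreasing in the mean (exact coupling across effect
## settings, used by monotonicity checks).
.clone_total <- function(k, disp, mu1) {
  out <- numeric(length(k))
  names(out) <- names(k)
  pos <- k > 0 & mu1 > 0
  u <- stats::runif(length(k))   # consume one uniform per cell regardless
  out[pos] <- stats::qnbinom(u[pos], size = k[pos] * disp,
                             mu = k[pos] * mu1[pos])
  out
}

## Internal: founder allocation over (shRNA x fraction) cells for one
## pool of embryos.  Returns list(k = n_shrna x 2 matrix of founder
## counts, n_transduced).
.draw_founders <- function(params, n_shrna, n_embryos) {
  n_trans <- stats::rbinom(1L, params$n_progenitors_per_embryo * n_embryos,
                           params$transduction_rate)
  prob <- rep(c(1 - params$hf_founder_fraction, params$hf_founder_fraction),
              each = n_shrna) / n_shrna
  k <- matrix(stats::rmultinom(1L, n_trans, prob), ncol = 2L)
  list(k = k, n_transduced = n_trans)
}

#' Simulate one embryo of the pooled screen
#'
#' Draws the number of transduced founders Binomial(progenitors,
#' transduction rate); assigns each founder one hairpin uniformly
#' (MOI <= 1) and an HF fate with probability `hf_founder_fraction`;
#' expands each clone by an overdispersed count law with mean
#' `expansion_mean` times the gene's fraction-specific fitness effect;
#' returns cells summed per hairpin and fraction.
#'
#' @param params A [sim_params()].
#' @param manifest An `shrna_manifest`.
#' @param effects An [effect_spec()] or `NULL` (all neutral).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return List with `cells` (matrix n_shrna x 2, columns EPI/HF),
#'   `founders` (same shape) and `n_transduced`.
#' @export
simulate_embryo <- function(params, manifest, effects = NULL, seed = NULL) {
  stopifnot(inherits(params, "sim_params"),
            inherits(manifest, "shrna_manifest"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(manifest)
  eff <- .effect_matrix(manifest, effects)
  fo <- .draw_founders(params, n, 1L)
  cells <- matrix(
    .clone_total(as.vector(fo$k), params$expansion_dispersion,
                 as.vector(eff) * params$expansion_mean),
    ncol = 2L, dimnames = list(manifest$shrna_id, c("EPI", "HF")))
  list(cells = cells,
       founders = matrix(fo$k, ncol = 2L,
                         dimnames = dimnames(cells)),
       n_transduced = fo$n_transduced)
}

#' Simulate a full pooled screen
#'
#' Produces a t0 in vitro reference sample plus `n_replicates` EPI and HF
#' samples.  Per replicate, founder counts are pooled over
#' `embryos_per_replicate` embryos (the pooled founder count is Binomial
#' in the pooled progenitor number, and pooled clone-size totals follow
#' the same negative-binomial law as summing per-embryo clones, so the
#' pooled draw is distributionally identical to simulating embryos one by
#' one).  Cell tallies (uniform library abundance for t0) are perturbed
#' by mean-1 gamma amplification noise per hairpin and sequenced by a
#' multinomial draw of `reads_per_sample` reads.
#'
#' @inheritParams simulate_embryo
#' @param seed Master seed (defaults to `params$seed`).
#' @return A [count_table()] with attributes `ground_truth` (the
#'   `effect_spec` used) and `achieved_coverage` (mean HF founders per
#'   hairpin per replicate).
#' @export
simulate_screen <- function(params, manifest, effects = NULL,
                            seed = params$seed) {
  stopifnot(inherits(params, "sim_params"),
            inherits(manifest, "shrna_manifest"))
  if (params$reads_per_sample <= 0) stop("reads_per_sample must be > 0")
  set.seed(seed)
  n <- nrow(manifest)
  eff <- .effect_matrix(manifest, effects)

  seq_sample <- function(tallies) {
    g <- stats::rgamma(n, shape = params$pcr_noise_shape,
                       rate = params$pcr_noise_shape)
    w <- tallies * g
    if (sum(w) <= 0) return(integer(n))
    as.integer(stats::rmultinom(1L, params$reads_per_sample, w))
  }

  cols <- list()
  meta <- list()
  ## t0 in vitro: uniform library representation
  cols[["T0"]] <- seq_sample(rep(1, n))
  meta[["T0"]] <- data.frame(label = "T0", fraction = "T0_INVITRO",
                             replicate = NA_integer_)
  hf_founders <- numeric(params$n_replicates)
  for (r in seq_len(params$n_replicates)) {
    fo <- .draw_founders(params, n, params$embryos_per_replicate)
    cells <- matrix(
      .clone_total(as.vector(fo$k), params$expansion_dispersion,
                   as.vector(eff) * params$expansion_mean),
      ncol = 2L)
    hf_founders[r] <- mean(fo$k[, 2L])
    for (f in c("EPI", "HF")) {
      lab <- sprintf("%s_%d", f, r)
      cols[[lab]] <- seq_sample(cells[, if (f == "EPI") 1L else 2L])
      meta[[lab]] <- data.frame(label = lab, fraction = f, replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- manifest$shrna_id
  ct <- count_table(counts, do.call(rbind, meta))
  attr(ct, "ground_truth") <- if (is.null(effects)) effect_spec() else effects
  attr(ct, "achieved_coverage") <- mean(hf_founders)
  ct
}

#' Simulate the two-color competition assay
#'
#' Founders in each embryo receive either the neutral GFP scrambled virus
#' or the RFP test virus with equal probability (a 1:1 input mix);
#' clones expand as in [simulate_embryo()], with the test effects applied
#' to RFP clones only.  Per embryo and fraction the normalized ratio
#' `(final RFP/GFP) / (initial RFP/GFP)` is reported; 1 means the test
#' hairpin is neutral, < 1 depletion, > 1 enrichment.
#'
#' @param params A [sim_params()].
#' @param test_effects Length-2 numeric `c(epi_effect, hf_effect)` for
#'   the RFP test virus.
#' @param seed Seed (defaults to `params$seed`).
#' @param n_embryos Number of embryos.
#' @return data.frame with columns `embryo`, `fraction`, `ratio`.
#'   Embryos in which a fraction has zero GFP cells are excluded from
#'   that fraction with a warning.
#' @export
simulate_competition <- function(params, test_effects = c(1, 1),
                                 seed = params$seed, n_embryos = 60L) {
  stopifnot(inherits(params, "sim_params"), length(test_effects) == 2L,
            all(test_effects >= 0), n_embryos >= 1L)
  set.seed(seed)
  out <- vector("list", n_embryos)
  n_dropped <- 0L
  for (i in seq_len(n_embryos)) {
    n_trans <- stats::rbinom(1L, params$n_progenitors_per_embryo,
                             params$transduction_rate)
    n_rfp <- stats::rbinom(1L, n_trans, 0.5)
    n_gfp <- n_trans - n_rfp
    if (n_gfp == 0L || n_rfp == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    init_ratio <- n_rfp / n_gfp
    ## founder fate split per color, then pooled clone totals
    hf_rfp <- stats::rbinom(1L, n_rfp, params$hf_founder_fraction)
    hf_gfp <- stats::rbinom(1L, n_gfp, params$hf_founder_fraction)
    k <- c(epi_gfp = n_gfp - hf_gfp, epi_rfp = n_rfp - hf_rfp,
           hf_gfp = hf_gfp, hf_rfp = hf_rfp)
    mu1 <- params$expansion_mean *
      c(1, test_effects[1L], 1, test_effects[2L])
    cells <- .clone_total(k, params$expansion_dispersion, mu1)
    rows <- list()
    for (f in c("EPI", "HF")) {
      gfp <- cells[[paste0(tolower(f), "_gfp")]]
      rfp <- cells[[paste0(tolower(f), "_rfp")]]
      if (gfp == 0) { n_dropped <- n_dropped + 1L; next }
      rows[[f]] <- data.frame(embryo = i, fraction = f,
                              ratio = (rfp / gfp) / init_ratio)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  if (n_dropped > 0L)
    warning(sprintf("%d embryo-fraction record(s) excluded (zero GFP cells)",
                    n_dropped))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Fixed flanking sequence used to pad simulated amplicon reads outside
## the barcode and hairpin regions (arbitrary but constant).
.READ_FLANK <- paste0(
  "TTGTGGAAAGGACGAAACACCGGTTTAAGAGCTATGCTGGAAACAGCATAGCAAGTTTAAATAAGG",
  "CTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGCTTTTTTGAATTCTCGACCTCGAGA")

#' Emit simulated FASTQ for a count table
#'
#' Writes one FASTQ file per sample.  Each read carries the sample's
#' barcode at the layout's barcode region and the hairpin sequence at the
#' hairpin region; remaining positions are filled from a fixed flanking
#' sequence.  The number of reads per hairpin equals the count-table
#' entry; qualities are a constant Phred 40 string.
#'
#' @param ct A [count_table()].
#' @param manifest The `shrna_manifest` the counts refer to.
#' @param layout A [read_layout()].
#' @param barcodes A [barcode_map()] covering every sample label in `ct`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written FASTQ paths.
#' @export
emit_fastq <- function(ct, manifest, layout, barcodes, out_dir) {
  stopifnot(inherits(ct, "count_table"),
            inherits(manifest, "shrna_manifest"),
            inherits(layout, "read_layout"),
            inherits(barcodes, "barcode_map"))
  if (layout$hairpin_length != attr(manifest, "hairpin_length"))
    stop("layout hairpin_length does not match manifest")
  idx <- match(rownames(ct$counts), manifest$shrna_id)
  if (anyNA(idx)) stop("count table rows missing from manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  read_len <- layout$read_length
  template <- strsplit(substr(strrep(.READ_FLANK,
                                     ceiling(read_len / nchar(.READ_FLANK))),
                              1L, read_len), "")[[1L]]
  qual <- strrep("I", read_len)
  paths <- character(0)
  for (s in seq_len(ncol(ct$counts))) {
    lab <- ct$samples$label[s]
    bc <- barcodes$barcode[match(lab, barcodes$label)]
    if (is.na(bc)) stop("no barcode for sample ", lab)
    counts <- ct$counts[, s]
    reads <- character(sum(counts))
    pos <- 1L
    for (i in which(counts > 0)) {
      chars <- template
      chars[(layout$barcode_start + 1L):
              (layout$barcode_start + layout$barcode_length)] <-
        strsplit(bc, "")[[1L]]
      chars[(layout$hairpin_start + 1L):
              (layout$hairpin_start + layout$hairpin_length)] <-
        strsplit(manifest$hairpin_seq[idx[i]], "")[[1L]]
      reads[pos:(pos + counts[i] - 1L)] <- paste(chars, collapse = "")
      pos <- pos + counts[i]
    }
    seqs <- Biostrings::DNAStringSet(reads)
    names(seqs) <- sprintf("%s_read%06d", lab, seq_along(reads))
    path <- file.path(out_dir, paste0(lab, ".fastq"))
    Biostrings::writeXStringSet(
      seqs, path, format = "fastq",
      qualities = Biostrings::BStringSet(rep(qual, length(seqs))))
    paths[lab] <- path
  }
  paths
}
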