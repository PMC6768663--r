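#' Library composition description
#'
#' Describes a pooled shRNA library at the level the screen is designed:
#' how many genes of each Rho-regulator class are targeted, the per-gene
#' hairpin floor, the number of scrambled (Scr) control hairpins and the
#' library total.  The default values describe the screen library used as
#' the reference design throughout this package: 166 targeted genes
#' (20 Rho GTPases, 77 RhoGEFs, 66 RhoGAPs, 3 RhoGDIs), at least 5
#' hairpins per gene, 20 scrambled controls and 999 hairpins in total.
#'
#' @param n_gtpase,n_gef,n_gap,n_gdi Number of targeted genes per
#'   regulator class.
#' @param n_scr Number of scrambled control shRNAs.
#' @param min_per_gene Minimum number of distinct shRNAs per targeted gene.
#' @param total Total number of shRNAs in the library.
#' @return An object of class `library_composition`: a list with the
#'   arguments above plus `n_genes`, the number of targeted genes.
#' @examples
#' comp <- library_composition()
#' comp$n_genes  # 166
#' @export
library_composition <- function(n_gtpase = 20, n_gef = 77, n_gap = 66,
                                n_gdi = 3, n_scr = 20, min_per_gene = 5,
                                total = 999) {
  counts <- c(n_gtpase = n_gtpase, n_gef = n_gef, n_gap = n_gap,
              n_gdi = n_gdi, n_scr = n_scr, min_per_gene = min_per_gene,
              total = total)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  comp <- list(n_gtpase = n_gtpase, n_gef = n_gef, n_gap = n_gap,
               n_gdi = n_gdi, n_scr = n_scr, min_per_gene = min_per_gene,
               total = total,
               n_genes = n_gtpase + n_gef + n_gap + n_gdi)
  class(comp) <- "library_composition"
  floor_total <- comp$n_genes * min_per_gene + n_scr
  if (total < floor_total)
    stop(sprintf(
      "infeasible composition: total %d < minimum feasible %d (%d genes x %d + %d Scr)",
      total, floor_total, comp$n_genes, min_per_gene, n_scr))
  comp
}

#' @export
print.library_composition <- function(x, ...) {
  cat(sprintf(
    "shRNA library composition: %d genes (%d GTPase, %d GEF, %d GAP, %d GDI),\n  >=%d shRNAs/gene, %d scrambled controls, %d shRNAs total\n",
    x$n_genes, x$n_gtpase, x$n_gef, x$n_gap, x$n_gdi,
    x$min_per_gene, x$n_scr, x$total))
  invisible(x)
}

.REG_CLASSES <- c("GTPASE", "GEF", "GAP", "GDI", "SCR")

## Internal: validate the records data.frame and attach class/attributes.
.as_manifest <- function(records, hairpin_length) {
  needed <- c("shrna_id", "gene", "reg_class", "hairpin_seq")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  records <- records[needed]
  for (j in needed) records[[j]] <- as.character(records[[j]])
  if (nrow(records) == 0L) stop("manifest has no records")
  if (anyDuplicated(records$shrna_id))
    stop("duplicate shrna_id in manifest: ",
         paste(unique(records$shrna_id[duplicated(records$shrna_id)]),
               collapse = ", "))
  bad <- !records$reg_class %in% .REG_CLASSES
  if (any(bad))
    stop("unknown reg_class value(s): ",
         paste(unique(records$reg_class[bad]), collapse = ", "))
  if (any((records$reg_class == "SCR") != (records$gene == "SCR")))
    stop("reg_class SCR must coincide exactly with gene == \"SCR\"")
  len <- nchar(records$hairpin_seq)
  if (any(len != hairpin_length))
    stop(sprintf("hairpin_seq length mismatch: expected %d nt, found %s",
                 hairpin_length,
                 paste(unique(len[len != hairpin_length]), collapse = ", ")))
  if (any(grepl("[^ACGT]", records$hairpin_seq)))
    stop("hairpin_seq contains characters outside {A,C,G,T}")
  if (anyDuplicated(records$hairpin_seq))
    warning("manifest contains duplicate hairpin sequences; ",
            "exact-match counting will refuse this library")
  rownames(records) <- NULL
  structure(records, hairpin_length = hairpin_length,
            class = c("shrna_manifest", "data.frame"))
}

#' Read an shRNA library manifest from TSV
#'
#' The manifest is a tab-separated file with a header row and the columns
#' `shrna_id`, `gene`, `reg_class` (one of GTPASE, GEF, GAP, GDI, SCR) and
#' `hairpin_seq` (the targeting hairpin, ACGT only).  Scrambled controls
#' carry `gene == "SCR"` and `reg_class == "SCR"`.
#'
#' @param path Path to the TSV file.
#' @param hairpin_length Expected hairpin length in nucleotides; every
#'   record must match it exactly.
#' @return An object of class `shrna_manifest` (a data.frame with
#'   attribute `hairpin_length`).
#' @seealso [synthesize_manifest()], [write_manifest()], [write_hairpin_fasta()]
#' @export
read_manifest <- function(path, hairpin_length = 21L) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  records <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse manifest ", path, ": ",
                             conditionMessage(e)))
  if (nrow(records) == 0L) stop("manifest ", path, " contains no records")
  .as_manifest(records, hairpin_length)
}

#' Write an shRNA library manifest to TSV
#'
#' @param manifest An `shrna_manifest`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "shrna_manifest"))
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive the composition of a manifest
#'
#' Recomputes a [library_composition()] from the records themselves:
#' genes per regulator class, the scrambled-control count, the minimum
#' per-gene hairpin count and the total.
#'
#' @param manifest An `shrna_manifest`.
#' @return A `library_composition`.
#' @export
composition_of <- function(manifest) {
  stopifnot(inherits(manifest, "shrna_manifest"))
  targ <- manifest[manifest$reg_class != "SCR", , drop = FALSE]
  class_of_gene <- tapply(targ$reg_class, targ$gene, function(x) x[[1L]])
  per_gene <- table(targ$gene)
  library_composition(
    n_gtpase = sum(class_of_gene == "GTPASE"),
    n_gef = sum(class_of_gene == "GEF"),
    n_gap = sum(class_of_gene == "GAP"),
    n_gdi = sum(class_of_gene == "GDI"),
    n_scr = sum(manifest$reg_class == "SCR"),
    min_per_gene = if (nrow(targ)) min(per_gene) else 0L,
    total = nrow(manifest))
}

#' Synthesize a library manifest from a composition
#'
#' Generates a fully specified manifest matching a [library_composition()]:
#' each targeted gene receives the per-gene floor of hairpins and the
#' surplus (total − floor − scrambled) is distributed one hairpin at a
#' time over a seeded random gene order (round-robin), so that the output
#' is deterministic for a fixed seed.  Hairpin sequences are distinct
#' random 21-mers (or `hairpin_length`-mers) over ACGT.  Gene symbols are
#' generated per class (`Gtp01`, `Gef01`, `Gap01`, `Gdi01`, ...).
#'
#' @param composition A `library_composition`.
#' @param seed Integer seed; fixed seed gives a byte-identical manifest.
#' @param hairpin_length Hairpin length in nucleotides.
#' @return An `shrna_manifest` with `composition$total` records.
#' @examples
#' m <- synthesize_manifest(library_composition(), seed = 1)
#' nrow(m)  # 999
#' @export
synthesize_manifest <- function(composition, seed, hairpin_length = 21L) {
  stopifnot(inherits(composition, "library_composition"))
  set.seed(seed)
  genes <- c(
    sprintf("Gtp%02d", seq_len(composition$n_gtpase)),
    sprintf("Gef%02d", seq_len(composition$n_gef)),
    sprintf("Gap%02d", seq_len(composition$n_gap)),
    sprintf("Gdi%02d", seq_len(composition$n_gdi)))
  classes <- rep(c("GTPASE", "GEF", "GAP", "GDI"),
                 c(composition$n_gtpase, composition$n_gef,
                   composition$n_gap, composition$n_gdi))
  n_genes <- length(genes)
  per_gene <- rep(composition$min_per_gene, n_genes)
  surplus <- composition$total - composition$n_scr -
    n_genes * composition$min_per_gene
  if (surplus > 0 && n_genes > 0) {
    order_rr <- sample.int(n_genes)          # seeded round-robin order
    extra <- order_rr[((seq_len(surplus) - 1L) %% n_genes) + 1L]
    add <- tabulate(extra, nbins = n_genes)
    per_gene <- per_gene + add
  }
  gene_col <- c(rep(genes, per_gene), rep("SCR", composition$n_scr))
  class_col <- c(rep(classes, per_gene), rep("SCR", composition$n_scr))
  n <- length(gene_col)
  stopifnot(n == composition$total)
  seqs <- .random_kmer(n, hairpin_length)
  records <- data.frame(
    shrna_id = sprintf("TRCN%07d", seq_len(n)),
    gene = gene_col,
    reg_class = class_col,
    hairpin_seq = seqs,
    stringsAsFactors = FALSE)
  .as_manifest(records, hairpin_length)
}

## distinct random k-mers over ACGT
.random_kmer <- function(n, k) {
  draw <- function(m) {
    mat <- matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE),
                  nrow = m)
    apply(mat, 1L, paste, collapse = "")
  }
  seqs <- draw(n)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- draw(length(dup))
  }
  seqs
}

#' Write manifest hairpins as FASTA
#'
#' One record per hairpin; the FASTA header is
#' `"shrna_id gene reg_class"`, so [read_hairpin_fasta()] can reconstruct
#' the full manifest.  Duplicate hairpin sequences are written with a
#' warning.
#'
#' @param manifest An `shrna_manifest`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_hairpin_fasta <- function(manifest, path) {
  stopifnot(inherits(manifest, "shrna_manifest"))
  if (anyDuplicated(manifest$hairpin_seq))
    warning("writing manifest with duplicate hairpin sequences")
  seqs <- Biostrings::DNAStringSet(manifest$hairpin_seq)
  names(seqs) <- paste(manifest$shrna_id, manifest$gene, manifest$reg_class)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a hairpin FASTA written by [write_hairpin_fasta()]
#'
#' @param path FASTA path.
#' @param hairpin_length Expected hairpin length.
#' @return An `shrna_manifest`.
#' @export
read_hairpin_fasta <- function(path, hairpin_length = 21L) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA ", path, " contains no records")
  fields <- strsplit(names(seqs), " ", fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop("FASTA headers must be \"shrna_id gene reg_class\"")
  records <- data.frame(
    shrna_id = vapply(fields, `[[`, "", 1L),
    gene = vapply(fields, `[[`, "", 2L),
    reg_class = vapply(fields, `[[`, "", 3L),
    hairpin_seq = as.character(seqs),
    stringsAsFactors = FALSE)
  .as_manifest(records, hairpin_length)
}

#' @export
print.shrna_manifest <- function(x, ...) {
  comp <- composition_of(x)
  cat(sprintf("shRNA manifest: %d hairpins (%d nt), %d genes, %d scrambled\n",
              nrow(x), attr(x, "hairpin_length"), comp$n_genes, comp$n_scr))
  invisible(x)
}
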