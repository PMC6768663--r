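#' Amplicon read layout
#'
#' Describes where the sample barcode and the hairpin sit within a
#' single-end amplicon read.  All coordinates are 0-based, half-open.
#' Reads are used as given (the vector orientation fixes the hairpin
#' strand; no reverse-complement search).
#'
#' @param barcode_start,barcode_length Barcode region offset and length.
#' @param hairpin_start Offset of the hairpin region.
#' @param hairpin_length Hairpin length in nucleotides.
#' @param allowed_mismatches Hamming mismatches tolerated when matching
#'   the hairpin (0 or 1).
#' @param read_length Total read length used when emitting FASTQ;
#'   defaults to the end of the hairpin region.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(barcode_start = 0L, barcode_length = 6L,
                        hairpin_start = 10L, hairpin_length = 21L,
                        allowed_mismatches = 0L,
                        read_length = hairpin_start + hairpin_length) {
  stopifnot(barcode_start >= 0, barcode_length >= 1, hairpin_start >= 0,
            hairpin_length >= 1, allowed_mismatches %in% c(0L, 1L),
            read_length >= hairpin_start + hairpin_length,
            read_length >= barcode_start + barcode_length)
  b <- c(barcode_start, barcode_start + barcode_length)
  h <- c(hairpin_start, hairpin_start + hairpin_length)
  if (max(b[1L], h[1L]) < min(b[2L], h[2L]))
    stop("barcode and hairpin regions overlap")
  structure(list(barcode_start = as.integer(barcode_start),
                 barcode_length = as.integer(barcode_length),
                 hairpin_start = as.integer(hairpin_start),
                 hairpin_length = as.integer(hairpin_length),
                 allowed_mismatches = as.integer(allowed_mismatches),
                 read_length = as.integer(read_length)),
            class = "read_layout")
}

#' Sample barcode map
#'
#' @param barcode Character vector of barcode sequences (unique, equal
#'   length).
#' @param label Sample labels (unique), parallel to `barcode`.
#' @param fraction,replicate Optional sample metadata.
#' @return An object of class `barcode_map` (data.frame).
#' @export
barcode_map <- function(barcode, label, fraction = NA_character_,
                        replicate = NA_integer_) {
  stopifnot(length(barcode) == length(label),
            !anyDuplicated(barcode), !anyDuplicated(label))
  if (length(unique(nchar(barcode))) > 1L)
    stop("barcodes must have equal length")
  structure(data.frame(barcode = as.character(barcode),
                       label = as.character(label),
                       fraction = fraction, replicate = replicate,
                       stringsAsFactors = FALSE),
            class = c("barcode_map", "data.frame"))
}

## Internal: read sequences from FASTQ (plain or gzipped) as character.
.read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Demultiplex amplicon reads by sample barcode
#'
#' Routes each read to the sample whose barcode matches exactly at the
#' layout's barcode region.  Reads shorter than the barcode region are
#' tallied separately as short; other non-matching reads are unassigned.
#' Reads are conserved: assigned + unassigned + short = input.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param layout A [read_layout()].
#' @param barcodes A [barcode_map()].
#' @return List with `samples` (named list of character vectors of
#'   reads), `unassigned` and `short` counts.
#' @export
demultiplex <- function(reads, layout, barcodes) {
  stopifnot(inherits(layout, "read_layout"),
            inherits(barcodes, "barcode_map"))
  if (length(reads) == 1L && file.exists(reads[[1L]]) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads[[1L]]))
    reads <- .read_fastq_seqs(reads)
  bc_len <- unique(nchar(barcodes$barcode))
  if (bc_len != layout$barcode_length)
    stop("barcode length does not match layout")
  end <- layout$barcode_start + layout$barcode_length
  short <- nchar(reads) < end
  seg <- substr(reads[!short], layout$barcode_start + 1L, end)
  hit <- match(seg, barcodes$barcode)
  samples <- lapply(seq_len(nrow(barcodes)), function(i)
    reads[!short][which(hit == i)])
  names(samples) <- barcodes$label
  list(samples = samples,
       unassigned = sum(is.na(hit)),
       short = sum(short))
}

#' Count hairpins in a read stream
#'
#' Trims each read to the hairpin region of the layout (21 nt by
#' default) and matches it against the library dictionary.  With
#' `allowed_mismatches = 0` only exact matches count.  With 1 mismatch,
#' a read whose segment matches exactly one hairpin within Hamming
#' distance 1 is assigned; segments matching two or more hairpins are
#' ambiguous and left unmatched.  Reads shorter than the hairpin region
#' are tallied as short.  Counts + unmatched + short = input reads.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param manifest An `shrna_manifest`; duplicate hairpin sequences are
#'   refused at dictionary build.
#' @param layout A [read_layout()].
#' @return List with `counts` (named integer vector per shrna_id),
#'   `unmatched` and `short` counts.
#' @export
count_hairpins <- function(reads, manifest, layout) {
  stopifnot(inherits(manifest, "shrna_manifest"),
            inherits(layout, "read_layout"))
  if (layout$hairpin_length != attr(manifest, "hairpin_length"))
    stop("layout hairpin_length does not match manifest hairpin length")
  if (anyDuplicated(manifest$hairpin_seq))
    stop("manifest contains duplicate hairpin sequences; ",
         "counting would be ambiguous")
  if (length(reads) == 1L && file.exists(reads[[1L]]) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", reads[[1L]]))
    reads <- .read_fastq_seqs(reads)
  end <- layout$hairpin_start + layout$hairpin_length
  short <- nchar(reads) < end
  seg <- substr(reads[!short], layout$hairpin_start + 1L, end)
  hit <- match(seg, manifest$hairpin_seq)
  if (layout$allowed_mismatches == 1L && anyNA(hit)) {
    miss <- unique(seg[is.na(hit)])
    res <- vapply(miss, .hamming1_lookup, 0L,
                  hairpins = manifest$hairpin_seq, k = layout$hairpin_length)
    rescue <- res[match(seg[is.na(hit)], miss)]
    hit[is.na(hit)] <- ifelse(rescue > 0L, rescue, NA_integer_)
  }
  counts <- tabulate(hit, nbins = nrow(manifest))
  names(counts) <- manifest$shrna_id
  list(counts = counts, unmatched = sum(is.na(hit)), short = sum(short))
}

## Internal: index of the unique hairpin within Hamming distance 1 of
## `seg`, 0 if none or ambiguous (>= 2 distinct hairpins).
.hamming1_lookup <- function(seg, hairpins, k) {
  chars <- strsplit(seg, "")[[1L]]
  hits <- integer(0)
  for (pos in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      v <- chars
      v[pos] <- b
      m <- match(paste(v, collapse = ""), hairpins)
      if (!is.na(m)) hits <- c(hits, m)
    }
  }
  hits <- unique(hits)
  if (length(hits) == 1L) hits else 0L
}

#' Remove hairpins with zero reads in every sample
#'
#' A hairpin is discarded only if its count is zero across *all*
#' samples; a hairpin that drops out in one sample but was present at t0
#' is a biological depletion and is retained (the pseudocount in
#' [normalize_log2fc()] keeps its fold change finite).
#'
#' @param ct A [count_table()].
#' @return The filtered `count_table`, with attribute
#'   `removed_shrnas` listing the discarded hairpin ids.
#' @export
filter_zero <- function(ct) {
  stopifnot(inherits(ct, "count_table"))
  zero <- rowSums(ct$counts) == 0
  removed <- rownames(ct$counts)[zero]
  if (length(removed))
    message(sprintf("discarding %d hairpin(s) with zero reads in all samples",
                    length(removed)))
  out <- count_table(ct$counts[!zero, , drop = FALSE], ct$samples)
  attr(out, "removed_shrnas") <- removed
  out
}
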