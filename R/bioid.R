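#' BioID replicate-presence interactome filter
#'
#' Retains a protein as part of the bait's proximity interactome if it
#' is detected (count > 0) in at least `min_bait` of the bait replicates
#' and in at most `max_control` of the control-bait replicates.  The
#' reference rule is detection in 2 of the 3 bait replicates and absence
#' from all control samples.
#'
#' @param counts Numeric matrix of detection counts (e.g.
#'   peptide-spectrum matches), rows = proteins (rownames required),
#'   columns = replicates.
#' @param arm Character vector, one per column, `"BAIT"` or
#'   `"CONTROL"`.
#' @param min_bait Minimum bait replicates with detection (default 2).
#' @param max_control Maximum control replicates with detection
#'   (default 0).
#' @return data.frame of class `interactome` with columns `protein`,
#'   `n_bait_detected`, `n_control_detected`, `total_count` (summed
#'   bait counts), sorted by descending `total_count` then
#'   alphabetically.
#' @export
filter_interactome <- function(counts, arm, min_bait = 2L,
                               max_control = 0L) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts needs protein rownames")
  if (ncol(counts) == 0L) stop("detection matrix has no replicate columns")
  if (length(arm) != ncol(counts))
    stop("arm must label every replicate column")
  if (!all(arm %in% c("BAIT", "CONTROL")))
    stop("arm values must be BAIT or CONTROL")
  if (any(counts < 0)) stop("detection counts must be non-negative")
  bait <- counts[, arm == "BAIT", drop = FALSE]
  ctrl <- counts[, arm == "CONTROL", drop = FALSE]
  if (ncol(bait) < min_bait)
    stop("fewer bait replicates than min_bait")
  n_bait <- rowSums(bait > 0)
  n_ctrl <- rowSums(ctrl > 0)
  keep <- n_bait >= min_bait & n_ctrl <= max_control
  res <- data.frame(protein = rownames(counts)[keep],
                    n_bait_detected = unname(n_bait[keep]),
                    n_control_detected = unname(n_ctrl[keep]),
                    total_count = unname(rowSums(bait)[keep]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$total_count, res$protein), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("interactome", "data.frame")
  res
}

#' Relative detection frequencies of an interactome
#'
#' Frequencies used to scale labels in an interactome cloud.  Because
#' "frequency" can mean summed spectral counts or the number of
#' replicates with detection, both normalizations are returned.
#'
#' @param entries An `interactome` from [filter_interactome()].
#' @return data.frame with `protein`, `freq_counts` (spectral-count
#'   share) and `freq_replicates` (replicate-detection share); each
#'   column sums to 1.
#' @export
interactome_frequencies <- function(entries) {
  stopifnot(inherits(entries, "interactome"))
  if (!nrow(entries)) stop("empty interactome")
  if (sum(entries$total_count) == 0) stop("all detection counts are zero")
  data.frame(protein = entries$protein,
             freq_counts = entries$total_count / sum(entries$total_count),
             freq_replicates = entries$n_bait_detected /
               sum(entries$n_bait_detected),
             stringsAsFactors = FALSE)
}
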