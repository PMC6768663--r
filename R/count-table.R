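#' shRNA count table
#'
#' Container for an shRNA-by-sample matrix of non-negative integer read
#' counts plus per-sample metadata: the tissue `fraction` (one of
#' `"T0_INVITRO"`, `"EPI"`, `"HF"`) and the biological `replicate` index
#' (`NA` for the t0 in vitro reference sample).
#'
#' @param counts Integer matrix, rows = shRNAs (rownames = shrna_id),
#'   columns = samples.
#' @param samples data.frame with one row per column of `counts` and
#'   columns `label`, `fraction`, `replicate`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have shrna_id rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  needed <- c("label", "fraction", "replicate")
  if (!all(needed %in% names(samples)))
    stop("samples needs columns: ", paste(needed, collapse = ", "))
  if (nrow(samples) != ncol(counts))
    stop("samples rows must match counts columns")
  bad <- !samples$fraction %in% c("T0_INVITRO", "EPI", "HF")
  if (any(bad)) stop("unknown fraction: ",
                     paste(unique(samples$fraction[bad]), collapse = ", "))
  if (anyDuplicated(samples$label)) stop("sample labels must be unique")
  colnames(counts) <- samples$label
  structure(list(counts = counts, samples = as.data.frame(samples)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("shRNA count table: %d hairpins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$samples$fraction)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Write a count table to TSV
#'
#' Rows are shRNAs (first column `shrna_id`), columns are sample labels.
#' Sample metadata is encoded in a `# fraction:` / `# replicate:` comment
#' header so that [read_count_table()] round-trips.
#'
#' @param ct A `count_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# fraction: ", paste(ct$samples$fraction, collapse = "\t")),
    paste0("# replicate: ", paste(ct$samples$replicate, collapse = "\t"))),
    con)
  df <- data.frame(shrna_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path.
#' @return A `count_table`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  hdr <- readLines(path, n = 2L)
  if (!all(grepl("^# (fraction|replicate): ", hdr)))
    stop("missing metadata header in ", path)
  fraction <- strsplit(sub("^# fraction: ", "", hdr[1L]), "\t")[[1L]]
  replicate <- suppressWarnings(
    as.integer(strsplit(sub("^# replicate: ", "", hdr[2L]), "\t")[[1L]]))
  df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$shrna_id
  count_table(counts, data.frame(label = colnames(counts),
                                 fraction = fraction, replicate = replicate,
                                 stringsAsFactors = FALSE))
}
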