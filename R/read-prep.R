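#' Trim a fixed number of nucleotides from each read end
#'
#' Positional (not quality-adaptive) trimming: each read keeps
#' `input[left + 1 : length - right]`, order preserved.  Reads too short to
#' survive (`nchar <= left + right`) are dropped and counted in the
#' `n_rejected` attribute.  When the surviving reads do not all share one
#' length a warning is emitted naming the length mix, because downstream
#' duplicate compression requires a fixed post-trim length.
#'
#' @param reads Character vector of read sequences.
#' @param left,right Nucleotides to remove from each end (defaults 2/2).
#' @param drop_ambiguous Drop reads containing `N` after trimming (default
#'   FALSE: ambiguous reads are kept verbatim).
#' @param expected_length Optional expected post-trim length; when the actual
#'   post-trim length differs a warning is emitted (the discrepancy is
#'   surfaced, never silently corrected).
#' @return Character vector of trimmed reads with attribute `n_rejected`.
#' @examples
#' trim_reads(c("ACGTACGTAC"), left = 2, right = 2)  # "GTACGT"
#' @export
trim_reads <- function(reads, left = 2L, right = 2L, drop_ambiguous = FALSE,
                       expected_length = NULL) {
  if (left < 0 || right < 0) stop("trim amounts must be >= 0")
  n <- nchar(reads)
  keep <- n > left + right
  n_rejected <- sum(!keep)
  if (n_rejected)
    warning(n_rejected, " read(s) shorter than left + right + 1 rejected")
  out <- substring(reads[keep], left + 1L, n[keep] - right)
  if (drop_ambiguous && length(out)) {
    amb <- grepl("N", out, fixed = TRUE)
    out <- out[!amb]
  }
  if (length(out) && length(unique(nchar(out))) > 1L)
    warning("trimmed reads have mixed lengths: ",
            paste(sort(unique(nchar(out))), collapse = ", "))
  if (!is.null(expected_length) && length(out) &&
      any(nchar(out) != expected_length))
    warning("post-trim length ", paste(unique(nchar(out)), collapse = "/"),
            " differs from expected_length = ", expected_length)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Compress reads into a unique-read table
#'
#' Removes duplicate sequences while keeping track of how many times each
#' sequence occurred in each sample: the result has one row per distinct
#' sequence across all samples and one count column per sample (0 where a
#' sample never produced the sequence).  Per-sample count totals equal the
#' number of input reads, a conservation law the test suite checks on every
#' simulated dataset.
#'
#' @param read_lists Named list, one character vector of (trimmed) reads per
#'   sample.  All reads must share one length.
#' @return data.frame of class `unique_read_table`: column `sequence` plus
#'   one integer count column per sample.
#' @examples
#' deduplicate(list(A = c("ACGT", "ACGT", "TTTT")))
#' @export
deduplicate <- function(read_lists) {
  if (is.null(names(read_lists)) || any(!nzchar(names(read_lists))))
    stop("`read_lists` must be a named list (sample ids)")
  lens <- unique(unlist(lapply(read_lists, function(x)
    if (length(x)) unique(nchar(x)))))
  if (length(lens) > 1L) {
    for (sm in names(read_lists)) {
      bad <- which(nchar(read_lists[[sm]]) != lens[1])
      if (length(bad))
        stop(sprintf("mixed read lengths: sample '%s' read %d has length %d (expected %d)",
                     sm, bad[1], nchar(read_lists[[sm]][bad[1]]), lens[1]))
    }
  }
  seqs <- unique(unlist(read_lists, use.names = FALSE))
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (sm in names(read_lists)) {
    idx <- match(read_lists[[sm]], seqs)
    out[[sm]] <- tabulate(idx, nbins = length(seqs))
  }
  class(out) <- c("unique_read_table", "data.frame")
  out
}

#' @export
print.unique_read_table <- function(x, ...) {
  cat("unique_read_table:", nrow(x), "distinct sequences,",
      ncol(x) - 1L, "sample(s)\n")
  NextMethod()
}

#' Unique-read table input / output (TSV dialect v1)
#'
#' The on-disk dialect is a plain TSV with a header line: first column
#' `sequence`, then one integer count column per sample, preceded by a
#' `#seqmed-unique-reads v1` comment line.
#'
#' @param table A `unique_read_table`.
#' @param path File path.
#' @return `write_unique_reads()` returns `path` invisibly;
#'   `read_unique_reads()` returns a `unique_read_table`.
#' @export
write_unique_reads <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#seqmed-unique-reads v1", con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unique_reads
#' @export
read_unique_reads <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(out)[1] != "sequence") stop("not a unique-read TSV: ", path)
  class(out) <- c("unique_read_table", "data.frame")
  out
}
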