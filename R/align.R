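#' Exact-match placement of unique reads on a genome
#'
#' Places each distinct read sequence at its exact occurrence in the genome
#' (forward strand only; the toy genome is unstranded by construction).
#' Matching is done with `Biostrings::matchPDict` (Aho-Corasick), so the scan
#' is linear in genome size.  Reads with zero occurrences, more than one
#' occurrence, or non-ACGT characters are not placed; they are routed to an
#' `unplaced` table with a reason (`no_hit`, `multi_hit`, `ambiguous`).
#' Reads spanning exon-exon junctions have no exact genomic occurrence and
#' therefore land in `unplaced` - the scheme deliberately ignores junction
#' reads.
#'
#' @param table A `unique_read_table` (see [deduplicate()]); all sequences
#'   must share one length.
#' @param genome Named character vector of contig sequences.
#' @return list with `placements` (data.frame: sequence, contig, start, end,
#'   1-based inclusive, plus the per-sample count columns) and `unplaced`
#'   (data.frame: sequence, reason, plus count columns).
#' @export
align_exact <- function(table, genome) {
  stopifnot(inherits(table, "unique_read_table"))
  if (is.null(names(genome))) stop("`genome` must be a named character vector")
  count_cols <- setdiff(names(table), "sequence")
  k <- unique(nchar(table$sequence))
  if (length(k) > 1L) stop("unique-read table has mixed sequence lengths")
  empty_place <- data.frame(sequence = character(0), contig = character(0),
                            start = integer(0), end = integer(0))
  if (nrow(table) == 0L)
    return(list(placements = cbind(empty_place, table[count_cols]),
                unplaced = cbind(data.frame(sequence = character(0),
                                            reason = character(0)),
                                 table[count_cols])))

  clean <- grepl("^[ACGT]+$", table$sequence)
  n_hits <- integer(nrow(table))
  hit_start <- rep(NA_integer_, nrow(table))
  contig_idx <- rep(NA_integer_, nrow(table))
  local <- hit_start
  if (any(clean)) {
    sep <- strrep("N", k)
    subject <- Biostrings::DNAString(paste(genome, collapse = sep))
    contig_off <- cumsum(c(0L, (nchar(genome) + k)[-length(genome)]))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(table$sequence[clean]))
    mi <- Biostrings::matchPDict(pd, subject)
    sl <- Biostrings::startIndex(mi)
    nh <- lengths(sl)
    n_hits[clean] <- nh
    one <- which(clean)[nh == 1L]
    hit_start[one] <- unlist(sl[nh == 1L])
    contig_idx <- findInterval(hit_start, contig_off + 1L)
    local <- hit_start - contig_off[contig_idx]
  }
  placed <- !is.na(hit_start)
  reason <- ifelse(!clean, "ambiguous",
                   ifelse(n_hits == 0L, "no_hit", "multi_hit"))
  placements <- cbind(
    data.frame(sequence = table$sequence[placed],
               contig = names(genome)[contig_idx[placed]],
               start = local[placed],
               end = local[placed] + k - 1L,
               stringsAsFactors = FALSE),
    table[placed, count_cols, drop = FALSE]
  )
  unplaced <- cbind(
    data.frame(sequence = table$sequence[!placed],
               reason = reason[!placed], stringsAsFactors = FALSE),
    table[!placed, count_cols, drop = FALSE]
  )
  rownames(placements) <- rownames(unplaced) <- NULL
  list(placements = placements, unplaced = unplaced)
}

#' Give each placed read a unique feature identity
#'
#' Among the annotation features overlapping a read's interval, the category
#' ranking first in the model's hierarchy wins; within a category the feature
#' with the largest overlap wins; remaining ties break lexicographically on
#' `feature_id`, so assignment is fully deterministic and independent of the
#' feature table's row order.  Reads overlapping no feature fall to an
#' intergenic catch-all identity when the model allows one, otherwise this is
#' a configuration error.
#'
#' @param placements The `placements` element of [align_exact()].
#' @param model A [feature_model()].
#' @return data.frame of class `assigned_reads`: sequence, contig, start,
#'   end, feature_id, gene_id, category, plus per-sample count columns.
#' @export
assign_identity <- function(placements, model) {
  stopifnot(inherits(model, "feature_model"))
  hier <- model_hierarchy(model)
  count_cols <- setdiff(names(placements),
                        c("sequence", "contig", "start", "end"))
  n <- nrow(placements)
  feature_id <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  category <- rep(NA_character_, n)
  if (n) {
    rg <- GenomicRanges::GRanges(placements$contig,
                                 IRanges::IRanges(placements$start,
                                                  placements$end))
    fg <- GenomicRanges::GRanges(model$contig,
                                 IRanges::IRanges(model$start, model$end))
    ov <- GenomicRanges::findOverlaps(rg, fg)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
      width <- pmin(placements$end[qi], model$end[si]) -
        pmax(placements$start[qi], model$start[si]) + 1L
      rank <- match(model$category[si], hier)
      if (anyNA(rank))
        stop("feature category missing from hierarchy: ",
             paste(unique(model$category[si][is.na(rank)]), collapse = ", "))
      ord <- order(qi, rank, -width, model$feature_id[si], method = "radix")
      first <- ord[!duplicated(qi[ord])]
      feature_id[qi[first]] <- model$feature_id[si[first]]
      gene_id[qi[first]] <- model$gene_id[si[first]]
      category[qi[first]] <- model$category[si[first]]
    }
  }
  orphan <- is.na(feature_id)
  if (any(orphan)) {
    if (!attr(model, "intergenic_catchall"))
      stop(sum(orphan), " read(s) overlap no feature and the model has no ",
           "intergenic catch-all")
    feature_id[orphan] <- "intergenic"
    gene_id[orphan] <- "intergenic"
    category[orphan] <- "intergenic"
  }
  out <- cbind(
    placements[c("sequence", "contig", "start", "end")],
    data.frame(feature_id = feature_id, gene_id = gene_id,
               category = category, stringsAsFactors = FALSE),
    placements[count_cols]
  )
  class(out) <- c("assigned_reads", "data.frame")
  out
}

#' Write assigned reads / unplaced summaries as TSV
#'
#' `write_assigned()` emits a BED-like TSV (contig, start, end, feature_id,
#' gene_id, then per-sample counts) plus the assignment hierarchy as a
#' comment, so the heuristic actually used is recorded with its output.
#'
#' @param assigned An `assigned_reads` data.frame.
#' @param unplaced The `unplaced` element of [align_exact()].
#' @param model The [feature_model()] used (for the hierarchy comment).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assigned <- function(assigned, path, model = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model))
    writeLines(sprintf("#seqmed-hierarchy %s",
                       paste(model_hierarchy(model), collapse = ",")), con)
  cols <- c("contig", "start", "end", "feature_id", "gene_id",
            setdiff(names(assigned), c("sequence", "contig", "start", "end",
                                       "feature_id", "gene_id", "category")))
  utils::write.table(as.data.frame(assigned)[cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assigned
#' @export
write_unplaced <- function(unplaced, path) {
  utils::write.table(unplaced, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
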