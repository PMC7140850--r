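#' Feature model: annotated intervals plus an assignment hierarchy
#'
#' A feature model is the annotation the read-assignment step consults: a set
#' of genomic intervals (exon, intron, miRNA), each belonging to a gene,
#' together with an ordered category hierarchy that decides which annotation
#' wins when a read overlaps several (the classic case being a miRNA inside
#' the intron of a host gene).
#'
#' Coordinates are 1-based inclusive throughout, the Bioconductor/GFF3
#' convention.
#'
#' @param features data.frame with columns `feature_id`, `gene_id`,
#'   `category`, `contig`, `start`, `end`.
#' @param hierarchy Character vector ordering the categories from highest to
#'   lowest priority.  Must contain every category present in `features`.
#' @param intergenic_catchall Logical; when TRUE reads overlapping no feature
#'   are assigned to a synthetic "intergenic" identity instead of raising a
#'   configuration error.
#' @param contig_lengths Optional named integer vector used to validate that
#'   intervals lie within contig bounds.
#' @return data.frame of class `feature_model` with the hierarchy attached as
#'   an attribute.
#' @export
feature_model <- function(features,
                          hierarchy = c("miRNA", "exon", "intron", "intergenic"),
                          intergenic_catchall = TRUE,
                          contig_lengths = NULL) {
  req <- c("feature_id", "gene_id", "category", "contig", "start", "end")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  features <- as.data.frame(features)[req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$end < features$start)) stop("feature with end < start")
  if (anyDuplicated(features$feature_id)) stop("duplicated feature_id")
  present <- unique(features$category)
  if (length(setdiff(present, hierarchy)))
    stop("hierarchy does not cover categories: ",
         paste(setdiff(present, hierarchy), collapse = ", "))
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[features$contig]
    if (any(is.na(len)) || any(features$end > len) || any(features$start < 1L))
      stop("feature interval outside contig bounds")
  }
  structure(features,
            hierarchy = hierarchy,
            intergenic_catchall = isTRUE(intergenic_catchall),
            class = c("feature_model", "data.frame"))
}

#' @export
print.feature_model <- function(x, ...) {
  cat("feature_model:", nrow(x), "features,",
      length(unique(x$gene_id)), "genes; hierarchy:",
      paste(attr(x, "hierarchy"), collapse = " > "), "\n")
  invisible(as.data.frame(x))
}

model_hierarchy <- function(model) attr(model, "hierarchy")

#' Write / read a feature model as GFF3
#'
#' Serialisation goes through `rtracklayer`, so files follow the GFF3
#' standard (1-based inclusive coordinates).  The assignment hierarchy is
#' stored in a `#seqmed-hierarchy` pragma so a round trip preserves it.
#'
#' @param model A [feature_model()].
#' @param path Output (input) file path.
#' @return `write_gff3()` returns `path` invisibly; `read_gff3()` returns a
#'   [feature_model()].
#' @export
write_gff3 <- function(model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = model$contig,
    ranges = IRanges::IRanges(model$start, model$end),
    strand = "+",
    type = model$category,
    ID = model$feature_id,
    gene_id = model$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  # append the hierarchy as a pragma comment (harmless to other parsers)
  cat(sprintf("#seqmed-hierarchy %s\n",
              paste(attr(model, "hierarchy"), collapse = ",")),
      file = path, append = TRUE)
  invisible(path)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  hier <- c("miRNA", "exon", "intron", "intergenic")
  pragma <- grep("^#seqmed-hierarchy ", readLines(path), value = TRUE)
  if (length(pragma))
    hier <- strsplit(sub("^#seqmed-hierarchy ", "", pragma[[1]]), ",")[[1]]
  feature_model(
    data.frame(
      feature_id = as.character(gr$ID),
      gene_id = as.character(gr$gene_id),
      category = as.character(gr$type),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    ),
    hierarchy = hier
  )
}
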