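#' Simulate a toy genome and its feature annotation
#'
#' Builds a single random contig carrying `n_genes` non-overlapping gene
#' models separated by intergenic spacers.  Most genes are a single exon; a
#' `mirna_frac` subset are two-exon genes hosting a miRNA inside their intron,
#' which is the annotation collision the assignment hierarchy exists to
#' resolve.  Because the sequence is uniform random and vastly shorter than
#' 4^k for the post-trim read length k, every emitted read sequence occurs at
#' one genomic locus with overwhelming probability (verified explicitly in the
#' test suite for the genome sizes used there).
#'
#' @param config A [sim_config()].
#' @return list with elements `genome` (named character vector of contig
#'   sequences), `annotation` (a [feature_model()]), and `genes` (per-gene
#'   summary table: gene_id, host flag, span).
#' @examples
#' sim <- simulate_genome(sim_config(seed = 1, n_genes = 5))
#' sim$annotation
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  is_host <- stats::runif(n) < config$mirna_frac
  span <- ifelse(is_host,
                 config$exon_length + config$intron_length + config$host_exon2_length,
                 config$exon_length)
  spacer <- config$spacer_length
  required <- spacer * (n + 1L) + sum(span)
  glen <- required
  if (!is.null(config$genome_length)) {
    if (config$genome_length < required)
      stop(sprintf(paste0("genome_length = %d cannot hold %d genes: ",
                          "gene models plus spacers require %d nt"),
                   config$genome_length, n, required))
    glen <- config$genome_length
  }
  contig <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  gene_start <- spacer + 1L + c(0L, cumsum(span + spacer))[seq_len(n)]
  gene_id <- sprintf("g%04d", seq_len(n))

  feats <- vector("list", n)
  for (i in seq_len(n)) {
    s <- gene_start[i]
    if (is_host[i]) {
      e1 <- c(s, s + config$exon_length - 1L)
      int <- c(e1[2] + 1L, e1[2] + config$intron_length)
      e2 <- c(int[2] + 1L, int[2] + config$host_exon2_length)
      mid <- int[1] + (config$intron_length - config$mirna_length) %/% 2L
      feats[[i]] <- data.frame(
        feature_id = paste0(gene_id[i], c(":exon1", ":intron1", ":exon2", ":mir")),
        gene_id = c(gene_id[i], gene_id[i], gene_id[i],
                    sub("^g", "mir", gene_id[i])),
        category = c("exon", "intron", "exon", "miRNA"),
        contig = "chrS",
        start = c(e1[1], int[1], e2[1], mid),
        end = c(e1[2], int[2], e2[2], mid + config$mirna_length - 1L),
        stringsAsFactors = FALSE
      )
    } else {
      feats[[i]] <- data.frame(
        feature_id = paste0(gene_id[i], ":exon1"),
        gene_id = gene_id[i], category = "exon", contig = "chrS",
        start = s, end = s + config$exon_length - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  annotation <- feature_model(do.call(rbind, feats),
                              contig_lengths = c(chrS = glen))
  list(
    genome = c(chrS = contig),
    annotation = annotation,
    genes = data.frame(gene_id = gene_id, host = is_host, start = gene_start,
                       span = span, stringsAsFactors = FALSE)
  )
}

#' Plant ground truth for a simulated annotation
#'
#' Assigns every gene in the annotation a baseline expression (target median
#' coverage) and marks a `frac_de` subset as truly differential with effect
#' `+/- true_log2fc` (random sign).  miRNA gene identities receive baseline 0:
#' the generator emits mRNA-length reads only, so intronic miRNAs are carried
#' as annotation (to exercise the hierarchy) but not expressed.
#'
#' @param annotation A [feature_model()] from [simulate_genome()].
#' @param config A [sim_config()].
#' @return data.frame (`truth_table`): gene_id, is_de, true_log2fc,
#'   baseline_expression; one row per gene in the annotation.
#' @export
make_truth_table <- function(annotation, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  ids <- unique(annotation$gene_id)
  mrna <- ids[!startsWith(ids, "mir")]
  n <- length(mrna)
  low <- stats::runif(n) < config$low_expr_frac
  base <- ifelse(low,
                 stats::runif(n, config$low_expr_range[1], config$low_expr_range[2]),
                 stats::rlnorm(n, log(config$baseline_mean), config$baseline_sdlog))
  n_de <- round(config$frac_de * n)
  de_idx <- sample.int(n, n_de)
  lfc <- numeric(n)
  lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$true_log2fc
  truth <- data.frame(
    gene_id = ids,
    is_de = ids %in% mrna[de_idx],
    true_log2fc = lfc[match(ids, mrna)],
    baseline_expression = base[match(ids, mrna)],
    stringsAsFactors = FALSE
  )
  truth$true_log2fc[is.na(truth$true_log2fc)] <- 0
  truth$baseline_expression[is.na(truth$baseline_expression)] <- 0
  class(truth) <- c("truth_table", "data.frame")
  truth
}
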