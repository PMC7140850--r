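#' Simulate single-end reads for a paired design
#'
#' Emits error-free, unstranded `read_length`-nt reads from the exons of a
#' simulated genome, for `n_pairs` pairs of (control, treated) samples.  The
#' generative model is:
#'
#' * every legal start site inside an exon gets a gamma-distributed intensity
#'   weight (mean 1, variance `spikiness`) drawn once per gene and shared by
#'   all samples, which yields the reproducible "non-uniform and spiky"
#'   positional coverage the median summary is designed for;
#' * per sample, fragment counts at each start are Poisson around
#'   weight x gene rate x pair offset, where the log-normal pair offset is
#'   shared by the two samples of a pair (so pairing is informative) and the
#'   gene rate is `2^true_log2fc` times larger in treated samples for planted
#'   DE genes;
#' * every fragment is emitted `1 + Poisson(dup_rate - 1)` times, injecting
#'   duplicate reads on top of the natural start-site collisions.
#'
#' Gene rates are calibrated so the expected *median positional coverage*
#' after the default 2/2 end trim equals the truth table's
#' `baseline_expression` (see the methods vignette for the closed form).
#'
#' @param genome Named character vector of contig sequences (from
#'   [simulate_genome()]).
#' @param annotation The matching [feature_model()].
#' @param config A [sim_config()].
#' @param truth Optional truth table from [make_truth_table()]; built from
#'   `config` when NULL.  Must cover every gene in the annotation.
#' @param trim Integer vector `c(left, right)` the downstream pipeline is
#'   expected to trim; used only to calibrate coverage (default 2/2).
#' @return list with `reads` (named list, one character vector of reads per
#'   sample, samples named `ctr_<i>` / `es_<i>`), `design` (pair table with
#'   columns pair_id, control, treated), `condition` (named vector), `truth`,
#'   and `pair_offsets`.
#' @export
simulate_reads <- function(genome, annotation, config, truth = NULL,
                           trim = c(2L, 2L)) {
  validate_sim_config(config)
  if (is.null(truth)) truth <- make_truth_table(annotation, config)
  ids <- unique(annotation$gene_id)
  if (length(setdiff(ids, truth$gene_id)))
    stop("truth table does not cover all genes in the annotation")
  set.seed(config$seed + 2L)

  rl <- config$read_length
  trimlen <- rl - sum(trim)
  if (trimlen < 1L) stop("trim removes the whole read")

  ex <- as.data.frame(annotation)
  ex <- ex[ex$category %in% c("exon", "miRNA"), , drop = FALSE]
  ex <- ex[order(ex$gene_id, ex$start), , drop = FALSE]
  ex$width <- ex$end - ex$start + 1L
  toff <- stats::ave(ex$width, ex$gene_id,
                     FUN = function(w) cumsum(c(0L, w[-length(w)])))
  tlen <- tapply(ex$width, ex$gene_id, sum)

  # one row per legal fragment start site
  n_starts <- pmax(ex$width - rl + 1L, 0L)
  rows <- data.table::data.table(
    gene_id = rep(ex$gene_id, n_starts),
    contig = rep(ex$contig, n_starts),
    s = unlist(lapply(seq_len(nrow(ex)),
                      function(i) if (n_starts[i] > 0)
                        seq.int(ex$start[i], length.out = n_starts[i]))),
    tpos = unlist(lapply(seq_len(nrow(ex)),
                         function(i) if (n_starts[i] > 0)
                           toff[i] + trim[1] + seq_len(n_starts[i])))
  )
  rows$w <- if (config$spikiness > 0)
    stats::rgamma(nrow(rows), shape = 1 / config$spikiness,
                  scale = config$spikiness) else rep(1, nrow(rows))

  # expected median coverage per unit rate, gene by gene (zeros included)
  genes <- names(tlen)
  goff <- stats::setNames(cumsum(c(0L, unname(tlen)[-length(tlen)])), genes)
  total_len <- sum(tlen)
  dd <- numeric(total_len + 1L)
  p0 <- goff[rows$gene_id] + rows$tpos
  dd_add <- tapply(rows$w, p0, sum)
  dd[as.integer(names(dd_add))] <- dd_add
  dd_sub <- tapply(rows$w, pmin(p0 + trimlen, total_len + 1L), sum)
  dd[as.integer(names(dd_sub))] <- dd[as.integer(names(dd_sub))] - dd_sub
  W <- cumsum(dd[seq_len(total_len)])
  gene_of_pos <- rep(genes, unname(tlen))
  med_w <- vapply(split(W, factor(gene_of_pos, levels = genes)),
                  stats::median, numeric(1))

  base <- truth$baseline_expression[match(genes, truth$gene_id)]
  lfc <- truth$true_log2fc[match(genes, truth$gene_id)]
  rate <- ifelse(med_w > 0, base / (med_w * config$dup_rate), 0)
  if (any(base > 0 & med_w == 0))
    warning("some genes with positive baseline have no legal read start ",
            "(exon shorter than read_length); they will emit no reads")
  if (all(base == 0))
    warning("all genes have zero expression; FASTQ output will be empty")

  rows$lam0 <- rate[match(rows$gene_id, genes)] * rows$w
  fcmult <- 2^lfc[match(rows$gene_id, genes)]

  seq80 <- substring(genome[rows$contig], rows$s, rows$s + rl - 1L)
  offsets <- stats::rlnorm(config$n_pairs, 0, config$pair_sd)
  reads <- list()
  condition <- character(0)
  for (j in seq_len(config$n_pairs)) {
    for (cond in c("ctr", "es")) {
      lam <- rows$lam0 * offsets[j] * (if (cond == "es") fcmult else 1)
      n_frag <- stats::rpois(length(lam), lam)
      occ <- n_frag
      extra <- config$dup_rate > 1
      if (extra) occ <- n_frag + stats::rpois(length(n_frag),
                                              n_frag * (config$dup_rate - 1))
      sm <- paste0(cond, "_", j)
      reads[[sm]] <- rep(seq80, occ)
      condition[sm] <- cond
    }
  }
  design <- data.frame(
    pair_id = paste0("p", seq_len(config$n_pairs)),
    control = paste0("ctr_", seq_len(config$n_pairs)),
    treated = paste0("es_", seq_len(config$n_pairs)),
    stringsAsFactors = FALSE
  )
  list(reads = reads, design = design, condition = condition, truth = truth,
       pair_offsets = offsets)
}

#' FASTQ input / output
#'
#' Thin wrappers around `Biostrings` FASTQ support.  Written reads carry a
#' constant quality string (the generator is error-free and the pipeline's
#' trimming is positional, not quality-adaptive).
#'
#' @param reads Character vector of read sequences.
#' @param path FASTQ file path (uncompressed).
#' @param prefix Read-name prefix.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` returns a
#'   character vector of read sequences.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s%07d", prefix, seq_along(x))
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
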