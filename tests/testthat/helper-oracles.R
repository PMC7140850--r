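# Independent oracles and tiny fixture builders used across the suite.
# These deliberately re-derive results by brute force / first principles and
# must stay independent of the package implementations they check.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force exact aligner: scan every offset of every contig
brute_align <- function(seqs, genome) {
  lapply(seqs, function(s) {
    k <- nchar(s)
    hits <- list()
    for (cn in names(genome)) {
      g <- genome[[cn]]
      L <- nchar(g)
      if (L < k) next
      offs <- which(vapply(seq_len(L - k + 1L),
                           function(i) substring(g, i, i + k - 1L) == s,
                           logical(1)))
      for (o in offs) hits[[length(hits) + 1L]] <- c(contig = cn, start = o)
    }
    hits
  })
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- i:m
    q[o[i]] <- min(1, min(m * p[o[j]] / j))
  }
  q
}

# exact hypergeometric upper tail by enumerating all C(N, n) draws
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_cat <- colSums(draws <= K)  # categories are items 1..K
  mean(in_cat >= k)
}

# hand quantile normalization: per-rank means, no tie handling (callers use
# tie-free matrices)
hand_qn <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) ref[rank(col)])
}

# minimal single-contig feature model
toy_model <- function(..., hierarchy = c("miRNA", "exon", "intron", "intergenic"),
                      intergenic_catchall = TRUE) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r[[1]], gene_id = r[[2]], category = r[[3]],
               contig = r[[4]], start = r[[5]], end = r[[6]],
               stringsAsFactors = FALSE)))
  feature_model(df, hierarchy = hierarchy,
                intergenic_catchall = intergenic_catchall)
}

# small, fast simulation config for integration tests
small_config <- function(seed, n_genes = 80, baseline_mean = 150,
                         baseline_sdlog = 0.5, ...) {
  sim_config(seed = seed, n_genes = n_genes, baseline_mean = baseline_mean,
             baseline_sdlog = baseline_sdlog, ...)
}

# unique-read table straight from sequence vectors (bypasses trimming)
as_unique_table <- function(...) {
  deduplicate(list(...))
}
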