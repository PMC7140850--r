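#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator into a validated list.
#' The defaults describe the study design the pipeline was built for: a paired
#' 3-versus-3 comparison of sham-treated and stimulated cultures, sequenced as
#' 80-bp single-end reads with abundant duplicate sequences and "spiky"
#' non-uniform positional coverage.
#'
#' Sequencing depth is a free parameter of the generator; the default
#' (`baseline_mean = 600` median-coverage units, log-normal with
#' `baseline_sdlog = 0.8`, i.e. a smooth distribution spanning about two
#' orders of magnitude as in real transcriptomes) was chosen by a power
#' calculation so that a paired t-test with only two degrees of freedom can
#' resolve a 4-fold change at FDR < 0.05, while keeping the between-sample
#' value distributions smooth enough for quantile normalization's
#' equal-distribution assumption (see the methods vignette).  A
#' `low_expr_frac` slice of genes is planted at median coverage <= 5 to
#' exercise the regularized fold change, whose whole purpose is to damp the
#' apparent fold change of such genes.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param n_genes Number of protein-coding-like genes to simulate.
#' @param n_pairs Number of sample pairs (control, treated); the design is
#'   paired, so each pair shares a library-scale offset.
#' @param read_length Read length in nucleotides before trimming.
#' @param frac_de Fraction of genes planted as truly differential.
#' @param true_log2fc Absolute planted effect size in log2 units; the sign is
#'   randomized per gene.
#' @param low_expr_frac Fraction of genes with baseline median coverage drawn
#'   uniformly from `low_expr_range` (default at or below 5 coverage units).
#' @param spikiness Variance of the gamma-distributed per-start-site intensity
#'   weights (mean 1).  0 gives uniform coverage; larger values give spikier
#'   coverage.  The weight profile is a property of the gene and is shared by
#'   all samples, as sequence-driven coverage bias is in real libraries.
#' @param dup_rate Expected number of occurrences of each sequenced fragment
#'   (1 = no duplicate injection); each fragment is emitted
#'   `1 + Poisson(dup_rate - 1)` times.
#' @param baseline_mean Log-normal location (linear scale) of baseline median
#'   coverage for ordinarily expressed genes.
#' @param baseline_sdlog Log-normal sdlog of baseline median coverage.
#' @param low_expr_range Range of baseline median coverage for low-expression
#'   genes.
#' @param mirna_frac Fraction of genes that host an intronic miRNA (these
#'   genes get a second exon so the miRNA sits in a real intron).
#' @param exon_length Length of the (first) exon of every gene.
#' @param host_exon2_length Length of the second exon of miRNA-host genes.
#' @param intron_length Intron length of miRNA-host genes.
#' @param mirna_length Length of the intronic miRNA feature.
#' @param spacer_length Intergenic spacer between consecutive genes (also used
#'   for the contig flanks).
#' @param pair_sd Log-normal sdlog of the pair-level library-scale offset
#'   shared by the two samples of a pair (what makes pairing informative).
#' @param genome_length Optional fixed contig length.  If supplied it must be
#'   at least the span required by the gene models, otherwise
#'   `simulate_genome()` refuses with a sizing message.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20)
#' cfg$n_pairs
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       n_pairs = 3,
                       read_length = 80,
                       frac_de = 0.1,
                       true_log2fc = 2,
                       low_expr_frac = 0.1,
                       spikiness = 1,
                       dup_rate = 1.2,
                       baseline_mean = 600,
                       baseline_sdlog = 0.8,
                       low_expr_range = c(2, 5),
                       mirna_frac = 0.2,
                       exon_length = 100,
                       host_exon2_length = 100,
                       intron_length = 80,
                       mirna_length = 22,
                       spacer_length = 60,
                       pair_sd = 0.25,
                       genome_length = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_pairs = as.integer(n_pairs), read_length = as.integer(read_length),
    frac_de = frac_de, true_log2fc = true_log2fc,
    low_expr_frac = low_expr_frac, spikiness = spikiness,
    dup_rate = dup_rate, baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog, low_expr_range = low_expr_range,
    mirna_frac = mirna_frac, exon_length = as.integer(exon_length),
    host_exon2_length = as.integer(host_exon2_length),
    intron_length = as.integer(intron_length),
    mirna_length = as.integer(mirna_length),
    spacer_length = as.integer(spacer_length), pair_sd = pair_sd,
    genome_length = if (!is.null(genome_length)) as.integer(genome_length)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.na(cfg$seed)) stop("`seed` must be an integer")
  if (cfg$n_genes < 1) stop("`n_genes` must be >= 1")
  if (cfg$n_pairs < 2) stop("`n_pairs` must be >= 2 (paired testing needs at least two pairs)")
  if (cfg$read_length < 10) stop("`read_length` must be >= 10")
  if (cfg$frac_de < 0 || cfg$frac_de > 1) stop("`frac_de` must be in [0, 1]")
  if (cfg$low_expr_frac < 0 || cfg$low_expr_frac > 1)
    stop("`low_expr_frac` must be in [0, 1]")
  if (cfg$spikiness < 0) stop("`spikiness` must be >= 0")
  if (cfg$dup_rate < 1) stop("`dup_rate` must be >= 1 (mean occurrences per fragment)")
  if (cfg$mirna_frac < 0 || cfg$mirna_frac > 1) stop("`mirna_frac` must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_pairs, "pairs,",
      x$read_length, "nt reads, frac_de =", x$frac_de,
      ", |log2FC| =", x$true_log2fc, ", seed =", x$seed, "\n")
  invisible(x)
}
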