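---
title: "seqmed: methods, modeling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqmed: methods, modeling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmed)
```

## The procedure

`seqmed` implements a deliberately simple bulk RNA-seq quantification and
differential-expression scheme for small paired designs (its reference use
case is a 3-versus-3 sham/stimulation comparison of primary glial cell
cultures, sequenced as 80-bp single-end reads), plus the statistics used for
the accompanying bench assays (EdU proliferation fractions, ddCt qPCR).
The sequencing pipeline is:

1. **Trim**: remove a fixed number of nucleotides (default 2) from each read
   end. Trimming is positional, not quality-adaptive.
2. **Duplicate compression**: collapse identical sequences into a
   unique-read table that records how many times each sequence occurred in
   each sample. All downstream steps work on distinct sequences with
   per-sample occurrence counts.
3. **Exact placement**: each unique read is placed at its exact occurrence
   on the reference (forward strand); reads with zero or multiple
   occurrences are set aside with a reason. Junction-spanning reads have no
   exact genomic occurrence and are deliberately ignored.
4. **Identity assignment**: among annotation features overlapping a read,
   the category ranked first in a configurable hierarchy (default
   `miRNA > exon > intron > intergenic`) wins; within a category the largest
   overlap wins; residual ties break on `feature_id`. Every placed read gets
   exactly one identity - the motivating case is a miRNA inside the intron
   of a host gene.
5. **Quantification**: per gene and sample, depth is accumulated over
   transcript positions (exons concatenated; zeros included) and expression
   is the **median of the positional coverage**. Coverage in this protocol
   is non-uniform and spiky, and the median is insensitive to isolated
   spikes (the test suite bounds the effect of an arbitrary-height
   single-position spike by the gap to the next order statistic).
6. **Quantile normalization** across samples (rank means; ties within a
   column get the mean of their rank slots' reference values).
7. **Regularized fold change**: `log2((a + r)/(b + r))` with `r = 5` by
   default (10 is the common alternative). For `a, b <= 5` and `r = 5` the
   magnitude cannot exceed 1, so weakly expressed genes cannot dominate the
   large-fold-change list.
8. **Paired testing**: two-sided paired t-test per gene on normalized
   values (`--log-before-test` offers the log-scale alternative),
   Benjamini-Hochberg FDR, and DEG calls by the conjunction
   `|log2FC| > log2(1.5)` and `p < 0.05` and `q < 0.05`. The fold-change
   gate is two-sided: down-regulation counts.
9. **Enrichment**: hypergeometric upper-tail over-representation of the DEG
   list against gene-set categories (GMT input), categories below 5
   universe-restricted members excluded before testing, BH across the
   tested categories only, significance at `q < 0.05`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| trim left/right | 2 / 2 | nt | fixed end trim; a configured `expected_length` mismatch is warned about, never silently corrected (80 − 2 − 2 = 76, whatever a protocol sheet may claim) |
| regularizer `r` | 5 | coverage units | caps the fold change of genes with expression around 5 or below; `r = 10` damps harder; recorded in output metadata |
| fold-change cutoff | 1.5 | ratio | two-sided gate on the regularized log2 FC |
| `p_cut`, `q_cut` | 0.05 | — | raw paired-t and BH-FDR gates; all three must pass |
| hierarchy | miRNA, exon, intron, intergenic | — | assignment priority; configurable and recorded with the output |
| ORA `min_size` | 5 | genes | categories smaller than this (within the universe) are not tested |

## The synthetic world

The generator (`sim_config()`, `simulate_genome()`, `simulate_reads()`,
`simulate_assay_counts()`) emulates the statistical structure the pipeline
was designed around, and supplies ground truth for recovery tests.

* **Design**: `n_pairs = 3` control/treated pairs; each pair shares a
  log-normal library-scale offset (`pair_sd = 0.25`), which is what makes
  pairing informative. Shuffling pair labels demonstrably inflates the
  variance of per-gene differences (a test asserts this).
* **Genes**: single-exon genes (100 nt) plus a `mirna_frac = 0.2` subset of
  two-exon hosts carrying a 22-nt intronic miRNA - the annotation collision
  the hierarchy resolves. Sequence is uniform random, so post-trim 76-mers
  are unique loci with overwhelming probability.
* **Coverage spikiness**: every legal start site gets a gamma intensity
  weight (mean 1, variance `spikiness = 1`), drawn once per gene and shared
  by all samples, as sequence-driven coverage bias is in real libraries.
  Heavy-tailed start intensities were an open modeling choice; gamma was
  picked over log-normal for its explicit variance parameter. Because the
  profile is shared, it cancels from between-sample comparisons - exactly
  why the median summary is paired with per-gene reproducible spikiness.
* **Duplicates**: each fragment is emitted `1 + Poisson(dup_rate - 1)`
  times (`dup_rate = 1.2`), on top of natural start-site collisions.
* **Baseline expression**: 90% of genes log-normal with median
  `baseline_mean = 600` coverage units and `baseline_sdlog = 0.8`; 10%
  uniform on [2, 5] to exercise the regularizer. Two choices deserve
  comment:
  * *Depth* is a free parameter (the protocol reports none). A paired
    t-test with two degrees of freedom must reach `p ~ 0.004` to clear BH
    at 2000 genes, which requires a coverage CV of roughly 7% on the weaker
    side of a 4-fold change; Poisson counting noise then dictates median
    coverage of several hundred. 600 gives recall ~0.84 with margin.
  * *Breadth* matters for quantile normalization. An early, narrower
    choice (sdlog 0.25) made the planted 4-fold genes a detached cluster
    beyond the entire null range; QN - which assumes equal distributions -
    then mapped top-ranked null genes in control samples onto reference
    values driven by the up-regulated cluster, manufacturing apparent
    ~2-fold changes and an end-to-end FDR near 0.2. A smooth two-decade
    dynamic range (sdlog 0.8), as real transcriptomes have, removes the
    artifact because fold changes move genes through a well-populated rank
    continuum. This is a genuine failure mode of QN on strongly asymmetric
    tails, worth knowing about beyond the simulation.
* **Undetected genes**: rows that are zero in every sample (e.g. the miRNA
  gene identities, which 80-bp mRNA reads cannot express) are excluded
  before normalization and testing and reported with `NA` p/q. Left in,
  QN tie-averaging gives all of them one shared per-sample value and the
  t-test one shared meaningless p-value, which visibly breaks p-value
  uniformity under the null.
* **Assay counts**: 9 fields per coverslip, Poisson(150) DAPI nuclei per
  field, binomial EdU counts at `base_p = 0.1` times a condition
  multiplier, with a log-normal per-culture effect (sdlog 0.2) shared
  across conditions within a pair. Under a null multiplier the paired
  t-test rejects at 4.7% over 2000 seeds.

What a green end-to-end test does **not** establish: the generator has no
sequencing errors, no strand, no isoforms, no junction reads, no GC or
length bias, and its duplicates are protocol-agnostic. The pipeline's
behaviour on real libraries - where placement loss, mismatches and
annotation ambiguity are far richer - is out of scope by construction.

## Numerical conventions

* Median of an even-length track = mean of the two central order
  statistics.
* Quantile normalization ties: tied input values receive the mean of the
  reference values over their rank slots, so ties stay tied.
* Degenerate paired tests (zero-variance differences) return `NA` and are
  excluded from the BH ranking; `fdr_adjust` propagates `NA` without
  counting it in `m`.
* Volcano `-log10 p` floors p at 1e-300 to stay finite.
* Coordinates are 1-based inclusive everywhere (the Bioconductor and GFF3
  convention); a language-agnostic sketch of this design used 0-based
  half-open coordinates internally, but in R that would fight every
  IRanges/GFF3 interface for no behavioural difference.
* All generator randomness derives from `sim_config(seed)`; distinct
  sub-streams (genome, truth, reads) use fixed small offsets of the seed.

## Open choices, resolved

* The protocol names its FDR method only as "false discovery rate":
  Benjamini-Hochberg is used and recorded in output metadata.
* Whether the reference results used `r = 5` or `r = 10`, and raw versus
  normalized values inside the t-test, is not stated; both knobs are
  exposed (`r=`, `log_before_test=`) and defaults are recorded in the
  result's `params` attribute.
* Expression medians are taken over exonic positions (reads are exonic by
  construction); `include_introns = TRUE` quantifies the full span instead.
* The volcano output exposes a neutral `highlight` flag rather than a
  color, since the reference material is self-contradictory about color
  semantics.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 300)
out <- simulate_and_run(cfg)
out$recovery            # recall / empirical FDR against planted truth
head(out$results[out$results$is_deg, ])
volcano <- volcano_table(out$results)

# enrichment of the calls against a toy collection
universe <- out$results$gene_id
sets <- list(planted = out$truth$gene_id[out$truth$is_de])
ora_test(out$results$gene_id[out$results$is_deg],
         gene_set_collection(sets, universe))
```
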