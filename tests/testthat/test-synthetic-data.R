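test_that("simulate_genome produces valid structures within bounds", {
  cfg <- sim_config(seed = 1, n_genes = 2)
  sim <- simulate_genome(cfg)
  expect_length(sim$genome, 1L)
  ann <- as.data.frame(sim$annotation)
  expect_setequal(unique(ann$gene_id[!startsWith(ann$gene_id, "mir")]),
                  c("g0001", "g0002"))
  ex <- ann[ann$category == "exon", ]
  expect_gte(sum(ex$gene_id == "g0001"), 1L)
  expect_gte(sum(ex$gene_id == "g0002"), 1L)
  expect_true(all(ann$start >= 1 & ann$end <= nchar(sim$genome)))
})

test_that("mirna_frac = 1 gives every gene an intronic miRNA", {
  cfg <- sim_config(seed = 2, n_genes = 10, mirna_frac = 1)
  sim <- simulate_genome(cfg)
  ann <- as.data.frame(sim$annotation)
  mir <- ann[ann$category == "miRNA", ]
  intr <- ann[ann$category == "intron", ]
  expect_equal(nrow(mir), 10L)
  expect_equal(nrow(intr), 10L)
  # each miRNA nested inside its host's intron
  expect_true(all(mir$start >= intr$start & mir$end <= intr$end))
})

test_that("same seed gives byte-identical FASTA and GFF3", {
  cfg <- sim_config(seed = 7, n_genes = 15)
  paths <- replicate(2, {
    sim <- simulate_genome(cfg)
    fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
    write_fasta(sim$genome, fa)
    write_gff3(sim$annotation, gff)
    c(fa, gff)
  })
  expect_identical(readBin(paths[1, 1], "raw", file.size(paths[1, 1])),
                   readBin(paths[1, 2], "raw", file.size(paths[1, 2])))
  expect_identical(readBin(paths[2, 1], "raw", file.size(paths[2, 1])),
                   readBin(paths[2, 2], "raw", file.size(paths[2, 2])))
  # reads are deterministic too
  g <- simulate_genome(cfg)
  r1 <- simulate_reads(g$genome, g$annotation, cfg)
  r2 <- simulate_reads(g$genome, g$annotation, cfg)
  expect_identical(r1$reads, r2$reads)
})

test_that("undersized genome_length is rejected with a sizing message", {
  expect_error(simulate_genome(sim_config(seed = 1, n_genes = 50,
                                          genome_length = 1000)),
               "cannot hold")
})

test_that("truth table covers every gene once and conserves frac_de", {
  cfg <- sim_config(seed = 3, n_genes = 200, frac_de = 0.13)
  sim <- simulate_genome(cfg)
  truth <- make_truth_table(sim$annotation, cfg)
  expect_setequal(truth$gene_id, unique(sim$annotation$gene_id))
  expect_equal(anyDuplicated(truth$gene_id), 0L)
  planted <- mean(truth$is_de[!startsWith(truth$gene_id, "mir")])
  expect_lte(abs(planted - 0.13), 1 / 200)
  # frac_de = 0 builds a null world
  tr0 <- make_truth_table(sim$annotation, sim_config(seed = 3, n_genes = 200,
                                                     frac_de = 0))
  expect_false(any(tr0$is_de))
  expect_true(all(tr0$true_log2fc == 0))
})

test_that("spikiness drives positional coverage dispersion", {
  base <- list(seed = 11, n_genes = 8, mirna_frac = 0, exon_length = 1000,
               baseline_mean = 120, baseline_sdlog = 0.1, dup_rate = 1,
               low_expr_frac = 0)
  cv_of <- function(spk) {
    cfg <- do.call(sim_config, c(base, list(spikiness = spk)))
    g <- simulate_genome(cfg)
    rr <- simulate_reads(g$genome, g$annotation, cfg)
    trimmed <- lapply(rr$reads, trim_reads)
    al <- align_exact(deduplicate(trimmed), g$genome)
    assigned <- assign_identity(al$placements, g$annotation)
    tracks <- build_coverage(assigned, g$annotation)
    depth <- tracks[["g0001"]][["ctr_1"]]
    # interior positions only: the geometric ramp at the exon ends (one read
    # length each side) is common to both runs and would mask the start-rate
    # dispersion this parameter controls
    depth <- depth[80:920]
    stats::sd(depth) / mean(depth)
  }
  expect_lt(cv_of(0), cv_of(5))
})

test_that("dup_rate controls mean occurrences per unique read", {
  cfg <- sim_config(seed = 5, n_genes = 40, mirna_frac = 0, exon_length = 1000,
                    baseline_mean = 8, baseline_sdlog = 0.1, low_expr_frac = 0,
                    dup_rate = 3, frac_de = 0, spikiness = 0)
  g <- simulate_genome(cfg)
  rr <- simulate_reads(g$genome, g$annotation, cfg)
  # per sample, as the unique-read table counts occurrences per sample
  mult <- vapply(rr$reads, function(r) length(r) / length(unique(r)),
                 numeric(1))
  # natural start-site collisions add a little on top of the injected rate
  expect_gt(mean(mult), 2.6)
  expect_lt(mean(mult), 3.5)
})

test_that("pair-level offsets make pairing informative", {
  cfg <- sim_config(seed = 9, n_genes = 60, n_pairs = 6, frac_de = 0,
                    low_expr_frac = 0, baseline_mean = 300,
                    baseline_sdlog = 0.3, pair_sd = 0.3)
  g <- simulate_genome(cfg)
  rr <- simulate_reads(g$genome, g$annotation, cfg)
  trimmed <- lapply(rr$reads, trim_reads)
  al <- align_exact(deduplicate(trimmed), g$genome)
  assigned <- assign_identity(al$placements, g$annotation)
  m <- unclass(expression_matrix(assigned, g$annotation,
                                 samples = names(rr$reads)))
  m <- m[rowSums(m) > 0, ]
  d_paired <- m[, rr$design$treated] - m[, rr$design$control]
  shuffled <- rr$design$control[c(2:6, 1)]  # derangement of pair labels
  d_shuf <- m[, rr$design$treated] - m[, shuffled]
  v <- function(d) sum(apply(d, 1, stats::var))
  expect_lt(v(d_paired), v(d_shuf))
})

test_that("simulate_assay_counts emits nine fields and honors multipliers", {
  tab <- simulate_assay_counts(c(sham = 1, es = 2), n_units = 200,
                               base_p = 0.1, unit_sd = 0, seed = 21)
  expect_true(all(table(tab$coverslip_id) == 9L))
  expect_true(all(tab$edu_count <= tab$dapi_count))
  fr <- edu_fraction(tab)
  m_es <- mean(fr$edu_percent[fr$condition == "es"])
  m_sh <- mean(fr$edu_percent[fr$condition == "sham"])
  expect_lt(abs(m_es - 20), 1)   # multiplier 2 on p = 0.1, in percent
  expect_lt(abs(m_sh - 10), 1)
  # multiplier 1: equal in expectation
  tab1 <- simulate_assay_counts(c(sham = 1, es = 1), n_units = 300,
                                unit_sd = 0, seed = 22)
  fr1 <- edu_fraction(tab1)
  expect_lt(abs(diff(tapply(fr1$edu_percent, fr1$condition, mean))), 0.5)
  expect_error(simulate_assay_counts(c(sham = 1, es = 20), base_p = 0.1),
               "outside \\[0, 1\\]")
})
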