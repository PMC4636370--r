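test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(rna_noise_sd = 0), "rna_noise_sd")
  expect_error(synthetic_config(frac_differential = 1.2), "frac_differential")
  expect_error(synthetic_config(protein_detect_fraction = -0.1),
               "protein_detect_fraction")
  expect_error(synthetic_config(states = c("A", "A")), "distinct")
})

test_that("identical configs (incl. seed) give identical datasets", {
  cfg <- synthetic_config(n_genes = 300, seed = 42)
  d1 <- generate_two_state_dataset(cfg)
  d2 <- generate_two_state_dataset(cfg)
  expect_identical(unclass(d1$rna), unclass(d2$rna))
  expect_identical(unclass(d1$protein), unclass(d2$protein))
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_two_state_dataset(synthetic_config(n_genes = 300, seed = 43))
  expect_false(identical(unclass(d1$rna), unclass(d3$rna)))
})

test_that("truth table is consistent with the configuration", {
  cfg <- synthetic_config(n_genes = 1000, frac_differential = 0.1,
                          effect_size_log2 = 2, seed = 5)
  d <- generate_two_state_dataset(cfg)
  expect_identical(d$truth$is_differential, d$truth$true_effect_log2 != 0)
  expect_equal(sum(d$truth$is_differential), 100)
  expect_true(all(abs(d$truth$true_effect_log2[d$truth$is_differential]) == 2))
  # frac_differential = 0 means every effect is 0
  d0 <- generate_two_state_dataset(
    synthetic_config(n_genes = 200, frac_differential = 0, seed = 1))
  expect_true(all(d0$truth$true_effect_log2 == 0))
})

test_that("protein depth matches the detection fraction", {
  d <- generate_two_state_dataset(
    synthetic_config(n_genes = 5200, protein_detect_fraction = 0.26, seed = 1))
  expect_lt(abs(nrow(d$protein) - 0.26 * 5200) / (0.26 * 5200), 0.05)
  # detected proteins sit at the top of the true abundance distribution
  det <- !is.na(d$truth$true_protein_baseline)
  base <- d$truth$true_rna_baseline
  expect_gt(mean(base[det]), mean(base[!det]))
})

test_that("per-feature state means recover the generator truth", {
  cfg <- synthetic_config(n_genes = 2000, rna_noise_sd = 0.5,
                          effect_size_log2 = 2, frac_differential = 0.1,
                          seed = 7)
  d <- generate_two_state_dataset(cfg)
  Z <- cross_state_Z(d$rna, std_cfg())
  # signed effect recovered on average for the truly differential features
  diff <- d$truth$is_differential
  signed <- Z[diff] * sign(d$truth$true_effect_log2[diff])
  expect_lt(abs(mean(signed) - 2), 3 * 0.5 / sqrt(sum(diff)))
  # per-feature state mean lies within 3*sd/sqrt(2) of truth almost surely
  b_mean <- rowMeans(unclass(d$rna)[, 3:4])
  b_true <- d$truth$true_rna_baseline + d$truth$true_effect_log2 / 2
  expect_gt(mean(abs(b_mean - b_true) < 3 * 0.5 / sqrt(2)), 0.99)
})

test_that("null generator is symmetric about zero", {
  d <- generate_two_state_dataset(
    synthetic_config(n_genes = 2000, frac_differential = 0, seed = 9))
  Z <- cross_state_Z(d$rna, std_cfg())
  expect_gt(stats::binom.test(sum(Z > 0), length(Z))$p.value, 0.01)
})

test_that("reads are exact substrings with multinomial gene balance", {
  genes <- random_gene_sequences(2, c(400, 600), seed = 3)
  am1 <- make_am(matrix(10, 1, 4), ids = names(genes)[1])
  r1 <- generate_reads(genes[1], am1, read_len = 100, n_reads = 10, seed = 1)
  expect_equal(nrow(r1), 40)  # 10 reads x 4 samples
  expect_true(all(vapply(seq_len(nrow(r1)), function(i)
    grepl(r1$sequence[i], genes[[r1$gene_id[i]]], fixed = TRUE), TRUE)))

  # log2 abundances {12, 10} give a ~4:1 read split (binomial CI oracle)
  am2 <- make_am(matrix(c(12, 10), 2, 4), ids = names(genes))
  r2 <- generate_reads(genes, am2, read_len = 100, n_reads = 4000, seed = 11)
  n1 <- sum(r2$gene_id == names(genes)[1] & r2$sample_id == r2$sample_id[1])
  ci <- stats::binom.test(n1, 4000, p = 0.8)$conf.int
  expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])

  # equal abundances split ~50/50
  am3 <- make_am(matrix(c(10, 10), 2, 4), ids = names(genes))
  r3 <- generate_reads(genes, am3, read_len = 100, n_reads = 2000, seed = 2)
  s1 <- r3[r3$sample_id == r3$sample_id[1], ]
  expect_lt(abs(mean(s1$gene_id == names(genes)[1]) - 0.5), 0.05)
})

test_that("genes shorter than the read length are skipped with a warning", {
  genes <- c(g_long = strrep("ACGT", 50), g_short = "ACGTACGT")
  am <- make_am(matrix(10, 2, 4), ids = names(genes))
  expect_warning(r <- generate_reads(genes, am, read_len = 100, n_reads = 50,
                                     seed = 1), "skipped")
  expect_true(all(r$gene_id == "g_long"))
})

test_that("peptide TIC sums conserve protein abundance", {
  d <- generate_two_state_dataset(synthetic_config(n_genes = 60, seed = 4))
  ev <- generate_peptide_evidence(d$protein, seed = 8)
  sums <- tapply(ev$evidence$tic,
                 list(ev$evidence$gene_id, ev$evidence$sample_id), sum)
  for (g in rownames(d$protein)) {
    expect_equal(unname(sums[g, colnames(d$protein)]),
                 unname(2^d$protein[g, ]), tolerance = 1e-12)
  }
})

test_that("violator proteins break exactly their assigned filter", {
  d <- generate_two_state_dataset(synthetic_config(n_genes = 200, seed = 6))
  ev <- generate_peptide_evidence(d$protein, frac_single = 0.1,
                                  frac_high_loge = 0.1,
                                  frac_missing_rep = 0.1, seed = 2)
  singles <- ev$truth$gene_id[ev$truth$violation == "single_peptide"]
  for (g in singles)
    expect_equal(length(unique(
      ev$evidence$peptide_seq[ev$evidence$gene_id == g])), 1L)
  high <- ev$truth$gene_id[ev$truth$violation == "high_loge"]
  expect_true(all(ev$evidence$loge[ev$evidence$gene_id %in% high] >= -1.5))
  missing <- ev$truth$gene_id[ev$truth$violation == "missing_replicate"]
  rep2 <- sample_sheet(d$protein)$sample_id[sample_sheet(d$protein)$replicate == 2]
  expect_false(any(ev$evidence$gene_id %in% missing &
                     ev$evidence$sample_id %in% rep2))
})

test_that("qPCR groups are moment-matched exactly", {
  g <- generate_qpcr_groups(0.36, 0.09, 3, seed = 2)
  expect_equal(mean(g), 0.36, tolerance = 1e-12)
  expect_equal(stats::sd(g), 0.09, tolerance = 1e-12)
  expect_equal(generate_qpcr_groups(5, 0, 3, seed = 1), rep(5, 3))
  gs <- generate_qpcr_groups(c(0.89, 0.49), c(0.15, 0.18), 3, seed = 7)
  expect_length(gs, 2)
  expect_equal(vapply(gs, mean, 0), c(0.89, 0.49), tolerance = 1e-12)
})

test_that("dataset round-trips through the TSV/FASTA/FASTQ writers", {
  d <- generate_two_state_dataset(synthetic_config(n_genes = 40, seed = 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_tsv(d$rna, tsv)
  back <- read_abundance_tsv(tsv)
  expect_equal(unclass(back), unclass(d$rna), tolerance = 1e-12)
  expect_identical(sample_sheet(back), sample_sheet(d$rna))

  genes <- random_gene_sequences(3, c(200, 300), seed = 1)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genes_fasta(genes, fa)
  expect_identical(read_genes_fasta(fa), genes)

  am <- make_am(matrix(8, 3, 4), ids = names(genes))
  reads <- generate_reads(genes, am, read_len = 50, n_reads = 20, seed = 1)
  fq <- withr::local_tempfile(fileext = ".fq")
  write_reads_fastq(reads, fq)
  back_r <- read_reads_fastq(fq)
  expect_identical(unname(back_r), reads$sequence)
})
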