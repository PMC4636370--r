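# Shared fixture builders and independent oracles.

# Quick abundance matrix: `values` is features x 4 (A1 A2 B1 B2).
make_am <- function(values, layer = "rna", states = c("A", "B"),
                    ids = NULL) {
  values <- rbind(values)
  if (!is.null(ids)) rownames(values) <- ids
  abundance_matrix(values,
                   data.frame(state = rep(states, each = 2),
                              replicate = rep(1:2, 2)),
                   layer)
}

std_cfg <- function(...) scoring_config(state_a = "A", state_b = "B", ...)

# Naive substring-search oracle for exact k-mer counting: a read hits a gene
# iff its first k bases occur verbatim in the gene (or its reverse
# complement). Independent of the package's window-hash index.
naive_count_oracle <- function(reads, gene_seqs, k = 100L,
                               strand_mode = "both") {
  if (is.data.frame(reads)) {
    seqs <- reads$sequence; samples <- reads$sample_id
  } else {
    seqs <- reads; samples <- rep("reads", length(reads))
  }
  rc <- vapply(gene_seqs, function(g)
    chartr("ACGT", "TGCA", paste(rev(strsplit(g, "")[[1]]), collapse = "")), "")
  sample_levels <- unique(samples)
  counts <- matrix(0, length(gene_seqs), length(sample_levels),
                   dimnames = list(names(gene_seqs), sample_levels))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < k) next
    kmer <- substr(seqs[i], 1, k)
    if (grepl("[^ACGT]", kmer)) next
    for (g in names(gene_seqs)) {
      hit <- grepl(kmer, gene_seqs[[g]], fixed = TRUE) ||
        (strand_mode == "both" && grepl(kmer, rc[[g]], fixed = TRUE))
      if (hit) counts[g, samples[i]] <- counts[g, samples[i]] + 1
    }
  }
  counts
}

# Brute-force application of the three protein acceptance rules to peptide
# evidence; returns the set of (gene, state) pairs accepted. Independent of
# protein_rollup()'s tapply pipeline.
brute_force_accept <- function(evidence, replicate_map, loge_max = -1.5,
                               min_peptides = 2L) {
  accepted <- character(0)
  for (g in unique(evidence$gene_id)) {
    for (st in unique(replicate_map$state)) {
      reps <- replicate_map$sample_id[replicate_map$state == st]
      ok <- TRUE
      for (s in reps) {
        rows <- evidence[evidence$gene_id == g & evidence$sample_id == s &
                           evidence$loge < loge_max, ]
        if (length(unique(rows$peptide_seq)) < min_peptides) ok <- FALSE
      }
      if (ok) accepted <- c(accepted, paste(g, st, sep = "|"))
    }
  }
  sort(accepted)
}

# DifferentialRecord frame for tiny fixtures where population calibration of
# Znet is meaningless: uses Z itself as the normalized score and a fixed
# S/N noise floor.
score_differential_stub <- function(x, cfg, floor = 1) {
  Z <- cross_state_Z(x, cfg)
  R <- intra_replicate_R(x)
  call <- call_differential(Z, cfg)
  pa <- presence_absence_calls(x, cfg)
  call[pa != "quantified"] <- pa[pa != "quantified"]
  data.frame(feature_id = rownames(x), layer = matrix_layer(x),
             Z = unname(Z),
             R_A = unname(R[, cfg$state_a]), R_B = unname(R[, cfg$state_b]),
             Znet = unname(Z), call = unname(call),
             feature_snr = unname(feature_snr(Z, R[, cfg$state_a],
                                              R[, cfg$state_b], floor)),
             stringsAsFactors = FALSE)
}
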