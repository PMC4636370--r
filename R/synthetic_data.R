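# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the two-state synthetic multi-omics generator
#'
#' Defaults emulate the regime of a paired bacterial transcriptome-proteome
#' study: ~5200 RNA-detected genes with log2 abundance roughly 7-13, ~26% of
#' them detected at the protein level with log2 TIC roughly 17-23, two states
#' x two biological replicates, a minority of truly differential features
#' with a fixed-magnitude log2 effect, replicate noise giving a cross-state /
#' intra-replicate system signal-to-noise near 3.5 for RNA and 1.5 for
#' protein, and RNA-protein coupling attenuated to R^2 of roughly 0.24-0.42.
#'
#' @param n_genes number of gene features.
#' @param frac_differential fraction in \[0,1\] of genes with a true
#'   cross-state effect.
#' @param effect_size_log2 magnitude (log2 units) of the true state-B minus
#'   state-A difference for differential genes; sign is +/- with equal
#'   probability. The shift is applied symmetrically (-effect/2 in state A,
#'   +effect/2 in state B).
#' @param rna_noise_sd,protein_noise_sd per-sample replicate noise sd (log2).
#' @param rna_baseline_mean,rna_baseline_sd log2 RNA baseline distribution.
#' @param protein_offset_mean,protein_offset_sd log2 RNA-to-protein offset
#'   (per-gene translation efficiency); mean ~10 places protein TICs in the
#'   17-23 range.
#' @param coupling_noise_sd extra per-gene decoupling noise (log2) between
#'   RNA and protein true levels; together with `protein_offset_sd` it sets
#'   the achievable RNA-protein R^2.
#' @param protein_detect_fraction fraction of genes detected at the protein
#'   level; detection is top-abundance with logistic dropout near the
#'   threshold.
#' @param protein_dropout_width logistic width (log2) of the detection edge.
#' @param states length-2 character vector, state A then state B.
#' @param seed integer RNG seed; identical configs give identical datasets.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 5200,
                             frac_differential = 0.16,
                             effect_size_log2 = 3,
                             rna_noise_sd = 0.25,
                             protein_noise_sd = 0.6,
                             rna_baseline_mean = 10,
                             rna_baseline_sd = 1,
                             protein_offset_mean = 10,
                             protein_offset_sd = 0.7,
                             coupling_noise_sd = 0.9,
                             protein_detect_fraction = 0.26,
                             protein_dropout_width = 0.2,
                             states = c("A", "B"),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              frac_differential = frac_differential,
              effect_size_log2 = effect_size_log2,
              rna_noise_sd = rna_noise_sd,
              protein_noise_sd = protein_noise_sd,
              rna_baseline_mean = rna_baseline_mean,
              rna_baseline_sd = rna_baseline_sd,
              protein_offset_mean = protein_offset_mean,
              protein_offset_sd = protein_offset_sd,
              coupling_noise_sd = coupling_noise_sd,
              protein_detect_fraction = protein_detect_fraction,
              protein_dropout_width = protein_dropout_width,
              states = as.character(states),
              seed = as.integer(seed))
  for (p in c("rna_noise_sd", "protein_noise_sd", "rna_baseline_sd",
              "protein_offset_sd", "coupling_noise_sd", "protein_dropout_width"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop("configuration error: `", p, "` must be > 0")
  for (p in c("frac_differential", "protein_detect_fraction"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: `", p, "` must be in [0,1]")
  if (cfg$n_genes < 1L) stop("configuration error: `n_genes` must be >= 1")
  if (length(cfg$states) != 2L || anyDuplicated(cfg$states))
    stop("configuration error: `states` must be two distinct labels")
  if (cfg$effect_size_log2 < 0) stop("configuration error: `effect_size_log2` must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a two-state, two-replicate multi-omics dataset with known truth
#'
#' Draws per-gene log2 RNA baselines, assigns a `frac_differential` subset a
#' signed cross-state effect of fixed magnitude, couples protein true levels
#' to RNA through a per-gene offset plus decoupling noise, detects proteins
#' by abundance rank with logistic dropout at the depth threshold, and adds
#' iid replicate noise per sample.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `rna` and `protein` ([abundance_matrix()]s;
#'   the protein matrix contains only detected genes) and `truth`, a data
#'   frame with `feature_id`, `true_effect_log2` (0 for null genes),
#'   `is_differential`, `true_rna_baseline`, `true_protein_baseline`
#'   (`NA` for proteins below detection).
#' @examples
#' d <- generate_two_state_dataset(synthetic_config(n_genes = 200, seed = 3))
#' d$rna
#' head(d$truth)
#' @export
generate_two_state_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    n <- config$n_genes
    ids <- sprintf("gene_%05d", seq_len(n))
    baseline <- stats::rnorm(n, config$rna_baseline_mean, config$rna_baseline_sd)

    n_diff <- round(config$frac_differential * n)
    is_diff <- rep(FALSE, n)
    is_diff[sample.int(n, n_diff)] <- TRUE
    effect <- numeric(n)
    effect[is_diff] <- sample(c(-1, 1), n_diff, replace = TRUE) * config$effect_size_log2
    # symmetric split keeps each state's population variance equal
    shift_a <- -effect / 2
    shift_b <- effect / 2

    samp <- data.frame(state = rep(config$states, each = 2L),
                       replicate = rep(1:2, times = 2L))
    state_shift <- cbind(shift_a, shift_a, shift_b, shift_b)

    rna_true <- baseline + state_shift
    rna_obs <- rna_true + matrix(stats::rnorm(n * 4L, 0, config$rna_noise_sd), n, 4L)
    rownames(rna_obs) <- ids
    rna <- abundance_matrix(rna_obs, samp, "rna")

    offset <- stats::rnorm(n, config$protein_offset_mean, config$protein_offset_sd)
    decouple <- stats::rnorm(n, 0, config$coupling_noise_sd)
    prot_base <- baseline + offset + decouple
    thr <- stats::quantile(prot_base, 1 - config$protein_detect_fraction, names = FALSE)
    p_detect <- stats::plogis((prot_base - thr) / config$protein_dropout_width)
    detected <- stats::runif(n) < p_detect

    prot_true <- prot_base + state_shift
    prot_obs <- prot_true + matrix(stats::rnorm(n * 4L, 0, config$protein_noise_sd), n, 4L)
    rownames(prot_obs) <- ids
    protein <- abundance_matrix(prot_obs[detected, , drop = FALSE], samp, "protein")

    truth <- data.frame(feature_id = ids,
                        true_effect_log2 = effect,
                        is_differential = is_diff,
                        true_rna_baseline = baseline,
                        true_protein_baseline = ifelse(detected, prot_base, NA_real_),
                        stringsAsFactors = FALSE)
    list(rna = rna, protein = protein, truth = truth, config = config)
  })
}

#' Generate random gene model sequences
#'
#' @param n number of genes.
#' @param length_range integer range of gene lengths (bp).
#' @param seed RNG seed.
#' @param ids optional feature identifiers (defaults to `gene_00001`, ...).
#' @return named character vector of DNA sequences.
#' @export
random_gene_sequences <- function(n, length_range = c(300L, 1500L), seed = 1L,
                                  ids = NULL) {
  if (is.null(ids)) ids <- sprintf("gene_%05d", seq_len(n))
  with_seed(seed, {
    lens <- length_range[1] + sample.int(length_range[2] - length_range[1] + 1L,
                                         n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
    names(seqs) <- ids
    seqs
  })
}

#' Simulate error-free reads from gene models
#'
#' Reads are exact substrings of their source gene, matching the exact-match
#' counting engine downstream; there is no sequencing-error or bias model.
#' Per-gene read counts are multinomial with probabilities proportional to
#' `2^abundance` in each sample. An optional mismatch-injection flag mutates
#' one base of a fraction of reads, solely to exercise the property that
#' mismatched reads are not counted.
#'
#' @param gene_seqs named character vector (or `DNAStringSet`) of gene models.
#' @param abundance an [abundance_matrix()] whose row names are a subset of
#'   `names(gene_seqs)`; `NA` abundances draw no reads.
#' @param read_len read length (bp); genes shorter than this are skipped with
#'   a warning.
#' @param n_reads reads per sample.
#' @param seed RNG seed.
#' @param mismatch_fraction fraction of reads receiving one substitution.
#' @return data frame with `read_id`, `sample_id`, `gene_id` (source gene),
#'   `sequence`, `mismatched` (logical).
#' @export
generate_reads <- function(gene_seqs, abundance, read_len = 100L, n_reads,
                           seed = 1L, mismatch_fraction = 0) {
  if (methods::is(gene_seqs, "DNAStringSet")) gene_seqs <- as.character(gene_seqs)
  genes <- intersect(rownames(abundance), names(gene_seqs))
  if (length(genes) == 0L) stop("no genes shared between `abundance` and `gene_seqs`")
  lens <- nchar(gene_seqs[genes])
  short <- lens < read_len
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than read_len skipped")
    genes <- genes[!short]
    lens <- lens[!short]
  }
  samp <- sample_sheet(abundance)
  with_seed(seed, {
    out <- vector("list", nrow(samp))
    for (j in seq_len(nrow(samp))) {
      ab <- abundance[genes, j]
      w <- ifelse(is.na(ab), 0, 2^ab)
      if (sum(w) == 0) next
      counts <- as.vector(stats::rmultinom(1L, n_reads, prob = w))
      src <- rep(genes, counts)
      starts <- floor(stats::runif(length(src)) * (nchar(gene_seqs[src]) - read_len + 1)) + 1L
      seqs <- substr(gene_seqs[src], starts, starts + read_len - 1L)
      mm <- stats::runif(length(src)) < mismatch_fraction
      if (any(mm)) {
        pos <- sample.int(read_len, sum(mm), replace = TRUE)
        for (i in which(mm)) {
          p <- pos[match(i, which(mm))]
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
      out[[j]] <- data.frame(sample_id = samp$sample_id[j], gene_id = src,
                             sequence = seqs, mismatched = mm,
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    if (is.null(res))
      res <- data.frame(sample_id = character(), gene_id = character(),
                        sequence = character(), mismatched = logical())
    res <- cbind(read_id = sprintf("read_%07d", seq_len(nrow(res))), res)
    rownames(res) <- NULL
    res
  })
}

#' Simulate peptide-level proteomic evidence from a protein abundance matrix
#'
#' For each detected protein and sample, member-peptide TICs are random
#' proportions of the protein's total TIC `2^abundance`, so the TIC rollup
#' conserves abundance by construction. Designated violator proteins break
#' exactly one of the three acceptance filters (single passing peptide;
#' all peptide log(e) above the credibility threshold; evidence missing from
#' replicate 2) so that filter tests have positive and negative cases.
#'
#' @param protein_abundance an [abundance_matrix()] of log2 TIC values.
#' @param peptides_per_protein integer vector of candidate peptide counts
#'   (sampled uniformly per protein).
#' @param loge_range range of log10 expectation values for passing peptides
#'   (must lie below -1.5).
#' @param frac_single,frac_high_loge,frac_missing_rep fractions of proteins
#'   assigned to each violator class (disjoint).
#' @param seed RNG seed.
#' @return list with `evidence` (data frame: `peptide_seq`, `gene_id`,
#'   `sample_id`, `loge`, `tic`) and `truth` (data frame: `gene_id`,
#'   `violation` in `none/single_peptide/high_loge/missing_replicate`).
#' @export
generate_peptide_evidence <- function(protein_abundance,
                                      peptides_per_protein = 2:5,
                                      loge_range = c(-8, -2),
                                      frac_single = 0, frac_high_loge = 0,
                                      frac_missing_rep = 0, seed = 1L) {
  if (frac_single + frac_high_loge + frac_missing_rep > 1)
    stop("violator fractions must sum to <= 1")
  ids <- rownames(protein_abundance)
  n <- length(ids)
  samp <- sample_sheet(protein_abundance)
  with_seed(seed, {
    violation <- rep("none", n)
    ord <- sample.int(n)
    n1 <- round(frac_single * n); n2 <- round(frac_high_loge * n)
    n3 <- round(frac_missing_rep * n)
    violation[ord[seq_len(n1)]] <- "single_peptide"
    violation[ord[n1 + seq_len(n2)]] <- "high_loge"
    violation[ord[n1 + n2 + seq_len(n3)]] <- "missing_replicate"

    rows <- vector("list", n)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in seq_len(n)) {
      n_pep <- if (violation[i] == "single_peptide") 1L
               else sample(peptides_per_protein, 1L)
      n_pep <- max(n_pep, if (violation[i] == "single_peptide") 1L else 2L)
      peps <- vapply(seq_len(n_pep), function(k)
        paste(sample(aa, 12L, replace = TRUE), collapse = ""), "")
      loge <- if (violation[i] == "high_loge")
        stats::runif(n_pep, -1.4, -0.5)
      else stats::runif(n_pep, loge_range[1], loge_range[2])
      keep_samples <- seq_len(nrow(samp))
      if (violation[i] == "missing_replicate")
        keep_samples <- which(samp$replicate != 2L)
      per_sample <- lapply(keep_samples, function(j) {
        ab <- protein_abundance[i, j]
        if (is.na(ab)) return(NULL)
        w <- stats::runif(n_pep, 0.5, 1.5)
        data.frame(peptide_seq = peps, gene_id = ids[i],
                   sample_id = samp$sample_id[j], loge = loge,
                   tic = 2^ab * w / sum(w), stringsAsFactors = FALSE)
      })
      rows[[i]] <- do.call(rbind, per_sample)
    }
    evidence <- do.call(rbind, rows)
    rownames(evidence) <- NULL
    list(evidence = evidence,
         truth = data.frame(gene_id = ids, violation = violation,
                            stringsAsFactors = FALSE))
  })
}

#' Moment-matched qPCR replicate groups
#'
#' Returns replicate values whose sample mean and sample sd (n-1 denominator)
#' equal the requested values exactly, so t-tests on the raw groups reproduce
#' t-tests computed from the printed mean +/- sd summaries to machine
#' precision.
#'
#' @param mean,sd target sample moments (vectors are recycled to the longer).
#' @param n replicates per group (>= 2).
#' @param seed RNG seed (the underlying shape of the group is random; its
#'   first two moments are not).
#' @return a numeric vector if one group is requested, else a list of them.
#' @examples
#' generate_qpcr_groups(0.36, 0.09, 3, seed = 2)
#' @export
generate_qpcr_groups <- function(mean, sd, n = 3L, seed = 1L) {
  if (n < 2L) stop("`n` must be >= 2")
  if (any(sd < 0)) stop("`sd` must be >= 0")
  k <- max(length(mean), length(sd))
  mean <- rep_len(mean, k); sd <- rep_len(sd, k)
  with_seed(seed, {
    groups <- lapply(seq_len(k), function(i) {
      if (sd[i] == 0) return(rep(mean[i], n))
      z <- stats::rnorm(n)
      z <- (z - base::mean(z)) / stats::sd(z)
      mean[i] + sd[i] * z
    })
    if (k == 1L) groups[[1L]] else groups
  })
}

#' Write simulated reads as FASTQ and gene models as FASTA
#'
#' FASTQ qualities are fixed at "I" (Q40): the counting engine ignores
#' quality, relying on exact matching.
#'
#' @param reads data frame from [generate_reads()].
#' @param path output file.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", qual), path)
  invisible(path)
}

#' @rdname write_reads_fastq
#' @param gene_seqs named character vector of sequences.
#' @export
write_genes_fasta <- function(gene_seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gene_seqs), path)
  invisible(path)
}
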