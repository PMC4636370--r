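#' Count reads by exact k-mer alignment against gene models
#'
#' The engine detects exact 100-mer alignments only: a read increments gene
#' `g` if and only if its first `k` bases occur verbatim in `g` (or, with
#' `strand_mode = "both"`, in the reverse complement of `g`). There is no
#' scoring, no gaps and no mismatch tolerance; the design relies on high
#' base quality to give sufficient counting statistics. Implemented as a
#' hash lookup of all reference k-length windows.
#'
#' @param reads character vector of read sequences, or a data frame with
#'   columns `sequence` and `sample_id` (e.g. from [generate_reads()]); with
#'   a data frame, counts are returned per sample.
#' @param gene_seqs named character vector (or `DNAStringSet`) of gene models.
#' @param k alignment word length (default 100).
#' @param strand_mode `"both"` (default; unstranded libraries) or `"forward"`.
#' @param multimap how reads matching several genes are counted: `"all"`
#'   (default; once per matching gene), `"unique"` (discarded), or
#'   `"fractional"` (1/m to each of m genes).
#' @return a `count_table`: numeric matrix, genes x samples (a single column
#'   `reads` for a plain read vector), with attribute `skipped` tallying
#'   reads shorter than `k` and reads with non-ACGT characters.
#' @examples
#' genes <- c(g1 = strrep("ACGT", 50))
#' count_exact_alignments(substr(genes[["g1"]], 1, 100), genes, k = 100)
#' @export
count_exact_alignments <- function(reads, gene_seqs, k = 100L,
                                   strand_mode = c("both", "forward"),
                                   multimap = c("all", "unique", "fractional")) {
  strand_mode <- match.arg(strand_mode)
  multimap <- match.arg(multimap)
  if (methods::is(gene_seqs, "DNAStringSet")) gene_seqs <- as.character(gene_seqs)
  if (length(gene_seqs) == 0L) stop("empty reference")
  if (is.null(names(gene_seqs))) stop("`gene_seqs` must be named")

  if (is.data.frame(reads)) {
    seqs <- reads$sequence
    samples <- reads$sample_id
  } else {
    seqs <- as.character(reads)
    samples <- rep("reads", length(seqs))
  }
  sample_levels <- unique(samples)

  # reference index: unique (k-mer, gene) pairs over all windows
  index_windows <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }
  pair_kmer <- list(); pair_gene <- list()
  for (g in names(gene_seqs)) {
    w <- index_windows(gene_seqs[[g]])
    if (strand_mode == "both")
      w <- c(w, index_windows(revcomp_dna(gene_seqs[[g]])))
    w <- unique(w)
    pair_kmer[[g]] <- w
    pair_gene[[g]] <- rep(g, length(w))
  }
  kmer <- unlist(pair_kmer, use.names = FALSE)
  gene <- unlist(pair_gene, use.names = FALSE)
  gene_by_kmer <- split(gene, kmer)

  too_short <- nchar(seqs) < k
  query <- substr(seqs, 1L, k)
  bad_char <- !too_short & grepl("[^ACGT]", query)
  keep <- !too_short & !bad_char

  genes <- names(gene_seqs)
  counts <- matrix(0, length(genes), length(sample_levels),
                   dimnames = list(genes, sample_levels))
  if (any(keep)) {
    hit <- gene_by_kmer[match(query[keep], names(gene_by_kmer))]
    n_hit <- lengths(hit)              # 0 for reads matching nowhere
    read_sample <- samples[keep]
    expanded_gene <- unlist(hit, use.names = FALSE)
    expanded_sample <- rep(read_sample, n_hit)
    weight <- switch(multimap,
      all = rep(1, sum(n_hit)),
      unique = rep(1, sum(n_hit)) * rep(as.numeric(n_hit == 1L), n_hit),
      fractional = rep(1 / pmax(n_hit, 1L), n_hit))
    if (length(expanded_gene)) {
      tab <- tapply(weight,
                    list(factor(expanded_gene, levels = genes),
                         factor(expanded_sample, levels = sample_levels)),
                    sum)
      tab[is.na(tab)] <- 0
      counts[] <- tab
    }
  }
  structure(counts,
            skipped = c(short = sum(too_short), non_acgt = sum(bad_char)),
            class = c("count_table", "matrix", "array"))
}

# reverse complement without requiring a valid DNAString (plain chartr)
revcomp_dna <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

#' Apply the minimum-alignment-count acceptance filter
#'
#' RNA quantities are accepted only where a gene has at least `min_count`
#' alignment counts in a sample; rejected entries become `NA` (not
#' quantified) rather than zero, and the filter is applied per sample.
#'
#' @param counts a `count_table` from [count_exact_alignments()].
#' @param min_count minimum accepted count (default 2).
#' @return the count table with sub-threshold entries set to `NA`.
#' @export
rna_accept_filter <- function(counts, min_count = 2L) {
  counts[counts < min_count] <- NA
  counts
}

#' Convert accepted alignment counts to a log2 abundance matrix
#'
#' No pseudo-count is used: log2 is only ever applied to accepted counts
#' (>= the acceptance minimum), so log2(0) cannot occur; `NA` stays `NA`.
#'
#' @param counts filtered `count_table`; column names must be
#'   `layer:state:replicate` sample ids (as emitted by [generate_reads()]),
#'   unless `samples` is given.
#' @param samples optional sample sheet (`state`, `replicate` per column).
#' @param layer layer label when `samples` is given.
#' @return an [abundance_matrix()].
#' @export
counts_to_log2 <- function(counts, samples = NULL, layer = "rna") {
  m <- log2(unclass(counts))
  if (is.null(samples)) {
    parts <- strsplit(colnames(counts), ":", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("column names are not layer:state:replicate; supply `samples`")
    layer <- unique(vapply(parts, `[`, "", 1L))
    samples <- data.frame(state = vapply(parts, `[`, "", 2L),
                          replicate = as.integer(vapply(parts, `[`, "", 3L)))
  }
  abundance_matrix(m, samples, layer)
}

#' Roll peptide evidence up to protein log2 TIC abundances
#'
#' Protein abundance in a sample is the log2 of the summed total ion counts
#' (TIC) of its member peptides that pass the identification credibility
#' filter `log(e) < loge_max`. A protein is accepted in a state only if at
#' least `min_peptides` passing peptides are observed in *both* biological
#' replicates of that state; otherwise it is not quantified (`NA`) in that
#' state.
#'
#' @param evidence data frame with columns `peptide_seq`, `gene_id`,
#'   `sample_id`, `loge` (log10 expectation value), `tic` (>= 0).
#' @param replicate_map data frame mapping each `sample_id` to `state` and
#'   `replicate`.
#' @param loge_max credibility threshold; peptides must satisfy
#'   `loge < loge_max` strictly (default -1.5).
#' @param min_peptides minimum passing peptides per replicate (default 2).
#' @return an [abundance_matrix()] with layer `"protein"` over all genes in
#'   `evidence` and all samples in `replicate_map`.
#' @export
protein_rollup <- function(evidence, replicate_map, loge_max = -1.5,
                           min_peptides = 2L) {
  stopifnot(all(c("peptide_seq", "gene_id", "sample_id", "loge", "tic") %in%
                  names(evidence)))
  if (any(evidence$tic < 0)) stop("negative TIC in evidence")
  unmapped <- setdiff(unique(evidence$sample_id), replicate_map$sample_id)
  if (length(unmapped))
    stop("sample_id(s) not in replicate_map: ", paste(unmapped, collapse = ", "))

  genes <- sort(unique(evidence$gene_id))
  ord <- order(replicate_map$state, replicate_map$replicate)
  rmap <- replicate_map[ord, , drop = FALSE]
  pass <- evidence[evidence$loge < loge_max, , drop = FALSE]

  gf <- factor(pass$gene_id, levels = genes)
  sf <- factor(pass$sample_id, levels = rmap$sample_id)
  tic_sum <- tapply(pass$tic, list(gf, sf), sum)
  n_pep <- tapply(pass$peptide_seq, list(gf, sf),
                  function(p) length(unique(p)))
  tic_sum[is.na(tic_sum)] <- 0
  n_pep[is.na(n_pep)] <- 0

  values <- log2(tic_sum)
  values[tic_sum == 0] <- NA
  for (st in unique(rmap$state)) {
    cols <- which(rmap$state == st)
    ok <- rowSums(n_pep[, cols, drop = FALSE] >= min_peptides) == length(cols)
    values[!ok, cols] <- NA
  }
  dimnames(values) <- list(genes, NULL)
  abundance_matrix(values,
                   data.frame(state = rmap$state, replicate = rmap$replicate),
                   "protein")
}

#' Read gene models / reads from FASTA / FASTQ
#'
#' Thin wrappers over Biostrings returning plain character vectors, the
#' representation the counting engine uses.
#'
#' @param path file path.
#' @return named character vector of sequences (FASTQ names are read ids).
#' @export
read_genes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_genes_fasta
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
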