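#' Summarize differential calls by COG functional category
#'
#' Counts significantly up- and down-regulated features per COG single-letter
#' category and layer. Genes annotated with several letters contribute once
#' to each; genes without an annotation are bucketed as `"unassigned"`.
#'
#' @param calls data frame from [score_differential()] (needs `feature_id`,
#'   `layer`, `call`).
#' @param annot data frame with columns `gene_id` and `cog` (one or more
#'   single-letter categories, e.g. `"I"` or `"EI"`).
#' @return data frame `category`, `layer`, `n_up`, `n_down`, sorted by
#'   category then layer.
#' @export
cog_summary <- function(calls, annot) {
  cog <- annot$cog[match(calls$feature_id, annot$gene_id)]
  cog[is.na(cog) | cog == ""] <- "unassigned"
  letters_per <- strsplit(cog, "")
  letters_per[cog == "unassigned"] <- list("unassigned")
  idx <- rep(seq_len(nrow(calls)), lengths(letters_per))
  long <- data.frame(category = unlist(letters_per),
                     layer = calls$layer[idx],
                     call = calls$call[idx],
                     stringsAsFactors = FALSE)
  key <- unique(long[, c("category", "layer")])
  key <- key[order(key$category, key$layer), , drop = FALSE]
  key$n_up <- mapply(function(cat, lay)
    sum(long$category == cat & long$layer == lay & long$call %in% "up"),
    key$category, key$layer)
  key$n_down <- mapply(function(cat, lay)
    sum(long$category == cat & long$layer == lay & long$call %in% "down"),
    key$category, key$layer)
  rownames(key) <- NULL
  key
}

#' Pathway-style gene table with presence/absence symbols
#'
#' Emits the familiar per-pathway report: one row per gene of interest with
#' its log2 RNA and protein abundance in a reference state, the normalized
#' scores (Rnet for RNA, Pnet for protein), and the printed symbol
#' conventions -- `"-"` for not detected, `"+"` for a protein detectable
#' only under the second state, and a `"*"` marker on proteins whose
#' per-feature S/N falls below the calibrated cutoff (FDR above the
#' calibrated level).
#'
#' @param genes data frame with columns `locus_tag` (matching feature ids)
#'   and `symbol`, in the desired row order.
#' @param rna,protein [abundance_matrix()]s.
#' @param rna_scores,protein_scores data frames from [score_differential()].
#' @param reference_state state whose abundances are printed.
#' @param snr_cutoff per-feature S/N below which the `"*"` marker is set
#'   (default 2.8, the Monte-Carlo calibrated 10%-FDR cutoff).
#' @param digits decimals for printed scores (default 2); the machine TSV
#'   written by [write_pathway_table()] keeps full precision of these
#'   formatted fields as printed.
#' @return data frame `locus_tag`, `symbol`, `rna_log2`, `protein_log2`,
#'   `rnet`, `pnet`, `low_snr_marker` with symbol semantics as above.
#' @export
pathway_table <- function(genes, rna, protein, rna_scores, protein_scores,
                          reference_state, snr_cutoff = 2.8, digits = 2) {
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, digits = digits, format = "f"))
  ref_mean <- function(mat, id) {
    if (!(id %in% rownames(mat))) return(NA_real_)
    v <- mat[id, state_columns(mat, reference_state)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  score_of <- function(scores, id, col) {
    i <- match(id, scores$feature_id)
    if (is.na(i)) NA else scores[[col]][i]
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    id <- genes$locus_tag[i]
    rnet <- score_of(rna_scores, id, "Znet")
    pnet <- score_of(protein_scores, id, "Znet")
    pcall <- score_of(protein_scores, id, "call")
    psnr <- score_of(protein_scores, id, "feature_snr")
    pnet_chr <- if (!is.na(pcall) && pcall == "present_only_in_B") "+"
                else fmt(pnet)
    data.frame(locus_tag = id,
               symbol = genes$symbol[i],
               rna_log2 = fmt(ref_mean(rna, id)),
               protein_log2 = fmt(ref_mean(protein, id)),
               rnet = fmt(rnet),
               pnet = pnet_chr,
               low_snr_marker = ifelse(!is.na(psnr) & psnr < snr_cutoff, "*", ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write differential scores, COG summaries and pathway tables as TSV
#'
#' Numeric score columns are written at full precision (`NA` as `NA`), so a
#' round-trip through [read_scores_tsv()] recovers them bit-exactly.
#'
#' @param scores data frame from [score_differential()].
#' @param path output path.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- scores
  for (col in c("Z", "R_A", "R_B", "Znet", "feature_snr"))
    df[[col]] <- sprintf("%.17g", df[[col]])
  df[df == "NA"] <- NA
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("Z", "R_A", "R_B", "Znet", "feature_snr"))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname write_scores_tsv
#' @param tab data frame (e.g. from [pathway_table()] or [cog_summary()]).
#' @export
write_report_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
write_pathway_table <- function(tab, path) write_report_tsv(tab, path)

#' Render a pathway table as Markdown
#'
#' @param tab data frame from [pathway_table()].
#' @return character vector of Markdown lines.
#' @export
format_pathway_markdown <- function(tab) {
  header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(tab, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, unname(body))
}
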