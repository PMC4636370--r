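#' Construct an abundance matrix
#'
#' The central container of the pipeline: a features x samples matrix of log2
#' abundances with `NA` marking features not quantified in a sample (the "-"
#' of printed pathway tables), plus a sample sheet describing each column.
#' One matrix holds one molecular layer (`"rna"` or `"protein"`); the two
#' layers are kept in separate matrices because they are normalized as
#' separate populations downstream.
#'
#' @param values numeric matrix, features in rows, samples in columns; `NA`
#'   means not quantified. Row names are feature identifiers.
#' @param samples data frame with one row per column of `values` and columns
#'   `state` (character) and `replicate` (integer). Row order matches column
#'   order of `values`.
#' @param layer `"rna"` or `"protein"`.
#'
#' @return An object of class `abundance_matrix`: the numeric matrix with
#'   attributes `samples` (the sample sheet, including a `sample_id` column
#'   `layer:state:replicate`) and `layer`.
#' @examples
#' m <- matrix(c(10, 11, 10.2, 11.1), 1, 4,
#'             dimnames = list("g1", NULL))
#' am <- abundance_matrix(m, data.frame(state = c("A", "A", "B", "B"),
#'                                      replicate = c(1L, 2L, 1L, 2L)), "rna")
#' sample_sheet(am)
#' @export
abundance_matrix <- function(values, samples, layer = c("rna", "protein")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("feature_", seq_len(nrow(values)))
  if (!is.data.frame(samples) || nrow(samples) != ncol(values))
    stop("`samples` must be a data frame with one row per matrix column")
  if (!all(c("state", "replicate") %in% names(samples)))
    stop("`samples` needs columns `state` and `replicate`")
  samples$state <- as.character(samples$state)
  samples$replicate <- as.integer(samples$replicate)
  samples$sample_id <- paste(layer, samples$state, samples$replicate, sep = ":")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate (state, replicate) pairs in sample sheet")
  if (any(!is.finite(values) & !is.na(values)))
    stop("all present values must be finite")
  colnames(values) <- samples$sample_id
  structure(values,
            samples = samples[, c("sample_id", "state", "replicate")],
            layer = layer,
            class = c("abundance_matrix", "matrix", "array"))
}

#' @rdname abundance_matrix
#' @param x an `abundance_matrix`.
#' @export
sample_sheet <- function(x) attr(x, "samples")

#' @rdname abundance_matrix
#' @export
matrix_layer <- function(x) attr(x, "layer")

#' @export
print.abundance_matrix <- function(x, ...) {
  s <- sample_sheet(x)
  cat(sprintf("abundance_matrix [%s]: %d features x %d samples (%d quantified values)\n",
              matrix_layer(x), nrow(x), ncol(x), sum(!is.na(x))))
  cat("states:", paste(unique(s$state), collapse = ", "), "\n")
  invisible(x)
}

# columns of `x` belonging to one state, in replicate order
state_columns <- function(x, state) {
  s <- sample_sheet(x)
  idx <- which(s$state == state)
  if (length(idx) == 0L) stop("state not found in sample sheet: ", state)
  idx[order(s$replicate[idx])]
}

#' Write / read an abundance matrix as TSV
#'
#' The TSV has a `feature_id` column followed by one column per sample with
#' header `layer:state:replicate`; `NA` encodes not-quantified.
#'
#' @param x an `abundance_matrix`.
#' @param path file path.
#' @export
write_abundance_tsv <- function(x, path) {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- df$feature_id
  m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  rownames(m) <- ids
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("sample headers must be layer:state:replicate")
  layer <- unique(vapply(parts, `[`, "", 1L))
  if (length(layer) != 1L) stop("mixed layers in one matrix")
  abundance_matrix(m,
                   data.frame(state = vapply(parts, `[`, "", 2L),
                              replicate = as.integer(vapply(parts, `[`, "", 3L))),
                   layer)
}
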