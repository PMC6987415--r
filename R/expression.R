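#' Construct an expression matrix with sample metadata
#'
#' Thin container for a genes x samples matrix of non-negative abundances
#' (RSEM/FPKM scale) or pre-transformed values, with per-sample metadata
#' (cohort, time_days, subtype, condition, ...).
#'
#' @param values Numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers. No missing values.
#' @param sample_meta Optional data.frame with one row per sample.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `sample_meta`.
#' @export
expression_matrix <- function(values, sample_meta = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("expression matrix needs >= 2 genes")
  if (ncol(values) < 1L) stop("expression matrix needs >= 1 sample")
  if (is.null(rownames(values)))
    stop("expression matrix requires gene identifiers as rownames")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(values))) stop("sample identifiers must be unique")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(values),
                              stringsAsFactors = FALSE)
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != ncol(values))
      stop("sample_meta must have one row per sample")
    if (is.null(sample_meta$sample_id)) sample_meta$sample_id <- colnames(values)
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  extra <- setdiff(names(x$sample_meta), "sample_id")
  if (length(extra)) cat("  sample metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read a delimited gene x sample expression matrix
#'
#' First column holds gene identifiers, header holds sample identifiers.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param sample_meta Optional metadata data.frame (see [expression_matrix]).
#' @return An [expression_matrix].
#' @export
read_expression_matrix <- function(path, sep = "\t", sample_meta = NULL) {
  tab <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  expression_matrix(m, sample_meta = sample_meta)
}

#' Write an expression matrix as delimited text
#'
#' @param m An [expression_matrix] or plain matrix with rownames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  v <- if (inherits(m, "expression_matrix")) m$values else as.matrix(m)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_expression_values <- function(m) {
  if (inherits(m, "expression_matrix")) m$values else as.matrix(m)
}
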