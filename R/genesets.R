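#' Construct a gene set
#'
#' A gene set is a named collection of unique, non-empty gene symbols, the
#' unit that drives all enrichment scoring (E-genes, M-genes, TES_UP/DOWN,
#' phenotype sets).
#'
#' @param name Short name for the set.
#' @param genes Character vector of gene identifiers. Duplicates are removed.
#' @param description Optional free-text description (kept from GMT files).
#' @return An object of class `gene_set` with elements `name`, `genes`
#'   (unique character vector) and `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a single non-empty string")
  genes <- as.character(genes)
  if (any(!nzchar(genes)) || any(is.na(genes)))
    stop("gene identifiers must be non-empty strings (set '", name, "')")
  genes <- unique(genes)
  if (length(genes) < 1L)
    stop("gene set '", name, "' is empty")
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Construct a gene-set collection
#'
#' @param sets A list of [gene_set] objects with unique names.
#' @return An object of class `gene_set_collection`: a named list of
#'   `gene_set` objects.
#' @export
gene_set_collection <- function(sets) {
  if (!length(sets)) stop("collection must contain at least one gene set")
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  nms <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate gene set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> with", length(x), "sets\n")
  for (s in x) cat("  ", s$name, ": ", length(s$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets from a GMT or one-column-per-set file
#'
#' GMT is the standard tab-separated dialect: set name, description, then
#' one gene per field. The column dialect expects a delimited table whose
#' header row holds set names and whose columns hold genes (ragged columns
#' padded with empty strings allowed).
#'
#' @param path Path to the file.
#' @param format `"gmt"` (default) or `"columns"`.
#' @param uppercase Normalize identifiers to upper case. Off by default:
#'   silent case folding can create false overlaps between sets of mixed
#'   conventions.
#' @param sep Field separator for `format = "columns"` (default tab).
#' @return A [gene_set_collection].
#' @export
read_gene_sets <- function(path, format = c("gmt", "columns"),
                           uppercase = FALSE, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no records in GMT file: ", path)
    sets <- lapply(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L)
        stop("malformed GMT record (fewer than 3 fields): ", f[1])
      genes <- f[-(1:2)]
      genes <- genes[nzchar(genes)]
      if (!length(genes)) stop("gene set '", f[1], "' is empty")
      if (uppercase) genes <- toupper(genes)
      gene_set(f[1], genes, description = f[2])
    })
  } else {
    tab <- utils::read.delim(path, sep = sep, header = TRUE,
                             colClasses = "character", check.names = FALSE)
    if (!ncol(tab)) stop("no columns in file: ", path)
    sets <- lapply(seq_len(ncol(tab)), function(j) {
      genes <- tab[[j]]
      genes <- genes[!is.na(genes) & nzchar(genes)]
      if (!length(genes)) stop("gene set '", names(tab)[j], "' is empty")
      if (uppercase) genes <- toupper(genes)
      gene_set(names(tab)[j], genes)
    })
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A [gene_set_collection].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Overlap between two gene sets
#'
#' Used for the redundancy check between phenotype sets and the E/M
#' signature sets: a phenotype score is only informative about a distinct
#' program if well under 20% of its genes belong to the E or M lists.
#'
#' @param a,b [gene_set] objects (or character vectors of genes).
#' @return A list with `count` (|a intersect b|, symmetric), `size_a`,
#'   `size_b`, and `fraction` = count / |a| (asymmetric, relative to `a`).
#' @export
overlap_report <- function(a, b) {
  ga <- if (inherits(a, "gene_set")) a$genes else unique(as.character(a))
  gb <- if (inherits(b, "gene_set")) b$genes else unique(as.character(b))
  if (!length(ga) || !length(gb)) stop("overlap_report: empty gene set")
  cnt <- length(intersect(ga, gb))
  list(count = cnt, size_a = length(ga), size_b = length(gb),
       fraction = cnt / length(ga))
}
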