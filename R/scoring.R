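#' Parameters of the random-walk enrichment statistic
#'
#' @param tau Non-negative rank-weight exponent (default 1).
#' @param es_mode How the enrichment score is read off the walk:
#'   `"max_diff"` (default) adds the positive maximum and the negative
#'   minimum; `"max_abs"` takes the deviation of largest magnitude.
#' @param kernel Kernel for the per-gene cumulative-density estimate:
#'   `"gaussian"` (default, bandwidth sd/`bandwidth_divisor`), `"none"`
#'   (rank-only), or `"poisson"` (reserved for count data; not implemented).
#' @param bandwidth_divisor Per-gene scale divisor for the Gaussian kernel
#'   bandwidth, h_i = sd_i / bandwidth_divisor (default 4).
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(tau = 1, es_mode = c("max_diff", "max_abs"),
                        kernel = c("gaussian", "none", "poisson"),
                        bandwidth_divisor = 4) {
  es_mode <- match.arg(es_mode)
  kernel <- match.arg(kernel)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("tau must be a non-negative number")
  if (bandwidth_divisor <= 0) stop("bandwidth_divisor must be positive")
  structure(list(tau = tau, es_mode = es_mode, kernel = kernel,
                 bandwidth_divisor = bandwidth_divisor),
            class = "walk_params")
}

#' Kernel-estimated expression statistic
#'
#' For each gene i and sample j, estimates the within-gene cumulative
#' density at the observed value using all samples:
#' z_ij = (1/n) sum_k K_cdf((x_ij - x_ik) / h_i), with h_i = sd_i /
#' `bandwidth_divisor` under the Gaussian kernel. Under `kernel = "none"`
#' the statistic is the within-gene average rank scaled to (0, 1], so only
#' cross-sample orderings matter.
#'
#' @param m An [expression_matrix] or genes x samples matrix.
#' @param kernel `"gaussian"`, `"none"`, or `"poisson"` (stub).
#' @param bandwidth_divisor See [walk_params].
#' @return A genes x samples matrix of statistics. Genes with zero variance
#'   under the Gaussian kernel get the constant 0.5 (middle rank region);
#'   their count is reported via `message()`.
#' @export
expression_statistic <- function(m, kernel = c("gaussian", "none", "poisson"),
                                 bandwidth_divisor = 4) {
  kernel <- match.arg(kernel)
  x <- as_expression_values(m)
  if (kernel == "poisson")
    stop("Poisson kernel is a stub: inputs here are continuous RSEM/FPKM; ",
         "use kernel = 'gaussian' or 'none'")
  n <- ncol(x)
  if (n < 2L) stop("cohort scoring requires >=2 samples")
  z <- x
  if (kernel == "none") {
    for (i in seq_len(nrow(x)))
      z[i, ] <- rank(x[i, ], ties.method = "average") / n
    return(z)
  }
  n_flat <- 0L
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    s <- stats::sd(xi)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      z[i, ] <- 0.5
      n_flat <- n_flat + 1L
    } else {
      h <- s / bandwidth_divisor
      # outer(-xi, xi, "+")[k, j] = x_j - x_k
      z[i, ] <- colMeans(stats::pnorm(outer(-xi, xi, "+") / h))
    }
  }
  if (n_flat > 0L)
    message(n_flat, " zero-variance gene(s) set to constant statistic 0.5")
  z
}

#' Cross-gene ranking and symmetric rank statistic
#'
#' Within each sample, genes are ranked by decreasing statistic (rank 1 =
#' largest; ties broken by input gene order for determinism) and folded
#' about the middle rank: rtilde_ij = |p/2 - r_ij|, so both extremes of the
#' ranking carry large weight.
#'
#' @param z Finite genes x samples matrix (from [expression_statistic]).
#' @return A list with `rank` (p x n integer ranks), `rtilde` (p x n folded
#'   ranks), and `ordering` (p x n; column j holds the gene indices of
#'   sample j sorted by decreasing z).
#' @export
symmetric_rank <- function(z) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("symmetric_rank requires finite input")
  p <- nrow(z); n <- ncol(z)
  r <- matrix(0L, p, n, dimnames = dimnames(z))
  ord <- matrix(0L, p, n)
  for (j in seq_len(n)) {
    o <- order(-z[, j])           # stable: ties keep input gene order
    ord[, j] <- o
    r[o, j] <- seq_len(p)
  }
  list(rank = r, rtilde = abs(p / 2 - r), ordering = ord)
}

#' Kolmogorov-Smirnov random walk over a ranked gene list
#'
#' Walks down one sample's ranked genes, stepping up by the normalized
#' folded-rank weight at in-set genes and down by 1/(p - m) at out-of-set
#' genes; the enrichment score in [-1, 1] summarizes the walk's extrema.
#'
#' @param ordering Integer permutation of gene indices, decreasing statistic.
#' @param rtilde Folded ranks for this sample, indexed by gene (length p).
#' @param set_mask Logical length-p vector marking set membership (m genes,
#'   1 <= m < p).
#' @param params A [walk_params] object.
#' @return List with `es` (the score) and `walk` (nu(l), l = 1..p; ends at 0).
#' @export
random_walk_es <- function(ordering, rtilde, set_mask, params = walk_params()) {
  p <- length(ordering)
  stopifnot(length(rtilde) == p, length(set_mask) == p)
  m <- sum(set_mask)
  if (m < 1L) stop("empty gene set")
  if (m >= p) stop("gene set covers every gene: decrement undefined")
  mask_o <- set_mask[ordering]
  w <- rtilde[ordering]^params$tau
  w[!mask_o] <- 0
  S <- sum(w)
  if (S <= 0) stop("degenerate set weights: all in-set folded ranks are zero")
  nu <- cumsum(w / S - (!mask_o) / (p - m))
  es <- switch(params$es_mode,
    max_diff = max(0, max(nu)) + min(0, min(nu)),
    max_abs  = nu[which.max(abs(nu))])
  list(es = es, walk = nu)
}

#' Score every sample against every gene set
#'
#' The full single-sample enrichment pipeline: kernel-estimated expression
#' statistic, cross-sample ranking, symmetric rank weights, and the KS
#' random walk per (sample, set). Scores are cohort-relative: adding or
#' removing samples changes the statistic of every sample.
#'
#' @param m An [expression_matrix] or genes x samples matrix.
#' @param sets A [gene_set_collection] (or named list of character vectors).
#' @param params A [walk_params] object.
#' @param log_transform Apply log2(x + 1) first. Use `TRUE` (default) for
#'   linear-scale abundances (RSEM/FPKM); set `FALSE` for pre-transformed
#'   input.
#' @param min_matched Minimum genes a set must match in the matrix (default
#'   2); sets below it raise an error naming the set.
#' @return A `score_table`: data.frame with `sample_id` and one column per
#'   set, values in [-1, 1]. Attribute `provenance` records each set's
#'   declared and effective (matched) size.
#' @export
score_matrix <- function(m, sets, params = walk_params(),
                         log_transform = TRUE, min_matched = 2L) {
  x <- as_expression_values(m)
  if (log_transform) {
    if (any(x < 0))
      stop("negative values with log_transform = TRUE; ",
           "set log_transform = FALSE for pre-transformed input")
    x <- log2(x + 1)
  }
  if (inherits(sets, "gene_set")) sets <- gene_set_collection(list(sets))
  if (!inherits(sets, "gene_set_collection")) {
    if (is.null(names(sets))) stop("gene sets must be named")
    sets <- gene_set_collection(mapply(gene_set, names(sets), sets,
                                       SIMPLIFY = FALSE))
  }
  p <- nrow(x); n <- ncol(x)
  genes <- rownames(x)
  masks <- list(); prov <- list()
  for (s in sets) {
    matched <- s$genes %in% genes
    eff <- sum(matched)
    if (eff < min_matched)
      stop("gene set '", s$name, "' matches ", eff,
           " gene(s) in the matrix (need >= ", min_matched, ")")
    if (eff < length(s$genes))
      message("set '", s$name, "': dropped ", length(s$genes) - eff,
              " gene(s) absent from the matrix")
    masks[[s$name]] <- genes %in% s$genes
    prov[[s$name]] <- data.frame(set = s$name, size = length(s$genes),
                                 effective_size = eff)
  }
  z <- expression_statistic(x, kernel = params$kernel,
                            bandwidth_divisor = params$bandwidth_divisor)
  sr <- symmetric_rank(z)
  scores <- matrix(NA_real_, n, length(masks),
                   dimnames = list(colnames(x), names(masks)))
  for (j in seq_len(n)) {
    ord <- sr$ordering[, j]
    rt <- sr$rtilde[, j]
    for (k in seq_along(masks))
      scores[j, k] <- random_walk_es(ord, rt, masks[[k]], params)$es
  }
  out <- data.frame(sample_id = colnames(x), scores,
                    check.names = FALSE, row.names = NULL)
  attr(out, "provenance") <- do.call(rbind, prov)
  class(out) <- c("score_table", class(out))
  out
}

#' Extract the score columns of a score table as a matrix
#'
#' @param scores A `score_table` (or data.frame with `sample_id`).
#' @param columns Optional score column names to keep, in order.
#' @return Numeric matrix, samples x scores, rownames = sample ids.
#' @export
score_values <- function(scores, columns = NULL) {
  df <- as.data.frame(scores)
  keep <- setdiff(names(df), "sample_id")
  if (!is.null(columns)) {
    missing <- setdiff(columns, keep)
    if (length(missing))
      stop("score column(s) not found: ", paste(missing, collapse = ", "))
    keep <- columns
  }
  v <- as.matrix(df[, keep, drop = FALSE])
  rownames(v) <- if ("sample_id" %in% names(df)) df$sample_id else rownames(df)
  v
}

#' Write / read a score table as delimited text
#'
#' @param scores A `score_table`.
#' @param path File path.
#' @param sep Field separator.
#' @return `path` invisibly (write); a `score_table` (read).
#' @export
write_score_table <- function(scores, path, sep = "\t") {
  utils::write.table(as.data.frame(scores), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path, sep = "\t") {
  out <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  class(out) <- c("score_table", class(out))
  out
}
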