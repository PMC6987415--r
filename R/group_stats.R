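#' Welch's t-test between two groups
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom and a confidence interval for the mean difference.
#'
#' @param a,b Numeric vectors (each >= 2 values; at least one group with
#'   positive variance).
#' @param conf_level Confidence level (default 0.95).
#' @return `group_comparison`: list with `t`, `df`, `p`, `mean_diff`,
#'   `ci_low`, `ci_high`, `n_a`, `n_b`.
#' @export
welch_test <- function(a, b, conf_level = 0.95) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_test needs >= 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate comparison: both groups have zero variance")
  ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(diff(rev(ht$estimate))),
                 ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
                 conf_level = conf_level,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> t = ", signif(x$t, 4), ", df = ", signif(x$df, 4),
      ", p = ", format(x$p, digits = 3), "\n  diff = ",
      signif(x$mean_diff, 4), " [", signif(x$ci_low, 4), ", ",
      signif(x$ci_high, 4), "] (", x$conf_level * 100, "%)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction; input order preserved, values
#' capped at 1.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Chi-squared enrichment of categories across clusters
#'
#' Tests the observed cluster x category table against a null in which
#' each cluster draws categories from the background distribution
#' (expected count = n_cluster * n_category / N). No continuity
#' correction. A low-count flag is raised when any expected cell drops
#' below 5 (the test's distributional assumption).
#'
#' @param cluster_labels,category_labels Equal-length vectors.
#' @return List with `statistic`, `df`, `p`, `observed`, `expected`,
#'   `low_count` (logical flag).
#' @export
enrichment_chi2 <- function(cluster_labels, category_labels) {
  stopifnot(length(cluster_labels) == length(category_labels))
  keep <- !is.na(cluster_labels) & !is.na(category_labels)
  tab <- table(cluster = cluster_labels[keep],
               category = category_labels[keep])
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("excluding empty cluster(s): ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2L) stop("need >= 2 non-empty clusters")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, observed = ht$observed, expected = ht$expected,
       low_count = any(ht$expected < 5))
}

#' Cluster-wise comparisons of scores or gene expression
#'
#' One Welch test per (variable, cluster pair), with Benjamini-Hochberg
#' adjustment applied across the whole table (one analysis = one BH
#' family; scope is controlled by what is passed in a single call).
#'
#' @param values Samples x variables matrix or data.frame (e.g., score
#'   columns, or expression of selected genes), or a `score_table`.
#' @param assignment `cluster_assignment` (semantic labels used when
#'   present) or a vector of per-sample group labels.
#' @param pairs Optional list of length-2 character vectors naming the
#'   cluster pairs to compare (default: all pairs).
#' @param conf_level Confidence level for difference CIs.
#' @return Data.frame with columns `variable`, `group1`, `group2`, `t`,
#'   `df`, `p`, `p_adj`, `ci_low`, `ci_high` (one row per variable x pair;
#'   rows whose test fails carry NA and a reason in `note`).
#' @export
compare_all <- function(values, assignment, pairs = NULL,
                        conf_level = 0.95) {
  if (inherits(values, "score_table")) values <- score_values(values)
  values <- as.matrix(as.data.frame(values))
  lab <- if (inherits(assignment, "cluster_assignment")) {
    if (!is.null(assignment$semantic_labels)) assignment$semantic_labels
    else as.character(assignment$labels)
  } else as.character(assignment)
  if (length(lab) != nrow(values))
    stop("assignment does not cover the samples")
  groups <- sort(unique(lab))
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  rows <- list()
  for (v in colnames(values)) for (pr in pairs) {
    res <- tryCatch(
      welch_test(values[lab == pr[1], v], values[lab == pr[2], v],
                 conf_level = conf_level),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group1 = pr[1], group2 = pr[2], t = NA_real_,
        df = NA_real_, p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        note = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group1 = pr[1], group2 = pr[2], t = res$t,
        df = res$df, p = res$p, ci_low = res$ci_low, ci_high = res$ci_high,
        note = "")
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out[, c("variable", "group1", "group2", "t", "df", "p", "p_adj",
          "ci_low", "ci_high", "note")]
}
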