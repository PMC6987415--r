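#' Quadrant census of samples in E-M score space
#'
#' Quadrants correspond to the four canonical corners of the EMT spectrum:
#' terminal epithelial (high-E-low-M), terminal mesenchymal (low-E-high-M),
#' hybrid intermediate (high-E-high-M) and characterless intermediate
#' (low-E-low-M). A score of exactly 0 counts as "low" (closed-left
#' boundary convention).
#'
#' @param scores A `score_table` (or data.frame) with `E` and `M` columns.
#' @return `quadrant_census`: data.frame with quadrant, count, fraction;
#'   counts sum to n, fractions to 1.
#' @export
quadrant_census <- function(scores) {
  v <- score_values(scores, c("E", "M"))
  hiE <- v[, "E"] > 0; hiM <- v[, "M"] > 0
  quad <- ifelse(hiE & hiM, "highE_highM",
          ifelse(hiE & !hiM, "highE_lowM",
          ifelse(!hiE & hiM, "lowE_highM", "lowE_lowM")))
  lev <- c("highE_highM", "highE_lowM", "lowE_highM", "lowE_lowM")
  counts <- as.integer(table(factor(quad, levels = lev)))
  out <- data.frame(quadrant = lev, count = counts,
                    fraction = counts / nrow(v))
  class(out) <- c("quadrant_census", class(out))
  out
}

#' Rotate E-M scores to progression/deviation coordinates
#'
#' Projects each (E, M) pair onto the line through the origin with slope -1
#' (the hypothetical linear EMT axis) and its orthogonal. `u = (E - M) /
#' sqrt(2)` is the EMT progression, positive toward the epithelial pole;
#' `v = (E + M) / sqrt(2)` is the deviation, positive toward the hybrid
#' high-E-high-M corner. The rotation is an isometry.
#'
#' @param E,M Numeric vectors of scores, or `E` a `score_table` with both
#'   columns (then `M` is ignored).
#' @return Data.frame with columns `u` and `v`.
#' @export
rotate_coordinates <- function(E, M = NULL) {
  if (is.null(M)) {
    v <- score_values(E, c("E", "M"))
    E <- v[, "E"]; M <- v[, "M"]
  }
  if (!all(is.finite(E)) || !all(is.finite(M)))
    stop("rotate_coordinates requires finite scores")
  data.frame(u = (E - M) / sqrt(2), v = (E + M) / sqrt(2))
}

# relative neighborhood graph / symmetrized kNN adjacency on cluster means
cluster_adjacency <- function(means, method = c("rng", "knn"), k = 2L) {
  method <- match.arg(method)
  K <- nrow(means)
  D <- as.matrix(stats::dist(means))
  A <- matrix(FALSE, K, K)
  if (method == "knn") {
    for (i in seq_len(K)) {
      nn <- order(D[i, -i])[seq_len(min(k, K - 1L))]
      A[i, setdiff(seq_len(K), i)[nn]] <- TRUE
    }
    A <- A | t(A)
  } else {
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
      others <- setdiff(seq_len(K), c(i, j))
      blocked <- length(others) &&
        any(pmax(D[i, others], D[j, others]) < D[i, j])
      A[i, j] <- A[j, i] <- !blocked
    }
  }
  A
}

#' Enumerate minimal EMT cluster paths
#'
#' Builds an adjacency graph on the mixture-component means and returns
#' every shortest path from the epithelial pole to the mesenchymal pole
#' (breadth-first search; loops and backtracking excluded). Adjacency
#' defaults to the relative neighborhood graph of the means, which links
#' clusters with no third cluster sitting between them; a symmetrized
#' k-nearest-neighbor graph is available via `method = "knn"`.
#'
#' @param model An `emt_gmm` with K in \{4, 5\} on (E, M) scores.
#' @param method `"rng"` (default) or `"knn"`.
#' @param k Neighbor count for `method = "knn"`.
#' @return List of character vectors (semantic label sequences, E first,
#'   M last, all of equal length).
#' @export
enumerate_min_paths <- function(model, method = c("rng", "knn"), k = 2L) {
  sem <- label_semantic(model)
  A <- cluster_adjacency(model$means, method = method, k = k)
  s <- which(sem == "E"); t <- which(sem == "M")
  # BFS layering from s
  dist <- rep(Inf, model$K); dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] & dist == Inf)
      dist[nb] <- dist[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t]))
    stop("E and M poles are disconnected in the cluster graph; ",
         "try method = 'knn' with a larger k")
  # collect all shortest paths by backward walk over BFS layers
  paths <- list(t)
  for (step in seq_len(dist[t])) {
    paths <- do.call(c, lapply(paths, function(p) {
      preds <- which(A[p[1], ] & dist == dist[p[1]] - 1)
      lapply(preds, function(q) c(q, p))
    }))
  }
  lapply(paths, function(p) unname(sem[p]))
}

#' Fit a segmented EMT path model in rotated coordinates
#'
#' Restricts the cohort to the samples assigned to the clusters of one
#' enumerated path, rotates their (E, M) scores to progression/deviation
#' coordinates, and fits deviation ~ progression by segmented regression
#' with the breakpoint count chosen by adjusted R-squared. The same model
#' fitted on all samples is attached for comparison, as are the Davies and
#' pseudo-score breakpoint-existence tests.
#'
#' @param scores `score_table` with `E` and `M` columns.
#' @param assignment A `cluster_assignment` with semantic labels (or a
#'   character vector of per-sample semantic labels).
#' @param path Character vector of semantic labels, E first, M last.
#' @param max_breaks Passed to [select_n_breakpoints] (default 4).
#' @param min_samples Minimum samples on the path (default 20).
#' @return `emt_path`: `cluster_sequence`, `member_samples`, `fit`
#'   (`segmented_fit` for the path), `selection` (full comparison table),
#'   `reference_fit` (all-sample fit), `davies_p`, `pseudo_score_p`.
#' @export
fit_emt_path <- function(scores, assignment, path, max_breaks = 4L,
                         min_samples = 20L) {
  lab <- if (inherits(assignment, "cluster_assignment"))
    assignment$semantic_labels else as.character(assignment)
  if (is.null(lab)) stop("assignment carries no semantic labels")
  v <- score_values(scores, c("E", "M"))
  if (length(lab) != nrow(v))
    stop("assignment and score table cover different samples")
  if (path[1] != "E" || path[length(path)] != "M")
    stop("path must start at E and end at M")
  member <- lab %in% path
  if (sum(member) < min_samples)
    stop("only ", sum(member), " samples on path; need >= ", min_samples)
  uv <- rotate_coordinates(v[member, "E"], v[member, "M"])
  sel <- select_n_breakpoints(uv$u, uv$v, max_breaks = max_breaks)
  uv_all <- rotate_coordinates(v[, "E"], v[, "M"])
  sel_all <- select_n_breakpoints(uv_all$u, uv_all$v, max_breaks = max_breaks)
  structure(list(
    cluster_sequence = path,
    member_samples = rownames(v)[member] %||% which(member),
    n_members = sum(member),
    fit = sel$best_fit, selection = sel,
    reference_fit = sel_all$best_fit,
    davies_p = davies_test(uv$u, uv$v)$p.value,
    pseudo_score_p = pseudo_score_test(uv$u, uv$v)$p.value),
    class = "emt_path")
}

#' @export
print.emt_path <- function(x, ...) {
  cat("<emt_path> ", paste(x$cluster_sequence, collapse = "-"), ": ",
      x$n_members, " samples\n", sep = "")
  cat("  path fit adjusted R2: ", signif(x$fit$adjusted_r2, 4),
      " (all samples: ", signif(x$reference_fit$adjusted_r2, 4), ")\n",
      sep = "")
  cat("  Davies p = ", format(x$davies_p, digits = 3),
      ", pseudo-score p = ", format(x$pseudo_score_p, digits = 3), "\n",
      sep = "")
  invisible(x)
}
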