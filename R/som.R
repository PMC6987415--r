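## Batch self-organizing map on a rectangular grid, used for semi-supervised
## subclustering of E- and M-genes from combinatorial perturbation profiles.

som_grid_coords <- function(shape) {
  as.matrix(expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2])))
}

#' Train a batch self-organizing map on gene profiles
#'
#' Genes are standardized per-gene (z-score across conditions) and tiled
#' onto a rectangular grid of prototype vectors. Training is batch: each
#' epoch assigns every gene to its best-matching unit (BMU) and replaces
#' each codebook by the neighborhood-weighted mean of the genes, with a
#' Gaussian neighborhood whose radius decays linearly from half the grid
#' width to 0.5 over the epochs. Deterministic under a fixed seed (the seed
#' controls the random data-point initialization of the codebooks).
#'
#' @param profiles Genes x conditions numeric matrix (rownames = genes);
#'   >= 2 conditions required.
#' @param shape Grid shape, default `c(10, 10)`.
#' @param epochs Training epochs (default 100).
#' @param seed Seed for codebook initialization (default 1).
#' @param standardize Per-gene z-scoring (default TRUE); constant-profile
#'   genes raise an error listing them.
#' @return `som_grid`: `codebooks` (nodes x conditions), `bmu` (gene ->
#'   node index), `grid` (node coordinates), `shape`, `qe` (per-epoch mean
#'   quantization error), `params`.
#' @export
train_som <- function(profiles, shape = c(10L, 10L), epochs = 100L,
                      seed = 1L, standardize = TRUE) {
  X <- as.matrix(profiles)
  if (ncol(X) < 2L) stop("SOM training requires >= 2 conditions")
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (standardize) {
    sds <- apply(X, 1, stats::sd)
    flat <- sds < .Machine$double.eps^0.5
    if (any(flat))
      stop("constant-profile gene(s) cannot be standardized: ",
           paste(utils::head(rownames(X)[flat], 10), collapse = ", "),
           if (sum(flat) > 10) " ...")
    X <- (X - rowMeans(X)) / sds
  }
  grid <- som_grid_coords(shape)
  n_nodes <- nrow(grid)
  Dgrid2 <- as.matrix(stats::dist(grid))^2
  set.seed(seed)
  init_idx <- sample.int(nrow(X), n_nodes, replace = nrow(X) < n_nodes)
  codebooks <- X[init_idx, , drop = FALSE] +
    matrix(stats::rnorm(n_nodes * ncol(X), sd = 1e-4), n_nodes)
  rownames(codebooks) <- NULL
  r0 <- max(shape) / 2; r1 <- 0.5
  qe <- numeric(epochs)
  x2 <- rowSums(X^2)
  bmu <- integer(nrow(X))
  for (ep in seq_len(epochs)) {
    # squared distances genes x nodes
    D <- outer(x2, rowSums(codebooks^2), "+") - 2 * X %*% t(codebooks)
    bmu <- max.col(-D, ties.method = "first")
    qe[ep] <- mean(sqrt(pmax(D[cbind(seq_len(nrow(X)), bmu)], 0)))
    r <- r0 + (r1 - r0) * (ep - 1) / max(1, epochs - 1)
    H <- exp(-Dgrid2 / (2 * r^2))        # nodes x nodes
    Wg <- H[bmu, , drop = FALSE]         # genes x nodes
    denom <- colSums(Wg)
    num <- t(Wg) %*% X
    upd <- denom > .Machine$double.eps
    codebooks[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  structure(list(codebooks = codebooks, bmu = stats::setNames(bmu, rownames(X)),
                 grid = grid, shape = shape, qe = qe,
                 params = list(epochs = epochs, seed = seed,
                               radius = c(r0, r1),
                               standardize = standardize)),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$shape[1], "x", x$shape[2], " grid, ",
      length(x$bmu), " genes, final quantization error ",
      signif(x$qe[length(x$qe)], 4), "\n", sep = "")
  invisible(x)
}

#' Classify SOM nodes by annotated E/M gene membership
#'
#' Counts the annotated E- and M-genes mapped to each node and labels the
#' node by majority (the supervised, nearest-neighbor step). Ties are
#' resolved by the majority label among the node's grid neighbors, then
#' toward the class holding more labeled nodes overall. Nodes with no
#' annotated genes inherit the label of the nearest labeled node in grid
#' distance.
#'
#' @param grid A `som_grid`.
#' @param e_set,m_set [gene_set]s (or character vectors) of annotated E-
#'   and M-genes.
#' @return Data.frame, one row per node: `node`, `e_count`, `m_count`,
#'   `label` ("E"/"M"), `ratio` (majority count over annotated count, NA
#'   for annotation-free nodes), `imputed`.
#' @export
classify_nodes <- function(grid, e_set, m_set) {
  stopifnot(inherits(grid, "som_grid"))
  eg <- if (inherits(e_set, "gene_set")) e_set$genes else as.character(e_set)
  mg <- if (inherits(m_set, "gene_set")) m_set$genes else as.character(m_set)
  genes <- names(grid$bmu)
  if (!any(genes %in% c(eg, mg)))
    stop("no annotated E/M genes map to the grid")
  n_nodes <- nrow(grid$grid)
  e_count <- tabulate(grid$bmu[genes %in% eg], n_nodes)
  m_count <- tabulate(grid$bmu[genes %in% mg], n_nodes)
  label <- rep(NA_character_, n_nodes)
  label[e_count > m_count] <- "E"
  label[m_count > e_count] <- "M"
  tied <- e_count == m_count & (e_count + m_count) > 0
  Dg <- as.matrix(stats::dist(grid$grid))
  if (any(tied)) {
    for (nd in which(tied)) {
      nb <- which(Dg[nd, ] > 0 & Dg[nd, ] < 1.8)   # queen neighborhood
      votes <- table(factor(label[nb], levels = c("E", "M")))
      label[nd] <- if (votes["E"] > votes["M"]) "E"
        else if (votes["M"] > votes["E"]) "M"
        else if (sum(label == "E", na.rm = TRUE) >=
                 sum(label == "M", na.rm = TRUE)) "E" else "M"
    }
  }
  empty <- which(is.na(label))
  labeled <- which(!is.na(label))
  imputed <- rep(FALSE, n_nodes)
  for (nd in empty) {
    d <- Dg[nd, labeled]
    near <- labeled[d == min(d)]
    votes <- table(factor(label[near], levels = c("E", "M")))
    label[nd] <- if (votes["E"] > votes["M"]) "E"
      else if (votes["M"] > votes["E"]) "M"
      else if (sum(label[labeled] == "E") >=
               sum(label[labeled] == "M")) "E" else "M"
    imputed[nd] <- TRUE
  }
  annotated <- e_count + m_count
  ratio <- ifelse(annotated > 0,
                  pmax(e_count, m_count) / annotated, NA_real_)
  data.frame(node = seq_len(n_nodes), e_count = e_count, m_count = m_count,
             label = label, ratio = ratio, imputed = imputed)
}

#' Subcluster the nodes of one class by hierarchical clustering
#'
#' Ward clustering of the class's node codebooks; the cluster count is
#' chosen by the elbow criterion on within-cluster sum of squares (largest
#' second difference of WSS over k = 1..`k_max`; ties favor smaller k).
#' Genes inherit the subcluster of their best-matching node.
#'
#' @param grid A `som_grid`.
#' @param node_labels Data.frame from [classify_nodes].
#' @param class `"E"` or `"M"`.
#' @param k_max Largest candidate subcluster count (default 8).
#' @param k Optional fixed subcluster count (skips elbow selection).
#' @return List of `gene_subcluster`s: each with `name` (E1..Ek / M1..Mk),
#'   `class`, `nodes`, `genes`; plus attributes `wss` and `k`.
#' @export
subcluster_nodes <- function(grid, node_labels, class = c("E", "M"),
                             k_max = 8L, k = NULL) {
  class <- match.arg(class)
  nodes <- node_labels$node[node_labels$label == class]
  if (length(nodes) < 2L) {
    warning("class ", class, " has ", length(nodes),
            " node(s); returning a single trivial subcluster")
    k <- 1L
  }
  cb <- grid$codebooks[nodes, , drop = FALSE]
  k_max <- min(k_max, length(nodes))
  wss_of <- function(cl) {
    sum(vapply(split(seq_along(cl), cl), function(ix) {
      ctr <- colMeans(cb[ix, , drop = FALSE])
      sum(sweep(cb[ix, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
  }
  hc <- if (length(nodes) > 1L)
    stats::hclust(stats::dist(cb), method = "ward.D2") else NULL
  wss <- vapply(seq_len(max(k_max, 1L)), function(kk) {
    if (kk == 1L || is.null(hc)) wss_of(rep(1L, length(nodes)))
    else wss_of(cutree(hc, k = kk))
  }, numeric(1))
  if (is.null(k)) {
    if (wss[1] < 1e-12 || k_max < 3L) {
      k <- 1L
    } else {
      # elbow on the log scale: the raw second difference is dominated by
      # the first split whenever WSS(1) is large, missing true k > 2
      lw <- log(pmax(wss, 1e-12))
      kk <- 2:(k_max - 1L)
      d2 <- lw[kk - 1L] - 2 * lw[kk] + lw[kk + 1L]
      k <- kk[which.max(d2)]          # which.max: first max, smaller k wins
    }
  }
  cl <- if (k == 1L || is.null(hc)) rep(1L, length(nodes)) else cutree(hc, k)
  genes_by_node <- split(names(grid$bmu), grid$bmu)
  out <- lapply(seq_len(k), function(i) {
    nd <- nodes[cl == i]
    structure(list(name = paste0(class, i), class = class, nodes = nd,
                   genes = unlist(genes_by_node[as.character(nd)],
                                  use.names = FALSE)),
              class = "gene_subcluster")
  })
  # node groups holding no genes (empty nodes only) carry no members
  out <- Filter(function(s) length(s$genes) > 0, out)
  # stable naming: order subclusters by their mean first-condition response
  ord <- order(vapply(out, function(s)
    mean(grid$codebooks[s$nodes, 1, drop = TRUE]), numeric(1)),
    decreasing = TRUE)
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$name <- paste0(class, i)
  attr(out, "wss") <- wss
  attr(out, "k") <- k
  out
}

#' @export
print.gene_subcluster <- function(x, ...) {
  cat("<gene_subcluster> ", x$name, ": ", length(x$nodes), " nodes, ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Score subclusters over a time-course (or any) expression matrix
#'
#' Turns each subcluster's member genes into a gene set and delegates to
#' [score_matrix], giving one enrichment score per subcluster per sample.
#'
#' @param m An [expression_matrix] (e.g., the TGF-beta induction course).
#' @param subclusters List of `gene_subcluster`s (output of
#'   [subcluster_nodes]; E and M lists may be concatenated).
#' @param ... Passed to [score_matrix].
#' @return A `score_table` with one column per subcluster.
#' @export
score_subclusters <- function(m, subclusters, ...) {
  sets <- gene_set_collection(lapply(subclusters, function(s)
    gene_set(s$name, s$genes)))
  score_matrix(m, sets, ...)
}

#' Membership table of gene subclusters
#'
#' @param subclusters List of `gene_subcluster`s.
#' @return Data.frame with columns `gene`, `class`, `subcluster`.
#' @export
subcluster_table <- function(subclusters) {
  do.call(rbind, lapply(subclusters, function(s)
    data.frame(gene = s$genes, class = s$class, subcluster = s$name)))
}
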