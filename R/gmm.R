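## Diagonal-family Gaussian mixtures for (E, M) score space.
##
## Structures follow the standard volume/shape nomenclature for the
## axis-aligned family: E/V = equal/varying across components, I = identity
## orientation. EII: shared spherical; VII: per-component spherical; EEI:
## shared diagonal; VEI: varying volume, equal shape; EVI: equal volume,
## varying shape; VVI: fully free diagonal.

DIAGONAL_STRUCTURES <- c("EII", "VII", "EEI", "VEI", "EVI", "VVI")

gmm_cov_params <- function(structure, K, d) {
  switch(structure,
    EII = 1, VII = K, EEI = d, VEI = K + (d - 1), EVI = 1 + K * (d - 1),
    VVI = K * d,
    stop("unknown covariance structure: ", structure))
}

# log pi_k + log N(x_i; mu_k, diag(v_k)), computed as three matrix products
gmm_log_component_dens <- function(x, means, variances, weights, x2 = x^2) {
  A <- 1 / (2 * variances)                       # K x d
  const <- log(weights) - 0.5 * rowSums(log(2 * pi * variances)) -
    rowSums(A * means^2)
  x %*% t(2 * A * means) - x2 %*% t(A) + rep(const, each = nrow(x))
}

gmm_posterior <- function(L) {
  n <- nrow(L)
  mx <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
  P <- exp(L - mx)
  rs <- rowSums(P)
  list(post = P / rs, loglik = sum(log(rs) + mx))
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' @param points Numeric n x d matrix (typically n x 2 of E and M scores),
#'   or a `score_table` with `E` and `M` columns.
#' @param K Number of components (n >= 5 K required).
#' @param structure One of `"EII"`, `"VII"`, `"EEI"`, `"VEI"`, `"EVI"`,
#'   `"VVI"` (see Details in [select_model]).
#' @param init `"hclust"` (default): deterministic Ward agglomerative
#'   partition cut at K, then EM; or `"kmeans"` (k-means++-style restart
#'   fallback, seeded).
#' @param init_labels Optional integer vector of starting hard assignments
#'   (overrides `init`).
#' @param seed Seed for the k-means fallback/restarts.
#' @param max_iter,tol EM stops when the relative log-likelihood change
#'   drops below `tol` (default 1e-8) or after `max_iter` (500) iterations.
#' @param max_restarts Restarts allowed when a component collapses
#'   (variance < 1e-12) before erroring.
#' @return An object of class `emt_gmm`: weights, means (K x d), diagonal
#'   `variances` (K x d), `loglik`, `loglik_trace`, `npar`, `bic`
#'   (-2 loglik + npar log n; lower is better), `converged`.
#' @export
fit_gmm <- function(points, K, structure = "EII", init = c("hclust", "kmeans"),
                    init_labels = NULL, seed = NULL, max_iter = 500L,
                    tol = 1e-8, max_restarts = 3L) {
  init <- match.arg(init)
  structure <- match.arg(structure, DIAGONAL_STRUCTURES)
  x <- if (inherits(points, "score_table") || is.data.frame(points))
    score_values(points) else as.matrix(points)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (K < 1L) stop("K must be >= 1")
  if (n < 5L * K) stop("need n >= 5 K points to fit ", K, " components")

  start_labels <- function(attempt) {
    if (!is.null(init_labels)) return(as.integer(init_labels))
    if (K == 1L) return(rep(1L, n))
    if (init == "hclust" && attempt == 0L) {
      cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k = K)
    } else {
      if (!is.null(seed)) set.seed(seed + attempt)
      stats::kmeans(x, centers = K, nstart = 5)$cluster
    }
  }

  code <- match(structure, DIAGONAL_STRUCTURES) - 1L
  for (attempt in 0:max_restarts) {
    lab <- start_labels(attempt)
    Z <- matrix(0, n, K); Z[cbind(seq_len(n), lab)] <- 1
    em <- gmm_em_cpp(x, Z, code, max_iter, tol)
    if (em$ok) {
      npar <- (K - 1L) + K * d + gmm_cov_params(structure, K, d)
      fit <- structure(list(
        K = K, structure = structure, weights = drop(em$weights),
        means = em$means, variances = em$variances, loglik = em$loglik,
        loglik_trace = em$trace, npar = npar,
        bic = -2 * em$loglik + npar * log(n), n = n, d = d,
        converged = em$converged, iterations = length(em$trace),
        var_names = colnames(x)), class = "emt_gmm")
      return(fit)
    }
  }
  stop("degenerate component (variance < 1e-12) after ", max_restarts,
       " restart(s); structure ", structure, ", K = ", K)
}

#' @export
print.emt_gmm <- function(x, ...) {
  cat("<emt_gmm> ", x$structure, " mixture, K = ", x$K, ", n = ", x$n,
      "\n  loglik = ", format(x$loglik), ", BIC = ", format(x$bic),
      " (lower is better)\n", sep = "")
  invisible(x)
}

#' @export
summary.emt_gmm <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$K),
                    weight = object$weights, object$means,
                    check.names = FALSE)
  names(tab)[3:(2 + object$d)] <-
    paste0("mean_", object$var_names %||% seq_len(object$d))
  print(object)
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' @export
logLik.emt_gmm <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
coef.emt_gmm <- function(object, ...) {
  list(weights = object$weights, means = object$means,
       variances = object$variances)
}

#' Posterior component probabilities for new points
#'
#' @param object An `emt_gmm`.
#' @param newdata n x d matrix of points.
#' @param ... Unused.
#' @return n x K matrix of posterior probabilities (rows sum to 1).
#' @export
predict.emt_gmm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "score_table") || is.data.frame(newdata))
    score_values(newdata) else as.matrix(newdata)
  if (ncol(x) != object$d) stop("newdata must have ", object$d, " columns")
  gmm_posterior(gmm_log_component_dens(x, object$means, object$variances,
                                       object$weights))$post
}

#' Simulate draws from a fitted mixture
#'
#' @param object An `emt_gmm`.
#' @param nsim Number of points.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List with `points` (nsim x d) and `component` (integer labels).
#' @export
simulate.emt_gmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(object$K, nsim, replace = TRUE, prob = object$weights)
  pts <- object$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(nsim * object$d), nsim) *
      sqrt(object$variances[comp, , drop = FALSE])
  colnames(pts) <- object$var_names
  list(points = pts, component = comp)
}

#' @export
plot.emt_gmm <- function(x, points = NULL, ...) {
  if (is.null(points)) {
    points <- simulate.emt_gmm(x, 500, seed = 1)$points
  } else if (inherits(points, "score_table") || is.data.frame(points)) {
    points <- score_values(points)
  }
  graphics::plot(points[, 1], points[, 2],
                 xlab = x$var_names[1] %||% "dim 1",
                 ylab = x$var_names[2] %||% "dim 2",
                 col = "grey60", pch = 16, cex = 0.6, ...)
  graphics::points(x$means[, 1], x$means[, 2], pch = 19, cex = 1.4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select component count and covariance structure by BIC
#'
#' Fits every combination of `K_range` and `structures` and picks the
#' minimum-BIC model (BIC = -2 loglik + npar log n, so lower is better).
#' The default structure set excludes the unequal-volume models (VEI, VVI),
#' which tend to win BIC narrowly while assigning clusters with higher
#' uncertainty; all six remain available.
#'
#' @param points n x d matrix or `score_table`.
#' @param K_range Candidate component counts (default 1..9).
#' @param structures Candidate structures (default EII, VII, EEI, EVI).
#' @param ... Passed to [fit_gmm].
#' @return `emt_gmm_selection`: list with `table` (structure, K, loglik,
#'   npar, bic; failed fits NA), `by_K` (mean and min BIC per K), `best_fit`
#'   (`emt_gmm`), `K`, `structure`, and `fits` (all successful fits).
#' @export
select_model <- function(points, K_range = 1:9,
                         structures = c("EII", "VII", "EEI", "EVI"), ...) {
  x <- if (inherits(points, "score_table") || is.data.frame(points))
    score_values(points) else as.matrix(points)
  structures <- match.arg(structures, DIAGONAL_STRUCTURES, several.ok = TRUE)
  hc_labels <- NULL
  if (nrow(x) >= 2L) {
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    hc_labels <- lapply(K_range, function(K)
      if (K == 1L) rep(1L, nrow(x)) else cutree(hc, k = K))
    names(hc_labels) <- as.character(K_range)
  }
  grid <- expand.grid(structure = structures, K = K_range,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  res <- data.frame(grid, loglik = NA_real_, npar = NA_integer_,
                    bic = NA_real_)
  for (i in seq_len(nrow(grid))) {
    K <- grid$K[i]
    fit <- tryCatch(
      fit_gmm(x, K = K, structure = grid$structure[i],
              init_labels = hc_labels[[as.character(K)]], ...),
      error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[i]] <- fit
      res$loglik[i] <- fit$loglik
      res$npar[i] <- fit$npar
      res$bic[i] <- fit$bic
    }
  }
  if (all(is.na(res$bic))) stop("no candidate model could be fitted")
  by_K <- do.call(rbind, lapply(split(res, res$K), function(df)
    data.frame(K = df$K[1], mean_bic = mean(df$bic, na.rm = TRUE),
               min_bic = suppressWarnings(min(df$bic, na.rm = TRUE)))))
  rownames(by_K) <- NULL
  best <- which.min(res$bic)
  structure(list(table = res, by_K = by_K, best_fit = fits[[best]],
                 K = res$K[best], structure = res$structure[best],
                 fits = fits[!vapply(fits, is.null, logical(1))]),
            class = "emt_gmm_selection")
}

#' @export
print.emt_gmm_selection <- function(x, ...) {
  cat("<emt_gmm_selection> best: ", x$structure, ", K = ", x$K,
      " (BIC = ", format(min(x$table$bic, na.rm = TRUE)), ")\n", sep = "")
  invisible(x)
}

#' Hard cluster assignment with uncertainties
#'
#' @param model A fitted `emt_gmm`.
#' @param points n x d matrix or `score_table` of the same dimensionality.
#' @param semantic Attach semantic EMT labels when K is 4 or 5 (default
#'   TRUE; silently skipped otherwise).
#' @return `cluster_assignment`: `labels` (argmax posterior), `posteriors`
#'   (n x K, rows sum to 1), `uncertainty` (1 - max posterior), `semantic`
#'   (component -> label map, or NULL), `semantic_labels` (per sample).
#' @export
assign_clusters <- function(model, points, semantic = TRUE) {
  post <- predict(model, points)
  labels <- max.col(post, ties.method = "first")
  unc <- 1 - post[cbind(seq_len(nrow(post)), labels)]
  sem <- NULL; sem_lab <- NULL
  if (semantic && model$K %in% c(4L, 5L) && model$d == 2L) {
    sem <- label_semantic(model)
    sem_lab <- sem[labels]
  }
  structure(list(labels = labels, posteriors = post, uncertainty = unc,
                 semantic = sem, semantic_labels = sem_lab),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " samples, ",
      ncol(x$posteriors), " components\n", sep = "")
  tab <- table(if (is.null(x$semantic_labels)) x$labels else x$semantic_labels)
  print(tab)
  invisible(x)
}

#' Semantic EMT labels for mixture components
#'
#' In (E, M) score space: the component maximizing mean(E) - mean(M) is the
#' epithelial pole `E`, the one maximizing mean(M) - mean(E) the mesenchymal
#' pole `M`. Among the intermediates, `I0` has the lowest mean(E) + mean(M)
#' (low-E-low-M, "characterless"), `I1` the highest (high-E-high-M hybrid),
#' and for K = 5 the remaining, M-adjacent component is `I2`.
#'
#' @param model An `emt_gmm` with K in \{4, 5\} fitted on 2-D (E, M) scores.
#' @return Character vector of length K mapping component index to label.
#' @export
label_semantic <- function(model) {
  if (!(model$K %in% c(4L, 5L)))
    stop("semantic labels are defined for K = 4 or 5; ",
         "use generic integer labels for other K")
  if (model$d != 2L) stop("semantic labels require 2-D (E, M) score space")
  mu <- model$means
  diffs <- mu[, 1] - mu[, 2]
  e_comp <- which.max(diffs)
  m_comp <- which.max(-diffs)
  rest <- setdiff(seq_len(model$K), c(e_comp, m_comp))
  sums <- mu[rest, 1] + mu[rest, 2]
  i0 <- rest[which.min(sums)]
  remaining <- setdiff(rest, i0)
  i1 <- remaining[which.max(sums[match(remaining, rest)])]
  lab <- character(model$K)
  lab[e_comp] <- "E"; lab[m_comp] <- "M"; lab[i0] <- "I0"; lab[i1] <- "I1"
  if (model$K == 5L) lab[setdiff(remaining, i1)] <- "I2"
  lab
}

#' Agreement between cluster assignments across covariance structures
#'
#' @param assignments Named list of `cluster_assignment` objects (or plain
#'   label vectors) over identical samples.
#' @return List with `ari` (pairwise adjusted Rand index matrix) and
#'   `mean_agreement` (per assignment, mean ARI against the others).
#' @export
compare_structures <- function(assignments) {
  if (length(assignments) < 2L) stop("need >= 2 assignments to compare")
  labs <- lapply(assignments, function(a)
    if (inherits(a, "cluster_assignment")) a$labels else as.vector(a))
  n <- unique(vapply(labs, length, integer(1)))
  if (length(n) != 1L) stop("assignments cover mismatched sample sets")
  m <- length(labs)
  nm <- names(assignments) %||% paste0("A", seq_len(m))
  ari <- matrix(1, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ari[i, j] <- ari[j, i] <- mclust::adjustedRandIndex(labs[[i]], labs[[j]])
  }
  mean_agreement <- (rowSums(ari) - 1) / (m - 1)
  list(ari = ari, mean_agreement = mean_agreement)
}
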