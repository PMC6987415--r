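# Brute-force single-sample enrichment oracle: naive double loops, written
# independently of the package's vectorized path.
oracle_scores <- function(x, set_genes, tau = 1, log_transform = TRUE) {
  lx <- if (log_transform) log2(x + 1) else x
  p <- nrow(lx); n <- ncol(lx)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    h <- stats::sd(lx[i, ]) / 4
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(n)) s <- s + stats::pnorm((lx[i, j] - lx[i, k]) / h)
      z[i, j] <- s / n
    }
  }
  es <- numeric(n)
  mask <- rownames(x) %in% set_genes
  for (j in seq_len(n)) {
    o <- order(-z[, j])
    r <- integer(p); r[o] <- seq_len(p)
    rt <- abs(p / 2 - r)
    w <- rt[o]^tau; w[!mask[o]] <- 0
    nu <- cumsum(w / sum(w) - (!mask[o]) / (p - sum(mask)))
    es[j] <- max(0, max(nu)) + min(0, min(nu))
  }
  es
}

# random positive expression matrix with gene/sample names
random_matrix <- function(p, n, seed) {
  set.seed(seed)
  matrix(2^rnorm(p * n, 6, 1), p, n,
         dimnames = list(sprintf("g%03d", seq_len(p)),
                         sprintf("s%02d", seq_len(n))))
}

# emt_gmm object with prescribed means (for semantic/path geometry tests)
gmm_with_means <- function(means, sd = 0.07) {
  K <- nrow(means)
  structure(list(K = K, structure = "EII",
                 weights = rep(1 / K, K), means = unname(as.matrix(means)),
                 variances = matrix(sd^2, K, 2), loglik = 0,
                 loglik_trace = 0, npar = 0, bic = 0, n = 100L, d = 2L,
                 converged = TRUE, iterations = 1L,
                 var_names = c("E", "M")),
            class = "emt_gmm")
}

fig2c_means <- rbind(c(0.45, -0.35), c(-0.15, -0.30), c(0.30, 0.25),
                     c(-0.05, 0.35), c(-0.50, 0.55))

# frozen output of score_matrix() on the seed-7 miniature cohort
REGRESSION_E_SCORES <- c(-0.221139896373, -0.578407960199,
                         0.603813559322, 0.620425531915)
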