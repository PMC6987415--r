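test_that("expression statistic is monotone, tie-ruled, and oracle-exact", {
  m <- rbind(g1 = c(0, 10), g2 = c(5, 5))
  m <- rbind(m, g3 = c(1, 2))   # >= 2 genes with variance
  z <- suppressMessages(expression_statistic(m))
  expect_gt(z["g1", 2], z["g1", 1])
  expect_equal(unname(z["g2", ]), c(0.5, 0.5))   # zero-variance tie rule

  x <- random_matrix(5, 4, seed = 3)
  z <- expression_statistic(log2(x + 1))
  zo <- matrix(0, 5, 4)
  for (i in 1:5) for (j in 1:4) {
    h <- sd(log2(x[i, ] + 1)) / 4
    zo[i, j] <- mean(pnorm((log2(x[i, j] + 1) - log2(x[i, ] + 1)) / h))
  }
  expect_equal(unname(z), zo, tolerance = 1e-12)
  expect_error(expression_statistic(matrix(1:2, 2, 1,
    dimnames = list(c("a", "b"), "s"))), ">=2 samples")
  expect_error(expression_statistic(x, kernel = "poisson"), "stub")
})

test_that("symmetric rank folds about the middle and stays a bijection", {
  z <- matrix(c(4, 3, 2, 1), 4, 1)   # ranks 1..4
  sr <- symmetric_rank(z)
  expect_equal(drop(sr$rank), 1:4)
  expect_equal(drop(sr$rtilde), c(1, 0, 1, 2))
  # all tied: tie rule = input gene order; still a bijection
  sr_t <- symmetric_rank(matrix(1, 5, 1))
  expect_setequal(drop(sr_t$rank), 1:5)
  # reversing the ordering reverses the permutation
  sr_r <- symmetric_rank(-z)
  expect_equal(drop(sr_r$rank), 4:1)
  expect_error(symmetric_rank(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("random walk matches hand-enumerated examples and conserves", {
  rtilde <- c(1, 0, 1, 2)      # indexed by gene, genes already in rank order
  ord <- 1:4
  w1 <- random_walk_es(ord, rtilde, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(w1$walk, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(w1$es, 1)
  w4 <- random_walk_es(ord, rtilde, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(w4$walk, c(-1 / 3, -2 / 3, -1, 0))
  expect_equal(w4$es, -1)
  # walk conservation nu(p) = 0 on random cases
  set.seed(42)
  for (i in 1:20) {
    p <- sample(5:40, 1)
    rt <- abs(p / 2 - sample(p))
    mask <- rep(FALSE, p); mask[sample(p, sample(p - 1, 1))] <- TRUE
    w <- random_walk_es(sample(p), rt, mask)
    expect_equal(w$walk[p], 0, tolerance = 1e-12)
    expect_true(w$es >= -1 && w$es <= 1)
  }
  expect_error(random_walk_es(1:4, rtilde, rep(TRUE, 4)), "every gene")
  expect_error(random_walk_es(1:4, c(0, 0, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               "degenerate")
})

test_that("score_matrix is oracle-exact, bounded, and equivariant", {
  x <- random_matrix(12, 5, seed = 11)
  sets <- gene_set_collection(list(
    gene_set("A", rownames(x)[1:4]),
    gene_set("B", rownames(x)[c(2, 6, 9, 11, 12)])))
  st <- score_matrix(x, sets)
  expect_s3_class(st, "score_table")
  expect_true(all(abs(score_values(st)) <= 1))
  expect_equal(st$A, oracle_scores(x, rownames(x)[1:4]), tolerance = 1e-12)
  expect_equal(st$B, oracle_scores(x, rownames(x)[c(2, 6, 9, 11, 12)]),
               tolerance = 1e-12)
  # permuting samples permutes rows identically
  perm <- c(3, 1, 5, 2, 4)
  st_p <- score_matrix(x[, perm], sets)
  expect_equal(score_values(st_p), score_values(st)[perm, ])
})

test_that("rank-only mode is invariant to order-preserving transforms", {
  x <- random_matrix(15, 6, seed = 12)
  params <- walk_params(kernel = "none")
  st1 <- score_matrix(x, list(S = rownames(x)[1:5]), params = params)
  # strictly increasing per-gene transform preserving cross-sample order
  x2 <- x^3 + 5
  st2 <- score_matrix(x2, list(S = rownames(x)[1:5]), params = params,
                      log_transform = FALSE)
  expect_equal(st1$S, st2$S)
})

test_that("gene dropping, undersized sets, and provenance behave", {
  x <- random_matrix(10, 4, seed = 13)
  expect_message(
    st <- score_matrix(x, list(S = c(rownames(x)[1:3], "ABSENT"))),
    "dropped 1")
  prov <- attr(st, "provenance")
  expect_equal(prov$size, 4L)
  expect_equal(prov$effective_size, 3L)
  expect_error(score_matrix(x, list(S = c(rownames(x)[1], "NOPE"))), "'S'")
})

test_that("scores for a fixed synthetic cohort are reproducible", {
  co <- generate_cohort(n_samples = 8, n_e_genes = 20, n_m_genes = 15,
                        n_background = 10, seed = 7)
  st <- score_matrix(co$matrix, co$sets)
  st2 <- score_matrix(co$matrix, co$sets)
  expect_identical(st, st2)
  # regression pin: cohort-relative scores depend on every sample, so any
  # change to the scoring path shows up here
  expect_equal(st$E[1:4], REGRESSION_E_SCORES, tolerance = 1e-10)
})
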