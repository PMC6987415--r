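test_that("K = 1 fit equals the closed-form Gaussian MLE", {
  set.seed(1)
  x <- cbind(rnorm(80, 1, 2), rnorm(80, -1, 0.5))
  f <- fit_gmm(x, K = 1, structure = "VVI")
  expect_equal(drop(f$means), colMeans(x), tolerance = 1e-8)
  v_mle <- apply(x, 2, function(c) mean((c - mean(c))^2))
  expect_equal(drop(f$variances), v_mle, tolerance = 1e-6)
  ll <- sum(dnorm(x[, 1], mean(x[, 1]), sqrt(v_mle[1]), log = TRUE)) +
    sum(dnorm(x[, 2], mean(x[, 2]), sqrt(v_mle[2]), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-6)
  # BIC convention: -2 loglik + d log n, lower is better
  expect_equal(f$bic, -2 * ll + f$npar * log(80), tolerance = 1e-6)
  expect_equal(f$npar, 0 + 2 + 2)
})

test_that("well-separated blobs are recovered and EM is monotone", {
  set.seed(2)
  truth <- rbind(c(0, 0), c(10, 10))
  x <- truth[rep(1:2, each = 250), ] + matrix(rnorm(1000), 500)
  f <- fit_gmm(x, K = 2, structure = "EII")
  expect_equal(f$means[order(f$means[, 1]), ], truth, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_false(is.unsorted(f$loglik_trace + 1e-8))
})

test_that("every structure's EM agrees with mclust from the same start", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  sim <- sample_path_spec(n_samples = 400, seed = 5)
  pts <- score_values(sim$scores)
  lab <- cutree(hclust(dist(pts), "ward.D2"), 3)
  Z0 <- matrix(0, nrow(pts), 3); Z0[cbind(seq_len(nrow(pts)), lab)] <- 1
  for (s in c("EII", "VII", "EEI", "VEI", "EVI", "VVI")) {
    f <- fit_gmm(pts, 3, s, init_labels = lab)
    m <- mclust::me(data = pts, modelName = s, z = Z0)
    expect_equal(f$loglik, m$loglik, tolerance = 1e-4,
                 label = paste("loglik", s))
    expect_false(is.unsorted(f$loglik_trace + 1e-6))
  }
})

test_that("select_model recovers K on separated mixtures and reports BIC", {
  sim <- sample_path_spec(n_samples = 600, seed = 8)
  sel <- select_model(sim$scores)
  expect_equal(sel$K, 5L)
  expect_true(all(c("structure", "K", "bic") %in% names(sel$table)))
  expect_equal(nrow(sel$table), 9 * 4)
  # chosen model attains the minimum BIC of the table
  expect_equal(sel$best_fit$bic, min(sel$table$bic, na.rm = TRUE))
  expect_equal(nrow(sel$by_K), 9L)
})

test_that("assignment posteriors, uncertainties, and K = 1 degenerate", {
  sim <- sample_path_spec(n_samples = 500, seed = 9)
  f <- fit_gmm(sim$scores, 5, "EII")
  asg <- assign_clusters(f, sim$scores)
  expect_equal(unname(rowSums(asg$posteriors)), rep(1, 500),
               tolerance = 1e-10)
  expect_true(all(asg$uncertainty >= 0 & asg$uncertainty < 1))
  # a point at a well-separated component mean is assigned confidently
  at_mean <- predict(f, f$means)
  expect_true(all(1 - apply(at_mean, 1, max) < 0.01))
  f1 <- fit_gmm(sim$scores, 1, "EII")
  asg1 <- assign_clusters(f1, sim$scores)
  expect_equal(unique(asg1$uncertainty), 0)
  expect_true(all(asg1$posteriors == 1))
})

test_that("semantic labels follow the E-M geometry rules", {
  g5 <- gmm_with_means(fig2c_means)
  expect_equal(label_semantic(g5), c("E", "I0", "I1", "I2", "M"))
  # invariant to component storage order
  perm <- c(4, 2, 5, 1, 3)
  g5p <- gmm_with_means(fig2c_means[perm, ])
  expect_equal(label_semantic(g5p), c("E", "I0", "I1", "I2", "M")[perm])
  g4 <- gmm_with_means(fig2c_means[-4, ])
  expect_setequal(label_semantic(g4), c("E", "I0", "I1", "M"))
  g3 <- gmm_with_means(fig2c_means[1:3, ])
  expect_error(label_semantic(g3), "generic integer")
})

test_that("structure agreement uses the adjusted Rand index correctly", {
  set.seed(10)
  a <- sample(5, 1000, replace = TRUE)
  relabeled <- c(3, 1, 5, 2, 4)[a]
  cmp <- compare_structures(list(one = a, two = a, three = relabeled))
  expect_equal(unname(cmp$ari[1, 2]), 1)
  expect_equal(unname(cmp$ari[1, 3]), 1)   # label-permutation invariance
  b <- sample(5, 1000, replace = TRUE)     # independent labeling
  cmp2 <- compare_structures(list(a = a, b = b))
  expect_true(abs(cmp2$ari[1, 2]) < 0.05)
  expect_error(compare_structures(list(a = a, b = b[1:10])), "mismatched")
})
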