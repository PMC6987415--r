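test_that("generators are seed-deterministic with honored dimensions", {
  a <- generate_cohort(n_samples = 30, n_e_genes = 15, n_m_genes = 12,
                       n_background = 8, seed = 51)
  b <- generate_cohort(n_samples = 30, n_e_genes = 15, n_m_genes = 12,
                       n_background = 8, seed = 51)
  c2 <- generate_cohort(n_samples = 30, n_e_genes = 15, n_m_genes = 12,
                        n_background = 8, seed = 52)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_false(identical(a$matrix$values, c2$matrix$values))
  expect_equal(dim(a$matrix$values), c(35L, 30L))
  expect_equal(nrow(a$truth$latent), 30L)
  tc <- generate_timecourse(times = c(0, 2, 5, 9), replicates = 4,
                            n_e_genes = 10, n_m_genes = 10,
                            n_background = 5, seed = 53)
  expect_equal(table(tc$matrix$sample_meta$time_days),
               table(rep(c(0, 2, 5, 9), each = 4)))
  sp1 <- sample_path_spec(n_samples = 50, seed = 54)
  sp2 <- sample_path_spec(n_samples = 50, seed = 54)
  expect_identical(sp1$scores, sp2$scores)
})

test_that("opposed latent clusters score on opposite sides of the axes", {
  spec <- emt_path_spec(
    centers = rbind(hi_e = c(0.5, -0.5), hi_m = c(-0.5, 0.5)),
    weights = c(0.5, 0.5), sds = c(0.07, 0.07),
    sequences = list(c("hi_e", "hi_m")))
  co <- generate_cohort(spec, n_samples = 80, seed = 55)
  st <- suppressMessages(score_matrix(co$matrix, co$sets))
  v <- score_values(st, c("E", "M"))
  he <- co$truth$cluster == "hi_e"
  expect_gte(mean(v[he, "E"] > 0 & v[he, "M"] < 0), 0.95)
  expect_gte(mean(v[!he, "E"] < 0 & v[!he, "M"] > 0), 0.95)
})

test_that("the pooled outgroup occupies the extreme low-E-low-M corner", {
  co <- generate_cohort(n_samples = 120, seed = 56)
  og <- generate_outgroup(40, co$truth, seed = 57)
  pooled <- cbind(co$matrix$values, og$matrix$values)
  st <- suppressMessages(score_matrix(
    expression_matrix(pooled), co$sets))
  v <- score_values(st, c("E", "M"))
  tot <- v[, "E"] + v[, "M"]
  is_out <- grepl("^OUT", rownames(v))
  expect_true(all(tot[is_out] < quantile(tot[!is_out], 0.05)))
  expect_equal(sum(is_out), 40L)
})

test_that("logic-gate panel responses follow the regulatory circuits", {
  pan <- generate_perturbation_panel(seed = 58, replicates = 4,
                                     gene_noise_sd = 0.2)
  meta <- pan$matrix$sample_meta
  lm2 <- log2(pan$matrix$values + 1)
  mean_resp <- function(sub, T, Z) {
    genes <- pan$truth$gene_params$gene[pan$truth$gene_params$subcluster == sub]
    cols <- meta$TGFB == T & meta$ZEB1 == Z
    base <- pan$truth$gene_params$baseline[
      pan$truth$gene_params$subcluster == sub]
    mean(lm2[genes, cols] - base)
  }
  # all regulators off: every subcluster at baseline
  for (s in c("E1", "E2", "E3", "M1", "M2", "M3"))
    expect_equal(mean_resp(s, 0, 0), 0, tolerance = 0.15)
  # E2 incoherent feed-forward: TGFB alone activates, ZEB1 suppresses
  expect_gt(mean_resp("E2", 1, 0), 1)
  expect_lt(mean_resp("E2", 1, 1), 0.1)
  # M1 AND gate: TGFB alone gives a reduced, intermediate response
  full <- mean_resp("M1", 1, 1)
  half <- mean_resp("M1", 1, 0)
  expect_gt(half, 0.25)
  expect_lt(half, full - 0.25)
  # E3 AND repression with opposite TGFB-alone effect
  expect_gt(mean_resp("E3", 1, 0), 0.25)
  expect_lt(mean_resp("E3", 1, 1), -1)
  expect_error(generate_perturbation_panel(
    conditions = data.frame(TGFB = 1), seed = 1), "both TGFB and ZEB1")
  expect_error(generate_perturbation_panel(
    conditions = data.frame(TGFB = c(0, 1), ZEB1 = c(0, 0)), seed = 1),
    "factorial")
})

test_that("zero-noise time course preserves latent segment sign patterns", {
  tc <- generate_timecourse(replicates = 1, latent_sd = 0,
                            gene_noise_sd = 0, seed = 59)
  st <- suppressMessages(score_matrix(tc$matrix, tc$sets))
  v <- score_values(st, c("E", "M"))
  tt <- tc$matrix$sample_meta$time_days
  # latent M rises throughout; E rises (weakly, the signature block can
  # saturate the rank statistic) before 2.5 d and falls sharply late
  expect_true(all(diff(v[order(tt), "M"]) > -1e-9))
  expect_gte(v[tt == 2, "E"], v[tt == 0, "E"])
  expect_lt(v[tt == 21, "E"], v[tt == 5, "E"])
})

test_that("the full cohort pipeline recovers the five-cluster structure", {
  skip_if_not_installed("mclust")
  co <- generate_cohort(n_samples = 400, n_e_genes = 60, n_m_genes = 50,
                        n_background = 60, seed = 60)
  st <- suppressMessages(score_matrix(co$matrix, co$sets))
  f5 <- fit_gmm(st, 5, "EII")
  asg <- assign_clusters(f5, st)
  expect_false(is.null(asg$semantic))
  ari <- mclust::adjustedRandIndex(asg$semantic_labels, co$truth$cluster)
  expect_gt(ari, 0.7)
  # the semantic poles match the latent truth poles
  e_true <- co$truth$cluster == "E"
  expect_equal(names(which.max(table(asg$semantic_labels[e_true]))), "E")
  m_true <- co$truth$cluster == "M"
  expect_equal(names(which.max(table(asg$semantic_labels[m_true]))), "M")
})
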