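archetype_profiles <- function(seed, n_per = 100, sd = 0.3) {
  set.seed(seed)
  arch <- rbind(c(2, 2, -2, -2, 0, 0), c(-2, 0, 2, -1, 2, -2))
  prof <- arch[rep(1:2, each = n_per), ] +
    matrix(rnorm(2 * n_per * 6, sd = sd), 2 * n_per)
  rownames(prof) <- paste0(rep(c("a", "b"), each = n_per), seq_len(n_per))
  prof
}

test_that("SOM training separates archetypes and is seed-deterministic", {
  prof <- archetype_profiles(seed = 31)
  som <- train_som(prof, shape = c(6, 6), epochs = 40, seed = 1)
  bmu_a <- unique(som$bmu[1:100]); bmu_b <- unique(som$bmu[101:200])
  expect_length(intersect(bmu_a, bmu_b), 0)
  som2 <- train_som(prof, shape = c(6, 6), epochs = 40, seed = 1)
  expect_identical(som$bmu, som2$bmu)
  # quantization error settles: the trained map fits better than the
  # early neighborhood-smoothed map, and the tail is non-increasing
  qe <- som$qe
  expect_lt(qe[length(qe)], qe[2])
  tail_qe <- qe[(length(qe) %/% 2):length(qe)]
  expect_true(all(diff(tail_qe) <= 0.05 * qe[1]))
  expect_error(train_som(prof[, 1, drop = FALSE]), ">= 2 conditions")
  flat <- rbind(prof, constant_gene = rep(1, 6))
  expect_error(train_som(flat), "constant_gene")
})

test_that("node classification counts, ties, and propagation behave", {
  prof <- archetype_profiles(seed = 32)
  som <- train_som(prof, shape = c(6, 6), epochs = 40, seed = 2)
  e_like <- rownames(prof)[1:100]; m_like <- rownames(prof)[101:200]
  labels <- classify_nodes(som, e_like, m_like)
  expect_equal(nrow(labels), 36L)
  expect_true(all(labels$label %in% c("E", "M")))
  # every node with annotated genes is labeled by its majority class
  with_votes <- labels[labels$e_count + labels$m_count > 0, ]
  maj <- ifelse(with_votes$e_count > with_votes$m_count, "E",
                ifelse(with_votes$m_count > with_votes$e_count, "M", NA))
  expect_true(all(is.na(maj) | maj == with_votes$label))
  expect_true(all(with_votes$ratio >= 0.5, na.rm = TRUE))
  # annotation-free nodes inherit from the nearest labeled node
  empty <- labels[labels$e_count + labels$m_count == 0, ]
  if (nrow(empty)) expect_true(all(empty$imputed))
  expect_error(classify_nodes(som, "nope1", "nope2"), "no annotated")
})

test_that("elbow subclustering recovers separated archetypes and partitions", {
  set.seed(33)
  arch3 <- rbind(c(3, 3, -3, -3), c(-3, 3, 3, -3), c(0, -3, 0, 3))
  prof <- arch3[rep(1:3, each = 80), ] + matrix(rnorm(960, sd = 0.2), 240)
  rownames(prof) <- paste0("g", 1:240)
  som <- train_som(prof, shape = c(6, 6), epochs = 40, seed = 3)
  labels <- classify_nodes(som, rownames(prof), "zzz_absent")
  expect_warning(subs <- subcluster_nodes(som, labels, "E"), NA)
  expect_equal(attr(subs, "k"), 3L)
  # subcluster genes partition the class's genes
  all_genes <- unlist(lapply(subs, `[[`, "genes"))
  expect_length(all_genes, 240L)
  expect_false(anyDuplicated(all_genes) > 0)
  expect_equal(vapply(subs, `[[`, character(1), "name"),
               paste0("E", 1:3))
})

test_that("identical codebooks collapse to one subcluster", {
  prof <- matrix(rep(c(1, -1, 2, -2), each = 50), 50)
  rownames(prof) <- paste0("g", 1:50)
  prof <- prof + matrix(rnorm(200, sd = 1e-9), 50)
  som <- train_som(prof, shape = c(3, 3), epochs = 10, seed = 4,
                   standardize = FALSE)
  labels <- classify_nodes(som, rownames(prof), "zzz_absent")
  subs <- suppressWarnings(subcluster_nodes(som, labels, "E"))
  expect_equal(attr(subs, "k"), 1L)
})

test_that("scoring a subcluster equal to a whole set reproduces its score", {
  pan <- generate_perturbation_panel(seed = 35, replicates = 3)
  e_genes <- pan$sets[["E"]]$genes
  fake_sub <- list(structure(list(name = "E", class = "E", nodes = 1L,
                                  genes = e_genes),
                             class = "gene_subcluster"))
  s1 <- suppressMessages(score_subclusters(pan$matrix, fake_sub))
  s2 <- suppressMessages(score_matrix(pan$matrix, pan$sets))
  expect_equal(s1$E, s2$E)
  expect_true(all(abs(score_values(s1)) <= 1))
})
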