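test_that("quadrant census follows the closed-left boundary convention", {
  st <- data.frame(sample_id = paste0("s", 1:4),
                   E = c(0.5, -0.1, 0.5, 0), M = c(0.5, 0.3, -0.2, 0))
  cen <- quadrant_census(st)
  expect_equal(cen$count[cen$quadrant == "highE_highM"], 1L)
  expect_equal(cen$count[cen$quadrant == "lowE_highM"], 1L)
  expect_equal(cen$count[cen$quadrant == "highE_lowM"], 1L)
  expect_equal(cen$count[cen$quadrant == "lowE_lowM"], 1L)  # (0,0) -> low
  expect_equal(sum(cen$count), 4L)
  expect_equal(sum(cen$fraction), 1, tolerance = 1e-12)
  # two per quadrant -> 0.25 each
  st8 <- data.frame(E = c(1, 2, 1, 2, -1, -2, -1, -2) / 10,
                    M = c(1, 2, -1, -2, 1, 2, -1, -2) / 10)
  expect_equal(quadrant_census(st8)$fraction, rep(0.25, 4))
})

test_that("rotation to progression/deviation coordinates is an isometry", {
  uv <- rotate_coordinates(0.5, -0.5)
  expect_equal(uv$u, sqrt(2) / 2, tolerance = 1e-6)
  expect_equal(uv$v, 0, tolerance = 1e-12)
  expect_equal(unlist(rotate_coordinates(0, 0)), c(u = 0, v = 0))
  uv2 <- rotate_coordinates(0.5, 0.5)
  expect_equal(uv2$u, 0, tolerance = 1e-12)
  expect_equal(uv2$v, sqrt(2) / 2, tolerance = 1e-6)
  set.seed(7)
  E <- rnorm(50); M <- rnorm(50)
  uv3 <- rotate_coordinates(E, M)
  expect_equal(uv3$u^2 + uv3$v^2, E^2 + M^2, tolerance = 1e-12)
  expect_error(rotate_coordinates(c(1, NA), c(0, 0)), "finite")
})

test_that("minimal paths on the five-cluster geometry match the two routes", {
  g5 <- gmm_with_means(fig2c_means)
  paths <- enumerate_min_paths(g5)
  path_strings <- sort(vapply(paths, paste, character(1), collapse = "-"))
  expect_equal(path_strings, c("E-I0-I2-M", "E-I1-I2-M"))
  expect_equal(unique(lengths(paths)), 4L)   # all shortest, equal length
})

test_that("collinear four-cluster geometry yields a single path", {
  means <- cbind(seq(0.6, -0.6, length.out = 4),
                 seq(-0.6, 0.6, length.out = 4))
  g4 <- gmm_with_means(means)
  paths <- enumerate_min_paths(g4)
  expect_length(paths, 1L)
  expect_length(paths[[1]], 4L)
  expect_equal(paths[[1]][1], "E")
  expect_equal(paths[[1]][4], "M")
  expect_setequal(paths[[1]][2:3], c("I0", "I1"))
})

test_that("a disconnected sparse graph raises an actionable error", {
  # two tight pairs far apart: symmetrized 1-NN links within pairs only
  means <- rbind(c(1, -1), c(0.99, -0.99), c(-1, 1), c(-0.99, 0.99))
  g <- gmm_with_means(means)
  expect_error(enumerate_min_paths(g, method = "knn", k = 1), "disconnected")
})

test_that("EMT path fits recover a noiseless bent path and flag flat ones", {
  # lambda-shaped path in (E, M): v rises then falls along u
  set.seed(8)
  u <- runif(120, -0.7, 0.7)
  v <- 0.4 - abs(u) * 0.6
  E <- (u + v) / sqrt(2); M <- (v - u) / sqrt(2)
  st <- data.frame(sample_id = paste0("s", 1:120), E = E, M = M)
  lab <- rep(c("E", "I1", "I2", "M"), length.out = 120)
  pf <- fit_emt_path(st, lab, c("E", "I1", "I2", "M"))
  expect_gt(pf$fit$adjusted_r2, 0.99)
  expect_equal(pf$fit$psi, 0, tolerance = 0.02)
  expect_lt(pf$davies_p, 1e-6)

  # straight anti-diagonal: v ~ 0, no breakpoint support in most replicates
  set.seed(9)
  flat <- replicate(100, {
    base <- runif(200, -0.6, 0.6)
    st <- data.frame(E = base + rnorm(200, sd = 0.05),
                     M = -base + rnorm(200, sd = 0.05))
    uv <- rotate_coordinates(st$E, st$M)
    davies_test(uv$u, uv$v)$p.value > 0.05
  })
  expect_gte(mean(flat), 0.9)
})

test_that("path membership and guards are enforced", {
  sim <- sample_path_spec(n_samples = 300, seed = 10)
  f <- fit_gmm(sim$scores, 5, "EII")
  asg <- assign_clusters(f, sim$scores)
  expect_error(fit_emt_path(sim$scores, asg, c("I0", "I2", "M")), "start at E")
  pf <- fit_emt_path(sim$scores, asg, c("E", "I1", "I2", "M"))
  expect_equal(pf$n_members,
               sum(asg$semantic_labels %in% c("E", "I1", "I2", "M")))
  expect_gte(pf$fit$adjusted_r2, pf$reference_fit$adjusted_r2 - 1e-8)
})
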