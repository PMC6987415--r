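# score-level triphasic fixture: latent trajectory + Gaussian score noise
triphasic_scores <- function(seed, sigma = 0.02,
                             times = c(0, 1, 2, 3, 4, 5, 8, 12, 16, 21),
                             reps = 3) {
  set.seed(seed)
  tt <- rep(times, each = reps)
  data.frame(
    sample_id = paste0("s", seq_along(tt)),
    time = tt,
    E = piecewise_linear(tt, 0.45, c(0.04, -0.02, -0.082), c(2.5, 10)) +
      rnorm(length(tt), sd = sigma),
    M = piecewise_linear(tt, -0.35, c(0.10, 0.02, 0.05), c(2.5, 10)) +
      rnorm(length(tt), sd = sigma))
}

test_that("triphasic breakpoints are recovered from noisy scores", {
  sc <- triphasic_scores(seed = 21)
  tm <- fit_timecourse(sc$time, sc)
  expect_equal(tm$m_fit$psi, c(2.5, 10), tolerance = 1)
  expect_equal(tm$e_fit$psi, c(2.5, 10), tolerance = 1)
  # two-breakpoint M model outperforms the single-breakpoint one
  cmp <- tm$comparison
  expect_gt(cmp$adjusted_r2[cmp$score == "M" & cmp$n_breakpoints == 2],
            cmp$adjusted_r2[cmp$score == "M" & cmp$n_breakpoints == 1])
  # default starting breakpoints are the 2.5/10-day anchors
  expect_equal(eval(formals(fit_timecourse)$psi0), c(2.5, 10))
})

test_that("degenerate and undersampled time courses are refused", {
  sc <- triphasic_scores(seed = 22)
  expect_error(fit_timecourse(sc$time[1:5], sc[1:5, ]), "distinct time")
  flat <- sc; flat$E <- 0.3; flat$M <- -0.2
  tm <- suppressWarnings(fit_timecourse(flat$time, flat))
  expect_length(tm$e_fit$psi, 0)   # no segmentation support
  expect_error(fit_timecourse(sc$time[1:10], sc), "different samples")
})

test_that("bound models pin the first E breakpoint at the CI endpoints", {
  sc <- triphasic_scores(seed = 23, sigma = 0)
  tm <- fit_timecourse(sc$time, sc)
  tm <- bound_models(tm)
  # zero noise: CI is tight, bounds coincide with the point fit
  expect_equal(tm$bounds$lower$psi[1], tm$e_fit$psi[1], tolerance = 0.25)
  sc2 <- triphasic_scores(seed = 24, sigma = 0.05)
  tm2 <- bound_models(fit_timecourse(sc2$time, sc2))
  expect_equal(tm2$bounds$lower$psi[1], tm2$e_ci[1, "lower"],
               tolerance = 1e-8)
  expect_equal(tm2$bounds$upper$psi[1], tm2$e_ci[1, "upper"],
               tolerance = 1e-8)
  # the bound trajectories embody the CI width: they disagree with each
  # other over the early phase and remain proper segmented fits
  grid <- seq(0, tm2$e_fit$psi[1], length.out = 20)
  lo <- predict(tm2$bounds$lower, grid)
  hi <- predict(tm2$bounds$upper, grid)
  expect_gt(max(abs(lo - hi)), 0.005)
  expect_true(tm2$bounds$lower$converged && tm2$bounds$upper$converged)
})

test_that("trajectory cluster probabilities are proper and well-located", {
  sc <- triphasic_scores(seed = 25)
  tm <- fit_timecourse(sc$time, sc)
  g5 <- gmm_with_means(fig2c_means, sd = 0.07)
  probs <- trajectory_cluster_probs(tm, g5, seq(0, 21, by = 1))
  expect_equal(rowSums(probs[, -1]), rep(1, 22), tolerance = 1e-10)
  # trajectory ends near the M pole
  expect_gt(probs$M[22], 0.95)
  # early times sit in the epithelial cluster
  expect_gt(probs$E[1], 0.5)
  # hybrid passage: interim I1 probability exceeds I0's
  mid <- probs[probs$time %in% 4:8, ]
  expect_gt(max(mid$I1), max(mid$I0))
  g1 <- gmm_with_means(matrix(c(0, 0), 1), sd = 0.3)
  p1 <- trajectory_cluster_probs(tm, g1, c(0, 5, 10))
  expect_true(all(p1[, 2] == 1))
  expect_error(trajectory_cluster_probs(tm, g5, c(-5, 30)), "extrapolation")
})
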