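#' Fit triphasic E(t) and M(t) segmented models to an induction time course
#'
#' Two-breakpoint segmented fits of the E and M scores against time, with
#' starting breakpoints at 2.5 and 10 days — between the early sampling
#' (days 2-3) and late sampling (days 8-12) transitions of TGF-beta-induced
#' EMT. One-breakpoint comparison fits are recorded with adjusted
#' R-squared. Replicate points enter the regression individually.
#'
#' @param times Numeric vector of sampling times (days), one per sample.
#' @param scores `score_table` with `E` and `M` columns (same samples,
#'   scored within the time-course cohort).
#' @param psi0 Starting breakpoints (days), default `c(2.5, 10)`.
#' @param ci_level Level for the first-E-breakpoint confidence interval.
#' @return `timecourse_model`: `e_fit`, `m_fit` (`segmented_fit`s),
#'   `comparison` (adjusted R2 of one- vs two-breakpoint fits per score),
#'   `e_ci`, `m_ci` (breakpoint confidence intervals), `times`.
#' @export
fit_timecourse <- function(times, scores, psi0 = c(2.5, 10),
                           ci_level = 0.95) {
  v <- score_values(scores, c("E", "M"))
  if (length(times) != nrow(v))
    stop("times and score table cover different samples")
  n_distinct <- length(unique(times))
  if (n_distinct < 6L)
    stop("need >= 6 distinct time points (got ", n_distinct, ")")
  if (n_distinct <= 2 + 2 * length(psi0))
    stop("fewer distinct times than model parameters")
  psi0 <- psi0[psi0 > min(times) & psi0 < max(times)]

  fit_one <- function(y) {
    f2 <- fit_segmented(times, y, psi0)
    f1 <- tryCatch(suppressWarnings(
      fit_segmented(times, y, stats::median(unique(times)))),
      error = function(e) NULL)
    list(two = f2, one = f1)
  }
  e <- fit_one(v[, "E"]); m <- fit_one(v[, "M"])
  comparison <- data.frame(
    score = rep(c("E", "M"), each = 2),
    n_breakpoints = rep(c(1L, 2L), 2),
    adjusted_r2 = c(if (is.null(e$one)) NA else e$one$adjusted_r2,
                    e$two$adjusted_r2,
                    if (is.null(m$one)) NA else m$one$adjusted_r2,
                    m$two$adjusted_r2))
  e_ci <- tryCatch(breakpoint_ci(e$two, level = ci_level),
                   error = function(err) NULL)
  m_ci <- tryCatch(breakpoint_ci(m$two, level = ci_level),
                   error = function(err) NULL)
  structure(list(e_fit = e$two, m_fit = m$two,
                 e_fit_1bp = e$one, m_fit_1bp = m$one,
                 comparison = comparison, e_ci = e_ci, m_ci = m_ci,
                 times = times), class = "timecourse_model")
}

#' @export
print.timecourse_model <- function(x, ...) {
  cat("<timecourse_model>\n  E breakpoints (days):",
      paste(signif(x$e_fit$psi, 4), collapse = ", "),
      "\n  M breakpoints (days):",
      paste(signif(x$m_fit$psi, 4), collapse = ", "), "\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Bound models from the first E-breakpoint confidence interval
#'
#' Refits the E-score model with its first breakpoint pinned at the lower
#' and upper endpoints of the confidence interval (remaining parameters
#' re-estimated), giving lower/upper bound trajectories for the early phase
#' of the time-course model.
#'
#' @param model A `timecourse_model` with an available `e_ci`.
#' @return The model with a `bounds` element: list of `segmented_fit`s
#'   `lower` and `upper`, each with the first breakpoint fixed.
#' @export
bound_models <- function(model) {
  stopifnot(inherits(model, "timecourse_model"))
  if (is.null(model$e_ci)) stop("first-E-breakpoint CI unavailable")
  tr <- range(model$times)
  refit_at <- function(p1) {
    if (p1 < tr[1] || p1 > tr[2]) {
      warning("CI endpoint outside the sampled time range; clamping")
      p1 <- min(max(p1, tr[1]), tr[2])
    }
    eps <- 1e-6 * diff(tr)
    p1 <- min(max(p1, tr[1] + eps), tr[2] - eps)
    psi <- sort(c(p1, model$e_fit$psi[-1]))
    fixed <- psi == p1
    suppressWarnings(fit_segmented(model$times, model$e_fit$y, psi,
                                   fixed = fixed))
  }
  model$bounds <- list(lower = refit_at(model$e_ci[1, "lower"]),
                       upper = refit_at(model$e_ci[1, "upper"]))
  model
}

#' Map a modeled trajectory to cluster probabilities over time
#'
#' Evaluates the fitted (E(t), M(t)) trajectory on a time grid and returns,
#' per grid time, the mixture posterior over semantic clusters — the
#' "background probability" strip behind time-course plots.
#'
#' @param model A `timecourse_model`.
#' @param gmm A 2-D `emt_gmm` over (E, M) scores (e.g., a cohort model).
#' @param times_grid Numeric grid of times.
#' @param allow_extrapolation Permit times outside the fitted range
#'   (default FALSE: refused with an error).
#' @return Data.frame: `time`, then one probability column per cluster
#'   (semantic names when K is 4 or 5); probability rows sum to 1.
#' @export
trajectory_cluster_probs <- function(model, gmm, times_grid,
                                     allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "timecourse_model"), inherits(gmm, "emt_gmm"))
  if (gmm$d != 2L) stop("gmm must be 2-D over (E, M)")
  tr <- range(model$times)
  if (!allow_extrapolation &&
      (any(times_grid < tr[1]) || any(times_grid > tr[2])))
    stop("times_grid outside the fitted range [", tr[1], ", ", tr[2],
         "]; set allow_extrapolation = TRUE to override")
  pts <- cbind(E = predict(model$e_fit, times_grid),
               M = predict(model$m_fit, times_grid))
  post <- predict(gmm, pts)
  cols <- if (gmm$K %in% c(4L, 5L)) label_semantic(gmm)
          else paste0("C", seq_len(gmm$K))
  colnames(post) <- cols
  data.frame(time = times_grid, post[, order(match(
    cols, c("E", "I0", "I1", "I2", "M"))), drop = FALSE],
    check.names = FALSE)
}
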