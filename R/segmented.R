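## Piecewise-linear (segmented) regression with iteratively estimated
## breakpoints, following the standard linearization: at working breakpoints
## psi the model y ~ 1 + x + (x - psi_k)_+ + gap_k, gap_k = -1(x > psi_k),
## is refitted and each psi_k updated by gamma_k / delta_k until the gap
## coefficients vanish.

# t statistic of the last column of a linear design (NA when collinear)
tstat_last <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(NA_real_)
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df <= 0) return(NA_real_)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * XtXinv[ncol(X), ncol(X)])
  if (!is.finite(se) || se == 0) return(NA_real_)
  beta[ncol(X)] / se
}

#' Fit a segmented (piecewise-linear) regression
#'
#' @param x,y Numeric vectors of equal length; n > 2 + 2 * length(psi0).
#' @param psi0 Initial breakpoints, strictly inside (min(x), max(x)).
#' @param fixed Logical vector (recycled): breakpoints flagged TRUE are held
#'   at their `psi0` value and not iterated (used by the time-course bound
#'   models).
#' @param max_iter,tol Iteration stops when the largest gap coefficient
#'   falls below `tol * sd(y)` (default 1e-8) or after `max_iter` (100)
#'   updates.
#' @param clamp Quantile pair inside which breakpoints are confined
#'   (default 2nd-98th data percentiles), avoiding boundary degeneracy.
#' @return An object of class `segmented_fit`: `psi` (ascending
#'   breakpoints), `coefficients` (intercept, base slope, slope change per
#'   breakpoint), `slopes` (per segment), `fitted.values`, `residuals`,
#'   `rss`, `adjusted_r2` (d.o.f. counting 2 + 2 * #breakpoints
#'   parameters), `converged`, and the data (`x`, `y`).
#' @export
fit_segmented <- function(x, y, psi0, fixed = FALSE, max_iter = 100L,
                          tol = 1e-8, clamp = c(0.02, 0.98)) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  psi <- sort(as.numeric(psi0))
  nb <- length(psi)
  if (nb < 1L) stop("psi0 must contain at least one breakpoint")
  if (n <= 2 + 2 * nb)
    stop("need n > ", 2 + 2 * nb, " observations for ", nb, " breakpoint(s)")
  if (any(psi <= min(x)) || any(psi >= max(x)))
    stop("psi0 outside the data range (", min(x), ", ", max(x), ")")
  fixed <- rep_len(as.logical(fixed), nb)
  bounds <- stats::quantile(x, clamp, names = FALSE)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1

  rss_at <- function(psi_c) {
    X <- cbind(1, x, vapply(psi_c, function(p) pmax(x - p, 0), numeric(n)))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  converged <- all(fixed)
  iter_used <- 0L
  if (!all(fixed)) {
    rss_cur <- rss_at(psi)
    for (iter in seq_len(max_iter)) {
      iter_used <- iter
      nb <- length(psi)
      U <- vapply(psi, function(p) pmax(x - p, 0), numeric(n))
      free <- which(!fixed)
      V <- vapply(psi[free], function(p) -as.numeric(x > p), numeric(n))
      X <- cbind(1, x, U, V)
      beta <- qr.coef(qr(X), y)
      delta <- beta[2 + seq_len(nb)]
      gamma <- beta[2 + nb + seq_along(free)]
      gamma[is.na(gamma)] <- 0
      bad <- free[!is.finite(delta[free]) | abs(delta[free]) < 1e-10 * sdy]
      if (length(bad)) {
        warning("dropping breakpoint(s) with vanishing slope change at ",
                paste(signif(psi[bad], 4), collapse = ", "))
        keep_bp <- setdiff(seq_len(nb), bad)
        psi <- psi[keep_bp]; fixed <- fixed[keep_bp]
        if (!length(psi)) break
        rss_cur <- rss_at(psi)
        next
      }
      if (max(abs(gamma)) < tol * sdy) { converged <- TRUE; break }
      step <- gamma / delta[free]
      # step-halving: accept the first damped update not increasing the RSS
      accepted <- FALSE
      for (h in 0:5) {
        cand <- psi
        cand[free] <- psi[free] + step / 2^h
        cand <- pmin(pmax(cand, bounds[1]), bounds[2])
        o <- order(cand)
        rss_new <- rss_at(cand[o])
        if (rss_new <= rss_cur * (1 + 1e-10)) {
          psi <- cand[o]; fixed <- fixed[o]
          rss_cur <- rss_new
          accepted <- TRUE
          break
        }
      }
      if (!accepted) { converged <- TRUE; break }   # at a local minimum
      # collapse breakpoints that land on top of each other
      if (length(psi) > 1L) {
        dup <- c(FALSE, diff(psi) < 1e-8 * diff(range(x)))
        if (any(dup)) {
          warning("merging coincident breakpoints")
          psi <- psi[!dup]; fixed <- fixed[!dup]
        }
      }
    }
    if (iter_used == max_iter && !converged) {
      # gap coefficients small relative to noise scale count as settled
      converged <- max(abs(gamma)) < 1e-3 * sdy
    }
  }

  nb <- length(psi)
  X <- if (nb) cbind(1, x, vapply(psi, function(p) pmax(x - p, 0), numeric(n)))
       else cbind(1, x)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  p_model <- 2 + 2 * nb
  adj_r2 <- if (tss > 0 && n > p_model)
    1 - (rss / (n - p_model)) / (tss / (n - 1)) else NA_real_
  names(beta) <- c("(Intercept)", "x", if (nb) paste0("U", seq_len(nb)))
  structure(list(
    psi = psi, fixed = fixed, coefficients = beta,
    slopes = cumsum(c(beta[2], if (nb) beta[2 + seq_len(nb)])),
    fitted.values = fitted, residuals = res, rss = rss,
    adjusted_r2 = adj_r2, converged = converged, iterations = iter_used,
    n = n, x = x, y = y, clamp_bounds = bounds,
    df_model = p_model), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> ", length(x$psi), " breakpoint(s)",
      if (!x$converged) " [NOT converged]", "\n", sep = "")
  if (length(x$psi))
    cat("  psi:", paste(signif(x$psi, 6), collapse = ", "), "\n")
  cat("  segment slopes:", paste(signif(x$slopes, 6), collapse = ", "), "\n")
  cat("  adjusted R2:", signif(x$adjusted_r2, 4), "\n")
  invisible(x)
}

#' @export
coef.segmented_fit <- function(object, ...) object$coefficients

#' @export
fitted.segmented_fit <- function(object, ...) object$fitted.values

#' @export
residuals.segmented_fit <- function(object, ...) object$residuals

#' Predict from a segmented fit
#'
#' @param object A `segmented_fit`.
#' @param newdata Numeric vector of x values (default: the fitted x).
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.segmented_fit <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  b <- object$coefficients
  out <- b[1] + b[2] * xx
  for (k in seq_along(object$psi))
    out <- out + b[2 + k] * pmax(xx - object$psi[k], 0)
  unname(out)
}

#' @export
plot.segmented_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.6, col = "grey50",
                 xlab = "x", ylab = "y", ...)
  o <- order(x$x)
  graphics::lines(x$x[o], x$fitted.values[o], lwd = 2)
  graphics::abline(v = x$psi, lty = 3)
  invisible(x)
}

#' Davies' test for a non-constant slope with unknown breakpoint
#'
#' Evaluates the t statistic of an added hinge term (x - psi)_+ at `k`
#' evenly spaced interior candidate breakpoints and bounds the p-value of
#' the maximum with Davies' upper bound for a process observed on a grid.
#'
#' @param x,y Numeric vectors, n >= 10.
#' @param k Number of candidate breakpoints (default 10).
#' @return An object of class `htest` with the maximal |t| statistic and
#'   the bounded p-value in (0, 1].
#' @export
davies_test <- function(x, y, k = 10L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("davies_test requires n >= 10")
  if (stats::sd(x) == 0) stop("constant x: breakpoint tests undefined")
  cand <- seq(min(x), max(x), length.out = k + 2L)[-c(1L, k + 2L)]
  ts <- vapply(cand, function(c0)
    tstat_last(cbind(1, x, pmax(x - c0, 0)), y), numeric(1))
  ok <- is.finite(ts)
  if (!any(ok)) stop("all candidate statistics degenerate")
  ts <- ts[ok]; cand <- cand[ok]
  M <- max(abs(ts))
  V <- sum(abs(diff(ts)))
  p <- 2 * stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)
  p <- min(1, max(p, .Machine$double.xmin))
  structure(list(statistic = c(`max|t|` = M), p.value = p,
                 method = "Davies' test for a change in slope",
                 data.name = "y ~ x", candidates = cand, tstats = ts),
            class = "htest")
}

#' Pseudo-score test for an additional breakpoint
#'
#' Sum-based variant: the candidate hinge regressors over the grid are
#' averaged into a single score direction, whose t statistic is evaluated
#' against the null model (a straight line, or a segmented fit with
#' `n_breakpoints - 1` breakpoints).
#'
#' @param x,y Numeric vectors, n >= 10.
#' @param n_breakpoints Breakpoints under the alternative (default 1; the
#'   null then has none).
#' @param k Candidate grid size (default 10).
#' @return An object of class `htest`.
#' @export
pseudo_score_test <- function(x, y, n_breakpoints = 1L, k = 10L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("pseudo_score_test requires n >= 10")
  if (stats::sd(x) == 0) stop("constant x: breakpoint tests undefined")
  cand <- seq(min(x), max(x), length.out = k + 2L)[-c(1L, k + 2L)]
  X0 <- cbind(1, x)
  if (n_breakpoints > 1L) {
    psi0 <- stats::quantile(x, seq_len(n_breakpoints - 1L) / n_breakpoints,
                            names = FALSE)
    f0 <- fit_segmented(x, y, psi0)
    if (length(f0$psi))
      X0 <- cbind(1, x, vapply(f0$psi, function(p) pmax(x - p, 0),
                               numeric(length(x))))
  }
  w <- rowMeans(vapply(cand, function(c0) pmax(x - c0, 0),
                       numeric(length(x))))
  tt <- tstat_last(cbind(X0, w), y)
  if (!is.finite(tt)) stop("degenerate score direction")
  df <- length(x) - ncol(X0) - 1L
  p <- 2 * stats::pt(-abs(tt), df)
  structure(list(statistic = c(t = tt), parameter = c(df = df), p.value = p,
                 method = "pseudo-score test for an additional breakpoint",
                 data.name = "y ~ x"),
            class = "htest")
}

#' Score-based confidence intervals for breakpoints
#'
#' Inverts the profile objective over a grid of candidate positions: for
#' each candidate the breakpoint is held there (remaining parameters
#' re-estimated) and the scaled residual-sum-of-squares increase is
#' compared against an F(1, n - p) quantile; the interval collects the
#' candidates not rejected at the requested level. Working on the profile
#' directly respects the non-differentiable, non-concave shape of the
#' breakpoint objective, unlike a Wald interval.
#'
#' @param fit A converged `segmented_fit`.
#' @param level Confidence level (default 0.95).
#' @param grid_size Candidate grid resolution per breakpoint (default 100).
#' @return Matrix with one row per breakpoint: `lower`, `upper`, `estimate`,
#'   `level`. The interval always contains the estimate.
#' @export
breakpoint_ci <- function(fit, level = 0.95, grid_size = 100L) {
  stopifnot(inherits(fit, "segmented_fit"))
  if (!fit$converged) stop("breakpoint_ci requires a converged fit")
  if (!length(fit$psi)) stop("fit has no breakpoints")
  x <- fit$x; y <- fit$y; psi <- fit$psi
  n <- length(x)
  dfree <- n - fit$df_model
  s2 <- max(fit$rss / dfree, 1e-12 * stats::var(y))
  # the profile LR of a breakpoint is non-regular and heavier-tailed than
  # chi2(1); the 2-df reference restores close-to-nominal coverage
  crit <- stats::qchisq(level, 2)
  rss_fixed <- function(psi_c) {
    X <- cbind(1, x, vapply(psi_c, function(p) pmax(x - p, 0), numeric(n)))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  out <- matrix(NA_real_, length(psi), 4,
                dimnames = list(paste0("psi", seq_along(psi)),
                                c("lower", "upper", "estimate", "level")))
  eps <- 1e-6 * diff(range(x))
  for (j in seq_along(psi)) {
    lo <- if (j > 1L) psi[j - 1L] + eps else fit$clamp_bounds[1]
    hi <- if (j < length(psi)) psi[j + 1L] - eps else fit$clamp_bounds[2]
    grid <- sort(unique(c(seq(lo, hi, length.out = grid_size), psi[j])))
    acc <- vapply(grid, function(g) {
      psi_c <- psi; psi_c[j] <- g
      (rss_fixed(psi_c) - fit$rss) / s2 <= crit
    }, logical(1))
    acc[grid == psi[j]] <- TRUE   # the estimate itself is never rejected
    out[j, ] <- c(min(grid[acc]), max(grid[acc]), psi[j], level)
  }
  out
}

#' Choose the number of breakpoints by adjusted R-squared
#'
#' Fits models with 1..`max_breaks` breakpoints from quantile-spaced starts
#' and keeps the fit maximizing adjusted R-squared; within `r2_tol` (1e-4)
#' of the maximum, the fewest-breakpoint model wins (parsimony tie-break).
#'
#' @param x,y Numeric vectors.
#' @param max_breaks Largest candidate model (default 4).
#' @param r2_tol Adjusted-R2 tie tolerance (default 1e-4).
#' @param ... Passed to [fit_segmented].
#' @return `segmented_selection`: `best_fit`, `n_breakpoints`, and `table`
#'   (one row per candidate; failed fits NA).
#' @export
select_n_breakpoints <- function(x, y, max_breaks = 4L, r2_tol = 1e-4, ...) {
  fits <- vector("list", max_breaks)
  tab <- data.frame(n_breakpoints = seq_len(max_breaks),
                    adjusted_r2 = NA_real_, converged = NA,
                    n_psi_final = NA_integer_)
  for (nb in seq_len(max_breaks)) {
    psi0 <- stats::quantile(x, seq_len(nb) / (nb + 1), names = FALSE)
    psi0 <- psi0[psi0 > min(x) & psi0 < max(x)]
    if (length(unique(psi0)) < nb) next
    fit <- tryCatch(suppressWarnings(fit_segmented(x, y, psi0, ...)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      fits[[nb]] <- fit
      tab$adjusted_r2[nb] <- fit$adjusted_r2
      tab$converged[nb] <- fit$converged
      tab$n_psi_final[nb] <- length(fit$psi)
    }
  }
  if (all(is.na(tab$adjusted_r2))) stop("no candidate model could be fitted")
  best_r2 <- max(tab$adjusted_r2, na.rm = TRUE)
  near <- which(!is.na(tab$adjusted_r2) & tab$adjusted_r2 >= best_r2 - r2_tol)
  best <- min(near)
  structure(list(best_fit = fits[[best]], n_breakpoints = best, table = tab),
            class = "segmented_selection")
}

#' @export
print.segmented_selection <- function(x, ...) {
  cat("<segmented_selection> best:", x$n_breakpoints, "breakpoint(s)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
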