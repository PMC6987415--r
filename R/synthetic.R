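## Seeded generators producing expression matrices with the statistical
## structure the analysis pipeline assumes: cohorts mixing clusters along a
## nonlinear path in latent E/M activity space, induction time courses with
## piecewise-linear latent trajectories, and combinatorial perturbation
## panels driven by a TGF-beta/ZEB1 logic-gate model.

#' Specification of a synthetic cohort in latent E/M activity space
#'
#' The default geometry mirrors a five-cluster breast-cohort mixture: an
#' epithelial pole, a low-E-low-M cluster (I0), a hybrid high-E-high-M
#' cluster (I1), an M-adjacent intermediate (I2) and a mesenchymal pole,
#' with two three-step paths E-I0-I2-M and E-I1-I2-M as ground truth.
#'
#' @param centers K x 2 matrix of cluster centers (E_activity, M_activity),
#'   rownames = cluster names.
#' @param weights Mixing weights (sum to 1).
#' @param sds Per-cluster spherical spread in latent units.
#' @param sequences List of true path sequences (cluster name vectors).
#' @return `emt_path_spec` object.
#' @export
emt_path_spec <- function(
    centers = rbind(E = c(0.45, -0.35), I0 = c(-0.15, -0.30),
                    I1 = c(0.30, 0.25), I2 = c(-0.05, 0.35),
                    M = c(-0.50, 0.55)),
    weights = c(E = 0.30, I0 = 0.15, I1 = 0.22, I2 = 0.10, M = 0.23),
    sds = rep(0.07, nrow(centers)),
    sequences = list(c("E", "I0", "I2", "M"), c("E", "I1", "I2", "M"))) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2L, length(weights) == nrow(centers),
            length(sds) == nrow(centers))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (anyDuplicated(centers)) stop("cluster centers must be distinct")
  colnames(centers) <- c("E_activity", "M_activity")
  structure(list(centers = centers, weights = weights, sds = sds,
                 sequences = sequences), class = "emt_path_spec")
}

# gene-level linear read-out of a latent activity, on log2 scale; slope
# range chosen so the kernel-CDF statistic stays un-saturated relative to
# the default gene noise (see the methods vignette)
synth_gene_params <- function(n_e, n_m, n_bg) {
  data.frame(
    gene = c(sprintf("EG%03d", seq_len(n_e)), sprintf("MG%03d", seq_len(n_m)),
             if (n_bg) sprintf("BG%03d", seq_len(n_bg))),
    class = c(rep("E", n_e), rep("M", n_m), rep("background", n_bg)),
    baseline = stats::runif(n_e + n_m + n_bg, 3, 9),
    slope = c(stats::runif(n_e + n_m, 0.5, 1.5), rep(0, n_bg)))
}

#' Sample score-space points directly from a path specification
#'
#' Draws (E, M) score pairs straight from the cluster mixture of `spec`,
#' bypassing the gene-expression read-out — the form in which mixture and
#' path recovery are benchmarked (enrichment scores are cohort-relative
#' ranks, so the expression round trip distorts absolute geometry; see the
#' methods vignette).
#'
#' @param spec An [emt_path_spec].
#' @param n_samples Number of points.
#' @param seed Seed.
#' @return List with `scores` (a `score_table` with E and M columns) and
#'   `cluster` (true labels).
#' @export
sample_path_spec <- function(spec = emt_path_spec(), n_samples = 1200L,
                             seed) {
  set.seed(seed)
  K <- nrow(spec$centers)
  comp <- sample.int(K, n_samples, replace = TRUE, prob = spec$weights)
  pts <- spec$centers[comp, , drop = FALSE] +
    matrix(stats::rnorm(2 * n_samples), n_samples) * spec$sds[comp]
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                    E = pts[, 1], M = pts[, 2])
  class(out) <- c("score_table", class(out))
  list(scores = out, cluster = rownames(spec$centers)[comp])
}

synth_expression <- function(gene_params, latent, noise_sd) {
  n <- nrow(latent)
  act <- matrix(0, nrow(gene_params), n)
  act[gene_params$class == "E", ] <-
    matrix(latent[, 1], sum(gene_params$class == "E"), n, byrow = TRUE)
  act[gene_params$class == "M", ] <-
    matrix(latent[, 2], sum(gene_params$class == "M"), n, byrow = TRUE)
  log2e <- gene_params$baseline + gene_params$slope * act +
    matrix(stats::rnorm(nrow(gene_params) * n, sd = noise_sd),
           nrow(gene_params))
  v <- 2^log2e
  rownames(v) <- gene_params$gene
  v
}

synth_sets <- function(gene_params) {
  gene_set_collection(list(
    gene_set("E", gene_params$gene[gene_params$class == "E"]),
    gene_set("M", gene_params$gene[gene_params$class == "M"])))
}

#' Generate a synthetic cohort along the EMT path mixture
#'
#' Samples latent (E_activity, M_activity) pairs from the cluster mixture
#' of `spec`, maps them to gene expression with positive per-gene slopes
#' plus Gaussian log-scale noise, and emits a linear-scale (RSEM/FPKM-like)
#' matrix. Background genes are latent-independent. Deterministic under
#' `seed`.
#'
#' @param spec An [emt_path_spec].
#' @param n_samples Cohort size (default 500).
#' @param n_e_genes,n_m_genes,n_background Gene counts (defaults 120, 100,
#'   120).
#' @param gene_noise_sd Log2-scale gene noise (default 0.7).
#' @param seed Seed (required).
#' @return List with `matrix` ([expression_matrix] with cluster metadata),
#'   `sets` (E/M [gene_set_collection] annotation), and `truth` (latent
#'   n x 2, cluster labels, gene parameters, spec, seed).
#' @export
generate_cohort <- function(spec = emt_path_spec(), n_samples = 500L,
                            n_e_genes = 120L, n_m_genes = 100L,
                            n_background = 120L, gene_noise_sd = 0.7,
                            seed) {
  stopifnot(inherits(spec, "emt_path_spec"), n_samples >= 1L)
  set.seed(seed)
  K <- nrow(spec$centers)
  comp <- sample.int(K, n_samples, replace = TRUE, prob = spec$weights)
  latent <- spec$centers[comp, , drop = FALSE] +
    matrix(stats::rnorm(2 * n_samples), n_samples) * spec$sds[comp]
  gp <- synth_gene_params(n_e_genes, n_m_genes, n_background)
  v <- synth_expression(gp, latent, gene_noise_sd)
  colnames(v) <- sprintf("S%04d", seq_len(n_samples))
  meta <- data.frame(sample_id = colnames(v),
                     cluster = rownames(spec$centers)[comp])
  list(matrix = expression_matrix(v, meta), sets = synth_sets(gp),
       truth = list(latent = latent, cluster = meta$cluster,
                    gene_params = gp, spec = spec, seed = seed))
}

#' Generate a low-E-low-M outgroup poolable with a cohort
#'
#' Emits samples whose latent E and M activities lie far below every
#' cohort cluster — a surrogate for a non-epithelial lineage. Uses the
#' cohort's gene parameters so the matrices can be column-bound and scored
#' jointly. The outgroup alone carries no E/M contrast, so it cannot be
#' scored against itself; it is meant to be pooled.
#'
#' @param n Number of outgroup samples.
#' @param template The `truth` element of a [generate_cohort] result.
#' @param seed Seed.
#' @param center Latent center (default c(-1.5, -1.5)).
#' @param sd Latent spread (default 0.07).
#' @return List with `matrix` and `truth` (latent, seed).
#' @export
generate_outgroup <- function(n, template, seed, center = c(-1.5, -1.5),
                              sd = 0.07) {
  stopifnot(n >= 1L, !is.null(template$gene_params))
  set.seed(seed)
  latent <- matrix(center, n, 2, byrow = TRUE) +
    matrix(stats::rnorm(2 * n, sd = sd), n)
  noise <- template$noise_sd %||% 0.7
  v <- synth_expression(template$gene_params, latent, noise)
  colnames(v) <- sprintf("OUT%04d", seq_len(n))
  meta <- data.frame(sample_id = colnames(v), cluster = "outgroup")
  list(matrix = expression_matrix(v, meta),
       truth = list(latent = latent, seed = seed))
}

#' Evaluate a piecewise-linear trajectory
#'
#' @param t Times at which to evaluate.
#' @param y0 Value at t = 0.
#' @param slopes One slope per phase (length = breaks + 1).
#' @param breaks Ascending breakpoint times.
#' @return Trajectory values at `t`.
#' @export
piecewise_linear <- function(t, y0, slopes, breaks) {
  stopifnot(length(slopes) == length(breaks) + 1L)
  y <- y0 + slopes[1] * pmin(t, breaks[1])
  for (k in seq_along(breaks)) {
    seg_end <- if (k < length(breaks)) breaks[k + 1L] else Inf
    y <- y + slopes[k + 1L] * pmax(pmin(t, seg_end) - breaks[k], 0)
  }
  y
}

#' Generate a TGF-beta-like induction time course
#'
#' Latent E and M activities follow triphasic piecewise-linear
#' trajectories with breakpoints at 2.5 and 10 days by default (an early
#' M-driven phase, a slow hybrid middle phase, then a late E-repression
#' phase), evaluated at each time x replicate with latent noise, and mapped
#' to genes as in [generate_cohort].
#'
#' @param times Sampling days (default c(0, 1, 2, 3, 4, 5, 8, 12, 16, 21)).
#' @param replicates Replicates per time (default 3).
#' @param breakpoints Trajectory breakpoints in days (default c(2.5, 10)).
#' @param e_start,m_start Latent values at day 0.
#' @param e_slopes,m_slopes Per-phase slopes (latent units/day).
#' @param latent_sd Replicate-level latent noise (default 0.02).
#' @param n_e_genes,n_m_genes,n_background,gene_noise_sd As in
#'   [generate_cohort].
#' @param seed Seed.
#' @return List with `matrix` (`time_days` and `replicate` metadata),
#'   `sets`, and `truth` (per-sample times, latent, trajectory parameters).
#' @export
generate_timecourse <- function(times = c(0, 1, 2, 3, 4, 5, 8, 12, 16, 21),
                                replicates = 3L, breakpoints = c(2.5, 10),
                                e_start = 0.45, m_start = -0.35,
                                e_slopes = c(0.04, -0.02, -0.082),
                                m_slopes = c(0.10, 0.02, 0.05),
                                latent_sd = 0.02, n_e_genes = 120L,
                                n_m_genes = 100L, n_background = 120L,
                                gene_noise_sd = 0.7, seed) {
  stopifnot(length(times) >= 2L)
  set.seed(seed)
  tt <- rep(times, each = replicates)
  n <- length(tt)
  latent <- cbind(
    piecewise_linear(tt, e_start, e_slopes, breakpoints),
    piecewise_linear(tt, m_start, m_slopes, breakpoints)) +
    matrix(stats::rnorm(2 * n, sd = latent_sd), n)
  gp <- synth_gene_params(n_e_genes, n_m_genes, n_background)
  v <- synth_expression(gp, latent, gene_noise_sd)
  colnames(v) <- sprintf("T%05.1f_R%d", tt, rep(seq_len(replicates),
                                                length(times)))
  meta <- data.frame(sample_id = colnames(v), time_days = tt,
                     replicate = rep(seq_len(replicates), length(times)))
  list(matrix = expression_matrix(v, meta), sets = synth_sets(gp),
       truth = list(times = tt, latent = latent,
                    breakpoints = breakpoints,
                    e_slopes = e_slopes, m_slopes = m_slopes, seed = seed))
}

#' Default TGF-beta/ZEB1 logic-gate model for E/M gene subclusters
#'
#' Six subcluster archetypes with distinct regulatory circuits, responses
#' in effect units as a function of TGFB and ZEB1 levels in [0, 1]:
#' E1 is repressed through an OR gate (either factor suffices); E2 is
#' activated by TGF-beta only when ZEB1 is absent and repressed by ZEB1
#' (incoherent feed-forward — the transiently pulsing cluster); E3 is
#' AND-repressed with an opposite (activating) effect of TGF-beta alone;
#' M1 is AND-activated with a reduced effect of TGF-beta alone; M2 is
#' OR-activated; M3 responds to ZEB1 alone.
#'
#' @return `gate_model`: list of subcluster descriptors with `name`,
#'   `class`, `regulators`, `gate`, and `response(T, Z)`.
#' @export
default_gate_model <- function() {
  sub <- function(name, class, regulators, gate, response)
    list(name = name, class = class, regulators = regulators, gate = gate,
         response = response)
  structure(list(
    sub("E1", "E", c("TGFB", "ZEB1"), "OR",
        function(T, Z) -pmax(T, Z)),
    sub("E2", "E", c("TGFB", "ZEB1"), "ffl-incoherent",
        function(T, Z) T * (1 - Z) - Z),
    sub("E3", "E", c("TGFB", "ZEB1"), "AND",
        function(T, Z) -T * Z + 0.5 * T * (1 - Z)),
    sub("M1", "M", c("TGFB", "ZEB1"), "AND",
        function(T, Z) 0.5 * T + 0.5 * T * Z),
    sub("M2", "M", c("TGFB", "ZEB1"), "OR",
        function(T, Z) pmax(T, Z)),
    sub("M3", "M", "ZEB1", "single",
        function(T, Z) Z)), class = "gate_model")
}

#' Generate a combinatorial TGF-beta/ZEB1 perturbation panel
#'
#' Each subcluster's mean response under every condition comes from its
#' logic gate; per-gene amplitudes and Gaussian log-scale noise are laid on
#' top, and the matrix is emitted on linear scale. Deterministic under
#' `seed`.
#'
#' @param gates A `gate_model` (default [default_gate_model()]).
#' @param conditions Data.frame with numeric `TGFB` and `ZEB1` columns
#'   (levels in [0, 1]). Default: the 2 x 2 on/off factorial. Both
#'   regulator levels must be present for every condition.
#' @param replicates Samples per condition (default 2).
#' @param genes_per_subcluster Default 40.
#' @param gene_noise_sd Log2-scale noise (default 0.3).
#' @param seed Seed.
#' @param check_factorial Require the full 2 x 2 on/off factorial among the
#'   conditions (default TRUE; disable for, e.g., time-course ramps).
#' @return List with `matrix` (metadata `TGFB`, `ZEB1`, `replicate`),
#'   `sets` (annotated E/M gene sets), and `truth` (per-gene subcluster,
#'   condition table, seed).
#' @export
generate_perturbation_panel <- function(gates = default_gate_model(),
                                        conditions = NULL, replicates = 2L,
                                        genes_per_subcluster = 40L,
                                        gene_noise_sd = 0.3, seed,
                                        check_factorial = TRUE) {
  if (is.null(conditions))
    conditions <- expand.grid(TGFB = c(0, 1), ZEB1 = c(0, 1))
  conditions <- as.data.frame(conditions)
  if (is.null(conditions$TGFB) || is.null(conditions$ZEB1) ||
      anyNA(conditions$TGFB) || anyNA(conditions$ZEB1))
    stop("every condition must state both TGFB and ZEB1 levels")
  if (check_factorial) {
    need <- expand.grid(TGFB = c(0, 1), ZEB1 = c(0, 1))
    have <- paste(conditions$TGFB, conditions$ZEB1)
    if (!all(paste(need$TGFB, need$ZEB1) %in% have))
      stop("conditions must include the 2 x 2 TGFB/ZEB1 factorial ",
           "(set check_factorial = FALSE to relax)")
  }
  set.seed(seed)
  nc <- nrow(conditions); ns <- nc * replicates
  cond_idx <- rep(seq_len(nc), each = replicates)
  gene_rows <- list(); resp <- list()
  for (g in gates) {
    genes <- sprintf("%s_g%03d", g$name, seq_len(genes_per_subcluster))
    gene_rows[[g$name]] <- data.frame(
      gene = genes, class = g$class, subcluster = g$name,
      baseline = stats::runif(genes_per_subcluster, 4, 8),
      amplitude = stats::runif(genes_per_subcluster, 1.5, 2.5))
    resp[[g$name]] <- g$response(conditions$TGFB, conditions$ZEB1)
  }
  gp <- do.call(rbind, gene_rows)
  R <- do.call(rbind, lapply(gp$subcluster, function(s) resp[[s]]))  # genes x cond
  log2e <- gp$baseline + gp$amplitude * R[, cond_idx, drop = FALSE] +
    matrix(stats::rnorm(nrow(gp) * ns, sd = gene_noise_sd), nrow(gp))
  v <- 2^log2e
  rownames(v) <- gp$gene
  colnames(v) <- sprintf("C%02d_R%d", cond_idx,
                         rep(seq_len(replicates), nc))
  meta <- data.frame(sample_id = colnames(v),
                     TGFB = conditions$TGFB[cond_idx],
                     ZEB1 = conditions$ZEB1[cond_idx],
                     replicate = rep(seq_len(replicates), nc))
  sets <- gene_set_collection(list(
    gene_set("E", gp$gene[gp$class == "E"]),
    gene_set("M", gp$gene[gp$class == "M"])))
  list(matrix = expression_matrix(v, meta), sets = sets,
       truth = list(gene_params = gp, conditions = conditions,
                    seed = seed))
}

#' Generate an induction time course driven by the logic-gate model
#'
#' Convenience wrapper: TGF-beta switches on at day 0 and stays on, ZEB1
#' ramps up linearly to full level at `zeb1_full_day`; each time point is a
#' condition of [generate_perturbation_panel]. The incoherent feed-forward
#' subcluster (E2) therefore pulses: it rises while ZEB1 is still low and
#' falls as ZEB1 accumulates.
#'
#' @param times Sampling days.
#' @param zeb1_full_day Day at which ZEB1 reaches its full level
#'   (default 10).
#' @param replicates,gates,genes_per_subcluster,gene_noise_sd,seed As in
#'   [generate_perturbation_panel].
#' @return As [generate_perturbation_panel], with `time_days` metadata.
#' @export
generate_gate_timecourse <- function(times = c(0, 1, 2, 3, 4, 5, 8, 12, 16, 21),
                                     zeb1_full_day = 10,
                                     replicates = 3L,
                                     gates = default_gate_model(),
                                     genes_per_subcluster = 40L,
                                     gene_noise_sd = 0.3, seed) {
  conditions <- data.frame(TGFB = as.numeric(times > 0),
                           ZEB1 = pmin(times / zeb1_full_day, 1))
  out <- generate_perturbation_panel(
    gates = gates, conditions = conditions, replicates = replicates,
    genes_per_subcluster = genes_per_subcluster,
    gene_noise_sd = gene_noise_sd, seed = seed, check_factorial = FALSE)
  out$matrix$sample_meta$time_days <- rep(times, each = replicates)
  out$truth$times <- rep(times, each = replicates)
  out
}
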