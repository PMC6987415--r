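#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML file; every tolerance, grid and seed
#' the pipeline uses is surfaced there, since reproducibility hinges on
#' otherwise-unstated defaults.
#'
#' @param path Path to a YAML file, or a list already in memory.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  config <- if (is.list(path)) path else yaml::read_yaml(path)
  validate_pipeline_config(config)
}

#' @rdname read_pipeline_config
#' @param config A config list.
#' @export
validate_pipeline_config <- function(config) {
  modes <- c("cohort", "timecourse", "perturbation", "simulate")
  if (is.null(config$mode) || !config$mode %in% modes)
    stop("config$mode must be one of: ", paste(modes, collapse = ", "))
  config$alpha <- config$alpha %||% 0.05
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    stop("alpha must lie in (0, 1)")
  config$seed <- as.integer(config$seed %||% 1L)
  config$output_dir <- config$output_dir %||% "emtspectrum_out"
  config$scoring <- config$scoring %||% list()
  config$gmm <- config$gmm %||% list()
  if (config$mode %in% c("cohort", "timecourse", "perturbation") &&
      is.null(config$simulate) &&
      (is.null(config$matrix) || is.null(config$gene_sets)))
    stop("mode '", config$mode, "' needs either input paths ",
         "(matrix, gene_sets) or a simulate: block")
  class(config) <- c("pipeline_config", "list")
  config
}

pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    args <- sim[setdiff(names(sim), "kind")]
    args$seed <- args$seed %||% config$seed
    kind <- sim$kind %||% "cohort"
    gen <- switch(kind,
                  cohort = generate_cohort,
                  timecourse = generate_timecourse,
                  perturbation = generate_perturbation_panel,
                  gate_timecourse = generate_gate_timecourse,
                  stop("unknown simulate kind: ", kind))
    do.call(gen, args)
  } else {
    m <- read_expression_matrix(config$matrix)
    if (!is.null(config$sample_meta))
      m$sample_meta <- utils::read.delim(config$sample_meta)
    list(matrix = m, sets = read_gene_sets(config$gene_sets), truth = NULL)
  }
}

segfit_record <- function(fit) {
  list(psi = fit$psi, coefficients = as.list(fit$coefficients),
       slopes = fit$slopes, adjusted_r2 = fit$adjusted_r2,
       converged = fit$converged)
}

gmm_record <- function(fit) {
  list(K = fit$K, structure = fit$structure, weights = fit$weights,
       means = fit$means, variances = fit$variances, loglik = fit$loglik,
       npar = fit$npar, bic = fit$bic)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates one of four analyses from a single config: `simulate`
#' (emit a synthetic data set), `cohort` (score, quadrant census, mixture
#' selection, cluster assignment, EMT path models, cluster comparisons),
#' `timecourse` (score, triphasic segmented models, bound models), or
#' `perturbation` (SOM subclustering of E/M genes). Stage outputs are
#' written deterministically under the configured seed; a failed stage is
#' recorded in the report and later stages are skipped, with earlier
#' outputs retained.
#'
#' @param config Path to a YAML config, or a config list (see
#'   [read_pipeline_config]).
#' @param out_dir Output directory (default from the config).
#' @return Run report (invisibly): artifact paths with MD5 checksums, the
#'   seed, package version, and any warnings or failed stage. Also written
#'   as `report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(mode = config$mode, seed = config$seed,
                 package_version = as.character(utils::packageVersion("emtspectrum")),
                 files = character(0), warnings = character(0),
                 failed_stage = NULL)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    report$files <<- c(report$files, path)
    path
  }
  warn_collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) {
    tryCatch(warn_collect(expr), error = function(e) {
      report$failed_stage <<- c(name, conditionMessage(e))
      NULL
    })
  }

  data <- stage("input", pipeline_inputs(config))
  if (!is.null(data)) {
    emit("matrix.tsv", function(p) write_expression_matrix(data$matrix, p))
    if (!is.null(data$sets))
      emit("gene_sets.gmt", function(p) write_gmt(data$sets, p))
    params <- do.call(walk_params, config$scoring[
      intersect(names(config$scoring),
                c("tau", "es_mode", "kernel", "bandwidth_divisor"))])
    log_tr <- config$scoring$log_transform %||% TRUE
    scores <- if (!is.null(data$sets))
      stage("scoring", suppressMessages(
        score_matrix(data$matrix, data$sets, params = params,
                     log_transform = log_tr)))
    if (!is.null(scores)) {
      emit("scores.tsv", function(p) write_score_table(scores, p))
      if (config$mode == "cohort")
        report <- pipeline_cohort(config, data, scores, emit, stage, report)
      if (config$mode == "timecourse")
        report <- pipeline_timecourse(config, data, scores, emit, stage,
                                      report)
    }
    if (config$mode == "perturbation")
      report <- pipeline_perturbation(config, data, emit, stage, report)
  }
  report$checksums <- as.list(tools::md5sum(report$files))
  emit_report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report[setdiff(names(report), "files")], emit_report,
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}

pipeline_cohort <- function(config, data, scores, emit, stage, report) {
  census <- stage("census", quadrant_census(scores))
  if (!is.null(census))
    emit("quadrant_census.tsv", function(p)
      utils::write.table(census, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  sel <- stage("gmm", do.call(select_model, c(list(scores), config$gmm[
    intersect(names(config$gmm), c("K_range", "structures"))])))
  if (is.null(sel)) return(report)
  emit("bic_table.tsv", function(p)
    utils::write.table(sel$table, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("gmm.json", function(p)
    jsonlite::write_json(gmm_record(sel$best_fit), p, auto_unbox = TRUE,
                         digits = NA))
  asg <- stage("assignment", assign_clusters(sel$best_fit, scores))
  if (is.null(asg)) return(report)
  emit("assignment.tsv", function(p) {
    df <- data.frame(sample_id = scores$sample_id, component = asg$labels,
                     uncertainty = asg$uncertainty)
    if (!is.null(asg$semantic_labels)) df$cluster <- asg$semantic_labels
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  if (!is.null(asg$semantic)) {
    paths <- stage("paths", enumerate_min_paths(sel$best_fit))
    if (!is.null(paths)) {
      path_fits <- stage("path_fits", lapply(paths, function(pth)
        fit_emt_path(scores, asg, pth)))
      if (!is.null(path_fits))
        emit("emt_paths.json", function(p) jsonlite::write_json(
          lapply(path_fits, function(pf) list(
            sequence = pf$cluster_sequence, n_members = pf$n_members,
            fit = segfit_record(pf$fit),
            reference_adjusted_r2 = pf$reference_fit$adjusted_r2,
            davies_p = pf$davies_p, pseudo_score_p = pf$pseudo_score_p)),
          p, auto_unbox = TRUE, digits = NA))
    }
    cmp <- stage("comparisons", compare_all(scores, asg))
    if (!is.null(cmp))
      emit("cluster_comparisons.tsv", function(p)
        utils::write.table(cmp, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))
  }
  report
}

pipeline_timecourse <- function(config, data, scores, emit, stage, report) {
  times <- data$matrix$sample_meta$time_days %||% config$times
  if (is.null(times)) {
    report$failed_stage <- c("timecourse", "no time_days metadata")
    return(report)
  }
  model <- stage("timecourse", {
    m <- fit_timecourse(times, scores)
    tryCatch(bound_models(m), error = function(e) m)
  })
  if (!is.null(model))
    emit("timecourse_model.json", function(p) jsonlite::write_json(
      list(e_fit = segfit_record(model$e_fit),
           m_fit = segfit_record(model$m_fit),
           comparison = model$comparison,
           e_ci = if (!is.null(model$e_ci)) as.data.frame(model$e_ci)),
      p, auto_unbox = TRUE, digits = NA))
  report
}

pipeline_perturbation <- function(config, data, emit, stage, report) {
  prof <- log2(data$matrix$values + 1)
  som <- stage("som", train_som(prof, seed = config$seed))
  if (is.null(som)) return(report)
  subs <- stage("subclusters", {
    labels <- classify_nodes(som, data$sets[["E"]], data$sets[["M"]])
    c(subcluster_nodes(som, labels, "E"),
      subcluster_nodes(som, labels, "M"))
  })
  if (!is.null(subs))
    emit("subclusters.tsv", function(p)
      utils::write.table(subcluster_table(subs), p, sep = "\t",
                         quote = FALSE, row.names = FALSE))
  report
}
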