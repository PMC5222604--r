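#' Load a pipeline run configuration
#'
#' YAML configuration with defaults filled in. Recognised fields: `seed`,
#' input paths (`rnaseq_matrix`, `panel_matrix`, `panel_design`,
#' `fold_change_table`, `candidates`) or `simulate: true` to generate all
#' inputs, `reference_gene`, `min_count`, `pseudocount`, `meta_threshold`,
#' `meta_fraction`, `young_age`, `old_age`, `alpha`, `family_size`,
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config Named list of configuration values; missing entries take the
#'   documented defaults.
#' @export
run_config <- function(config = list()) {
  defaults <- list(
    seed = 1L, simulate = TRUE,
    rnaseq_matrix = NULL, panel_matrix = NULL, panel_design = NULL,
    fold_change_table = NULL, candidates = NULL,
    reference_gene = "Cry2", min_count = 20, pseudocount = 0.5,
    meta_threshold = 1.2, meta_fraction = 0.9,
    young_age = 3, old_age = 24, alpha = 0.05, family_size = NULL,
    out_dir = "stabnorm_results"
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (cfg$meta_fraction <= 0 || cfg$meta_fraction > 1)
    stop("meta_fraction must lie in (0, 1]")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$min_count < 0) stop("min_count must be non-negative")
  class(cfg) <- c("run_config", "list")
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

.load_pipeline_inputs <- function(config) {
  if (isTRUE(config$simulate)) {
    params <- default_panel_params()
    panel <- simulate_panel(panel_design(), params, seed = config$seed)
    screen <- simulate_rnaseq_screen(n_genes = 1444, n_age_pools = 4,
                                     stable_fraction = 0.1,
                                     seed = config$seed + 1L)
    candidates <- params$gene_id[seq_len(16)]
    # plant the candidate genes in the genome-wide screen so the median
    # criterion can see them: stable, well-expressed profiles
    set.seed(config$seed + 2L)
    cand_baseline <- params$baseline[seq_len(16)]
    cand <- matrix(stats::rnbinom(16 * ncol(screen$matrix),
                                  mu = rep(cand_baseline, ncol(screen$matrix)) *
                                    rep(screen$truth$depth_factors, each = 16),
                                  size = 100),
                   16, ncol(screen$matrix),
                   dimnames = list(candidates, colnames(screen$matrix)))
    screen$matrix <- rbind(cand, screen$matrix)
    scales <- stats::setNames(rep(0.05, 16), candidates)
    meta <- simulate_meta_studies(candidates, n_studies = 130,
                                  stability_profile = scales,
                                  seed = config$seed + 3L)
    list(rnaseq = screen$matrix, panel = panel$matrix,
         panel_design = panel$design, fold_changes = meta,
         candidates = candidates)
  } else {
    need <- c("rnaseq_matrix", "panel_matrix", "panel_design",
              "fold_change_table", "candidates")
    missing <- need[vapply(need, function(f) is.null(config[[f]]), logical(1L))]
    if (length(missing))
      stop("configuration missing input path(s): ", paste(missing, collapse = ", "))
    list(rnaseq = read_expression_matrix(config$rnaseq_matrix),
         panel = read_expression_matrix(config$panel_matrix),
         panel_design = read_sample_design(config$panel_design),
         fold_changes = read_fold_change_table(config$fold_change_table),
         candidates = read_candidate_set(config$candidates))
  }
}

#' Run the full selection-normalisation-detection pipeline
#'
#' Chains the three analysis stages: (1) stability selection of marker genes
#' from a genome-wide screen, a targeted panel and a meta-analytic
#' fold-change table; (2) geometric-mean normalisation of the panel by the
#' extended marker set; (3) repeated-measures detection of age effects on the
#' normalised panel. With `simulate: true` (the default) all inputs are
#' generated by the synthetic-data module under the configured seed, making
#' the run fully reproducible; otherwise they are read from the configured
#' paths. Result tables are written to `out_dir` together with the
#' configuration (including its hash) and a plain-text log.
#'
#' @param config A `run_config` (or plain list of overrides).
#' @param out_dir Output directory; overrides `config$out_dir`; `NULL`
#'   disables writing.
#' @return List with `assessments`, `sets`, `factors`, `normalised`,
#'   `detection`, `config`, `config_hash`, and `log` (character vector).
#' @export
run_pipeline <- function(config = list(), out_dir = config$out_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  hash <- .config_hash(config)
  log <- c(sprintf("stabnorm pipeline, config hash %s, seed %d",
                   hash, config$seed))
  inputs <- .load_pipeline_inputs(config)
  if (!length(inputs$candidates)) stop("empty candidate list")
  log <- c(log, sprintf("inputs: %d-gene screen, %d-gene panel (%d samples), %d candidates",
                        nrow(inputs$rnaseq), nrow(inputs$panel),
                        ncol(inputs$panel), length(inputs$candidates)))

  sel <- run_selection(
    candidates = inputs$candidates,
    screens = list(rnaseq = list(matrix = inputs$rnaseq,
                                 min_count = config$min_count)),
    panel = list(matrix = inputs$panel,
                 reference_gene = config$reference_gene),
    fold_changes = inputs$fold_changes,
    pseudocount = config$pseudocount,
    meta_threshold = config$meta_threshold,
    meta_fraction = config$meta_fraction
  )
  log <- c(log, sprintf("selection: core = {%s}; extended = {%s}",
                        paste(sel$sets$core, collapse = ", "),
                        paste(sel$sets$extended, collapse = ", ")))
  if (!length(sel$sets$extended))
    stop("selection stage produced an empty extended marker set")

  factors <- marker_normalisation_factors(inputs$panel, sel$sets$extended)
  normalised <- apply_normalisation(inputs$panel, factors)
  log <- c(log, sprintf("normalisation: %d marker genes, factor range [%.3f, %.3f]",
                        length(sel$sets$extended), min(factors), max(factors)))

  test_genes <- setdiff(rownames(normalised), inputs$candidates)
  detection <- detect_age_effects(
    normalised, inputs$panel_design,
    young_age = config$young_age, old_age = config$old_age,
    alpha = config$alpha,
    family_size = if (is.null(config$family_size)) length(test_genes) else
      config$family_size,
    genes = test_genes
  )
  log <- c(log, sprintf("detection: %d genes tested, %d significant at alpha %g / %d",
                        nrow(detection), sum(detection$significant),
                        config$alpha,
                        if (is.null(config$family_size)) length(test_genes) else
                          config$family_size))

  result <- list(assessments = sel$assessments, sets = sel$sets,
                 factors = factors, normalised = normalised,
                 detection = detection, config = config, config_hash = hash,
                 log = log)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_assessment_table(sel$assessments,
                           file.path(out_dir, "assessments.tsv"))
    sets_df <- data.frame(
      gene_id = sel$sets$extended,
      set = ifelse(sel$sets$extended %in% sel$sets$core, "core", "extended"),
      stringsAsFactors = FALSE)
    write_report(list(marker_sets = sets_df, detection = detection), out_dir)
    write_expression_matrix(normalised,
                            file.path(out_dir, "normalised_matrix.tsv"))
    yaml::write_yaml(c(unclass(config), list(config_hash = hash)),
                     file.path(out_dir, "run_config.yaml"))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  result
}
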