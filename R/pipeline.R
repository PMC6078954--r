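#' Default pipeline configuration
#'
#' Stage parameters default to the analysis values: 500 permutations at
#' voxel threshold 0.05 for the lesion-mapping stage, 5 modeling
#' repetitions, train fraction 111/169, enhancement threshold z = 2,
#' 26-neighbor cluster connectivity.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    cohort_dir = NULL,
    output_dir = NULL,
    stages = list(simulate = TRUE, extract = TRUE, lesion_stats = TRUE,
                  model = TRUE),
    n_cases = 169L, n_institutions = 11L,
    grid_shape = c(40L, 40L, 40L), spacing_mm = c(2.5, 2.5, 2.5),
    n_permutations = 500L, alpha = 0.05, connectivity = 26L,
    flip_union = FALSE,
    n_rep = 5L, train_fraction = 111 / 169, n_folds = 10L,
    z_thresh = 2.0, task = "idh_binary",
    seed = 1L)
}

validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  # explicit nulls (e.g. `~` in YAML) mean "unset": fall back to defaults
  config <- config[!vapply(config, is.null, logical(1))]
  out <- utils::modifyList(def, config)
  if (out$alpha <= 0 || out$alpha >= 1) stop("alpha must be in (0, 1)")
  if (out$train_fraction <= 0 || out$train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (out$n_permutations < 1) stop("n_permutations must be >= 1")
  if (out$n_rep < 2) stop("n_rep must be >= 2")
  if (!out$connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  if (!out$task %in% c("idh_binary", "subtype_3class")) stop("unknown task")
  out
}

#' Load, save and validate a pipeline configuration
#'
#' `load_config()` reads a YAML configuration, rejects unknown keys,
#' checks ranges and fills defaults (see [default_config()]).
#' `save_config()` writes a configuration at full numeric precision,
#' omitting unset (NULL) entries, so that save/load round-trips are
#' exact.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' @rdname load_config
#' @param config configuration list to write.
#' @export
save_config <- function(config, path) {
  cfg <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(cfg, path, precision = 17L)
  invisible(path)
}

#' Derive a stage seed from the master seed
#'
#' Deterministic per-stage seeds (stage-name hashing) so stages can be
#' re-run independently while the whole pipeline stays reproducible.
#'
#' @param master master seed (integer).
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483629)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> extract (normalization, derived channels,
#' 109-feature table) -> lesion mapping (voxel-wise Fisher + cluster
#' permutation correction) -> predictive modeling (repeated
#' institution-balanced LASSO with and without location features), and
#' returns an aggregated run report. With `config$output_dir` set, the
#' feature table, cluster table, metrics and the report JSON are written
#' there.
#'
#' @param config configuration list (see [default_config()]); validated
#'   before use.
#' @return report list (feature counts, split sizes, cluster table,
#'   metric summaries, seeds and parameter echo).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  report <- list(parameters = cfg[c("n_cases", "n_institutions",
                                    "n_permutations", "alpha", "n_rep",
                                    "train_fraction", "z_thresh",
                                    "connectivity", "task", "seed")],
                 stages_run = character(0))
  if (!any(unlist(cfg$stages))) return(report)

  cohort <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    spec <- cohort_spec(n_cases = cfg$n_cases,
                        n_institutions = cfg$n_institutions,
                        grid_shape = cfg$grid_shape,
                        spacing_mm = cfg$spacing_mm,
                        seed = derive_seed(cfg$seed, "simulate"))
    cohort <- simulate_cohort(spec, dir = cfg$cohort_dir)
    report$stages_run <- c(report$stages_run, "simulate")
    report$n_cases_simulated <- length(cohort$cases)
    report$subtype_counts <- as.list(table(cohort$manifest$subtype))
  }
  if (isTRUE(cfg$stages$extract)) {
    if (is.null(cohort)) stop("extract stage needs a simulated cohort")
    table <- assemble_feature_table(cohort$cases, cohort$atlas_mni,
                                    cohort$atlas_ho, z_thresh = cfg$z_thresh)
    report$stages_run <- c(report$stages_run, "extract")
    report$n_features <- length(feature_columns(table))
    report$n_cases_complete <- nrow(table)
  }
  if (isTRUE(cfg$stages$lesion_stats)) {
    if (is.null(cohort)) stop("lesion_stats stage needs a simulated cohort")
    vois <- lapply(cohort$cases, `[[`, "voi")
    cl <- cluster_permutation_correct(
      vois, cohort$manifest$subtype, n_permutations = cfg$n_permutations,
      alpha = cfg$alpha, connectivity = cfg$connectivity,
      seed = derive_seed(cfg$seed, "lesion_stats"),
      flip_union = cfg$flip_union)
    report$stages_run <- c(report$stages_run, "lesion_stats")
    report$clusters <- cl$clusters
    report$n_significant_clusters <- sum(cl$clusters$significant)
    cluster_result <- cl
  }
  if (isTRUE(cfg$stages$model)) {
    if (!isTRUE(cfg$stages$extract)) stop("model stage needs the feature table")
    rc <- repeat_and_compare(table, task = cfg$task, n_rep = cfg$n_rep,
                             train_fraction = cfg$train_fraction,
                             n_folds = cfg$n_folds,
                             seed = derive_seed(cfg$seed, "model"))
    report$stages_run <- c(report$stages_run, "model")
    sp <- institution_balanced_split(table, cfg$train_fraction,
                                     seed = derive_seed(cfg$seed, "model") + 1L)
    report$split_sizes <- c(train = length(sp$train),
                            validation = length(sp$validation))
    report$metrics <- lapply(rc$summary, function(s)
      stats::setNames(as.list(s$mean), s$metric))
    report$metrics_sd <- lapply(rc$summary, function(s)
      stats::setNames(as.list(s$sd), s$metric))
    report$location_comparison_p <- rc$comparison_p
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (exists("table", inherits = FALSE))
      utils::write.csv(table, file.path(cfg$output_dir, "feature_table.csv"),
                       row.names = FALSE)
    if (exists("cluster_result", inherits = FALSE))
      utils::write.csv(cluster_result$clusters,
                       file.path(cfg$output_dir, "clusters.csv"),
                       row.names = FALSE)
    jsonlite::write_json(report_for_json(report),
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_for_json <- function(report) {
  conv <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.table(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, conv))
    x
  }
  conv(report)
}
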