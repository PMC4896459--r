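log_stage <- function(stage, ..., level = "info", log_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[log_level]])
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Assemble a pipeline configuration
#'
#' Either simulate inputs (`simulate = TRUE`, using `sim`) or read them
#' from `microdata_path` / `macro_path`. All downstream options of the
#' chain (model list, cross-validation sizes, interval construction) are
#' collected here so a run is fully described by one object.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed integer seed controlling every random draw.
#' @param simulate generate synthetic inputs (default TRUE).
#' @param sim an [sim_config()]; its seed is overridden by `seed`.
#' @param microdata_path,macro_path input CSVs when `simulate = FALSE`.
#' @param models which candidate models to fit (names into
#'   [default_model_specs()]).
#' @param cv_k leave-out sizes to compute.
#' @param criterion_k leave-out size driving model selection.
#' @param z,rmse_k confidence-interval construction (see
#'   [predict_all_lmics()]).
#' @param use_observed substitute observed prevalences for surveyed
#'   countries in the projection.
#' @param log_level one of "debug", "info", "warn", "error".
#' @return list of class `ecdi_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            sim = sim_config(),
                            microdata_path = NULL, macro_path = NULL,
                            models = c("stunting", "hdi", "both"),
                            cv_k = c(1L, 2L), criterion_k = 1L,
                            z = 1.96, rmse_k = 2L, use_observed = FALSE,
                            log_level = "info") {
  if (z <= 0) stop("invalid configuration field 'z': must be positive")
  if (!simulate) {
    for (p in c(microdata_path, macro_path))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or not found: ", p %||% "(NULL)")
  }
  if (!criterion_k %in% cv_k)
    stop("criterion_k must be one of cv_k")
  if (!rmse_k %in% cv_k) stop("rmse_k must be one of cv_k")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = isTRUE(simulate), sim = sim,
                 microdata_path = microdata_path, macro_path = macro_path,
                 models = models, cv_k = as.integer(cv_k),
                 criterion_k = as.integer(criterion_k), z = z,
                 rmse_k = as.integer(rmse_k),
                 use_observed = isTRUE(use_observed),
                 log_level = log_level),
            class = "ecdi_pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path a `.json` or `.yaml`/`.yml` file whose keys match
#'   [pipeline_config()] arguments (with `sim` an object of
#'   [sim_config()] arguments).
#' @return an `ecdi_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(pipeline_config, raw)
}

#' Run the full estimation chain
#'
#' simulate (optional) -> classify -> per-country prevalence -> fit and
#' cross-validate candidate models -> select -> project to all LMICs ->
#' aggregate to regions and globe. Every intermediate table is written to
#' `out_dir` as CSV, and a JSON manifest records the configuration, seed,
#' package version and row counts. Reruns with the same configuration and
#' seed reproduce byte-identical outputs.
#'
#' @param config an [pipeline_config()] (or path readable by
#'   [read_pipeline_config()]).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ecdi_pipeline_config"))
  ll <- config$log_level
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  if (config$simulate) {
    log_stage("simulate", "generating synthetic panel and microdata",
              log_level = ll)
    simc <- config$sim
    simc$seed <- config$seed
    macro <- generate_country_panel(simc)
    micro <- generate_microdata(macro, simc)
    p <- write_simulation(macro, micro, simc, config$out_dir)
    paths$macro <- p[["macro"]]; paths$microdata <- p[["microdata"]]
  } else {
    log_stage("read", "reading ", config$microdata_path, log_level = ll)
    micro <- read_microdata(config$microdata_path)
    macro <- read_macro(config$macro_path)
    paths$macro <- config$macro_path
    paths$microdata <- config$microdata_path
  }

  log_stage("classify", "scoring and classifying ", nrow(micro), " children",
            log_level = ll)
  classified <- classify_microdata(micro)
  stim_cols <- grep("^stim_", names(classified), value = TRUE)
  if (length(stim_cols) == 6) {
    sq <- build_stimulation_quintiles(classified[stim_cols],
                                      classified$weight)
    classified$stim_quintile <- sq$quintile
  }
  paths$classified <- file.path(config$out_dir, "classified.csv")
  write_table(classified, paths$classified)

  log_stage("prevalence", "estimating per-country prevalence", log_level = ll)
  prev <- country_prevalence(classified)
  paths$country_prevalence <- file.path(config$out_dir, "country_prevalence.csv")
  write_table(prev, paths$country_prevalence)

  log_stage("fit", "fitting candidate models with leave-{",
            paste(config$cv_k, collapse = ","), "}-out CV", log_level = ll)
  panel <- merge(prev, macro, by = "country_id")
  specs <- default_model_specs()[config$models]
  fits <- fit_country_models(panel, specs, cv_k = config$cv_k)
  model_tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$spec$name,
               predictors = paste(f$spec$predictors, collapse = "+"),
               intercept = f$coefficients[["(Intercept)"]],
               r_squared = f$r_squared, n_obs = f$n_obs,
               t(stats::setNames(unlist(f$cv_rmse),
                                 paste0("cv_rmse_k", names(f$cv_rmse)))),
               stringsAsFactors = FALSE)
  }))
  paths$model_table <- file.path(config$out_dir, "model_table.csv")
  write_table(model_tab, paths$model_table)

  selected <- select_model(fits, criterion_k = config$criterion_k)
  log_stage("select", "selected model: ", selected$spec$name, log_level = ll)

  log_stage("project", "projecting to all LMICs", log_level = ll)
  proj <- predict_all_lmics(selected, macro, z = config$z,
                            rmse_k = config$rmse_k,
                            use_observed = config$use_observed,
                            observed = prev)
  paths$projections <- file.path(config$out_dir, "projections.csv")
  write_table(proj, paths$projections)

  regional <- aggregate_projections(proj)
  paths$regional <- file.path(config$out_dir, "regional_estimates.csv")
  write_table(regional, paths$regional)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ecdiglobal")),
    seed = config$seed,
    config = unclass_config(config),
    selected_model = selected$spec$name,
    row_counts = list(
      microdata = nrow(micro), classified = nrow(classified),
      excluded = sum(classified$excluded),
      countries_surveyed = nrow(prev), countries_projected = nrow(proj)
    ),
    artifacts = paths
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", "artifacts in ", config$out_dir, log_level = ll)
  invisible(manifest)
}

unclass_config <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out
}
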