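#' Patient-count flow through study exclusions
#'
#' TRIPOD-style accounting: starting from the screened total, subtracts each
#' named exclusion and reports the running count, so the inclusion arithmetic
#' of a cohort is reproducible and auditable.
#'
#' @param screened number of patients screened.
#' @param exclusions named integer vector of exclusion counts, applied in
#'   order.
#' @return list with `included` and a data.frame `flow` (stage, excluded,
#'   remaining).
#' @examples
#' cohort_flow(1235, c(no_cmr = 126, incomplete_protocol = 86,
#'                     no_follow_up = 2))$included
#' @export
cohort_flow <- function(screened, exclusions) {
  stopifnot(screened >= 0, all(exclusions >= 0),
            !is.null(names(exclusions)), all(nzchar(names(exclusions))))
  remaining <- screened - cumsum(as.numeric(exclusions))
  if (any(remaining < 0)) stop("exclusions exceed the screened total")
  flow <- data.frame(stage = c("screened", names(exclusions)),
                     excluded = c(0, as.numeric(exclusions)),
                     remaining = c(screened, remaining),
                     stringsAsFactors = FALSE)
  list(included = utils::tail(remaining, 1), flow = flow)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: the cohort specification,
#' grid size `G`, spline upsampling factor, diastasis velocity threshold,
#' atlas variance threshold, cross-validation parameters, and the named
#' candidate feature blocks evaluated as models. The default blocks mirror
#' the usual nesting: ejection fraction alone, the baseline volumetric block
#' (ESV, EDV), that block plus conventional transient metrics, and that block
#' plus the atlas mode weights.
#'
#' @param cohort a [cohort_spec()].
#' @param G atlas grid size.
#' @param upsample_factor spline upsampling for metric extraction.
#' @param diastasis_threshold velocity threshold, fraction of SV per second.
#' @param variance_threshold atlas retained-variance fraction.
#' @param k,n_splits,seed cross-validation parameters.
#' @param family model family for selection/evaluation (`"lda"` or `"cox"`).
#' @param blocks named list of candidate feature sets; entries may reference
#'   columns of the feature table, conventional metric names, or the special
#'   token `"@vt_ai"` which expands to the retained atlas weights.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), G = 100,
                            upsample_factor = 10,
                            diastasis_threshold = 0.8,
                            variance_threshold = 0.95,
                            k = 10, n_splits = 100, seed = 1,
                            family = "lda",
                            blocks = list(
                              lvef = "ef_pct",
                              cmr = c("esv_ml", "edv_ml"),
                              cmr_vt = c("esv_ml", "edv_ml", "rr_ms",
                                         "diastolic_time_ms"),
                              cmr_vt_ai = c("esv_ml", "edv_ml", "@vt_ai")
                            )) {
  stopifnot(inherits(cohort, "cohort_spec"),
            diastasis_threshold > 0, diastasis_threshold < 1,
            variance_threshold > 0, variance_threshold <= 1,
            k >= 2, n_splits >= 1)
  out <- list(cohort = cohort, G = G, upsample_factor = upsample_factor,
              diastasis_threshold = diastasis_threshold,
              variance_threshold = variance_threshold,
              k = k, n_splits = n_splits, seed = seed, family = family,
              blocks = blocks)
  class(out) <- "pipeline_config"
  out
}

#' Read a pipeline configuration from YAML
#'
#' Scalar keys mirror the [pipeline_config()] arguments; cohort settings sit
#' under `cohort:` (`n_patients`, `mace_rate`, `seed`, ...); feature blocks
#' under `blocks:`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  cohort <- do.call(cohort_spec, cohort_args)
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- cohort
  do.call(pipeline_config, args)
}

#' Run the end-to-end synthetic pipeline
#'
#' Chains every stage: simulate the cohort, write the transients, extract the
#' conventional metrics, fit the atlas and project the mode weights, assemble
#' the model feature table, run backward stepwise selection per feature block
#' and evaluate each selected model under repeated stratified k-fold
#' cross-validation. All artifacts (CSV/JSON) and a run report with seeds and
#' patient counts at each filter are written under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisible list: `cohort`, `metrics`, `atlas`, `weights`,
#'   `features`, `models` (per block: selection + performance), `report`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("lvt_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$cohort$seed,
                 n_patients = config$cohort$n_patients,
                 config_hash = config_hash(config),
                 counts = list())

  cohort <- generate_cohort(config$cohort)
  write_transients_csv(cohort$transients, file.path(out_dir, "transients.csv"))

  metrics <- compute_metrics_cohort(
    cohort$transients, cohort$rr_lists,
    upsample_factor = config$upsample_factor,
    threshold_frac = config$diastasis_threshold)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  report$counts$diastasis_found <- sum(metrics$diastasis_found)

  normalized <- lapply(cohort$transients, normalize_transient, G = config$G)
  atlas <- fit_atlas(normalized, config$variance_threshold)
  write_atlas_json(atlas, file.path(out_dir, "atlas.json"))
  W <- project_transient(atlas, as_curve_matrix(normalized))
  weights <- data.frame(patient_id = rownames(W), W, stringsAsFactors = FALSE)
  utils::write.csv(weights, file.path(out_dir, "weights.csv"),
                   row.names = FALSE)
  report$counts$atlas_modes <- atlas$n_modes

  # keep the measured ESV/EDV/EF from the transients (the automated pipeline's
  # own estimates), not the generator's planted covariate copies
  covs <- cohort$features[, setdiff(names(cohort$features),
                                    c("esv_ml", "edv_ml", "ef_pct")),
                          drop = FALSE]
  features <- merge(covs, metrics, by = "patient_id", sort = FALSE)
  features <- merge(features, weights, by = "patient_id", sort = FALSE)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)

  vt_ai_cols <- colnames(W)
  models <- list()
  for (block in names(config$blocks)) {
    cand <- config$blocks[[block]]
    cand <- unique(unlist(lapply(cand, function(v) {
      if (v == "@vt_ai") vt_ai_cols else v
    })))
    missing_cols <- setdiff(cand, names(features))
    if (length(missing_cols)) {
      stop("block '", block, "' references unknown features: ",
           paste(missing_cols, collapse = ", "))
    }
    n_complete <- sum(stats::complete.cases(features[, cand, drop = FALSE]))
    sel <- backward_stepwise(features, cand, family = config$family)
    vars <- if (length(sel$selected)) sel$selected else cand
    perf <- evaluate_cv(features, vars, family = config$family,
                        k = config$k, n_splits = config$n_splits,
                        seed = config$seed)
    models[[block]] <- list(candidates = cand, selection = sel,
                            performance = perf, n_complete = n_complete)
    report$counts[[paste0("complete_cases_", block)]] <- n_complete
  }

  report$models <- lapply(models, function(m) {
    list(candidates = m$candidates, selected = m$selection$selected,
         coefficients = as.list(m$selection$coefficients),
         p_values = as.list(m$selection$p_values),
         n_used = m$selection$n_used, n_complete = m$n_complete,
         metric = m$performance$metric,
         resubstitution = m$performance$resubstitution,
         cv_median = m$performance$median,
         cv_iqr = m$performance$iqr)
  })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, metrics = metrics, atlas = atlas,
                 weights = weights, features = features, models = models,
                 report = report, out_dir = out_dir))
}

# Deterministic digest of the configuration (no external digest dependency):
# serialize to canonical JSON and take a simple polynomial rolling hash of
# the bytes (collision resistance is not a goal, only change detection).
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                         digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}
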