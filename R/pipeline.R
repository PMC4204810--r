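# End-to-end pipeline: simulate/load -> filter -> fit or sweep -> profiles
# -> associations, with a reproducibility manifest. Configuration is a flat
# key-value list, readable from JSON.

#' Build a run configuration
#'
#' @param output_dir directory for all artifacts (created if absent)
#' @param cohort_csv optional path to an existing cohort CSV; when `NULL` a
#'   synthetic cohort is generated from [default_truth()]
#' @param seed master seed (mandatory; drives simulation, fitting and splits)
#' @param family model family to fit
#' @param n_classes class count for a single fit, or `NULL` to sweep
#' @param n_range class-number range for the sweep
#' @param pseudocount Dirichlet pseudocount
#' @param evidence_method `"holdout"` or `"bic"`
#' @param min_timepoints inclusion filter threshold (k observed ages per
#'   symptom; 0 disables)
#' @param exclude_mild_eczema apply the mild-eczema exclusion filter and emit
#'   a confusion matrix against the unfiltered run
#' @param asthma_variant replace wheeze with derived current asthma
#' @param control an [em_control()]
#' @return list of class `run_config`
#' @export
run_config <- function(output_dir, cohort_csv = NULL, seed,
                       family = "latent_profile", n_classes = 8,
                       n_range = NULL, pseudocount = 1,
                       evidence_method = "holdout",
                       min_timepoints = 2, exclude_mild_eczema = FALSE,
                       asthma_variant = FALSE, control = em_control()) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(output_dir = output_dir, cohort_csv = cohort_csv,
                 seed = as.integer(seed), family = family,
                 n_classes = n_classes, n_range = n_range,
                 pseudocount = pseudocount, evidence_method = evidence_method,
                 min_timepoints = min_timepoints,
                 exclude_mild_eczema = exclude_mild_eczema,
                 asthma_variant = asthma_variant, control = control),
            class = "run_config")
}

#' Read a run configuration from flat JSON
#' @param path JSON file with the fields of [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctrl_fields <- intersect(names(x), names(formals(em_control)))
  ctrl <- do.call(em_control, x[ctrl_fields])
  args <- x[setdiff(intersect(names(x), names(formals(run_config))), "control")]
  args$control <- ctrl
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the configured inclusion filters,
#' fits a single model or sweeps class numbers, writes profile and
#' association tables, and emits a JSON manifest with seeds and output
#' checksums. Re-running with an identical configuration is bit-identical.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the cohort, fit (or sweep), and paths
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  log_stage <- function(fmt, ...) {
    message(sprintf("[%.1fs] ", as.numeric(Sys.time() - t0, units = "secs")),
            sprintf(fmt, ...))
  }
  # --- cohort ---------------------------------------------------------------
  if (is.null(config$cohort_csv)) {
    log_stage("simulating default synthetic cohort (seed %d)", config$seed)
    truth <- default_truth(seed = config$seed)
    cohort <- generate_cohort(truth)
    write_cohort_csv(cohort, out("cohort.csv"))
    utils::write.csv(data.frame(child_id = cohort$child_id,
                                true_class = attr(cohort, "true_class")),
                     out("truth_classes.csv"), row.names = FALSE)
  } else {
    log_stage("reading cohort from %s", config$cohort_csv)
    cohort <- read_cohort_csv(config$cohort_csv)
  }
  if (config$asthma_variant) {
    log_stage("asthma variant: replacing wheeze with derived current asthma")
    cohort <- use_asthma_variant(cohort)
  }
  if (config$min_timepoints > 0) {
    n0 <- nrow(cohort)
    cohort <- filter_min_timepoints(cohort, k = config$min_timepoints)
    log_stage("min-timepoints filter (k=%d): %d -> %d children",
              config$min_timepoints, n0, nrow(cohort))
  }
  cohort_full <- cohort
  if (config$exclude_mild_eczema) {
    n0 <- nrow(cohort)
    cohort <- filter_mild_eczema(cohort)
    log_stage("mild-eczema exclusion: %d -> %d children", n0, nrow(cohort))
  }
  # --- fit / sweep ----------------------------------------------------------
  sweep_res <- NULL
  if (!is.null(config$n_range)) {
    log_stage("sweeping %s over n in {%s}", config$family,
              paste(config$n_range, collapse = ", "))
    sweep_res <- sweep_models(cohort, families = config$family,
                              n_range = config$n_range,
                              pseudocounts = config$pseudocount,
                              seed = config$seed, control = config$control,
                              method = config$evidence_method)
    write_sweep_csv(sweep_res, out("sweep.csv"))
    if (is.null(sweep_res$selected)) stop("no converged fit in sweep")
    fit_res <- sweep_res$selected$fit
  } else {
    spec <- model_spec(config$family, n_classes = config$n_classes,
                       pseudocount = config$pseudocount)
    log_stage("fitting %s with n = %d", config$family, config$n_classes)
    fit_res <- fit(cohort, spec, seed = config$seed, control = config$control)
  }
  params_to_json(fit_res$params, out("params.json"))
  write_membership_csv(fit_res, out("memberships.csv"))
  # --- profiles -------------------------------------------------------------
  log_stage("writing profile and prevalence tables")
  prof <- profile_table(fit_res, cohort)
  utils::write.csv(as.data.frame(prof), out("profiles.csv"), row.names = FALSE)
  utils::write.csv(prevalence_table(cohort), out("prevalence.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(membership_quality(fit_res)),
                   out("membership_quality.csv"), row.names = FALSE)
  # --- associations ---------------------------------------------------------
  sens <- cohort_sensitisation(cohort)
  assoc <- NULL
  if (any(!is.na(sens))) {
    baseline <- which.max(tabulate(fit_res$assignment, fit_res$spec$n_classes))
    assoc <- class_trait_table(fit_res$assignment, sens,
                               baseline_class = baseline)
    write_assoc_csv(assoc, out("assoc_sensitisation.csv"))
    log_stage("association table written (baseline class %d)", baseline)
  }
  # --- mild-eczema confusion matrix ----------------------------------------
  confusion <- NULL
  if (config$exclude_mild_eczema) {
    log_stage("refitting on the unfiltered cohort for the confusion matrix")
    spec_full <- fit_res$spec
    fit_full <- fit(cohort_full, spec_full,
                    seed = derive_seed(config$seed, "full"),
                    control = config$control)
    confusion <- cross_tabulate(
      stats::setNames(fit_res$assignment, fit_res$child_id),
      stats::setNames(fit_full$assignment, fit_full$child_id))
    utils::write.csv(as.data.frame(confusion$counts), out("confusion.csv"),
                     row.names = FALSE)
  }
  # --- manifest -------------------------------------------------------------
  files <- list.files(config$output_dir, pattern = "\\.(csv|json)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("symptomLCA")),
    r_version = R.version.string,
    seed = config$seed,
    family = config$family,
    n_children = nrow(cohort),
    converged = fit_res$converged,
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("done; manifest at %s", out("manifest.json"))
  invisible(list(cohort = cohort, fit = fit_res, sweep = sweep_res,
                 assoc = assoc, confusion = confusion,
                 output_dir = config$output_dir))
}

# Derive per-child sensitisation at the shared skin-prick age from whatever
# wheal columns are present (wheal_<allergen>_<age> vs negctl_<age>).
cohort_sensitisation <- function(cohort) {
  df <- as.data.frame(cohort)
  wheal_cols <- grep("^wheal_", names(df), value = TRUE)
  negctl_cols <- grep("^negctl_", names(df), value = TRUE)
  if (!length(wheal_cols) || !length(negctl_cols))
    return(rep(NA_real_, nrow(df)))
  age <- sub(".*_", "", negctl_cols[1])
  wheal_cols <- wheal_cols[endsWith(wheal_cols, paste0("_", age))]
  vapply(seq_len(nrow(df)), function(i)
    derive_sensitised(as.numeric(df[i, wheal_cols]),
                      df[[negctl_cols[1]]][i]),
    numeric(1))
}
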