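#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: either a simulation config
#' or a directory of tidy input tables (exactly one of the two), the
#' resampling plan, model options, and the output directory.
#'
#' @param out_dir directory for the output tables and manifest.
#' @param simulation a [community_config()], or `NULL` when reading inputs.
#' @param input_dir directory holding `hosts.tsv`, `roster.tsv`,
#'   `oviposition.tsv`, `survival.tsv`, or `NULL` when simulating.
#' @param plan a [resampling_plan()].
#' @param cell_response cell-level egg response for the deviance models.
#' @param pvalue `"F"` or `"chisq"`.
#' @param write_inputs also write the four input tables (and `truth.tsv`
#'   when simulating) into `out_dir`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = community_config(),
                            input_dir = NULL,
                            plan = resampling_plan(),
                            cell_response = c("sum", "mean"),
                            pvalue = c("F", "chisq"),
                            write_inputs = FALSE) {
  if (is.null(simulation) == is.null(input_dir))
    stop("exactly one of 'simulation' and 'input_dir' must be set", call. = FALSE)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop(sprintf("input directory '%s' does not exist", input_dir), call. = FALSE)
  structure(list(out_dir = out_dir, simulation = simulation,
                 input_dir = input_dir, plan = plan,
                 cell_response = match.arg(cell_response),
                 pvalue = match.arg(pvalue),
                 write_inputs = isTRUE(write_inputs)),
            class = "pipeline_config")
}

#' Run the full preference-performance pipeline
#'
#' Simulate (or ingest) a community, resample interaction matrices, estimate
#' per-species alpha-diversity distributions, classify specialists vs
#' generalists, run the three correlation analyses and the quasi-Poisson
#' deviance-model suite, and write every stage's table plus a run manifest.
#' The run is a pure function of `(inputs, config)`: a rerun with the same
#' config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `dataset`, `truth` (or `NULL`),
#'   `estimates`, `classification`, `correlations`, `suite`, `manifest`.
#'   Side effect: writes `diversity_estimates.tsv`, `alpha_samples.tsv`,
#'   `classification.tsv`, `correlations.tsv`, `deviance_tables.tsv` and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", generate_community(config$simulation))
    dataset <- sim$dataset
    truth <- sim$truth
  } else {
    dataset <- stage("ingest", read_community(config$input_dir))
    truth <- NULL
  }
  v <- attr(dataset, "validation")
  if (length(v$missing_egg_cells))
    note("%d unobserved egg cell(s)", length(v$missing_egg_cells))
  if (length(v$cup_range_notes))
    note("%d cell(s) outside the declared cup range", length(v$cup_range_notes))

  estimates <- stage("diversity", alpha_distributions(dataset, config$plan))
  dropped <- sum(estimates$summary$n_dropped)
  if (dropped > 0) note("%d degenerate resample(s) dropped", dropped)
  classification <- stage("classify", classify_by_alpha(estimates, dataset$roster))

  correlations <- stage("correlate", {
    rows <- list()
    cc <- alpha_pref_perf_correlation(estimates)
    rows[[1]] <- data.frame(analysis = "alpha_pref_perf", species = "community",
                            r = cc$r, n = cc$n, t = cc$t, p = cc$p)
    for (sp in dataset$roster$species) {
      pp <- species_pref_perf_correlation(dataset, sp)
      rows[[length(rows) + 1]] <- data.frame(analysis = "species_pref_perf",
                                             species = sp, r = pp$r, n = pp$n,
                                             t = pp$t, p = pp$p)
      has_choice <- any(dataset$oviposition$assay == "choice" &
                          dataset$oviposition$species == sp)
      if (has_choice) {
        cn <- choice_nochoice_consistency(dataset, sp)
        rows[[length(rows) + 1]] <- data.frame(analysis = "choice_consistency",
                                               species = sp, r = cn$r, n = cn$n,
                                               t = cn$t, p = cn$p)
      }
    }
    do.call(rbind, rows)
  })

  suite <- stage("glm", model_suite(dataset, estimates,
                                    response = config$cell_response,
                                    pvalue = config$pvalue))
  nonconv <- names(suite)[!vapply(suite, function(d) isTRUE(attr(d, "converged")),
                                  logical(1))]
  if (length(nonconv)) note("non-converged model(s): %s", paste(nonconv, collapse = ", "))

  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  est_tab <- estimates$summary
  est_tab$q <- 1
  write_tidy_table(est_tab[, c("species", "measure", "q", "mean_alpha",
                               "var_alpha", "n_resamples")],
                   file.path(out, "diversity_estimates.tsv"))
  write_tidy_table(estimates$samples, file.path(out, "alpha_samples.tsv"))
  write_tidy_table(as.data.frame(classification), file.path(out, "classification.tsv"))
  write_tidy_table(correlations, file.path(out, "correlations.tsv"))
  write_tidy_table(deviance_suite_table(suite), file.path(out, "deviance_tables.tsv"))
  if (config$write_inputs) {
    write_community(dataset, out)
    if (!is.null(truth)) write_truth_table(truth, file.path(out, "truth.tsv"))
  }

  manifest <- list(
    package = "prefperf",
    package_version = as.character(utils::packageVersion("prefperf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = if (!is.null(config$simulation)) config$simulation$seed else NULL,
    resampling = unclass(config$plan),
    cell_response = config$cell_response,
    pvalue = config$pvalue,
    simulated = !is.null(config$simulation),
    config = if (!is.null(config$simulation))
      Filter(Negate(is.null), unclass(config$simulation)) else
        list(input_dir = config$input_dir),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = dataset, truth = truth, estimates = estimates,
                 classification = classification, correlations = correlations,
                 suite = suite, manifest = manifest))
}
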