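#' Analysis configuration
#'
#' All tunable parameters of the pipeline, with the defaults the
#' analysis is designed around: pseudocount 0.5 for the clr transform,
#' rarefaction to the minimum sample depth, 100 half-sample iterations
#' with a >90 reproducibility threshold for the cross-validated nearest
#' balance, parameter de-duplication at |Spearman rho| > 0.8, a
#' neighbourhood-selection network with 10 subsamples and a 10-value
#' lambda path down to 0.2 of lambda_max, the genus prevalence filter
#' (>20 reads in >10 samples), 999 permutations for beta-diversity
#' tests, and FDR control at 0.05.
#'
#' @param pseudocount replacement for zero counts before the clr
#'   transform.
#' @param rarefaction_depth `"min"` or a positive integer read depth.
#' @param cv_iterations number of half-sample iterations for the
#'   cross-validated nearest balance.
#' @param cv_threshold side-membership count a taxon must exceed to
#'   enter the final balance (strict `>`).
#' @param dedup_rho absolute Spearman correlation above which two
#'   parameters are considered duplicates.
#' @param n_subsamples,n_lambda,lambda_min,subsample_frac,stability_threshold
#'   co-abundance network parameters: number of stability subsamples,
#'   number of lambda-path values, smallest lambda as a fraction of
#'   lambda_max, subsample fraction, and the edge selection-frequency
#'   threshold.
#' @param min_reads,min_samples genus filter: keep genera with
#'   `> min_reads` reads in `> min_samples` samples.
#' @param n_permutations permutations for beta-diversity tests.
#' @param fdr_alpha significance threshold on BH-adjusted q-values.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return an `analysis_config` object (a validated list).
#' @export
analysis_config <- function(pseudocount = 0.5,
                            rarefaction_depth = "min",
                            cv_iterations = 100L,
                            cv_threshold = 90L,
                            dedup_rho = 0.8,
                            n_subsamples = 10L,
                            n_lambda = 10L,
                            lambda_min = 0.2,
                            subsample_frac = 0.8,
                            stability_threshold = 0.8,
                            min_reads = 20L,
                            min_samples = 10L,
                            n_permutations = 999L,
                            fdr_alpha = 0.05,
                            seed = 1L) {
  cfg <- list(pseudocount = pseudocount,
              rarefaction_depth = rarefaction_depth,
              cv_iterations = as.integer(cv_iterations),
              cv_threshold = as.integer(cv_threshold),
              dedup_rho = dedup_rho,
              n_subsamples = as.integer(n_subsamples),
              n_lambda = as.integer(n_lambda),
              lambda_min = lambda_min,
              subsample_frac = subsample_frac,
              stability_threshold = stability_threshold,
              min_reads = min_reads,
              min_samples = min_samples,
              n_permutations = as.integer(n_permutations),
              fdr_alpha = fdr_alpha,
              seed = as.integer(seed))
  num <- c("pseudocount", "cv_iterations", "cv_threshold", "dedup_rho",
           "n_subsamples", "n_lambda", "lambda_min", "subsample_frac",
           "stability_threshold", "min_reads", "min_samples",
           "n_permutations", "fdr_alpha")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  if (cfg$cv_threshold > cfg$cv_iterations)
    stop("cv_threshold must not exceed cv_iterations")
  if (!identical(cfg$rarefaction_depth, "min") &&
      !(is.numeric(cfg$rarefaction_depth) && cfg$rarefaction_depth > 0))
    stop("rarefaction_depth must be \"min\" or a positive integer")
  structure(cfg, class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return an [analysis_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
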