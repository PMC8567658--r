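#' Run the full sex-differential methylation meta-analysis
#'
#' Chains the main stages over a list of cohorts: per-cohort EWAS (repeated
#' measures collapsed, OLS + empirical-Bayes moderation), empirical-null
#' calibration of each cohort's scores, inverse-variance fixed-effects
#' meta-analysis over probes present in at least `min_cohorts` cohorts, BH
#' DMP calling, and kernel-smoothing DMR calling.
#'
#' @param cohorts List of `cohort_study` objects.
#' @param annotation Probe annotation (`probe_id`, `chrom`, `pos`, ...).
#' @param alpha FDR threshold for DMPs and DMRs (default 0.005).
#' @param min_cohorts Minimum cohorts per probe (default 2).
#' @param lambda,C DMR kernel parameters (defaults 1000 bp, 2).
#' @param condition Condition column for [collapse_repeats()] where a cohort
#'   has repeated measures (default `"timepoint"` when present).
#' @param calibrate Apply empirical-null calibration per cohort
#'   (default TRUE).
#' @return List: `ewas` (per-cohort calibrated results), `nulls` (per-cohort
#'   `null_estimate`), `meta` (meta_result with `fdr`, `is_dmp`), `dmps`
#'   (DMP probe ids), `smoothed`, `dmrs` (`dmr_result`).
#' @export
run_sex_meta <- function(cohorts, annotation, alpha = 0.005,
                         min_cohorts = 2L, lambda = 1000, C = 2,
                         condition = "timepoint", calibrate = TRUE) {
  fits <- lapply(cohorts, function(st) {
    cond <- if (!is.null(condition) && condition %in% names(st$samples) &&
                length(unique(st$samples[[condition]])) > 1) condition else NULL
    if (anyDuplicated(st$samples$subject_id))
      st <- collapse_repeats(st, cond)
    ebayes_moderate(fit_cpg_models(st))
  })
  nulls <- NULL
  if (calibrate) {
    nulls <- lapply(fits, function(f)
      suppressWarnings(estimate_empirical_null(f$t)))
    fits <- mapply(correct_scores, fits, nulls, SIMPLIFY = FALSE)
  } else {
    fits <- lapply(fits, function(f) { f$z <- f$t; f })
  }
  meta <- call_dmps(ivw_meta(fits, min_cohorts = min_cohorts), alpha = alpha)
  smoothed <- smooth_statistics(meta, annotation, lambda = lambda, C = C)
  dmrs <- call_regions(smoothed, meta, lambda = lambda, alpha = alpha)
  list(ewas = fits, nulls = nulls, meta = meta,
       dmps = meta$probe_id[meta$is_dmp], smoothed = smoothed, dmrs = dmrs)
}
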