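#' Collapse repeated measures by within-cell averaging
#'
#' Samples from the same subject and condition cell are replaced by their
#' mean beta profile before model fitting, so each subject contributes one
#' observation per cell. This is a deliberate simplification of a
#' consensus-correlation mixed model: within-cell averaging leaves the sex
#' contrast unbiased while removing the repeated-measures correlation.
#'
#' @param study A `cohort_study`.
#' @param condition Optional name of a sample-sheet column defining the
#'   condition cell (e.g. `"timepoint"`); `NULL` collapses to one observation
#'   per subject.
#' @return A `cohort_study` with one column per subject-by-condition cell;
#'   attribute `n_collapsed` records samples per cell.
#' @export
collapse_repeats <- function(study, condition = NULL) {
  s <- study$samples
  sx <- tapply(s$sex, s$subject_id, function(v) length(unique(v)))
  if (any(sx > 1))
    stop("conflicting sex within subject: ", names(sx)[sx > 1][1])
  cell <- if (is.null(condition)) s$subject_id
          else paste(s$subject_id, s[[condition]], sep = "|")
  if (!anyDuplicated(cell)) {
    attr(study, "n_collapsed") <- setNames(rep(1L, nrow(s)), cell)
    return(study)
  }
  idx <- split(seq_len(nrow(s)), cell)
  beta <- vapply(idx, function(i) rowMeans(study$beta[, i, drop = FALSE]),
                 numeric(nrow(study$beta)))
  first <- vapply(idx, `[`, integer(1), 1)
  samples <- s[first, , drop = FALSE]
  samples$sample_id <- names(idx)
  colnames(beta) <- names(idx)
  out <- cohort_study(study$name, beta, samples, study$design)
  attr(out, "n_collapsed") <- lengths(idx)
  out
}

# Build the design matrix: sex (F reference) first, then declared terms.
# Missing numeric covariates are imputed by within-sex mean.
build_design <- function(samples, terms, response = "sex") {
  s <- samples
  s$sex <- factor(s$sex, levels = c("F", "M"))
  for (v in intersect(all.vars(stats::reformulate(c("1", terms))), names(s))) {
    if (is.numeric(s[[v]]) && anyNA(s[[v]])) {
      for (g in levels(s$sex)) {
        i <- s$sex == g & is.na(s[[v]])
        s[[v]][i] <- mean(s[[v]][s$sex == g], na.rm = TRUE)
      }
      message("imputed ", v, " by within-sex mean")
    }
  }
  rhs <- if (identical(response, "sex")) c("sex", terms) else c(response, terms)
  X <- model.matrix(stats::reformulate(rhs), data = s)
  if (qr(X)$rank < ncol(X)) {
    ali <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(ali, collapse = ", "))
  }
  X
}

#' Fit per-CpG linear models and extract the coefficient of interest
#'
#' Ordinary least squares per probe on beta values (matrix fitting through
#' limma's `lmFit`). The returned effect is the coefficient of `coef`:
#' by default the sex main effect (M minus F, so positive = hypermethylated in
#' males), evaluated at reference levels of any interacting factors.
#' Zero-variance probes are flagged (`se = NA`) and later excluded from
#' moderation with p = 1.
#'
#' @param study A `cohort_study`.
#' @param terms Covariate terms beyond `sex` (default: the study's design).
#' @param coef Name of the design-matrix coefficient to report
#'   (default `"sexM"`).
#' @param covariate Optional: model a numeric covariate instead of sex
#'   (e.g. fibre proportion); supply its values via a sample-sheet column name
#'   and set `coef` to that name.
#' @return Data frame of class `ewas_result`: `probe_id`, `effect`, `se`,
#'   `t`, `df`, `p`, `n`, `sigma`, `stdev_unscaled` (unmoderated statistics).
#' @export
fit_cpg_models <- function(study, terms = study$design, coef = "sexM",
                           covariate = NULL) {
  X <- build_design(study$samples, terms,
                    response = if (is.null(covariate)) "sex" else covariate)
  if (nrow(X) - ncol(X) < 2) stop("fewer than 2 residual degrees of freedom")
  if (!coef %in% colnames(X))
    stop("coefficient '", coef, "' not in design (columns: ",
         paste(colnames(X), collapse = ", "), ")")
  fit <- limma::lmFit(study$beta, X)
  eff <- fit$coefficients[, coef]
  su <- fit$stdev.unscaled[, coef]
  sigma <- fit$sigma
  df <- fit$df.residual
  se <- su * sigma
  tt <- eff / se
  p <- 2 * pt(-abs(tt), df)
  zero_var <- sigma <= .Machine$double.eps^0.5
  se[zero_var] <- NA_real_
  tt[zero_var] <- NA_real_
  p[zero_var] <- 1
  out <- data.frame(probe_id = rownames(study$beta), effect = eff, se = se,
                    t = tt, df = df, p = p, n = nrow(X), sigma = sigma,
                    stdev_unscaled = su, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("ewas_result", "data.frame")
  attr(out, "cohort") <- study$name
  out
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Shrinks per-probe residual variances towards a common prior estimated by
#' matching moments of the log sample variances to a scaled-F distribution
#' (limma's `squeezeVar`), and recomputes moderated t statistics with
#' `df_total = df + prior df`. Zero-variance probes are excluded from
#' hyperparameter estimation and keep p = 1.
#'
#' @param fit An `ewas_result` from [fit_cpg_models()].
#' @return The `ewas_result` with moderated `se`, `t`, `df`, `p`; attributes
#'   `df_prior` and `var_prior` carry the estimated hyperparameters.
#' @export
ebayes_moderate <- function(fit) {
  ok <- fit$sigma > .Machine$double.eps^0.5
  if (sum(ok) < 100)
    warning("fewer than 100 probes for hyperparameter estimation")
  if (any(!is.finite(fit$sigma[ok]))) stop("non-finite residual variances")
  sq <- limma::squeezeVar(fit$sigma[ok]^2, fit$df[ok])
  s_post <- sqrt(sq$var.post)
  df_tot <- fit$df[ok] + sq$df.prior
  se <- s_post * fit$stdev_unscaled[ok]
  tt <- fit$effect[ok] / se
  out <- fit
  out$se[ok] <- se
  out$t[ok] <- tt
  out$df[ok] <- df_tot
  out$p[ok] <- 2 * pt(-abs(tt), df_tot)
  out$p[!ok] <- 1
  attr(out, "df_prior") <- sq$df.prior
  attr(out, "var_prior") <- sq$var.prior
  out
}

#' Run one cohort's EWAS (collapse, fit, moderate)
#'
#' @inheritParams fit_cpg_models
#' @param condition Condition column for [collapse_repeats()] (`NULL` if the
#'   cohort has no repeated measures).
#' @return Moderated `ewas_result`.
#' @export
run_ewas <- function(study, terms = study$design, coef = "sexM",
                     condition = NULL) {
  if (anyDuplicated(study$samples$subject_id))
    study <- collapse_repeats(study, condition)
  ebayes_moderate(fit_cpg_models(study, terms, coef))
}

#' Cohort-characteristics table (Welch t and Fisher's exact tests)
#'
#' For each continuous covariate, a Welch two-sample t-test between the sexes;
#' for each two-level categorical covariate, a two-sided Fisher's exact test
#' of equal sex representation. Groups with fewer than 2 observations give NA.
#'
#' @param samples Sample sheet with a `sex` column.
#' @param continuous,categorical Column names to test.
#' @return Data frame `variable`, `test`, `statistic`, `p`.
#' @export
cohort_characteristics <- function(samples, continuous = "age",
                                   categorical = character()) {
  rows <- list()
  for (v in continuous) {
    x <- samples[[v]][samples$sex == "M"]
    y <- samples[[v]][samples$sex == "F"]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
      rows[[v]] <- data.frame(variable = v, test = "welch_t",
                              statistic = NA_real_, p = NA_real_)
    } else {
      tt <- t.test(x, y)
      rows[[v]] <- data.frame(variable = v, test = "welch_t",
                              statistic = unname(tt$statistic), p = tt$p.value)
    }
  }
  for (v in categorical) {
    tab <- table(samples$sex, samples[[v]])
    if (!all(dim(tab) == c(2, 2)) || any(rowSums(tab) == 0)) {
      rows[[v]] <- data.frame(variable = v, test = "fisher_exact",
                              statistic = NA_real_, p = NA_real_)
    } else {
      ft <- fisher.test(tab)
      rows[[v]] <- data.frame(variable = v, test = "fisher_exact",
                              statistic = unname(ft$estimate), p = ft$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
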