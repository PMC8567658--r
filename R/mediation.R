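#' Type-I fibre proportion from myosin heavy-chain expression
#'
#' The slow-twitch marker MYH7 as a fraction of the three adult myosin
#' heavy-chain isoforms: `MYH7 / (MYH7 + MYH2 + MYH1)` (type I, IIA, IIX).
#' Scale-invariant in the expression units (TPMs).
#'
#' @param myh7,myh2,myh1 Non-negative expression values (vectors recycled).
#' @return Type-I ratio in \[0, 1\]; `NA` (with a warning) where the total
#'   is zero.
#' @export
estimate_fibre_from_tpm <- function(myh7, myh2, myh1) {
  if (any(c(myh7, myh2, myh1) < 0, na.rm = TRUE))
    stop("TPM values must be non-negative")
  tot <- myh7 + myh2 + myh1
  out <- myh7 / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("zero total myosin expression; returning NA")
    out[tot == 0] <- NA_real_
  }
  out
}

#' Beta regression of a proportion on covariates
#'
#' Maximum likelihood for `y ~ Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = X beta` and constant `log(phi)`, optimized by BFGS with
#' analytic gradients from a logit-scale OLS start. Boundary observations are
#' mapped inside (0, 1) by the usual compression
#' `y' = (y (n - 1) + 0.5) / n`. Wald tests come from the inverse observed
#' information.
#'
#' @param y Proportions in \[0, 1\].
#' @param data Data frame of covariates.
#' @param formula RHS formula for the mean model (default `~ sex`).
#' @return Object of class `beta_regression`: `coefficients` (with `se`,
#'   `z`, `p`), `phi`, `loglik`, `loglik_start`, `converged`, `vcov`.
#' @export
beta_regression <- function(y, data, formula = ~ sex) {
  X <- model.matrix(formula, data = data)
  n <- length(y)
  if (any(y < 0 | y > 1)) stop("proportions must lie in [0,1]")
  if (any(y <= 0 | y >= 1)) y <- (y * (n - 1) + 0.5) / n
  negll <- function(par) {
    eta <- X %*% par[-length(par)]
    mu <- plogis(eta)
    phi <- exp(par[length(par)])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
  }
  grad <- function(par) {
    eta <- X %*% par[-length(par)]
    mu <- as.numeric(plogis(eta))
    phi <- exp(par[length(par)])
    ystar <- log(y) - log1p(-y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    dmu <- phi * (ystar - mustar) * mu * (1 - mu)
    dbeta <- -crossprod(X, dmu)
    dphi <- -sum(digamma(phi) - mu * digamma(mu * phi) -
                   (1 - mu) * digamma((1 - mu) * phi) +
                   mu * log(y) + (1 - mu) * log1p(-y)) * phi
    c(dbeta, dphi)
  }
  start_beta <- lm.fit(X, qlogis(y))$coefficients
  mu0 <- plogis(X %*% start_beta)
  r <- y - mu0
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(var(as.numeric(r)), 1e-8) - 1, 2)
  start <- c(start_beta, log(phi0))
  ll_start <- -negll(start)
  opt <- optim(start, negll, grad, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop(sprintf("beta regression did not converge (gradient norm %.3g)",
                 sqrt(sum(grad(opt$par)^2))))
  V <- tryCatch(solve(opt$hessian), error = function(e)
    stop("singular information matrix in beta regression"))
  kq <- ncol(X)
  se <- sqrt(pmax(diag(V)[seq_len(kq)], 0))
  est <- opt$par[seq_len(kq)]
  z <- est / se
  co <- data.frame(term = colnames(X), estimate = est, se = se, z = z,
                   p = 2 * pnorm(-abs(z)), row.names = NULL,
                   stringsAsFactors = FALSE)
  structure(list(coefficients = co, phi = exp(opt$par[kq + 1]),
                 loglik = -opt$value, loglik_start = ll_start,
                 converged = TRUE, vcov = V),
            class = "beta_regression")
}

#' @export
print.beta_regression <- function(x, ...) {
  cat("<beta_regression> logLik =", format(x$loglik), " phi =",
      format(x$phi), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Sex-stratified fibre-type meta-analysis over sex-biased CpGs
#'
#' Fibre-type proportion is a downstream effect of sex, so it cannot enter the
#' sex model as a covariate; instead each cohort is split by sex and the
#' per-CpG model `DNAm ~ type1_ratio + covariates` is fitted within each
#' single-sex group (sex never appears as a regressor, enforced structurally),
#' moderated, calibrated against its empirical null, and the groups are
#' combined with the same inverse-variance machinery as the main analysis.
#' FDR adjustment is then performed within the supplied sex-DMP set only.
#'
#' @param cohorts List of `cohort_study` objects whose sample sheets carry a
#'   `type1_ratio` column (use [estimate_fibre_from_tpm()] upstream). Missing
#'   ratios are imputed by within-sex mean.
#' @param sex_dmps Character vector of sex-DMP probe ids.
#' @param terms Extra covariate terms per group (default `"age"`).
#' @param alpha FDR threshold (default 0.005).
#' @param min_group Minimum samples per sex-stratified group; smaller groups
#'   are excluded with a warning (default 10).
#' @param calibrate Calibrate each group's scores against its empirical null
#'   (default TRUE).
#' @return List: `meta` (meta_result over all probes), `restricted`
#'   (meta rows at sex-DMPs with `fdr` within that set and `is_fibre_cpg`),
#'   `n_fibre_cpgs`, `fraction_of_sex_dmps`, `groups_used`.
#' @export
stratified_fibre_meta <- function(cohorts, sex_dmps, terms = "age",
                                  alpha = 0.005, min_group = 10L,
                                  calibrate = TRUE) {
  if (any(c("sex", "sexM") %in% terms))
    stop("sex must not be a regressor in the stratified fibre analysis")
  groups <- list()
  for (st in cohorts) {
    for (sx in c("F", "M")) {
      i <- st$samples$sex == sx
      if (sum(i) < min_group) {
        warning(sprintf("group %s/%s has %d samples (< %d); excluded",
                        st$name, sx, sum(i), min_group))
        next
      }
      s <- st$samples[i, , drop = FALSE]
      if (anyNA(s$type1_ratio))
        s$type1_ratio[is.na(s$type1_ratio)] <-
          mean(s$type1_ratio, na.rm = TRUE)
      g <- cohort_study(paste(st$name, sx, sep = "_"),
                        st$beta[, i, drop = FALSE], s, terms)
      groups[[g$name]] <- g
    }
  }
  if (length(groups) < 2) stop("need >= 2 sex-stratified groups")
  fits <- lapply(groups, function(g) {
    f <- ebayes_moderate(fit_cpg_models(g, terms = terms,
                                        coef = "type1_ratio",
                                        covariate = "type1_ratio"))
    if (calibrate) correct_scores(f, estimate_empirical_null(f$t)) else {
      f$z <- f$t
      f
    }
  })
  meta <- ivw_meta(fits, min_cohorts = 2L)
  restricted <- meta[meta$probe_id %in% sex_dmps, , drop = FALSE]
  restricted <- restricted[order(restricted$p, restricted$probe_id), ,
                           drop = FALSE]
  restricted$fdr <- p.adjust(restricted$p, method = "BH")
  restricted$is_fibre_cpg <- restricted$fdr < alpha
  rownames(restricted) <- NULL
  n_fib <- sum(restricted$is_fibre_cpg)
  list(meta = meta, restricted = restricted, n_fibre_cpgs = n_fib,
       fraction_of_sex_dmps = if (nrow(restricted)) n_fib / nrow(restricted)
                              else NA_real_,
       groups_used = names(groups))
}

#' Scan a single-sex cohort for hormone-associated CpGs
#'
#' Per-CpG model `DNAm ~ hormone + covariates` within one sex (to avoid
#' collinearity of hormone levels with sex), empirical-Bayes moderated, BH
#' adjusted. Counts of hits at `fdr < alpha` are reported genome-wide and
#' within the supplied sex-DMP subset (FDR re-computed within the subset).
#' `hormone` may be a single measured hormone or a principal component of a
#' hormone panel (see [hormone_pcs()]).
#'
#' @param study A `cohort_study` restricted to one sex.
#' @param hormone Named numeric vector (names = sample ids) of the hormone
#'   covariate; missing values imputed by the mean.
#' @param terms Extra covariate terms (default `"age"`).
#' @param sex_dmps Optional sex-DMP probe ids.
#' @param alpha FDR threshold (default 0.005).
#' @return List: `result` (moderated `ewas_result` with `fdr`),
#'   `n_dmps_genomewide`, `n_dmps_in_sex_dmps`.
#' @export
hormone_scan <- function(study, hormone, terms = "age", sex_dmps = NULL,
                         alpha = 0.005) {
  if (length(unique(study$samples$sex)) != 1)
    stop("hormone scans run within a single sex")
  h <- hormone[study$samples$sample_id]
  if (anyNA(h)) h[is.na(h)] <- mean(h, na.rm = TRUE)
  if (sd(h) == 0) stop("hormone covariate is constant")
  st <- study
  st$samples$hormone <- as.numeric(h)
  fit <- ebayes_moderate(fit_cpg_models(st, terms = terms, coef = "hormone",
                                        covariate = "hormone"))
  fit$fdr <- p.adjust(fit$p, method = "BH")
  n_gw <- sum(fit$fdr < alpha)
  n_sub <- NA_integer_
  if (!is.null(sex_dmps)) {
    sub <- fit[fit$probe_id %in% sex_dmps, , drop = FALSE]
    n_sub <- sum(p.adjust(sub$p, method = "BH") < alpha)
  }
  list(result = fit, n_dmps_genomewide = n_gw, n_dmps_in_sex_dmps = n_sub)
}

#' First principal components of a hormone panel
#'
#' Hormones are log-transformed and standardized before PCA (levels are
#' log-normal); intended for combining correlated ovarian hormones into a
#' small number of covariates.
#'
#' @param panel Hormone panel data frame (rows = samples).
#' @param hormones Column names to combine.
#' @param n_pcs Number of PCs to return (default 2).
#' @return Matrix (samples x PCs) with rownames from `panel$sample_id`;
#'   attribute `var_explained` gives the per-PC variance fractions.
#' @export
hormone_pcs <- function(panel, hormones, n_pcs = 2L) {
  M <- scale(log(as.matrix(panel[, hormones, drop = FALSE])))
  pc <- prcomp(M, center = FALSE, scale. = FALSE)
  out <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  rownames(out) <- panel$sample_id
  attr(out, "var_explained") <- pc$sdev^2 / sum(pc$sdev^2)
  out
}

## --- hormone-derived indices ------------------------------------------------

# Mass-action constants for the free-testosterone calculation (standard
# literature values; configurable through derive_hormone_indices()).
SODERGARD_K_SHBG <- 1.0e9    # L/mol
SODERGARD_K_ALB <- 3.6e4     # L/mol
ALBUMIN_MW <- 66430          # g/mol

#' Free testosterone from the mass-action binding model
#'
#' Solves the equilibrium of testosterone partitioned between the free pool,
#' SHBG (association constant 1.0e9 L/mol) and albumin (3.6e4 L/mol), with
#' ligand depletion of both binders:
#' `T = F + Ks F S / (1 + Ks F) + Ka F A / (1 + Ka F)`,
#' a cubic in the free concentration `F` with a unique positive root.
#'
#' @param t_nmol Total testosterone, nmol/L.
#' @param shbg_nmol SHBG, nmol/L.
#' @param albumin_gdl Albumin, g/dL (default 4.3).
#' @return Free testosterone in pmol/L.
#' @export
sodergard_free_t <- function(t_nmol, shbg_nmol, albumin_gdl = 4.3) {
  stopifnot(all(t_nmol > 0), all(shbg_nmol > 0))
  Ks <- SODERGARD_K_SHBG; Ka <- SODERGARD_K_ALB
  Tt <- t_nmol * 1e-9
  S <- rep_len(shbg_nmol * 1e-9, length(Tt))
  A <- albumin_gdl * 10 / ALBUMIN_MW
  vapply(seq_along(Tt), function(i) {
    Ti <- Tt[i]; Si <- S[i]
    ## expand T*(1+KsF)(1+KaF) = F(1+KsF)(1+KaF) + KsF Si (1+KaF) + KaF A (1+KsF)
    a3 <- Ks * Ka
    a2 <- Ks + Ka + Ks * Ka * (Si + A - Ti)
    a1 <- 1 + Ks * (Si - Ti) + Ka * (A - Ti)
    a0 <- -Ti
    r <- polyroot(c(a0, a1, a2, a3))
    r <- Re(r[abs(Im(r)) < 1e-9 * Mod(r) | Im(r) == 0])
    r <- r[r > 0]
    if (!length(r)) stop("no positive root in free-testosterone calculation")
    min(r) * 1e12        # mol/L -> pmol/L
  }, numeric(1))
}

#' Derive free androgen index and free testosterone for a hormone panel
#'
#' `FAI = T x 100 / SHBG`; free testosterone from [sodergard_free_t()].
#'
#' @param panel Data frame with columns `T` (nmol/L) and `SHBG` (nmol/L).
#' @param albumin_gdl Albumin, g/dL (default 4.3).
#' @return The panel with `FAI` and `free_T` (pmol/L) columns.
#' @export
derive_hormone_indices <- function(panel, albumin_gdl = 4.3) {
  stopifnot(all(panel$T > 0), all(panel$SHBG > 0))
  panel$FAI <- panel$T * 100 / panel$SHBG
  panel$free_T <- sodergard_free_t(panel$T, panel$SHBG, albumin_gdl)
  panel
}
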