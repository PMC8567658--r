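#' Genomic inflation factor
#'
#' `lambda_gc = median(z^2) / qchisq(0.5, 1)` (the 0.4549 constant).
#'
#' @param z Vector of z scores.
#' @return Scalar inflation factor.
#' @export
lambda_gc <- function(z) {
  median(z^2, na.rm = TRUE) / qchisq(0.5, 1)
}

#' Estimate the empirical null of a z-score vector
#'
#' Fits a three-component Gaussian mixture
#' `f(z) = p0 N(mu, sigma^2) + p+ N(mu+, s+^2) + p- N(mu-, s-^2)`
#' by constrained EM (mu- < mu < mu+, p0 initialized at 0.9) with
#' deterministic initialization (mu = median, sigma = 1.4826 x raw median
#' absolute deviation), and returns the null component: `mu` is the bias and
#' `sigma` the inflation of the test statistics. Unmeasured technical and
#' biological confounding inflates EWAS statistics; dividing out this null
#' restores calibration. For identifiability the signal means are kept at
#' least 2.5 null standard deviations away from the null mean, which stops
#' the signal components from absorbing ordinary null tail mass when there is
#' little or no true signal. Convergence: |delta log-likelihood| per score
#' < `tol` (default 1e-6), at most `max_iter` iterations; on non-convergence
#' the (median, MAD) estimator is returned with a warning.
#'
#' @param z Numeric vector of z scores (>= 10000 recommended; warns below).
#' @param tol,max_iter EM stopping parameters.
#' @return Object of class `null_estimate`: `mu`, `sigma`, `p0`,
#'   `lambda_gc` (of the input), `converged`, `n_iter`.
#' @export
estimate_empirical_null <- function(z, tol = 1e-6, max_iter = 1000L) {
  z <- z[is.finite(z)]
  if (length(z) < 10000)
    warning("fewer than 10000 scores; empirical-null estimate may be unstable")
  mu0 <- median(z)
  s0 <- mad(z, constant = 1.4826)
  if (s0 <= 0) s0 <- sd(z)
  ## deterministic init: wide null, sparse signal components at +-3 sigma
  mu <- c(mu0, mu0 + 3 * s0, mu0 - 3 * s0)
  sg <- c(s0, s0, s0)
  pr <- c(0.9, 0.05, 0.05)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  min_sep <- 2.5
  for (it in seq_len(max_iter)) {
    d <- cbind(pr[1] * dnorm(z, mu[1], sg[1]),
               pr[2] * dnorm(z, mu[2], sg[2]),
               pr[3] * dnorm(z, mu[3], sg[3]))
    tot <- rowSums(d)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- d / tot
    nk <- colSums(r)
    pr <- pmax(nk / length(z), 1e-8)
    pr <- pr / sum(pr)
    for (k in 1:3) {
      if (nk[k] > 1e-6) {
        mu[k] <- sum(r[, k] * z) / nk[k]
        sg[k] <- sqrt(sum(r[, k] * (z - mu[k])^2) / nk[k])
      }
      sg[k] <- max(sg[k], 0.05)
    }
    ## ordering + separation constraints on component means
    if (mu[2] < mu[1] + min_sep * sg[1]) mu[2] <- mu[1] + min_sep * sg[1] + 1e-6
    if (mu[3] > mu[1] - min_sep * sg[1]) mu[3] <- mu[1] - min_sep * sg[1] - 1e-6
    if (is.finite(ll_old) && abs(ll - ll_old) / length(z) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    warning("empirical-null EM did not converge; falling back to median/MAD")
    est <- list(mu = mu0, sigma = s0, p0 = 1, lambda_gc = lambda_gc(z),
                converged = FALSE, n_iter = it)
  } else {
    est <- list(mu = mu[1], sigma = sg[1], p0 = pr[1],
                lambda_gc = lambda_gc(z), converged = TRUE, n_iter = it)
  }
  class(est) <- "null_estimate"
  est
}

#' @export
print.null_estimate <- function(x, ...) {
  cat(sprintf(
    "<null_estimate> bias mu = %.4f, inflation sigma = %.4f, p0 = %.3f, lambda_gc = %.3f (%s, %d iter)\n",
    x$mu, x$sigma, x$p0, x$lambda_gc,
    if (x$converged) "EM converged" else "median/MAD fallback", x$n_iter))
  invisible(x)
}

#' Calibrate an EWAS against its empirical null
#'
#' Rescales the score of every probe: `z' = (z - mu) / sigma`,
#' `p' = 2 Phi(-|z'|)`, and reconstructs the standard error on the
#' effect-size scale as `se' = |effect / z'|` so that downstream
#' inverse-variance weighting operates in calibrated units. Effects are
#' unchanged. Probes with `z' = 0` get infinite `se` (weight zero).
#'
#' @param ewas An `ewas_result` (moderated).
#' @param null A `null_estimate` from the same cohort's scores.
#' @return The `ewas_result` with columns `z`, `p`, `se` replaced by their
#'   calibrated versions (original moderated t kept in `t`).
#' @export
correct_scores <- function(ewas, null) {
  stopifnot(inherits(null, "null_estimate"))
  z <- ewas$t
  zc <- (z - null$mu) / null$sigma
  p <- 2 * pnorm(-abs(zc))
  se <- abs(ewas$effect / zc)
  se[!is.finite(zc) | zc == 0] <- Inf
  p[!is.finite(z)] <- 1
  zc[!is.finite(z)] <- 0
  out <- ewas
  out$z <- zc
  out$p <- p
  out$se <- se
  out
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Combines per-cohort calibrated effects: weights `w_i = 1/se_i^2`, combined
#' effect `sum(w b)/sum(w)`, `se = 1/sqrt(sum w)`, two-sided normal p.
#' Cochran's Q (`sum w (b - bbar)^2`, chi-square on k-1 df) and
#' `I2 = max(0, (Q - (k-1))/Q) x 100` quantify between-cohort heterogeneity;
#' probes with I2 > 50% are flagged (`heterogeneous`), not removed. Only
#' probes present with finite weights in at least `min_cohorts` cohorts are
#' combined.
#'
#' @param ewas_list Named list of calibrated `ewas_result` data frames.
#' @param min_cohorts Minimum cohorts per probe (default 2).
#' @return Data frame of class `meta_result`: `probe_id`, `effect`, `se`,
#'   `z`, `p`, `q_stat`, `q_p`, `i2`, `k`, `direction` (one character per
#'   cohort: `+`, `-`, or `?` when absent), `heterogeneous`.
#' @export
ivw_meta <- function(ewas_list, min_cohorts = 2L) {
  k_all <- length(ewas_list)
  if (is.null(names(ewas_list)))
    names(ewas_list) <- sprintf("cohort%d", seq_len(k_all))
  ids <- unique(unlist(lapply(ewas_list, `[[`, "probe_id")))
  B <- W <- matrix(NA_real_, length(ids), k_all,
                   dimnames = list(ids, names(ewas_list)))
  for (j in seq_len(k_all)) {
    e <- ewas_list[[j]]
    i <- match(e$probe_id, ids)
    B[i, j] <- e$effect
    W[i, j] <- 1 / e$se^2
  }
  W[!is.finite(W)] <- NA_real_
  ok <- is.finite(B) & is.finite(W) & W > 0
  k <- rowSums(ok)
  keep <- k >= min_cohorts
  if (!any(keep)) stop("no probe present in >= min_cohorts cohorts")
  B <- B[keep, , drop = FALSE]; W <- W[keep, , drop = FALSE]
  ok <- ok[keep, , drop = FALSE]; k <- k[keep]
  W[!ok] <- 0
  Bz <- B; Bz[!ok] <- 0
  sw <- rowSums(W)
  eff <- rowSums(W * Bz) / sw
  se <- 1 / sqrt(sw)
  z <- eff / se
  p <- 2 * pnorm(-abs(z))
  q <- rowSums(W * (Bz - eff)^2 * ok)
  q_p <- pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- pmax(0, (q - (k - 1)) / q) * 100
  i2[q <= 0] <- 0
  dirs <- matrix("?", nrow(B), k_all)
  dirs[ok & B > 0] <- "+"
  dirs[ok & B < 0] <- "-"
  direction <- apply(dirs, 1, paste, collapse = "")
  out <- data.frame(probe_id = rownames(B), effect = eff, se = se, z = z,
                    p = p, q_stat = q, q_p = q_p, i2 = i2, k = k,
                    direction = direction, heterogeneous = i2 > 50,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Call differentially methylated positions at an FDR threshold
#'
#' Benjamini-Hochberg step-up FDR over the meta-analysis p-values; probes with
#' `fdr < alpha` are DMPs. Rows are ordered by p (ties broken by probe id) so
#' the adjustment is reproducible.
#'
#' @param meta A `meta_result`.
#' @param alpha FDR threshold (default 0.005).
#' @return The `meta_result` with `fdr` and `is_dmp` columns; attribute
#'   `summary` holds DMP counts and hyper/hypo fractions by effect sign.
#' @export
call_dmps <- function(meta, alpha = 0.005) {
  ord <- order(meta$p, meta$probe_id)
  meta <- meta[ord, , drop = FALSE]
  meta$fdr <- p.adjust(meta$p, method = "BH")
  meta$is_dmp <- meta$fdr < alpha
  n_dmp <- sum(meta$is_dmp)
  hyper <- sum(meta$is_dmp & meta$effect > 0)
  attr(meta, "summary") <- list(
    n_dmp = n_dmp, n_tested = nrow(meta),
    frac_hyper = if (n_dmp) hyper / n_dmp else NA_real_,
    frac_hypo = if (n_dmp) (n_dmp - hyper) / n_dmp else NA_real_)
  rownames(meta) <- NULL
  meta
}

#' Variance in DMP methylation explained by sex via PCA
#'
#' Principal components of the samples-by-DMP matrix (centred and scaled);
#' the reported PC is the one among the first `n_pcs` with the largest
#' absolute point-biserial correlation with sex, and the statistic is the
#' adjusted R-squared of the linear model `PC ~ sex`.
#'
#' @param beta Probes-by-samples beta matrix restricted to DMPs.
#' @param sex Character vector (`"M"`/`"F"`) aligned with the columns.
#' @param n_pcs Candidate PCs (default 5).
#' @return List `pc` (index), `adj_r2`, `cor` (point-biserial correlation).
#' @export
pca_variance_explained <- function(beta, sex, n_pcs = 5L) {
  if (nrow(beta) < 2) stop("need at least 2 probes")
  if (min(table(sex)) < 2) stop("need >= 2 samples per sex")
  X <- t(beta)
  keep <- apply(X, 2, sd) > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  m <- min(n_pcs, ncol(pc$x))
  s01 <- as.numeric(sex == "M")
  cors <- abs(apply(pc$x[, seq_len(m), drop = FALSE], 2, cor, y = s01))
  j <- which.max(cors)
  fit <- lm(pc$x[, j] ~ s01)
  list(pc = unname(j), adj_r2 = summary(fit)$adj.r.squared,
       cor = unname(cors[j]))
}
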