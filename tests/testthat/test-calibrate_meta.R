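test_that("the empirical null recovers a standard-normal score vector", {
  set.seed(1)
  e <- estimate_empirical_null(rnorm(50000))
  expect_true(e$converged)
  expect_lt(abs(e$mu), 0.03)
  expect_gt(e$sigma, 0.97)
  expect_lt(e$sigma, 1.03)
  expect_warning(estimate_empirical_null(rnorm(500)), "fewer than 10000")
})

test_that("the empirical null recovers planted bias and inflation", {
  set.seed(2)
  n <- 50000
  lab <- runif(n) < 0.95
  z <- ifelse(lab, 0.2 + 1.5 * rnorm(n), rnorm(n, 4, 1))
  e <- estimate_empirical_null(z)
  expect_lt(abs(e$sigma - 1.5), 0.08)
  expect_lt(abs(e$mu - 0.2), 0.05)
  # after correction the null fraction is standard normal
  zc <- (z[lab] - e$mu) / e$sigma
  expect_gt(lambda_gc(zc), 0.95)
  expect_lt(lambda_gc(zc), 1.05)
  # lambda_gc is recomputable from its definition
  expect_equal(e$lambda_gc, median(z^2) / qchisq(0.5, 1))
})

test_that("score correction rescales z, p and se consistently", {
  fit <- structure(
    data.frame(probe_id = c("a", "b", "c"), effect = c(0.1, -0.2, 0.05),
               se = c(0.05, 0.1, 0.05), t = c(2, -2, 1), df = 20,
               p = 0.05, n = 10, sigma = 1, stdev_unscaled = 1),
    class = c("ewas_result", "data.frame"))
  ident <- structure(list(mu = 0, sigma = 1, p0 = 1, lambda_gc = 1,
                          converged = TRUE, n_iter = 1),
                     class = "null_estimate")
  c1 <- correct_scores(fit, ident)
  expect_equal(c1$z, fit$t)
  expect_equal(c1$p, 2 * pnorm(-abs(fit$t)))
  half <- ident; half$sigma <- 2
  c2 <- correct_scores(fit, half)
  expect_equal(c2$z, fit$t / 2)
  expect_equal(c2$se, abs(fit$effect / (fit$t / 2)))
  # corrected p of a simulated null is uniform
  set.seed(3)
  z <- 0.3 + 1.4 * rnorm(30000)
  e <- estimate_empirical_null(z)
  p <- 2 * pnorm(-abs((z - e$mu) / e$sigma))
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("inverse-variance weighting matches hand formulas and metafor", {
  mk <- function(b, se) structure(
    data.frame(probe_id = "cg1", effect = b, se = se, t = b / se, df = 50,
               p = 0.5, n = 20, sigma = 1, stdev_unscaled = 1, z = b / se),
    class = c("ewas_result", "data.frame"))
  # two identical studies: replication
  m <- ivw_meta(list(a = mk(0.10, 0.05), b = mk(0.10, 0.05)))
  expect_equal(m$effect, 0.10)
  expect_equal(m$se, 0.05 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$q_stat, 0)
  expect_equal(m$i2, 0)
  expect_equal(m$direction, "++")

  # three studies vs the hand-computed weighted mean
  m3 <- ivw_meta(list(a = mk(0.2, 0.1), b = mk(0.1, 0.05), c = mk(0.15, 0.2)))
  expect_equal(m3$effect, 63.75 / 525, tolerance = 1e-10)
  expect_equal(m3$se, 1 / sqrt(525), tolerance = 1e-10)

  # independent oracle: metafor fixed-effects fit
  skip_if_not_installed("metafor")
  rf <- metafor::rma(yi = c(0.2, 0.1, 0.15), sei = c(0.1, 0.05, 0.2),
                     method = "FE")
  expect_equal(m3$effect, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(m3$se, rf$se, tolerance = 1e-10)
  expect_equal(m3$q_stat, rf$QE, tolerance = 1e-10)

  # antisymmetry: flipping all signs flips the combined sign only
  mneg <- ivw_meta(list(a = mk(-0.2, 0.1), b = mk(-0.1, 0.05),
                        c = mk(-0.15, 0.2)))
  expect_equal(mneg$effect, -m3$effect)
  expect_equal(mneg$p, m3$p)
  expect_equal(mneg$direction, "---")

  # combined variance never exceeds the best single study
  expect_lt(m3$se, 0.05)
  # single-study meta equals that study (production guards with k >= 2)
  m1 <- ivw_meta(list(a = mk(0.2, 0.1)), min_cohorts = 1)
  expect_equal(m1$effect, 0.2)
  expect_equal(m1$se, 0.1)
})

test_that("probes are combined only when seen in enough cohorts", {
  mk2 <- function(ids, b) structure(
    data.frame(probe_id = ids, effect = b, se = 0.05, t = b / 0.05, df = 50,
               p = 0.5, n = 20, sigma = 1, stdev_unscaled = 1, z = b / 0.05),
    class = c("ewas_result", "data.frame"))
  m <- ivw_meta(list(a = mk2(c("x", "y"), 0.1), b = mk2(c("y", "z"), 0.1)))
  expect_equal(m$probe_id, "y")
  expect_equal(m$k, 2)
  # probes with an infinite se in one cohort keep the other cohorts
  e1 <- mk2(c("x", "y"), 0.1); e1$se[1] <- Inf
  m2 <- ivw_meta(list(a = e1, b = mk2(c("x", "y"), 0.1),
                      c = mk2(c("x", "y"), 0.1)))
  expect_equal(m2$k[m2$probe_id == "x"], 2)
  expect_equal(substr(m2$direction[m2$probe_id == "x"], 1, 1), "?")
})

test_that("BH DMP calling matches hand and brute-force step-up", {
  mk_meta <- function(p) structure(
    data.frame(probe_id = sprintf("cg%03d", seq_along(p)), effect = 0.1,
               se = 0.1, z = 1, p = p, q_stat = 0, q_p = 1, i2 = 0, k = 2,
               direction = "++", heterogeneous = FALSE),
    class = c("meta_result", "data.frame"))
  m <- call_dmps(mk_meta(c(0.001, 0.02, 0.03, 0.5)))
  expect_equal(m$fdr, c(0.004, 0.04, 0.04, 0.5))

  m1 <- call_dmps(mk_meta(rep(1, 10)))
  expect_equal(sum(m1$is_dmp), 0)

  set.seed(4)
  p <- runif(1000)^2
  m2 <- call_dmps(mk_meta(p))
  expect_equal(m2$fdr, bh_brute_force(sort(p)), tolerance = 1e-12)
})

test_that("DMP summaries report hyper/hypo fractions", {
  m <- structure(
    data.frame(probe_id = sprintf("cg%d", 1:4), effect = c(0.1, -0.2, -0.3, 0.1),
               se = 0.01, z = 1, p = c(1e-8, 1e-8, 1e-8, 0.9), q_stat = 0,
               q_p = 1, i2 = 0, k = 2, direction = "++",
               heterogeneous = FALSE),
    class = c("meta_result", "data.frame"))
  s <- attr(call_dmps(m), "summary")
  expect_equal(s$n_dmp, 3)
  expect_equal(s$frac_hypo, 2 / 3)
})

test_that("PCA variance explained by sex behaves across regimes", {
  set.seed(5)
  n <- 60
  sex <- rep(c("F", "M"), each = n / 2)
  # perfect separation: probes are copies of the sex indicator
  beta <- matrix(rep(as.numeric(sex == "M"), each = 10), 10, n, byrow = FALSE) +
    matrix(rnorm(10 * n, 0, 1e-3), 10, n)
  r <- pca_variance_explained(beta, sex)
  expect_gt(r$adj_r2, 0.99)

  # permuted labels: no variance explained
  set.seed(6)
  beta2 <- matrix(runif(200 * 100), 200, 100)
  r2 <- pca_variance_explained(beta2, sample(rep(c("F", "M"), 50)))
  expect_lt(abs(r2$adj_r2), 0.05)

  # planted effect size increases R^2 monotonically
  r2s <- vapply(c(0.05, 0.15, 0.3), function(d) {
    cfg <- sim_config(n_cohorts = 1, n_probes = 300, n_samples = 60,
                      frac_sex_cpgs = 1, effect_mean_hyper = d,
                      effect_mean_hypo = d, effect_fixed = TRUE,
                      frac_fibre_cpgs = 0, cohort_probe_frac = 1, seed = 30)
    sim <- simulate_cohorts(cfg)
    st <- sim$cohorts[[1]]
    pca_variance_explained(st$beta, st$samples$sex)$adj_r2
  }, numeric(1))
  expect_true(all(diff(r2s) > 0))
  expect_error(pca_variance_explained(matrix(0.5, 1, 10),
                                      rep(c("F", "M"), 5)), "at least 2")
})
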