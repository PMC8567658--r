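test_that("context chi-square matches hand computation and its identities", {
  # identical category distribution across statuses: chi2 = 0, p = 1
  status <- rep(c("hyper", "hypo", "non"), each = 30)
  category <- rep(rep(c("TssA", "Enh", "Quies"), each = 10), 3)
  r0 <- context_chi2(status, category)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # 2x2 (10,20;20,10): chi2 = N(ad-bc)^2/(r1 r2 c1 c2) = 6.667
  st <- rep(c("dmp", "non"), c(30, 30))
  ct <- c(rep(c("in", "out"), c(10, 20)), rep(c("in", "out"), c(20, 10)))
  r1 <- context_chi2(st, ct)
  expect_equal(r1$chi2, 60 * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  expect_equal(r1$chi2, 20 / 3, tolerance = 1e-10)
  expect_equal(r1$p, pchisq(20 / 3, 1, lower.tail = FALSE), tolerance = 1e-10)

  # Pearson residuals square-sum to chi2 on a random 3x4 table
  set.seed(10)
  status2 <- sample(c("hyper", "hypo", "non"), 600, TRUE)
  cat2 <- sample(c("a", "b", "c", "d"), 600, TRUE, prob = c(1, 2, 3, 4))
  r2 <- context_chi2(status2, cat2)
  expect_equal(sum(r2$residuals^2), r2$chi2, tolerance = 1e-10)

  # invariant to row/column permutation
  r3 <- context_chi2(factor(status2, levels = c("non", "hyper", "hypo")),
                     factor(cat2, levels = c("d", "a", "c", "b")))
  expect_equal(r3$chi2, r2$chi2, tolerance = 1e-10)
})

test_that("sex-discordant state odds ratio reproduces the published table", {
  # 56,813 DMPs with 38.7% in discordant states; 576,832 non-DMPs with 32.4%
  n_dmp <- 56813; n_non <- 633645 - 56813
  d_dmp <- round(0.387 * n_dmp); d_non <- round(0.324 * n_non)
  is_dmp <- rep(c(TRUE, FALSE), c(n_dmp, n_non))
  disc <- c(rep(c(TRUE, FALSE), c(d_dmp, n_dmp - d_dmp)),
            rep(c(TRUE, FALSE), c(d_non, n_non - d_non)))
  r <- sex_state_or(is_dmp, disc)
  expect_equal(round(r$odds_ratio, 2), 0.76)
  expect_equal(round(r$ci, 2), c(0.75, 0.77))
  expect_lt(r$fisher_p, 1e-15)

  # independent flags: OR ~ 1
  set.seed(11)
  a <- runif(20000) < 0.3; b <- runif(20000) < 0.4
  rn <- sex_state_or(a, b)
  expect_lt(abs(log(rn$odds_ratio)), 0.1)

  # swapping row order inverts the OR exactly
  rs <- sex_state_or(!is_dmp, disc)
  expect_equal(rs$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
})

test_that("probe-count bias correction in the gene-set test works", {
  # equal probe counts: monte-carlo p agrees with the hypergeometric tail
  genes <- sprintf("g%02d", 1:40)
  gm <- data.frame(probe_id = sprintf("cg%03d", 1:120),
                   gene = rep(genes, each = 3))
  sig_genes <- genes[1:10]
  sig_probes <- gm$probe_id[gm$gene %in% sig_genes]
  set_genes <- genes[c(1:6, 31:34)]
  r <- gene_set_test(sig_probes, gm$probe_id, gm,
                     list(s = set_genes), n_iter = 20000, seed = 2)
  hyper <- phyper(r$DE - 1, length(set_genes), 40 - length(set_genes), 10,
                  lower.tail = FALSE)
  expect_lt(abs(r$p - hyper), 0.02)

  # a set of probe-rich genes is penalized relative to the plain test
  set.seed(12)
  counts <- c(rep(25, 8), rep(1, 32))            # 8 probe-rich genes
  gm2 <- data.frame(probe_id = sprintf("cp%04d", seq_len(sum(counts))),
                    gene = rep(genes, counts))
  sig_probes2 <- sample(gm2$probe_id, 60)
  sig_genes2 <- unique(gm2$gene[gm2$probe_id %in% sig_probes2])
  rich_set <- genes[1:8]
  r2 <- gene_set_test(sig_probes2, gm2$probe_id, gm2,
                      list(rich = rich_set), n_iter = 10000, seed = 3)
  plain <- phyper(length(intersect(rich_set, sig_genes2)) - 1, 8, 32,
                  length(sig_genes2), lower.tail = FALSE)
  expect_gt(r2$p, plain * 5)

  # wallenius mode agrees with monte-carlo on the biased fixture
  rw <- gene_set_test(sig_probes2, gm2$probe_id, gm2, list(rich = rich_set),
                      method = "wallenius")
  expect_lt(abs(rw$p - r2$p), 0.1)
})

test_that("monte-carlo gene-set p matches exhaustive enumeration on 6 genes", {
  genes <- letters[1:6]
  w <- c(4, 3, 2, 1, 1, 1)                      # probes per gene
  gm <- data.frame(probe_id = sprintf("e%02d", seq_len(sum(w))),
                   gene = rep(genes, w))
  sig_genes <- c("a", "b")                       # k = 2 significant genes
  sig_probes <- gm$probe_id[match(c("a", "b"), gm$gene)]
  set_genes <- c("a", "b", "c")
  obs <- length(intersect(set_genes, sig_genes))
  # exact null: sequential weighted draws of 2 genes without replacement
  p_exact <- 0
  for (i in 1:6) for (j in setdiff(1:6, i)) {
    pr <- (w[i] / sum(w)) * (w[j] / (sum(w) - w[i]))
    ov <- sum(genes[c(i, j)] %in% set_genes)
    if (ov >= obs) p_exact <- p_exact + pr
  }
  r <- gene_set_test(sig_probes, gm$probe_id, gm, list(s = set_genes),
                     n_iter = 20000, seed = 4)
  expect_equal(r$DE, obs)
  expect_lt(abs(r$p - p_exact), 0.01)

  # reproducible under a fixed seed
  r2 <- gene_set_test(sig_probes, gm$probe_id, gm, list(s = set_genes),
                      n_iter = 20000, seed = 4)
  expect_identical(r$p, r2$p)
})

test_that("TFBS enrichment uses the half-open overlap and a background", {
  anno <- data.frame(probe_id = sprintf("t%04d", 1:5000), chrom = "chr1",
                     pos = seq(1000, by = 100, length.out = 5000), genes = "")
  set.seed(13)
  dmps <- sample(anno$probe_id, 500)
  # planted TF covering 80% of DMPs vs ~10% of background
  cover <- c(sample(dmps, 400), sample(setdiff(anno$probe_id, dmps), 450))
  pos <- anno$pos[match(cover, anno$probe_id)]
  tf_planted <- data.frame(chrom = "chr1", start = pos - 1, end = pos)
  # a TF covering every probe discriminates nothing
  tf_all <- data.frame(chrom = "chr1", start = 0, end = 1e7)
  r <- tfbs_enrichment(dmps, list(planted = tf_planted, all = tf_all), anno)
  expect_lt(r$p[r$dataset == "planted"], 1e-6)
  expect_equal(r$p[r$dataset == "all"], 1)
  expect_equal(r$dataset[1], "planted")           # ranked by -log10 p

  # boundary: CpG at 1-based 100 is outside [100,200) but inside [99,200)
  anno_b <- data.frame(probe_id = c("b1", "b2"), chrom = "chr1",
                       pos = c(100, 150), genes = "")
  r_out <- tfbs_enrichment("b1", list(tf = data.frame(chrom = "chr1",
                                                      start = 100, end = 200)),
                           anno_b)
  expect_equal(r_out$n_dmp_in, 0L)
  r_in <- tfbs_enrichment("b1", list(tf = data.frame(chrom = "chr1",
                                                     start = 99, end = 200)),
                          anno_b)
  expect_equal(r_in$n_dmp_in, 1L)

  # a dataset with no overlapping probe is flagged with p = 1
  r_none <- tfbs_enrichment("b1", list(tf = data.frame(chrom = "chr2",
                                                       start = 0, end = 10)),
                            anno_b)
  expect_true(r_none$no_overlap)
  expect_equal(r_none$p, 1)
})

test_that("enrichment p falls as DMP-in-TFBS count rises with fixed margins", {
  p_at <- function(a) fisher.test(matrix(c(a, 100 - a, 300, 1700), 2,
                                         byrow = TRUE),
                                  alternative = "greater")$p.value
  ps <- vapply(c(20, 30, 40, 50), p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("overlap resampling calibrates against the array universe", {
  universe <- sprintf("u%05d", 1:10000)
  dmps <- universe[1:1000]
  # reference = universe: every draw overlaps fully, p = 1
  r1 <- overlap_resampling(dmps, universe, universe, n_iter = 200, seed = 5)
  expect_equal(r1$p, 1)
  # disjoint small reference: no evidence
  r2 <- overlap_resampling(dmps, universe[9990:9999], universe,
                           n_iter = 500, seed = 6)
  expect_gt(r2$p, 0.5)
  # planted enrichment: 100 of 500 reference CpGs inside the DMP set
  ref <- c(universe[1:100], universe[5001:5400])
  r3 <- overlap_resampling(dmps, ref, universe, n_iter = 10000, seed = 7)
  expect_lt(r3$p, 1e-4)
  expect_error(overlap_resampling(dmps, "not_in_universe", universe),
               "subset")
})
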