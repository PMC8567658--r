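mk_meta_at <- function(ids, z, p = 2 * pnorm(-abs(z)), effect = z / 10) {
  structure(data.frame(probe_id = ids, effect = effect, se = 0.1, z = z,
                       p = p, q_stat = 0, q_p = 1, i2 = 0, k = 2,
                       direction = "++", heterogeneous = FALSE,
                       stringsAsFactors = FALSE),
            class = c("meta_result", "data.frame"))
}

test_that("kernel smoothing handles isolated and coincident CpGs", {
  # isolated CpG: no neighbour within 3 sigma -> chi-square(1) tail of z^2
  anno <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                     pos = c(1000, 100000), genes = "")
  meta <- mk_meta_at(c("a", "b"), z = c(2.5, 1))
  sm <- smooth_statistics(meta, anno)
  expect_equal(sm$y_smooth[sm$probe_id == "a"], 2.5^2)
  expect_equal(sm$df[sm$probe_id == "a"], 1)
  expect_equal(sm$p_smooth[sm$probe_id == "a"],
               pchisq(2.5^2, 1, lower.tail = FALSE))

  # two coincident CpGs with equal z: stat z^2 on 2 df, smaller p
  anno2 <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                      pos = c(5000, 5000), genes = "")
  meta2 <- mk_meta_at(c("a", "b"), z = c(2.5, 2.5))
  sm2 <- smooth_statistics(meta2, anno2)
  expect_equal(sm2$y_smooth, rep(2.5^2, 2))
  expect_equal(sm2$df, rep(2, 2))
  expect_equal(sm2$p_smooth, rep(pchisq(2 * 2.5^2, 2, lower.tail = FALSE), 2))
  expect_lt(sm2$p_smooth[1], pchisq(2.5^2, 1, lower.tail = FALSE))
})

test_that("smoothed null p-values are calibrated where region calling uses them", {
  # The moment-matched null is a two-moment approximation, so the body of the
  # p distribution deviates measurably at 10k probes; what region calling
  # consumes are the tails, which must hold their nominal levels.
  set.seed(7)
  n <- 10000
  anno <- data.frame(probe_id = sprintf("cg%05d", 1:n), chrom = "chr1",
                     pos = sort(sample.int(3e7, n)), genes = "")
  meta <- mk_meta_at(anno$probe_id, z = rnorm(n))
  sm <- smooth_statistics(meta, anno)
  expect_lt(abs(mean(sm$p_smooth < 0.05) - 0.05), 0.01)
  expect_lt(abs(mean(sm$p_smooth < 0.005) - 0.005), 0.003)
  expect_equal(sum(p.adjust(sm$p_smooth, "BH") < 0.005), 0)
})

test_that("a planted 8-CpG region is recovered with all three statistics", {
  cfg <- sim_config(n_cohorts = 2, n_probes = 2000, n_samples = c(200, 200),
                    frac_sex_cpgs = 8 / 2000, effect_mean_hyper = 0.2,
                    effect_mean_hypo = 0.2, effect_fixed = TRUE,
                    frac_fibre_cpgs = 0, cohort_probe_frac = c(1, 1),
                    seed = 41)
  sim <- simulate_cohorts(cfg)
  res <- run_sex_meta(sim$cohorts, sim$annotation)
  planted <- sim$truth$probe_id[sim$truth$is_sex_cpg]
  expect_equal(length(planted), 8)
  sig <- res$dmrs[res$dmrs$significant, , drop = FALSE]
  expect_equal(nrow(sig), 1)
  members <- strsplit(sig$probe_ids, ";")[[1]]
  expect_gte(length(intersect(members, planted)), 6)
  expect_lt(sig$stouffer, 0.005)
  expect_lt(sig$fisher_p, 0.005)
  expect_lt(sig$hmfdr, 0.005)
  # boundaries are the min/max member positions
  pos <- sim$annotation$pos[match(members, sim$annotation$probe_id)]
  expect_equal(sig$start, min(pos))
  expect_equal(sig$end, max(pos))
})

test_that("region calling respects thresholds, gaps and monotonicity", {
  # one lone significant CpG never forms a region
  anno <- data.frame(probe_id = sprintf("p%d", 1:5), chrom = "chr1",
                     pos = c(1000, 60000, 120000, 180000, 240000), genes = "")
  meta <- call_dmps(mk_meta_at(anno$probe_id, z = c(8, 0.1, 0.2, -0.3, 0.1)))
  sm <- smooth_statistics(meta, anno)
  expect_equal(nrow(call_regions(sm, meta)), 0)

  # clustered significant CpGs form one region; lambda merging is monotone
  anno2 <- data.frame(probe_id = sprintf("p%d", 1:6), chrom = "chr1",
                      pos = c(1000, 1200, 1400, 2800, 3000, 90000), genes = "")
  meta2 <- call_dmps(mk_meta_at(anno2$probe_id,
                                z = c(7, 7.5, 8, 7, 7.2, 0.1)))
  sm2 <- smooth_statistics(meta2, anno2)
  r_narrow <- call_regions(sm2, meta2, lambda = 1000)
  r_wide <- call_regions(sm2, meta2, lambda = 2000)
  expect_gte(max(r_wide$n_cpgs), max(r_narrow$n_cpgs))
  expect_true(all(vapply(seq_len(nrow(r_narrow)), function(i)
    any(r_wide$start <= r_narrow$start[i] & r_wide$end >= r_narrow$end[i]),
    logical(1))))

  # hmfdr is at least the smallest member fdr; fisher_p drops as a
  # strong member joins
  m <- meta2[meta2$probe_id %in% sprintf("p%d", 1:5), ]
  reg <- call_regions(sm2, meta2, lambda = 2000)
  expect_gte(reg$hmfdr[1], min(m$fdr))
  fisher_of <- function(p) pchisq(-2 * sum(log(p)), 2 * length(p),
                                  lower.tail = FALSE)
  p_base <- c(0.01, 0.02, 0.04)
  expect_lt(fisher_of(c(p_base, 0.001)), fisher_of(p_base))
})

test_that("null pipelines rarely produce significant regions", {
  hits <- vapply(1:5, function(r) {
    cfg <- sim_config(n_probes = 5000, n_samples = c(30, 30, 30),
                      frac_sex_cpgs = 0, frac_fibre_cpgs = 0,
                      seed = 100 + r)
    sim <- simulate_cohorts(cfg)
    res <- run_sex_meta(sim$cohorts, sim$annotation)
    sum(res$dmrs$significant)
  }, numeric(1))
  expect_gte(sum(hits == 0), 4)
})

test_that("DMR gene mapping is the union over member CpGs", {
  anno <- data.frame(probe_id = c("p1", "p2", "p3"), chrom = "chr1",
                     pos = c(1, 2, 3),
                     genes = c("A", "A;B", ""), stringsAsFactors = FALSE)
  dmrs <- structure(
    data.frame(chrom = "chr1", start = 1, end = 3, n_cpgs = 3,
               stouffer = 1e-4, fisher_p = 1e-4, hmfdr = 1e-4,
               maxdiff = 0.1, meandiff = 0.1, significant = TRUE,
               probe_ids = "p1;p2;p3", stringsAsFactors = FALSE),
    class = c("dmr_result", "data.frame"))
  mp <- map_dmrs_to_genes(dmrs, anno)
  expect_equal(mp$dmrs$genes, "A;B")
  expect_setequal(mp$genes$gene, c("A", "B"))

  # intergenic region keeps an empty gene list
  dmr2 <- dmrs; dmr2$probe_ids <- "p3"
  expect_equal(map_dmrs_to_genes(dmr2, anno)$dmrs$genes, "")

  # counts match a brute-force join on a random fixture
  set.seed(9)
  n <- 300
  anno3 <- data.frame(probe_id = sprintf("q%03d", 1:n), chrom = "chr1",
                      pos = 1:n,
                      genes = replicate(n, paste(
                        sample(LETTERS[1:12], sample(0:2, 1)), collapse = ";")),
                      stringsAsFactors = FALSE)
  regs <- lapply(1:100, function(i) sample(anno3$probe_id, sample(2:6, 1)))
  dmr3 <- structure(
    data.frame(chrom = "chr1", start = 1, end = 2,
               n_cpgs = lengths(regs), stouffer = 0, fisher_p = 0, hmfdr = 0,
               maxdiff = 0, meandiff = 0, significant = TRUE,
               probe_ids = vapply(regs, paste, "", collapse = ";"),
               stringsAsFactors = FALSE),
    class = c("dmr_result", "data.frame"))
  mp3 <- map_dmrs_to_genes(dmr3, anno3)
  brute <- table(unlist(lapply(regs, function(p) {
    unique(unlist(strsplit(anno3$genes[anno3$probe_id %in% p], ";")))
  })))
  brute <- brute[nzchar(names(brute))]
  expect_equal(setNames(mp3$genes$n_dmrs, mp3$genes$gene)[names(brute)],
               setNames(as.integer(brute), names(brute)))
})
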