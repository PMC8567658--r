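#' Configuration for the synthetic multi-cohort generator
#'
#' Defaults emulate the structure of a three-cohort skeletal-muscle sex EWAS:
#' about 10% of autosomal CpGs carry a sex effect, 94% of those are
#' hypomethylated in males, mean absolute beta differences are 0.028
#' (hypermethylated) and 0.035 (hypomethylated), females have a higher type-I
#' fibre proportion than males, and one cohort is typed on a much smaller
#' (27K-style) array so the at-least-two-cohorts rule is exercised.
#'
#' Signal is built on the logit2 (M-value) scale: effects are sized so the
#' target delta-beta is realized at a baseline of 0.5 and attenuate towards
#' the extremes, matching array behaviour. CpGs come in blocks (default 8
#' probes, 150 bp apart) sharing a baseline and a per-sample block effect, so
#' neighbouring probes are correlated while probes more than a few block
#' lengths apart are not.
#'
#' @param n_cohorts Number of cohorts (default 3).
#' @param n_probes Probes on the full array (default 20000).
#' @param n_samples Integer vector of per-cohort sample sizes (split evenly by
#'   sex); recycled to `n_cohorts`. Default `c(80, 64, 22)`.
#' @param frac_sex_cpgs Fraction of probes with a planted sex effect.
#' @param frac_hypo_in_males Among sex CpGs, fraction hypomethylated in males.
#' @param effect_mean_hyper,effect_mean_hypo Mean |delta-beta| of hyper-/
#'   hypomethylated sex effects (gamma-distributed, shape 4), or exact value
#'   when `effect_fixed = TRUE`.
#' @param effect_fixed If TRUE every sex CpG gets exactly the mean |delta-beta|
#'   of its direction class (useful for power studies).
#' @param frac_fibre_cpgs Fraction of probes with a fibre-type effect.
#' @param frac_sex_also_fibre Among sex CpGs, fraction that additionally carry
#'   a fibre effect (the fibre-mediated share; default 0.155).
#' @param fibre_effect_mean Mean |delta-beta per unit type-I proportion| of
#'   fibre effects (sign: 70% positive, type-I fibres hypermethylated).
#' @param fibre_beta_mean_f,fibre_beta_mean_m,fibre_beta_precision Beta
#'   distribution of type-I fibre proportion per sex (mean/precision
#'   parameterisation; defaults 0.52 / 0.42 / 30).
#' @param batch_sd,subject_sd,residual_sd,block_sd Standard deviations (logit2
#'   units) of per-probe batch offsets, subject random intercepts (used when
#'   `n_reps > 1`), residual noise, and the shared block-by-sample effect.
#' @param block_size,intra_block_gap,inter_block_gap Probes per block, spacing
#'   within a block (bp) and mean gap between blocks (bp); the block
#'   correlation length is `block_size * intra_block_gap`.
#' @param n_reps Samples per subject (repeated measures; default 1).
#' @param cohort_probe_frac Fraction of the array typed in each cohort
#'   (default `c(1, 1, 0.05)`-style: last cohort emulates a 27K array).
#' @param discordant_frac_null,discordant_frac_sex Probability that a block's
#'   male and female chromatin states differ, for blocks without / with a
#'   planted sex effect.
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 3L, n_probes = 20000L,
                       n_samples = c(80L, 64L, 22L),
                       frac_sex_cpgs = 0.10, frac_hypo_in_males = 0.94,
                       effect_mean_hyper = 0.028, effect_mean_hypo = 0.035,
                       effect_fixed = FALSE,
                       frac_fibre_cpgs = 0.026, frac_sex_also_fibre = 0.155,
                       fibre_effect_mean = 0.15,
                       fibre_beta_mean_f = 0.52, fibre_beta_mean_m = 0.42,
                       fibre_beta_precision = 30,
                       batch_sd = 0.1, subject_sd = 0.25, residual_sd = 0.5,
                       block_sd = 0.3,
                       block_size = 8L, intra_block_gap = 150L,
                       inter_block_gap = 4000L,
                       n_reps = 1L,
                       cohort_probe_frac = NULL,
                       discordant_frac_null = 0.324,
                       discordant_frac_sex = 0.387,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  n_samples <- rep_len(as.integer(n_samples), n_cohorts)
  if (is.null(cohort_probe_frac)) {
    cohort_probe_frac <- rep(1, n_cohorts)
    if (n_cohorts >= 3) cohort_probe_frac[n_cohorts] <- 0.05
  }
  cohort_probe_frac <- rep_len(cohort_probe_frac, n_cohorts)
  fr <- c(frac_sex_cpgs, frac_hypo_in_males, frac_fibre_cpgs,
          frac_sex_also_fibre, cohort_probe_frac)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0,1]")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# delta-beta -> logit2-scale effect sized at baseline 0.5
dbeta_to_dlogit <- function(d) {
  s <- sign(d); d <- pmin(abs(d), 0.98)
  s * 2 * log2((1 + d) / (1 - d))
}

inv_logit2 <- function(x) 1 / (1 + 2^(-x))

#' Simulate multi-cohort methylation studies with known ground truth
#'
#' Generates `n_cohorts` beta matrices on a shared synthetic genome, a probe
#' annotation (chromosome, position, genes, island relation, male/female
#' chromatin states) and a truth table recording which probes carry sex and
#' fibre effects and their signed target delta-beta. Identical seeds give
#' identical output.
#'
#' @param config A [sim_config()].
#' @return List with `cohorts` (list of `cohort_study`), `annotation`
#'   (data frame), `truth` (data frame: `probe_id`, `sex_effect`,
#'   `fibre_effect`, `is_sex_cpg`, `is_fibre_cpg`) and `fibre` (named list per
#'   cohort of type-I proportions by sample).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  np <- cfg$n_probes
  bs <- cfg$block_size
  n_blocks <- ceiling(np / bs)
  block_of <- rep(seq_len(n_blocks), each = bs)[seq_len(np)]

  ## genome: blocks laid round-robin across 22 autosomes
  chrom_of_block <- sprintf("chr%d", (seq_len(n_blocks) - 1L) %% 22L + 1L)
  pos <- integer(np)
  for (ch in unique(chrom_of_block)) {
    bl <- which(chrom_of_block == ch)
    p <- 1e5
    for (b in bl) {
      idx <- which(block_of == b)
      pos[idx] <- p + (seq_along(idx) - 1L) * cfg$intra_block_gap
      p <- pos[max(idx)] + round(stats::rexp(1, 1 / cfg$inter_block_gap)) +
        3L * cfg$block_size * cfg$intra_block_gap
    }
  }
  probe_id <- sprintf("cg%08d", seq_len(np))
  chrom <- chrom_of_block[block_of]

  ## baselines: bimodal across blocks, probes deviate mildly within a block
  comp <- sample(1:3, n_blocks, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  block_base_beta <- c(rbeta(n_blocks, 2, 8), rbeta(n_blocks, 8, 2),
                       rbeta(n_blocks, 5, 5))[cbind(seq_len(n_blocks)) +
                                              (comp - 1L) * n_blocks]
  block_base <- log2(pmin(pmax(block_base_beta, 0.02), 0.98) /
                     (1 - pmin(pmax(block_base_beta, 0.02), 0.98)))
  mu <- block_base[block_of] + rnorm(np, 0, 0.25)

  ## planted sex effects: whole blocks share a direction, per-probe magnitude
  n_sex <- round(cfg$frac_sex_cpgs * np)
  sex_blocks <- integer(0)
  if (n_sex > 0) {
    sex_blocks <- sample(n_blocks, ceiling(n_sex / bs))
    sex_idx <- which(block_of %in% sex_blocks)
    sex_idx <- sex_idx[seq_len(min(n_sex, length(sex_idx)))]
  } else sex_idx <- integer(0)
  is_sex <- seq_len(np) %in% sex_idx

  sex_effect <- numeric(np)
  if (n_sex > 0) {
    hypo_block <- setNames(runif(n_blocks) < cfg$frac_hypo_in_males,
                           seq_len(n_blocks))
    dir_sign <- ifelse(hypo_block[block_of[sex_idx]], -1, 1)
    mn <- ifelse(dir_sign < 0, cfg$effect_mean_hypo, cfg$effect_mean_hyper)
    mag <- if (cfg$effect_fixed) mn else
      pmin(rgamma(length(sex_idx), shape = 4, scale = mn / 4), 0.5)
    sex_effect[sex_idx] <- dir_sign * pmax(mag, 0.002)
  }

  ## fibre effects: a share of sex CpGs plus extra null-sex probes
  n_fib_from_sex <- round(cfg$frac_sex_also_fibre * n_sex)
  n_fib_total <- max(round(cfg$frac_fibre_cpgs * np), n_fib_from_sex)
  fib_idx <- integer(0)
  if (n_fib_total > 0) {
    from_sex <- if (n_fib_from_sex > 0) sample(sex_idx, n_fib_from_sex) else integer(0)
    pool <- setdiff(seq_len(np), sex_idx)
    extra <- sample(pool, min(n_fib_total - n_fib_from_sex, length(pool)))
    fib_idx <- c(from_sex, extra)
  }
  is_fib <- seq_len(np) %in% fib_idx
  fibre_effect <- numeric(np)
  if (length(fib_idx)) {
    sgn <- ifelse(runif(length(fib_idx)) < 0.7, 1, -1)
    mag <- if (cfg$effect_fixed) rep(cfg$fibre_effect_mean, length(fib_idx))
           else pmin(rgamma(length(fib_idx), shape = 4,
                            scale = cfg$fibre_effect_mean / 4), 0.45)
    fibre_effect[fib_idx] <- sgn * pmax(mag, 0.01)
  }

  ## chromatin-state annotation (15-label reference-epigenome vocabulary)
  states <- c("TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
              "ZNF/Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC",
              "ReprPCWk", "Quies")
  st_m_block <- sample(states, n_blocks, replace = TRUE,
                       prob = c(4, 4, 2, 8, 10, 4, 8, 1, 2, 1, 1, 1, 3, 5, 20))
  p_disc <- ifelse(seq_len(n_blocks) %in% sex_blocks,
                   cfg$discordant_frac_sex, cfg$discordant_frac_null)
  disc_block <- runif(n_blocks) < p_disc
  st_f_block <- st_m_block
  if (any(disc_block)) {
    st_f_block[disc_block] <- vapply(st_m_block[disc_block], function(s)
      sample(setdiff(states, s), 1), "")
  }
  island_block <- sample(c("island", "shore", "shelf", "open_sea"), n_blocks,
                         replace = TRUE, prob = c(0.30, 0.25, 0.10, 0.35))
  gene_block <- sprintf("GENE%05d", seq_len(n_blocks))
  genes <- gene_block[block_of]
  two <- runif(np) < 0.10                          # some probes map to 2 genes
  genes[two] <- paste(genes[two],
                      gene_block[pmax(block_of[two] - 1L, 1L)], sep = ";")

  annotation <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                           genes = genes,
                           island_relation = island_block[block_of],
                           state_male = st_m_block[block_of],
                           state_female = st_f_block[block_of],
                           stringsAsFactors = FALSE)
  annotation$state_discordant <- annotation$state_male != annotation$state_female
  annotation$regulatory_class <- regulatory_class(annotation$state_male)

  truth <- data.frame(probe_id = probe_id, sex_effect = sex_effect,
                      fibre_effect = fibre_effect, is_sex_cpg = is_sex,
                      is_fibre_cpg = is_fib, stringsAsFactors = FALSE)

  d_sex <- dbeta_to_dlogit(sex_effect)
  d_fib <- fibre_effect / (log(2) * 0.25)          # slope per unit proportion

  cohorts <- vector("list", cfg$n_cohorts)
  fibre_list <- vector("list", cfg$n_cohorts)
  for (c_i in seq_len(cfg$n_cohorts)) {
    frac <- cfg$cohort_probe_frac[c_i]
    keep_blocks <- if (frac < 1)
      sort(sample(n_blocks, max(2L, round(frac * n_blocks)))) else seq_len(n_blocks)
    pidx <- which(block_of %in% keep_blocks)

    n_sub <- cfg$n_samples[c_i]
    sex <- rep(c("F", "M"), length.out = n_sub)[order(runif(n_sub))]
    n_tot <- n_sub * cfg$n_reps
    subject <- rep(sprintf("%s_S%03d", paste0("C", c_i), seq_len(n_sub)),
                   each = cfg$n_reps)
    rep_lab <- rep(sprintf("t%d", seq_len(cfg$n_reps)), times = n_sub)
    sample_id <- paste(subject, rep_lab, sep = "_")
    sex_s <- rep(sex, each = cfg$n_reps)
    age <- round(rep(stats::rnorm(n_sub, 50, 10), each = cfg$n_reps))
    batch <- sample(c("b1", "b2"), n_tot, replace = TRUE)

    t1 <- ifelse(sex == "F",
                 rbeta(n_sub, cfg$fibre_beta_mean_f * cfg$fibre_beta_precision,
                       (1 - cfg$fibre_beta_mean_f) * cfg$fibre_beta_precision),
                 rbeta(n_sub, cfg$fibre_beta_mean_m * cfg$fibre_beta_precision,
                       (1 - cfg$fibre_beta_mean_m) * cfg$fibre_beta_precision))
    t1_s <- rep(t1, each = cfg$n_reps)

    npc <- length(pidx)
    sex01 <- as.numeric(sex_s == "M")
    E <- matrix(mu[pidx], npc, n_tot) +
      outer(d_sex[pidx], sex01 - 0.5) +
      outer(d_fib[pidx], t1_s)
    ## batch offsets (per probe x batch)
    for (b in unique(batch)) {
      off <- rnorm(npc, 0, cfg$batch_sd)
      E[, batch == b] <- E[, batch == b] + off
    }
    ## block-by-sample shared effect -> spatial correlation
    bl_loc <- block_of[pidx]
    ublk <- unique(bl_loc)
    Z <- matrix(rnorm(length(ublk) * n_tot, 0, cfg$block_sd),
                length(ublk), n_tot)
    E <- E + Z[match(bl_loc, ublk), , drop = FALSE]
    ## subject random intercept (repeated measures only)
    if (cfg$n_reps > 1L) {
      S <- matrix(rnorm(npc * n_sub, 0, cfg$subject_sd), npc, n_sub)
      E <- E + S[, rep(seq_len(n_sub), each = cfg$n_reps), drop = FALSE]
    }
    E <- E + matrix(rnorm(npc * n_tot, 0, cfg$residual_sd), npc, n_tot)

    beta <- inv_logit2(E)
    dimnames(beta) <- list(probe_id[pidx], sample_id)
    samples <- data.frame(sample_id = sample_id, subject_id = subject,
                          sex = sex_s, age = age, batch = batch,
                          timepoint = rep_lab, type1_ratio = t1_s,
                          stringsAsFactors = FALSE)
    design <- c("age", "batch")
    cohorts[[c_i]] <- cohort_study(sprintf("cohort%d", c_i), beta, samples,
                                   design)
    fibre_list[[c_i]] <- setNames(t1_s, sample_id)
  }
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  names(fibre_list) <- names(cohorts)
  list(cohorts = cohorts, annotation = annotation, truth = truth,
       fibre = fibre_list)
}

#' Simulate a sex-differential expression table coupled to planted methylation
#'
#' Each gene's expression effect sign is inverse to its mean planted
#' methylation effect with probability `coupling`, and random otherwise, so
#' downstream quadrant analyses have a known inverse-correlation fraction.
#'
#' @param truth Truth table from [simulate_cohorts()].
#' @param gene_map Probe-to-gene map ([probe_gene_map()] output).
#' @param coupling Probability in \[0, 1\] that a methylated gene's expression
#'   effect is inverse-signed.
#' @param seed RNG seed.
#' @return Data frame `gene`, `effect`, `p` (small for coupled genes),
#'   `meth_effect` (mean planted delta-beta of the gene's probes).
#' @export
simulate_expression <- function(truth, gene_map, coupling, seed = 1L) {
  stopifnot(coupling >= 0, coupling <= 1)
  set.seed(seed)
  m <- merge(gene_map, truth[, c("probe_id", "sex_effect")], by = "probe_id")
  gmean <- tapply(m$sex_effect, m$gene, mean)
  genes <- names(gmean)
  meth <- as.numeric(gmean)
  mag <- rlnorm(length(genes), log(0.5), 0.5)
  sgn <- numeric(length(genes))
  has_meth <- meth != 0
  inv <- runif(length(genes)) < coupling
  sgn[has_meth & inv] <- -sign(meth[has_meth & inv])
  sgn[has_meth & !inv] <- sample(c(-1, 1), sum(has_meth & !inv), replace = TRUE)
  sgn[!has_meth] <- sample(c(-1, 1), sum(!has_meth), replace = TRUE)
  data.frame(gene = genes, effect = sgn * mag,
             p = ifelse(has_meth, runif(length(genes), 0, 1e-4),
                        runif(length(genes))),
             meth_effect = meth, stringsAsFactors = FALSE)
}

#' Simulate a circulating-hormone panel (null for the methylation scan)
#'
#' Log-normal draws with sex-specific geometric means: testosterone far higher
#' in males, estradiol higher in females; SHBG overlapping; FSH/LH/progesterone
#' generated for females. Free testosterone and the free androgen index are
#' derived through the mass-action model ([derive_hormone_indices()]). By
#' construction the panel is independent of methylation.
#'
#' @param samples Sample sheet (needs `sample_id`, `sex`).
#' @param t_mean_m,t_mean_f Geometric mean testosterone (nmol/L) by sex.
#' @param e2_mean_m,e2_mean_f Geometric mean estradiol (pmol/L) by sex.
#' @param shbg_mean Geometric mean SHBG (nmol/L).
#' @param sdlog Log-scale SD of every hormone.
#' @param seed RNG seed.
#' @return Data frame, one row per sample, with `T`, `SHBG`, `E2`, `FSH`,
#'   `LH`, `progesterone`, `free_T` (pmol/L) and `FAI`.
#' @export
simulate_hormones <- function(samples, t_mean_m = 20, t_mean_f = 1.2,
                              e2_mean_m = 90, e2_mean_f = 300,
                              shbg_mean = 45, sdlog = 0.3, seed = 1L) {
  set.seed(seed)
  n <- nrow(samples)
  male <- samples$sex == "M"
  if (!any(male) || all(male)) stop("both sexes must be present")
  panel <- data.frame(
    sample_id = samples$sample_id, sex = samples$sex,
    T = rlnorm(n, log(ifelse(male, t_mean_m, t_mean_f)), sdlog),
    SHBG = rlnorm(n, log(shbg_mean), sdlog),
    E2 = rlnorm(n, log(ifelse(male, e2_mean_m, e2_mean_f)), sdlog),
    FSH = ifelse(male, NA, rlnorm(n, log(6), sdlog)),
    LH = ifelse(male, NA, rlnorm(n, log(5), sdlog)),
    progesterone = ifelse(male, NA, rlnorm(n, log(1.5), sdlog)),
    stringsAsFactors = FALSE)
  derive_hormone_indices(panel)
}

#' Write a simulated study to disk in the package's TSV formats
#'
#' One beta matrix + sample sheet per cohort, plus `annotation.tsv` and
#' `truth.tsv`.
#'
#' @param sim Output of [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in sim$cohorts)
    write_beta_matrix(st, file.path(dir, paste0(st$name, "_beta.tsv")),
                      file.path(dir, paste0(st$name, "_samples.tsv")))
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
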