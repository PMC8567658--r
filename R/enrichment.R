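#' Chi-square test of DMP status against a genomic category
#'
#' r-by-c chi-square of homogeneity (no continuity correction) of DMP status
#' (hyper / hypo / non) against a per-probe category such as chromatin state
#' or CpG-island relation, with standardized Pearson residuals
#' `(O-E)/sqrt(E(1-row)(1-col))`; cells with |standardized residual| above
#' `flag_threshold` are flagged as making a greater contribution to the
#' association. Probes with missing category are dropped (by convention,
#' probes annotated to two differing chromatin states are removed upstream).
#'
#' @param status Factor/character per probe (e.g. `"hyper"`, `"hypo"`,
#'   `"non"`).
#' @param category Factor/character per probe.
#' @param flag_threshold |standardized residual| cutoff for the
#'   greater-contribution flag (default 4).
#' @return Object of class `contingency_result`: `table`, `chi2`, `df`, `p`,
#'   `residuals` (Pearson), `std_residuals`, `flagged` (logical matrix). For
#'   2x2 tables also `odds_ratio`, `ci` (Woolf 95%) and `fisher_p`; when more
#'   than 20% of expected counts fall below 5 a warning is issued and, for
#'   2x2, `p` falls back to Fisher's exact test.
#' @export
context_chi2 <- function(status, category, flag_threshold = 4) {
  keep <- !is.na(status) & !is.na(category)
  tab <- table(status[keep], category[keep])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  res <- list(table = tab, chi2 = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              residuals = ct$residuals, std_residuals = ct$stdres,
              flagged = abs(ct$stdres) > flag_threshold)
  low <- mean(ct$expected < 5)
  if (all(dim(tab) == c(2, 2))) {
    or_ci <- woolf_or(tab)
    res$odds_ratio <- or_ci$or
    res$ci <- or_ci$ci
    res$fisher_p <- fisher.test(tab)$p.value
    if (low > 0.2) {
      warning("more than 20% of expected counts < 5; using Fisher's exact p")
      res$p <- res$fisher_p
    }
  } else if (low > 0.2) {
    warning("more than 20% of expected counts < 5; chi-square approximation doubtful")
  }
  class(res) <- "contingency_result"
  res
}

# Cross-product odds ratio with Woolf logit 95% CI
# (Haldane-Anscombe 0.5 correction applied to the CI only when a cell is 0).
woolf_or <- function(tab) {
  a <- as.numeric(tab[1, 1]); b <- as.numeric(tab[1, 2])
  c <- as.numeric(tab[2, 1]); d <- as.numeric(tab[2, 2])
  or <- (a * d) / (b * c)
  cc <- if (any(tab == 0)) 0.5 else 0
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  lo <- exp(log((a + cc) * (d + cc) / ((b + cc) * (c + cc))) - 1.96 * se)
  hi <- exp(log((a + cc) * (d + cc) / ((b + cc) * (c + cc))) + 1.96 * se)
  list(or = or, ci = c(lo, hi))
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi2 = %.4g on %d df, p = %.3g\n",
              x$chi2, x$df, x$p))
  if (!is.null(x$odds_ratio))
    cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), Fisher p = %.3g\n",
                x$odds_ratio, x$ci[1], x$ci[2], x$fisher_p))
  invisible(x)
}

#' Odds of a DMP lying in a sex-discordant chromatin state
#'
#' 2x2 table of DMP status against chromatin-state discordance (male vs
#' female reference annotation disagreeing). Oriented as
#' (non-DMP odds of discordant state) / (DMP odds of discordant state), so an
#' odds ratio below 1 means DMPs are overrepresented in sex-discordant states
#' (OR 0.76 corresponds to a factor 1/0.76 = 1.3 increase in DMP odds).
#'
#' @param is_dmp Logical per probe.
#' @param discordant Logical per probe.
#' @return A `contingency_result` (2x2, with OR, Woolf CI, Fisher p).
#' @export
sex_state_or <- function(is_dmp, discordant) {
  keep <- !is.na(is_dmp) & !is.na(discordant)
  tab <- table(factor(ifelse(is_dmp[keep], "dmp", "non_dmp"),
                      levels = c("non_dmp", "dmp")),
               factor(ifelse(discordant[keep], "discordant", "concordant"),
                      levels = c("discordant", "concordant")))
  context_chi2_from_table(tab)
}

# shared 2x2 wrapper used by sex_state_or
context_chi2_from_table <- function(tab) {
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  or_ci <- woolf_or(tab)
  res <- list(table = tab, chi2 = unname(ct$statistic),
              df = unname(ct$parameter), p = ct$p.value,
              residuals = ct$residuals, std_residuals = ct$stdres,
              flagged = abs(ct$stdres) > 4,
              odds_ratio = or_ci$or, ci = or_ci$ci,
              fisher_p = fisher.test(tab)$p.value)
  class(res) <- "contingency_result"
  res
}

#' Gene-set test corrected for per-gene probe-count bias
#'
#' Genes covered by many probes are more likely to contain a significant probe
#' by chance; a plain hypergeometric test over genes is therefore biased. A
#' gene is significant when at least one of its probes is significant; each
#' gene's bias weight is its probe count in the background. Two corrections:
#' `montecarlo` (default) draws `n_iter` gene sets of the observed number of
#' significant genes with probability proportional to probe count (sequential
#' weighted sampling without replacement) and reports
#' `p = (1 + #draws with overlap >= observed) / (n_iter + 1)`; `wallenius`
#' evaluates the noncentral hypergeometric tail with odds equal to the ratio
#' of mean probe counts inside vs outside the set.
#'
#' @param sig_probes Character vector of significant probe ids.
#' @param background_probes All tested probe ids.
#' @param gene_map Probe-to-gene map ([probe_gene_map()]); probes mapping to
#'   several genes contribute to each.
#' @param gene_sets Named list of character vectors of gene symbols.
#' @param method `"montecarlo"` or `"wallenius"`.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed RNG seed for the Monte-Carlo null.
#' @return Data frame of class `gene_set_result`: `set`, `N` (set genes on
#'   the array), `DE` (significant genes in set), `p`, `sig_genes`
#'   (";"-separated).
#' @export
gene_set_test <- function(sig_probes, background_probes, gene_map, gene_sets,
                          method = c("montecarlo", "wallenius"),
                          n_iter = 10000L, seed = 1L) {
  method <- match.arg(method)
  map <- gene_map[gene_map$probe_id %in% background_probes, , drop = FALSE]
  if (!nrow(map)) stop("empty background after mapping probes to genes")
  w <- table(map$gene)                         # probes per gene = bias weight
  universe <- names(w)
  sig_genes <- unique(map$gene[map$probe_id %in% sig_probes])
  k <- length(sig_genes)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  obs <- vapply(sets, function(s) length(intersect(s, sig_genes)), integer(1))
  Ns <- lengths(sets)
  p <- numeric(length(sets))
  if (method == "montecarlo") {
    set.seed(seed)
    wt <- as.numeric(w)
    ge <- integer(length(sets))
    in_set <- lapply(sets, function(s) universe %in% s)
    for (b in seq_len(n_iter)) {
      draw <- sample.int(length(universe), k, prob = wt)
      for (si in seq_along(sets))
        if (sum(in_set[[si]][draw]) >= obs[si]) ge[si] <- ge[si] + 1L
    }
    p <- (1 + ge) / (n_iter + 1)
  } else {
    for (si in seq_along(sets)) {
      s <- sets[[si]]
      m1 <- length(s); m2 <- length(universe) - m1
      if (m1 == 0 || k == 0) { p[si] <- 1; next }
      odds <- mean(w[s]) / mean(w[setdiff(universe, s)])
      p[si] <- wallenius_tail(obs[si], m1, m2, k, odds)
    }
  }
  out <- data.frame(set = names(gene_sets), N = Ns, DE = obs, p = p,
                    sig_genes = vapply(sets, function(s)
                      paste(intersect(s, sig_genes), collapse = ";"), ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_set_result", "data.frame")
  attr(out, "n_sig_genes") <- k
  out
}

# Upper tail P(X >= x) of the Wallenius noncentral hypergeometric
# distribution (m1 set genes, m2 others, n draws, odds w) by the standard
# mean/variance normal approximation: the mean solves the implicit equation
# mu/m1 = 1 - (1 - (n - mu)/m2)^w, the variance is the conditional-information
# form evaluated at the mean, and the tail uses a continuity correction.
wallenius_tail <- function(x, m1, m2, n, w) {
  lo <- max(0, n - m2); hi <- min(n, m1)
  if (x <= lo) return(1)
  f <- function(mu) mu / m1 - (1 - (1 - (n - mu) / m2)^w)
  mu <- uniroot(f, c(lo + 1e-9, hi - 1e-9), tol = 1e-12)$root
  s2 <- 1 / (1 / mu + 1 / max(m1 - mu, 1e-9) + 1 / max(n - mu, 1e-9) +
               1 / max(m2 - n + mu, 1e-9))
  pnorm((x - 0.5 - mu) / sqrt(s2), lower.tail = FALSE)
}

#' Transcription-factor binding-site enrichment with background
#'
#' For each TFBS dataset, probes are intersected with its intervals (BED
#' dialect, 0-based half-open: a CpG at 1-based position p overlaps \[s, e)
#' iff s <= p-1 < e), a 2x2 table of (DMP vs non-DMP background) by (in TFBS
#' vs not) is built, and a one-sided Fisher enrichment p-value is reported
#' unadjusted (TFBS datasets are not independent, so FDR assumptions fail),
#' ranked by -log10 p.
#'
#' @param dmp_probes Character vector of DMP probe ids.
#' @param tfbs Named list of BED paths, BED-like data frames
#'   (`chrom`,`start`,`end`) or `GRanges`, one per TF dataset.
#' @param annotation Annotation with `probe_id`, `chrom`, `pos`.
#' @param background_probes All tested probe ids (defaults to the whole
#'   annotation).
#' @return Data frame `dataset`, `n_dmp_in`, `n_bg_in`, `odds_ratio`, `p`,
#'   `neg_log10_p`, `no_overlap` flag, sorted by decreasing `neg_log10_p`.
#' @export
tfbs_enrichment <- function(dmp_probes, tfbs, annotation,
                            background_probes = annotation$probe_id) {
  anno <- annotation[annotation$probe_id %in% background_probes, , drop = FALSE]
  cpg <- GenomicRanges::GRanges(anno$chrom,
                                IRanges::IRanges(anno$pos, width = 1L))
  is_dmp <- anno$probe_id %in% dmp_probes
  rows <- lapply(names(tfbs), function(nm) {
    gr <- bed_to_granges(tfbs[[nm]])
    inb <- suppressWarnings(GenomicRanges::countOverlaps(cpg, gr) > 0)
    a <- sum(is_dmp & inb); b <- sum(is_dmp & !inb)
    c2 <- sum(!is_dmp & inb); d <- sum(!is_dmp & !inb)
    if (a + c2 == 0 || b + d == 0) {
      return(data.frame(dataset = nm, n_dmp_in = a, n_bg_in = c2,
                        odds_ratio = NA_real_, p = 1, no_overlap = TRUE,
                        stringsAsFactors = FALSE))
    }
    ft <- fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(dataset = nm, n_dmp_in = a, n_bg_in = c2,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               no_overlap = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(pmax(out$p, 1e-300))
  out <- out[order(-out$neg_log10_p, out$dataset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resampling test for overlap with a reference CpG set
#'
#' Observed statistic: |dmps intersect reference|. Null: draw |reference|
#' probes uniformly from the array universe `n_iter` times and record the
#' overlap with the DMP set; `p = (1 + #null >= observed) / (n_iter + 1)`.
#'
#' @param dmps Character vector of DMP probe ids.
#' @param reference Reference CpG set (must be a subset of `universe`).
#' @param universe All probes of the reference array.
#' @param n_iter Resampling iterations (default 10000).
#' @param seed RNG seed.
#' @return List `observed`, `p`, `null_mean`.
#' @export
overlap_resampling <- function(dmps, reference, universe, n_iter = 10000L,
                               seed = 1L) {
  if (!all(reference %in% universe))
    stop("reference must be a subset of the universe")
  set.seed(seed)
  in_dmp <- universe %in% dmps
  obs <- sum(reference %in% dmps)
  m <- length(reference)
  null <- vapply(seq_len(n_iter),
                 function(i) sum(in_dmp[sample.int(length(universe), m)]),
                 integer(1))
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_iter + 1),
       null_mean = mean(null))
}
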