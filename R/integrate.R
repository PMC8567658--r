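#' Overlap of differentially methylated and differentially expressed genes
#'
#' Harmonizes gene symbols (uppercased; unmapped entries dropped with a
#' message), computes all Venn intersection counts between the DMG list and
#' one or two DEG lists, and tests enrichment of the DEG list among DMGs with
#' the probe-bias-corrected [gene_set_test()] (the DEG list acting as the
#' gene set).
#'
#' @param dmgs Character vector of differentially methylated genes.
#' @param degs Named list of one or more character vectors of differentially
#'   expressed genes.
#' @param sig_probes,background_probes,gene_map Passed to [gene_set_test()]
#'   for the enrichment p-value; if `NULL` the enrichment is skipped.
#' @param method,n_iter,seed Passed to [gene_set_test()].
#' @return List with `venn` (named intersection counts, names like
#'   `"dmg"`, `"dmg&deg1"`, ...), `sizes`, and `enrichment` (a
#'   `gene_set_result` or `NULL`).
#' @export
dmg_deg_overlap <- function(dmgs, degs, sig_probes = NULL,
                            background_probes = NULL, gene_map = NULL,
                            method = "montecarlo", n_iter = 10000L,
                            seed = 1L) {
  clean <- function(x) unique(toupper(x[!is.na(x) & nzchar(x)]))
  lists <- c(list(dmg = clean(dmgs)), lapply(degs, clean))
  nm <- names(lists)
  n <- length(lists)
  venn <- list()
  for (mask in seq_len(2^n - 1)) {
    inn <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    cell <- Reduce(intersect, lists[inn])
    if (any(!inn) && length(cell))
      cell <- setdiff(cell, unique(unlist(lists[!inn])))
    venn[[paste(nm[inn], collapse = "&")]] <- length(cell)
  }
  enr <- NULL
  if (!is.null(sig_probes) && !is.null(gene_map) &&
      !is.null(background_probes)) {
    sets <- lapply(degs, clean)
    gm <- gene_map
    gm$gene <- toupper(gm$gene)
    enr <- gene_set_test(sig_probes, background_probes, gm, sets,
                         method = method, n_iter = n_iter, seed = seed)
  }
  list(venn = unlist(venn), sizes = lengths(lists), enrichment = enr)
}

#' Quadrant concordance of methylation and expression effects
#'
#' For DMR-gene pairs in promoter and enhancer regions, the fraction of pairs
#' whose methylation and expression effects have opposite signs
#' (inverse correlation), with a permutation null obtained by shuffling the
#' methylation effect vector across pairs within each region class:
#' `p = (1 + #permuted fraction >= observed) / (n_iter + 1)`. Pairs with a
#' zero effect sign are dropped (count reported).
#'
#' @param pairs Data frame with columns `class` (`"promoter"` /
#'   `"enhancer"`), `meth_effect`, `expr_effect`; one row per DMR-gene pair
#'   (a gene with several DMRs contributes one row per DMR).
#' @param n_iter Permutations (default 10000).
#' @param seed RNG seed.
#' @return Object of class `quadrant_result`: data frame with one row per
#'   class (`class`, `n_pairs`, `inverse_fraction`, `p`), plus attributes
#'   `n_iter`, `seed`, `n_dropped`.
#' @export
quadrant_concordance <- function(pairs, n_iter = 10000L, seed = 1L) {
  set.seed(seed)
  sm <- sign(pairs$meth_effect)
  se <- sign(pairs$expr_effect)
  keep <- sm != 0 & se != 0 & !is.na(sm) & !is.na(se)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " pair(s) with zero effect sign dropped")
  pairs <- pairs[keep, , drop = FALSE]
  sm <- sm[keep]; se <- se[keep]
  rows <- lapply(unique(pairs$class), function(cl) {
    i <- which(pairs$class == cl)
    obs <- mean(sm[i] != se[i])
    ge <- 0L
    for (b in seq_len(n_iter)) {
      perm <- sample(sm[i])
      if (mean(perm != se[i]) >= obs) ge <- ge + 1L
    }
    data.frame(class = cl, n_pairs = length(i), inverse_fraction = obs,
               p = (1 + ge) / (n_iter + 1), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quadrant_result", "data.frame")
  attr(out, "n_iter") <- n_iter
  attr(out, "seed") <- seed
  attr(out, "n_dropped") <- dropped
  out
}

#' Rank candidate housekeeping genes by stability
#'
#' Stability is the variance of the (triplicate-averaged) Ct values across
#' samples; the lowest-variance candidates rank first.
#'
#' @param ct Long-format qPCR table: `sample`, `gene`, `replicate`, `ct`.
#' @param candidates Candidate housekeeper gene names.
#' @return Character vector of candidates ordered by increasing Ct variance.
#' @export
rank_housekeepers <- function(ct, candidates) {
  m <- qpcr_triplicate_means(ct[ct$gene %in% candidates, , drop = FALSE])
  v <- tapply(m$ct, m$gene, var, na.rm = TRUE)
  names(sort(v))
}

# average triplicates; sets cells with replicate SD > 1 Ct to NA (stated
# technical-quality filter)
qpcr_triplicate_means <- function(ct) {
  agg <- aggregate(ct ~ sample + gene, data = ct,
                   FUN = function(v) c(m = mean(v), s = sd(v)))
  out <- data.frame(sample = agg$sample, gene = agg$gene,
                    ct = agg$ct[, "m"], sd = agg$ct[, "s"],
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$sd) & out$sd > 1
  out$ct[bad] <- NA_real_
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' qPCR relative expression and male/female fold change (2^-ddCt)
#'
#' Triplicate Cts are averaged per sample and gene (triplicates with SD > 1 Ct
#' are excluded); each target's delta-Ct is its Ct minus the mean Ct of the
#' two housekeepers (equivalent to normalizing expression to the geometric
#' mean of the housekeepers); per-sample relative expression is `2^-dCt`; the
#' fold change in males versus females is `2^-(mean dCt_M - mean dCt_F)`,
#' with a two-sided Welch t-test on the delta-Ct values.
#'
#' @param ct Long-format table: `sample`, `gene`, `replicate`, `ct`.
#' @param housekeepers Exactly two housekeeper gene names (use
#'   [rank_housekeepers()] to choose the two most stable candidates).
#' @param groups Named character vector or data frame mapping `sample` to
#'   sex (`"M"`/`"F"`).
#' @return Data frame per target gene: `gene`, `n_m`, `n_f`, `fold_change`,
#'   `p`; attribute `n_excluded` counts discarded triplicates.
#' @export
qpcr_fold_change <- function(ct, housekeepers, groups) {
  if (length(housekeepers) != 2)
    stop("exactly two housekeeper genes are required")
  if (!all(housekeepers %in% ct$gene))
    stop("missing housekeeper: ",
         paste(setdiff(housekeepers, ct$gene), collapse = ", "))
  if (is.data.frame(groups))
    groups <- setNames(groups$sex, groups$sample)
  m <- qpcr_triplicate_means(ct)
  hk <- m[m$gene %in% housekeepers, , drop = FALSE]
  hk_mean <- tapply(hk$ct, hk$sample, mean)      # mean Ct == geometric-mean norm
  targets <- setdiff(unique(m$gene), housekeepers)
  rows <- lapply(targets, function(g) {
    t_g <- m[m$gene == g, , drop = FALSE]
    dct <- t_g$ct - hk_mean[as.character(t_g$sample)]
    sex <- groups[as.character(t_g$sample)]
    ok <- !is.na(dct) & sex %in% c("M", "F")
    dm <- dct[ok & sex == "M"]; df_ <- dct[ok & sex == "F"]
    fc <- 2^-(mean(dm) - mean(df_))
    p <- if (length(dm) >= 2 && length(df_) >= 2)
      tryCatch(t.test(dm, df_)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(gene = g, n_m = length(dm), n_f = length(df_),
               fold_change = fc, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- attr(m, "n_excluded")
  out
}
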