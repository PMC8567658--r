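#' Kernel-smoothed per-CpG region statistics
#'
#' Squared calibrated meta z-scores are treated as chi-square(1) variables and
#' smoothed along each chromosome with a Gaussian kernel of bandwidth
#' `sigma = lambda / C` (defaults 1000 bp / 2), truncated at 3 sigma for
#' linear-time scanning. With normalized weights `w~`, the smoothed statistic
#' `Y_i = sum_j w~_ij z_j^2` is referred to its Satterthwaite
#' moment-matched null: `Y ~ c chi-square(nu)` with scale
#' `c_i = sum_j w~_ij^2` and `nu_i = 1 / c_i`. An isolated CpG (no
#' neighbour within 3 sigma) keeps its own chi-square(1) tail.
#'
#' @param meta A `meta_result` (needs `z`).
#' @param annotation Annotation with `probe_id`, `chrom`, `pos`.
#' @param lambda Kernel scale in bp (default 1000).
#' @param C Bandwidth divisor (default 2).
#' @return Data frame `probe_id`, `chrom`, `pos`, `z`, `y_smooth`, `scale`,
#'   `df`, `p_smooth`, sorted by chromosome and position.
#' @export
smooth_statistics <- function(meta, annotation, lambda = 1000, C = 2) {
  a <- annotation[match(meta$probe_id, annotation$probe_id),
                  c("chrom", "pos")]
  if (anyNA(a$pos)) stop("meta probes missing from annotation")
  d <- data.frame(probe_id = meta$probe_id, chrom = a$chrom, pos = a$pos,
                  z = meta$z, stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  sigma <- lambda / C
  cutoff <- 3 * sigma
  y <- scl <- nu <- numeric(nrow(d))
  for (ch in unique(d$chrom)) {
    i <- which(d$chrom == ch)
    pos <- d$pos[i]
    z2 <- d$z[i]^2
    lo <- findInterval(pos - cutoff, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + cutoff, pos)
    for (t in seq_along(i)) {
      j <- lo[t]:hi[t]
      w <- exp(-((pos[j] - pos[t])^2) / (2 * sigma^2))
      w <- w / sum(w)
      y[i[t]] <- sum(w * z2[j])
      scl[i[t]] <- sum(w^2)
      nu[i[t]] <- 1 / scl[i[t]]
    }
  }
  d$y_smooth <- y
  d$scale <- scl
  d$df <- nu
  d$p_smooth <- pchisq(y / scl, df = nu, lower.tail = FALSE)
  rownames(d) <- NULL
  d
}

#' Call differentially methylated regions
#'
#' Smoothed p-values are BH-adjusted genome-wide; significant CpGs
#' (`fdr < alpha`) are grouped into maximal runs in which consecutive members
#' are at most `lambda` bp apart, and runs with at least `min_cpgs` members
#' become regions. Each region carries three combination statistics over its
#' member CpGs' meta-analysis results: `stouffer` (two-sided normal p of
#' `sum(z_i)/sqrt(k)`, z signed by the meta effect), `fisher_p`
#' (`-2 sum log p_i` on chi-square(2k)), and `hmfdr` (harmonic mean
#' `k / sum(1/fdr_i)` of member FDR values). A region is significant when all
#' three are below `alpha`. `maxdiff` is the member effect of largest
#' magnitude, `meandiff` the mean member effect.
#'
#' @param smoothed Output of [smooth_statistics()].
#' @param meta A `meta_result` processed by [call_dmps()] (needs `z`, `p`,
#'   `fdr`, `effect`).
#' @param lambda Maximum gap between consecutive member CpGs (bp).
#' @param alpha Significance threshold (default 0.005).
#' @param min_cpgs Minimum CpGs per region (default 2).
#' @return Data frame of class `dmr_result`: `chrom`, `start`, `end`
#'   (1-based inclusive member CpG positions), `n_cpgs`, `stouffer`,
#'   `fisher_p`, `hmfdr`, `maxdiff`, `meandiff`, `significant`, `probe_ids`
#'   (";"-separated).
#' @export
call_regions <- function(smoothed, meta, lambda = 1000, alpha = 0.005,
                         min_cpgs = 2L) {
  sm <- smoothed
  sm$fdr_smooth <- p.adjust(sm$p_smooth, method = "BH")
  sig <- sm[sm$fdr_smooth < alpha, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), stouffer = numeric(),
                      fisher_p = numeric(), hmfdr = numeric(),
                      maxdiff = numeric(), meandiff = numeric(),
                      significant = logical(), probe_ids = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("dmr_result", "data.frame")
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  new_run <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                     diff(sig$pos) > lambda)
  run <- cumsum(new_run)
  mi <- match(sig$probe_id, meta$probe_id)
  rows <- lapply(split(seq_len(nrow(sig)), run), function(ii) {
    if (length(ii) < min_cpgs) return(NULL)
    m <- meta[mi[ii], , drop = FALSE]
    kk <- nrow(m)
    zbar <- sum(m$z) / sqrt(kk)
    stouffer <- 2 * pnorm(-abs(zbar))
    fisher_p <- pchisq(-2 * sum(log(pmax(m$p, 1e-300))), df = 2 * kk,
                       lower.tail = FALSE)
    hmfdr <- kk / sum(1 / pmax(m$fdr, 1e-300))
    data.frame(chrom = sig$chrom[ii[1]], start = min(sig$pos[ii]),
               end = max(sig$pos[ii]), n_cpgs = kk, stouffer = stouffer,
               fisher_p = fisher_p, hmfdr = hmfdr,
               maxdiff = m$effect[which.max(abs(m$effect))],
               meandiff = mean(m$effect),
               significant = stouffer < alpha && fisher_p < alpha &&
                 hmfdr < alpha,
               probe_ids = paste(sig$probe_id[ii], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("dmr_result", "data.frame")
  out
}

#' Map DMRs to genes
#'
#' A region's genes are the union of the gene annotations of its member CpGs.
#'
#' @param dmrs A `dmr_result`.
#' @param annotation Annotation with `probe_id` and `genes`.
#' @return List with `dmrs` (input plus a `genes` column), `genes` (data
#'   frame `gene`, `n_dmrs` over unique genes).
#' @export
map_dmrs_to_genes <- function(dmrs, annotation) {
  map <- probe_gene_map(annotation)
  per_region <- lapply(strsplit(dmrs$probe_ids, ";", fixed = TRUE),
                       function(p) sort(unique(map$gene[map$probe_id %in% p])))
  dmrs$genes <- vapply(per_region, paste, "", collapse = ";")
  tab <- table(unlist(per_region))
  genes <- data.frame(gene = as.character(names(tab)),
                      n_dmrs = as.integer(tab), stringsAsFactors = FALSE)
  if (nrow(genes))
    genes <- genes[order(-genes$n_dmrs, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  list(dmrs = dmrs, genes = genes)
}

#' Write DMRs as a BED-like TSV
#'
#' Columns: chrom, start-1 (0-based), end, name, n_cpgs, stouffer, fisher_p,
#' hmfdr, maxdiff, meandiff, genes.
#'
#' @param dmrs A `dmr_result` (after [map_dmrs_to_genes()] if gene annotation
#'   is wanted).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  out <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1L,
                    end = dmrs$end,
                    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
                    n_cpgs = dmrs$n_cpgs, stouffer = dmrs$stouffer,
                    fisher_p = dmrs$fisher_p, hmfdr = dmrs$hmfdr,
                    maxdiff = dmrs$maxdiff, meandiff = dmrs$meandiff,
                    genes = if ("genes" %in% names(dmrs)) dmrs$genes else "",
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
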