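# Small in-code fixtures shared across test files.

# a tiny deterministic cohort: n_probes x n_samples, balanced sexes
make_tiny_study <- function(n_probes = 10, n_per_sex = 4, seed = 1,
                            name = "tiny") {
  set.seed(seed)
  n <- 2 * n_per_sex
  beta <- matrix(runif(n_probes * n, 0.2, 0.8), n_probes, n,
                 dimnames = list(sprintf("cg%03d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n))))
  samples <- data.frame(
    sample_id = colnames(beta),
    subject_id = sprintf("sub%02d", seq_len(n)),
    sex = rep(c("F", "M"), each = n_per_sex),
    age = round(runif(n, 25, 60)),
    stringsAsFactors = FALSE)
  cohort_study(name, beta, samples)
}

# a linear annotation: probes every `gap` bp on one chromosome
make_linear_annotation <- function(probe_ids, gap = 150, chrom = "chr1",
                                   start = 1000) {
  data.frame(probe_id = probe_ids, chrom = chrom,
             pos = start + (seq_along(probe_ids) - 1L) * gap,
             genes = "", stringsAsFactors = FALSE)
}

# brute-force BH step-up: adj_(i) = min_{j >= i} min(1, m p_(j) / j)
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}
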