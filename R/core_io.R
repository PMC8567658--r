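#' Construct a cohort study object
#'
#' Bundles a probes-by-samples beta-value matrix with its sample sheet and the
#' covariate terms of the cohort's design. Beta values are methylated-signal
#' fractions and must lie in \[0, 1\].
#'
#' @param name Cohort label.
#' @param beta Numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns (colnames = sample ids).
#' @param samples Data frame with at least `sample_id`, `subject_id`,
#'   `sex` (`"M"`/`"F"`) and `age`; extra covariate columns are free.
#' @param design Character vector of covariate terms entering the linear model
#'   in addition to `sex` (e.g. `c("sex:timepoint", "age", "set")`). May be
#'   empty.
#' @return An object of class `cohort_study`: a list with elements `name`,
#'   `beta`, `samples`, `design`.
#' @export
cohort_study <- function(name, beta, samples, design = character()) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) stop("beta matrix must have probe ids as rownames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe id in beta matrix: ",
         rownames(beta)[duplicated(rownames(beta))][1])
  if (anyNA(beta) || any(beta < 0 | beta > 1)) {
    bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("beta value outside [0,1] at probe '%s', sample '%s'",
                 rownames(beta)[bad[1]], colnames(beta)[bad[2]]))
  }
  samples <- as.data.frame(samples)
  req <- c("sample_id", "subject_id", "sex")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("sample_id values must be unique")
  if (!all(samples$sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'")
  if (!setequal(colnames(beta), samples$sample_id))
    stop("beta matrix columns and sample sheet sample_id disagree")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(name = name, beta = beta, samples = samples,
                 design = as.character(design)),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study '%s'>: %d probes x %d samples (%d M / %d F)\n",
              x$name, nrow(x$beta), ncol(x$beta),
              sum(x$samples$sex == "M"), sum(x$samples$sex == "F")))
  if (length(x$design))
    cat("  design terms: sex +", paste(x$design, collapse = " + "), "\n")
  invisible(x)
}

#' Read a beta-value matrix and sample sheet into a cohort study
#'
#' The beta matrix is a TSV whose first column (`probe_id`) holds probe ids and
#' whose remaining columns are samples. The sample sheet is a TSV with the
#' columns documented in [cohort_study()]. Probes absent from `annotation`
#' are retained but flagged in the `unannotated` attribute.
#'
#' @param path Path to the beta-value TSV.
#' @param sample_sheet Path to the sample-sheet TSV, or a data frame.
#' @param annotation Optional probe annotation (see [read_annotation()]).
#' @param name Cohort label; defaults to the file name.
#' @param design Covariate terms, passed to [cohort_study()].
#' @return A `cohort_study`; attribute `unannotated` lists probe ids missing
#'   from the annotation (empty when no annotation given).
#' @export
read_beta_matrix <- function(path, sample_sheet, annotation = NULL,
                             name = sub("\\.[^.]*$", "", basename(path)),
                             design = character()) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "probe_id")
    stop("first column of a beta matrix must be 'probe_id'")
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe id in ", path, ": ",
         tab$probe_id[duplicated(tab$probe_id)][1])
  beta <- as.matrix(tab[, -1, drop = FALSE])
  rownames(beta) <- tab$probe_id
  if (is.character(sample_sheet))
    sample_sheet <- read_sample_sheet(sample_sheet)
  study <- cohort_study(name, beta, sample_sheet, design)
  unann <- character()
  if (!is.null(annotation)) {
    unann <- setdiff(rownames(beta), annotation$probe_id)
    if (length(unann))
      message(length(unann), " probe(s) not present in annotation (retained, flagged)")
  }
  attr(study, "unannotated") <- unann
  study
}

#' Write a cohort study's beta matrix (and sample sheet) as TSV
#'
#' Values are written in full precision (`%.17g`) so a write/read round trip
#' is bitwise exact.
#'
#' @param study A `cohort_study`.
#' @param path Output path for the beta TSV.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(study, path, sample_sheet_path = NULL) {
  df <- data.frame(probe_id = rownames(study$beta),
                   apply(study$beta, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(study$beta))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    write.table(study$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `sex`, `age`, plus
#'   free covariate columns.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a probe annotation manifest (with optional chromatin-state BEDs)
#'
#' The manifest is a TSV with columns `probe_id`, `chrom`, `pos` (1-based),
#' `genes` (";"-separated symbols, possibly empty) and `island_relation`
#' (island/shore/shelf/open_sea). Chromatin states may be given either as
#' manifest columns `state_male` / `state_female` or as two BED files whose
#' name field carries the state label; a CpG at 1-based position p overlaps a
#' BED interval \[s, e) iff s <= p-1 < e.
#'
#' Derived columns: `state_discordant` (male and female state differ) and
#' `regulatory_class` (TssA/TssAFlnk -> promoter, Enh/EnhG -> enhancer,
#' otherwise other, from the male-state annotation).
#'
#' @param manifest Path to the manifest TSV, or a data frame.
#' @param state_male_bed,state_female_bed Optional BED file paths.
#' @return Annotation data frame.
#' @export
read_annotation <- function(manifest, state_male_bed = NULL,
                            state_female_bed = NULL) {
  anno <- if (is.character(manifest)) read.delim(manifest, stringsAsFactors = FALSE)
          else as.data.frame(manifest)
  req <- c("probe_id", "chrom", "pos")
  miss <- setdiff(req, names(anno))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(anno$pos < 1)) stop("annotation positions must be 1-based (>= 1)")
  if (!is.null(state_male_bed))
    anno$state_male <- state_at_positions(state_male_bed, anno$chrom, anno$pos)
  if (!is.null(state_female_bed))
    anno$state_female <- state_at_positions(state_female_bed, anno$chrom, anno$pos)
  if (all(c("state_male", "state_female") %in% names(anno))) {
    anno$state_discordant <- !is.na(anno$state_male) & !is.na(anno$state_female) &
      anno$state_male != anno$state_female
    anno$regulatory_class <- regulatory_class(anno$state_male)
  }
  anno
}

#' @rdname read_annotation
#' @param states Character vector of chromatin-state labels.
#' @export
regulatory_class <- function(states) {
  out <- rep("other", length(states))
  out[states %in% c("TssA", "TssAFlnk")] <- "promoter"
  out[states %in% c("Enh", "EnhG")] <- "enhancer"
  out[is.na(states)] <- NA_character_
  out
}

# Label CpG point positions with the name field of BED intervals
# (BED is 0-based half-open: 1-based pos p hits [s,e) iff s <= p-1 < e).
state_at_positions <- function(bed, chrom, pos) {
  gr <- bed_to_granges(bed)
  cpg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(cpg, gr, select = "first")
  labs <- rep(NA_character_, length(cpg))
  labs[!is.na(hits)] <- as.character(gr$name[hits[!is.na(hits)]])
  labs
}

# Accept a BED path (via rtracklayer), a data.frame(chrom,start,end[,name])
# in BED dialect, or a ready GRanges.
bed_to_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.character(x)) return(rtracklayer::import(x, format = "BED"))
  x <- as.data.frame(x)
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  gr$name <- if ("name" %in% names(x)) x$name else seq_len(nrow(x))
  gr
}

#' Probe mask set for filtering
#'
#' Four (possibly overlapping) sets of probe ids scheduled for removal:
#' detection failures, sex-chromosome probes, cross-hybridizing probes and
#' SNP-associated probes. Filtering removes their union.
#'
#' @param detection_fail,sex_chrom,cross_hybridizing,snp_associated Character
#'   vectors of probe ids (any may be empty).
#' @return A `probe_mask_set` (named list of character vectors).
#' @export
probe_mask_set <- function(detection_fail = character(),
                           sex_chrom = character(),
                           cross_hybridizing = character(),
                           snp_associated = character()) {
  structure(list(detection_fail = unique(as.character(detection_fail)),
                 sex_chrom = unique(as.character(sex_chrom)),
                 cross_hybridizing = unique(as.character(cross_hybridizing)),
                 snp_associated = unique(as.character(snp_associated))),
            class = "probe_mask_set")
}

#' Remove masked probes from a cohort study
#'
#' Drops the union of the four mask categories. Mask ids not present in the
#' study are ignored (their count is reported in the `ignored` attribute).
#' Removal counts per category are in the `removed` attribute.
#'
#' @param study A `cohort_study`.
#' @param masks A [probe_mask_set()].
#' @return The filtered `cohort_study`.
#' @export
filter_probes <- function(study, masks) {
  stopifnot(inherits(study, "cohort_study"), inherits(masks, "probe_mask_set"))
  present <- rownames(study$beta)
  union_ids <- unique(unlist(masks, use.names = FALSE))
  removed <- vapply(masks, function(s) sum(s %in% present), integer(1))
  ignored <- sum(!union_ids %in% present)
  keep <- setdiff(present, union_ids)
  if (!length(keep)) stop("all probes filtered")
  out <- study
  out$beta <- study$beta[keep, , drop = FALSE]
  attr(out, "removed") <- removed
  attr(out, "ignored") <- ignored
  out
}

#' Beta-value / M-value conversion
#'
#' `beta_to_m()` is the logit2 transform `m = log2(beta / (1 - beta))`, with
#' beta clipped to \[eps, 1 - eps\] first; `m_to_beta()` is its inverse. The
#' pair is a strictly increasing bijection on (0, 1).
#'
#' @param beta Proportions in \[0, 1\].
#' @param eps Clipping bound (default 1e-6).
#' @return Numeric vector of M-values (resp. beta values).
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  n_clip <- sum(beta < eps | beta > 1 - eps, na.rm = TRUE)
  if (n_clip > 0)
    message(n_clip, " beta value(s) clipped to [", eps, ", ", 1 - eps, "]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Partition probes by cohort membership
#'
#' Returns, for every probe observed in any study, the cohorts that carry it,
#' and the subset present in at least `min_cohorts` cohorts (the probes that
#' enter the meta-analysis).
#'
#' @param studies List of `cohort_study` objects.
#' @param min_cohorts Minimum number of cohorts a probe must appear in
#'   (default 2).
#' @return List with `membership` (logical matrix, probes x cohorts),
#'   `n_cohorts` (integer per probe) and `meta_probes` (character vector).
#' @export
intersect_probes <- function(studies, min_cohorts = 2L) {
  if (min_cohorts < 2L) stop("min_cohorts must be >= 2")
  if (min_cohorts > length(studies))
    stop("min_cohorts exceeds the number of studies")
  all_ids <- unique(unlist(lapply(studies, function(s) rownames(s$beta))))
  membership <- vapply(studies, function(s) all_ids %in% rownames(s$beta),
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids,
                                       vapply(studies, `[[`, "", "name")))
  n <- rowSums(membership)
  list(membership = membership, n_cohorts = n,
       meta_probes = all_ids[n >= min_cohorts])
}

# Expand a ";"-separated genes column into a long probe->gene map.
#' Probe-to-gene long map from an annotation table
#'
#' @param annotation Annotation data frame with `probe_id` and `genes`
#'   (";"-separated symbols; empty string = intergenic).
#' @return Data frame with columns `probe_id`, `gene` (one row per pair;
#'   probes annotated to several genes contribute one row per gene).
#' @export
probe_gene_map <- function(annotation) {
  genes <- strsplit(ifelse(is.na(annotation$genes), "", annotation$genes), ";",
                    fixed = TRUE)
  n <- lengths(genes)
  out <- data.frame(probe_id = rep(annotation$probe_id, n),
                    gene = unlist(genes), stringsAsFactors = FALSE)
  out[nzchar(out$gene), , drop = FALSE]
}
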