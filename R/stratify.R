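#' @title Gene-length and exon-count stratification
#' @description Trichotomizes the transcriptome by genomic span (exons plus
#'   introns), runs per-stratum shift tests on log2 fold changes, compares a
#'   target gene set against the background, and checks labeling-time
#'   linearity of the total label intensity.
#' @name stratify
NULL

#' Assign genes to short / medium / long length classes
#'
#' Default boundaries follow the executed analysis: short = \[0, 250),
#' medium = \[250, 10001) (i.e. 250-10,000 nt inclusive), long = 10,001 nt
#' and above. Cutoffs are configurable because the source description of the
#' boundaries is internally inconsistent by one nucleotide at each cut.
#'
#' @param annotation data.frame with `gene_id` and `length_nt`.
#' @param cutoffs strictly increasing integer pair: lower bounds of the
#'   medium and long classes.
#' @return a factor (levels short, medium, long) named by `gene_id`.
#' @export
trichotomize <- function(annotation, cutoffs = c(250, 10001)) {
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0)
    .config_error("cutoffs must be two strictly increasing values")
  if (any(annotation$length_nt < 0)) .config_error("lengths must be >= 0")
  cls <- cut(annotation$length_nt, breaks = c(-Inf, cutoffs, Inf),
             labels = c("short", "medium", "long"), right = FALSE)
  names(cls) <- annotation$gene_id
  cls
}

.stratum_row <- function(label, vals, mu = 0) {
  n <- length(vals)
  if (n < 2L || var(vals) == 0 && n < 2L) {
    return(data.frame(stratum = label, n_genes = n,
                      mean_log2FC = if (n) mean(vals) else NA_real_,
                      p_value = NA_real_, testable = FALSE,
                      stringsAsFactors = FALSE))
  }
  p <- if (var(vals) == 0) {
    if (isTRUE(all.equal(mean(vals), mu))) 1 else 1e-300
  } else t.test(vals, mu = mu)$p.value
  data.frame(stratum = label, n_genes = n, mean_log2FC = mean(vals),
             p_value = p, testable = TRUE, stringsAsFactors = FALSE)
}

#' Per-stratum shift tests on log2 fold changes
#'
#' Mode "vs_zero" (default) runs a one-sample t-test of each stratum's
#' log2FC values against 0; mode "pairwise" runs two-sample equal-variance
#' t-tests between all stratum pairs. Strata with fewer than two genes are
#' flagged untestable (p unset).
#'
#' @param table a `DifferentialTable` (needs `transcript_id`, `log2FC`).
#' @param class_map factor from [trichotomize()] (or any gene -> stratum
#'   labeling) covering the tested genes.
#' @param mode "vs_zero" or "pairwise".
#' @param var_equal use the equal-variance (Student's) two-sample test in
#'   pairwise mode (default TRUE).
#' @return data.frame of `StratumResult`s; in pairwise mode columns
#'   `stratum` / `stratum2` name the pair.
#' @export
stratified_shift <- function(table, class_map,
                             mode = c("vs_zero", "pairwise"),
                             var_equal = TRUE) {
  mode <- match.arg(mode)
  cls <- class_map[table$transcript_id]
  if (anyNA(cls))
    .config_error("class map does not cover all tested genes")
  groups <- split(table$log2FC, cls)
  if (mode == "vs_zero") {
    do.call(rbind, lapply(names(groups), function(g)
      .stratum_row(g, groups[[g]])))
  } else {
    labs <- names(groups)
    pairs <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      a <- labs[pairs[k, 1L]]; b <- labs[pairs[k, 2L]]
      x <- groups[[a]]; y <- groups[[b]]
      if (length(x) < 2L || length(y) < 2L) {
        return(data.frame(stratum = a, stratum2 = b,
                          n_genes = length(x) + length(y),
                          mean_log2FC = NA_real_, p_value = NA_real_,
                          testable = FALSE, stringsAsFactors = FALSE))
      }
      data.frame(stratum = a, stratum2 = b, n_genes = length(x) + length(y),
                 mean_log2FC = mean(x) - mean(y),
                 p_value = .t2_p(x, y, var_equal = var_equal),
                 testable = TRUE, stringsAsFactors = FALSE)
    }))
  }
}

#' Compare a target gene set against the background
#'
#' Two-sample Student's t-test of log2 fold changes, in-set versus
#' out-of-set.
#'
#' @param table a `DifferentialTable`.
#' @param gene_set character vector of gene ids (non-empty; must intersect
#'   the table but not swallow it).
#' @param var_equal equal-variance test (default TRUE).
#' @return list: `mean_log2FC_in_set`, `mean_log2FC_out`, `p_value`, `n_in`,
#'   `n_out`.
#' @export
target_set_shift <- function(table, gene_set, var_equal = TRUE) {
  if (!length(gene_set)) .config_error("gene_set must be non-empty")
  inside <- table$transcript_id %in% gene_set
  if (!any(inside))
    .config_error("gene_set does not intersect the differential table")
  if (all(inside))
    .config_error("gene_set covers every tested gene; in/out comparison undefined")
  x <- table$log2FC[inside]; y <- table$log2FC[!inside]
  list(mean_log2FC_in_set = mean(x), mean_log2FC_out = mean(y),
       p_value = .t2_p(x, y, var_equal = var_equal),
       n_in = length(x), n_out = length(y))
}

#' Stratify by exon count
#'
#' Splits genes into high-complexity (`exon_count > cutoff`) and background
#' (`<= cutoff`) strata and applies the same shift statistics as
#' [stratified_shift()].
#'
#' @param table a `DifferentialTable`.
#' @param annotation annotation with `gene_id` and `exon_count`.
#' @param exon_cutoff exon-count cutoff (default 30: "over 30 exons").
#' @param mode passed to [stratified_shift()].
#' @return data.frame of `StratumResult`s with strata
#'   `over_cutoff` / `at_or_below_cutoff`.
#' @export
exon_stratify <- function(table, annotation, exon_cutoff = 30,
                          mode = c("vs_zero", "pairwise")) {
  exo <- annotation$exon_count[match(table$transcript_id, annotation$gene_id)]
  if (anyNA(exo)) .config_error("annotation lacks exon counts for tested genes")
  cls <- factor(ifelse(exo > exon_cutoff, "over_cutoff", "at_or_below_cutoff"),
                levels = c("over_cutoff", "at_or_below_cutoff"))
  names(cls) <- table$transcript_id
  res <- stratified_shift(table, cls, mode = match.arg(mode))
  # an empty stratum never reaches split(); surface it as untestable
  missing <- setdiff(levels(cls), res$stratum)
  if (length(missing) && match.arg(mode) == "vs_zero") {
    res <- rbind(res, data.frame(stratum = missing, n_genes = 0L,
                                 mean_log2FC = NA_real_, p_value = NA_real_,
                                 testable = FALSE, stringsAsFactors = FALSE))
  }
  res
}

#' Ratio of total label intensity between two labeling times
#'
#' Reports both the raw ratio of summed TC-read counts and the normalized
#' ratio of summed rpmu values (t2 over t1). Under linear-regime labeling
#' kinetics a t2/t1 = 3 time ratio yields a ~threefold intensity ratio.
#'
#' @param counts_t1,counts_t2 normalized count data.frames over the same
#'   transcript universe (columns `gene_id`, `tcReadCount`, `rpmu`).
#' @return list: `raw` (sum tcReadCount ratio), `normalized` (sum rpmu
#'   ratio).
#' @export
label_time_ratio <- function(counts_t1, counts_t2) {
  if (!setequal(counts_t1$gene_id, counts_t2$gene_id))
    .config_error("count tables cover different transcript universes")
  tc1 <- sum(counts_t1$tcReadCount); tc2 <- sum(counts_t2$tcReadCount)
  if (tc1 == 0) .config_error("zero total TC reads at t1; ratio undefined")
  r1 <- sum(counts_t1$rpmu); r2 <- sum(counts_t2$rpmu)
  list(raw = tc2 / tc1,
       normalized = if (r1 > 0) r2 / r1 else NA_real_)
}
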