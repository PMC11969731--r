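#' @title Bait-normalized AP-MS interactome analysis
#' @description The AP-MS workflow: zero intensities are pseudo-coded to 1,
#'   every protein is normalized to the bait's intensity within the same
#'   sample (cancelling immunoprecipitation-efficiency differences),
#'   replicate means give the fold change versus control, and a Student's
#'   t-test provides significance. Gained/lost classes follow the sign of
#'   the log2 fold change at p < 0.05.
#' @name interactome
NULL

#' Pseudo-code missing detections to 1
#'
#' Replaces intensities of exactly 0 with 1 and leaves everything else
#' untouched; idempotent. Must run before [bait_normalize()].
#'
#' @param mat an `IntensityMatrix` or bare numeric matrix.
#' @return the same type, floored, with attribute `imputed_floor`: a logical
#'   matrix marking the floored cells.
#' @export
pseudo_floor <- function(mat) {
  m <- if (inherits(mat, "IntensityMatrix")) mat$intensity else mat
  if (any(m < 0)) .format_error("negative intensities are invalid")
  prior <- attr(m, "imputed_floor")
  floored <- m == 0
  m[floored] <- 1
  attr(m, "imputed_floor") <- if (is.null(prior)) floored else prior | floored
  if (inherits(mat, "IntensityMatrix")) { mat$intensity <- m; mat } else m
}

#' Normalize every protein to the bait within each sample
#'
#' Each column (sample) is divided by the bait's intensity in that column;
#' the bait row becomes exactly 1 everywhere. Requires a strictly positive
#' bait in every sample, which [pseudo_floor()] guarantees.
#'
#' @param mat an `IntensityMatrix`, or a bare matrix with `bait_id` given.
#' @param bait_id bait protein id (taken from the object when omitted).
#' @return same type with normalized intensities.
#' @export
bait_normalize <- function(mat, bait_id = NULL) {
  m <- if (inherits(mat, "IntensityMatrix")) mat$intensity else mat
  bait_id <- bait_id %||% if (inherits(mat, "IntensityMatrix")) mat$bait_id else NULL
  if (is.null(bait_id) || !bait_id %in% rownames(m))
    .format_error("bait protein '%s' not found in the matrix",
                  bait_id %||% "<unset>")
  bait <- m[bait_id, ]
  if (any(bait <= 0))
    .format_error("bait intensity must be > 0 in every sample (run pseudo_floor first)")
  fl <- attr(m, "imputed_floor")
  m <- sweep(m, 2L, bait, "/")
  attr(m, "imputed_floor") <- fl
  if (inherits(mat, "IntensityMatrix")) { mat$intensity <- m; mat } else m
}

#' Differential interactome between two conditions
#'
#' Replicate means of bait-normalized intensities per condition; fold change
#' is mean treated over mean control; p-value from a two-sample Student's
#' t-test on per-replicate normalized values (set `log_scale = TRUE` to test
#' log2 values instead). Class: gained if p < alpha and log2FC > 0, lost if
#' p < alpha and log2FC < 0, else unchanged.
#'
#' @param mat a floored, bait-normalized `IntensityMatrix` (the pipeline
#'   order floor -> normalize is enforced via the bait row).
#' @param control,treated condition labels in `mat$samples$condition`.
#' @param alpha significance level (default 0.05).
#' @param log_scale run the t-test on log2 normalized values.
#' @return `InteractomeTable` data.frame: `protein_id`,
#'   `mean_norm_control`, `mean_norm_treated`, `fold_change`, `log2FC`,
#'   `p_value`, `class`, `imputed_floor`.
#' @export
differential_interactome <- function(mat, control, treated, alpha = 0.05,
                                     log_scale = FALSE) {
  stopifnot(inherits(mat, "IntensityMatrix"))
  m <- mat$intensity
  if (!isTRUE(all.equal(unname(m[mat$bait_id, ]),
                        rep(1, ncol(m)), tolerance = 1e-8)))
    .format_error("matrix is not bait-normalized (bait row != 1); run pseudo_floor then bait_normalize")
  ctrl <- mat$samples$sample_id[mat$samples$condition == control]
  trt <- mat$samples$sample_id[mat$samples$condition == treated]
  if (length(ctrl) < 2L || length(trt) < 2L)
    .config_error("each condition needs >= 2 replicates")
  C <- m[, ctrl, drop = FALSE]; Tt <- m[, trt, drop = FALSE]
  mean_c <- rowMeans(C); mean_t <- rowMeans(Tt)
  fc <- mean_t / mean_c
  l2 <- log2(fc)
  tc <- if (log_scale) log2(Tt) else Tt
  cc <- if (log_scale) log2(C) else C
  pv <- vapply(seq_len(nrow(m)), function(i) .t2_p(tc[i, ], cc[i, ]), 0)
  cls <- ifelse(pv < alpha & l2 > 0, "gained",
                ifelse(pv < alpha & l2 < 0, "lost", "unchanged"))
  fl <- attr(m, "imputed_floor")
  imputed <- if (is.null(fl)) rep(FALSE, nrow(m)) else rowSums(fl) > 0
  data.frame(protein_id = rownames(m), mean_norm_control = mean_c,
             mean_norm_treated = mean_t, fold_change = fc, log2FC = l2,
             p_value = pv, class = cls, imputed_floor = imputed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proteins responding strongly to two perturbations
#'
#' The stringent dual cut: proteins significant in both tables with
#' |log2FC| at or above the cutoff in both. Direction concordance is
#' reported per protein (concordant-gained, concordant-lost, discordant).
#'
#' @param tableA,tableB `InteractomeTable`s over the same protein universe.
#' @param lfc_cutoff absolute log2 fold-change cutoff (default 2).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `protein_id`, `log2FC_A`, `log2FC_B`, `concordance`.
#' @export
dual_response_filter <- function(tableA, tableB, lfc_cutoff = 2,
                                 alpha = 0.05) {
  if (!setequal(tableA$protein_id, tableB$protein_id))
    .config_error("the two tables cover different protein universes")
  b <- tableB[match(tableA$protein_id, tableB$protein_id), ]
  hit <- tableA$p_value < alpha & b$p_value < alpha &
    abs(tableA$log2FC) >= lfc_cutoff & abs(b$log2FC) >= lfc_cutoff
  out <- data.frame(protein_id = tableA$protein_id[hit],
                    log2FC_A = tableA$log2FC[hit], log2FC_B = b$log2FC[hit],
                    stringsAsFactors = FALSE)
  out$concordance <- ifelse(sign(out$log2FC_A) != sign(out$log2FC_B),
                            "discordant",
                            ifelse(out$log2FC_A > 0, "concordant-gained",
                                   "concordant-lost"))
  out
}

#' Per-condition exclusive and intersection sets of responders
#'
#' For lost and gained proteins separately, builds the membership mask per
#' condition, the size of every intersection pattern (upset-style), and the
#' "selective" set: proteins significant in exactly one condition.
#'
#' @param tables named list of `InteractomeTable`s (>= 2) over a shared
#'   universe.
#' @return list with elements `lost` and `gained`, each holding
#'   `membership` (logical matrix protein x condition), `exclusive` (named
#'   list of selective protein sets) and `patterns` (data.frame of
#'   intersection pattern sizes).
#' @export
selective_sets <- function(tables) {
  if (length(tables) < 2L) .config_error("need >= 2 tables")
  universe <- sort(unique(tables[[1L]]$protein_id))
  for (tb in tables) if (!setequal(tb$protein_id, universe))
    .config_error("tables cover different protein universes")
  one_dir <- function(direction) {
    memb <- sapply(tables, function(tb)
      universe %in% tb$protein_id[tb$class == direction])
    memb <- matrix(memb, nrow = length(universe),
                   dimnames = list(universe, names(tables)))
    nsig <- rowSums(memb)
    exclusive <- lapply(colnames(memb), function(cn)
      universe[memb[, cn] & nsig == 1L])
    names(exclusive) <- colnames(memb)
    pat <- apply(memb, 1L, function(r) paste(colnames(memb)[r], collapse = "&"))
    pat <- pat[nzchar(pat)]
    patterns <- if (length(pat)) {
      tab <- table(pat)
      data.frame(pattern = names(tab), size = as.integer(tab),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pattern = character(0), size = integer(0),
                 stringsAsFactors = FALSE)
    }
    list(membership = memb, exclusive = exclusive, patterns = patterns)
  }
  list(lost = one_dir("lost"), gained = one_dir("gained"))
}

#' Complex-level relative binding summary
#'
#' For each complex member, the mean bait-normalized treated intensity over
#' the mean control intensity ("relative binding", control = 1); plus the
#' complex mean and the fraction of members below/above 1. Members absent
#' from the matrix are reported missing and excluded from the mean.
#'
#' @param mat a floored, bait-normalized `IntensityMatrix`.
#' @param members character vector of complex member ids.
#' @param control,treated condition labels.
#' @return list: `per_member` (data.frame `protein_id`, `relative_binding`),
#'   `complex_mean`, `frac_below_1`, `frac_above_1`, `missing`.
#' @export
complex_summary <- function(mat, members, control, treated) {
  stopifnot(inherits(mat, "IntensityMatrix"))
  m <- mat$intensity
  present <- intersect(members, rownames(m))
  missing <- setdiff(members, rownames(m))
  if (!length(present))
    .format_error("no complex member detected; absent: %s",
                  paste(missing, collapse = ", "))
  ctrl <- mat$samples$sample_id[mat$samples$condition == control]
  trt <- mat$samples$sample_id[mat$samples$condition == treated]
  rb <- rowMeans(m[present, trt, drop = FALSE]) /
    rowMeans(m[present, ctrl, drop = FALSE])
  list(per_member = data.frame(protein_id = present,
                               relative_binding = unname(rb),
                               stringsAsFactors = FALSE),
       complex_mean = mean(rb),
       frac_below_1 = mean(rb < 1), frac_above_1 = mean(rb > 1),
       missing = missing)
}
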