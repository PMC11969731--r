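#' @title Differentially labelled transcript (DLT) calling
#' @description Calls differential labeling between two conditions from
#'   RPMu-normalized counts. The headline thresholds are fixed by the
#'   analysis design: p-value < 0.05 and |log2 fold change| >= 1.
#' @name differential
NULL

# Equal-variance two-sample t p-value with degenerate-input guards:
# zero pooled variance and equal means -> p = 1; unequal means -> p ~ 0.
.t2_p <- function(x, y, var_equal = TRUE) {
  vx <- var(x); vy <- var(y)
  if ((vx + vy) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 1e-300)
  }
  p <- tryCatch(
    t.test(x, y, var.equal = var_equal)$p.value,
    error = function(e) 1)
  max(p, 1e-300)
}

#' Call differentially labelled transcripts
#'
#' log2 fold change is computed on condition means of the rpmu values with a
#' pseudocount; the p-value comes from a per-transcript two-sample test on
#' per-replicate log2(rpmu + pseudocount) ("student", the default, or
#' "welch"), or from a quasi-Poisson Wald test on raw tcReadCount with
#' RPMu-derived size-factor offsets ("nb"). Transcripts that are all-zero in
#' both conditions are reported with log2FC = 0 and p = 1.
#'
#' @param counts normalized count data.frame (`gene_id`, `sample`, `rpmu`,
#'   and `tcReadCount`/`readCount` for the "nb" method).
#' @param design data.frame mapping `sample` to `condition` (and optionally
#'   `replicate`).
#' @param control,treated condition labels; defaults are the first two
#'   condition levels in `design`.
#' @param pseudocount added on the rpmu scale before logs (default 1).
#' @param test_method "student" (equal-variance t on log2 rpmu; default),
#'   "welch", or "nb".
#' @param alpha significance level on the p-value (default 0.05).
#' @param lfc absolute log2 fold-change threshold (default 1).
#' @param bh apply Benjamini-Hochberg correction before thresholding
#'   (default FALSE: the thresholds act on raw p-values).
#' @return `DifferentialTable` data.frame: `transcript_id`, `log2FC`,
#'   `p_value`, `significant`, `direction`.
#' @export
differential_labeling <- function(counts, design, control = NULL,
                                  treated = NULL, pseudocount = 1,
                                  test_method = c("student", "welch", "nb"),
                                  alpha = 0.05, lfc = 1, bh = FALSE) {
  test_method <- match.arg(test_method)
  stopifnot(all(c("gene_id", "sample", "rpmu") %in% names(counts)))
  conds <- unique(design$condition)
  control <- control %||% conds[1L]
  treated <- treated %||% conds[2L]
  ctrl_samples <- design$sample[design$condition == control]
  trt_samples <- design$sample[design$condition == treated]
  if (length(ctrl_samples) < 2L || length(trt_samples) < 2L)
    .config_error("each condition needs >= 2 replicates (control: %d, treated: %d)",
                  length(ctrl_samples), length(trt_samples))
  if (pseudocount < 0) .config_error("pseudocount must be >= 0")

  wide <- function(samples, col) {
    m <- sapply(samples, function(s) {
      sub <- counts[counts$sample == s, ]
      sub[[col]][match(ids, sub$gene_id)]
    })
    matrix(m, ncol = length(samples))
  }
  ids <- sort(unique(counts$gene_id))
  rc <- wide(c(ctrl_samples, trt_samples), "rpmu")
  if (anyNA(rc)) .config_error("rpmu values missing for some gene/sample pairs")
  nC <- length(ctrl_samples)
  C <- rc[, seq_len(nC), drop = FALSE]
  Tt <- rc[, nC + seq_along(trt_samples), drop = FALSE]

  log2fc <- log2(rowMeans(Tt) + pseudocount) - log2(rowMeans(C) + pseudocount)
  all_zero <- rowSums(C) == 0 & rowSums(Tt) == 0

  if (test_method %in% c("student", "welch")) {
    lC <- log2(C + pseudocount); lT <- log2(Tt + pseudocount)
    pv <- vapply(seq_along(ids), function(i)
      .t2_p(lT[i, ], lC[i, ], var_equal = test_method == "student"),
      0)
  } else {
    pv <- .nb_wald_p(counts, ids, ctrl_samples, trt_samples)
  }
  pv[all_zero] <- 1
  log2fc[all_zero] <- 0
  p_adj <- if (bh) p.adjust(pv, "BH") else pv
  sig <- p_adj < alpha & abs(log2fc) >= lfc
  direction <- ifelse(!sig, "none", ifelse(log2fc > 0, "up", "down"))
  data.frame(transcript_id = ids, log2FC = log2fc, p_value = pv,
             significant = sig, direction = direction,
             stringsAsFactors = FALSE)
}

# Overdispersed-count Wald test: quasi-Poisson GLM on raw tcReadCount with
# log size-factor offsets derived from each sample's non-TC read sum.
.nb_wald_p <- function(counts, ids, ctrl_samples, trt_samples) {
  stopifnot(all(c("tcReadCount", "readCount") %in% names(counts)))
  samples <- c(ctrl_samples, trt_samples)
  sf <- vapply(samples, function(s) {
    sub <- counts[counts$sample == s, ]
    sum(sub$readCount - sub$tcReadCount)
  }, 0)
  sf <- sf / exp(mean(log(pmax(sf, 1))))
  cond <- factor(rep(c("control", "treated"),
                     c(length(ctrl_samples), length(trt_samples))),
                 levels = c("control", "treated"))
  tc <- sapply(samples, function(s) {
    sub <- counts[counts$sample == s, ]
    sub$tcReadCount[match(ids, sub$gene_id)]
  })
  tc <- matrix(tc, ncol = length(samples))
  vapply(seq_along(ids), function(i) {
    y <- tc[i, ]
    if (all(y == 0)) return(1)
    fit <- tryCatch(
      glm(y ~ cond, family = quasipoisson(), offset = log(sf)),
      error = function(e) NULL, warning = function(w) suppressWarnings(
        glm(y ~ cond, family = quasipoisson(), offset = log(sf))))
    if (is.null(fit)) return(1)
    co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (is.null(co) || nrow(co) < 2L || !is.finite(co[2L, 4L])) return(1)
    max(co[2L, 4L], 1e-300)
  }, 0)
}

#' Summarize a differential table volcano-style
#'
#' @param table a `DifferentialTable`.
#' @return named numeric: `n_up`, `n_down`, `n_tested`.
#' @export
volcano_summary <- function(table) {
  c(n_up = sum(table$significant & table$direction == "up"),
    n_down = sum(table$significant & table$direction == "down"),
    n_tested = nrow(table))
}
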