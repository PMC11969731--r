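#' @title SLAM-seq conversion counting and RPMu normalization
#' @description Per-read T>C conversion counting from SAM records with MD
#'   tags (or a tabular read summary), labeled-read classification,
#'   per-transcript aggregation, and RPMu normalization: the TC-read count of
#'   a transcript divided by the library-wide sum of non-TC reads, times
#'   10,000,000.
#' @name slam_quant
NULL

.format_error <- function(...) {
  cond <- structure(class = c("nascentflow_format_error", "error", "condition"),
                    list(message = sprintf(...), call = sys.call(-1)))
  stop(cond)
}

#' Read alignment records from a SAM file
#'
#' Minimal reader for the fields the quantifier needs: read id, reference
#' name, position, flag, CIGAR, SEQ and the MD tag. Mapped records only.
#'
#' @param path SAM file path.
#' @return a list of read records (each a list with `read_id`, `flag`,
#'   `transcript_id`, `pos`, `cigar`, `seq`, `md`).
#' @export
parse_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L) .format_error("truncated SAM record: %s", substr(l, 1, 60))
    md <- sub("^MD:Z:", "", grep("^MD:Z:", f[-(1:11)], value = TRUE)[1])
    list(read_id = f[1L], flag = as.integer(f[2L]), transcript_id = f[3L],
         pos = as.integer(f[4L]), cigar = f[6L], seq = f[10L],
         md = if (is.na(md)) NULL else md)
  })
}

# Reconstruct (genomic position, ref base, read base) for every aligned
# position of one record, from CIGAR + MD + SEQ.
.aligned_positions <- function(read) {
  if (is.null(read$md) || !nzchar(read$md))
    .format_error("read '%s' carries no MD tag; cannot recover reference bases",
                  read$read_id)
  ops <- regmatches(read$cigar, gregexpr("\\d+[MIDNSHP=X]", read$cigar))[[1L]]
  if (!length(ops)) .format_error("read '%s' has unparseable CIGAR '%s'",
                                  read$read_id, read$cigar)
  seq <- strsplit(toupper(read$seq), "")[[1L]]
  gpos <- read$pos; ridx <- 1L
  g <- integer(0); rb <- character(0)
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^\\d+", "", op)
    if (type %in% c("M", "=", "X")) {
      g <- c(g, gpos:(gpos + n - 1L))
      rb <- c(rb, seq[ridx:(ridx + n - 1L)])
      gpos <- gpos + n; ridx <- ridx + n
    } else if (type %in% c("I", "S")) {
      ridx <- ridx + n
    } else if (type %in% c("D", "N")) {
      gpos <- gpos + n
    }
  }
  # MD walk assigns the reference base at each aligned (non-deleted) position
  toks <- regmatches(read$md,
                     gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", read$md))[[1L]]
  ref <- character(length(rb)); i <- 1L
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      n <- as.integer(tk)
      if (n > 0L) { ref[i:(i + n - 1L)] <- rb[i:(i + n - 1L)]; i <- i + n }
    } else if (startsWith(tk, "^")) {
      # deleted reference bases: consume no aligned position
    } else {
      ref[i] <- toupper(tk); i <- i + 1L
    }
  }
  if (i - 1L != length(rb))
    .format_error("read '%s': MD tag covers %d positions but CIGAR aligns %d",
                  read$read_id, i - 1L, length(rb))
  list(gpos = g, ref = ref, read = rb)
}

#' Count T>C conversions on one aligned read
#'
#' Counts reference-T positions covered by the read (excluding masked
#' genomic positions) and, among them, those where the read base is C. Reads
#' on the minus strand (SAM flag 0x10) are evaluated as A>G in genome space,
#' which is T>C in transcript space.
#'
#' @param read a record from [parse_sam()] (or any list with the same
#'   fields).
#' @param snp_mask integer vector of excluded genomic positions (1-based, as
#'   in SAM), e.g. known SNPs; default empty.
#' @return list `ReadConversionSummary`: `read_id`, `transcript_id`,
#'   `n_ref_T`, `n_TC`.
#' @export
count_conversions <- function(read, snp_mask = integer(0)) {
  al <- .aligned_positions(read)
  minus <- bitwAnd(read$flag %||% 0L, 16L) != 0L
  ref_base <- if (minus) "A" else "T"
  conv_base <- if (minus) "G" else "C"
  keep <- al$ref == ref_base & !(al$gpos %in% snp_mask)
  list(read_id = read$read_id, transcript_id = read$transcript_id,
       n_ref_T = sum(keep), n_TC = sum(keep & al$read == conv_base))
}

#' Classify a read as labeled
#'
#' @param summary a `ReadConversionSummary` (or anything with `n_TC`).
#' @param threshold minimum number of T>C conversions (>= 1).
#' @return TRUE iff `n_TC >= threshold`.
#' @export
classify_labeled <- function(summary, threshold = 1L) {
  if (threshold < 1) .config_error("conversion threshold must be >= 1")
  summary$n_TC >= threshold
}

#' Aggregate read summaries into per-transcript counts
#'
#' @param summaries data.frame with columns `read_id`, `transcript_id`,
#'   `n_ref_T`, `n_TC` (one row per read).
#' @param annotation annotation data.frame with `gene_id`; transcripts with
#'   zero reads appear with zero counts.
#' @param threshold conversion-call threshold passed to [classify_labeled()].
#' @param sample_id sample label for the output.
#' @return count data.frame (`gene_id`, `sample`, `readCount`,
#'   `tcReadCount`).
#' @export
aggregate_counts <- function(summaries, annotation, threshold = 1L,
                             sample_id = "S1") {
  ids <- annotation$gene_id
  if (nrow(summaries)) {
    unknown <- setdiff(unique(summaries$transcript_id), ids)
    if (length(unknown))
      .format_error("reads reference unknown transcript id(s): %s",
                    paste(unknown, collapse = ", "))
  }
  rc <- table(factor(summaries$transcript_id, levels = ids))
  labeled <- summaries$n_TC >= threshold
  tc <- table(factor(summaries$transcript_id[labeled], levels = ids))
  data.frame(gene_id = ids, sample = sample_id,
             readCount = as.integer(rc), tcReadCount = as.integer(tc),
             stringsAsFactors = FALSE)
}

#' RPMu-normalize a count table
#'
#' Per sample, the TC-read count of each transcript is divided by the sum of
#' the non-TC reads over all transcripts in that sample (a library-size
#' proxy) and multiplied by 10,000,000.
#'
#' @param counts data.frame with `gene_id`, `sample`, `readCount`,
#'   `tcReadCount`; may hold one or several samples.
#' @return the input with an `rpmu` column appended.
#' @export
rpmu_normalize <- function(counts) {
  stopifnot(all(c("gene_id", "sample", "readCount", "tcReadCount") %in%
                  names(counts)))
  if (any(counts$tcReadCount > counts$readCount))
    .format_error("tcReadCount exceeds readCount")
  counts$rpmu <- NA_real_
  for (s in unique(counts$sample)) {
    idx <- counts$sample == s
    non_tc <- sum(counts$readCount[idx] - counts$tcReadCount[idx])
    if (non_tc <= 0) {
      cond <- structure(
        class = c("nascentflow_degenerate_error", "error", "condition"),
        list(message = sprintf(
          "sample '%s' has no non-TC reads; RPMu normalization undefined", s),
          call = sys.call(-1)))
      stop(cond)
    }
    counts$rpmu[idx] <- counts$tcReadCount[idx] / non_tc * 1e7
  }
  counts
}

#' Quantify a SAM file end to end
#'
#' Convenience wrapper: parse, count conversions per read, aggregate, and
#' RPMu-normalize.
#'
#' @inheritParams aggregate_counts
#' @param path SAM path.
#' @param snp_mask masked genomic positions (1-based).
#' @return normalized count data.frame.
#' @export
quantify_sam <- function(path, annotation, threshold = 1L,
                         snp_mask = integer(0), sample_id = "S1") {
  reads <- parse_sam(path)
  summaries <- do.call(rbind, lapply(reads, function(r)
    as.data.frame(count_conversions(r, snp_mask), stringsAsFactors = FALSE)))
  if (is.null(summaries))
    summaries <- data.frame(read_id = character(0),
                            transcript_id = character(0),
                            n_ref_T = integer(0), n_TC = integer(0))
  rpmu_normalize(aggregate_counts(summaries, annotation, threshold, sample_id))
}
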