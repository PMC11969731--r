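# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (MD walking, cumulative-sum scans) so that each
# check compares two independent routes to the same number.

# Build a SAM record line from explicit reference/read base vectors
# (ungapped, plus strand unless flag says otherwise). The MD tag is derived
# here by direct comparison, independent of the package's .build_md.
sam_record <- function(read_id, rname, ref, read, flag = 0L, pos = 1L) {
  stopifnot(length(ref) == length(read))
  md <- character(0); run <- 0L
  for (i in seq_along(ref)) {
    if (ref[i] == read[i]) run <- run + 1L
    else { md <- c(md, run, ref[i]); run <- 0L }
  }
  md <- paste0(paste(md, collapse = ""), run)
  sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tMD:Z:%s",
          read_id, flag, rname, pos, length(read),
          paste(read, collapse = ""), md)
}

# Exhaustive base-by-base conversion counter on explicit ref/read vectors.
oracle_conversions <- function(ref, read, pos = 1L, snp_mask = integer(0),
                               minus = FALSE) {
  gpos <- pos + seq_along(ref) - 1L
  ref_base <- if (minus) "A" else "T"
  conv_base <- if (minus) "G" else "C"
  keep <- ref == ref_base & !(gpos %in% snp_mask)
  list(n_ref_T = sum(keep), n_TC = sum(keep & read == conv_base))
}

# Exhaustive position scan for the best IPA split (double loop over means).
oracle_ipa_scan <- function(depth, min_flank) {
  L <- length(depth)
  best_score <- -Inf; best_k <- NA_integer_
  for (k in min_flank:(L - min_flank)) {
    mu <- mean(depth[1:k]); md <- mean(depth[(k + 1):L])
    s <- if (mu > 0) (mu - md) / mu else -Inf
    if (s > best_score) { best_score <- s; best_k <- k }
  }
  list(k = best_k, score = best_score)
}

# Analytic probability that a read with nu uridines at per-uridine
# conversion probability p carries >= thr conversions.
tc_tail <- function(nu, p, thr = 1L) pbinom(thr - 1L, nu, p, lower.tail = FALSE)

# A tiny annotation with fixed lengths and no randomness beyond the seed.
tiny_annotation <- function(n = 3, lengths = c(100, 5000, 50000), seed = 1) {
  simulate_transcriptome(n, lengths = lengths, seed = seed)
}
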