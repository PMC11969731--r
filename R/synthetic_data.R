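#' @title Synthetic data generators
#' @description Seeded generators that emulate the statistical structure the
#'   downstream analysis assumes: transcript annotations, metabolic-labeling
#'   (4sU) T>C conversion counts, bait-anchored AP-MS intensity matrices with
#'   spiked interactors, and per-intron coverage profiles with an optional
#'   premature-polyadenylation step-down. Every generator is a pure function
#'   of its parameters and a seed (see [substream_seed()]).
#' @name synthetic_data
NULL

# Run code under a temporary RNG state so generators never disturb the
# caller's random stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a transcript annotation collection
#'
#' Gene spans (exons plus introns, in nucleotides) are drawn log-normally;
#' exon counts are `1 + Poisson(exon_lambda)`. Intron intervals are carved
#' from the span by splitting it into `2k - 1` alternating exon/intron
#' segments with Dirichlet-distributed proportions. The number of reference
#' uridines per read window is proportional to the read length, not the gene
#' length (reads are fixed-width windows on the transcript).
#'
#' @param n_genes number of genes to simulate.
#' @param lengths optional explicit vector of gene lengths (overrides the
#'   log-normal draw; recycled to `n_genes`).
#' @param length_meanlog,length_sdlog log-normal parameters of the genomic
#'   span in nucleotides. Defaults emulate human gene spans (median 20 kb).
#' @param exon_lambda Poisson rate for `exon_count - 1`.
#' @param read_length sequencing read length in bases (default 100 nt,
#'   single-read short-read chemistry).
#' @param u_fraction expected fraction of read positions that are reference T
#'   (default 0.30, i.e. 30 uridines per 100-base read).
#' @param seed integer seed; identical calls with identical seeds are
#'   byte-identical.
#' @return a `data.frame` with columns `gene_id`, `length_nt`, `exon_count`,
#'   `n_uridines`, and a list-column `introns` of two-column data frames
#'   (`start`, `end`; 0-based half-open offsets within the gene span).
#' @export
simulate_transcriptome <- function(n_genes, lengths = NULL,
                                   length_meanlog = log(20000),
                                   length_sdlog = 1.6,
                                   exon_lambda = 8,
                                   read_length = 100,
                                   u_fraction = 0.3,
                                   seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    .config_error("n_genes must be a positive integer")
  if (!is.finite(length_meanlog) || !is.finite(length_sdlog) || length_sdlog < 0)
    .config_error("invalid length distribution parameters")
  if (!is.finite(exon_lambda) || exon_lambda < 0)
    .config_error("invalid exon distribution parameters")
  if (u_fraction <= 0 || u_fraction > 1 || read_length < 1)
    .config_error("read_length must be >= 1 and u_fraction in (0, 1]")
  n_genes <- as.integer(n_genes)

  .with_seed(seed, {
    len <- if (is.null(lengths)) {
      pmax(1L, as.integer(round(rlnorm(n_genes, length_meanlog, length_sdlog))))
    } else {
      as.integer(rep_len(lengths, n_genes))
    }
    if (any(len < 1)) .config_error("gene lengths must be >= 1")
    exo <- 1L + rpois(n_genes, exon_lambda)
    introns <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      k <- exo[i]
      if (k == 1L || len[i] < 2L * k) {
        introns[[i]] <- data.frame(start = integer(0), end = integer(0))
        next
      }
      # 2k-1 alternating segments (exon, intron, ..., exon)
      w <- rgamma(2L * k - 1L, shape = 1)
      cuts <- round(cumsum(w) / sum(w) * len[i])
      cuts <- unique(pmin(pmax(cuts, seq_along(cuts)), len[i]))
      bounds <- c(0L, as.integer(cuts))
      if (length(bounds) < 2L * k) {  # degenerate split; no resolvable introns
        introns[[i]] <- data.frame(start = integer(0), end = integer(0))
        next
      }
      idx <- seq(2L, 2L * k - 1L, by = 2L)  # even segments are introns
      introns[[i]] <- data.frame(start = bounds[idx], end = bounds[idx + 1L])
    }
    ann <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      length_nt = len,
      exon_count = exo,
      n_uridines = as.integer(round(read_length * u_fraction)),
      stringsAsFactors = FALSE
    )
    ann$introns <- introns
    ann
  })
}

#' Construct and validate a metabolic-labeling model
#'
#' The per-uridine T>C conversion probability of a labeled read is
#' `labeling_time_min * conversion_rate_per_min + background_error_rate`
#' (linear-regime kinetics); unlabeled reads convert only at the background
#' error rate.
#'
#' @param labeling_time_min labeling pulse length in minutes (> 0).
#' @param conversion_rate_per_min per-uridine conversion probability gained
#'   per minute of labeling, in (0, 1).
#' @param background_error_rate per-base sequencing/chemistry error rate,
#'   in \[0, 1).
#' @param labeled_fraction fraction of reads originating from labeled
#'   transcripts, in \[0, 1\] (scalar or per-transcript vector).
#' @param seed integer seed for downstream simulation.
#' @return a validated `labeling_model` list.
#' @export
labeling_model <- function(labeling_time_min, conversion_rate_per_min,
                           background_error_rate = 1e-4,
                           labeled_fraction = 1, seed = 1L) {
  if (!is.finite(labeling_time_min) || labeling_time_min <= 0)
    .config_error("labeling_time_min must be a positive real")
  if (!is.finite(conversion_rate_per_min) ||
      conversion_rate_per_min <= 0 || conversion_rate_per_min >= 1)
    .config_error("conversion_rate_per_min must be in (0, 1)")
  if (!is.finite(background_error_rate) ||
      background_error_rate < 0 || background_error_rate >= 1)
    .config_error("background_error_rate must be in [0, 1)")
  if (any(!is.finite(labeled_fraction)) ||
      any(labeled_fraction < 0) || any(labeled_fraction > 1))
    .config_error("labeled_fraction must be in [0, 1]")
  p <- labeling_time_min * conversion_rate_per_min + background_error_rate
  if (p >= 1)
    .config_error("labeling_time_min * conversion_rate_per_min + background >= 1: invalid per-uridine probability")
  structure(list(labeling_time_min = labeling_time_min,
                 conversion_rate_per_min = conversion_rate_per_min,
                 background_error_rate = background_error_rate,
                 labeled_fraction = labeled_fraction,
                 seed = as.integer(seed)),
            class = "labeling_model")
}

#' Simulate per-transcript SLAM-seq conversion counts
#'
#' Each read is labeled with probability `labeled_fraction`; a labeled read
#' carries `Binomial(n_uridines, time * rate + background)` T>C conversions
#' and an unlabeled read `Binomial(n_uridines, background)`. Reads with at
#' least `conversion_call_threshold` conversions are counted as TC reads.
#' Sampling uses the exact binomial tail, so runtime is per transcript, not
#' per read.
#'
#' @param annotation annotation from [simulate_transcriptome()] (columns
#'   `gene_id`, `n_uridines`).
#' @param model a [labeling_model()].
#' @param n_reads_per_transcript reads simulated per transcript (scalar or
#'   vector).
#' @param conversion_call_threshold minimum T>C conversions for a read to
#'   count as labeled (default 1).
#' @param sample_id sample label attached to the output rows.
#' @return a `data.frame` with columns `gene_id`, `sample`, `readCount`,
#'   `tcReadCount` (the count-file shape consumed by [rpmu_normalize()]).
#' @export
simulate_slam_counts <- function(annotation, model, n_reads_per_transcript,
                                 conversion_call_threshold = 1L,
                                 sample_id = "S1") {
  stopifnot(inherits(model, "labeling_model"))
  if (any(n_reads_per_transcript < 0))
    .config_error("n_reads_per_transcript must be >= 0")
  if (conversion_call_threshold < 1)
    .config_error("conversion_call_threshold must be >= 1")
  n <- nrow(annotation)
  reads <- as.integer(rep_len(n_reads_per_transcript, n))
  lf <- rep_len(model$labeled_fraction, n)
  p_lab <- model$labeling_time_min * model$conversion_rate_per_min +
    model$background_error_rate
  p_bg <- model$background_error_rate
  nu <- annotation$n_uridines
  thr <- as.integer(conversion_call_threshold)
  # P(read scored TC) = P(Binom(nU, p) >= thr)
  tail_lab <- pbinom(thr - 1L, nu, p_lab, lower.tail = FALSE)
  tail_bg  <- pbinom(thr - 1L, nu, p_bg,  lower.tail = FALSE)
  .with_seed(substream_seed(model$seed, paste0("slam:", sample_id)), {
    n_lab <- rbinom(n, reads, lf)
    tc <- rbinom(n, n_lab, tail_lab) + rbinom(n, reads - n_lab, tail_bg)
    data.frame(gene_id = annotation$gene_id, sample = sample_id,
               readCount = reads, tcReadCount = as.integer(tc),
               stringsAsFactors = FALSE)
  })
}

#' Describe an AP-MS spike-in design
#'
#' @param n_proteins size of the protein universe (bait included).
#' @param bait_id id of the immunoprecipitation target (default "BAIT").
#' @param n_replicates replicates per condition (>= 2; a t-test is undefined
#'   below that).
#' @param lognormal_sigma sdlog of the multiplicative measurement noise.
#' @param spiked named numeric vector: protein id -> log2 effect applied in
#'   the treated condition only.
#' @param missing_rate fraction of non-bait entries zeroed to emulate missing
#'   detections (default 0).
#' @param conditions character(2): control and treated condition labels.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-protein baseline abundance.
#' @param seed integer seed.
#' @return a validated `interactome_design` list.
#' @export
interactome_design <- function(n_proteins, bait_id = "BAIT",
                               n_replicates = 3L, lognormal_sigma = 0.2,
                               spiked = numeric(0), missing_rate = 0,
                               conditions = c("control", "treated"),
                               baseline_meanlog = log(1e6),
                               baseline_sdlog = 1.5, seed = 1L) {
  if (n_proteins < 1) .config_error("n_proteins must be >= 1")
  if (n_replicates < 2)
    .config_error("n_replicates_per_condition < 2: t-test undefined")
  if (!is.finite(lognormal_sigma) || lognormal_sigma < 0)
    .config_error("lognormal_sigma must be a non-negative real")
  if (missing_rate < 0 || missing_rate >= 1)
    .config_error("missing_rate must be in [0, 1)")
  proteins <- c(bait_id, sprintf("P%04d", seq_len(n_proteins - 1L)))
  if (length(spiked) && !all(names(spiked) %in% proteins))
    .config_error("spiked protein ids must belong to the protein universe")
  structure(list(proteins = proteins, bait_id = bait_id,
                 n_replicates = as.integer(n_replicates),
                 lognormal_sigma = lognormal_sigma, spiked = spiked,
                 missing_rate = missing_rate, conditions = conditions,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "interactome_design")
}

#' Simulate an AP-MS intensity matrix
#'
#' Baseline abundances are log-normal per protein; each sample carries its own
#' multiplicative IP-efficiency factor (so the bait intensity varies across
#' samples and bait normalization has real work to do); spiked proteins are
#' shifted by `2^log2_effect` in the treated condition before the per-sample
#' scaling; measurement noise is log-normal with `lognormal_sigma`; a
#' `missing_rate` fraction of non-bait entries is set to exactly 0.
#'
#' @param design an [interactome_design()].
#' @return an `IntensityMatrix`: list with `intensity` (protein x sample
#'   matrix), `samples` (data.frame `sample_id`, `condition`, `replicate`)
#'   and `bait_id`.
#' @export
simulate_interactome <- function(design) {
  stopifnot(inherits(design, "interactome_design"))
  d <- design
  samples <- data.frame(
    sample_id = paste0(rep(d$conditions, each = d$n_replicates), "_",
                       rep(seq_len(d$n_replicates), times = 2L)),
    condition = rep(d$conditions, each = d$n_replicates),
    replicate = rep(seq_len(d$n_replicates), times = 2L),
    stringsAsFactors = FALSE
  )
  np <- length(d$proteins); ns <- nrow(samples)
  .with_seed(substream_seed(d$seed, "interactome"), {
    base <- rlnorm(np, d$baseline_meanlog, d$baseline_sdlog)
    names(base) <- d$proteins
    base[d$bait_id] <- exp(d$baseline_meanlog) * 10  # bait is the most abundant pull-down component
    ip_eff <- rlnorm(ns, 0, 0.3)
    eff <- matrix(1, np, ns, dimnames = list(d$proteins, samples$sample_id))
    if (length(d$spiked)) {
      treated_cols <- samples$condition == d$conditions[2L]
      eff[names(d$spiked), treated_cols] <- 2^unname(d$spiked)
    }
    noise <- matrix(rlnorm(np * ns, 0, d$lognormal_sigma), np, ns)
    # the bait's across-sample variation IS the IP-efficiency scale; its
    # measurement noise is folded into that scale so lognormal_sigma is the
    # noise of bait-NORMALIZED interactor intensities
    noise[match(d$bait_id, d$proteins), ] <- 1
    intensity <- base * eff * noise * rep(ip_eff, each = np)
    dimnames(intensity) <- list(d$proteins, samples$sample_id)
    if (d$missing_rate > 0) {
      non_bait <- which(rownames(intensity) != d$bait_id)
      cells <- as.matrix(expand.grid(non_bait, seq_len(ns)))
      drop <- cells[runif(nrow(cells)) < d$missing_rate, , drop = FALSE]
      intensity[drop] <- 0
    }
    structure(list(intensity = intensity, samples = samples,
                   bait_id = d$bait_id),
              class = "IntensityMatrix")
  })
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat(sprintf("IntensityMatrix: %d proteins x %d samples (bait: %s)\n",
              nrow(x$intensity), ncol(x$intensity), x$bait_id))
  invisible(x)
}

#' Simulate per-intron coverage profiles with an optional IPA step-down
#'
#' Per-base depth is Poisson around `depth` upstream of the true site and
#' around `depth * (1 - usage_fraction)` downstream. `usage_fraction = 0`
#' yields a flat-mean profile with no site.
#'
#' @param annotation annotation with the `introns` list-column (only genes
#'   with at least one intron produce profiles; the first intron is used).
#' @param usage_fraction fraction of transcripts terminating at the intronic
#'   site, in \[0, 1\] (scalar or per-gene).
#' @param depth expected per-base read depth upstream (>= 1).
#' @param seed integer seed.
#' @param site_frac relative position of the true site within the intron
#'   (default 0.5, strictly inside).
#' @return a list of `CoverageProfile`s: `gene_id`, `intron` (c(start, end),
#'   0-based half-open), integer `depth` vector, `true_ipa_site` (position in
#'   intron coordinates or NA), `true_usage_fraction`.
#' @export
simulate_ipa_coverage <- function(annotation, usage_fraction, depth,
                                  seed = 1L, site_frac = 0.5) {
  if (any(usage_fraction < 0) || any(usage_fraction > 1))
    .config_error("usage_fraction must be in [0, 1]")
  if (depth < 1) .config_error("depth must be >= 1")
  keep <- vapply(annotation$introns, nrow, 0L) > 0L
  ann <- annotation[keep, , drop = FALSE]
  uf <- rep_len(usage_fraction, nrow(ann))
  .with_seed(substream_seed(seed, "ipa_coverage"), {
    lapply(seq_len(nrow(ann)), function(i) {
      iv <- ann$introns[[i]][1L, ]
      L <- iv$end - iv$start
      if (uf[i] == 0) {
        prof <- rpois(L, depth)
        site <- NA_integer_
      } else {
        site <- iv$start + max(1L, min(L - 1L, as.integer(floor(L * site_frac))))
        k <- site - iv$start
        prof <- c(rpois(k, depth), rpois(L - k, depth * (1 - uf[i])))
      }
      structure(list(gene_id = ann$gene_id[i],
                     intron = c(start = iv$start, end = iv$end),
                     depth = as.integer(prof),
                     true_ipa_site = site,
                     true_usage_fraction = uf[i]),
                class = "CoverageProfile")
    })
  })
}

#' Emit a small SAM file with MD tags encoding T>C mismatches
#'
#' I/O-testing convenience only: the counts-level simulator is canonical.
#' For each transcript a read-length reference window is built whose T
#' positions number `n_uridines`; each read is emitted as a full-length match
#' with T>C mismatches at a random subset of T positions, encoded in the MD
#' tag and SEQ field.
#'
#' @param annotation annotation subset (small).
#' @param model a [labeling_model()].
#' @param n_reads reads per transcript.
#' @param path output SAM path.
#' @param read_length read window length.
#' @param conversion_threshold unused here; conversions per read are drawn
#'   from the model exactly as in [simulate_slam_counts()].
#' @return invisibly, the data.frame of true per-read conversion counts
#'   (`read_id`, `transcript_id`, `n_ref_T`, `n_TC`).
#' @export
simulate_slam_sam <- function(annotation, model, n_reads, path,
                              read_length = 100L, conversion_threshold = 1L) {
  stopifnot(inherits(model, "labeling_model"))
  p_lab <- model$labeling_time_min * model$conversion_rate_per_min +
    model$background_error_rate
  .with_seed(substream_seed(model$seed, "slam_sam"), {
    lines <- c("@HD\tVN:1.6\tSO:unsorted")
    truth <- list()
    for (g in seq_len(nrow(annotation))) {
      nu <- annotation$n_uridines[g]
      gid <- annotation$gene_id[g]
      # reference window: nu T positions among A/G/C filler
      ref <- sample(c("A", "G", "C"), read_length, replace = TRUE)
      tpos <- sort(sample.int(read_length, nu))
      ref[tpos] <- "T"
      lines <- c(lines, sprintf("@SQ\tSN:%s\tLN:%d", gid, read_length))
      lf <- rep_len(model$labeled_fraction, nrow(annotation))[g]
      for (r in seq_len(n_reads)) {
        labeled <- runif(1) < lf
        p <- if (labeled) p_lab else model$background_error_rate
        conv <- tpos[runif(nu) < p]
        seq <- ref
        seq[conv] <- "C"
        md <- .build_md(ref, seq)
        rid <- sprintf("%s_r%04d", gid, r)
        lines <- c(lines, sprintf(
          "%s\t0\t%s\t1\t60\t%dM\t*\t0\t0\t%s\t*\tMD:Z:%s",
          rid, gid, read_length, paste(seq, collapse = ""), md))
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = rid, transcript_id = gid, n_ref_T = nu,
          n_TC = length(conv), stringsAsFactors = FALSE)
      }
    }
    writeLines(lines, path)
    invisible(do.call(rbind, truth))
  })
}

# MD tag for an ungapped alignment of equal-length ref/read vectors
.build_md <- function(ref, seq) {
  out <- character(0); run <- 0L
  for (i in seq_along(ref)) {
    if (ref[i] == seq[i]) run <- run + 1L
    else { out <- c(out, as.character(run), ref[i]); run <- 0L }
  }
  paste0(paste(out, collapse = ""), run)
}
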