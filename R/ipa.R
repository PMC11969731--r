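#' @title Intronic polyadenylation (IPA) detection from coverage
#' @description Simplified change-point scorer for composite IPA events:
#'   premature cleavage/polyadenylation inside an intron leaves a coverage
#'   step-down, scored as (mean upstream - mean downstream) / mean upstream
#'   at the best split. This is a transparent stand-in for population-level
#'   IPA callers; only within-run contrasts of event counts are meaningful,
#'   not absolute counts.
#' @name ipa
NULL

#' Score one intron coverage profile for an IPA event
#'
#' Scans every split position with at least `min_flank` bases on each side,
#' maximizing `(mean_up - mean_down) / mean_up` (ties to the leftmost
#' position; cumulative sums make the scan linear). An event is returned iff
#' `mean_up >= min_depth` and the score reaches `min_score`. Profiles
#' shorter than `2 * min_flank` are skipped with a warning.
#'
#' @param profile a `CoverageProfile` (see [simulate_ipa_coverage()]) or any
#'   list with `gene_id`, `intron = c(start, end)` and integer `depth`.
#' @param min_flank minimum bases on each side of the candidate site
#'   (default 100).
#' @param min_depth minimum upstream mean depth (default 10).
#' @param min_score minimum IPA score (default 0.25).
#' @return an `IPAEvent` list (`gene_id`, `intron`, `site`, `ipa_score`,
#'   `mean_up`, `mean_down`, `passed`) or `NULL` for flat/short profiles.
#'   `site` is in intron coordinates (0-based, strictly inside).
#' @export
score_ipa <- function(profile, min_flank = 100L, min_depth = 10,
                      min_score = 0.25) {
  d <- as.numeric(profile$depth)
  L <- length(d)
  if (L < 2L * min_flank) {
    warning(sprintf("intron of %s is shorter than 2 * min_flank (%d < %d); skipped",
                    profile$gene_id, L, 2L * min_flank), call. = FALSE)
    return(NULL)
  }
  cs <- cumsum(d); total <- cs[L]
  k <- seq.int(min_flank, L - min_flank)
  mean_up <- cs[k] / k
  mean_down <- (total - cs[k]) / (L - k)
  score <- ifelse(mean_up > 0, (mean_up - mean_down) / mean_up, -Inf)
  best <- which.max(score)  # which.max takes the leftmost maximum
  s <- score[best]; mu <- mean_up[best]; md <- mean_down[best]
  if (!is.finite(s) || md > mu) return(NULL)
  passed <- mu >= min_depth && s >= min_score
  if (!passed) return(NULL)
  structure(list(gene_id = profile$gene_id, intron = profile$intron,
                 site = unname(profile$intron["start"]) + k[best],
                 ipa_score = s, mean_up = mu, mean_down = md,
                 passed = TRUE),
            class = "IPAEvent")
}

#' Score a collection of profiles
#'
#' @param profiles list of `CoverageProfile`s.
#' @param sample_id sample label attached to each event.
#' @inheritParams score_ipa
#' @return data.frame of events (zero rows if none), columns `gene_id`,
#'   `sample`, `site`, `ipa_score`, `mean_up`, `mean_down`, `passed`.
#' @export
score_ipa_all <- function(profiles, sample_id = "S1", min_flank = 100L,
                          min_depth = 10, min_score = 0.25) {
  rows <- lapply(profiles, function(p) {
    ev <- score_ipa(p, min_flank, min_depth, min_score)
    if (is.null(ev)) return(NULL)
    data.frame(gene_id = ev$gene_id, sample = sample_id, site = ev$site,
               ipa_score = ev$ipa_score, mean_up = ev$mean_up,
               mean_down = ev$mean_down, passed = ev$passed,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene_id = character(0), sample = character(0),
                      site = integer(0), ipa_score = numeric(0),
                      mean_up = numeric(0), mean_down = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Count IPA events per sample
#'
#' @param events event data.frame from [score_ipa_all()] (may pool several
#'   samples).
#' @param pass_only count only passed events (default TRUE).
#' @return named integer vector of event counts per sample.
#' @export
count_ipa <- function(events, pass_only = TRUE) {
  if (!nrow(events)) return(integer(0))
  if (pass_only) events <- events[events$passed, , drop = FALSE]
  tab <- table(events$sample)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
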