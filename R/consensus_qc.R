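# Dual-caller consensus and quality-control cascade.
#
# Call-level filters: (1) consensus between the two callers at >= 10%
# overlap with matching direction; (2) confidence strictly above 2 (log-odds
# scale); (3) at least 5 markers and at least 4 kb; (4) at most 1 Mb.
# Sample-level filters: more than 110 calls, more than 7.5 Mb total CNV
# length, median copy-number variance above 2, or LRR SD above 0.4 removes
# the sample and all its calls. Rare calls with more than 50% of their bases
# inside segmental duplications are removed after stratification.

#' QC configuration
#'
#' All thresholds of the consensus/QC cascade with their defaults. The
#' inequalities are strict where the rule says "larger than" (so a call at
#' exactly LOD 2.0 is removed, a sample at exactly 110 calls is kept) and
#' inclusive where it says "less than" (a call of exactly 4,000 bases and 5
#' markers is kept).
#'
#' @param min_overlap_fraction Minimum fraction of the primary-caller call
#'   covered by a same-direction secondary-caller call (default 0.10).
#' @param min_confidence Calls must have confidence strictly above this
#'   log-odds score (default 2).
#' @param min_markers Minimum marker count, inclusive (default 5).
#' @param min_length Minimum call length in bases, inclusive (default 4000).
#' @param max_length Maximum call length in bases, inclusive (default 1e6).
#' @param max_calls_per_sample Samples with strictly more calls are removed
#'   (default 110).
#' @param max_total_length_per_sample Samples with strictly more total CNV
#'   bases are removed (default 7.5e6).
#' @param max_median_cn_variance Strict upper bound (default 2).
#' @param max_lrr_sd Strict upper bound (default 0.4).
#' @param max_segdup_fraction Rare calls with strictly more of their length
#'   inside segmental duplications are removed (default 0.5).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_overlap_fraction = 0.10,
                      min_confidence = 2,
                      min_markers = 5L,
                      min_length = 4000L,
                      max_length = 1000000L,
                      max_calls_per_sample = 110L,
                      max_total_length_per_sample = 7500000,
                      max_median_cn_variance = 2,
                      max_lrr_sd = 0.4,
                      max_segdup_fraction = 0.5) {
  cfg <- list(min_overlap_fraction = min_overlap_fraction,
              min_confidence = min_confidence,
              min_markers = min_markers,
              min_length = min_length,
              max_length = max_length,
              max_calls_per_sample = max_calls_per_sample,
              max_total_length_per_sample = max_total_length_per_sample,
              max_median_cn_variance = max_median_cn_variance,
              max_lrr_sd = max_lrr_sd,
              max_segdup_fraction = max_segdup_fraction)
  stopifnot(all(vapply(cfg, function(x) is.finite(x) && length(x) == 1,
                       TRUE)),
            cfg$min_overlap_fraction >= 0, cfg$min_overlap_fraction <= 1,
            cfg$min_length < cfg$max_length,
            cfg$max_segdup_fraction >= 0, cfg$max_segdup_fraction <= 1)
  structure(cfg, class = "qc_config")
}

#' Fraction of interval `a` covered by interval `b`
#'
#' Asymmetric by design: the denominator is the length of `a` (the
#' primary-caller call is authoritative for all downstream coordinates).
#' Intervals on different chromosomes overlap by 0. Vectorized over rows.
#'
#' @param a,b Data frames (or one-row lists) with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return Numeric vector in `[0, 1]`: shared bases divided by `length(a)`.
#' @export
overlap_fraction <- function(a, b) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start) + 1
  ov <- pmax(ov, 0) * (as.character(a$chrom) == as.character(b$chrom))
  ov / (a$end - a$start + 1)
}

#' Consensus between two callers
#'
#' A primary-caller call is kept if and only if the same sample has a
#' secondary-caller call in the same direction (both deletions or both
#' duplications) overlapping at least `min_overlap_fraction` of the primary
#' call. Kept calls retain the primary-caller boundaries. Samples present in
#' only one of the two call sets are dropped with a warning: their calls
#' cannot be confirmed.
#'
#' Direction must agree because a 1-copy and a 3-copy call at one locus are
#' contradictory evidence, not confirmation. The operation is idempotent.
#'
#' @param primary_calls,secondary_calls CNV call data frames.
#' @param cfg A [qc_config()].
#' @return The kept primary calls (same columns, original boundaries).
#' @export
consensus_calls <- function(primary_calls, secondary_calls,
                            cfg = qc_config()) {
  shared <- intersect(unique(primary_calls$sample_id),
                      unique(secondary_calls$sample_id))
  lonely <- setdiff(union(unique(primary_calls$sample_id),
                          unique(secondary_calls$sample_id)), shared)
  if (length(lonely))
    warning("sample(s) present in only one call set dropped: ",
            paste(lonely, collapse = ", "), call. = FALSE)
  p <- primary_calls[primary_calls$sample_id %in% shared, , drop = FALSE]
  s <- secondary_calls[secondary_calls$sample_id %in% shared, , drop = FALSE]
  if (nrow(p) == 0 || nrow(s) == 0) return(p[integer(0), , drop = FALSE])
  h <- GenomicRanges::findOverlaps(.calls_gr(p), .calls_gr(s))
  q <- S4Vectors::queryHits(h)
  j <- S4Vectors::subjectHits(h)
  ok <- p$sample_id[q] == s$sample_id[j] &
    (p$copy_number[q] < 2) == (s$copy_number[j] < 2)
  ov <- pmin(p$end[q], s$end[j]) - pmax(p$start[q], s$start[j]) + 1
  frac <- ov / (p$end[q] - p$start[q] + 1)
  keep <- sort(unique(q[ok & frac >= cfg$min_overlap_fraction]))
  p[keep, , drop = FALSE]
}

#' Call-level quality filters
#'
#' Keeps calls with confidence strictly above `min_confidence`, at least
#' `min_markers` markers, and length within `[min_length, max_length]`.
#' Calls with missing confidence or marker count (e.g. from the bed_like
#' dialect) fail the respective filter and are removed.
#'
#' @param calls CNV call data frame (consensus already applied).
#' @param cfg A [qc_config()].
#' @return The surviving calls.
#' @export
filter_call_quality <- function(calls, cfg = qc_config()) {
  len <- cnv_length(calls)
  keep <- !is.na(calls$confidence) & calls$confidence > cfg$min_confidence &
    !is.na(calls$n_markers) & calls$n_markers >= cfg$min_markers &
    len >= cfg$min_length & len <= cfg$max_length
  calls[keep, , drop = FALSE]
}

#' Sample-level filters
#'
#' Recomputes `n_calls` and `total_cnv_length` from the surviving calls and
#' removes a sample (with all its calls) when any of the four rules fires:
#' more than `max_calls_per_sample` calls, total CNV length above
#' `max_total_length_per_sample`, `median_cn_variance` above its bound, or
#' `lrr_sd` above its bound. The two array-quality metrics are input
#' metadata and must be present (`NA` is an error naming the sample):
#' silently passing an unmeasured sample would bias the cohort.
#'
#' @param calls CNV call data frame after call-level filters.
#' @param samples Sample table from [read_sample_table()].
#' @param cfg A [qc_config()].
#' @return `list(samples, calls, report)` where `report` is a data frame of
#'   per-filter sample removal counts in application order.
#' @export
filter_samples <- function(calls, samples, cfg = qc_config()) {
  stray <- setdiff(unique(calls$sample_id), samples$sample_id)
  if (length(stray))
    stop("call(s) from sample(s) absent from the sample table: ",
         paste(stray, collapse = ", "), call. = FALSE)
  n_calls <- as.integer(table(factor(calls$sample_id,
                                     levels = samples$sample_id)))
  tot_len <- vapply(split(cnv_length(calls),
                          factor(calls$sample_id,
                                 levels = samples$sample_id)),
                    sum, 0)
  miss <- is.na(samples$median_cn_variance) | is.na(samples$lrr_sd)
  if (any(miss))
    stop("missing QC metric(s) for sample(s): ",
         paste(samples$sample_id[miss], collapse = ", "), call. = FALSE)
  drop_calls <- n_calls > cfg$max_calls_per_sample
  drop_len <- tot_len > cfg$max_total_length_per_sample
  drop_var <- samples$median_cn_variance > cfg$max_median_cn_variance
  drop_lrr <- samples$lrr_sd > cfg$max_lrr_sd
  drop <- drop_calls | drop_len | drop_var | drop_lrr
  report <- data.frame(
    filter = c("sample_n_calls", "sample_total_length",
               "sample_cn_variance", "sample_lrr_sd"),
    n_removed = c(sum(drop_calls),
                  sum(drop_len & !drop_calls),
                  sum(drop_var & !drop_calls & !drop_len),
                  sum(drop_lrr & !drop_calls & !drop_len & !drop_var)),
    unit = "samples", stringsAsFactors = FALSE)
  kept <- samples[!drop, , drop = FALSE]
  kept$n_calls <- n_calls[!drop]
  kept$total_cnv_length <- unname(tot_len[!drop])
  list(samples = kept,
       calls = calls[calls$sample_id %in% kept$sample_id, , drop = FALSE],
       report = report)
}

# Fraction of each call covered by the union of the regions.
.segdup_cover_fraction <- function(calls, regions) {
  if (nrow(calls) == 0) return(numeric(0))
  if (is.null(regions) || nrow(regions) == 0) return(rep(0, nrow(calls)))
  red <- GenomicRanges::reduce(.calls_gr(regions))
  cg <- .calls_gr(calls)
  h <- GenomicRanges::findOverlaps(cg, red)
  q <- S4Vectors::queryHits(h)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    cg[q], red[S4Vectors::subjectHits(h)]))
  covered <- vapply(split(ov, factor(q, levels = seq_len(nrow(calls)))),
                    sum, 0)
  unname(covered) / cnv_length(calls)
}

#' Segmental-duplication filter for rare calls
#'
#' Removes a call when strictly more than `max_segdup_fraction` of its bases
#' lie inside the union of the segmental-duplication regions (overlapping
#' reference fragments are merged first so shared bases are not counted
#' twice). Applied to the rare stratum only, after [classify_calls()]:
#' such regions are prone to artifactual calls.
#'
#' @param rare_calls Rare-stratum CNV call data frame.
#' @param segdup_regions Data frame `chrom, start, end` (1-based inclusive),
#'   e.g. from [read_region_bed()].
#' @param cfg A [qc_config()].
#' @return The surviving calls.
#' @export
filter_segdup <- function(rare_calls, segdup_regions, cfg = qc_config()) {
  frac <- .segdup_cover_fraction(rare_calls, segdup_regions)
  rare_calls[frac <= cfg$max_segdup_fraction, , drop = FALSE]
}

#' Run the consensus + call-level + sample-level QC cascade
#'
#' Applies, in order: dual-caller consensus, the call-quality filters, and
#' the sample-level filters. The segmental-duplication filter is *not*
#' included here because it applies only to the rare stratum, which is not
#' known until after [classify_calls()]; see [run_cnv_pipeline()] for the
#' full cascade.
#'
#' @param primary_calls,secondary_calls CNV call data frames.
#' @param samples Sample table.
#' @param cfg A [qc_config()].
#' @return `list(calls, samples, report)`; `report` counts removals per
#'   filter in application order (calls for call-level filters, samples for
#'   sample-level ones).
#' @export
run_qc <- function(primary_calls, secondary_calls, samples,
                   cfg = qc_config()) {
  n0 <- nrow(primary_calls)
  cons <- consensus_calls(primary_calls, secondary_calls, cfg)
  n1 <- nrow(cons)
  conf <- cons[!is.na(cons$confidence) &
                 cons$confidence > cfg$min_confidence, , drop = FALSE]
  n2 <- nrow(conf)
  len <- cnv_length(conf)
  small <- conf[!is.na(conf$n_markers) & conf$n_markers >= cfg$min_markers &
                  len >= cfg$min_length, , drop = FALSE]
  n3 <- nrow(small)
  big <- small[cnv_length(small) <= cfg$max_length, , drop = FALSE]
  n4 <- nrow(big)
  fs <- filter_samples(big, samples, cfg)
  call_report <- data.frame(
    filter = c("consensus", "confidence", "markers_or_min_length",
               "max_length", "sample_filters"),
    n_removed = c(n0 - n1, n1 - n2, n2 - n3, n3 - n4, n4 - nrow(fs$calls)),
    unit = "calls", stringsAsFactors = FALSE)
  list(calls = fs$calls, samples = fs$samples,
       report = rbind(call_report, fs$report))
}
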