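# CNV regions and the maximum-stack carrier-frequency rule.
#
# A CNV region is a connected component of the interval-overlap graph of the
# QC-passed calls on one chromosome (overlap means sharing at least one
# base; merely adjacent calls are separate regions). The carrier frequency
# of a region is taken at the locus inside the region where the largest
# number of distinct samples stack, divided by the cohort size. Regions at
# frequency above 1% are "common", all others "rare"; a region at exactly 1%
# is rare.

#' Merge overlapping calls into CNV regions
#'
#' @param calls QC-passed CNV call data frame.
#' @return A list of class `cnv_regions` with elements `regions` (data frame
#'   `region_id, chrom, start, end, n_calls, n_samples, max_stack_count,
#'   locus_start, locus_end`, sorted by `(chrom, start)`) and `call_region`
#'   (integer region id per input call row). The region span is the union
#'   envelope of the member calls; the locus columns give the leftmost
#'   interval attaining the maximum distinct-sample stack depth.
#' @export
merge_regions <- function(calls) {
  if (nrow(calls) == 0) {
    regions <- data.frame(region_id = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          n_calls = integer(0), n_samples = integer(0),
                          max_stack_count = integer(0),
                          locus_start = integer(0), locus_end = integer(0))
    return(structure(list(regions = regions, call_region = integer(0)),
                     class = "cnv_regions"))
  }
  gr <- .calls_gr(calls)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  h <- GenomicRanges::findOverlaps(gr, red)
  raw_region <- S4Vectors::subjectHits(h)[order(S4Vectors::queryHits(h))]
  stopifnot(length(raw_region) == nrow(calls))
  # deterministic region numbering by (chrom, start), independent of the
  # input call order and of GRanges seqlevel ordering
  rchrom <- as.character(GenomicRanges::seqnames(red))
  rstart <- GenomicRanges::start(red)
  rend <- GenomicRanges::end(red)
  ord <- order(rchrom, rstart, rend)
  new_id <- integer(length(ord))
  new_id[ord] <- seq_along(ord)
  call_region <- new_id[raw_region]
  idx <- split(seq_len(nrow(calls)), call_region)
  stacks <- lapply(idx, function(i) stack_max(calls[i, , drop = FALSE]))
  rid <- as.integer(names(idx))
  regions <- data.frame(
    region_id = rid,
    chrom = rchrom[ord][rid],
    start = rstart[ord][rid],
    end = rend[ord][rid],
    n_calls = unname(lengths(idx)),
    n_samples = vapply(idx, function(i) length(unique(calls$sample_id[i])),
                       0L, USE.NAMES = FALSE),
    max_stack_count = vapply(stacks, `[[`, 0L, "max_stack_count",
                             USE.NAMES = FALSE),
    locus_start = vapply(stacks, `[[`, 0L, "locus_start",
                         USE.NAMES = FALSE),
    locus_end = vapply(stacks, `[[`, 0L, "locus_end", USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  regions <- regions[order(regions$region_id), , drop = FALSE]
  row.names(regions) <- NULL
  structure(list(regions = regions, call_region = call_region),
            class = "cnv_regions")
}

#' Maximum distinct-sample stack of a region
#'
#' Sweep over the member-call breakpoints and return the leftmost interval
#' where the number of distinct samples with an overlapping call is
#' maximal. A sample with several mutually overlapping calls counts once at
#' any base (its calls are unioned per sample before the sweep).
#'
#' @param calls Member calls of one region (single chromosome).
#' @return `list(locus_start, locus_end, max_stack_count)`.
#' @export
stack_max <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  if (length(unique(calls$chrom)) != 1)
    stop("stack_max expects calls from a single chromosome", call. = FALSE)
  ir <- IRanges::IRanges(calls$start, calls$end)
  per_sample <- unlist(IRanges::reduce(
    IRanges::IRangesList(split(ir, calls$sample_id))))
  cov <- IRanges::coverage(per_sample)
  depth <- max(S4Vectors::runValue(cov))
  v <- IRanges::slice(cov, lower = depth)
  list(locus_start = IRanges::start(v)[1],
       locus_end = IRanges::end(v)[1],
       max_stack_count = as.integer(depth))
}

#' Stratify calls into common and rare
#'
#' Builds CNV regions, computes each region's carrier frequency as
#' `max_stack_count / n_samples`, labels it `common` when the frequency is
#' strictly above `threshold` and `rare` otherwise (a region at exactly the
#' threshold is rare), and propagates the region label to every member
#' call.
#'
#' By default deletions and duplications are pooled when stacking
#' ("any type of aberration"); `direction = "del"` or `"dup"` restricts the
#' region construction and frequencies to one direction, in which case calls
#' of the other direction get an `NA` stratum.
#'
#' @param calls QC-passed CNV call data frame.
#' @param n_samples Cohort size (cases + controls) used as the frequency
#'   denominator.
#' @param threshold Common/rare frequency threshold (default 0.01).
#' @param direction `"any"` (default), `"del"` or `"dup"`.
#' @return `calls` with added columns `stratum` (`"common"`/`"rare"`),
#'   `region_id` and `region_frequency`; the `cnv_regions` object (with
#'   `frequency` and `stratum` columns added) is attached as attribute
#'   `regions`.
#' @export
classify_calls <- function(calls, n_samples, threshold = 0.01,
                           direction = c("any", "del", "dup")) {
  direction <- match.arg(direction)
  stopifnot(n_samples > 0)
  use <- switch(direction,
                any = rep(TRUE, nrow(calls)),
                del = calls$copy_number < 2,
                dup = calls$copy_number > 2)
  rg <- merge_regions(calls[use, , drop = FALSE])
  reg <- rg$regions
  reg$frequency <- reg$max_stack_count / n_samples
  reg$stratum <- ifelse(reg$frequency > threshold, "common", "rare")
  calls$stratum <- NA_character_
  calls$region_id <- NA_integer_
  calls$region_frequency <- NA_real_
  if (any(use)) {
    calls$region_id[use] <- rg$call_region
    m <- match(rg$call_region, reg$region_id)
    calls$stratum[use] <- reg$stratum[m]
    calls$region_frequency[use] <- reg$frequency[m]
  }
  attr(calls, "regions") <- structure(
    list(regions = reg, call_region = rg$call_region),
    class = "cnv_regions")
  calls
}
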