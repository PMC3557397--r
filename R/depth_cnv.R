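# Copy-number estimation from targeted-sequencing read counts.
#
# The depth ratio is the region read count normalized by region length and
# by the sample's total read count (scaled by 1e9 for readability); it is
# proportional to copy number. Exact zeros are homozygous deletions (no
# template DNA, no reads) and are assigned copy number 0 before clustering;
# the remaining ratios are split into clusters by exact one-dimensional
# partitioning (no random initialization), and clusters map to increasing
# copy numbers in increasing ratio order.

#' Sequence depth ratio
#'
#' `ratio = region_reads / region_length / total_reads * 1e9`. The scale
#' constant 1e9 puts typical targeted-capture values near 0.1-10.
#' Vectorized.
#'
#' @param region_reads Reads mapped in the target region (>= 0).
#' @param region_length Region length in bases (> 0).
#' @param total_reads Total mapped reads of the sample (> 0).
#' @return Numeric depth ratio; 0 iff `region_reads` is 0.
#' @export
depth_ratio <- function(region_reads, region_length, total_reads) {
  if (any(total_reads <= 0))
    stop("total_reads must be positive (sample-level failure)",
         call. = FALSE)
  if (any(region_length <= 0))
    stop("region_length must be positive", call. = FALSE)
  stopifnot(all(region_reads >= 0))
  region_reads / region_length / total_reads * 1e9
}

#' Read a per-region read-count table
#'
#' Tab-delimited with header and columns `sample_id, region, region_length,
#' region_reads, total_reads`; the depth ratio is computed and appended.
#'
#' @param path Path to the table.
#' @return Data frame with a `ratio` column added.
#' @export
read_depth_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("sample_id", "region", "region_length", "region_reads",
            "total_reads")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$ratio <- depth_ratio(df$region_reads, df$region_length,
                          df$total_reads)
  df
}

# exact 1-D partition of sorted values into g groups minimizing the
# within-group sum of squares (dynamic programming over split points)
.optimal_1d_partition <- function(x_sorted, g) {
  n <- length(x_sorted)
  cs <- cumsum(x_sorted)
  cs2 <- cumsum(x_sorted^2)
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, g, n)
  B <- matrix(1L, g, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (g > 1) {
    for (k in 2:g) {
      for (j in k:n) {
        best <- Inf
        bi <- k
        for (i in k:j) {
          v <- D[k - 1, i - 1] + sse(i, j)
          if (v < best - 1e-12) {
            best <- v
            bi <- i
          }
        }
        D[k, j] <- best
        B[k, j] <- bi
      }
    }
  }
  grp <- integer(n)
  j <- n
  for (k in g:1) {
    i <- B[k, j]
    grp[i:j] <- k
    j <- i - 1
    if (j < 1) break
  }
  grp
}

#' Cluster depth ratios into copy numbers
#'
#' Ratios exactly 0 are pre-assigned copy number 0 (homozygous deletion:
#' no template, no reads). The remaining ratios are clustered into `k - 1`
#' groups by exact one-dimensional partitioning (dynamic programming
#' minimizing the within-cluster sum of squares — deterministic, no random
#' initialization), and clusters are mapped to copy numbers 1, 2, ... in
#' increasing ratio order. With fewer distinct nonzero values than
#' requested clusters, the clustering collapses to the available count
#' with a warning.
#'
#' `anchor_sample` names a reference sample of known copy number 2; the
#' nonzero cluster labels are shifted so that its cluster is labelled 2.
#' This guards against the mislabelling that occurs when software assumes
#' the most common state is the diploid one while the population actually
#' carries a deletion allele at high frequency.
#'
#' @param ratios Named numeric vector of depth ratios (names = sample ids).
#' @param k Total number of copy-number classes including the zero class
#'   (default 3: homozygous deletion, heterozygous deletion, two copies).
#' @param anchor_sample Optional sample id of known copy number 2.
#' @return Named integer vector of copy numbers.
#' @export
cluster_copy_number <- function(ratios, k = 3, anchor_sample = NULL) {
  stopifnot(is.numeric(ratios), k >= 2)
  if (length(ratios) < k)
    stop("need at least k samples to resolve k classes", call. = FALSE)
  cn <- stats::setNames(integer(length(ratios)), names(ratios))
  nz <- which(ratios > 0)
  if (length(nz)) {
    g <- k - 1L
    vals <- ratios[nz]
    d <- length(unique(vals))
    if (d < g) {
      warning("only ", d, " distinct nonzero ratio value(s); collapsing to ",
              d, " cluster(s)", call. = FALSE)
      g <- d
    }
    ord <- order(vals)
    grp_sorted <- .optimal_1d_partition(vals[ord], g)
    grp <- integer(length(vals))
    grp[ord] <- grp_sorted            # groups already in ascending order
    cn[nz] <- grp                     # lowest-ratio cluster -> CN 1
  }
  if (!is.null(anchor_sample)) {
    if (!anchor_sample %in% names(ratios))
      stop("anchor sample not found: ", anchor_sample, call. = FALSE)
    if (ratios[[anchor_sample]] == 0)
      stop("anchor sample has zero depth ratio; cannot anchor copy number 2",
           call. = FALSE)
    offset <- 2L - cn[[anchor_sample]]
    cn[nz] <- pmax(0L, cn[nz] + offset)
  }
  cn
}

#' Concordance between two cluster assignments
#'
#' Counts the samples placed in the same cluster by both assignments after
#' optimal label matching (the labelling of a clustering is arbitrary, so
#' agreement is maximized over label permutations; exhaustive for the small
#' k used here).
#'
#' @param assignment_a,assignment_b Named integer/factor vectors of cluster
#'   labels; compared on the shared sample ids.
#' @return `c(n_agree, n_total)`.
#' @export
cluster_concordance <- function(assignment_a, assignment_b) {
  shared <- intersect(names(assignment_a), names(assignment_b))
  if (!length(shared))
    stop("assignments share no sample ids", call. = FALSE)
  a <- as.vector(assignment_a[shared])
  b <- as.vector(assignment_b[shared])
  labs <- sort(unique(c(a, b)))
  if (length(labs) > 6)
    stop("label matching supports at most 6 distinct labels", call. = FALSE)
  perms <- .permutations(labs)
  best <- 0L
  for (p in perms) {
    m <- stats::setNames(p, labs)
    best <- max(best, sum(a == m[as.character(b)]))
  }
  c(n_agree = as.integer(best), n_total = length(shared))
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}
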