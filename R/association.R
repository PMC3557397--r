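# Exact 2x2 carrier inference and the permutation machinery shared by the
# locus, gene and pathway analyses.
#
# Carrier tables are (a, b, c, d) = (case carriers, case non-carriers,
# control carriers, control non-carriers). Inference conditions on the
# margins: the two-sided p sums hypergeometric probabilities no larger than
# the observed table's (relative tolerance 1e-7), and the odds ratio is the
# conditional maximum-likelihood estimate under the noncentral
# hypergeometric likelihood with its exact confidence interval.

.check_table <- function(a, b, cc, d) {
  stopifnot(length(a) == 1, length(b) == 1, length(cc) == 1, length(d) == 1,
            a >= 0, b >= 0, cc >= 0, d >= 0,
            a == round(a), b == round(b), cc == round(cc), d == round(d))
}

#' Two-sided Fisher exact test of a 2x2 carrier table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, with
#' margins fixed, of every table whose point probability is no larger than
#' the observed one (relative tolerance 1e-7 to absorb floating point).
#' A table with a zero margin (no carriers at all, or everyone a carrier)
#' carries no information and returns p = 1 by convention.
#'
#' @param a,b Case carriers and non-carriers.
#' @param cc,d Control carriers and non-carriers.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(5, 184, 0, 380)  # 0.0039
#' @export
fisher_exact <- function(a, b, cc, d) {
  .check_table(a, b, cc, d)
  if ((a + cc) == 0 || (b + d) == 0 || (a + b) == 0 || (cc + d) == 0)
    return(1)
  stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2,
                            byrow = TRUE))$p.value
}

#' Conditional maximum-likelihood odds ratio with exact CI
#'
#' The estimate maximizes the noncentral hypergeometric conditional
#' likelihood of the table; the confidence interval inverts the exact
#' conditional test. A zero carrier cell on one side gives an infinite (or
#' zero) estimate with a finite one-sided bound; a table with no carriers
#' on either side is uninformative and reported as missing.
#'
#' @param a,b,cc,d Carrier table cells as in [fisher_exact()].
#' @param conf_level Confidence level (default 0.95).
#' @return `list(estimate, ci_low, ci_high)`.
#' @examples
#' odds_ratio_cmle(10, 179, 6, 374)$estimate  # 3.47
#' @export
odds_ratio_cmle <- function(a, b, cc, d, conf_level = 0.95) {
  .check_table(a, b, cc, d)
  if (a == 0 && cc == 0) {
    warning("no carriers in either group; odds ratio undefined",
            call. = FALSE)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                           conf.level = conf_level)
  list(estimate = unname(ft$estimate),
       ci_low = ft$conf.int[1],
       ci_high = ft$conf.int[2])
}

# p-value lookup for carrier tables sharing the group sizes: P[k+1, a+1] is
# the two-sided Fisher p for a case carriers out of k total carriers.
# Permutations only move carriers between groups, so (k, a) determines the
# table and the battery reduces to indexing this matrix.
.fisher_p_lookup <- function(n_cases, n_controls, kmax) {
  P <- matrix(NA_real_, kmax + 1, kmax + 1)
  for (k in 0:kmax) {
    for (a in max(0, k - n_controls):min(k, n_cases)) {
      P[k + 1, a + 1] <- fisher_exact(a, n_cases - a,
                                      k - a, n_controls - (k - a))
    }
  }
  P
}

#' Permutation min-p family-wise error control
#'
#' Re-runs a battery of tests under case/control label permutation, keeping
#' the carrier structure fixed, and compares each observed p-value against
#' the permutation distribution of the *minimum* p across the battery. This
#' controls the family-wise error rate: `p_empirical(i) =
#' (1 + #\{perm : min_p(perm) <= p_obs(i)\}) / (n_perm + 1)`. The add-one
#' estimator never returns zero, so `p_empirical >= 1/(n_perm+1)`.
#'
#' @param test_battery Function taking a phenotype vector (`"case"` /
#'   `"control"`, one per sample, order fixed) and returning the vector of
#'   unadjusted p-values, deterministically.
#' @param phenotypes Observed phenotype vector.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional RNG seed for the permutation stream.
#' @return Vector of empirical p-values aligned with the battery output.
#' @export
minp_permutation <- function(test_battery, phenotypes, n_perm, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  p_obs <- test_battery(phenotypes)
  if (!length(p_obs)) return(numeric(0))
  if (!is.null(seed)) set.seed(seed)
  mins <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    mins[i] <- min(test_battery(sample(phenotypes)))
  }
  tol <- 1 + 1e-12
  vapply(p_obs, function(p) (1 + sum(mins <= p * tol)) / (n_perm + 1), 0)
}

# carrier incidence: features x samples logical matrix (>=1 overlapping
# call of the requested direction, counted once per sample per feature)
.carrier_matrix <- function(calls, feature_gr, feature_ids, sample_ids,
                            direction = c("any", "del", "dup")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 any = rep(TRUE, nrow(calls)),
                 del = calls$copy_number < 2,
                 dup = calls$copy_number > 2)
  calls <- calls[keep, , drop = FALSE]
  M <- matrix(0, length(feature_ids), length(sample_ids),
              dimnames = list(feature_ids, sample_ids))
  if (nrow(calls) == 0) return(M)
  h <- GenomicRanges::findOverlaps(feature_gr, .calls_gr(calls))
  if (length(h)) {
    si <- match(calls$sample_id[S4Vectors::subjectHits(h)], sample_ids)
    ok <- !is.na(si)
    M[cbind(S4Vectors::queryHits(h)[ok], si[ok])] <- 1
  }
  M
}

.pheno_vec <- function(samples) {
  stats::setNames(samples$phenotype, samples$sample_id)
}

#' Per-gene carrier counts of rare CNVs
#'
#' A sample is a carrier for a gene when at least one of its rare calls
#' shares at least one base with the gene interval (no minimum overlap
#' fraction); a sample counts once per gene regardless of how many calls
#' hit it.
#'
#' @param rare_calls Rare-stratum CNV call data frame.
#' @param genes Gene models from [read_gene_models()].
#' @param samples Sample table (defines the cohort and phenotypes).
#' @param direction Restrict to deletions, duplications, or any (default).
#' @return Data frame per gene: `symbol, a, b, c, d, n_carriers` where
#'   `(a, b, c, d)` is the carrier table.
#' @export
gene_carrier_counts <- function(rare_calls, genes, samples,
                                direction = "any") {
  M <- .carrier_matrix(rare_calls, .calls_gr(genes), genes$symbol,
                       samples$sample_id, direction)
  case <- samples$phenotype == "case"
  a <- as.vector(M %*% as.numeric(case))
  k <- rowSums(M)
  data.frame(symbol = genes$symbol,
             a = as.integer(a),
             b = as.integer(sum(case) - a),
             c = as.integer(k - a),
             d = as.integer(sum(!case) - (k - a)),
             n_carriers = as.integer(k),
             stringsAsFactors = FALSE, row.names = NULL)
}

# shared battery/permutation core for carrier-matrix associations
.carrier_association <- function(M, samples, n_perm, seed) {
  case <- samples$phenotype == "case"
  n_cases <- sum(case)
  n_controls <- sum(!case)
  k <- rowSums(M)
  P <- .fisher_p_lookup(n_cases, n_controls, max(k))
  battery <- function(pheno) {
    a <- as.vector(M %*% as.numeric(pheno == "case"))
    P[cbind(k + 1, a + 1)]
  }
  p_emp <- minp_permutation(battery, samples$phenotype, n_perm, seed)
  a <- as.vector(M %*% as.numeric(case))
  p_obs <- P[cbind(k + 1, a + 1)]
  or <- lapply(seq_along(k), function(i)
    odds_ratio_cmle(a[i], n_cases - a[i], k[i] - a[i],
                    n_controls - (k[i] - a[i])))
  n <- n_cases + n_controls
  data.frame(a = as.integer(a),
             b = as.integer(n_cases - a),
             c = as.integer(k - a),
             d = as.integer(n_controls - (k - a)),
             p_unadjusted = p_obs,
             p_empirical = p_emp,
             odds_ratio = vapply(or, `[[`, 0, "estimate"),
             ci_low = vapply(or, `[[`, 0, "ci_low"),
             ci_high = vapply(or, `[[`, 0, "ci_high"),
             pct_cases = 100 * a / n,
             pct_controls = 100 * (k - a) / n,
             pct_cases_within = 100 * a / n_cases,
             pct_controls_within = 100 * (k - a) / n_controls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-level rare-CNV association with permutation FWER control
#'
#' Fisher's exact test per gene on the carrier table, with empirical
#' genome-wide p-values from the permutation min-p procedure over the whole
#' gene battery ([minp_permutation()]). Genes with no carriers in the cohort
#' are skipped. Carrier percentages are reported both over the combined
#' cohort (`pct_*`, the table convention) and within each group
#' (`pct_*_within`).
#'
#' @inheritParams gene_carrier_counts
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return Data frame per tested gene, sorted by `p_unadjusted`: carrier
#'   table, `p_unadjusted`, `p_empirical`, CMLE odds ratio with exact CI,
#'   and carrier percentages. Attributes `n_perm` and `seed` record the
#'   permutation settings.
#' @export
gene_association <- function(rare_calls, genes, samples, n_perm = 1000,
                             seed = NULL, direction = "any") {
  M <- .carrier_matrix(rare_calls, .calls_gr(genes), genes$symbol,
                       samples$sample_id, direction)
  M <- M[rowSums(M) > 0, , drop = FALSE]
  if (nrow(M) == 0) {
    return(data.frame(symbol = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p_unadjusted = numeric(0), p_empirical = numeric(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), pct_cases = numeric(0),
                      pct_controls = numeric(0),
                      pct_cases_within = numeric(0),
                      pct_controls_within = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- suppressWarnings(.carrier_association(M, samples, n_perm, seed))
  res <- cbind(data.frame(symbol = rownames(M), stringsAsFactors = FALSE),
               res)
  res <- res[order(res$p_unadjusted, res$symbol), , drop = FALSE]
  row.names(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}

#' Locus scan over common CNVs
#'
#' Test loci are the breakpoint-bounded elementary intervals of the stacked
#' common calls (of the requested direction). At each locus a sample is a
#' carrier when at least one of its calls covers the locus. Consecutive
#' loci with identical carrier sets are collapsed into one test.
#' Edge loci — the first or last locus of a region whose carrier set is a
#' strict subset of its inner neighbour's — arise only from boundary
#' truncation of the wider calls and are excluded.
#'
#' @param common_calls Common-stratum CNV call data frame.
#' @param samples Sample table.
#' @param direction `"any"` (default), `"del"` or `"dup"`.
#' @return Data frame per kept locus: `chrom, start, end, a, b, c, d,
#'   p_unadjusted, odds_ratio, ci_low, ci_high` plus a list column
#'   `carriers` of carrier sample ids (used by [locus_association()]).
#'   The number of edge-excluded loci is recorded in attribute
#'   `n_edge_excluded`.
#' @export
locus_scan <- function(common_calls, samples,
                       direction = c("any", "del", "dup")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 any = rep(TRUE, nrow(common_calls)),
                 del = common_calls$copy_number < 2,
                 dup = common_calls$copy_number > 2)
  calls <- common_calls[keep, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      p_unadjusted = numeric(0), odds_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0))
  empty$carriers <- list()
  if (nrow(calls) == 0) {
    attr(empty, "n_edge_excluded") <- 0L
    return(empty)
  }
  case <- samples$phenotype == "case"
  n_cases <- sum(case)
  n_controls <- sum(!case)
  is_case <- stats::setNames(case, samples$sample_id)
  loci <- list()
  n_edge <- 0L
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(cc$start, cc$end + 1L)))
    if (length(bp) < 2) next
    st <- bp[-length(bp)]
    en <- bp[-1] - 1L
    grid <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, en))
    h <- GenomicRanges::findOverlaps(grid, .calls_gr(cc))
    covered <- sort(unique(S4Vectors::queryHits(h)))
    if (!length(covered)) next
    carr <- lapply(split(cc$sample_id[S4Vectors::subjectHits(h)],
                         factor(S4Vectors::queryHits(h), levels = covered)),
                   function(s) sort(unique(s)))
    st <- st[covered]
    en <- en[covered]
    # region envelope: connected components of the covered intervals
    region <- cumsum(c(1L, as.integer(st[-1] > en[-length(en)] + 1L)))
    key <- vapply(carr, paste, "", collapse = ";")
    for (r in unique(region)) {
      ri <- which(region == r)
      runs <- rle(key[ri])
      idx_end <- cumsum(runs$lengths)
      idx_start <- idx_end - runs$lengths + 1L
      loc <- data.frame(chrom = ch,
                        start = st[ri[idx_start]],
                        end = en[ri[idx_end]],
                        stringsAsFactors = FALSE)
      loc_carr <- carr[ri[idx_start]]
      nl <- nrow(loc)
      drop_edge <- rep(FALSE, nl)
      if (nl > 1) {
        first_sub <- all(loc_carr[[1]] %in% loc_carr[[2]]) &&
          length(loc_carr[[1]]) < length(loc_carr[[2]])
        last_sub <- all(loc_carr[[nl]] %in% loc_carr[[nl - 1]]) &&
          length(loc_carr[[nl]]) < length(loc_carr[[nl - 1]])
        drop_edge[1] <- first_sub
        drop_edge[nl] <- last_sub
      }
      n_edge <- n_edge + sum(drop_edge)
      loc <- loc[!drop_edge, , drop = FALSE]
      loc_carr <- loc_carr[!drop_edge]
      if (nrow(loc)) {
        loc$carriers <- unname(loc_carr)
        loci[[length(loci) + 1]] <- loc
      }
    }
  }
  if (!length(loci)) {
    attr(empty, "n_edge_excluded") <- n_edge
    return(empty)
  }
  out <- do.call(rbind, loci)
  a <- vapply(out$carriers, function(s) sum(is_case[s]), 0)
  k <- lengths(out$carriers)
  out$a <- as.integer(a)
  out$b <- as.integer(n_cases - a)
  out$c <- as.integer(k - a)
  out$d <- as.integer(n_controls - (k - a))
  out$p_unadjusted <- mapply(fisher_exact, out$a, out$b, out$c, out$d)
  or <- suppressWarnings(
    mapply(function(a, b, cc, d) odds_ratio_cmle(a, b, cc, d),
           out$a, out$b, out$c, out$d, SIMPLIFY = FALSE))
  out$odds_ratio <- vapply(or, `[[`, 0, "estimate")
  out$ci_low <- vapply(or, `[[`, 0, "ci_low")
  out$ci_high <- vapply(or, `[[`, 0, "ci_high")
  out <- out[, c("chrom", "start", "end", "a", "b", "c", "d",
                 "p_unadjusted", "odds_ratio", "ci_low", "ci_high",
                 "carriers")]
  row.names(out) <- NULL
  attr(out, "n_edge_excluded") <- n_edge
  out
}

#' Locus association of common CNVs with permutation FWER control
#'
#' Runs [locus_scan()] and attaches empirical genome-wide p-values from the
#' permutation min-p procedure over the locus battery.
#'
#' @inheritParams locus_scan
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional RNG seed.
#' @return The [locus_scan()] table with a `p_empirical` column (the
#'   `carriers` list column is dropped).
#' @export
locus_association <- function(common_calls, samples, n_perm = 1000,
                              seed = NULL, direction = "any") {
  sc <- locus_scan(common_calls, samples, direction)
  if (nrow(sc) == 0) {
    sc$p_empirical <- numeric(0)
    sc$carriers <- NULL
    return(sc)
  }
  M <- matrix(0, nrow(sc), nrow(samples),
              dimnames = list(NULL, samples$sample_id))
  for (i in seq_len(nrow(sc))) M[i, sc$carriers[[i]]] <- 1
  case <- samples$phenotype == "case"
  k <- rowSums(M)
  P <- .fisher_p_lookup(sum(case), sum(!case), max(k))
  battery <- function(pheno) {
    a <- as.vector(M %*% as.numeric(pheno == "case"))
    P[cbind(k + 1, a + 1)]
  }
  sc$p_empirical <- minp_permutation(battery, samples$phenotype, n_perm,
                                     seed)
  sc$carriers <- NULL
  attr(sc, "n_perm") <- n_perm
  attr(sc, "seed") <- seed
  sc
}

#' Flag likely false positives against a known-CNV reference
#'
#' A significant gene is flagged when some reference region overlapping the
#' gene has a reported population frequency at least as high as the gene's
#' case carrier frequency: a "hit" seen just as often in reference
#' populations is most parsimoniously an artifact or a benign polymorphism,
#' not a case association. Genes absent from the reference are never
#' flagged.
#'
#' @param results A [gene_association()] result (needs `symbol`, `a`, `b`
#'   and `p_empirical`).
#' @param known_cnv_regions Reference regions with a `frequency` column,
#'   e.g. from `read_region_bed(path, frequency_col = TRUE)`.
#' @param genes Gene models giving the coordinates of the result genes.
#' @param alpha Significance threshold on `p_empirical` (default 0.05);
#'   only significant genes are assessed.
#' @return `results` with a logical `known_cnv_flag` column.
#' @export
dgv_flag <- function(results, known_cnv_regions, genes, alpha = 0.05) {
  results$known_cnv_flag <- FALSE
  if (nrow(results) == 0) return(results)
  if (is.null(known_cnv_regions$frequency) ||
      all(is.na(known_cnv_regions$frequency))) {
    if (nrow(known_cnv_regions) > 0)
      warning("reference regions carry no frequency; no genes flagged",
              call. = FALSE)
    return(results)
  }
  sig <- which(results$p_empirical < alpha)
  if (!length(sig)) return(results)
  ref <- known_cnv_regions[!is.na(known_cnv_regions$frequency), ,
                           drop = FALSE]
  gm <- genes[match(results$symbol[sig], genes$symbol), , drop = FALSE]
  h <- GenomicRanges::findOverlaps(.calls_gr(gm), .calls_gr(ref))
  case_freq <- results$a[sig] / (results$a[sig] + results$b[sig])
  for (i in seq_along(sig)) {
    rj <- S4Vectors::subjectHits(h)[S4Vectors::queryHits(h) == i]
    if (length(rj) && any(ref$frequency[rj] >= case_freq[i]))
      results$known_cnv_flag[sig[i]] <- TRUE
  }
  results
}
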