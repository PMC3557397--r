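# Gene-set carrier association with an empirical-Bayes local false
# discovery rate.
#
# Each gene set gets a signed-root likelihood-ratio statistic z from its
# 2x2 carrier table. The mixture density f of the observed z and the null
# density f0 of the permutation z are both estimated by the same smoother
# (binned counts, ridge-stabilized log-polynomial fit), and
# local_fdr(z) = min(1, p0 * f0(z) / f(z)) with the null proportion p0
# estimated by the median density ratio capped at 1 (Efron-Tibshirani
# density-ratio construction).

#' Size-filter gene sets against the annotation
#'
#' Keeps a set when between `min_genes` and `max_genes` of its members
#' (inclusive) are present in the gene models; membership is counted
#' against the annotation, not the raw GMT line, and each kept set's gene
#' list is restricted to the annotated genes. Sets whose genes are all
#' absent are removed with a warning. Very small sets carry no statistical
#' signal and very large ones are near-uninformative catch-alls.
#'
#' @param sets Gene sets from [read_gene_sets()].
#' @param genes Gene models.
#' @param min_genes,max_genes Inclusive size bounds (defaults 5 and 700).
#' @return The filtered gene-set list.
#' @export
filter_gene_sets <- function(sets, genes, min_genes = 5, max_genes = 700) {
  ann <- unique(genes$symbol)
  trimmed <- lapply(sets, function(s) {
    s$genes <- intersect(s$genes, ann)
    s
  })
  sizes <- vapply(trimmed, function(s) length(s$genes), 0L)
  lost <- sizes == 0 & vapply(sets, function(s) length(s$genes), 0L) > 0
  if (any(lost))
    warning("set(s) with no annotated genes removed: ",
            paste(names(sets)[lost], collapse = ", "), call. = FALSE)
  trimmed[sizes >= min_genes & sizes <= max_genes]
}

#' Per-set carrier counts of rare CNVs
#'
#' A sample is a carrier for a gene set when at least one of its rare calls
#' overlaps at least one member gene; a sample counts once per set however
#' many member genes it hits.
#'
#' @param rare_calls Rare-stratum CNV call data frame.
#' @param genes Gene models.
#' @param sets Gene sets (after [filter_gene_sets()]).
#' @param samples Sample table.
#' @param direction Restrict to deletions, duplications, or any (default).
#' @return Data frame per set: `set_id, name, n_genes, a, b, c, d`.
#' @export
set_carrier_counts <- function(rare_calls, genes, sets, samples,
                               direction = "any") {
  Mg <- .carrier_matrix(rare_calls, .calls_gr(genes), genes$symbol,
                        samples$sample_id, direction)
  rownames(Mg) <- genes$symbol
  Ms <- .set_carrier_matrix(Mg, sets)
  case <- samples$phenotype == "case"
  a <- as.vector(Ms %*% as.numeric(case))
  k <- rowSums(Ms)
  data.frame(set_id = vapply(sets, `[[`, "", "set_id"),
             name = vapply(sets, `[[`, "", "name"),
             n_genes = vapply(sets, function(s) length(s$genes), 0L),
             a = as.integer(a),
             b = as.integer(sum(case) - a),
             c = as.integer(k - a),
             d = as.integer(sum(!case) - (k - a)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# sets x samples carrier matrix from a gene x samples matrix; symbols may
# annotate several loci, so aggregate over all rows matching a member gene
.set_carrier_matrix <- function(Mg, sets) {
  Ms <- matrix(0, length(sets), ncol(Mg),
               dimnames = list(vapply(sets, `[[`, "", "set_id"),
                               colnames(Mg)))
  for (i in seq_along(sets)) {
    rows <- which(rownames(Mg) %in% sets[[i]]$genes)
    if (length(rows))
      Ms[i, ] <- as.numeric(colSums(Mg[rows, , drop = FALSE]) > 0)
  }
  Ms
}

#' Signed-root likelihood-ratio statistic of a carrier table
#'
#' `z = sign * sqrt(G)` where `G` is the likelihood-ratio (G-test)
#' statistic of the 2x2 table and the sign is positive when the case
#' carrier proportion exceeds the control proportion. Zero cells use the
#' `0 * log(0) = 0` convention, so the statistic is defined for every
#' table; it is antisymmetric under swapping case and control and
#' approximately standard normal under the null.
#'
#' @param a,b,cc,d Carrier table cells as in [fisher_exact()].
#' @return The signed z statistic.
#' @export
set_statistic <- function(a, b, cc, d) {
  .check_table(a, b, cc, d)
  .z_signed_g(a, a + cc, a + b, cc + d)
}

# vectorized over a (vector or matrix, k recycled along rows):
# a = case carriers, k = total carriers, n1 cases, n0 controls
.z_signed_g <- function(a, k, n1, n0) {
  N <- n1 + n0
  b <- n1 - a
  cc <- k - a
  d <- n0 - cc
  xlx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  G <- 2 * (xlx(a, n1 * k / N) + xlx(b, n1 * (N - k) / N) +
              xlx(cc, n0 * k / N) + xlx(d, n0 * (N - k) / N))
  s <- sign(a / n1 - cc / n0)
  s * sqrt(pmax(G, 0))
}

#' Empirical-Bayes local false discovery rate from permutation nulls
#'
#' Density-ratio local FDR in the empirical-Bayes style: for each observed
#' statistic the ratio of null to mixture mass at least as extreme (in the
#' same direction) is measured directly on the data,
#' `r(z) = E0[# sets >= z] / #\{observed z_i >= z\}` for `z >= 0` (and the
#' mirrored left tail for `z < 0`), where the null expectation comes from
#' the pooled permutation statistics scaled to one battery of sets. Then
#' `local_fdr(z) = min(1, p0 * r(z))` with the null proportion `p0`
#' defaulting to the median of `r` over the observed statistics capped at
#' 1 (near 1 when most sets are null), and `posterior = 1 - local_fdr`.
#' Finally the estimate is monotonized to be non-increasing with distance
#' from zero on each tail (a set never gets a better local FDR than a more
#' extreme one), which also stabilizes sparse-tail flukes.
#'
#' Counting exceedances rather than smoothing two separate densities keeps
#' the far tail honest: a statistic beyond almost every permutation draw
#' gets a small local FDR because the permutation null itself says such
#' values are rare, without trusting a parametric extrapolation.
#'
#' At least ~10 sets are needed for the ratio to be meaningful. If every
#' observed statistic is identical the estimate is degenerate and all
#' local FDRs are 1, with a warning.
#'
#' @param observed_z Vector of observed set statistics.
#' @param permuted_z Matrix of permutation statistics (`n_perm` rows x
#'   `n_sets` columns, or any layout — it is pooled).
#' @param p0 Optional null proportion in `[0, 1]`; estimated when `NULL`.
#' @return Data frame `(z, posterior, local_fdr)` aligned with
#'   `observed_z`; the null proportion used is attached as attribute `p0`.
#' @export
ebam_local_fdr <- function(observed_z, permuted_z, p0 = NULL) {
  perm <- as.vector(permuted_z)
  if (!length(perm)) stop("empty permutation matrix", call. = FALSE)
  stopifnot(length(observed_z) >= 2)
  if (length(unique(observed_z)) == 1) {
    warning("all observed statistics identical; local FDR degenerate",
            call. = FALSE)
    return(structure(data.frame(z = observed_z, posterior = 0,
                                local_fdr = 1), p0 = 1))
  }
  scale <- length(observed_z) / length(perm)
  r <- vapply(observed_z, function(z) {
    if (z >= 0) sum(perm >= z) * scale / sum(observed_z >= z)
    else sum(perm <= z) * scale / sum(observed_z <= z)
  }, 0)
  if (is.null(p0)) p0 <- min(1, stats::median(r))
  stopifnot(p0 >= 0, p0 <= 1)
  if (p0 == 0)
    warning("p0 = 0 forces every local FDR to zero (degenerate)",
            call. = FALSE)
  fdr <- pmin(1, p0 * r)
  pos <- which(observed_z >= 0)
  neg <- which(observed_z < 0)
  if (length(pos)) {
    o <- pos[order(observed_z[pos])]
    fdr[o] <- rev(cummax(rev(fdr[o])))
  }
  if (length(neg)) {
    o <- neg[order(observed_z[neg], decreasing = TRUE)]
    fdr[o] <- rev(cummax(rev(fdr[o])))
  }
  structure(data.frame(z = observed_z, posterior = 1 - fdr,
                       local_fdr = fdr), p0 = p0)
}

#' Pathway (gene-set) association with local FDR
#'
#' Full gene-set analysis: size-filters the sets, counts set-level carriers
#' of rare CNVs, computes the signed-root G statistic per set, builds the
#' permutation null by shuffling case/control labels `n_perm` times with
#' the carrier structure fixed, and estimates posterior and local FDR per
#' set via [ebam_local_fdr()]. Each set is annotated with its top
#' contributing gene (the member gene carried by the most samples), so
#' set-level hits driven by a single gene-level association are visible.
#' `exclude_gene` removes every call overlapping the named gene before the
#' analysis — the diagnostic for exactly that situation.
#'
#' @inheritParams set_carrier_counts
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Optional RNG seed.
#' @param exclude_gene Optional gene symbol whose calls are removed first.
#' @param min_genes,max_genes Size filter bounds passed to
#'   [filter_gene_sets()].
#' @param fdr_threshold Threshold on local FDR for the `significant`
#'   column (default 0.05).
#' @return Data frame per kept set, sorted by local FDR: counts, `z`,
#'   `posterior`, `local_fdr`, `significant`, odds ratio with exact CI,
#'   cohort-denominator carrier percentages, and `top_gene` /
#'   `top_gene_carriers`. Attributes `p0`, `n_perm`, `seed`.
#' @export
pathway_association <- function(rare_calls, genes, sets, samples,
                                n_perm = 1000, seed = NULL,
                                exclude_gene = NULL, min_genes = 5,
                                max_genes = 700, fdr_threshold = 0.05) {
  if (!is.null(exclude_gene)) {
    gm <- genes[genes$symbol == exclude_gene, , drop = FALSE]
    if (nrow(gm) == 0)
      stop("exclude_gene not in the gene models: ", exclude_gene,
           call. = FALSE)
    h <- GenomicRanges::findOverlaps(.calls_gr(rare_calls), .calls_gr(gm))
    drop <- unique(S4Vectors::queryHits(h))
    if (length(drop))
      rare_calls <- rare_calls[-drop, , drop = FALSE]
  }
  sets <- filter_gene_sets(sets, genes, min_genes, max_genes)
  if (!length(sets)) stop("no gene set passes the size filter",
                          call. = FALSE)
  Mg <- .carrier_matrix(rare_calls, .calls_gr(genes), genes$symbol,
                        samples$sample_id)
  rownames(Mg) <- genes$symbol
  Ms <- .set_carrier_matrix(Mg, sets)
  case <- samples$phenotype == "case"
  n1 <- sum(case)
  n0 <- sum(!case)
  k <- rowSums(Ms)
  a_obs <- as.vector(Ms %*% as.numeric(case))
  z_obs <- .z_signed_g(a_obs, k, n1, n0)
  if (!is.null(seed)) set.seed(seed)
  n <- length(case)
  Pm <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) Pm[sample.int(n, n1), j] <- 1
  A <- Ms %*% Pm                       # n_sets x n_perm
  Z <- .z_signed_g(A, k, n1, n0)
  eb <- ebam_local_fdr(z_obs, t(Z))
  or <- suppressWarnings(lapply(seq_along(k), function(i)
    odds_ratio_cmle(a_obs[i], n1 - a_obs[i], k[i] - a_obs[i],
                    n0 - (k[i] - a_obs[i]))))
  # top contributing gene: member gene with the most carriers in the set
  top <- lapply(sets, function(s) {
    rows <- which(rownames(Mg) %in% s$genes)
    if (!length(rows)) return(list(gene = NA_character_, n = 0L))
    cnt <- tapply(rowSums(Mg[rows, , drop = FALSE]),
                  rownames(Mg)[rows], sum)
    list(gene = names(cnt)[which.max(cnt)], n = as.integer(max(cnt)))
  })
  res <- data.frame(
    set_id = vapply(sets, `[[`, "", "set_id"),
    name = vapply(sets, `[[`, "", "name"),
    n_genes = vapply(sets, function(s) length(s$genes), 0L),
    a = as.integer(a_obs),
    b = as.integer(n1 - a_obs),
    c = as.integer(k - a_obs),
    d = as.integer(n0 - (k - a_obs)),
    z = z_obs,
    posterior = eb$posterior,
    local_fdr = eb$local_fdr,
    significant = eb$local_fdr < fdr_threshold,
    odds_ratio = vapply(or, `[[`, 0, "estimate"),
    ci_low = vapply(or, `[[`, 0, "ci_low"),
    ci_high = vapply(or, `[[`, 0, "ci_high"),
    pct_cases = 100 * a_obs / (n1 + n0),
    pct_controls = 100 * (k - a_obs) / (n1 + n0),
    top_gene = vapply(top, `[[`, "", "gene"),
    top_gene_carriers = vapply(top, `[[`, 0L, "n"),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$local_fdr, -abs(res$z)), , drop = FALSE]
  row.names(res) <- NULL
  attr(res, "p0") <- attr(eb, "p0")
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}
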