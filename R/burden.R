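# Global rare-CNV burden: per-sample aggregate load compared between cases
# and controls with a one-sided permutation test on the case:control ratio.

.BURDEN_METRICS <- c("rate", "gene_rate", "mean_length", "total_length")
.BURDEN_STRATA <- c("all", "dup_only", "del_only")

#' Per-sample rare-CNV burden metrics
#'
#' Four metrics per sample — the number of calls (`rate`), the number of
#' distinct genes overlapped by at least one call (`gene_rate`), the mean
#' call length and the total call length (bases) — computed for the three
#' type strata `all`, `dup_only` and `del_only`. Samples without calls in a
#' stratum contribute 0 to `rate`, `gene_rate` and `total_length`, but are
#' excluded (`NA`) from `mean_length`, whose mean over an empty set is
#' undefined.
#'
#' @param rare_calls Rare-stratum CNV call data frame.
#' @param samples Sample table.
#' @param genes Gene models (for `gene_rate`).
#' @return `list(per_sample, summary)`: `per_sample` is a long data frame
#'   `(sample_id, phenotype, stratum, rate, gene_rate, mean_length,
#'   total_length)` covering every sample; `summary` holds
#'   `(metric, stratum, case_mean, control_mean, ratio)` with
#'   `ratio = case_mean / control_mean`.
#' @export
burden_metrics <- function(rare_calls, samples, genes) {
  if (nrow(samples) == 0) stop("empty cohort", call. = FALSE)
  sid <- samples$sample_id
  gh <- GenomicRanges::findOverlaps(.calls_gr(rare_calls), .calls_gr(genes))
  per <- lapply(.BURDEN_STRATA, function(str) {
    keep <- switch(str,
                   all = rep(TRUE, nrow(rare_calls)),
                   dup_only = rare_calls$copy_number > 2,
                   del_only = rare_calls$copy_number < 2)
    calls <- rare_calls[keep, , drop = FALSE]
    f <- factor(calls$sample_id, levels = sid)
    lens <- split(cnv_length(calls), f)
    # distinct genes overlapped, per sample, within the stratum
    qk <- which(keep)
    hit <- S4Vectors::queryHits(gh) %in% qk
    gsym <- split(S4Vectors::subjectHits(gh)[hit],
                  factor(rare_calls$sample_id[S4Vectors::queryHits(gh)[hit]],
                         levels = sid))
    data.frame(sample_id = sid,
               phenotype = samples$phenotype,
               stratum = str,
               rate = as.integer(table(f)),
               gene_rate = vapply(gsym, function(g) length(unique(g)), 0L,
                                  USE.NAMES = FALSE),
               mean_length = vapply(lens, function(x)
                 if (length(x)) mean(x) else NA_real_, 0,
                 USE.NAMES = FALSE),
               total_length = vapply(lens, sum, 0, USE.NAMES = FALSE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  per <- do.call(rbind, per)
  list(per_sample = per, summary = .burden_summary(per))
}

.burden_summary <- function(per_sample) {
  case <- per_sample$phenotype == "case"
  out <- expand.grid(metric = .BURDEN_METRICS, stratum = .BURDEN_STRATA,
                     stringsAsFactors = FALSE)
  out$case_mean <- NA_real_
  out$control_mean <- NA_real_
  for (i in seq_len(nrow(out))) {
    x <- per_sample[per_sample$stratum == out$stratum[i],
                    out$metric[i]]
    ca <- case[per_sample$stratum == out$stratum[i]]
    out$case_mean[i] <- mean(x[ca], na.rm = TRUE)
    out$control_mean[i] <- mean(x[!ca], na.rm = TRUE)
  }
  out$ratio <- out$case_mean / out$control_mean
  out
}

#' One-sided permutation test on burden ratios
#'
#' For each (metric, stratum) pair the observed case:control ratio of means
#' is compared with its distribution under case/control label permutation
#' (the per-sample metric multiset is fixed; only labels move). The p-value
#' is one-sided for excess burden in cases:
#' `p = (1 + #\{perm : ratio_perm >= ratio_obs\}) / (n_perm + 1)`. One
#' shared permutation stream is used across all twelve tests.
#'
#' @param per_sample The `per_sample` table from [burden_metrics()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed.
#' @return The summary table with a `p` column; attributes `n_perm` and
#'   `seed` record the permutation settings.
#' @export
burden_permutation <- function(per_sample, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  summ <- .burden_summary(per_sample)
  sid <- unique(per_sample$sample_id)
  pheno <- per_sample$phenotype[match(sid, per_sample$sample_id)]
  n <- length(sid)
  n_cases <- sum(pheno == "case")
  # value and availability matrices: samples x (metric, stratum)
  V <- W <- matrix(0, n, nrow(summ))
  for (i in seq_len(nrow(summ))) {
    block <- per_sample[per_sample$stratum == summ$stratum[i], , drop = FALSE]
    x <- block[match(sid, block$sample_id), summ$metric[i]]
    W[, i] <- as.numeric(!is.na(x))
    V[, i] <- ifelse(is.na(x), 0, x)
  }
  tot_v <- colSums(V)
  tot_w <- colSums(W)
  if (!is.null(seed)) set.seed(seed)
  Pm <- matrix(0, n, n_perm)
  for (j in seq_len(n_perm)) Pm[sample.int(n, n_cases), j] <- 1
  case_v <- crossprod(Pm, V)   # n_perm x 12
  case_w <- crossprod(Pm, W)
  ratio_perm <- (case_v / case_w) /
    ((rep(1, n_perm) %o% tot_v - case_v) / (rep(1, n_perm) %o% tot_w - case_w))
  obs_case <- pheno == "case"
  obs_v <- colSums(V[obs_case, , drop = FALSE])
  obs_w <- colSums(W[obs_case, , drop = FALSE])
  ratio_obs <- (obs_v / obs_w) / ((tot_v - obs_v) / (tot_w - obs_w))
  tol <- 1e-12
  summ$p <- vapply(seq_len(nrow(summ)), function(i)
    (1 + sum(ratio_perm[, i] >= ratio_obs[i] - tol * max(1, abs(ratio_obs[i])))) /
      (n_perm + 1), 0)
  attr(summ, "n_perm") <- n_perm
  attr(summ, "seed") <- seed
  summ
}

#' Burden metrics and permutation p-values in one call
#'
#' @inheritParams burden_metrics
#' @inheritParams burden_permutation
#' @return `list(per_sample, summary)` with `summary` including the
#'   one-sided permutation `p`.
#' @export
burden_association <- function(rare_calls, samples, genes, n_perm = 10000,
                               seed = NULL) {
  bm <- burden_metrics(rare_calls, samples, genes)
  list(per_sample = bm$per_sample,
       summary = burden_permutation(bm$per_sample, n_perm, seed))
}
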