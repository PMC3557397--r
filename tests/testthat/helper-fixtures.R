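# Shared fixture builders. Everything is constructed in code; the only
# files read are the small text fixtures bundled under extdata.

mk_calls <- function(sample_id, chrom, start, end, copy_number,
                     n_markers = 10L, confidence = 10,
                     caller = "primary_caller") {
  data.frame(sample_id = as.character(sample_id),
             chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             copy_number = as.integer(copy_number),
             n_markers = as.integer(n_markers),
             confidence = as.numeric(confidence),
             caller = caller, stringsAsFactors = FALSE)
}

mk_samples <- function(ids, phenotype, lrr_sd = 0.1, cn_var = 1) {
  data.frame(sample_id = as.character(ids), phenotype = phenotype,
             n_calls = NA_integer_, total_cnv_length = NA_real_,
             median_cn_variance = cn_var, lrr_sd = lrr_sd,
             stringsAsFactors = FALSE)
}

mk_genes <- function(symbol, chrom, start, end) {
  data.frame(symbol = symbol, chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "rarecnv")

# the sixteen-call cell-migration fixture plus a full 189/380 cohort in
# which its ten case samples and six control samples are embedded
cellmig_fixture <- function() {
  calls <- read_cnv_calls(extdata("cellmig_cnvs.tsv"))
  genes <- read_gene_models(extdata("cellmig_genes_synthetic.bed"))
  sets <- read_gene_sets(extdata("cellmig_set.gmt"))
  carrier_case <- unique(calls$sample_id[grep("^[0-9]", calls$sample_id)])
  carrier_ctrl <- unique(calls$sample_id[grep("^M", calls$sample_id)])
  case_ids <- c(carrier_case,
                sprintf("CA%04d", seq_len(189 - length(carrier_case))))
  ctrl_ids <- c(carrier_ctrl,
                sprintf("CO%04d", seq_len(380 - length(carrier_ctrl))))
  samples <- mk_samples(c(case_ids, ctrl_ids),
                        rep(c("case", "control"), c(189, 380)))
  list(calls = calls, genes = genes, sets = sets, samples = samples)
}

# independent per-base oracle for the union-coverage fraction of a call
brute_cover_fraction <- function(call, regions) {
  bases <- call$start:call$end
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(regions))) {
    if (regions$chrom[i] != call$chrom) next
    covered <- covered | (bases >= regions$start[i] &
                            bases <= regions$end[i])
  }
  mean(covered)
}

# independent per-base oracle for the maximum distinct-sample stack
brute_stack_max <- function(calls) {
  lo <- min(calls$start)
  hi <- max(calls$end)
  depth <- integer(hi - lo + 1)
  for (s in unique(calls$sample_id)) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    hit <- rep(FALSE, hi - lo + 1)
    for (i in seq_len(nrow(cs)))
      hit[(cs$start[i]:cs$end[i]) - lo + 1] <- TRUE
    depth <- depth + hit
  }
  m <- max(depth)
  first <- which(depth == m)[1]
  run_end <- first
  while (run_end < length(depth) && depth[run_end + 1] == m)
    run_end <- run_end + 1
  list(locus_start = lo + first - 1, locus_end = lo + run_end - 1,
       max_stack_count = m)
}

# full-enumeration two-sided Fisher oracle: every table with the observed
# margins, summing the point probabilities <= the observed one
fisher_oracle <- function(a, b, cc, d) {
  k <- a + cc
  n1 <- a + b
  n0 <- cc + d
  if (k == 0 || k == n1 + n0 || n1 == 0 || n0 == 0) return(1)
  xs <- max(0, k - n0):min(k, n1)
  probs <- stats::dhyper(xs, n1, n0, k)
  p_obs <- stats::dhyper(a, n1, n0, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# conditional likelihood grid-search oracle for the CMLE odds ratio
or_cmle_oracle <- function(a, b, cc, d, grid = 10^seq(-3, 3, 1e-3)) {
  k <- a + cc
  n1 <- a + b
  n0 <- cc + d
  xs <- max(0, k - n0):min(k, n1)
  loglik <- vapply(grid, function(psi) {
    w <- stats::dhyper(xs, n1, n0, k) * psi^xs
    a * log(psi) - log(sum(w))
  }, 0)
  grid[which.max(loglik)]
}
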