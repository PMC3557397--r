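# Synthetic cohorts with the statistical structure the pipeline assumes:
# a Poisson background CNV process per sample (rates and type mix set to
# the post-QC cohort the analysis is designed for), log-normal call lengths
# truncated to the QC window, a noisy secondary-caller view (boundary
# jitter, false negatives, false positives), gene/gene-set annotations,
# optional planted gene- and pathway-level risk effects with an exact truth
# table, and depth-count tables for the read-depth module.

#' Default synthetic genome
#'
#' Twenty-two autosome-like chromosomes with approximately human lengths
#' (2.87 Gb total), so call densities, gene densities and overlap rates are
#' on the scale of a real genome-wide call set.
#'
#' @return Data frame `chrom, length`.
#' @export
default_genome <- function() {
  data.frame(chrom = paste0("chr", 1:22),
             length = c(247, 243, 199, 191, 181, 171, 159, 146, 140, 135,
                        134, 132, 114, 106, 100, 89, 79, 76, 63, 62, 47,
                        50) * 1e6,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults describe the cohort the pipeline targets: 189 cases and 380
#' controls after QC, about 4.8 CNV calls per control and 5.17 per case, a
#' deletion fraction of 0.60 (2.9 of 4.8 calls), and log-normal call
#' lengths truncated to the 4 kb - 1 Mb QC window with mean about 77 kb
#' (`meanlog = 10.764`, `sdlog = 1`).
#'
#' @param n_cases,n_controls Cohort sizes (defaults 189 / 380).
#' @param cnv_rate_control,cnv_rate_case Mean CNV calls per sample
#'   (defaults 4.8 / 5.17).
#' @param deletion_fraction Probability a background call is a deletion
#'   (default 0.60).
#' @param length_log_mean,length_log_sd Log-normal call-length parameters
#'   (defaults 10.764 / 1, mean about 77 kb after truncation).
#' @param min_length,max_length Truncation window in bases (4 kb / 1 Mb).
#' @param genome Data frame `chrom, length`.
#' @param n_genes Number of gene models (default 20000).
#' @param n_sets Number of gene sets (default 200).
#' @param set_size_range Inclusive range of set sizes (default `c(5, 100)`).
#' @param planted_gene Optional `list(symbol, case_penetrance,
#'   control_penetrance)`. Penetrance is realized as a deterministic
#'   carrier count `round(penetrance * n_group)` over randomly chosen
#'   samples, so the planted truth is exact.
#' @param planted_set Optional `list(set_id, case_excess)`: each case gains
#'   a carrier call at each member gene with probability `case_excess`.
#' @param caller2_boundary_jitter_sd SD (bases) of the Gaussian boundary
#'   jitter of the secondary caller (default 500).
#' @param caller2_fp_rate,caller2_fn_rate Secondary-caller false-positive
#'   and false-negative rates in `[0, 1]` (defaults 0.05 / 0.05); false
#'   positives are drawn as a Poisson fraction of the sample's true count.
#' @param n_segdups Number of segmental-duplication regions (default 100).
#' @param seed Master seed; per-stream seeds are derived by fixed offsets.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 189L, n_controls = 380L,
                       cnv_rate_control = 4.8, cnv_rate_case = 5.17,
                       deletion_fraction = 0.60,
                       length_log_mean = 10.764, length_log_sd = 1,
                       min_length = 4000, max_length = 1e6,
                       genome = default_genome(),
                       n_genes = 20000L, n_sets = 200L,
                       set_size_range = c(5L, 100L),
                       planted_gene = NULL, planted_set = NULL,
                       caller2_boundary_jitter_sd = 500,
                       caller2_fp_rate = 0.05, caller2_fn_rate = 0.05,
                       n_segdups = 100L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_cases > 0, cfg$n_controls > 0,
            cfg$cnv_rate_control >= 0, cfg$cnv_rate_case >= 0,
            cfg$deletion_fraction >= 0, cfg$deletion_fraction <= 1,
            all(cfg$genome$length > 0),
            cfg$caller2_fp_rate >= 0, cfg$caller2_fp_rate <= 1,
            cfg$caller2_fn_rate >= 0, cfg$caller2_fn_rate <= 1,
            cfg$min_length < cfg$max_length)
  if (!is.null(planted_gene))
    stopifnot(planted_gene$case_penetrance >= 0,
              planted_gene$case_penetrance <= 1,
              planted_gene$control_penetrance >= 0,
              planted_gene$control_penetrance <= 1)
  structure(cfg, class = "sim_config")
}

.rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  lo_q <- stats::plnorm(lo, meanlog, sdlog)
  hi_q <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(n, lo_q, hi_q)
  pmin(hi, pmax(lo, round(stats::qlnorm(u, meanlog, sdlog))))
}

.random_intervals <- function(n, genome, lengths) {
  chrom_idx <- sample.int(nrow(genome), n, replace = TRUE,
                          prob = genome$length)
  L <- genome$length[chrom_idx]
  lengths <- pmin(lengths, L)
  start <- floor(stats::runif(n, 1, L - lengths + 1))
  data.frame(chrom = genome$chrom[chrom_idx],
             start = as.integer(start),
             end = as.integer(start + lengths - 1),
             stringsAsFactors = FALSE)
}

#' Simulate gene, gene-set and segmental-duplication annotations
#'
#' Genes are placed uniformly on the genome (length-weighted chromosome
#' choice) with log-normal lengths around 20 kb; sets draw member genes
#' without replacement; segmental duplications are uniform intervals of
#' 50-500 kb.
#'
#' @param cfg A [sim_config()].
#' @return `list(genes, sets, segdups)` in the formats the readers produce.
#' @export
simulate_annotation <- function(cfg) {
  set.seed(cfg$seed + 1L)
  glen <- .rlnorm_trunc(cfg$n_genes, log(2e4), 0.8, 2e3, 1.5e6)
  genes <- .random_intervals(cfg$n_genes, cfg$genome, glen)
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  genes <- data.frame(symbol = sprintf("G%05d", seq_len(cfg$n_genes)),
                      genes, stringsAsFactors = FALSE, row.names = NULL)
  set.seed(cfg$seed + 2L)
  sets <- lapply(seq_len(cfg$n_sets), function(i) {
    size <- sample(cfg$set_size_range[1]:cfg$set_size_range[2], 1)
    list(set_id = sprintf("SET%03d", i),
         name = sprintf("synthetic gene set %d", i),
         source = "synthetic",
         genes = sample(genes$symbol, size))
  })
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  set.seed(cfg$seed + 3L)
  sdlen <- round(stats::runif(cfg$n_segdups, 5e4, 5e5))
  segdups <- .random_intervals(cfg$n_segdups, cfg$genome, sdlen)
  segdups <- segdups[order(segdups$chrom, segdups$start), , drop = FALSE]
  row.names(segdups) <- NULL
  list(genes = genes, sets = sets, segdups = segdups)
}

.background_calls <- function(sample_ids, n_per_sample, cfg, caller) {
  n <- sum(n_per_sample)
  if (n == 0) {
    out <- .empty_calls()
    return(out)
  }
  lens <- .rlnorm_trunc(n, cfg$length_log_mean, cfg$length_log_sd,
                        cfg$min_length, cfg$max_length)
  iv <- .random_intervals(n, cfg$genome, lens)
  is_del <- stats::runif(n) < cfg$deletion_fraction
  cn <- ifelse(is_del,
               ifelse(stats::runif(n) < 0.9, 1L, 0L),
               ifelse(stats::runif(n) < 0.9, 3L, 4L))
  data.frame(sample_id = rep(sample_ids, n_per_sample),
             iv,
             copy_number = cn,
             n_markers = pmax(1L, stats::rpois(n, lens / 500)),
             confidence = stats::rgamma(n, shape = 2, scale = 5),
             caller = caller,
             stringsAsFactors = FALSE, row.names = NULL)
}

# a call guaranteed to overlap the gene and to survive the call filters
.planted_call <- function(sample_ids, gene, cfg) {
  n <- length(sample_ids)
  if (n == 0) return(.empty_calls())
  lens <- .rlnorm_trunc(n, cfg$length_log_mean, cfg$length_log_sd,
                        cfg$min_length, cfg$max_length)
  lo <- pmax(1, gene$start - lens + 1)
  start <- floor(stats::runif(n, lo, gene$end + 1))
  data.frame(sample_id = sample_ids,
             chrom = gene$chrom,
             start = as.integer(start),
             end = as.integer(start + lens - 1),
             copy_number = 1L,
             n_markers = pmax(5L, stats::rpois(n, lens / 500)),
             confidence = 3 + stats::rgamma(n, shape = 2, scale = 5),
             caller = "planted",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a case-control CNV cohort
#'
#' Generates samples, the primary-caller call set, a degraded
#' secondary-caller view of it, annotations, and an exact truth table of
#' planted carriers. Per sample the background call count is Poisson with
#' the phenotype's rate; planted effects add carrier calls on top of the
#' background, so true carrier status is unambiguous.
#'
#' @param cfg A [sim_config()].
#' @param annotation Optional `list(genes, sets, segdups)` reused across
#'   replicates (e.g. in calibration loops); regenerated from `cfg` when
#'   `NULL`.
#' @return `list(samples, primary_calls, secondary_calls, genes, sets,
#'   segdups, truth, config)`; `truth` has one row per planted carrier
#'   (`sample_id, target_type, target_id`).
#' @export
simulate_cohort <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(cfg)
  genes <- annotation$genes
  sets <- annotation$sets
  set.seed(cfg$seed + 4L)
  sample_ids <- c(sprintf("CA%04d", seq_len(cfg$n_cases)),
                  sprintf("CO%04d", seq_len(cfg$n_controls)))
  phenotype <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  n_bg <- stats::rpois(length(sample_ids),
                       ifelse(phenotype == "case", cfg$cnv_rate_case,
                              cfg$cnv_rate_control))
  calls <- .background_calls(sample_ids, n_bg, cfg, "primary_caller")
  truth <- data.frame(sample_id = character(0), target_type = character(0),
                      target_id = character(0), stringsAsFactors = FALSE)
  set.seed(cfg$seed + 6L)
  if (!is.null(cfg$planted_gene)) {
    pg <- cfg$planted_gene
    gene <- genes[genes$symbol == pg$symbol, , drop = FALSE]
    if (nrow(gene) == 0)
      stop("planted gene absent from the annotation: ", pg$symbol,
           call. = FALSE)
    gene <- gene[1, ]
    n_ca <- round(pg$case_penetrance * cfg$n_cases)
    n_co <- round(pg$control_penetrance * cfg$n_controls)
    carriers <- c(sample(sample_ids[phenotype == "case"], n_ca),
                  sample(sample_ids[phenotype == "control"], n_co))
    calls <- rbind(calls, .planted_call(carriers, gene, cfg))
    if (length(carriers))
      truth <- rbind(truth, data.frame(sample_id = carriers,
                                       target_type = "gene",
                                       target_id = pg$symbol,
                                       stringsAsFactors = FALSE))
  }
  if (!is.null(cfg$planted_set)) {
    ps <- cfg$planted_set
    if (!ps$set_id %in% names(sets))
      stop("planted set absent from the annotation: ", ps$set_id,
           call. = FALSE)
    member <- sets[[ps$set_id]]$genes
    for (sym in member) {
      gene <- genes[genes$symbol == sym, , drop = FALSE][1, ]
      hit <- sample_ids[phenotype == "case"][
        stats::runif(cfg$n_cases) < ps$case_excess]
      if (length(hit)) {
        calls <- rbind(calls, .planted_call(hit, gene, cfg))
        truth <- rbind(truth, data.frame(sample_id = hit,
                                         target_type = "set",
                                         target_id = ps$set_id,
                                         stringsAsFactors = FALSE))
      }
    }
    truth <- unique(truth)
  }
  calls$caller <- "primary_caller"
  calls <- .sort_calls(calls)
  secondary <- .secondary_view(calls, cfg)
  set.seed(cfg$seed + 7L)
  samples <- data.frame(
    sample_id = sample_ids,
    phenotype = phenotype,
    n_calls = as.integer(table(factor(calls$sample_id,
                                      levels = sample_ids))),
    total_cnv_length = vapply(
      split(cnv_length(calls), factor(calls$sample_id,
                                      levels = sample_ids)),
      sum, 0, USE.NAMES = FALSE),
    median_cn_variance = stats::rgamma(length(sample_ids), shape = 16,
                                       scale = 1 / 16),
    lrr_sd = abs(stats::rnorm(length(sample_ids), 0.15, 0.04)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(samples = samples, primary_calls = calls,
       secondary_calls = secondary, genes = genes, sets = sets,
       segdups = annotation$segdups, truth = truth, config = cfg)
}

# degraded copy of the primary calls: false-negative drops, boundary
# jitter, and false-positive extra calls
.secondary_view <- function(calls, cfg) {
  set.seed(cfg$seed + 5L)
  keep <- stats::runif(nrow(calls)) >= cfg$caller2_fn_rate
  sec <- calls[keep, , drop = FALSE]
  if (nrow(sec) && cfg$caller2_boundary_jitter_sd > 0) {
    js <- round(stats::rnorm(nrow(sec), 0, cfg$caller2_boundary_jitter_sd))
    je <- round(stats::rnorm(nrow(sec), 0, cfg$caller2_boundary_jitter_sd))
    sec$start <- pmax(1L, as.integer(sec$start + js))
    sec$end <- pmax(sec$start, as.integer(sec$end + je))
  }
  sids <- unique(calls$sample_id)
  n_true <- as.integer(table(factor(calls$sample_id, levels = sids)))
  n_fp <- stats::rpois(length(sids), cfg$caller2_fp_rate * n_true)
  fp <- .background_calls(sids, n_fp, cfg, "secondary_caller")
  sec <- rbind(sec, fp)
  sec$caller <- "secondary_caller"
  .sort_calls(sec)
}

#' Write a simulated cohort to a directory
#'
#' Emits the files the pipeline readers consume — two `cnv_table` call
#' tables, the sample table, gene and segmental-duplication BED files, the
#' gene-set GMT, and the truth table — each tab-delimited table carrying
#' the master seed in a `#` header comment.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = sim$config$seed)
  write_cnv_calls(sim$primary_calls, file.path(dir, "primary.calls.tsv"),
                  meta = meta)
  write_cnv_calls(sim$secondary_calls,
                  file.path(dir, "secondary.calls.tsv"), meta = meta)
  con <- file(file.path(dir, "samples.tsv"), "w")
  writeLines(sprintf("# seed: %d", sim$config$seed), con)
  utils::write.table(sim$samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  g <- sim$genes
  utils::write.table(data.frame(g$chrom, g$start - 1L, g$end, g$symbol),
                     file.path(dir, "genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  s <- sim$segdups
  utils::write.table(data.frame(s$chrom, s$start - 1L, s$end),
                     file.path(dir, "segdups.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  gmt <- vapply(sim$sets, function(x)
    paste(c(x$set_id, x$name, x$genes), collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "sets.gmt"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a targeted-sequencing depth-count table
#'
#' Copy-number classes are assigned by largest-remainder rounding of
#' `proportions` (so class counts are deterministic) and then shuffled
#' across samples. Samples in a zero-center class get exactly 0 region
#' reads (no template DNA); other classes draw Poisson counts around
#' `center * region_length * total_reads / 1e9` with multiplicative
#' log-normal noise of standard deviation `noise_sd`.
#'
#' @param n_samples Number of samples (default 62).
#' @param proportions Class proportions over increasing copy number,
#'   summing to 1 (default `c(0.52, 0.40, 0.08)` for copy numbers 0/1/2).
#' @param centers Expected depth ratio per class (default `c(0, 0.5, 1)`).
#' @param noise_sd Log-scale SD of the per-sample rate noise (default
#'   0.02; must be non-negative).
#' @param total_reads Total reads per sample (default 2e7, a multiplexed
#'   high-throughput lane share; at the default region length this puts
#'   about 100 reads on a single-copy target, well-separating the
#'   clusters).
#' @param region_length Target region length in bases (default 10000).
#' @param seed RNG seed.
#' @return Data frame `sample_id, region, region_length, region_reads,
#'   total_reads, ratio, true_cn`.
#' @export
simulate_depth_counts <- function(n_samples = 62L,
                                  proportions = c(0.52, 0.40, 0.08),
                                  centers = c(0, 0.5, 1),
                                  noise_sd = 0.02,
                                  total_reads = 2e7,
                                  region_length = 10000L,
                                  seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  stopifnot(abs(sum(proportions) - 1) < 1e-8,
            length(centers) == length(proportions))
  set.seed(seed)
  raw <- proportions * n_samples
  sizes <- floor(raw)
  left <- n_samples - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  cn <- sample(rep(seq_along(centers) - 1L, sizes))
  mu <- centers[cn + 1L] * exp(stats::rnorm(n_samples, 0, noise_sd)) *
    region_length * total_reads / 1e9
  reads <- ifelse(centers[cn + 1L] == 0, 0L, stats::rpois(n_samples, mu))
  data.frame(sample_id = sprintf("P%03d", seq_len(n_samples)),
             region = "target",
             region_length = region_length,
             region_reads = as.integer(reads),
             total_reads = total_reads,
             ratio = depth_ratio(reads, region_length, total_reads),
             true_cn = cn,
             stringsAsFactors = FALSE, row.names = NULL)
}
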