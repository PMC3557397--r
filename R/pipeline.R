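# End-to-end orchestration: QC -> stratification -> segdup filter ->
# locus / gene / burden / pathway association -> TSV outputs with a
# provenance manifest. Each stage logs to stderr with timing; permutation
# outputs record seed and n_perm in their headers, so a rerun with the
# same inputs and seed reproduces identical bytes.

.read_if_path <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[rarecnv] %s ...", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[rarecnv] %s done (%.1f s)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full CNV association pipeline
#'
#' Stages, in order: dual-caller consensus and call/sample QC
#' ([run_qc()]); region construction and common/rare stratification
#' ([classify_calls()]); segmental-duplication filter on the rare stratum
#' ([filter_segdup()]); locus association of common CNVs
#' ([locus_association()]); gene association of rare CNVs
#' ([gene_association()], optionally flagged against a known-CNV
#' reference with [dgv_flag()]); global burden ([burden_association()]);
#' and pathway association ([pathway_association()]) when gene sets are
#' supplied. Every stage's table is written to `out_dir` and a
#' `manifest.json` records input/output checksums, seed and permutation
#' counts.
#'
#' @param primary_calls,secondary_calls Call tables (data frames, or paths
#'   read with the `cnv_table` dialect).
#' @param samples Sample table (data frame or path).
#' @param genes Gene models (data frame or BED path).
#' @param sets Gene sets (list from [read_gene_sets()], GMT path, or
#'   `NULL` to skip the pathway stage).
#' @param segdups Segmental-duplication regions (data frame, BED path, or
#'   `NULL` to skip that filter).
#' @param known_cnv Known-CNV reference with frequencies (data frame, BED
#'   path, or `NULL` to skip flagging).
#' @param out_dir Output directory, created if missing.
#' @param qc A [qc_config()].
#' @param freq_threshold Common/rare frequency threshold (default 0.01).
#' @param n_perm Named list of permutation counts per stage (defaults
#'   `locus = 1000, gene = 1000, burden = 10000, pathway = 1000`).
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param direction Carrier direction passed to the association stages.
#' @return Invisibly, a list with every stage's result.
#' @export
run_cnv_pipeline <- function(primary_calls, secondary_calls, samples,
                             genes, sets = NULL, segdups = NULL,
                             known_cnv = NULL, out_dir,
                             qc = qc_config(), freq_threshold = 0.01,
                             n_perm = list(locus = 1000, gene = 1000,
                                           burden = 10000, pathway = 1000),
                             seed = 1L, direction = "any") {
  for (p in list(primary_calls, secondary_calls, samples, genes, sets,
                 segdups, known_cnv)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  }
  primary_calls <- .read_if_path(primary_calls, read_cnv_calls)
  secondary_calls <- .read_if_path(secondary_calls, read_cnv_calls)
  samples <- .read_if_path(samples, read_sample_table)
  genes <- .read_if_path(genes, read_gene_models)
  sets <- .read_if_path(sets, read_gene_sets)
  segdups <- .read_if_path(segdups, read_region_bed)
  known_cnv <- .read_if_path(known_cnv, read_region_bed,
                             frequency_col = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  qcres <- .stage("consensus and QC",
                  run_qc(primary_calls, secondary_calls, samples, qc))
  n_samples <- nrow(qcres$samples)
  strat <- .stage("stratification",
                  classify_calls(qcres$calls, n_samples, freq_threshold))
  regions <- attr(strat, "regions")$regions
  common <- strat[!is.na(strat$stratum) & strat$stratum == "common", ,
                  drop = FALSE]
  rare <- strat[!is.na(strat$stratum) & strat$stratum == "rare", ,
                drop = FALSE]
  if (!is.null(segdups)) {
    n0 <- nrow(rare)
    rare <- .stage("segdup filter", filter_segdup(rare, segdups, qc))
    qcres$report <- rbind(qcres$report,
                          data.frame(filter = "segdup_rare",
                                     n_removed = n0 - nrow(rare),
                                     unit = "calls"))
  }
  locus <- .stage("locus association",
                  locus_association(common, qcres$samples,
                                    n_perm = n_perm$locus,
                                    seed = seed + 11L,
                                    direction = direction))
  gene <- .stage("gene association",
                 gene_association(rare, genes, qcres$samples,
                                  n_perm = n_perm$gene, seed = seed + 12L,
                                  direction = direction))
  if (!is.null(known_cnv))
    gene <- dgv_flag(gene, known_cnv, genes)
  burden <- .stage("burden analysis",
                   burden_association(rare, qcres$samples, genes,
                                      n_perm = n_perm$burden,
                                      seed = seed + 13L))
  pathway <- NULL
  if (!is.null(sets))
    pathway <- .stage("pathway association",
                      pathway_association(rare, genes, sets,
                                          qcres$samples,
                                          n_perm = n_perm$pathway,
                                          seed = seed + 14L))

  write_results(qcres$report, file.path(out_dir, "qc_report.tsv"))
  write_cnv_calls(strat[, .CNV_COLS], file.path(out_dir, "calls_qc.tsv"))
  write_results(regions, file.path(out_dir, "regions.tsv"))
  write_results(locus, file.path(out_dir, "locus_assoc.tsv"),
                meta = list(seed = seed + 11L, n_perm = n_perm$locus))
  write_results(gene, file.path(out_dir, "gene_assoc.tsv"),
                meta = list(seed = seed + 12L, n_perm = n_perm$gene))
  write_results(burden$summary, file.path(out_dir, "burden.tsv"),
                meta = list(seed = seed + 13L, n_perm = n_perm$burden))
  if (!is.null(pathway))
    write_results(pathway, file.path(out_dir, "pathway_assoc.tsv"),
                  meta = list(seed = seed + 14L, n_perm = n_perm$pathway))

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "rarecnv",
    version = as.character(utils::packageVersion("rarecnv")),
    seed = seed,
    n_perm = n_perm,
    freq_threshold = freq_threshold,
    n_samples_after_qc = n_samples,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qcres, calls = strat, regions = regions,
                 locus = locus, gene = gene, burden = burden,
                 pathway = pathway, manifest = manifest))
}

#' Summarize a pipeline run directory
#'
#' Formats the result tables of a completed [run_cnv_pipeline()] run into
#' a plain-text report (per-filter QC counts, top loci and genes with
#' empirical p-values and odds ratios, the burden table, significant
#' pathways). Missing tables produce a warning and a partial report.
#'
#' @param run_dir Directory written by [run_cnv_pipeline()].
#' @param max_rows Rows shown per association table (default 10).
#' @return Character vector of report lines (also written to
#'   `report.txt` in `run_dir`), invisibly.
#' @export
make_report <- function(run_dir, max_rows = 10) {
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) {
      warning("missing table: ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.delim(p, stringsAsFactors = FALSE, comment.char = "#")
  }
  lines <- c("rarecnv run report", strrep("=", 18), "")
  qc <- rd("qc_report.tsv")
  if (!is.null(qc)) {
    lines <- c(lines, "QC removals:",
               sprintf("  %-22s %6d %s", qc$filter, qc$n_removed, qc$unit),
               "")
  }
  disp <- function(df, base, digits = 2, p = FALSE) {
    d <- df[[paste0(base, "_display")]]
    if (!is.null(d)) return(d)
    x <- df[[base]]
    if (is.null(x)) return(rep("-", nrow(df)))
    if (p) format_pvalue(x) else formatC(x, format = "f", digits = digits)
  }
  fmt_assoc <- function(df, id_col, title) {
    if (is.null(df) || nrow(df) == 0)
      return(c(title, "  no associations", ""))
    df <- utils::head(df, max_rows)
    c(title,
      sprintf("  %-14s P_emp %-9s P_unadj %-9s OR %s (%s-%s)  cases %s%%  controls %s%%",
              df[[id_col]], disp(df, "p_empirical", p = TRUE),
              disp(df, "p_unadjusted", p = TRUE),
              disp(df, "odds_ratio"), disp(df, "ci_low"),
              disp(df, "ci_high"), disp(df, "pct_cases", 1),
              disp(df, "pct_controls", 1)),
      "")
  }
  gene <- rd("gene_assoc.tsv")
  if (!is.null(gene)) lines <- c(lines, fmt_assoc(gene, "symbol",
                                                  "Gene association:"))
  locus <- rd("locus_assoc.tsv")
  if (!is.null(locus)) {
    if (nrow(locus)) locus$locus <- sprintf("%s:%d-%d", locus$chrom,
                                            locus$start, locus$end)
    lines <- c(lines, fmt_assoc(locus, "locus", "Locus association:"))
  }
  burden <- rd("burden.tsv")
  if (!is.null(burden)) {
    lines <- c(lines, "Burden (case:control ratio, one-sided permutation P):",
               sprintf("  %-12s %-9s ratio %-6s P %s", burden$metric,
                       burden$stratum, round(burden$ratio, 2),
                       disp(burden, "p", p = TRUE)),
               "")
  }
  pw <- rd("pathway_assoc.tsv")
  if (!is.null(pw)) {
    sig <- pw[pw$significant %in% c(TRUE, "TRUE"), , drop = FALSE]
    if (nrow(sig) == 0) {
      lines <- c(lines, "Pathway association:", "  no associations", "")
    } else {
      lines <- c(lines, "Pathway association (local FDR < 0.05):",
                 sprintf("  %-10s posterior %.2f local FDR %.3f OR %s  top gene %s",
                         sig$set_id, sig$posterior, sig$local_fdr,
                         disp(sig, "odds_ratio"), sig$top_gene),
                 "")
    }
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}

#' Histogram of primary/secondary overlap fractions
#'
#' Diagnostic for the consensus step: for each primary-caller call, the
#' best same-sample, same-direction overlap fraction achieved by any
#' secondary-caller call.
#'
#' @param primary_calls,secondary_calls Call tables.
#' @param ... Passed to [graphics::hist()].
#' @return The best-overlap fractions, invisibly.
#' @export
plot_overlap_histogram <- function(primary_calls, secondary_calls, ...) {
  best <- rep(0, nrow(primary_calls))
  h <- GenomicRanges::findOverlaps(.calls_gr(primary_calls),
                                   .calls_gr(secondary_calls))
  q <- S4Vectors::queryHits(h)
  j <- S4Vectors::subjectHits(h)
  ok <- primary_calls$sample_id[q] == secondary_calls$sample_id[j] &
    (primary_calls$copy_number[q] < 2) ==
    (secondary_calls$copy_number[j] < 2)
  if (any(ok)) {
    ov <- pmin(primary_calls$end[q], secondary_calls$end[j]) -
      pmax(primary_calls$start[q], secondary_calls$start[j]) + 1
    frac <- ov / (primary_calls$end[q] - primary_calls$start[q] + 1)
    agg <- tapply(frac[ok], q[ok], max)
    best[as.integer(names(agg))] <- agg
  }
  graphics::hist(best, xlab = "overlap fraction of primary call",
                 main = "dual-caller overlap", ...)
  invisible(best)
}
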