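# Internal coordinate convention: 1-based, inclusive on both ends, everywhere.
# BED-style input/output converts at the boundary (BED start is 0-based
# half-open). Chromosome names are kept verbatim and compared string-exact.

.CNV_COLS <- c("sample_id", "chrom", "start", "end",
               "copy_number", "n_markers", "confidence", "caller")

#' Length of CNV calls in bases
#'
#' Coordinates are 1-based inclusive, so a call spanning a single base has
#' length 1.
#'
#' @param calls A CNV call data frame with `start` and `end` columns.
#' @return Integer vector of lengths (`end - start + 1`).
#' @export
cnv_length <- function(calls) calls$end - calls$start + 1

#' Type of CNV calls
#'
#' Type is derived from the copy number, never stored: a copy number below
#' the diploid 2 is a deletion, above 2 a duplication. Copy number 2 is not a
#' CNV and is rejected at read time.
#'
#' @param calls A CNV call data frame with a `copy_number` column.
#' @return Character vector, `"deletion"` or `"duplication"`.
#' @export
cnv_type <- function(calls) {
  ifelse(calls$copy_number < 2, "deletion", "duplication")
}

# GRanges view of a call (or any chrom/start/end) table; row index kept.
.calls_gr <- function(x) {
  GenomicRanges::GRanges(as.character(x$chrom),
                         IRanges::IRanges(x$start, x$end))
}

.sort_calls <- function(x) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  row.names(x) <- NULL
  x
}

.validate_calls <- function(df, lines, strict = TRUE) {
  bad_coord <- df$start > df$end
  bad_cn <- df$copy_number == 2
  bad_mark <- !is.na(df$n_markers) & df$n_markers < 1
  bad_conf <- !is.na(df$confidence) & df$confidence < 0
  bad <- bad_coord | bad_cn | bad_mark | bad_conf
  if (any(bad)) {
    msg <- character(0)
    if (any(bad_coord))
      msg <- c(msg, sprintf("start > end at line(s) %s",
                            paste(lines[bad_coord], collapse = ", ")))
    if (any(bad_cn))
      msg <- c(msg, sprintf(
        "copy_number = 2 (a CNV call must depart from the diploid state) at line(s) %s",
        paste(lines[bad_cn], collapse = ", ")))
    if (any(bad_mark))
      msg <- c(msg, sprintf("n_markers < 1 at line(s) %s",
                            paste(lines[bad_mark], collapse = ", ")))
    if (any(bad_conf))
      msg <- c(msg, sprintf("negative confidence at line(s) %s",
                            paste(lines[bad_conf], collapse = ", ")))
    if (strict) stop("invalid CNV rows: ", paste(msg, collapse = "; "),
                     call. = FALSE)
    warning("skipping invalid CNV rows: ", paste(msg, collapse = "; "),
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' Read a CNV call table
#'
#' Two dialects are supported. `cnv_table` is a tab-delimited file with a
#' header and columns `sample_id, chrom, start, end, copy_number, n_markers,
#' confidence, caller`; coordinates are 1-based inclusive. `bed_like` is a
#' headerless 5-column table `chrom, start, end, sample_id, copy_number` with
#' BED conventions (0-based half-open start); coordinates are converted to
#' the internal 1-based inclusive convention, and the marker count,
#' confidence and caller fields are filled with `NA`.
#'
#' Malformed rows (start beyond end, copy number exactly 2, non-positive
#' marker counts, negative confidence) fail the whole read by default;
#' `strict = FALSE` skips them with a warning naming the offending line
#' numbers. Silent row loss would corrupt downstream carrier counts, hence
#' the strict default.
#'
#' @param path Path to the file. Lines starting with `#` are ignored.
#' @param dialect `"cnv_table"` or `"bed_like"`.
#' @param strict Fail (default) or skip-and-warn on malformed rows.
#' @return A data frame of calls sorted by `(chrom, start, end)` with columns
#'   `sample_id, chrom, start, end, copy_number, n_markers, confidence,
#'   caller`.
#' @export
read_cnv_calls <- function(path, dialect = c("cnv_table", "bed_like"),
                           strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  if (!any(keep)) {
    warning("empty CNV call table: ", path, call. = FALSE)
    return(.empty_calls())
  }
  body <- raw[keep]
  lines <- which(keep)
  if (dialect == "cnv_table") {
    hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    missing_cols <- setdiff(.CNV_COLS, hdr)
    if (length(missing_cols))
      stop("format error: missing column(s) ",
           paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
    df <- utils::read.delim(text = body, stringsAsFactors = FALSE)
    lines <- lines[-1]
    df <- data.frame(sample_id = as.character(df$sample_id),
                     chrom = as.character(df$chrom),
                     start = as.integer(df$start),
                     end = as.integer(df$end),
                     copy_number = as.integer(df$copy_number),
                     n_markers = as.integer(df$n_markers),
                     confidence = as.numeric(df$confidence),
                     caller = as.character(df$caller),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(text = body, header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 5)
      stop("format error: bed_like dialect needs 5 columns ",
           "(chrom, start, end, sample_id, copy_number)", call. = FALSE)
    df <- data.frame(sample_id = as.character(df[[4]]),
                     chrom = as.character(df[[1]]),
                     start = as.integer(df[[2]]) + 1L,  # 0-based -> 1-based
                     end = as.integer(df[[3]]),
                     copy_number = as.integer(df[[5]]),
                     n_markers = NA_integer_,
                     confidence = NA_real_,
                     caller = NA_character_,
                     stringsAsFactors = FALSE)
  }
  df <- .validate_calls(df, lines, strict = strict)
  .sort_calls(df)
}

.empty_calls <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             copy_number = integer(0), n_markers = integer(0),
             confidence = numeric(0), caller = character(0),
             stringsAsFactors = FALSE)
}

#' Write a CNV call table
#'
#' Inverse of [read_cnv_calls()]: `cnv_table` writes the internal 1-based
#' columns with a header; `bed_like` converts back to BED (0-based half-open
#' start, no header) so that bed_like -> internal -> bed_like is the
#' identity on well-formed rows.
#'
#' @param calls CNV call data frame.
#' @param path Output path.
#' @param dialect Output dialect, as in [read_cnv_calls()].
#' @param meta Optional named list written as `# key: value` comment lines
#'   (cnv_table dialect only).
#' @export
write_cnv_calls <- function(calls, path, dialect = c("cnv_table", "bed_like"),
                            meta = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "cnv_table") {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(meta))
      writeLines(sprintf("# %s: %s", names(meta),
                         vapply(meta, format, "")), con)
    utils::write.table(calls[, .CNV_COLS], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(calls$chrom, calls$start - 1L, calls$end,
                      calls$sample_id, calls$copy_number)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a sample phenotype/QC table
#'
#' Tab-delimited with header; required columns `sample_id` and `phenotype`
#' (values `case`/`control`); optional per-sample QC metrics `n_calls`,
#' `total_cnv_length`, `median_cn_variance`, `lrr_sd` (filled with `NA` if
#' absent).
#'
#' @param path Path to the table.
#' @return Data frame with one row per sample; sample ids must be unique.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "phenotype")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  bad <- !df$phenotype %in% c("case", "control")
  if (any(bad))
    stop("phenotype must be 'case' or 'control'; offending sample(s): ",
         paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
  for (m in c("n_calls", "total_cnv_length", "median_cn_variance", "lrr_sd"))
    if (is.null(df[[m]])) df[[m]] <- NA_real_
  df
}

#' Read gene models from a 4-column BED file
#'
#' Columns `chrom, start, end, symbol`; BED start is converted to the
#' internal 1-based inclusive convention. Zero-length features are rejected.
#' Duplicate symbols are kept with a warning (a symbol may legitimately
#' annotate several loci in draft annotations); output is sorted by
#' `(chrom, start)`.
#'
#' @param path Path to the BED file.
#' @return Data frame `symbol, chrom, start, end`.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 4)
    stop("format error: gene BED needs 4 columns (chrom, start, end, symbol)",
         call. = FALSE)
  if (any(df[[2]] >= df[[3]]))
    stop("zero- or negative-length gene feature(s) at line(s) ",
         paste(which(df[[2]] >= df[[3]]), collapse = ", "), call. = FALSE)
  out <- data.frame(symbol = as.character(df[[4]]),
                    chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$symbol))
    warning("duplicate gene symbol(s) kept: ",
            paste(unique(out$symbol[duplicated(out$symbol)]), collapse = ", "),
            call. = FALSE)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Read genomic regions from a BED file
#'
#' Generic 3+ column BED reader used for segmental-duplication tracks and
#' known-CNV reference tracks. If `frequency_col` is `TRUE` the 4th column is
#' read as a numeric population frequency (as needed by [dgv_flag()]); when
#' absent or non-numeric the frequency is `NA` with a warning.
#'
#' @param path Path to the BED file.
#' @param frequency_col Expect a numeric frequency in column 4.
#' @return Data frame `chrom, start, end` (1-based inclusive), plus
#'   `frequency` when requested.
#' @export
read_region_bed <- function(path, frequency_col = FALSE) {
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  if (!length(raw)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    if (frequency_col) out$frequency <- numeric(0)
    return(out)
  }
  df <- utils::read.delim(text = raw, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop("format error: region BED needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (frequency_col) {
    freq <- if (ncol(df) >= 4) suppressWarnings(as.numeric(df[[4]]))
            else rep(NA_real_, nrow(df))
    if (all(is.na(freq)))
      warning("no usable frequency column in ", path, call. = FALSE)
    out$frequency <- freq
  }
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-delimited `set_id, description,
#' gene1, gene2, ...`. Duplicated symbols within a set are deduplicated with
#' a warning; a line with fewer than three fields (i.e. no genes) is a
#' format error. A `source` tag is derived from a `SOURCE:` prefix of the
#' set id when present (e.g. `go:0030334` -> `go`).
#'
#' @param path Path to the GMT file.
#' @return Named list of gene sets; each element is a list with fields
#'   `set_id`, `name`, `source`, `genes` (unique character vector).
#' @export
read_gene_sets <- function(path) {
  raw <- readLines(path)
  raw <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  sets <- vector("list", length(raw))
  dup_sets <- character(0)
  for (i in seq_along(raw)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop("format error in GMT line ", i,
           ": need set_id, description and at least one gene", call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      dup_sets <- c(dup_sets, f[1])
      genes <- unique(genes)
    }
    src <- if (grepl(":", f[1], fixed = TRUE)) sub(":.*$", "", f[1]) else ""
    sets[[i]] <- list(set_id = f[1], name = f[2], source = src, genes = genes)
  }
  if (length(dup_sets))
    warning("duplicated gene symbols deduplicated in set(s): ",
            paste(dup_sets, collapse = ", "), call. = FALSE)
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(names(sets)))
    stop("duplicate set_id in ", path, call. = FALSE)
  sets
}

#' Format a p-value for display
#'
#' Two significant digits in scientific notation, the convention used for
#' the result tables (e.g. `0.0039014` -> `"3.9e-03"`).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), NA_character_,
                formatC(signif(p, 2), format = "e", digits = 1))
  out
}

#' Write a result table with display rounding
#'
#' Tab-delimited with header; every numeric column is written at full
#' precision, and display companions are appended using the table
#' conventions of the analysis: p-values to 2 significant digits
#' (scientific), odds ratios / confidence bounds / ratios to 2 decimals,
#' percentages to 1 decimal.
#'
#' @param records Homogeneous result data frame.
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header comment
#'   lines (used to record `seed` and `n_perm` for permutation-based
#'   outputs).
#' @export
write_results <- function(records, path, meta = NULL) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(records)) {
    x <- records[[nm]]
    if (!is.numeric(x)) next
    if (grepl("^p$|^p_|_p$|p_value", nm)) {
      out[[paste0(nm, "_display")]] <- format_pvalue(x)
    } else if (nm %in% c("odds_ratio", "ci_low", "ci_high", "ratio")) {
      out[[paste0(nm, "_display")]] <- ifelse(is.na(x), NA_character_,
                                              formatC(x, format = "f",
                                                      digits = 2))
    } else if (grepl("pct|percent", nm)) {
      out[[paste0(nm, "_display")]] <- ifelse(is.na(x), NA_character_,
                                              formatC(x, format = "f",
                                                      digits = 1))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, format, "")), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
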