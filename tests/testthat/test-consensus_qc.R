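iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end)
}

test_that("overlap fraction counts shared bases over the first interval", {
  expect_equal(overlap_fraction(iv("chr1", 100, 199), iv("chr1", 100, 199)),
               1.0)
  expect_equal(overlap_fraction(iv("chr1", 100, 199), iv("chr1", 300, 400)),
               0.0)
  expect_equal(overlap_fraction(iv("chr1", 100, 199), iv("chr1", 150, 249)),
               0.5)  # shared bases 150..199 = 50 of 100
  expect_equal(overlap_fraction(iv("chr1", 100, 199), iv("chr2", 100, 199)),
               0.0)
  # asymmetric: denominator is the first interval
  expect_equal(overlap_fraction(iv("chr1", 150, 249), iv("chr1", 100, 199)),
               0.5)
  expect_equal(overlap_fraction(iv("chr1", 100, 199), iv("chr1", 100, 399)),
               1.0)
})

test_that("consensus keeps same-direction calls at >= 10% overlap", {
  p <- mk_calls("S1", "chr1", 1001, 2000, 1)
  # identical call in both callers -> kept
  expect_equal(nrow(consensus_calls(p, p)), 1)
  # 50% overlap but opposite direction -> dropped
  dup <- mk_calls("S1", "chr1", 1501, 2500, 3)
  expect_equal(nrow(consensus_calls(p, dup)), 0)
  # 9% overlap -> dropped; 10% -> kept (primary call is the denominator)
  s9 <- mk_calls("S1", "chr1", 1911, 2500, 1)   # 90 of 1000 bases
  s10 <- mk_calls("S1", "chr1", 1901, 2500, 1)  # 100 of 1000 bases
  expect_equal(nrow(consensus_calls(p, s9)), 0)
  expect_equal(nrow(consensus_calls(p, s10)), 1)
  # kept calls retain primary boundaries
  kept <- consensus_calls(p, s10)
  expect_equal(kept$start, 1001L)
  expect_equal(kept$end, 2000L)
})

test_that("consensus drops samples present in only one call set", {
  p <- rbind(mk_calls("S1", "chr1", 1001, 2000, 1),
             mk_calls("S2", "chr1", 1001, 2000, 1))
  s <- mk_calls("S1", "chr1", 1001, 2000, 1)
  expect_warning(kept <- consensus_calls(p, s), "S2")
  expect_equal(kept$sample_id, "S1")
})

test_that("consensus is idempotent", {
  set.seed(42)
  n <- 60
  p <- mk_calls(sample(paste0("S", 1:6), n, replace = TRUE), "chr1",
                st <- sample.int(1e6, n), st + sample.int(5e4, n),
                sample(c(1, 3), n, replace = TRUE))
  s <- p
  s$start <- pmax(1L, s$start + sample(-2e4:2e4, n, replace = TRUE))
  s$end <- pmax(s$start, s$end + sample(-2e4:2e4, n, replace = TRUE))
  once <- consensus_calls(p, s)
  twice <- consensus_calls(once, s)
  expect_identical(twice, once)
})

test_that("call-quality boundaries follow the stated inequalities", {
  base <- mk_calls("S1", "chr1", 10001, 14000, 1, n_markers = 5,
                   confidence = 2.1)  # 4000 bp exactly
  expect_equal(nrow(filter_call_quality(base)), 1)
  lod2 <- base; lod2$confidence <- 2.0      # "larger than two" is strict
  expect_equal(nrow(filter_call_quality(lod2)), 0)
  short <- base; short$end <- 13999L        # 3999 bp
  expect_equal(nrow(filter_call_quality(short)), 0)
  few <- base; few$n_markers <- 4L
  expect_equal(nrow(filter_call_quality(few)), 0)
  mb <- base; mb$end <- base$start + 1000000L  # 1,000,001 bp
  expect_equal(nrow(filter_call_quality(mb)), 0)
  mb$end <- base$start + 999999L               # exactly 1 Mb kept
  expect_equal(nrow(filter_call_quality(mb)), 1)
})

test_that("call-level filters commute (intersection-of-keeps)", {
  set.seed(7)
  n <- 200
  calls <- mk_calls(paste0("S", sample(5, n, TRUE)), "chr1",
                    st <- sample.int(1e7, n),
                    st + sample(c(1e3, 5e3, 2e6), n, TRUE),
                    sample(c(0, 1, 3), n, TRUE),
                    n_markers = sample(3:8, n, TRUE),
                    confidence = runif(n, 0, 5))
  cfg <- qc_config()
  ab <- filter_call_quality(calls, cfg)
  # same result as applying sub-filters in any order
  conf_first <- calls[calls$confidence > 2, ]
  len <- cnv_length(conf_first)
  rest <- conf_first[conf_first$n_markers >= 5 & len >= 4000 &
                       len <= 1e6, ]
  expect_identical(ab, rest)
})

test_that("sample filters use strict inequalities and recompute metrics", {
  mk_n <- function(id, n) mk_calls(rep(id, n), "chr1",
                                   st <- seq(1, by = 20000, length.out = n),
                                   st + 9999, 1)
  calls <- rbind(mk_n("S110", 110), mk_n("S111", 111), mk_n("OK", 2))
  samples <- mk_samples(c("S110", "S111", "OK", "BAD_LRR"),
                        c("case", "case", "control", "control"),
                        lrr_sd = c(0.4, 0.1, 0.1, 0.41))
  fs <- filter_samples(calls, samples)
  expect_setequal(fs$samples$sample_id, c("S110", "OK"))  # 110 kept, 0.4 kept
  expect_false("S111" %in% fs$calls$sample_id)
  # metrics recomputed from surviving calls
  expect_equal(fs$samples$n_calls[fs$samples$sample_id == "OK"], 2L)
  expect_equal(fs$samples$total_cnv_length[fs$samples$sample_id == "OK"],
               20000)
  # report consistent with input - output
  expect_equal(sum(fs$report$n_removed),
               nrow(samples) - nrow(fs$samples))
  # total length rule: > 7.5 Mb removed
  big <- mk_calls("S1", "chr1", 1, 7500001, 1)
  s1 <- mk_samples("S1", "case")
  expect_equal(nrow(filter_samples(big, s1)$samples), 0)
  big$end <- 7500000L
  expect_equal(nrow(filter_samples(big, s1)$samples), 1)
  # missing metric errors with the sample name
  s_na <- mk_samples("S1", "case", lrr_sd = NA)
  expect_error(filter_samples(big, s_na), "S1")
})

test_that("segdup filter removes calls with > 50% union coverage", {
  cfg <- qc_config()
  call <- mk_calls("S1", "chr1", 1001, 2000, 1)
  inside <- data.frame(chrom = "chr1", start = 900, end = 2100)
  expect_equal(nrow(filter_segdup(call, inside, cfg)), 0)
  # two fragments covering 30% + 30% with 10% mutual overlap: union 50%,
  # kept at the boundary
  half <- data.frame(chrom = "chr1", start = c(1001, 1201),
                     end = c(1300, 1500))  # union 1001..1500 = 500 = 50%
  expect_equal(nrow(filter_segdup(call, half, cfg)), 1)
  over <- data.frame(chrom = "chr1", start = c(1001, 1201),
                     end = c(1300, 1501))  # 501 bases = 50.1%
  expect_equal(nrow(filter_segdup(call, over, cfg)), 0)
  # empty segdup table is the identity
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  expect_identical(filter_segdup(call, empty, cfg), call)
})

test_that("union segdup coverage matches a per-base oracle and kept calls
           never exceed 50%", {
  set.seed(11)
  for (rep in 1:20) {
    call <- mk_calls("S1", "chr1", 501, 1500, 1)
    k <- sample(1:4, 1)
    st <- sample(300:1600, k)
    regions <- data.frame(chrom = "chr1", start = st,
                          end = st + sample(50:600, k, replace = TRUE))
    frac <- rarecnv:::.segdup_cover_fraction(call, regions)
    expect_equal(frac, brute_cover_fraction(call, regions))
    kept <- filter_segdup(call, regions, qc_config())
    if (nrow(kept)) expect_lte(frac, 0.5)
  }
})

test_that("the full QC report accounts for every removed call and sample", {
  set.seed(3)
  n <- 150
  p <- mk_calls(paste0("S", sample(8, n, TRUE)), "chr1",
                st <- sample.int(5e6, n), st + sample(c(3e3, 1e4), n, TRUE),
                sample(c(1, 3), n, TRUE), n_markers = sample(4:9, n, TRUE),
                confidence = runif(n, 0, 6))
  samples <- mk_samples(paste0("S", 1:8),
                        rep(c("case", "control"), 4),
                        lrr_sd = c(0.1, 0.1, 0.45, rep(0.1, 5)))
  res <- run_qc(p, p, samples)
  calls_removed <- sum(res$report$n_removed[res$report$unit == "calls"])
  expect_equal(calls_removed, n - nrow(res$calls))
  samples_removed <- sum(res$report$n_removed[res$report$unit == "samples"])
  expect_equal(samples_removed, nrow(samples) - nrow(res$samples))
})
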