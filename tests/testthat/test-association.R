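test_that("Fisher worked examples reproduce the reported carrier tables", {
  expect_equal(signif(fisher_exact(5, 184, 0, 380), 2), 3.9e-3)
  expect_equal(signif(fisher_exact(7, 182, 0, 380), 2), 4.1e-4)
  expect_equal(fisher_exact(0, 10, 0, 20), 1)  # zero carrier margin
  expect_equal(fisher_exact(10, 0, 20, 0), 1)  # everyone a carrier
})

test_that("fisher_exact equals the enumeration oracle on small tables", {
  set.seed(1)
  for (rep in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:25, 1), rep(1, 4)))
    expect_equal(fisher_exact(cells[1], cells[2], cells[3], cells[4]),
                 fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("conditional MLE odds ratio matches reported values and oracle", {
  or <- odds_ratio_cmle(10, 179, 6, 374)
  expect_equal(round(or$estimate, 2), 3.47)
  expect_equal(round(or$ci_low, 2), 1.12)
  expect_equal(round(or$ci_high, 2), 11.82)
  # symmetric table -> estimate 1
  expect_equal(odds_ratio_cmle(5, 15, 5, 15)$estimate, 1,
               tolerance = 1e-6)
  # grid-search maximization of the conditional likelihood agrees
  got <- odds_ratio_cmle(3, 7, 1, 9)$estimate
  want <- or_cmle_oracle(3, 7, 1, 9)
  expect_equal(got, want, tolerance = 0.01)
  # zero cell: infinite estimate, finite lower bound
  z <- odds_ratio_cmle(5, 184, 0, 380)
  expect_equal(z$estimate, Inf)
  expect_true(is.finite(z$ci_low) && z$ci_low > 1)
  # no carriers anywhere: undefined
  expect_warning(nd <- odds_ratio_cmle(0, 10, 0, 20), "undefined")
  expect_true(is.na(nd$estimate))
})

test_that("min-p permutation obeys its formula and floor", {
  # battery of independent carrier tables over 20 samples
  samples <- mk_samples(paste0("S", 1:20),
                        rep(c("case", "control"), each = 10))
  M <- matrix(0, 3, 20, dimnames = list(NULL, samples$sample_id))
  M[1, 1:6] <- 1            # all six carriers are cases
  M[2, c(1, 11)] <- 1
  M[3, 10 + (1:6)] <- 1     # all six carriers are controls
  battery <- function(pheno) {
    case <- pheno == "case"
    apply(M, 1, function(m)
      fisher_exact(sum(m * case), sum(case) - sum(m * case),
                   sum(m * !case), sum(!case) - sum(m * !case)))
  }
  p_emp <- minp_permutation(battery, samples$phenotype, n_perm = 199,
                            seed = 4)
  expect_true(all(p_emp >= 1 / 200))
  expect_true(all(p_emp <= 1))
  # monotone in the unadjusted p within the battery
  p_obs <- battery(samples$phenotype)
  expect_true(all(diff(p_emp[order(p_obs)]) >= 0))
  # an observed p of 1 keeps p_empirical at 1
  expect_equal(p_emp[which.max(p_obs)], 1)
  expect_error(minp_permutation(battery, samples$phenotype, 0), "n_perm")
})

test_that("gene carrier counting is once-per-sample with >= 1 shared base", {
  genes <- mk_genes(c("G1", "G2"), "chr1", c(1000, 5000), c(2000, 6000))
  samples <- mk_samples(c("A", "B"), c("case", "control"))
  calls <- rbind(mk_calls("A", "chr1", 1100, 1200, 1),
                 mk_calls("A", "chr1", 1500, 1600, 1),  # same gene twice
                 mk_calls("A", "chr1", 4000, 4999, 1))  # ends 1 base short
  cc <- gene_carrier_counts(calls, genes, samples)
  expect_equal(cc$a[cc$symbol == "G1"], 1L)   # counted once
  expect_equal(cc$a[cc$symbol == "G2"], 0L)   # no shared base
  # single-base overlap is a carrier
  touch <- mk_calls("B", "chr1", 2000, 2500, 3)
  cc2 <- gene_carrier_counts(touch, genes, samples)
  expect_equal(cc2$c[cc2$symbol == "G1"], 1L)
})

test_that("the cell-migration fixture reproduces the reported gene counts", {
  fx <- cellmig_fixture()
  cc <- gene_carrier_counts(fx$calls, fx$genes, fx$samples)
  expect_equal(cc$a[cc$symbol == "PTPRK"], 2L)
  expect_equal(cc$a[cc$symbol == "CDH13"], 2L)
  expect_equal(cc$a[cc$symbol == "MUC2"], 1L)
  expect_equal(cc$a[cc$symbol == "MUC5AC"], 1L)
  expect_equal(cc$a[cc$symbol == "CORO1A"], 2L)
  # genes hit in cases only, per the reported table
  case_only <- c("BCL2", "CDH13", "CORO1A", "KDR", "MUC2", "MUC5AC",
                 "ONECUT2", "PTPRK")
  expect_true(all(cc$c[cc$symbol %in% case_only] == 0L))
  expect_equal(sum(cc$n_carriers > 0), 14L)
})

test_that("gene association degenerates to the unadjusted p for a single
           gene and attaches permutation metadata", {
  genes <- mk_genes("G1", "chr1", 1000, 2000)
  samples <- mk_samples(paste0("S", 1:30),
                        rep(c("case", "control"), each = 15))
  calls <- mk_calls(paste0("S", 1:5), "chr1", 1200, 1800, 1)
  res <- gene_association(calls, genes, samples, n_perm = 400, seed = 2)
  expect_equal(nrow(res), 1)
  # battery of one: FWER adjustment degenerates to the permutation p of
  # the single test, close to its exact p
  expect_equal(res$p_empirical, res$p_unadjusted, tolerance = 0.35)
  expect_equal(attr(res, "n_perm"), 400)
  # genes with no carriers are skipped
  far <- mk_genes("G2", "chr9", 1, 100)
  res2 <- gene_association(calls, rbind(genes, far), samples, n_perm = 50)
  expect_equal(res2$symbol, "G1")
})

test_that("locus scan collapses identical carrier sets and drops
           truncation edges", {
  samples <- mk_samples(paste0("S", 1:40),
                        rep(c("case", "control"), each = 20))
  # one wide call per carrier, one narrower: the edge intervals carried
  # only by the wide calls are truncation artifacts
  carriers_wide <- paste0("S", c(1:6, 21:22))
  carriers_narrow <- paste0("S", c(1:6, 21:22, 7:12, 23:24))
  calls <- rbind(mk_calls(carriers_wide, "chr1", 1000, 9000, 1),
                 mk_calls(carriers_narrow, "chr1", 3000, 7000, 1))
  sc <- locus_scan(calls, samples)
  # three elementary intervals; the two edges are subsets -> one test
  expect_equal(nrow(sc), 1)
  expect_equal(c(sc$start, sc$end), c(3000L, 7000L))
  expect_equal(attr(sc, "n_edge_excluded"), 2L)
  expect_equal(sc$a, 12L)
  expect_equal(sc$c, 4L)
  expect_equal(sc$p_unadjusted, fisher_exact(12, 8, 4, 16))
  # direction filter: no duplications -> empty scan
  expect_equal(nrow(locus_scan(calls, samples, direction = "dup")), 0)
  # identical carrier sets across adjacent intervals collapse to one test
  two_seg <- rbind(mk_calls(c("S1", "S2"), "chr2", 100, 500, 1),
                   mk_calls(c("S1", "S2"), "chr2", 400, 900, 1))
  sc2 <- locus_scan(two_seg, samples)
  expect_equal(nrow(sc2), 1)
  expect_equal(c(sc2$start, sc2$end), c(100L, 900L))
})

test_that("known-CNV flagging marks equal-frequency reference overlaps", {
  genes <- mk_genes(c("KCNB2like", "PTPN1like"), "chr1",
                    c(1000, 50000), c(2000, 60000))
  res <- data.frame(symbol = c("KCNB2like", "PTPN1like"),
                    a = c(7L, 5L), b = c(182L, 184L),
                    p_empirical = c(0.02, 0.04),
                    stringsAsFactors = FALSE)
  # reference CNVs at the first gene at matching frequency; none at the
  # second
  ref <- data.frame(chrom = "chr1", start = 900, end = 2100,
                    frequency = 7 / 189)
  out <- dgv_flag(res, ref, genes)
  expect_true(out$known_cnv_flag[1])
  expect_false(out$known_cnv_flag[2])
  # lower reference frequency does not flag
  ref$frequency <- 0.001
  expect_false(any(dgv_flag(res, ref, genes)$known_cnv_flag))
  # reference without frequencies: warn, flag nothing
  ref$frequency <- NA
  expect_warning(out3 <- dgv_flag(res, ref, genes), "no genes flagged")
  expect_false(any(out3$known_cnv_flag))
  # empty reference: no flags, no warning
  expect_silent(out4 <- dgv_flag(res, ref[0, ], genes))
  expect_false(any(out4$known_cnv_flag))
  # non-significant genes are never flagged
  res$p_empirical <- c(0.5, 0.5)
  ref$frequency <- 1
  expect_false(any(dgv_flag(res, ref, genes)$known_cnv_flag))
})
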