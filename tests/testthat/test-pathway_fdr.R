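mk_sets <- function(...) {
  sets <- list(...)
  names(sets) <- vapply(sets, `[[`, "", "set_id")
  sets
}

gs <- function(id, genes) list(set_id = id, name = id, source = "",
                               genes = genes)

test_that("the size filter is inclusive at 5 and 700 annotated genes", {
  genes <- mk_genes(paste0("G", 1:800), "chr1",
                    s <- seq(1, by = 1e4, length.out = 800), s + 5000)
  sets <- mk_sets(gs("four", paste0("G", 1:4)),
                  gs("five", paste0("G", 1:5)),
                  gs("s700", paste0("G", 1:700)),
                  gs("s701", paste0("G", 1:701)),
                  gs("ghost", c("NOPE1", "NOPE2")),
                  gs("mixed", c(paste0("G", 1:4), "NOPE3")))
  expect_warning(kept <- filter_gene_sets(sets, genes), "ghost")
  expect_setequal(names(kept), c("five", "s700"))
  # membership counted against the annotation: "mixed" has 4 real genes
  expect_false("mixed" %in% names(kept))
})

test_that("set carriers count once per sample over any member gene", {
  fx <- cellmig_fixture()
  cc <- set_carrier_counts(fx$calls, fx$genes, fx$sets, fx$samples)
  expect_equal(cc$a, 10L)
  expect_equal(cc$c, 6L)
  expect_equal(cc$n_genes, 14L)
  # a sample with calls in two member genes still counts once: sample
  # 210711 hits both MUC2 and MUC5AC
  expect_equal(sum(fx$calls$sample_id == "210711"), 1L)
  # a set disjoint from all calls has no carriers
  far <- mk_sets(gs("far", "NOWHERE"))
  genes2 <- rbind(fx$genes, mk_genes("NOWHERE", "chr21", 1, 1000))
  cc2 <- set_carrier_counts(fx$calls, genes2, far, fx$samples)
  expect_equal(cc2$a + cc2$c, 0L)
})

test_that("the signed-root G statistic behaves like a signed association
           measure", {
  expect_equal(set_statistic(5, 15, 5, 15), 0)
  # antisymmetry under swapping case and control
  expect_equal(set_statistic(10, 179, 6, 374),
               -set_statistic(6, 374, 10, 179))
  # matches the hand-computed G formula
  hand_g <- function(a, b, cc, d) {
    o <- c(a, b, cc, d)
    n1 <- a + b; n0 <- cc + d; k <- a + cc; N <- n1 + n0
    e <- c(n1 * k, n1 * (N - k), n0 * k, n0 * (N - k)) / N
    2 * sum(ifelse(o > 0, o * log(o / e), 0))
  }
  expect_equal(set_statistic(10, 179, 6, 374),
               sqrt(hand_g(10, 179, 6, 374)))
  # zero cells are fine
  expect_equal(set_statistic(5, 184, 0, 380),
               sqrt(hand_g(5, 184, 0, 380)))
  expect_lt(set_statistic(0, 189, 5, 375), 0)
})

test_that("local FDR estimates are proper probabilities with
           posterior + local_fdr = 1", {
  set.seed(33)
  z_obs <- c(rnorm(150), 3.5)
  z_perm <- matrix(rnorm(151 * 50), nrow = 50)
  eb <- ebam_local_fdr(z_obs, z_perm)
  expect_true(all(eb$local_fdr >= 0 & eb$local_fdr <= 1))
  expect_equal(eb$posterior + eb$local_fdr, rep(1, 151))
  p0 <- attr(eb, "p0")
  expect_true(p0 > 0 && p0 <= 1)
  # monotone on the positive tail: larger z never has larger local FDR
  # once past the fitted mode (checked on the sorted upper tail)
  up <- sort(z_obs[z_obs > 1.5])
  f <- eb$local_fdr[match(up, eb$z)]
  expect_true(all(diff(f) <= 1e-8))
})

test_that("degenerate local-FDR inputs are handled explicitly", {
  expect_error(ebam_local_fdr(rnorm(20), numeric(0)), "empty permutation")
  expect_warning(eb <- ebam_local_fdr(rep(1, 20), matrix(rnorm(100), 5)),
                 "identical")
  expect_equal(eb$local_fdr, rep(1, 20))
  set.seed(1)
  z <- rnorm(30)
  expect_warning(eb0 <- ebam_local_fdr(z, matrix(rnorm(300), 10), p0 = 0),
                 "degenerate")
  expect_equal(eb0$local_fdr, rep(0, 30))
})

test_that("null statistics mostly get high local FDR", {
  set.seed(12)
  n_sets <- 200
  n_perm <- 40
  z_obs <- rnorm(n_sets)
  z_perm <- matrix(rnorm(n_sets * n_perm), nrow = n_perm)
  eb <- ebam_local_fdr(z_obs, z_perm)
  expect_gte(mean(eb$local_fdr > 0.5), 0.95)
})

test_that("pathway association finds a planted set and names its driver", {
  set.seed(77)
  n_genes <- 60
  genes <- mk_genes(paste0("G", sprintf("%02d", 1:n_genes)), "chr1",
                    s <- seq(1e4, by = 1e5, length.out = n_genes),
                    s + 4e4)
  sets <- mk_sets(gs("hit", genes$symbol[1:10]),
                  gs("null1", genes$symbol[11:25]),
                  gs("null2", genes$symbol[26:40]),
                  gs("null3", genes$symbol[41:55]),
                  gs("null4", genes$symbol[c(2, 12, 22, 32, 42, 52)]),
                  gs("null5", genes$symbol[seq(5, 55, 5)]),
                  gs("null6", genes$symbol[seq(3, 57, 6)]),
                  gs("null7", genes$symbol[seq(4, 58, 6)]),
                  gs("null8", genes$symbol[seq(6, 54, 4)]),
                  gs("null9", genes$symbol[seq(7, 55, 4)]),
                  gs("nullA", genes$symbol[seq(8, 56, 4)]),
                  gs("nullB", genes$symbol[seq(9, 57, 4)]))
  samples <- mk_samples(c(sprintf("CA%03d", 1:189),
                          sprintf("CO%03d", 1:380)),
                        rep(c("case", "control"), c(189, 380)))
  # background: sparse random gene hits; planted: 12 extra case carriers
  # concentrated on one member gene of the "hit" set
  n_bg <- 150
  bg_gene <- sample(n_genes, n_bg, replace = TRUE)
  bg <- mk_calls(sample(samples$sample_id, n_bg, replace = TRUE), "chr1",
                 genes$start[bg_gene], genes$end[bg_gene],
                 sample(c(1, 3), n_bg, TRUE))
  driver <- genes$symbol[3]
  planted <- mk_calls(sprintf("CA%03d", 1:12), "chr1",
                      genes$start[3], genes$end[3], 1)
  res <- pathway_association(rbind(bg, planted), genes, sets, samples,
                             n_perm = 300, seed = 5)
  expect_equal(res$set_id[1], "hit")
  expect_equal(res$top_gene[res$set_id == "hit"], driver)
  expect_lt(res$local_fdr[1], res$local_fdr[nrow(res)])
  # excluding the driver gene removes the signal
  res2 <- pathway_association(rbind(bg, planted), genes, sets, samples,
                              n_perm = 300, seed = 5,
                              exclude_gene = driver)
  expect_gt(res2$local_fdr[res2$set_id == "hit"],
            res$local_fdr[res$set_id == "hit"])
  expect_error(pathway_association(bg, genes, sets, samples,
                                   exclude_gene = "ABSENT"), "ABSENT")
})
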