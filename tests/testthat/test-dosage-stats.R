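test_that("DE filtering requires FDR below cutoff in every clone with consistent sign", {
  mk <- function(lfc, fdr) data.frame(gene_id = sprintf("g%d", seq_along(lfc)),
                                      log2fc = lfc, fdr = fdr,
                                      stringsAsFactors = FALSE)
  a <- mk(c(-0.6, 0.5, -0.5, 0.2), c(0.04, 0.01, 0.01, 0.5))
  b <- mk(c(-0.4, -0.5, -0.4, 0.3), c(0.06, 0.01, 0.02, 0.6))
  out <- filter_de(list(a, b))
  # g1 fails clone 2 FDR; g2 fails sign consistency; g4 fails both FDRs
  expect_equal(out$gene_id, "g3")
  expect_equal(out$log2fc, -0.45)

  lit <- filter_de(list(a, b), require_sign_consistency = FALSE)
  expect_setequal(lit$gene_id, c("g2", "g3"))

  # differing universes restrict to the intersection with a warning
  b2 <- b[1:3, ]
  expect_warning(out2 <- filter_de(list(a, b2)), "intersection")
  expect_equal(attr(out2, "universe"), sprintf("g%d", 1:3))
})

test_that("orthologue translation keeps only 1:1 pairs", {
  o <- data.frame(
    gene_a = c("f1", "f2", "f3", "f3", "f4"),
    gene_b = c("m1", "m2", "m3", "m4", NA),
    one2one = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  res <- orthologue_set(c("f1", "f2", "f3", "f4"), o)
  expect_setequal(res$genes, c("m1", "m2"))
  expect_equal(unname(res$report["n_input"]), 4)
  expect_equal(unname(res$report["n_one2one"]), 2)
  full <- orthologue_set(c("f1", "f2"), o)
  expect_length(full$genes, 2)
})

test_that("HAS-proximal genes respect the inclusive 2344 bp boundary and exclude overlaps", {
  # HAS interval [10000, 10200), center 10100
  has <- genomic_intervals("chrX", 10000, 10200, id = "has1")
  ann <- gene_annotation(
    c("overlap", "at_boundary", "past_boundary", "other_chrom"),
    c("chrX", "chrX", "chrX", "chr2L"),
    c(10100, 10100 + 2344 + 1, 10100 + 2345 + 1, 10100),
    c(12000, 10100 + 2344 + 1500, 10100 + 2345 + 1500, 12000),
    rep("+", 4)
  )
  # distances from gene start to center: at_boundary = 2345? start = center + d + 1,
  # nearest base is start, distance = start - center
  res <- has_proximal_genes(ann, has, max_dist = 2344)
  expect_equal(res$overlapping, "overlap")
  expect_false("overlap" %in% res$proximal)
  expect_false("other_chrom" %in% res$proximal)
  # construct exact boundary cases directly
  ann2 <- gene_annotation(c("d2344", "d2345"), "chrX",
                          c(10100 + 2344, 10100 + 2345),
                          c(10100 + 2344 + 1500, 10100 + 2345 + 1500), c("+", "+"))
  res2 <- has_proximal_genes(ann2, has, max_dist = 2344)
  expect_equal(res2$proximal, "d2344")
})

test_that("bootstrap set test matches its definition and flags a planted shift", {
  set.seed(17)
  universe <- stats::setNames(rnorm(400, 0, 0.3), sprintf("g%03d", 1:400))
  gs <- names(universe)[1:10]
  res <- bootstrap_set_test(gs, universe, B = 500, alternative = "less", seed = 3)
  expect_equal(res$observed, mean(universe[gs]))
  expect_length(res$null, 500)
  expect_equal(res$p, (1 + sum(res$null <= res$observed)) / 501)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
  # reproducible given the seed
  res2 <- bootstrap_set_test(gs, universe, B = 500, alternative = "less", seed = 3)
  expect_identical(res$null, res2$null)

  # planted -0.5 shift on 66 genes, noise 0.3: decisively significant
  shifted <- universe
  shifted[1:66] <- shifted[1:66] - 0.5
  resS <- bootstrap_set_test(names(shifted)[1:66], shifted, B = 2000,
                             alternative = "less", seed = 4)
  expect_lt(resS$p, 0.001)

  # whole-universe set under with-replacement: two-sided p near 1
  resU <- bootstrap_set_test(names(universe), universe, B = 500,
                             alternative = "two_sided", seed = 5,
                             mode = "with_replacement")
  expect_gt(resU$p, 0.5)

  expect_error(bootstrap_set_test(names(universe), universe[1:10], B = 10),
               "not contained")
  expect_error(bootstrap_set_test(gs, universe, B = 0), "B must be")
  expect_error(bootstrap_set_test(names(universe)[1], universe, B = 10),
               "at least 2")
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (r in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("Welch test matches the closed form and handles degenerate input", {
  res <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674, tolerance = 5e-4)
  expect_equal(res$df, 4)
  # closed form: t = (mean(a)-mean(b)) / sqrt(va/na + vb/nb)
  a <- c(2.1, 3.5, 1.2, 4.4); b <- c(5.5, 6.1, 4.9)
  se <- sqrt(var(a) / 4 + var(b) / 3)
  tt <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 3)^2 / 2)
  res2 <- welch_t_test(a, b)
  expect_equal(res2$t, tt, tolerance = 1e-9)
  expect_equal(res2$df, df, tolerance = 1e-9)
  expect_equal(res2$p, 2 * pt(tt, df), tolerance = 1e-9)

  same <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  res3 <- welch_t_test(c(1, 2), c(5, 6), alternative = "less")
  expect_lt(res3$p, 0.5)
})

test_that("H4K16ac gain/loss classification is diagonal-based with concordance", {
  wt <- c(a = 2.0, b = 1.0, c = 0.5, d = 3.0)
  mut <- c(a = 1.5, b = 1.0, c = 0.8, d = 2.0)
  res <- classify_h4k16(wt, mut)
  expect_equal(unname(res$labels[c("a", "b", "c", "d")]),
               c("loss", "unchanged", "gain", "loss"))
  expect_true(is.na(res$concordance))

  lfc <- c(a = -1, c = 0.5, d = -0.2)
  res2 <- classify_h4k16(wt, mut, lfc)
  expect_equal(res2$concordance, 1.0)
  expect_warning(classify_h4k16(wt, mut[1:3]), "unpaired")

  # planted acetylation loss on downregulated genes: concordance >= 0.9
  w <- small_world()
  set1 <- w$annotation$gene_id[1:20]
  de <- simulate_de_tables(w$annotation, list(cluster1 = set1), w$cfg)
  lfc_all <- stats::setNames(de$clone_A$log2fc, de$clone_A$gene_id)
  wt_sc <- stats::setNames(rep(1, nrow(w$annotation)), w$annotation$gene_id)
  mut_sc <- wt_sc + 0.3 * sign(lfc_all) # acetylation tracks expression change
  res3 <- classify_h4k16(wt_sc, mut_sc, lfc_all)
  expect_gte(res3$concordance, 0.9)
})

test_that("qPCR efficiency and relative quantification follow their formulas", {
  dil <- data.frame(dilution = c(1, 0.1, 0.01, 0.001),
                    ct = 20 + 3.321928 * (0:3))
  expect_equal(qpcr_efficiency(dil), 2, tolerance = 1e-3)
  dil$ct <- 20 + 3.5 * (0:3)
  expect_equal(qpcr_efficiency(dil), 10^(1 / 3.5), tolerance = 1e-6)
  expect_error(qpcr_efficiency(dil[1:2, ]), "3 dilution")

  plate <- list(
    measurements = data.frame(gene = c("t", "r1", "r2", "r3"),
                              ct = c(19, 20, 20, 20)),
    efficiencies = c(t = 2, r1 = 2, r2 = 2, r3 = 2)
  )
  expect_equal(qpcr_relative(plate, "t", "r1"), 2)
  expect_equal(qpcr_relative(plate, "t", c("r1", "r2", "r3")), 2)
  # three references with quantities 1,2,4 and target 2 -> geomean 2 -> 1.0
  plate2 <- list(
    measurements = data.frame(gene = c("t", "a", "b", "c"),
                              ct = -log2(c(2, 1, 2, 4))),
    efficiencies = c(t = 2, a = 2, b = 2, c = 2)
  )
  expect_equal(qpcr_relative(plate2, "t", c("a", "b", "c")), 1.0)
  expect_error(qpcr_relative(plate, "t", "missing"), "not measured")

  # zero-noise simulated plate recovers generator truth ratios exactly
  cfg <- small_cfg(qpcr_ct_sd = 0)
  genes <- c("tgt", "RpL32", "Pfk", "U6")
  plate3 <- simulate_qpcr_plate(genes,
                                c(tgt = 3, RpL32 = 1, Pfk = 2, U6 = 0.5),
                                stats::setNames(c(2, 2, 1.9, 1.8), genes), cfg)
  rel <- qpcr_relative(plate3, "tgt", c("RpL32", "Pfk", "U6"))
  expect_equal(rel, 3 / exp(mean(log(c(1, 2, 0.5)))), tolerance = 1e-9)
  est_e <- qpcr_efficiency(plate3$dilution_series)
  expect_equal(unname(est_e[genes]), c(2, 2, 1.9, 1.8), tolerance = 1e-6)
})

test_that("conservation_test applies BH across sets", {
  set.seed(31)
  universe <- stats::setNames(rnorm(300, 0, 0.3), sprintf("g%03d", 1:300))
  universe[1:30] <- universe[1:30] - 0.6
  sets <- list(shifted = names(universe)[1:30],
               null1 = names(universe)[31:80],
               null2 = names(universe)[81:130])
  res <- conservation_test(sets, universe, B = 1000, seed = 9)
  expect_equal(res$p_adj, bh_adjust(res$p))
  expect_lt(res$p_adj[res$set == "shifted"], 0.05)
})
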