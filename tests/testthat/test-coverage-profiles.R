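test_that("fragment partition is exhaustive with an inclusive 140 bp small class", {
  frags <- data.frame(chrom = "c", start = 0, end = c(100, 140, 141, 300))
  pt <- partition_fragments(frags)
  expect_equal(pt$small$end, c(100, 140))
  expect_equal(pt$large$end, c(141, 300))
  expect_equal(nrow(pt$small) + nrow(pt$large), nrow(frags))

  set.seed(1)
  rnd <- data.frame(chrom = "c", start = 0,
                    end = sample(40:250, 500, replace = TRUE))
  pt <- partition_fragments(rnd)
  expect_true(all(pt$small$end - pt$small$start <= 140))
  expect_true(all(pt$large$end - pt$large$start > 140))
  expect_equal(nrow(pt$small) + nrow(pt$large), 500)
})

test_that("mapq filter keeps quality 10 and removes exact duplicates", {
  frags <- data.frame(chrom = "c", start = c(0, 0, 0, 10, 10),
                      end = c(50, 50, 50, 60, 60),
                      mapq = c(30, 30, 30, 9, 10))
  out <- filter_fragments(frags)
  expect_equal(nrow(out), 2) # one copy of the triplicate, mapq-10 kept
  expect_true(all(out$mapq >= 10))
  expect_equal(nrow(filter_fragments(frags[0, ])), 0)
})

test_that("raw coverage matches the per-base oracle and conserves mass", {
  g <- genome_model(c(chr1 = 10, chrX = 10), "chrX")
  tr <- coverage_track(data.frame(chrom = "chr1", start = 0, end = 4), g, 2)
  expect_equal(tr$values$chr1, c(1, 1, 0, 0, 0))
  expect_equal(tr$values$chrX, rep(0, 5))

  # linearity: stacking a fragment doubles its bins
  tr2 <- coverage_track(data.frame(chrom = "chr1", start = c(0, 0), end = c(4, 4)), g, 2)
  expect_equal(tr2$values$chr1, 2 * tr$values$chr1)

  for (seed in 1:3) {
    rt <- random_track(seed, L = 4001, binsize = 2)  # odd length: partial last bin
    expect_equal(rt$track$values$chrT,
                 brute_coverage(rt$frags, 4001, 2))
    mass <- sum(rt$track$values$chrT) * 2
    expect_equal(mass, sum(rt$frags$end - rt$frags$start), tolerance = 1e-12)
    # midpoint mode: one count per fragment
    mid <- coverage_track(rt$frags, rt$genome, 2, use = "midpoint")
    expect_equal(mid$values$chrT, brute_coverage(rt$frags, 4001, 2, "midpoint"))
    expect_equal(sum(mid$values$chrT) * 2, nrow(rt$frags))
  }
  expect_error(coverage_track(data.frame(chrom = "chr1", start = 5, end = 15), g, 2),
               "beyond chromosome end")
})

test_that("normalization modes implement their formulas with X excluded from scaling", {
  g <- genome_model(c(chrA = 100, chrX = 100), "chrX")
  chip <- dosagelens:::new_coverage_track(
    list(chrA = rep(3, 50), chrX = rep(3, 50)), 2, g, "raw")
  ctrl <- dosagelens:::new_coverage_track(
    list(chrA = rep(1, 50), chrX = rep(1, 50)), 2, g, "raw")

  # identical tracks -> log2 ratio zero
  lr0 <- normalize_tracks(chip, chip, "log2_ratio")
  expect_true(all(abs(unlist(lr0$values)) < 1e-12))

  # depth equalization scales chip (mass 300) down to control mass (100):
  # bins become 1 vs 1 -> ratio 0; with equal depths 3 vs 1, pc 1 -> 1 bit
  chip1 <- dosagelens:::new_coverage_track(
    list(chrA = c(3, rep(1, 49)), chrX = rep(1, 50)), 2, g, "raw")
  ctrl1 <- dosagelens:::new_coverage_track(
    list(chrA = c(1, rep(1, 49)), chrX = rep(1, 50)), 2, g, "raw")
  # totals on chrA differ slightly; use equal-mass tracks for the formula check
  chip2 <- dosagelens:::new_coverage_track(
    list(chrA = c(3, 1, rep(1, 48)), chrX = rep(1, 50)), 2, g, "raw")
  ctrl2 <- dosagelens:::new_coverage_track(
    list(chrA = c(1, 3, rep(1, 48)), chrX = rep(1, 50)), 2, g, "raw")
  lr <- normalize_tracks(chip2, ctrl2, "log2_ratio", pseudocount = 1)
  expect_equal(lr$values$chrA[1], log2((3 + 1) / (1 + 1)))
  sub <- normalize_tracks(chip2, ctrl2, "subtract")
  expect_equal(sub$values$chrA[1], 2)
  expect_equal(sub$values$chrA[3], 0)

  # one_x: autosomal mean per-base coverage exactly 1
  sim <- local({
    w <- small_world()
    simulate_chip_experiment(w$genome, w$sites, w$cfg, "male", "msl2")
  })
  w <- small_world()
  raw <- coverage_track(filter_fragments(sim$input), w$genome, 2)
  one <- normalize_tracks(raw, mode = "one_x")
  auto_mean <- mean(unlist(one$values[autosomes(w$genome)]))
  expect_equal(auto_mean, 1, tolerance = 1e-9)

  bad <- dosagelens:::new_coverage_track(list(chrA = rep(1, 25), chrX = rep(1, 25)), 4, g, "raw")
  expect_error(normalize_tracks(chip, bad, "subtract"), "binsize mismatch")
  zero <- dosagelens:::new_coverage_track(list(chrA = rep(0, 50), chrX = rep(0, 50)), 2, g, "raw")
  expect_error(normalize_tracks(zero, mode = "one_x"), "zero total")
})

test_that("reference-point matrices equal the brute-force resampler, with strand flips and edge masking", {
  rt <- random_track(11, L = 8000, binsize = 2)
  set.seed(12)
  n <- 25
  centers <- c(sample(500:7500, n - 2), 100, 7950) # two rows out of bounds
  regions <- genomic_intervals(rep("chrT", n), centers - 50, centers + 50,
                               strand = sample(c("+", "-"), n, replace = TRUE))
  sm <- matrix_reference_point(rt$track, regions, flank = 400, binsize = 10)
  expect_equal(dim(sm$matrix), c(n, 80))
  for (i in seq_len(n)) {
    expect_equal(unname(sm$matrix[i, ]),
                 brute_refpoint_row(rt$track$values$chrT, 2, 8000,
                                    floor((regions$start[i] + regions$end[i]) / 2),
                                    400, 10, regions$strand[i]))
  }
  expect_true(anyNA(sm$matrix)) # out-of-bounds rows carry the mask
  expect_error(matrix_reference_point(rt$track, regions, flank = 405, binsize = 10),
               "multiple")

  # uniform track gives an all-ones matrix
  g <- rt$genome
  unif <- dosagelens:::new_coverage_track(
    list(chrT = rep(1, 4000), chrX = rep(1, 4000)), 2, g, "raw")
  smu <- matrix_reference_point(unif, regions[1:5, ], 400, 10)
  expect_true(all(smu$matrix == 1))

  # mirror-image property for opposite strands over the same window
  reg2 <- genomic_intervals(c("chrT", "chrT"), c(3000, 3000), c(3100, 3100),
                            strand = c("+", "-"))
  smm <- matrix_reference_point(rt$track, reg2, 400, 10)
  expect_equal(unname(smm$matrix[1, ]), rev(unname(smm$matrix[2, ])))
})

test_that("scaled-region matrices equal the brute-force resampler and scale invariantly", {
  rt <- random_track(13, L = 10000, binsize = 2)
  set.seed(14)
  genes <- gene_annotation(
    sprintf("g%02d", 1:8), "chrT",
    start = c(600, 1800, 3100, 4500, 5600, 7000, 8300, 200),
    end = c(600, 1800, 3100, 4500, 5600, 7000, 8300, 200) +
      c(1500, 2200, 900, 1200, 3000, 1100, 1600, 501),
    strand = c("+", "-", "+", "-", "+", "-", "+", "+")
  )
  sm <- matrix_scaled_region(rt$track, genes, unscaled = 500, body_bp = 1000,
                             binsize = 10)
  expect_equal(ncol(sm$matrix), 200)
  kept <- rownames(sm$matrix)
  for (gid in kept) {
    gi <- genes[genes$gene_id == gid, ]
    expect_equal(unname(sm$matrix[gid, ]),
                 brute_scaled_row(rt$track$values$chrT, 2, 10000, gi$tss,
                                  gi$start, gi$end, gi$strand, 500, 1000, 10))
  }
  # genes with body <= unscaled flank are dropped with a warning
  short <- gene_annotation("tiny", "chrT", 1000, 1400, "+")
  expect_warning(matrix_scaled_region(rt$track, rbind(genes, short)),
                 "dropped")

  # uniform track: all-ones rows regardless of gene length
  unif <- dosagelens:::new_coverage_track(
    list(chrT = rep(1, 5000), chrX = rep(1, 5000)), 2, rt$genome, "raw")
  smu <- matrix_scaled_region(unif, genes)
  expect_true(all(smu$matrix[, ] == 1, na.rm = TRUE))

  # signal confined to the last 10% of the body lands in the last 10% of
  # the scaled segment for any gene length
  for (Lg in c(1500, 2500, 6000)) {
    v <- rep(0, 5000)
    gene <- gene_annotation("g", "chrT", 1000, 1000 + Lg, "+")
    body_last <- seq(1000 + 500 + ceiling(0.9 * (Lg - 500)), 1000 + Lg - 1)
    v[(body_last %/% 2) + 1] <- 1
    trk <- dosagelens:::new_coverage_track(
      list(chrT = v, chrX = rep(0, 5000)), 2, rt$genome, "raw")
    row <- matrix_scaled_region(trk, gene)$matrix[1, ]
    body_cols <- 101:200
    hot <- which(row[body_cols] > 0)
    expect_true(all(hot >= 89))
    expect_gt(length(hot), 0)
  }
})

test_that("region scores are overlap-weighted bin means", {
  g <- genome_model(c(c1 = 30, chrX = 30), "chrX")
  trk <- dosagelens:::new_coverage_track(
    list(c1 = c(2, 4, 6), chrX = rep(0, 3)), 10, g, "raw")
  iv <- genomic_intervals(c("c1", "c1", "c1"), c(10, 0, 5), c(20, 30, 25))
  s <- region_score(trk, iv)
  expect_equal(unname(s[1]), 4)       # exactly one bin
  expect_equal(unname(s[2]), 4)       # full mean of 2,4,6
  expect_equal(unname(s[3]), (2 * 5 + 4 * 10 + 6 * 5) / 20) # weighted
  expect_length(region_score(trk, iv[0, ]), 0)
  # uniform track scores c for any interval
  unif <- dosagelens:::new_coverage_track(
    list(c1 = rep(7, 3), chrX = rep(7, 3)), 10, g, "raw")
  expect_equal(unname(region_score(unif, iv)), rep(7, 3))
})

test_that("footprint recovery: small fragments peak at site centers, large at phased offsets", {
  w <- small_world(chrom_length_bp = 2e5, n_genes_per_chrom = 40L,
                   n_has = 20L)
  sim <- simulate_chip_experiment(w$genome, w$sites, w$cfg, "male", "msl2")
  f <- filter_fragments(sim$chip)
  pt <- partition_fragments(f)
  has <- w$sites[w$sites$class == "HAS", ]
  prof_s <- matrix_profile(matrix_reference_point(
    coverage_track(pt$small, w$genome, 2, use = "midpoint"), has, 800, 10))
  prof_l <- matrix_profile(matrix_reference_point(
    coverage_track(pt$large, w$genome, 2, use = "midpoint"), has, 800, 10))
  nc <- length(prof_s)
  center_cols <- c(nc / 2, nc / 2 + 1)
  expect_true(which.max(prof_s) %in% center_cols)
  # planted offsets -200/+200 -> columns 60/61 and 100/101 (+/- 1 bin)
  left <- which.max(prof_l[1:(nc / 2)])
  right <- nc / 2 + which.max(prof_l[(nc / 2 + 1):nc])
  expect_true(abs(left - 60.5) <= 1.5)
  expect_true(abs(right - 100.5) <= 1.5)
})
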