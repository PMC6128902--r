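# Small synthetic study used across unit tests: 3 chromosomes of 60 kb,
# 20 genes each, 10 HAS and 5 autosomal sites per cluster.

small_cfg <- function(seed = 42, ...) {
  defaults <- list(chrom_length_bp = 6e4, n_genes_per_chrom = 20L,
                   n_has = 10L, n_auto_sites_per_cluster = c(5L, 5L, 5L),
                   site_emission_rate = 100, flash_depth = 300L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_world <- function(seed = 42, ...) {
  cfg <- small_cfg(seed, ...)
  gm <- make_genome(cfg)
  ps <- plant_sites(gm$genome, gm$annotation, cfg)
  list(cfg = cfg, genome = gm$genome, annotation = gm$annotation,
       sites = ps$sites, truth = ps$truth)
}

# A raw coverage track built from random fragments on a short genome,
# for matrix-geometry tests.
random_track <- function(seed, L = 10000, binsize = 2, n_frags = 400) {
  set.seed(seed)
  g <- genome_model(c(chrT = L, chrX = L), "chrX")
  start <- sample.int(L - 300, n_frags) - 1
  len <- sample(30:250, n_frags, replace = TRUE)
  frags <- data.frame(chrom = "chrT", start = start, end = start + len)
  list(genome = g, track = coverage_track(frags, g, binsize), frags = frags)
}
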