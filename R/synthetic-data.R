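# Synthetic-data generator: produces every input the pipeline consumes with
# planted ground truth, emulating the study design of a fly-like dosage
# compensation experiment — an X chromosome carrying high-affinity sites
# (HAS), autosomal promoter-bound site clusters, male X monosomy visible in
# input coverage, MNase-style footprint/nucleosomal fragment classes, FLASH
# libraries with barcodes + random tags + PCR duplication, per-clone DE
# tables with a planted shift, and qPCR plates with known efficiencies.

#' Simulation configuration
#'
#' Central configuration for all generators. Defaults define the package's
#' reference synthetic study: a small two-arm autosomal genome plus one X,
#' footprint fragments well below the 140 bp partition boundary and
#' nucleosomal fragments well above it, flanking nucleosomes phased at
#' +/-200 bp of bound sites, a single-copy X in males, and a planted
#' -0.5 log2FC downregulation of the cluster-1 orthologue set.
#'
#' @param n_autosomes number of autosomes.
#' @param chrom_length_bp length of every chromosome (bp).
#' @param n_genes_per_chrom genes per chromosome.
#' @param n_has number of X high-affinity sites.
#' @param n_auto_sites_per_cluster integer vector of length 3: autosomal
#'   site counts for clusters 1-3.
#' @param footprint_len_mean,footprint_len_sd footprint fragment length
#'   (bp); truncated to \[40, 140\] so the class lands at or below the
#'   140 bp partition boundary by construction.
#' @param nucleosomal_len_mean,nucleosomal_len_sd nucleosomal fragment
#'   length (bp); truncated to \[141, 250\].
#' @param phased_offsets_bp centers of the phased flanking nucleosomes
#'   relative to a bound-site center (bp).
#' @param background_rate background fragments per bp per diploid locus.
#' @param site_emission_rate expected ChIP fragments emitted per bound site
#'   (per diploid locus).
#' @param male_x_ploidy,female_x_ploidy X copy number by sex.
#' @param flash_barcodes sample barcodes (equal length, pairwise Hamming
#'   distance >= 5 so distance-2 demultiplexing is unambiguous).
#' @param umi_len random-tag (UMI) length in nt.
#' @param pcr_dup_mean expected PCR duplicates per unique molecule.
#' @param flash_depth expected unique FLASH molecules per library.
#' @param flash_insert_len insert length of synthetic FLASH reads (nt).
#' @param de_effect_cluster1 planted mean log2FC shift of the cluster-1 set.
#' @param de_noise_sd per-gene log2FC noise sd.
#' @param low_mapq_frac fraction of ChIP fragments given mapping quality
#'   below 10 (for filter testing).
#' @param dup_frac fraction of ChIP fragments duplicated exactly (for
#'   duplicate-removal testing).
#' @param footprint_frac fraction of site-emitted fragments that are
#'   footprints (the rest are phased nucleosomal fragments).
#' @param site_jitter_sd positional jitter sd of fragment centers around
#'   their target (bp).
#' @param qpcr_ct_sd Ct measurement noise sd (cycles).
#' @param seed master seed; each generator derives a named substream from
#'   it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_autosomes = 2L,
                       chrom_length_bp = 3e5,
                       n_genes_per_chrom = 60L,
                       n_has = 30L,
                       n_auto_sites_per_cluster = c(20L, 20L, 20L),
                       footprint_len_mean = 90, footprint_len_sd = 15,
                       nucleosomal_len_mean = 165, nucleosomal_len_sd = 12,
                       phased_offsets_bp = c(-200L, 200L),
                       background_rate = 0.02,
                       site_emission_rate = 150,
                       male_x_ploidy = 1L, female_x_ploidy = 2L,
                       flash_barcodes = c("ACGTCA", "TGACAT", "GTCAGC", "CATGTG"),
                       umi_len = 7L,
                       pcr_dup_mean = 3,
                       flash_depth = 1500L,
                       flash_insert_len = 40L,
                       de_effect_cluster1 = -0.5,
                       de_noise_sd = 0.3,
                       low_mapq_frac = 0.05,
                       dup_frac = 0.05,
                       footprint_frac = 0.5,
                       site_jitter_sd = 10,
                       qpcr_ct_sd = 0.15,
                       seed = 1L) {
  cfg <- as.list(environment())
  lens <- c(cfg$chrom_length_bp, cfg$footprint_len_mean, cfg$nucleosomal_len_mean,
            cfg$umi_len, cfg$flash_insert_len)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (cfg$footprint_len_mean > 140) {
    stop("footprint_len_mean must be <= 140 so footprints land in the small class")
  }
  if (cfg$nucleosomal_len_mean <= 140) {
    stop("nucleosomal_len_mean must be > 140 so nucleosomal fragments land in the large class")
  }
  if (length(cfg$n_auto_sites_per_cluster) != 3) {
    stop("n_auto_sites_per_cluster must have length 3")
  }
  bc <- cfg$flash_barcodes
  if (length(unique(nchar(bc))) != 1) stop("barcodes must have equal length")
  if (length(bc) > 1) {
    for (i in seq_along(bc)[-1]) {
      d <- hamming_to_each(bc[i], bc[seq_len(i - 1)])
      if (any(d < 5)) {
        stop("barcode collision: pairwise Hamming distance must be >= 5")
      }
    }
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic genome and gene annotation
#'
#' Builds one X chromosome plus `n_autosomes` autosomes of equal length and
#' places non-overlapping genes with bodies of at least 1.5 kb (so that
#' scaled-gene-body matrices are defined for every gene). Deterministic
#' given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genome` (a `genome_model`) and `annotation`
#'   (a [gene_annotation()] data.frame).
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_auto <- cfg$n_autosomes
  auto_names <- if (n_auto <= 4) c("chr2L", "chr2R", "chr3L", "chr3R")[seq_len(n_auto)]
                else paste0("chrA", seq_len(n_auto))
  chroms <- c("chrX", auto_names)
  L <- cfg$chrom_length_bp
  genome <- genome_model(stats::setNames(rep(L, length(chroms)), chroms), "chrX")

  min_body <- 1500
  slot <- floor(L / cfg$n_genes_per_chrom)
  if (slot < min_body + 200) {
    stop("sizing error: chromosome too short to host ", cfg$n_genes_per_chrom,
         " non-overlapping genes with bodies >= ", min_body, " bp")
  }
  set.seed(substream_seed(cfg$seed, "genome"))
  ann <- do.call(rbind, lapply(chroms, function(ch) {
    n <- cfg$n_genes_per_chrom
    body <- round(stats::runif(n, min_body, min(4000, slot - 150)))
    offset <- vapply(seq_len(n), function(i) {
      round(stats::runif(1, 0, slot - body[i] - 1))
    }, numeric(1))
    start <- (seq_len(n) - 1) * slot + offset
    data.frame(
      gene_id = sprintf("%s_g%03d", ch, seq_len(n)),
      chrom = ch, start = start, end = start + body,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  list(
    genome = genome,
    annotation = gene_annotation(ann$gene_id, ann$chrom, ann$start, ann$end,
                                 ann$strand, genome = genome)
  )
}

#' Plant bound sites with ground truth
#'
#' Places `n_has` high-affinity sites (HAS) on the X and three clusters of
#' autosomal sites, each centered within 200 bp of a distinct autosomal
#' gene TSS so the promoter-assignment stage can recover the links.
#'
#' @param genome a `genome_model`.
#' @param annotation gene annotation from [make_genome()].
#' @param cfg a [sim_config()].
#' @return list with `sites` (interval data.frame with a `class` column,
#'   classes `HAS`, `cluster1`, `cluster2`, `cluster3`) and `truth`
#'   (site_id, class, chrom, center, gene_id; NA gene for HAS).
#' @export
plant_sites <- function(genome, annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(annotation) == 0) stop("annotation is empty")
  set.seed(substream_seed(cfg$seed, "sites"))
  half <- 100
  Lx <- genome$lengths[[genome$x_chrom]]

  has_centers <- if (cfg$n_has > 0) {
    sort(sample(seq(1000, Lx - 1000), cfg$n_has))
  } else integer(0)
  rows <- list()
  if (cfg$n_has > 0) {
    rows[[1]] <- data.frame(
      chrom = genome$x_chrom, center = has_centers, class = "HAS",
      gene_id = NA_character_, stringsAsFactors = FALSE
    )
  }
  auto_genes <- annotation[annotation$chrom != genome$x_chrom, ]
  n_needed <- sum(cfg$n_auto_sites_per_cluster)
  if (n_needed > nrow(auto_genes)) {
    stop("more autosomal sites requested (", n_needed, ") than autosomal genes (",
         nrow(auto_genes), ")")
  }
  if (n_needed > 0) {
    host <- auto_genes[sample(nrow(auto_genes), n_needed), ]
    cls <- rep(paste0("cluster", 1:3), times = cfg$n_auto_sites_per_cluster)
    center <- host$tss + sample(-100:100, n_needed, replace = TRUE)
    center <- pmin(pmax(center, half), genome$lengths[host$chrom] - half)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = host$chrom, center = center, class = cls,
      gene_id = host$gene_id, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, rows)
  if (is.null(truth)) {
    truth <- data.frame(chrom = character(0), center = numeric(0),
                        class = character(0), gene_id = character(0))
  }
  truth$site_id <- sprintf("site_%03d", seq_len(nrow(truth)))
  sites <- genomic_intervals(truth$chrom, truth$center - half,
                             truth$center + half, id = truth$site_id,
                             genome = genome)
  sites$class <- truth$class
  list(sites = sites, truth = truth[, c("site_id", "class", "chrom", "center", "gene_id")])
}

#' Simulate an MNase ChIP experiment
#'
#' Emits fragments with the MNase ChIP signature at bound sites: short
#' protected footprints centered on the site plus nucleosome-scale
#' fragments at the configured phased offsets, over a uniform background.
#' The matched input carries background only. Fragment rates on the X scale
#' with sex ploidy, so male input shows the X at half autosomal coverage.
#' A configurable fraction of fragments is given mapping quality below 10
#' and a fraction is duplicated exactly, for filter testing.
#'
#' @param genome,sites from [make_genome()]/[plant_sites()] (`sites` may be
#'   the full site table; the antibody selects which classes are bound).
#' @param cfg a [sim_config()].
#' @param sex `"male"` or `"female"`.
#' @param antibody `"msl2"` (binds HAS and all autosomal clusters),
#'   `"mle"` (binds HAS only), or `"input"` (no sites).
#' @return list with fragment data.frames `chip` and `input` (columns
#'   chrom, start, end, mapq, dup_flag).
#' @export
simulate_chip_experiment <- function(genome, sites, cfg, sex = "male",
                                     antibody = "msl2") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!sex %in% c("male", "female")) stop("unknown sex: ", sex)
  bound_classes <- switch(antibody,
    msl2 = c("HAS", "cluster1", "cluster2", "cluster3"),
    mle = "HAS",
    input = character(0),
    stop("unknown antibody: ", antibody)
  )
  tag <- sum(utf8ToInt(paste0(sex, antibody)))
  set.seed((substream_seed(cfg$seed, "fragments") + tag) %% 2147483629)

  x_ploidy <- if (sex == "male") cfg$male_x_ploidy else cfg$female_x_ploidy
  ploidy_factor <- function(chrom) {
    ifelse(chrom == genome$x_chrom, x_ploidy / 2, 1)
  }

  draw_lengths <- function(n, kind) {
    if (n == 0) return(numeric(0))
    if (kind == "footprint") {
      round(rnorm_trunc(n, cfg$footprint_len_mean, cfg$footprint_len_sd, 40, 140))
    } else {
      round(rnorm_trunc(n, cfg$nucleosomal_len_mean, cfg$nucleosomal_len_sd, 141, 250))
    }
  }
  frags_from <- function(chrom, center, len, L) {
    start <- pmin(pmax(round(center - len / 2), 0), L - len)
    data.frame(chrom = chrom, start = start, end = start + len,
               stringsAsFactors = FALSE)
  }

  background <- function() {
    do.call(rbind, lapply(genome$chroms, function(ch) {
      L <- genome$lengths[[ch]]
      n <- stats::rpois(1, cfg$background_rate * L * ploidy_factor(ch))
      if (n == 0) return(NULL)
      is_fp <- stats::runif(n) < 0.5
      len <- numeric(n)
      len[is_fp] <- draw_lengths(sum(is_fp), "footprint")
      len[!is_fp] <- draw_lengths(sum(!is_fp), "nucleosomal")
      frags_from(ch, stats::runif(n, 0, L), len, L)
    }))
  }

  site_signal <- function() {
    use <- sites[sites$class %in% bound_classes, , drop = FALSE]
    if (nrow(use) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(use)), function(i) {
      ch <- use$chrom[i]
      L <- genome$lengths[[ch]]
      center <- floor((use$start[i] + use$end[i]) / 2)
      n <- stats::rpois(1, cfg$site_emission_rate * ploidy_factor(ch))
      if (n == 0) return(NULL)
      is_fp <- stats::runif(n) < cfg$footprint_frac
      n_fp <- sum(is_fp); n_nuc <- n - n_fp
      parts <- list()
      if (n_fp > 0) {
        c_fp <- center + stats::rnorm(n_fp, 0, cfg$site_jitter_sd)
        parts$fp <- frags_from(ch, c_fp, draw_lengths(n_fp, "footprint"), L)
      }
      if (n_nuc > 0) {
        off <- sample(cfg$phased_offsets_bp, n_nuc, replace = TRUE)
        c_nuc <- center + off + stats::rnorm(n_nuc, 0, cfg$site_jitter_sd)
        parts$nuc <- frags_from(ch, c_nuc, draw_lengths(n_nuc, "nucleosomal"), L)
      }
      do.call(rbind, parts)
    }))
  }

  decorate <- function(df) {
    if (is.null(df) || nrow(df) == 0) {
      return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                        mapq = integer(0), dup_flag = integer(0)))
    }
    n <- nrow(df)
    df$mapq <- rep(30L, n)
    low <- stats::runif(n) < cfg$low_mapq_frac
    df$mapq[low] <- sample(0:9, sum(low), replace = TRUE)
    df$dup_flag <- 0L
    n_dup <- floor(cfg$dup_frac * n)
    if (n_dup > 0) {
      dup <- df[sample(n, n_dup), ]
      dup$dup_flag <- 1L
      df <- rbind(df, dup)
    }
    rownames(df) <- NULL
    df
  }

  chip <- decorate(rbind(background(), site_signal()))
  input <- decorate(background())
  attr(chip, "label") <- list(sex = sex, antibody = antibody, sample = "chip")
  attr(input, "label") <- list(sex = sex, antibody = "input", sample = "input")
  list(chip = chip, input = input)
}

#' Simulate a FLASH library
#'
#' Generates paired reads whose merged sequence begins with the library
#' barcode followed by a random tag (UMI) and the insert. Unique molecules
#' are sampled per gene in proportion to the supplied crosslink rates and
#' each molecule is sequenced `1 + Poisson(pcr_dup_mean)` times (its PCR
#' duplicates share the UMI and insert). Read pairs are constructed with a
#' guaranteed overlap above the 30 nt merging threshold. Because genome
#' alignment is out of scope, an alignment table (read id, gene, mapping
#' quality) accompanies the reads, emulating the aligner output.
#'
#' @param annotation gene annotation; every gene in `enrichment_map` must
#'   be present.
#' @param enrichment_map named numeric vector of relative crosslink rates
#'   per gene (genes absent from the map have rate 0).
#' @param cfg a [sim_config()].
#' @param barcode the library barcode; must be one of
#'   `cfg$flash_barcodes`.
#' @return list with `fwd`/`rev` read data.frames (id, seq, qual),
#'   `alignment` (read_id, gene_id, mapq), `truth` (gene_id, n_unique) and
#'   `barcode`.
#' @export
simulate_flash_library <- function(annotation, enrichment_map, cfg,
                                   barcode = cfg$flash_barcodes[1]) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!barcode %in% cfg$flash_barcodes) stop("barcode not in configured whitelist")
  unknown <- setdiff(names(enrichment_map), annotation$gene_id)
  if (length(unknown)) stop("unknown gene(s) in enrichment_map: ",
                            paste(utils::head(unknown, 3), collapse = ", "))
  tag <- sum(utf8ToInt(barcode))
  set.seed((substream_seed(cfg$seed, "flash") + tag) %% 2147483629)

  rates <- enrichment_map[enrichment_map > 0]
  n_mol <- if (length(rates)) {
    stats::setNames(stats::rpois(length(rates), rates / sum(rates) * cfg$flash_depth),
                    names(rates))
  } else integer(0)
  n_mol <- n_mol[n_mol > 0]

  fwd <- list(); rev <- list(); aln <- list()
  read_i <- 0L
  for (g in names(n_mol)) {
    k <- n_mol[[g]]
    # distinct within the gene: duplicate-removal then recovers the unique
    # molecule count exactly (no random-tag birthday collisions)
    umis <- random_dna_distinct(k, cfg$umi_len)
    inserts <- random_dna(k, cfg$flash_insert_len)
    copies <- 1L + stats::rpois(k, cfg$pcr_dup_mean)
    for (j in seq_len(k)) {
      merged <- paste0(barcode, umis[j], inserts[j])
      L <- nchar(merged)
      rlen <- L - 8L  # pair overlap = 2*rlen - L = L - 16, comfortably > 30
      f <- substr(merged, 1, rlen)
      r <- revcomp(substr(merged, L - rlen + 1, L))
      for (cp in seq_len(copies[j])) {
        read_i <- read_i + 1L
        id <- sprintf("rd_%s_%06d", barcode, read_i)
        fwd[[read_i]] <- c(id, f)
        rev[[read_i]] <- c(id, r)
        aln[[read_i]] <- c(id, g)
      }
    }
  }
  to_df <- function(lst) {
    if (length(lst) == 0) {
      return(data.frame(id = character(0), seq = character(0), qual = character(0)))
    }
    m <- do.call(rbind, lst)
    data.frame(id = m[, 1], seq = m[, 2],
               qual = strrep("I", nchar(m[, 2])), stringsAsFactors = FALSE)
  }
  aln_df <- if (length(aln)) {
    m <- do.call(rbind, aln)
    data.frame(read_id = m[, 1], gene_id = m[, 2], mapq = 30L,
               stringsAsFactors = FALSE)
  } else data.frame(read_id = character(0), gene_id = character(0), mapq = integer(0))
  truth <- data.frame(gene_id = names(n_mol), n_unique = as.integer(n_mol),
                      stringsAsFactors = FALSE)
  list(fwd = to_df(fwd), rev = to_df(rev), alignment = aln_df,
       truth = truth, barcode = barcode)
}

#' Simulate per-clone differential-expression tables
#'
#' Produces two knockout-clone DE tables over the full gene universe with a
#' planted, deterministic per-gene log2FC shift (the cluster-1 set by
#' default) plus independent Gaussian noise per clone. P-values come from a
#' one-sample z-model on the observed log2FC with known noise sd, adjusted
#' by Benjamini-Hochberg within each clone, so strongly shifted genes pass
#' FDR < 0.05 while null genes pass at about the nominal rate.
#'
#' @param annotation gene annotation providing the gene universe.
#' @param planted_sets named list of gene-id vectors; set `cluster1` (if
#'   present) receives `cfg$de_effect_cluster1` unless `effects` overrides.
#' @param cfg a [sim_config()].
#' @param effects named numeric of per-set mean shifts; defaults to
#'   `c(cluster1 = cfg$de_effect_cluster1)` for sets named `cluster1`.
#' @return list with `clone_A`, `clone_B` (gene_id, log2fc, pvalue, fdr,
#'   clone) and `truth` (gene_id, shift).
#' @export
simulate_de_tables <- function(annotation, planted_sets, cfg, effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  universe <- annotation$gene_id
  if (is.null(effects)) {
    effects <- stats::setNames(numeric(length(planted_sets)), names(planted_sets))
    if ("cluster1" %in% names(effects)) effects[["cluster1"]] <- cfg$de_effect_cluster1
  }
  shift <- stats::setNames(numeric(length(universe)), universe)
  for (s in names(planted_sets)) {
    genes <- planted_sets[[s]]
    unknown <- setdiff(genes, universe)
    if (length(unknown)) stop("unknown gene in planted set '", s, "': ", unknown[1])
    shift[genes] <- effects[[s]] %||% 0
  }
  set.seed(substream_seed(cfg$seed, "de"))
  make_clone <- function(label) {
    lfc <- shift + stats::rnorm(length(universe), 0, cfg$de_noise_sd)
    p <- 2 * stats::pnorm(-abs(lfc) / cfg$de_noise_sd)
    data.frame(gene_id = universe, log2fc = as.numeric(lfc), pvalue = p,
               fdr = stats::p.adjust(p, method = "BH"), clone = label,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(clone_A = make_clone("A"), clone_B = make_clone("B"),
       truth = data.frame(gene_id = universe, shift = as.numeric(shift),
                          stringsAsFactors = FALSE))
}

#' Build a synthetic orthology map between two annotations
#'
#' A deterministic fraction of genes from the first species receives
#' exactly one partner in the second (flagged `one2one`); the remainder
#' alternate between zero partners and two partners, so 1:1 filtering has
#' material to reject.
#'
#' @param annotation_a,annotation_b gene annotations of the two species.
#' @param one2one_frac fraction (rounded to a count) of species-A genes
#'   given exactly one partner.
#' @param cfg a [sim_config()] (seed source).
#' @return data.frame (gene_a, gene_b, one2one); genes with no partner
#'   appear once with `gene_b = NA`.
#' @export
make_orthology <- function(annotation_a, annotation_b, one2one_frac = 0.8,
                           cfg = sim_config()) {
  if (nrow(annotation_a) == 0 || nrow(annotation_b) == 0) {
    stop("both annotations must be nonempty")
  }
  set.seed(substream_seed(cfg$seed, "orthology"))
  a <- annotation_a$gene_id
  b <- annotation_b$gene_id
  k <- round(one2one_frac * length(a))
  if (k > length(b)) stop("not enough partner genes for the requested 1:1 fraction")
  one_a <- a[seq_len(k)]
  one_b <- sample(b, k)
  rows <- list(data.frame(gene_a = one_a, gene_b = one_b, one2one = TRUE,
                          stringsAsFactors = FALSE))
  rest <- a[setdiff(seq_along(a), seq_len(k))]
  pool <- setdiff(b, one_b)
  for (i in seq_along(rest)) {
    if (i %% 2 == 1 || length(pool) < 2) {
      rows[[length(rows) + 1]] <- data.frame(gene_a = rest[i], gene_b = NA_character_,
                                             one2one = FALSE, stringsAsFactors = FALSE)
    } else {
      partners <- sample(pool, 2)
      rows[[length(rows) + 1]] <- data.frame(gene_a = rest[i], gene_b = partners,
                                             one2one = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR plate
#'
#' Draws Ct values such that efficiency-corrected quantities
#' `Q = E^(-Ct)` reproduce the supplied true relative levels up to
#' Gaussian Ct noise, and attaches a 10-fold serial-dilution series per
#' primer for efficiency estimation.
#'
#' @param genes gene names measured on the plate.
#' @param true_rel_levels named numeric of true expression levels (same
#'   arbitrary unit for all genes).
#' @param efficiencies named numeric of per-primer amplification
#'   efficiencies, each in (1, 2\].
#' @param cfg a [sim_config()] (noise sd and seed).
#' @param n_dilutions number of 10-fold dilution points per primer.
#' @return list of class `qpcr_plate` with `measurements` (gene, ct),
#'   `dilution_series` (gene, dilution, ct) and `efficiencies`.
#' @export
simulate_qpcr_plate <- function(genes, true_rel_levels, efficiencies, cfg,
                                n_dilutions = 4L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(efficiencies <= 1 | efficiencies > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  missing <- setdiff(genes, names(true_rel_levels))
  if (length(missing)) stop("no true level for gene: ", missing[1])
  missing_e <- setdiff(genes, names(efficiencies))
  if (length(missing_e)) stop("no efficiency for gene: ", missing_e[1])
  set.seed(substream_seed(cfg$seed, "qpcr"))
  # shared detection threshold C across assays: level * E^Ct = C, so the
  # efficiency-corrected quantity E^(-Ct) equals level / C for every
  # primer; C is set so a unit level at E = 2 crosses at 25 cycles
  log_c <- 25 * log(2)
  ct_true <- (log_c - log(true_rel_levels[genes])) / log(efficiencies[genes])
  meas <- data.frame(
    gene = genes,
    ct = as.numeric(ct_true + stats::rnorm(length(genes), 0, cfg$qpcr_ct_sd)),
    stringsAsFactors = FALSE
  )
  dil <- do.call(rbind, lapply(genes, function(g) {
    conc <- 10^(-(seq_len(n_dilutions) - 1))  # 1, 0.1, 0.01, ...
    data.frame(
      gene = g, dilution = conc,
      ct = as.numeric(ct_true[[g]] - log(conc) / log(efficiencies[[g]]) +
                        stats::rnorm(n_dilutions, 0, cfg$qpcr_ct_sd)),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(measurements = meas, dilution_series = dil,
                 efficiencies = efficiencies[genes]),
            class = "qpcr_plate")
}
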