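# Statistical core: DE filtering across knockout clones, orthologue-set
# construction, the bootstrap gene-set conservation test with
# Benjamini-Hochberg correction, Welch tests, H4K16ac gain/loss
# classification and qPCR relative quantification.

#' Filter differential expression across knockout clones
#'
#' A gene counts as differentially expressed when its FDR is below `alpha`
#' in every clone and (by default) the log2FC sign agrees across clones —
#' reproducibility "in both clones" read as reproducible direction. The
#' consensus log2FC is the mean across clones.
#'
#' @param tables list of per-clone DE data.frames (gene_id, log2fc, fdr).
#' @param alpha FDR cutoff (exclusive).
#' @param require_sign_consistency set FALSE for the literal FDR-only rule.
#' @return data.frame gene_id, log2fc (consensus), plus per-clone fdr
#'   columns; attribute `universe` holds the shared gene universe used.
#' @export
filter_de <- function(tables, alpha = 0.05, require_sign_consistency = TRUE) {
  stopifnot(length(tables) >= 2)
  universes <- lapply(tables, `[[`, "gene_id")
  shared <- Reduce(intersect, universes)
  if (any(lengths(universes) != length(shared))) {
    warning("clone gene universes differ; restricting to their intersection (",
            length(shared), " genes)")
  }
  aligned <- lapply(tables, function(t) t[match(shared, t$gene_id), ])
  fdr <- sapply(aligned, `[[`, "fdr")
  lfc <- sapply(aligned, `[[`, "log2fc")
  keep <- rowSums(fdr < alpha) == ncol(fdr)
  if (require_sign_consistency) {
    signs <- sign(lfc)
    keep <- keep & apply(signs, 1, function(s) all(s == s[1]) && all(s != 0))
  }
  out <- data.frame(gene_id = shared[keep],
                    log2fc = rowMeans(lfc)[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(aligned)) out[[paste0("fdr_clone", i)]] <- fdr[keep, i]
  attr(out, "universe") <- shared
  out
}

#' Translate a gene set through 1:1 orthology
#'
#' Keeps only genes with exactly one orthologue (the `one2one` flag, which
#' by definition excludes genes with zero or several partners and partners
#' shared between source genes) and collapses duplicates.
#'
#' @param gene_set character vector of source-species gene ids.
#' @param orthology data.frame (gene_a, gene_b, one2one) as from
#'   [make_orthology()].
#' @return list: `genes` (translated ids), `report` (n_input, n_one2one,
#'   n_dropped).
#' @export
orthologue_set <- function(gene_set, orthology) {
  o <- orthology[orthology$one2one & orthology$gene_a %in% gene_set, , drop = FALSE]
  genes <- unique(o$gene_b[!is.na(o$gene_b)])
  list(
    genes = genes,
    report = c(n_input = length(unique(gene_set)),
               n_one2one = length(genes),
               n_dropped = length(unique(gene_set)) - length(unique(o$gene_a)))
  )
}

#' Genes proximal to high-affinity sites
#'
#' Returns genes whose distance to the nearest HAS center is at most
#' `max_dist` bp (boundary inclusive), excluding genes whose interval
#' directly overlaps a HAS — those belong to the HAS group itself.
#'
#' @param annotation gene annotation.
#' @param has_sites HAS interval data.frame.
#' @param max_dist maximum gene-to-HAS-center distance in bp.
#' @return list with `proximal` and `overlapping` gene-id vectors.
#' @export
has_proximal_genes <- function(annotation, has_sites, max_dist = 2344) {
  centers <- floor((has_sites$start + has_sites$end) / 2)
  overlapping <- logical(nrow(annotation))
  min_dist <- rep(Inf, nrow(annotation))
  for (j in seq_len(nrow(has_sites))) {
    same <- annotation$chrom == has_sites$chrom[j]
    if (!any(same)) next
    ov <- same & annotation$start < has_sites$end[j] &
      annotation$end > has_sites$start[j]
    overlapping <- overlapping | ov
    d <- interval_point_distance(annotation$chrom, annotation$start,
                                 annotation$end, has_sites$chrom[j], centers[j])
    min_dist <- pmin(min_dist, d)
  }
  list(
    proximal = annotation$gene_id[!overlapping & min_dist <= max_dist],
    overlapping = annotation$gene_id[overlapping]
  )
}

#' Bootstrap gene-set test on log2 fold changes
#'
#' Tests whether the mean log2FC of a gene set departs from what random
#' gene sets of the same size show: the observed statistic is compared to
#' `B` means of random samples drawn from the gene universe (without
#' replacement by default; with replacement available). The empirical
#' p-value uses the +1 correction, `(1 + #extreme) / (B + 1)`, so it is
#' never exactly zero.
#'
#' @param gene_set character vector, subset of `names(universe_log2fc)`.
#' @param universe_log2fc named numeric vector of per-gene log2FC over the
#'   whole universe.
#' @param B number of resamples.
#' @param alternative `less` (coherent downregulation), `greater`, or
#'   `two_sided` (absolute deviation from the null mean).
#' @param seed RNG seed.
#' @param mode `without_replacement` (random gene sets of the same size)
#'   or `with_replacement` (classical bootstrap).
#' @param statistic `mean` (default) or `median`.
#' @return list of class `bootstrap_result`: `label`, `n`, `observed`,
#'   `null` (length B), `p`, `alternative`, `mode`, `seed`, `B`.
#' @export
bootstrap_set_test <- function(gene_set, universe_log2fc, B = 10000,
                               alternative = "less", seed = 1,
                               mode = "without_replacement",
                               statistic = "mean") {
  alternative <- match.arg(alternative, c("less", "greater", "two_sided"))
  mode <- match.arg(mode, c("without_replacement", "with_replacement"))
  statistic <- match.arg(statistic, c("mean", "median"))
  if (B < 1) stop("B must be >= 1")
  missing <- setdiff(gene_set, names(universe_log2fc))
  if (length(missing)) stop("gene set not contained in universe: ", missing[1])
  n <- length(gene_set)
  if (n < 2) stop("gene set must have at least 2 members")
  m <- length(universe_log2fc)
  if (mode == "without_replacement" && n > m) {
    stop("set larger than universe in without-replacement mode")
  }
  stat <- if (statistic == "mean") mean else stats::median
  observed <- stat(universe_log2fc[gene_set])
  x <- unname(universe_log2fc)
  set.seed(seed)
  null <- if (mode == "without_replacement") {
    vapply(seq_len(B), function(b) stat(x[sample.int(m, n)]), numeric(1))
  } else {
    vapply(seq_len(B), function(b) {
      stat(x[sample.int(m, n, replace = TRUE)])
    }, numeric(1))
  }
  p <- switch(alternative,
    less = (1 + sum(null <= observed)) / (B + 1),
    greater = (1 + sum(null >= observed)) / (B + 1),
    two_sided = {
      center <- mean(null)
      (1 + sum(abs(null - center) >= abs(observed - center))) / (B + 1)
    }
  )
  structure(
    list(label = attr(gene_set, "label") %||% NA_character_, n = n,
         observed = observed, null = null, p = p,
         alternative = alternative, mode = mode, seed = seed, B = B),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: n = %d, observed %s = %.4f, p (%s) = %.4g [B = %d, %s]\n",
              x$n, "statistic", x$observed, x$alternative, x$p, x$B, x$mode))
  invisible(x)
}

#' Run the conservation test over several gene sets
#'
#' Applies [bootstrap_set_test()] to each set against a shared universe
#' and corrects the empirical p-values across sets by Benjamini-Hochberg.
#'
#' @param sets named list of gene-id vectors.
#' @param universe_log2fc named numeric log2FC universe.
#' @param B,alternative,seed,mode passed to [bootstrap_set_test()].
#' @return data.frame set, n, observed, p, p_adj.
#' @export
conservation_test <- function(sets, universe_log2fc, B = 10000,
                              alternative = "less", seed = 1,
                              mode = "without_replacement") {
  results <- lapply(seq_along(sets), function(i) {
    bootstrap_set_test(sets[[i]], universe_log2fc, B = B,
                       alternative = alternative,
                       seed = substream_seed(seed + i, "bootstrap"),
                       mode = mode)
  })
  p <- vapply(results, `[[`, numeric(1), "p")
  data.frame(
    set = names(sets),
    n = vapply(results, `[[`, numeric(1), "n"),
    observed = vapply(results, `[[`, numeric(1), "observed"),
    p = p,
    p_adj = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: sort p ascending, compute
#' `p_i * m / i`, enforce monotonicity from the largest rank, cap at 1,
#' return in input order.
#'
#' @param pvals numeric vector in \[0, 1\].
#' @return adjusted p-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03)) # 0.03 0.04 0.04
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | !is.finite(pvals))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom. The degenerate case of zero variance in both samples with
#' equal means returns t = 0, p = 1.
#'
#' @param a,b numeric samples (length >= 2 each).
#' @param alternative `two_sided`, `less` or `greater` (alternative about
#'   `mean(a) - mean(b)`).
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))$t # -3.674
welch_t_test <- function(a, b, alternative = "two_sided") {
  alternative <- match.arg(alternative, c("two_sided", "less", "greater"))
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = length(a) + length(b) - 2,
                p = if (alternative == "two_sided") 1 else 0.5))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = sub("two_sided", "two.sided", alternative))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Classify H4K16ac gain or loss per gene
#'
#' Genes whose acetylation score drops in the mutant relative to wild type
#' lie below the wt = mut diagonal and are labelled `loss`; genes above it
#' `gain`; exact ties `unchanged`. When a DE log2FC is supplied, the
#' concordance is the fraction of downregulated genes labelled `loss`
#' plus upregulated genes labelled `gain`, among all genes with nonzero
#' log2FC.
#'
#' @param score_wt,score_mut named numeric enrichment scores (TSS-to-TES
#'   H4K16ac/H3) per gene.
#' @param de_log2fc optional named numeric log2FC per gene.
#' @return list with `labels` (named character) and `concordance` (NA when
#'   no log2FC given).
#' @export
classify_h4k16 <- function(score_wt, score_mut, de_log2fc = NULL) {
  genes <- intersect(names(score_wt), names(score_mut))
  skipped <- setdiff(union(names(score_wt), names(score_mut)), genes)
  if (length(skipped)) warning(length(skipped), " unpaired gene(s) skipped")
  wt <- score_wt[genes]; mut <- score_mut[genes]
  labels <- ifelse(mut < wt, "loss", ifelse(mut > wt, "gain", "unchanged"))
  names(labels) <- genes
  concordance <- NA_real_
  if (!is.null(de_log2fc)) {
    shared <- intersect(genes, names(de_log2fc))
    lfc <- de_log2fc[shared]
    informative <- lfc != 0
    if (any(informative)) {
      expected <- ifelse(lfc[informative] < 0, "loss", "gain")
      concordance <- mean(labels[shared][informative] == expected)
    }
  }
  list(labels = labels, concordance = concordance)
}

#' Estimate qPCR amplification efficiency from a dilution series
#'
#' Least-squares slope of Ct against log10 relative concentration;
#' efficiency `E = 10^(-1/slope)`. A perfect doubling assay has slope
#' -3.3219 and E = 2.
#'
#' @param dilution_series data.frame with columns `dilution` (relative
#'   concentration, e.g. 1, 0.1, 0.01) and `ct`; optionally a `gene`
#'   column for several primers at once.
#' @return named numeric efficiencies (single unnamed value when no gene
#'   column).
#' @export
qpcr_efficiency <- function(dilution_series) {
  one <- function(df) {
    if (nrow(df) < 3) stop("need at least 3 dilution points")
    fit <- stats::lm(ct ~ log10(dilution), data = df)
    slope <- stats::coef(fit)[[2]]
    ord <- order(df$dilution, decreasing = TRUE)
    if (slope >= 0 || any(diff(df$ct[ord]) < -1)) {
      warning("Ct not monotone in dilution beyond noise tolerance: check series")
    }
    10^(-1 / slope)
  }
  if (!is.null(dilution_series$gene)) {
    vapply(split(dilution_series, dilution_series$gene), one, numeric(1))
  } else {
    one(dilution_series)
  }
}

#' Relative expression from qPCR Ct values
#'
#' Efficiency-corrected quantity `Q_g = E_g^(-Ct_g)`; the result is the
#' target quantity divided by the geometric mean of the reference-gene
#' quantities (one or several references).
#'
#' @param plate a `qpcr_plate` (from [simulate_qpcr_plate()]) or a list
#'   with `measurements` (gene, ct) and `efficiencies` (named).
#' @param target target gene.
#' @param references character vector of reference genes.
#' @return relative expression (numeric scalar).
#' @export
#' @examples
#' plate <- list(measurements = data.frame(gene = c("t", "r"), ct = c(19, 20)),
#'               efficiencies = c(t = 2, r = 2))
#' qpcr_relative(plate, "t", "r") # 2
qpcr_relative <- function(plate, target, references) {
  meas <- plate$measurements
  eff <- plate$efficiencies
  get_q <- function(g) {
    ct <- meas$ct[meas$gene == g]
    if (length(ct) == 0) stop("gene not measured on plate: ", g)
    e <- eff[[g]]
    if (is.null(e)) stop("no efficiency for gene: ", g)
    e^(-mean(ct))
  }
  q_target <- get_q(target)
  q_refs <- vapply(references, get_q, numeric(1))
  q_target / geometric_mean(q_refs)
}
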