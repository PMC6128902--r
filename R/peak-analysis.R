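# Peak post-processing: replicate merging, TSS assignment, chromosome
# overrepresentation, and k-means clustering of multi-track peak signal.

#' Merge peak sets across replicates
#'
#' Concatenates the replicate peak sets, sorts, and merges intervals whose
#' gap is at most `max_gap` bp (bedtools-merge semantics), matching the
#' standard post-processing of per-replicate MACS2 calls.
#'
#' @param peaksets list of interval data.frames (or a single one).
#' @param max_gap maximum merge gap in bp.
#' @return merged interval data.frame; attribute `sources` records the
#'   union of input source labels (attribute `source` of each set, when
#'   present).
#' @export
merge_replicate_peaks <- function(peaksets, max_gap = 10) {
  if (is.data.frame(peaksets)) peaksets <- list(peaksets)
  common <- Reduce(intersect, lapply(peaksets, names))
  all_peaks <- do.call(rbind, lapply(peaksets, function(p) p[, common, drop = FALSE]))
  out <- merge_intervals(all_peaks, max_gap = max_gap)
  srcs <- unlist(lapply(peaksets, function(p) attr(p, "source")))
  attr(out, "sources") <- unique(srcs)
  out
}

# Peak overlaps the closed TSS window [tss - dist, tss + dist] iff
# peak covers some base of it; window clipped at chromosome bounds.
#' @keywords internal
peak_hits_window <- function(peak_start, peak_end, tss, dist, chrom_len = Inf) {
  lo <- pmax(tss - dist, 0)
  hi <- pmin(tss + dist, chrom_len - 1)
  peak_start <= hi & (peak_end - 1) >= lo
}

#' Assign peaks to genes by TSS proximity
#'
#' A gene is assigned to a peak when the peak interval intersects the
#' closed window of `dist` bp on either side of the gene's TSS ("within
#' 200 bp of the TSS" read inclusively). A peak may hit several genes and
#' a gene several peaks.
#'
#' @param peaks interval data.frame.
#' @param annotation gene annotation data.frame.
#' @param dist TSS window half-width in bp.
#' @param genome optional `genome_model` for window clipping.
#' @return list with `assignments` (data.frame gene_id, peak_id, distance
#'   from TSS to the nearest covered peak base, 0 when the peak covers the
#'   TSS) and `n_peaks_assigned` (count of peaks with at least one gene).
#' @export
assign_peaks_to_tss <- function(peaks, annotation, dist = 200, genome = NULL) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    same <- annotation$chrom == peaks$chrom[i]
    if (!any(same)) next
    ann <- annotation[same, , drop = FALSE]
    clen <- if (!is.null(genome)) genome$lengths[[peaks$chrom[i]]] else Inf
    hit <- peak_hits_window(peaks$start[i], peaks$end[i], ann$tss, dist, clen)
    if (!any(hit)) next
    ann <- ann[hit, , drop = FALSE]
    d <- interval_point_distance(peaks$chrom[i], peaks$start[i], peaks$end[i],
                                 ann$chrom, ann$tss)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = ann$gene_id, peak_id = peaks$id[i], distance = d,
      stringsAsFactors = FALSE
    )
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), peak_id = character(0),
               distance = numeric(0))
  rownames(assignments) <- NULL
  list(assignments = assignments,
       n_peaks_assigned = length(unique(assignments$peak_id)))
}

#' Genes carrying a peak near their TSS
#'
#' Convenience wrapper around [assign_peaks_to_tss()] returning only the
#' gene set, with the wider 1 kb default used for peak-bearing gene sets
#' in the mouse comparison.
#'
#' @inheritParams assign_peaks_to_tss
#' @return character vector of gene ids.
#' @export
genes_with_tss_peak <- function(peaks, annotation, dist = 1000, genome = NULL) {
  if (nrow(peaks) == 0) return(character(0))
  unique(assign_peaks_to_tss(peaks, annotation, dist, genome)$assignments$gene_id)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability for a 2x2 contingency table, as
#' used to test overrepresentation of X-linked peaks. `greater` tests
#' enrichment of the top-left cell (odds ratio > 1); `two_sided` sums all
#' tables with probability at most that of the observed table.
#'
#' @param table 2x2 numeric matrix or a length-4 vector (a, b, c, d,
#'   row-wise).
#' @param alternative `greater`, `less` or `two_sided`.
#' @return the p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(9, 1, 1, 9), 2, byrow = TRUE), "greater") # 101/184756
fisher_exact <- function(table, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less", "two_sided"))
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table,
                     alternative = sub("two_sided", "two.sided", alternative))$p.value
}

#' Chromosome overrepresentation of one peak set versus another
#'
#' Builds the 2x2 table of peak counts (X vs autosome) x (set A vs set B)
#' and tests one-sided for X overrepresentation in set A. The alternative
#' construction `expectation` compares set A against the genomic
#' length expectation (X bases vs autosomal bases) instead of a second
#' peak set.
#'
#' @param peaks_a,peaks_b interval data.frames (`peaks_b` ignored for mode
#'   `expectation`).
#' @param genome a `genome_model`.
#' @param mode `versus_b` (default) or `expectation`.
#' @param alternative passed to [fisher_exact()].
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
chromosome_overrepresentation <- function(peaks_a, peaks_b = NULL, genome,
                                          mode = "versus_b",
                                          alternative = "greater") {
  mode <- match.arg(mode, c("versus_b", "expectation"))
  if (nrow(peaks_a) == 0) stop("peak set A is empty")
  count_xa <- function(p) {
    x <- sum(p$chrom == genome$x_chrom)
    c(x = x, auto = nrow(p) - x)
  }
  a <- count_xa(peaks_a)
  if (mode == "versus_b") {
    if (is.null(peaks_b) || nrow(peaks_b) == 0) stop("peak set B is empty")
    b <- count_xa(peaks_b)
  } else {
    # expected split of the A total by chromosome length
    x_len <- genome$lengths[[genome$x_chrom]]
    auto_len <- sum(genome$lengths[autosomes(genome)])
    tot <- sum(a)
    b <- c(x = round(tot * x_len / (x_len + auto_len)), auto = 0)
    b["auto"] <- tot - b["x"]
  }
  tab <- matrix(c(a["x"], a["auto"], b["x"], b["auto"]), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("X", "autosome")))
  list(table = tab, p = fisher_exact(tab, alternative))
}

#' Cluster peaks on multi-track signal
#'
#' Standardizes each track's signal matrix to zero mean and unit variance
#' over all cells, concatenates the per-row vectors across tracks, and
#' runs k-means (10 restarts, best within-cluster sum of squares kept).
#' Clusters are relabelled 1..k by descending mean signal of the first
#' track, so cluster numbering is reproducible; rows are ranked within
#' each cluster by descending mean first-track signal.
#'
#' @param matrices list of `signal_matrix` objects over identical rows
#'   (same ids, any order; rows are aligned to the first matrix).
#' @param k number of clusters.
#' @param seed RNG seed for the restarts.
#' @return list of class `cluster_result`: `labels` (named integer vector
#'   per row id), `order` (row ids in heatmap display order), `centers`
#'   (k x feature matrix), `row_rank` (rank within cluster).
#' @export
cluster_peaks <- function(matrices, k = 3, seed = 1) {
  if (inherits(matrices, "signal_matrix")) matrices <- list(matrices)
  ids <- rownames(matrices[[1]]$matrix)
  feats <- lapply(matrices, function(sm) {
    if (!identical(sort(rownames(sm$matrix)), sort(ids))) {
      stop("matrices are not row-aligned")
    }
    m <- sm$matrix[ids, , drop = FALSE]
    m[is.na(m)] <- 0
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) stop("constant signal matrix: zero variance")
    (m - mean(m)) / s
  })
  X <- do.call(cbind, feats)
  if (nrow(X) < k) stop("fewer rows (", nrow(X), ") than clusters (", k, ")")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  first_means <- rowMeans(matrices[[1]]$matrix[ids, , drop = FALSE], na.rm = TRUE)
  cluster_signal <- vapply(seq_len(k), function(cl) {
    mean(first_means[km$cluster == cl])
  }, numeric(1))
  relabel <- match(seq_len(k), order(cluster_signal, decreasing = TRUE))
  labels <- stats::setNames(relabel[km$cluster], ids)
  ord <- order(labels, -first_means)
  row_rank <- stats::setNames(integer(length(ids)), ids)
  for (cl in seq_len(k)) {
    in_cl <- names(labels)[labels == cl]
    row_rank[in_cl] <- rank(-first_means[in_cl], ties.method = "first")
  }
  structure(
    list(labels = labels, order = ids[ord],
         centers = km$centers[order(cluster_signal, decreasing = TRUE), ,
                              drop = FALSE],
         row_rank = row_rank),
    class = "cluster_result"
  )
}
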