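# Fragment-size partitioning, binned coverage with the normalization modes
# used for MNase ChIP data, and the two meta-profile matrix geometries
# (reference-point and scaled gene body).

#' @keywords internal
new_coverage_track <- function(values, binsize, genome, normalization,
                               exclude_scaling = character(0)) {
  structure(
    list(values = values, binsize = binsize, genome = genome,
         normalization = normalization, exclude_scaling = exclude_scaling),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track: binsize", x$binsize, "bp, normalization", x$normalization,
      "\n  chromosomes:", paste(names(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Partition fragments by the footprint length boundary
#'
#' MNase ChIP fragments at or below the threshold (140 bp by default)
#' represent the direct protein footprint; longer fragments reflect
#' crosslinks with adjacent nucleosomes. The boundary is inclusive on the
#' small side: a 140 bp fragment is small, a 141 bp fragment is large.
#'
#' @param frags fragment data.frame (chrom, start, end, ...).
#' @param threshold partition boundary in bp.
#' @return list with `small` and `large` fragment data.frames; every input
#'   row lands in exactly one of them.
#' @export
partition_fragments <- function(frags, threshold = 140) {
  len <- frags$end - frags$start
  small <- frags[len <= threshold, , drop = FALSE]
  large <- frags[len > threshold, , drop = FALSE]
  rownames(small) <- NULL; rownames(large) <- NULL
  list(small = small, large = large)
}

#' Filter ChIP fragments by mapping quality and exact duplicates
#'
#' Removes fragments with mapping quality strictly below `min_mapq`
#' (quality 10 is kept at the default) and keeps a single representative
#' among fragments with identical (chrom, start, end).
#'
#' @param frags fragment data.frame with a `mapq` column.
#' @param min_mapq minimum mapping quality kept (inclusive).
#' @return filtered fragment data.frame.
#' @export
filter_fragments <- function(frags, min_mapq = 10) {
  keep <- frags$mapq >= min_mapq
  out <- frags[keep, , drop = FALSE]
  if (nrow(out)) {
    key <- paste(out$chrom, out$start, out$end, sep = ":")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Raw binned coverage from fragments
#'
#' Bin value = per-base fragment depth summed over the bin divided by the
#' bin size, i.e. the mean depth over the bin (a trailing partial bin is
#' implicitly zero-padded). This makes coverage mass exactly conserved:
#' the sum of `bin value * binsize` over the genome equals the total
#' fragment length (clipped at chromosome ends).
#'
#' With `use = "midpoint"` each fragment contributes only at its midpoint
#' base (dyad-density style, as used for nucleosome positioning), which
#' keeps positional peaks sharp instead of smearing them over the fragment
#' length; mass is then the fragment count rather than the length total.
#'
#' @param frags fragment data.frame.
#' @param genome a `genome_model`.
#' @param binsize bin width in bp.
#' @param use `"full"` (per-base depth over the whole fragment) or
#'   `"midpoint"` (fragment-center density).
#' @return a `coverage_track` with normalization `raw`.
#' @export
#' @examples
#' g <- genome_model(c(chr1 = 10, chrX = 10), "chrX")
#' f <- data.frame(chrom = "chr1", start = 0, end = 4)
#' coverage_track(f, g, binsize = 2)$values$chr1 # 1 1 0 0 0
coverage_track <- function(frags, genome, binsize = 2, use = "full") {
  stopifnot(binsize >= 1)
  use <- match.arg(use, c("full", "midpoint"))
  if (nrow(frags)) {
    if (any(frags$start < 0)) stop("fragment with negative start")
    over <- which(frags$end > genome$lengths[frags$chrom])
    if (length(over)) stop("fragment beyond chromosome end (row ", over[1], ")")
    unknown <- setdiff(unique(frags$chrom), genome$chroms)
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
  }
  values <- lapply(stats::setNames(genome$chroms, genome$chroms), function(ch) {
    L <- genome$lengths[[ch]]
    nbins <- ceiling(L / binsize)
    sel <- frags$chrom == ch
    if (!any(sel)) return(numeric(nbins))
    s <- frags$start[sel]
    e <- frags$end[sel]
    if (use == "midpoint") {
      mid <- (s + e) %/% 2
      depth <- tabulate(mid + 1, nbins = L)
    } else {
      # depth via difference array: +1 at start, -1 at end
      d <- tabulate(s + 1, nbins = L + 1) - tabulate(e + 1, nbins = L + 1)
      depth <- cumsum(d[seq_len(L)])
    }
    padded <- c(depth, numeric(nbins * binsize - L))
    .colSums(padded, binsize, nbins) / binsize
  })
  new_coverage_track(values, binsize, genome, "raw")
}

#' @keywords internal
track_mass <- function(track, chroms = NULL) {
  chroms <- chroms %||% names(track$values)
  sum(vapply(chroms, function(ch) sum(track$values[[ch]]) * track$binsize,
             numeric(1)))
}

#' Normalize a ChIP track against its control
#'
#' Implements the three normalization modes used for the ChIP data, with
#' the X chromosome (or any listed chromosome) excluded from the scaling
#' statistics — a male sample carries a single X, which would otherwise
#' distort depth equalization:
#' \describe{
#'   \item{log2_ratio}{`log2((chip + pc) / (control + pc))` per bin after
#'     depth-equalizing both tracks (both scaled to the smaller total
#'     coverage mass over non-excluded chromosomes).}
#'   \item{subtract}{depth-equalized `chip - control`.}
#'   \item{one_x}{control ignored; chip scaled so mean per-base coverage
#'     over non-excluded chromosomes is exactly 1.}
#' }
#'
#' @param chip,control `coverage_track`s on the same genome and binsize
#'   (`control` may be NULL for mode `one_x`).
#' @param mode one of `log2_ratio`, `subtract`, `one_x`.
#' @param exclude_scaling chromosomes excluded from scaling statistics
#'   (default: the genome's X).
#' @param pseudocount pseudocount for `log2_ratio`.
#' @return normalized `coverage_track`.
#' @export
normalize_tracks <- function(chip, control = NULL, mode = "log2_ratio",
                             exclude_scaling = NULL, pseudocount = 1.0) {
  stopifnot(inherits(chip, "coverage_track"))
  mode <- match.arg(mode, c("log2_ratio", "subtract", "one_x"))
  exclude_scaling <- exclude_scaling %||% chip$genome$x_chrom
  scale_chroms <- setdiff(names(chip$values), exclude_scaling)
  if (length(scale_chroms) == 0) stop("no chromosomes left for scaling")

  if (mode == "one_x") {
    mass <- track_mass(chip, scale_chroms)
    if (mass <= 0) stop("zero total coverage on scaling chromosomes")
    bases <- sum(chip$genome$lengths[scale_chroms])
    f <- bases / mass  # mean per-base coverage over scaling chroms -> 1
    values <- lapply(chip$values, function(v) v * f)
    return(new_coverage_track(values, chip$binsize, chip$genome, "one_x",
                              exclude_scaling))
  }
  stopifnot(inherits(control, "coverage_track"))
  if (chip$binsize != control$binsize) stop("binsize mismatch between tracks")
  if (!identical(names(chip$values), names(control$values))) {
    stop("tracks are on different genomes")
  }
  m_chip <- track_mass(chip, scale_chroms)
  m_ctrl <- track_mass(control, scale_chroms)
  if (m_chip <= 0 || m_ctrl <= 0) stop("zero total coverage on scaling chromosomes")
  target <- min(m_chip, m_ctrl)
  f_chip <- target / m_chip
  f_ctrl <- target / m_ctrl
  values <- stats::setNames(lapply(names(chip$values), function(ch) {
    a <- chip$values[[ch]] * f_chip
    b <- control$values[[ch]] * f_ctrl
    if (mode == "log2_ratio") {
      log2((a + pseudocount) / (b + pseudocount))
    } else {
      a - b
    }
  }), names(chip$values))
  new_coverage_track(values, chip$binsize, chip$genome, mode, exclude_scaling)
}

# Per-base track values over [from, to); positions outside the chromosome
# give NA. `from` may be negative.
#' @keywords internal
track_values_per_base <- function(track, chrom, from, to) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  L <- track$genome$lengths[[chrom]]
  pos <- seq.int(from, to - 1)
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 0 & pos < L
  out[ok] <- v[pos[ok] %/% track$binsize + 1]
  out
}

# Average a per-base value vector into fixed-width matrix bins, masking
# all-NA bins as NA.
#' @keywords internal
bin_means <- function(vals, bin) {
  m <- matrix(vals, nrow = bin)
  res <- colMeans(m, na.rm = TRUE)
  res[is.nan(res)] <- NA_real_
  res
}

#' @keywords internal
new_signal_matrix <- function(mat, mode, bin_width, geometry) {
  structure(list(matrix = mat, mode = mode, bin_width = bin_width,
                 geometry = geometry),
            class = "signal_matrix")
}

#' Reference-point signal matrix
#'
#' One row per region: the track signal over
#' `[center - flank, center + flank)` (center = `floor((start + end) / 2)`)
#' averaged into columns of `binsize` bp. Minus-strand regions are
#' column-reversed so all rows read 5' to 3'. Bases outside the chromosome
#' contribute a missing-value mask (NA), never zero.
#'
#' @param track a `coverage_track`.
#' @param regions interval data.frame (strand column honoured).
#' @param flank half-window in bp; must be a multiple of `binsize`.
#' @param binsize matrix column width in bp.
#' @return a `signal_matrix` (rows named by region id).
#' @export
matrix_reference_point <- function(track, regions, flank = 800, binsize = 10) {
  if (flank %% binsize != 0) stop("flank must be a multiple of binsize")
  ncol <- 2 * flank / binsize
  mat <- matrix(NA_real_, nrow = nrow(regions), ncol = ncol,
                dimnames = list(regions$id, NULL))
  for (i in seq_len(nrow(regions))) {
    center <- floor((regions$start[i] + regions$end[i]) / 2)
    vals <- track_values_per_base(track, regions$chrom[i],
                                  center - flank, center + flank)
    if (!is.null(regions$strand) && regions$strand[i] == "-") vals <- rev(vals)
    mat[i, ] <- bin_means(vals, binsize)
  }
  new_signal_matrix(mat, "reference_point", binsize,
                    list(flank_bp = flank))
}

#' Scaled-gene-body signal matrix
#'
#' One row per gene, read in gene orientation: 500 bp upstream of the TSS
#' and the first 500 bp of the body unscaled, then the remainder of the
#' body to the TES linearly resampled to a fixed 1 kb. Each virtual scaled
#' base takes the value of the body base at
#' `floor(k * (body - unscaled) / scaled_body)`. Genes whose body is not
#' longer than the unscaled flank are dropped with a warning.
#'
#' @param track a `coverage_track`.
#' @param genes gene annotation data.frame.
#' @param unscaled unscaled flank around the TSS in bp.
#' @param body_bp length the body remainder is scaled to, in bp.
#' @param binsize matrix column width in bp; `2 * unscaled + body_bp` must
#'   be a multiple of it.
#' @return a `signal_matrix` with `(2 * unscaled + body_bp) / binsize`
#'   columns; attribute `dropped` lists excluded gene ids.
#' @export
matrix_scaled_region <- function(track, genes, unscaled = 500, body_bp = 1000,
                                 binsize = 10) {
  total <- 2 * unscaled + body_bp
  if (total %% binsize != 0) stop("matrix width must be a multiple of binsize")
  body_len <- genes$end - genes$start
  drop <- body_len <= unscaled
  if (any(drop)) {
    warning(sum(drop), " gene(s) with body <= ", unscaled, " bp dropped: ",
            paste(utils::head(genes$gene_id[drop], 5), collapse = ", "))
  }
  genes <- genes[!drop, , drop = FALSE]
  body_len <- body_len[!drop]
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = total / binsize,
                dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    L <- body_len[i]
    # oriented offsets from the TSS: upstream flank, unscaled body start,
    # then the body remainder resampled to body_bp virtual bases
    t_body <- unscaled + floor(seq.int(0, body_bp - 1) * (L - unscaled) / body_bp)
    t_all <- c(seq.int(-unscaled, unscaled - 1), t_body)
    pos <- if (genes$strand[i] == "+") genes$tss[i] + t_all else genes$tss[i] - t_all
    v <- track$values[[genes$chrom[i]]]
    Lc <- track$genome$lengths[[genes$chrom[i]]]
    vals <- rep(NA_real_, length(pos))
    ok <- pos >= 0 & pos < Lc
    vals[ok] <- v[pos[ok] %/% track$binsize + 1]
    mat[i, ] <- bin_means(vals, binsize)
  }
  out <- new_signal_matrix(mat, "scaled_region", binsize,
                           list(unscaled_bp = unscaled, body_bp = body_bp))
  attr(out, "dropped") <- setdiff(rownames(mat), genes$gene_id)
  out
}

#' Mean column profile of a signal matrix
#' @param sm a `signal_matrix`.
#' @return numeric vector of column means (masked cells excluded).
#' @export
matrix_profile <- function(sm) {
  colMeans(sm$matrix, na.rm = TRUE)
}

#' Mean track value over intervals
#'
#' Enrichment score per interval: the mean of bin values whose bins
#' overlap the interval, weighted by the number of overlapping bases.
#'
#' @param track a `coverage_track`.
#' @param intervals interval data.frame (any table with chrom, start, end).
#' @return numeric vector of per-interval scores (named by `id` or
#'   `gene_id` when present).
#' @export
region_score <- function(track, intervals) {
  if (nrow(intervals) == 0) return(numeric(0))
  scores <- vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    s <- intervals$start[i]; e <- intervals$end[i]
    b0 <- s %/% track$binsize
    b1 <- (e - 1) %/% track$binsize
    bins <- b0:b1
    ov_start <- pmax(bins * track$binsize, s)
    ov_end <- pmin((bins + 1) * track$binsize, e)
    w <- ov_end - ov_start
    sum(v[bins + 1] * w) / sum(w)
  }, numeric(1))
  names(scores) <- intervals$id %||% intervals$gene_id
  scores
}
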