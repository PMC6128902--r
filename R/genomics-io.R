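# Readers/writers for the plain-text genomic formats the pipeline touches
# and the interval algebra every stage shares. All internal coordinates are
# 0-based half-open (BED convention); GTF is converted at the boundary.

#' Construct a genome model
#'
#' A genome model is the ordered set of chromosome names and lengths plus an
#' explicit designation of the X chromosome. The X designation matters
#' because coverage normalization excludes the X from depth scaling (a male
#' sample carries a single X, so including it would distort autosomal
#' scaling).
#'
#' @param chrom_lengths named numeric vector: chromosome name -> length (bp).
#' @param x_chrom name of the chromosome designated as the X.
#' @return An object of class `genome_model` with elements `chroms`,
#'   `lengths`, `x_chrom`.
#' @export
#' @examples
#' genome_model(c(chrX = 1e5, chr2L = 1e5, chr2R = 1e5), x_chrom = "chrX")
genome_model <- function(chrom_lengths, x_chrom) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  if (anyDuplicated(names(chrom_lengths))) stop("chromosome names must be unique")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!x_chrom %in% names(chrom_lengths)) stop("x_chrom not among chromosomes")
  structure(
    list(
      chroms = names(chrom_lengths),
      lengths = stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths)),
      x_chrom = x_chrom
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chroms), "chromosomes, X =", x$x_chrom, "\n")
  print(x$lengths)
  invisible(x)
}

#' Autosome names of a genome model
#' @param genome a `genome_model`.
#' @return character vector of non-X chromosome names.
#' @export
autosomes <- function(genome) setdiff(genome$chroms, genome$x_chrom)

#' Construct a table of genomic intervals
#'
#' Intervals are stored as a data.frame with 0-based half-open coordinates.
#' Validation enforces `0 <= start < end` and, when a genome is supplied,
#' `end <= chromosome length` and known chromosome names.
#'
#' @param chrom,start,end interval coordinates.
#' @param id optional interval identifiers (auto-generated when missing).
#' @param score optional numeric score.
#' @param strand optional strand, one of `+`, `-`, `.` (default `.`).
#' @param genome optional `genome_model` for bounds checking.
#' @return data.frame with columns chrom, start, end, id, score, strand.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, score = NA_real_,
                              strand = ".", genome = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    id = if (is.null(id)) sprintf("iv_%d", seq_len(n)) else as.character(id),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, genome)
  df
}

#' @keywords internal
validate_intervals <- function(df, genome = NULL) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop("invalid interval at row ", bad[1], ": start=", df$start[bad[1]],
         " end=", df$end[bad[1]])
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(df$chrom), genome$chroms)
    if (length(unknown)) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    over <- which(df$end > genome$lengths[df$chrom])
    if (length(over)) stop("interval beyond chromosome end at row ", over[1])
  }
  invisible(df)
}

#' Read a BED file
#'
#' Accepts BED3 to BED6. Coordinates are kept 0-based half-open as in the
#' file. Malformed lines (start >= end, negative coordinates, chromosomes
#' absent from a supplied genome) raise an error carrying the line number.
#'
#' @param path BED file path.
#' @param genome optional `genome_model` used to validate chromosome names
#'   and bounds.
#' @return interval data.frame as from [genomic_intervals()].
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop("BED parse error at line ", which(nf < 3)[1], ": fewer than 3 fields")
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) stop("BED parse error at line ", bad[1], ": invalid coordinates")
  df <- data.frame(
    chrom = get(1, NA),
    start = start,
    end = end,
    id = ifelse(nf >= 4, get(4, ""), NA),
    score = suppressWarnings(as.numeric(ifelse(nf >= 5, get(5, ""), NA))),
    strand = ifelse(nf >= 6, get(6, "."), "."),
    stringsAsFactors = FALSE
  )
  df$id[is.na(df$id)] <- sprintf("iv_%d", which(is.na(df$id)))
  if (!is.null(genome)) {
    unknown <- which(!df$chrom %in% genome$chroms)
    if (length(unknown)) stop("BED parse error at line ", unknown[1], ": unknown chromosome")
    over <- which(df$end > genome$lengths[df$chrom])
    if (length(over)) stop("BED parse error at line ", over[1], ": beyond chromosome end")
  }
  validate_intervals(df)
  df
}

#' Write intervals as BED6
#' @param intervals interval data.frame.
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  score <- ifelse(is.na(intervals$score), 0, intervals$score)
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$id, score,
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Build a gene annotation table
#'
#' Adds derived TSS and TES point coordinates to a gene interval table.
#' With half-open intervals the last covered base is `end - 1`, so a
#' minus-strand gene has its TSS at `end - 1` and its TES at `start`.
#'
#' @param gene_id,chrom,start,end,strand per-gene fields; strand must be
#'   `+` or `-`.
#' @param genome optional `genome_model` for validation.
#' @return data.frame with columns gene_id, chrom, start, end, strand,
#'   tss, tes.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand, genome = NULL) {
  if (anyDuplicated(gene_id)) stop("duplicate gene_id")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be + or -")
  df <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0 | df$start >= df$end)) stop("invalid gene interval")
    if (!is.null(genome)) {
      validate_intervals(data.frame(df, id = df$gene_id, score = NA_real_), genome)
    }
  }
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tes <- ifelse(df$strand == "+", df$end - 1, df$start)
  df
}

#' Read gene records from a GTF file
#'
#' Only `gene` feature lines are used. GTF coordinates are 1-based closed
#' and are converted to the internal 0-based half-open convention:
#' GTF (start=1, end=100) becomes the interval \[0, 100).
#'
#' @param path GTF file path.
#' @param genome optional `genome_model`.
#' @return gene annotation data.frame as from [gene_annotation()].
#' @export
read_gtf <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) stop("no gene records in GTF")
  gene_id <- vapply(fields, function(f) {
    m <- regmatches(f[9], regexec('gene_id "([^"]+)"', f[9]))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }, character(1))
  strand <- vapply(fields, `[`, character(1), 7)
  if (anyNA(gene_id)) stop("GTF parse error: missing gene_id")
  if (!all(strand %in% c("+", "-"))) stop("GTF parse error: missing or invalid strand")
  gene_annotation(
    gene_id = gene_id,
    chrom = vapply(fields, `[`, character(1), 1),
    start = as.numeric(vapply(fields, `[`, character(1), 4)) - 1,
    end = as.numeric(vapply(fields, `[`, character(1), 5)),
    strand = strand,
    genome = genome
  )
}

#' Write a gene annotation as GTF
#'
#' Inverse of [read_gtf()]: internal half-open \[start, end) becomes
#' 1-based closed (start+1, end).
#'
#' @param annotation gene annotation data.frame.
#' @param path output path.
#' @param source source field for column 2.
#' @export
write_gtf <- function(annotation, path, source = "dosagelens") {
  lines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   annotation$chrom, source,
                   as.integer(annotation$start) + 1L,
                   as.integer(annotation$end),
                   annotation$strand, annotation$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Merge intervals closer than a gap threshold
#'
#' Gap semantics follow `bedtools merge -d`: two intervals merge when the
#' gap between them is at most `max_gap`; bookended or overlapping
#' intervals always merge. Output is sorted and the operation is
#' idempotent.
#'
#' @param intervals interval data.frame.
#' @param max_gap maximum gap in bp (default 0 merges only overlapping or
#'   bookended intervals).
#' @return merged interval data.frame (ids regenerated).
#' @export
#' @examples
#' iv <- genomic_intervals(c("c", "c"), c(0, 15), c(10, 20))
#' merge_intervals(iv, max_gap = 10) # one interval [0, 20)
merge_intervals <- function(intervals, max_gap = 0) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0) return(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(df) {
    df <- df[order(df$start, df$end), ]
    ms <- df$start[1]; me <- df$end[1]
    starts <- numeric(0); ends <- numeric(0)
    for (i in seq_len(nrow(df))[-1]) {
      if (df$start[i] - me <= max_gap) {
        me <- max(me, df$end[i])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- df$start[i]; me <- df$end[i]
      }
    }
    data.frame(chrom = df$chrom[1], start = c(starts, ms), end = c(ends, me),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  genomic_intervals(res$chrom, res$start, res$end)
}

#' Distance between an interval and a point
#'
#' Zero when the point lies inside the half-open interval, otherwise the
#' distance to the nearest covered base (`start` or `end - 1`). Points on a
#' different chromosome are at `Inf`.
#'
#' @param chrom,start,end the interval (vectors recycled against points).
#' @param point_chrom,point point coordinates.
#' @return numeric distances in bp.
#' @export
#' @examples
#' interval_point_distance("c", 100, 200, "c", 250) # 51
interval_point_distance <- function(chrom, start, end, point_chrom, point) {
  n <- max(length(chrom), length(point))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  point_chrom <- rep_len(point_chrom, n); point <- rep_len(point, n)
  d <- ifelse(point >= start & point < end, 0,
              pmin(abs(point - start), abs(point - (end - 1))))
  d[chrom != point_chrom] <- Inf
  d
}

#' Write a coverage track as bedGraph
#'
#' Emits one record per run of equal-valued bins (run-length merging), with
#' record boundaries on the track's bin grid, so that reading the file back
#' with [read_bedgraph()] reproduces bin values exactly.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @param allow_nan replace non-finite bins by 0 instead of erroring.
#' @export
write_bedgraph <- function(track, path, allow_nan = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (any(!is.finite(v))) {
      if (!allow_nan) stop("non-finite bin values on ", chrom,
                           " (use allow_nan = TRUE to mask as 0)")
      v[!is.finite(v)] <- 0
    }
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bp <- c(0, ends_bin[-length(ends_bin)]) * track$binsize
    ends_bp <- pmin(ends_bin * track$binsize, track$genome$lengths[[chrom]])
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, as.integer(starts_bp),
                       as.integer(ends_bp), r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()]
#'
#' @param path bedGraph path.
#' @param genome `genome_model` the track lives on.
#' @param binsize bin width of the original track.
#' @return a `coverage_track` with normalization mode `raw`.
#' @export
read_bedgraph <- function(path, genome, binsize) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[`, character(1), 2))
  end <- as.numeric(vapply(fields, `[`, character(1), 3))
  val <- as.numeric(vapply(fields, `[`, character(1), 4))
  values <- lapply(stats::setNames(genome$chroms, genome$chroms), function(ch) {
    nb <- ceiling(genome$lengths[[ch]] / binsize)
    v <- numeric(nb)
    sel <- which(chrom == ch)
    for (i in sel) {
      b0 <- start[i] %/% binsize + 1
      b1 <- ceiling(end[i] / binsize)
      v[b0:b1] <- val[i]
    }
    v
  })
  new_coverage_track(values, binsize, genome, "raw")
}

#' Write a fragment table as TSV
#' @param frags fragment data.frame (chrom, start, end, mapq, dup_flag).
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  utils::write.table(frags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fragment table written by [write_fragments()]
#' @param path TSV path.
#' @return fragment data.frame.
#' @export
read_fragments <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
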