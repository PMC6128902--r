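# FLASH read processing: pair merging, barcode demultiplexing, random-tag
# (UMI) PCR-duplicate removal, gene-level crosslink counts and MA values.
#
# Note the mapping-quality conventions differ on purpose between modules:
# ChIP filtering removes quality < 10 (10 kept), FLASH keeps quality
# strictly > 10 (10 removed).

#' Read a FASTQ file
#' @param path FASTQ path (plain text).
#' @return data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(
    id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    seq = lines[idx + 1],
    qual = lines[idx + 3],
    stringsAsFactors = FALSE
  )
}

#' Write reads as FASTQ
#' @param reads data.frame with id, seq, qual.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Merge an overlapping read pair
#'
#' Reverse-complements the reverse read and joins the pair at the longest
#' exact suffix/prefix overlap of at least `min_overlap` nt, giving a
#' merged sequence of length `|fwd| + |rev| - overlap`. Pairs without a
#' qualifying overlap are returned unmerged.
#'
#' @param fwd,rev read sequences (character scalars).
#' @param min_overlap minimum overlap in nt (30 for FLASH, 10 for ChIP
#'   read pairs).
#' @return list with `merged` (logical) and `seq` (merged sequence, or NA
#'   when unmerged).
#' @export
#' @examples
#' merge_pairs("ACGTACGTACGT", revcomp_seq("GTACGTACGTAA"), min_overlap = 4)
merge_pairs <- function(fwd, rev, min_overlap = 30) {
  stopifnot(min_overlap >= 1)
  if (grepl("[^ACGTNacgtn]", fwd) || grepl("[^ACGTNacgtn]", rev)) {
    stop("non-ACGTN characters in read sequence")
  }
  r <- revcomp(rev)
  nf <- nchar(fwd); nr <- nchar(r)
  if (min(nf, nr) < min_overlap) return(list(merged = FALSE, seq = NA_character_))
  for (ov in seq(min(nf, nr), min_overlap)) {
    if (substr(fwd, nf - ov + 1, nf) == substr(r, 1, ov)) {
      return(list(merged = TRUE,
                  seq = paste0(fwd, substr(r, ov + 1, nr))))
    }
  }
  list(merged = FALSE, seq = NA_character_)
}

#' Reverse complement
#' @param seq DNA sequence(s).
#' @return reverse-complemented sequence(s).
#' @export
revcomp_seq <- function(seq) revcomp(seq)

#' Merge all pairs of a library
#'
#' @param fwd,rev read data.frames (id, seq, qual), pair-aligned by row.
#' @param min_overlap minimum overlap in nt.
#' @return data.frame id, seq, merged (logical); unmerged pairs keep the
#'   forward sequence with `merged = FALSE`.
#' @export
merge_read_pairs <- function(fwd, rev, min_overlap = 30) {
  stopifnot(nrow(fwd) == nrow(rev), all(fwd$id == rev$id))
  res <- lapply(seq_len(nrow(fwd)), function(i) {
    merge_pairs(fwd$seq[i], rev$seq[i], min_overlap)
  })
  merged <- vapply(res, `[[`, logical(1), "merged")
  seqs <- vapply(res, `[[`, character(1), "seq")
  data.frame(id = fwd$id, seq = ifelse(merged, seqs, fwd$seq),
             merged = merged, stringsAsFactors = FALSE)
}

#' Demultiplex merged reads by barcode
#'
#' The barcode is read from the leading bases of each sequence and
#' assigned when exactly one whitelist entry lies within `max_hamming`
#' mismatches ("only uniquely identifiable barcodes"); reads matching zero
#' or several entries are discarded with a reason code. The barcode and
#' the following `umi_len` bases are stripped from the sequence; the UMI
#' is retained as a column.
#'
#' @param reads data.frame with id, seq.
#' @param whitelist character vector of equal-length barcodes.
#' @param umi_len UMI length in nt (follows the barcode).
#' @param max_hamming maximum barcode Hamming distance.
#' @return list with `assigned` (id, sample = barcode, umi, seq) and
#'   `discarded` (id, reason in {too_short, no_match, ambiguous}).
#' @export
demultiplex <- function(reads, whitelist, umi_len, max_hamming = 2) {
  if (length(unique(nchar(whitelist))) != 1) {
    stop("whitelist barcodes must have equal length")
  }
  bclen <- nchar(whitelist[1])
  need <- bclen + umi_len
  n <- nrow(reads)
  sample <- character(n); umi <- character(n); insert <- character(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    if (nchar(s) < need + 1) { reason[i] <- "too_short"; next }
    d <- hamming_to_each(substr(s, 1, bclen), whitelist)
    hits <- which(d <= max_hamming)
    if (length(hits) == 0) { reason[i] <- "no_match"; next }
    if (length(hits) > 1) { reason[i] <- "ambiguous"; next }
    sample[i] <- whitelist[hits]
    umi[i] <- substr(s, bclen + 1, need)
    insert[i] <- substr(s, need + 1, nchar(s))
  }
  ok <- is.na(reason)
  list(
    assigned = data.frame(id = reads$id[ok], sample = sample[ok],
                          umi = umi[ok], seq = insert[ok],
                          stringsAsFactors = FALSE),
    discarded = data.frame(id = reads$id[!ok], reason = reason[!ok],
                           stringsAsFactors = FALSE)
  )
}

#' Remove PCR duplicates by random tag
#'
#' Keeps tags with mapping quality strictly above `min_mapq` ("uniquely
#' mapped"), then retains one representative per duplicate key. The key is
#' gene id + UMI when the tags carry a `gene_id` column (synthetic
#' transcriptome mode), otherwise chrom + position + strand + UMI.
#'
#' @param tags data.frame with columns umi, mapq and either gene_id or
#'   (chrom, pos, strand).
#' @param min_mapq exclusive mapping-quality cutoff (default 10: quality
#'   10 is removed, 11 kept).
#' @return deduplicated tag data.frame.
#' @export
dedup_tags <- function(tags, min_mapq = 10) {
  out <- tags[tags$mapq > min_mapq, , drop = FALSE]
  if (nrow(out)) {
    key <- if (!is.null(out$gene_id)) {
      paste(out$gene_id, out$umi, sep = "|")
    } else {
      paste(out$chrom, out$pos, out$strand, out$umi, sep = "|")
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Gene-level crosslink counts
#'
#' Counts deduplicated tags per gene. Tags carrying a `gene_id` column are
#' counted directly; positional tags are assigned to the gene whose
#' interval contains their position on the matching strand. Unassigned
#' tags are tallied separately.
#'
#' @param tags deduplicated tag data.frame.
#' @param annotation gene annotation (required for positional tags).
#' @return list with `counts` (named integer vector per gene over the full
#'   annotation universe) and `n_unassigned`.
#' @export
count_by_gene <- function(tags, annotation) {
  universe <- annotation$gene_id
  counts <- stats::setNames(integer(length(universe)), universe)
  n_unassigned <- 0L
  if (nrow(tags) == 0) return(list(counts = counts, n_unassigned = 0L))
  if (!is.null(tags$gene_id)) {
    known <- tags$gene_id %in% universe
    n_unassigned <- sum(!known)
    tab <- table(tags$gene_id[known])
    counts[names(tab)] <- as.integer(tab)
  } else {
    for (i in seq_len(nrow(tags))) {
      hit <- which(annotation$chrom == tags$chrom[i] &
                     annotation$start <= tags$pos[i] &
                     annotation$end > tags$pos[i] &
                     annotation$strand == tags$strand[i])
      if (length(hit)) {
        counts[hit[1]] <- counts[hit[1]] + 1L
      } else {
        n_unassigned <- n_unassigned + 1L
      }
    }
  }
  list(counts = counts, n_unassigned = n_unassigned)
}

#' MA values between two count vectors
#'
#' Per-gene log ratio and mean log abundance between two samples:
#' `M = log2((a + pc) / (b + pc))`,
#' `A = (log2(a + pc) + log2(b + pc)) / 2`.
#'
#' @param counts_a,counts_b named count vectors over a shared gene
#'   universe.
#' @param pseudocount added to both counts.
#' @return data.frame gene_id, M, A.
#' @export
ma_values <- function(counts_a, counts_b, pseudocount = 1) {
  genes <- union(names(counts_a), names(counts_b))
  a <- ifelse(genes %in% names(counts_a), counts_a[genes], 0)
  b <- ifelse(genes %in% names(counts_b), counts_b[genes], 0)
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  data.frame(
    gene_id = genes,
    M = log2((a + pseudocount) / (b + pseudocount)),
    A = 0.5 * (log2(a + pseudocount) + log2(b + pseudocount)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Full FLASH quantification chain
#'
#' Convenience wrapper: merge pairs, demultiplex, attach alignments,
#' deduplicate by random tag, count per gene — the complete processing of
#' one pooled FLASH run.
#'
#' @param fwd,rev paired read data.frames.
#' @param alignment read alignment table (read_id, gene_id, mapq).
#' @param whitelist barcode whitelist.
#' @param annotation gene annotation.
#' @param umi_len UMI length.
#' @param min_overlap pair-merge minimum overlap.
#' @param max_hamming barcode distance cutoff.
#' @param min_mapq exclusive mapping-quality cutoff for dedup.
#' @return list with per-sample `counts` (named list of count vectors),
#'   `n_unassigned` per sample, and the `discarded` demultiplexing log.
#' @export
flash_quant <- function(fwd, rev, alignment, whitelist, annotation,
                        umi_len, min_overlap = 30, max_hamming = 2,
                        min_mapq = 10) {
  merged <- merge_read_pairs(fwd, rev, min_overlap)
  merged <- merged[merged$merged, , drop = FALSE]
  dm <- demultiplex(merged, whitelist, umi_len, max_hamming)
  tags <- merge(dm$assigned, alignment, by.x = "id", by.y = "read_id")
  out_counts <- list(); out_unassigned <- list()
  for (bc in unique(tags$sample)) {
    sub <- tags[tags$sample == bc, , drop = FALSE]
    uniq <- dedup_tags(sub, min_mapq)
    cg <- count_by_gene(uniq, annotation)
    out_counts[[bc]] <- cg$counts
    out_unassigned[[bc]] <- cg$n_unassigned
  }
  list(counts = out_counts, n_unassigned = out_unassigned,
       discarded = dm$discarded)
}
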