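#' Default analysis parameters
#'
#' Bundles every threshold the pipeline uses so that all stages share one
#' authoritative set of values. Defaults reflect the standard choices for
#' MNase ChIP footprint analysis of the fly dosage compensation system:
#' fragments at or below 140 bp are treated as sub-nucleosomal protein
#' footprints and fragments above 140 bp as nucleosome-scale; ChIP fragments
#' need mapping quality >= 10 while FLASH reads must exceed 10; peak
#' replicate merging bridges gaps of up to 10 bp; promoter assignment uses a
#' 200 bp TSS window for fly peaks and 1 kb for mouse; meta-profiles use an
#' 800 bp flank around reference points or a 500 bp unscaled flank plus a
#' gene body scaled to 1 kb.
#'
#' @param ... named overrides for individual parameters.
#'
#' @return A named list of parameters:
#' \describe{
#'   \item{footprint_max_len}{fragment length (bp) at or below which a
#'     fragment counts as a footprint (140).}
#'   \item{min_mapq}{minimum mapping quality kept for ChIP fragments,
#'     inclusive (10).}
#'   \item{coverage_binsize}{coverage track bin width in bp (2).}
#'   \item{matrix_binsize}{signal-matrix column width in bp (10).}
#'   \item{peak_merge_gap}{maximum gap (bp) bridged when merging replicate
#'     peaks (10).}
#'   \item{tss_assign_dist}{TSS window half-width (bp) for fly peak-to-gene
#'     assignment (200).}
#'   \item{tss_peak_dist_mouse}{TSS window half-width (bp) for mouse
#'     peak-bearing gene sets (1000).}
#'   \item{ref_point_flank}{reference-point matrix flank (bp, 800).}
#'   \item{unscaled_flank}{unscaled flank around the TSS in scaled-region
#'     matrices (bp, 500).}
#'   \item{scaled_body}{length (bp) the remaining gene body is scaled to
#'     (1000).}
#'   \item{pair_min_overlap_chip}{minimum read-pair overlap for ChIP merging
#'     (10 nt).}
#'   \item{pair_min_overlap_flash}{minimum read-pair overlap for FLASH
#'     merging (30 nt).}
#'   \item{max_barcode_hamming}{maximum Hamming distance for barcode
#'     assignment (2).}
#'   \item{flash_min_mapq}{FLASH mapping-quality cutoff, exclusive: quality
#'     must be strictly greater (10).}
#'   \item{de_fdr}{FDR cutoff for differential expression (0.05).}
#'   \item{bootstrap_B}{bootstrap resamples for gene-set tests (10000).}
#'   \item{has_proximal_max_dist}{maximum gene-to-HAS-center distance (bp)
#'     for the HAS-proximal set (2344).}
#'   \item{kmeans_k}{number of peak clusters (3).}
#'   \item{log2_pseudocount}{pseudocount for log2 ratios (1.0).}
#' }
#' @export
#' @examples
#' p <- analysis_params()
#' p$footprint_max_len
#' analysis_params(bootstrap_B = 2000)$bootstrap_B
analysis_params <- function(...) {
  p <- list(
    footprint_max_len = 140L,
    min_mapq = 10L,
    coverage_binsize = 2L,
    matrix_binsize = 10L,
    peak_merge_gap = 10L,
    tss_assign_dist = 200L,
    tss_peak_dist_mouse = 1000L,
    ref_point_flank = 800L,
    unscaled_flank = 500L,
    scaled_body = 1000L,
    pair_min_overlap_chip = 10L,
    pair_min_overlap_flash = 30L,
    max_barcode_hamming = 2L,
    flash_min_mapq = 10L,
    de_fdr = 0.05,
    bootstrap_B = 10000L,
    has_proximal_max_dist = 2344L,
    kmeans_k = 3L,
    log2_pseudocount = 1.0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))))
  p
}
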