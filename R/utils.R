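# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed for a named component from a master seed.
# Keeps every stage regenerable on its own without perturbing the others.
#' @keywords internal
substream_seed <- function(seed, component) {
  offsets <- c(
    genome = 101L, sites = 211L, fragments = 307L, flash = 401L,
    de = 503L, qpcr = 601L, cluster = 701L, orthology = 809L,
    bootstrap = 907L
  )
  if (!component %in% names(offsets)) {
    stop("unknown RNG substream: ", component)
  }
  as.integer((as.double(seed) * 1009 + offsets[[component]]) %% 2147483629)
}

# Truncated normal by rejection; bounds are always within a few sd of the
# mean in this package, so acceptance is high and the loop terminates fast.
#' @keywords internal
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  stopifnot(lower < upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out
}

#' @keywords internal
hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Vectorised Hamming distance of one string against a character vector of
# equal-length strings.
#' @keywords internal
hamming_to_each <- function(x, pool) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(pool, ""), function(p) sum(p != xs), integer(1))
}

#' @keywords internal
revcomp <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), character(1))
}

#' @keywords internal
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# n distinct random DNA k-mers (indices sampled without replacement).
#' @keywords internal
random_dna_distinct <- function(n, len) {
  if (n > 4^len) stop("cannot draw ", n, " distinct ", len, "-mers")
  idx <- sample.int(4^len, n) - 1
  bases <- c("A", "C", "G", "T")
  vapply(idx, function(v) {
    digits <- integer(len)
    for (p in seq_len(len)) {
      digits[p] <- v %% 4
      v <- v %/% 4
    }
    paste(bases[digits + 1], collapse = "")
  }, character(1))
}

#' @keywords internal
geometric_mean <- function(x) exp(mean(log(x)))

#' @keywords internal
is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
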