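# Independent brute-force oracles. These are deliberately dumb per-base /
# per-table loops, sharing no code with the implementation they check.

# Per-base depth accumulated fragment by fragment, then averaged per bin.
brute_coverage <- function(frags, L, binsize, use = "full") {
  depth <- numeric(L)
  for (i in seq_len(nrow(frags))) {
    if (use == "midpoint") {
      p <- (frags$start[i] + frags$end[i]) %/% 2
      depth[p + 1] <- depth[p + 1] + 1
    } else {
      depth[(frags$start[i] + 1):frags$end[i]] <-
        depth[(frags$start[i] + 1):frags$end[i]] + 1
    }
  }
  nb <- ceiling(L / binsize)
  out <- numeric(nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1) * binsize + 1
    hi <- min(b * binsize, L)
    out[b] <- sum(depth[lo:hi]) / binsize
  }
  out
}

# Value of a binned track at a single base, NA outside the chromosome.
track_at <- function(vals, binsize, L, p) {
  if (p < 0 || p >= L) return(NA_real_)
  vals[p %/% binsize + 1]
}

brute_refpoint_row <- function(vals, binsize, L, center, flank, mbin, strand) {
  per_base <- numeric(0)
  for (p in seq(center - flank, center + flank - 1)) {
    per_base <- c(per_base, track_at(vals, binsize, L, p))
  }
  if (strand == "-") per_base <- rev(per_base)
  ncol <- 2 * flank / mbin
  row <- numeric(ncol)
  for (j in seq_len(ncol)) {
    v <- per_base[((j - 1) * mbin + 1):(j * mbin)]
    row[j] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  row
}

brute_scaled_row <- function(vals, binsize, L_chrom, tss, gstart, gend, strand,
                             unscaled, body_bp, mbin) {
  Lg <- gend - gstart
  offs <- seq(-unscaled, unscaled - 1)
  for (k in 0:(body_bp - 1)) {
    offs <- c(offs, unscaled + floor(k * (Lg - unscaled) / body_bp))
  }
  per_base <- numeric(0)
  for (t in offs) {
    p <- if (strand == "+") tss + t else tss - t
    per_base <- c(per_base, track_at(vals, binsize, L_chrom, p))
  }
  ncol <- (2 * unscaled + body_bp) / mbin
  row <- numeric(ncol)
  for (j in seq_len(ncol)) {
    v <- per_base[((j - 1) * mbin + 1):(j * mbin)]
    row[j] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  row
}

# Exact Fisher p by enumerating every table with the observed margins,
# using choose() directly.
brute_fisher <- function(tab, alternative) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  a_all <- a_min:a_max
  prob <- choose(r1, a_all) * choose(r2, c1 - a_all) / choose(n, c1)
  a_obs <- tab[1, 1]
  p_obs <- prob[a_all == a_obs]
  switch(alternative,
    greater = sum(prob[a_all >= a_obs]),
    less = sum(prob[a_all <= a_obs]),
    two_sided = sum(prob[prob <= p_obs * (1 + 1e-7)])
  )
}

# Direct BH step-up formula with an explicit monotone pass.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(ord)]
}

# Interval union coverage by per-base marking.
brute_union_bases <- function(intervals, L) {
  covered <- logical(L)
  for (i in seq_len(nrow(intervals))) {
    covered[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  covered
}
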