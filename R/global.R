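#' Contact-probability decay curve P(s)
#'
#' Mean contact frequency as a function of genomic separation, over
#' logarithmic distance bins pooled across chromosomes. The conventional
#' span is 20 kb to 50 Mb in 500 log bins; both ends and the bin count are
#' parameters so short test chromosomes can be profiled too. Distance bins
#' containing no pixel pairs are reported as NA (missing), not zero.
#'
#' @param map a `contact_map` (balanced values are used when available,
#'   raw counts otherwise)
#' @param dmin,dmax distance range in bp
#' @param nbins number of logarithmic bins
#' @return a `decay_curve` data.frame with `dist_lo`, `dist_hi`, `dist_mid`
#'   (geometric midpoint) and `value`
#' @export
contact_decay_curve <- function(map, dmin = 2e4, dmax = 5e7, nbins = 500L) {
  stopifnot(dmin > 0, dmax > dmin, nbins >= 1)
  edges <- exp(seq(log(dmin), log(dmax), length.out = nbins + 1))
  sums <- counts <- numeric(nbins)
  bw <- map$bins$bin_size
  for (ch in names(map$cis)) {
    m <- if (map$balanced) balanced_cis(map, ch) else map$cis[[ch]]
    n <- nrow(m)
    if (n < 2) next
    for (s in seq_len(n - 1)) {
      d <- s * bw
      if (d < dmin || d >= dmax) next
      k <- findInterval(d, edges, rightmost.closed = TRUE)
      v <- m[cbind(seq_len(n - s), seq_len(n - s) + s)]
      v <- v[!is.na(v)]
      sums[k] <- sums[k] + sum(v)
      counts[k] <- counts[k] + length(v)
    }
  }
  value <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(data.frame(dist_lo = edges[-(nbins + 1)], dist_hi = edges[-1],
                       dist_mid = sqrt(edges[-(nbins + 1)] * edges[-1]),
                       value = value),
            class = c("decay_curve", "data.frame"))
}

#' Jensen-Shannon divergence between two decay curves (or distributions)
#'
#' Both inputs are renormalized to probability distributions over the bins
#' that are non-missing in both, then JSD is computed with the natural-log
#' convention: `0.5 KL(p||m) + 0.5 KL(q||m)` with `m = (p+q)/2`. The value
#' is symmetric, zero iff the distributions agree, and bounded by ln 2 even
#' for disjoint supports.
#'
#' @param p,q `decay_curve` objects with identical binning, or bare numeric
#'   vectors of the same length
#' @return nonnegative scalar in \[0, ln 2\]
#' @export
jensen_shannon_divergence <- function(p, q) {
  pv <- if (is.data.frame(p)) p$value else as.numeric(p)
  qv <- if (is.data.frame(q)) q$value else as.numeric(q)
  if (length(pv) != length(qv)) stop("distributions must share binning")
  keep <- !is.na(pv) & !is.na(qv)
  pv <- pv[keep]; qv <- qv[keep]
  if (!length(pv) || sum(pv) <= 0 || sum(qv) <= 0)
    stop("no jointly non-missing mass")
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  m <- (pv + qv) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(pv, m) + kl(qv, m)) / 2
}

#' Von Neumann entropy of a chromosome's contact structure
#'
#' Quantifies intra-chromosomal disorder: the cis matrix M is
#' log2-transformed (with a pseudocount), converted to the Pearson
#' correlation matrix C of its columns, and the eigenvalues of C are clipped
#' at zero and normalized to sum to one; the entropy is `-sum(lambda *
#' ln(lambda))` with `0 ln 0 := 0`. Higher values mean a flatter spectrum,
#' i.e. less coherent long-range structure. Bounded by `ln(n)` for an
#' n-bin chromosome.
#'
#' @param map a `contact_map` (conventionally at 100 kb resolution)
#' @param chrom chromosome name
#' @param pseudocount added before log2 (default 1); the transform is
#'   `log2(M + pseudocount)`
#' @return nonnegative scalar entropy (nats)
#' @export
von_neumann_entropy <- function(map, chrom, pseudocount = 1) {
  m <- map$cis[[chrom]]
  if (is.null(m)) stop("unknown chromosome: ", chrom)
  keep <- rowSums(m) > 0
  m <- m[keep, keep, drop = FALSE]
  if (nrow(m) < 2) stop("chromosome ", chrom, " has < 2 covered bins")
  lm <- log2(m + pseudocount)
  if (any(apply(lm, 2, stats::sd) == 0))
    stop("constant matrix columns: correlation undefined on ", chrom)
  C <- stats::cor(lm)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev <- ev / sum(ev)
  ev <- ev[ev > 0]
  -sum(ev * log(ev))
}

#' Entropy of a correlation matrix's eigenvalue spectrum
#'
#' The spectral step of [von_neumann_entropy()] on an already-computed
#' correlation (or any symmetric PSD) matrix: eigenvalues clipped at zero,
#' normalized to sum one, Shannon entropy in nats.
#'
#' @param C symmetric matrix
#' @return nonnegative scalar
#' @export
spectral_entropy <- function(C) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev <- ev / sum(ev)
  ev <- ev[ev > 0]
  -sum(ev * log(ev))
}

#' Fraction of contacts that are inter-chromosomal
#'
#' @param map a `contact_map` with trans totals recorded
#' @return scalar `trans / (cis + trans)`
#' @export
cis_trans_ratio <- function(map) {
  cis <- total_contacts(map, "cis")
  trans <- total_contacts(map, "trans")
  if (cis + trans == 0) stop("empty map: cis/trans ratio undefined")
  trans / (cis + trans)
}
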