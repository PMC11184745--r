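#' Construct a binned Hi-C contact map
#'
#' A contact map holds one symmetric raw-count matrix per chromosome (cis),
#' inter-chromosomal (trans) contacts as per-chromosome-pair totals, and,
#' after balancing, per-bin weights and a mask of zero-coverage bins.
#'
#' @param bins a [genome_bins()] object
#' @param cis named list of symmetric nonnegative matrices, one per
#'   chromosome, each `nbin x nbin` for that chromosome. Missing chromosomes
#'   are filled with zeros.
#' @param trans symmetric matrix of trans contact totals per chromosome pair
#'   (zero diagonal), or NULL for none.
#' @return a `contact_map` object
#' @export
contact_map <- function(bins, cis = NULL, trans = NULL) {
  stopifnot(inherits(bins, "genome_bins"))
  chroms <- names(bins$chrom_sizes)
  out <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    n <- bins$nbin[[ch]]
    m <- if (!is.null(cis) && !is.null(cis[[ch]])) cis[[ch]] else matrix(0, n, n)
    stopifnot(nrow(m) == n, ncol(m) == n)
    if (max(abs(m - t(m))) > 1e-8) stop("cis matrix for ", ch, " is not symmetric")
    if (min(m) < 0) stop("negative counts in cis matrix for ", ch)
    out[[ch]] <- m
  }
  if (is.null(trans)) {
    trans <- matrix(0, length(chroms), length(chroms),
                    dimnames = list(chroms, chroms))
  }
  structure(list(bins = bins, cis = out, trans = trans,
                 weights = NULL, masked = NULL, balanced = FALSE),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d chromosome(s), bin size %g bp, total %g contacts (%s)\n",
              length(x$cis), x$bins$bin_size, total_contacts(x),
              if (x$balanced) "balanced" else "unbalanced"))
  invisible(x)
}

#' Total contact count of a map
#'
#' Cis pairs are counted once (upper triangle including the diagonal) plus
#' all trans totals.
#' @param map a `contact_map`
#' @param what "all", "cis" or "trans"
#' @export
total_contacts <- function(map, what = c("all", "cis", "trans")) {
  what <- match.arg(what)
  cis <- sum(vapply(map$cis, function(m) sum(m[upper.tri(m, diag = TRUE)]),
                    numeric(1)))
  trans <- sum(map$trans[upper.tri(map$trans)])
  switch(what, all = cis + trans, cis = cis, trans = trans)
}

#' Read a sparse triplet contact file
#'
#' Two dialects are accepted: `bin1 bin2 count` with 1-based genome-wide bin
#' indices, or `chrom1 start1 chrom2 start2 count` with 0-based bp starts.
#' Records are symmetrized; duplicate (i,j)/(j,i) records are summed.
#' Inter-chromosomal records accumulate into per-pair trans totals.
#'
#' @param path triplet text file (whitespace-separated, no header)
#' @param bins a [genome_bins()] object the records refer to
#' @return a `contact_map`
#' @export
read_triplets <- function(path, bins) {
  tab <- tryCatch(utils::read.table(path, header = FALSE),
                  error = function(e) NULL)
  map <- contact_map(bins)
  if (is.null(tab) || nrow(tab) == 0) return(map)
  if (ncol(tab) == 3) {
    i <- tab[[1]]; j <- tab[[2]]; cnt <- tab[[3]]
    if (!is.numeric(i) || !is.numeric(j))
      stop("bin indices must be integers")
    if (any(i < 1 | i > nbins(bins) | j < 1 | j > nbins(bins)))
      stop("bin index out of range at record ",
           which(i < 1 | i > nbins(bins) | j < 1 | j > nbins(bins))[1])
  } else if (ncol(tab) == 5) {
    for (col in c(1, 3)) {
      bad <- !(as.character(tab[[col]]) %in% names(bins$chrom_sizes))
      if (any(bad)) stop("unknown chromosome at record ", which(bad)[1])
    }
    i <- bin_index(bins, tab[[1]], tab[[2]])
    j <- bin_index(bins, tab[[3]], tab[[4]])
    cnt <- tab[[5]]
  } else stop("triplet file must have 3 or 5 columns")
  if (!is.numeric(cnt) || any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be nonnegative integers (record ",
         which(!is.finite(cnt) | cnt != round(cnt) | cnt < 0)[1], ")")
  chr_i <- bin_chrom(bins, i); chr_j <- bin_chrom(bins, j)
  cisrec <- chr_i == chr_j
  for (ch in unique(chr_i[cisrec])) {
    sel <- cisrec & chr_i == ch
    off <- bins$offset[[ch]]
    li <- i[sel] - off; lj <- j[sel] - off
    m <- map$cis[[ch]]
    for (k in seq_along(li)) {
      m[li[k], lj[k]] <- m[li[k], lj[k]] + cnt[sel][k]
      if (li[k] != lj[k]) m[lj[k], li[k]] <- m[lj[k], li[k]] + cnt[sel][k]
    }
    map$cis[[ch]] <- m
  }
  if (any(!cisrec)) {
    for (k in which(!cisrec)) {
      map$trans[chr_i[k], chr_j[k]] <- map$trans[chr_i[k], chr_j[k]] + cnt[k]
      map$trans[chr_j[k], chr_i[k]] <- map$trans[chr_j[k], chr_i[k]] + cnt[k]
    }
  }
  map
}

#' Write a contact map as upper-triangular triplet text
#'
#' @param map a `contact_map`
#' @param path output path; cis records use 1-based genome-wide bin indices
#' @export
write_triplets <- function(map, path) {
  recs <- list()
  for (ch in names(map$cis)) {
    m <- map$cis[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    if (nrow(idx)) {
      off <- map$bins$offset[[ch]]
      recs[[ch]] <- data.frame(i = idx[, 1] + off, j = idx[, 2] + off,
                               count = m[idx])
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(i = integer(), j = integer(), count = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a dense whitespace-separated matrix as a single-chromosome map
#'
#' @param path dense matrix text file
#' @param chrom chromosome name
#' @param bin_size bin width in bp
#' @return a `contact_map` over one chromosome
#' @export
read_dense_matrix <- function(path, chrom = "chr1", bin_size = 5e4) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  gb <- genome_bins(stats::setNames(nrow(m) * bin_size, chrom), bin_size)
  contact_map(gb, cis = stats::setNames(list((m + t(m)) / 2), chrom))
}

# balanced cis matrix (W M W) for one chromosome, NA on masked bins (internal)
balanced_cis <- function(map, chrom) {
  m <- map$cis[[chrom]]
  if (!map$balanced) return(m)
  w <- map$weights[[chrom]]
  b <- m * outer(w, w)
  msk <- map$masked[[chrom]]
  b[msk, ] <- NA_real_; b[, msk] <- NA_real_
  b
}

#' Balance a contact map to equal row sums
#'
#' Sinkhorn/Knight-Ruiz-style iterative scaling of each cis matrix: finds
#' per-bin weights w so that the rescaled matrix diag(w) M diag(w) has equal
#' row sums on unmasked bins. Bins with zero marginal are masked, not
#' balanced. The contract is the row-sum postcondition, not a particular
#' algorithm.
#'
#' @param map a `contact_map`
#' @param tol relative row-sum residual at convergence
#' @param max_iter maximum iterations per chromosome
#' @return the map with `weights`, `masked` filled and `balanced = TRUE`;
#'   if a chromosome fails to converge a warning reports the residual and
#'   the map is returned with `balanced = FALSE`.
#' @export
kr_balance <- function(map, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(map, "contact_map"))
  chroms <- names(map$cis)
  weights <- masked <- stats::setNames(vector("list", length(chroms)), chroms)
  ok <- TRUE
  for (ch in chroms) {
    m <- map$cis[[ch]]
    marg <- rowSums(m)
    msk <- marg == 0
    masked[[ch]] <- msk
    w <- rep(NA_real_, nrow(m))
    if (all(msk)) { weights[[ch]] <- w; next }
    sub <- m[!msk, !msk, drop = FALSE]
    ws <- rep(1, nrow(sub))
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      r <- rowSums(sub * outer(ws, ws))
      rel <- max(abs(r / mean(r) - 1))
      if (rel < tol) { conv <- TRUE; break }
      ws <- ws / sqrt(r / mean(r))
    }
    if (!conv) {
      warning(sprintf("balancing did not converge on %s (residual %.3g)", ch, rel))
      ok <- FALSE
    }
    # scale so balanced total matches raw total on unmasked bins
    bal_tot <- sum((sub * outer(ws, ws))[upper.tri(sub, diag = TRUE)])
    raw_tot <- sum(sub[upper.tri(sub, diag = TRUE)])
    if (bal_tot > 0) ws <- ws * sqrt(raw_tot / bal_tot)
    w[!msk] <- ws
    weights[[ch]] <- w
  }
  map$weights <- weights
  map$masked <- masked
  map$balanced <- ok
  map
}

#' Observed/expected normalization of a balanced map
#'
#' Divides each cis entry by the mean balanced contact among unmasked pairs
#' at the same bin separation on that chromosome (per-chromosome,
#' per-diagonal empirical expected).
#'
#' @param map a balanced `contact_map`
#' @return an `oe_matrix` object: list with `bins`, `values` (per-chromosome
#'   matrices, NA on masked bins and on diagonals with zero mean), `masked`,
#'   and `expected` (per-chromosome vector of per-separation means).
#' @export
observed_over_expected <- function(map) {
  if (!map$balanced) stop("map must be balanced first (kr_balance)")
  chroms <- names(map$cis)
  values <- expected <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) {
    b <- balanced_cis(map, ch)
    n <- nrow(b)
    if (all(map$masked[[ch]])) {
      warning("chromosome ", ch, " fully masked; empty O/E")
      values[[ch]] <- matrix(NA_real_, n, n)
      expected[[ch]] <- rep(NA_real_, n)
      next
    }
    sep <- abs(row(b) - col(b))
    exp_by_sep <- vapply(0:(n - 1), function(s) {
      v <- b[sep == s]
      mean(v, na.rm = TRUE)
    }, numeric(1))
    emat <- matrix(exp_by_sep[sep + 1], n, n)
    oe <- b / emat
    oe[!is.finite(oe)] <- NA_real_
    values[[ch]] <- oe
    expected[[ch]] <- exp_by_sep
  }
  structure(list(bins = map$bins, values = values, masked = map$masked,
                 expected = expected),
            class = "oe_matrix")
}

#' @export
print.oe_matrix <- function(x, ...) {
  cat(sprintf("oe_matrix: %d chromosome(s), bin size %g bp\n",
              length(x$values), x$bins$bin_size))
  invisible(x)
}

#' Downsample a contact map to a target total
#'
#' Contacts are drawn without replacement jointly over all cis pixels and
#' trans totals (multivariate hypergeometric), so the cis/trans proportion
#' and matrix symmetry are preserved in expectation.
#'
#' @param map a `contact_map` with integer counts
#' @param target_total desired total contact count (<= current total)
#' @param seed RNG seed for reproducibility
#' @return a `contact_map` with `total_contacts() == target_total`
#' @export
downsample_map <- function(map, target_total, seed = 1L) {
  tot <- total_contacts(map)
  if (target_total > tot) stop("target_total exceeds map total")
  if (target_total == tot) return(map)
  set.seed(seed)
  # flatten: per-chromosome upper-tri pixels then trans pairs
  pieces <- lapply(names(map$cis), function(ch) {
    m <- map$cis[[ch]]
    m[upper.tri(m, diag = TRUE)]
  })
  ntr <- map$trans[upper.tri(map$trans)]
  v <- c(unlist(pieces), ntr)
  out <- numeric(length(v))
  k <- target_total; rem <- sum(v)
  nz <- which(v > 0)
  for (p in nz) {
    if (k <= 0) break
    x <- stats::rhyper(1, v[p], rem - v[p], k)
    out[p] <- x
    k <- k - x; rem <- rem - v[p]
  }
  res <- map
  pos <- 0
  for (ch in names(map$cis)) {
    m <- map$cis[[ch]]
    ut <- upper.tri(m, diag = TRUE)
    nn <- sum(ut)
    newm <- matrix(0, nrow(m), ncol(m))
    newm[ut] <- out[pos + seq_len(nn)]
    newm <- newm + t(newm) - diag(diag(newm))
    res$cis[[ch]] <- newm
    pos <- pos + nn
  }
  tr <- map$trans; tr[] <- 0
  tr[upper.tri(tr)] <- out[pos + seq_len(sum(upper.tri(tr)))]
  res$trans <- tr + t(tr)
  res$weights <- NULL; res$masked <- NULL; res$balanced <- FALSE
  res
}

#' Random-walk reproducibility score between two maps
#'
#' GenomeDISCO-style concordance: per chromosome, both raw cis matrices are
#' row-normalized into transition matrices over bins with coverage in either
#' map, smoothed by `smoothing_steps` random-walk steps, and compared by the
#' L1 difference normalized by the number of participating bins. The score
#' is 1 minus the mean normalized difference over chromosomes; identical
#' maps score exactly 1.
#'
#' @param mapA,mapB `contact_map`s on the same bins
#' @param smoothing_steps random-walk steps t (default 3)
#' @return scalar score in \[-1, 1\]
#' @export
reproducibility_score <- function(mapA, mapB, smoothing_steps = 3L) {
  if (!identical(mapA$bins$bins, mapB$bins$bins))
    stop("maps must share identical binning")
  per_chrom <- vapply(names(mapA$cis), function(ch) {
    a <- mapA$cis[[ch]]; b <- mapB$cis[[ch]]
    keep <- rowSums(a) > 0 | rowSums(b) > 0
    if (sum(keep) < 2) return(NA_real_)
    a <- a[keep, keep, drop = FALSE]; b <- b[keep, keep, drop = FALSE]
    pa <- row_normalize(a / sum(a)); pb <- row_normalize(b / sum(b))
    ra <- pa; rb <- pb
    if (smoothing_steps > 1) for (s in seq_len(smoothing_steps - 1)) {
      ra <- ra %*% pa; rb <- rb %*% pb
    }
    1 - sum(abs(ra - rb)) / sum(keep)
  }, numeric(1))
  mean(per_chrom, na.rm = TRUE)
}

row_normalize <- function(m) {
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  m / rs
}
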