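#' Insulation score track
#'
#' Per bin, sums the balanced contacts in the square window spanning
#' `window` bp upstream by `window` bp downstream across the bin, and
#' reports `log2(sum / chromosome mean of sums)`. The score is missing
#' where the window crosses a chromosome end or at least half the window
#' bins are masked.
#'
#' @param map a balanced `contact_map` (conventionally at 50 kb)
#' @param window one-sided window size in bp; must be a multiple of the bin
#'   size and at least 2 bins
#' @return an `insulation_track`: list with `bins`, `score` (genome-wide
#'   vector, NA where undefined), `window`, and empty `boundaries`/`tads`
#'   slots filled by [call_boundaries()]
#' @export
insulation_score <- function(map, window = 5e5) {
  if (!map$balanced) stop("map must be balanced first (kr_balance)")
  bw <- map$bins$bin_size
  w <- as.integer(round(window / bw))
  if (w < 2 || window %% bw != 0)
    stop("window must be a multiple of the bin size and >= 2 bins")
  score <- rep(NA_real_, nbins(map$bins))
  for (ch in names(map$cis)) {
    b <- balanced_cis(map, ch)
    n <- nrow(b)
    msk <- map$masked[[ch]]
    sums <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - w < 1 || i + w > n) next
      up <- (i - w):(i - 1); dn <- (i + 1):(i + w)
      if (sum(msk[c(up, dn)]) >= w) next  # >= 50% of the 2w window bins
      v <- b[up, dn]
      sums[i] <- sum(v, na.rm = TRUE)
    }
    mu <- mean(sums[sums > 0], na.rm = TRUE)
    sc <- ifelse(!is.na(sums) & sums > 0 & is.finite(mu) & mu > 0,
                 log2(sums / mu), NA_real_)
    score[chrom_bin_range(map$bins, ch)] <- sc
  }
  structure(list(bins = map$bins, score = score, window = window,
                 boundaries = NULL, tads = NULL),
            class = "insulation_track")
}

#' @export
print.insulation_track <- function(x, ...) {
  cat(sprintf("insulation_track: window %g bp, %d scored bins, %d boundaries\n",
              x$window, sum(!is.na(x$score)),
              if (is.null(x$boundaries)) 0L else nrow(x$boundaries)))
  invisible(x)
}

#' Call TAD boundaries from an insulation track
#'
#' Crane-style minimum detection: the delta vector at bin i is the mean
#' score over the `delta_window` bins to the right minus the mean over the
#' bins to the left; boundaries sit at upward zero-crossings of delta whose
#' boundary strength (local max minus local min of delta within the
#' window) reaches `strength_min`. TADs are the intervals between
#' consecutive boundaries; candidate boundaries that would create a TAD
#' shorter than `min_tad_bins` are resolved by keeping the stronger
#' boundary.
#'
#' @param track an `insulation_track`
#' @param delta_window bp over which delta means are taken (default 100 kb)
#' @param strength_min minimum boundary strength (default 0.5; at 50 kb
#'   resolution noise-level delta swings reach ~0.2 while genuine domain
#'   boundaries swing near or above 1, so 0.5 separates the two regimes)
#' @param min_tad_bins minimum TAD length in bins (default 3)
#' @return the track with `boundaries` (data.frame chrom/bin/strength/score,
#'   local bin indices) and `tads` (data.frame chrom/start_bin/end_bin,
#'   inclusive local indices) filled
#' @export
call_boundaries <- function(track, delta_window = 1e5, strength_min = 0.5,
                            min_tad_bins = 3L) {
  bw <- track$bins$bin_size
  dw <- max(1L, as.integer(round(delta_window / bw)))
  all_b <- list(); all_t <- list()
  for (ch in names(track$bins$chrom_sizes)) {
    idx <- chrom_bin_range(track$bins, ch)
    sc <- track$score[idx]
    n <- length(sc)
    delta <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      l <- sc[max(1, i - dw):max(1, i - 1)]
      r <- sc[min(n, i + 1):min(n, i + dw)]
      if (i == 1 || i == n) next
      if (all(is.na(l)) || all(is.na(r))) next
      delta[i] <- mean(r, na.rm = TRUE) - mean(l, na.rm = TRUE)
    }
    cand <- integer(0); strength <- numeric(0)
    for (i in seq_len(n - 1)) {
      if (is.na(delta[i]) || is.na(delta[i + 1])) next
      if (delta[i] < 0 && delta[i + 1] >= 0) {
        # strength spans the nearest delta extrema flanking the crossing
        j <- i
        while (j > 1 && !is.na(delta[j - 1]) && delta[j - 1] <= delta[j])
          j <- j - 1
        k <- i + 1
        while (k < n && !is.na(delta[k + 1]) && delta[k + 1] >= delta[k])
          k <- k + 1
        s <- delta[k] - delta[j]
        # the boundary bin is the local score minimum near the crossing
        win <- max(1, i - 1):min(n, i + 2)
        bin <- win[which.min(sc[win])]
        if (is.finite(s) && s >= strength_min) {
          cand <- c(cand, bin); strength <- c(strength, s)
        }
      }
    }
    if (length(cand)) {
      o <- order(cand)
      cand <- cand[o]; strength <- strength[o]
      dup <- duplicated(cand)
      cand <- cand[!dup]; strength <- strength[!dup]
      # enforce the minimum TAD size by dropping the weaker of close pairs
      repeat {
        gaps <- diff(cand)
        viol <- which(gaps < min_tad_bins)
        if (!length(viol)) break
        k <- viol[1]
        drop <- if (strength[k] < strength[k + 1]) k else k + 1L
        cand <- cand[-drop]; strength <- strength[-drop]
      }
      all_b[[ch]] <- data.frame(chrom = ch, bin = cand, strength = strength,
                                score = sc[cand], stringsAsFactors = FALSE)
    }
    edges <- c(0L, if (length(cand)) cand else integer(0), n)
    tad_start <- edges[-length(edges)] + 1L
    tad_end <- edges[-1]
    keep <- tad_end - tad_start + 1L >= min_tad_bins
    if (any(keep))
      all_t[[ch]] <- data.frame(chrom = ch, start_bin = tad_start[keep],
                                end_bin = tad_end[keep],
                                stringsAsFactors = FALSE)
  }
  track$boundaries <- if (length(all_b)) do.call(rbind, all_b) else
    data.frame(chrom = character(), bin = integer(), strength = numeric(),
               score = numeric())
  track$tads <- if (length(all_t)) do.call(rbind, all_t) else
    data.frame(chrom = character(), start_bin = integer(), end_bin = integer())
  rownames(track$boundaries) <- rownames(track$tads) <- NULL
  track
}

#' Aggregate profile around boundaries
#'
#' Mean insulation score per offset within +/- `flank` bins of each
#' boundary, and (when an O/E matrix is supplied) the mean O/E submatrix
#' centered on the boundary diagonal pixel. The 2-D aggregate is
#' summarized by corner means: intra-TAD = upper-left plus lower-right
#' quadrant blocks, inter-TAD = upper-right plus lower-left.
#'
#' @param track an `insulation_track` with scores
#' @param boundaries data.frame with `chrom` and `bin` (local indices);
#'   defaults to the track's own boundaries
#' @param flank flank size in bins (default 10)
#' @param oe optional `oe_matrix` for the 2-D aggregate
#' @return list with `offsets`, `profile` (mean score per offset),
#'   `n_used`, `n_skipped`, and when `oe` is given `matrix`
#'   ((2 flank + 1)^2 mean O/E) plus `intra_tad` / `inter_tad` corner means
#' @export
aggregate_boundary_profile <- function(track, boundaries = NULL, flank = 10L,
                                       oe = NULL) {
  if (is.null(boundaries)) boundaries <- track$boundaries
  if (is.null(boundaries) || !nrow(boundaries)) stop("no boundaries supplied")
  offs <- -flank:flank
  acc <- matrix(NA_real_, nrow(boundaries), length(offs))
  agg2 <- matrix(0, 2 * flank + 1, 2 * flank + 1)
  n2 <- 0L; skipped <- 0L
  for (k in seq_len(nrow(boundaries))) {
    ch <- boundaries$chrom[k]; b <- boundaries$bin[k]
    idx <- chrom_bin_range(track$bins, ch)
    n <- length(idx)
    if (b - flank < 1 || b + flank > n) { skipped <- skipped + 1L; next }
    acc[k, ] <- track$score[idx][b + offs]
    if (!is.null(oe)) {
      sub <- oe$values[[ch]][b + offs, b + offs]
      if (!anyNA(sub)) { agg2 <- agg2 + sub; n2 <- n2 + 1L }
    }
  }
  out <- list(offsets = offs, profile = colMeans(acc, na.rm = TRUE),
              n_used = nrow(boundaries) - skipped, n_skipped = skipped)
  if (!is.null(oe) && n2 > 0) {
    m <- agg2 / n2
    q <- seq_len(flank)
    ctr <- flank + 1L
    hi <- ctr + q
    out$matrix <- m
    out$intra_tad <- mean(c(m[q, q], m[hi, hi]))
    out$inter_tad <- mean(c(m[q, hi], m[hi, q]))
  }
  out
}

#' Shared TADs between two samples
#'
#' Two TADs are shared when their overlap covers at least `min_frac` of
#' BOTH lengths (reciprocal-overlap rule); matching is one-to-one by best
#' reciprocal overlap.
#'
#' @param tadsA,tadsB data.frames chrom/start_bin/end_bin (inclusive bins)
#' @param min_frac reciprocal overlap fraction (default 0.75)
#' @return list with `shared` (data.frame of matched index pairs and their
#'   overlap fractions), `a_specific`, `b_specific` (row indices) and
#'   `n_shared`
#' @export
shared_tads <- function(tadsA, tadsB, min_frac = 0.75) {
  pairs <- list()
  for (i in seq_len(nrow(tadsA))) {
    for (j in seq_len(nrow(tadsB))) {
      if (tadsA$chrom[i] != tadsB$chrom[j]) next
      ov <- min(tadsA$end_bin[i], tadsB$end_bin[j]) -
        max(tadsA$start_bin[i], tadsB$start_bin[j]) + 1L
      if (ov <= 0) next
      fa <- ov / (tadsA$end_bin[i] - tadsA$start_bin[i] + 1L)
      fb <- ov / (tadsB$end_bin[j] - tadsB$start_bin[j] + 1L)
      if (fa >= min_frac && fb >= min_frac)
        pairs[[length(pairs) + 1]] <- data.frame(a = i, b = j, frac_a = fa,
                                                 frac_b = fb)
    }
  }
  if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    pr <- pr[order(-pmin(pr$frac_a, pr$frac_b)), , drop = FALSE]
    # greedy one-to-one matching by best reciprocal overlap
    used_a <- used_b <- integer(0); rows <- integer(0)
    for (r in seq_len(nrow(pr))) {
      if (pr$a[r] %in% used_a || pr$b[r] %in% used_b) next
      rows <- c(rows, r); used_a <- c(used_a, pr$a[r]); used_b <- c(used_b, pr$b[r])
    }
    shared <- pr[rows, , drop = FALSE]
  } else {
    shared <- data.frame(a = integer(), b = integer(), frac_a = numeric(),
                         frac_b = numeric())
  }
  list(shared = shared,
       a_specific = setdiff(seq_len(nrow(tadsA)), shared$a),
       b_specific = setdiff(seq_len(nrow(tadsB)), shared$b),
       n_shared = nrow(shared))
}

#' Rank and cluster variable TAD boundaries across stages
#'
#' The boundary universe is every bin called as a boundary in ANY stage.
#' Each universe bin is scored by the standard deviation of its insulation
#' score across stages, ranked descending, and the top `top_k` are selected
#' (ties broken by bin order). The selected rows (per-stage scores,
#' standardized) are clustered by hierarchical clustering (Euclidean
#' distance, complete linkage) into `k_clusters` groups.
#'
#' @param tracks list of `insulation_track`s (one per stage, same bins),
#'   each with boundaries called
#' @param top_k number of most variable boundaries to keep (default 1000)
#' @param k_clusters number of clusters (default 4)
#' @return data.frame with genome-wide `bin`, per-stage scores, `sd`,
#'   `rank` and `cluster`; attribute `n_excluded` counts universe bins
#'   missing a score in some stage
#' @export
boundary_variability <- function(tracks, top_k = 1000L, k_clusters = 4L) {
  stopifnot(length(tracks) >= 2)
  bins <- tracks[[1]]$bins
  universe <- sort(unique(unlist(lapply(tracks, function(tr) {
    if (is.null(tr$boundaries) || !nrow(tr$boundaries)) return(integer(0))
    bins$offset[tr$boundaries$chrom] + tr$boundaries$bin
  }))))
  if (!length(universe)) stop("no boundaries in any stage")
  scores <- sapply(tracks, function(tr) tr$score[universe])
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  complete <- stats::complete.cases(scores)
  n_excluded <- sum(!complete)
  universe <- universe[complete]
  scores <- scores[complete, , drop = FALSE]
  sds <- apply(scores, 1, stats::sd)
  o <- order(-sds, universe)
  sel <- o[seq_len(min(top_k, length(o)))]
  sel_scores <- scores[sel, , drop = FALSE]
  z <- t(apply(sel_scores, 1, function(r) {
    s <- stats::sd(r)
    if (s == 0) r * 0 else (r - mean(r)) / s
  }))
  cluster <- if (nrow(z) > k_clusters) {
    stats::cutree(stats::hclust(stats::dist(z), method = "complete"),
                  k = k_clusters)
  } else rep(1L, nrow(z))
  out <- data.frame(bin = universe[sel], sel_scores, sd = sds[sel],
                    rank = seq_along(sel), cluster = cluster)
  names(out)[2:(1 + length(tracks))] <- paste0("stage", seq_along(tracks))
  attr(out, "n_excluded") <- n_excluded
  out
}
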