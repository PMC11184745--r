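# shifted-sum accumulation: S[i,j] = sum over offsets of M[i+di, j+dj],
# off-matrix cells contribute 0 (internal)
neighborhood_sum <- function(m, offsets) {
  n1 <- nrow(m); n2 <- ncol(m)
  s <- matrix(0, n1, n2)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets[k, 1]; dj <- offsets[k, 2]
    ri <- max(1, 1 - di):min(n1, n1 - di)
    rj <- max(1, 1 - dj):min(n2, n2 - dj)
    if (!length(ri) || !length(rj)) next
    s[ri, rj] <- s[ri, rj] + m[ri + di, rj + dj, drop = FALSE]
  }
  s
}

# the four HiCCUPS-style neighborhood offset sets for inner radius p and
# outer radius w, excluding the center pixel (internal)
loop_neighborhoods <- function(p = 2L, w = 5L) {
  grid <- expand.grid(di = -w:w, dj = -w:w)
  inner <- abs(grid$di) <= p & abs(grid$dj) <= p
  donut <- !inner & grid$di != 0 & grid$dj != 0
  lower_left <- grid$di > p & grid$di <= w & grid$dj < -p & grid$dj >= -w
  horizontal <- abs(grid$di) <= 1 & !inner
  vertical <- abs(grid$dj) <= 1 & !inner
  lapply(list(donut = donut, lower_left = lower_left,
              horizontal = horizontal, vertical = vertical),
         function(sel) as.matrix(grid[sel, , drop = FALSE]))
}

#' Call focal chromatin loops (simplified HiCCUPS-style)
#'
#' Single-resolution loop detection against four local-neighborhood
#' expectations. For each candidate pixel, the distance-decay expected
#' value is rescaled by the observed/expected ratio of each of four
#' neighborhoods (donut, lower-left, horizontal stripe, vertical stripe);
#' the Poisson upper-tail p-value of the raw count against the most
#' conservative (largest) of the four expecteds is computed, BH-corrected
#' within log2 distance strata, and pixels passing the FDR and a
#' fold-enrichment floor are merged by 8-connectivity into loops, each
#' represented by its most significant pixel. This is a documented
#' simplification of HiCCUPS (no multi-resolution merging, no
#' lambda-chunking) and makes no claim of equivalence to Juicer.
#'
#' @param map a balanced `contact_map` (conventionally at 10 kb)
#' @param fdr BH false-discovery-rate threshold (default 0.1)
#' @param p_inner,w_outer inner and outer neighborhood radii in bins
#' @param min_sep,max_sep anchor separation range in bp (defaults 20 kb and
#'   2 Mb)
#' @param ratio_min minimum observed / max-expected fold enrichment
#'   (default 1.5, the Juicer-style enrichment floor)
#' @return a `loop_set`: data.frame with `chrom`, `bin1`, `bin2` (local bin
#'   indices of the summit pixel), `observed`, `expected` (max of the four),
#'   `qvalue`, `n_pixels` (cluster size); attributes record the parameters
#' @export
call_loops <- function(map, fdr = 0.1, p_inner = 2L, w_outer = 5L,
                       min_sep = 2e4, max_sep = 2e6, ratio_min = 1.5) {
  if (!map$balanced) stop("map must be balanced first (kr_balance)")
  bw <- map$bins$bin_size
  smin <- max(2L, as.integer(ceiling(min_sep / bw)))
  smax <- as.integer(floor(max_sep / bw))
  hoods <- loop_neighborhoods(p_inner, w_outer)
  res <- list()
  for (ch in names(map$cis)) {
    bal <- balanced_cis(map, ch)
    n <- nrow(bal)
    if (n <= smin) next
    msk <- map$masked[[ch]]
    w <- map$weights[[ch]]
    bal0 <- bal; bal0[is.na(bal0)] <- 0
    sep <- abs(row(bal) - col(bal))
    # per-diagonal expected from balanced values
    exp_by_sep <- vapply(0:(n - 1), function(s) {
      v <- bal[sep == s]; mean(v, na.rm = TRUE)
    }, numeric(1))
    emat <- matrix(exp_by_sep[sep + 1], n, n)
    emat0 <- emat; emat0[is.na(emat0) | is.na(bal)] <- 0
    lam_bal <- matrix(-Inf, n, n)
    for (h in hoods) {
      so <- neighborhood_sum(bal0, h)
      se <- neighborhood_sum(emat0, h)
      lam <- ifelse(se > 0, emat * so / se, NA_real_)
      lam_bal <- pmax(lam_bal, lam, na.rm = TRUE)
    }
    cand <- which(upper.tri(bal) & sep >= smin & sep <= smax &
                    is.finite(lam_bal) & lam_bal > 0 &
                    !msk[row(bal)] & !msk[col(bal)],
                  arr.ind = TRUE)
    if (!nrow(cand)) next
    obs <- map$cis[[ch]][cand]
    # convert the balanced expectation back to raw-count scale
    lam_raw <- lam_bal[cand] / (w[cand[, 1]] * w[cand[, 2]])
    pval <- stats::ppois(obs - 1, lam_raw, lower.tail = FALSE)
    # one BH family per chromosome: stratified families would each admit
    # their own rank-1 false call under the global null
    qval <- stats::p.adjust(pval, method = "BH")
    enrich <- obs / pmax(lam_raw, .Machine$double.eps)
    sig <- which(qval < fdr & enrich >= ratio_min)
    if (!length(sig)) next
    pix <- data.frame(i = cand[sig, 1], j = cand[sig, 2],
                      observed = obs[sig], expected = lam_raw[sig],
                      qvalue = qval[sig])
    # merge significant pixels by 8-connectivity; summit = min q
    key <- pix$i * (n + 1) + pix$j
    comp <- seq_len(nrow(pix))
    repeat {
      changed <- FALSE
      for (a in seq_len(nrow(pix))) {
        nb <- which(abs(pix$i - pix$i[a]) <= 1 & abs(pix$j - pix$j[a]) <= 1)
        cc <- min(comp[nb])
        if (any(comp[nb] != cc)) { comp[nb] <- cc; changed <- TRUE }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      rows <- which(comp == cc)
      s <- rows[order(pix$qvalue[rows], -pix$observed[rows])][1]
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, bin1 = pix$i[s], bin2 = pix$j[s],
        observed = pix$observed[s], expected = pix$expected[s],
        qvalue = pix$qvalue[s], n_pixels = length(rows),
        stringsAsFactors = FALSE)
    }
  }
  loops <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
               observed = numeric(), expected = numeric(),
               qvalue = numeric(), n_pixels = integer())
  rownames(loops) <- NULL
  structure(loops, class = c("loop_set", "data.frame"),
            bin_size = bw, fdr = fdr)
}

#' Loop anchors as a BED data.frame
#'
#' One interval per distinct anchor bin of a loop set (anchor extent = one
#' bin).
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param bins the `genome_bins` of the loop map
#' @return BED data.frame chrom/start/end
#' @export
loop_anchors <- function(loops, bins) {
  if (!nrow(loops)) return(data.frame(chrom = character(), start = numeric(),
                                      end = numeric()))
  anc <- unique(rbind(data.frame(chrom = loops$chrom, bin = loops$bin1),
                      data.frame(chrom = loops$chrom, bin = loops$bin2)))
  g <- bins$offset[anc$chrom] + anc$bin
  data.frame(chrom = anc$chrom, start = bins$bins$start[g],
             end = bins$bins$end[g], stringsAsFactors = FALSE)
}

#' Aggregate peak analysis (APA)
#'
#' Averages the O/E submatrices centered on each loop pixel. The APA score
#' is the center pixel divided by the mean of the lower-left corner
#' quadrant block (the Juicer convention); values near 1 indicate no
#' collective enrichment.
#'
#' @param oe an `oe_matrix` (10 kb convention)
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param flank flank size in bins (default 10)
#' @return list with `matrix` ((2 flank + 1)^2 mean O/E), `score`,
#'   `n_used`, `n_skipped`
#' @export
apa <- function(oe, loops, flank = 10L) {
  if (!nrow(loops)) stop("empty loop set")
  agg <- matrix(0, 2 * flank + 1, 2 * flank + 1)
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(loops))) {
    ch <- loops$chrom[k]
    v <- oe$values[[ch]]
    i <- loops$bin1[k]; j <- loops$bin2[k]
    n <- nrow(v)
    if (i - flank < 1 || j + flank > n || j - flank < 1 || i + flank > n) {
      skipped <- skipped + 1L; next
    }
    sub <- v[(i - flank):(i + flank), (j - flank):(j + flank)]
    if (anyNA(sub)) { skipped <- skipped + 1L; next }
    agg <- agg + sub
    used <- used + 1L
  }
  if (!used) stop("no loops usable for APA (all skipped)")
  m <- agg / used
  ctr <- flank + 1L
  h <- max(1L, flank %/% 2L)
  ll <- m[(2 * flank + 2 - h):(2 * flank + 1), 1:h]  # lower-left corner
  list(matrix = m, score = m[ctr, ctr] / mean(ll), n_used = used,
       n_skipped = skipped)
}

#' Shared loops between two sets
#'
#' Greedy one-to-one matching (best q-value first): two loops are shared
#' when both anchors shift by at most `max_shift` bins.
#'
#' @param setA,setB `loop_set`s at the same resolution
#' @param max_shift maximum per-anchor shift in bins (default 1)
#' @return list with `pairs` (data.frame of matched row indices),
#'   `a_specific`, `b_specific`, `n_shared`
#' @export
shared_loops <- function(setA, setB, max_shift = 1L) {
  ba <- attr(setA, "bin_size"); bb <- attr(setB, "bin_size")
  if (!is.null(ba) && !is.null(bb) && !identical(ba, bb))
    stop("loop sets at different resolutions")
  ordA <- if (nrow(setA) && !is.null(setA$qvalue))
    order(setA$qvalue, setA$chrom, setA$bin1, setA$bin2) else seq_len(nrow(setA))
  usedB <- rep(FALSE, nrow(setB))
  pairs <- list()
  for (a in ordA) {
    cnd <- which(!usedB & setB$chrom == setA$chrom[a] &
                   abs(setB$bin1 - setA$bin1[a]) <= max_shift &
                   abs(setB$bin2 - setA$bin2[a]) <= max_shift)
    if (!length(cnd)) next
    d <- abs(setB$bin1[cnd] - setA$bin1[a]) + abs(setB$bin2[cnd] - setA$bin2[a])
    b <- cnd[order(d, cnd)][1]
    usedB[b] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(a = a, b = b)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = integer(), b = integer())
  list(pairs = pairs,
       a_specific = setdiff(seq_len(nrow(setA)), pairs$a),
       b_specific = setdiff(seq_len(nrow(setB)), pairs$b),
       n_shared = nrow(pairs))
}

#' Cosine similarity of loop-pixel contact vectors between two maps
#'
#' Extracts the balanced contact frequency at every loop pixel from both
#' maps and returns the cosine of the two nonnegative vectors; invariant to
#' global depth scaling of either map.
#'
#' @param mapA,mapB balanced `contact_map`s on the same bins
#' @param loops data.frame with chrom/bin1/bin2
#' @return scalar in \[0, 1\]
#' @export
loop_contact_similarity <- function(mapA, mapB, loops) {
  if (!nrow(loops)) stop("empty loop set")
  get_vec <- function(map) {
    vapply(seq_len(nrow(loops)), function(k) {
      v <- balanced_cis(map, loops$chrom[k])[loops$bin1[k], loops$bin2[k]]
      if (is.na(v)) 0 else v
    }, numeric(1))
  }
  va <- get_vec(mapA); vb <- get_vec(mapB)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    warning("zero contact vector; similarity undefined")
    return(NA_real_)
  }
  sum(va * vb) / (na * nb)
}

#' Classify loop anchors by regulatory element content
#'
#' Each anchor (one bin) is labelled P if it shares >= 1 bp with any
#' promoter region, else E if it overlaps an enhancer, else None
#' (promoter-over-enhancer precedence). The loop class is the unordered
#' anchor-label pair.
#'
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param bins the `genome_bins` of the loop map
#' @param enhancers BED data.frame of enhancer intervals
#' @param promoters BED data.frame of promoter regions
#' @return data.frame with per-loop `anchor1`, `anchor2` labels and `class`
#'   (e.g. "E-P", "P-P", "None-None")
#' @export
classify_anchors <- function(loops, bins, enhancers, promoters) {
  if (!nrow(loops))
    return(data.frame(anchor1 = character(), anchor2 = character(),
                      class = character()))
  anchor_label <- function(chrom, bin) {
    g <- bins$offset[chrom] + bin
    iv <- data.frame(chrom = chrom, start = bins$bins$start[g],
                     end = bins$bins$end[g])
    gr <- bed_to_granges(iv)
    isP <- if (nrow(promoters))
      IRanges::overlapsAny(gr, bed_to_granges(promoters)) else
        rep(FALSE, length(gr))
    isE <- if (nrow(enhancers))
      IRanges::overlapsAny(gr, bed_to_granges(enhancers)) else
        rep(FALSE, length(gr))
    ifelse(isP, "P", ifelse(isE, "E", "None"))
  }
  a1 <- anchor_label(loops$chrom, loops$bin1)
  a2 <- anchor_label(loops$chrom, loops$bin2)
  ord <- function(x, y) {
    lv <- c(P = 1, E = 2, None = 3)
    ifelse(lv[x] <= lv[y], paste(x, y, sep = "-"), paste(y, x, sep = "-"))
  }
  data.frame(anchor1 = a1, anchor2 = a2, class = ord(a1, a2),
             stringsAsFactors = FALSE)
}

#' Expression of genes connected by loops versus not
#'
#' A gene is loop-connected when any loop anchor shares >= 1 bp with its
#' promoter region; the two expression distributions are compared with a
#' rank-based (Wilcoxon) test.
#'
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param bins the `genome_bins` of the loop map
#' @param promoters BED data.frame of promoter regions with a `name`
#'   column of gene ids
#' @param expression data.frame with `gene_id` and an expression column
#'   (second column used)
#' @return list with `in_loops`, `not_in_loops` (expression vectors),
#'   `test` (htest or NULL)
#' @export
loop_gene_expression <- function(loops, bins, promoters, expression) {
  expr <- stats::setNames(expression[[2]], expression$gene_id)
  connected <- character(0)
  if (nrow(loops) && nrow(promoters)) {
    anc <- loop_anchors(loops, bins)
    hit <- IRanges::overlapsAny(bed_to_granges(promoters),
                                bed_to_granges(anc))
    connected <- unique(promoters$name[hit])
  }
  in_loops <- expr[names(expr) %in% connected]
  not_in <- expr[!(names(expr) %in% connected)]
  test <- if (length(in_loops) >= 2 && length(not_in) >= 2)
    stats::wilcox.test(in_loops, not_in, alternative = "greater") else NULL
  list(in_loops = in_loops, not_in_loops = not_in, test = test)
}
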