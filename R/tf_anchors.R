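#' Enrichment of TF peaks on loop anchors versus random regions
#'
#' Observed statistic: fraction of TF peaks sharing >= 1 bp with any
#' anchor. Background: `n_rand` draws, each placing one random region per
#' anchor (same chromosome, same length, uniform start), and recording the
#' fraction of peaks overlapping the random set. The empirical p-value is
#' the fraction of background draws at least as large as the observed
#' value, with the +1 correction so p is never 0.
#'
#' @param tf_peaks BED data.frame
#' @param anchors BED data.frame of loop-anchor intervals
#' @param chrom_sizes named vector of chromosome lengths
#' @param n_rand number of background draws (default 200)
#' @param seed RNG seed
#' @return list with `observed`, `background` (vector of draws), `p_value`
#' @export
anchor_peak_enrichment <- function(tf_peaks, anchors, chrom_sizes,
                                   n_rand = 200L, seed = 1L) {
  set.seed(seed)
  len <- anchors$end - anchors$start
  if (any(len > chrom_sizes[anchors$chrom]))
    stop("anchor longer than its chromosome")
  if (!nrow(tf_peaks)) {
    warning("empty peak set")
    return(list(observed = 0, background = rep(0, n_rand), p_value = 1))
  }
  pk <- bed_to_granges(tf_peaks)
  observed <- mean(IRanges::overlapsAny(pk, bed_to_granges(anchors)))
  background <- vapply(seq_len(n_rand), function(r) {
    maxstart <- unname(chrom_sizes[anchors$chrom]) - len
    st <- floor(stats::runif(nrow(anchors)) * (maxstart + 1))
    rnd <- data.frame(chrom = anchors$chrom, start = st, end = st + len)
    mean(IRanges::overlapsAny(pk, bed_to_granges(rnd)))
  }, numeric(1))
  p <- (sum(background >= observed) + 1) / (n_rand + 1)
  list(observed = observed, background = background, p_value = p)
}

#' Classify genes by TF occupancy of their promoter-connecting loops
#'
#' For each gene, all loops with either anchor overlapping (>= 1 bp) the
#' gene's promoter region are collected; among them the best loop decides
#' the class: "both" if any loop has TF peaks on both anchors, else "one"
#' if any loop has exactly one bound anchor, else "none". Genes without a
#' promoter-connecting loop are "no_loop".
#'
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param bins the `genome_bins` of the loop map
#' @param promoters BED data.frame of promoter regions with `name` gene ids
#' @param tf_peaks BED data.frame of TF ChIP peaks
#' @return data.frame with `gene_id`, `class`
#'   (both/one/none/no_loop) and `n_loops` connecting the promoter
#' @export
classify_gene_occupancy <- function(loops, bins, promoters, tf_peaks) {
  genes <- unique(promoters$name)
  if (!length(genes))
    return(data.frame(gene_id = character(), class = character(),
                      n_loops = integer()))
  if (nrow(loops)) {
    a1 <- data.frame(chrom = loops$chrom,
                     g = bins$offset[loops$chrom] + loops$bin1)
    a2 <- data.frame(chrom = loops$chrom,
                     g = bins$offset[loops$chrom] + loops$bin2)
    iv <- function(g) data.frame(chrom = bins$bins$chrom[g],
                                 start = bins$bins$start[g],
                                 end = bins$bins$end[g])
    gr1 <- bed_to_granges(iv(a1$g)); gr2 <- bed_to_granges(iv(a2$g))
    tf <- if (nrow(tf_peaks)) bed_to_granges(tf_peaks) else NULL
    bound1 <- if (is.null(tf)) rep(FALSE, nrow(loops)) else
      IRanges::overlapsAny(gr1, tf)
    bound2 <- if (is.null(tf)) rep(FALSE, nrow(loops)) else
      IRanges::overlapsAny(gr2, tf)
    n_bound <- bound1 + bound2
    pr <- bed_to_granges(promoters)
    h1 <- GenomicRanges::findOverlaps(pr, gr1)
    h2 <- GenomicRanges::findOverlaps(pr, gr2)
    conn <- rbind(
      data.frame(gene = promoters$name[S4Vectors::queryHits(h1)],
                 loop = S4Vectors::subjectHits(h1)),
      data.frame(gene = promoters$name[S4Vectors::queryHits(h2)],
                 loop = S4Vectors::subjectHits(h2)))
    conn <- unique(conn)
  } else {
    conn <- data.frame(gene = character(), loop = integer())
    n_bound <- integer(0)
  }
  cls <- vapply(genes, function(g) {
    lp <- conn$loop[conn$gene == g]
    if (!length(lp)) return("no_loop")
    best <- max(n_bound[lp])
    c("none", "one", "both")[best + 1]
  }, character(1))
  nlp <- vapply(genes, function(g) sum(conn$gene == g), integer(1))
  data.frame(gene_id = genes, class = unname(cls), n_loops = unname(nlp),
             stringsAsFactors = FALSE)
}

#' Expressed fraction and expression level by occupancy class
#'
#' Per class: fraction of genes with FPKM at or above `fpkm_expressed`
#' (>= rule) and the FPKM distribution among expressed genes; both-vs-one
#' and one-vs-none rank (Wilcoxon) comparisons, BH-corrected across the
#' pairwise set.
#'
#' @param classes data.frame from [classify_gene_occupancy()]
#' @param expression data.frame with `gene_id` and an FPKM column (second
#'   column used)
#' @param fpkm_expressed expression threshold (default 2)
#' @return list with `expressed_fraction` (named by class), `fpkm` (list of
#'   per-class expressed-gene FPKM vectors), `tests` (data.frame of
#'   pairwise comparisons with BH-adjusted p), `n_per_class`
#' @export
occupancy_expression_summary <- function(classes, expression,
                                         fpkm_expressed = 2) {
  fpkm <- stats::setNames(expression[[2]], expression$gene_id)
  classes <- classes[classes$gene_id %in% names(fpkm), , drop = FALSE]
  lv <- c("both", "one", "none")
  per_class <- lapply(stats::setNames(lv, lv), function(cl)
    fpkm[classes$gene_id[classes$class == cl]])
  expressed_fraction <- vapply(per_class, function(v)
    if (length(v)) mean(v >= fpkm_expressed) else NA_real_, numeric(1))
  expr_vals <- lapply(per_class, function(v) v[v >= fpkm_expressed])
  cmp <- list(c("both", "one"), c("one", "none"))
  tests <- do.call(rbind, lapply(cmp, function(pair) {
    x <- per_class[[pair[1]]]; y <- per_class[[pair[2]]]
    p <- if (length(x) >= 2 && length(y) >= 2)
      stats::wilcox.test(x, y)$p.value else NA_real_
    data.frame(group1 = pair[1], group2 = pair[2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  list(expressed_fraction = expressed_fraction, fpkm = expr_vals,
       tests = tests,
       n_per_class = vapply(per_class, length, integer(1)))
}

#' Loop interaction scores stratified by TF-bound anchor count
#'
#' Loops are stratified by how many anchors carry a TF peak (2/1/0) and
#' the per-stratum score distributions are compared pairwise by rank
#' (Wilcoxon) tests with BH correction.
#'
#' @param loop_scores numeric vector of per-loop scores (same order as
#'   `loops` rows)
#' @param loops a `loop_set` or data.frame with chrom/bin1/bin2
#' @param bins the `genome_bins` of the loop map
#' @param tf_peaks BED data.frame
#' @return list with `scores` (list by stratum "2"/"1"/"0"), `tests`
#' @export
loop_score_by_occupancy <- function(loop_scores, loops, bins, tf_peaks) {
  stopifnot(length(loop_scores) == nrow(loops))
  iv <- function(g) data.frame(chrom = bins$bins$chrom[g],
                               start = bins$bins$start[g],
                               end = bins$bins$end[g])
  g1 <- bins$offset[loops$chrom] + loops$bin1
  g2 <- bins$offset[loops$chrom] + loops$bin2
  tf <- if (nrow(tf_peaks)) bed_to_granges(tf_peaks) else NULL
  b1 <- if (is.null(tf)) rep(FALSE, nrow(loops)) else
    IRanges::overlapsAny(bed_to_granges(iv(g1)), tf)
  b2 <- if (is.null(tf)) rep(FALSE, nrow(loops)) else
    IRanges::overlapsAny(bed_to_granges(iv(g2)), tf)
  strat <- factor(b1 + b2, levels = c(2, 1, 0))
  scores <- split(loop_scores, strat)
  names(scores) <- c("2", "1", "0")
  cmp <- list(c("2", "1"), c("1", "0"))
  tests <- do.call(rbind, lapply(cmp, function(pair) {
    x <- scores[[pair[1]]]; y <- scores[[pair[2]]]
    p <- if (length(x) >= 2 && length(y) >= 2)
      stats::wilcox.test(x, y)$p.value else NA_real_
    data.frame(group1 = pair[1], group2 = pair[2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "BH")
  list(scores = scores, tests = tests)
}
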