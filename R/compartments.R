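# BED data.frame (chrom/start/end, 0-based half-open) -> GRanges (internal)
bed_to_granges <- function(bed) {
  GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$start + 1, end = bed$end))
}

# GRanges of a genome_bins object (internal)
bins_granges <- function(bins) bed_to_granges(bins$bins)

#' Per-bin TSS count (gene density)
#'
#' @param bins a `genome_bins` object
#' @param tss BED data.frame of transcription start sites (chrom/start/end)
#' @return integer vector over genome-wide bins
#' @export
tss_density <- function(bins, tss) {
  gd <- integer(nbins(bins))
  if (nrow(tss)) {
    hits <- GenomicRanges::countOverlaps(bins_granges(bins),
                                         bed_to_granges(tss))
    gd <- as.integer(hits)
  }
  gd
}

#' Call A/B compartments from an O/E matrix
#'
#' Per chromosome, computes the Pearson correlation matrix of the O/E
#' columns over unmasked bins and takes its first eigenvector. The sign is
#' fixed so that positive values (A) have the higher mean gene density;
#' bins with positive eigenvector value are labelled A, negative B.
#' Chromosomes with fewer than `min_bins` unmasked bins are masked entirely.
#'
#' @param oe an `oe_matrix` from [observed_over_expected()]
#' @param gene_density per-bin TSS count (genome-wide vector), e.g. from
#'   [tss_density()]
#' @param min_bins minimum unmasked bins per chromosome (default 10)
#' @param stage optional stage identifier stored on the profile
#' @return a `compartment_profile`: list with `bins`, `e1` (genome-wide,
#'   NA on masked bins), `label` ("A"/"B"/NA) and `stage`
#' @export
call_compartments <- function(oe, gene_density, min_bins = 10L,
                              stage = NA_character_) {
  bins <- oe$bins
  stopifnot(length(gene_density) == nbins(bins))
  e1 <- rep(NA_real_, nbins(bins))
  label <- rep(NA_character_, nbins(bins))
  for (ch in names(oe$values)) {
    idx <- chrom_bin_range(bins, ch)
    v <- oe$values[[ch]]
    keep <- !oe$masked[[ch]] & colSums(!is.na(v)) > 1
    if (sum(keep) < min_bins) next
    sub <- v[keep, keep, drop = FALSE]
    sub[is.na(sub)] <- 1  # missing diagonals carry no information: O/E mean
    if (any(apply(sub, 2, stats::sd) == 0)) next
    C <- stats::cor(sub)
    vec <- eigen(C, symmetric = TRUE)$vectors[, 1]
    gd <- gene_density[idx][keep]
    pos <- vec > 0
    if (any(pos) && any(!pos)) {
      if (mean(gd[pos]) < mean(gd[!pos])) vec <- -vec
    } else if (stats::sd(gd) > 0 && stats::cor(vec, gd) < 0) {
      vec <- -vec
    }
    e1[idx][keep] <- vec
    label[idx][keep] <- ifelse(vec > 0, "A", "B")
  }
  structure(list(bins = bins, e1 = e1, label = label, stage = stage),
            class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, ...) {
  cat(sprintf("compartment_profile (%s): %d A, %d B, %d masked bins\n",
              x$stage, sum(x$label == "A", na.rm = TRUE),
              sum(x$label == "B", na.rm = TRUE), sum(is.na(x$label))))
  invisible(x)
}

#' Compartmentalization strength score AB/(AA+BB)
#'
#' Mean O/E over A-B cis bin pairs divided by the sum of the mean O/E over
#' A-A pairs and over B-B pairs. Lower values indicate stronger segregation
#' of the two compartments; a structureless matrix scores 0.5.
#'
#' @param oe an `oe_matrix`
#' @param profile a `compartment_profile`
#' @param chrom chromosome name
#' @return scalar score, or NA with a warning if a label class is absent
#' @export
compartment_strength <- function(oe, profile, chrom) {
  idx <- chrom_bin_range(oe$bins, chrom)
  lab <- profile$label[idx]
  v <- oe$values[[chrom]]
  keep <- !is.na(lab)
  if (!any(lab[keep] == "A") || !any(lab[keep] == "B")) {
    warning("label class absent on ", chrom, "; strength undefined")
    return(NA_real_)
  }
  ut <- upper.tri(v)
  la <- lab[row(v)]; lb <- lab[col(v)]
  ok <- ut & !is.na(v) & !is.na(la) & !is.na(lb)
  aa <- mean(v[ok & la == "A" & lb == "A"])
  bb <- mean(v[ok & la == "B" & lb == "B"])
  ab <- mean(v[ok & la != lb])
  ab / (aa + bb)
}

#' Compartmentalization saddle matrix
#'
#' Bins are ranked genome-wide by their first-eigenvector value (ascending:
#' strongest B first), split into `ngroups` near-equal quantile groups, and
#' the mean cis O/E between every group pair is reported. Corner summaries
#' average the extreme `corner_frac` of groups: BB (both low), AA (both
#' high), AB (one low, one high).
#'
#' @param oe an `oe_matrix`
#' @param profile a `compartment_profile`
#' @param ngroups number of quantile groups (default 50)
#' @param corner_frac fraction of groups per corner summary (default 0.2)
#' @return a `saddle_matrix`: list with `values` (ngroups x ngroups),
#'   `counts`, and `corners` (named AA/BB/AB means)
#' @export
saddle <- function(oe, profile, ngroups = 50L, corner_frac = 0.2) {
  e1 <- profile$e1
  unmasked <- which(!is.na(e1))
  if (length(unmasked) < ngroups) stop("fewer unmasked bins than groups")
  rk <- rank(e1[unmasked], ties.method = "first")
  grp <- ceiling(rk * ngroups / length(unmasked))
  group_of <- rep(NA_integer_, length(e1))
  group_of[unmasked] <- grp
  sums <- cnts <- matrix(0, ngroups, ngroups)
  for (ch in names(oe$values)) {
    idx <- chrom_bin_range(oe$bins, ch)
    g <- group_of[idx]
    v <- oe$values[[ch]]
    ut <- upper.tri(v)
    gi <- g[row(v)]; gj <- g[col(v)]
    ok <- ut & !is.na(v) & !is.na(gi) & !is.na(gj)
    if (!any(ok)) next
    a <- pmin(gi[ok], gj[ok]); b <- pmax(gi[ok], gj[ok])
    agg <- rowsum(cbind(v[ok], 1), group = paste(a, b))
    ij <- do.call(rbind, strsplit(rownames(agg), " "))
    ai <- as.integer(ij[, 1]); bi <- as.integer(ij[, 2])
    sums[cbind(ai, bi)] <- sums[cbind(ai, bi)] + agg[, 1]
    cnts[cbind(ai, bi)] <- cnts[cbind(ai, bi)] + agg[, 2]
  }
  sums <- sums + t(sums) - diag(diag(sums))
  cnts <- cnts + t(cnts) - diag(diag(cnts))
  values <- ifelse(cnts > 0, sums / cnts, NA_real_)
  k <- max(1L, round(corner_frac * ngroups))
  lo <- seq_len(k); hi <- seq.int(ngroups - k + 1L, ngroups)
  corners <- c(AA = mean(values[hi, hi], na.rm = TRUE),
               BB = mean(values[lo, lo], na.rm = TRUE),
               AB = mean(values[lo, hi], na.rm = TRUE))
  structure(list(values = values, counts = cnts, corners = corners,
                 ngroups = ngroups),
            class = "saddle_matrix")
}

#' @export
print.saddle_matrix <- function(x, ...) {
  cat(sprintf("saddle_matrix: %d groups; corners AA=%.3f BB=%.3f AB=%.3f\n",
              x$ngroups, x$corners[["AA"]], x$corners[["BB"]],
              x$corners[["AB"]]))
  invisible(x)
}

#' Per-bin compartment switch categories between two stages
#'
#' @param p1,p2 `compartment_profile`s on the same bins
#' @return list with `category` (per-bin factor over A2A/B2B/A2B/B2A/masked)
#'   and `fractions` (share of unmasked bins per category)
#' @export
compartment_switches <- function(p1, p2) {
  if (!identical(p1$bins$bins, p2$bins$bins)) stop("profiles on different bins")
  l1 <- p1$label; l2 <- p2$label
  cat_ <- rep("masked", length(l1))
  ok <- !is.na(l1) & !is.na(l2)
  cat_[ok] <- paste0(l1[ok], "2", l2[ok])
  category <- factor(cat_, levels = c("A2A", "B2B", "A2B", "B2A", "masked"))
  tab <- table(category[ok])
  fractions <- if (sum(ok)) as.numeric(tab) / sum(ok) else rep(0, length(tab))
  names(fractions) <- names(tab)
  list(category = category, fractions = fractions)
}

#' Expression change by compartment-switch category
#'
#' Genes are assigned the switch category of their TSS bin; per-category
#' log2 fold-change distributions are reported together with a rank-based
#' (Wilcoxon) comparison of B2A versus A2B genes.
#'
#' @param switches result of [compartment_switches()]
#' @param bins the `genome_bins` the switches refer to
#' @param tss BED data.frame with a `name` column of gene ids
#' @param log2fc named numeric vector of per-gene log2 fold-changes
#' @return list with `per_gene` data.frame (gene_id, category, log2fc),
#'   `medians` per category, `test` (htest B2A vs A2B or NULL) and
#'   `n_dropped` genes without usable TSS/fold-change
#' @export
switch_expression_association <- function(switches, bins, tss, log2fc) {
  common <- intersect(tss$name, names(log2fc))
  n_dropped <- length(union(tss$name, names(log2fc))) - length(common)
  tss <- tss[match(common, tss$name), , drop = FALSE]
  gene_bin <- bin_index(bins, tss$chrom, tss$start)
  per_gene <- data.frame(gene_id = common,
                         category = as.character(switches$category[gene_bin]),
                         log2fc = as.numeric(log2fc[common]),
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[per_gene$category != "masked", , drop = FALSE]
  medians <- tapply(per_gene$log2fc, per_gene$category, stats::median)
  b2a <- per_gene$log2fc[per_gene$category == "B2A"]
  a2b <- per_gene$log2fc[per_gene$category == "A2B"]
  test <- if (length(b2a) >= 2 && length(a2b) >= 2)
    stats::wilcox.test(b2a, a2b, exact = FALSE) else NULL
  list(per_gene = per_gene, medians = medians, test = test,
       n_dropped = n_dropped)
}

#' Count peaks per compartment label
#'
#' A peak counts toward a label when it shares at least 1 bp with any bin
#' carrying that label; a peak straddling an A/B boundary counts toward
#' both. Peaks on unknown chromosomes are dropped with a warning.
#'
#' @param peaks BED data.frame
#' @param profile a `compartment_profile`
#' @return named counts `c(A = , B = )` plus attribute `n_dropped`
#' @export
peak_compartment_overlap <- function(peaks, profile) {
  bins <- profile$bins
  known <- peaks$chrom %in% names(bins$chrom_sizes)
  if (any(!known)) {
    warning(sum(!known), " peak(s) on unknown chromosomes dropped")
    peaks <- peaks[known, , drop = FALSE]
  }
  out <- c(A = 0L, B = 0L)
  if (nrow(peaks)) {
    pk <- bed_to_granges(peaks)
    bg <- bins_granges(bins)
    for (lab in c("A", "B")) {
      sel <- which(!is.na(profile$label) & profile$label == lab)
      if (length(sel))
        out[[lab]] <- sum(IRanges::overlapsAny(pk, bg[sel]))
    }
  }
  attr(out, "n_dropped") <- sum(!known)
  out
}
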