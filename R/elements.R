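#' Active enhancers: H3K27ac peaks not overlapping H3K4me3
#'
#' Retains H3K27ac peaks sharing zero bp with every H3K4me3 peak (any
#' overlap of >= 1 bp excludes a peak).
#'
#' @param h3k27ac,h3k4me3 BED data.frames
#' @return BED data.frame of enhancer intervals
#' @export
define_enhancers <- function(h3k27ac, h3k4me3) {
  if (!nrow(h3k27ac)) return(h3k27ac)
  if (!nrow(h3k4me3)) return(h3k27ac)
  hit <- IRanges::overlapsAny(bed_to_granges(h3k27ac),
                              bed_to_granges(h3k4me3))
  h3k27ac[!hit, , drop = FALSE]
}

#' Active promoters: windows around TSS of expressed genes
#'
#' Genes with FPKM strictly above `fpkm_min` get a `window`-bp interval
#' centered on the TSS, clipped to chromosome bounds. Strand is ignored
#' (the window is symmetric).
#'
#' @param tss BED data.frame with a `name` column of gene ids
#' @param expression data.frame with `gene_id` and an FPKM column (second
#'   column used)
#' @param chrom_sizes named vector of chromosome lengths for clipping
#' @param fpkm_min expression threshold (strict >, default 1)
#' @param window full window width in bp (default 6000)
#' @return BED data.frame with gene ids in `name`; attribute `n_skipped`
#'   counts expressed genes without a TSS
#' @export
define_active_promoters <- function(tss, expression, chrom_sizes,
                                    fpkm_min = 1, window = 6000) {
  fpkm <- stats::setNames(expression[[2]], expression$gene_id)
  active <- names(fpkm)[fpkm > fpkm_min]
  n_skipped <- sum(!(active %in% tss$name))
  sel <- tss[tss$name %in% active, , drop = FALSE]
  out <- promoter_regions(sel, chrom_sizes, halfwidth = window / 2)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Promoter regions: TSS +/- halfwidth
#'
#' @param tss BED data.frame with a `name` column
#' @param chrom_sizes named vector of chromosome lengths for clipping
#' @param halfwidth half-window in bp (default 3000)
#' @return BED data.frame (chrom, start, end, name), clipped to \[0, size)
#' @export
promoter_regions <- function(tss, chrom_sizes, halfwidth = 3000) {
  if (!nrow(tss))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character()))
  data.frame(chrom = tss$chrom,
             start = pmax(0, tss$start - halfwidth),
             end = pmin(unname(chrom_sizes[tss$chrom]), tss$start + halfwidth),
             name = tss$name, stringsAsFactors = FALSE)
}
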