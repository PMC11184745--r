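#' Fixed-size genomic bins over a genome
#'
#' Tiles each chromosome with consecutive bins of `bin_size` bp (the terminal
#' bin of a chromosome may be shorter). Coordinates are 0-based half-open
#' throughout the package; bins are indexed 1..n genome-wide in chromosome
#' order.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp, or a
#'   two-column data.frame (chrom, size) as read from a chrom.sizes file.
#' @param bin_size bin width in bp (working resolutions are typically 1e4,
#'   5e4 or 1e5).
#' @return A `genome_bins` object: list with `chrom_sizes`, `bin_size`,
#'   `bins` (data.frame chrom/start/end), `offset` (0-based genome-wide index
#'   offset per chromosome) and `nbin` (bins per chromosome).
#' @examples
#' gb <- genome_bins(c(chr1 = 1e6, chr2 = 5e5), 1e5)
#' nbins(gb)
#' @export
genome_bins <- function(chrom_sizes, bin_size) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- chrom_sizes[[2]]
    names(sizes) <- as.character(chrom_sizes[[1]])
    chrom_sizes <- sizes
  }
  stopifnot(length(chrom_sizes) >= 1, !is.null(names(chrom_sizes)),
            all(chrom_sizes > 0), length(bin_size) == 1, bin_size >= 1)
  nbin <- as.integer(ceiling(chrom_sizes / bin_size))
  offset <- c(0L, cumsum(nbin))[seq_along(nbin)]
  names(offset) <- names(nbin) <- names(chrom_sizes)
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    start <- seq(0, chrom_sizes[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, chrom_sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(chrom_sizes = chrom_sizes, bin_size = bin_size,
                 bins = bins, offset = offset, nbin = nbin),
            class = "genome_bins")
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d chromosome(s), bin size %g bp, %d bins\n",
              length(x$chrom_sizes), x$bin_size, nbins(x)))
  invisible(x)
}

#' Total number of bins
#' @param bins a `genome_bins` object
#' @export
nbins <- function(bins) sum(bins$nbin)

#' Map genomic positions to bin indices
#'
#' @param bins a `genome_bins` object
#' @param chrom chromosome names
#' @param pos 0-based positions in bp
#' @return genome-wide 1-based bin indices; error for unknown chromosomes.
#' @export
bin_index <- function(bins, chrom, pos) {
  chrom <- as.character(chrom)
  bad <- !(chrom %in% names(bins$chrom_sizes))
  if (any(bad)) stop("unknown chromosome(s): ",
                     paste(unique(chrom[bad]), collapse = ", "))
  local <- pmin(as.integer(pos %/% bins$bin_size), bins$nbin[chrom] - 1L)
  as.integer(bins$offset[chrom] + local + 1L)
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#' @param path file path
#' @return named numeric vector of chromosome sizes
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$size, tab$chrom)
}

# chromosome of each genome-wide bin index (internal)
bin_chrom <- function(bins, idx) bins$bins$chrom[idx]

# genome-wide indices of one chromosome's bins (internal)
chrom_bin_range <- function(bins, chrom) {
  off <- bins$offset[[chrom]]
  seq.int(off + 1L, off + bins$nbin[[chrom]])
}
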