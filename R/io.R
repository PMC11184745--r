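#' Read a BED file
#'
#' Minimal BED reader: chrom, start, end and optional name column,
#' 0-based half-open coordinates.
#' @param path BED/TSV file
#' @return data.frame chrom/start/end(/name)
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4) names(tab)[4] <- "name"
  tab
}

#' Write a BED data.frame
#' @param bed data.frame with chrom/start/end and optional further columns
#' @param path output path
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-bin track as BedGraph
#' @param bins a `genome_bins` object
#' @param values genome-wide per-bin numeric vector (NAs skipped)
#' @param path output path
#' @export
write_bedgraph <- function(bins, values, path) {
  stopifnot(length(values) == nbins(bins))
  keep <- !is.na(values)
  out <- cbind(bins$bins[keep, c("chrom", "start", "end")],
               value = values[keep])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' TSV with a header: first column gene id, remaining columns FPKM/TPM per
#' stage.
#' @param path TSV file
#' @return data.frame with `gene_id` first
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1] <- "gene_id"
  tab
}

#' Write loops as BEDPE-like TSV
#' @param loops a `loop_set`
#' @param bins the `genome_bins` of the loop map
#' @param path output path
#' @export
write_loops_bedpe <- function(loops, bins, path) {
  g1 <- bins$offset[loops$chrom] + loops$bin1
  g2 <- bins$offset[loops$chrom] + loops$bin2
  out <- data.frame(chrom1 = loops$chrom,
                    start1 = bins$bins$start[g1], end1 = bins$bins$end[g1],
                    chrom2 = loops$chrom,
                    start2 = bins$bins$start[g2], end2 = bins$bins$end[g2],
                    score = loops$observed,
                    qvalue = loops$qvalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE-like loop TSV
#' @param path file with chrom1 start1 end1 chrom2 start2 end2 [score qvalue]
#' @param bins the `genome_bins` to map anchors onto
#' @return a `loop_set` data.frame
#' @export
read_loops_bedpe <- function(path, bins) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (any(tab$chrom1 != tab$chrom2)) stop("trans loops not supported")
  b1 <- bin_index(bins, tab$chrom1, tab$start1) - bins$offset[tab$chrom1]
  b2 <- bin_index(bins, tab$chrom2, tab$start2) - bins$offset[tab$chrom2]
  out <- data.frame(chrom = tab$chrom1, bin1 = as.integer(b1),
                    bin2 = as.integer(b2),
                    observed = if (ncol(tab) >= 7) tab[[7]] else NA_real_,
                    expected = NA_real_,
                    qvalue = if (ncol(tab) >= 8) tab[[8]] else NA_real_,
                    n_pixels = NA_integer_, stringsAsFactors = FALSE)
  structure(out, class = c("loop_set", "data.frame"),
            bin_size = bins$bin_size)
}

#' Write a structure specification as flat key=value text
#' @param spec a `structure_spec`
#' @param path output path
#' @export
write_structure_spec <- function(spec, path) {
  fmt_b <- function(tb) paste(vapply(names(tb), function(ch)
    paste0(ch, ":", paste(tb[[ch]], collapse = ",")), character(1)),
    collapse = ";")
  fmt_l <- function(lp) paste(sprintf("%s:%d-%d@%g", lp$chrom, lp$bin1,
                                      lp$bin2, lp$intensity), collapse = ";")
  lines <- c(
    paste0("chrom_sizes=", paste(sprintf("%s:%g", names(spec$bins$chrom_sizes),
                                         spec$bins$chrom_sizes),
                                 collapse = ",")),
    paste0("bin_size=", spec$bins$bin_size),
    paste0("decay_exponent=", spec$decay_exponent),
    paste0("contrast=", spec$contrast),
    paste0("comp_labels=", if (is.null(spec$comp_labels)) "" else
      paste(spec$comp_labels, collapse = "")),
    paste0("tad_boundaries=", if (is.null(spec$tad_boundaries)) "" else
      fmt_b(spec$tad_boundaries)),
    paste0("tad_factor=", spec$tad_factor),
    paste0("loops=", if (is.null(spec$loops) || !nrow(spec$loops)) "" else
      fmt_l(spec$loops)),
    paste0("depth=", spec$depth),
    paste0("sigma=", spec$sigma),
    paste0("trans_fraction=", spec$trans_fraction))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure specification written by [write_structure_spec()]
#' @param path key=value file
#' @return a `structure_spec`
#' @export
read_structure_spec <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    if (length(x) > 1) x[2] else "", character(1)),
    vapply(kv, `[[`, character(1), 1))
  cs <- strsplit(strsplit(vals[["chrom_sizes"]], ",")[[1]], ":")
  sizes <- stats::setNames(as.numeric(vapply(cs, `[[`, character(1), 2)),
                           vapply(cs, `[[`, character(1), 1))
  bins <- genome_bins(sizes, as.numeric(vals[["bin_size"]]))
  labels <- if (nzchar(vals[["comp_labels"]]))
    strsplit(vals[["comp_labels"]], "")[[1]] else NULL
  tb <- NULL
  if (nzchar(vals[["tad_boundaries"]])) {
    parts <- strsplit(vals[["tad_boundaries"]], ";")[[1]]
    tb <- list()
    for (p in parts) {
      s <- strsplit(p, ":")[[1]]
      tb[[s[1]]] <- as.integer(strsplit(s[2], ",")[[1]])
    }
  }
  loops <- NULL
  if (nzchar(vals[["loops"]])) {
    parts <- strsplit(vals[["loops"]], ";")[[1]]
    m <- regmatches(parts, regexec("^(.+):([0-9]+)-([0-9]+)@(.+)$", parts))
    loops <- do.call(rbind, lapply(m, function(x)
      data.frame(chrom = x[2], bin1 = as.integer(x[3]),
                 bin2 = as.integer(x[4]), intensity = as.numeric(x[5]),
                 stringsAsFactors = FALSE)))
  }
  structure_spec(bins,
                 decay_exponent = as.numeric(vals[["decay_exponent"]]),
                 comp_labels = labels,
                 contrast = as.numeric(vals[["contrast"]]),
                 tad_boundaries = tb,
                 tad_factor = as.numeric(vals[["tad_factor"]]),
                 loops = loops,
                 depth = as.numeric(vals[["depth"]]),
                 sigma = as.numeric(vals[["sigma"]]),
                 trans_fraction = as.numeric(vals[["trans_fraction"]]))
}
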