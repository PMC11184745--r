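#' Ground-truth structure specification for simulated Hi-C maps
#'
#' Describes the planted architecture of a simulated contact map: a
#' power-law distance decay background, an A/B compartment checkerboard with
#' a contrast parameter, TAD blocks delimited by boundary bins, focal loops,
#' sequencing depth, multiplicative noise and a trans-contact fraction.
#' Expected pixel rates are
#' `depth-scale * (s+1)^(-decay_exponent) * comp * tad * loop * noise`,
#' where the compartment factor is `(1+contrast)` for like-labelled bin
#' pairs and `(1-contrast)` for unlike pairs, the TAD factor applies to
#' pairs wholly inside one TAD (boundary bins belong to the TAD on their
#' left), and the loop factor multiplies the planted pixels.
#'
#' @param bins a [genome_bins()] object
#' @param decay_exponent power-law slope of the background P(s) (default 1,
#'   the canonical contact-probability slope)
#' @param comp_labels per-bin compartment label "A"/"B" (genome-wide vector),
#'   or NULL for no compartment structure
#' @param contrast compartment contrast c in \[0, 1)
#' @param tad_boundaries named list per chromosome of sorted local bin
#'   indices acting as TAD boundaries, or NULL
#' @param tad_factor within-TAD enrichment factor (>= 1)
#' @param loops data.frame(chrom, bin1, bin2, intensity) of planted loops
#'   (local bin indices, bin1 < bin2, separation >= 2, intensity >= 1), or NULL
#' @param depth expected total contact count
#' @param sigma log-normal dispersion of pixel rates (0 = none)
#' @param trans_fraction expected fraction of contacts that are
#'   inter-chromosomal
#' @return a `structure_spec` object
#' @export
structure_spec <- function(bins, decay_exponent = 1, comp_labels = NULL,
                           contrast = 0, tad_boundaries = NULL,
                           tad_factor = 3, loops = NULL, depth = 1e6,
                           sigma = 0, trans_fraction = 0) {
  stopifnot(inherits(bins, "genome_bins"),
            contrast >= 0, contrast < 1, tad_factor >= 1,
            depth >= 0, sigma >= 0,
            trans_fraction >= 0, trans_fraction < 1)
  if (!is.null(comp_labels)) {
    stopifnot(length(comp_labels) == nbins(bins),
              all(comp_labels %in% c("A", "B")))
  }
  if (!is.null(tad_boundaries)) {
    for (ch in names(tad_boundaries)) {
      b <- tad_boundaries[[ch]]
      stopifnot(ch %in% names(bins$chrom_sizes),
                all(diff(b) > 0), all(b >= 1), all(b <= bins$nbin[[ch]]))
    }
  }
  if (!is.null(loops) && nrow(loops)) {
    stopifnot(all(c("chrom", "bin1", "bin2", "intensity") %in% names(loops)),
              all(loops$chrom %in% names(bins$chrom_sizes)),
              all(loops$bin2 - loops$bin1 >= 2),
              all(loops$intensity >= 1))
  }
  structure(list(bins = bins, decay_exponent = decay_exponent,
                 comp_labels = comp_labels, contrast = contrast,
                 tad_boundaries = tad_boundaries, tad_factor = tad_factor,
                 loops = loops, depth = depth, sigma = sigma,
                 trans_fraction = trans_fraction),
            class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  cat(sprintf(
    "structure_spec: %d bins, decay %g, contrast %g, %d boundaries, %d loops, depth %g\n",
    nbins(x$bins), x$decay_exponent, x$contrast,
    sum(lengths(x$tad_boundaries)),
    if (is.null(x$loops)) 0L else nrow(x$loops), x$depth))
  invisible(x)
}

#' Alternating A/B block labels for a genome
#'
#' @param bins a `genome_bins` object
#' @param block_bins bins per compartment block
#' @return character vector of per-bin labels starting with "A" on each
#'   chromosome
#' @export
checkerboard_labels <- function(bins, block_bins = 10L) {
  unlist(lapply(names(bins$chrom_sizes), function(ch) {
    n <- bins$nbin[[ch]]
    rep(c("A", "B"), length.out = ceiling(n / block_bins),
        each = 1)[ceiling(seq_len(n) / block_bins)]
  }), use.names = FALSE)
}

# TAD id per local bin; boundary bins close the TAD on their left (internal)
tad_membership <- function(n, boundaries) {
  id <- integer(n)
  cur <- 1L; prev <- 0L
  bs <- sort(boundaries)
  for (b in bs) {
    id[(prev + 1):b] <- cur
    cur <- cur + 1L; prev <- b
  }
  if (prev < n) id[(prev + 1):n] <- cur
  id
}

#' Expected cis rate matrices of a structure specification
#'
#' Deterministic expected pixel rates (no Poisson sampling, no noise),
#' scaled so the total expected cis count equals `depth * (1 -
#' trans_fraction)`. Useful as the infinite-depth, noiseless limit in which
#' planted factors are recovered exactly.
#'
#' @param spec a `structure_spec`
#' @return named list of per-chromosome expected-rate matrices
#' @export
expected_cis_rates <- function(spec) {
  bins <- spec$bins
  mats <- stats::setNames(vector("list", length(bins$nbin)), names(bins$nbin))
  for (ch in names(bins$nbin)) {
    n <- bins$nbin[[ch]]
    sep <- abs(row(diag(n)) - col(diag(n)))
    m <- (sep + 1)^(-spec$decay_exponent)
    if (!is.null(spec$comp_labels) && spec$contrast > 0) {
      lab <- spec$comp_labels[chrom_bin_range(bins, ch)]
      same <- outer(lab, lab, "==")
      m <- m * ifelse(same, 1 + spec$contrast, 1 - spec$contrast)
    }
    if (!is.null(spec$tad_boundaries[[ch]])) {
      id <- tad_membership(n, spec$tad_boundaries[[ch]])
      m <- m * ifelse(outer(id, id, "=="), spec$tad_factor, 1)
    }
    if (!is.null(spec$loops) && nrow(spec$loops)) {
      lp <- spec$loops[spec$loops$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(lp))) {
        i <- lp$bin1[k]; j <- lp$bin2[k]
        m[i, j] <- m[i, j] * lp$intensity[k]
        m[j, i] <- m[i, j]
      }
    }
    mats[[ch]] <- m
  }
  tot <- sum(vapply(mats, function(m) sum(m[upper.tri(m, diag = TRUE)]),
                    numeric(1)))
  target <- spec$depth * (1 - spec$trans_fraction)
  scale <- if (tot > 0) target / tot else 0
  lapply(mats, function(m) m * scale)
}

#' Simulate a contact map from a structure specification
#'
#' Poisson-samples counts around the expected rates of [expected_cis_rates()],
#' with optional log-normal pixel-level over-dispersion (mean-one
#' multiplier), and draws trans totals proportional to chromosome-size
#' products.
#'
#' @param spec a `structure_spec`
#' @param seed RNG seed
#' @return a symmetric `contact_map`
#' @export
simulate_contact_map <- function(spec, seed = 1L) {
  set.seed(seed)
  rates <- expected_cis_rates(spec)
  map <- contact_map(spec$bins)
  for (ch in names(rates)) {
    r <- rates[[ch]]
    n <- nrow(r)
    ut <- upper.tri(r, diag = TRUE)
    lam <- r[ut]
    if (spec$sigma > 0)
      lam <- lam * stats::rlnorm(length(lam),
                                 meanlog = -spec$sigma^2 / 2,
                                 sdlog = spec$sigma)
    cnt <- stats::rpois(length(lam), lam)
    m <- matrix(0, n, n)
    m[ut] <- cnt
    m <- m + t(m) - diag(diag(m))
    map$cis[[ch]] <- m
  }
  if (spec$trans_fraction > 0 && length(rates) > 1) {
    chroms <- names(spec$bins$chrom_sizes)
    sz <- spec$bins$chrom_sizes
    wts <- outer(sz, sz)
    diag(wts) <- 0
    wts <- wts[upper.tri(wts)]
    lam <- spec$depth * spec$trans_fraction * wts / sum(wts)
    tr <- map$trans
    tr[upper.tri(tr)] <- stats::rpois(length(lam), lam)
    map$trans <- tr + t(tr)
  }
  map
}

#' Apply a structured edit to a structure specification
#'
#' Edits model developmental-stage differences: compartment contrast
#' scaling, label flips, TAD-boundary insertion/deletion, TAD/loop strength
#' scaling, depth changes.
#'
#' @param spec a `structure_spec`
#' @param edit list with any of: `contrast_scale`, `tad_factor_scale`
#'   (applied to the enrichment above 1), `loop_intensity_scale` (applied to
#'   the enrichment above 1), `flip_bins` (genome-wide bin indices whose A/B
#'   label toggles), `add_boundaries` / `remove_boundaries` (named list per
#'   chromosome of local bin indices), `depth`, `trans_fraction`
#' @return the edited `structure_spec`
#' @export
perturb_spec <- function(spec, edit = list()) {
  s <- spec
  if (!is.null(edit$contrast_scale)) s$contrast <- s$contrast * edit$contrast_scale
  if (!is.null(edit$tad_factor_scale))
    s$tad_factor <- 1 + (s$tad_factor - 1) * edit$tad_factor_scale
  if (!is.null(edit$loop_intensity_scale) && !is.null(s$loops))
    s$loops$intensity <- 1 + (s$loops$intensity - 1) * edit$loop_intensity_scale
  if (!is.null(edit$flip_bins) && !is.null(s$comp_labels)) {
    fb <- edit$flip_bins
    s$comp_labels[fb] <- ifelse(s$comp_labels[fb] == "A", "B", "A")
  }
  if (!is.null(edit$add_boundaries)) {
    for (ch in names(edit$add_boundaries)) {
      s$tad_boundaries[[ch]] <- sort(unique(c(s$tad_boundaries[[ch]],
                                              edit$add_boundaries[[ch]])))
    }
  }
  if (!is.null(edit$remove_boundaries)) {
    for (ch in names(edit$remove_boundaries)) {
      s$tad_boundaries[[ch]] <-
        setdiff(s$tad_boundaries[[ch]], edit$remove_boundaries[[ch]])
    }
  }
  if (!is.null(edit$depth)) s$depth <- edit$depth
  if (!is.null(edit$trans_fraction)) s$trans_fraction <- edit$trans_fraction
  s
}

#' Simulate a multi-stage series of contact maps
#'
#' Generates one map per stage from per-stage edits of a base
#' specification. Typical use plants a "relaxed" early stage by scaling
#' contrast, TAD strength and loop intensity down, mirroring weaker
#' architecture early in development.
#'
#' @param base a `structure_spec` describing the full-strength architecture
#' @param perturbations list (one element per stage) of edit lists as in
#'   [perturb_spec()]; an empty list means the base spec unchanged
#' @param seeds integer vector of per-stage seeds
#' @return list with `maps` (list of `contact_map`), `specs` (per-stage
#'   `structure_spec`) and `diffs` (per-stage record of the edits applied)
#' @export
simulate_stage_series <- function(base, perturbations, seeds) {
  stopifnot(length(perturbations) == length(seeds))
  specs <- lapply(perturbations, function(ed) perturb_spec(base, ed))
  maps <- mapply(function(sp, sd) simulate_contact_map(sp, seed = sd),
                 specs, seeds, SIMPLIFY = FALSE)
  list(maps = maps, specs = specs, diffs = perturbations)
}

#' Simulate gene, peak and expression annotations paired to a structure spec
#'
#' Places TSS across the genome (one gene is planted at the first anchor of
#' a stated fraction of loops so promoter-connecting loops exist), assigns
#' each loop a TF-occupancy class (both/one/none anchors bound) and plants
#' TF peaks accordingly, draws log-normal FPKM with an A-compartment
#' expression ratio and occupancy-class multipliers, and scatters
#' H3K27ac/H3K4me3/ATAC peaks with an A/B placement ratio. When stage specs
#' are supplied, expression gains a column per stage and genes in bins whose
#' label switches B-to-A (A-to-B) between consecutive stages are multiplied
#' (divided) by `switch_up`.
#'
#' @param spec a `structure_spec`
#' @param effect_model list of generator parameters; defaults:
#'   `n_genes = 400`, `base_fpkm_meanlog = log(2)`, `fpkm_sdlog = 1`,
#'   `a_expr_ratio = 3`, `occupancy_multipliers = c(both = 4, one = 2, none = 1)`,
#'   `loop_class_probs = c(both = 1/3, one = 1/3, none = 1/3)`,
#'   `promoter_frac = 0.8`, `tf_background_peaks = 50`, `n_peaks = 200`,
#'   `peak_a_ratio = 4`, `peak_width = 1000`, `switch_up = 2`,
#'   `gene_a_ratio = 3` (A:B placement ratio of background gene TSS)
#' @param seed RNG seed
#' @param stage_specs optional list of `structure_spec`s (same bins) whose
#'   compartment labels define per-stage expression columns
#' @return an `annotation_bundle`: list with BED data.frames `tss`,
#'   `h3k27ac_peaks`, `h3k4me3_peaks`, `atac_peaks`, `tf_peaks`, an
#'   `expression` table (gene_id + one fpkm column per stage), `true_loops`,
#'   and `gene_meta` recording each gene's bin, compartment label and
#'   planted occupancy class
#' @export
simulate_annotations <- function(spec, effect_model = list(), seed = 1L,
                                 stage_specs = NULL) {
  set.seed(seed)
  em <- utils::modifyList(list(
    n_genes = 400L, base_fpkm_meanlog = log(2), fpkm_sdlog = 1,
    a_expr_ratio = 3, occupancy_multipliers = c(both = 4, one = 2, none = 1),
    loop_class_probs = c(both = 1 / 3, one = 1 / 3, none = 1 / 3),
    promoter_frac = 0.8, tf_background_peaks = 50L, n_peaks = 200L,
    peak_a_ratio = 4, peak_width = 1000, switch_up = 2,
    gene_a_ratio = 3), effect_model)
  om <- em$occupancy_multipliers
  stopifnot(om[["both"]] >= om[["one"]], om[["one"]] >= om[["none"]])
  bins <- spec$bins
  bdf <- bins$bins
  bw <- bins$bin_size

  loops <- spec$loops
  n_loops <- if (is.null(loops)) 0L else nrow(loops)
  loop_class <- character(0)
  if (n_loops) {
    loop_class <- sample(names(em$loop_class_probs), n_loops, replace = TRUE,
                         prob = em$loop_class_probs)
  }

  # genes: one planted at anchor1 of a fraction of loops, rest uniform
  gene_bin <- integer(0); gene_occ <- character(0)
  if (n_loops) {
    planted <- stats::runif(n_loops) < em$promoter_frac
    gene_bin <- bins$offset[loops$chrom[planted]] + loops$bin1[planted]
    gene_occ <- loop_class[planted]
  }
  n_bg <- max(0L, em$n_genes - length(gene_bin))
  # background genes land preferentially in A bins (gene density is the
  # orientation signal compartment calling relies on)
  gw <- if (is.null(spec$comp_labels)) rep(1, nbins(bins)) else
    ifelse(spec$comp_labels == "A", em$gene_a_ratio, 1)
  gene_bin <- c(gene_bin, sample.int(nbins(bins), n_bg, replace = TRUE,
                                     prob = gw))
  gene_occ <- c(gene_occ, rep("background", n_bg))
  ng <- length(gene_bin)
  gene_id <- sprintf("gene%04d", seq_len(ng))
  tss_pos <- pmin(bdf$start[gene_bin] + floor(stats::runif(ng) * bw),
                  bdf$end[gene_bin] - 1)
  tss <- data.frame(chrom = bdf$chrom[gene_bin], start = tss_pos,
                    end = tss_pos + 1, name = gene_id,
                    stringsAsFactors = FALSE)

  # TF peaks on loop anchors by class, plus background
  tf <- list()
  if (n_loops) {
    for (k in seq_len(n_loops)) {
      anchors <- switch(loop_class[k],
                        both = c(loops$bin1[k], loops$bin2[k]),
                        one = loops$bin1[k],
                        none = integer(0))
      for (a in anchors) {
        g <- bins$offset[[loops$chrom[k]]] + a
        ctr <- bdf$start[g] + bw / 2
        tf[[length(tf) + 1]] <- data.frame(
          chrom = loops$chrom[k], start = floor(ctr - em$peak_width / 2),
          end = floor(ctr + em$peak_width / 2), stringsAsFactors = FALSE)
      }
    }
  }
  if (em$tf_background_peaks > 0) {
    g <- sample.int(nbins(bins), em$tf_background_peaks, replace = TRUE)
    tf[[length(tf) + 1]] <- data.frame(
      chrom = bdf$chrom[g],
      start = bdf$start[g] + floor(stats::runif(length(g)) * (bw - em$peak_width)),
      end = NA, stringsAsFactors = FALSE)
    tf[[length(tf)]]$end <- tf[[length(tf)]]$start + em$peak_width
  }
  tf_peaks <- if (length(tf)) do.call(rbind, tf) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  tf_peaks$start <- pmax(tf_peaks$start, 0)

  # histone/ATAC peaks with A/B placement ratio
  labels <- spec$comp_labels
  place_peaks <- function(n) {
    w <- if (is.null(labels)) rep(1, nbins(bins)) else
      ifelse(labels == "A", em$peak_a_ratio, 1)
    g <- sample.int(nbins(bins), n, replace = TRUE, prob = w)
    st <- bdf$start[g] + floor(stats::runif(n) * pmax(1, bw - em$peak_width))
    data.frame(chrom = bdf$chrom[g], start = st, end = st + em$peak_width,
               stringsAsFactors = FALSE)
  }
  h3k27ac <- place_peaks(em$n_peaks)
  atac <- place_peaks(em$n_peaks)
  # H3K4me3 marks promoters of a random half of genes
  pr_genes <- sample.int(ng, ng %/% 2)
  h3k4me3 <- data.frame(chrom = tss$chrom[pr_genes],
                        start = pmax(0, tss$start[pr_genes] - 500),
                        end = tss$start[pr_genes] + 500,
                        stringsAsFactors = FALSE)

  # expression
  mult <- ifelse(gene_occ %in% names(om), om[gene_occ], 1)
  a_mult <- if (is.null(labels)) rep(1, ng) else
    ifelse(labels[gene_bin] == "A", em$a_expr_ratio, 1)
  base_fpkm <- stats::rlnorm(ng, em$base_fpkm_meanlog, em$fpkm_sdlog) *
    mult * a_mult
  if (is.null(stage_specs)) {
    expression <- data.frame(gene_id = gene_id, fpkm = base_fpkm,
                             stringsAsFactors = FALSE)
  } else {
    expression <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
    cur <- base_fpkm
    prev_lab <- NULL
    for (s in seq_along(stage_specs)) {
      lab <- stage_specs[[s]]$comp_labels
      if (!is.null(prev_lab) && !is.null(lab)) {
        b2a <- prev_lab[gene_bin] == "B" & lab[gene_bin] == "A"
        a2b <- prev_lab[gene_bin] == "A" & lab[gene_bin] == "B"
        cur <- cur * ifelse(b2a, em$switch_up, ifelse(a2b, 1 / em$switch_up, 1))
      }
      expression[[paste0("fpkm_stage", s)]] <- cur
      prev_lab <- lab
    }
  }

  structure(list(tss = tss, h3k27ac_peaks = h3k27ac, h3k4me3_peaks = h3k4me3,
                 atac_peaks = atac, tf_peaks = tf_peaks,
                 expression = expression, true_loops = loops,
                 gene_meta = data.frame(gene_id = gene_id, bin = gene_bin,
                                        label = if (is.null(labels)) NA_character_
                                                else labels[gene_bin],
                                        occupancy = gene_occ,
                                        stringsAsFactors = FALSE)),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("annotation_bundle: %d genes, %d TF peaks, %d H3K27ac peaks\n",
              nrow(x$tss), nrow(x$tf_peaks), nrow(x$h3k27ac_peaks)))
  invisible(x)
}
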