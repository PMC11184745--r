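#' Default three-stage pipeline configuration
#'
#' Describes a desk-scale three-stage study: per analysis layer, one
#' simulated genome at its working resolution (100 kb for compartments,
#' 50 kb for TADs, 10 kb for loops) with stage edits that relax the first
#' stage (scaled-down contrast, TAD strength and loop intensity) relative
#' to the later two, mirroring weaker architecture early in development.
#'
#' @param seed master seed; all stage seeds derive from it
#' @return a named config list accepted by [run_pipeline()]
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    equal_depth = TRUE,
    stages = c("nascent", "fetal", "adult"),
    compartments = list(
      chrom_sizes = c(chr1 = 2e7, chr2 = 2e7), bin_size = 1e5,
      block_bins = 10L,
      contrast = 0.6, depth = 1e6, sigma = 0.2, trans_fraction = 0.1,
      stage_edits = list(
        list(contrast_scale = 0.3, trans_fraction = 0.2),
        list(flip_frac = 0.1),
        list())),
    tads = list(
      chrom_size = 2e7, bin_size = 5e4, n_boundaries = 9L,
      tad_factor = 3, depth = 1e6, sigma = 0.2,
      stage_edits = list(
        list(tad_factor_scale = 0.5),
        list(),
        list())),
    loops = list(
      chrom_size = 5e6, bin_size = 1e4, n_loops = 30L,
      intensity = 4, depth = 3e6, sigma = 0,
      stage_edits = list(
        list(loop_intensity_scale = 0.5),
        list(),
        list())),
    annotations = list(n_genes = 400L))
}

# evenly spaced boundary positions for an n-bin chromosome (internal)
even_boundaries <- function(n, k) {
  as.integer(round(seq(0, n, length.out = k + 2)))[2:(k + 1)]
}

# planted loop list on an n-bin chromosome: separations 20-100 bins,
# anchors clear of the ends by the APA flank (internal)
planted_loops <- function(chrom, n, k, intensity, flank = 12L) {
  sep <- as.integer(round(seq(20, 100, length.out = k)))
  a1 <- as.integer(round(seq(flank + 1, n - flank - max(sep), length.out = k)))
  data.frame(chrom = chrom, bin1 = a1, bin2 = a1 + sep,
             intensity = intensity, stringsAsFactors = FALSE)
}

#' Run the full multi-scale three-stage analysis
#'
#' Simulates the per-layer stage series from the config, optionally
#' downsamples every stage to the shallowest stage's depth, balances, and
#' runs each analysis layer: global metrics (P(s), JSD, VNE, cis/trans),
#' compartments (calling, strength, saddle, switches), TADs (insulation,
#' boundaries, sharing, variability), loops (calling, APA, sharing,
#' cosine similarity, anchor classification) and TF-anchor statistics.
#' Per-stage tracks and calls are written under `out_dir` along with a
#' machine-readable `summary.json` and a parameter log; the summary is
#' byte-identical across runs with the same config.
#'
#' @param config list as produced by [default_pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return the summary list, invisibly
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = file.path(tempdir(), "hicscape_run")) {
  for (field in c("seed", "stages", "compartments", "tads", "loops"))
    if (is.null(config[[field]]))
      stop("config is missing required field: ", field)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stages <- config$stages
  ns <- length(stages)
  summary <- list(seed = seed, stages = as.list(stages))

  ## ---- compartment layer (100 kb) ----
  cc <- config$compartments
  gb_c <- genome_bins(cc$chrom_sizes, cc$bin_size)
  labels <- checkerboard_labels(gb_c, cc$block_bins)
  base_c <- structure_spec(gb_c, comp_labels = labels, contrast = cc$contrast,
                           depth = cc$depth, sigma = cc$sigma,
                           trans_fraction = cc$trans_fraction)
  edits <- cc$stage_edits
  set.seed(seed + 101L)
  edits <- lapply(edits, function(ed) {
    if (!is.null(ed$flip_frac)) {
      ed$flip_bins <- sample.int(nbins(gb_c),
                                 round(ed$flip_frac * nbins(gb_c)))
      ed$flip_frac <- NULL
    }
    ed
  })
  ser_c <- simulate_stage_series(base_c, edits, seeds = seed + seq_len(ns))
  maps_c <- ser_c$maps
  if (isTRUE(config$equal_depth)) {
    mint <- min(vapply(maps_c, total_contacts, numeric(1)))
    maps_c <- lapply(seq_along(maps_c), function(k)
      downsample_map(maps_c[[k]], mint, seed = seed + 200L + k))
    summary$equal_depth_total <- mint
  }
  maps_c <- lapply(maps_c, kr_balance)
  oes <- lapply(maps_c, observed_over_expected)
  ann_c <- simulate_annotations(base_c, config$annotations, seed = seed + 301L,
                                stage_specs = ser_c$specs)
  gd <- tss_density(gb_c, ann_c$tss)
  profiles <- lapply(seq_len(ns), function(k)
    call_compartments(oes[[k]], gd, stage = stages[k]))
  chroms_c <- names(cc$chrom_sizes)
  summary$compartment_strength <- stats::setNames(lapply(seq_len(ns), function(k)
    round(mean(vapply(chroms_c, function(ch)
      compartment_strength(oes[[k]], profiles[[k]], ch), numeric(1))), 6)),
    stages)
  summary$a_fraction <- stats::setNames(lapply(profiles, function(p)
    round(mean(p$label == "A", na.rm = TRUE), 6)), stages)
  sw <- compartment_switches(profiles[[1]], profiles[[2]])
  summary$switch_fraction_s1_s2 <-
    round(sum(sw$fractions[c("A2B", "B2A")]), 6)
  summary$cis_trans <- stats::setNames(lapply(maps_c, function(m)
    round(cis_trans_ratio(m), 6)), stages)
  summary$vne <- stats::setNames(lapply(maps_c, function(m)
    round(mean(vapply(chroms_c, function(ch)
      von_neumann_entropy(m, ch), numeric(1))), 6)), stages)
  curves <- lapply(maps_c, contact_decay_curve,
                   dmin = 2e5, dmax = min(cc$chrom_sizes), nbins = 100L)
  jsd <- matrix(0, ns, ns, dimnames = list(stages, stages))
  for (a in seq_len(ns)) for (b in seq_len(ns))
    jsd[a, b] <- jensen_shannon_divergence(curves[[a]], curves[[b]])
  summary$jsd <- round(jsd, 8)
  for (k in seq_len(ns)) {
    write_bedgraph(gb_c, profiles[[k]]$e1,
                   file.path(out_dir, paste0("e1_", stages[k], ".bedgraph")))
    utils::write.table(curves[[k]][, c("dist_mid", "value")],
                       file.path(out_dir, paste0("ps_", stages[k], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- TAD layer (50 kb) ----
  tc <- config$tads
  gb_t <- genome_bins(c(chrT = tc$chrom_size), tc$bin_size)
  nb_t <- nbins(gb_t)
  base_t <- structure_spec(gb_t,
                           tad_boundaries = list(chrT = even_boundaries(nb_t, tc$n_boundaries)),
                           tad_factor = tc$tad_factor, depth = tc$depth,
                           sigma = tc$sigma)
  ser_t <- simulate_stage_series(base_t, tc$stage_edits,
                                 seeds = seed + 400L + seq_len(ns))
  maps_t <- lapply(ser_t$maps, kr_balance)
  tracks <- lapply(maps_t, function(m)
    call_boundaries(insulation_score(m)))
  summary$n_tads <- stats::setNames(lapply(tracks, function(tr)
    nrow(tr$tads)), stages)
  summary$n_boundaries <- stats::setNames(lapply(tracks, function(tr)
    nrow(tr$boundaries)), stages)
  sh <- shared_tads(tracks[[2]]$tads, tracks[[3]]$tads)
  summary$shared_tads_s2_s3 <- sh$n_shared
  summary$mean_boundary_is <- stats::setNames(lapply(tracks, function(tr)
    round(mean(tr$boundaries$score), 6)), stages)
  bv <- boundary_variability(tracks, top_k = min(1000L, nb_t),
                             k_clusters = 4L)
  summary$n_variable_boundaries <- nrow(bv)
  for (k in seq_len(ns)) {
    write_bedgraph(gb_t, tracks[[k]]$score,
                   file.path(out_dir, paste0("is_", stages[k], ".bedgraph")))
    tads <- tracks[[k]]$tads
    write_bed(data.frame(chrom = tads$chrom,
                         start = (tads$start_bin - 1) * tc$bin_size,
                         end = tads$end_bin * tc$bin_size),
              file.path(out_dir, paste0("tads_", stages[k], ".bed")))
  }

  ## ---- loop layer (10 kb) ----
  lc <- config$loops
  gb_l <- genome_bins(c(chrL = lc$chrom_size), lc$bin_size)
  nb_l <- nbins(gb_l)
  base_l <- structure_spec(gb_l,
                           loops = planted_loops("chrL", nb_l, lc$n_loops,
                                                 lc$intensity),
                           depth = lc$depth, sigma = lc$sigma)
  ser_l <- simulate_stage_series(base_l, lc$stage_edits,
                                 seeds = seed + 500L + seq_len(ns))
  maps_l <- lapply(ser_l$maps, kr_balance)
  oes_l <- lapply(maps_l, observed_over_expected)
  loopsets <- lapply(maps_l, call_loops)
  summary$n_loops <- stats::setNames(lapply(loopsets, nrow), stages)
  if (nrow(loopsets[[3]])) {
    ap <- apa(oes_l[[3]], loopsets[[3]])
    summary$apa_score <- round(ap$score, 6)
    shl <- shared_loops(loopsets[[2]], loopsets[[3]])
    summary$shared_loops_s2_s3 <- shl$n_shared
    summary$loop_cosine_s2_s3 <-
      round(loop_contact_similarity(maps_l[[2]], maps_l[[3]],
                                    loopsets[[3]]), 6)
    write_loops_bedpe(loopsets[[3]],
                      gb_l, file.path(out_dir, "loops_stage3.bedpe"))
  }

  ## ---- annotations, elements and TF statistics on the loop genome ----
  ann <- simulate_annotations(base_l, config$annotations, seed = seed + 601L)
  enh <- define_enhancers(ann$h3k27ac_peaks, ann$h3k4me3_peaks)
  prom <- promoter_regions(ann$tss, gb_l$chrom_sizes)
  true_loops <- base_l$loops
  cls <- classify_anchors(true_loops, gb_l, enh, prom)
  summary$loop_classes <- as.list(table(cls$class))
  anchors <- loop_anchors(true_loops, gb_l)
  enr <- anchor_peak_enrichment(ann$tf_peaks, anchors, gb_l$chrom_sizes,
                                n_rand = 100L, seed = seed + 602L)
  summary$tf_anchor_enrichment <- list(
    observed = round(enr$observed, 6),
    background_mean = round(mean(enr$background), 6),
    p_value = round(enr$p_value, 6))
  occ <- classify_gene_occupancy(true_loops, gb_l, prom, ann$tf_peaks)
  osum <- occupancy_expression_summary(occ, ann$expression)
  summary$occupancy_expressed_fraction <-
    lapply(as.list(osum$expressed_fraction), round, 6)

  ## ---- emit ----
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    paste0("hicscape version: ",
           as.character(utils::packageVersion("hicscape"))),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ", ")),
    paste0("equal_depth: ", isTRUE(config$equal_depth)),
    paste0("compartments: bin ", cc$bin_size, " contrast ", cc$contrast,
           " depth ", cc$depth, " sigma ", cc$sigma),
    paste0("tads: bin ", tc$bin_size, " factor ", tc$tad_factor,
           " depth ", tc$depth),
    paste0("loops: bin ", lc$bin_size, " intensity ", lc$intensity,
           " depth ", lc$depth))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
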