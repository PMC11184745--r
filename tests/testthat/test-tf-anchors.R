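test_that("anchor enrichment attains its minimal p when peaks sit on anchors", {
  sizes <- c(c1 = 1e7)
  anchors <- data.frame(chrom = "c1",
                        start = seq(1e5, 9e5, by = 1e5), end = NA)
  anchors$end <- anchors$start + 1e4
  peaks <- data.frame(chrom = "c1", start = anchors$start + 2000,
                      end = anchors$start + 3000)
  res <- anchor_peak_enrichment(peaks, anchors, sizes, n_rand = 99, seed = 1)
  expect_identical(res$observed, 1)
  expect_equal(res$p_value, 1 / 100)
  # determinism under seed
  res2 <- anchor_peak_enrichment(peaks, anchors, sizes, n_rand = 99, seed = 1)
  expect_identical(res$background, res2$background)
  # empty peak set flagged
  expect_warning(r0 <- anchor_peak_enrichment(peaks[0, ], anchors, sizes,
                                              n_rand = 10), "empty")
  expect_identical(r0$observed, 0)
})

test_that("anchor enrichment is calibrated for unrelated peaks", {
  sizes <- c(c1 = 1e7)
  set.seed(2)
  anchors <- data.frame(chrom = "c1",
                        start = sort(sample.int(9.9e6, 50)), end = NA)
  anchors$end <- anchors$start + 1e4
  inside <- vapply(1:20, function(r) {
    st <- sample.int(9.99e6, 100)
    peaks <- data.frame(chrom = "c1", start = st, end = st + 1000)
    res <- anchor_peak_enrichment(peaks, anchors, sizes, n_rand = 100,
                                  seed = r)
    qs <- stats::quantile(res$background, c(0.025, 0.975))
    res$observed >= qs[1] && res$observed <= qs[2]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("gene occupancy classes follow the best-loop rule", {
  gb <- genome_bins(c(c1 = 1e6), 1e4)
  # gene g1 promoter inside bin 10; two loops connect it
  promoters <- data.frame(chrom = "c1", start = 92000, end = 98000,
                          name = "g1")
  loops <- data.frame(chrom = "c1", bin1 = c(10L, 10L), bin2 = c(40L, 70L))
  # loop 1 has one bound anchor (bin 40), loop 2 has none
  tf <- data.frame(chrom = "c1", start = 395000, end = 396000)
  out <- classify_gene_occupancy(loops, gb, promoters, tf)
  expect_equal(out$class[out$gene_id == "g1"], "one")
  expect_equal(out$n_loops[out$gene_id == "g1"], 2L)
  # both anchors bound on either loop upgrades to "both"
  tf2 <- rbind(tf, data.frame(chrom = "c1", start = 95000, end = 96000))
  out2 <- classify_gene_occupancy(loops, gb, promoters, tf2)
  expect_equal(out2$class, "both")
  # gene with no connecting loop
  prom2 <- rbind(promoters,
                 data.frame(chrom = "c1", start = 820000, end = 826000,
                            name = "g2"))
  out3 <- classify_gene_occupancy(loops, gb, prom2, tf)
  expect_equal(out3$class[out3$gene_id == "g2"], "no_loop")
  # classes partition the promoter-connected gene set
  expect_setequal(out3$gene_id, prom2$name)
})

test_that("FPKM exactly at the expressed threshold counts as expressed", {
  classes <- data.frame(gene_id = c("a", "b", "c"),
                        class = c("both", "one", "none"),
                        n_loops = 1L)
  expr <- data.frame(gene_id = c("a", "b", "c"), fpkm = c(2, 1.99, 50))
  out <- occupancy_expression_summary(classes, expr)
  expect_equal(out$expressed_fraction[["both"]], 1)   # == 2 counts
  expect_equal(out$expressed_fraction[["one"]], 0)
})

test_that("occupancy-expression summary recovers the planted ordering", {
  fx <- tf_fixture()
  ann <- simulate_annotations(fx$spec, seed = 61)
  prom <- promoter_regions(ann$tss, fx$bins$chrom_sizes)
  occ <- classify_gene_occupancy(fx$loops, fx$bins, prom, ann$tf_peaks)
  out <- occupancy_expression_summary(occ, ann$expression)
  ef <- out$expressed_fraction
  expect_gt(ef[["both"]], ef[["one"]])
  expect_gt(ef[["one"]], ef[["none"]])
  expect_true(all(out$tests$p_adj < 0.05))
})

test_that("loop scores stratified by bound anchors recover planted ordering", {
  gb <- genome_bins(c(c1 = 3e7), 1e4)
  set.seed(62)
  n <- 240
  a1 <- sort(sample(20:2800, n))
  loops <- data.frame(chrom = "c1", bin1 = a1,
                      bin2 = a1 + sample(20:100, n, replace = TRUE))
  klass <- rep(c(2L, 1L, 0L), each = n / 3)
  tf <- do.call(rbind, lapply(seq_len(n), function(k) {
    bins_bound <- switch(klass[k] + 1L, integer(0), loops$bin1[k],
                         c(loops$bin1[k], loops$bin2[k]))
    if (!length(bins_bound)) return(NULL)
    data.frame(chrom = "c1", start = (bins_bound - 1) * 1e4 + 4000,
               end = (bins_bound - 1) * 1e4 + 5000)
  }))
  scores <- stats::rlnorm(n, meanlog = log(2) + klass, sdlog = 0.5)
  out <- loop_score_by_occupancy(scores, loops, gb, tf)
  med <- vapply(out$scores, stats::median, numeric(1))
  expect_gt(med[["2"]], med[["1"]])
  expect_gt(med[["1"]], med[["0"]])
  expect_true(all(out$tests$p_adj < 0.05))
  # null scores: no consistent ordering detected
  null_sig <- vapply(1:20, function(r) {
    set.seed(100 + r)
    s0 <- stats::rlnorm(n, log(2), 0.5)
    any(loop_score_by_occupancy(s0, loops, gb, tf)$tests$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(!null_sig), 0.8)
  # all loops unbound: single stratum, tests NA
  out0 <- loop_score_by_occupancy(scores, loops, gb, tf[0, ])
  expect_length(out0$scores[["2"]], 0)
  expect_true(all(is.na(out0$tests$p_value)))
})
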