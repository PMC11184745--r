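test_that("loop caller enforces the separation floor and input contract", {
  gb <- genome_bins(c(c1 = 2e6), 1e4)  # 200 bins
  spec <- structure_spec(gb, depth = 5e5)
  m <- simulate_contact_map(spec, seed = 51)
  expect_error(call_loops(m), "balanced")
  mb <- kr_balance(m)
  # an intense adjacent-bin pixel is never called (separation >= 2 bins)
  mb$cis$c1[100, 101] <- mb$cis$c1[100, 101] + 500
  mb$cis$c1[101, 100] <- mb$cis$c1[100, 101]
  ls <- call_loops(mb)
  if (nrow(ls)) expect_true(all(ls$bin2 - ls$bin1 >= 2))
})

test_that("single-loop APA reproduces that loop's own window", {
  spec <- loop_spec(k = 5)
  m <- sim_balanced(spec, seed = 52)
  oe <- observed_over_expected(m)
  one <- spec$loops[3, ]
  a <- apa(oe, one, flank = 5)
  expect_equal(a$n_used, 1L)
  direct <- oe$values$chrL[(one$bin1 - 5):(one$bin1 + 5),
                           (one$bin2 - 5):(one$bin2 + 5)]
  expect_equal(a$matrix, direct)
  expect_error(apa(oe, spec$loops[0, ]), "empty")
})

test_that("loop sharing matches the plus/minus one bin rule exactly", {
  mk <- function(b1, b2) {
    structure(data.frame(chrom = "c1", bin1 = b1, bin2 = b2,
                         observed = 10, expected = 2,
                         qvalue = 1e-4, n_pixels = 1L),
              class = c("loop_set", "data.frame"), bin_size = 1e4)
  }
  a <- mk(c(50L, 100L), c(80L, 140L))
  expect_equal(shared_loops(a, a)$n_shared, 2L)
  # both anchors shifted one bin: shared
  b1 <- mk(51L, 81L)
  expect_equal(shared_loops(a[1, ], b1)$n_shared, 1L)
  # one anchor shifted two bins: not shared
  b2 <- mk(52L, 80L)
  expect_equal(shared_loops(a[1, ], b2)$n_shared, 0L)
  # symmetry and the cardinality bound
  sAB <- shared_loops(a, b1)
  expect_equal(sAB$n_shared, shared_loops(b1, a)$n_shared)
  expect_lte(sAB$n_shared, min(nrow(a), nrow(b1)))
  # resolution mismatch rejected
  b3 <- mk(51L, 81L); attr(b3, "bin_size") <- 5e4
  expect_error(shared_loops(a, b3), "resolution")
})

test_that("loop contact similarity is 1 on self and depth-scale invariant", {
  spec <- loop_spec(k = 10, depth = 1e6)
  m1 <- sim_balanced(spec, seed = 53)
  loops <- spec$loops
  expect_equal(loop_contact_similarity(m1, m1, loops), 1, tolerance = 1e-12)
  # depth scaling of one map leaves the cosine unchanged
  m_scaled <- m1
  m_scaled$cis$chrL <- m_scaled$cis$chrL * 4
  expect_equal(loop_contact_similarity(m1, m_scaled, loops),
               1, tolerance = 1e-9)
  # same spec beats different spec
  m2 <- sim_balanced(spec, seed = 54)
  spec_other <- loop_spec(k = 10, depth = 1e6)
  set.seed(55)
  spec_other$loops$bin1 <- sample(spec_other$loops$bin1)
  spec_other$loops <- spec_other$loops[
    spec_other$loops$bin2 - spec_other$loops$bin1 >= 2, ]
  m3 <- sim_balanced(spec_other, seed = 56)
  expect_gt(loop_contact_similarity(m1, m2, loops),
            loop_contact_similarity(m1, m3, loops))
  # zero vector flagged
  m0 <- m1; m0$cis$chrL[] <- 0
  m0$weights$chrL <- rep(1, 500); m0$masked$chrL <- rep(FALSE, 500)
  expect_warning(out <- loop_contact_similarity(m1, m0, loops), "zero")
  expect_true(is.na(out))
})

test_that("anchor classification applies promoter-over-enhancer precedence", {
  gb <- genome_bins(c(c1 = 1e6), 1e4)
  loops <- data.frame(chrom = "c1", bin1 = c(10L, 30L, 50L),
                      bin2 = c(20L, 40L, 60L))
  # bin k covers [ (k-1)*1e4, k*1e4 )
  promoters <- data.frame(chrom = "c1", start = c(95000, 295000),
                          end = c(96000, 296000), name = c("g1", "g2"))
  enhancers <- data.frame(chrom = "c1",
                          start = c(195000, 295500, 495000),
                          end = c(196000, 296500, 496000))
  cls <- classify_anchors(loops, gb, enhancers, promoters)
  expect_equal(cls$anchor1, c("P", "P", "E"))  # bin 30 has both -> P
  expect_equal(cls$anchor2, c("E", "None", "None"))
  expect_equal(cls$class, c("P-E", "P-None", "E-None"))
})

test_that("loop-connected genes show their planted expression advantage", {
  fx <- tf_fixture(n_loops = 200L)
  ann <- simulate_annotations(fx$spec, effect_model = list(
    occupancy_multipliers = c(both = 3, one = 3, none = 3)), seed = 57)
  prom <- promoter_regions(ann$tss, fx$bins$chrom_sizes)
  res <- loop_gene_expression(fx$loops, fx$bins, prom, ann$expression)
  expect_gt(stats::median(res$in_loops), stats::median(res$not_in_loops))
  expect_lt(res$test$p.value, 0.01)
  # no loops: graceful empty report
  r0 <- loop_gene_expression(fx$loops[0, ], fx$bins, prom, ann$expression)
  expect_length(r0$in_loops, 0)
  expect_null(r0$test)
})

test_that("BEDPE round-trip preserves loop anchors", {
  spec <- loop_spec(k = 8)
  ls <- structure(data.frame(chrom = "chrL", bin1 = spec$loops$bin1,
                             bin2 = spec$loops$bin2, observed = 5,
                             expected = 1, qvalue = 0.01, n_pixels = 1L),
                  class = c("loop_set", "data.frame"), bin_size = 1e4)
  f <- withr::local_tempfile()
  write_loops_bedpe(ls, spec$bins, f)
  back <- read_loops_bedpe(f, spec$bins)
  expect_equal(back$bin1, ls$bin1)
  expect_equal(back$bin2, ls$bin2)
})
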