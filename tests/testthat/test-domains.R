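test_that("insulation score is near zero on uniform matrices", {
  n <- 60
  gb <- genome_bins(c(c1 = n * 5e4), 5e4)
  m <- kr_balance(contact_map(gb, list(c1 = matrix(5, n, n))))
  tr <- insulation_score(m, window = 5e5)
  expect_lt(max(abs(tr$score), na.rm = TRUE), 1e-9)
  # edges where the window does not fit are missing
  expect_true(all(is.na(tr$score[1:10])))
  expect_error(insulation_score(m, window = 5e4), "2 bins")
})

test_that("planted boundaries are deep insulation minima on noiseless maps", {
  spec <- tad_spec(tad_factor = 3, sigma = 0)
  rates <- expected_cis_rates(spec)
  m <- kr_balance(contact_map(spec$bins, lapply(rates, function(r) r * 1e3)))
  tr <- insulation_score(m)
  bnd <- planted_tad_boundaries()
  expect_true(all(tr$score[bnd] < -0.5))
  # each planted boundary is the local minimum of its neighborhood,
  # up to the one-bin tie with its right neighbor (whose window is also
  # fully cross-TAD)
  for (b in bnd) expect_true(which.min(tr$score[(b - 5):(b + 5)]) %in% 6:7)
})

test_that("boundary calling recovers planted boundaries and respects limits", {
  spec <- tad_spec(tad_factor = 3, depth = 1e6, sigma = 0.2)
  m <- sim_balanced(spec, seed = 41)
  tr <- call_boundaries(insulation_score(m))
  bnd <- planted_tad_boundaries()
  recall <- mean(vapply(bnd, function(b)
    any(abs(tr$boundaries$bin - b) <= 1), logical(1)))
  precision <- mean(vapply(tr$boundaries$bin, function(b)
    any(abs(bnd - b) <= 1), logical(1)))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # boundaries partition the chromosome into TADs covering every bin
  tads <- tr$tads
  covered <- sum(tads$end_bin - tads$start_bin + 1)
  expect_equal(covered, 400)
  # infinite strength threshold -> no boundaries, one TAD per chromosome
  tr_inf <- call_boundaries(insulation_score(m), strength_min = Inf)
  expect_equal(nrow(tr_inf$boundaries), 0L)
  expect_equal(nrow(tr_inf$tads), 1L)
  expect_equal(tr_inf$tads$end_bin - tr_inf$tads$start_bin + 1L, 400L)
})

test_that("close boundary pairs are resolved by the minimum TAD size rule", {
  # construct a track with two artificial minima 2 bins apart
  gb <- genome_bins(c(c1 = 3e6), 5e4)  # 60 bins
  sc <- rep(0.2, 60)
  sc[c(1:10, 51:60)] <- NA
  sc[30] <- -1.0; sc[32] <- -0.8
  sc[29] <- -0.5; sc[31] <- -0.45; sc[33] <- -0.4
  tr <- structure(list(bins = gb, score = sc, window = 5e5,
                       boundaries = NULL, tads = NULL),
                  class = "insulation_track")
  out <- call_boundaries(tr, strength_min = 0.1)
  expect_lte(nrow(out$boundaries), 1L)
  if (nrow(out$boundaries)) expect_equal(out$boundaries$bin, 30)
})

test_that("aggregate boundary profile dips at planted boundaries, flat on controls", {
  spec <- tad_spec(tad_factor = 3, depth = 1e6, sigma = 0.2)
  m <- sim_balanced(spec, seed = 42)
  tr <- insulation_score(m)
  bnd <- data.frame(chrom = "chrT", bin = planted_tad_boundaries())
  prof <- aggregate_boundary_profile(tr, bnd, flank = 10)
  expect_equal(which.min(prof$profile), 11L)  # offset 0
  expect_lt(prof$profile[11], -0.5)
  # random mid-TAD positions give a flat profile
  set.seed(43)
  rand <- data.frame(chrom = "chrT",
                     bin = planted_tad_boundaries() + 20L)
  prof0 <- aggregate_boundary_profile(tr, rand, flank = 5)
  expect_lt(max(abs(prof0$profile)), 0.35)
  # 2-D aggregate: intra-TAD corners exceed inter-TAD corners
  oe <- observed_over_expected(m)
  prof2 <- aggregate_boundary_profile(tr, bnd, flank = 10, oe = oe)
  expect_gt(prof2$intra_tad, prof2$inter_tad)
  # flank 0 reduces to the mean boundary score
  p0 <- aggregate_boundary_profile(tr, bnd, flank = 0)
  expect_equal(p0$profile, mean(tr$score[bnd$bin]))
})

test_that("TAD sharing follows the 75% reciprocal-overlap rule exactly", {
  a <- data.frame(chrom = "c1", start_bin = c(1L, 101L),
                  end_bin = c(100L, 200L))
  # identical sets: all shared
  sh <- shared_tads(a, a)
  expect_equal(sh$n_shared, 2L)
  expect_length(sh$a_specific, 0)
  # shift by 30% of length: reciprocal overlap 70% < 75% -> not shared
  b <- data.frame(chrom = "c1", start_bin = 31L, end_bin = 130L)
  expect_equal(shared_tads(a[1, ], b)$n_shared, 0L)
  # shift by 20%: overlap 80% -> shared
  b2 <- data.frame(chrom = "c1", start_bin = 21L, end_bin = 120L)
  expect_equal(shared_tads(a[1, ], b2)$n_shared, 1L)
  # nested TAD at 50% of parent length fails the "both" rule
  nest <- data.frame(chrom = "c1", start_bin = 26L, end_bin = 75L)
  expect_equal(shared_tads(a[1, ], nest)$n_shared, 0L)
  # symmetry
  expect_equal(shared_tads(b2, a[1, ])$n_shared, 1L)
})

test_that("boundary variability ranks planted stage differences first", {
  # three synthetic stage tracks over one 200-bin chromosome
  gb <- genome_bins(c(c1 = 1e7), 5e4)
  mk_track <- function(score, bnds) {
    structure(list(bins = gb, score = score, window = 5e5,
                   boundaries = data.frame(chrom = "c1", bin = bnds,
                                           strength = 1,
                                           score = score[bnds]),
                   tads = NULL), class = "insulation_track")
  }
  base <- rep(0.1, 200)
  stable <- seq(20, 180, by = 20)       # present in all stages
  variable <- c(15, 55, 95, 135, 175)   # stage-1 only
  s1 <- base; s1[stable] <- -1; s1[variable] <- -1
  s2 <- base; s2[stable] <- -1
  s3 <- base; s3[stable] <- -1
  tr1 <- mk_track(s1, sort(c(stable, variable)))
  tr2 <- mk_track(s2, stable)
  tr3 <- mk_track(s3, stable)
  bv <- boundary_variability(list(tr1, tr2, tr3), top_k = 5, k_clusters = 2)
  expect_setequal(bv$bin, variable)
  # identical tracks -> all SDs zero, ties broken by bin order
  bv0 <- boundary_variability(list(tr2, tr3), top_k = 3, k_clusters = 1)
  expect_true(all(bv0$sd == 0))
  expect_equal(bv0$bin, sort(stable)[1:3])
})

test_that("variable-boundary clustering recovers planted stage patterns", {
  gb <- genome_bins(c(c1 = 2e7), 5e4)  # 400 bins
  set.seed(44)
  n_per <- 25
  patterns <- list(c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1), c(-1, -1, 0))
  bins_used <- sample.int(380, 4 * n_per) + 10
  truth <- rep(1:4, each = n_per)
  scores <- matrix(0.1, 400, 3)
  for (k in seq_along(bins_used)) {
    scores[bins_used[k], ] <- patterns[[truth[k]]] +
      stats::rnorm(3, sd = 0.05)
  }
  mk <- function(col) structure(
    list(bins = gb, score = scores[, col], window = 5e5,
         boundaries = data.frame(chrom = "c1", bin = sort(bins_used),
                                 strength = 1,
                                 score = scores[sort(bins_used), col]),
         tads = NULL), class = "insulation_track")
  bv <- boundary_variability(list(mk(1), mk(2), mk(3)),
                             top_k = 4 * n_per, k_clusters = 4)
  truth_of <- truth[match(bv$bin, bins_used)]
  # adjusted Rand index between clusters and planted patterns
  tab <- table(bv$cluster, truth_of)
  a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2)); n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  ari <- (a - expected) / ((b + cc) / 2 - expected)
  expect_gte(ari, 0.8)
})
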