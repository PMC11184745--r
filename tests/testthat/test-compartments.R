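# noiseless map whose counts are the expected rates themselves
noiseless_map <- function(spec) {
  rates <- expected_cis_rates(spec)
  kr_balance(contact_map(spec$bins, lapply(rates, function(r) r * 1e3)))
}

gene_density_for <- function(spec, a = 3L, b = 1L) {
  ifelse(spec$comp_labels == "A", a, b)
}

test_that("compartment labels are recovered from a noiseless checkerboard", {
  spec <- checker_spec(contrast = 0.6)
  oe <- observed_over_expected(noiseless_map(spec))
  prof <- call_compartments(oe, gene_density_for(spec))
  agree <- mean(prof$label == spec$comp_labels, na.rm = TRUE)
  expect_gte(agree, 0.99)
})

test_that("orientation follows gene density (flipping density flips labels)", {
  spec <- checker_spec(contrast = 0.6)
  oe <- observed_over_expected(noiseless_map(spec))
  p1 <- call_compartments(oe, gene_density_for(spec, 3, 1))
  p2 <- call_compartments(oe, gene_density_for(spec, 1, 3))
  ok <- !is.na(p1$label) & !is.na(p2$label)
  expect_true(all(p1$label[ok] != p2$label[ok]))
  # orientation contract: mean gene density of A >= B
  gd <- gene_density_for(spec)
  expect_gte(mean(gd[p1$label == "A"], na.rm = TRUE),
             mean(gd[p1$label == "B"], na.rm = TRUE))
})

test_that("structureless maps give small unstable eigenvectors", {
  gb <- genome_bins(c(chrC = 4e7), 1e5)
  spec0 <- structure_spec(gb, depth = 1e6)
  profs <- lapply(1:2, function(sd) {
    oe <- observed_over_expected(sim_balanced(spec0, seed = sd))
    call_compartments(oe, rep(1L, 400))
  })
  # both classes occur, eigenvector values are small, and the labelling
  # has no stability across seeds
  expect_true(all(c("A", "B") %in% profs[[1]]$label))
  expect_lt(stats::median(abs(profs[[1]]$e1), na.rm = TRUE), 0.1)
  agree <- mean(profs[[1]]$label == profs[[2]]$label, na.rm = TRUE)
  expect_lt(abs(agree - 0.5), 0.3)  # no stability across seeds
})

test_that("strength is 0.5 on uniform matrices and decreases with contrast", {
  n <- 60
  gb <- genome_bins(c(c1 = n * 1e5), 1e5)
  m <- kr_balance(contact_map(gb, list(c1 = matrix(7, n, n))))
  oe <- observed_over_expected(m)
  lab <- rep(c("A", "B"), length.out = n)
  prof <- structure(list(bins = gb, e1 = ifelse(lab == "A", 1, -1),
                         label = lab, stage = NA), class = "compartment_profile")
  expect_equal(compartment_strength(oe, prof, "c1"), 0.5, tolerance = 1e-9)

  scores <- vapply(c(0.1, 0.3, 0.6), function(ct) {
    spec <- checker_spec(contrast = ct)
    oe <- observed_over_expected(noiseless_map(spec))
    p <- call_compartments(oe, gene_density_for(spec))
    compartment_strength(oe, p, "chrC")
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  # permuted labels never score lower than the true labels
  spec <- checker_spec(contrast = 0.6)
  oe6 <- observed_over_expected(noiseless_map(spec))
  truep <- structure(list(bins = spec$bins,
                          e1 = ifelse(spec$comp_labels == "A", 1, -1),
                          label = spec$comp_labels, stage = NA),
                     class = "compartment_profile")
  s_true <- compartment_strength(oe6, truep, "chrC")
  set.seed(10)
  for (i in 1:3) {
    pp <- truep; pp$label <- sample(pp$label)
    expect_gte(compartment_strength(oe6, pp, "chrC"), s_true)
  }
})

test_that("saddle is flat on uniform input and corner-ordered under contrast", {
  n <- 120
  gb <- genome_bins(c(c1 = n * 1e5), 1e5)
  m <- kr_balance(contact_map(gb, list(c1 = matrix(3, n, n))))
  oe <- observed_over_expected(m)
  lab <- rep(c("A", "B"), length.out = n)
  set.seed(2)
  prof <- structure(list(bins = gb, e1 = stats::rnorm(n), label = lab,
                         stage = NA), class = "compartment_profile")
  sd1 <- saddle(oe, prof, ngroups = 20)
  expect_equal(max(abs(sd1$values - 1), na.rm = TRUE), 0, tolerance = 1e-9)

  spec <- checker_spec(contrast = 0.6)
  oe2 <- observed_over_expected(noiseless_map(spec))
  p2 <- call_compartments(oe2, gene_density_for(spec))
  sd2 <- saddle(oe2, p2, ngroups = 50)
  expect_gt(sd2$corners[["AA"]] * sd2$corners[["BB"]], sd2$corners[["AB"]]^2)
  # saddle grand mean stays near the genome-wide O/E mean
  expect_equal(mean(sd2$values, na.rm = TRUE), 1, tolerance = 0.25)
  # group sizes differ by at most 1
  grp_sizes <- table(cut(rank(p2$e1[!is.na(p2$e1)], ties.method = "first"),
                         breaks = 50))
  expect_lte(diff(range(grp_sizes)), 1)
})

test_that("switch categories partition bins and recover planted flips", {
  spec <- checker_spec(contrast = 0.6, depth = 1e6, sigma = 0.2)
  set.seed(11)
  flips <- sample.int(400, 40)
  spec2 <- perturb_spec(spec, list(flip_bins = flips))
  gd <- gene_density_for(spec)
  p1 <- call_compartments(observed_over_expected(sim_balanced(spec, 31)), gd)
  p2 <- call_compartments(observed_over_expected(sim_balanced(spec2, 32)), gd)
  sw <- compartment_switches(p1, p2)
  expect_identical(sum(table(sw$category)), 400L)
  switched <- which(sw$category %in% c("A2B", "B2A"))
  recall <- mean(flips %in% switched)
  expect_gte(recall, 0.9)
  # identical profiles -> zero switching
  sw0 <- compartment_switches(p1, p1)
  expect_equal(sum(sw0$fractions[c("A2B", "B2A")]), 0)
  gb2 <- genome_bins(c(x = 1e6), 1e5)
  p_other <- structure(list(bins = gb2, e1 = rep(1, 10),
                            label = rep("A", 10), stage = NA),
                       class = "compartment_profile")
  expect_error(compartment_switches(p1, p_other), "bins")
})

test_that("switch-expression association recovers planted direction and nulls", {
  spec <- checker_spec(contrast = 0.6)
  set.seed(12)
  spec2 <- perturb_spec(spec, list(flip_bins = sample.int(400, 60)))
  truep <- function(s) structure(
    list(bins = s$bins, e1 = ifelse(s$comp_labels == "A", 1, -1),
         label = s$comp_labels, stage = NA), class = "compartment_profile")
  sw <- compartment_switches(truep(spec), truep(spec2))
  ann <- simulate_annotations(spec, effect_model = list(n_genes = 400L),
                              seed = 13, stage_specs = list(spec, spec2))
  lfc <- stats::setNames(log2(ann$expression$fpkm_stage2 /
                                ann$expression$fpkm_stage1),
                         ann$expression$gene_id)
  res <- switch_expression_association(sw, spec$bins, ann$tss, lfc)
  expect_gt(res$medians[["B2A"]], res$medians[["A2B"]])
  expect_lt(res$test$p.value, 0.05)
  # null effect model: fold-changes shuffled -> mostly non-significant
  set.seed(14)
  sig <- vapply(1:20, function(i) {
    lfc0 <- stats::setNames(sample(lfc), names(lfc))
    r <- switch_expression_association(sw, spec$bins, ann$tss, lfc0)
    !is.null(r$test) && r$test$p.value < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.8)
  # empty category: no crash
  sw_id <- compartment_switches(truep(spec), truep(spec))
  r0 <- switch_expression_association(sw_id, spec$bins, ann$tss, lfc)
  expect_true(is.null(r0$test) || is.na(r0$medians["B2A"]))
})

test_that("peak-compartment overlap follows the 1 bp rule", {
  gb <- genome_bins(c(c1 = 1e6), 1e5)  # 10 bins
  lab <- rep(c("A", "B"), 5)
  prof <- structure(list(bins = gb, e1 = ifelse(lab == "A", 1, -1),
                         label = lab, stage = NA), class = "compartment_profile")
  # fully inside an A bin
  inA <- data.frame(chrom = "c1", start = 10, end = 50)
  expect_equal(as.integer(peak_compartment_overlap(inA, prof)), c(1L, 0L))
  # straddling the A/B edge at 1e5 -> counted in both
  strad <- data.frame(chrom = "c1", start = 99999, end = 100001)
  expect_equal(as.integer(peak_compartment_overlap(strad, prof)), c(1L, 1L))
  # unknown chromosome dropped with warning
  expect_warning(
    out <- peak_compartment_overlap(
      data.frame(chrom = "cX", start = 0, end = 10), prof), "unknown")
  expect_equal(as.integer(out), c(0L, 0L))
  # planted 4:1 A:B placement recovered in density ratio
  spec <- checker_spec()
  ann <- simulate_annotations(spec, effect_model = list(n_peaks = 400L),
                              seed = 15)
  profc <- structure(list(bins = spec$bins,
                          e1 = ifelse(spec$comp_labels == "A", 1, -1),
                          label = spec$comp_labels, stage = NA),
                     class = "compartment_profile")
  cnt <- peak_compartment_overlap(ann$h3k27ac_peaks, profc)
  expect_gt(cnt[["A"]] / cnt[["B"]], 2.5)
})
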