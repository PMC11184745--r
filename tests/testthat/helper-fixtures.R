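# shared fixture builders; all synthetic, generated at test time

# 400-bin chromosome at 100 kb with an alternating 10-bin checkerboard
checker_spec <- function(contrast = 0.6, depth = 1e6, sigma = 0,
                         block = 10L) {
  gb <- genome_bins(c(chrC = 4e7), 1e5)
  structure_spec(gb, comp_labels = checkerboard_labels(gb, block),
                 contrast = contrast, depth = depth, sigma = sigma)
}

# 400-bin chromosome at 50 kb with 9 evenly spaced TAD boundaries
tad_spec <- function(tad_factor = 3, depth = 1e6, sigma = 0.2) {
  gb <- genome_bins(c(chrT = 2e7), 5e4)
  bnd <- as.integer(round(seq(0, 400, length.out = 11)))[2:10]
  structure_spec(gb, tad_boundaries = list(chrT = bnd),
                 tad_factor = tad_factor, depth = depth, sigma = sigma)
}

planted_tad_boundaries <- function() {
  as.integer(round(seq(0, 400, length.out = 11)))[2:10]
}

# 500-bin chromosome at 10 kb with k planted loops, separations 20-100 bins
loop_spec <- function(k = 30L, intensity = 4, depth = 3e6, sigma = 0) {
  gb <- genome_bins(c(chrL = 5e6), 1e4)
  sep <- as.integer(round(seq(20, 100, length.out = k)))
  a1 <- as.integer(round(seq(13, 500 - 12 - max(sep), length.out = k)))
  loops <- data.frame(chrom = "chrL", bin1 = a1, bin2 = a1 + sep,
                      intensity = intensity, stringsAsFactors = FALSE)
  structure_spec(gb, loops = loops, depth = depth, sigma = sigma)
}

# wide annotation genome with many loops for TF-occupancy statistics;
# sized so ~360 genes carry promoter-connecting loops (>= the stated
# 300-gene condition) with few anchor/promoter collisions
tf_fixture <- function(n_loops = 450L, seed = 42L) {
  gb <- genome_bins(c(chrA = 6e7), 1e4)
  set.seed(seed)
  a1 <- sort(sample(20:5800, n_loops))
  loops <- data.frame(chrom = "chrA", bin1 = a1,
                      bin2 = a1 + sample(20:100, n_loops, replace = TRUE),
                      intensity = 4, stringsAsFactors = FALSE)
  list(bins = gb, spec = structure_spec(gb, loops = loops, depth = 0),
       loops = loops)
}

# fraction of rows in `truth` matched within +/- tol bins by `called`
pair_recall <- function(truth, called, tol = 1L) {
  if (!nrow(truth)) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(k) {
    any(called$chrom == truth$chrom[k] &
          abs(called$bin1 - truth$bin1[k]) <= tol &
          abs(called$bin2 - truth$bin2[k]) <= tol)
  }, logical(1)))
}

# simulate + balance in one step
sim_balanced <- function(spec, seed) kr_balance(simulate_contact_map(spec, seed))
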