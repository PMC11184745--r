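# hicscape

Multi-scale analysis of Hi-C chromatin architecture in R, with a
planted-structure simulator for end-to-end validation.

Hi-C experiments measure genome-wide contact frequencies between pairs of
genomic bins. The 3D genome is organized hierarchically — megabase-scale
A/B compartments, sub-megabase topologically associating domains (TADs),
and focal chromatin loops between pairs of 10 kb anchors — and
developmental comparisons (for example hematopoietic stem/progenitor
maturation, where nascent cells show weaker, more disordered architecture
than fetal and adult cells) require quantifying each layer comparably
across stages. `hicscape` provides that toolkit for researchers analysing
binned contact matrices:

* **matrix preparation** — triplet/dense I/O, Knight–Ruiz-style balancing
  to equal row sums, observed/expected (O/E) normalization against the
  per-diagonal mean, hypergeometric depth downsampling, and a
  random-walk reproducibility score between libraries;
* **global metrics** — contact-probability decay curves P(s) on log
  distance bins, Jensen–Shannon divergence (JSD) between curves, the Von
  Neumann entropy VNE = −Σᵢ λᵢ ln λᵢ of the normalized eigenvalue spectrum
  of corr(log₂(M+1)) as a per-chromosome disorder index, and the
  trans-contact fraction;
* **compartments** — A/B calling from the first eigenvector of the O/E
  correlation matrix (oriented by gene density), the strength score
  AB/(AA+BB) (lower = stronger segregation), 50-group saddle matrices,
  switch categories between stages and their association with expression
  changes;
* **TADs** — insulation scores (log₂ of the cross-bin window sum over the
  chromosome mean), Crane-style boundary calling at delta zero-crossings,
  aggregate boundary profiles, 75% reciprocal-overlap TAD sharing, and
  ranking/clustering of the most variable boundaries across stages;
* **loops** — a simplified HiCCUPS-style caller (four local-neighborhood
  expecteds, Poisson upper-tail test, BH-FDR, fold floor), aggregate peak
  analysis (APA), ±1-bin loop sharing, cosine similarity of loop contact
  vectors, and enhancer/promoter classification of anchors;
* **regulatory elements & TF occupancy** — literal element definitions
  (enhancer = H3K27ac peak free of H3K4me3 overlap; active promoter = 6 kb
  around the TSS of FPKM > 1 genes), TF-peak enrichment on loop anchors
  versus length-matched random regions, and both/one/none anchor-occupancy
  gene classes with expression summaries (expressed = FPKM ≥ 2);
* **synthetic data** — `structure_spec()` plants compartment
  checkerboards, TAD blocks and loops into a power-law decay background
  with Poisson sampling and optional log-normal over-dispersion, plus
  paired TSS/peak/expression annotations with occupancy-dependent effects,
  so every stage of the analysis can be checked against known ground
  truth;
* **pipeline** — `run_pipeline()` runs the whole three-stage study from
  one seeded config and writes tracks plus a deterministic
  `summary.json`.

## Worked example

Simulate a 20 Mb chromosome at 50 kb with four planted TAD boundaries,
balance it, and call boundaries from the insulation track:

```r
library(hicscape)

gb <- genome_bins(c(chr7 = 2e7), 5e4)
spec <- structure_spec(gb,
  tad_boundaries = list(chr7 = c(80L, 160L, 240L, 320L)),
  tad_factor = 3, depth = 1e6, sigma = 0.2)
map <- kr_balance(simulate_contact_map(spec, seed = 1))
map
#> contact_map: 1 chromosome(s), bin size 50000 bp, total 997597 contacts (balanced)

track <- call_boundaries(insulation_score(map, window = 5e5))
track
#> insulation_track: window 500000 bp, 380 scored bins, 4 boundaries
track$boundaries
#>   chrom bin strength     score
#> 1  chr7  81 1.646003 -1.396411
#> 2  chr7 160 1.528777 -1.255324
#> 3  chr7 241 1.585898 -1.357681
#> 4  chr7 320 1.534149 -1.315179

von_neumann_entropy(map, "chr7")
#> [1] 2.654925
```

All four planted boundaries are recovered within one bin (81 vs 80, 241 vs
240 — the boundary bin and its right neighbor both have fully cross-domain
windows, so the minimum can land on either). Their insulation scores around
−1.3 mean contacts across the boundary are roughly 2.5-fold depleted
relative to the chromosome average, and the boundary strengths (~1.5) are
far above the 0.5 calling threshold. The entropy value is the disorder
index used to compare stages: for a fixed genome, noisier or less
structured maps score closer to the ln(n) maximum.

The same pattern scales up: `default_pipeline_config()` +
`run_pipeline()` simulate a relaxed nascent stage and two full-strength
stages per layer, equalize depth, and emit per-stage compartment strength,
VNE, JSD, TAD and loop calls, APA, sharing and TF-occupancy summaries into
`summary.json`.

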