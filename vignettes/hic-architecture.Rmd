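---
title: "Multi-scale analysis of Hi-C chromatin architecture with planted-structure validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale analysis of Hi-C chromatin architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`hicscape` analyses binned Hi-C contact matrices across the three canonical
organizational layers of the vertebrate 3D genome, each at its conventional
working resolution:

* **A/B compartments** at 100 kb — megabase-scale partition of chromatin into
  an active (A) and an inactive (B) class, read off the first eigenvector of
  the contact correlation matrix;
* **TADs** at 50 kb — contiguous domains of enriched internal contact,
  delimited by insulation-score minima;
* **chromatin loops** at 10 kb — focal pairwise enrichments between two
  anchors, detected against local neighborhood expectations.

Above these sit genome-scale disorder metrics (contact-decay curves and their
Jensen–Shannon divergence, Von Neumann entropy, the trans-contact fraction),
and below them functional annotation: regulatory-element classification of
loop anchors and transcription-factor occupancy statistics that relate anchor
binding to loop strength and gene expression. The package targets
developmental comparisons — e.g. hematopoietic stem/progenitor maturation,
where early ("nascent") cells display weaker, more disordered architecture
than later stages — so every metric is designed to be comparable across
stages after depth equalization.

Because deposited Hi-C datasets are far too deep to re-process at desk scale,
the package carries a first-class synthetic generator. Its planted structure
is the ground truth against which every analysis stage is validated.

## The synthetic contact-map model

A `structure_spec` describes one genome. The expected rate of pixel $(i,j)$
at separation $s = |i-j|$ bins is

$$\lambda_{ij} \;=\; D \cdot (s+1)^{-\alpha} \cdot c_{ij} \cdot t_{ij} \cdot \ell_{ij} \cdot \varepsilon_{ij},$$

with the factors:

* $D$ — a global scale fixed so the expected cis total equals
  `depth * (1 - trans_fraction)`;
* $(s+1)^{-\alpha}$ — power-law distance decay; `decay_exponent` defaults to
  $\alpha = 1$, the canonical contact-probability slope. The $+1$ offset
  keeps the diagonal finite;
* $c_{ij}$ — compartment factor: $(1+c)$ when bins $i,j$ share their planted
  A/B label, $(1-c)$ otherwise, with contrast $c \in [0,1)$;
* $t_{ij}$ — TAD factor: `tad_factor` $\ge 1$ when both bins fall wholly
  inside one TAD. Boundary bins belong to the TAD on their left (a recorded
  tie-break);
* $\ell_{ij}$ — loop factor: the planted intensity at loop pixels, 1
  elsewhere;
* $\varepsilon_{ij}$ — optional mean-one log-normal multiplier with
  dispersion `sigma`, the simplest over-dispersion consistent with real Hi-C.

Counts are Poisson draws around $\lambda$, sampled on the upper triangle and
mirrored, so symmetry is exact. Trans contacts are drawn as
per-chromosome-pair Poisson totals proportional to size products.
`expected_cis_rates()` exposes the noiseless rates directly; in this
infinite-depth limit the planted factors are recovered exactly, which the
test suite uses as its sharpest oracle.

### Study conditions

The generator's defaults define the package's reference study conditions,
chosen once on field-realistic grounds:

* compartments: one to two 20–40 Mb chromosomes at 100 kb (400 bins), an
  alternating 10-bin (1 Mb) checkerboard, contrast 0.6 for high-contrast
  fixtures, depth $10^6$, `sigma` 0.2;
* TADs: a 20 Mb chromosome at 50 kb (400 bins), nine evenly spaced
  boundaries (2 Mb domains, matching the megabase-scale domains typical of
  vertebrate maps), within-TAD enrichment 3, depth $10^6$, `sigma` 0.2;
* loops: a 5 Mb segment at 10 kb (500 bins), 30 loops of intensity 4 at
  separations 200 kb–1 Mb, depth $3\times10^6$, no over-dispersion (the
  caller's statistical model is Poisson; see below). The depth was fixed by
  a power calculation made before any recovery was measured: at depth
  $3\times10^6$ the Poisson tail test retains $\ge 95\%$ worst-case power
  (Benjamini–Hochberg rank-1 threshold over $\sim10^5$ candidate pixels) for
  an intensity-4 loop at the largest planted separation; at $10^6$ that
  power is under 30%.
* annotations: 400–450 genes with log-normal FPKM (meanlog $\log 2$, sdlog
  1), a 3:1 A:B expression ratio, TF-occupancy multipliers (4, 2, 1) for
  genes whose promoters connect to loops with both/one/no TF-bound anchors,
  4:1 A:B placement of histone/ATAC peaks, and 3:1 A:B placement of
  background gene TSS — the gene-density gradient the compartment
  orientation rule relies on.

The generator emulates: distance decay, compartment checkerboards,
domain blocks, focal loops, finite depth, over-dispersion, stage-to-stage
edits (label flips, boundary insertions, strength scaling) and paired
annotations with occupancy-dependent expression. It deliberately does
**not** emulate: mappability/GC/copy-number bias (coverage is uniform, so
balancing is nearly a no-op on synthetic maps), nested sub-TAD hierarchies,
loop extension beyond a single pixel, structured trans contacts, or
polymer-physics realism. Passing tests therefore demonstrate correctness of
the estimators under a known generative model, not robustness to every
artifact of real libraries.

## Matrix preparation

**Balancing.** `kr_balance()` finds per-bin weights by symmetric iterative
proportional scaling until unmasked row sums of $WMW$ agree to a relative
tolerance (default $10^{-6}$, 1000 iterations). The contract is the
postcondition (equal row sums), not a particular algorithm; weights are
rescaled so the balanced total matches the raw total. Bins with zero
marginal are masked, not balanced; no additional coverage filtering is
applied.

**Observed/expected.** The expected value at separation $s$ is the
per-chromosome empirical mean of balanced contacts on that diagonal — no
smoothing. This is the simplest model satisfying the mean-one invariant the
rest of the package relies on (saddle values, APA, aggregate boundary plots
are all interpretable as fold enrichments because of it).

**Downsampling.** Cross-stage comparisons first downsample every map to the
shallowest stage's total. Contacts are removed without replacement by a
sequential multivariate hypergeometric over all cis pixels and trans totals
jointly, preserving symmetry exactly and cis/trans proportions in
expectation.

**Reproducibility.** `reproducibility_score()` implements the random-walk
concordance idea: per chromosome, depth-normalized contact matrices are
row-normalized into transition matrices, smoothed by $t$ random-walk steps
(default $t = 3$, exposed; no claim is made that any published analysis used
this exact $t$), and compared by L1 distance normalized by the number of
participating bins.

## Global disorder metrics

**P(s).** Mean contact frequency per logarithmic distance bin
(conventionally 20 kb–50 Mb in 500 bins; both ends are parameters so short
test chromosomes can be profiled). Empty distance bins are reported missing,
never zero.

**JSD.** Decay curves are renormalized over jointly non-missing bins and
compared by Jensen–Shannon divergence in the natural-log convention
(bounded by $\ln 2$, finite even for disjoint supports).

**Von Neumann entropy.** For a chromosome's matrix $M$, the Pearson
correlation matrix $C$ of $\log_2(M + 1)$ columns is eigendecomposed; the
eigenvalues are clipped at zero (they are analytically nonnegative but can
be tiny negatives numerically), normalized to sum one, and the entropy
$-\sum_i \lambda_i \ln \lambda_i$ is reported with the convention
$0 \ln 0 = 0$. The $+1$ pseudocount is a recorded decision — a bare
$\log_2$ of counts is undefined at zero pixels — and is exposed as a
parameter. Bins with zero coverage are removed before the correlation, not
imputed, since imputation would inject spurious order. The entropy is
bounded by $\ln n$ (flat spectrum) and attains 0 for rank-1 correlation;
noisier maps score higher, which is what makes it a disorder index.

## Compartments

The first eigenvector is computed per chromosome from the Pearson
correlation matrix of the O/E map (the field-standard autocorrelation
convention; computing it on raw balanced counts is possible but the
O/E-correlation route is the default because distance decay otherwise
dominates the leading eigenvector). The sign is oriented so that positive
values have the higher mean gene density (TSS count per bin) and positive
bins are labelled A. Chromosomes with fewer than 10 unmasked bins are fully
masked.

**Strength** is AB/(AA+BB): the mean O/E over unlike-labelled cis pairs
divided by the sum of the two within-class means, over all pairs (a
saddle-corner variant can be formed from `saddle()` output). Lower values =
stronger segregation; a structureless matrix scores 0.5. Because the score
is computed on O/E, depth cancels, which is what makes cross-stage
comparisons after downsampling meaningful.

**Saddle.** Bins ranked by eigenvector value genome-wide, split into 50
near-equal groups (sizes differ by at most one); the mean cis O/E between
every group pair forms the saddle matrix, with corner summaries over the
extreme 20% of groups. No extreme-quantile trimming is applied (exposed
parameter).

**Switches** are per-bin joint labels (A2A/B2B/A2B/B2A/masked) between two
stages; genes are assigned the category of their TSS bin and per-category
log2 fold-change distributions are compared with a two-sided rank test (B2A
versus A2B). Peak–compartment overlap uses the ≥1 bp rule; a peak straddling
an A/B boundary counts toward both labels.

## TADs

**Insulation score.** For each bin, the sum of balanced contacts in the
square window spanning `window` bp (default 500 kb = 10 bins at 50 kb)
upstream by downstream across the bin, log2-normalized to the chromosome
mean of such sums (chromosome-mean rather than genome-mean, so chromosomes
remain comparable in aggregate plots). Scores are missing where the window
leaves the chromosome or at least half the window bins are masked.

**Boundary calling** follows the delta-vector zero-crossing construction:
delta at bin $i$ is the mean score over `delta_window` (default 100 kb) bins
to the right minus to the left; boundaries sit at upward zero-crossings, at
the local score minimum, with boundary strength measured between the nearest
delta extrema flanking the crossing. The default `strength_min` is 0.5: at
50 kb resolution, noise-level delta swings on depth-$10^6$ over-dispersed
maps reach about 0.2 while planted factor-3 boundaries swing near 1.5, so
0.5 separates the two regimes with a wide margin on both sides. (The
published worm-data value of 0.1 sits inside the noise band at this
resolution; the parameter is exposed for users who want it.) TADs are the
inter-boundary intervals; a minimum TAD size of 3 bins (150 kb) is enforced
by dropping the weaker of any too-close boundary pair — consistent with
real vertebrate median TAD sizes (750–800 kb) being far above the
resolution.

**Sharing** uses the 75% reciprocal-overlap rule — the overlap must cover at
least 75% of *both* TADs — with one-to-one matching by best reciprocal
overlap. **Variability ranking** takes every bin used as a boundary in any
stage, scores it by the SD of its insulation score across stages, keeps the
top 1000 (ties broken by bin order), standardizes rows and clusters them
hierarchically (Euclidean distance, complete linkage — a recorded choice;
the analysis this mirrors names only a heatmap package) into $k$ groups.

## Loops

`call_loops()` is a deliberately simplified single-resolution variant of the
HiCCUPS idea and claims no equivalence to Juicer. For every candidate pixel
(separation 20 kb–2 Mb, default; the 2-bin floor avoids diagonal bleed),
four local neighborhoods — donut, lower-left quadrant, horizontal and
vertical stripes (inner radius 2, outer radius 5 bins) — each rescale the
distance-decay expected value by their own observed/expected ratio. The
most conservative (largest) of the four expecteds, mapped back to raw-count
scale through the balancing weights, parameterizes a Poisson upper-tail
test of the raw count. p-values are BH-corrected in **one family per
chromosome**: with the distance-stratified correction sometimes used, each
stratum admits its own rank-1 false rejection under the global null, so a
structureless map would still yield a call about half the time; a single
family keeps the probability of any false call on a null map near the
nominal FDR, and the Poisson discreteness in practice pushes it lower.
Pixels additionally need 1.5-fold enrichment over the most conservative
expected (the Juicer-style fold floor). Significant pixels merge by
8-connectivity; each cluster is reported at its most significant pixel.

**APA** averages O/E submatrices over loop pixels; the score is the center
divided by the mean of the lower-left corner quadrant block, so 1 means no
collective enrichment. **Sharing** matches loops greedily (best q-value
first) with both anchors within ±1 bin. **Cosine similarity** compares the
balanced contact values at a fixed loop list between two maps and is
invariant to global depth scaling. **Anchor classification** labels each
1-bin anchor P if it touches a promoter region (TSS ± 3 kb), else E if it
touches an enhancer, else None — promoter-over-enhancer precedence is the
recorded tie-break for anchors containing both.

## Regulatory elements and TF occupancy

Element definitions are deliberately literal: active enhancers are H3K27ac
peaks sharing zero bp with any H3K4me3 peak; active promoters are 6 kb
windows centered on the TSS of genes with FPKM strictly above 1; promoter
regions are TSS ± 3 kb, strand-ignored (the definition is symmetric).
Overlap semantics everywhere are ≥ 1 bp on half-open intervals.

TF-anchor enrichment compares the fraction of TF peaks overlapping any loop
anchor with `n_rand` background draws, each placing one random region per
anchor — same chromosome, same length, uniform start, overlaps among random
regions allowed. The empirical p-value uses the +1 correction, so its floor
is $1/(n_\mathrm{rand}+1)$. Gene occupancy classes use the best-loop rule: a
gene is "both" if at least one promoter-connecting loop has TF peaks on both
anchors, else "one" if some loop has exactly one bound anchor, else "none";
genes without promoter-connecting loops are "no_loop". Expression summaries
use the ≥ 2 FPKM expressed rule and two-sided rank tests (both-vs-one,
one-vs-none) with BH correction across the fixed pairwise set.

## Pipeline

`run_pipeline()` drives the three-stage study from one config: per layer it
simulates the stage series (stage 1 relaxed via contrast/TAD/loop-strength
scaling), optionally equalizes depth by downsampling to the minimum,
balances, runs the layer's analyses and writes per-stage tracks plus a
machine-readable `summary.json`. All randomness derives from the single
config seed, and two runs with the same config produce byte-identical
summaries. Any missing config section fails validation with the field
named.

## Numerical choices and degenerate inputs

* Balancing non-convergence returns the unbalanced map with a warning and
  residual; fully masked chromosomes yield empty (all-NA) O/E with a
  warning.
* O/E diagonals with zero mean are masked, not divided.
* Correlation on constant columns (e.g. uniform matrices) is rejected with
  a diagnostic rather than producing NaN entropy.
* Wilcoxon comparisons fall back gracefully (NULL/NA) when a class has
  fewer than two members; empty categories are reported, never fatal.
* Ties in the top-k variability selection break by bin order; equal-overlap
  TAD matches break by scan order — both documented, both deterministic.

## Limitations

The loop caller's Poisson model is anticonservative under strong
over-dispersion; on real libraries a local background estimated from deeper
neighborhoods (or a negative-binomial tail) would be needed at the same
FDR. The compartment eigenvector is per-chromosome only; no genome-wide
stitching or sub-compartment (multi-eigenvector) calling is attempted.
Boundary calling reports single-bin boundaries; nested domain hierarchies
are out of scope. All validation rests on the generative model above —
results on real data additionally depend on artifacts the generator does
not emulate.
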