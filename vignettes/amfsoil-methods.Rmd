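---
title: "Methods: closed-reference AMF community analysis and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-reference AMF community analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(amfsoil)
```

# The analysis problem

Soil contains arbuscular mycorrhizal fungi (AMF, Glomeromycota) both as
extraradical mycelium and as spores, so amplicon surveys of soil DNA see
a community that root-colonisation surveys miss. The pipeline in this
package takes barcoded SSU rRNA amplicon reads from a plot-based soil
survey — several 10 × 10 m plots with a 3 × 3 sampling grid, one plot
revisited across a growing season — and asks two questions: do plots a
few tens of metres apart harbour compositionally different AMF
communities, and does composition change through the season?

Taxonomic units are *virtual taxa* (VT): reference-defined SSU sequence
groups. Reads are assigned by closed-reference matching against a VT
database, so the unit definition is stable but limited to what the
reference contains.

# Pipeline stages and their contracts

## Demultiplexing

A raw read must begin with an 8-nt barcode from the run's barcode map,
followed by the forward primer (NS31, `TTGGAGGGCAAGTCTGGTGCC`), followed
by the template payload. Checks are applied in the order barcode →
primer → payload length (≥ 170 nt after stripping), and each read is
counted under exactly one outcome, so the rejection counts always
partition the input. Matching is exact by default; a Hamming mismatch
budget exists for the primer only (`max_primer_mismatches`), because
barcode mismatches would risk cross-sample misassignment. Reads with an
ambiguous base (N) in the barcode region are rejected rather than
rescued: a single N makes the sample identity of the read uncertain.
The reverse primer is deliberately not required — the acceptance
criteria for a read are forward primer, barcode and length only, since
454-style reads frequently do not reach the reverse primer.

Median read length uses the midpoint convention (mean of the central
pair for even n).

## Closed-reference assignment

Alignment hits arrive as the standard 12-column tabular dialect
(`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
evalue bitscore`). A hit is a candidate match when

* percent identity ≥ 97,
* |alignment length − min(query length, subject length)| ≤ 10 nt,
* e-value < 1e-50 (strict).

Among passing hits of a read, the best hit is the one with maximal
bitscore. The remaining tie-break — lower e-value, then
lexicographically smallest subject id — is not part of the original
criteria set; it was added so that assignment is deterministic and
independent of hit-file order, which matters for reproducibility and is
verified by a permutation property test.

The package does not run an aligner. Hits are inputs; in the synthetic
testbed they are produced by `simulate_hits()` (below).

## Matrix filtering and normalisation

Samples with fewer than 10 assigned reads are removed, as are singleton
VT. Both filters interact (removing a sample can turn a VT into a
singleton; removing a VT can push a sample below 10 reads), so they are
iterated to a fixed point, which makes the result independent of
application order. VT left with zero reads are dropped as unobserved. A
removal log records every removed entity and the reason.

"Singleton" defaults to a VT with exactly one read in the whole
retained matrix — the conventional reading in amplicon quality control —
but `singleton = "samples"` (present in exactly one sample) is
available, since the phrase is genuinely ambiguous in field usage.

Normalisation divides each row by its total, so downstream
dissimilarities compare proportional composition, not library size.

## Dissimilarity, rarefaction

Bray–Curtis dissimilarity is computed as
\(BC(i,j)=\sum_k |x_{ik}-x_{jk}| / \sum_k (x_{ik}+x_{jk})\). On
proportions it lies in [0, 1]. Note that BC on raw counts equals BC on
proportions only when row totals are equal; the tests assert both sides
of this to guard against silent normalisation assumptions.

Expected richness in a subsample of size n is the analytic rarefaction
formula \(E[S_n]=\sum_i\left(1-\binom{N-N_i}{n}/\binom{N}{n}\right)\),
evaluated with `lchoose` so large depths (the study-scale maximum is
1986 reads) do not overflow. Group rarefaction curves average samples
that can support each depth and report how many did.

## PERMANOVA

The total sum of squares of a distance matrix is the trace of the
Gower-centred inner-product matrix \(G\); term sums of squares are
\(\mathrm{tr}(H_\Delta G)\) for the increments \(H_\Delta\) of
sequential (Type-I) projections onto the cumulative model matrix, and
pseudo-F is MS(term)/MS(residual). Significance uses free permutation
of sample labels (rows/columns of \(G\)), with
\(p=(1+\#\{F^*\ge F\})/(1+B)\) so p is never exactly zero. Sequential
sums of squares were chosen because the two-factor seasonal model
(Season + within-plot sample identity) is reported in both term orders;
when the factors are near-balanced the order barely matters, and
reporting both makes that visible rather than assumed. Free permutation
is also used for the two-factor model — no restricted permutation
scheme is imposed — matching the conventional default of
distance-based permutation ANOVA.

Degenerate inputs fail loudly: a distance matrix of identical samples
(SS_total ≈ 0), a single-level factor, or zero residual degrees of
freedom are errors, not NaNs.

## Dispersion homogeneity

A significant PERMANOVA term can reflect differences in group spread
rather than location. The check embeds the distance matrix by principal
coordinates; Bray–Curtis is semi-metric, so negative eigenvalues occur
and their axes contribute *negatively* to squared distances — the
standard correction. Each sample's distance to its own group centre is
compared across groups by a one-way ANOVA F on (k − 1, n − k) df. The
centre defaults to the group centroid (deterministic, closed form); a
spatial-median option is provided (Weiszfeld iteration on the
positive-eigenvalue axes, centroid on the negative axes) for
compatibility with the common alternative default. Squared distances
that come out marginally negative after the correction are floored at
zero.

The dispersion check is reported for both the spatial grouping (plots,
final date; df 2, n − 3) and the seasonal grouping (four dates in the
revisited plot; df 3, n − 4). With 27 seasonal samples the latter gives
df (3, 23); published df of that shape match the seasonal grouping
rather than the three plots, so computing and reporting both groupings
avoids guessing which was meant.

## Richness comparison

Per-sample VT richness is compared between groups with a log-link
Poisson GLM (`stats::glm`, i.e. IRLS); the test statistic is the
deviance difference to the intercept-only model on k − 1 df. Group
means under the log-link MLE equal the arithmetic means, which the
tests assert.

## Distance decay of similarity

All n(n − 1)/2 sample pairs contribute a similarity 1 − BC and a
distance: Euclidean metres between grid coordinates (spatial mode) or
absolute difference in days between collection dates (temporal mode).
Days are the natural unit for a within-season design spanning ~101
days; a slope of order −0.001 per day is then directly comparable with
a spatial slope of order −0.01 per metre.

Similarity is logit-transformed (it is bounded in [0, 1]); values at
the boundary are clamped into [eps, 1 − eps] with eps = 1e-3, and the
number of clamped values is always reported so boundary handling is
auditable. The model is ordinary least squares of logit similarity on
distance. For the transform comparison, AIC under the Gaussian
likelihood (constant included) is reported for untransformed distance
and for log1p(distance); log1p rather than log because temporal designs
contain zero-distance pairs (same-day samples) for which log is
undefined, and log1p is the monotone log-family transform that is total
on [0, ∞).

Pairwise observations share samples and are not independent, so no
analytic p-value is attached to the slope. Significance comes from a
label permutation: a permutation reassigns whole samples to positions,
the similarity matrix is re-indexed and the slope refitted — pairs are
never shuffled independently, which would destroy the dependence
structure the test must respect. The test is one-sided toward decay
(more negative slope) by default, mirroring the directional hypothesis;
a two-sided option exists. The permuted-slope distribution is retained
in the result.

## Thinning (depth equalisation)

Library sizes vary by two orders of magnitude, so the main analyses are
repeated on matrices in which every sample is subsampled without
replacement (multivariate hypergeometric) to a common depth — by
default the minimum row total, which at study scale is 13 reads. For
each of `n_matrices` (default 1000) thinned matrices, the spatial and
seasonal PERMANOVAs are re-run and both decay slopes refitted; decay
significance is *not* re-assessed by permutation inside the study (only
slope signs are recorded and summarised), keeping 1000 repetitions
affordable. PERMANOVA inside the study uses 199 permutations by default
— granular enough to call p < 0.05 — while headline analyses use 999.
The per-matrix significance threshold is α = 0.05; both strict (<) and
non-strict (≤) counts are reported because "significant" is ambiguous
at the boundary. Depth and singleton filters are not re-applied after
thinning: the study thins the final matrix.

## Read-trimming comparison

To check that taxonomic assignment is robust to read length, reads
longer than 400 nt are trimmed from the 3′ end to 400, 350, 300, 250,
200 and 170 nt and re-assigned. For each trimmed set versus the 400-nt
reference: the percentage of reads with identical outcomes (no-hit on
both sides counts as identical); the same percentage excluding reads
unassigned in either set; VT richness and its percentage of the
reference; and, after normalising per-sample profiles and dropping
samples with fewer than 10 assigned reads in either set, the mean
sample-wise Bray–Curtis dissimilarity and Pearson correlation (over the
union VT set; two identical flat profiles correlate 1 by convention,
and profiles with zero variance on one side only are excluded from the
mean).

# The synthetic-data generator

The generator exists so that every stage — including the aligner-facing
ones — can be tested against known truth without downloads.

* **Reference**: `make_reference()` draws random sequences and verifies
  by exhaustive pairwise comparison that identities stay below
  100 − divergence (default 10%), so 97%-identity assignment is
  unambiguous whenever read error rates are small relative to the
  divergence. It is a synthetic stand-in carrying no biological signal.
* **Design**: three plots at the corners of a 40-m triangle (plot edges
  ~30 m apart, largest pairwise sample distance ≈ 54 m), 3 × 3 grids at
  5-m spacing; plot A sampled on four dates (2009-05-25 to 2009-09-03),
  plots B and C on the final date. The between-plot geometry is a
  package convention — the motivating sampling design does not pin it
  down numerically.
* **Communities**: per-VT log-abundance scores = baseline (normal, SD
  1.3, giving a realistic dominance structure and per-sample richness
  near 5–9 of 37 VT) + plot shift + date shift + a spatially
  autocorrelated Gaussian field. Plot shift vectors have a *fixed*
  root-mean-square magnitude (`plot_effect_size`, default 0.75) and
  random orientation, so the effective effect size does not fluctuate
  between seeds; date shifts default to zero (temporally stable
  communities). Scores are softmaxed and realised compositions drawn
  from a Dirichlet with concentration θ = 4 (strong compositional
  overdispersion, as in real amplicon data). Counts are multinomial at
  a log-uniform depth in [13, 1986]; ten samples per run instead draw
  < 10 reads, emulating failed libraries that the depth filter removes
  (54 collected → 44 retained).
* **Spatial field calibration**: the field uses a Gaussian correlation
  with 20-m range; its SD is `sqrt(-beta * kappa)` with kappa = 39,
  fixed once by simulating across field SDs (plot effect off) and
  regressing fitted final-date decay slopes on SD². With the field
  alone, the expected fitted logit slope ≈ `spatial_decay_beta`. At the
  defaults the plot structure itself already induces most of the
  observed decay (plots are located in space), so the default field is
  weak (β = −0.002); the default configuration yields fitted September
  slopes around −0.015 and a plot R² near 0.21.
* **Reads**: barcode + NS31 + a 5′ prefix of the template, length from
  a truncated normal (median 382, clamped to [170, 557] and to the
  template length), substitution errors at `error_rate` (default 0).
  Non-target reads (the 1 − 0.058 complement of the library) come from
  a decoy pool of shuffled reference sequences — guaranteed far below
  any assignment threshold without modelling non-target biology.
* **Hits**: each read is compared ungapped from its 5′ end against the
  same-length prefix of every reference; identity is the exact mismatch
  fraction. The score surrogate is fixed and documented —
  bitscore = 2L(identity/100 − 0.25), e-value = 1e9·2^(−bitscore) —
  monotone in length and identity; tests depend only on thresholded
  behaviour, never on its absolute scale.

With error rate 0 the whole pipeline reproduces the generator's truth
table exactly (demultiplexing, assignment and the count matrix), and
with a 2% error rate against 10% reference divergence assignment
accuracy stays above 99%; both are asserted in the tests.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: 454 homopolymer indel errors (only
substitutions are simulated; real identity distributions are wider),
chimeras (excluded by design: full-length closed-reference matching
makes them unlikely to pass), PCR amplification bias, phylogenetic
structure among references (divergence is uniform, whereas real VT form
clusters near the 97% boundary), and database incompleteness (every
simulated AMF read has a true reference). Conclusions about those
failure modes require real data.

# Numerical and design choices

* Permutation p-values use (1 + b)/(1 + B): never zero, exact under the
  null.
* A single seeded RNG stream drives each analysis invocation; the
  orchestrator derives distinct sub-seeds per stage from its `seed`
  argument, and every randomised result records its seed.
* The PCoA eigendecomposition drops eigenvalues within 1e-8·max|λ| of
  zero; the Gaussian-field Cholesky adds a 1e-8 ridge because repeated
  grid coordinates across dates make the correlation matrix singular
  (by design: the field is persistent at a grid point across the
  season).
* Bray–Curtis is computed as Manhattan distance divided by paired row
  sums, which is exactly the elementwise formula but lets the thinning
  study reuse optimised distance code; similarities 1 ± 1e-16 from
  floating point are snapped into [0, 1] before the logit.
* Problem sizes: tests and the acceptance script use the study-scale
  matrix (54 → 44 samples, 37 VT), 999 permutations for headline tests,
  1000 thinned matrices at 199 permutations, 500-replicate null
  calibrations at 99 permutations, and a read-level demonstration at
  reduced per-sample depths (13–60 assigned reads) with the full 5.8%
  AMF read fraction — sizes chosen so the whole suite re-runs in
  minutes on a laptop while keeping every statistical check at its
  intended resolution.

# Known limitations

* The artifact consumes tabular hits; criteria are only as meaningful
  as the aligner and reference that produced them, and closed-reference
  assignment is blind to taxa absent from the reference.
* Free permutation in the two-factor seasonal model ignores the
  repeated-measures structure of the revisited plot; with a strong
  within-plot sample effect the Season test can be mildly conservative.
  The within-plot factor is fitted precisely to absorb that structure,
  and the null calibration in the tests covers the exchangeable case.
* The decay model treats pairs as observations for fitting; only the
  permutation p is valid inference, and the OLS confidence interval is
  calibrated only under independent pair noise (as in the simulation
  check), not under the shared-sample dependence of real pair sets.
* The spatial-field calibration constant is empirical, valid around the
  default design geometry; radically different layouts should recheck
  it with `fit_decay()` on generator output.
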