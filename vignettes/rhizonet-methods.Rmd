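---
title: "Methods and design choices in rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`rhizonet` studies microbial adaptation along the bulk-soil /
rhizosphere gradient from ASV count tables. This vignette explains the
statistical machinery, the defaults and why they were chosen, what the
synthetic generators do and do not emulate, and the numerical decisions
a maintainer would want spelled out.

## Data model and filtering

An `asv_table` is a samples-by-ASVs integer matrix with per-sample
metadata (compartment, host family, kingdom) and a seven-rank taxonomy
per ASV. Filtering proceeds in a fixed order: rarefaction, rare-ASV
removal, then the abundance filter. The literature this workflow comes
from does not pin the order of the last two steps relative to
rarefaction; we rarefy first so that occurrence frequencies and mean
relative abundances are computed on depth-standardised libraries, which
makes the thresholds comparable across samples.

* **Rarefaction** subsamples each library without replacement
  (hypergeometric), the same semantics as QIIME 2's even resampling;
  libraries below the target depth are dropped. Defaults: 7000 reads
  for bacterial libraries, 4000 for fungal ones — conventional depths
  for soil 16S/ITS surveys. Deterministic given a seed.
* **Rare-ASV removal** discards singletons (total count 1) and ASVs
  seen in a single sample, the usual guard against spurious sequence
  variants. The operation is idempotent.
* **Abundance filter**: mean relative abundance strictly greater than
  `1e-4` *and* occurrence frequency strictly greater than 0.15
  (bacteria) or 0.10 (fungi). Both inequalities are strict; occurrence
  counts any nonzero count, with no minimum-count refinement.

## Niche divergence

Proportionality is the association measure of choice for compositional
data: Pearson or Spearman correlations of relative abundances can
invert the sign of the association present in absolute abundances.
We compute `rho = 1 - var(a - b)/(var(a) + var(b))` on clr-transformed
counts, where `clr(x)_i = log(x_i + 0.5) - mean_j log(x_j + 0.5)`.
The 0.5 pseudocount is a conventional choice for sequencing counts
with structural zeros; because `a - b` is invariant to the per-sample
clr centring, rho inherits the scale-invariance that makes it
meaningful on relative data. Rho is computed across *all* samples
(both compartments jointly): niche similarity is meant to span the
habitat gradient, and restricting to one compartment would remove the
very variation the parameter summarises.

Nucleotide divergence uses the K80 model,
`d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` substitutions/site, with
pairwise deletion of alignment columns containing a gap or `N` in
either sequence (the alignment dialect of the upstream tools is not
fixed, and pairwise deletion wastes the least signal). When the
observed divergence exceeds what the model can invert
(`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance is undefined; we
return `NA` and exclude the pair downstream rather than fabricating a
capped value.

Pairs are formed within genera only, restricted to `d < d_max = 0.5`:
beyond that window two amplicons rarely describe ecologically
comparable organisms, and empirical within-genus distance
distributions usually show a gap near there. The per-genus trend is an
ordinary least-squares fit of rho on distance with a two-sided t-test
on the slope. We label a genus `differentiation` only when the slope
is significantly negative **and** `R² >= r2_min` (default 0.1,
configurable); a significant slope explaining almost no variance is
reported `inconclusive` instead — fitting a line through a shapeless
cloud should not produce a biological claim.

## Functional redundancy

For function `f` with carrier set `S_f` (trait present and abundance
positive), `FRI_f = sum_{i,k in S_f} p_i p_k d*_ik`, where `d*` equals
the pairwise distance off the diagonal and the community's smallest
nonzero distance on the diagonal. The diagonal floor makes a
single-carrier function small (`p_i^2 d_min`) but not zero — "low
redundancy", distinct from the exact zero reserved for absent
functions. Dividing by the same sum over *all* ASV pairs gives `rFRI`
in `[0, 1]` (1 when every member carries the function); dividing by a
fixed reference distance `d_ref` gives `aFRI`, comparable across
communities that share the reference. The pipeline uses the mean
pairwise K80 distance of the analysed ASV set as `d_ref`; any shared
constant only rescales aFRI, so cross-community *rankings* do not
depend on it. Saturated (undefined) distances entering the FRI
distance matrix are capped at the largest observed distance — they sit
beyond the metric's range and only need to register as "far".

The exact functional form of redundancy indices attached to
16S-based function prediction is not published; ours is a declared
surrogate engineered to satisfy the properties those indices are
described by: zero iff absent, low for single carriers or tight
clades, high for abundant and phylogenetically spread carriers,
community normalisation reaching 1 for universal functions.

Compartment contrasts: `log((aFRI_rhizo + 1e-6)/(aFRI_bulk + 1e-6))`
per function (antisymmetric by construction), and per-function
Wilcoxon rank-sum tests on sample-level KO abundances with
Benjamini–Hochberg adjustment, significance at `q < 0.05`.

## Co-occurrence networks

Spearman correlation (rank-based, robust to the monotone distortions
of compositional rendering; Pearson available by flag) with two-sided
p-values from the t approximation. Edges require `|r| >= r_min` and
`p < p_max = 0.001`; both signs of correlation qualify, with the sign
recorded on the edge.

The cutoff is chosen by the RMT transition: at each candidate cutoff
the thresholded matrix's eigenvalues are unfolded and the
nearest-neighbour spacing distribution is scored against the Poisson
law `exp(-s)` and the Wigner–Dyson (GOE) law
`(pi s/2) exp(-pi s^2/4)` by a chi-square over 12 equal bins on
`[0, 3]` plus a tail bin. The chosen threshold is the smallest grid
point where Poisson fits better than GOE *and* the Poisson chi-square
is below the 0.95 critical value. Numerical details: degenerate
eigenvalues are collapsed before unfolding (hard thresholding creates
large degenerate blocks whose zero spacings would otherwise swamp the
distribution); unfolding fits a cubic smoothing spline to the
eigenvalue-rank curve with `df = min(10, n/10)`, clips any negative
spacing to zero, and normalises spacings to unit mean; grid points
with fewer than 20 distinct eigenvalues are flagged unusable rather
than scored. If no grid point qualifies, the scan reports `NA` and
the pipeline falls back to the configured `r_min = 0.6`.

Modules come from fast-greedy modularity maximisation on the
unweighted graph — deterministic for a fixed graph, with isolated
nodes as their own modules. `Zi` is the z-score of a node's
within-module degree among its module's members (defined as 0 when
the module's spread is zero); `Pi = 1 - sum_s (k_is/k_i)^2` (0 for
isolated nodes), so `Pi < 1` always and an equal split over `m`
modules gives `1 - 1/m`. Role thresholds default to `Zi > 0.25`,
`Pi > 0.62`. The 0.25 value is deliberately lower than the 2.5
customary in the original role taxonomy for metabolic networks; both
appear in the microbial-network literature, the default here follows
the co-occurrence-network usage, and the thresholds are plain
arguments for anyone preferring the stricter convention.

Betweenness is the unnormalised sum over unordered node pairs
(endpoints excluded) of the fraction of shortest paths through the
node — on networks of a few hundred nodes this gives the magnitudes
(10²–10³) at which connector behaviour is usually discussed.
Closeness is the reciprocal of the *mean distance to reachable nodes
only*: the textbook `N - 1` denominator silently zeroes the measure on
any disconnected network, whereas restricting to the node's component
keeps the "how quickly can this node reach its neighbours" reading;
isolated nodes get 0 by convention. The average path length likewise
averages over connected pairs only, and is reported missing for an
edgeless graph.

## The synthetic scenario

The generators are pure functions of a `scenario_config` (identical
seeds give byte-identical outputs, including written files). The
default scenario is desk-scale: 60 samples per compartment at depth
7500 (so the standard 7000-read rarefaction actively subsamples), 12
genera of 8 ASVs with 1000-site sequences, 200 trait functions, and a
network scenario of 4 blocks of 30 nodes plus 2 fungal bridges
observed over 120 samples.

* **Sequences** evolve from a random root along a random bifurcating
  tree per genus under a K80 process with transition bias
  `kappa = 2`, branch lengths rescaled so the mean pairwise distance
  equals `distance_scale = 0.2` — placing most within-genus pairs
  inside the 0.5 window with some beyond it.
* **Counts** come from a Gaussian copula: latent log-abundances are
  multivariate normal with within-genus correlation following the
  planted line `rho0 + beta * d` (`0.9 - 0.5 d` by default) on the
  true tree distances, repaired to the nearest positive semidefinite
  correlation by eigenvalue clipping with the unit diagonal restored,
  then rendered as one multinomial draw per sample at the configured
  depth.
* **Compartment effects** multiply designated genera (a quarter of
  genera, alternating enrichment and depletion at |log2FC| = 2) in
  rhizosphere samples. Because a composition is closed, naively
  shifting some genera deflects the relative abundance of every other
  genus; the generator therefore weights the enriched and depleted
  genera's baseline masses so the planted shifts are mass-balanced
  (the depleted carriers hold `2^|lfc|` times the enriched carriers'
  baseline mass). With that balance the background genera stay null
  and the planted fold changes land at their nominal values on the
  relative-abundance scale — the scale on which `differential_genera`
  measures them.
* **Traits** evolve as a symmetric binary gain/loss Markov process
  along the genus trees (rate 1 per unit branch length), giving
  phylogenetically conserved functions, plus two marker functions
  with a redundancy ordering guaranteed by construction (carried by
  everyone vs by the two closest ASVs of one genus).
* **The network scenario** drives each block's nodes from a shared
  latent factor (within-block correlation 0.7, between-block 0.2);
  bridge nodes load evenly on several blocks with loadings sized so
  their correlation into each spanned block is comparable to the
  within-block level. Bridges carry the fungal label; regular nodes
  are bacterial — the planted form of the "fungi as cross-module
  intermediaries" signal.

What the generators do **not** emulate: read-level error (no FASTQ,
chimeras, or denoising artefacts), taxonomic mis-assignment,
overdispersion beyond the copula (no Dirichlet-multinomial extra
variance by default), varying library sizes, spatial or temporal
autocorrelation between samples, and genuine trait-to-abundance
coupling. Passing tests therefore demonstrate that the estimators
recover the structures they target under clean compositional noise,
not that any particular field system behaves this way.

## Accuracy of end-to-end recovery

Two recovery regimes are worth distinguishing. Fitting the
niche-divergence regression on *pair records with direct noise*
(distances exact, rho = planted line + N(0, 0.05)) recovers the
planted slope inside its own 95% CI at the nominal rate. Fitting it
*through the whole measurement chain* — multinomial counts, clr,
plug-in rho, estimated K80 distances — attenuates the slope by
roughly 10% (errors-in-variables on the distance axis plus shrinkage
of the plug-in proportionality at finite depth), while the CI width
reflects only residual scatter; the tests therefore assert sign,
significance, and a magnitude band for the end-to-end fit rather than
strict CI coverage. This is a property of plug-in estimation at
finite sequencing depth, not of the implementation.

## Problem sizes in the test suite

The suite exercises: 500 random vector pairs for the rho identity and
100 random alignments against an independent K80 reference
implementation (1e-9 agreement); 200 random graphs of up to 10 nodes
against brute-force shortest-path enumeration for betweenness and
closeness (exact agreement); 50-seed recovery studies for the planted
slope (-0.5, 60 pairs, noise 0.05) and its null; 20-seed studies for
the RMT cutoff on the 4-block scenario and for differential-genus
recovery at 30 samples/side; 200-replicate uniformity checks for the
ANOSIM permutation null; and byte-level determinism of two full
pipeline runs. The full suite runs in well under a minute on one
core.

## Known limitations

* Rho is computed with a fixed clr reference and a fixed pseudocount;
  alternative log-ratio references (e.g. per-genus ALR) may shift
  per-genus slopes.
* The RMT scan needs enough distinct eigenvalues (matrix dimension
  >= 30, >= 20 distinct eigenvalues per grid point) to be meaningful;
  very sparse networks exhaust the usable grid quickly.
* The FRI surrogate is one member of the family of
  abundance-weighted spread indices; absolute values are not
  comparable to other software's indices, though orderings driven by
  carrier spread are.
* `differential_genera` tests genus-aggregated relative abundances
  with Welch t-tests on logs; strongly zero-inflated genera are
  better served by dedicated count models, which are out of scope
  here.
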