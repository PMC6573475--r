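---
title: "Methods: paternal population structure and scenario choice for a non-recombining locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paternal population structure and scenario choice for a non-recombining locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msyabc)
```

# Scope and data model

`msyabc` analyses one haploid, non-recombining, uniparentally inherited
locus — the MSY in the motivating use case, but nothing in the machinery
is Y-specific. The central container, `haplotype_alignment`, stores only
the polymorphic site columns plus the total surveyed length
`locus_length_bp`; monomorphic sites affect per-bp rates only, never the
statistics computed here, so carrying them would be waste. Sample ids are
unique, every sample maps to a population, and states are `A/C/G/T/N` or,
for simulator output, polarized `0/1` with per-site ancestral states.

Missing data have two policies. Haplotype collapsing and the AMOVA family
default to *complete deletion* (drop any column containing `N`), because
haplotype identity must be defined on a common site set — two sequences
that differ only in where they are missing should not become distinct
haplotypes. Mean pairwise differences may instead use *pairwise deletion*,
which wastes less data when missingness is scattered; the choice is
exposed everywhere it matters because the tools this package mirrors do
not document a single convention.

# Within-population statistics

Diversity uses Nei's unbiased estimator
$h = \frac{n}{n-1}\bigl(1-\sum_i p_i^2\bigr)$ for both haplotype and
haplogroup frequencies, so the two are directly comparable. MPD is the
mean of all $\binom{n}{2}$ pairwise difference counts, in units of sites.

Tajima's $D$ is computed from $S$ and $\pi$ counted **on the same site
set** (complete deletion), so numerator terms are internally consistent.
$S = 0$ yields a flagged undefined result, not an error: monomorphic
populations are a real outcome, and a hunter-gatherer isolate with no
variation must flow through a study-wide summary table without crashing
it.

Significance of $D$ comes from a simulated null rather than the beta
approximation: neutral constant-size coalescent genealogies with exactly
$S$ mutations placed multinomially on branches proportional to length.
Conditioning on $S$ removes the nuisance mutation-rate parameter; the
two-sided p-value uses the add-one correction $(b+1)/(n_{\text{sims}}+1)$
so a p of exactly 0 is impossible, which keeps downstream $-\log p$
summaries finite. The default 10,000 replicates is configurable; the
per-population replicate count used in a given run is recorded in the
run manifest.

# Between-population statistics

## AMOVA and Φ statistics

The nested analysis of molecular variance decomposes squared molecular
distances into among-group ($\sigma^2_a$), among-population-within-group
($\sigma^2_b$) and within-population ($\sigma^2_c$) components via the
classical moment estimators on sums of squared deviations. Two details
are deliberate:

* **Distance convention.** The input distance is the pairwise
  site-difference count $d_{ij}$; the sums of squares use $d_{ij}^2$ by
  default (`distance = "squared"`), with the plain count as an exposed
  alternative (`"plain"`, the convention in which the difference count is
  itself treated as a squared Euclidean distance). Which convention a
  given legacy analysis used is often undocumented; both are supported so
  either can be reproduced, and every Φ statistic in this package states
  its convention in the result object.
* **Negative components are kept.** Moment estimators can legitimately go
  negative when a stratum explains less variance than sampling noise
  predicts; truncating at zero would bias percentage tables, and real
  studies print negative percentages. Percentages are computed on the
  signed sum and must total 100 (enforced to 1e-9 in tests).

Permutation schemes follow the stratum being tested: individuals among
populations across all groups for $\sigma^2_c$; individuals among
populations *within* their group for $\sigma^2_b$; whole populations
among groups for $\sigma^2_a$. The degenerate design in which every
population is its own group leaves the among-population stratum empty;
$\sigma^2_b$ is then defined as zero rather than 0/0. Defaults are 10,000
permutations (Φst and AMOVA) and 9,999 (Mantel), always with the add-one
correction.

Pairwise Φst is exactly the two-population AMOVA (an identity that is
tested to 1e-12), and Nei's net divergence
$d_A = \pi_{XY} - (\pi_X + \pi_Y)/2$ is computed from the same pairwise
difference machinery. $d_A$ can be slightly negative for very similar
populations; this is normal and is not clamped.

## Mantel, MDS, rank contrasts

The Mantel statistic is the Pearson correlation over off-diagonal upper
triangles, with significance by jointly permuting row/column order of one
matrix. Geographic distances are haversine great circles on a sphere of
radius 6371.0088 km; resistance- or cost-based distances can be supplied
as plain matrices, since the test accepts any externally computed
distance matrix.

NMDS minimizes Kruskal stress-1 via monotone regression with iterative
majorization (the global-model engine of **vegan**), taking the best of
20 restarts (one classical-scaling start plus random starts), `k = 2` by
default because the ordinations such studies publish are planar. Φst can
be slightly negative; negative input distances are clamped to zero with a
warning since NMDS requires dissimilarities.

Mann–Whitney contrasts report the $U$ statistic, a tie-corrected normal
$Z$, and a two-sided p. The exact null distribution of $U$ is used when
$n_1 n_2 \le 400$ *and* there are no ties — with ties the exact
distribution is not well defined, so the tie-corrected normal
approximation is always used there. Fully tied data return $Z = 0$,
$p = 1$ rather than 0/0.

# The structured coalescent and its scenarios

The simulator is an event-driven structured Hudson coalescent: within
deme $d$ holding $k_d$ lineages, coalescence occurs at rate
$k_d(k_d-1)/(2N_d)$ per generation ($N_d$ = haploid effective size);
migration moves single lineages at per-lineage rate $m$; deme mergers
occur at fixed times. The three scenarios share an ancestral AA–DAI split
at `t_root_years`; TARGET originates at `t_target_years` from DAI
(demic, continuous-migration) or AA (cultural); continuous migration adds
symmetric TARGET↔AA migration active only more recently than the TARGET
origin.

Choices a user should know about:

* **Time units.** Mutation rates are quoted per bp per *year*
  (default $\mu = 8.71 \times 10^{-10}$) and split times in years, but
  the coalescent runs in generations; `generation_time_years` (default
  30) converts. The generation time is a genuinely uncertain quantity and
  is exposed prominently rather than buried.
* **One genealogy per replicate.** The locus does not recombine, so the
  full `locus_length_bp` (default 2,364,048 bp) evolves on a single
  genealogy and mutation counts are Poisson with mean (total branch
  length × $\mu g L$). Treating the length as independent loci would
  understate the variance of every summary statistic by orders of
  magnitude. A corollary is that a single replicate's SFS is very noisy:
  its classes reflect the one realized tree.
* **Ancestral sizes.** Branches inherit the size of their surviving deme:
  the root carries AA's size, the DAI-parent branch DAI's. Per-branch
  ancestral priors could be added, but absent documented values the
  inherited-size rule is the most parsimonious.
* **Default times** `t_target = 2000` and `t_root = 4500` years sit on
  the Bronze-Age scale relevant to mainland Southeast Asian language
  dispersals (a Neolithic-era root and a later target-population origin);
  both are ordinary arguments, not constants.
* **Default priors** $N_e \sim U(10^3, 10^5)$ per deme and
  $m \sim U(10^{-5}, 10^{-2})$ per generation span the plausible range
  for regional ethnolinguistic populations while keeping simulation cost
  bounded.

Summaries are the per-deme *unfolded* SFS vectors
$\xi_1..\xi_{n_d-1}$ (classes fixed within a deme contribute nothing)
concatenated, plus total $S$ — marginal spectra rather than a pooled or
joint spectrum, matching how per-population spectra are computed by SFS
utilities for multi-population samples. Observed data are subsampled
without replacement to the model's per-deme sample sizes so observed and
simulated summaries are exchangeable.

# ABC with random forests

Model choice trains a classification forest (default 500 trees) on the
reference table; the scenario with most tree votes at the observed
summary wins, ties broken by the canonical model order demic < cultural <
continuous-migration. The reported posterior probability is not the vote
fraction: a regression forest is trained on the indicator of out-of-bag
classification success and evaluated at the observed point, which
estimates $\Pr(\text{selected model is correct} \mid \text{summary})$.
The out-of-bag misclassification rate is reported as the prior error.
Parameter posteriors for the selected scenario come from per-parameter
quantile regression forests (point estimate = forest mean; 5/50/95%
quantiles from the weighted out-of-bag response distribution), with a
flatness diagnostic — posterior 5–95% width over prior 5–95% width —
because near-flat posteriors are the expected outcome when summaries
carry little information about a parameter.

## The separated-prior recovery regime

`abc_test_regime()` defines the design used for recovery experiments:
the three scenarios carry pairwise-disjoint size priors (demic
$U(10^3, 5{\times}10^3)$, continuous-migration $U(10^4, 3{\times}10^4)$,
cultural $U(5{\times}10^4, 10^5)$ on all demes), full-length locus,
10 samples per deme. This measures the machinery — simulator, summaries,
forests — against a known answer.

Why not separate by topology alone? At the default split times the three
topologies differ only in which deme TARGET's lineages occupy for roughly
80 generations out of a tree whose depth is set by ancestral deme sizes
in the thousands of generations; with a single non-recombining genealogy,
that signal is far below the between-replicate noise of the SFS, and a
classifier trained on topology-only tables performs near chance. That is
a property of the inference problem — visible in this package as an
indistinguishable-model control that yields chance-level out-of-bag error
— not a defect of the classifier, and it is consistent with the weak tree
votes such analyses report on real data. Parameter-recovery experiments
use a truth at the middle of its prior band; note that for
weakly informative summaries the forest mean regresses toward the prior
mean, so mid-prior recovery is a check of calibration, not of high
information content (the flatness diagnostic tells the two apart).

# The synthetic-data generator

`generate_study()` builds each language-family block as an independent
island model: the AA-like block has small demes (default $N_e = 2000$)
and little migration ($5 \times 10^{-4}$), giving low within-population
diversity and high among-population heterogeneity; the TK-like block is
the opposite ($N_e = 20000$, $m = 5 \times 10^{-3}$); the ST-like block
sits between. AA-like populations are labelled patrilocal and TK-like
matrilocal, so the residence contrast has a known construction direction
for a paternally inherited locus. The default desk-scale design — 12
populations (5+5+2), 15 samples each, a 50 kb locus — runs in seconds.

What the generator does *not* emulate: between-block gene flow (blocks
are independent genealogies, so between-block divergence is arbitrary and
block-private sites are ancestral elsewhere), within-branch growth or
bottlenecks, mutation-model heterogeneity, missing data, and haplogroup
nomenclature (labels are clades older than an age threshold, default
50 ka, named `HG1..HGk`). Tests passing on synthetic data therefore
validate the statistical machinery and the documented construction
contrasts — not any claim about real population history, where
isolation-by-distance, admixture and sampling artifacts add structure the
generator deliberately omits.

Randomness is governed by one design seed; per-block streams derive as
`derive_seed(design_seed, block_index)` (a fixed affine map into 32-bit
range), so any block can be regenerated in isolation and every truth
parameter is in the emitted manifest.

# Numerical and engineering choices

* Permutation and simulation p-values use the add-one correction
  throughout; reported p is never 0.
* Reproducibility: every stochastic function takes a seed and restores
  the caller's RNG state afterwards. Quantile forests additionally draw
  node values through R's RNG, so forest calls run inside the same
  seed-scoping wrapper — two calls with equal inputs are bit-identical.
* Batch rows are seeded `base_seed + i - 1`, so row $i$ is reproducible
  without regenerating the batch; keep base seeds below $2^{31}$.
* Degenerate inputs: $n < 2$ populations error in diversity statistics;
  populations with $n < 2$ are skipped (with warning) in Φst matrices
  and reported as undefined rows in summary tables; empty strata give
  defined zeros, not NaN; matrices that cannot support a statistic
  (constant Mantel input, unpolarized alignments for the SFS) error
  early with a named reason.
* Problem sizes in the shipped tests (e.g. 2,000 coalescent calibration
  replicates, 200 null datasets for p-value uniformity, 2,000-row/model
  reference tables with 100 pseudo-observed datasets per scenario, 500
  trees) were chosen so the full suite completes in a few minutes on one
  core while keeping Monte-Carlo error well below the tested tolerances.

# Known limitations

* No recombination, selection, growth, or more than three demes in the
  scenario models; no joint multidimensional SFS.
* The AMOVA family assumes the difference count is an adequate molecular
  distance; no substitution-model correction is applied.
* Mantel tests are offered because the field expects them; their known
  sensitivity to spatial autocorrelation is not corrected here.
* The summary vector is the concatenated marginal SFS; users can append
  pairwise $d_A$ between demes, but no linear-discriminant augmentation
  of summaries is provided.
* FASTA input assumes nucleotide states; polarized 0/1 data enter via
  site tables or the simulator API, not FASTA.
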