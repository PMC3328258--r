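---
title: "Methods: models, estimators and design choices in codonrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in codonrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonrates)
```

`codonrates` estimates and compares substitution rates and selective
pressure between two clades of protein-coding genes. This vignette is the
package's own account of its methods: the models and their assumptions,
the estimator conventions, what the synthetic-data generator does and does
not emulate, and the choices made where the design was genuinely open.
Every number quoted here is computed by the package's tests or by
`scripts/acceptance.R`; none is asserted from memory.

## The codon substitution model

All likelihood computations use a reversible Goldman–Yang-type model on
the 61 sense codons of the standard nuclear genetic code (stop codons TAA,
TAG, TGA carry no mass anywhere). The off-diagonal rate from codon $i$ to
$j$ is non-zero only for single-nucleotide changes and equals
$\pi_j$, $\kappa\pi_j$, $\omega\pi_j$ or $\omega\kappa\pi_j$ for
synonymous transversions, synonymous transitions, non-synonymous
transversions and non-synonymous transitions respectively. The matrix is
scaled so that $\sum_i \pi_i (-q_{ii}) = 1$: one unit of $t$ is one
expected substitution per codon. Because the chain is reversible
($\pi_i q_{ij} = \pi_j q_{ji}$, checked to $10^{-10}$ in the test suite),
transition probabilities come from an eigendecomposition of the
symmetrised matrix $D_\pi^{1/2} Q D_\pi^{-1/2}$, which is numerically
stable and exact.

Codon frequencies follow the F3x4 construction: position-specific
nucleotide frequencies, pooled over both sequences, multiplied across the
three codon positions and renormalised over sense codons. A nucleotide
unobserved at a position gives zero frequency to codons requiring it;
those codons are dropped from the state space for that pair (a uniform
alternative is available through `codon_freqs`).

### Pairwise maximum likelihood

`gy94_ml_estimate()` maximises
$\ell(t, \kappa, \omega) = \sum_{\text{columns}} \log\left[\pi_i P_{ij}(t)\right]$
over codon-column patterns. Optimisation is bounded quasi-Newton
(L-BFGS-B) in log-parameter space, with a convergence tolerance of about
$10^{-9}$ relative on the log-likelihood, starting from the Nei–Gojobori
total divergence with $\kappa = 2$, $\omega = 0.4$. Two further dispersed
starts run only when the first fails to converge or lands on a parameter
bound: across thousands of simulated fits the pairwise three-parameter
surface has shown a single interior optimum, and the test suite audits
local optimality of every reported MLE against a $5^3$ grid around it, so
unconditional multi-starting would triple the cost of the dominant
operation for no observed benefit. The likelihood kernel (rate-matrix
assembly, eigendecomposition, pattern sum) is compiled C++ (RcppArmadillo)
— the one hot loop in the package.

A fit whose maximiser sits on a parameter bound is not reported as a
valid estimate. $\hat\omega$ at its upper bound means the pair contains
no usable synonymous signal; such pairs get status `undefined_ratio`, the
same class as identical sequences and the analogue of the `98.99`
sentinel that pairwise codeml-style output prints when $dS \approx 0$
(an export shim writes that sentinel for compatibility).
$\hat t$ at the saturation ceiling or $\hat\kappa$ at a bound yields
status `failed`. Downstream saturation filtering drops both classes
first, with typed reasons.

From the MLE, per-site distances use the mutational-opportunity site
definition: with $\rho_S$ the synonymous fraction of substitution flow
$\sum_{i \ne j} \pi_i q_{ij}$ at $(\hat\kappa, \hat\omega)$ and
$\rho_S^1$ the same fraction recomputed at $\omega = 1$ ($\hat\kappa$
fixed),
$dS = t\,\rho_S / (3\rho_S^1)$ and $dN = t\,(1-\rho_S)/(3(1-\rho_S^1))$,
and $\omega = dN/dS$ exactly recovers the rate-ratio parameter.

### Nei–Gojobori counting

`ng86_estimate()` is the package's independent counting estimator and the
initialiser for the ML fit. Synonymous site counts enumerate the three
single-nucleotide neighbours of each codon position; changes to stop
codons are excluded from both the numerator and the denominator of the
per-position synonymous fraction. This convention keeps
$S + N = 3 \times$ codons exact and, more importantly, keeps the
estimator centred: counting stop-changes as non-synonymous inflates the
non-synonymous site budget by the stop-neighbour capacity and biases
$\hat\omega$ to about 0.94 under neutral simulation, which the test suite
would reject. Differences between codons are averaged with equal weight
over all shortest substitution pathways through sense codons (pathways
crossing a stop codon are excluded; in the rare case that every pathway
is blocked, the unrestricted set is used). Both proportions are corrected
with Jukes–Cantor $d = -\tfrac{3}{4}\log(1 - 4p/3)$; $p \ge 3/4$ is a
typed failure, not a number.

The two estimators use different synonymous-site definitions: NG86
implicitly assumes no transition/transversion bias, so at $\kappa = 2$
its $dS$ runs about 9% above the ML value even at low divergence. The
neutral-calibration test ($\omega = 1$ recovered within $\pm 0.05$)
therefore runs at $\kappa = 1$, where the counting model matches the
generator; at $\kappa = 2$ the check would measure the site-definition
gap rather than the estimator. The low-divergence concordance check
(ML vs counting within 20% at $dS \le 0.1$) runs at $\kappa = 2$ and
passes because 9% is within that band.

### 4-fold degenerate distance

A codon column contributes a 4D site iff both codons share their first
two positions and that prefix is a 4-fold degenerate family (any third
position encodes the same amino acid). The p-distance over qualifying
third positions is corrected with Kimura's 2-parameter formula using the
transition/transversion partition; $\kappa$ is a first-class parameter of
this package's model, so K2P is the default and Jukes–Cantor an option.
No qualifying column is a typed absence (`no_sites`), never $d4 = 0$. At
angiosperm-like divergence ($dS \gtrsim 2$) the K2P correction is
undefined for a substantial minority of genes; clade summaries of $d4$
therefore average over the genes where it is defined and report that
count (`n_d4`).

## From distances to absolute rates

Rates are $\mu = d/(2T)$ for a fossil-calibrated divergence time $T$
(years), assuming equal rates on both lineages; the reported range
evaluates the working distance at $T_{high}$ and $T_{low}$. When one
lineage is believed to evolve $\rho$ times faster,
$\mu_{slow} = d/((1+\rho)T)$ and $\mu_{fast} = \rho d/((1+\rho)T)$, which
conserves $(\mu_{slow}+\mu_{fast})T = d$ exactly (a property test draws
random $(d, T, \rho)$ and checks the identity to $10^{-12}$).

Clade summaries report the mean of per-gene $dN/dS$ ratios, not the ratio
of mean $dN$ over mean $dS$. The two differ whenever $\omega$ and $dS$
covary across genes — a distinguishing fixture in the test suite has
mean-of-ratios 0.5 against ratio-of-means 0.17 — and the mean-of-ratios
is the convention of published two-clade rate tables. Being a mean
of ratios, it carries a small upward noise inflation from genes with few
synonymous events; the simulator reproduces this honestly (a generative
clade mean of 0.31 is recovered as roughly 0.32–0.35 at 170-codon genes),
which is the same phenomenon visible in published tables where the
mean-of-ratios exceeds the ratio-of-means by ~20%.

Fold-change tables orient ratios numerator:denominator, label them
`x:1` (or `1:x` when the numerator is smaller) after half-even rounding
to one decimal, and compute rate folds from unrounded rates.
Bootstrap confidence intervals are percentile intervals over gene-level
resampling (1000 replicates by default, deterministic under a seed);
coverage of a known mean is verified to land in [93%, 97%] at nominal
95%.

## Saturation filters

`apply_filters()` drops genes in rule order — undefined-ratio/failed
status first, then $dS$ above the clade threshold, then $dN$ above its
guard — recording exactly one reason per gene. Defaults mirror the
two-clade design the package targets: $dS > 0.5$ for the low-divergence
clade; $dS > 4$ and $dN > 5$ for the high-divergence clade. The
thresholds are configuration, not inference: choosing them by inspecting
a $dN$-versus-$dS$ scatter is left to the analyst.

## Alignment and column filtering

Codon alignments are protein-guided: ORFs are translated, proteins
aligned globally with BLOSUM62 and affine gaps (open 11, extend 1,
configurable), and the alignment is mapped back onto codons so gaps occur
only in whole-codon units; back-mapping is byte-exact by construction and
by test. This global-alignment-plus-filter route replaces segment-based
anchor aligners: the downstream statistics need reliable gap-free
homologous codon columns, not anchor chains. Filtering drops all gap
columns and then gap-free runs of at most `min_run_codons` (default 3
codons ≈ 7–9 nt) flanked by gaps or ends — short aligned islands between
gaps are the codon-level reading of excluding short unreliable gap-free
segments; the literal complement (dropping *long* clean runs) would
discard all signal, so the package adopts the only operable reading and
exposes the threshold. Alignments with fewer than 30 codons after
filtering (30 amino acids) are discarded whole. Filtering is idempotent
and monotone in the run threshold (property tests).

## ORF discovery and the two selection strategies

`find_orfs()` enumerates maximal start-to-stop ORFs per frame (forward
strand by default — cDNA and EST-cluster inputs are oriented; reverse
frames behind a flag), with open-ended ORFs (missing ATG and/or stop at
run boundaries) enumerated only when requested. Two selection strategies
reflect two input qualities:

- **Full-length cDNAs**: the ORF owning the best similarity hit wins
  (lowest e-value, then higher bitscore, then longer, then leftmost);
  with no hit, the longest ORF is selected as fallback. A transcript with
  no ORF at all is a typed error.
- **Fragmented EST-cluster consensus**: the fragment may lack the true
  start and/or stop, so among open-ended ORFs in the same frame as the
  best reference hit, the one with the longest overlap with the hit
  interval is selected; equal overlaps prefer complete ORFs. No ORF in
  the hit frame is a typed absence and the fragment is excluded
  downstream.

On untruncated transcripts the two strategies select the same region when
the reference hit covers the true ORF (tested). Coordinates are 0-based
half-open internally and 1-based inclusive in written reports. Codons
containing N stay in coordinates but are excluded pairwise from all
substitution counting.

## Orthology

Reciprocal best hits: $(a, b)$ is a pair iff each is the other's unique
best hit at $e \le e_{max}$ (default $10^{-20}$), best = lowest e-value
then highest bitscore, multiple HSPs per ordered pair reduced to the best
first. Remaining exact ties are ambiguous and conservatively excluded —
the target is strict 1:1 orthology, and a tie between candidate partners
is evidence of recent paralogy. RBH output is symmetric under swapping
the directed hit lists and monotone in $e_{max}$ (property tests).

The built-in search is exact Smith–Waterman (BLOSUM62, affine gaps)
with Karlin–Altschul e-values from standard ungapped constants; scores
are verified against a plain DP oracle, but the e-values are approximate
and ingested BLAST tabular files are authoritative when supplied. Within
`run_pipeline()` the orthology method is per-clade: an RBH search suits a
low-divergence clade, while a high-divergence clade whose 1:1 set comes
from a curated comparative-genomics resource should be given as an
orthologue list — running a strict e-value RBH there preferentially
loses the fastest-evolving (high-$\omega$) pairs and would bias the
clade contrast.

## Functional-category tests

Annotation transfer copies the full term set of a gene's best reference
hit iff $e \le 10^{-5}$; unannotated genes simply drop out of category
tests. Genes with several terms contribute to each (standard practice for
flat term sets; no ontology-graph propagation — inputs are GO-slim-like).

Three statistics operate on per-gene values:

- **Between clades, per category**: two-sided Mann–Whitney U (exact
  $\le 20$ per clade, normal approximation with tie correction above),
  direction by median.
- **Across categories**: Kruskal–Wallis with tie correction.
- **Along the $\omega$ ranking**: genes are ranked descending (ties
  broken by id for determinism; genes with no non-synonymous
  substitution removed first). The segmentation test cuts the ranking at
  30 equally spaced rank quantiles and computes a Fisher exact test per
  (category, cut). Benjamini–Hochberg FDR is applied **jointly across the
  whole category-by-partition collection**, and each category reports its
  best cut. Treating the per-category minimum p as a single test and
  correcting only across categories was evaluated and rejected: under a
  full null (200 genes, 20 categories, 500 replicates) it produces a 30%
  any-false-positive rate, while the joint family keeps it at ~2%,
  within the package's calibration requirement of ≤ 7%. The logistic
  trend test models membership probability as a logistic function of rank
  percentile with a Wald test on the slope; under complete separation it
  falls back to the score test (well-defined under the null) and flags
  the row.

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
truth. It emulates, per clade: orthologous codon pairs diverged under the
GY94-type model (ancestral sequence from the stationary distribution,
each lineage evolved $t/2$ by exact matrix-exponential transition
probabilities — not event-by-event simulation, for reproducibility and
speed); cDNA wrappers with ATG/stop and ATG-free random UTRs so the
planted ORF is provably the longest; optional 5′ truncation emulating
EST fragments; paralog-like decoys for orthology stress tests; and
planted functional categories whose member genes have their $\omega$
multiplied, for enrichment round-trips. Every stochastic operation takes
an explicit seed and restores the global random state; a study is
byte-reproducible from its seed.

Default study conditions target a conifer-like clade (170-codon genes,
$\kappa = 2$, mean $dS$ 0.19, mean $\omega$ 0.31) against an
angiosperm-like clade (129-codon genes, mean body $dS$ 2.2 with 25% of
genes in a saturated tail above $dS = 4$, mean $\omega$ 0.09). Gene
lengths reflect typical average gap-free alignment lengths for such
clade pairs (510 and 387 nt). Two generator choices deserve
explanation:

- **Body-mean semantics.** With a saturated tail configured, `ds_mean`
  targets the mean of the estimable body below the threshold, because
  clade mean $dS$ in this kind of study is always reported *after*
  saturation filtering; an overall pre-filter mean of 2.2 with a 25%
  tail above 4 would force the body mean to ~1.45 and be inconsistent
  with the reported kept-set mean. The body is a gamma truncated below
  the threshold whose scale is calibrated by root finding; the tail is a
  shifted exponential entirely above the threshold, so an oracle filter's
  survivor fraction is $1 - $ `ds_tail_frac` by construction.
- **Dispersion.** No per-gene dispersion is published for these
  quantities, but gene-level bootstrap intervals pin the between-gene SD:
  a 95% CI half-width of 0.0025 on a mean $dS$ of 0.1908 over 3,723
  genes implies SD ≈ 0.078, CV ≈ 0.41, i.e. gamma shape ≈ 6 — the
  conifer-like default. Per-gene $\omega$ uses gamma shape 2 (CV 0.71),
  which reproduces both the observed fraction of $\hat\omega > 1$ genes
  (~2–3%) and the magnitude of the mean-of-ratios inflation seen in
  published tables. The angiosperm-like body keeps shape 2; its kept-set
  CV is dominated by truncation and the clade contrast is insensitive to
  it.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: no indels (alignment gaps in
tests come from engineered deletions, so the aligner's gap placement is
exercised but not realistic indel processes), no among-site rate
variation, no codon-usage-bias selection, no recombination, no chimeric
or mis-clustered EST consensus sequences, no genuine many-to-many
paralogy (decoys are single extra copies), and uniform codon frequencies
rather than clade-specific composition. Conclusions about estimator bias
transfer to real data only to the extent the GY94+F3x4 model does.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes while keeping Monte-Carlo error well inside the
asserted tolerances: 200 replicate pairs at 500 codons for parameter
recovery; a 300 + 300-gene study for the end-to-end fold-change contrast;
500 replicates for bootstrap-coverage and enrichment-calibration checks;
2,000–10,000 codons for stationarity and neutrality checks. All
stochastic entry points take explicit seeds; `run_pipeline()` derives all
stage randomness from the single config seed, and rerunning with the same
seed produces byte-identical per-gene estimate tables.

## Known limitations

- E-values of the built-in search use ungapped Karlin–Altschul constants;
  they rank hits correctly but are not calibrated against gapped search
  statistics.
- The ML optimiser treats each pair independently; there is no sharing of
  $\kappa$ across genes, matching pairwise `Runmode = -2`-style analyses
  but leaving per-gene $\hat\kappa$ noisy at short gene lengths.
- $d4$ saturates earlier than the model-based $dS$ because K2P has no
  codon context; at high divergence its clade mean covers only the genes
  where the correction is defined.
- Site-level and branch-site selection models are out of scope: with two
  sequences only gene-average $\omega$ is identifiable.
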