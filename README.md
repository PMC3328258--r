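# codonrates

Comparative molecular evolution between two clades of seed plants — or any
pair of clades with orthologous protein-coding genes. `codonrates` turns
coding sequences into per-gene evolutionary quantities and clade-level
contrasts: open-reading-frame discovery in full-length cDNAs and fragmented
EST clusters, reciprocal-best-hit (RBH) orthology, protein-guided codon
alignment with gap/short-run filtering, pairwise dN/dS by both
Nei–Gojobori counting and maximum likelihood under a Goldman–Yang codon
model, distances at 4-fold degenerate (4D) sites, absolute substitution
rates calibrated with fossil divergence times, fold-change tables,
gene-level bootstrap confidence intervals, and functional-category
selection tests.

It is written for analysts reproducing or extending two-clade substitution
rate studies — e.g. a slowly evolving conifer pair (spruce–pine-like,
low dS, elevated dN/dS) against a fast angiosperm pair
(*Arabidopsis*–poplar-like, partly saturated dS, low dN/dS) — and for
method development: a built-in simulator generates every input the
pipeline consumes with known generative truth, so each stage is testable
without downloads.

## The model

Per orthologous pair the package estimates, by maximum likelihood, the
parameters of a reversible 61-state Goldman–Yang codon substitution
model. Off-diagonal rates between codons *i*, *j* differing at one
nucleotide are

```
q_ij =  π_j          synonymous transversion
        κ π_j        synonymous transition
        ω π_j        non-synonymous transversion
        ω κ π_j      non-synonymous transition
```

with F3x4 codon frequencies π estimated from the data, zero rate for
multi-nucleotide changes, and Q scaled so one unit of branch length t is
one expected substitution per codon. From the MLE (t̂, κ̂, ω̂), per-site
distances follow the mutational-opportunity site definition:
dS = t·ρ_S/(3ρ_S¹) and dN = t·ρ_N/(3(1−ρ_S¹)), where ρ_S is the
synonymous fraction of substitution flow and ρ_S¹ the same fraction at
ω = 1. A Nei–Gojobori counting estimator (pathway-averaged differences,
Jukes–Cantor correction) serves as an independent cross-check, and d4 is
a Kimura 2-parameter distance on third positions of conserved 4-fold
degenerate codon families.

Clade contrasts are plain arithmetic on the filtered per-gene estimates:
absolute rates μ = d/(2T) for a fossil-calibrated divergence time T (with
a range over [T_low, T_high]), asymmetric-lineage apportionment
μ_slow = d/((1+ρ)T), μ_fast = ρd/((1+ρ)T), fold-change ratios, and
percentile bootstrap CIs over genes. Enrichment of functional categories
along the ω ranking uses Fisher exact tests over a collection of rank
partitions and a logistic trend test, with Benjamini–Hochberg FDR.

## Worked example

Simulate one orthologous codon-sequence pair under known truth
(t = 0.5 substitutions/codon, κ = 2, ω = 0.3), estimate its parameters
by ML, and compute the 4D distance:

```r
library(codonrates)

reg  <- sim_regime(n_codons = 300, t_codon = 0.5, kappa = 2, omega = 0.3, seed = 1)
pair <- simulate_codon_pair(reg)
tidy(gy94_ml_estimate(pair$a, pair$b, pair_id = "demo"))
#>   pair_id      t kappa  omega     dN     dS   lnL status
#> 1    demo 0.5056 1.311 0.3643 0.1164 0.3196 -1724     ok
d4_distance(pair$a, pair$b, pair_id = "demo")
#>   pair_id     d4 n4D n_diff status
#> 1    demo 0.3042 112     28     ok
```

The branch length is recovered almost exactly (t̂ = 0.51 vs 0.5); ω̂ and
κ̂ scatter around their truth at this gene length and tighten with more
codons (averaged over 200 replicates at 500 codons, mean ω̂ is within
±0.03 of 0.3). Converting a clade mean distance into an absolute rate —
here a conifer-like mean dS of 0.1908 with a spruce–pine divergence of
140 (range 120–160) million years:

```r
substitution_rate(0.1908, divergence_scenario(140, 120, 160), "synonymous")
#>   site_class      d        mu    mu_low  mu_high
#> 1 synonymous 0.1908 6.814e-10 5.962e-10 7.95e-10
```

i.e. μ_S = 0.68 × 10⁻⁹ substitutions per synonymous site per year, lying
between 0.60 and 0.80 × 10⁻⁹ over the fossil range. `run_pipeline()`
chains every stage (ORFs → orthology → alignment → estimation → filters →
rates → enrichment) for a synthetic study or for FASTA input, and writes
per-stage TSV reports.

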