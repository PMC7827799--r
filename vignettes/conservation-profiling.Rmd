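---
title: "Site-specific conservation profiling with conservscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific conservation profiling with conservscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conservscape)
```

## The model

`conservscape` estimates, for every column of a protein multiple sequence
alignment, how slowly that position has evolved, and turns the estimate into
the conservation scores, grades, region summaries, fingerprint calls and
structure colorings used in comparative studies of enzyme families such as
cytochrome P450 aromatase (CYP19A1).

The statistical core is an empirical-Bayes estimate of the relative
evolutionary rate of each site. Sites evolve independently along a shared
phylogeny under a time-reversible amino-acid substitution process with rate
matrix $Q$ (JTT exchangeabilities by default, calibrated to one expected
substitution per site per unit branch length) scaled per site by a relative
rate $r$. The prior on $r$ is a mean-one gamma distribution with shape
$\alpha$, discretized into $K$ equal-weight categories $r_1 < \dots < r_K$
(each category is the conditional mean of its quantile bin, so the category
means average exactly to 1). For column $i$ the likelihood $L_i(r_k)$ is
computed by Felsenstein's pruning algorithm with transition matrices
$P(t\,r_k) = e^{Q t r_k}$; gap and `X` characters are missing data
(all-ones partial vectors), and per-node rescaling keeps deep trees finite.
The reported raw rate is the posterior mean

$$\hat r_i \;=\; \frac{\sum_k r_k \, L_i(r_k)}{\sum_k L_i(r_k)},$$

and the shape $\alpha$ is fitted by maximizing
$\sum_i \log \frac1K \sum_k L_i(r_k)$ with a golden-section search on
$\log\alpha \in [\log 0.05, \log 10]$ (tolerance $10^{-3}$; an estimate
pinned at a bound is flagged, as happens for an alignment with no observed
variation).

Raw rates are z-normalized over all scored columns — mean exactly 0,
standard deviation exactly 1 — using the population (1/N) standard
deviation, because the normalization is a rescaling of the complete score
set rather than an estimate from a sample. Low score therefore means
conserved. For structure coloring, scores are binned into nine equal-count
quantile grades with 9 = most conserved; ties break toward the conserved
side, which is the conservative direction for "highly conserved" calls.

## The guide tree

The tree is built by neighbor joining on Kimura-corrected protein distances
$d = -\ln(1 - p - p^2/5)$, where $p$ is the mismatch fraction over mutually
non-gap columns; pairs beyond $p \ge 0.85$, where the correction is
undefined, are capped at $d = 5.2$ with a warning, and negative NJ branch
lengths are clamped to zero. Branch lengths are deliberately *not*
re-optimized by maximum likelihood: at the scale this package targets, NJ
lengths are accurate enough for rate *ranking*, which is what every
downstream consumer (grades, region percentages, fingerprints) uses.
Absolute posterior rates — and hence absolute score values for a given real
alignment — will differ from pipelines that re-fit branch lengths, so only
orderings and properties should be compared across tools.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 16 | gamma rate categories; 16 follows the convention of discrete-gamma rate estimation (8 is visibly coarser, 32 changes third decimals) |
| `alpha` | `"estimate"` | gamma shape; fixed values bypass the ML fit |
| model | JTT | any exchangeability table in the same layout (WAG, LG) can be passed to `subst_model()` |
| `conserved_grade` | 8 | grades counted as "conserved" in region percentages (top two of nine); a required, logged analysis choice |
| `tau_c`, `tau_v` | −0.5, 0.0 | fingerprint thresholds on the normalized score scale |
| `offset` | 1 | first residue number of the reference row, absorbing construct-vs-full-length numbering differences |
| default branch length | 0.1 | substitutions/site for Newick edges without lengths, keeping likelihoods finite |

Every default that an analysis resolves is written to `run.log` by
`run_pipeline()`; none is silent.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates the package's ground-truth fixtures: a
pure-birth (Yule) topology with exponential(mean 0.1) branch lengths, clade
labels laid over the leaves in traversal-order blocks with the class
proportions of the aromatase dataset (mammal : bird : reptile : amphibian :
fish : invertebrate = 66 : 8 : 12 : 18 : 259 : 2, rescaled), sites evolved
independently at known rates from the stationary distribution down the
tree, and optional motif plants that overwrite exact residues in selected
clades *after* evolution, so planted truth is never entangled with
substitution noise.

The standard study conditions used throughout the tests are 60 taxa and 300
sites with designed two-rate truth (10% of sites at rate 0.1, the rest at
1.5) or gamma truth ($\alpha = 0.5$, typical of strong among-site rate
variation in protein families). These sizes keep a full scoring run in
seconds while leaving the rate signal realistically noisy.

The fingerprint experiment pairs two such alignments the way a
family-vs-superfamily comparison is structured: a conserved core present in
both (90 of 200 sites at rate 0.05, standing in for the shared P450 fold),
ten family-only conserved positions (rate 0.05 within the family, rate 2
across the superfamily), and a variable remainder (rate 2 in both). The
bimodal design matters: a position's z-score can only be compared against
thresholds if conserved and variable sites actually separate, which is also
true of the real alignments this mimics — within-family alignments of a
substrate-specific enzyme are strongly bimodal, while a site whose rate
equals the alignment-wide mean is undecidable by construction.

What the generator does **not** emulate: indels (alignments are gap-free,
so column = site and truth is unambiguous; gap handling is tested with
hand-made gapped fixtures), alignment error, heterotachy, codon-level
effects, database sampling bias (the real dataset is 71% fish), and
long-branch attraction in the guide tree. Passing tests therefore certify
the estimator and its plumbing, not robustness to misalignment or biased
taxon sampling.

## Numerical choices

* Transition matrices come from a symmetric eigendecomposition of
  $D^{1/2} Q D^{-1/2}$ (valid for any reversible $Q$); tiny negative
  entries are clamped and rows renormalized.
* Pruning rescales partial vectors by their column sums at every internal
  node, accumulating the log scale, so likelihoods of hundreds of taxa stay
  finite.
* All-gap columns carry no information: their raw rate is fixed at the
  prior mean 1, they are flagged, and they are excluded from normalization
  (which otherwise covers *all* residue columns).
* A zero-variance rate vector (e.g. an alignment of identical sequences)
  is a refused input for normalization, not silently zeroed.
* Region percentages are reported to one decimal, round-half-up, the style
  used in the literature this supports (e.g. 69.7%, 15.4%).
* Consensus residues are the modal state with alphabetical tie-break;
  motif scanning treats sequence `X` as matching nothing, so presence
  calls are conservative.
* Two-taxon guide "trees" place each leaf at half the pairwise distance,
  preserving the leaf-to-leaf path length.

## Open design points, resolved

* **SRS boundaries are not bundled.** The exact residue intervals of the
  six substrate recognition sites are annotation-dependent; shipping a
  default would silently impose one annotation. They are user-supplied
  region definitions; only the structural elements printed for human
  aromatase (helix A 65–78, helix E 187–205, helix I core 302–318, …) ship
  as `aromatase_elements()`.
* **"Homology percent" is interpreted as BLOSUM62-positive pairs** over
  mutually non-gap columns. Any matrix with residue dimnames can be
  substituted.
* **Kinase-consensus anchoring uses window mode**: a sequence is positive
  for PKA/PKG at 262–268 if any hit falls inside its own ungapped image of
  the reference window, rather than requiring the phospho-acceptor at one
  fixed position — the more faithful reading of how such consensi are
  tallied across a clade-stratified alignment.
* **Conservation cut-off for region percentages** is grade ≥ 8. The
  literature rarely states its cut-off; making it a required, logged
  parameter keeps reanalyses comparable.

## Known limitations

Scores are comparable *within* one alignment only (the z-scale is
per-alignment). NJ branch lengths bias absolute rates slightly toward the
prior; rankings are unaffected in the tested regimes. The alpha search is
bounded in $[0.05, 10]$; data preferring shapes outside that range are
flagged rather than extrapolated. PDB output carries two decimals of
B-factor, which limits painted-score precision to 0.01. Stockholm parsing
covers sequence lines only (HMMER output), not annotation markup.
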