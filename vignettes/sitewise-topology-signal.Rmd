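---
title: "Sitewise topology signal: model, statistic, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sitewise topology signal: model, statistic, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofilter)
```

## The problem

Deep nodes of the animal tree — most prominently whether ctenophores or
sponges are the sister group of all other animals — are decided by
concatenated protein supermatrices in which the overwhelming majority of
alignment columns carry essentially no information about the contested
node. The question this package operationalizes is: *which individual
sites carry that information, how much of it is there, and what happens
to the inferred topology when a small, topology-targeted subset of those
sites is removed?*

The workflow is a fixed-candidate-topology design. The contested node is a
four-branch resolution problem: two focal clades (call them A and B), the
remaining ingroup C, and the outgroup O admit three binary resolutions,

* **T1** — A sister to everything else (the split {B,C} | {A,O}),
* **T2** — B sister to everything else (the split {A,C} | {B,O}),
* **T3** — A and B as sisters (the split {A,B} | {C,O}),

which are pairwise Robinson-Foulds distance 2 apart (they differ in
exactly one bipartition each).

## Model

Per-site log-likelihoods are computed under LG+F+Γ:

* **LG** empirical amino-acid exchangeabilities $s_{ij}$ (Le & Gascuel
  2008), embedded as a plain-text constant table;
* **+F** stationary frequencies $\pi$ estimated by counting residues over
  all non-missing cells (pseudocount 0.5 per residue class so no
  frequency is exactly zero, which would break the reversibility
  scaling), or optionally the published LG frequencies;
* **+Γ** among-site rate variation with a mean-one discrete Gamma: $k=4$
  equal-probability bands, each represented by its conditional mean rate.

The rate matrix is $Q_{ij} = s_{ij}\pi_j$, scaled so the expected rate
$-\sum_i \pi_i Q_{ii} = 1$; branch lengths are therefore expected
substitutions per site. Because $\mathrm{diag}(\pi)\,Q$ is symmetric,
$P(t) = e^{Qt}$ comes from one symmetric eigendecomposition per model.
Gaps and the ambiguity codes X/B/Z/J/?/* are one missing class whose
partial-likelihood vector is all ones.

Site likelihoods use Felsenstein pruning with per-node rescaling of the
conditional-likelihood vectors (accumulated in log space), which keeps
76-taxon-deep products inside double precision. Site patterns are
compressed to unique columns with weights for all likelihood work and
re-expanded for per-site output, so compression never changes results.

## Per-topology optimization

Mirroring a per-site likelihood evaluation run in standard ML software,
each candidate topology is evaluated *at its own optimum*: branch lengths
and the Gamma shape are optimized independently per topology before
per-site values are emitted (`per_site_table()`), and both totals are
recorded. Optimization is exact coordinate ascent: a depth-first pass
over branches, each solved by Brent's method on the log scale against
cached flanking conditional likelihoods, followed by a one-dimensional
shape optimization, repeated until the total improves by less than
`tol = 1e-4` lnL units (at most 50 sweeps; a warning reports
non-convergence). Two numerical details matter:

* Branch lengths are bounded to $[10^{-8}, 50]$; the lower bound is more
  than three orders of magnitude below the 0.5 dlnL signal scale.
* The one-dimensional search starts from a ×10 window around the current
  value and expands toward a bound only when the optimum lands on the
  window edge. A blind search over the whole $[10^{-8}, 50]$ range can
  step across narrow interior optima, which manifests as premature
  convergence.

Every accepted move must improve the cached objective, so the total
log-likelihood never decreases across sweeps; a re-run from the returned
optimum changes the total by less than the tolerance.

## The strength statistic

For each site with per-topology log-likelihoods $\ell_1,\ell_2,\ell_3$,
the strength is

$$\mathrm{dlnL} = \ell_{(1)} - \ell_{(2)},$$

the best value minus the second best — a non-negative number that is zero
exactly when the top two topologies tie. A site is **strong** when
$\mathrm{dlnL} \ge 0.5$ (threshold inclusive); ties are never strong, and
the tie is recorded so no information is lost. The alternative statistic
used by earlier work — the mean of the absolute pairwise differences
involving each topology — is provided for comparison (`shen_strength()`);
for the best topology it is never smaller than dlnL and it inflates the
apparent strength of sites where one topology is merely much *worse* than
the other two, which is precisely why the gap statistic is preferred.

Filtering (`select_removals()` + `apply_filter()`) removes strong sites
whose best topology lies in a chosen *favored set*, leaving strong sites
of the other topologies untouched, and `evaluate_flip()` re-optimizes
every candidate on the filtered matrix to see whether the winner changes.
By default this re-optimizes branch lengths and shape on each matrix
(mirroring re-inference); a fixed-parameter mode evaluates both matrices
with unchanged parameters, which makes repeated filtering exactly
idempotent and is the mode used for idempotence tests.

## What the synthetic generator emulates — and what it does not

Real supermatrices for this problem are not redistributable inputs for a
test suite, so validation runs on simulated matrices with the signal
structure the analysis assumes: ~98% of sites carrying essentially no
information about the contested node, and small planted minorities
carrying strong signal for each resolution.

`mixture_spec()` defaults define the package's reference conditions:

| parameter | default | meaning |
|---|---|---|
| clade sizes | A=3, B=3, C=4, O=2 | 12 taxa around the contested edge |
| proportions | 1%, 0.8%, 0.5% | sites simulated under T1, T2, T3 |
| contested branch | 0.5 | substitutions/site on signal sites |
| star branch | 1e-6 | contested edge for background sites |
| background branches | Exp(mean 0.05) | drawn once, shared across T1/T2/T3 |
| n_sites, seed | 20,000, 42 | matrix size and RNG stream |

The proportions, contested-branch length, star-branch length, matrix
size, seed and the exponential background mean are the reference
conditions stated with the design; the clade sizes were chosen once to
give a 12-taxon matrix with both multi-taxon focal clades and a
multi-taxon outgroup, and the simulation Gamma shape is 1 (a moderate,
typical amount of protein rate heterogeneity). The three topologies share
every branch length except the contested edge, so planted signal is the
*only* systematic difference between them. Sites are simulated forward
(root state from $\pi$, one Gamma category per site, states propagated
edge by edge), concatenated, and shuffled; ground-truth labels travel
with the shuffle. A single RNG stream seeded from `seed` covers, in
order: topology branch lengths, per-site categories and states per block
(T1, T2, T3, star), and the shuffle — so equal seeds give bit-identical
matrices.

What the generator does **not** emulate: missing data patterns (real
matrices are 40–60% gaps; simulated ones are fully occupied),
lineage-specific process shifts (heteropecilly), indels, and
non-stationary composition. Passing tests therefore demonstrate that the
statistic, the filtering rule and the flip phenomenon behave correctly
when the model matches the data; they do not certify behavior under the
model violations present in real supermatrices.

On the reference mixture the pipeline reproduces the headline phenomenon
in miniature: T1 (the majority-signal resolution) wins on the full
matrix; removing strong sites favoring T1 or T2 — under 3% of sites —
flips the winner to T3; removing only T3-favoring strong sites leaves T1
in place. The suite also checks that the realized strength distribution
matches the design (fraction of near-zero sites within ±0.02 of the
planted weak fraction; the 0.5 threshold landing 2–4 standard deviations
above the mean) and that ≥90% of planted sites with realized
dlnL ≥ 0.5 are attributed to their generating topology.

## Numerical and design choices

* **Coordinates**: all site indices are 1-based inclusive in files and
  reports (matching the partition-file convention); internal storage is
  0-based only transiently inside pattern compression.
* **Missing branch lengths** on input trees default to 0.1 with a
  warning: candidate topologies are often supplied as cladograms and
  branch lengths are re-optimized anyway.
* **Tie-breaking**: the best topology of a tied site is the first in
  input order, the tie is flagged, and tied sites are never strong
  (dlnL = 0 is below any positive threshold; at threshold 0 ties are
  excluded explicitly).
* **Empty results are refused**: filtering every site, or writing an
  empty alignment, is an error rather than a silent degenerate output.
* **Per-site files**: the plain-text dialect (`read_persite()` /
  `write_persite()`) has a `<n_trees> <n_sites>` header and one
  labelled row per tree, so externally computed tables can replace the
  internal engine (`run_config(persite = ...)`) and the filtering
  stages interoperate with other tools.
* **Problem sizes in the suite**: oracle-equivalence tests run hundreds
  of sites against brute-force enumeration on ≤4-leaf trees; conservation
  sums cover all 400 two-taxon and 8,000 three-taxon patterns; the
  mixture checks run once at the full 12 × 20,000 reference size and are
  shared across test blocks.

## Known limitations

* Exactly one contested node per run; nested or multiple contested edges
  are out of scope.
* Amino-acid data only, LG exchangeabilities only (the constant table is
  pluggable in principle, but WAG/JTT are not shipped).
* No invariant-sites category; no tree search — the package compares
  *fixed* candidate topologies, it does not find trees.
* `shen_strength()` is defined only for the three-topology design.
* Bootstrap/posterior support of the re-inferred trees is out of scope;
  `evaluate_flip()` reports optimized totals and margins instead.
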