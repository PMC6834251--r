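---
title: "Methods: mixed-model GWAS of root growth under nutrient deficiencies"
author: "nutriGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model GWAS of root growth under nutrient deficiencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

nutriGWAS analyses primary-root growth of a panel of fully inbred plant
accessions (naturally occurring *Arabidopsis thaliana* lines) grown on a
control medium (Ct) and on nutrient-deficient media: -P, -Fe, -Zn and the
combined deficiencies -P-Fe and -P-Zn. The chain is:

1. **Growth-rate estimation.** Primary root length is measured on 3-, 4- and
   5-day-old seedlings, twelve replicate seedlings per accession and medium.
   The root growth rate (RGR, mm/day) of each (accession, condition) cell is
   the slope of one pooled ordinary-least-squares regression of length on
   age over all replicates.
2. **Trait construction.** Because accessions differ in germination and
   intrinsic vigor, GWAS is run on *normalized* RGR — the deficiency RGR
   divided by the same accession's control RGR — and on *delta* traits that
   isolate the interaction between a combined and a single deficiency, e.g.
   `deltaRGR(-P-Fe,-Fe) = RGRnorm(-P-Fe/Ct) - RGRnorm(-Fe/Ct)`.
3. **Mixed-model association.** Each trait is scanned with a linear mixed
   model that corrects for population structure through a kinship matrix
   computed from all common markers under the infinitesimal model.
4. **Downstream interpretation.** Significant markers are merged into
   genomic regions, mapped to candidate genes through fixed 10-kb windows,
   compared across traits (Venn counts and a cross-trait overlap test), and
   projected onto a weighted gene co-function network to extract connected
   candidate modules, which are tested for annotation-term enrichment.

Every step is exercised end-to-end on synthetic data with planted ground
truth; the real accession panel, genotypes and co-function network are not
shipped and are not required.

# Growth-rate estimation

For a cell with measurements $(d_i, \ell_i)$ the pooled OLS slope is
$\hat\beta = S_{d\ell}/S_{dd}$ with the usual centered sums; its standard
error and a two-sided $t$-test of $\beta = 0$ on $n-2$ df are reported.
Design choices:

* **Pooled regression, not per-replicate averaging.** All replicate points
  enter one fit. Per-replicate germination offsets (constant across days
  within a seedling) are *exactly orthogonal* to the slope on a balanced day
  grid, so they bias nothing — but they do inflate the pooled residual, so
  the nominal 95% confidence intervals become conservative under replicate
  offsets and are exact under iid measurement noise. The test suite checks
  both properties.
* **Degenerate cells.** A cell with fewer than two distinct days yields `NA`
  estimates and is flagged missing; it never aborts a run. Missing
  phenotypes are dropped, never imputed — the mixed model tolerates
  reduced n.
* **Ratio guard.** Normalization divides by the control slope; accessions
  whose control slope is below `minRefSlope` (default: 10% of the
  panel-median control slope) are dropped and recorded in the trait's
  provenance. Whether the original experimental analysis applied such a
  guard is unknown; it is exposed as a parameter rather than guessed, and
  the default only removes accessions whose ratio would be numerically
  meaningless.

# The mixed model

The null model is $y = X\beta + u + e$ with $u \sim N(0, V_G K)$ and
$e \sim N(0, V_E I)$; $X$ is an intercept by default (covariates can be
supplied). The kinship $K$ is the realized relationship matrix
$WW^\top/m$ over centered, SD-scaled dosage columns (markers at MAF
$\ge$ 5%), computed on the inbred haploid 0/1 coding — the panel consists of
fully inbred lines, so fictitious heterozygotes never appear. An
identity-by-state kinship is available as an alternative. $K$ is
symmetrized and, if needed, its diagonal is shifted by the smallest amount
that makes the minimum eigenvalue $\ge 10^{-8}$.

**REML by spectral profiling.** With $\delta = V_E/V_G$, the restricted
likelihood depends on $\delta$ only through the eigenvalues of $SKS$ (the
kinship projected off the fixed effects) and the rotated residuals, so one
eigendecomposition reduces REML to a 1-D optimization. The profile can be
multimodal; the implementation evaluates a 100-point log-spaced grid on
$\delta \in [10^{-5}, 10^5]$ and refines every grid-local maximum by bounded
optimization, returning the global optimum (the test suite asserts the
optimality certificate against the grid). Pseudo-heritability is
$H^2 = V_G/(V_G+V_E) = 1/(1+\delta)$, reported bit-consistently with the
stored components. REML is the default, matching the convention of
EMMA-lineage association software; ML is available behind a flag.

**EMMAX-style scan.** Variance components are estimated once on the null
model and $\hat V = V_G K + V_E I$ is held fixed for every marker
(the single-fit approximation of the EMMA family). Each marker is tested by
generalized least squares on the eigenbasis of $K$ (computed once,
reused for all markers), with an F statistic on $(1, n - q)$ df where $q$
counts all fixed effects including the marker. Exact per-marker
behaviour is covered by two oracles in the tests: a dense GLS
implementation that explicitly inverts $\hat V$, and the analytic
degeneration to ordinary least squares when $V_G = 0$ (the weights are then
exactly constant and the scan takes a dedicated OLS path, so the identity
holds to machine precision rather than approximately).

**Marker hygiene.** MAF is computed after aligning accessions to the trait;
the threshold is inclusive (`>= 0.05`, "at least 5%"). Monomorphic markers,
markers below the MAF threshold and markers with more than 20% missingness
are flagged untested (`NA` statistics) rather than dropped from the output
table; remaining missing dosages are mean-imputed. The Bonferroni threshold
is $\alpha$ divided by the number of markers actually tested.

**Diagnostics.** `genomicInflation()` reports $\lambda_{GC}$, the median
$\chi^2_1$-transformed p-value over its null median; `plotManhattan()` and
`plotQQ()` provide the standard visual checks.

# Candidate-gene mapping

"Genes within a 10-kb window around a significant marker" is read literally:
a gene is a candidate for a marker iff the gene body (1-based, closed
interval, GFF3/VCF convention) intersects the closed interval
$[pos - w, pos + w]$ with $w = 10\,000$ bp by default. Gene-body
intersection was chosen over TSS distance as the most literal reading; both
the window and the rule are configurable. Regions are formed by merging
marker windows that share at least one base, transitively — equivalently,
markers at most $2w$ apart join one region. Merely adjacent windows
(gap of one base) stay separate. LD-based windows are deliberately *not*
computed: the fixed-width rule is what the windowing convention describes,
and the synthetic genotypes carry no LD anyway (markers are drawn
independently). On disk, regions are exported as BED (0-based half-open);
everything internal is 1-based closed, with the conversion delegated to
`rtracklayer` and property-tested.

# Cross-trait overlap

Two traits' hit sets at a relaxed screening threshold
($-\log_{10} p \ge 4$, boundary inclusive) are compared against two nulls:

* **Analytic / random markers.** The observed overlap $k$ of sets of sizes
  $a, b$ in a universe of $M$ tested markers is referred to the
  hypergeometric upper tail $P(X \ge k)$, computed by direct log-space
  summation of binomial-coefficient terms (accurate deep into the tail);
  the resampling version redraws size-$b$ marker sets uniformly and uses the
  add-one rule $(1 + \#\{\text{overlap} \ge k\})/(1 + R)$, which cannot
  return zero — the floor $1/(R+1)$ is part of the reported metadata.
* **Phenotype permutation.** One shared accession-label permutation is
  applied to both traits per iteration (genotypes untouched, so genotype
  structure is preserved) and both scans are re-run. This is expensive and
  intended for small instances; the exact permutation scheme behind the
  original analysis is not documented anywhere, so both nulls are provided
  and labelled, and neither is claimed to reproduce any particular
  published p-value.

# Network modules and enrichment

Modules are the connected components of the subgraph induced by candidate
genes in the co-function network (edges with score $\ge$ `minScore`),
discarding components below `minSize = 3` — a single edge is not called a
module. Guilt-by-association expansion (adding non-candidate linker genes)
is deliberately not emulated: the module definition used here is "candidate
genes connected with one another", and whether the original web tool added
linker genes is not documented. Term enrichment uses the same log-space
hypergeometric upper tail with the background defaulting to all annotated
genes (configurable); raw p-values are primary, Benjamini–Hochberg q-values
are attached as a convenience.

# The synthetic-data generator

The generator emulates the study design: 227 accessions in `k`
subpopulations, six media, 12 replicates, days 3–5.

* **Genotypes.** Balding–Nichols structure: ancestral frequencies uniform on
  $[0.1, 0.9]$ (avoiding near-fixed markers), subpopulation frequencies
  $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, accessions assigned round-robin,
  haploid 0/1 dosages. A test recovers the $F_{st}$ knob with an
  independently coded Hudson estimator. No LD, recombination maps or
  sequence-level realism — deliberately out of scope.
* **Phenotypes.** True RGR = per-condition baseline + planted QTL effects +
  polygenic term + iid residual. The polygenic term is drawn through the
  symmetric square root of the kinship matrix and scaled so the requested
  condition-specific heritability holds exactly in expectation, which makes
  heritability-recovery tests well-posed. The realized variance
  decomposition is recorded and sums to the total by construction.
* **Lengths.** `max(0, offset + RGR*day + noise)` with per-replicate
  Gaussian germination offsets and iid Gaussian measurement noise. The
  linear-growth + Gaussian-noise model is an *assumption*: the noise
  structure of real plate measurements is not documented, so passing tests
  validate the machinery, not the realism of plate-level error.
* **Defaults** (chosen once, as plausible for early seedling roots, and used
  by the pipeline demo): baselines 2.5 (Ct), 2.8 (-P), 1.8 (-Fe), 2.0
  (-Zn), 2.4 (-P-Fe, -P-Zn) mm/day — P starvation mildly promotes early
  root growth, Fe/Zn starvation inhibits it, the combinations are
  alleviated; polygenic $h^2$ 0.8 (Ct) down to 0.1 (-Fe); residual SD 0.25
  mm/day; germination-offset SD 0.5 mm; measurement SD 0.4 mm. The default
  pipeline architecture plants nine QTLs on common markers (MAF $\ge$ 0.3):
  a P-response QTL, a Zn-response QTL, three -P-Fe-only and two -P-Zn-only
  interaction QTLs, and two interaction QTLs shared between the combined
  stresses; effect sizes (0.3–0.6 mm/day) were chosen so the planted
  architecture is detectable at the default panel size of 227 accessions.
* **Annotation, network, GO.** Equal-length genes tiled with fixed spacing
  (GFF3 round-trip safe); planted network modules are connected by a random
  spanning tree plus extra intra-module edges over an Erdős–Rényi
  background; a designated annotation term covers a chosen fraction of the
  planted module against a uniform background, so enrichment has a known
  answer.

# Validation designs and problem sizes

The statistical acceptance tests run at these sizes, chosen to make each
property measurable with comfortable margins:

* **GLS oracle equivalence**: 60 accessions × 500 markers against dense
  per-marker GLS (agreement to $10^{-6}$ in $\log_{10} p$); OLS limit at
  $V_G = 0$ to $10^{-8}$.
* **Structure correction**: 100 replicates of a two-subpopulation panel
  ($F_{st} = 0.1$, n = 200, m = 2000) with a *structured null* phenotype —
  a one-residual-SD subpopulation mean shift plus a polygenic background
  ($h^2 = 0.3$), no per-marker effects. Naive OLS inflates
  ($\lambda_{GC}$ median well above 1.2), the mixed model stays calibrated
  ($\lambda_{GC} \approx 1$, pooled type-I error at 5%). A purely polygenic
  null at moderate $h^2$ does not reliably push OLS $\lambda_{GC}$ past
  1.2 at this $F_{st}$; the mean-shift design is the textbook confounding
  scenario and realizes the phenomenon robustly.
* **Heritability recovery**: $h^2 \in \{0.2, 0.5, 0.8\}$, n = 300, 50 trait
  draws each on a fixed kinship; mean $\hat H^2$ within $\pm 0.1$.
* **G×E specificity**: 50 replicates at n = 227, m = 10 000. Because slope
  estimation is linear in the lengths, a planted effect $b$ on condition
  $c$ shifts the normalized trait by exactly $b\,g/\hat{R}_{Ct}$; the
  harness exploits this to size the interaction QTL to *exactly* 15% of the
  realized delta-trait variance (solving the share equation), and a
  shared-effect QTL to 15% of the normalized -P-Fe trait. The interaction
  QTL must reach the 5% Bonferroni threshold on the delta trait in
  $\ge$ 80% of runs; the shared QTL must stay below the
  $-\log_{10} p \ge 4$ screen on the delta trait in $\ge$ 90% of runs
  (it cancels identically) while clearing that screen in each
  single-condition scan in $\ge$ 80%.
* **Interval calibration**: 2000 cells; 95% CI coverage within $\pm 2$%
  under iid noise, conservative ($\ge$ 95%) with germination offsets.
* **Combinatorics**: hypergeometric tails against closed forms and
  enumeration to $10^{-12}$; region merging and window mapping against
  brute-force union-find / all-pairs scans on 1000 random configurations
  each; module extraction against a BFS oracle on 200 random graphs.
* **Overlap-null calibration**: 500 independence-null simulations with
  $M = 20\,000$, $|A| = |B| = 2000$, 999 resamples. The add-one empirical p
  is discrete; these sizes make the overlap statistic fine-grained enough
  (SD $\approx$ 13, maximal point mass $\approx$ 0.03) that a
  Kolmogorov–Smirnov test against U(0,1) at the 1% level is an appropriate
  check. Convergence of the empirical to the analytic p is verified at
  $10^5$ resamples within three Monte-Carlo SEs.
* **End-to-end**: the default pipeline (227 × 5000) runs its seven trait
  GWAS (five normalized, two delta) and reproduces every artifact
  bit-for-bit under a fixed seed.

# Numerical choices and degenerate inputs

* Eigendecomposition of $S(K+I)S$ minus the unit shift (steadier than
  $SKS$ directly); eigenvalues clipped at zero before profiling.
* p-values floored at the smallest positive double so reported values stay
  in $(0, 1]$.
* Collinear (post-weighting) markers, zero-variance traits, empty candidate
  sets, empty merges and zero-hit enrichment terms all take defined paths —
  flagged, errored with context, or reported at p = 1 as appropriate —
  and are unit-tested.
* All writers serialize doubles with 17 significant digits so every
  write/read round trip is bit-identical; the run manifest records the
  fanned-out per-stage seeds (counter scheme below $2^{31}$), input
  checksums and applied thresholds.

# Known limitations

* Growth is modelled as linear over days 3–5; nonlinear growth models and
  day-specific analyses are out of scope (the pooled slope is only an
  "ideal measurement" under near-linear growth).
* The synthetic genotypes carry no LD, so window-based mapping hits at most
  the genes physically near a causal marker; counts of regions or candidate
  genes from real, LD-rich panels are not reproducible here and are not
  targets.
* The EMMAX single-fit approximation is the default; exact per-marker
  refitting is available only implicitly through the dense-GLS test oracle
  and would be the natural extension for small panels.
* Outlier-robust regression for plate artefacts is a documented extension
  point, not implemented.
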