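---
title: "Models and methods behind aquarisk"
author: "aquarisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aquarisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

aquarisk implements the standard assessment chain for a mining-impacted
groundwater survey: quality control, guideline screening, hydrochemical
facies, deterministic oral-ingestion health risk, receptor-model source
apportionment, clustering, mineral saturation and spatial vulnerability
mapping. This vignette explains the models, their assumptions, the
tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## The data model

A survey is a `WaterChemSet`, a `SummarizedExperiment` whose `"conc"`
assay holds parameters (rows) by samples (columns): pH (unitless), EC
(µS/cm), TDS (mg/L), turbidity (NTU), ORP (mV), temperature (°C), and
the nine major ions plus Cr, Ni, Mn in mg/L. Sample metadata — the group
label (`mining`, `non_mining`, `mine_water`), planar coordinates, well
depth and elevation — live in `colData`. Validity enforces nonnegative
concentrations (ORP and temperature are the only signed variables), pH
in [0, 14] and the fixed parameter vocabulary. Missing cells mean "not
measured": they are excluded from sums with a warning and never imputed
as zero.

## Charge-balance QC

The ion charge balance error is computed in meq/L,
$\mathrm{ICBE} = 100\,(\sum C - \sum A)/(\sum C + \sum A)$, with cations
{Na, K, Ca, Mg} and anions {HCO3, Cl, SO4, NO3, PO4} (PO4 charge −3).
Whether NO3 and PO4 belong in the balance is survey-specific, so the ion
sets are arguments. The conversion constants (molar masses, charges)
are a versioned data table (`ionTable()`); |ICBE| ≤ 5% is flagged as
acceptable, and no correction of concentrations is ever applied — QC
flags only.

## Pollution indices

Single-factor ratios divide each concentration by its WHO guideline
limit (`whoStandards()`: EC 400 µS/cm, turbidity 5 NTU, TDS 1000, Na
200, K 12, Mg 50, Ca 100, PO4 0.1, NO3 50, HCO3 500, Cl 250, SO4 500,
Cr 0.05, Ni 3.0, Mn 0.5 mg/L). The Nemerow composite is
$\mathrm{NPI} = \sqrt{(\overline{r}^2 + r_{\max}^2)/2}$ over the chosen
ratio set, so it always lies between $r_{\max}/\sqrt2$ and $r_{\max}$.
pH is two-sided and is excluded from the composite by default; a ratio
form against a user-supplied denominator (e.g. 7.8) is available but
deliberately not a default, because no principled single denominator
exists for a two-sided parameter.

## Facies classification

Gibbs coordinates are computed on mass concentrations by default
(`Na/(Na+Ca)`, `Cl/(Cl+HCO3)` against log10 TDS), with a meq option.
The classic Gibbs zone boundaries are figure conventions rather than
equations, so the package emits coordinates, not zone labels. Chadha
coordinates are milliequivalent percentages of each panel:
$x = 100\,[(\mathrm{Ca}+\mathrm{Mg})-(\mathrm{Na}+\mathrm{K})]/\Sigma_\mathrm{cat}$,
$y = 100\,[\mathrm{HCO_3}-(\mathrm{Cl}+\mathrm{SO_4})]/\Sigma_\mathrm{an}$,
and the sign quadrant alone determines the type — which makes the
classification invariant under uniform dilution. A coordinate exactly 0
is assigned to the positive side and flagged as a boundary case:
deterministic, reported, rare.

## Health risk

The chain is the US-EPA deterministic oral-ingestion model:
$\mathrm{CDI} = C \cdot IR \cdot EF \cdot ED/(BW \cdot AT)$,
$\mathrm{HQ} = \mathrm{CDI}/\mathrm{RfD}$, $\mathrm{HI} = \sum \mathrm{HQ}$,
$\mathrm{CR} = \mathrm{CDI} \cdot \mathrm{CSF}$, with cohorts child /
male / female at IR 2 / 2.5 / 3 L/day and BW 18 / 65 / 62 kg. Dermal and
inhalation routes are out of scope; the model is deterministic (no
Monte-Carlo variant).

Two exposure-time conventions ship. The default, `"lifetime"`, sets
ED = 70 y, EF = 365 d/y, AT = 25550 d so that $EF \cdot ED / AT = 1$ and
CDI reduces to $C \cdot IR / BW$; this is the convention under which the
published per-cohort intake tables for this kind of survey are
internally consistent (e.g. 4.5 mg/L Cr → child CDI 0.500 mg/kg/day).
The `"printed"` profile carries the constants often printed next to the
intake equation (ED 350, EF 365, AT 70×365), which yield values about
4.8× larger; it is retained so the discrepancy can be inspected rather
than silently resolved.

Toxicity constants: CSF Cr 0.5, Ni 0.91 (Mn is not treated as
carcinogenic — requesting a CR for it is an error, not a zero). The RfDs
(Cr 1.5, Ni 0.02, Mn 0.14 mg/kg/day) are derived constants: they are the
unique values consistent with the published CDI/HQ pairs this chain
reproduces, and they are documented as such in `defaultToxicity()`.
Note a consequence worth stating plainly: with these RfDs the mean
hazard-quotient ordering across metals is Ni > Mn > Cr in every group
and cohort. The frequently quoted ordering Ni > Cr > Mn holds for the
carcinogenic chain (where Mn has no slope factor), not for HQ.

## Source apportionment

**PMF.** The receptor model factorizes the samples × parameters matrix
as $X \approx GF$ with $G, F \ge 0$, minimizing
$Q = \sum_{ij} \left[(x_{ij} - \sum_k g_{ik}f_{kj})/u_{ij}\right]^2$.
Cell uncertainties follow the detection-limit model:
$u = \tfrac56\,\mathrm{MDL}$ when $C \le \mathrm{MDL}$, else
$u = \sqrt{\mathrm{MDL}^2 + (0.035\,C)^2}$ (error fraction 3.5%
default; bundled MDLs Cr 0.1 and Ni 0.5 mg/L, other parameters 2% of
their median by default). The solver uses multiplicative updates on the
weighted Frobenius objective (weights $1/u^2$), which keep the iterates
nonnegative and make Q provably nonincreasing — asserted per iteration
in the tests. Defaults: best of 20 random nonnegative starts, at most
5000 iterations, convergence when the relative drop in Q over a
20-iteration window falls below 1e-8; non-convergence flags the result
rather than erroring. `Q(robust)` caps scaled residuals at |e/u| = 4
(contribution capped at 16), and a factor-count scan (`scanFactors`,
p = 3…5) is reported without automatic selection. Per-parameter factor
contributions are $\sum_i g_{ik} f_{kj}$ normalized to 100% per
parameter. For recovery tests, factors are matched to the truth by
exhaustive assignment on profile cosine similarity (factor counts are
small, so exhaustive search replaces a Hungarian solver). Two
limitations are intentional: no bootstrap/displacement error estimation,
and no Fpeak rotation. Note also that exact NMF factorizations with
overlapping profile support are not strictly identifiable, so
contribution recovery is asserted in aggregate (mean absolute error)
rather than cell by cell.

**APCS-MLR.** Variables are z-scored, a PCA is taken on the correlation
matrix, and the retained loadings are varimax-rotated. A subtlety found
during development: `stats::varimax`'s fixed-point iteration can stall
short of the rotation optimum for highly symmetric loading patterns
(e.g. two equally sized source blocks), leaving systematic factor
leakage. The package therefore restarts varimax from several random
orthogonal rotations and polishes the winner by exact pairwise-angle
coordinate ascent. Absolute principal component scores are obtained by
scoring an artificial all-zero-concentration sample and subtracting its
scores; a least-squares regression of the total measured burden (row
sum; a per-species mode is available) on the APCS converts factors to
percent contributions, $100\,\overline{b_k\,\mathrm{APCS}_k}/\overline{\hat y}$,
with the residual share reported as unexplained. Whether the historical
method regressed a total burden or individual species varies across the
literature; total burden is the default here because it yields shares
that sum to ~100%.

## Clustering

`haca` z-scores the chosen variables (mixed units make this necessary —
the option exists to disable it), uses Euclidean distance with Ward
linkage (`ward.D2`), and cuts the tree at k clusters (k = 3 mirrors the
usual least / moderately / severely polluted reading; no automatic k
selection). Centroids are reported in original units; the
within/between variance decomposition is computed in the clustering
space and sums to 100% by construction. Severity ranking orders the
three clusters by the centroid sum of metal single-factor ratios, with
a lexicographic, flagged tie-break.

## Speciation

The engine is intentionally minimal: molalities from mg/L under the
dilute approximation, ionic strength $I = \tfrac12\sum m_i z_i^2$,
Davies activity coefficients
$\log_{10}\gamma = -0.5092\,z^2(\sqrt I/(1+\sqrt I) - 0.3I)$ at a fixed
25 °C (a warning beyond I = 0.7 mol/kg), H⁺ activity from pH, and
carbonate from $a_{CO_3} = K_2\,a_{HCO_3}/a_H$ with
$K_2 = 10^{-10.33}$. Saturation indices are
$\mathrm{SI} = \log_{10}\mathrm{IAP} - \log_{10}K$ over a small bundled
set of congruent phases (calcite −8.48, aragonite −8.34, dolomite
−17.09, gypsum −4.58, anhydrite −4.36, halite +1.570, rhodochrosite
−11.13, brucite +16.84 in the proton-dissolution convention), stored as
versioned, overridable data. The classification threshold is SI = 0
(supersaturated above, undersaturated below), which is the universal
convention; a literal threshold of 1 — which appears in some narrative
descriptions — is available as an option but not the default, since
positive-SI-equals-saturated is what the tabulated interpretations
assume. Redox couples and Cr/Ni oxide phases are out of scope: they
require measured redox state, not equilibrium computation.

## Spatial interpolation

IDW uses $d^{-p}$ weights (p = 2 default) and returns the observation
exactly at a data point. Ordinary kriging solves the semivariogram-form
system with the unbiasedness constraint; with a zero nugget it
interpolates exactly with zero variance at data points. The empirical
semivariogram is method-of-moments with 12 bins to half the maximum
distance, fitted by pair-count-weighted least squares; the spherical
model is the default family. Coincident data points trigger one
jitter-and-retry before erroring. Coordinates are treated as planar
(no projection engine). Vulnerability classes cut the predicted surface
into five equal-width intervals between its minimum and maximum —
the scheme that reproduces published class breaks such as
0.02–0.45–0.88–1.32–1.75–2.19 mg/L for Ni. Grids default to the sample
bounding box; the pipeline uses a modest 25×25 grid by default
(quadratic cost in resolution, linear information gain — raise it for
production maps).

## The synthetic generator

`generateSamples` emulates the study design the analysis assumes: group
sizes 35/20/5 (mining, non-mining, mine water); each parameter drawn
from a truncated normal whose parent parameters are fitted so the
truncated mean matches the published group mean *exactly* (root-finding
in the parent mean) and the sd as closely as the family allows
(optimization in the parent sd). A handful of published mean±sd/range
combinations exceed the truncated-normal's maximum sd on their interval
(e.g. mine-water ORP sd 38 on a range of width 90 centered at the
mean); for those rows the generator matches the mean and saturates the
sd — the convergence tests therefore check means, not sds. Far-tail
parent regimes are handled by a truncated-exponential limit to avoid
floating-point underflow.

Water types are imposed with quadrant weights 46.6/26.6/23.3/1.6%
(Ca-HCO3, Na-HCO3, Na-Cl, Ca-Mg-Cl) by reallocating meq between
(Ca+Mg) and (Na+K), and between HCO3 and (Cl+SO4), preserving each
panel's total — so the charge balance is untouched. Anion totals are
then rescaled multiplicatively toward a random ICBE target within ±4%,
guaranteeing the ±5% screen. TDS is drawn as its own variable and is
not recomputed from the ions. Consequences to keep in mind: after
facies imposition and rebalancing, individual ion distributions deviate
from their published marginals (metals and physicochemical variables do
not); cross-parameter correlations (e.g. EC–TDS) are not modelled
(independence default, deliberately simple); well coordinates are
uniform scatter with no spatial autocorrelation, so kriging tests use
separately constructed smooth fields. Passing tests on this generator
demonstrate correctness of the estimators under the stated design, not
performance on real aquifer data.

`generateSourceMixture` builds block-dominant nonnegative profiles with
a weak common background (set it to zero for strictly orthogonal
sources), gamma-distributed contributions, optional exact mass shares
per source, and noise from the uncertainty model, clipped at zero.
`generateBlobs` produces separated clusters with a burden gradient for
clustering recovery (default 12/8/40, giving the engineered 66.67%
severely polluted share).

## Problem sizes and reproducibility

The bundled tests run the receptor models at the survey scale (n = 60,
m = 16, p = 3, 20 starts), APCS recovery at n = 80, and generator
convergence checks at n = 2000 per group — sizes chosen to exercise the
estimators at realistic survey dimensions while keeping the whole suite
under a minute. All stochastic stages take explicit integer seeds;
`fitPMF` and the pipeline restore the caller's RNG state, and pipeline
reruns with identical inputs are file-identical (the manifest carries
no timestamps).

## Known limitations

- The speciation engine is not a full thermodynamic code: fixed 25 °C,
  Davies activities, eight congruent phases, no redox.
- PMF uncertainty handling implements the base model only (no BS/DISP).
- APCS-MLR shares inherit PCA's orthogonality assumption; correlated
  sources bias shares at small n.
- The health-risk chain is single-route (oral) and deterministic.
- Kriging assumes planar coordinates and an isotropic variogram.
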