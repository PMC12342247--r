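---
title: "Detecting vulnerable brain regions from individualized structural covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting vulnerable brain regions from individualized structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Structural covariance — the tendency of morphometric features of brain
region pairs to co-vary — is classically estimated *across* subjects,
yielding a single network per group and discarding individual variability.
`scnvuln` works with *individualized* structural covariance networks: each
subject contributes one network per modality, built from its own regional
measurements, and the question becomes which regions' network-level
representations differ across risk-factor groups. A region whose
representation shifts with a factor combination (genotype × sex, say) is
called *vulnerable* to it.

The package is designed around a mouse model of Alzheimer's risk: three
humanized ApoE genotypes (E2/E3/E4), both sexes, a continuous age covariate
binarized within genotype, an immunity contrast (humanized NOS2, "HN",
versus mouse Nos2), and a diet contrast (control versus high-fat). Inputs
are plain tables — subjects × regions CSVs of regional volume (mm³) and
regional mean fractional anisotropy, a covariate CSV, and a region list
TSV — so nothing in the package touches images.

## Model and procedure

**Networks.** Within each subject, volumes are normalized by the subject's
total (sum of atlas regions) and FA by the subject's regional maximum, so
each feature vector lies in [0, 1] and is invariant to the subject's global
scale. The network is the pairwise absolute difference matrix
`A_ij = |x_i − x_j|`: symmetric, hollow, [0, 1]-weighted. Two points about
these dissimilarity networks matter downstream:

* normalization couples regions — under sum-normalization a change in one
  region slightly rescales all others of that subject;
* the networks are relational — an effect on region r changes the entry
  `(r, s)` of every other region s's profile, most visibly for regions
  with baseline values close to r's.

**Random dot product graph view.** Treating each network as a weighted
RDPG, every region gets a latent position whose dot products generate the
expected network. Latent positions estimated separately per subject are
only identified up to rotation, which defeats cross-subject comparison; the
omnibus embedding solves this by embedding one `mn × mn` matrix whose
diagonal blocks are the subject networks and whose off-diagonal blocks are
pairwise averages. The embedding `Û |Ŝ|^{1/2}` (eigenpairs by descending
magnitude; negative eigenvalues enter through their absolute value) is
computed once, and its m consecutive n-row blocks are mutually aligned
per-subject latent positions. Under homogeneity the blocks concentrate
around a common value; group differences surface as systematic block
differences — which is precisely what the test stage consumes.

**Dimension selection.** The latent dimension is the *second* elbow of the
omnibus scree under the Zhu–Ghodsi profile log-likelihood criterion
(successive elbows found by recursing on the tail beyond the previous
elbow). The first elbow of these matrices virtually always isolates the
single dominant Perron-type eigenvalue that reflects overall scale; the
second captures the structured signal. On rank-3 latent models with small
noise the second elbow recovers 3 in ≈ 95 % of simulations (the acceptance
suite measures this), and on distance networks from the cohort simulator it
selects 3 per modality, giving 6-dimensional concatenated features. Both
the elbow index and a fixed `d` override are exposed
(`omni_embed(n_elbows =, d =)`) since reasonable spectra can disagree about
which elbow is "the" signal edge.

**Testing.** For each region, the s cohort subjects contribute their
latent feature rows; a factor subset defines groups as the observed cells
of the level cross-product (one-hot encoded; empty cells dropped; any cell
with fewer than two subjects makes the spec untestable and it is skipped
with a warning rather than silently judged). The K-sample null — all group
distributions equal — is tested by the unbiased (U-centered) distance
correlation between Euclidean feature distances and label distances
(distinct groups sit at distance √2). The statistic doubles as the
reported effect size (floored at zero for reporting). P-values come from
the fast chi-squared approximation: `s·dcorr + 1` referred to the upper
tail of χ²₁. A permutation oracle (`permutation_pvalue()`) implements the
exact test; the suite verifies the approximation's rejections are a subset
of the oracle's and its type-I error sits near nominal (measured ≈ 0.04–
0.05 at α = 0.05).

**The battery and FWER.** Analysis A restricts to the control-diet cohort
and crosses genotype, sex, age, immunity; analysis B restricts to the
humanized-immunity cohort and crosses genotype, sex, age, diet. Diet and
immunity never co-occur because the design has no mice in the high-fat ×
mouse-Nos2 cells. All `2⁴ − 1 = 15` non-empty factor subsets are
enumerated; genotype-containing subsets can be repeated under one-vs-rest
codings. Holm–Bonferroni is applied within a *family*; two family choices
are provided because they answer different questions:

* `per_spec` (default): all regions tested for one analysis × factor
  combination — the family matching per-panel reporting, i.e. "which
  regions are significant for this combination";
* `global`: all regions × combinations of an analysis at once — the family
  to use when the claim is "no false rejection anywhere in the battery".
  The null-calibration acceptance check uses this family, since "zero
  rejections across the whole battery" is a battery-wide FWER event that
  per-combination families do not control (fifteen 5 % families union to
  far more than 5 %).

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_elbows` | 2 | scree elbow used for `d`; first elbow is the Perron eigenvalue |
| `d` | `NULL` | fixed embedding dimension override, per modality |
| `dense_limit` | 2000 | largest `m·n` embedded by full dense eigendecomposition; above it an implicit operator + ARPACK top-k path is used (the full-cohort omnibus, 169 × 332 ≈ 56k rows, must never be materialized) |
| `n_spectrum` | `min(n, 100)` | leading eigenvalue magnitudes fed to elbow selection; elbows are local features of the leading spectrum and the deep tail is noise |
| `alpha` | 0.05 | familywise level |
| `family` | `per_spec` | Holm family, see above |
| `codings` | `three_level` | genotype codings; add `APOE*_vs_rest` for one-vs-rest contrasts |

Numerical conventions: eigenvector signs are fixed so each column's
largest-magnitude entry is positive (all statistics are invariant to this;
it only makes outputs byte-reproducible); age ties go to `young` (age equal
to the genotype median), keeping the split deterministic; degenerate
distance variance (all points coincident) yields statistic 0 and p = 1
rather than NaN.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the pipeline assumes: three
genotypes × two sexes × diet × immunity, with high-fat × mouse-Nos2 cells
empty — reproducing the confound that forces the two-analysis split. The
default 96-subject cohort places 6 subjects in each of the 12 control-diet
cells and 4 in each of the 6 high-fat × HN cells, on a 40-region
hemisphere-balanced atlas (two orders of magnitude below the real 169 × 332
problem, chosen so the calibration suites run in minutes on one CPU while
keeping every group cell testable).

Volumes are log-normal around fixed per-region baselines (0.6–2.5 mm³,
mirrored across hemispheres as in a symmetrized atlas; noise
σ_v = 0.1 on the log scale, i.e. ~10 % regional variability); FA is
Gaussian around fixed baselines 0.15–0.50, clipped to (0.01, 0.99), with
σ_f = 0.02. Baselines are deterministic profiles rather than random draws:
region sizes are fixed anatomy, and (more practically) a random FA baseline
near the per-subject maximum would let a planted effect flip *which* region
attains the maximum, rescaling every region of affected subjects — an
artifact of the fixture, not a property of the method. Ages are uniform on
12–20 months. All draws run through named substreams of one seed, so an
FA-only change never perturbs the volume draws.

Planted effects add `delta_vol` (log scale) and `delta_fa` (FA units) at
chosen regions for subjects matching a factor level. The calibration
default plants five vulnerable regions bilaterally (two mirror pairs plus
one left-only region) with `delta_vol = 0.15` (~16 % regional volume
change — large but within reported atrophy/hypertrophy ranges) and
`delta_fa = 0.035` on females. These sizes were fixed by a design pilot
*before* the acceptance assertions were finalized, at the point where the
two failure modes balance: much larger effects leak — through
sum-normalization and the shared eigenbasis — into null regions (mirror
regions first, since their baseline profiles are closest), while much
smaller ones lose power at 72 control-diet subjects. That a feasible window
exists, and where it lies, is itself informative about the method: effect
recovery is reliable only when effects are strong enough to detect yet
sparse/moderate enough not to contaminate the joint embedding. Planting on
binarized age is unsupported (the bin derives from the generated ages, so
the effect definition would be circular); effects target genotype, sex,
diet or immunity.

What passing the calibration suites does *not* show about real data: the
generator draws independent noise per region (no spatially correlated
segmentation error), plants additive effects (no variance or shape
differences, though the test is sensitive to them), and contains no
modality correlation beyond the planted effects. Real regional features
also violate log-normality in the tails.

## Measured calibration (recomputed by `scripts/acceptance.R` and the test suite)

With the defaults above, over 100 simulation seeds per property: null
cohorts show zero Holm rejections battery-wide in ≈ 98 % of seeds
(global family); all five planted regions are recovered with at most 5 % of
null regions falsely flagged in ≈ 94 % of seeds; the second scree elbow
recovers the generating rank 3 in ≈ 95 % of seeds; and the chi-squared
test's type-I error sits at ≈ 0.05. The embedding is exact (Procrustes
residual at machine precision) on noiseless low-rank inputs, and the
distance-correlation implementation agrees with a brute-force U-centering
oracle to full double precision.

## Known limitations

* Leakage is intrinsic: strong localized effects perturb their partners'
  network profiles (mirror regions especially), so single-region
  attribution at very large effect sizes should be read cautiously —
  the battery bounds, but cannot eliminate, this.
* The chi-squared null is an approximation; it is validated here as
  conservative-to-nominal for the one-hot label geometry, and the
  permutation oracle remains available when exactness matters.
* The published cohort totals used in the accounting checks are expanded
  from printed per-genotype marginals; the joint sex × diet × immunity
  assignment within genotype is a synthetic reconstruction constrained by
  those marginals, suitable for count accounting only.
* Weighted RDPGs lack the binary model's full statistical guarantees; the
  embedding is used as a purely spectral representation, not a likelihood
  fit.
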