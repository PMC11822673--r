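---
title: "Methods: models, parameters and design choices in uroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in uroquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uroquant)
```

# What this package quantifies

Bladder umbrella cells — the large, polyploid, terminally differentiated
cells lining the bladder lumen — display several hallmarks of cellular
senescence across the mouse lifespan: senescence-associated
β-galactosidase (SA β-gal) activity, telomere-associated DNA-damage foci
(TAFs), and, in old animals, p16 (*Cdkn2a*) expression. Whether these cells
respond to senolytics, and whether bladder function (cystometry, voiding
behaviour) changes with age or treatment, is assessed through a battery of
quantitative assays. `uroquant` implements each quantifier as tested code
and pairs every input with a seeded synthetic-data generator carrying
machine-readable ground truth. The generators exist so that each
quantifier can be validated end-to-end against known truth; they are
first-class, tested components, not test fixtures.

# Imaging quantifiers

## TAF calling

A TAF is a colocalization between a telomere signal and a γH2AX
DNA-damage focus. The pipeline is:

1. `detect_objects()` — connected components (6-connectivity in 3-D) above
   an intensity threshold, gated inclusively on *equivalent diameter*, the
   diameter of the sphere (3-D) or circle (2-D) with the object's voxel
   count. Sub- and supra-gate components are retained with a rejection
   reason; two touching puncta that merge into a supra-gate blob are
   rejected, not split (no watershed — a documented limitation).
2. `flag_autofluorescent()` — lipofuscin, the autofluorescent "aging
   pigment" abundant in umbrella cells, appears in *both* detection
   channels at the same voxels. An object pair with reciprocal voxel
   overlap ≥ 0.7 in both directions is flagged in both sets and excluded
   downstream. A genuine TAF pair overlaps partially and asymmetrically
   and is never caught by this rule.
3. `call_tafs()` — every unflagged telomere–damage pair with voxel overlap
   ratio ≥ 1% yields a TAF, assigned to the nucleus containing the overlap
   centroid; a cell with ≥ 2 TAFs is called senescent.

Two conventions needed fixing where the instrument definition is silent:

* **Overlap-ratio denominator.** "At least 1% overlapped volume" does not
  say 1% *of what*. We use `|A∩B| / min(|A|, |B|)` — the most permissive
  symmetric choice, so no pair that any reasonable denominator would admit
  is lost; `denominator = "union"` (Jaccard) is available in
  `quant_config()`.
* **One TAF per telomere.** A telomere touching two damage foci counts
  once: a TAF is a telomere in a damage context, and double counting would
  inflate per-cell counts. The partner with the largest overlap wins, ties
  broken by lowest object id. Configurable.

TAFs whose overlap centroid falls outside every nucleus are reported as
unassigned and excluded from per-cell counts; including perinuclear TAFs
is not defensible when the nuclear mask defines the region of interest.

## RNAscope p16 quantification

Puncta are gated at 3–10 px equivalent diameter (excluding sub-gate debris
and supra-gate lipofuscin aggregates), nuclei at 10–50 px, actin at
3–50 px; a nucleus is p16-positive iff at least one accepted punctum's
centroid lies inside it. Detection thresholds in real workflows come from
`threshold_from_positive_control()`: the 10th percentile of object-level
mean intensities in a parallel positive-control image — low enough to keep
faint puncta, anchored enough to reject background. An empty control is an
error; there is no silent default.

## SA β-gal scoring

Positivity is restricted to the luminal (surface) layer, matching the
biology: only umbrella cells stain. A cell in the luminal mask is positive
when its mean colour is blue-dominant (`blue > 1.3 × max(red, green)`), a
deliberately simple colour rule adequate for the synthetic chromogen;
colour deconvolution of real histology is out of scope. Field percentages
average within section, then sections within animal
(`sabgal_aggregate()`), the usual 3-fields × 3-sections scheme; fields
with no luminal cells are excluded and listed.

# Cystometry

`gen_cmg_trace()` renders fill/void cycles at 30 Hz under 1.5 mL/h
infusion: a storage plateau at Pbase, a slow filling ramp (15 s) to
Pthresh, a rapid voiding contraction (2 s, half-cosine) peaking at Pmax
exactly at flow onset, linear decline to Pend over the 2.5 s flow phase
while the collected-volume channel rises by exactly
`infusion_rate × IVI` (conservation holds by construction), then 3 s of
relaxation. Default landmarks (7.03 / 16.51 / 53.01 / 25.32 cm H₂O,
IVI 172.86 s) are the middle-aged female means, making the per-cycle
voided volume 1.5/3600 × 172.86 ≈ 0.072 mL — the printed 0.07 mL
magnitude. Nonvoiding contractions are Gaussian pressure transients
(amplitude 5 cm H₂O, sub-threshold) with no volume step. Pressure noise
defaults to 0.5 cm H₂O; the volume channel carries 1 µL of transducer
noise.

Extraction design, where the variables are defined semantically but no
algorithm is stated:

* **Void detection** works on the volume channel only, so NVCs can never
  be detected as voids. Flow edges are refined to the half-plateau
  crossings of the smoothed volume derivative; the plateau level is the
  run *median* of a re-smoothed derivative, so a single noise-inflated
  sample can neither set nor break an edge.
* **Pbase** is the 10th percentile of smoothed storage-phase pressure —
  robust to NVCs occupying a minority of storage.
* **Pthresh** is the pressure at the start of the final voiding
  contraction: walking back from the peak, the last contiguous run whose
  smoothed slope exceeds 10% of the peak slope, floored at
  `Pbase + 3σ` (σ estimated from storage-phase first differences). A pure
  band-crossing rule cannot work here: the slow filling ramp crosses any
  noise band near Pbase long before the contraction begins, so the
  contraction onset must be identified by its slope signature.
* **Pmax** is the maximum of a lightly smoothed (0.2 s) pressure in a
  ±5 s window around flow onset — the heavy 0.5 s smoothing used
  elsewhere would clip the narrow peak, and the raw maximum would ride
  the noise.
* **Pend** is read at the voiding-decay/relaxation slope break in the
  pressure channel near flow end, which carries a sharper timing
  signature than the noisy volume edge.
* **IVI** is measured flow-onset to flow-onset of sequential voids; the
  last cycle has no following void and reports `NA`.

`summarize_mouse()` averages each variable over the first 3 consecutive
usable cycles whose IVIs have a coefficient of variation below 0.5 — our
operationalisation of an "established regular fill/void pattern", which
has no published criterion; the bound is configurable and the choice is
deliberately permissive (anaesthetised mice cycle quite regularly once
they cycle at all). Operator exclusions (leak, death, bad catheter
placement) pass through as machine-readable codes.

Recovery performance under the default study conditions (50 traces,
5 cycles, noise 0.5 cm H₂O, NVCs at 3/min): mean absolute landmark error
≤ 0.4 cm H₂O per landmark — under 1% of the ~46 cm H₂O dynamic range,
with zero spurious or missed voids; the acceptance script recomputes
this.

# Voiding spot assay

Spots are connected bright components with area ≥ 0.1 cm², converted via
the pixel calibration squared. The four reported metrics are total voids,
total area, percent of void area in cage corners, and percent large voids.
Two geometry conventions are ours to fix:

* **Corners** are the four `0.25·W × 0.25·H` rectangles; membership is by
  centroid (simple and reproducible; area-weighted membership would need
  overlap integration for marginal spots and changes results by little).
* **"Large" (> 3 cm)** is read as equivalent-circle *diameter* — a length
  in cm most naturally describes a spot's size — with
  `large_metric = "area"` available since area-binning tools exist.

Merged overlapping spots are not split; the generator therefore keeps
spots disjoint, and on real images the metric inherits the usual
connected-component behaviour.

# Molecular quantification

## Multi-reference-gene Pfaffl

Relative expression is efficiency-corrected and normalised to the
*geometric mean* of three reference genes:
`ratio = E_t^{ΔCt_t} / geomean_r(E_r^{ΔCt_r})`, with
`ΔCt = mean Ct(calibrator) − Ct(sample)` and the calibrator being the
young sex-matched group (its mean ratio is 1 by construction in the
noise-free case). With every efficiency at 2 this reduces exactly to the
2^−ΔΔCt method with a geometric-mean reference — a closed-form limit the
tests check. Unreported efficiencies default to 2. The generator's
per-sample loading shift (common to all genes of a sample) is precisely
the nuisance geometric reference averaging removes, which is why the
noise-free round trip is exact.

## DE engine and filter cascades

The differential-expression engine is deliberately minimal and fully
documented: log2 CPM with a 0.5 pseudocount, per-gene Welch t, BH
adjustment. It is *not* a negative-binomial GLM; the cascade logic, not
the test family, is the object of interest, and the toy-table acceptance
checks evaluate the cascades by brute-force row-wise evaluation
independent of the engine.

The two cascades:

* **Aging filter**: significant (adj p < 0.05) between middle-aged and
  old AND |log2 FC| < 0.2 between young and middle-aged. The stability
  bound is read on the log2 scale: a *linear* ratio below 0.2 would mean
  a ≥ 5-fold change, which cannot be "minimal change"; the scale is
  configurable and recorded in the audit.
* **Senolytic (D+Q) filter**: significant old-vs-D+Q change that
  *reverses* the aging direction, with |log2 FC| < 0.2 in both water-only
  and vehicle-only comparisons (gavage/vehicle confound exclusion), and —
  by default — aging significance as well, since the reported lists are
  "top genes changed with aging whose expression moved back under D+Q".
  Survivors are ranked by |log2 FC (M vs O)|, ties by smaller adjusted p
  then gene id, for top-k reporting.

Every gene gets an audit row naming the first criterion it failed;
survivors ∪ rejected = the input universe by construction.

## Count generator realism

Counts are negative-binomial with dispersion 0.01 (biological CV 10%, the
typical value for genetically identical model organisms), log-normal
library-size factors (CV 20%), and baseline means of 2^8–2^13 per gene —
deliberately deep, matching total-RNA libraries sequenced at hundreds of
millions of read pairs where expressed genes carry thousands of counts.
At shallower depth or higher dispersion the |FC| < 0.2 stability gates
lose sensitivity for mechanical reasons (the gate is applied to a noisy
estimate whose SE approaches the bound); the vignette notes this rather
than hiding it, and both knobs are generator parameters. The three
planted gene sets have disjoint memberships, but D+Q-responsive genes
deliberately carry the aging-direction shift *plus* full reversal under
treatment — that co-occurrence is what the reversal filter detects, and
members of the aging set are therefore legitimate co-survivors of the
aging filter.

# Statistics engine

All tests are two-tailed. From printed summaries (mean, SD, n):

* **Welch t** with Welch–Satterthwaite fractional df (t tail via the
  regularised incomplete beta, `stats::pt`; no table lookup), and
  **pooled t** with `n₁+n₂−2` df. Published cystometry tables reproduce
  under Welch even for rows footnoted as plain t tests (the
  normal-vs-high-fat-diet maximum-pressure row matches the printed p only
  under Welch); both forms are exported and the summary tables ship in
  `inst/extdata` for recomputation.
* **Dunnett** many-to-one comparisons: pooled MSE, per-comparison t, and
  two-sided adjusted p from the joint multivariate-t null with the
  correlation structure `ρ_ij = √(n_i n_j / ((n_i+n₀)(n_j+n₀)))`,
  evaluated by `mvtnorm::pmvt` quadrature with a Monte-Carlo cross-check
  mode that simulates the same joint distribution.
* **Tukey(-Kramer)** all-pairs via the studentized range
  (`stats::ptukey`), with the Kramer unequal-n standard error and an MC
  cross-check.
* **Mann–Whitney U**: exact two-tailed p (twice the smaller tail of the
  exact U distribution) when there are no ties; otherwise a tie- and
  continuity-corrected normal approximation whose worst-case gap from
  exact at n = 8 vs 8 is 0.011 (computed by enumeration over the whole
  null distribution).
* **Kruskal–Wallis + Dunn** is a thin raw-data operation (rank-sum z with
  tie correction, Bonferroni-style multiplicity over the requested
  comparisons); no summary-statistics mode.

Adjusted p-values are floored at the unadjusted p, so the
unadjusted ≤ adjusted ≤ Bonferroni ordering holds identically.

# What the synthetic data does and does not show

The generators emulate the *statistical structure* each analysis assumes:
punctate foci with controllable colocalization and dual-channel
autofluorescent confounders; cyclic pressure traces with programmable
landmarks and sub-threshold NVCs; corner-biased spot layouts; Ct tables
whose only nuisance is per-sample loading; counts with age-restricted,
gavage-confounded and treatment-reversed effects. They do not emulate
realistic optics (PSF anisotropy beyond a Gaussian blur, bleed-through,
depth attenuation), chromogen chemistry, bladder biomechanics, or
alignment/counting upstream of the count matrix. Passing recovery tests
therefore demonstrates that the quantifiers are correct *given* clean
segmentation-scale images and well-behaved traces — not that they are
robust to every artefact of real microscopy or urodynamics. Geometry is
scaled down (nuclei of radius 3 µm at 0.3 × 0.3 × 0.4 µm voxels) to keep
stacks small; all size-dependent logic works in gate units, so the
scaling does not touch the decision rules.

Problem sizes used by the test suite and acceptance script — 20 oracle
stacks at 64×64×22 voxels, 50 recovery fields of 100 cells per assay, 50
noisy traces of 5 cycles, 2000-replicate null simulations and 10⁶-draw
Monte-Carlo cross-checks — were chosen to keep every binomial/Monte-Carlo
error bar several times smaller than the effects being verified.

# Known limitations

* No watershed splitting of merged objects (foci, nuclei, spots).
* The DE engine is a log-CPM Welch test, not an NB GLM; at very low
  counts its CPM variance model is misspecified.
* The Pthresh slope rule needs a contraction visibly steeper than the
  filling ramp; traces where voiding builds up gradually (some
  pathological phenotypes) would need a lower `slope_fraction`.
* Exact Mann–Whitney is undefined under ties; the approximation takes
  over, as in standard practice.
* Dunnett quadrature rounds fractional error df to the nearest integer
  for `pmvt`; at the group sizes used here the effect is < 10⁻⁴ in p.
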