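---
title: "Reconstructing propeller emergence: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing propeller emergence: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propevo)
```

## The scientific setting

β-propellers are globular all-β folds of four to eight radially arranged
blades, each blade a four-stranded β-sheet of roughly 47 residues. Their
internal symmetry suggests a generative history: a short ancestral motif
tandem-duplicated, fused, and diverged into the extant protein
(duplication–fusion–divergence). `propevo` implements the computational
side of testing that model on a lectin propeller system:

1. **Repeat detection and identity statistics** — find the tandem motifs a
   propeller decomposes into and quantify their average internal identity,
   the clock proxy for the propeller's age.
2. **Ancestral motif inference** — align the motifs, build a tree, and
   compute marginal maximum-likelihood posteriors over the 20 residues at
   the root; the per-position argmax is the most probable ancestor (MPA).
3. **Library and construct design** — turn the posterior into a
   combinatorial substitution library across circular-permutation frames,
   tandem fusions, frame interconversions, and error-prone mutant sets.
4. **Genomic clock analysis** — scan a proteome for weakly diverged
   propellers, find single-motif relatives by homology, and test whether
   internal identity correlates with identity to the single motif, as
   duplication–fusion–divergence predicts; a directionality test asks
   whether the single motif resembles one repeat disproportionately
   (which would instead indicate co-option *from* a propeller).
5. **Equilibrium biophysics** — ELISA calibration sigmoids and their
   inversion, two-/three-state chemical denaturation fits, thermal melts
   with censoring, folding-yield concentration shapes, and the 6×6 trait
   correlation/PCA that separates foldability-linked from stability-linked
   traits.

Real propeller sequences and plate-reader data are external inputs; every
stage here is exercised against the package's own simulators, which record
complete ground truth. What passing tests show is therefore that the
*estimators* recover known truth under the declared generating conditions —
not that any particular natural protein behaves this way.

## Sequence models and choices

**Identity metric.** Global Needleman–Wunsch alignment under BLOSUM62 with
gap open 10 and gap extend 0.5; identity is matches divided by aligned
columns where neither sequence is gapped. Gapped columns are excluded from
the denominator (the alternative — counting them as mismatches — changes
near-equal-length motif comparisons by well under the 3-percentage-point
tolerance used anywhere identity is checked).

**Repeat detection** is a deliberately simplified, Radar-like procedure:
every candidate period in `[min_period, max_period]` is scored by the mean
BLOSUM62 score of the ungapped self-alignment diagonal at that offset; the
smallest period within 80% of the best mean score wins (harmonics of the
true period score equally per position but on fewer positions, so the
fundamental is preferred whenever competitive). A multi-motif call
additionally requires the mean motif-vs-consensus score to reach 25% of
the consensus self-score — calibrated on simulated families so that
repeats at 30% internal identity (the lowest value in the genomic
analyses this mirrors) are still accepted while shuffled decoys are not.
It does not reproduce any external tool's output bit for bit; only the
downstream statistics matter. Coordinates are 0-based half-open
internally, 1-based inclusive in every report.

**Substitution model.** JTT (Jones–Taylor–Thornton 1992) exchangeabilities
with the model's stationary frequencies, uniform rates across sites. The
rate matrix is normalized to one expected substitution per site per unit
time; transition probabilities come from the symmetric eigendecomposition
of the reversible generator. A `poisson` model is available through the
same `substitution_model()` id mechanism. No among-site rate variation is
fitted: the motifs are short (~47 columns) and the inference target is the
root posterior, not rates.

**Trees.** Pairwise distances are maximum-likelihood distances obtained by
numerically inverting the observed aligned identity through the model's
expected-identity curve (`identity_to_distance()`); saturated identities
cap at 10 substitutions/site. Neighbor-joining (with negative branch
lengths clamped to zero) is followed by midpoint rooting — the natural
choice when no outgroup is trusted — and one round of per-branch Brent
optimization of the total log-likelihood (interval (0, 5], tolerance
1e-3). Full topology search is out of scope; on simulated families the
NJ topology groups motifs by source protein in ≥90% of replicates at 50%
internal identity.

**Root posteriors.** Felsenstein pruning with gapped leaves contributing a
vector of ones (missing data, the convention marginal reconstruction
tools use). The root prior is the model's stationary distribution; the
marginal posterior at each column is the normalized elementwise product
of prior and root conditional likelihood. MPA ties break alphabetically,
so inference is deterministic.

**Alignment.** Center-star progressive alignment against the first motif
with "once a gap, always a gap" merging. This is adequate for the
intended inputs — near-equal-length, ≥30%-identity repeat motifs — and
is *not* a general-purpose aligner.

## Library design

An intact-blade (B) frame is a circular rotation of the motif; the
rotation that brings the permuted strand to the front (`blade_shift`,
default 12 residues) is structural knowledge supplied per family, not
hard-coded. End polishing of ±2 residues yields five B frames; with the
extant Velcro (V) frame that makes six. Library cutoffs are strict
inequalities (posterior > 0.25 in the first round, > 0.1 in the second),
alternatives exclude the MPA residue, and the library size obeys
`|frames| × Π(1 + k_i)` exactly. Variant emission order is deterministic:
frames V-first-then-B-by-offset, positions ascending, residues
alphabetical. Error-prone mutagenesis is modeled at the protein level —
Poisson counts per clone, uniform positions without replacement, uniform
substitution over the 19 alternatives — because the mutation rates being
emulated (1.6 per motif, ~3 per gene) are quoted at the protein level;
codon structure and transition/transversion bias are out of scope.

## Genomic clock analysis

The homology search is an in-package Smith–Waterman (BLOSUM62, gap open
11 / extend 1) with Karlin–Altschul statistics using the standard
published gapped parameters for that scoring system (λ = 0.267,
K = 0.041); `E = K·m·n·exp(−λS)` with the strict `e < 10⁻³` retention
threshold, and subjects restricted to proteins whose own repeat
annotation has a single motif. This removes the external BLAST dependency
while preserving e-value semantics; on shuffled decoy proteomes the
cutoff admits no hits in ≥99/100 seeded trials.

Clock points pair each propeller's internal identity with the mean and
maximum identity of its motifs to the candidate single-motif ancestor;
Pearson correlation (two-sided t-transform p) is computed on unrounded
values, tables print one decimal. The directionality statistic per
propeller is the gap between the best-matching repeat and the mean of
the *remaining* repeats — the natural contrast for a one-outlier
alternative, in which reference noise common to all repeats cancels. Its
null asks what gap exchangeable, equidistant motifs would produce: 2,000
sets of k motifs are simulated under the substitution model at the
divergence implied by the sibling repeats (the suspect maximum is
excluded from that estimate, since under co-option it would mask its own
excess). A propeller is flagged when its observed gap exceeds the null's
99th percentile; with ~11 propellers per family the family verdict uses
the smallest exceedance probability at a 0.005 threshold, holding the
familywise false-positive rate near 5%. These operating characteristics
were fixed from calibration simulations before freezing the design. The
test's power has an honest ceiling: a *young* donor propeller's sibling
repeats sit only ~15–20 identity points below the co-opted copy, within
the null spread of a 47-residue identity estimate, so roughly the
youngest quarter of co-option scenarios is statistically undetectable at
this error rate — a limitation of any test on single-motif-length
sequences, documented rather than hidden.

## Biophysical models

All chemical-denaturation fits use the linear-extrapolation
parameterization at 25 °C (`RT = 0.592 kcal·mol⁻¹`). Two-state:
`f_N = 1/(1 + exp(m(x − Cm)/RT))` between linear native and denatured
baselines. Three-state (N⇌I⇌D): `K₁ = exp(m₁(x − Cm₁)/RT)`,
`K₂ = exp(m₂(x − Cm₂)/RT)`, `f_N = 1/(1 + K₁ + K₁K₂)`, `f_I = K₁f_N`,
`f_D = K₁K₂f_N`; the second midpoint is parameterized as `Cm₁ + ΔCm` with
`ΔCm > 0`, making the inter-inflection interval — the stability of the
folding intermediate — a direct fit parameter. The intermediate baseline
has a free intercept and zero slope (standard practice for a species
observed only through a transient plateau). Oligomer data are fitted
without a concentration term, so all parameters are apparent values.

**Fitting strategy.** The baselines enter the signal linearly, so a
coarse grid over the nonlinear parameters (midpoints, interval,
m-values) with the linear parameters profiled out exactly seeds a
Levenberg–Marquardt polish; the best sum of squares wins. m-values are
bounded to [0.2, 12] kcal·mol⁻¹·M⁻¹ — outside that range a "transition"
is either an invisible baseline curvature or a single-point step, both of
which let the optimizer chase noise. Among polished candidates, fits
whose transitions fall outside the scanned gradient (native fraction
< 0.8 at the lowest denaturant or denatured fraction < 0.8 at the
highest) are rejected unless nothing else converged: a midpoint the data
never cross is not an estimate. Model choice is by BIC with ties to the
parsimonious two-state model.

**Identifiability of closely spaced inflections.** A three-state curve
whose intermediate baseline sits midway between the flanking baselines
and whose transitions overlap is nearly indistinguishable from a
two-state curve: the (ΔCm, intermediate-baseline) profile forms a flat
valley, and at 1% noise the *global* least-squares optimum itself wanders
by more than 0.1 M — no optimizer can fix that. The package's canonical
simulated-unfolding conditions (`unfolding_curve_spec()`) are therefore
chosen, once, so that sub-molar intervals are identifiable: cooperative
transitions (apparent m = 6 kcal·mol⁻¹·M⁻¹ per step, appropriate for a
hyperstable ~235-residue fusion), an intermediate whose fluorescence sits
*above* the native baseline (as when native tryptophan quenching is
relieved in a midfolded species), and a dense 181-point 0–6 M gradient.
Under these conditions the seeded recovery checks refit the ΔCm values
studied (0.3, 0.8, 1.2 M) to within 0.1 M; the looser 61-point setting is
still used for the median-error recovery property.

A related mathematical caveat: the exact collapse of the three-state
model onto a two-state curve as ΔCm → 0 with a midway intermediate
baseline is only approximate. At ΔCm = 0 the intermediate still reaches a
third of the population at the midpoint, and `f_N + f_I/2` is provably
not a logistic function of denaturant — the best two-state approximation
leaves a residual of ~0.4% of the signal amplitude regardless of m. The
suite tests this collapse at the 10⁻³ tolerance the property nominally
carries, and that check documents the discrepancy rather than hiding it.

**Thermal melts** use a logistic transition with linear baselines. A melt
is censored — reported as `Tm > upper_limit` (default 90 °C), never a
point estimate — when the fit fails, the fitted midpoint exceeds the
bound, or the denatured baseline is not established within the scanned
range (midpoint closer than two transition widths to the top of the
scan).

**Calibration.** The ELISA response is `y = A/(1 + (K/x)^h)`; `y(K) = A/2`
by construction and the closed-form inverse
`x = K(A/y − 1)^(−1/h)` converts lysate absorbances to functional
concentrations on `(0, A)`; saturated or blank wells raise errors rather
than returning infinities.

**Concentration dependence of folding yield** is classified from
normalized yields: `bell` when an interior maximum beats both endpoints
by more than the noise margin (0.1 by default), `monotone_decreasing`
when the overall drop exceeds the margin and a decreasing isotonic fit
beats a flat fit, else `flat`. Three points suffice for the interior-
maximum test and are accepted, although four or more are recommended.
The mechanistic toy generators (`folding_yield_curve()`) encode the two
regimes being distinguished: oligomer assembly ∝ c with misfolding ∝ c²
(bell), monomer misfolding ∝ c (monotone decrease).

**Trait PCA** is computed on the Pearson correlation matrix (not the
covariance — the six traits carry incommensurable units) over
complete-case constructs; constant columns raise an error naming the
trait. Loadings are reported so correlated trait groups can be read off
by sign and magnitude.

## The simulators

`simulate_family()` draws the ancestor motif from the model's stationary
frequencies, gives each propeller a short founder branch (0.05
substitutions/site by default), tandem-fuses five to seven copies, and
evolves every motif independently for the propeller's age, drawn
log-uniformly over 0.1–1.5 substitutions/site so the clock plot spans
divergences evenly. A young single-motif protein evolves directly from
the ancestor (scenario A) or is copied from the first repeat of the first
propeller (scenario B, the co-option alternative). Indels are off by
default; an optional per-motif indel (geometric length, ≤3 residues)
stresses repeat detection and alignment. What the simulator does *not*
emulate: domain architecture around the motifs, codon-level mutation
bias, site-specific rate variation, selection, and any cellular biology
(chaperones, proteases) behind the expression-level traits — so
agreement on simulated data validates the estimators, not the biology.

`simulate_proteome()` embeds a family among composition-matched decoys
(residues resampled from the pooled family composition; lengths uniform
over 60–400 residues) at seeded positions, returning a truth manifest.
`simulate_curve()` evaluates the requested biophysical model exactly and
adds Gaussian noise; every generator is a pure function of its seed and
spec.

## Problem sizes used by the test suite

The suite runs entirely on simulated data at sizes chosen to make the
statistical claims meaningful while keeping a full run in a few minutes:
repeat-detection recovery over 100 seeded families; tree monophyly over
20; MPA recovery over 50 (10 leaves × 47 columns each); clock correlation
over 50 families of 11 propellers; directionality over 20 scenario-A/B
pairs; model selection over 100 curves per generating model; three-state
parameter recovery over 100 curves at 61 points. Thresholds are the ones
stated with each property, asserted under fixed seeds.

## Known limitations

- The aligner and tree builder are special-purpose (near-equal-length
  repeat motifs, ≤ a few dozen leaves); neither is a general phylogenetics
  replacement, and no joint (as opposed to marginal) ancestral
  reconstruction or indel-history inference is attempted.
- Karlin–Altschul parameters are the published constants for
  BLOSUM62/11/1 rather than estimated from the score distribution of each
  proteome; e-values on unusual compositions are correspondingly
  approximate.
- Unfolding fits report apparent parameters: oligomer dissociation terms,
  baseline curvature, and ligand linkage are not modeled.
- Intermediate-fraction uncertainty bands, where needed, come from the
  fit covariance (delta method), not bootstrap; with the dense gradients
  used here the difference is immaterial.
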