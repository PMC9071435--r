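---
title: "Modelling and profiling end-joining ligation fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and profiling end-joining ligation fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligfid)
```

## The assay and its data model

In a multiplexed end-joining assay, a hairpin substrate carrying a
randomized four-base 5′ overhang is ligated in one pot, so all 256 overhangs
compete for all possible partners simultaneously. Sequencing each ligation
product yields top- and bottom-strand consensus sequences from which the two
joined overhangs are read off. `ligfid` represents the outcome as a
256 × 256 **pair-count matrix**: because the labelling of the two strands of
a product is arbitrary, every product is counted once in each orientation
(top→bottom and bottom→top). This convention has three consequences the
package relies on throughout:

* the matrix is exactly symmetric, and the total ordered count is
  2 × the number of products;
* a palindromic self-ligation (e.g. ACGT with itself) contributes 2 to its
  diagonal cell, so the parity invariant holds without special cases;
* ordered-event fractions equal product fractions, and each orientation
  attributes to its *top* overhang, so per-overhang statistics see each
  product once per participating overhang.

Geometry: overhang positions N1..N4 are numbered 5′→3′ on each strand, and
top position *i* opposes bottom position 5 − *i*. The Watson–Crick partner
of an overhang is therefore its reverse complement. Positions 1 and 4 are
the **edge** of the junction (adjacent to the nick being sealed), positions
2 and 3 the **middle**; mismatch statistics aggregate at exactly this
granularity because that is how positional mismatch tolerance differs in
practice. A mismatch record is written `top:bottom` (e.g. T:G), and because
both orientations are counted, the T:G and G:T labels of one physical
mismatch both appear in the spectrum — deliberately, as both orientations of
the junction are chemically distinct ligation sites.

## The generative model

The simulator is an event-level model of the competitive annealing
equilibrium: each ligation event draws an unordered overhang pair from a
multinomial whose weights are

$$\mathrm{propensity}(a, b) = w_a\, w_b\; e^{\alpha\, \mathrm{gc\_pairs}(a,b)}
  \prod_{\text{mismatched positions}} \mathrm{tol}(\text{type},
  \text{class})$$

with parameters:

| parameter | meaning | default |
|---|---|---|
| `weights` (w) | per-overhang ligation propensity (unitless, relative) | 1 (uniform) |
| `anneal_coeff` (α) | log-scale boost per correctly paired G:C position | 0 |
| `tolerance` | mismatch tolerance in [0, 1] per unordered base-pair type × edge/middle | 0 (Watson–Crick-only) |

Design choices made here, and why:

* **Event-level multinomial, not annealing kinetics.** The assay outcome is
  a competition among annealed pairings; a propensity-weighted multinomial
  is the smallest model that exposes exact closed forms
  (`expected_profile()`) for every downstream statistic, which is what makes
  oracle testing possible. Progress curves, enzyme saturation and abortive
  intermediates are intentionally out of scope.
* **Tolerance keyed on unordered type × position class.** G:T and T:G are
  one physical pairing; edge and middle are the two empirically distinct
  position regimes. Finer keying (per exact position, per neighbour context)
  would not be identifiable from pair counts alone.
* **GC-pair count, not nearest-neighbour ΔG.** The stratification used in
  reporting is GC content, so the model's annealing term uses the same
  coordinate. A thermodynamic stacking model is a non-goal.
* **Symmetry.** All three terms are symmetric under (a, b) → (b, a), so the
  expected ordered-pair distribution is symmetric — matching the
  dual-orientation convention of real data.

### What the model does and does not predict about GC trends

With α > 0 and Watson–Crick-only tolerances, expected normalized frequency
increases strictly with GC bin — the observed bias direction. Fidelity is
subtler. Under this propensity model a mismatch at a G:C position *forfeits*
its annealing credit, so with a tolerance that is uniform across mismatch
types, the mismatch/WC propensity ratio for an overhang with k G/C bases is
$3t\,(k e^{-\alpha} + (4-k))$ — i.e. fidelity would *rise* with GC content.
The decreasing fidelity-vs-GC trend seen in real ligases emerges from the
same model once mismatch tolerance is concentrated on G/C-involving types
(G:T, G:G, C:C), because G/C-rich overhangs then simply have more tolerated
mispairing opportunities. The `"permissive"` preset is parameterized this
way and reproduces the decreasing trend; the property test asserts it on the
exact expectation, not on samples.

```{r gc-direction, eval = FALSE}
E <- expected_profile(ligase_model_preset("permissive"))
gc_binned_summary(per_overhang_fidelity(E))$mean  # strictly decreasing
```

### Presets

`ligase_model_preset()` ships four illustrative regimes: `uniform` (no
bias), `strict-gc` (strong α, very low tolerance — the high-bias,
high-fidelity corner), `moderate` (mild α, G:T-dominated tolerance) and
`permissive` (α ≈ 0, broad tolerance including purine:purine). These are
parameter regimes for testing and exploration, **not** fits to any measured
ligase: no public parameter values exist for this model class.

## The synthetic-data generator

`emit_reads()` writes one product per event: top and bottom strands, each
5′→3′, with layout `left anchor | overhang | right anchor | control | tail`.
The layout emulates the real substrate *structurally*: fixed 20-mer constant
anchors (package constants — the real substrate sequence is proprietary to
the assay design and is not reproduced), a four-base overhang, and an
internal 6-base randomized region that mirrors the synthesis-bias control.
Uniform per-base substitution errors model residual consensus errors. What
the generator does **not** emulate: hairpin secondary structure,
quality-score profiles, indels, chimeric reads, or BsaI digestion artefacts.
Tests that pass on generated data therefore validate the *analysis logic*
(counting conventions, statistics, round-trip identities), not robustness to
every artefact of real sequencing runs.

Synthesis bias is simulated by multiplying model weights with
`synthesis_weights(base_freqs)` (pool abundance = product of per-position
base frequencies) while emitting control regions from the same composition;
`synthesis_bias_correction()` then divides the observed frequency by the
expected abundance inferred from the control tallies and renormalizes to
mean 1. On the exact expectation of a fully permissive uniform ligase this
correction is the identity transform of the skew — flat at 1.0 to machine
precision — which is the closed-form test of the correction. Raw
(uncorrected) frequencies are the default output, since whether published
profiles are pre-corrected is assay-pipeline-specific; both modes are
available.

## Extraction

Anchors are located by **exact** substring match; the four bases between
left anchor and right anchor are the overhang. Consensus reads are high
accuracy, so a read whose anchors do not match is treated as unusable rather
than rescued — with an opt-in fuzzy mode (≤ 1 substitution per anchor) for
noisier inputs. Failures are classified (`anchor-missing`,
`wrong-gap-length`, `non-ACGT`), tallied and reported; they are never
silently dropped. No further read-level QC is imposed. The right anchor used
for matching is the constant prefix *before* the randomized control window,
which is why the substrate spec requires `control_offset ≥ 2`.

Count tables are read from CSV in either long form
(`top_overhang,bottom_overhang,count`, header optional) or wide 256 × 256
form, autodetected; asymmetric input — single-orientation counts — is
accepted with a warning and folded (`C + Cᵀ`) only on explicit request.
Replicates are combined by elementwise summation before any statistic is
computed, with metadata agreement enforced.

## Statistics: conventions and numerical choices

* **Normalized frequency** is scaled to mean 1 over the 256 overhangs
  (sums to 256). Mean-1 makes group summaries directly interpretable: a
  TNNA-family mean below 1 *is* under-representation.
* **Per-overhang fidelity of palindromes** counts the diagonal cell as
  correct — forced by the Watson–Crick definition, since a palindrome is its
  own partner.
* **Undefined values** (overhangs with zero events) are reported as `NA`,
  never 0, and excluded from bin means/medians to avoid biasing summaries of
  sparse samples.
* **Spectra** are normalized within each position class, so edge and middle
  panels are each interpretable as a composition.
* **Scale and relabeling invariance**: every statistic is invariant under
  multiplying all counts by a constant and under transposing the matrix;
  both are property-tested.
* **Bin comparisons** use a two-sided Mann–Whitney rank test between
  adjacent GC bins (`gc_bin_tests()`): per-overhang fidelities are bounded,
  skewed quantities for which a rank test is the conservative default.
* **Kinetics**: the initial-velocity fit retains timepoints up to but
  excluding the first one whose conversion exceeds the 25% cap (the cap
  applies to conversion, not time); OLS slope and its standard error are
  reported, with the standard error set to 0 for exactly collinear retained
  points and `NA` when only two points remain (zero residual degrees of
  freedom). Replicate averages report both the propagated fit error
  (quadrature, √Σse²/n) and the replicate SD, because published "error of
  the average" conventions are ambiguous between the two readings — this way
  either is recoverable.

## Problem sizes and tolerances in the test suite

Exhaustive checks run over all 256 overhangs and all 65,536 ordered pairs
(reverse-complement involution, palindrome count, mismatch enumeration
against a positionwise brute force, GC bin populations 16/64/96/64/16).
Closed-form oracle equivalence is asserted to machine precision (1e−14) on
`expected_profile()` against an independently constructed propensity matrix.
Stochastic checks use 10⁶ events: sampled overall fidelity within 3 binomial
standard errors of the closed form, a G:T-edge tolerance of 0.3 recovered
within 10% relative error from a single pair-to-WC count ratio, and
replicate frequency profiles correlating above 0.99. Pipeline identity
(simulate → emit reads at zero error → extract → tabulate) is exact, not
approximate, and is tested at multiple seeds; these sizes keep the full
suite around ten seconds.

## Known limitations

* The model is linear in propensities: it cannot express saturation effects,
  ligase excess/limitation, or time-dependence; it describes the end-point
  event composition only.
* Only 4-base 5′ overhangs are supported; 3′ overhangs, blunt ends and other
  lengths are out of scope.
* The mismatch tolerance table is position-class-level; real enzymes may
  distinguish N1 from N4.
* Anchor matching assumes consensus-grade reads; raw subreads would need
  alignment-based extraction, which the package does not attempt.
* Preset parameter regimes are illustrative. Fitting the model to measured
  count matrices (e.g. by maximum likelihood over the multinomial) would be
  a natural extension but is not implemented.
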