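---
title: "Methods: quantifying transmembrane-helix backbone dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transmembrane-helix backbone dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixdx)
```

## Scope and scientific setting

`helixdx` quantifies the backbone dynamics of single transmembrane (TM)
helices — the motivating system is the amyloid precursor protein C99
TM domain, the substrate of the intramembrane protease γ-secretase —
from two complementary data sources:

* **amide exchange kinetics** measured by mass spectrometry:
  deuterium-to-hydrogen exchange (DHX) of exhaustively deuterated
  peptides diluted into protonated solvent, with residue resolution from
  electron-transfer-dissociation (ETD) c/z fragment ladders; and
* **molecular dynamics trajectories** of the same helix, analysed for
  intrahelical H-bond occupancies, side-chain back-bonding, carbonyl
  packing, backbone fluctuations, hinge bend/swivel geometry, and the
  collective motion maximally correlated with H-bond opening
  (PLS functional mode analysis).

The bridge between the two worlds is the EX2 exchange regime: the
observed exchange rate of an amide is the intrinsic (fully exposed)
chemical rate times the probability that its H-bond is open.

## Intrinsic exchange rates

The intrinsic rate of a backbone amide is modelled as

$$k_{ch} = k_A\,[\mathrm{H^+}] \cdot F_A + k_B\,[\mathrm{OH^-}] \cdot F_B
          + k_W \cdot F_B,$$

with poly-DL-alanine reference constants and multiplicative
nearest-neighbour side-chain corrections $F_A, F_B$ (the classic
Bai–Englander factor tables, as curated in the SPHERE lineage; our exact
transcription is documented in `R/chem_rates.R`).  Separate reference
sets describe deuteron loss into H₂O (DHX) and proton loss into D₂O
(HDX); they differ in the rate constants *and* in the solvent ion
product (pK 14.17 for H₂O vs 15.05 for D₂O at 20 °C), which is why
intrinsic DHX is ~5-fold faster than HDX at the same meter reading —
the package reproduces this as a sequence-average
$k_{ch,DHX}/k_{ch,HDX} \approx 5$.

Design choices worth stating explicitly:

* **Operational pH.** The `pH` argument is the instrument reading; no
  glass-electrode (pD) correction is applied unless requested via
  `ph_offset`.  All headline numbers use the operational convention.
* **Acetylated N-terminus.** The model peptides are N-acetylated, so
  residue 1 carries a measurable backbone amide.  The acetyl cap has no
  entry in the published factor tables; we model it as an alanine-like
  amide neighbour (zero log-factor).  Its acid term is negligible at
  pH ≥ 4, so this choice does not move any reported quantity.
* **Temperature.** Arrhenius scaling per catalysis term (14/17/19
  kcal/mol for acid/base/water) and van't Hoff scaling of the solvent
  ion product; the reference temperature 293.15 K is also the default,
  so the correction is usually a no-op.
* **Validity range.** pH is restricted to [2, 9], inside which the
  factor tables were calibrated; ionizable side chains (Asp, Glu, His)
  blend their protonated/deprotonated factor sets by a
  Henderson–Hasselbalch fraction.

```{r rates}
pep <- app_peptide("A26-55_WT")
iso <- hdx_dhx_chemical_ratio(pep, pH = 5.0, temperature = 293.15)
round(c(mean_HDX_over_DHX = iso$mean_ratio, fold = iso$mean_inverse), 3)
```

## From exchange curves to free energies

Site-resolved analysis proceeds in four steps, each its own function so
every intermediate is testable:

1. `residue_content_from_fragments()` differences adjacent c (and,
   independently, z) fragments to localize deuterons to single amides.
   The ETD bookkeeping — the amide hydrogen of the cleaved residue
   travels with the c fragment, so $c_n - c_{n-1}$ localizes the amide
   of residue $n+1$ — is centralized in one pair of functions used
   identically by the synthetic generator, so the convention cannot
   drift.  The two terminal amides are never singly resolved by either
   ladder; they are reported through coverage flags and contribute to
   reconstructions through configurable bounds.
2. `fit_site_rate()` fits $y(t) = 0.95\,e^{-kt} + 0.05$ per residue —
   amplitude and baseline fixed by the 5 % residual deuterated solvent
   left by the 1:20 dilution — by weighted least squares
   (inverse-variance over replicates; unweighted fallback below two
   replicates).  Unidentifiable positions (signal at the floor) are
   flagged, never silently defaulted.
3. `delta_g()` converts rates to Linderstrøm–Lang opening free energies
   $\Delta G = -RT\,\ln\left(k_{exp}/(k_{ch}-k_{exp})\right)$, defined
   only where $k_{exp} < k_{ch}$.  Positions violating the domain are
   flagged `undefined`; positions within two standard errors of
   $k_{ch}$ are flagged `lower_bound` (the estimate is then an upper
   bound on flexibility, i.e. a lower bound on stability).  Intervals
   come from Monte-Carlo propagation with rejection counting.
4. `reconstruct_overall()` and `superpose_scale()` close the loop:
   summed site fits must reproduce the directly measured overall curve,
   and DHX/HDX curve pairs superpose under a single time-scale factor
   that reflects the chemical-rate ratio (~0.2 when scaling HDX onto
   DHX).  The reconstruction-agreement property doubles as the
   hydrogen-scrambling sanity check, since blocked termini rule out the
   ammonia-loss test.

The pH-matched time mapping `map_ph_time()` (equivalent time scales as
$10^{\Delta pH}$) is valid only while base catalysis dominates; the
function verifies the ≥95 % dominance precondition when given a peptide.

## Trajectory features

* **H-bond closure** uses the geometric criterion: O···H distance
  < 0.26 nm (strict inequality at the boundary) and O···H–N angle
  within 60° of linear (inclusive).  α (i→i−4) and 3₁₀ (i→i−3) bonds
  are counted separately; "helix" occupancy counts frames where either
  is closed, and a frame closed as both counts once.
* **Packing scores** sum a smooth switching function (1 below 0.35 nm,
  cosine ramp to 0 at 0.50 nm) over side-chain heavy atoms around each
  carbonyl oxygen.  The bounds are arguments, not constants.
* **Block MSF** superposes each block's frames iteratively on the block
  mean (tolerance 1e-6 nm) before computing Cα fluctuations, then
  standardizes the profile to zero mean and unit variance.  The
  conventional 30 ns block (3000 frames at 10 ps spacing) should exceed
  twice the autocorrelation time; short synthetic fixtures use
  proportionally smaller blocks.
* **MD→DHX bridge** (`md_to_dhx()`): per-residue rates
  $k_i = k_{ch,i}(1-\mathrm{occ}_i)$ (EX2 open-fraction form, exposed
  as a pluggable `rate_model`), overall curve
  $D(t) = \sum_i 0.95\,e^{-k_i f (t+t_0)} + 0.05$, with scaling $f$ and
  offset $t_0$ fitted by least squares and quality reported as the
  normalized $\chi^2$ (mean squared deviation over the variance of the
  experimental series — a convention chosen so that a constant model at
  the data mean scores exactly 1).  Note the documented degeneracy:
  only the product $f \cdot k_{ch}$ is determined.

## Helix geometry

Bending θ and swivel Φ describe the orientation of the C-terminal
segment axis (default I47–M51, carrying the ε-cleavage sites) relative
to the N-terminal segment axis (default I31–M35).

The **axis estimator** is the single largest unstated choice in this
kind of analysis.  We use the Kahn local-axis construction — cross
products of successive differences of Cα bond vectors — because it is
exact on ideal helices even for 5-residue segments.  A sliding-window
midpoint-PCA estimator is retained as an alternative strategy for long
segments, but on 5-residue segments the window mean does not cancel the
helical phase and biases the axis by ~15°, which is why it is not the
default.  For near-planar (extended) chains, where the curvature cross
products vanish, the estimator falls back to the principal direction of
the positions; truly collinear input is rejected.

The Φ = 0 reference is anchored at the Cα of G33 projected
perpendicular to the N-segment axis — an arbitrary but fixed
convention.  All consumers treat Φ on the circle: K-means clustering
runs on the planar embedding $(θ\cosΦ, θ\sinΦ)$, and free-energy
surfaces ($G = -RT\ln p$, minimum shifted to zero, empty bins NA)
are binned on the angles directly.

**Hinge classification** is a deliberately simplified rotation-axis
decomposition in the spirit of domain-motion analysis: superpose on the
N-segment, extract the residual rotation of the C-segment, and compute
percent closure $= 100\sin^2\psi$ with $\psi$ the angle between the
rotation axis and the inter-segment direction.  Closure > 50 % labels
the motion bending (B), otherwise twisting (T); two disjoint
deformation regions between the rigid segments yield double-hinge
labels (BB/BT/TB/TT) by classifying each rotation against the middle
rigid block.  Rotations below 2° are "no significant motion".  This
reproduces the *concept* of the published domain-motion programs and is
validated against planted constructions, not against their binaries.

## Functional mode analysis

The order parameter is the per-frame count of closed helix H-bonds in a
residue window (default V44–I47).  PLS1 regression (NIPALS; authored
here because the mode-extraction algebra is the method's core, and
cross-checked against an independent PLS implementation in the test
suite) maps centered backbone heavy-atom coordinates (N, Cα, C, O of
G29–L52 — we include the carbonyl O and document that choice) onto the
order parameter.  Training uses the chronological first half of the
trajectory, validation the second; the ensemble-weighted maximally
correlated motion (ewMCM) is the training covariance applied to the
regression coefficients, unit-normalized, so that overlap between modes
is a plain absolute inner product.  The number of components is chosen
where the validation correlation plateaus (gain < 0.02), and the full
$R_m$ curve is reported.

## Statistics

* `autocorrelation_time()`: first zero passage of the biased empirical
  autocorrelation function (the biased estimator damps the large-lag
  noise that would otherwise produce spuriously early crossings).
  Blocks for averaging should exceed twice this time.
* `bca_bootstrap()`: BCa intervals over resampled whole blocks
  (residues within a block stay together), 10,000 resamples by default,
  deterministic under a fixed seed.  Degenerate inputs yield flagged
  zero-width intervals rather than errors.
* `mc_propagate()`: independent Gaussian sampling (log-normal optional
  for strictly positive rates), with invalid draws — e.g.
  $k_{exp} \ge k_{ch}$ in the free-energy transform — rejected and
  counted; more than 50 % rejections flags the result unreliable.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
exercised; they emulate the *statistical structure* of the real
measurements, not their physics.

**Exchange datasets** (`gen_exchange_dataset()`): a per-residue ΔG
truth profile is inverted through
$k_i = k_{ch,i}/(1+e^{\Delta G_i/RT})$, per-residue retentions follow
the 0.95/0.05 model, fragment ladders accumulate them with the shared
ETD bookkeeping, and independent Gaussian noise (σ = 0.05 deuterons, a
typical fragment-level spread) is added per fragment, time point and
replicate.  The default design — 13 log-spaced incubation times from
0.1 min to 7 days, 3 replicates — copies the real measurement design so
that identifiability in tests matches identifiability in practice.  The
shipped truth profile (`tm_helix_truth_profile()`) is the archetypal
substrate helix: a flexible Gly-rich N-terminal half (ΔG < 2 kcal/mol)
joined to a rigid C-terminal half (~5 kcal/mol).

**Helix trajectories** (`gen_helix_trajectory()`): an ideal α-helix
backbone (φ = −57°, ψ = −47°, canonical bond geometry) with a planted
hinge bend (amplitude sampled per frame, AR(1)-correlated, with a
controllable bend direction), H-bond opening realized by displacing the
acceptor carbonyl 0.12 nm past the closure criterion under a two-state
Markov chain with prescribed stationary open probability and lag-1
correlation, optional Thr/Ser hydroxyl back-bond geometry, per-residue
positional jitter, and an optional planted linear mode with a recorded
scalar series.  Geometry is constructive, not dynamical: there is no
force field, no solvent, no membrane, and no coupling between H-bond
state and backbone geometry beyond what is planted.  Passing tests
therefore demonstrate that the *estimators* recover planted truth under
realistic noise and correlation structure — not that the generator
reproduces real TM-helix ensembles.

Problem sizes used in the test suite (500–5000 frames, 0.1–0.5 ns
blocks, 200–2000 bootstrap resamples in simulation loops) are the
package's own choice of scale for constructive fixtures; the analysis
defaults (30 ns blocks, 10,000 resamples) remain those appropriate for
µs-scale trajectories.

## Known limitations

* The intrinsic-rate tables are a transcription of published reference
  parameters; systematic solvent effects (e.g. reduced water activity
  in 80 % TFE) are not modelled, so derived ΔG values are upper
  estimates, as is inherent to the method.
* Fragment differencing cannot resolve the two most N-terminal amides;
  they enter reconstructions only through bounds.
* EX1-type correlated exchange, bimodal isotope envelopes and raw
  spectrum deconvolution are out of scope (EX2 only).
* The hinge classifier is a simplified two/three-segment decomposition;
  it does not reproduce published per-residue hinge-propensity
  percentages, which require the original µs ensembles.
* Trajectory I/O supports PDB (single/multi-model) and DCD; XTC is not
  read or written.
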