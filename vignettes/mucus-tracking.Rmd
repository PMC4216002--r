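---
title: "Tracking mucus obstruction in a branching airway tree: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking mucus obstruction in a branching airway tree: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungtrack)
```

## The problem

Cystic fibrosis (CF) and other obstructive lung diseases fill airways with
mucus. The clinic sees two kinds of evidence: spirometry — FEV1 (the volume
exhaled in the first second of a forced expiration) and FVC (the total
forced vital capacity) — and occasional imaging (MRI/CT), which localizes
"pockets" of mucus at roughly centimeter resolution. A 1 cm³ imaging voxel,
however, contains the last ten generations of the bronchial tree: thousands
of bronchioles whose individual state no scan resolves. `lungtrack`
estimates that unresolved micro-distribution — and its consequences for
future lung function — by sampling the space of mucus configurations that
are *consistent* with whatever is measured, and reporting the distribution
of consistent states rather than a single guess. Most consistent states
turn out to concentrate in narrow ranges of the quantities of interest
(which generations hold the mucus, how obstructed a voxel is), so this
maximum-entropy-flavored estimate is informative despite the enormous
degeneracy.

## The airway model

The lung is a complete symmetric binary tree of cylindrical segments over
generations 0 (trachea) to 23 (alveolar level). Geometry is fractal:
diameter and length scale by a fixed factor per generation, default
$2^{-1/3}$, which preserves total cross-sectional scaling in the spirit of
Murray's law and makes the lumen *volume* halve each generation. The
default trachea is 1.8 cm wide and 12 cm long; both values and the scale
factor are parameters of `airway_tree()`.

Each imaging voxel is identified with one generation-13 subtree
($2^{13} = 8192$ of them, matching the number of centimeter voxels in a
~6 L lung), spanning generations 13–23: ten bifurcations, 1024 terminal
bronchioles. Mucus volumes are quantized in units of the *smallest*
bronchiole's lumen volume (the generation-23 segment, ~0.0036 mm³ with the
default geometry): every configuration assigns each segment an integer
number of unit volumes, never exceeding its lumen. This quantization makes
exhaustive enumeration exact on small trees, which the test suite exploits.

All operations are parameterized by generation bounds; reduced trees (4–6
levels) and reduced lungs (16–64 voxels) are first-class objects used
throughout the tests and examples. The mapping from voxel coordinates to
subtrees (`assign_voxels()`) is a deterministic recursive bisection of the
coordinate bounding box that mirrors the tree's bifurcations — spatial
realism is deliberately sacrificed for exact reproducibility, and the
inverse problem is exchangeable over voxel order anyway.

## Airflow and accessible alveoli

Each segment's resistance is laminar Poiseuille flow, $8\mu L/(\pi r^4)$,
with air viscosity $\mu = 1.81\times10^{-5}$ Pa·s (20 °C). Mucus is
treated as a uniform annular lining: a fill fraction $f$ reduces the
effective radius to $r\sqrt{1-f}$, multiplying the resistance by
$(1-f)^{-2}$; $f = 1$ blocks the segment outright. The tree's total
resistance follows the series/parallel recursion
$R = R_{\text{seg}} + \left(\sum_{\text{children}} R_c^{-1}\right)^{-1}$,
with blocked subtrees contributing zero conductance (infinite resistance
propagates as conductance 0, never as floating-point arithmetic on
infinities). The second summary of a configuration is AA%, the percentage
of terminal segments reachable from the root through no fully blocked
segment. The recursion is verified in the tests against an independent
Kirchhoff nodal solve of the equivalent conductance network, exhaustively
on all small trees.

This flow model is intentionally the simplest defensible surrogate — it is
confined behind the `segment_resistance()` / `tree_flow()` contract, and
anything more sophisticated (transitional flow, compliant walls) can
replace it without touching the samplers.

## From lung state to spirometry

Whole-lung state is one (resistance ratio, AA%) pair per voxel. Voxel
subtrees combine in parallel beneath a series "upper airway" resistance
(generations 0–12, mucus-free by default since imaging attributes mucus to
voxels); whole-lung AA% is the equal-weight mean over voxels (the trees are
symmetric, so every voxel carries the same number of alveoli). Spirometry
is then:

* **FVC** — proportional to accessible alveoli:
  $\mathrm{FVC} = \mathrm{FVC}_{\text{healthy}} \cdot \mathrm{AA}/100$,
  anchored to the NHANES III adult reference regression (coefficients
  shipped as a versioned CSV in `inst/extdata`, clamped with a warning
  outside the table's validity range).
* **FEV1** — single-compartment RC emptying over one second:
  $\mathrm{FEV1} = \mathrm{FVC}\,(1 - e^{-1/RC})$, with the compliance
  constant calibrated once so the healthy lung gives the textbook
  FEV1/FVC = 0.8. Equivalently
  $\mathrm{FEV1}/\mathrm{FVC} = 1 - 5^{-R_h/R}$: monotone in resistance,
  0.8 at health, 0 for a fully blocked lung.

These two choices pin the *functional form* of the observable map. They are
the weakest part of any such model and are documented as replaceable; every
qualitative result in the package (monotonicity, endpoint behavior,
recovery of self-consistent targets) is insensitive to the particular
monotone forms.

## The Metropolis machinery

All sampling uses one constant-temperature Metropolis–Hastings driver
(`run_chain()`). Energies are squared relative errors with weights
$w_1 = w_2 = 1$:

* spirometric: $E = w_1\!\left(\frac{\mathrm{FEV1}-\mathrm{FEV1}^*}{\mathrm{FEV1}^*}\right)^2 + w_2\!\left(\frac{\mathrm{FVC}-\mathrm{FVC}^*}{\mathrm{FVC}^*}\right)^2$,
* voxel drill-down: the same form on (resistance ratio, AA%).

Degenerate targets degrade gracefully: an AA target of 0 uses an absolute
term on the AA fraction, a blocked (infinite) ratio target an absolute term
on the conductance ratio.

The proposal for mucus configurations draws one ordered pair of distinct
segments uniformly and moves one unit volume from the first to the second;
if that move is illegal (empty donor, full acceptor) the proposal is a null
move. This kernel is *exactly* symmetric — the probability of proposing any
legal unit move is $1/(N(N-1))$ in both directions — so the acceptance rule
needs no Hastings correction: accept when $\Delta E \le 0$, else with
probability $e^{-\Delta E/T}$. A uniform-donor/uniform-acceptor rule
without the null-move convention would *not* be symmetric (eligible-donor
and eligible-acceptor counts differ between states) and would distort the
flat-energy stationary law away from uniform; the tests verify both the
kernel symmetry (by exact enumeration) and the uniform stationary
distribution (chi-square against enumeration).

Temperature is a genuine tuning constant:

* `chain_settings()` defaults to $T = 0.01$ — at the squared-relative-error
  scale, a 1% spirometric mismatch costs about one $k_BT$, appropriate for
  *exploration*.
* For inverse fits that must land within a tolerance `tol`, the Boltzmann
  spread at temperature $T$ corresponds to roughly $\sqrt{T}$ relative
  mismatch, so the fitting examples and the acceptance runs use
  $T \approx \mathrm{tol}^2 = 5\times10^{-4}$ for a 2% tolerance.

Burn-in defaults to 10% of the chain, thinning to 10. Distribution-level
tests thin more aggressively (10–20) because chi-square statistics assume
nearly independent draws. Every chain is seeded once at entry and consumes
the global RNG in a documented order, so all results are bit-for-bit
reproducible from (config, seed).

## The offline tables: PDFE-2D

For a voxel at mucus fraction $f$, the joint density of (resistance ratio,
AA%) over all configurations holding that total is tabulated offline: fill
the subtree randomly, run the *flat-energy* chain (every legal move
accepted — unbiased exploration at fixed total volume), and histogram the
flow summaries of the retained states. The flat energy is deliberate: the
table is the conditional prior of a voxel's summaries given its mucus
content; all target-steering happens later, in the whole-lung chain that
consumes the tables. Two fractions need no chain: $f=0$ is a point mass at
(ratio 1, AA 100) and $f=1$ a point mass in the (blocked, AA 0) cell.

Binning: 100 AA bins on [0, 100] × 100 resistance bins on a log10 scale
over [0, 6] — ratios genuinely span orders of magnitude, up to ~$10^6$ just
before total blockage — plus one overflow row for blocked states.
Representative cell values are midpoints except at the physical extremes,
which snap to the attainable boundary (first ratio bin → exactly 1, blocked
row → ∞, last AA bin → 100, first → 0) so that healthy and fully blocked
voxels stay *exact* through the whole pipeline. The production fraction
grid steps by 0.02; tests and examples use coarser grids (0.1–0.25).
Densities at intermediate fractions are linear interpolations of the two
bracketing slices, renormalized.

Tables persist as a structured JSON container — one record per fraction
with integer cell counts and sample sizes, plus bin parameters and build
metadata (tree parameters, chain settings, seed), written with 17
significant digits so doubles round-trip exactly. Densities are recomputed
from counts on load, making save → load bit-exact. The per-slice sample
budget in the shipped defaults ($10^4$–$10^5$ retained samples per
fraction) is enough to resolve the mode structure and all monotone trends;
the table build is embarrassingly parallel over fractions if more
resolution is wanted.

## The inverse problem

`fit_lung()` (imaging mode): each listed voxel has a known mucus volume,
hence a known PDFE slice; the chain state is one (ratio, AA) pair per
voxel. The proposal resamples one uniformly chosen voxel's pair from its
slice. Because this *independence proposal* draws from the prior $\pi_0$,
the Metropolis–Hastings ratio for the target
$\pi(x) \propto \pi_0(x)\,e^{-E(x)/T}$ is

$$\frac{\pi(x')\,q(x\mid x')}{\pi(x)\,q(x'\mid x)}
  = \frac{\pi_0(x')e^{-E'/T}\,\pi_0(x)}{\pi_0(x)e^{-E/T}\,\pi_0(x')}
  = e^{-(E'-E)/T},$$

so the plain Metropolis rule samples prior × Boltzmann exactly. The
minimum retained energy is compared against a feasibility threshold
(default $10^{-3}$, ~2% mismatch per term); an infeasible fit — targets no
lung state can reach — is flagged, not hidden.

`fit_lung_spirometry()` (no imaging): per-voxel mucus volumes join the
state. Two additional symmetric move types operate on a quantized
allocation — transfer of one quantum between an ordered pair of voxels, and
birth/death of one quantum in one voxel (each direction with probability
1/2, illegal moves null). The quantum defaults to 2% of a voxel's lumen
capacity, matching the production fraction grid; using the generation-23
unit volume here would make inter-voxel mixing astronomically slow. A voxel
whose mucus changes gets its (ratio, AA) pair redrawn from the slice at its
new fraction, so the pair part of the proposal remains an independence draw
and the acceptance rule is unchanged. The chain starts from a
moment-matched total (the AA needed for the FVC target, inverted through
the table's mode curve) — this positions the start, not the posterior.

**Identifiability and calibration.** Spirometry alone cannot resolve
*where* mucus sits, so the spirometry-only posterior is an inference under
the sampler's maximum-entropy prior: allocations uniform over the
quantized lattice, pairs from the offline tables. Its credible intervals
are calibrated in exactly that sense — when the true lung state is itself
a draw from this generative prior, the central 90% interval covers the
true total mucus at the nominal rate, and the test suite checks this by
simulation-based calibration. Two systematic caveats follow for truths
that are *not* prior draws. First, mucus beyond a voxel's blocking
threshold is spirometrically invisible (a blocked voxel looks the same
with any further mucus), so totals in saturated pockets are bounded below,
never pinned. Second, pocket-concentrated truths violate the spread-out
allocation prior, and the posterior total then runs systematically high
(typically tens of percent on the reduced test lungs): the same
spirometric deficit is most numerously realized by many mildly loaded
voxels carrying more total mucus than a few concentrated pockets. The
tests assert order-of-magnitude accuracy (within a factor of two) for
pocket truths; when imaging is available, `fit_lung()` removes the
ambiguity entirely because per-voxel totals are data, not state.

## Drill-down and the generation profile

`drilldown_voxel()` runs the configuration chain inside one voxel at fixed
total volume with the voxel energy steering toward the voxel's sampled
(ratio, AA) pair, then averages per-generation mucus over retained samples.
The profile is reported as *normalized mucus*: the generation's share of
the voxel's mucus divided by its share of the voxel's air volume — 1
everywhere means mucus spread in proportion to available lumen; the
profile is invariant to rescaling all mucus by a common factor, and a voxel
with no mucus reports an all-zero profile by convention. A target pair is
considered met at ≤5% relative residual per component (on the reduced test
trees the AA granularity of 100/16 makes finer residuals unattainable by
construction); otherwise the best-found profile is returned flagged with
its residuals. Mildly obstructed voxels put the dominant normalized
generation at the distal end; heavily obstructed ones shift it proximally
into larger bronchioles — the acceptance suite checks this reversal.

## Forecasting

`grow_mucus()` extrapolates each voxel linearly at a global or per-voxel
rate (mm³/year), clamped to [0, lumen capacity]; negative rates model
treatment response. There is deliberately *no default rate* — it is an
external clinical input. `predict_spirometry()` then draws, independently
per iteration, one pair per voxel from the grown fractions' slices and
histograms the resulting (FEV1, FVC) — simple Monte Carlo, not a chain,
since nothing conditions the draws. Horizon 0 reproduces the ungrown
forecast exactly under the same seed, and non-negative rates shift the FVC
distribution stochastically downward.

## The synthetic-patient generator

`generate_patient()` emulates the imaging summary: a lung-shaped voxel set
(two ellipsoidal masks on the 1 cm grid), a small number of contiguous
spherical pockets with fractions drawn from a given range (default
0.3–0.8, a realistic severity spread for established CF disease), and —
crucially — a concrete ground-truth *micro-configuration* per pocket voxel
(uniform random fill), whose exact flow summaries aggregate to the
ground-truth FEV1/FVC. Default demographics (22 years, 170 cm, male) sit in
the typical adult-CF range. The generator does **not** emulate MRI noise,
partial-volume effects, lobar anatomy, or asymmetric airway trees, so
passing recovery tests demonstrate the *inference machinery* is correct and
calibrated on model-consistent data — not that the physiological model is
an accurate image of any particular patient.

## Numerical choices and problem sizes

* Exact integer bookkeeping for mucus (unit volumes) — conservation is
  exact, never approximate.
* Blocked segments are zero conductance throughout; `Inf` appears only in
  reported resistances and ratios.
* Mode-curve ties break toward lower resistance, then higher AA —
  deterministic output.
* Test and acceptance problem sizes: full voxel subtrees (generations
  13–23, 2047 segments) with $10^4$ retained samples per fraction on a
  6-point grid; reduced 64-voxel lungs for whole-lung fits (40k steps);
  5-level subtrees and enumerable toy trees for the exact oracles. These
  sizes resolve every monotone trend and endpoint identity with margin
  while keeping a laptop-scale runtime; scaling any of them up is a
  parameter change, not a code change.

## Known limitations

* Symmetric (Weibel-type) geometry only; real bronchial trees are
  asymmetric and the voxel ↔ subtree map here is combinatorial, not
  anatomical.
* The FEV1(resistance) map is a calibrated one-compartment surrogate.
* Spirometry-only total-mucus inference is a lower bound once pockets
  saturate (see Identifiability above).
* Upper airways (generations 0–12) are assumed mucus-free; proximal
  disease would be attributed to voxels.
* PDFE tables assume every voxel shares one subtree geometry; per-voxel
  geometry would need one table per geometry class.
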