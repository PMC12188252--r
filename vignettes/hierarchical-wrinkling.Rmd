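---
title: "Hierarchical wrinkling of growing bilayers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical wrinkling of growing bilayers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoridge)
```

## The physical picture

An accretionary structure such as a mollusc shell records the shape of a
thin generative zone — a stiff organic layer (the periostracum) bonded to a
softer, faster-growing elastic layer (the mantle edge) — as it deforms over
developmental time. The growing length mismatch between the layers drives a
wrinkling instability; continued growth both amplifies the wrinkles and
expands the domain, opening space into which smaller wrinkles of the next
hierarchical level intercalate. The spatial pattern therefore encodes its
own developmental history: level 1 is oldest and largest, level `k + 1`
appears in every gap of the current pattern. From two primaries the label
sequence runs `1.1`, `1.2.1`, `1.3.2.3.1`, `1.4.3.4.2.4.3.4.1`, and the
per-level counts follow `N_{k+1} = (total bumps) − 1`.

## Reduced model

The interface is a graph `y(S, t)` on `[−L(t), L(t)]` with energy

$$E[y] = \int \tfrac{E_b}{2}\,(y'')^2 + \tfrac{K}{2}\,(y-\hat y)^m \,\mathrm{d}S,
\qquad \tfrac12 \int (y')^2 \,\mathrm{d}S = 2\delta(t),$$

minimized quasi-statically: growth is slow compared with elastic
relaxation, so the shape is always an energy minimum under the current
constraint. The shape is restricted to a sum of *separated* Gaussian bumps
(footprint convention `4σ`), one amplitude and width per hierarchical
level. For a single bump the three integrals evaluate exactly to
`c_b a²/σ³`, `c_l a²/σ` and `c_i(m) (a-\hat a)^m σ` with
`c_b = (3/2)√(π/2)`, `c_l = √(π/8)`, `c_i(m) = √(π/m)`; these coefficients
are verified against adaptive quadrature in the test suite, and the package
exposes both the raw convention and the reduced one in which the constants
are absorbed into `μ` and `δ`:

$$E = \sum_k N_k\left(\frac{a_k^2}{\sigma_k^3}
      + \mu\,(a_k-\hat a_k)^m \sigma_k\right),
\qquad \sum_k N_k \frac{a_k^2}{\sigma_k} = 2\delta(t).$$

The conversion is `E_raw = E_b c_b E_red` with `μ = (K/2E_b)·c_i(m)/c_b`
and `δ_raw = c_l δ_red`. Gaussians are not Euler–Lagrange solutions; the
reduction is an energy-method (Rayleigh–Ritz) restriction whose quality is
checked by the in-package oracle (below).

## Solving the hierarchy

Eliminating the constraint with a multiplier `λ` gives, per level and
without memory, `x_k = a_k² = [2(λσ_k²−1)/(mμσ_k⁴)]^{2/(m−2)}` for
`λσ_k² > 1` and `x_k = 0` otherwise; `λ` follows from the constraint
(linearly for `m = 4`, by monotone bracketing otherwise). The energy is
convex in the `x_k`, so this stationary point is the global constrained
minimum. Three consequences drive everything else:

* **Width selection.** With `a₁` eliminated, the level-1 energy
  `2δ/σ² + μN₁^{1−m/2}(2δ)^{m/2}σ^{1+m/2}` has the closed-form minimizer
  implemented in `select_sigma1()`; for `m = 2` it is the
  `δ`-independent `μ^{−1/4}`, for `m = 4` it scales as `δ^{−1/5}`.
* **Bifurcation times.** Level `k` can first carry amplitude when
  `λ(t)σ_k(t)² = 1`, with `σ_k(t)` fixed by the requirement that all
  footprints tile the domain, `Σ_{j≤k} 4N_jσ_j = 2L(t_k)`. Widths freeze at
  their bifurcation value (wrinkle wavelengths in such systems are set at
  onset and persist). Onset times are refined by bisection between grid
  points; ties at the margin are broken toward `a_k = 0`, avoiding
  subcritical ambiguity.
* **The `m = 2` theorem.** With the optimal level-1 width, the two-level
  energy is linear in the level-2 length share with slope
  `(σ₁²−σ₂²)(1/σ₁²σ₂² − μ) ≥ 0` for every narrower `σ₂`; a linear
  foundation force therefore never produces a hierarchy.
  `level2_onset_margin()` exposes this margin and the tests sweep it.

**Window convention.** For `m > 2` the optimal width diverges as
`δ → 0`, so under growth from a pristine state the first mode to fit is a
single domain-spanning bump — which has no gaps and can never intercalate.
Hierarchy simulations therefore open the observation window with a small
pre-existing excess (`delta0 > 0` in `growth_schedule()`), representing a
system observed after its initial instability has established a level-1
pattern; the level-1 mode is then the maximal count whose optimal-width
footprints fit at the window start (the energy at fixed `δ` decreases with
the mode number for `m > 2`, so the maximal fitting mode is the
energy-minimizing one). The canonical two-primary runs force `N1 = 2`
explicitly. If a level's onset condition already holds when its
predecessor freezes (abundant leftover space), its onset clamps to that
time.

**Defaults.** `L(t) = L0(1 + t)`, `δ(t) = δ0 + g L0 t` with `L0 = 6`,
`g = 0.1`, `δ0 = 0.04`, `μ = 30`, `m = 4`, grid `dt = 10⁻³`–`2·10⁻²`
depending on horizon. Under these conditions the solver attains six levels
by `t = 8`; the acceptance script reports exactly this run (401 stored time
points at `dt = 0.02`). The morphospace demonstration uses
`μ ∈ {3, 30, 100, 300}`, `g ∈ {0.05, 0.1, 0.15, 0.2}`, chosen so that every
cell has an interior level-2 onset: the level-1 count rises from 2 to 4
across the `μ` range and `t₂` falls with `g` in every row.

## Memory

Remodelling relaxes the foundation rest shape toward the deformed shape,
`∂ŷ/∂t = η(y − ŷ)`; within the reduction `ŷ` shares widths and centres
with `y`, so only the memory amplitudes `â_k` evolve. `evolve_with_memory()`
uses operator splitting per step: quasi-static minimization with the
shifted interaction `(a_k − â_k)^m`, then the exact exponential update
`â' = a + (â − a)e^{−ηΔt}`. Minimize-then-relax order is a documented
choice; with the exact integrator the two orders differ at `O(Δt)` and
converge on refinement. A newly bifurcated level starts with `â = 0`. With
`η = 0` the code path reduces to the memory-less engine, bit-identically on
the same grid.

Memory is what preserves hierarchy: without it the multiplier grows until
narrower levels are cheaper per unit length (`x(σ)` becomes decreasing in
`σ` once `λσ² > 2`) and level 2 overtakes level 1 — under the default
conditions the crossing happens near `t ≈ 0.84`. With `η = 0.5` the level-1
memory keeps its interaction cost low and the ordering `a₁ ≥ a₂` holds
throughout the same horizon.

## Spine dilation

A growth burst (`L` frozen, `δ` rising ~100× faster, defaults `μ = 10`,
burst to `δ = 1`) dilates a pre-existing ridge pattern. Ridge fixtures tile
the domain (`Σ N_k 4σ_k = 2L`) with a per-level width ratio of 1/2, so the
same label sequence on a smaller domain is a denser, narrower pattern. Two
pathways are compared under the identical constraint and marginal-stability
machinery:

* **Linear**: each ridge amplifies in place at its ridge width. In dense
  patterns the multiplier never reaches `1/σ₂²` and level-2 amplification
  simply never onsets — an outcome of the same test, not an assumption.
* **Fractal-like**: one root spine per level-1 ridge takes the domain
  width (`4σ_root = 2L/N₁`), and deeper ridge levels become children on the
  flanks of the previous level (`"chain"` policy; `"spread"` attaches all
  to the root). A child appears once its parent's amplitude reaches the
  child footprint, `a_parent ≥ 4σ_child` — the parent flank is the child's
  domain, and its amplitude is the natural proxy for available flank
  length. The threshold factor is configurable. Energy stays additive over
  nodes because each bump remains separated on its own (flank) domain.

Since per bump the excess length scales as `a²/σ`, bending as `a²/σ³` and
the quartic interaction as `σa⁴`, narrow ridges make in-place
amplification bending-dominated (`E ≈ 2δ/σ₁²`) while a domain-wide root
pays mostly interaction (`∝ μδ²σ³`). The difference
`E_lin − E_frac ≈ 64δ/L² − 0.48μδ²L³` is monotone in `L`, so the favoured
pathway flips exactly once along a density sweep — the sequence
`3.2.3.1.3.2.3` dilates linearly at `L = 3` and fractally at `L = 1`.

## Validation oracle

`minimize_full()` minimizes the discretized raw functional over nodal
heights (second differences, trapezoid weights, clamped-flat ends
`y = y' = 0` at `±L`, a stated choice consistent with bumps vanishing at
the boundary). Two technical points matter. First, the discrete arc-length
functional is quadratic in the height vector, so the constraint is enforced
*exactly* by radially rescaling inside the objective, leaving a smooth
unconstrained problem for L-BFGS with an analytic gradient. Second, the
minimization is restricted to one-sided deflections `y ≥ 0`: the even
interaction `y⁴` admits lower-energy two-sided waves, but the modelled
system deflects away from the rigid substrate only, and the one-signed
Gaussian ansatz builds that in — the oracle must compare like with like.
Starting from the ansatz profile, monotone descent guarantees
`E_full ≤ E_ansatz` at matched excess.

`minimize_overlapping_gaussians()` relaxes only the separation assumption,
optimizing amplitudes, widths and centres jointly with all cross terms by
quadrature (fixed fine trapezoid grid), the same rescaling trick, and a
fixed deterministic list of perturbed starts (no RNG). The restriction
chain `E_full ≤ E_overlap ≤ E_separated` and amplitude agreement within 5%
before the level-2 onset are asserted in the tests on a compact
configuration (`m = 4`, `μ = 100`, `L0 = 2`, `δ0 = 0.25`, grids of 161–321
nodes; refinement changes the energy by under 0.1%).

## Rendering

`sweep_surface()` stacks one profile row per stored time: as a planar strip
(the shell-edge record), as an expanding disc (arc coordinate mapped to
angle, radius `L(t)/π` plus the displacement — the radial-history motif of
mushroom lamellae), or painted as a normal displacement onto a logarithmic
helicospiral generating curve. The helicospiral mapping is a deliberately
simplified dressing of a smooth coiled surface with the mechanically
computed pattern; shell geometry does not feed back into the mechanics.
Meshes export as ASCII OBJ/PLY and round-trip through the bundled readers.

## What the generator does and does not emulate

The configuration records produced by `growth_schedule()`,
`material_params()` and `ridge_pattern()` *are* the study conditions: growth
is deterministic and linear (or burst-like), all bumps of a level are
identical, and there is no measurement noise, spatial heterogeneity or
biological variability. Passing tests therefore demonstrate internal
consistency of the mechanical theory and its reduction — not agreement with
measured shells. Real systems add stochastic growth, non-identical bumps,
viscoelasticity beyond the single relaxation rate `η`, and genuinely
three-dimensional mechanics.

## Known limitations

* The hierarchy path assumes intercalated sequences; arbitrary bump
  arrangements are supported by the energetics but not by the solver.
* For `m > 2` with a pristine start (`δ0 = 0`) the model's first fitting
  mode is a single bump; hierarchical runs require the positive-`δ0`
  window convention described above.
* Onset detection with memory (`η > 0`) resolves bifurcation times only to
  the step size; the memory-less path refines them by bisection.
* The flank-fit criterion and child-placement policies of the fractal
  pathway are reconstructions with configurable knobs, not derived from a
  three-dimensional model.
* `m = 3` relies on guarded scalar root-finding rather than closed forms
  and is slower; `m ∈ {2, 3, 4}` are the supported exponents.
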