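---
title: "Methods: a multicellular SR latch as a stiff ODE system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multicellular SR latch as a stiff ODE system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(srlatch)
```

## The model

The package simulates a four-cell yeast consortium implementing a 1-bit
set-reset latch. Each engineered cell type is described by a small number of
lumped intracellular states; the cells are coupled only through two
medium-borne α-factor pheromones (X and Y), assumed well mixed, at constant
cell density.

**Sender cells (1 and 2).** Input induction is a Hill function of the
external inducer concentration (R for cell 1, S for cell 2):

$$\dot M = k_{tx}\frac{u^{n}}{K_u^{n}+u^{n}} + k_{tx0} - d_m M,\qquad
  \dot A = k_{tl} M - (k_{sec}+d_p) A,$$

with mRNA $M$ and prepro-α-factor pool $A$. Cell 1 feeds the medium pool
of pheromone Y, cell 2 feeds X. (This wiring makes a (1,0) write drive the
readout negative; the original circuit description is internally
inconsistent on which pheromone the senders secrete, and the package
follows the convention consistent with the readout's sign.)

**NOT cells (3 and 4).** A saturable pathway stage $F$ (a lumped proxy for
the activated mating MAPK cascade, capacity $F_{tot}$), a repressor $Z$
(LacI-type), and the cell's own prepro-α-factor $\varphi$:

$$\dot F = k_{act}\frac{L}{K_L+L}(F_{tot}-F) - k_{deact}F,\qquad
  \dot Z = k_{34} F - d_Z Z,$$
$$\dot\varphi = \frac{\gamma}{1+(Z/\beta_c)^{h}} - (k_{sec}+d_p)\varphi,$$

where $L$ is the cognate medium pheromone (Y for cell 3, X for cell 4).
Cell 3 produces $\varphi_x$ (feeding medium X), cell 4 produces
$\varphi_y$ (feeding Y): each NOT cell silences the pheromone the *other*
one senses, closing the cross-repression loop.

**Medium and reporter.**

$$\dot X = \sigma (A_2 + \varphi_x) - k_{\alpha,deg} X,\qquad
  \dot Y = \sigma (A_1 + \varphi_y) - k_{\alpha,deg} Y,\qquad
  \dot G = k_{gfp}\frac{1}{1+(Z_4/\beta_c)^{h}} - k_{gfp,deg} G.$$

$\sigma$ is an effective secretion factor proportional to cell density
($\sigma = k_{sec}\cdot\text{density}/5\times10^6$), lumping export and the
intracellular-to-culture volume ratio. GFP is co-expressed with
$\varphi_y$ in cell 4.

One first-order stage is used from pathway activity to repressor; whether
the repressor rate constant acts on its mRNA or protein is not resolved by
the original description, and lumping them changes only the effective
turnover time, which is calibrated anyway. $k_{34}$ multiplies the
pathway-activity concentration directly so that it keeps units of
s$^{-1}$, the unit in which its published scan ranges are quoted.

## Parameters and calibration

The published supplementary rate table behind the original study was not
available, so the defaults of `circuit_params()` are a calibrated reference
set. The calibration contract (enforced by the test suite) is behavioral:

* bistable at $k_{\alpha,deg}=0.134$ s$^{-1}$ (at 192 and at 40 µg/ml
  input), monostable at 30 s$^{-1}$ with the equilibrium on the
  medium-pheromone diagonal;
* transient memory grows as the clearance rate approaches the bistable
  window from above;
* quality $\Theta_S\approx0.6$ at $\lambda=0.4$ for the default set,
  matching the baseline reported for the original circuit design.

Choices a user may care about:

* `hill_rep = hill_in = 2`: cooperativity ≥ 2 is needed for a robustly
  bistable cross-repression loop; the original description leaves the exponents unstated.
* `K_u = 40` µg/ml: half-saturation of input induction, set to the lowest
  input concentration reported to latch the original design.
* `K_L = 1e-10` mmol/ml (0.1 nM): receptor-pathway half-saturation, placed
  between the latched and cleared medium-pheromone levels so that the loop
  gain collapses at high clearance (monostability) but saturates in the
  latched state.
* Repressor turnover `d_Z = 5e-4` 1/s (≈ 23 min half-life): the write speed
  of the latch is limited by this cascade stage; slower turnover degrades
  the response score S_r far below the hold score S_m, which is exactly the
  pattern reported for the original parameter set.
* `k_tx0 = 0`: no basal sender expression. With it, the origin is absorbing
  only if the constitutive NOT-cell source γ is also zero, since the
  repressible promoter is active at zero repressor.

With these defaults the upper edge of the bistable region sits at
2.5–3.9 s$^{-1}$ — a narrow *subcritical* band in which the symmetric state
is already stable while the latched states still exist — versus ≈ 8.7 in
the original study. Its lower monostable window (clearance below
~0.1 s$^{-1}$) is absent here: it presumably arises from basal-expression
details of the full published pathway, and adding enough basal
transcription to recreate it destroys bistability at 0.134 s$^{-1}$ in
this coarse-grained model. Both deviations affect only numeric boundary
reproduction, not the qualitative regime structure.

## Numerical integration

The system is stiff: medium clearance rates scanned up to 500 s$^{-1}$
coexist with hour-scale repressor dynamics over 300-h horizons. No stiff
ODE solver package is assumed; the package compiles its own adaptive
**L-stable Rosenbrock 2(3)** step (Shampine–Reichelt type) with an analytic
Jacobian, step-doubling-free embedded error control, and integration
restarts at every input breakpoint so the step controller never straddles a
discontinuity. Breakpoints therefore appear exactly in the output grid.

* Default tolerances: `rtol = 1e-12`, `atol = 1e-26` (far below the
  smallest meaningful concentration). The historical choice of a 1e-15
  relative tolerance for this problem is below double-precision round-off
  for an adaptive method; 1e-12 is the tightest numerically meaningful
  setting and the test suite verifies that tightening to 1e-13 moves
  endpoints by < 1e-6 relative.
* Output cadence: 60 s by default; the test suite verifies quality scores
  move by < 1e-3 when refined to 6 s.
* Non-negativity is preserved structurally (every loss term is proportional
  to its own species); Hill terms clamp negative arguments, and the
  integrator rejects non-finite states.
* Screening tasks (stability classification, sweeps) default to looser
  tolerances (1e-8 to 1e-10) since they need attractors, not 12 digits.

## Quality statistics: conventions

* Areas are reported in mmol·min/ml; $R_1, R_3$ integrate only
  correctly-signed excursions (sign indicators), $R_2, R_4$ are plain
  signed integrals so wrong-sign excursions subtract.
* The perfect rectangles use the signed global extrema over the scored
  window: $P_1 = m(t_1-t_0)$, $P_2 = m(t_2-t_1)$ (negative),
  $P_3 = M(t_3-t_2)$, $P_4 = M(t_4-t_3)$ (positive); every ratio
  $R_i/P_i$ is 1 for the ideal signal.
* Each ratio is clamped to [0,1] before averaging, and the final
  $\Theta_S$ is clamped again; the order of clamping is immaterial for any
  signal that passes the zero-quality rules.
* The zero-quality rules are evaluated on the two halves of the scored
  window (first/last 15 h for the canonical protocol, scaled
  proportionally otherwise) and take precedence over everything else.
  Degenerate non-switching signals (m = 0 or M = 0) score 0 rather than
  raising, so sweeps stay total.
* Quadrature is trapezoidal on the saved grid. The fixture generator
  `ideal_signal()` encodes its discontinuity as two samples 1 µs apart so
  that the trapezoid resolves the jump; with that convention the ideal
  rectangle scores 1 to ~1e-11 and exponential-relaxation fixtures match
  closed-form integrals to the (r·dt)²/12 trapezoid bound.

## Stability, memory, boundary

`classify_stability()` follows the simulation-based approach of the original study:
integrate a log-spaced grid of medium-pheromone initial conditions (default
1e-15…1e-5 mmol/ml, matching the range the calibrated model actually
visits) under (0,0) inputs to a 300-h horizon, then single-linkage cluster
the terminal (X, Y) points in log space with a 3-fold separation
threshold. Exactly-diagonal initial pairs are excluded by construction:
in the bistable regime they converge to the symmetric saddle and would
contaminate the clustering with a third terminal point. A run counts as
converged when every component's relative rate of change at the horizon is
below `conv_rate` (default 1e-8 s$^{-1}$); near the stability boundary,
critical slowing down legitimately leaves runs inconclusive, and the report
says so instead of guessing.

`memory_time()` measures how long the readout stays on the written side
during the first (0,0) hold after a (1,0) write. A symmetric monostable
circuit approaches Φ = 0 from below without crossing, so a strict sign test
would always return the full window; memory is instead considered erased
when Φ recovers to within a small fraction (default 0.1%) of its write
depth. Bistable circuits return the full window length.

`bistability_boundary()` bisects the clearance rate in log space. Endpoints
are checked with full classification; the refinement probes the *sign of
the diagonal instability* (whether a small X/Y asymmetry seeded through the
fast medium pools grows or shrinks late in a long run), which remains
decisive arbitrarily close to the boundary. In the subcritical band the
probe locates the lower (diagonal-restabilization) edge.

## Sweeps

`sweep2d()` pre-equilibrates, simulates and scores each grid point
independently and deterministically; failures are recorded as zero quality
with a flag rather than aborting. Amplitude normalizers $m_T$ (most
negative minimum) and $M_T$ (largest maximum) are taken over the points of
that sweep only — $\Theta_A$ values are comparable within a map, not across
maps. `lambda_scan()` exploits the affinity of $\Theta_S$ in λ to rescore
cached (S_r, S_m) pairs without re-integration; the test suite verifies the
cache against from-scratch recomputation.

## What a green test establishes — and what it does not

The synthetic world here is the calibrated reference model itself plus
analytic signal fixtures. Green tests establish that the quality statistics
are computed exactly as defined, that the integrator is converged and
symmetric, and that the calibrated circuit reproduces the qualitative
regime structure (bistable/monostable switch, diagonal equilibrium,
memory-time ordering, quality plateau near 0.6). They do **not** establish
numeric agreement with the original study's regime boundaries or map
coordinates, which depend on the unavailable published rate table; the
machinery accepts a transcribed table (`inst/extdata/params_template.json`)
through the same interfaces. No stochastic (Gillespie) dynamics, spatial
effects, cell growth, or mating-arrest biology are modeled.
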