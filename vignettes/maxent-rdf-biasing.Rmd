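---
title: "Maximum-entropy RDF biasing: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy RDF biasing: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
estimator and the bias, the controller that learns the Lagrange
multipliers, the choices made where the design was genuinely open, and what
the bundled desk-scale experiments do and do not demonstrate.

## The ensemble problem

Given an unbiased ensemble $P_0(r^N) \propto e^{-\beta U(r^N)}$ and a
target radial distribution function $\tilde g_b^{\mathrm{target}}$ on bins
$b = 1,\dots,B$, we seek a biased ensemble $P$ whose *mean* RDF matches the
target while staying as close as possible to $P_0$ in Kullback–Leibler
divergence.  Maximising the relative entropy under the matching constraints
yields a bias **linear** in the constrained observables,
$$E_{\mathrm{bias}}(r^N) = \sum_{b=1}^{B} \hat\lambda_b\, g_b(r^N),$$
with one multiplier per bin; $\hat\lambda_b$ carries energy units
($\hat\lambda_b = k_B T\,\lambda_b$ relative to the dimensionless
multipliers of the exponential family).  Linearity is the point: the bias
constrains only what the data constrains — the ensemble mean — unlike
quadratic (least-squares) biases, which implicitly constrain the variance
of $g$ as well.

Only the *gradient* of the underlying variational objective is ever
needed: $\partial\Gamma/\partial\lambda_b = \tilde g_b^{\mathrm{target}} -
\langle g_b\rangle$.  The objective itself contains a partition-function
term and is intractable; the controller never evaluates it.  Because bin
intensities are statistically correlated, the objective need not be convex;
the controller therefore reports its full MAE history so stalls at local
minima are visible, and deliberately has no restart heuristics.

## The kernel RDF estimator

The delta-function histogram is not differentiable, so each pair distance
$r_{ij}$ deposits a rectangular kernel of width $\Delta$ (exactly one bin
width, unit integral).  Its overlap with the bin containing $r_{ij}$ and
with one adjacent bin gives the two fractions counted; which neighbour
receives mass depends on whether $r_{ij}$ lies left or right of the bin
center.  Conventions fixed here:

* bins are half-open $[r_{lo}+(b{-}1)\Delta,\, r_{lo}+b\Delta)$, 1-based in
  the interfaces;
* a distance exactly on a bin edge splits 0.5/0.5 (the rectangle straddles
  the edge symmetrically); exactly at a center it contributes fully to that
  bin;
* a kernel is accepted while *any* part of it overlaps the grid
  ($r \in [r_{lo}-\Delta/2,\; r_{lo}+B\Delta+\Delta/2)$); the out-of-grid
  portion is dropped, never renormalised, and the total dropped mass is
  reported once per run.  Counting the in-grid portion of boundary
  kernels keeps the ideal-gas expectation at exactly 1 for *every* bin,
  including the edge bins — rejecting such pairs outright would starve the
  last bin of its inflow and bias it low by $\sim 1/8$.

Normalisation uses ordered-pair counting $N_{\mathrm{eff}}^2 = N(N-1)$
rather than $N^2$: for the small systems this package targets, that makes
the ideal-gas expectation exactly 1 (a deliberate small-$N$ correction to
the macroscopic formula).  Two intrinsic estimator artefacts remain and are
worth knowing:

* **small-$r$ smearing**: the width-$\Delta$ kernel inflates the
  expectation of a bin at radius $r_b$ by a factor
  $\approx 1 + (\Delta^2/12)/r_b^2$; negligible for $r_b \gtrsim 3\Delta$
  but visible in the first bins of grids that start at zero;
* **minimum image only**: the grid (plus half a kernel width) must fit
  within half the smallest box length; this is enforced, not warned.

Partial RDFs are normalised per species pair so each has ideal-gas
expectation 1; the total is their weighted sum.  X-ray weighting follows
the Warren–Krutter–Morningstar approximation with **constant** effective
scattering factors,
$w^{\alpha\beta} = (2-\delta_{\alpha\beta})\, c_\alpha c_\beta f_\alpha
f_\beta / (\sum_\gamma c_\gamma f_\gamma)^2$.  The exact placement of the
form factors is configurable input, and this normalisation (weights summing
to 1) is the package's stated convention; packaged defaults for $f$ are
atomic numbers, and arbitrary per-species values may be supplied.
$q$-dependent analytic form-factor parametrisations are intentionally out
of scope — constancy in $q$ is the point of the approximation.

## Bias forces and virial

Forces are the exact gradient $F_i = -\nabla_i E_{\mathrm{bias}}$.  For the
rectangular kernel, the derivative of a pair's bin fractions is
$\mp s/\Delta$ where $s$ is the side of the bin center the pair sits on, so
each pair generates force terms from at most the two bins its kernel
touches; pairs whose kernel partially leaves the grid simply lose the
missing bin's term.  All prefactors and signs are pinned by the
finite-difference contract (tested to $10^{-6}$ relative), which determines
them uniquely.  A hard minimum-distance guard of $10^{-6}\Delta$ avoids the
$\hat r_{ij}$ singularity for coincident particles.

The bias virial is the pairwise force virial
$T_{\mathrm{ME}} = \tfrac{1}{3}\sum_{\mathrm{pairs}} r_{ij}\!\cdot\!F_{ij}$,
decomposed per bin by which multiplier generated each term; the per-bin
values sum to the total identically.  One design decision makes the energy,
force and virial pictures consistent: **the RDF prefactor inside the bias
uses a fixed reference volume** (stored in the `bias_state`, normally the
volume at setup) instead of the instantaneous box volume.  With an
instantaneous-volume prefactor, $E_{\mathrm{bias}}$ would carry an explicit
$V$ dependence and the force virial would no longer equal the
volume-scaling derivative $-\tfrac13\,\partial E_{\mathrm{bias}}/\partial
\ln s$.  In constant-volume runs the two conventions coincide exactly;
under a barostat the controller absorbs the small rescaling into the
multipliers it learns.  Measurement RDFs (everything outside the bias)
always use the instantaneous frame volume.

## The multiplier controller

Updates happen once per averaging window:
$$\hat\lambda_b \leftarrow \hat\lambda_b - \gamma\, k_B T\, \kappa_b\,
\frac{\tilde g_b^{\mathrm{target}} - \langle g_b\rangle}
     {\sum_{b'} |\tilde g_{b'}^{\mathrm{target}} - \langle g_{b'}\rangle|}.$$

* **Sign**: where the target exceeds the measured average the multiplier
  *decreases*, lowering the bias energy of configurations with more
  intensity there.  This is validated operationally by the MAE-decrease
  property of the matching experiment.
* **Normalisation**: the $\ell_1$ norm of each update is exactly
  $\gamma k_B T$ when $\kappa \equiv 1$, independent of how close the match
  already is — without it, updates would stall as the gradient shrinks.
  The flip side is that converged multipliers keep fluctuating with the
  same step; post-hoc averaging over the late update cycles
  (`lambda_converged()`) recovers a smooth profile.
* **$\kappa_b$ damping**: optionally, bins whose windowed per-bin virial
  $\langle T_{\mathrm{ME}}^b\rangle$ is negative (driving contraction) or
  positive (expansion) get their update scaled by a factor in $(0,1]$ —
  the tool for keeping isobaric systems from collapsing or blowing up
  while the bias builds.  Conventional damping strength is 0.25.
* **Cadence**: sampling every 10 steps with windows of 100–1000 steps and
  an optional short post-update equilibration covers the regimes that work
  in practice; step sizes $\gamma \approx 10$–$5$ suit RDF matching in
  liquids, $5$–$1$ liquid-to-solid transitions (larger steps make forces
  jump and destabilise the run).  A perfectly matched window (zero
  gradient norm) is a logged no-op, so multipliers can never become
  non-finite.
* **Window averages reset after every update.**  Whether to reset or
  continue the running average across updates was an open choice;
  resetting keeps each gradient estimate unbiased with respect to the
  multipliers that generated it, at the cost of higher per-window noise.
* **Binning guidance**: at startup the expected ideal-gas pair count in the
  narrowest bin per window is estimated; below ~10 counts a warning
  suggests a coarser grid or longer window, since noisy gradients mean
  noisy forces.  For grids that start at $r = 0$ the innermost bins always
  trigger this — harmless when no pairs ever sample the core, but the
  warning errs on the side of speaking up.

## The engine

A deliberately minimal periodic Lennard-Jones engine in reduced units
($k_B = 1$; users of physical units convert via
$T^* = k_B T/\varepsilon$, $t^* = t\sqrt{\varepsilon/m\sigma^2}$):
velocity-Verlet; Langevin thermostat whose damping time is a first-class
knob (strong damping is the standard mitigation when sharply peaked
crystalline targets pump heat into the system); isotropic Berendsen
barostat driven by the *total* virial $T_0 + T_{\mathrm{ME}}$, chosen over
extended-Lagrangian barostats for robustness at small $N$ (volume scaling
clamped to ±5% per step).  The Lennard-Jones truncation is configurable:
energy-shifted (default), shifted-force (continuous forces, the right
choice for NVE conservation checks), or bare.  All randomness flows through
R's RNG, so a single seed makes whole runs bit-reproducible.  One caveat
inherited from the rectangular kernel: $E_{\mathrm{bias}}$ is piecewise
linear in each pair distance, so bias forces jump at bin centers and edges;
with large multipliers this degrades NVE energy conservation — the
thermostatted ensembles the method targets are insensitive to this.

## Target generators

`reference_run_target()` measures the time-averaged kernel RDF of an
unbiased simulation — the standard way to create a matching target from a
reference model — and warns when block averages of the pair energy drift
(unequilibrated input).  `lattice_target()` builds crystalline targets
analytically as Gaussian-broadened coordination shells,
$$g(r) = \sum_k \frac{z_k}{4\pi r^2 \rho}\,\mathcal N(r;\,r_k,\sigma),$$
with shells enumerated from the actual lattice geometry (fcc, bcc, sc,
hcp), so each peak integrates to its coordination number $z_k$ exactly,
independent of $\sigma$.  This is the same mathematical object as a
sharply peaked target measured from a cold crystal simulation, but
available in closed form at desk scale.  Peaks thinner than a third of a
bin trigger a warning: such targets produce large multiplier differences
between adjacent bins and violently varying forces — the known instability
scenario for crystalline targets.

## Diagnostics

* **MAE** between histograms is the convergence measure throughout.
* **ADF**: angles subtended at each central atom by neighbour pairs within
  a cutoff; the histogram is normalised to unit integral (a choice — no
  standard normalisation exists), and ADF comparisons use these densities.
* **MSD / diffusion**: time- and particle-averaged MSD on unwrapped
  coordinates; $D$ is the least-squares slope over the second half of the
  lag range divided by $2d$.  Results are flagged (not silently returned)
  when the fit is poor ($R^2 < 0.9$) or the log-log slope is far from 1
  (e.g. ballistic motion).  Fit window and trajectory cadence are caller
  choices, not constants of nature.
* **Bond order**: averaged local Steinhardt parameters
  $\bar q_l$ — $q_{lm}(i)$ averaged over $\{i\}\cup\mathcal N(i)$ before
  the rotation-invariant contraction — with either cutoff or
  k-nearest-neighbour rules, both needed in practice (e.g. a 3.5 Å cutoff
  for water-like systems, 12 nearest neighbours for dense ionic ones).
  The spherical harmonics use the package's own associated-Legendre
  recurrence; the test suite pins it to an independent implementation at
  $10^{-8}$ and to the known perfect-fcc value $\bar q_6 \approx 0.5745$.
  Conventional classification thresholds (0.07 for ice-like $\bar q_6$,
  0.073/0.085 for $\bar q_8$/$\bar q_{10}$ polymorph work) ship as
  presets; the liquid/solid label is a threshold on $\bar q_l$.

## The desk-scale experiments

`lj_matching_experiment()` is the packaged study: a 500-atom LJ liquid at
$\rho^* = 0.8$, $T^* = 1.0$ with $\varepsilon = 1.0$ biased toward the
reference RDF of $\varepsilon = 1.3$, grid $\Delta = 0.05\sigma$ to
$4\sigma$ (80 bins), $\gamma = 5$, sampling every 10 steps over 200-step
windows, 300 update cycles.  Problem sizes were chosen so the full
experiment runs in minutes on one CPU while keeping per-window noise well
below the structural signal; the target is averaged over 400 samples of an
independently equilibrated reference run.  Because the learned bias is
pairwise, its converged multipliers encode an effective pair potential
$u_{\mathrm{bias}}(r_b) = \hat\lambda_b \cdot 2V/(N(N-1)V_b)$; for this
target, generated by a known potential difference, pairwise-inverse
uniqueness says $u_{\mathrm{bias}}$ must approach
$\Delta u(r) = 4(\varepsilon_{1.3}-\varepsilon_{1.0})(r^{-12}-r^{-6})$
over the sampled range.  The recovery diagnostic therefore averages the
multiplier trace over the final 50 cycles, applies a 3-bin (0.15σ) moving
average — below the width of any physical feature — and correlates with
$\Delta u$ over the first coordination shell (0.9–1.55σ), where the liquid
actually samples.  Two practical notes: the $\ell_1$ budget of
$\gamma k_B T$ per cycle means the multiplier *amplitude* builds over
hundreds of cycles even after the measured RDF is statistically
indistinguishable from the target; and the correlation is computed on
$+u_{\mathrm{bias}}$ versus $+\Delta u$, the sign pair that the update
convention above actually produces.

`lj_nucleation_experiment()` is the liquid-to-solid analogue: a supercooled
dense LJ liquid ($T^* = 0.4$, $\rho^* = 0.95$) biased with a broadened-fcc
lattice target ($\gamma = 2$), monitored by the $\bar q_6$ solid fraction.
Nucleation is stochastic; this experiment ships as a demonstration script,
not a timed guarantee.

**What these experiments do not show.**  The synthetic systems are
single-species, point-particle, short-ranged and small.  Passing them
demonstrates the estimator, the force/virial algebra and the controller —
it does not demonstrate rigid-molecule constraint coupling, long-range
electrostatics, real WAXS noise and Fourier-truncation artefacts,
$q$-dependent form factors, or finite-size effects in genuinely
ns-scale condensed-phase runs.  Those belong to production MD codes; the
interfaces here (force-provider contract, RDF file format, extended-XYZ)
are designed so the same bias definition transfers.

## Known limitations

* Gradient descent on a non-convex objective: convergence to *a* matching
  ensemble, not a certified global optimum.
* Constant-$\ell_1$ updates never shrink; converged multipliers fluctuate
  and need trace averaging for smooth profiles.
* Rectangular-kernel forces are discontinuous at bin boundaries (energy is
  only $C^0$), so large multipliers degrade microcanonical energy
  conservation and can heat thermostatted systems — counter with stronger
  damping, smaller time steps, or wider bins.
* Orthorhombic periodic boxes only; no triclinic cells, no non-periodic
  clusters, no $S(q)$-space biasing.
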