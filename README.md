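# rdfbias

Bias molecular dynamics simulations so that their ensemble-averaged radial
distribution function (RDF) reproduces a *target* RDF — one measured from a
better force field, computed from a crystal structure, or derived from
wide-angle X-ray scattering — using the principle of **maximum relative
entropy**.

This is aimed at simulators who have structural information in the form of a
pair correlation function g(r) and want to fold it into an MD ensemble
without distorting the underlying force field more than the data demands:
refining a cheap water-like model toward a better one, steering a liquid
into a crystalline phase defined only by its RDF, or recovering the
pair-interaction correction that explains a measured structure.

## The method

The RDF is estimated as a differentiable histogram: each pair distance
r<sub>ij</sub> deposits a rectangular kernel of width Δ (one bin) whose
overlap with bins *b* and *b*±1 gives the fractions counted there, with the
usual 2V/(N(N−1)V<sub>b</sub>) normalisation (ideal gas → 1 per bin).
Multi-species systems combine partial RDFs by pair frequency or by X-ray
weights under the Warren–Krutter–Morningstar approximation,

&nbsp;&nbsp; w<sup>αβ</sup> = (2−δ<sub>αβ</sub>) c<sub>α</sub>c<sub>β</sub>f<sub>α</sub>f<sub>β</sub> / (Σ<sub>γ</sub> c<sub>γ</sub>f<sub>γ</sub>)².

Among all ensembles that reproduce a target g̃<sub>b</sub>, the one closest
(minimum Kullback–Leibler divergence) to the unbiased ensemble is obtained
by a bias **linear** in the constrained observables,

&nbsp;&nbsp; E<sub>bias</sub> = Σ<sub>b</sub> λ̂<sub>b</sub> g<sub>b</sub>(r<sup>N</sup>),

with one Lagrange multiplier λ̂<sub>b</sub> (energy units) per bin.  Because
the kernel is rectangular, each pair contributes force terms only at the two
bins its kernel touches; forces are the exact gradient −∇E<sub>bias</sub>,
and the bias virial T<sub>ME</sub> = (1/3)Σ r<sub>ij</sub>·F<sub>ij</sub>
decomposes exactly into per-bin contributions T<sub>ME</sub><sup>b</sup>.

The multipliers are learned on the fly by gradient descent on the maxent
objective, whose gradient is simply g̃<sub>b</sub><sup>target</sup> −
⟨g<sub>b</sub>⟩.  Updates are normalised by the l1 norm of that gradient,

&nbsp;&nbsp; λ̂<sub>b</sub> ← λ̂<sub>b</sub> − γ k<sub>B</sub>T κ<sub>b</sub>
(g̃<sub>b</sub><sup>target</sup> − ⟨g<sub>b</sub>⟩) / Σ<sub>b'</sub>
|g̃<sub>b'</sub><sup>target</sup> − ⟨g<sub>b'</sub>⟩|,

so every update cycle spends exactly γ·k<sub>B</sub>T of multiplier change
no matter how close the match already is.  The optional per-bin damping
κ<sub>b</sub> slows updates for bins whose average virial contribution
drives unwanted contraction (or expansion) of an isobaric system.

The package bundles a minimal periodic Lennard-Jones engine (velocity
Verlet, Langevin thermostat, isotropic Berendsen barostat; reduced units,
k<sub>B</sub> = 1), generators for target RDFs (unbiased reference runs and
analytic Gaussian-broadened lattice shells for fcc/bcc/sc/hcp), and the
diagnostics used to judge the result: RDF/ADF mean absolute error, MSD
diffusion coefficients, and averaged local Steinhardt bond-order parameters
q̄<sub>l</sub> (Lechner–Dellago) with liquid/solid classification.

## Worked example

Match a Lennard-Jones liquid (ε = 1.0) to the RDF of a stiffer one
(ε = 1.3) and read off the pair-potential correction the bias learned:

```r
library(rdfbias)
set.seed(7)
frame <- lattice_frame(3, density = 0.8)          # 108 atoms, fcc start
grid  <- rdf_grid(delta = 0.05, b = 50)           # bins to r = 2.5 sigma

cfg13 <- engine_config(epsilon = 1.3, temperature = 1, damp = 1)
target <- reference_run_target(frame, cfg13, grid,
                               n_frames = 200, equil_steps = 2000)

cfg10 <- engine_config(epsilon = 1.0, temperature = 1, damp = 1)
melt <- run_md(frame, cfg10, 2000)
run <- run_biased_md(melt$frame, cfg10, target,
                     bias_schedule(gamma = 5, sample_every = 10, window = 200),
                     n_updates = 60, velocities = melt$velocities)
print(run)
#> biased MD run: 60 update cycles, final windowed MAE = 0.02253

round(run$mae_history[c(1, 10, 30, 60)], 4)
#> [1] 0.0172 0.0242 0.0205 0.0225

pp <- bias_pair_potential(run$state, n = 108,
                          lambda_hat = lambda_converged(run, 20))
round(subset(pp, r > 1.05 & r < 1.3), 4)
#>        r       u
#> 22 1.075 -0.1116
#> 23 1.125 -0.1669
#> 24 1.175 -0.1452
#> 25 1.225 -0.1048
#> 26 1.275 -0.0668
```

The windowed MAE sits at the sampling noise floor of this small system
(~0.02 for 20 samples per window at N = 108), i.e. the measured RDF is
statistically indistinguishable from the target.  The recovered effective
pair potential u<sub>bias</sub>(r) = λ̂(r)·2V/(N(N−1)V<sub>b</sub>) has
developed a well of −0.17 at r ≈ 1.12σ after only 60 cycles, partway toward
the true difference Δu(1.125) = −0.30 — each cycle adds at most
γk<sub>B</sub>T of multiplier change, so the amplitude keeps building with
more cycles (the packaged 300-cycle experiment reaches Pearson ≈ 0.85
against Δu over the first coordination shell).

A command-line front end (`exec/rdfbias`) exposes the same machinery:
`simulate`, `bias`, `make-target`, `rdf`, `adf`, `msd`, `boop`, `compare`,
driven by a YAML config (see `?read_run_config`).

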