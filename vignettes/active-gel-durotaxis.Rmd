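---
title: "A mechanosensitive active gel model of amoeboid durotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanosensitive active gel model of amoeboid durotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durogel)
```

## The scientific problem

Durotaxis — migration towards stiffer substrate — is well understood for
mesenchymal cells, which pull on the matrix through focal adhesions. Amoeboid
cells (T cells, neutrophils, *Dictyostelium*) crawl fast and without stable
adhesions, yet they too migrate up stiffness gradients under confinement, and
they do so with non-muscle myosin IIA (NMIIA) accumulated on the *soft* side
of the cell. `durogel` implements a continuum model of this behaviour: an
active polar gel droplet whose myosin transport senses substrate stiffness,
together with the trajectory statistics used to quantify directional
migration (forward migration index, velocity, persistence, angular
displacement) and a synthetic track generator with known ground truth.

## The model

The cell is a phase-field droplet of actin density $c(\mathbf r, t)$ with
reference interior density $c_0$, carrying a polarity field
$\mathbf P(\mathbf r, t)$ and a myosin density $m(\mathbf r, t)$, embedded in
a 2D incompressible fluid with velocity $\mathbf v$ on a periodic grid.

**Free energy.** Phase coexistence and polar order come from

$$F[c,\mathbf P]=\int \Big\{\tfrac{4a}{c_0^4}c^2(c-c_0)^2
 +\tfrac{k}{2}|\nabla c|^2
 -\tfrac{\alpha}{2}\tfrac{2c-c_0}{c_0}|\mathbf P|^2
 +\tfrac{\alpha}{4}|\mathbf P|^4
 +\tfrac{\kappa}{2}(\nabla \mathbf P)^2\Big\}\,d\mathbf r,$$

with $(\nabla\mathbf P)^2=\sum_{ij}(\partial_i P_j)^2$ (the one-constant
liquid-crystal contraction; the cross-term structure is not specified by the
model statement, so the standard one-constant form is assumed). The two
uniform minimisers are the solvent phase $(c,|\mathbf P|)=(0,0)$ and the
polar active phase $(c_0,1)$; for uniform $c\in(c_0/2,c_0]$ the preferred
polarity magnitude obeys $|\mathbf P|^2=(2c-c_0)/c_0$.

**Transport.** Actin follows a conservative advection–relaxation law,
$\partial_t c+\nabla\!\cdot[c(\mathbf v+w\mathbf P)-M\nabla\mu]=0$ with
$\mu=\delta F/\delta c$; $w$ is the polymerization rate, so $w\mathbf P$ is
the protrusive self-advection. Myosin is advected *against* the polarity
($\mathbf v-w\mathbf P$: rearward transport), diffuses with the
mechanosensitive coefficient $D_m(E)$ below, and relaxes with the bistable
reaction $-\frac{\alpha_m}{\Gamma_m}\big[-\mathrm{sign}(2c-c_0)\,m+m^3/m_0^2\big]$,
whose stable fixed points are $m=m_0$ inside the cell and $m=0$ outside.

**Flow.** $\nabla\cdot\mathbf v = 0$ and
$\rho(\partial_t+\mathbf v\cdot\nabla)\mathbf v=-\nabla\Pi+\nabla\cdot\sigma-\gamma\mathbf v$,
where $\sigma$ sums the viscous stress $\eta(\nabla\mathbf v+\nabla\mathbf
v^T)$, the elastic stress
$-\tfrac12(\mathbf P\mathbf h-\mathbf h\mathbf P)+\tfrac{\xi}{2}(\mathbf
P\mathbf h+\mathbf h\mathbf P)-\kappa\,\nabla\mathbf P\cdot(\nabla\mathbf
P)^T$ with $\mathbf h=\delta F/\delta\mathbf P$, the interfacial stress
$(f-c\mu)\mathbf I-k\,\nabla c\otimes\nabla c$, and the contractile active
stress $\bar\zeta c\,\mathbf P\mathbf P$. Pressure is eliminated by taking
the scalar curl: the package advances the vorticity
$\rho(\partial_t\omega+\mathbf v\cdot\nabla\omega)=\eta\nabla^2\omega-\gamma\omega+\hat{\mathbf z}\cdot\nabla\times(\nabla\cdot\sigma^{\mathrm{ela+int+act}})$,
recovers the stream function from $\nabla^2\psi=-\omega$ (zero-mean gauge)
and sets $\mathbf v=(\partial_y\psi,-\partial_x\psi)$, which is
divergence-free by construction. A friction-dominated Stokes mode
($\rho = 0$) is available in `solveFlow()` and is used for the closed-form
single-mode test.

**Mechanosensing.** Under the cell (support $c\ge c_0/2$) the myosin
diffusivity is

$$D_m(E)=\frac{\bar\zeta D_0}{\bar\zeta_{\mathrm{thr}}}
 \left(\frac{E-E_{\min}}{E_{\max}-E_{\min}}\right)^2
 \left[1-\frac{1}{1+e^{(E_m-E_{\mathrm{aver}})/E_0}}\right],$$

with $E_{\min}, E_{\max}, E_{\mathrm{aver}}$ the extremes and mean of the
stiffness currently sensed by the cell (recomputed every step from the moving
support), and $D_m = D_0$ outside. Myosin therefore diffuses faster on the
stiffer side of the cell and is gated off when the cell sits on a stiff
average environment ($E_{\mathrm{aver}}\gg E_m$). On a uniform substrate
$E_{\max}=E_{\min}$ and the quadratic factor is defined as zero — no
stiffness contrast, no mechanosensitive transport; the case is flagged, not
errored, so uniform-gel control simulations run.

**Polarity.** $\mathbf P$ is advected and co-rotated by the flow
($-\Omega\cdot\mathbf P+\xi\,\bar{\mathbf v}\cdot\mathbf P$, with
$\Omega,\bar{\mathbf v}$ the antisymmetric/symmetric parts of
$\nabla\mathbf v$ carrying the conventional $1/2$ factors), relaxes through
$-\mathbf h/\Gamma$, and is steered by the global cue
$\hat{\mathbf n}_{\mathrm{polar}}$, the unit vector from the myosin centre
of mass to the cell centroid (both computed with periodic circular means;
the cue is disabled when the offset is shorter than `eps_n`). The steering
term is implemented as the literal
$-\bar\zeta\,[\mathbf P\cdot(R_{\pi/2}\hat{\mathbf n}_{\mathrm{polar}})]\,(R_{\pi/2}\mathbf P)$:
both rotations share one handedness, which makes the term an exact
infinitesimal rotation of each local $\mathbf P$ towards the cue at rate
$\bar\zeta\sin\varphi$, preserving $|\mathbf P|$. (The superficially similar
form $-\bar\zeta(\mathbf P\cdot\mathbf q)\mathbf q$ is *not* equivalent: it
aligns $\mathbf P$ with the $\pm$cue axis, shrinks the magnitude, and leaves
down-gradient headings stable, which destroys the up-gradient bias; see the
0D test in `test-dynamics.R`.)

**Mechanism of durotaxis.** On a gradient, $D_m$ is larger on the stiff side,
so myosin leaks across the stiff-side interface (where the reaction destroys
it) and accumulates on the soft side. The myosin centre shifts down-gradient,
$\hat{\mathbf n}_{\mathrm{polar}}$ tilts up-gradient, the polarity rotates
towards it at rate $\bar\zeta$, and the cell — advected at $w\mathbf P$ —
migrates up the gradient. Each link of this chain is tested separately, and
the whole chain by the ensemble checks.

## Numerics

* **Spatial scheme.** All production dynamics use 2nd-order centered finite
  differences in *flux form* on the periodic grid: the discrete divergence
  telescopes, so total actin mass is conserved to rounding error
  (measured drift $\sim10^{-14}$ over $10^3$ RK4 steps), and the
  stream-function velocity has exactly zero discrete divergence (the x and y
  centered stencils commute). The Poisson solve inverts the 5-point
  Laplacian exactly through its Fourier eigenvalues. A spectral (FFT)
  backend is provided for every operator and is used as the high-accuracy
  oracle in the tests; spectral products can be de-aliased with the 2/3
  rule (`dealias` argument).
* **Discrete energetics.** `chemicalPotential()` and `molecularField()` are
  the *exact* gradients of the discrete functional: under the FD backend
  `freeEnergy()` evaluates the gradient-squared terms with forward
  differences (the Lyapunov function of the 5-point Laplacian), so the
  central-difference functional-derivative oracle agrees to $\sim10^{-9}$
  and relaxational dynamics decrease the energy monotonically.
* **Time stepping.** Classical RK4 advances $c$, $m$, $\mathbf P$ and
  $\omega$ simultaneously; the flow is re-solved from the vorticity at every
  substage. Stiffness sensing, $D_m$ and the polarity cue are frozen over
  the four substages of a step (the support moves far less than one node per
  step). The compiled core (`src/engine.cpp`) evaluates the identical
  right-hand sides as the R reference and is cross-checked against it at
  $10^{-12}$; negative myosin from advection overshoot is clamped to zero
  and counted.
* **Degenerate inputs.** Empty cell support raises a simulation-failure
  error; zero total myosin or a sub-`eps_n` myosin offset disables the
  steering torque for that step; non-finite fields abort with the failure
  time.

## Parameters

The contractility values $\bar\zeta\in\{0, 0.002\}$, shape factor
$\xi=1.1$, droplet radius $R=7$, grid spacing $\Delta x=1$ (1 unit = 1 µm)
and time step $\Delta t=0.1$ are fixed by the model's published setup, with
normalisation scales 1 µm / 10 ms / 100 nN. The remaining coefficients are
package defaults, chosen once by two physical requirements and then frozen:

* **Phase coexistence quality.** The polar coupling shifts the interior
  density to $c_0 + \alpha/(8a)$ and interface curvature adds a
  Gibbs–Thomson shift $\approx$ (interface width)/(6R). With $a=1$,
  $k=1.8$ (interface width $\sqrt{k/8a}\approx0.47$), $\alpha=0.04$, the
  relaxed droplet interior sits within 2% of $c_0$ and the polarity
  magnitude within 5% of 1. $\kappa=0.04$ keeps the polarity healing length
  $\sqrt{\kappa/\alpha}=1$ well below $R$.
* **The mechanosensitive window.** $E_m=85$ kPa and $E_0=15$ kPa place the
  three probe stiffnesses of the gradient assay — 30, 70 and 200 kPa at the
  initial centroid — deep inside, part-way up, and outside the sensitive
  range of the sigmoid gate, reproducing strong durotaxis from soft and
  middle starts and random migration from the stiff start. $D_0=0.3$ with
  $\bar\zeta_{\mathrm{thr}}=0.001$ sets the stiff-side myosin diffusivity
  scale (up to $0.6$) that polarizes myosin within a few hundred time units.
* The transport and flow coefficients ($M=0.02$, $w=0.02$, $\Gamma=0.25$,
  $\Gamma_m=\alpha_m=m_0=1$, $\eta=0.2$, $\rho=1$, $\gamma=0.3$) keep every
  linear rate below the RK4 stability bound at $\Delta t=0.25$ on a
  unit-spacing grid, and set the crawl speed ($\approx w$) so a cell
  traverses well under half the periodic domain per run, which keeps the
  start-stiffness conditions distinct.

The default gradient slope is 0.8 kPa/µm: steep enough that the 30-to-200 kPa
regime fits the simulated domain with positive stiffness everywhere, and
irrelevant to the *strength* of sensing, which is normalised by the
intra-cell stiffness contrast.

## Problem sizes used by the tests and the acceptance script

Single-run audits (conservation, incompressibility) use the full 128×128
grid with $\Delta t=0.1$ for $10^3$ steps. The ensemble experiments use a
scaled-down configuration chosen as the package's reference desk-scale
setting: 64×64 grid (the $R=7$ droplet is still under a quarter of the
domain width), $\Delta t=0.25$, 8000 steps ($T=2000$ time units, several
multiples of the $1/\bar\zeta=500$ steering time), 10 seeds per condition.
All conditions share one seed set, so between-condition comparisons are
paired. The alignment time is the slowest scale in the model, so run length
mainly controls how completely initially down-gradient cells re-orient;
longer runs increase the mean FMI of durotactic conditions but do not change
the orderings.

## What the synthetic generator does and does not emulate

`generateTracks()` produces constant-speed persistent random walks with a
von Mises-type restoring turn towards +y
($\theta_{t+1}=\theta_t-\mathrm{bias}\,\sin\theta_t+\mathrm{turn\_sd}\,\varepsilon_t$).
This mirrors how amoeboid durotaxis manifests in the assay the model
addresses — re-steering with unchanged speed — and makes the ensemble mean
velocity exactly the configured speed (default 16.21 µm/min, a typical fast
T-cell speed) and yFMI analytically tractable via the Monte-Carlo oracle
`expectedYfmi()`. It does **not** emulate speed variability, pauses,
collisions, confinement geometry, or finite-precision tracking noise, so
passing statistics tests here validates the estimator layer, not any claim
about real-cell track distributions.

## Known limitations

* 2D periodic domain only; a cell migrating far enough wraps around and
  re-enters the gradient at the soft edge (runs are sized to avoid this).
* Friction $\gamma\mathbf v$ acts over the whole domain, as the momentum
  balance is written; no substrate deformation or traction feedback.
* The myosin diffusion term is the literal $D_m\nabla^2 m$ (coefficient
  outside the Laplacian); the Fickian form
  $\nabla\cdot(D_m\nabla m)$ is available via `modelParams(fickian = TRUE)`
  for comparison.
* No thermal noise: run-to-run variability comes entirely from the random
  initial polarity, so each trajectory is smoother than an experimental
  track.
* The supplementary coefficient table of the original model is not
  reproduced here; the defaults are the package's own calibration as
  described above, and quantitative FMI magnitudes should be read as
  regime-level, not fitted, predictions.

## A short run

```{r, eval = FALSE}
cfg <- experimentConfig(grid = makeGrid(64, 64),
                        params = modelParams(dt = 0.25),
                        substrate_kind = "gradient", E_ref = 70, slope = 0.8,
                        n_steps = 2000, record_every = 100, seed = 1)
res <- runExperiment(cfg)
trackYfmi(res$trajectory[, c("t", "x", "y")])
tail(res$diagnostics)

# ensemble over seeds, pooled statistics
ens <- runEnsemble(cfg, n_seeds = 10, master_seed = 1)
ens$stats
```
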