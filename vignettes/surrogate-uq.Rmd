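---
title: "Polynomial-chaos surrogates for sensitivity analysis and Bayesian inference in yeast mating models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polynomial-chaos surrogates for yeast mating models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Fitting mechanistic models of cell signalling to data requires exploring a
parameter space in which every evaluation is a differential-equation solve.
For a spatial model this quickly becomes prohibitive: a reaction–diffusion
simulation that takes minutes, inside an MCMC chain of $10^6$ steps, is
years of CPU time.  `gpcyeast` implements the surrogate-model route around
this cost: a cheap polynomial approximation of the simulator's
parameter-to-output map is fit from a modest number of simulator runs, and
all downstream analysis — global sensitivity screening, Bayesian posterior
sampling, optimization — queries the polynomial instead of the simulator.

The package ships the two yeast pheromone-response models the machinery is
demonstrated on:

* **The heterotrimeric G-protein cycle** (`gproteinSimulate`): four ODEs for
  receptor `R`, receptor–ligand complex `RL`, heterotrimeric G-protein `G`
  and active Gα `Ga` (molecules/cell, seconds), with the derived species
  `Gd = Gt - G - Ga` and `Gbg = Gt - G`.  The output is the free-Gβγ
  fraction `Gbg/Gt` on a 15-point grid: a time course at 1000 nM ligand and
  a dose–response at 60 s.
* **Pheromone-induced Cdc42 polarization** (`simulatePolarization`): a
  reaction–diffusion system for eleven membrane species on a circular
  membrane of radius 2 µm (receptor module, G-protein module, and the
  Cdc24/Cdc42/Bem1/Cla4 polarity module with its Bem1-mediated positive
  feedback and Cla4-mediated negative feedback), plus conserved cytoplasmic
  Cdc24 and Bem1 pools.  The output is the polarization factor (PF) of
  active Cdc42, optionally passed through a Hill-type cut-off that
  penalizes states with negligible total activation.

# The surrogate

All parameters are mapped onto the reference cube $[-1,1]^n$
(`toCube`/`fromCube`); ranges quoted over orders of magnitude map through
$\log_{10}$, so that equal multiplicative steps become equal additive steps
and no parameter dominates by sheer magnitude.  With independent uniform
parameters the natural orthogonal basis is the (unnormalized) Legendre
family, $P_m(1)=1$, in a total-degree multi-index set
$\{\alpha : |\alpha| \le d\}$ of size $\binom{n+d}{n}$, enumerated in
graded-lexicographic order so serialized coefficient files are stable.

Coefficients are estimated from uniform random samples of the cube
(`sampleUniform`, one simulator run per sample):

* **Oversampled** ($m \ge \binom{n+d}{n}$): least squares via QR
  (`fitLeastSquares`), with a minimum-norm fallback on rank deficiency.
* **Undersampled**: basis-pursuit denoising
  $\min \|x\|_1 \ \mathrm{s.t.}\ \|Ax-b\|_2 \le \epsilon$ (`fitL1`), the
  compressed-sensing formulation.  No second-order-cone solver is available
  in the dependency stack, so the package implements the solver directly as
  an ADMM splitting whose two proximal steps are exact: a soft threshold,
  and a Euclidean projection onto the residual ball computed through a
  one-time SVD of the design matrix and a monotone scalar root find, with
  residual-balancing penalty adaptation.  The default radius is
  $\epsilon = 0.05\|b\|_2$ and is exposed, since the reference choice for
  this constant is not documented anywhere; planted-sparse-recovery tests
  exercise the solver at $\epsilon \approx 0$.

Accuracy is estimated by $k$-fold cross-validation (`crossValidate`),
reporting the mean, standard deviation and mean absolute value of the
held-out error, pooled over folds.

# Analytic global sensitivities

The global sensitivity of response $z$ to cube coordinate $y_j$ is
$S_j = E[\partial z/\partial y_j]$ under the uniform measure.  For a
Legendre expansion this needs no sampling: the expectation factorizes,
$E[P_m]=\delta_{m0}$ and $E[P_m'] = (P_m(1)-P_m(-1))/2$, which is 1 for odd
$m$ and 0 for even $m$, so $S_j$ is the sum of the coefficients whose
multi-index is odd in dimension $j$ and zero elsewhere
(`sensitivityFromCoeffs`; verified against tensor Gauss–Legendre quadrature
to $10^{-10}$ in the tests).  Because no closed form exists for
$E|\partial z/\partial y_j|$, the mean-absolute version is estimated by
Monte Carlo from the surrogate's analytic gradient on $10^4$ seeded cube
points.  Screening (`sensitivityReport`) retains parameters with
$|\mathrm{mean}_r S_{j,r}|$ above a threshold (default 0.01); the
mean-of-absolute-values variant is reported alongside, since the two differ
when signs flip across responses.

# Bayesian inference and refinement

The prior is the uniform distribution on the cube — the same measure the
surrogate was built under.  The likelihood is independent Gaussian per
observation with the dataset's reported standard deviation; for the
polarization model the single datum is the measured PF of active Cdc42
(0.87) with σ = 0.1, a value that is exposed in the API because no
measurement uncertainty is published for it.  `surrogateLikelihood` can
additionally fold a surrogate-error standard deviation (for instance the
cross-validated error sd) into the observation sds in quadrature: when
emulator error is comparable to measurement noise, ignoring it makes the
posterior over-confident, and the package's posterior-recovery tests show
exactly this effect.

`mhChain` is a Metropolis–Hastings random walk in cube coordinates with
Gaussian proposals, evaluated in compiled code ($10^6$ steps in seconds).
Proposals leaving the cube are rejected — that is the prior's zero density,
handled exactly.  The proposal width is tuned by short pilot runs to a
20–40% acceptance rate (`tuneProposalSD`) and then frozen; chains can be
started from the best point of a coarse surrogate scan (`startFromScan`),
which matters when the posterior concentrates on a thin ridge.  Convergence
is checked across independent chains by per-parameter histogram
total-variation distance and a Kolmogorov–Smirnov statistic
(`convergenceCheck`).  `posteriorSummary` reports marginal histograms (100
bins, uniform in cube coordinates — hence logarithmic bins for log-scaled
parameters), the marginal mode as the highest-density bin (a joint mode in
15 dimensions is not estimable from $10^6$ samples), the mean parameter set
computed in cube coordinates and mapped back, central credible intervals,
and the cube-coordinate correlation matrix.  `simulatedAnnealing` refines a
point estimate on the surrogate objective with geometric cooling and
cube-clipped Gaussian moves, tracking the best-so-far point so the result
never regresses.

# Numerical scheme of the polarization model

The membrane is a circle discretized by 400 equally spaced points (the
angle α is measured from the negative x-axis; the pheromone gradient — 10 nM
midpoint, 0.1 nM/µm slope — has its maximum at the +x pole).  Surface
diffusion is the second derivative in arc length with periodic second-order
finite differences.  Time stepping is Crank–Nicolson for diffusion combined
with a semi-implicit treatment of the reactions: each field's rate is split
as production minus (frozen linear decay coefficient × field), the decay
taken implicitly and the production explicitly, followed by one trapezoidal
fixed-point correction.  The split keeps the step linear (one periodic
tridiagonal solve per field, via cyclic Thomas/Sherman–Morrison) while
remaining stable for the stiff G-protein reassociation term
(`kG1·Gd·Gbg`, with an effective rate of hundreds per second), which a
fully explicit reaction treatment cannot integrate at any practical step.
Checks: the pure-diffusion limit reproduces the closed-form
Crank–Nicolson Fourier amplification factor to $10^{-10}$ (discrete
eigenvalue) and $10^{-8}$ (continuous), and the full model at the baseline
parameters changes by $< 10^{-4}$ (relative, maximum over all fields) under
time-step halving.

Choices worth recording:

* `dt = 0.05` s, `t_end = 1000` s for production runs; the steady-state
  diagnostic (relative change over the final 10 s) is returned with every
  run.
* The nonlocal coefficients follow their normalization intent: δ scales the
  relative free-Gβγ signal to unit membrane mean before the q-Hill switch,
  γ = SA/(2∫B1m ds) half-mean-normalizes membrane Bem1 inside the h-Hill
  switch, and the receptor-synthesis bias p\_s is active Cdc42 over its
  membrane mean (1 when nothing is active).  Vanishing integrals take the
  Hill-function limit (switch output 0); Hill arguments are clamped at
  $10^{-12}$ before exponentiation and the switch output is asserted to lie
  in [0, 1].
* SA is the circumference 2πr ≈ 12.57 µm and V the enclosed area
  πr² ≈ 12.57 µm², so the SA/V-scaled rate-constant entries of the baseline
  table stay internally consistent and membrane averages are true averages.
* Cytoplasmic Cdc24/Bem1 are recovered from their conservation constraints
  after each membrane update (conservation holds by construction; the
  recruitment rates use the pools clamped at zero, and the minimum
  unclamped pool value is reported as a diagnostic).
* Initial conditions are exactly uniform; symmetry is broken only by the
  ligand gradient, never by injected noise.
* PF: the frontal arc $S_p$ is grown greedily from the field's maximum
  towards the larger neighbour (ties towards increasing index), with the
  final fractional cell linearly interpolated.  PF is invariant under
  positive scaling and rotation; the arc centred at the field maximum and
  the arc centred at the gradient pole coincide at steady state.
* The cut-off response uses $a = 2\,\mathrm{SA}/C42t$, so the Hill argument
  is 1 exactly when the C42a peak equals half the uniform initial Cdc42
  concentration; the exponent is 5.

# The synthetic datasets, and what the tests do and do not show

The experimental free-Gβγ dataset exists only in supplementary material of
the original experimental study and is not redistributable here, so the
package generates a stand-in (`generateGproteinData`, bundled as
`gproteinSyntheticData()`): model responses at the published
maximum-likelihood estimate $(k_{Ga}, k_{Gd}) = (10^{-5}, 0.11)$ on the
standard 15-point grid plus Gaussian noise, clipped to [0, 1].  The noise
scale is the one quantity the literature pins down about those residuals:
the published mean squared error of the best fit, $1.3\times10^{-4}$,
implies RMS residuals of $\sqrt{1.3\times10^{-4}} \approx 0.011$, and that
is the generator's default `noise_sd`.  Two consequences are worth stating
plainly.  First, the published MSE at the *posterior-mode* estimate
($4.1\times10^{-4}$) cannot be reproduced by any dataset generated from the
model at the maximum-likelihood point: the mean squared difference between
the model responses at the two published estimates is $1.3\times10^{-3}$,
several times larger, so the real data must sit "between" the two fits in a
way no model-generated stand-in can imitate.  Second, everything a test
shows against synthetic data is internal consistency — that the pipeline
recovers what generated its input — not agreement with the biology of the
real measurements.

The membrane stand-in (`generatePolarizationProfile`) is a von-Mises-shaped
field, the natural unimodal density on a circle, scaled to a prescribed
total; its PF grows monotonically with the sharpness κ, which makes it a
clean probe of the PF computation.

The posterior-recovery property (20 seeded replicates of
generate-data/run-MCMC/check-coverage) is run with the emulator error
folded into the likelihood and a degree-14 surrogate: at the residual-scale
noise of 0.011, a degree-10 fit from 1000 samples has cross-validated error
of the same order as the noise, and its biased posterior visibly
undercovers.  This is a real feature of surrogate-based inference, not an
artifact, and it is the reason `surrogateLikelihood` exposes `model_sd`.

# Problem sizes of the shipped analyses

The analyses the test suite and `scripts/acceptance.R` run end to end were
sized so a complete pass is a coffee break, not a cluster job, and those
sizes are package choices:

* Model 1: 1000 simulator runs for the degree-10 surrogate (the production
  study size), $10^6$-step MCMC with $10^5$ burn-in.
* Model 2: the full-resolution model (400 mesh points, dt = 0.05 s) is used
  for single evaluations; surrogate sample sets use 300 runs on a coarser
  100-point mesh with dt = 0.2 s, which reproduces the full-resolution
  cut-off response to ~0.005.  The reduced space is the screened
  15-parameter subspace; the surrogate is degree 2 (136 terms) rather than
  the full-scale degree-5/6000-sample fit, and the MCMC chain is
  $5\times10^5$ steps.  The full 35-dimensional degree-5 study (658,008
  basis terms, 5000 samples) is out of desk scale by construction and is
  exercised through its machinery (basis enumeration, ℓ1 recovery,
  cross-validation behaviour) rather than at full size.

Known limitations at these sizes: the degree-2 surrogate of the
polarization response is accurate near the bulk of the prior but optimistic
in corners, so simulated-annealing refinement against the surrogate can
select points whose full-model PF is lower than at the posterior mean — at
full scale, with a degree-5 surrogate, the refinement is reported to help.
The posterior mean of the reduced-space chain, mapped through the full
model, reproduces the published PF of 0.57 closely, which is the package's
strongest end-to-end check on the polarization half of the pipeline.
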