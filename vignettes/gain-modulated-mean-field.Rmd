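---
title: "Modeling receptor-weighted gain modulation of cortical BOLD connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling receptor-weighted gain modulation of cortical BOLD connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfgain)
```

# The model

`dmfgain` implements a dynamic mean-field (DMF) network model of cortical
activity and the analysis stack needed to study how a spatially heterogeneous
modulation of neural gain — for example, one weighted by a receptor-gene
expression map — reshapes BOLD functional connectivity.

Each of the N parcels hosts one excitatory (E) and one inhibitory (I)
population, described by synaptic gating fractions $S^E_i, S^I_i$. The
population currents are

$$I^E_i = W_E I_b + w_{EE} S^E_i + G J \textstyle\sum_j C_{ij} S^E_j - w_{EI,i} S^I_i,
\qquad I^I_i = W_I I_b + w_{IE} S^E_i - S^I_i,$$

where $C$ is the row-normalized structural connectome (zero diagonal; each
row sums to one so long-range input is balanced across parcels) and $G$
scales all long-range projections. Currents map to firing rates through the
soft-rectifying transfer function

$$r = \phi(I) = \frac{aI - b}{1 - e^{-d(aI - b)}},$$

whose slope parameter $a$ is the neural gain. $\phi$ is strictly positive,
strictly increasing, and continuous at $aI = b$ with limit $1/d$; the
implementation switches to a series expansion near the removable singularity
and to exponentially rescaled forms for large arguments, so it is accurate
over the whole real line. Gating evolves as

$$\dot S^E_i = -S^E_i/\tau_E + (1 - S^E_i)\,\gamma\, r^E_i + \sigma \nu_i(t),
\qquad \dot S^I_i = -S^I_i/\tau_I + r^I_i + \sigma \nu_i(t).$$

Note the structural asymmetry: the excitatory gating carries a saturation
factor $(1 - S^E)$, the inhibitory gating does not. We keep that asymmetry
as printed in the model's standard formulation; the inhibitory fixed point
may in principle exceed 1, and the stochastic integrator clamps $S^E$ to
$[0,1]$ but clamps $S^I$ only at 0.

## Gain modulation

A perturbation (e.g. a pharmacological one) is modeled as a fractional change
of gain, scaled per node by a weight map $h_i \in [0,1]$:

$$a^p_i = (1 + h_i\,\delta_p)\,a^p_0, \qquad p \in \{E, I\}.$$

Two strengths $\delta_E, \delta_I$ allow cell-type-specific modulation. We
deliberately use the multiplicative-on-baseline convention: with
$\delta = 0$, or with $h = 0$ everywhere, the unmodulated gains are recovered
*exactly*, and the whole downstream pipeline is bit-identical to the
unperturbed one. (An alternative convention in which $h_i$ multiplies the
whole gain would zero out the baseline wherever $h_i = 0$ and break this
neutrality, so we rejected it.) Expression-like maps are bounded to $(0,1)$
by a cumulative-normal transform before they are used as $h$.

## Feedback inhibition control

`apply_fic()` tunes the inhibitory-to-excitatory weight $w_{EI,i}$ per node
so that the unmodulated fixed point has $r^E_i$ at a 3 Hz target everywhere.
The procedure is closed-form up to two scalar root-finds: invert $\phi_E$ at
the target rate; set $S^{E*} = \gamma r \tau_E / (1 + \gamma r \tau_E)$;
solve the inhibitory fixed point (the same scalar equation at every node,
since the I population receives no long-range input); and read each weight
off the excitatory current balance. The result agrees with an iterative
tuning loop to $10^{-6}$ (tested) and satisfies the 3 Hz constraint to
$10^{-6}$ Hz. FIC is computed once, before any gain modulation, and the
weights are frozen for all gain sweeps — it stands in for slow homeostatic
regulation that does not track acute perturbations.

## Parameters

Synaptic defaults (units in parentheses): $I_b = 0.382$ (nA), $J = 0.15$
(nA), $\gamma = 0.641$, $W_E = 1$, $W_I = 0.7$, $\tau_E = 0.1$ (s),
$\tau_I = 0.01$ (s), $a_E = 310$ (nC$^{-1}$), $b_E = 125$ (Hz),
$d_E = 0.16$ (s), $a_I = 615$ (nC$^{-1}$), $b_I = 177$ (Hz), $d_I = 0.087$
(s). Three constants are not part of that canonical table and are set from
the predecessor model lineage, all configurable: $w_{EE} = 0.21$ nA
($= 1.4 J$), $w_{IE} = J = 0.15$ nA, and $\sigma = 0.01$ nA. Uniform
$\sigma$ only scales covariances by $\sigma^2$; correlations, GBC and
loading are invariant to it (tested to $10^{-12}$), so its exact value is
immaterial for the shipped statistics.

Hemodynamic defaults: $\rho = 0.34$, $\alpha = 0.32$, $V_0 = 0.02$,
$\gamma_h = 0.41$ s$^{-1}$, $\kappa = 0.65$ s$^{-1}$, $k_1 = 3.72$,
$k_2 = 0.53$, $k_3 = 0.53$ (3 T constants). The transit time
$\tau_h = 0.98$ s completes the parameter set these values come from.
Symbol collisions with the synaptic equations ($\gamma, \tau, \kappa$) are
resolved by the `_h` suffix.

# From synaptic dynamics to BOLD covariance

Excitatory gating drives the Balloon–Windkessel cascade per node:
vasodilatory signal $x$, inflow $f$, volume $v$, deoxyhemoglobin $q$, and
the static BOLD readout $y = V_0[k_1(1-q) + k_2(1 - q/v) + k_3(1-v)]$. The
$x$-equation is driven by the raw gating variable, so the operating point
has a nonzero baseline BOLD; all shipped statistics are correlation-based
and unaffected. The hemodynamic steady state under constant gating $s$ is
closed-form: $x = 0$, $f = 1 + s/\gamma_h$, $v = f^\alpha$, and $q$ from the
zero of the deoxyhemoglobin equation.

Rather than estimating FC from long stochastic simulations, the package
linearizes the full $6N$-dimensional system (per-node state order
$S_E, S_I, x, f, v, q$, nodes blocked) at its stable fixed point and solves
the continuous Lyapunov equation

$$A P + P A^\top + Q_N = 0,$$

with $Q_N$ diagonal, $\sigma^2$ on both gating rows and zero on hemodynamic
rows. The BOLD covariance is the projection $P_{\mathrm{BOLD}} = K P K^\top$
with $K$ the Jacobian of the BOLD readout (nonzero only in each node's $v$
and $q$ columns). The Jacobian is assembled analytically and verified
against central finite differences to $10^{-6}$ relative error.

No installed linear-algebra package exposes a continuous Lyapunov solver,
so `solve_lyapunov()` performs the direct dense solve via the
eigendecomposition of $A$ (the transformed equation is diagonal and divides
by $d_i + \bar d_j$). Every solution is checked against the residual bound
$\|AP + PA^\top + Q\|_{\max} < 10^{-8}\|Q\|_{\max}$ and cross-validated in
the test suite against the scalar Ornstein–Uhlenbeck closed form
$\sigma^2/2\theta$ and against time-average covariances of simulated linear
SDEs. Unstable operating points (any eigenvalue with non-negative real
part) are refused rather than silently solved.

## How good is the linearization?

The package carries its own oracle: an Euler–Maruyama integrator of the full
nonlinear system (`simulate()`, compiled code; noise $\sigma\sqrt{dt}$ per
step on both gating variables, step $\le 1$ ms). On a 10-node synthetic
network at $\sigma = 0.01$ nA, analytic BOLD correlations match a 20,000 s
simulation within $|\Delta r| < 0.1$. The residual discrepancy at that
duration is dominated by Monte-Carlo sampling error, which does not depend
on $\sigma$; to resolve the *linearization* error we therefore use a paired
design, comparing each $\sigma$-run against a common-seed run at
$\sigma = 10^{-4}$ (identical noise draws, effectively linear regime). The
paired discrepancy shrinks in proportion to $\sigma$ over
$\sigma \in \{0.02, 0.01, 0.005\}$, confirming that the linearization error
vanishes in the weak-noise limit.

# Connectivity statistics

* **FC**: Pearson correlations from the (optionally GS-regressed) BOLD
  covariance.
* **GBC**: per-parcel mean of Fisher r-to-Z transformed off-diagonal
  correlations; magnitudes are clipped at $1 - 10^{-12}$ before `atanh`.
* **ΔGBC**: perturbed-minus-baseline GBC, aligned by parcel label.
* **Loading**: $\langle m, e\rangle / \langle e, e\rangle$ of a model map
  $m$ onto an empirical map $e$ — sensitive to topography *and* magnitude
  ($m = 2e$ gives 2, not 1).
* **Relative E/I ratio**: mean excitatory over mean inhibitory rate,
  relative to the unperturbed model.

Global signal regression is performed analytically on the covariance:

$$\operatorname{Cov}(\epsilon_i,\epsilon_j) = \operatorname{Cov}(y_i,y_j)
 - \frac{\sum_k \operatorname{Cov}(y_i,y_k)\sum_l \operatorname{Cov}(y_j,y_l)}
        {\sum_{mn}\operatorname{Cov}(y_m,y_n)},$$

which is exactly the covariance of time-domain residuals of regressing each
signal on the summed signal (tested to $10^{-10}$ against `lm`). Row sums of
the output vanish identically and the operation is idempotent. By default
GSR is applied to the model pipeline (`gsr = TRUE`), on the assumption that
the empirical target maps were GSR-processed; the flag exists because that
parity must match the target's preprocessing, and turning it off reproduces
the no-GSR comparison.

# Fitting

Calibration is a two-stage grid search, matching how such models are fit in
practice:

1. **Global coupling** (`calibrate_g()`): grid over $G \in [0.01, 0.85]$,
   step 0.01. Each point re-runs FIC (the weights depend on $G$), solves the
   fixed point, and scores the Spearman rank correlation between
   upper-triangular model and target FC. Unstable grid points are recorded
   as missing, never fatal unless all fail. On a self-generated target the
   generating $G$ is recovered within one grid step (tested).
2. **Gain modulation** (`sweep_gain()`): $11 \times 11$ grid over
   $\delta_E, \delta_I \in [0, 0.03]$, step 0.003, FIC weights and baseline
   GBC frozen from the unperturbed model; each cell is scored by loading
   against the target ΔGBC map. Ties resolve to the smallest
   $(\delta_I, \delta_E)$ lexicographically — deterministic and
   parsimonious. Subject-level fitting (`fit_subjects()`) reuses one shared
   model sweep, since the model maps do not depend on the target.

Everything is deterministic: identical inputs give bit-identical surfaces.

A known property of the loading objective deserves emphasis: because it
rewards magnitude, a target generated by the model itself at an interior
grid cell is *not* recovered at that cell — the model map stays aligned
with such a target while its norm grows with $\delta_E$, so the surface
increases toward the grid edge. Interior maxima (the band structure seen
with empirical targets) arise only when over-driving the model degrades the
*sign pattern* match with an external target. Parameter-recovery
experiments on self-generated targets are therefore meaningful for the
coupling search (rank objective) but not for the gain search (loading
objective); we verified this across coupling strengths up to the stability
edge.

Across the gain grid, loading is largely a function of one scalar — the
relative E/I firing-rate ratio: binning grid cells by E/I ratio leaves
within-bin scatter at a small fraction of the across-bin range (tested),
the one-dimensional collapse that motivates reading E/I balance as the
effective mechanism.

# Spatial-autocorrelation-preserving surrogate maps

Naive permutation nulls are invalid for spatially autocorrelated brain
maps. `generate_surrogate()` builds variogram-matched surrogates: permute
the map; smooth over $k$ nearest neighbors with an exponential kernel of
bandwidth equal to the $k$-th neighbor distance; score each candidate $k$
by least-squares match between the surrogate and empirical variograms (a
fitted multiplicative scale absorbs amplitude, and leaves ranks unchanged);
keep the best $k$; finally re-assign the empirical values rank-for-rank, so
the surrogate's value multiset equals the original's exactly. Defaults: 25
uniform distance bins, candidate $k \in \{5\%, \dots, 50\%\}$ of $N$. The
method's literature leaves these free; our defaults mirror that lineage and
are configurable. On strongly autocorrelated synthetic maps the mean
surrogate variogram matches the empirical one within 2% relative SSE where
naive permutations miss by >20% (tested).

`surrogate_null_test()` evaluates an arbitrary map statistic on the
empirical map and on $n$ independently seeded surrogates and reports the
one-sided proportion $p = \#\{\text{null} \ge \text{obs}\}/n$ — the plain
proportion convention, so an observation above every null sample gives
$p = 0$; the conservative $(r+1)/(n+1)$ form is available via
`conservative = TRUE`. For maps with no spatial structure the resulting
p-values are approximately uniform (Kolmogorov–Smirnov-checked over
repeated synthetic draws).

# Linear decomposition

`map_pca()` eigendecomposes $C = X^\top X/(M-1)$ after column centering;
components are ordered by descending eigenvalue and signed so each
component's largest-magnitude element is positive (eigenvectors are
sign-ambiguous; fixing the sign makes map comparisons reproducible). For
$M < N$ maps at most $M - 1$ eigenvalues are nonzero.
`pc_permutation_test()` permutes each map independently and compares each
observed variance fraction against the null's 95th percentile; both the 5th
and 95th percentiles are returned, since either convention appears in
practice — significance defaults to "observed above the null 95th
percentile" (one-sided $p < 0.05$).
`subspace_variance_fraction()` is $\operatorname{tr}(P^\top C P) /
\operatorname{tr}(C)$ for an orthonormal basis $P$, which reduces to the
cumulative variance fraction on the covariance's own leading axes.
`experiential_regression_maps()` regresses, across subjects, each score
dimension on each parcel's ΔGBC, via the closed-form OLS slope
$\operatorname{cov}/\operatorname{var}$ (cross-checked against `lm`).

An identifiability caveat: the per-parcel variance in the OLS denominator
means the slope map recovers the underlying score-coupling pattern only
when per-parcel variation across subjects is not dominated by a single
global strength factor; in the factor-dominated regime the slope map tends
toward the reciprocal pattern. The synthetic recovery tests state their
regime explicitly.

# The synthetic-data generator

All tests and the acceptance script run on synthetic data built in code:

* `make_connectome()`: parcels placed uniformly on a 100 mm 2-D sheet;
  weights decay exponentially with Euclidean distance (default length 30
  mm, the scale at which tractography-derived connection probability falls
  off) under multiplicative lognormal jitter (sdlog 0.5); symmetrized,
  hollow, row-normalized.
* `make_expression_map()`: Gaussian random field with covariance
  $e^{-D/\lambda}$, z-scored and mapped through the standard-normal CDF to
  $(0,1)$ — the same bounded linearization applied to empirical expression
  maps. Receptor-expression maps have cortex-scale gradients, so
  autocorrelation-sensitive tests use $\lambda$ comparable to the sheet
  size (60 mm).
* `make_cohort()`: 24 subjects by default; each map is a subject-scaled
  group pattern plus rank-limited individual variation (patterns
  orthogonalized against the group map so the planted subspace is
  identifiable) plus i.i.d. noise; five score dimensions are linear in the
  maps through known coupling maps, so recovery experiments have ground
  truth.

What the generator does *not* emulate: realistic tractography degree
distributions, geodesic (as opposed to Euclidean) distances, hemispheric
asymmetries, empirical measurement noise spectra, or subject-level
connectome variation. Passing tests therefore demonstrate correctness of
the machinery and recoverability under the stated generative assumptions,
not performance on empirical data.

# Numerical choices

* Fixed-point solver: damped Newton on the $2N$ drift field with analytic
  Jacobian, tolerance $10^{-12}$ on the max drift, at most $10^4$
  iterations, init $S_E = S_I = 0.1$; damped pseudo-time fallback.
  Accepted solutions satisfy max drift $< 10^{-10}$.
* Transfer function: series switch at $|d(aI - b)| < 10^{-5}$;
  exponentially rescaled branch for negative arguments to avoid overflow.
* SDE integration: Euler–Maruyama, $dt \le 1$ ms enforced; noise
  $\sigma\sqrt{dt}\,\mathcal N(0,1)$ per node and population;
  deterministic runs converge with $O(dt)$ (halving $dt$ moves a 100 s
  endpoint by $< 10^{-4}$, tested); blow-ups abort with the time index.
* Problem sizes in the shipped tests: 5–80 node networks, 20,000 s
  simulations for the linearization oracle, 200-surrogate null for the
  positive control, 200-permutation PCA nulls — sizes at which every check
  runs in seconds to a few minutes on one core.

# Limitations

Beyond the generator's idealizations: the model has no subcortical nodes,
a single interneuron type, and no spiking; FC dynamics (sliding-window
statistics) are out of scope; the loading objective's magnitude sensitivity
makes gain-parameter self-recovery ill-posed (see *Fitting*); and fitting
is grid-search only — no gradients, no posterior.
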