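# dmfgain

Biophysically based modeling of how spatially heterogeneous changes in
neural gain — for instance, receptor-mediated pharmacological modulation
weighted by a receptor-gene expression map — reshape the topography of
cortical BOLD functional connectivity. The package is aimed at
computational neuroscientists who fit large-scale circuit models to
parcellated neuroimaging data and need the full chain from synaptic
parameters to connectivity statistics, with spatially aware null tests and
subject-level decomposition analyses.

## What it computes

Each parcel hosts coupled excitatory/inhibitory populations (a dynamic
mean-field reduction), interacting through a row-normalized structural
connectome `C` scaled by a global coupling `G`:

    I_E = W_E*Ib + w_EE*S_E + G*J*(C S_E) - w_EI ∘ S_I
    I_I = W_I*Ib + w_IE*S_E - S_I
    r   = φ(I) = (aI - b) / (1 - exp(-d(aI - b)))

with per-node feedback inhibition control tuning `w_EI` so baseline
excitatory rates sit at 3 Hz, and gain modulation
`a_i = (1 + h_i δ) a_0` weighted by a brain map `h`. Synaptic activity
drives Balloon–Windkessel hemodynamics; BOLD covariance is obtained
semi-analytically by linearizing the full 6N-dimensional system and solving
the Lyapunov equation `AP + PAᵀ + Q = 0`, then projecting through the BOLD
readout. On top of that sit: Pearson FC, analytic global signal regression
performed directly on covariances, global brain connectivity (GBC) maps and
their drug-minus-placebo-style differences (ΔGBC), model-empirical loading,
grid-search calibration of `G` (Spearman objective) and of `(δ_E, δ_I)`
(loading objective) at group and subject level, variogram-matched
spatial-autocorrelation-preserving surrogate-map null tests, PCA of map
ensembles with permutation significance, subspace variance fractions, and
per-parcel experiential regression maps.

A full account of the model, conventions, and numerical choices is in the
vignette: `vignettes/gain-modulated-mean-field.Rmd`.

## Worked example

```r
library(dmfgain)

# synthetic study system: 30-parcel distance-decay connectome on a 2-D
# sheet, and a spatially autocorrelated expression-like map in (0, 1)
sc    <- make_connectome(n_nodes = 30, seed = 0)
model <- dmf_model(sc, dmf_params(G = 0.5))   # runs FIC, solves fixed point
model
#> Dynamic mean-field model: 30 nodes, G = 0.5, FIC target 3 Hz
#>   baseline r_E in [3.0000, 3.0000] Hz, stable: TRUE

h      <- make_expression_map(sc, autocorr_length = 60, seed = 3)
target <- model_dgbc(model, gain_mod(h, 0.012, 0.006), gsr = TRUE)

fit <- sweep_gain(model, h, target)           # 11 x 11 (δ_E, δ_I) grid
fit
#> Gain-modulation grid search: 11 x 11 cells (0 unstable)
#>   best (delta_E, delta_I) = (0.03, 0), loading = 7.6101

ss <- model_steady_state(model, gain_mod(h, coef(fit)[1], coef(fit)[2]))
ei_ratio(ss, model$baseline)
#> [1] 1.672
```

The baseline model sits at exactly 3 Hz excitatory rates (that is what FIC
guarantees). The grid search maximizes the loading of the model ΔGBC map
onto the target; note that loading rewards magnitude as well as topography
(`loading(2e, e) = 2`), so against a target the model itself generated the
surface keeps rising with `δ_E` and the best cell sits at the grid edge
with loading 7.6 — see the vignette's *Fitting* section for why this is a
property of the objective, not a solver artifact. The fitted cell raises
the excitatory-to-inhibitory firing-rate ratio by 67% relative to baseline.

Coupling calibration against a self-generated FC target recovers the
generating value:

```r
target_fc <- model_fc(dmf_model(sc, dmf_params(G = 0.40)), gsr = TRUE)
calibrate_g(sc, dmf_params(), target_fc)
#> Global coupling calibration: 85 grid points (0 unstable)
#>   best G = 0.4 (Spearman rho = 1.0000)
```

A thin command-line front end over these functions is included at
`inst/cli/dmfgain.R` (subcommands `make-fixtures`, `gbc`, `calibrate-g`,
`sweep-gain`, `simulate`, `surrogate-test`, `decompose`, `regress-maps`).

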