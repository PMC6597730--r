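# micromotion

Motion analysis for enzyme-powered micromotors, with a fully synthetic
replication pipeline.

Catalytically active microparticles — micron-sized silica spheres coated with
an enzyme such as urease — self-propel when their substrate is present: the
surface reaction generates an asymmetric product gradient that drives the
particle at up to a few µm s⁻¹. The standard readout of this activity is
single-particle tracking: record the particle under an optical microscope,
extract its 2-D trajectory, compute the time-averaged mean squared
displacement (MSD), and fit the short-lag MSD to separate directed propulsion
from thermal diffusion. `micromotion` implements that entire inference chain
for R users, together with a physics-based simulator so every stage can be
validated against known ground truth — no experimental videos required.

## The model

For a trajectory sampled at uniform intervals, the time-averaged MSD at lag
Δt averages the squared displacement over all overlapping windows:

```
MSD(Δt) = ⟨ (x(t + Δt) − x(t))² + (y(t + Δt) − y(t))² ⟩_t
```

A self-propelled sphere is modeled as a 2-D active Brownian particle (ABP):
it moves at speed *v* along a heading that decorrelates by rotational
diffusion *D_r*, on top of translational diffusion *D_t*. In the propulsive
regime *t* ≪ *τ_r* = 1/*D_r*, the ABP MSD reduces to

```
MSD(t) = 4 D_t t + v² t²
```

and an ordinary least-squares fit on the design {4t, t²} yields *D_t* and
*v*. The fit window is bounded by the rotational diffusion time, obtained
from the Stokes–Einstein relation

```
D_r = k_B T / (8 π η r³),    τ_r = 1 / D_r
```

For the reference particle (radius 1.00 µm, 24 °C, solvent viscosity
0.9107×10⁻³ kg m⁻¹ s⁻¹) this gives *D_r* = 0.1792 s⁻¹ and *τ_r* = 5.579 s;
the translational counterpart *D_t* = k_B T/(6πηr) = 0.239 µm² s⁻¹.

Upstream of the motion model, a kinetic module maps substrate concentration
*S* and inhibitor concentration *I* to a relative catalytic rate

```
rate(S, I) = v_max · S / ( K_m (1 + I/K_i) + S (1 + S/K_s) )
```

(competitive inhibition raises the apparent K_m; substrate inhibition caps
the rate at excess substrate) and couples propulsion speed linearly to that
rate — so dose–response sweeps, inhibitor titrations and speed–activity
correlations can be replicated end to end in silico. A frame renderer and a
spot-detection + linking tracker close the loop through synthetic microscopy
videos.

## Worked example

```r
library(micromotion)

tp <- thermal_params()   # 1.00 um sphere, 297.15 K, water-like viscosity
rotational_scale(tp)
#> # A tibble: 1 × 2
#>   D_r_per_s tau_r_s
#>       <dbl>   <dbl>
#> 1     0.179    5.58

# a substrate dose-response, 20 simulated particles per condition
kp <- urease_kinetics()
conds <- tibble::tibble(substrate_mM = c(0, 10, 100, 300), inhibitor_mM = 0)
sweep <- run_sweep(conds, kinetics = kp, thermal = tp, seed = 42)
dplyr::select(sweep, substrate_mM, rate, true_speed_um_s,
              mean_v_um_s, sem_v_um_s, propulsive)
#> # A tibble: 4 × 6
#>   substrate_mM  rate true_speed_um_s mean_v_um_s sem_v_um_s propulsive
#>          <dbl> <dbl>           <dbl>       <dbl>      <dbl> <lgl>
#> 1            0 0               0           0.140     0.0359 FALSE
#> 2           10 0.248           0.514       0.447     0.0494 TRUE
#> 3          100 0.645           1.34        1.26      0.0288 TRUE
#> 4          300 0.541           1.12        1.03      0.0301 TRUE
```

Reading the table: with no substrate the condition is correctly called
non-propulsive (the 0.14 µm s⁻¹ "speed" is the expected positive bias of
speed magnitudes fitted to purely Brownian tracks — hence the calibrated
significance call rather than a threshold on the mean). Speed rises with
substrate, peaks near 100 mM and falls again at 300 mM, following the
substrate-inhibited kinetics of the preset.

Fitting a 20-particle ensemble MSD at a known propulsion speed of
2.07 µm s⁻¹ recovers it within a few percent:

```r
D_t <- translational_diffusion(tp); D_r <- rotational_diffusion(tp)
trajs <- simulate_ensemble(20, 2.07, D_t, D_r, seed = 1)
msd   <- compute_msd(trajs, max_lag_s = 0.2 * 5.579)
fit_propulsive(ensemble_msd(msd), tau_r = 5.579)
#> <propulsive_fit>  MSD(t) = 4*Dt*t + v^2*t^2
#>   v   = 1.9363 um/s (se 0.0021)
#>   D_t = 0.2663 um^2/s (se 0.0018)
#>   window (0, 1.12 s], 27 lags, R^2 = 1.0000
```

`plot_msd()`, `plot_dose_response()` and `autoplot()` methods visualize
curves, sweeps and fits; `tidy()`/`glance()` return fitted objects as
tibbles.

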