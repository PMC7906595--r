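# fermkin

Batch alcoholic fermentation kinetics with byproduct inhibition.

In yeast fermentations the secondary metabolites — glycerol, acetic acid
and succinic acid — accumulate in proportion to the glucose consumed and
progressively slow growth. `fermkin` implements a modified Monod model in
which the specific growth rate is multiplied by an inhibition factor
driven by the lumped byproduct concentration *Z*:

```
μ(S, Z) = μ_max0 · S/(K_s + S) · f(Z)

dX/dt =  μ X                    (biomass)
dS/dt = -μ X / Y_x/s            (glucose)
dP/dt = -Y_p/s · dS/dt          (ethanol)
dZ/dt = -Y_z/s · dS/dt          (byproducts)
```

with `f(0) = 1` and `f(Z) = 0` for `Z ≥ Z_m`, the concentration at which
fermentation stops entirely. Three inhibition families are built in —
linear `1 − Z/Z_m`, parabolic `1 − (Z/Z_m)²`, and the Luong-type power law
`(1 − Z/Z_m)^K_z` (tag `exponential`) — and the registry is user-extensible.
The calibrated defaults are `μ_max0 = 0.244 h⁻¹`, `K_s = 11.5 g/L`,
`Z_m = 60 g/L`, `K_z = 0.83`, with yields `Y_x/s = 0.28`, `Y_p/s = 0.42`,
`Y_z/s = 0.0442` g/g.

The package is aimed at bioprocess modellers who need to simulate batch
runs, calibrate the inhibition law from growth-rate measurements, estimate
yield coefficients, and compare the inhibited model against classical
Monod with the usual error statistics (MSE, RMSE, total absolute
deviation, R², fermentation-time delay).

## Worked example

```r
library(fermkin)

params <- kinetic_params(0.244, 11.5, Z_m = 60, K_z = 0.83)
yields <- yield_coefficients(0.28, 0.42, 0.0442)
inoc   <- batch_state(X = 1, S = 100)          # 1 g/L inoculum, 100 g/L glucose

traj <- simulate_batch(inoc, params, yields)   # RK4, dt = 0.01 h, 72 h
traj
#> Batch trajectory: 7201 samples, t = 0..72 h (dt = 0.01 h, rk4)
#>   final state: X = 29.000, S = 2.8e-49, P = 42.000, Z = 4.4200 g/L

fermentation_time(traj)                        # h to 99% glucose consumption
#> [1] 17.74229
model_delay(params, yields, inoc)              # h later than classical Monod
#> [1] 0.3581101
```

The endpoints are the stoichiometric ones: 100 g/L of glucose leaves
`1 + 0.28·100 = 29` g/L biomass, `42` g/L ethanol and `4.42` g/L
byproducts, i.e. 0.0442 g byproduct per g glucose. The inhibited run
finishes ~0.36 h later than classical Monod would predict.

Calibrating the inhibition law from growth-rate observations and selecting
the best family:

```r
obs <- generate_mu_vs_z(params, noise = noise_model(0, 0, seed = 1))
select_inhibition_family(obs)
#> Inhibition family selection (best first):
#>       family r_squared n_free converged rank
#>  exponential 1.0000000      3      TRUE    1
#>       linear 0.9975704      2      TRUE    2
#>    parabolic 0.9510203      2      TRUE    3

split_byproducts(4.42, byproduct_mixture())    # 56/36/8 mass fractions
#> glycerol   acetic succinic
#>   2.4752   1.5912   0.3536
```

## Command line

A thin wrapper ships at `inst/cli/fermkin`; all subcommands work from any
R session via `fermkin_cli()`:

```sh
fermkin simulate        --config cfg.json --out traj.csv
fermkin generate        --config cfg.json --out obs.csv [--type mu-vs-z] [--seed 7]
fermkin fit-inhibition  --obs obs.csv --family linear,parabolic,exponential
fermkin estimate-yields --endpoints endpoints.csv
fermkin compare         --obs course.csv --config cfg.json [--config-b other.json]
```

A complete example configuration (the calibrated defaults above) ships at
`inst/extdata/config_reference.json`. All tabular I/O is comma-separated
UTF-8 with `.` decimals; the time-course layout is
`time_h,biomass_g_L,glucose_g_L,ethanol_g_L,byproduct_g_L` (columns
matched by name, empty cells = missing), growth-rate observations are
`Z_g_L,mu_max_per_h[,Ks_g_L]`, and yield endpoints are `S0,dS,dX,dP,dZ`.

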