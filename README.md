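# rcaswitch

Kinetics of polymerase template switching in rolling circle replication.

## The problem

Rolling circle amplification (RCA) with a strand-displacing polymerase
(phi29) is widely assumed to produce single-stranded DNA concatamers
indefinitely. In practice, unprotected reactions accumulate large amounts of
double-stranded DNA, ssDNA production peaks and then vanishes, and the total
yield saturates — unless single-stranded-DNA-binding (SSB) protein is added,
which keeps the product single-stranded. All of this is explained by a
single stochastic event: the polymerase switches from its circular template
onto the displaced strand, converts the ssDNA it had produced into dsDNA by
fill-in synthesis at the same rate, and terminates when the strand runs out.

`rcaswitch` is for anyone quantifying RCA time courses (gel densitometry or
equivalent) who wants to estimate the switching rate constant, predict
ss/dsDNA partitioning over time, or test the mechanism against data.

## The model

Switch times are i.i.d. Exponential(λ), so the switched-template fraction is
`1 − exp(−λt)`. A template that switches at τ terminates at 2τ (equal
elongation rate during displacement and fill-in), and each fill-in
nucleotide yields one base pair — two mass units — of dsDNA. Averaging over
the switch-time distribution, with amplitude `A = 2·n₀·φ` (n₀ templates,
elongation rate φ):

    N_ds(t) = (A/λ)·(e^(−λt) − 2·e^(−λt/2) + 1)
    N_ss(t) = (A/λ)·(e^(−λt/2) − e^(−λt))
    N_ss(t) + N_ds(t) = (A/λ)·(1 − e^(−λt/2))

ssDNA peaks at `2·ln2/λ` and decays to zero; the total saturates at the
termination plateau `A/λ`. With SSB protein, switching is blocked (λ = 0)
and production is linear, `n₀·φ·t`. Only the product `n₀·φ` is identifiable
from mass data.

The package provides:

* **closed-form model** — `model_params()`, `mass_ss()`, `mass_ds()`,
  `dsdna_rate()`, `switched_fraction()`, `half_life()`, `ss_peak_time()`,
  `rcr_predict()`;
* **event-driven stochastic simulator** — `sim_config()`, `simulate_rcr()`,
  `expected_masses()`, `validate_simulator()` (exact per-template evaluation,
  no time discretization);
* **synthetic gel-densitometry data** — `noise_model()`,
  `generate_measurements()` (total and dsDNA channels independently
  corrupted, ssDNA by subtraction, as on real two-gel quantification);
* **Levenberg–Marquardt fitting** — `fit_switching()` (ssDNA-only objective
  by default, log-parameterized, heteroscedasticity-robust uncertainties),
  `predict_with_fit()`, `recovery_experiment()`;
* **CLI** — `inst/scripts/rcr` wrapping
  `generate | fit | predict | simulate | validate | recover`.

## Worked example

Simulate a noisy 1–72 h time course at the literature rate (half-life
9.9 h, plateau 50 mass units), then fit it:

```r
library(rcaswitch)
truth <- model_params(lam = log(2) / (9.9 * 3600), amplitude = 50 * 1.95e-5)
tab <- generate_measurements(truth, noise = noise_model(0.10, 0.5, seed = 1),
                             mode = "stochastic", n_templates = 10000)
head(round(as.data.frame(tab), 2), 4)
#>   time_h total_dna ds_dna ss_dna
#> 1      1      1.55   0.00   1.55
#> 2      3      5.09   0.97   4.12
#> 3      6      8.86   2.77   6.09
#> 4      9     14.18   4.19   9.99

fit_switching(tab)
#> Template-switching fit (Levenberg-Marquardt, ss_only objective)
#>   lambda    : 1.275e-05 +/- 1.5e-06 per s  (half-life 15.1 h)
#>   amplitude : 0.0006268 +/- 8.2e-05 mass units per s
#>   RSS 21.13 over 11 points; converged in 7 iterations
```

A single noisy time course determines λ only to a few tens of percent (the
subtracted ssDNA channel is noisiest exactly where it informs the rate); the
replicated experiment centers on the truth:

```r
recovery_experiment(truth, n_replicates = 50, cv = 0.10,
                    mode = "stochastic", n_templates = 10000, seed = 1)
#> Parameter recovery: 50 replicates (50 converged)
#>   true lambda   : 1.945e-05 /s
#>   mean estimate : 1.865e-05 /s (replicate sd 4.3e-06)
#>   relative bias : -4.09%   relative RMSE: 22.26%
#>   2-sd coverage : 84%
```

The fitted λ of the original densitometry experiment, 1.95 × 10⁻⁵ events
s⁻¹ template⁻¹, corresponds to a template half-life of 9.87 h before
switching, and predicts that ssDNA is ~96.6% of the product mass after 1 h
while dsDNA dominates by 72 h.

The same pipeline from the shell:

```sh
Rscript inst/scripts/rcr generate --out run.csv --seed 7
Rscript inst/scripts/rcr fit --data run.csv --out fit.json --predict-out curves.csv
Rscript inst/scripts/rcr validate --n-templates 100000
```

See `vignettes/template-switching-kinetics.Rmd` for the model's derivation,
assumptions, noise model, and numerical choices.

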