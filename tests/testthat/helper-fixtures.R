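# Shared fixtures: the fitted switching rate from the original densitometry
# experiment and a truth whose termination plateau is 50 mass units.
fitted_lam <- 1.95e-5
plateau50_params <- function(lam = fitted_lam) {
  model_params(lam = lam, amplitude = 50 * lam)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
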