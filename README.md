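# scro: swarm-based chemical reaction optimization for dynamic-model calibration

Dynamic models of biochemical systems — ODEs or discrete maps — carry
kinetic parameters that must be estimated by fitting model output to noisy,
incomplete time-series data.  `scro` implements the **S-CRO** hybrid
metaheuristic for this bounded nonlinear least-squares problem,

    theta_hat = argmin_theta  sum over observed (n, s) of
                (y_obs[n, s] - y_model[n, s; theta])^2,
                subject to  lower <= theta <= upper,

together with three reference population methods (differential evolution,
the firefly algorithm, and chemical reaction optimization), statistical
validation of the estimates, and model selection.

Each S-CRO iteration sorts the population by fitness and splits it in two:
the *potential* half is refined by firefly attraction moves
(`beta(r) = beta0 * exp(-mu r^2)`) followed by one CRO reaction per member
(on-wall collision, decomposition, inter-molecular collision or synthesis,
selected by a uniform draw, with strict kinetic/potential energy
accounting), while the *weak* half is re-initialised by a best-guided
random update.  The package also provides:

* a registry of three benchmark systems — a discrete nonlinear map
  (`a = 0.8`, `b = 1.5`), a two-switch transcriptional oscillator
  (`theta = (0.57 uM, 1.5, 2.5 uM, 6.5, 6.5)`), and a 17-parameter
  DegS–DegU extracellular protease production network — plus user-defined
  models via `make_dynamical_model()`;
* a synthetic-data generator (`make_benchmark()`): percent white Gaussian
  noise (relative by default), optional exact-count missingness, and the
  recorded per-state injected-noise variance;
* a chi-square residual-variance test of practical identifiability
  (`identifiability_test()`) and AIC-based comparison of candidate model
  structures (`compare_models()`);
* a command-line tool (`inst/scripts/dynfit`) with `simulate`, `estimate`,
  `validate`, `select` and `benchmark` subcommands.

## Worked example

Generate a 15%-noise dataset from the oscillator at its true parameters,
refit it with S-CRO under the study settings (20 solutions, 100
iterations, `beta0 = 0.5`, `mu = 0.01`), and validate the estimates:

```r
library(scro)

model <- benchmark_model("oscillator")
bench <- make_benchmark(model, noise = noise_spec(15), seed = 1)
fit   <- fit_model(model, bench$data,
                   control = scenario_control("oscillator"), seed = 1)
summary(fit)
```

```
Dynamical model fit ('oscillator', method SCRO)
  best fitness (SSE): 42.4615 over 400 observed entries
  evaluations: 6343; seed: 1
Parameter set (5 parameters)
       value lower upper unit
K1 0.5602215   0.1   1.2   uM
n1 1.6571422   0.5   3.0     
K2 2.4707453   1.0   5.0   uM
n2 6.0998072   3.0  10.0     
v  6.4421258   3.0  10.0     

  n = 400 observed entries, D = 5 parameters
  MSE = 0.1061538,  AIC = -887.1467

Residual-variance identifiability test (gamma = 0.95)
 state real_variance variance_point            interval passed
     A      0.028900       0.027800    [0.0214, 0.0375]   TRUE
     B      0.390000       0.391000      [0.302, 0.528]   TRUE
     C      0.008280       0.008330   [0.00642, 0.0112]   TRUE
     D      0.000885       0.000907 [0.000699, 0.00122]   TRUE
Overall: Pass
```

The estimates approach the generating values `(0.57, 1.5, 2.5, 6.5, 6.5)`
(a single run at 15% noise carries 5–10% scatter; the shipped studies
report medians over 20 seeded replicates), and the residual variance of
every observed state falls inside its 95% chi-square interval around the
injected-noise variance, so the test declares the reconstruction
plausible.  Compare
candidate structures on the same data with

```r
ablated <- fix_parameters(model, c(K1 = 0, n1 = 0, v = 0))
compare_models(list(original = model, ablated = ablated), bench$data,
               control = scenario_control("oscillator", NP = 20,
                                          iterations = 60), seed = 1)
```

which reports the AIC of both fits and declares the original model the
winner (the ablated variant also fails the variance test).

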