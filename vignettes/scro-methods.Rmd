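---
title: "Estimating dynamic-model parameters with S-CRO: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic-model parameters with S-CRO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scro)
```

## The estimation problem

Dynamic models of biochemical systems — ordinary differential equations or
discrete maps over a state vector — carry kinetic parameters that are rarely
measurable directly.  They are instead estimated by fitting the model output
to time-series measurements that are noisy and often incomplete.  The
package formulates this as bounded nonlinear least squares: for parameters
$\theta$ inside a box $[\ell, u]$,

$$\hat\theta = \arg\min_\theta \sum_{n,s \in \text{observed}}
  \bigl(\tilde y_{ns} - y_{ns}(\theta)\bigr)^2,$$

where $\tilde y$ are the observations, $y(\theta)$ the model prediction on
the same sampling grid, and the sum runs over the masked-in entries only.
No normalisation by the number of samples is applied inside the objective;
`aic_score()` converts the optimal value to a mean squared error where a
per-sample quantity is needed.  Residuals are unweighted by default (a
per-state weight option exists in the objective internals); with states of
very different magnitude this makes the largest states dominate the fit,
which is one reason the built-in benchmarks are designed with commensurate
state scales.

Because candidate parameters proposed by a global optimizer routinely make
a system stiff or unstable, integration failure is mapped to a fitness of
`+Inf` rather than an error, and the evaluation still counts against the
run's budget.

## The optimizers

Four population methods share one substrate (uniform-in-box initialisation,
bound clamping as the out-of-bounds repair, a single seeded RNG stream per
run, and an elitist best-ever snapshot that makes every convergence trace
non-increasing):

* **Differential evolution (DE)**, `DE/rand/1/bin`.  The benchmark study
  conditions prescribe a mutation factor of 2.5 and a "crossover
  coefficient" of 1.5; since 1.5 is outside the valid crossover-probability
  range, the package interprets the first as $F$ and clamps the second to
  $CR = 1$.  Both are exposed in `optimizer_control()`.  ($F > 1$ makes DE
  highly explorative; it is implemented exactly as configured because it is
  a *reference* method here, not a method we tuned.)
* **Firefly algorithm (FA)**.  Attractiveness decays with distance as
  $\beta(r) = \beta_0 e^{-\mu r^2}$ (Euclidean $r$ in raw parameter units);
  a solution moves towards every brighter neighbour by
  $x_i \leftarrow x_i + \beta (x_j - x_i) + \alpha (u - 0.5) w$ with $u$
  uniform per coordinate and $w$ the per-coordinate bound width.  Scaling
  the random step by the bound width keeps the perturbation meaningful when
  parameters span several orders of magnitude (the protease rates range
  from $10^{-4}$ to $10$).  The standalone baseline uses canonical sweep
  bookkeeping: brightness comparisons against the sweep-start snapshot and
  one re-evaluation per firefly per sweep.
* **Chemical reaction optimization (CRO)**.  Each molecule carries a
  potential energy (its fitness) and a kinetic energy, a tolerance budget
  that lets reactions accept worse solutions early on.  Four reactions are
  implemented with strict energy accounting — an accepted outcome never
  increases the total energy of the molecules involved:
  on-wall collision (small Gaussian perturbation, scale 1% of the bound
  width, accepted iff $PE' \le PE + KE$, surviving kinetic energy
  $(PE + KE - PE')\,q$ with $q \sim U(LR, 1)$); decomposition (two
  offspring perturbed at 50% of the bound width, executed only when the
  parent's total energy covers both offspring, surplus split by a uniform
  $k$); inter-molecular collision (the pairwise analogue of the on-wall
  rule with a uniform redistribution of the surplus); and synthesis
  (per-coordinate recombination of a pair, the child inheriting the entire
  energy surplus).
* **S-CRO**, the hybrid under study.  Each iteration: (1) *initial
  selection* — sort by fitness and split into a potential and a weak
  sub-population (fraction 0.5 by default; the proportion is a free design
  choice); (2) *neighbouring improvement* — a firefly pass over the
  potential sub-population, evaluating each attraction move immediately so
  later comparisons see current fitness, with the global-best snapshot
  acting as one additional attractor (the population is explicitly drawn
  towards the current best solution), followed by the *evolutionary
  combinatorial step*: each potential member draws one reaction (draw
  $\le 0.33$ on-wall, $(0.33, 0.5)$ decomposition, $[0.5, 0.7]$ synthesis,
  $> 0.7$ inter-molecular collision; partners uniform among the other
  potential members); (3) *random update* of the weak sub-population,
  $x \leftarrow x + r_1 (x_{best} - x) + r_2 (u - x)$ with scalar
  $r_1, r_2 \sim U(0,1)$ and $u$ uniform in the box, with kinetic energy
  re-endowed.  After the merge the population is repaired to exactly `NP`
  molecules (worst dropped, or best-guided clones added).

Coefficients the study conditions fix are the defaults
(`scenario_control()`): $\beta_0 = 0.5$, $\mu = 0.01$, 20 solutions and 100
iterations for the small-scale systems; $\beta_0 = 0.7$, $\mu = 0.05$, 50
solutions and 200 iterations (and DE amplified to $F = 3$) for the protease
network.  Coefficients the study conditions do not fix were frozen as
package defaults after a design study on the benchmark suite and are
documented here so they can be criticised: the firefly step scale
$\alpha = 0.2$ with geometric decay $0.97$ per iteration (an annealed step
is standard firefly practice; a constant step is available via
`alpha_decay = 1`), kinetic-energy loss rate $LR = 0.2$, and an initial
kinetic energy of 1.  The last deserves a note: endowing molecules with a
kinetic budget proportional to the initial population fitness (an obvious
scale-free rule) makes early on-wall collisions accept arbitrary
deterioration on large-SSE problems and measurably slows convergence; a
small absolute budget keeps the tolerance mechanism meaningful on
well-scaled objectives without destroying the early population on badly
scaled ones.

### What the comparisons do and do not show

With all four methods implemented competently and reported elitistically,
their final-fitness differences on these smooth, essentially unimodal
calibration problems are small (often under 1%).  The hybrid's advantage is
robustness: its convergence depth is nearly independent of the firefly
step scale, while the plain FA degrades quickly when $\alpha$ grows, and DE
collapses under the prescribed $F = 2.5$.  The comparative test in the
suite asserts the median ordering (S-CRO no worse than each reference
method at an equal population/iteration budget over 20 seeds), not the
orders-of-magnitude gaps a weaker baseline implementation would produce.
One structural limitation is asserted as such: the canonical CRO explores
with a fixed-width reaction kernel, so its attainable precision at a fixed
budget is kernel-limited (about $10^{-4}$ on the unit-box quadratic sanity
problem) where the other three polish to numerical depth.  An optional
geometric kernel anneal (`onwall_decay`) is provided but off by default.

## Benchmark systems

The three built-in systems are concrete realizations written for this
package; their published parameter values, bounds, state roles and study
conditions are respected, and each right-hand side lives in one unit-tested
function (compiled in C for the ODE systems, with reference R
implementations tested against the compiled versions).

**Discrete nonlinear map** (`simulated_nonlinear`): three states,
$x_1' = a x_1 + x_2/(1+x_2^2) + e_1$, $x_2' = b x_2 (1 - x_2) + e_2$,
$x_3' = x_1 x_2 + e_3$, true $(a, b) = (0.8, 1.5)$, bounds $a \in [0, 1]$,
$b \in [0, 3]$, initial state $(0.1, 0.1, 0.1)$, independent zero-mean
Gaussian process noise with sd 0.02 per state (the map's only stochastic
term; estimation fits the deterministic skeleton).  The default series is
800 steps.  The map mixes a stable linear channel, a logistic channel and
a bilinear observation channel, so both parameters are identifiable from
the transient and the noise-excited steady state.

**Two-switch transcriptional oscillator** (`oscillator`): RNA activator
$A$ switches Sw21 on through a Hill function with threshold $K_1 = 0.57$
µM and coefficient $n_1 = 1.5$; Sw21 produces RNA inhibitor $B$; $B$
switches Sw12 off (threshold $K_2 = 2.5$ µM, coefficient $n_2 = 6.5$);
Sw12 produces $A$ at rate $v = 6.5$.  All relaxation rates are scaled to 1
(dimensionless time).  The negative feedback loop with the sharp second
switch yields a lightly damped oscillation of period $\approx 6.4$; the
default grid (100 uniform points over $[0, 20]$ from the excited state
$(1, 1, 0.5, 0.5)$) spans the large initial excursion plus two to three
periods, during which $A$ crosses $K_1$ and $B$ crosses $K_2$ — the
excursions that make the thresholds and Hill coefficients identifiable.
Bounds are $K_1 \in [0.1, 1.2]$, $n_1 \in [0.5, 3]$, $K_2 \in [1, 5]$,
$n_2, v \in [3, 10]$.

**Extracellular protease production** (`protease`): the DegS–DegU
two-component system driving subtilisin expression, six states (AprE,
DegU, DegU~P, the DegU~P dimer, mAprE, mDegU) and 17 parameters with the
published values and bounds.  Phosphorylation ($k_{10} = 12\,s^{-1}$) and
two dephosphorylation paths ($k_{16} = k_{17} = 7\,s^{-1}$) exchange DegU
and DegU~P; DegU~P dimerises reversibly (association $k_8 = 7$,
dissociation $k_{11} = 7$); the dimer activates
mAprE transcription through a saturable switch ($k_{15}, k_{14}$); mAprE
decays slowly ($k_{12} = 0.0099\,s^{-1}$) and is translated into AprE
($k_7$), which decays at $k_4$; DegU is supplied constitutively
($k_{13}$, plus translation of mDegU via $k_1$) and DegU~P degrades at
$k_3 = 0.15\,s^{-1}$.  Units are carried as metadata only.  The roles were
assigned so that each spot-checked parameter has a distinct observable
signature under the unweighted objective: $k_{10}$ through the sub-second
DegU/DegU~P equilibration ratio and rate, $k_3$ through both the level and
the $\sim$40 s relaxation of the phospho-pool, and $k_{12}$ through the
slow mAprE transient.  Because the kinetics genuinely span four decades of
timescale (0.04 s equilibration to a 100 s mRNA transient), a uniform
100-point grid cannot inform both ends; the default grid is therefore
two-phase — $t = 0$, 29 log-spaced points in $[0.02, 2]$ s, then 70
uniform points to 400 s — the sampling an identifiability-aware
experimental design would choose.  Initial state: a bolus of
unphosphorylated DegU, $(0, 1, 0, 0, 0, 0)$.

A local-least-squares oracle (bounded quasi-Newton from random in-box
starts) recovers all target parameters from 15%-noise data with median
errors of a few percent on all three systems, confirming the designs are
practically identifiable before any metaheuristic enters the picture.

## Synthetic data

`make_benchmark()` reproduces any study condition in one call: simulate
the model at the true parameters, add $x$% white Gaussian noise —
*relative* by default, $\tilde y = y (1 + \frac{x}{100} z)$ with $z$ iid
standard normal, the natural reading of "percent noise" and the scheme
under which every state is measured equally well in relative terms; an
*absolute* per-state scheme ($\frac{x}{100}$ of the state's signal sd) is
available — optionally mask out an exact fraction of the observed entries
(keeping at least one observation per state), and record the per-state
variance of the actually injected noise sample, computed with the same
estimator the identifiability test uses.  The study noise levels are 5, 10
and 15%; missingness defaults to 0, and the "incomplete data" scenarios in
the test suite use a masked fraction of 0.2 as a repository convention.

What the generator does *not* emulate: correlated or heteroscedastic
measurement error beyond the relative scheme, systematic (bias) error,
irregular sampling jitter, and model misspecification other than the
deliberate ablations.  Passing tests therefore demonstrate correct
behaviour under the stated noise model, not robustness to every failure
mode of real data.

## Practical identifiability and model selection

If the fitted model is right and the fit is good, the residuals
$e_{ns} = \tilde y_{ns} - y_{ns}(\hat\theta)$ should look like the
measurement noise.  For each observed state the package computes the
unbiased sample variance of the residuals (mean-centred by default;
zero-centred available) and the two-sided chi-square confidence interval

$$\left[\frac{(N-1)\hat s^2}{\chi^2_{(1+\gamma)/2,\,N-1}},\;
        \frac{(N-1)\hat s^2}{\chi^2_{(1-\gamma)/2,\,N-1}}\right]$$

at confidence $100\gamma$% (default $\gamma = 0.95$, i.e. significance
0.05).  If the reference ("real") noise variance falls outside the
interval for any state, the estimated parameters could not plausibly have
generated the data, and the per-state verdicts are AND-ed into a single
Pass/Fail.  For synthetic data the reference is the variance of the
actually injected noise sample; against that sample-based reference a
truth fit passes with probability close to 1 (the two estimators coincide),
while against the theoretical noise variance the pass rate equals the
nominal coverage — the suite checks both behaviours, plus the 95% ± 1.5%
coverage of the interval itself over 2000 Gaussian trials.  The chi-square
calibration assumes iid Gaussian residuals per state; under the relative
noise scheme residuals are heteroscedastic within a state, which in
practice shifts coverage only mildly but is the reason the coverage
simulations use homoscedastic noise.

Model selection refits every candidate structure on the *same* dataset and
compares $\mathrm{AIC} = N \ln(\mathrm{MSE}) + 2D$ (with $N$ the number of
observed entries and $D$ the number of estimated parameters; perfect fits
are floored at machine epsilon; constant-offset AIC variants shift all
candidates equally, so the verdict is convention-independent), alongside
the variance test.  The ablated variants used in the suite zero three
parameters each — the oscillator loses its first switch threshold, Hill
coefficient and production rate; the protease network loses its three
synthesis inputs — leaving model structures that cannot reproduce the data
at any admissible parameter values, which is what the selection machinery
is supposed to detect.

## Numerical choices

* Integration: `deSolve::ode` (lsoda) with `rtol = 1e-6`, `atol = 1e-8`;
  solutions are reported exactly on the requested grid, and halving the
  tolerances changes sampled states by less than $10^{-5}$ relative
  (asserted in the suite).  Slightly negative solver excursions are
  clamped to zero inside Hill/power terms before exponentiation.
* Out-of-bounds repair is clamping to the violated bound — simple and
  reproducible.
* Sorting ties (equal fitness) preserve insertion order (stable sort).
* All randomness flows from R's RNG seeded once per run; identical
  `(method, data, control, seed)` reproduce results bit for bit, including
  the evaluation count.
* The divergence guard for discrete maps errors with the offending step
  index at $|x| > 10^8$ or non-finite values.

## Problem sizes in the shipped tests

The test suite and the acceptance script reproduce the study conditions at
the replicate counts a desk machine handles comfortably: 20 seeded
replicates for the map and oscillator recoveries and the comparative
ordering, 10 for the protease recovery, 20 repetitions per model-selection
scenario (refits at a reduced 20-solution / 60-iteration budget, which the
feasibility study showed separates the candidate structures as cleanly as
the full budget), and 2000 trials for the coverage simulation.  The
benchmark harness (`dynfit benchmark`) defaults to 20 replicates per grid
cell; the full 100-replicate grid is a flag away.

## Known limitations

* Structural identifiability is out of scope; the variance test detects
  practical non-identifiability against a given dataset only.
* The unweighted objective lets large-magnitude states dominate; weights
  exist as an option but the shipped studies follow the unweighted
  formulation.
* The canonical CRO baseline's precision is kernel-limited (see above).
* AIC here is the least-squares form without small-sample correction;
  with $N$ in the hundreds the difference is immaterial for the verdicts
  the package draws.
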