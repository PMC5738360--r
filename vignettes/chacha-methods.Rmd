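---
title: "Models and methods behind the chacha package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the chacha package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chacha)
```

## The system being modelled

The ChaCha architecture couples a G-protein-coupled receptor to CRISPR
transcriptional control. The receptor carries TEV protease on its
cytoplasmic tail; ligand binding recruits a beta-arrestin-2 adaptor fused
to dCas9-VPR through a TEV cleavage sequence, and cleavage releases free
dCas9-VPR that activates a reporter gene. Because the protease remains
receptor-bound, a single active receptor can in principle process several
adaptor molecules — the stoichiometry exponent $n$ quantifies this.

Two deterministic mass-action models are implemented.

### The five-species ChaCha rate model

States: inactive receptor $R$, active receptor $R^*$, adaptor fusion $A$,
released effector $C$, reporter $G$, with ligand input $L$:

$$
\begin{aligned}
\dot R &= \alpha_R - \alpha_{R^*} R L - \beta_R R \\
\dot R^* &= \alpha_{R^*} R L - \beta_{R^*} R^* - \gamma_C R^* A^{n} \\
\dot A &= \alpha_A - \beta_A A - \gamma_C R^* A^{n} \\
\dot C &= \gamma_C R^* A^{n} - (\gamma_G + \beta_C)\, C \\
\dot G &= \gamma_G C - \beta_G G
\end{aligned}
$$

At steady state the system collapses to
$G = G_{\max} \frac{L}{L + K_L} \frac{A^{n}}{K_A + A^{n}}$ with
$G_{\max} = \frac{\gamma_G}{\beta_G}\frac{\alpha_R}{\gamma_G + \beta_C}$,
$K_L = \beta_R/\alpha_{R^*}$, $K_A = \beta_{R^*}/\gamma_C$. The surface
is zero at $L = 0$ or $A = 0$, monotone nondecreasing in both arguments,
and linear in $G_{\max}$; these are tested as properties.

Model assumptions worth stating: a two-state receptor (no
internalization or recycling pool), well-mixed deterministic kinetics (no
spatial structure, no stochastic chemical kinetics), no cell division or
dilution, and no basal ligand-free production of $C$ or $G$. The last
assumption forces $G = 0$ at $L = 0$ even though real reporter lines are
somewhat leaky; an optional additive baseline exists in the fitting layer
only (`basal = TRUE`), never in the core equations, so the closed form
stays exactly the derived surface by default.

The exponent $n$ enters as the order of the cleavage term $A^n$ and is
read as effector molecules processed per active receptor. "Recruited
per receptor" and "released per receptor" are treated as the same
number — the model has a single cleavage event per recruitment and
cannot distinguish them. $n$ is allowed non-integer and $A^n$ is
evaluated with real powers, since the fitted value is an effective
reaction order, not a molecule count.

### The dox-induction model

Adaptor/effector expression is doxycycline-titrated:
$\dot C = \alpha_1 \frac{D^{n}}{K_D + D^{n}} - \beta_1 C$,
$\dot G = \alpha_2 C^{m} - \beta_2 G$, giving the steady state
$G = \kappa_1 \kappa_2 \frac{D^{n}}{K_D + D^{n}}$ when $m = 1$, with
$\kappa_i = \alpha_i/\beta_i$. Two deliberate readings of the printed
form are kept:

* $K_D$ is used exactly as written, $D^n/(K_D + D^n)$ — it carries the
  units of $D^n$, and is *not* interpreted as $K_D^n$. A consequence,
  covered by a test, is that rescaling all dox levels by a factor $c$
  maps $K_D \mapsto c^n K_D$ while leaving the fitted cooperativity
  unchanged.
* The reporter arm is written with a general exponent $m$ but the
  steady-state reduction drops it; the two statements only agree at
  $m = 1$. The constructor therefore defaults to $m = 1$ (consistent
  with the non-cooperativity of dCas9-VPR activation, which the fitting
  module checks by simulation) while retaining general $m$ as an option
  in both the algebra and the ODE right-hand side.

## Numerical choices

**Units.** Time in hours, concentrations in arbitrary units (ligand
doses in nM where titrations mirror typical experiments). The model is
scale-free, so units are documented rather than enforced.

**Coupled steady state.** The fixed point is reduced to one scalar
equation in $A_{ss}$ by substituting the closed forms for $R_{ss}$ and
$R^*_{ss}$ into the adaptor balance. Cleavage can only pull the adaptor
below its no-ligand level $\alpha_A/\beta_A$, and the balance is strictly
positive as $A \to 0^+$, so the root is bracketed on
$(0, \alpha_A/\beta_A]$ and found with `uniroot` at machine-level
tolerance — guaranteed bracketing was preferred to multi-dimensional
root finding. Solutions are accepted only if all five scaled residuals
are below $10^{-10}$ (tests demand $10^{-8}$); otherwise the solver
fails loudly with the residuals in the message.

**ODE integration.** `deSolve::ode` with `lsoda`, which switches to a
stiff method automatically — degradation constants may span decades.
Default tolerances are `rtol = 1e-6`, `atol = 1e-9`; a convergence test
checks that halving them moves trajectories by less than the coarser
tolerance. Piecewise-constant inputs are handled by restarting the
integrator at every schedule breakpoint, so input steps are exact rather
than smoothed, and pulse experiments need no step-size heroics.
Values within ten absolute tolerances below zero are clipped to zero.
The default initial condition for ligand simulations is the ligand-free
coupled steady state, matching protocols that pre-induce the adaptor for
days before ligand addition; `init = "zero"` gives naive cells.

**Fitting.** All fits minimize unweighted squared error on linear
response values (the regression is deliberately plain — no weighting, no
errors-in-variables correction). Positivity is structural, so the
optimizer works in log-parameter space with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`); $n$ is additionally bounded to $[0.1, 10]$, a
generous band around plausible stoichiometries. Starts form a
deterministic log-grid — each free parameter at its moment-based guess
and $\pm 2$ decades ($3^k$ starts; guesses: plateau $\approx$ max
response, half-point dose nearest the response mid-range, unit
stoichiometry) — and the best final loss wins, so fits are reproducible
without a seed. Standard errors come from the Gauss–Newton curvature at
the optimum, mapped to the natural scale by the delta method; the
goodness-of-fit `r` is the Pearson correlation of fitted versus observed
values (a plain-regression $R$-type statistic would be an equally
defensible reading; Pearson is used and documented). The surface fit
uses the noisy `adaptor_readout` covariate by default, mirroring an
mCherry-measured rather than known adaptor level; `adaptor = "true"`
switches to the design value for oracle tests.

**Dose–response form.** The four-parameter logistic in log-dose
(bottom, top, EC50, Hill slope) was chosen over the two- or
three-parameter Hill forms because real reporter data have a nonzero
baseline (leakiness) and the quantity of interest, EC50, should not be
distorted by forcing the baseline through zero.

**ΔΔCt.** Detected Ct values above 35 cycles, and undetected wells
(no Ct within 50 cycles), are clamped to exactly 35 before any
arithmetic; clamping is idempotent and clamped replicates are counted in
the output. Technical replicates are averaged *in Ct space* within each
sample–gene condition before the ΔΔCt formula; averaging in expression
space would weight high-expression outliers more heavily, and the
Ct-space mean is the field convention. Relative expression is
$2^{-\Delta\Delta C_t}$ against a housekeeping gene and a reference
condition, and fold changes are ratios of relative expressions.

## What the synthetic data emulate — and what they do not

The generators stand in for well-level summaries of flow-cytometry /
plate-reader experiments:

* `generate_grid_dataset`: adaptor levels crossed with ligand doses,
  expected GFP from the steady-state surface, noise per well. Defaults —
  6 log-spaced adaptor levels (0.1–10 AU), 8 log-spaced doses
  (1–10,000 nM), 3 technical replicates — mirror a realistic titration
  plate, and the frozen truth (`inst/extdata/demo_config.json`) places
  $K_L$ at 105 nM and the half-maximal adaptor level mid-grid so both
  saturation arms are sampled.
* `generate_dose_response`: single-variable titrations from the
  four-parameter logistic.
* `generate_qpcr_plate`: Ct tables with one cycle per two-fold
  expression change, Gaussian Ct noise, and explicit undetected wells
  below a dropout threshold.

The default noise law is multiplicative lognormal with CV 0.10,
normalized to mean one so the expected readout equals the model
prediction: fluorescence intensities are positive with roughly
scale-proportional spread, and no replicate noise magnitude is dictated
by the experimental design itself, so 0.10 is the package's documented
choice of a realistic technical CV. Every generator draws from a private
RNG stream seeded by its `noise_model`, restoring the caller's RNG
state, so tables are bit-reproducible and independent of call order.

Not emulated: per-cell cytometry events, gating, spectral compensation,
autofluorescence background, day effects between biological replicates,
and errors-in-variables structure beyond the noisy adaptor readout.
Passing recovery tests therefore shows the estimator is consistent and
nearly unbiased *under this noise law at this design scale*; it does not
certify behaviour under gating artifacts or heavier-tailed instrument
noise.

## Study conditions used by the tests and the acceptance script

Recovery checks run 20 seeded replicates per scenario: the stoichiometry
grid (truth $n = 2.33$, 144 wells each), the wide EC50 titration (truth
105 nM, doses 1–10,000 nM) and the narrow one (truth 13 nM, doses
0.1–1,000 nM), each at CV 0.10 with 3 replicates, reporting the median
fitted parameter. Property suites use 50 random rate-constant draws
spanning 0.1–10 per hour with $n \in \{0.5, 1, 2, 2.33, 3\}$, and
closed-form/ODE agreement is demanded at $10^{-4}$ relative after
integrating 40 time constants of the slowest mode. These sizes keep the
whole suite in the tens of seconds while leaving the medians' sampling
error well inside the tolerance bands.

The reversibility demonstration uses `chacha_demo_params()`: receptor
and adaptor turnover near 1/h, but slow effector and reporter rates
($\beta_C = 0.04$, $\gamma_G = 0.02$, $\beta_G = 0.05$ per hour). The
separation of time scales is what produces the signature behaviour — the
reporter keeps rising after a one-day ligand pulse ends (existing free
effector still drives it) and then relaxes to baseline over several
days:

```{r pulse, fig.width = 6, fig.height = 4}
tr <- simulate_chacha(chacha_demo_params(),
                      schedule(c(0, 24), c(10, 0)), c(0, 240))
plot(tr, symbols = c("C", "G"))
abline(v = 24, lty = 2)
```

## Known limitations

* No rate-constant values exist for the full five-species model (only
  lumped fitted quantities are identifiable from steady-state data), so
  dynamic scenarios use the documented demo set and are validated
  qualitatively.
* Standard errors are curvature-based; for strongly correlated
  parameters (e.g. $K_A$ and $n$ on a narrow adaptor range) they
  understate uncertainty. No bootstrap or Bayesian machinery is
  provided.
* The fit treats the noisy adaptor readout as an ordinary covariate;
  with large covariate noise this attenuates/distorts $n$ slightly, and
  the recovery tests quantify the net effect at CV 0.10 rather than
  correcting it.
* ΔΔCt assumes perfect doubling efficiency; no Pfaffl correction or
  standard curves.
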