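---
title: "Modelling cMyBP-C multisite phosphorylation with phoscycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cMyBP-C multisite phosphorylation with phoscycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoscycle)
```

## The biological system and the state scheme

Cardiac myosin-binding protein-C (cMyBP-C) regulates heart muscle
contractility through phosphorylation of several serines in its
cardiac-specific m-motif.  Four sites matter here, written with the greek
shorthand that orders them by the strictly sequential protein kinase A
(PKA) mechanism: alpha (rat pS288), beta (pS279) and gamma (pS313) are
added by PKA in that order, while delta (pS308) is an independently
regulated site phosphorylated by PKC-epsilon (and in vivo also PKD).
RSK2 phosphorylates alpha only.  Both protein phosphatase 1 (PP1) and
protein phosphatase 2A (PP2A) dephosphorylate all sites, essentially in
the reverse of the PKA order -- gamma before beta before alpha -- with
delta removable at any point.

Because of the sequential hierarchy only eight of the sixteen conceivable
site combinations occur:

```{r}
phos_network("M1")
```

The structural-transition variant adds a ninth, purely kinetic state
`aprime`: removal of beta from `ab` or of delta from `ad` can leave the
mono-alpha-phosphorylated m-motif in a transiently ordered conformation
that remains an excellent phosphatase substrate before it relaxes into
the disordered `a` state, whose alpha site is dephosphorylated only
slowly.  This is the model's explanation for the abrupt slow-down of
1P dephosphorylation once the 2P pool is exhausted.

```{r}
phos_network("M4")
```

## Rate laws

All enzymatic steps use Michaelis-Menten kinetics with substrate
competition: every phospho-form an enzyme can act on competes for the
same active site, so reaction $i$ of enzyme $E$ proceeds at

$$v_i \;=\; \frac{k_{\mathrm{cat},i}\, e\, s_i}
{K_i\!\left(1 + \kappa_E - s_i/K_i\right) + s_i},
\qquad
\kappa_E = \sum_j \frac{s_j}{K_j},$$

the sum running over the enzyme's substrates.  Algebraically this equals
$k_{\mathrm{cat},i}\, e\, (s_i/K_i)/(1+\kappa_E)$, the rapid-equilibrium
partitioning of the enzyme among competing substrates; the test suite
checks both forms against an independent enzyme-conservation oracle.
When one chemical species can be attacked at two sites (e.g. `abgd` at
gamma or delta), each reaction contributes its own $s/K$ term to
$\kappa_E$, treating the two binding modes as distinct complexes.

Four model variants share this backbone:

* **M1** -- competitive Michaelis-Menten only.
* **M2 (phenomenological)** -- the alpha-removal rate of each phosphatase
  is multiplied by $1 + f_{\mathrm{act}}\, r_{23}/(K_{\mathrm{act}} +
  r_{23})$, where $r_{23}$ is the fraction of substrate in 2P and 3P
  forms (`ab`, `ad`, `abg`, `abd`; the 4P form is excluded because the
  experimental observation concerns bis- and tris-phosphorylated
  species).
* **M3 (allosteric activation)** -- the alpha-removal step follows a
  rapid-equilibrium rate law in which the 2P pool $A = [ab] + [ad]$ acts
  as an allosteric activator with activated turnover $k_A$, dissociation
  constant $K_A$ and a preference factor $\lambda$ for the activated
  complex.  The competitive term of the other substrates enters as
  $K_j \sum_{i \ne j} s_i/K_i$; the complex concentrations of the printed
  steady-state derivation reduce to these $s/K$ ratios under the same
  rapid-equilibrium substitution used to derive the law, which is the
  reading implemented here.
* **M4 (structural transition)** -- the `aprime` state with its own
  (fast) phosphatase kinetics; first-order isomerization
  $v = k_{\mathrm{iso,F}}[\mathrm{a'}]$ and
  $k_{\mathrm{iso,R}}[\mathrm{a}]$.  Kinases act on `aprime` with the
  same constants as on `a` (the conformer is chemically
  mono-alpha-phosphorylated; treating it otherwise would introduce a
  kinetic trap the data give no reason for).

For regimes where enzyme and substrate concentrations are comparable the
package offers the total quasi-steady-state (tQSSA) rate mode,

$$v_j = \frac{k_j\, e_T\, s_j}{(K_j + e_T)\left(1 + \sum_i
\dfrac{s_i}{K_i + e_T}\right)},$$

which converges to the competitive law as $e_T \to 0$ and is bounded by
$k_j e_T$.

## Numerical methods

The ODE systems are integrated either with a fixed-step classical
Runge-Kutta scheme (`integrate_rk4()`, default step 1 s, automatic
restarts at 0.1 s and 0.01 s if a state dips below $-10^{-9}$ of the
total or becomes non-finite) or adaptively with LSODA
(`integrate_adaptive()`, default `rtol` 1e-8, `atol` $10^{-12}$ of the
substrate total).  Mass conservation is structural -- the stoichiometry
matrix columns sum to zero -- and is asserted to $10^{-9}$ relative over
hour-long trajectories.

`steady_state()` integrates in staged windows (quarter-horizon segments
first, then doubling windows up to 64 times the 3600 s horizon) and
declares convergence when $\max_i |\dot y_i|/\sum_i y_i$ falls below
`tol` (default $10^{-9}\,\mathrm{s}^{-1}$).  This is an operational
criterion, not a uniqueness proof; since multistability is possible in
kinase-phosphatase networks the test suite includes a two-start check
(all-0P versus all-4P initial conditions).  Negative solver drift is
clamped to zero inside the right-hand side and tolerated up to
$10^{-9}$ of the total by the observation operators.

## The ground-truth preset

`phos_preset()` returns the package's reference kinetics (mol/L and
seconds throughout).  Exact kinetic constants for this system are not
portable between preparations, so the preset encodes the robust
qualitative findings instead, chosen once during design:

* strictly sequential PKA phosphorylation (alpha, then beta, then gamma);
* alpha is a poor phosphatase substrate: for both phosphatases its Km is
  four-fold that of delta with a much lower kcat;
* the ordered conformer is a far better phosphatase substrate than `a`
  (specificity constant more than twenty-fold higher);
* for PP1 the specificity ratio of the `ab`/`abg` cycle exceeds that of
  the `abd`/`abgd` cycle (gamma removal is faster on the delta-bearing
  substrate), whereas for PP2A the two ratios are equal -- the delta site
  impairs net gamma phosphorylation only in the presence of PP1;
* PP1 removes delta much faster than PP2A, so clamping the whole
  phosphatase pool to PP1 makes delta-bearing states unattainable while
  a free PP1/PP2A split leaves them reachable;
* kinase specificity constants sit roughly an order of magnitude above
  phosphatase ones, so nanomolar kinases balance micromolar phosphatase
  pools (the physiological enzyme-concentration boxes assume exactly
  this), while phosphatase constants keep 0.1 umol/L dephosphorylation
  of 20 umol/L substrate on its tens-of-minutes timescale;
* the beta- and gamma-cycle balance points lie close together, so the
  lumped 3P+4P response to PKA is switch-like with a Hill coefficient
  near two, steeper for PP1 than for PP2A; substrate sits near the
  kinase Km, so the steepness comes from the sequential mechanism rather
  than zero-order saturation (the Hill exponent must not grow as
  phosphatase concentration falls).

Every quantitative downstream test is a recovery or property test
against this preset truth.

## What the synthetic generator does and does not emulate

`gen_dephos_timecourse()`, `gen_initial_rate_dataset()`,
`gen_dose_response_dataset()` and `gen_distribution_dataset()` reproduce
the designs of the underlying in vitro experiments: 20 umol/L substrate
(a 50/50 `abd`/`abgd` mixture for the reference time course) with
0.1 umol/L phosphatase sampled over 60 min; initial-rate assays quenched
early (the generator records a warning if the quench consumes more than
15% of the largest substrate concentration); 60-min steady-state
dose-responses; and steady-state 0P-4P distributions from a known enzyme
vector.  Noise is additive Gaussian on the fraction scale (default SD
0.03, three replicates), truncated to $[0,1]$ and renormalized per time
point, because PhosTag quantification divides each band by its lane
total.  Initial-rate data receive multiplicative noise of the same
relative magnitude.

The generator does **not** emulate gel-image artifacts (the faint band
between 2P and 3P is ignored, as in the quantification it mimics),
enzyme activity loss over the incubation, or the mutual interference of
the ATP and MnCl2 cofactors that shifts real kinase/phosphatase mixtures
relative to single-enzyme assays.  Tests passing against synthetic data
therefore certify the estimation machinery, not the transferability of
any particular rate constant to tissue.

## Calibration

`phos_fit()` estimates kinetic constants by repeated global+local
search: a real-coded genetic algorithm (tournament selection $k=2$,
uniform crossover with per-gene probability 0.5, per-gene Gaussian
mutation of 0.1 decade with probability 0.2, elitism 1; population 25,
250 generations at full scale) followed by Hooke-Jeeves pattern search
(iteration limit 50, tolerance $10^{-5}$, contraction 0.2).  All rate
constants are searched on the log10 scale because they are identifiable
only over orders of magnitude; an additional evaluation cap
(`hj_max_evals`) bounds the pattern search's runtime without changing
its path.  The objective is
$\sum_e w_e\, \mathrm{SSE}_e / N_e$ with per-point weights $1/\sigma^2$
-- the per-experiment normalization divides by the residual count, and
replicate SDs are floored at 0.01 on the fraction scale so that
noiseless fixtures do not produce degenerate weights.  Failed
simulations score a large finite penalty ($10^{12}$) so stochastic
searches remain total functions.

Two design choices deserve emphasis:

* **Two-stage fitting.**  The mono-site constants (alpha and delta
  removal) are pinned first by Michaelis-Menten fits to the dedicated
  initial-rate assays (`pin_monosite_params()`), exactly as such assays
  are used experimentally; only the constants the time courses actually
  constrain (gamma removal on both strata, beta removal, the conformer
  kinetics and the isomerization rates) enter the stochastic search.
  This mirrors the layered experimental design and keeps the search
  space small enough for reliable recovery.
* **Ensembles, not point estimates.**  Individual kcat and Km values are
  poorly identifiable (their ensemble coefficients of variation are
  large), whereas specificity constants kcat/Km are much tighter; all
  predictions are therefore made over the ensemble and reported as
  medians.  `filter_ensemble()` flags members whose simulations deviate
  from the Akima interpolant of the data by more than
  mean + 0.5 SD across members for any experiment (linear interpolation
  substitutes below five points and in the end segments where the Akima
  scheme is undefined; with zero spread nothing is flagged).  Flagged
  members are annotated, never deleted.

## Model selection

`aic_score()` uses the least-squares form
$\mathrm{AIC} = n \ln(\mathrm{SSE}/n) + 2k$ and reports the small-sample
corrected AICc alongside (flagged undefined when $n \le k+1$).  The
parameter count $k$ is the number of constants actually searched, not
the nominal size of the parameter set.  `compare_variants()` computes
AIC per ensemble member per variant, runs all pairwise two-sided
Mann-Whitney tests plus a one-way ANOVA on log2-normalized AICs, adjusts
the pairwise p-values with the Benjamini-Hochberg step-up procedure at
FDR 0.05, and declares a variant superior only at a significantly lower
AIC.  On data generated under the structural-transition truth, the plain
competitive-MM variant cannot reproduce the biphasic accumulation of
dephosphorylated protein in the 2P time course, which is what the AIC
comparison detects.

## Dose-response analysis

`dose_response()` titrates one enzyme over a log grid (at least 20
points across three or more decades in the standard analyses), computes
the steady state per grid point and ensemble member, and projects onto
PhosTag bands, the delta-lumped groups (`0P+d`, `a+ad`, `ab+abd`,
`abg+abgd`) or raw state fractions.  `hill_fit()` fits
$y = y_{\min} + (y_{\max}-y_{\min})\,x^{n}/( \mathrm{EC}_{50}^{n} +
x^{n})$ with free baseline and plateau -- simulated plateaus fall short
of 1, so clamping them would bias the exponent -- using a deterministic
multi-start over $n \in \{0.5, 1, 2, 4\}$.  "About two" comparisons for
the Hill coefficient are implemented as ensemble medians with a +/-25%
band, stated openly in the tests.  `switch_metrics()` defines the
transition midpoint as the concentration where the response reaches half
its fitted plateau, evaluates the response at twice that concentration,
and reports the 10%-90% transition width in decades.  Hill fits are
applied to raw (not renormalized) fractions.

## Enzyme-level inference

`fit_enzyme_levels()` and `maximize_state()` search enzyme
concentrations inside physiologically motivated boxes
(`condition_preset()`): PKA 5e-10 to 5e-7, PKC-epsilon and RSK2 0 to
2e-7, PP1 1e-10 to 1e-6 and total phosphatase 1e-10 to 1e-6 mol/L for
donor-heart fitting; the heart-failure fit fixes the phosphatase total
at twice the donor value; the maximally-achievable-fraction (MAF)
analyses use PKA up to 1.36e-6 (donor) or 2.89e-7 (heart failure) with
the phosphatase total fixed at 1e-6 or 2e-6 mol/L, optionally
restricting PKC-epsilon/RSK2 to 1.5e-7 and clamping the pool to pure
PP1 or pure PP2A.  The pool is parameterized as (total, PP1 share) with
PP2A the difference, so the split can vary freely or be clamped exactly.
Concentrations are searched on the log10 scale with zero lower bounds
floored at 1e-12 mol/L (far below any kinetic effect); the share is
searched linearly on $[0,1]$.  The loss for distribution fitting is the
plain SSE on the five band fractions.  Each search is a multi-start
Hooke-Jeeves run (8 starts for MAF optimization, guarding the
non-convex objective).  `run_with_tqssa()` repeats any of these analyses
under the tQSSA rate mode at a lowered substrate total.

The package ships no tissue data: distribution targets are synthetic
stand-ins generated by `gen_distribution_dataset()` from a known enzyme
vector (and any user-supplied 5-vector is accepted), so enzyme-recovery
claims are tested against known truth.

## Problem sizes used by the shipped tests and script

The full-scale search settings (250 generations, 50-100 runs) are
impractical for routine checking; the package's own test suite and the
reproduction script use a scaled design chosen once: 50 GA generations,
8-10 ensemble runs, Hooke-Jeeves capped at 2000-2500 evaluations, and
25-point dose-response grids over four decades.  Recovery quality at
this scale is itself part of the test suite (well-excited specificity
constants within 20%; "well-excited" is decided by integrated reaction
flux along the truth trajectories, threshold 10% of the substrate
total).  The model-selection check runs ten seeded repetitions with
five-member ensembles per variant on the discriminating 2P
dephosphorylation experiment.

## Known limitations

* The steady-state claim is residual-based; true bistability would
  appear only as a two-start discrepancy.
* The allosteric variant's competitive term follows the package's
  reading of the rapid-equilibrium reduction (recorded above), and the
  tQSSA mode pairs the M2 correction multiplicatively but omits the M3
  allosteric law (the final structural-transition model is the one used
  with tQSSA).
* Upstream signalling (CaMKII, PKD, GSK3, inhibitor-1, phosphatase
  subunit targeting) is out of scope; enzyme concentrations are free
  inputs, not outputs of a signalling model.
* Parameter values are package defaults encoding qualitative
  constraints, not measurements; conclusions about real tissue require
  recalibration against real data.
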