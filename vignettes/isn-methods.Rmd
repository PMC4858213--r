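---
title: "Methods: the steady-state insulin signalling network and the linked cell-population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the steady-state ISN and cell-population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isnet)
```

This vignette documents the models implemented in `isnet`, the assumptions
behind them, the numerical choices, what the synthetic-data generators do
and do not emulate, and the design decisions taken where the design was
genuinely open.

## 1. The normalized steady-state network

The model describes the insulin signalling cascade at steady state, i.e.
the dose-response behaviour at a constant extracellular insulin level
`Ie`, not the transient after an insulin step.  Every protein level is
normalized to its synthesis-over-degradation ratio, so each state variable
is a dimensionless occupancy in $[0,1]$.  The underlying kinetic
assumptions are the classical ones for Michaelis–Menten networks: the
degradation of enzyme–substrate complexes is negligible against
dissociation plus catalysis; synthesis and degradation rate constants do
not change over the time horizon of a dose-response experiment;
subcellular localization and trafficking are lumped (see §5 for when this
is adequate); phosphatase levels are constant.

**Receptor layer.**  Free insulin $I$ follows from total insulin by a
binding quadratic; the positive root is the only nonnegative one and is
the one taken.  Phosphorylated receptor is
$IR^Y_n = (a_b + I)/(a_b + a_0 + I)$ with basal fraction
$\rho = a_b/(a_b+a_0)$ at zero insulin.  Instead of $(a_0, a_1)$ the user
supplies the half-response insulin `Ie_half` (nM) and the slope `S_half`
(1/nM) of the receptor curve at that point; the internal constants are
recovered by

$$a_0 = \Big(\tfrac{1}{2S_{0.5}} - \tfrac{I_{e,0.5}}{1-2\rho}\Big)
        \tfrac{1-\rho}{1-2\rho},\qquad
  a_1 = \Big(\tfrac{4I_{e,0.5}(1-\rho)}{1-2\rho} - \tfrac{1}{S_{0.5}}\Big)
        \tfrac{1-\rho}{1-2\rho}.$$

Both brackets must be positive, which confines `S_half` to
$\big((1-2\rho)/(4I_{e,0.5}(1-\rho)),\,(1-2\rho)/(2I_{e,0.5})\big)$.  The
forward map $I_{e,0.5} = (a_0+a_1/2)(1-2\rho)/(1-\rho)$,
$S_{0.5} = (1-\rho)/(a_1+4a_0(1-\rho))$ is the exact algebraic inverse;
we verified the identity symbolically and the test suite re-verifies it
against a root-finding oracle on the receptor curve.

**Feedback structure.**  Three loops close the network: S6K1 serine
phosphorylation of IRS1 (strength `a4`), S6K1 inhibition of mTORC2 through
Rictor (`a12`), and an optional positive feedback of doubly phosphorylated
Akt on PTP1B (`aP`, off by default in the myoblast configuration because
receptor phosphorylation is insensitive to PTEN silencing there).

**Akt block.**  Thr308 (PDK1) and Ser473 (mTORC2) phosphorylation are
independent, so partially phosphorylated forms $Akt^T$, $Akt^S$ and the
doubly phosphorylated $Akt^{T,S}$ coexist; the three rational forms share
one denominator.  A near-cancelling combination of constants in that
denominator equals $a_{17\delta}a_{19\varepsilon}\,\mu$ with
$\mu \ll 1$ (the ratio of phospho-Akt degradation to dephosphorylation);
the package stores $\mu$ directly (`mu_ratio`, bounded at 0.01).  The
positivity constraints `a17d > a17g*a_eta_d`, `a19e > a19g*a_theta_e` are
enforced at construction; a property test over $10^4$ random draws
confirms each form stays in $[0,1]$ and the sum never exceeds one.  This
independence is essential: a hierarchical scheme in which Ser473 requires
prior Thr308 phosphorylation cannot produce a high basal pAkt(Ser473)
with a blunted insulin response, which is exactly the insulin-resistant
phenotype (§3).

**Substrate layer.**  Cytoplasmic FoxO1 is driven by the
Ser473-containing forms, GSK3β and mTORC1/GLUT4/AS160 by the
Thr308-containing forms.  GLUT4 at the plasma membrane is
$(a_{28}+a_{29}x)/(1+a_{30}x)$ with $a_{28}<1$ and $a_{29}<a_{30}$, which
caps it below one.  S6K1 requires both mTORC1 (Thr389) and PDK1 (Thr229).
2-deoxyglucose uptake is modelled as proportional to surface GLUT4; the
proportionality constant cancels under the renormalization convention
(§3), which is why `uptake2DG` simply maps to `GLUT4n` there.

## 2. Solving the fixed point

Given $(PDK1_n, mTORC2_n)$ the whole state follows algebraically, and the
upstream layers return an updated pair, so a steady state is a fixed point
of a 2-D map on the unit square.  `isn_steady_state()` uses damped
iteration $x \leftarrow x + 0.5\,(F(x)-x)$, tolerance $10^{-12}$ on the
residual, at most $10^4$ iterations, vectorized over the insulin grid.
Damping 0.5 was chosen because the undamped map can overshoot when the
feedback gain is large; with damping the iteration converged for every
parameter set we ever drew.  If a point fails, the solver falls back to
`isn_grid_solve()` — minimization of the squared residual over a
$401\times401$ grid with eight rounds of $41\times41$ local zoom — and
errors only if even the fallback residual exceeds $10^{-8}$.  The grid
solver is deliberately independent of the iteration path; the acceptance
suite compares the two on random parameter sets to $<10^{-6}$ per
component.  When all three feedback strengths are zero the fixed point
equals a single forward sweep, a limit the tests check to $10^{-12}$.

Degenerate inputs are valid by construction: `Ie = 0`, `J = 0` and
`PIP3 = 0` propagate exact zeros; denominators can vanish only at
parameter values excluded by validation (the one guarded division is the
PIP3 layer when `a7 + a8*PTEN_n + PI3Kn = 0`, returned as zero).

## 3. Conditions, fitting and renormalization

Experimental conditions are parameter/environment modifiers
(`apply_condition()`): PTEN silencing sets $PTEN_n$ from 1 to 0.1;
rapamycin scales the mTORC1 constant `a24` by 0.1; the dual-site inhibitor
preset scales `a10`, `a11`, `a24` by 0.15; the PDK1 inhibitor preset
scales `a9` by 0.1.  The insulin-resistant conditioned-medium preset sets
the mTORC2-activating factor to `J = 0.07` (against 0.001 in control),
activates GSK3β sequestration (`W = 1`, with GSK3β driven by the
Ser473-containing Akt forms in this state), halves the GLUT4
translocation constants `a28`, `a29` (the default 0.5 is a package choice
representing diminished vesicle delivery; it is an argument), and
represents a twofold increase of the IRS1 degradation rate.  Because PI3K
activation is quadratic in phospho-IRS1 — `a6` carries the square of the
IRS1 scale and `a6p` the first power — that twofold increase maps to
`a6/4` and `a6p/2`; the factor is likewise an argument.

`isn_fit()` estimates a *shared* parameter vector across conditions (the
conditions differ only through their presets), optionally with
per-condition environment unknowns such as `J@dbdb`.  The loss is an
unweighted sum of squares by default — the weighting used historically for
such fits is rarely reported — with $1/\sigma^2$ weighting available.
Since densitometry data are relative, both data and predictions are
renormalized to a unity control value at the maximal insulin
concentration; predictions are divided by that reference per analyte.
Rows can be excluded from the loss (but still predicted) through a
`used_in_fit` flag, the mechanism intended for basal inhibitor points
whose variability makes them unusable for fitting.

The optimizer is a projected compass (coordinate) search: derivative-free,
always feasible, with a provably non-increasing sequence of accepted loss
values — that monotonicity is part of the fitting contract and is tested.
Multistart perturbs each free parameter by a random factor in $[0.5, 2]$.
Identifiability caveat: with few analytes and insulin levels, parameters
are often not individually identified even at zero noise; what is
recovered (and what the tests assert) is the *curves*, to RMSE $<10^{-3}$
with 20 starts.  For the population model (§6), which adds a
Nelder–Mead polish after the compass stage because its loss surface has
strongly correlated valleys, exact data do recover the parameters
themselves to well under 1%.

## 4. Sensitivity analysis

`isn_sensitivity()` computes $\partial\log c/\partial\log p$ at a given
insulin level by central differences on a symmetric ±10% perturbation
(the perturbation fraction is an argument; whether one-sided or central
differences are used in comparable published matrices is usually
unstated, and central differences are second-order accurate, so they are
the default here).  Entries for zero concentrations are reported as
undefined (`NA` plus a flag matrix), never silently propagated.  Three
structural facts serve as built-in checks: sensitivities to `S_half`
vanish identically when evaluated at `Ie = Ie_half` (the reparameterization
pins the receptor curve there); sensitivities to `a12` scale with `a12`
and are below $10^{-5}$ for the reference sets, consistent with a
negligible role of the S6K1→mTORC2 loop; and parameters on terminal
branches (e.g. the FoxO1 constant `a21`) have exactly zero sensitivity
for every other read-out, which doubles as a wiring test.

## 5. The mTORC1 activation submodel and Akt localization

The lumped one-constant mTORC1 law is refined by an explicit
TSC2/Rheb/PRAS40 layer: Akt (Thr308-containing forms, drive $A$)
inactivates TSC2; active TSC2 keeps Rheb GDP-loaded; Rheb·GTP activates
mTORC1; PRAS40 binds and inhibits mTORC1 and is relieved by Akt
phosphorylation:

$$TSC2_n = \frac{1}{1+K_{TSC}A},\quad
  Rheb^{GTP}_n = \frac{1}{1+b_{TSC}K_{Rheb}TSC2_n},\quad
  PRAS40_n = \frac{1}{1+K_{PRAS}A},$$
$$mTORC1_n = \frac{x}{1+x},\qquad
  x = \frac{(K_{mTOR}/b_{PRAS})\,b_{Rheb}Rheb^{GTP}_n + K_{mTOR\mu}/b_{PRAS}}
           {K_{mTORC1}\,(1 + \tfrac{b_{PRAS}}{1+\varphi}PRAS40_n)}.$$

Here $1+\varphi = b_{mTORC1}/b_{PRAS}$ encodes the synthesis-rate ratio
(default $\varphi = -0.67$, i.e. PRAS40 synthesized three times faster
than the mTORC1 core), and the catalytic constants scale inversely with
PRAS40 synthesis, so PRAS40 knockdown ($b_{PRAS}\times0.1$) raises
$K_{mTOR}$ tenfold and overexpression ($\times 2$) halves it.  The
saturation constants default to $K_{TSC}=65.95$, $K_{Rheb}=6.48$,
$K_{mTORC1}=7.2\cdot10^{-3}$, $K_{PRAS}=16.72$,
$K_{mTOR\mu}=10^{-4}$; $K_{mTOR}$ (default 0.0124) is calibrated by
`calibrate_mtorc1_submodel()` so that, driven by the reference myotube Akt
profile, the submodel reproduces the lumped law.  The calibration residual
is RMSE ≈ 0.07 on the mTORC1 curve — the two laws have genuinely
different shapes at low drive — and 0.1 is the documented wiring
tolerance; the S6K1 output of the full network differs by $<0.014$
between the two forms.  `PRAS40n` is normalized to its own pool, so
knockdown changes its *abundance* (through $b_{PRAS}$ in the inhibition
term), not the reported fraction.

Perturbation presets (`simulate_perturbation()`): PRAS40
knockdown/overexpression ($b_{PRAS}\times 0.1$ / $\times 2$), Rheb
overexpression ($b_{Rheb}\times5$), TSC2 loss ($b_{TSC}=0$, which pins
$Rheb^{GTP}_n$ at exactly 1), and rapamycin — short-term scales the
catalytic constant by 0.1; long-term additionally scales the
mTORC2-synthesis-bearing Akt constants `a15e`, `a19e`, `a19g` by 0.1,
because sequestration of newly synthesized mTOR prevents mTORC2 assembly.
Display insulin defaults are 1 nM (PRAS/TSC panels) and 10 nM (rapamycin
panels).  A documented limitation: the TSC2-null simulation lowers PI3K
only mildly at the reference feedback strength `a4`; reproducing the
strongly depressed PI3K of TSC2-null fibroblasts would require a larger
`a4` than the reference value, i.e. a stronger negative feedback.

`akt_localization_equalization()` implements the steady-state adequacy
conditions under which the membrane/cytosol/nucleus Akt compartments
equalize and the lumped Akt block is justified: balanced nuclear
import/export, membrane-to-cytosol transport matching cytosolic
dephosphorylation, comparable recruitment drives for Akt and PDK1,
negligible back-transport, and transport dominating membrane
dephosphorylation.  It reports per-condition booleans with numeric
margins; it deliberately computes no state.

## 6. The cell-population model

G0/G1 cells exit to S with rate constant $\lambda_1$ or die with rate
$\mu'$; S and G2M are age-structured transit compartments of fixed
durations $T_2$, $T_3$ with the same death rate; mitosis returns two G1
cells.  Dead cells remain transiently measurable (compartments $D_{1-3}$),
fragment with rate $\mu''$ into subG1 material $A$, which clears at
$\mu_{deg}$.  In balanced growth all compartments share the rate $\alpha$
solving $\alpha+\mu'+\lambda_1 = 2\lambda_1e^{-(\alpha+\mu')(T_2+T_3)}$;
the left side increases and the right decreases in $\alpha$, so the root
(in $(-\mu', \lambda_1-\mu']$) is unique and found by bracketed
root-finding to $10^{-14}$.  Validity additionally requires
$\alpha+\mu''>0$ and $\alpha+\mu_{deg}>0$ — a declining population whose
fragments cleared more slowly than the decline would accumulate them
without bound, and no balanced composition exists.

The measurable fractions count dead-but-intact cells with their phase
(e.g. $f_{G1} = (N_1+D_1)/N_{tot}$ with $N_{tot}$ including fragments).
The closed forms for $f_{G1}, f_S, f_{G2M}$, $f_A = 1 - \sum$, the total
dead fraction, and the labeling index were derived by integrating the
balance equations along the balanced-growth age profiles.  One derivation
note: the total dead-and-fragment fraction comes out as
$\mu'(\alpha+\mu_{deg}+\mu'')/[\mu''\mu' +
(\alpha+\mu_{deg})(\alpha+\mu''+\mu')]$ — with $\mu''$, not $\mu'$, in
the numerator parenthesis; the independent age-structured simulator
agrees with this form to $<10^{-3}$ over random parameter sets (the two
variants coincide when $\mu'=\mu''$).

**Labeling index.**  The tracer convention: every cell residing in S at
any time during the labeling period $\Delta$ (default 6 h) is labeled,
labels are inherited at division, labeled cells remain counted while
transiently measurable after death, and fragments enter the denominator
only.  The closed form (`labeling_index()`) is obtained by tracking the
*unlabeled* complement, which stays closed because after time
$\min(\Delta, T_3)$ every dividing cell is labeled; the expression is
piecewise in $\Delta \lessgtr T_3$ and uses a numerically stable
$(e^{xt}-1)/x$ helper near the removable singularities
$\mu''\to\mu'$ and $\mu''\to\lambda_1+\mu'$.  At $\Delta = 0$ it reduces
to the viable S fraction; at $\lambda_1 = 0$ it is zero.

**Simulator oracle.**  `simulate_population()` advances age cohorts one
bin per step (unit CFL, so transport is exact), with exponential
within-step death, exact partitioning of the two competing G1 exits, and
a fractional final G2M cohort so arbitrary $T_3$ incurs no rounding bias;
the default step is $\min(T_2,T_3)/200$.  Composition converges to the
closed forms like the slowest transient, whose rate can be as small as
$\mu''-\alpha$; comparisons therefore run to 150 days of simulated time
(the labelled-cohort run-in uses the same floor), after which agreement
is a few $10^{-4}$ — comfortably inside the $10^{-3}$ oracle tolerance at
these problem sizes (12 random sets in the unit tests, 50 in the
acceptance suite).  The labeling bookkeeping duplicates the state into
labeled/unlabeled halves during the pulse; because the step divides
$T_2$ exactly but generally not $\Delta$, the index is evaluated at the
two bracketing step counts and interpolated linearly in time.

**Fitting.**  `cellpop_fit()` fits per dose.  For control, an externally
measured $\alpha$ is fixed and eliminates $\lambda_1$ through the
balanced-growth relation (infeasible regions, where
$2e^{-(\alpha+\mu')(T_2+T_3)} \le 1$, are rejected by penalty); the
fragment clearance $\mu_{deg}$, unidentifiable from composition data, is
pinned to the fitted control $\mu''$ for all doses.  For treated doses
all five parameters are free and $\alpha$ follows from the relation.
Counting degrees of freedom: three independent fractions plus the dead
fraction give four constraints for five unknowns, so the labeling index
(or its treated/control ratio, converted through the fitted control
index) is needed for full identifiability — the exact-data recovery test
includes it.  Without it the composition is still fit and the labeling
index becomes a prediction, which is precisely how a control index can be
reported when it was never measured.

## 7. Link analysis

Constitutive PI3K/Akt activation of leukemic blasts is represented by a
constant "equivalent insulin" input; its value is not identifiable from a
control-normalized profile alone, so `equivalent_insulin_refit()` takes
it as a fixed setting (default 10 nM) unless a second profile
(pAkt(Ser473)) is supplied, in which case it is estimated jointly.
Drug action is represented by one inhibition multiplier per dose applied
jointly to `a10`, `a11`, `a24` — per-dose refitting rather than a
parametric dose law, because the mapping from inhibitor concentration to
rate-constant scaling is not known mechanistically.  Each multiplier is
found by 1-D root finding (the normalized pS6K1 ratio is monotone in it).
`fit_link()` then fits the saturating relations between signalling
read-outs and population parameters — $y = Ax/(B+x)$ against $\lambda_1$,
$y = A/(B+x)$ against the mean cycle time $T_c = 1/\lambda_1+T_2+T_3$,
and $y = A/(B+x^n)$ (exponent free only in this form) against $\mu'$ —
via Levenberg–Marquardt with positivity bounds, falling back to a
derivative-free search on log-parameters when the data are nearly flat
and the Jacobian degenerates.  The fits are scale-equivariant in $y$
(rescaling moves only $A$), and the end-to-end property holds: rising
dose jointly depresses pAkt(Ser473) and pS6K1 on the signalling side and
$\lambda_1$ on the population side while $\mu'$ rises.

## 8. Synthetic data and the reference parameter sets

The generators emulate the *structure* of the data this methodology is
used on: `synth_dose_response()` produces control-renormalized analyte
tables on the insulin grid {0, 0.1, 1, 10, 100} nM with independent
Gaussian noise (default sd 0.05, the magnitude class of densitometry
error bars) truncated at zero; `synth_population()` perturbs the
composition on the simplex by Dirichlet resampling (concentration mapped
from sd so a mid-range fraction has the requested spread, preserving
sum-to-one) plus truncated Gaussian noise on the dead fraction and
labeling index.  A fixed seed makes every table bit-reproducible.  What
they do *not* emulate: correlated errors within a blot, multiplicative
and baseline components of densitometry noise, gating uncertainty in flow
cytometry, and inter-replicate normalization drift.  Passing recovery
tests on these data therefore demonstrates correctness of the estimation
machinery under the stated error model, not robustness to real-data
pathologies.

The packaged reference sets (`inst/extdata/*synthetic*`) are synthetic
constructions, not redistributed experimental estimates.  They were
calibrated once, before the test suite was finalized, so that the model
reproduces characteristic published observables of each system: the
myoblast-like set a weak maximal response (total phospho-Akt 8.61% of
total Akt and surface GLUT4 48.3% at 100 nM insulin, with receptor
half-response at 44.68 nM and basal fraction 0.03); the myotube-like set
a strong response (78.7%, half-response 9.69 nM), GLUT4 translocation
rises of 61.8% (control) versus 36.7% (PDK1-inhibited), a small `a12`
(so the S6K1→mTORC2 loop is negligible, with sensitivities below
$10^{-5}$), and `J` of 0.001/0.07 in control/conditioned medium.  The
population table fixes the control doubling time at 3.86 days and the
control labeling index at 31.2% (solving for $T_2$), and sets the
treated declines to halving times of 2.036, 1.364 and 0.783 days at 10,
100, 1000 nM by choosing $(\lambda_1, T_2, T_3)$ per dose and solving
$\mu'$ from the balanced-growth relation; fragmentation rates were chosen
fast enough that the balanced composition exists at the steepest decline
($\mu_{deg} > |\alpha|$) and the measurable dead fraction stays in a
realistic range.  The acceptance script recomputes all of these numbers
from the fixtures through the model machinery at run time.

## 9. Known limitations

* Steady-state only: no transients, receptor internalization/recycling,
  or hysteresis analyses; the FoxO1→TSC2 and GSK3→S6K1 routes are
  omitted.
* Parameter values are cell-type specific; the two reference sets differ
  substantially, and individual parameters are generally not identified
  by curve data (curves are).
* The TSC2/Rheb/PRAS40 layer is a minimal saturating-kinetics
  construction constrained by qualitative perturbation outcomes and the
  printed constants; its shape mismatch with the lumped law (RMSE ≈ 0.07)
  is inherent, not a solver artifact.
* The population model's loss rates are phenomenological; they cannot be
  attributed mechanistically to autophagy versus apoptosis, and the link
  functions are descriptive relations, not causal pathway models.
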