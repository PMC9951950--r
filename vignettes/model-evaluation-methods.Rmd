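---
title: "Evaluating intake and methane predictions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating intake and methane predictions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumeval)
```

## The problem

Mechanistic rumen models predict, per animal and diet, the voluntary dry
matter intake (DMI, kg DM/animal/day) and the enteric methane emission
(L/animal/day). Before such a model is used for inventories or
decision support it must be evaluated against paired observations: for each
animal we have an observed value $O_i$ (intake from feed offered minus
refused; methane from whole-animal chamber measurements) and a simulated
value $S_i$ from the model under the same diet and animal description.
`rumeval` implements the standard accuracy/precision descriptor suite for
such paired data, a subsetting pipeline for diets with and without Leucaena
(a tropical legume whose condensed tannins suppress methanogenesis in ways
a fermentation-stoichiometry model does not capture), a one-at-a-time
forage-quality sensitivity analysis, and a synthetic-data generator so the
whole pipeline is testable when the original animal data are not
distributable.

## The descriptor suite

All moments are **population moments** (divide by $n$): $\bar O$, $\bar S$,
$SD_o$, $SD_s$, $\mathrm{cov}_{os}$, $r = \mathrm{cov}_{os}/(SD_o SD_s)$.
This is a deliberate choice: it is the only convention under which the MSPE
partition below is an exact identity. A `sample = TRUE` flag on `moments()`
exposes the $n-1$ convention for cross-checks only.

**Accuracy** — how close the simulation is to the observations on average:

* Mean S/O ratio, $\mathrm{MSOR} = \frac{1}{n}\sum_i S_i/O_i$; 1 is
  perfect, below 1 underestimation.
* Regression slope of $O$ on $S$: `mode = "moment"` gives
  $\beta_1 = \mathrm{cov}_{os}/SD_s^2$ (the default), `mode = "origin"`
  the zero-intercept slope $\sum O_i S_i / \sum S_i^2$. Both are offered
  because the two parameterizations are in circulation for this analysis
  and the choice cannot be decided from the published tables alone; slope
  t-tests against 1 and 0 use $n-2$ and $n-1$ degrees of freedom
  respectively.
* Mean bias, $\mathrm{MB\%} = 100(\bar S - \bar O)/\bar O$ — **signed so
  that underestimation is negative**. (The descriptor is sometimes
  typeset with an $\sum(O_i - S_i)$ numerator, which has the opposite
  sign; the convention here matches how reported values are read, with
  underestimation negative.)

**Precision** — how much scatter remains around the relationship:

* CV of the S/O ratios, $100 \cdot SD(S/O)/\mathrm{MSOR}$.
* $R^2$, the squared Pearson correlation.
* Model efficiency,
  $\mathrm{ME} = 1 - \sum (S_i-O_i)^2 / \sum (O_i-\bar O)^2$:
  1 is perfect, 0 matches the "predict the observed mean" baseline, and
  negative values mean the model is worse than that baseline (which is
  exactly what happens for methane on Leucaena diets).

**Combined**:

* $\mathrm{MSPE} = \frac{1}{n}\sum (S_i - O_i)^2$, partitioned exactly into
  overall bias $(\bar S - \bar O)^2$, slope deviation
  $SD_s^2 (1-\beta_1)^2$, and random variation $(1 - r^2) SD_o^2$; the
  three shares always sum to 100% (asserted at $10^{-9}$). A perfect fit
  ($\mathrm{MSPE}=0$) is flagged, not an error, with shares reported as
  zero. The significance of the overall bias is a two-sided paired t-test
  of $O$ against $S$ (reported p-values in this literature are consistent
  with that test, though it is rarely named).
* Lin's concordance correlation coefficient
  $\mathrm{CCC} = 2\,\mathrm{cov}_{os} / (SD_o^2 + SD_s^2 + (\bar S - \bar
  O)^2)$, factored as $\mathrm{CCC} = C_a \times r$ with the accuracy
  component $C_a = 2 SD_o SD_s / (SD_o^2 + SD_s^2 + (\bar S - \bar O)^2)$.
  The factorization holds to machine precision and is asserted at
  $10^{-12}$.

Two formulas one sometimes sees typeset differently deserve a note, since
the package deliberately implements the standard forms: a "$1 -$" prefix on
$R^2$ is inconsistent with any table in which $R^2 \approx r^2$ (e.g.
$0.941^2 = 0.885 \approx 0.886$), and a "$(1 + r^2)$" random MSPE component
breaks the sum-to-MSPE identity that published partitions themselves
satisfy. Both are treated as typesetting slips; the test suite checks the
standard forms against an independently written brute-force oracle on 200
random series at $10^{-10}$.

## The evaluation pipeline

`run_evaluation()` pairs one variable's observed and simulated columns,
labels each pair with the Leucaena flag of the record's diet (a diet
attribute, never inferred from composition), and evaluates the descriptor
suite on the full data and optionally on the without/with-Leucaena subsets.
A subset with fewer than 3 records is dropped with a warning rather than
failing the run. `write_report()` emits the standard 13-row descriptor
table (CSV or markdown) rounded for display — 3 decimals for ratio-like
rows, 1 for percentages — while the in-memory report keeps full precision.

## The stub predictor

The dynamic fermentation model this package is designed to evaluate is
external to it; its internals are not reimplemented. So that every
downstream stage is executable, the package ships a pluggable predictor
registry (`register_predictor()` / `get_predictor()`) plus a fully
specified stoichiometric **stub**:

* Intake: $\mathrm{DMI} = c_I\, bw^{0.75} (\mathrm{NDF}_{ref} /
  \mathrm{NDF})^{\theta}$ — metabolic body size with an NDF fill
  constraint ($c_I = 0.095$, $\mathrm{NDF}_{ref} = 65\%$,
  $\theta = 1.25$; at 206 kg and 69.2% NDF this gives 4.78 kg/d).
* Methane: the fermentable substrate mass combines digestible fiber
  (inhibited by the non-structural carbohydrate share
  $\phi = \mathrm{NSC}/(\mathrm{NSC}+\mathrm{NDF})$, factor
  $1-\gamma\phi$), digestible NSC ($d_s = 0.9$), a saturating protein
  factor $\mathrm{CP}/(\mathrm{CP}+K_{CP})$, and linear fat and ash
  penalties. It is converted to CH$_4$ through a Wolin-type hexose yield
  $y_0 - y_1\phi$ (mol CH$_4$/mol hexose, positive over
  $\phi \in [0, 0.35]$), the hexose molar mass (162 g/mol) and the molar
  gas volume (22.4 L/mol), times a calibration scale $c_M = 1.6$ chosen so
  stub methane sits near 104 L/d at the observed intake scale — the same
  order as the evaluated model's simulated mean.

The **normative contract is the sign pattern, not the constants**: over the
observed forage-quality ranges (NDF 56.8–72.9, NSC 3.4–12.5, CP 6.5–14.7,
EE 2.51–3.78, ash 9.6–12.5, IVDMD 58.7–64.1 % DM), stub methane is strictly
decreasing in NDF, NSC, EE and ash and strictly increasing in CP and IVDMD,
from every diet base — verified by 50-point sweeps per variable per diet in
the test suite. Intake depends on NDF only.

## Sensitivity analysis

`build_oat_design()` substitutes, one variable at a time with each diet as
base, the minimum and maximum of that variable across the diet table
(`levels_per_variable` evenly spaced values in general; NSC is substituted
as an independent input, not re-derived by difference). With six diets, six
variables, two levels and baselines this is 78 runs; a historical count of
256 runs for this design is not derivable from six diets and six variables,
so the design size here is configuration, not dogma. `run_sensitivity()`
reports a **consensus sign per variable requiring unanimity across bases**
(disagreement is reported as `"mixed"` rather than majority-voted, because
a single unqualified sign per variable is only meaningful if every base
agrees), and a PCA of the standardized run matrix. What exactly should
enter that PCA is ambiguous in the source analysis; the package includes
both the substituted input values and the predicted methane, and
standardizes columns to unit variance.

## Synthetic data: the stated world

`generator_config()` encodes the study conditions as defaults: 6 diets
$\times$ 4 steers, body weight $206 \pm 36$ kg truncated above 120 kg,
observed DMI anchored to the stub intake (near 4.6 kg/d), observed methane
= 34.5 L CH$_4$ per kg DMI (placing emissions near 159 L/d), a 10%
observed-emission reduction on Leucaena diets, and simulated values =
observed $\times$ target S/O ratio (1.07 for DMI; 0.637 / 0.769 for
methane without/with Leucaena) $\times$ lognormal simulation error
($\sigma_{sim} = 0.05$). All noise is multiplicative lognormal because
every quantity is a positive rate and no additive error model is reported;
the animal effect ($\sigma = 0.12$) and day-to-day emission noise
($\sigma = 0.08$) are plausible placeholders for variance components the
source does not report, chosen once and not tuned.

What the generator does **not** emulate: repeated days within animal,
period carry-over, real between-animal covariance between intake and
emission beyond the shared intake factor, or any genuine animal science in
the intake anchor. A green recovery test therefore establishes that the
*statistics* recover known truth — `recovery_check()` verifies the
evaluated mean S/O per group against the analytic lognormal mean
$\rho\,e^{\sigma_{sim}^2/2}$ within 2% at 500+ animals per group — not
that the generator resembles any particular herd.

## Numerical choices

* Partition identity asserted at $10^{-9}$, CCC factorization at
  $10^{-12}$, oracle equivalence at $10^{-10}$.
* Exact fits: a zero slope standard error makes the slope t-statistic
  degenerate; the p-value is defined as 1 when the slope equals the null
  value and 0 otherwise. A constant predictor gets a zero slope component
  and the whole non-bias remainder assigned to the random term.
* Diet validation allows 0.15 percentage points of slack on both the
  NSC-by-difference cross-check and the fractions-sum-to-100 check,
  because published compositions are rounded to 1–2 decimals (four of the
  six packaged diets sum to slightly above 100 as printed).
* CSV round trips write 17 significant digits so doubles survive exactly.
* CLI config files are JSON (flags win over file values); exit codes are
  0 ok, 1 validation, 2 I/O, 3 internal.

## Known limitations

* The descriptor suite needs $n \ge 3$ and non-constant simulated values;
  degenerate inputs error early with named messages rather than returning
  NaN.
* The stub predictor is a calibration artifact. Its magnitudes are
  realistic but carry no mechanistic authority; only its response
  directions are contractual.
* Published descriptor tables can only be partially reconstructed without
  the raw per-animal data: the package's acceptance checks therefore
  combine printed-value identities (CCC $= C_a \times r$, partition sums)
  with property-based tests on synthetic data, and make no claim to
  reproduce the original tables cell by cell.
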