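---
title: "Quantifying drug-pair synergy in patient-derived culture screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-pair synergy in patient-derived culture screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(synergyscreen)
```

## The problem

High-throughput viability screens test whether a candidate potentiator
(here modeled on the stilbenoid pterostilbene) strengthens the effect of
partner drugs (an EGFR inhibitor and an SSRI) across a panel of
patient-derived glioblastoma cell cultures. Each culture is exposed to
each drug alone over a serial dilution, and to the pair diluted at a
*fixed dose ratio* derived from the working doses (20 uM : 7 uM and
20 uM : 10 uM, giving ratios 0.35 and 0.5). Viability is a fluorescence
readout normalized to vehicle (DMSO) wells on the same plate,
`W = Y_treated / Y_control`.

Two complementary interaction metrics are computed per culture:

* the **Bliss interaction score** `IS = w_ab - w_a * w_b`, the departure
  of the observed combination survival from the product expected if the
  drugs acted independently; negative values indicate potentiation;
* the **combination index** `CI_y = X_a/x_a + X_b/x_b` at effect level
  `y` (inhibition `1 - W`), where `X_a, X_b` are the component doses at
  which the *combination* reaches `y` and `x_a, x_b` the single-drug
  doses achieving the same effect alone. `CI < 1` is the classical
  synergy annotation; values are averaged over 21 levels spanning the
  40--60% inhibition band, where the curves are steep and inversion is
  stable.

Cohort-level evidence is summarized by two-sided one-sample Wilcoxon
signed-rank tests of the per-culture medians (IS against 0, CI against
1), exact for up to 25 non-zero differences and normal-approximated with
continuity correction above that.

## Dose-response model

All curve-based quantities rest on the four-parameter log-logistic
sigmoid

$$W(d) = L + \frac{U - L}{1 + (d/e)^h},$$

with upper asymptote $U$ (viability at zero dose, ~1 after
normalization), lower asymptote $L$, midpoint $e$ (uM) and slope $h > 0$.
This parameterization was chosen because its inverse is closed-form,
which makes the CI computation exact given the fitted curves. Fits use
bounded multi-start nonlinear least squares (`stats::optim`, L-BFGS-B)
on replicate-mean ratios: five deterministic starts built from the data
($U$ = max ratio, $L$ = min ratio, midpoint candidates at the dose
nearest half-range and the geometric-mean dose, slopes 0.5/1/2), best
residual sum of squares wins, ties to the smaller slope. Default bounds
are $L \in [0,1]$, $U \in [0.5, 1.5]$, $e$ within a tenfold extension of
the tested range and $h \in (0, 10]$; they keep the asymptotes near the
physically meaningful range and prevent runaway extrapolation. Because
ratios are control-normalized, `fix_upper = TRUE` optionally pins
$U = 1$. A series with no signal (all ratios equal) returns a flagged
degenerate fit and is excluded from synergy scoring. L-BFGS-B
occasionally reports an abnormal line-search exit at an optimum it has
already reached; a polish restart accepts convergence when no further
progress is possible.

The fixed-ratio CI needs three curves per culture and pair: each single
drug versus its own dose, and the combination versus the anchor
(first-compound) dose, with the partner dose locked at `ratio * d_a`.
Unattainable effect levels are handled explicitly: if a *single* drug
never reaches the target inhibition its dose term contributes 0 (the
limit of an inert constituent, which preserves the sham and
inert-partner identities below); if the *combination* cannot reach the
level, that level is undefined and excluded from the band average. A
strict mode treats partially attainable levels as undefined instead.

Two identities anchor the implementation and are enforced in the test
suite to tight numerical tolerance:

* **Sham combination**: a drug combined with itself at ratio 1 is pure
  dose addition, so `CI = 1` across the whole attainable band
  (`|CI - 1| < 1e-6`);
* **Bliss null**: when the combination response equals the product of
  the single-drug curves, every per-dose IS is zero to machine
  precision.

Note that these two identities are anchored in *different* null models.
The fixed-ratio CI of a Bliss-independent (product) combination is not 1
in general: for two matched curves with Hill slope $h$ it equals
$2 \cdot 0.414^{1/h}$ at 50% inhibition — below 1 for shallow curves and
above 1 for steep ones. The two metrics therefore probe different parts
of the interaction landscape, which is why both are reported.

## Significance of a single factorial plate

For small factorial experiments (control / drug a / drug b / combination
in replicate wells) the interaction score's significance comes from a
label-permutation test: well values are normalized once by the observed
control-well mean (making the statistic invariant to common rescaling of
the plate), treatment labels are shuffled 10,000 times by default, and
the empirical p-value uses the add-one rule
`(1 + #extreme)/(1 + n_perm)`. Wells are brought to a canonical order
before permuting so the result does not depend on how replicates happen
to be labelled. Calibration under the null is verified against the exact
binomial band in the acceptance suite.

## Biomarker prediction

Per-culture synergy (CI) is regressed on molecular profiles — log2
expression or log2 copy-number matrices, cultures by features — with the
elastic net,

$$\frac{1}{2N}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
\lambda \sum_j \left(\frac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\right),
\qquad \alpha = 0.9,$$

solved by cyclic coordinate descent (compiled, with warm starts along
the penalty path) on columns standardized to mean 0 and 1/N-unit
variance, unpenalized intercept, coefficients reported on the original
scale, convergence when the largest coefficient change in a sweep falls
below 1e-7. The penalty is tuned by leave-one-out cross-validation on a
100-point log-spaced grid from $\lambda_{max}$ (the smallest all-zero
penalty) down to $10^{-3}\lambda_{max}$, selecting the $\lambda$ with
the highest Pearson correlation between observed and left-out predicted
values; ties go to the stronger penalty. Feature importance is the
*selection frequency*: the fraction of the N leave-one-out refits, at
the selected penalty, in which the feature keeps a nonzero coefficient.
Expression and copy number are analyzed as separate models.

Associations with categorical predictors use a Welch t-test (binary
mutation flags), one-way ANOVA (three or more subtype groups), or — for
a single mutant culture — a singleton z-test,
`z = (x_1 - mean(ref))/sd(ref)` with a two-sided normal p-value, a
documented construction since no standard two-sample test applies to a
group of one. Clinical covariates (age, survival with no censoring) use
Pearson correlation.

**A caveat on cross-validated correlations.** With many more features
than cultures, the LOOCV correlation at the *selected* penalty is
optimistically biased under the null: on pure-noise responses with
N = 41 and p = 200 its null distribution has median ~0.16 and 95th
percentile ~0.6 (the same behavior reproduces with an independent
solver, so it is a property of the procedure, not of this
implementation). An honest null reference for a reported cross-validated
correlation in the p >> N regime should come from response permutations,
not from assuming the null correlation is near zero. In the classical
p < N regime the selected correlation behaves as expected, and the
package's null-calibration test runs there.

## Cell-cycle analysis

Per-nucleus integrated DNA-stain intensities (the module starts at the
image-analysis export boundary; segmentation is out of scope) are binned
into 100-level histograms with bin edges shared across all doses of a
culture, and nuclei are gated into G1 / S / G2M. Manual gates are the
primary path; `"auto"` gates locate the G1 mode from the histogram peak
of the lowest-dose sample and place G1 = [0.75m, 1.3m), S = [1.3m,
1.7m), G2M = [1.7m, 2.5m], with an error (rather than a guess) when two
comparable modes make the G1 peak ambiguous. Fractions are normalized
over gated nuclei, and gating is scale-equivariant.

Dose dependence is quantified two ways: per-culture ordinary least
squares of each phase fraction on log10 dose (slopes in fraction per
tenfold dose; zero doses are excluded, since they have no logarithm),
with cohort-level sign concordance assessed by the exact binomial sign
test (two-sided = twice the smaller tail, capped at 1); and a
linear mixed-effects model

$$y_{ij} = c^{F} + \beta^{F} x_{ij} + c_j + \beta_j x_{ij} +
\varepsilon_{ij}$$

with independent random intercepts and slopes per culture, fit by
maximum likelihood (`lme4`). Independence of the random effects is an
identifiability choice appropriate to ~14 groups. The common slope
$\beta^F$ is reported with a Wald normal 95% interval and p-value (a t
reference with `n_cultures - 2` degrees of freedom is available by
option); a singular fit falls back to pooled OLS with a flag.

## Factorial knockdown / antioxidant models

2x2 designs (siRNA or NAC crossed with drug) are fit by the saturated
linear model `w = w0 + dw_a + dw_b + dw_inter` under treatment coding
with the both-off cell as reference, so each printed delta is a
departure from baseline and the interaction term is the deviation of the
both-on cell from additivity. Time points can be pooled (default) or
blocked. Phenotype-ratio comparisons between two groups use the
Mann-Whitney test, exact for tie-free combined samples up to 20,
otherwise normal-approximated with tie and continuity corrections.

## The synthetic cohort and what it does (not) show

The generator emulates the structure of the motivating screen: 41
cultures, 11-point 3-fold dilutions, fixed-ratio combination series from
the 20/7 and 20/10 uM working doses, triplicate wells, 16 vehicle wells
per plate, one plate per culture, raw signal = plate scale x true
viability x multiplicative log-normal noise (5% CV by default; plate
scale 10,000 with 10% between-plate CV). Subtype, age, sex and survival
annotations come from simple categorical/normal models matched to the
cohort's published composition (25 male / 16 female, mean age ~65).

True single-drug curves use $U = 1$, $L \sim U(0.05, 0.25)$, midpoints
log-normal around half the working dose, and slopes near the hyperbolic
value ($h \sim U(0.9, 1.4)$ shared per culture, with small
compound-specific jitter), with drug sensitivity modeled as a shared
per-culture log-potency scale (sd 0.3) plus compound-specific departures
(sd 0.15). The shared scale keeps the fixed dose ratio roughly matched
to per-culture potencies — which is what choosing the ratio from working
doses is meant to achieve — and near-hyperbolic slopes are typical of
72-hour viability readouts. Under these conditions the Bliss-null CI
baseline sits slightly below 1 (see the sham/Bliss distinction above),
and a planted interaction of strength 0.3 moves the cohort median CI to
about 0.7.

Synergy is planted through a one-parameter multiplicative Bliss-excess
kernel tied to the anchor drug's receptor-occupancy curve:

$$W_{ab}(d) = W_a(d)\, W_b(\rho d)\,(1 - \sigma s(d)), \qquad
s(d) = \frac{(d/e_a)^{h_a}}{1 + (d/e_a)^{h_a}},$$

so $\sigma = 0$ gives exactly Bliss-independent combinations (the
mutual-consistency check between generator and scorers), $\sigma > 0$
smooth fixed-ratio synergy of known strength, and the truth record
carries an analytically inverted `ci_true` per culture so recovery
studies can use a noise-free reference without refitting.

The molecular generator plants an independent linear signal: `n_causal`
expression features each contribute `effect_size` to the response
(noise sd 0.1), a contiguous copy-number segment tracks the causal
transcript signal with extra noise — dosage acting through expression,
so copy number predicts the response but less well than transcripts —
and one mutation flag marks the 8 cultures highest on a noisy copy of
the response. The response is a centered CI surrogate; all association
tests used on it are shift-invariant. DNA-content tables draw G1 at
Normal($\mu$, 5% CV), G2M at twice $\mu$, S uniform between 1.15$\mu$
and 1.85$\mu$, with per-dose phase weights interpolating logistically in
log dose from a G1-rich (0.60/0.25/0.15) to an S/G2M-enriched
(0.35/0.40/0.25) composition.

What passing these studies shows: the estimators recover what the
generator planted, at the stated sizes and noise levels, and the exact
identities hold to numerical precision. What it does not show: real
screens have edge effects, non-log-normal noise, biphasic responses,
drifting controls and batch structure, none of which are emulated; and
the planted-signal geometry (independent Gaussian features, smooth
fixed-ratio response surfaces) is friendlier than real transcriptomes
and real interaction landscapes. Conclusions about real data should rest
on the per-dataset diagnostics (fit flags, defined-level counts,
permutation calibration), not on the simulation results.

## Problem sizes and numerical choices

Simulation studies in the test and acceptance suites use the cohort
sizes the methods target (41 cultures, 11 doses; 14 cultures for the
cell-cycle module; 500 features) with seed counts of 20-500 chosen per
study so each suite completes comfortably on a single CPU. Root finding
for curve inversion brackets on log10 dose (tolerance 1e-12); the
permutation and LOOCV procedures are deterministic given their seeds;
all generators restore the session RNG state. One module-level example
(noise-free sparse recovery at N = 20, p = 200) sits at the
sparse-recovery phase transition and is pinned to a fixed design draw;
the cohort-scale recovery study (N = 41, p = 500) is seed-robust.

## A worked example

```{r example, eval = FALSE}
cfg <- list(simulate = simulation_config(n_cultures = 41, sigma = 0.3,
                                         cv = 0.05),
            pairs = "pterostilbene+sertraline")
report <- run_screen_analysis(cfg, seed = 1)
report$cohort
```

The cohort table reports, per pair, the median interaction score and
combination index with their Wilcoxon p-values; `report$per_culture`
holds the per-culture values, defined-level counts and fit flags that
should be inspected before trusting any cohort summary.
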