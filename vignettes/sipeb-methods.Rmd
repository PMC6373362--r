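---
title: "Structurally informed empirical Bayes for effective connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally informed empirical Bayes for effective connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipeb)
```

## The problem

Effective connectivity — the directed causal influence one brain region
exerts over another — is inferred from fMRI time series by inverting a
generative model (a dynamic causal model, DCM). White-matter anatomy
constrains which influences are plausible, but the mapping from structural
connection strength (a probabilistic-tractography streamline statistic) to
effective connectivity is not one-to-one: regions can communicate
polysynaptically, and task context can silence anatomically strong routes.
`sipeb` treats the structure–function link probabilistically: structural
strength does not impose connectivity, it licenses it, by widening the
prior variance of the corresponding coupling parameter. The form and
strength of that licence is itself learned by Bayesian model comparison.

## The model stack

### First level: subject DCM

Neuronal dynamics are the one-state bilinear approximation

$$\dot z = \Big(A + \sum_j u_j B^{(j)}\Big) z + \tfrac{1}{16}\,C u,$$

with $z$ the regional neural activity, $u$ the experimental inputs
(optionally mean-centred), $A$ the extrinsic/self coupling (Hz), $B^{(j)}$
input-dependent modulation of the *self*-connections (intrinsic
excitability) and $C$ the driving inputs. Self-connections are
parameterised as $A_{ii} = -\tfrac{1}{2}\exp(a_{ii} + \sum_j u_j
b^{(j)}_{ii})$, which keeps self-feedback negative and the system stable at
small extrinsic weights. The $C/16$ factor is a units convention: it puts a
unit-variance prior on $C$ on a footing comparable to couplings in Hz and
keeps boxcar inputs in a physiological regime (without it, sustained
unit-scale drive collapses simulated blood flow).

Observations follow the balloon/windkessel haemodynamic cascade per region
— vasodilatory signal, blood flow, venous volume, deoxyhaemoglobin — with
fixed constants (decay 0.64 s⁻¹, autoregulation 0.32 s⁻¹, transit 2.0 s,
stiffness 0.32, resting extraction 0.4; `hdm_constants()`) and two free
log-scaling parameters per region: venous transit time and neurovascular
gain. BOLD is read out in percent-signal units; i.i.d. Gaussian observation
noise with one log-precision per region completes the likelihood.

**Integration.** Inputs live on a microtime grid of `microtime_bins`
(default 16) subdivisions per TR. The neuronal subsystem is linear for a
fixed input vector, so it is propagated *exactly* by the matrix exponential
of the augmented affine system, cached per unique input vector (a boxcar
has two). The nonlinear haemodynamic states are advanced by classical RK4
at the same step, with the neuronal drive interpolated across the bin; they
are carried as logarithms so positivity is structural, and clamped at
$e^{\pm 8}$ as a guard against pathological excursions during optimisation.
A pure local-linearisation (matrix-exponential) step for the haemodynamics
would require a per-step Jacobian for no accuracy benefit at dt = TR/16;
the test suite checks that halving the step changes the noiseless BOLD by
well under 1%.

### Priors

Every parameter has an independent zero-mean Gaussian prior
(`dcm_priors()`): extrinsic couplings $\Sigma_y = 0.5$ (the maximal prior
variance used throughout), log self-connections and modulatory terms 1/64,
driving inputs 1, haemodynamic log-scalings 1/64. The extrinsic value is
the method's anchor; the others are declared package defaults — the
framework leaves them to the estimation scheme — and are echoed in every
output. A prior variance of exactly zero pins a parameter to its prior
mean; structurally forbidden pairs are handled this way.

### Inversion: variational Laplace

`dcm_fit()` (and the generic engine `vl_fit()`) maximises the variational
free energy

$$F = \underbrace{\mathrm{E}_q[\log p(y \mid \theta)]}_{\text{accuracy}} -
\underbrace{\mathrm{KL}\big(q(\theta)\,\|\,p(\theta)\big) -
\mathrm{KL}\big(q(\lambda)\,\|\,p(\lambda)\big)}_{\text{complexity}},$$

a lower bound on the log model evidence, by Gauss–Newton ascent with
Levenberg–Marquardt regularisation. Derivatives are central finite
differences with a fixed step (1e-4), computed in compiled code;
determinism was preferred over an autodiff dependency. Noise
log-precisions $\lambda$ (Gaussian hyperprior, mean 0, variance 16) are
updated by damped Newton steps *inside* every objective evaluation, so $F$
is a function of $\theta$ alone; candidate steps are only accepted when
they increase $F$, making the recorded trace monotone by construction.
Convergence is declared when $|\Delta F| < 0.01$ on 4 consecutive
iterations (at most 64). On a linear observation model the whole machinery
collapses to conjugate Bayesian regression, which the tests exploit as an
exact oracle (posterior and evidence to 1e-6).

### Second level: parametric empirical Bayes

`peb_fit()` pools the subjects' posteriors over the extrinsic $A$
parameters — only Gaussian sufficient statistics, the time series are never
revisited, which is what makes the subsequent model search cheap. Removing
the first-level prior from each posterior leaves a per-subject data
likelihood; the hierarchy

$$A^{(1)}_i = X_i\,A^{(2)} + \varepsilon^{(2)}, \qquad
\varepsilon^{(2)} \sim N\!\big(0,\ e^{-\gamma} Q\big),\quad
Q = \Sigma_0/16,$$

is then linear-Gaussian given the random-effects log-precision $\gamma$
(Gaussian hyperprior, mean 0, variance 1/16; prior expectation sets
between-subject variance to 1/16 of the prior variance). The group
free energy is analytic given $\gamma$, which is optimised by 1-D search
with a Laplace correction. Subjects contribute in proportion to their
first-level precision: inefficient estimates are automatically
down-weighted. The default design matrix is a single ones column (the
group mean); covariate columns are supported but unexercised.

### Bayesian model reduction

For a model differing from an estimated one only in its priors, the
evidence ratio is a Gaussian integral of the posterior and the prior ratio
(the Savage–Dickey generalisation). In precision form, with $\Pi_q$ the
posterior, $\Pi_0$ the full prior and $\Pi_{0R}$ the reduced prior
precision:

$$\Pi_{qR} = \Pi_q + \Pi_{0R} - \Pi_0, \qquad
\Delta F = \tfrac12\big(\log\det \Pi_q + \log\det \Pi_{0R}
 - \log\det \Pi_0 - \log\det \Pi_{qR}\big) + \tfrac12\,(\text{quadratic terms}).$$

`bmr_reduce()` is non-iterative; `score_model_set()` applies it to
hundreds of priors in well under a second. Pinned parameters are handled
in precision space with a large-but-finite cap (1e8), which matches
"switched off entirely" semantics without special-casing exact zeros. An
implied reduced-posterior precision that is not positive definite (possible
when an approximate posterior is wider than its prior and the reduced
prior relaxes it further) is a per-model error, flagged rather than fatal
in batch scoring.

### The structure–function mapping

Structural strength $\varphi \in [0,1]$ (symmetrized, group-averaged,
max-scaled streamline counts; no thresholding) maps to second-level prior
variance through a logistic function

$$\Sigma_y(\varphi) = \frac{\Sigma_{y\max}}{1 + \exp(\alpha - \delta\varphi)},$$

with ceiling $\Sigma_{y\max}$, slope $\delta$ and inflection $\alpha$. The
default lattice — $\alpha \in \{-2, -1.5, \dots, 2\}$, $\delta \in \{0, 2,
\dots, 16\}$, $\Sigma_{y\max} \in \{0.1, \dots, 0.5\}$ — yields 405
mappings, of which the 45 flat ones ($\delta = 0$) are the null models in
which structure carries no information. `sipeb_search()` scores all of
them against the full (uninformed, $\Sigma_y = 0.5$) PEB model by BMR,
reports softmax posterior probabilities, and judges structure by the
margin between the best informed and the best flat model against a
strong-evidence threshold of 3 log units (~95% pairwise probability). Both
the margin relative to the full model and relative to the best null are
reported, since "relative to the uninformed model" admits either reading.
Ties (models within the threshold of the maximum) are reported, and the
"best" field takes the first by lattice order for determinism. The mapping
modulates prior *variances* only, never prior means. Per-subject
re-optimisation of the mapping is deliberately not offered; the group-level
winner is applied to individual DCMs (`apply_mapping_to_subject()`) as the
more conservative choice.

## The synthetic cohort generator

`make_cohort()` emulates the study design the package targets: 12
subjects, TR 4 s, 114 volumes per session (a 24 s baseline then 24 s
on/off stimulation blocks driving region 1), a random heavy-tailed
structural connectome (exponential strengths, max-scaled — streamline
counts are heavy-tailed in practice), group couplings drawn from the
sigmoid mapping $(\alpha = 0.5, \delta = 8, \Sigma_{y\max} = 0.5)$,
between-subject random effects with sd $\sqrt{0.5/16} \approx 0.18$ Hz
(the model's own prior expectation), and observation noise of 0.5 percent
signal, placing the data near unit signal-to-noise. All randomness flows
from one master seed through named sub-streams, so changing the noise
level alone leaves the structural fixtures and ground-truth connectivity
bit-identical. Draws yielding an unstable neuronal system are rejected and
redrawn — a truncation to the dynamically admissible regime that any
simulation of this model family requires.

What the generator does *not* emulate: regional haemodynamic variability,
physiological (non-white) noise, motion, and the structured topology of
real cortical networks. Passing recovery tests therefore demonstrates the
estimator's internal consistency under its own assumptions, not
performance on real data.

**Problem sizes.** Test and acceptance studies use 5-region cohorts with
48-volume sessions — the package's chosen desk-scale configuration. The
evidence analyses below explain why region count, not volume count, is the
quantity that matters for the mapping search.

## What scale does to the evidence for structure

The margin between the best informed and the best flat mapping is bounded
by the summed KL divergence between the per-connection generative
variances and the single best flat variance — roughly 0.06–0.14 log units
per connection under the default mapping, *independently of how precisely
the group means are measured*. A 5-region network has 20 extrinsic
connections, so the expected margin is of order one log unit; a 12-region
network (~110 connections) supports margins several times larger. Strong
(≥ 3) group-level evidence for structural priors is thus an intrinsically
large-network phenomenon, and the same bound applies per subject at the
individual level. The test suite states its recovery checks at the small,
fast scale and records exactly this limitation; users applying the method
to networks of a dozen regions should expect — and the machinery is built
for — far more decisive margins. A related dynamical point: at ~110
connections, *unstructured* random couplings with variances up to 0.5
exceed the stability margin of the −0.5 Hz self-inhibition, so a
full-scale 12-region cohort cannot be generated from the unstructured
prior at all; real large networks are stable because their connectivity is
structured, which the generator does not imitate.

## Numerical choices and degenerate inputs

- Region label order is canonical everywhere; label mismatches between
  connectome, spec and priors are hard errors, never silently reordered.
- An all-zero structural matrix skips max-scaling with a warning and yields
  the uniform small variance $\Sigma_{y\max}/(1+e^{\alpha})$ downstream
  ("no thresholding" is taken literally: near-zero $\varphi$ is data).
- Integration divergence is reported with the first unstable region and
  time; during optimisation a diverging candidate simply evaluates to
  $F = -\infty$ and is rejected.
- The first-level "data precision" left after removing the prior from a
  subject posterior is eigenvalue-floored at 1e-8 of its largest magnitude
  before use.
- All pipeline outputs are plain text (TSV/CSV/JSON) and stamped with a
  hash of the scientific configuration; reruns are bit-identical.

## Known limitations

- One-state, deterministic, bilinear DCM only; no two-state, stochastic or
  nonlinear variants, and no resting-state (cross-spectral) formulation.
- The AR(1) error structure of first-level activation GLMs is out of scope;
  the DCM likelihood assumes white observation noise.
- BMR evidence for a reduced prior is computed at the full model's
  random-effects estimate; the mapping search does not re-optimise
  $\gamma$ per candidate (the standard, and fast, approximation).
- The biological-motion network template ships as labels and an exclusion
  mask only (the cerebellar node is labelled per the published coordinate
  table, "Crus I", where the running text says "lobule VI") — it makes no
  claim about real anatomy.
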