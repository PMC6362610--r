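---
title: "Estimating survival and breeding probability with a multievent robust-design model"
author: "mevrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survival and breeding probability with a multievent robust-design model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mevrd)
```

## The estimation problem

Many long-lived iteroparous animals skip breeding in some years.  Breeding
probability — the probability that a surviving female attempts to breed in a
given year — is among the hardest demographic rates to estimate, because
nonbreeders typically stay away from the breeding colony and are therefore
much harder (or impossible) to detect there.  If only breeding-colony surveys
are analysed, the nonbreeder state is unobservable: transition rates to and
from it are weakly identified and state-dependent survival cannot be
estimated at all.

`mevrd` implements a multievent (hidden Markov) capture–recapture model with
a robust-design observation process for exactly this situation, motivated by
long-term resighting of tagged female southern elephant seals: females breed
ashore in a synchronous spring season, every seal of either breeding state
must haul out again to moult in summer, and some are also seen ashore in
winter.  Combining within-season breeding surveys with those
nonbreeding-season resights makes the nonbreeder state observable.

## The model

### State process

Each marked female occupies one of three states in year $t$: breeder ($B$,
pupped this year), nonbreeder ($NB$, pupped previously but not this year),
or dead ($D$, absorbing; permanent emigration and tag loss are confounded
with death, so $\phi$ is *apparent* survival).  The annual transition matrix
is the product of a survival step and a conditional breeding step,

$$
\begin{pmatrix} \phi_B & 0 & 1-\phi_B \\ 0 & \phi_{NB} & 1-\phi_{NB} \\ 0 & 0 & 1 \end{pmatrix}
\begin{pmatrix} \psi_{B\text{-}B} & 1-\psi_{B\text{-}B} & 0 \\ \psi_{NB\text{-}B} & 1-\psi_{NB\text{-}B} & 0 \\ 0 & 0 & 1 \end{pmatrix},
$$

so e.g. the breeder row is $(\phi_B\psi_{B\text{-}B},\;
\phi_B(1-\psi_{B\text{-}B}),\; 1-\phi_B)$.  Breeding is first-order
Markovian: next year's breeding probability depends on the current state,
which is the biological hypothesis of interest (reproductive cost or
carry-over effects make $\psi_{B\text{-}B} \ne \psi_{NB\text{-}B}$).
`transition_matrix()` builds this product.

### Observation process: the robust design and the eight events

Within each breeding season there are 8 weekly island-wide surveys.  Because
breeding females arrive and depart in a staggered fashion (about 4 weeks
ashore each), the season is not closed, so the 8 secondary surveys are
collapsed into two alternating capture periods: the "uneven" weeks
$\kappa^U$ (1, 3, 5, 7) and the "even" weeks $\kappa^E$ (2, 4, 6, 8); a
typical female is exposed to roughly two surveys in each.  All sightings
outside the breeding season (moult or winter) collapse into a third period
$\kappa^M$.  The sighting pattern over $(\kappa^M, \kappa^U, \kappa^E)$
defines one of eight composite events per seal-year (September to August),
coded 0–7: NS, MUE, MU, ME, M, UE, U, E (`event_table()`).

Seen in the breeding season implies breeder; event 4 (seen only at the
moult/winter) is state-ambiguous — that is the "multievent" part.  The
emission probabilities are the product of three row-stochastic matrices
(`event_matrices()`): $B^M$ (3×4, moult/winter detection $m_B$, $m_{NB}$),
$B^U$ (4×6, uneven-week detection $p^u$, breeders only), and $B^E$ (6×8,
even-week detection $b^e$).  Nonbreeders are structurally unavailable in the
breeding season, so their $B^U$/$B^E$ rows carry no free parameters.  For a
breeder the composite row factorizes into three independent Bernoulli
detections — the unit tests use that closed form as an oracle for the matrix
product.  The order in which the three periods are modelled does not affect
the composite.  Because breeding-season and moult data are combined within
one seal-year, the model effectively assumes no mortality between breeding
and moult; violations depress the moult detection estimate rather than
survival, which remains an annual rate.

### Likelihood

Histories are conditioned on the first breeding-season detection: the
initial state is breeder with probability 1 and the first event contributes
no detection term.  `history_loglik()` runs the forward algorithm with
per-occasion rescaling (histories of hundreds of occasions do not
underflow); `brute_force_history_prob()` is an exponential-time
state-path enumeration kept as an independent oracle and cross-checked on
thousands of fuzzed cases.  `total_loglik()` evaluates all histories in one
vectorized forward pass, after merging identical histories with summed
multiplicities.  An impossible history evaluates to $-\infty$ (with the
offending ids attached), never an error.

## Model structures and fitting

A structure string such as `"phi(.) psi(state*t) m(state*t) pu(t) be(t)"`
declares, per parameter family, one of four variation patterns (constant,
time, state, state×time) plus a fixed-value pattern `=v`.  The fixed pattern
is not a fifth variation pattern but a practical necessity: boundary values
such as perfect detection cannot be represented on the logit scale, and
fixing parameters is standard practice in capture–recapture software.  Every
free probability is logit-linked; each emission row has at most one free
parameter, so no multinomial link is needed.  The working vector layout is
family-major (phi, psi, m, pu, be), state B before NB, time within state —
documented and stable, so fits are reproducible across versions.

`fit_mevrd()` minimises the deviance by BFGS from `n_starts` random starts
drawn uniformly on a working-scale box (default $[-2, 2]$, i.e.
probabilities roughly 0.12–0.88).  Multievent likelihoods with state
uncertainty are prone to local minima, so multiple starts are recommended
for time-varying structures; all start outcomes are retained in the fit
object.  The best solution is then polished (BFGS restart, then damped
Newton steps on the numerical Hessian), which brings closed-form cases to
agreement within ~1e-9.  An EM stage was deliberately not implemented:
multi-start quasi-Newton reaches the same stationary points and is simpler
to test.

Standard errors come from the inverse numerical Hessian of the negative
log-likelihood; intervals are Wald intervals on the working scale,
back-transformed so they respect $[0,1]$.  The Hessian's numerical rank
(SVD threshold `dim * eps * largest eigenvalue`) is reported next to the
slot count `np`: in time-varying structures some slots (e.g. terminal-year
detection/transition products) are not separately estimable, and the rank
makes that visible instead of pretending all slots are informative.
Published parameter counts from other software embed their own
identifiability conventions, so `n_par()` makes no attempt to reproduce
them.  Working-scale estimates beyond $|\beta| > 10$ are flagged as
boundary estimates and their intervals suppressed rather than fabricated.

## Model selection and overdispersion

`model_table()` assembles the usual QAIC table
($\mathrm{QAIC} = \mathrm{deviance}/\hat c + 2\,np$) with
$\Delta$QAIC and Akaike weights.  `bootstrap_chat()` estimates the
overdispersion factor by median parametric bootstrap — datasets simulated at
the MLE conditional on the observed first captures, refitted (warm-started
at the MLE), and $\hat c$ taken as observed deviance over the median
bootstrap deviance.  Other $\hat c$ estimators exist (Fletcher,
contingency-table methods); since the choice matters, `model_table()` also
accepts a user-supplied $\hat c$ directly, so a value obtained elsewhere can
be injected.  $\hat c < 1$ is clamped to 1 with a warning.  On model-true
simulated data the bootstrap $\hat c$ sits within a few percent of 1 (the
test suite checks $|\hat c - 1| < 0.1$ with 100 replicates).

## The synthetic-data generator

The simulator is first-class, tested code and defines the study conditions
for the package's own validation.  It emulates: cohorts of first-time
breeders entering per year (recruits are breeders in their entry year, as in
the conditioned population — no prebreeder stage); Markovian state-dependent
annual transitions; state-dependent moult/winter detection; and, at the
weekly level (`simulate_weekly_records()`), staggered attendance — an
arrival week drawn from a unimodal distribution over weeks 1–5 peaking at
week 3 (mirroring the mid-October peak of breeding-female counts), a 4-week
residence window clipped at week 8, and independent weekly detection with
probability `p_week`, implying a period-level capture probability
$1-(1-p_{week})^k$ after exposure to $k$ weeks of a period.
`simulate_histories()` draws composite events directly from the emission
matrix; both levels are conditioned on first breeding-season detection
exactly as the encoder `build_histories()` conditions real records, and the
tests verify that encoding the raw weekly records reproduces the directly
emitted event sequence realization-for-realization.

What the generator does *not* emulate — individual heterogeneity ("frail"
individuals), tag loss, environmental covariates on rates, within-season
mortality, spatial structure — bounds what passing tests show: parameter
recovery demonstrates the estimator is correct *under the model*, not that
the model is adequate for any particular field dataset.

Default truth values used by the built-in fixtures sit near published
elephant-seal estimates ($\phi = 0.76$, $\psi_{B\text{-}B} = 0.84$,
$\psi_{NB\text{-}B} = 0.66$, moult detection around 0.7) so that simulated
data exercise the realistic regime of fairly high detection and strongly
Markovian breeding.  Problem sizes in the test suite (e.g. 2,000 recruits
over 8 cohort years and 15 occasions for the recovery study; 1,000 recruits
and 100 bootstrap replicates for the $\hat c$ calibration) were chosen as
the smallest designs at which the checks are statistically meaningful.

## Numerical choices and degenerate inputs

* Forward-pass rescaling at every occasion; accumulated log-scale.
* Deviance of $-\infty$-likelihood parameter points is replaced by a large
  finite penalty inside the optimizer only; user-facing evaluation reports
  $-\infty$ honestly.
* Ties in model ranking are broken by table order; weights are computed
  after re-baselining $\Delta$ so they are invariant to adding constants.
* Empty resight files yield an empty dataset with a warning; records with
  unknown context labels or years outside the occasion axis are rejected
  with the offending values named.
* Duplicate sightings in one survey week collapse silently (the event is a
  pure function of the set of capture periods sighted).
* Pre-first-breeding sightings (e.g. a moult sighting before the first
  breeding capture) are discarded by the conditioning rule, and their count
  reported per individual; how the original analysis handled such records
  is not documented, so truncation is this package's explicit choice.

## Known limitations

Tag loss, prebreeder recruitment, within-season breeder/nonbreeder
uncertainty, dead recoveries, random effects and environmental covariates
are out of scope.  Only the four variation patterns (plus fixed values) are
supported — no additive state+time decompositions.  Wald intervals degrade
near boundaries (hence the suppression rule); profile likelihood is
available manually by refitting with a pinned value via the `=v` pattern on
a custom structure, as the test suite does for its profile-versus-Wald
curvature check.
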