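---
title: "Inferring juvenile social-learning pathways with multinetwork TADA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring juvenile social-learning pathways with multinetwork TADA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadanet)
```

## The problem

Juvenile birds in species with short dependence periods — great tits are the
motivating system — can acquire a novel foraging skill (here, solving a
two-option puzzle box) along several social pathways: vertically from their
parents, obliquely from other adults, horizontally from siblings, or from
unrelated peers, as well as asocially by individual exploration. `tadanet`
implements the full inferential chain for distinguishing these pathways from
automated field data:

1. **Event streams.** RFID feeder detections, puzzle-box solve/visit logs and
   a brood/pedigree registry, as plain CSV.
2. **Dynamic multi-layer networks.** Co-feeding gathering events detected by
   1-D Gaussian-mixture clustering of detection timestamps, gambit-of-the-group
   simple-ratio association indices, routed into four dyad-class layers, and
   recomputed in a sliding window around each acquisition event.
3. **Multinetwork time-of-acquisition diffusion analysis (TADA).** A
   continuous-time survival model of who learned when, with per-layer social
   transmission rates, model averaging over all network/covariate
   combinations, profile-likelihood intervals and per-event pathway
   decomposition.
4. **Decision-strategy regressions.** How parental exposure predicts whether
   a juvenile learns at all, and how social versus personal information
   predicts which side it chooses.
5. **A synthetic generator** that emulates all of the above with known ground
   truth, so every stage is testable without field data.

## The acquisition model

While naive, present, and past its entry time (fledging), individual $i$
acquires the behaviour with hazard

$$
\lambda_i(t) = \lambda_0(t)\Big[\exp(\beta_A^\top x_i(t)) +
\sum_k s_k \,\exp(\beta_S^\top x_i(t))
\sum_j a_{ij}^{(k)}\, w_j(t)\, z_j(t)\, \pi_j(t)\Big]
$$

where $k$ indexes the four network layers, $a_{ij}^{(k)}$ is the simple-ratio
association in layer $k$, $z_j$ indicates that $j$ is knowledgeable, $\pi_j$
that $j$ is present, and $w_j$ is $j$'s transmission weight — its solving
rate per experimental day since its own acquisition, so prolific solvers
transmit more. $s_k \ge 0$ is the social transmission rate through layer $k$
*relative to the baseline asocial rate*; realistic fitted values can be large
(hundreds) when almost nobody learns asocially. Individual-level variables
(ILVs) $x_i(t)$ — parental solves during dependence and the juvenile's own
scrounge count — may act on the asocial rate ($\beta_A$), the social rate
($\beta_S$), both, or neither ("unconstrained" placement). The baseline
$\lambda_0$ is either constant ($1/\theta$) or Weibull
($(\kappa/\theta)(t/\theta)^{\kappa-1}$), in units of days.

Covariates are piecewise-constant between acquisition events. The
log-likelihood sums $\log\lambda_0(t_e) + \log R_{i_e}(t_e)$ over events and
subtracts each at-risk individual's integrated hazard
$R_i\,[\Lambda_0(\text{end}) - \Lambda_0(\max(\text{start},
\text{entry}_i))]$ over the slices in which it is naive and present, with
non-learners censored at the site end time. Sites are separate diffusions
sharing parameters; the total likelihood is the sum. The exactness of this
expression (given piecewise-constant covariates) is verified in the tests
against trapezoid quadrature of the pointwise hazard.

Demonstrators (adults knowledgeable before the diffusion starts) and
"filtered" adults (adults acquiring during the diffusion) contribute as
transmitters but never as learners; a filtered adult's $z_j$ switches on at
the first event boundary after its acquisition.

### Model set, averaging, intervals

`enumerate_model_set()` builds all $2^4$ network subsets $\times$ $4^2$ ILV
placements per baseline family — 256 specifications with four networks and
two unconstrained ILVs. Each is fitted by box-constrained quasi-Newton
(`L-BFGS-B`) from multiple seeded starts with $s$ spanning 0.1–10 (the
parameter is scale-free and the surface can be multimodal); $\theta$ and
$\kappa$ are optimised on the log scale. Support is summarised by AICc
(sample size = total acquisition events) and Akaike weights; the summed
weight of all models containing a layer or ILV measures its support.
"Model-averaged medians" are computed as Akaike-weight-weighted medians
across the models containing a parameter (weights renormalised) — one of
two defensible readings of that phrase, and the one we label in the output.

95% intervals use profile likelihood: the set of parameter values whose
profile log-likelihood (all other parameters re-optimised) lies within
$\chi^2_{1,0.95}/2 = 1.92$ of the maximum. When the profile never crosses the
threshold within bounds — common for weakly identified transmission rates at
sites with few learners — that side is reported open rather than invented.

### Pathway decomposition

Because the hazard is a sum of an asocial component and one component per
layer, each observed acquisition event decomposes exactly:
$p_k(e) = s_k e^{\beta_S x_i} T_i^{(k)} / R_i$ and
$p_{\text{asocial}}(e) = e^{\beta_A x_i}/R_i$, each row summing to 1. The
mean of $p_k$ over events, $\times 100$, is the estimated percentage of
acquisition events attributable to social transmission through layer $k$
(%ST). Learners are classed `first_in_cohort` when no same-brood bird was
knowledgeable at their acquisition, else `subsequent`; per-class summaries
report both means and medians, since a median over strongly bimodal
per-event probabilities can sit far from the mean.

## Networks from detections

Gathering events are found per site-day by fitting 1-D Gaussian mixtures to
detection timestamps for $K = 1 \ldots \min(10, n)$ components (equal- and
unequal-variance families), selecting $K$ by BIC, and assigning detections
to their maximum-responsibility component (`mclust`). The model-based
hierarchical initialisation makes this deterministic. Associations use the
simple-ratio index, joint sightings / (joint + either-alone), per dyad over
the gathering events in the week before and after each acquisition event.
Birds with fewer than 10 feeder registrations over the whole study are
excluded as transients (a global, not per-window, filter). Each dyad belongs
to at most one layer by pedigree: juvenile–own-parent (vertical),
juvenile–other-adult (oblique), same-brood (sibling), different-brood
juveniles (peer); adult–adult dyads carry no transmission. Presence at an
event requires a feeder or puzzle registration at that event's site in the
previous 7 days.

Two data-preparation rules deserve mention. A bird is *knowledgeable* after
10 solves — a deliberately conservative threshold because perch antennas can
misattribute solver identity when several juveniles crowd the perch — while
its *acquisition time* is its 3rd solve, a compromise between noise
robustness and timing accuracy. Birds with 3–9 total solves are therefore
not treated as learners. Tied acquisition times are separated by 1 s in
recorded order, and all windows are half-open intervals $(t_0, t_1]$ to
avoid double-counting boundary events.

## Regressions

- **Exposure model.** One record per juvenile: learned (knowledgeable) or
  not, and $\log_{10}(\text{count}+1)$ of parental solves and scrounges from
  fledging to the juvenile's acquisition (learners) or to fledging + 15 d
  (non-learners; the typical latency until juveniles start solving). The
  estimator is a maximum-a-posteriori logistic regression under N(0, 10)
  (intercept) and N(0, 5) (slope) priors with Wald intervals from the
  curvature at the mode — the priors make the fit well-defined under complete
  separation. The log10 scale means an odds ratio is "per tenfold increase"
  in parental behaviour; zero counts are admissible.
- **Side choices.** One record per juvenile solve: the proportion and count
  of right solves by *other* birds at the site in the prior 5 minutes
  (social information), the juvenile's own right proportion in the prior
  hour (personal information), and its cumulative solve count (experience,
  scaled per 100 solves for interactions). The all-days model keeps only
  records with both information sources available and fits a mixed logistic
  regression with a juvenile random intercept (`lme4::glmer`); first-day
  models use the first solving calendar day. Parental strategy during
  dependence is classed none / nonconflicting right / nonconflicting left /
  conflicting by a strict 90% majority of parental solves.

## The synthetic generator

`scenario_config()` fixes the study conditions; every stochastic component
derives from its single seed. The defaults describe a desk-scale breeding
population: 4 puzzle-box sites, 12 pairs per site with clutches of 4–6,
fledging spread over 10 days, an 8-week diffusion, 2 feeder days per week
with 8 gathering events per day, and 2 knowledgeable demonstrator adults per
site with side restrictions. Gathering membership is family-biased
(inclusion probabilities 0.6 siblings > 0.35 parents > 0.12 others), which
reproduces the empirically observed ordering of association strengths
(sibling > parent–offspring > background). Solve rates are lognormal around
6 solves/day. True transmission rates default to sibling-dominant
($s = 600$ sibling, 6 oblique, 8 vertical, 0 peer, $\theta = 6000$ d),
chosen so that a quarter or so of the ~240 juveniles learn within the study
window, almost none asocially, with oblique/vertical seeding of broods and
rapid within-brood sibling cascades — the qualitative regime the field
system exhibits. Side choices follow a conformist-then-personal logistic
rule whose default odds ratios (social 19.5, personal 7.3, experience
interactions 0.76 and 1.22 per 100 solves) mirror the magnitudes such field
studies report.

The diffusion simulator is an exact event-driven sampler: between entry
points, waiting times are drawn by time-rescaling of the integrated baseline
(valid for constant and Weibull baselines alike), the learner is drawn
proportional to its rate, and the ground-truth pathway label is drawn
proportional to the hazard components. Because the likelihood integrates
exposure from each bird's entry time exactly, the simulator and the fitted
model agree without discretisation error — the parameter-recovery tests
exercise precisely this correspondence, free of network-estimation noise,
by fitting on the generator's true networks and rates
(`as_diffusion_data()`). The full stream path (re-clustered gatherings,
re-estimated weights) is exercised separately by the pipeline tests.

The puzzle stream emits learners' first three solves at their scheduled
acquisition time (+0/60/120 s) and tops their totals up to the knowledgeable
threshold, so `knowledge_states()` recovers the simulated schedule exactly;
the cost is that solve counts for late learners slightly exceed their
nominal Poisson rates. Scrounges are inserted within (0.5, 2] s of solves
with configured probability. Feeders and puzzle boxes run on a weekly
schedule in the field; the simulator lets the puzzle record every day, which
simplifies timing without affecting any tested property.

What the generator does *not* emulate: spatial movement and home-range
structure, mortality and dispersal (presence is driven by fledging only),
antenna misreads, inter-site floaters, and seasonal drift in association
preferences. Passing tests therefore demonstrate the *inferential machinery*
is correct under the stated generative assumptions, not that field data meet
those assumptions.

## Numerical choices

- **ILV transform.** The diffusion ILVs are $\log_{10}(\text{count}+1)$,
  centered by subtracting the learner-pool mean at the diffusion start.
  Counts enter through $\exp(\beta x)$, so raw counts in the hundreds
  overflow the rate for moderate $\beta$; the log scale matches the
  exposure regression's "per magnitude" convention.
- **Optimiser.** 5 starts by default (s ∈ {0.1, 1, 10} plus two jittered),
  `L-BFGS-B`, bounds $s \in [0, 10^7]$, $|\beta| \le 20$,
  $\kappa \in [0.05, 20]$; non-finite likelihoods are mapped to a large
  finite penalty so line searches cannot fail on them. The asocial scale is
  initialised at total at-risk exposure per event, which is its closed-form
  MLE in the asocial constant-baseline model.
- **Profile search.** Outward doubling from the MLE followed by
  root-finding on the profile deviance; 40 doublings without a crossing
  reports an open interval.
- **Degenerate inputs.** Single detections form singleton gatherings;
  zero-variance timestamp sets skip the mixture; dyads never co-observed get
  weight 0 (not missing) so matrices stay complete; empty network windows
  yield all-zero layers with a message; sites with fewer than 3 acquisition
  events are dropped from fitting; a single-juvenile random intercept falls
  back to a fixed-effects GLM with a warning.

## Problem sizes used by the test-suite

The validation studies run at desk scale, chosen to finish in minutes while
leaving the statistical checks sharp: parameter recovery uses 20 replicates
of the 4-site scenario with $s_{\text{sibling}} = 5$ and $\theta = 400$ d
(~40–70 learners each; the asocial scale calibrated so sibling-seeded and
asocial events both occur); the null study uses 20 replicates with all
$s_k = 0$ and $\theta = 200$ d; the next-learner Monte-Carlo check uses
10,000 single-event draws on a 1-site population; side-choice recovery uses
20 replicates of 200 juveniles × 4 solves with a stronger experience
interaction (OR 2 per 100 solves) than the field-scale estimate, since the
desk-scale record count is an order of magnitude smaller than the field
data's. The quadrature oracle uses a hand-built 10-bird, 6-event fixture
with all four layers, both ILVs, a mid-diffusion filtered adult, a presence
gap and staggered entries.

## Known limitations

- Networks are piecewise-constant between acquisition events; no
  continuous-time interpolation.
- The order-of-acquisition (OADA) variant and Bayesian NBDA are out of
  scope.
- The stream-path builder assigns each juvenile to a single primary site
  (most registrations); birds splitting time across sites are censored only
  at their primary site.
- Model-averaged medians across models (rather than bootstrap replicates)
  are reported; both readings are defensible and the output labels which is
  computed.
- With few learners per site, upper profile bounds for transmission rates
  are frequently open; this is reported honestly rather than truncated.
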