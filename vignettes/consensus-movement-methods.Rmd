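---
title: "Extracting and modelling shared movement decisions from group tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting and modelling shared movement decisions from group tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusmove)
```

## The problem

Cohesive animal groups — the motivating system is wild vulturine guineafowl
(*Acryllium vulturinum*), tracked with synchronous 1 Hz solar GPS tags —
reach consensus about where to move through many small leadership
interactions: one bird walks away (an initiation), and the rest either
follow or do not. Classic theory for collective motion makes two
quantitative predictions about how followers resolve conflicts between
simultaneous initiators: (i) followers should *compromise* (average the
proposed directions) when the angular disagreement between initiators is
small and *choose* one direction when it is large, with a critical angle
separating the regimes; and (ii) when choosing, followers should go with
the numerical *majority* of initiators. `consensusmove` implements the
full analysis chain that tests these predictions from raw trajectories,
together with the influence/dominance analyses that ask *who* leads.

The pipeline has five stages, each exposed as ordinary R functions:

1. **Preprocessing** (`read_trajectories`, `remove_outliers`,
   `interpolate_gaps`, `coverage_mask`): Movebank-style fixes are gridded
   per individual on a shared 1 Hz time base, gross outliers outside the
   study area are discarded, and single-second gaps are filled at the
   midpoint of the straight line between the flanking fixes. Longer gaps
   stay missing: dyadic computations at those seconds are skipped, never
   imputed.
2. **Dyadic initiation attempts** (`extract_attempts`): minima and maxima
   of each pair's distance series define attempts; the individual that
   moved most while the distance grew is the initiator, and the attempt is
   a *pull* (successful) if the other individual closed the gap, or an
   *anchor* (failed) if the initiator came back.
3. **Events** (`build_events`, `event_metrics`): attempts acting on the
   same candidate follower that overlap in time are merged by a chain rule
   into multi-initiator events; each event gets its initiators'
   directions, their agreement (one minus the circular variance of the
   unit vectors from follower to initiators), a success flag (at least one
   pull), and the follower's subsequent direction.
4. **Influence and dominance** (`influence_matrix`, `elo_ranks`,
   permutation tests): dyadic pull counts give the influence index
   $I_{ij} = (P_{ij} - P_{ji})/(P_{ij} + P_{ji})$; agonistic interactions
   give randomized-Elo dominance ranks; permutation tests relate the two
   and test for sex effects.
5. **Decision models** (`fit_follow_model`, `regime_classification`,
   `cluster_initiator_directions`, `majority_rule_fit`): the three
   headline inferences described below.

## Attempt extraction in detail

**Reversal filter.** The distance series between a dyad is reduced to an
alternating min/max sequence by a reversal ("zigzag") filter: an extremum
is emitted once the series has moved more than `min_change` away from the
running extremum in the opposite sense. Consecutive extrema therefore
differ by more than the threshold, which is exactly the semantics of the
minimum-change criterion; on test instances the filter provably emits the
maximal alternating sequence (the test suite checks this against a
dynamic-programming enumeration). The default `min_change` is 3.5 m — the
study system's setting, chosen in the field to sit above the tags'
relative position error (within 1 m, 95% of the time) while matching the
small spatial scale of guineafowl movements.

**Plateau handling.** A stationary dyad sits on a long near-constant
stretch of the distance series, and the literal arg-min of such a plateau
is an arbitrary (noise-selected) sample. Displacement windows anchored
there can reach back across unrelated earlier movements and misattribute
the initiator. We therefore resolve each extremum to a plateau interval:
all samples within `plateau_slack` of the extremal value between the
neighbouring extrema. An attempt's first segment runs from the *end* of
the preceding minimum plateau to the *first* arrival at the maximum, and
its second segment from the end of the maximum plateau to the first
arrival at the closing minimum. The slack defaults to `min_change`
itself, on the filter's own logic that a change smaller than the
threshold is not movement; distances $d_1, d_2, d_3$ are always taken at
the true extremal samples, so the retention criteria are unaffected. For
marginal attempts whose amplitude is close to the threshold the slack
bands can overlap; the windows then fall back to the extremal samples.

**Classification and scores.** Displacements are net Euclidean (end minus
start), not path length, which would inflate with GPS jitter. The
initiator is the individual with the larger net displacement over the
first segment; exact ties are rejected (`"tie"`), as are attempts with a
missing fix at a window endpoint (`"missing_fix"`). Disparity is the
geometric mean over the two segments of $|d_a - d_b| / (d_a + d_b)$: 0
when both individuals moved equally, 1 when one did all the moving.
Strength is the geometric mean of $(d_2 - d_1)/d_2$ and $(d_2 - d_3)/d_2$:
near 0 for small changes relative to the dyadic distance, 1 when the
change spans the whole distance. Retained attempts need
$\min(d_2-d_1,\, d_2-d_3) > 3.5\,$m, disparity $\ge 0.1$ and strength
$\ge 0.1$. The disparity/strength aggregation (geometric mean across
segments) satisfies the endpoint behaviour that defines the scores;
other aggregations consistent with those endpoints exist, and
bit-compatibility with other implementations is not claimed.

**Chain rule.** Events are connected components of the interval-overlap
graph of attempts on one follower, with *strictly positive* overlap
required: consecutive attempts on a dyad share, by construction, the
minimum between them, and a shared endpoint alone must not chain a
follower's entire day into one event. Events that touch any second where
fewer than the coverage fraction (default 0.5; 0.8 as the robustness
setting) of the group's tags were recording are dropped entirely —
conservative, but immune to composition artefacts.

**Direction conventions.** Angles are radians, counterclockwise from east
(+x); tables report degrees. An initiator's direction is the vector from
the follower's position at the attempt's start (t1) to the initiator's
position at maximal separation (t2) — the attempt's maximal-separation
geometry; `reference = "t2_t2"` takes both at t2 instead. An initiator
with several attempts in one event contributes its most recent attempt
(one vector per initiator, since agreement is over initiators). The
follower's direction is its net displacement over the earliest pull's
closing segment.

## The three decision analyses

**Follow model.** Whether the candidate follower was pulled (1) or
anchored (0) is modelled as a binomial-logit marginal model in the number
of simultaneous initiators, their agreement, and the interaction. Events
already pool simultaneous initiations, so no autocorrelation structure is
used; the model is the independence-working-correlation marginal model,
fitted as an ordinary binomial GLM with cluster-robust (sandwich)
standard errors clustered on follower identity. With one event per
follower this collapses exactly onto the plain logistic fit. Optional
covariates (tracked fraction, initiator–follower distance) support
robustness analyses. Complete separation is detected and flagged rather
than hidden: small scripted datasets can be separable, and the
coefficients are then explicitly marked unreliable.

**Compromise versus choose.** Successful two-initiator events are placed
in a symmetric frame: the frame is rotated so the two initiator
directions sit at $\pm\theta/2$ about zero, and the follower's direction
is measured there — compromise predicts mass near 0, choosing predicts
modes near $\pm\theta/2$. Events are pooled into 12° bins of
disagreement $\theta$ and each bin is labelled by two tests at
$\alpha = 0.05$:

* a **dip test** of non-unimodality. The Hartigan–Hartigan dip statistic
  is computed exactly by an equivalent convex/concave-hull construction:
  for every candidate mode, the one-sided band gaps between the empirical
  cdf and its greatest convex minorant (left) / least concave majorant
  (right) are evaluated, and the dip is half the smallest worst-case gap.
  The implementation is validated against hand-derivable exact values
  (e.g. 1/4 for two balanced point masses, $1/(2n)$ for equally spaced
  points). P-values are Monte-Carlo. For linear data the classic
  least-favourable uniform null is available, but it is known to be very
  conservative for peaked samples; for the circular regime analysis we
  calibrate instead against a von Mises null with concentration fitted to
  the sample (a parametric bootstrap), after rotating the sample so its
  circular mean sits at zero (otherwise linearisation splits the mode at
  $\pm\pi$). So calibrated, the test holds close to its nominal level on
  unimodal von Mises data (about 0.05 at $n = 100$, $\kappa = 2$).
* a **converging-modes test** of whether followers are *more* unimodal
  than they would be if they always chose one of the two initiator
  directions. The null is a balanced two-component von Mises mixture at
  $\pm\theta/2$ with a shared concentration fitted by maximum likelihood
  to the bin's angles. The statistic is the mean resultant length of the
  observed angles — continuous, exactly invariant under rotation and
  mirror reflection, and monotone in "concentration on a single
  direction". (A mode-separation statistic from a kernel density estimate
  was considered and rejected: it has an atom at zero whenever the
  estimate is unimodal, which destroys the test's resolution precisely in
  the compromise regime.)

A bin is *compromise* if it is not significantly non-unimodal **and**
significantly more unimodal than the two-mode null; *choose* if the
reverse pair holds; anything else is *transition*, and bins with fewer
than 10 events are reported as `insufficient_data`. The transition range
runs from the upper edge of the last pure-compromise bin to the lower
edge of the first pure-choose bin above it; an isolated choose flag below
a later compromise bin is treated as the false positive it almost surely
is. At small disagreement the two hypotheses coincide (the two-mode null
is itself nearly unimodal), so the smallest bins are intrinsically
unresolvable and tend to be labelled transition — a resolution limit of
the question, not of the implementation.

**Majority rule.** Events with two or more pulling initiators have their
pullers' directions clustered with a von Mises mixture fitted by EM
(20 restarts, concentrations capped at 100 so singleton clusters stay
finite), the number of components chosen by BIC among $k \in \{1,2,3\}$
(capped at the number of directions). A circular mixture is used
deliberately: a Euclidean mixture on raw angles splits clusters that
straddle ±180°. Two-cluster events enter the majority analysis: cluster 1
is relabelled at random per event (so its identity carries no
information), the follower's chosen cluster is the one whose mean is
nearer its direction, and $P(\text{choose cluster 1})$ is fitted by
weighted nonlinear least squares as a one-parameter logistic in
$n_1 - n_2$, constrained through (0, 0.5) by construction. Per-difference
95% intervals use the uniform-draw procedure: for a difference observed
in $n$ events with empirical probability $p$, draw $n$ uniform variates,
record the share at or below $p$, repeat 1000 times, and take the
2.5th/97.5th percentiles. The summary quantity `dn80` is the difference
at which the fitted curve reaches 0.8, i.e. $\log(4)/\hat\beta$.

## Influence, dominance, and the permutation tests

The influence index is antisymmetric by construction and undefined (kept
`NA`, never imputed as 0) for dyads with no events; influence ranks order
the row sums of defined entries. Successful-initiation rates divide each
individual's pull-event count by its *tracked* hours (tags differ in
uptime); calendar hours are available as an option. Dominance comes from
randomized Elo (K = 100, initial score 1000, logistic scale 400,
1000 random orderings by default — the update's standard parameters,
exposed as configuration), with hierarchy stability summarised by
split-half Spearman repeatability over random order-splits.

The permutation tests follow the field's reporting convention exactly:
the reported `p` is the share of randomized statistics *larger* than the
observed one, so a rank-alignment statistic significantly close to zero
shows up as `p >= 0.95`; each result also carries a `significant` flag at
the chosen level, with the orientation handled internally (the
mixed-sex two-puller test is one-sided for a male advantage). Because
rank statistics are discrete, each result additionally carries
`p_uniform`, a tie-randomized variant that is exactly uniform under the
null; the calibration tests use it, the reported convention stays as the
headline number. Within-sex variants re-rank both hierarchies inside the
subset before comparing. Ties in ranks use average ranks throughout
("dense" ranks would distort the absolute-difference statistic).

## The synthetic generator

`simulate_group()` produces a tracking day with *known* ground truth so
every pipeline stage has a recoverable target. Its design choices mirror
the study system:

* **Formation**: agents hold offsets within ~1.5 m of the group centroid
  (guineafowl groups are tightly cohesive), with slow AR(1) jitter
  (SD 0.15 m) around them.
* **GPS error**: each tag's 2D error vector has RMS `gps_noise_sd`
  (default 0.5 m, consistent with field-tested relative accuracy within
  1 m at 95%) and drifts with a ~50 s AR(1) time constant. The drift
  matters: white per-second error of the same magnitude produces
  single-sample relative excursions that a 3.5 m threshold was never
  meant to face, whereas real 1 Hz GPS error is strongly autocorrelated.
* **Episodes**: scripted initiations separated by at least 60 s of
  quiescence. Single-initiator episodes plant a pull (initiator walks
  10 m out, the group translates to it) or an anchor (the initiator
  returns). Two-initiator (or two-cluster) episodes plant directions at
  $\pm\theta/2$ about a base bearing with a 40 m displacement; the
  follow decision is drawn from the planted logit
  $0.6 - 0.8k + 0.5A + 1.2kA$ (k initiators, agreement A), and followers
  respond by compromising along the bisector below the planted 100°
  transition angle or choosing a cluster with probability
  $\mathrm{logistic}(\beta (n_1 - n_2))$, $\beta = \log(4)/4$, above it;
  mixed-sex two-puller contests go to the male with probability 0.55.
  Follower directions get von Mises noise with $\kappa = 20$ (~13°
  scatter). Unsuccessful initiators give up at the decision point and
  chase the moving formation — which is also what makes the method
  record them as anchors rather than attributing the initiation to the
  departing group.
* **Interactions**: winners of agonistic interactions are drawn by a
  logistic in the latent score difference, males above all females, with
  steepness 10 (steep, near-transitive) by default.

With zero noise and missingness, single-initiator schedules are
recovered exactly (identity, outcome, and timing to within the window
convention's few-second offsets). Multi-initiator episodes additionally
generate genuine secondary attempts (the travelling group "pulls" its
waiting initiators when they rejoin), which are real consequences of the
method's definitions and are deliberately not enumerated in the truth
table. What the generator does **not** emulate: continuous background
travel (real groups forage while moving, so real distance series have no
long flat plateaus), habitat structure, inter-group encounters, or
tag-specific duty cycling. Passing recovery tests therefore demonstrates
the correctness of the extraction machinery under controlled kinematics,
not field-readiness of any particular threshold choice.

Event-level generators (`sim_follow_events`, `sim_two_initiator_frame`,
`sim_cluster_choice`, `sim_mixed_puller`) draw directly from the planted
statistical models, providing the sample sizes the inference stages need
(thousands of events) without simulating kinematics. The trajectory and
event-level generators share one set of planted parameters — the study
conditions — and those defaults are not tuned per analysis.

## Numerical choices and degenerate inputs

* Geographic coordinates are projected to a local equirectangular
  tangent plane about the study-area centroid (exactly invertible;
  sub-centimetre distortion at the few-kilometre scale of a group's
  range). Planar input is accepted directly.
* Sub-second timestamps are rounded to the grid with a warning; unknown
  ids are skipped with a warning; unparsable timestamps are an error
  naming the row. Grids are split per group and per UTC day, so no event
  can span days.
* The von Mises concentration is estimated by root-finding on the Bessel
  ratio $A_1(\kappa) = R$ (exponentially scaled Bessel functions keep
  large $\kappa$ finite); $\kappa$ is capped at 500 for estimation and
  100 inside mixtures.
* EM restarts are seeded from random data points; components that empty
  out abort the restart. BIC counts $3k - 1$ parameters.
* Monte-Carlo null tables for the dip test are cached per sample size
  (and per 0.25-rounded fitted concentration for the circular variant)
  within a session; p-values use the add-one convention
  $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{sim}} + 1)$.
* Zero-length direction vectors drop the initiator (with a message);
  successful events with zero net follower displacement get `NA`
  direction and leave the regime analyses; a majority fit with all
  cluster differences zero is reported as undefined rather than fitted.
* All stochastic steps (permutations, bootstrap, EM restarts, cluster
  relabelling, generators) run off the caller's RNG state; `run_pipeline`
  seeds it once from its configuration, making reruns byte-identical.

## Problem sizes

The bundled analyses and tests run at sizes chosen to make every
inference demonstrably recoverable on a desk machine: one scripted
tracking day of 10 agents (~3000 s, ~300 planted attempts), 5000 events
for the follow model, 2000 two-initiator events over 15 disagreement
bins for the regime classification, 3000 two-cluster events for the
majority rule, 500 replicate datasets for the calibration checks, and
1000 permutations/bootstrap draws for the tests (the paper-scale
default). The headline field-study quantities (hundreds of thousands of
leader–follower cases) require the original GPS dataset and are outside
the package's scope; nothing in the implementation depends on scale
beyond linear memory in fixes and dyads.

## Known limitations

* The disparity/strength aggregation and the direction reference times
  are defensible choices within verbally specified contracts; other
  implementations may differ in detail. Both are configurable where the
  ambiguity matters.
* The dip test's circular calibration uses a fitted von Mises null; for
  strongly skewed or heavy-tailed unimodal alternatives its level is not
  guaranteed to be nominal.
* Attempt windows carry a few seconds of convention-dependent offset
  (the plateau slack divided by movement speed), so planted-time
  comparisons use an 8 s tolerance rather than exact equality.
* The chain rule is temporal only; a spatial criterion for grouping
  attempts is deliberately out of scope.
* With very few initiators per event the BIC choice among mixture sizes
  is coarse; events whose pullers do not form exactly two clusters are
  simply excluded from the majority analysis, as intended.
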