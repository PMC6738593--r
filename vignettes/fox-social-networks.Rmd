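---
title: "Association networks from camera-trap detections: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association networks from camera-trap detections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxsna)
```

`foxsna` infers social structure in territorial canids from camera-trap
detections at provisioned food patches, and asks three questions of such
data: do individuals have preferred and avoided companions, do they
associate in communities that match territorial space use, and how long do
relationships last? This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## From detections to associations

A detection is one identification of one individual at one patch at one
time. Detections are clustered into *patch visits* (`cluster_visits()`):
within a patch, a gap of more than `gap_minutes` between consecutive
detections starts a new visit. The default of 10 minutes is a stand-in —
the right value depends on camera trigger behaviour and should be set from
knowledge of the hardware; results in this package's own analyses are not
sensitive to values between 5 and 20 minutes because co-visits are emitted
within a two-minute window.

Associations follow the *gambit of the group*: every pair of individuals
sharing a visit is taken to associate. The sampling period is a
noon-to-noon day (`assign_sampling_day()`, half-open interval), because the
study animals are nocturnal (active roughly 20:00–04:00), so one night of
activity falls inside one period. Dyadic association is binarised at the
day level: however many co-visits a dyad shares in one night, it counts
once, because the association index is defined over sampling periods.

The *simple ratio index* for a dyad (A, B) is

$$\mathrm{SRI}_{AB} = \frac{x}{x + y_{AB} + y_A + y_B}$$

where, over sampling periods, $x$ counts days associated, $y_{AB}$ days
both identified but not associated, and $y_A$, $y_B$ days only one was
identified. Dyads whose denominator is zero are *masked*, not set to zero:
"never identified together on any common day" is lack of data, not
evidence of avoidance. Masked dyads are excluded from all downstream
summary statistics by default; this matters for the permutation tests, and
both behaviours can be obtained by operating on the exported matrices.
Individuals seen on fewer than `min_days = 5` distinct days are excluded;
the scope of this filter is per survey (territory × season) for the
seasonal networks and whole-study for the pooled network, which is why the
two kinds of network can retain different rosters.

## Social differentiation and power

Latent dyadic association probabilities are modelled as Beta-distributed;
observed counts are then beta-binomial, $x_{ij} \sim
\mathrm{BetaBin}(d_{ij}, \mu, S)$, where $S$ — the coefficient of
variation of the latent probabilities — is the *social differentiation*.
$S < 0.2$ marks a poorly differentiated society, $S > 0.8$ a strongly
differentiated one. The likelihood is maximised on (logit mean, log CV)
coordinates from three starts; if the binomial limit ($S = 0$) beats the
interior optimum, $S = 0$ is reported. The *power* $r$ — the correlation
between true and estimated indices — is computed by Monte-Carlo from the
fitted model: draw latent probabilities from the fitted Beta at the
observed denominators, draw counts, and correlate. The original
closed-form approximation for $r$ is not restated in the literature we
implement from, so the simulation estimator is the package's documented
convention; at the fixture sizes used in the tests the two agree to well
within the bootstrap error. Standard errors come from resampling sampling
days with replacement (days are the independence unit), 100 replicates by
default.

## Preferred and avoided companions

Two Markov-chain permutation tests, both operating within days:

* **Group swaps** (`permute_groups_within_days()`): a checkerboard swap
  picks two same-day groups and two individuals, each present in exactly
  one of them, and exchanges them. Group sizes and each individual's
  number of groups per day are conserved; gregariousness is not. Isolates
  are excluded (the method is sensitive to them). Three statistics are
  saved per permutation: the CV of the SRI (right tail; high CV = long-term
  preferred *and* avoided companions), the mean SRI (left tail; low mean =
  short-term, within-day preferences), and the SD across individuals of the
  mean number of conspecifics encountered per day (right tail; individual
  gregariousness differences).
* **Association swaps** (`permute_associations_within_days()`): two
  same-day day-level dyadic records with four distinct individuals exchange
  partners, conserving each individual's daily association count. This
  controls for gregariousness — rejections cannot be an artefact of some
  individuals simply being more sociable — but detects only long-term
  (between-day) structure and needs more data. Isolates are retained.

Both chains are cumulative: after one burn-in block, `trials` swap
attempts (default 1000) separate saved statistic evaluations, and `n_perm`
(default 5000) states are saved. The proposal is uniform-with-rejection:
an illegal candidate is discarded and counts as an attempt. p-values use
the add-one convention, $(1 + \#\{\text{null at or beyond observed}\}) /
(1 + n_{perm})$, so they are never exactly zero, and significance is
reported at both 0.05 and 0.1. A network with no legal swap is reported as
"too sparse to permute" rather than given a fabricated p. The chains are
implemented in C++; the calibration experiments in the test suite (200
replicates × 500 permutations) would not be feasible in pure R.

## Communities

Modularity of a labelled division is computed against the weighted
configuration null,

$$Q = \frac{1}{2W}\sum_{ij}\left(A_{ij} - \frac{s_i s_j}{2W}\right)
\delta(c_i, c_j),$$

with $s_i$ the SRI row sums and $2W$ the total weight; the null term keeps
its diagonal, so a single community scores exactly zero. Because the
expected weight is proportional to $s_i s_j$, the null preserves
individual gregariousness. The exact form of the gregariousness control
used by the original SOCPROG implementation is not published; this
standard weighted-configuration form is validated by self-consistency
(exhaustive-search tests) rather than against any published Q value.

`eigenvector_communities()` recursively bisects by the sign of the leading
eigenvector of the (generalised) modularity matrix, then refines with
Kernighan–Lin-style moves: greedy single-vertex moves between communities,
community merges, pairwise membership exchanges, pair relocations and —
for groups of at most 20 — triple relocations, run from both the bisection
result and an all-singletons start (plus a few deterministic randomised
starts on small graphs). On hundreds of random instances with $n \le 8$
this optimiser attains the brute-force maximum exactly; the recursion
alone can stall well short of it on weakly structured graphs.
`average_linkage_communities()` clusters on dissimilarity
$\max(\mathrm{SRI}) - \mathrm{SRI}$ and cuts the dendrogram at the level
maximising Q. Following standard practice for these data, a division with
$Q < 0.3$ is not considered useful and collapses to one community; the
method with the higher Q is selected when both are run
(`detect_communities()`). Individuals with no unmasked positive edge are
labelled `"unassigned"` and excluded from the optimisation but retained in
exports.

Supporting diagnostics: `community_mantel()` correlates the SRI matrix
with the within/between-community indicator under label permutation, and
reports both the convention in which a *high* p supports
within-community preference and the usual upper-tail p;
`spatial_profile()` gives each community's percentage of patch visits per
territory; `patch_use_network()` rebuilds the SRI with association
redefined as same-patch-same-day co-occurrence (a superset of true
co-occurrence — the spatiotemporal $x$ is elementwise at most the
patch-day $x$); `seasonal_consistency()` matches communities across
seasonal partitions by greedy maximum membership overlap (ties to the
smaller community id) and reports per-individual assignment stability.

## Temporal stability

The *lagged association rate* (LAR) estimates the probability that a dyad
associated on day $d$ associates again on day $d + \tau$, given both
members were identified on day $d + \tau$. The estimator pools (dyad, day
pair) events within each lag bin as a ratio of sums; the alternative of
weighting each dyad equally is noted but not implemented. Bins are
integer days to lag 40 and logarithmically widened beyond (configurable
and recorded in the output). Empty bins are reported with `n_pairs = 0`.
Errors are leave-one-day-out temporal jackknife,
$\mathrm{SE} = \sqrt{\frac{m-1}{m}\sum_i(\hat\theta_{(i)} -
\bar\theta)^2}$.

The *null association rate* (NAR) is the LAR expected under random partner
choice given observed gregariousness. For individuals $i, j$ both seen on
day $e$, with $a_i(e)$ distinct associates among $n_e$ individuals seen,
the package uses

$$P_{ij}(e) = \min\!\left(1, \frac{a_i(e)\,a_j(e)}{(n_e - 1)\,\bar a(e)}
\right),$$

averaged over the LAR denominator events. This closed form is exact at
saturation (everyone associates with everyone: NAR = 1) and exact in
expectation under homogeneous independent association; against
heterogeneous data it is validated within Monte-Carlo error against a
partner-swap permutation oracle in the test suite. LAR above NAR at a lag
indicates non-random (preferred) association at that time scale.

The *lagged identification rate* (LIR) is the demographic baseline: the
probability that an individual identified on day $d$ is the one identified
on day $d + \tau$, estimated as same-individual pairs over all
identification pairs. A closed population of $N$ fully detected animals
gives $1/N$ at every lag.

Exponential decay families are fitted to both curves by binomial
likelihood over the per-bin (events, successes) counts. LAR families:
constant; single exponential; exponential + constant; two exponentials;
two exponentials + constant. LIR families: closed; emigration + mortality
($e^{-\delta\tau}/N$); emigration + reimmigration; and the full model
$e^{-\delta\tau}\,(1/N)\,(\lambda_r + \lambda_e e^{-(\lambda_e +
\lambda_r)\tau})/(\lambda_e + \lambda_r)$, parameterised by $N$, mean days
in and out of the study area, and daily mortality. Starting values follow
the convention of 0.5 on the natural scale, with perturbed restarts on
non-convergence; a family that still fails is flagged and dropped from the
ranking, never fabricated. Ranking is by QAIC with the overdispersion
$\hat c$ taken once from the most general family (Pearson statistic over
residual df, floored at 1) and shared across candidates; the top two
models are both reported when $\Delta\mathrm{QAIC} < 2$.

Fitted LAR components are interpreted as relationship classes: a constant
term is the proportion of permanent companionships, each exponential term
a casual-acquaintance class with proportion equal to its weight and mean
duration $1/\lambda$, and the deficit $1 - g(0^+)$ the proportion of rapid
disassociations (not outlasting one sampling period). Durations longer
than the observed lag range are extrapolations and flagged as such;
`class_proportions()` counts such components as permanent, since a
constant is the $\lambda \to 0$ limit of an exponential and the two are
not distinguishable at the scale of the data. Parameter SEs from the
quasi-binomial Hessian understate LIR uncertainty badly — every day pair
reuses the same individuals, and demographic stochasticity dominates — so
`lir_bootstrap_se()` resamples whole identification histories.

## Comparing matrices across seasons

`match_matrices()` restricts two networks to their shared individuals
(at least three required). `mantel_test()` correlates off-diagonal
entries under simultaneous row-and-column permutation; `"mantel_z"` is the
Pearson statistic, `"dietz_r"` ranks the off-diagonal entries of each
matrix first, which tames extreme values. Whether the original analyses
were one- or two-sided is not stated in the source literature; both tails
are always reported, with the two-sided p as the default and a one-sided
option used by the seasonal stability report. The repeated-run convention
(three runs of 10,000 permutations, mean p) is provided for parity by
`mantel_repeated()`, but the single-run add-one p is the default because
averaging p-values has no added inferential content.

Fisher's omnibus statistic $-2\sum\ln p \sim \chi^2_{2k}$ combines
independent p-values and is additive over disjoint sets — combining the
per-territory statistics and summing them give identical results, which is
the arithmetic identity the acceptance checks exercise on the bundled
published reference table. `seasonal_stability_report()` tests all
within-territory season pairs with both statistics, groups them by the
time difference between seasons (1 = consecutive, 2 = one season apart,
3 = two apart), and combines the Dietz-R p-values per territory, per time
difference, and across territories.

## The synthetic generator

No raw detection data are deposited for the study this package
re-implements, so `simulate_population()` generates detection tables with
known latent structure; every downstream stage is tested against that
truth. The default configuration *is* the emulated study design: seven
territories with four patches each, four 40-day seasonal surveys separated
by 50-day gaps, a dominant pair plus three subordinates of each sex per
territory, nightly activity 20:00–04:00, solo visits at 1.5 per night,
dyadic propensities with mean 0.1 and CV 1.25 within territories (the
planted social differentiation, matching the strongly differentiated
society the method family was built for) and mean 0.02 between adjacent
territories (extra-territorial visitors; intrusion rates are not
quantified by season in the source, so this is a documented free
parameter), log-normal gregariousness (sd 0.4) multiplying both visit
rates and dyadic propensities, 30% of dyad propensities redrawn at each
season boundary (relationship turnover — without it the pooled LAR does
not show the within-survey-high / between-survey-low pattern that real
gap-structured surveys produce, because survivorship alone *raises*
cross-gap re-association among persisting dyads), and per-day mortality
0.002 and dispersal 0.001.

Two deliberate modelling choices deserve emphasis. First, the latent
dyadic value is a *Poisson rate* of nightly co-visits, not a Bernoulli
probability: a dyad can meet twice in one night. Forbidding repeats is
itself a within-day avoidance pattern that the day-binarised permutation
statistics correctly detect, so a Bernoulli null scenario is *not* null
with respect to the margin-preserving swap chains. For small rates the two
parameterisations coincide; the day-level association probability is
$1 - e^{-\text{rate}}$. Second, gregariousness multiplies dyadic
propensities as well as visit rates: with explicit dyad-level co-visit
draws, a visit-rate-only multiplier would leave association rates
homogeneous and give the gregariousness statistic nothing to detect.

`scenario()` provides fixed presets: a homogeneous null
(`random_association`), a gregarious-but-unselective population
(`gregarious_unselective` — the type-1-error trap the association-swap
variant exists to avoid), strong dyadic preferences
(`preferred_companions`), three well-separated territories
(`planted_communities`), seasonal surveys with elevated turnover
(`demographic_turnover`), and planted relationship duration classes
(`permanent_plus_casual`) whose association events split roughly 33%
permanent / 14% casual (mean 20 days) / 53% single-day. The null and
class presets use diffuse patch layouts (20 and 60 patches): at dense
patches, unrelated visits merge by time coincidence, which both injects
non-null day-level structure into the calibration scenario and dilutes the
planted class shares. The `recruitment = "replacement"` mode keeps the
population constant by giving each death a fresh-id successor in the same
social position; this is the demographic regime the LIR mortality models
assume, and the regime in which the mortality hazard is identifiable at
all — with pure attrition the pooled LIR is flat in lag, because
numerator and denominator shrink together.

What the generator does *not* emulate: image-level identification error,
camera failure, spatially explicit movement, social bias in patch quality
use, overlapping communities, and any within-night temporal structure
beyond uniform visit times. Passing tests therefore show that the
estimators recover planted structure of the kinds described above; they do
not show robustness to identification error or detection heterogeneity,
which the simple ratio index assumes away by design.

## Problem sizes, tolerances and reproducibility

The test suite runs the heavy experiments at deliberately chosen sizes:
permutation calibration uses 200 replicates of a 12-individual, 30-day
null survey at 500 saved permutations with 400 swap attempts between
saves (the production default stays at 5000 × 1000); power uses 100
replicates of the preference scenario; community recovery uses 20
replicates plus 100 exhaustive-search comparisons at $n \le 8$;
differentiation recovery uses 50 replicates of 300 dyads at 40 days;
decay-model selection uses 50 curve-level replicates per family and 20
full-pipeline replicates of the class scenario. Calibration is asserted
against the binomial 95% interval around the nominal 0.05 level, and
recovery criteria use the tolerances stated with each test.

All stochastic functions take explicit seeds and restore the caller's RNG
state, so a fixed seed reproduces any result byte-for-byte, including
simulated CSV exports and whole report bundles. Numerical edge cases are
handled explicitly rather than by propagating NaN: masked dyads, d = 0
denominators, degenerate (unswappable) networks, all-zero count tables,
constant matrices in Mantel tests, and zero p-values in the omnibus
combination (rejected, since add-one permutation p-values cannot be
zero).

## Known limitations

The beta-binomial differentiation model ignores group-size structure (a
negative-binomial alternative is out of scope). The NAR closed form is an
approximation validated empirically, not a derived conditional
expectation under the swap null. The LAR estimator pools pair-days, so
highly observed dyads carry more weight; the dyad-weighted alternative is
not implemented. Mean relationship durations that exceed the observed lag
range — including any projection of permanent-companionship length — are
extrapolations under the fitted model, not measurements. Finally, the
permutation chains cannot condition on sighting location, so spatial
confounding of association (shared patches rather than shared company) is
addressed only descriptively, through the patch-use network comparison.
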