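# foxsna

Social network analysis of camera-trap detections in territorial canids.

Camera traps at provisioned food patches record timestamped
identifications of known individuals. From such detection tables, this
package infers and tests social structure the way behavioural ecologists
analyse fission–fusion societies: who associates with whom, whether those
associations are social preferences or chance aggregations at shared
resources, whether the population divides into communities that match
territorial space use, and how long relationships last. It was built for a
study system of urban red foxes — seven territories, each surveyed by
always-on cameras for 40 days in four consecutive seasons — and ships a
synthetic detection generator with planted social structure that stands in
for the (undeposited) field data, so every estimator is testable against
known truth.

## What it computes

* **Associations.** Detections are clustered into patch visits; the
  *gambit of the group* makes every pair sharing a visit an association.
  Sampling periods are noon-to-noon days. Dyadic association strength is
  the simple ratio index, `SRI = x / (x + y_AB + y_A + y_B)` over sampling
  periods; dyads never observed on a common day are masked, not zeroed,
  and individuals seen on fewer than 5 days are excluded.
* **Social differentiation and power.** Beta-binomial maximum likelihood
  gives `S` (the CV of the latent association probabilities; `S > 0.8` is
  a strongly differentiated society) and `r` (correlation between true and
  estimated indices), with day-bootstrap standard errors.
* **Preferred/avoided companions.** Manly/Bejder Markov-chain permutation
  tests (in C++): group swaps within days (long-term CV, short-term mean,
  gregariousness SD) and association swaps within days (gregariousness-
  controlled CV), with add-one p-values and explicit "too sparse to
  permute" handling.
* **Communities.** Leading-eigenvector and average-linkage modularity
  maximisation under a gregariousness-preserving null, the `Q < 0.3`
  collapse rule, within/between Mantel diagnostics, spatial profiles,
  same-day patch-use networks, and cross-season assignment consistency.
* **Temporal stability.** Lagged association rate vs the null association
  rate, lagged identification rate, exponential decay model families
  fitted by binomial quasi-likelihood with QAIC selection and temporal
  jackknife errors, interpreted as permanent / casual / rapid
  relationship classes.
* **Season comparisons.** Matched-matrix Mantel z and Dietz R permutation
  tests, combined with Fisher's omnibus method
  (`-2 Σ ln p ~ χ²(2k)`).

## Worked example

The `analysis/` directory holds the numbered workflow. `01_simulate.R`
generates the default synthetic survey (seven territories, four 40-day
seasonal surveys); the later scripts analyse it and write flat CSVs under
`results/`. Running them in order prints, among other lines:

```
simulated 16448 detections of 56 individuals at 28 patches
28 seasonal networks (7 territories x seasons)
pooled differentiation S = 2.36 (strongly differentiated), power r = 0.97
long-term companionships (group-swap CV): 16/28 at 0.05, 18/28 at 0.1
eigenvector: 4 communities, Q = 0.527; average-linkage: 7, Q = 0.513
within > between: correlation 0.486, t = 19.6, p(high) = 1.000
LAR at lag 1: 0.201; NAR: 0.047 (non-random associations)
survey-gap artefact: within-survey mean 0.211 vs between-survey 0.181
relationship classes (planted 33/14/53): permanent 34%, casual 9%, rapid 57%
consecutive seasons combined: chi2 = 212.37, df = 42, p = 1.3e-24
```

Reading those numbers: the pooled network is strongly differentiated
(most dyads never meet, a few associate often), over half the seasonal
networks show significant long-term companionships by the group-swap CV
test, community detection recovers territory-scale structure (a high
within-community Mantel correlation with `p(high) ≈ 1` under the
convention where high p supports within > between), the lagged
association rate sits far above the random-association baseline and sags
at between-survey lags (the gap artefact of seasonal survey designs), and
the decay-model decomposition recovers the planted mix of permanent,
casual and single-day relationships. The equivalent computations are
available programmatically through `run_pipeline()`.

A minimal in-R session:

```r
library(foxsna)
sim <- scenario("planted_communities", seed = 1)
groups <- extract_groups(cluster_visits(sim$detections))
m <- simple_ratio(tally_dyads(groups))
detect_communities(m)$selected
#> Partition (eigenvector): 3 communities, Q = 0.575
```

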