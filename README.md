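# camtrapnets

Social networks and observer-agreement statistics from two-channel
camera-trap annotations.

## The problem

Camera traps record short videos of animals that live in fission–fusion
societies: a stable community whose members travel in temporary parties of
varying size and composition. When the same footage is annotated by two
independent observer channels — say, experienced researchers and a
consensus-based citizen-science platform that confirms an individual ID
only when at least three annotators agree with no dissent — two questions
follow:

1. **Agreement** — do the channels see the same thing? Per-video counts,
   individual-ID assignment rates, ID agreement, and Cohen's κ.
2. **Networks** — if each channel's identifications are turned into an
   association network, do the networks agree on social structure?

`camtrapnets` implements the full pipeline. Videos at the same camera
within 15 min chain into *events*; under the gambit of the group, all
individuals identified in an event form one party; dyadic association is
the simple ratio index

SRI(A,B) = x / (x + y_AB + y_A + y_B),

the fraction of sampling units in which a pair was together. Networks are
then compared via leading-eigenvector community detection on the weighted
modularity matrix, MRQAP with double semi-partialling (Dekker et al. 2007,
t-statistic pivot, node permutations of the residualized predictor),
Spearman-correlated node strength and eigenvector centrality, and a
subsampling robustness curve (estimated networks at increasing event
counts, rank-correlated with the complete network, with bootstrap 95%
CIs). A seeded fission–fusion simulator generates ground-truth communities
and both imperfect observation channels, so every stage is testable with
no field data.

## Worked example

```r
library(camtrapnets)

dat <- simulate_community(sim_config(n_events = 200, seed = 42))
#> camera-trap dataset: 36 individuals, 200 events, 347 videos, 6914 detections (both channels)

ev     <- group_events(dat$videos)
roster <- select_shared_roster(dat$detections)   # weaned, seen in both channels
net_ex <- build_network(gambit_party(ev, dat$detections, "expert"),  roster)
net_cz <- build_network(gambit_party(ev, dat$detections, "citizen"), roster)

leading_eigenvector_communities(net_ex)
#> network partition: 4 communities, Q = 0.4018

mrqap_dsp(net_ex, list(citizen = unclass(net_cz)), n_permutations = 1000, seed = 7)
#> MRQAP (double semi-partialling), 1000 permutations, 276 dyads
#>                coef      t        p
#> (Intercept) 0.01446  3.868       NA
#> citizen     1.33855 59.200 0.000999
#> R2 = 0.9275  adj. R2 = 0.9272

spearman_rho(eigenvector_centrality(net_ex), eigenvector_centrality(net_cz))
#> [1] 0.9147826
```

Here the 24 weaned individuals identified by both channels yield a
276-dyad regression: the citizen-channel network strongly predicts the
expert one (p is the smallest attainable value under 1,000 permutations
with the add-one convention), the partitions of the two networks place 92%
of individuals in the same aligned community, and individual network
positions are highly rank-correlated across channels. `run_report()` runs
the same pipeline end to end — inclusion filtering, minute linking,
agreement statistics, networks, MRQAP, robustness — and writes a single
JSON summary plus CSV/GraphML artifacts; with a fixed seed its output is
byte-identical across runs.

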