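---
title: "Methods: from two-channel camera-trap annotations to comparable social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-channel camera-trap annotations to comparable social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapnets)
```

## The problem

Motion-triggered camera traps record 60-s videos of animals that live in
fission–fusion societies: a stable community whose members travel in
temporary "parties" of variable size and composition. When two independent
observer channels annotate the same footage — for instance professional
observers with years of experience identifying the animals, and a
consensus-based citizen-science channel that confirms an individual ID only
after at least three annotators agree — two questions arise. First, how well
do the channels agree on what they saw (counts per video, individual
identifications)? Second, if each channel's identifications are turned into
a social network, do the two networks tell the same story about social
structure?

`camtrapnets` implements that comparison pipeline end to end, and ships a
seeded simulator of the whole observation process so that every stage can be
validated against a known ground truth.

## Data model and filtering

The unit of annotation is a 15-s clip; four consecutive clips form one
1-min video (clips are quartered to limit annotator fatigue). A clip counts
as a chimpanzee clip when at least two distinct annotators said "chimp" — a
single classification could be erroneous — or when a moderator added a
`#chimp` hashtag; a moderator `#omit` hashtag forces the flag off
(`chimp_clip_flag()`).

A video enters the between-channel comparison only if all four clips were
viewed and the video was positively recognized as containing at least one
animal: at least one chimp-flagged clip, with every non-flagged clip
unanimously blank across at least three classifications
(`video_inclusion_filter()`). The four clips are then linked back into one
minute (`link_minute()`): with producer-linked individual tokens the
minute's count is the size of the union across clips; with bare per-clip
counts it is the per-clip maximum, a stated lower-bound convention, because
the same animal may span clips.

Consensus ID confirmation (`confirm_id()`) promotes a prospective ID to
confirmed only when at least three annotators agree, no annotator dissents,
and the animal was seen in two temporally and spatially independent clips.
Independence is defined only by example in field practice
("nonconsecutive clips or clips from different camera locations"); we
operationalize it as: two sightings at the same camera are dependent iff
they are at most 60 s apart (i.e. clips of the same minute), and everything
else — different cameras, or the same camera further apart in time — is
independent. This is deliberately the weakest reading that still excludes
within-minute pseudo-replication.

## Events, gambit of the group, and the simple ratio index

Videos recorded at the same camera whose start times fall within 15 min of
each other are grouped into one *event* (`group_events()`). The rule is
applied to video start times with transitive chaining and an inclusive
boundary: a gap of exactly 15:00 still merges, and an event may span more
than 15 min end to end. Anchor semantics (measuring from the first video of
the event) would be the alternative; chaining was chosen because it is
order-independent and idempotent — regrouping an event's own member videos
reproduces the event, which the tests verify.

Under the gambit of the group, all individuals identified anywhere in an
event are one associating party (`gambit_party()`). Dyadic association uses
the simple ratio index,

$$\mathrm{SRI}(A,B) = \frac{x}{x + y_{AB} + y_A + y_B},$$

the fraction of relevant sampling units (events) in which the pair was
together; $y_{AB}$ (both seen, but apart) is structurally zero when the
sampling unit is a single camera's event, but is kept in the formula for
API generality. Only events containing at least one member of the network
roster count as sampling units; an event containing neither member of a
dyad leaves that dyad's index unchanged, which the tests check as a
property. When one member of a pair is present but unidentified, the event
still counts toward the identified member's denominator — the data cannot
distinguish "absent" from "present but anonymous", and treating anonymity
as absence is the convention that requires no extra assumptions.

The roster for network comparison is the set of weaned individuals (old
enough to range independently and be reliably identifiable) identified at
least once in *each* channel, after standardizing citizen ID names onto
expert names via an explicit map (`select_shared_roster()`, `read_id_map()`;
a citizen ID that an expert associated with two individuals is kept under
its first mapping and flagged as chimeric).

## Comparing networks

**Communities.** `leading_eigenvector_communities()` implements Newman's
spectral method on the weighted modularity matrix
$B_{ij} = A_{ij} - s_i s_j / 2W$ (strengths $s$, total edge weight $W$):
recursively split by the sign of the leading eigenvector of the
generalized modularity matrix, stopping when the leading eigenvalue drops
below $10^{-10}$ or the split does not increase $Q$. Components exactly at
zero join the positive block, deterministically. The usual Kernighan–Lin
refinement step is intentionally omitted: plain sign-split recursion is
fully deterministic and can be validated against exhaustive modularity
maximization on 8-node planted-block graphs, which the acceptance tests
do. Partitions from the two channels are compared by maximum-overlap label
alignment (exhaustive over label permutations — community counts here are
single digits), reporting the share of individuals in the same aligned
community.

**MRQAP.** `mrqap_dsp()` regresses the response network's
$n(n-1)/2$ lower-triangle dyads on the predictors' dyads by OLS and obtains
permutation p-values by double semi-partialling (Dekker et al.): each
predictor is residualized on the others, the residual matrix's rows and
columns are jointly permuted by a node permutation, the model is refit with
the permuted residual in that predictor's slot, and the permuted
$|t|$-statistics form the reference distribution. The pivotal statistic is
the t-statistic (robust under collinearity and autocorrelation); p-values
use the add-one convention, so the smallest attainable p with 1,000
permutations is 1/1001. A perfect fit has zero residual variance; its
t-statistic is capped at a large finite value so permutation comparisons
remain well defined. With four nodes the 24 node permutations can be
enumerated exhaustively, which anchors the sampled procedure to an exact
oracle in the tests. The regression direction is an explicit argument
(`mrqap_response`); the default asks whether the citizen network predicts
the expert one.

**Node metrics.** Strength is the row sum of weights; eigenvector
centrality is the principal eigenvector of the weight matrix, taken
non-negative and max-normalized to 1 (the common graph-library convention;
the Spearman correlations used to compare channels are scale-invariant, so
the normalization is cosmetic). On disconnected graphs the eigenvector is
computed on the full matrix and the dominant component carries the mass.

**Robustness.** `robustness_curve()` asks whether the available number of
events suffices for stable structure: for each size on a grid (default 15
to 170 events in steps of 5, i.e. 32 estimated networks), it repeatedly
(default 1,000 replicates) draws that many events uniformly *without*
replacement, rebuilds the SRI network, and Spearman-correlates its dyad
vector (all roster pairs, zeros included, ties mid-ranked) with the
complete network's; replicates give the mean and percentile 95% CI per
size. Without-replacement sampling was chosen over a classical bootstrap
because it makes the full-sample endpoint exactly 1 — a clean, testable
anchor; a with-replacement mode is available via `replace = TRUE`. Dyads,
not node metrics, are the correlation units, matching the reading of
"network structure"; node-metric ranks are the plausible alternative.
`plateau_size()` reports the smallest size whose mean is within 0.02 of
the final mean.

## Agreement statistics

`detection_agreement()`, `id_assignment_rate()`, `id_agreement()`,
`underestimate_pct()`, `cohens_kappa()` and `prospective_id_resolution()`
compute the printed-summary statistics: per-video count agreement with the
under/over split of disagreements, per-channel ID assignment rates, ID
agreement for co-identified detections with mismatches classified by
age–sex class, roster underestimates, chance-corrected inter-observer
agreement ($\kappa = (p_o - p_e)/(1 - p_e)$), and the three-way resolution
of prospective IDs. All percentages are rounded half-up to integers, the
presentation convention of the field's reports. The "detection" unit
throughout is one individual in one 1-min video, after minute linking.

## The simulator: what it emulates and what it does not

`simulate_community()` generates the study conditions the pipeline is
validated under. Defaults: 36 individuals in 3 latent communities, a
weaned fraction of 2/3 (two dozen weaned animals), 500 events at 25
cameras, 1 + Poisson(0.8) videos per event (mean 1.8, respecting the
at-least-one-video constraint), four clips per video with each present
individual in a uniformly chosen non-empty clip subset, an expert channel
identifying 85% of detections, a citizen channel confirming 46%, and
per-video citizen count-error probabilities of 0.09 (drop one present
individual) and 0.04 (add one anonymous extra), making undercounts roughly
a 69:31 majority of disagreements, with small magnitudes. Party formation
is seed-plus-independent-inclusion with `p_within = 0.7`,
`p_between = 0.05`: the simplest mechanism that produces variable party
sizes and assortative co-detection, since field descriptions of
fission–fusion dynamics are verbal only. Events are spaced an hour apart
so the 15-min rule recovers them exactly; within-event video gaps are 1–10
min.

Features of real data the simulator deliberately does not emulate:
annotator-level skill heterogeneity and learning, *incorrect* confirmed
IDs (simulated IDs are missing at random but never wrong, so simulated ID
agreement is 100% where field data showed 99%), chimeric IDs, spatial
structure in camera placement, and temporal autocorrelation of party
composition. Passing tests therefore demonstrate that the pipeline's
arithmetic and inference are correct under a known generative model — not
that any particular field dataset meets that model's assumptions.

## Numerical choices and degenerate inputs

Eigen-decompositions use LAPACK via `eigen(symmetric = TRUE)`; the
spectral stop tolerance is $10^{-10}$ and split acceptance requires a
strict $Q$ increase beyond $10^{-12}$. An all-zero network yields all-zero
centralities with a warning; modularity on an empty network is an error;
a constant vector makes Spearman's correlation undefined (`NA` with a
warning); `detection_agreement` with disjoint video sets, unmapped citizen
IDs, and grids exceeding the event count are errors naming the offending
items. Timestamps are parsed strictly as ISO 8601 UTC and timezone-naive
input is rejected.

## Problem sizes used in validation

The test suite validates against exhaustive oracles at small sizes (all
24 node permutations at $n=4$ for MRQAP; all partitions into at most four
blocks of 8 nodes for modularity), uses 500 simulated regressions of
15-node networks with 200 permutations for the type-I-error check, and
runs parameter recovery on the default 500-event community. The
end-to-end `run_report()` driver defaults to 1,000 MRQAP permutations and
1,000 robustness replicates over the 32-point grid, the study-scale
settings.
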