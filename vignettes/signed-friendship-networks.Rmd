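---
title: "Analysing signed friendship nomination networks: circles, communities, reciprocity and balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing signed friendship nomination networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(signedcircles)
```

## The setting

`signedcircles` analyses sociometric survey data in which every student of a
school cohort can nominate any other student as a friend or an enemy at two
intensity levels. Two survey waves, months apart, give two snapshots of the
same cohort. The data model is deliberately minimal:

* a **roster** (`id`, `group`, `gender`, `wave1`, `wave2`) listing the cohort,
  its class groups and each student's participation per wave;
* a **nomination table** (`ego`, `alter`, `wave`, `sign`, `intensity`), one
  row per survey answer, with intensity 1 the inner level ("best friend" /
  "worst enemy") and intensity 2 the outer level ("friend" / "enemy").

`resolve_weights()` turns one wave's nominations into a
`signed_network`, a directed graph with weights in $\{-2,-1,1,2\}$. Three
rules resolve multiple reports on the same ordered pair: within a sign the
most intense report wins; if both signs are reported, the two resolved
weights are summed; and a zero sum removes the link. Because per-sign
resolution leaves one value of magnitude at most 2 per sign, resolved
weights always stay in $\{-2,-1,1,2\}$.

```{r}
roster <- load_roster(system.file("extdata", "toy_roster.csv",
                                  package = "signedcircles"))
noms <- load_nominations(system.file("extdata", "toy_nominations.csv",
                                     package = "signedcircles"), roster)
resolve_weights(noms, wave = 1, roster = roster)$edges
```

Students who skipped a wave stay on the roster but are excluded from that
wave's ego set; if they are nominated nonetheless they are kept as alters
and flagged (`attr(net, "non_participants")`), because the survey gives no
way to know their own answers. Cross-wave statistics use the students
common to both waves.

## Personal-network circles: the $\mu$ and $\rho$ parameters

For one ego, the inner circle $C_1$ counts nominations of weight $\pm 2$ and
the cumulative circle $C_2$ counts all nominations of the sign. Under the
resource-allocation model of layered personal networks, ring sizes scale by
$e^{\mu}$ per layer when consecutive layers differ by a unit cost; with
exactly two elicited layers the fitted scaling constant collapses to the
closed form

$$\mu = \log\!\left(\frac{l_2}{l_1}\right) = \log\!\left(\frac{C_2 - C_1}{C_1}\right),$$

with the natural logarithm, which is what `compute_mu()` evaluates. The
canonical circle scaling of about 3 between consecutive layers corresponds
to $\mu = \log 2 \approx 0.7$; negative $\mu$ means the ego's relationships
concentrate in the inner circle. $\rho$ (`compute_rho()`) is the same
statistic on received nominations.

$\mu$ is singular when $C_1 = 0$ or $C_2 = C_1$. Such egos are returned as
`NA`, excluded from group means and counted in explicit `n_excluded`
columns: with only two elicited layers there is no defensible imputation at
the singularity, and group summaries must say how many students they dropped.
Negative-sign $\mu$ is computed on request but never aggregated by default;
enmity nominations are an order of magnitude sparser than friendships and
per-group means would rest on a handful of defined values.

`mu_increment()` takes the per-student difference $\Delta\mu$ between waves
over students with defined $\mu$ in both, and `increment_tests()` runs the
survey-analysis battery on it: per-group Shapiro-Wilk, per-group one-sample
t against zero, one-way ANOVA across groups and Tukey HSD pairwise
comparisons, all through the standard `stats` implementations. Groups with
fewer than three values are skipped with a reason; zero-variance groups are
flagged rather than producing spurious statistics.

## Signed community structure

Community detection uses the signed, directed, weighted modularity

$$Q = \frac{w^{+}}{w^{+}+|w^{-}|}\,Q^{+} - \frac{|w^{-}|}{w^{+}+|w^{-}|}\,Q^{-},
\qquad
Q^{+} = \frac{1}{2w^{+}} \sum_{i,j}\left(w^{+}_{ij}
  - \frac{w^{+,out}_i\, w^{+,in}_j}{2w^{+}}\right)\delta(C_i, C_j),$$

with $Q^-$ the same expression on $|w^-_{ij}|$. Positive weight inside
communities raises $Q$; negative weight inside communities lowers it. Two
implementation constants deserve a note:

* **Normalization.** The $2w$ in both the prefactor and the null term is
  implemented exactly as written, although part of the directed-modularity
  literature uses $w$; `normalization = "w"` exposes the alternative so $Q$
  values can be compared across conventions. The default makes the absolute
  $Q$ values of this package directly comparable with the definition above.
* **Diagonal terms.** Networks carry no self-loops, but the double sum is
  unrestricted, so the null-model term at $i = j$ is included. The
  brute-force oracle and the fast implementation agree to $10^{-12}$
  because both honour this convention.

`optimize_partition()` maximizes $Q$ without fixing the number of
communities. It is a multi-start heuristic in the spirit of the
multi-algorithm optimizers used for modularity: restarts are seeded from
singletons, from a single community and from random $k$-way assignments;
each restart alternates greedy local moves (a node may join any community
or open a new one; ties break to the lowest community id so runs are
reproducible) with greedy community merges, then attempts a few
perturbation-and-reconverge escapes. On exhaustive benchmarks
(`brute_force_partition()`, capped at 10 nodes where set-partition
enumeration is feasible) the heuristic attains the global optimum on all
tested random instances; the test suite re-certifies this on 50 instances
at every run. Modularity optimization is NP-hard, so beyond oracle scale
the guarantee is empirical, not formal.

Two comparison tools mirror the downstream questions: `community_flows()`
builds the wave-1 x wave-2 membership contingency table with per-community
gender and group composition, and `positive_only_comparison()` contrasts
the signed partition with the positive-only partition to report which
communities owe their separation to negative links.

```{r}
pp <- planted_partition_signed(c(10, 10, 10), p_in_pos = 0.6,
                               p_out_pos = 0.05, p_in_neg = 0,
                               p_out_neg = 0.1, seed = 1)
fit <- optimize_partition(pp$network, n_restarts = 5, seed = 1)
fit$modularity
table(fit$partition$membership, pp$truth)
```

## Reciprocity and its rewiring null

`reciprocity()` is the fraction of directed edges of a sign whose reverse
edge exists with the same sign, intensity-blind (a "+2" answered by a "+1"
counts). `rewiring_null()` calibrates it: the default mode redraws every
ego's out-nominations uniformly among all other students, preserving each
out-degree exactly, so the expected null reciprocity is approximately the
mean out-degree over $n-1$; a `double_edge_swap` mode preserving both
degree sequences is available for comparison. The null reports a percentile
confidence interval (95% by default) and the exceedance count against the
observed value. Both modes and the percentile CI choice follow the simplest
reading of "rewiring the links at random"; the two modes are reported side
by side when they matter.

## Structural balance

Balance theory needs an undirected signed graph, while nominations are
directed and dyads often disagree in sign. `project_signed()` offers the two
defensible projections: criterion `"a"` calls a pair negative only when both
directions are present and negative; criterion `"b"` as soon as one
direction is negative. Intensity is collapsed before projection — negative
links are too sparse to support a two-intensity balance theory.

`triangle_census()` stratifies triangles by their number of negative edges
(odd = unbalanced), and `permutation_balance_test()` runs the
embedding-preserving null: edges are classed by their embedding (number of
triangles containing them, `edge_embedding()`), and each realization
shuffles signs uniformly *within* each class. This preserves the topology,
the embedding index and the per-class negative-edge counts, avoiding the
known bias of nulls that move edges between structurally different
positions, since positive and negative subnetworks have very different
embedding profiles. What is permuted is the *signs* of links within an
embedding class, the minimal scheme that preserves both topology and
embedding exactly; permuting edge endpoints instead would alter the
positive subnetwork's structure and is deliberately not offered. The
headline statistic is the fraction of realizations with strictly fewer
unbalanced triangles than observed. The default is $10^4$ realizations —
desk-scale; the statistic is a simple exceedance fraction, so more
realizations sharpen resolution, not location.

```{r}
net <- generate_balanced(c(12, 12), p_within = 0.9, p_between = 0.6, seed = 1)
bt <- permutation_balance_test(project_signed(net, "a"),
                               n_realizations = 2000, seed = 1)
bt
```

## The synthetic cohort generator

No public accession exists for school nomination surveys of this kind, so
`generate_wave()` / `generate_pair()` produce cohorts with the marginal
structure the analysis assumes, making every stage testable end to end. The
defaults encode the study conditions: five groups of 29-31 students (151 in
total), gender ratios from balanced to 20:9, planted communities of about
12 students (the sympathy-group scale) with a 0.85 gender bias, inner/outer
positive circle means 14.5 and 27 in wave 1 (ratio 1.86), about 7 negative
nominations per student (30% at the inner level), reciprocity 0.566, and a
wave-2 drift to an inner mean of 11.3 with ratio 2.53 plus 30% community
churn. Where the study conditions state no value (gender homophily 0.7,
intra-community preference 0.35, cross-community enmity bias 0.8), a single
realistic choice was made and is not revisited.

Design choices worth knowing:

* **Degrees are Poisson.** $C_1$ and the ring $C_2 - C_1$ are drawn from
  Poisson distributions with the configured means, truncated to the number
  of available alters — the minimal count model when only means and
  quartile ranges are known. A consequence used by the tests: for circle
  ratio $r$, the mean defined $\mu$ converges to $\log(r-1)$ (up to a small
  Jensen correction of order $1/(2\lambda)$), so a ratio-3 cohort recovers
  $\mu \approx \log 2$.
* **Reciprocity by mutual-dyad construction.** Adding reverse edges to a
  fraction $t$ of arcs would both overshoot the realized reciprocity
  ($2t/(1+t) \ne t$) and inflate every ego's outer circle beyond its drawn
  size, breaking the circle-ratio target. Instead the generator draws the
  out-degrees first, matches $D = \mathrm{round}(t\,m/2)$ mutual dyads
  between egos with remaining out-capacity (under the same community and
  gender preferences), and fills the rest with single arcs that are
  forbidden from closing a dyad by accident. Realized reciprocity is then
  $2D/m \approx t$ while every out-degree stays as drawn. At $t = 1$ there
  is no single-arc quota, so odd leftover capacity is dropped rather than
  breaking full reciprocation.
* **Preferences as odds weights.** Community and gender preferences are
  per-draw probabilities converted to candidate weights
  $p\,n_{\text{out}} / ((1-p)\,n_{\text{in}})$, so the target probability
  holds approximately regardless of pool sizes and degrades gracefully when
  a small pool is exhausted (an ego who wants 27 friends cannot take 35%
  of them from an 11-person community).
* **Negatives avoid positive targets**, so the generator never produces the
  cross-sign cancellation case; that resolution rule is exercised by the
  bundled fixture instead. Negative-tie reciprocity and the positive
  in/out-neighbourhood overlap are not calibrated — the survey literature
  gives no targets for them, and the generator makes no claim about them.
* **Determinism.** Every generator call derives sub-seeds from the
  configuration seed by stable stage-name offsets (roster vs wave-1 edges
  vs churn vs wave-2 edges), so regenerating one part never shifts another.

What passing tests on synthetic cohorts do **not** show: the generator
matches stated marginals (circle means, reciprocity, sparsity, homophily,
block structure), not the full joint distribution of real classroom
networks — degree-degree correlations, transitivity of positive ties beyond
what reciprocity induces, and the interplay of enmity with status are all
absent. Results on real data depend on the marginals only insofar as the
statistics above do.

## Numerical choices and problem sizes

* Move/merge acceptance uses a $10^{-12}$ tolerance; ties break
  deterministically (largest gain, then lowest community id), and node
  order is shuffled per restart from the seed.
* `brute_force_partition()` refuses networks beyond 10 nodes
  (Bell-number growth; $B_{10} = 115\,975$).
* The test suite certifies: oracle equivalence of the modularity
  evaluation on 100 random networks ($n \le 20$, tolerance $10^{-12}$);
  heuristic-equals-exhaustive on 50 random instances ($n \le 8$); planted
  recovery at ARI $\ge 0.9$ in at least 95 of 100 seeds on blocks of
  (10, 10, 10); balance lower bound with $10^4$ embedding-preserving
  realizations on a 24-node balanced graph; rewiring-null calibration on a
  200-node, out-degree-10 network against the analytic $10/199$; and $\mu$
  recovery within 0.05 of $\log 2$ on ten 500-student ratio-3 cohorts.
  These sizes keep the full suite under a few minutes on one CPU.
* `run_pipeline()` writes per-stage CSV/JSON plus a manifest with all
  sub-seeds; identical configurations give byte-identical reports.

## Known limitations

* The heuristic optimizer's global-optimality guarantee is empirical
  (exhaustive cross-checks at small $n$); on larger networks it reports the
  best of its restarts.
* $\mu$ with two layers is a log-ratio, not a fit over many layers; which
  pair of Dunbar circles a two-level questionnaire actually elicits is a
  substantive question the statistic cannot settle — layers are positional
  here.
* The balance null permutes signs within embedding classes; endpoint-
  permuting variants are out of scope.
* Whether undefined-$\mu$ students should be excluded or imputed in group
  tables is a genuine analytic fork; this package excludes and counts them,
  and all summaries carry the exclusion counts.
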