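# signedcircles

Analysis of **two-wave, signed, directed, weighted friendship nomination
networks** from sociometric school surveys, for researchers studying how
adolescent relationship structure evolves. Every student can nominate any
classmate as a friend or an enemy at two intensity levels; resolved link
weights live in {−2, −1, +1, +2}. The package covers the full analysis
chain:

* **Dunbar-circle statistics per student.** With inner-circle count `C1`
  ("best friends", |w| = 2) and cumulative count `C2` (all friends), the
  circle-structure parameter is

  ```
  mu = log(l2 / l1) = log((C2 - C1) / C1)
  ```

  (natural log; `rho` is the same statistic on received nominations).
  `mu ≈ 0.7` is the canonical ratio-3 circle scaling; `mu < 0` means
  relationships concentrate in the inner circle. Group summary tables and
  cross-wave increment tests (Shapiro–Wilk, one-sample t, ANOVA, Tukey HSD)
  are built in.

* **Signed community detection.** The signed, directed, weighted modularity

  ```
  Q = w+/(w+ + |w-|) * Q+  -  |w-|/(w+ + |w-|) * Q-
  Q+ = 1/(2w+) * sum_ij ( w+_ij - w+out_i * w+in_j / (2w+) ) * delta(C_i, C_j)
  ```

  is maximized by a multi-start heuristic agnostic to the number of
  communities, certified against an exhaustive brute-force oracle at small
  n. Cross-wave membership flows and a with/without-negative-links
  comparison are included.

* **Reciprocity** with a degree-preserving rewiring null and percentile CIs.

* **Structural balance**: projection of the directed signed network onto an
  undirected signed graph under two conflict criteria, triangle census by
  number of negative edges, and the embedding-preserving sign-permutation
  test (only edges lying in the same number of triangles exchange signs).

* **A synthetic cohort generator** reproducing the marginal structure such
  surveys show (circle-structured out-degrees, reciprocity, gender
  homophily, planted gender-biased communities, sparse enmity), so the whole
  pipeline is testable without access to confidential survey data.

## Worked example

```r
library(signedcircles)

# simulate a two-wave cohort with the default study conditions
cfg <- generator_config(seed = 2026)
sim <- generate_pair(cfg)
sim$pair
#> network_pair over 151 students
#>   wave 1: signed_network: 151 nodes, 5077 edges (w+ = 6181, w- = -1360)
#>   wave 2: signed_network: 151 nodes, 5414 edges (w+ = 6139, w- = -1337)

# per-group mu means per wave and the per-student increment
prof1 <- circle_profiles(sim$pair$wave1, sim$pair$roster, wave = 1)
prof2 <- circle_profiles(sim$pair$wave2, sim$pair$roster, wave = 2)
inc <- mu_increment(sim$pair)
group_mu_table(prof1, prof2, inc)[, c("group", "mean_wave1", "mean_wave2",
                                      "mean_increment")]
#>   group mean_wave1 mean_wave2 mean_increment
#> 1     A     -0.056       0.52           0.58
#> 2     B     -0.233       0.30           0.53
#> 3     C     -0.140       0.46           0.60
#> 4     D     -0.238       0.47           0.71
#> 5     E     -0.102       0.38           0.48
#> 6 TOTAL     -0.155       0.42           0.58
```

The wave-1 cohort sits at `mu ≈ -0.15` (outer ring smaller than the inner
circle, the clique-like structure of newly formed classes at circle ratio
1.86) and drifts to positive `mu` in wave 2 as the configured ratio grows —
the transition from intense small cliques toward a standard circle
structure.

```r
# signed community structure of wave 1
fit <- optimize_partition(sim$pair$wave1, n_restarts = 10, seed = 1)
fit$modularity
#> Q = 0.18605  (Q+ = 0.24592, Q- = 0.08604; w+ = 6181, |w-| = 1360, norm 2w)

# reciprocity against its rewiring null
rewiring_null(sim$pair$wave1, n_samples = 300, seed = 1)
#> Null distribution (300 samples)
#>   mean 0.1770, 95% CI (0.1605; 0.1923)
#>   observed 0.5658 (0/300 null samples >= observed)

# structural balance under criterion (b)
bt <- permutation_balance_test(project_signed(sim$pair$wave1, "b"),
                               n_realizations = 2000, seed = 1)
bt
#> triangles: 23522 total (0/1/2/3 negative edges: 10905/8655/3544/418); 14449 balanced, 9073 unbalanced
#> null unbalanced: mean 9909.1, 95% CI (9767; 10043) over 2000 realizations
#> fraction of realizations with fewer unbalanced triangles: 0
```

Observed reciprocity (0.566) sits far above every rewired realization
(null ≈ 0.18), and no embedding-preserving sign permutation produces fewer
unbalanced triangles than the observed configuration — the two signatures
the analysis is built to detect.

`run_pipeline(config, outdir)` chains all stages (ingest or simulate →
circles → communities → reciprocity → balance) and writes per-stage
CSV/JSON reports plus a manifest of all sub-seeds; identical configurations
yield byte-identical reports.

See `vignettes/signed-friendship-networks.Rmd` for the models, the
parameter conventions (including the `2w` modularity normalization) and the
design of the synthetic generator.

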