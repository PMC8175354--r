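test_that("circle sizes count inner and cumulative nominations by scope and direction", {
  roster <- toy_roster()
  # s1 -> s2(+2), s3(+2), s4(+1), s5(+1) and s2 -> s1(+1)
  net <- signed_network(roster$id, data.frame(
    from = c("s1", "s1", "s1", "s1", "s2"),
    to = c("s2", "s3", "s4", "s5", "s1"),
    weight = c(2, 2, 1, 1, 1)))
  expect_equal(circle_sizes(net, "s1"), c(C1 = 2, C2 = 4))
  expect_equal(circle_sizes(net, "s1", direction = "in"), c(C1 = 0, C2 = 1))
  expect_equal(circle_sizes(net, "s3", direction = "out"), c(C1 = 0, C2 = 0))
  # intra-group: s1 is in A with s2, s3; the +1s to B are excluded
  expect_equal(circle_sizes(net, "s1", scope = "intra_group", roster = roster),
               c(C1 = 2, C2 = 2))
  expect_error(circle_sizes(net, "zz"), "unknown ego")
})

test_that("mu follows the closed form and is undefined at its singularities", {
  expect_equal(compute_mu(5, 15), log(2))
  expect_equal(compute_mu(4, 8), 0)
  expect_equal(compute_mu(4, 6), log(2 / 4))
  expect_true(is.na(compute_mu(0, 5)))   # no inner circle
  expect_true(is.na(compute_mu(3, 3)))   # empty outer ring
  expect_error(compute_mu(5, 3), "C2")
  # ratio-3 scaling gives exactly log 2 for every C1
  for (c1 in 1:25) expect_equal(compute_mu(c1, 3 * c1), log(2))
})

test_that("rho is mu on received nominations", {
  ids <- paste0("s", 1:10)
  roster <- as_roster(data.frame(id = ids, group = "A", gender = "F",
                                 wave1 = TRUE, wave2 = TRUE))
  e <- data.frame(from = ids[2:10], to = "s1",
                  weight = c(2, 2, 2, 1, 1, 1, 1, 1, 1))
  net <- signed_network(ids, e)
  expect_equal(compute_rho(net, "s1", roster), log(6 / 3))
  # all inner: C2 == C1, undefined
  net2 <- signed_network(ids, data.frame(from = ids[2:4], to = "s1", weight = 2))
  expect_true(is.na(compute_rho(net2, "s1", roster)))
  expect_true(is.na(compute_rho(net2, "s2", roster)))  # no in-edges at all
})

test_that("mu ignores negative edges and alter relabeling", {
  ids <- paste0("s", 1:8)
  e <- data.frame(from = "s1", to = ids[2:6], weight = c(2, 2, 1, 1, 1))
  net <- signed_network(ids, e)
  mu0 <- compute_mu(circle_sizes(net, "s1")[1], circle_sizes(net, "s1")[2])
  withneg <- signed_network(ids, rbind(e, data.frame(from = "s1", to = c("s7", "s8"),
                                                     weight = c(-1, -2))))
  cs <- circle_sizes(withneg, "s1", sign = "positive")
  expect_equal(unname(compute_mu(cs[1], cs[2])), unname(mu0))
})

test_that("intra-group circle sizes never exceed all-scope sizes", {
  w <- generate_wave(generator_config(
    n_groups = 3, group_sizes = 15, girl_fraction = 0.5, mean_C1 = 3,
    circle_ratio = 2.5, neg_rate = 2, wave2_drift = list(), seed = 21), 1)
  all_p <- circle_profiles(w$network, w$roster, 1)
  intra <- circle_profiles(w$network, w$roster, 1, scope = "intra_group")
  expect_equal(intra$ego, all_p$ego)
  expect_true(all(intra$C1 <= all_p$C1))
  expect_true(all(intra$C2 <= all_p$C2))
})

test_that("mu increments subtract per student over common defined participants", {
  roster <- as_roster(data.frame(id = paste0("s", 1:6), group = "A",
                                 gender = "F", wave1 = TRUE,
                                 wave2 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)))
  mk <- function(w13, w14) signed_network(roster$id, data.frame(
    from = c("s1", "s1", "s1", "s2", "s2", "s2", "s2"),
    to = c("s2", "s3", "s4", "s1", "s3", "s4", "s5"),
    weight = c(2, w13, w14, 2, 2, 1, 1)))
  # wave1: s1 has {+2,+1,+1} -> mu = log(2); wave2: {+2,+2,+1} -> mu = log(1/2)
  pair <- network_pair(mk(1, 1), mk(2, 1), roster)
  inc <- mu_increment(pair)
  s1 <- inc[inc$ego == "s1", ]
  expect_equal(s1$delta, log(1 / 2) - log(2))
  # s2 identical in both waves: delta exactly 0
  expect_equal(inc$delta[inc$ego == "s2"], 0)
  # students with undefined mu in either wave are excluded but counted
  elig <- attr(inc, "eligibility")
  expect_equal(unname(elig["eligible"]), nrow(inc))
  expect_true(elig["common_participants"] >= elig["eligible"])
})

test_that("group mu table reports means, SDs, counts and missing cells", {
  p1 <- data.frame(ego = paste0("s", 1:4), group = c("A", "A", "B", "B"),
                   mu = c(0.7, 0.7, 0.2, NA))
  p2 <- data.frame(ego = paste0("s", 1:4), group = c("A", "A", "B", "B"),
                   mu = c(0.9, 0.5, NA, NA))
  inc <- data.frame(ego = paste0("s", 1:2), group = "A", delta = c(0.2, -0.2))
  tab <- group_mu_table(p1, p2, inc)
  a <- tab[tab$group == "A", ]
  expect_equal(a$mean_wave1, 0.7)
  expect_equal(a$sd_wave1, 0)
  expect_equal(a$n_wave1, 2)
  b <- tab[tab$group == "B", ]
  expect_equal(b$n_wave1, 1)
  expect_equal(b$sd_wave1, 0)          # single value flagged by n = 1
  expect_true(is.na(b$mean_wave2))     # empty cell reported missing
  expect_equal(b$n_excluded_wave2, 2)
  tot <- tab[tab$group == "TOTAL", ]
  expect_equal(tot$n_wave1, 3)
  expect_equal(tot$mean_increment, 0)
})

test_that("increment tests run Shapiro, t, ANOVA and Tukey with guards", {
  set.seed(42)
  inc <- data.frame(group = rep(c("A", "B", "C"), each = 20),
                    delta = c(rnorm(20, 1), rnorm(20, 0), rnorm(20, 0)))
  res <- increment_tests(inc)
  expect_equal(nrow(res$per_group), 3)
  expect_true(all(res$per_group$shapiro_p >= 0, na.rm = TRUE))
  expect_equal(res$anova$df_between, 2)
  expect_equal(res$anova$df_within, 57)
  expect_equal(nrow(res$tukey), 3)
  expect_lt(res$tukey$p_adj[res$tukey$comparison == "B-A"], 0.05)

  # tiny group skipped with a reason
  inc2 <- rbind(inc, data.frame(group = "D", delta = c(0.1, 0.2)))
  res2 <- increment_tests(inc2)
  expect_equal(res2$skipped$group, "D")
  expect_match(res2$skipped$reason, "n = 2")

  # all-zero increments: zero variance flagged, statistics undefined
  inc3 <- data.frame(group = rep(c("A", "B"), each = 5), delta = 0)
  res3 <- increment_tests(inc3)
  expect_true(all(res3$per_group$zero_variance))
  expect_true(res3$anova$zero_variance)
})

test_that("ANOVA stage detects a two-group mean shift at high power", {
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    inc <- data.frame(group = rep(c("A", "B"), each = 50),
                      delta = c(rnorm(50, 0), rnorm(50, 2)))
    increment_tests(inc)$anova$p < 0.01
  }, logical(1))
  expect_gte(sum(rejections), 95)
})

test_that("mean defined mu recovers log(ratio - 1) on a large synthetic cohort", {
  cfg <- generator_config(n_groups = 2, group_sizes = 250, girl_fraction = 0.5,
                          mean_C1 = 14.5, circle_ratio = 3,
                          wave2_drift = list(), seed = 5)
  w <- generate_wave(cfg, 1)
  prof <- circle_profiles(w$network, w$roster, 1)
  expect_lt(abs(mean(prof$mu, na.rm = TRUE) - log(2)), 0.05)
})
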