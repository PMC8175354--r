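test_that("signed modularity matches the literal double-sum evaluation", {
  for (s in 1:40) {
    net <- random_signed_net(sample(4:12, 1), seed = s)
    if (!nrow(net$edges)) next
    set.seed(1000 + s)
    m <- stats::setNames(sample(1:3, length(net$nodes), replace = TRUE),
                         net$nodes)
    for (norm in c("2w", "w")) {
      fast <- modularity_signed(net, m, norm)
      slow <- naive_modularity(net, m, norm)
      expect_lt(abs(fast$Q - slow$Q), 1e-12)
      expect_lt(abs(fast$Q_plus - slow$Q_plus), 1e-12)
      expect_lt(abs(fast$Q_minus - slow$Q_minus), 1e-12)
    }
  }
})

test_that("modularity identities hold on hand-computable cases", {
  # all-positive network: Q == Q+
  net <- random_signed_net(8, p_pos = 0.4, p_neg = 0, seed = 3)
  m <- stats::setNames(rep(1:2, each = 4), net$nodes)
  r <- modularity_signed(net, m)
  expect_equal(r$Q, r$Q_plus)
  expect_equal(r$w_minus_abs, 0)

  # singleton partition: only the diagonal null terms survive
  singles <- stats::setNames(seq_along(net$nodes), net$nodes)
  r <- modularity_signed(net, singles)
  s <- signedcircles:::node_strengths(net, "positive")
  expect_equal(r$Q_plus, -sum(s$out * s$`in`) / (2 * r$w_plus)^2)

  # two disjoint positive directed 3-cycles, unit weights
  net <- signed_network(paste0("v", 1:6), data.frame(
    from = paste0("v", c(1, 2, 3, 4, 5, 6)),
    to = paste0("v", c(2, 3, 1, 5, 6, 4)), weight = 1))
  m <- stats::setNames(rep(1:2, each = 3), paste0("v", 1:6))
  # within = 3 per cycle, null = (3*3)/12 per cycle, prefactor 1/12
  expect_equal(modularity_signed(net, m)$Q_plus, (2 * (3 - 9 / 12)) / 12)

  # the decomposition identity Q = a Q+ - b Q-
  net <- random_signed_net(9, seed = 8)
  m <- stats::setNames(sample(1:3, 9, replace = TRUE), net$nodes)
  r <- modularity_signed(net, m)
  wt <- r$w_plus + r$w_minus_abs
  expect_equal(r$Q, r$w_plus / wt * r$Q_plus - r$w_minus_abs / wt * r$Q_minus)
})

test_that("Q is invariant under community relabeling", {
  net <- random_signed_net(10, seed = 5)
  set.seed(2)
  m <- stats::setNames(sample(1:4, 10, replace = TRUE), net$nodes)
  q0 <- modularity_signed(net, m)$Q
  for (i in 1:5) {
    perm <- sample(4)
    expect_equal(modularity_signed(net, stats::setNames(perm[m], names(m)))$Q, q0)
  }
})

test_that("turning an intra-community positive edge negative never raises Q", {
  for (s in 1:10) {
    net <- random_signed_net(8, seed = 200 + s)
    set.seed(s)
    m <- stats::setNames(sample(1:2, 8, replace = TRUE), net$nodes)
    e <- net$edges
    internal_pos <- which(e$weight > 0 & m[e$from] == m[e$to])
    if (!length(internal_pos)) next
    k <- internal_pos[1]
    q0 <- modularity_signed(net, m)$Q
    e$weight[k] <- -e$weight[k]
    q1 <- modularity_signed(signed_network(net$nodes, e), m)$Q
    expect_lte(q1, q0 + 1e-12)
  }
})

test_that("optimizer never falls below trivial partitions or the planted truth", {
  for (s in 1:8) {
    pp <- planted_partition_signed(c(6, 6), 0.7, 0.1, 0.05, 0.3, seed = s)
    net <- pp$network
    fit <- optimize_partition(net, n_restarts = 5, seed = s)
    q <- fit$modularity$Q
    one <- stats::setNames(rep(1, length(net$nodes)), net$nodes)
    singles <- stats::setNames(seq_along(net$nodes), net$nodes)
    expect_gte(q, modularity_signed(net, one)$Q - 1e-12)
    expect_gte(q, modularity_signed(net, singles)$Q - 1e-12)
    expect_gte(q, modularity_signed(net, pp$truth)$Q - 1e-12)
  }
})

test_that("optimizer recovers separable structure exactly", {
  # two disjoint positive 6-cliques
  ids <- paste0("v", 1:12)
  blk <- rep(1:2, each = 6)
  rows <- expand.grid(i = 1:12, j = 1:12)
  rows <- rows[rows$i != rows$j & blk[rows$i] == blk[rows$j], ]
  net <- signed_network(ids, data.frame(from = ids[rows$i], to = ids[rows$j],
                                        weight = 1))
  fit <- optimize_partition(net, n_restarts = 5, seed = 1)
  expect_equal(fit$partition$n_communities, 2)
  expect_equal(unname(fit$partition$membership[1] ==
                        fit$partition$membership[7]), FALSE)

  # perfectly separable signed planted partition
  pp <- planted_partition_signed(c(8, 8), 1, 0, 0, 1, seed = 2)
  fit <- optimize_partition(pp$network, n_restarts = 5, seed = 2)
  expect_equal(mclust::adjustedRandIndex(
    fit$partition$membership[names(pp$truth)], pp$truth), 1.0)
})

test_that("brute force enumerates and guards its size limit", {
  net1 <- signed_network("a", data.frame(from = character(), to = character(),
                                         weight = numeric()))
  expect_error(brute_force_partition(net1), "edgeless")
  # n = 1 with a second node and one edge: Q from diagonal terms only
  net <- signed_network(c("a", "b"), data.frame(from = "a", to = "b", weight = 1))
  bf <- brute_force_partition(net)
  expect_s3_class(bf$partition, "partition")
  # two disjoint positive triangles: enumeration returns the 2-clique split
  ids <- paste0("v", 1:6); blk <- rep(1:2, each = 3)
  rows <- expand.grid(i = 1:6, j = 1:6)
  rows <- rows[rows$i != rows$j & blk[rows$i] == blk[rows$j], ]
  net <- signed_network(ids, data.frame(from = ids[rows$i], to = ids[rows$j],
                                        weight = 2))
  bf <- brute_force_partition(net)
  expect_equal(bf$partition$n_communities, 2)
  expect_equal(unname(bf$partition$membership[ids[1]]),
               unname(bf$partition$membership[ids[3]]))
  big <- signed_network(paste0("v", 1:11),
                        data.frame(from = "v1", to = "v2", weight = 1))
  expect_error(brute_force_partition(big), "refuse")
  # set partition counts follow the Bell numbers
  expect_equal(nrow(signedcircles:::set_partitions(4)), 15)
  expect_equal(nrow(signedcircles:::set_partitions(6)), 203)
})

test_that("optimizer attains the exhaustive optimum on random small instances", {
  for (s in 1:12) {
    net <- random_signed_net(sample(4:7, 1), p_pos = 0.3, p_neg = 0.15,
                             seed = 300 + s)
    if (!nrow(net$edges)) next
    bf <- brute_force_partition(net)
    op <- optimize_partition(net, n_restarts = 10, seed = s)
    expect_equal(op$modularity$Q, bf$modularity$Q, tolerance = 1e-10)
  }
})

test_that("community flows build the contingency and composition tables", {
  roster <- as_roster(data.frame(id = paste0("s", 1:6),
                                 group = rep(c("A", "B"), each = 3),
                                 gender = rep(c("F", "M"), 3),
                                 wave1 = TRUE, wave2 = TRUE))
  net <- signed_network(roster$id, data.frame(from = "s1", to = "s2", weight = 1))
  pair <- network_pair(net, net, roster)
  m1 <- stats::setNames(c(1, 1, 1, 2, 2, 2), roster$id)
  fl <- community_flows(pair, m1, m1, roster)
  expect_true(all(fl$flow[row(fl$flow) != col(fl$flow)] == 0))
  expect_equal(sum(fl$flow), 6)
  # wave 2 merges the two wave-1 communities into one column
  m2 <- stats::setNames(rep(1, 6), roster$id)
  fl2 <- community_flows(pair, m1, m2, roster)
  expect_equal(dim(fl2$flow), c(2L, 1L))
  expect_equal(unname(fl2$flow[, 1]), c(3, 3))
  expect_equal(unname(fl2$gender_composition$wave1[, "F"]), c(2, 1))
})

test_that("negative links split communities that merge without them", {
  net <- two_block_fixture()
  # brute force certifies the fixture: signed optimum splits the blocks,
  # positive-only optimum is the single community
  bf_signed <- brute_force_partition(net)
  expect_equal(bf_signed$partition$n_communities, 2)
  bf_pos <- brute_force_partition(subnetwork(net, sign = "positive"))
  expect_equal(bf_pos$partition$n_communities, 1)

  pc <- positive_only_comparison(net, seed = 4)
  expect_equal(pc$signed$partition$n_communities, 2)
  expect_equal(pc$positive_only$partition$n_communities, 1)
  expect_equal(length(pc$merged_groups), 1)
  expect_setequal(pc$merged_groups[[1]], c(1, 2))

  # no negative edges: the two analyses coincide
  pos <- subnetwork(net, sign = "positive")
  expect_warning(pc2 <- positive_only_comparison(pos, seed = 4), "no negative")
  expect_equal(pc2$signed$modularity$Q, pc2$positive_only$modularity$Q)
})

test_that("optimization is deterministic given the seed", {
  net <- random_signed_net(15, seed = 77)
  f1 <- optimize_partition(net, n_restarts = 4, seed = 11)
  f2 <- optimize_partition(net, n_restarts = 4, seed = 11)
  expect_identical(f1$partition$membership, f2$partition$membership)
})
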