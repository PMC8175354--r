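test_that("roster loading validates structure and rejects duplicates", {
  path <- system.file("extdata", "toy_roster.csv", package = "signedcircles")
  roster <- load_roster(path)
  expect_s3_class(roster, "roster")
  expect_equal(nrow(roster), 5)
  expect_setequal(roster$id, paste0("s", 1:5))

  dup <- data.frame(id = c("s1", "s1"), group = "A", gender = "F",
                    wave1 = TRUE, wave2 = TRUE)
  expect_error(as_roster(dup), "duplicate")

  empty <- tempfile(fileext = ".csv")
  writeLines("id,group,gender,wave1,wave2", empty)
  expect_equal(nrow(load_roster(empty)), 0)

  nogrp <- tempfile(fileext = ".csv")
  writeLines(c("id,gender,wave1,wave2", "s1,F,TRUE,TRUE"), nogrp)
  expect_error(load_roster(nogrp), "group")
})

test_that("nomination loading validates and reports unknown ids", {
  roster <- toy_roster()
  ok <- as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
                                  sign = "positive", intensity = 1), roster)
  expect_equal(nrow(ok), 1)

  expect_error(as_nominations(data.frame(ego = "s1", alter = "s1", wave = 1,
                                         sign = "positive", intensity = 1),
                              roster),
               "self-nomination")
  expect_error(as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
                                         sign = "positive", intensity = 3),
                              roster),
               "intensity")
  expect_warning(
    res <- as_nominations(data.frame(ego = c("s1", "s1"),
                                     alter = c("s2", "zz"), wave = 1,
                                     sign = "positive", intensity = 1),
                          roster),
    "rejected")
  expect_equal(nrow(res), 1)
  expect_equal(attr(res, "rejected")$alter, "zz")
})

test_that("question-level merging maps the six raw questions to two levels", {
  roster <- toy_roster()
  raw <- data.frame(ego = "s1", alter = "s2", wave = 1, question = 1:6)
  recs <- merge_question_levels(raw, roster)
  expect_equal(recs$sign, rep(c("positive", "negative"), each = 3))
  expect_equal(recs$intensity, c(2L, 2L, 1L, 2L, 2L, 1L))
})

test_that("weight resolution applies most-intense, cross-sign sum and zero removal", {
  roster <- toy_roster()
  # duplicate reports within a sign: the most intense wins
  recs <- as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
                                    sign = "positive", intensity = c(1, 2)),
                         roster)
  net <- resolve_weights(recs, 1, roster)
  expect_equal(net$edges$weight, 2)

  # opposite signs of equal magnitude cancel and the link disappears
  recs <- as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
                                    sign = c("positive", "negative"),
                                    intensity = c(2, 2)), roster)
  net <- resolve_weights(recs, 1, roster)
  expect_equal(nrow(net$edges), 0)

  # opposite signs of different magnitude sum
  recs <- as_nominations(data.frame(ego = "s1", alter = "s2", wave = 1,
                                    sign = c("positive", "negative"),
                                    intensity = c(1, 2)), roster)
  net <- resolve_weights(recs, 1, roster)
  expect_equal(net$edges$weight, 1)  # +2 + (-1)
})

test_that("weight resolution is invariant to record order and yields legal weights", {
  roster <- toy_roster()
  path <- system.file("extdata", "toy_nominations.csv", package = "signedcircles")
  recs <- load_nominations(path, roster)
  net <- resolve_weights(recs, 1, roster)
  for (s in 1:5) {
    set.seed(s)
    shuffled <- recs[sample(nrow(recs)), ]
    net2 <- resolve_weights(shuffled, 1, roster)
    expect_identical(net2$edges, net$edges)
  }
  expect_true(all(net$edges$weight %in% c(-2, -1, 1, 2)))
  expect_false(any(net$edges$from == net$edges$to))
})

test_that("non-participant egos are dropped and nominated non-participants flagged", {
  roster <- as_roster(data.frame(id = c("s1", "s2", "s3"), group = "A",
                                 gender = "F", wave1 = c(TRUE, TRUE, FALSE),
                                 wave2 = TRUE))
  recs <- as_nominations(data.frame(ego = c("s1", "s3"), alter = c("s3", "s1"),
                                    wave = 1, sign = "positive", intensity = 1),
                         roster)
  expect_warning(net <- resolve_weights(recs, 1, roster), "did not participate")
  expect_equal(attr(net, "non_participants"), "s3")
  expect_equal(net$edges$from, "s1")  # s3's nomination dropped, s3 kept as alter
})

test_that("subnetwork restricts by group and sign and is idempotent", {
  roster <- toy_roster()
  net <- signed_network(roster$id, data.frame(
    from = c("s1", "s1", "s4", "s2"), to = c("s2", "s4", "s5", "s3"),
    weight = c(2, 1, -1, -2)))
  a <- subnetwork(net, roster, groups = "A")
  expect_setequal(a$nodes, c("s1", "s2", "s3"))
  expect_equal(nrow(a$edges), 2)  # s1->s2 and s2->s3 survive
  expect_identical(subnetwork(a, roster, groups = "A")$edges, a$edges)

  pos <- subnetwork(net, sign = "positive")
  expect_true(all(pos$edges$weight > 0))
  neg <- subnetwork(net, sign = "negative")
  expect_equal(nrow(neg$edges), 2)
  expect_error(subnetwork(net, roster, groups = "Z"), "unknown group")

  all_pos <- signed_network(c("a", "b"), data.frame(from = "a", to = "b",
                                                    weight = 1))
  expect_identical(subnetwork(all_pos, sign = "positive")$edges, all_pos$edges)
})

test_that("GraphML round-trip preserves nodes, edges, weights and attributes", {
  roster <- toy_roster()
  recs <- load_nominations(system.file("extdata", "toy_nominations.csv",
                                       package = "signedcircles"), roster)
  net <- resolve_weights(recs, 1, roster)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, path, roster)
  rt <- read_graphml(path)
  expect_setequal(rt$network$nodes, net$nodes)
  ord <- function(e) e[order(e$from, e$to), ]
  expect_equal(ord(rt$network$edges), ord(net$edges), ignore_attr = TRUE)
  expect_equal(rt$node_attributes$group[match(roster$id, rt$node_attributes$id)],
               roster$group)

  # empty network round-trips to empty
  e0 <- signed_network(c("x", "y"))
  p0 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(e0, p0)
  expect_equal(nrow(read_graphml(p0)$network$edges), 0)

  expect_error(read_graphml(p0 <- withr::local_tempfile(fileext = ".graphml",
                                                        lines = "not xml")),
               "malformed")
})

test_that("signed_network rejects invalid weights, loops and duplicates", {
  expect_error(signed_network("a", data.frame(from = "a", to = "a", weight = 1)),
               "self-loop")
  expect_error(signed_network(c("a", "b"),
                              data.frame(from = "a", to = "b", weight = 0)),
               "weights")
  expect_error(signed_network(c("a", "b"),
                              data.frame(from = c("a", "a"), to = c("b", "b"),
                                         weight = c(1, 2))),
               "duplicate")
  net <- signed_network(c("a", "b", "c"),
                        data.frame(from = c("a", "b"), to = c("b", "c"),
                                   weight = c(2, -1)))
  tot <- network_totals(net)
  expect_equal(tot$w_plus, 2)
  expect_equal(tot$w_minus, -1)
  s <- signedcircles:::node_strengths(net, "positive")
  expect_equal(sum(s$out), tot$w_plus)
  expect_equal(sum(s$`in`), tot$w_plus)
})
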