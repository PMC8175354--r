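#' Configuration for the synthetic nomination-network generator
#'
#' Defaults emulate the surveyed cohort: five class groups of 29-31 students
#' (151 in total), gender ratios spanning balanced to strongly imbalanced
#' groups, planted friendship communities of about a dozen students (the
#' "sympathy group" scale) with a gender bias, inner/outer positive circles
#' with wave-1 means 14.5 and 27 (ratio 1.86), sparse negative nominations
#' (about 7 per student), reciprocity around 57%, and a second wave with a
#' smaller inner circle, a larger circle ratio and some community churn.
#'
#' @param n_groups number of class groups.
#' @param group_sizes integer vector of group sizes (recycled to `n_groups`).
#' @param girl_fraction per-group fraction of girls (recycled).
#' @param community_size target size of planted communities within a group.
#' @param community_gender_bias fraction of each planted community drawn
#'   from its majority gender.
#' @param mean_C1 Poisson mean of the inner-circle out-degree (C1).
#' @param circle_ratio expected C2 / C1, so the outer ring C2 - C1 has
#'   Poisson mean `mean_C1 * (circle_ratio - 1)`. Must exceed 1.
#' @param p_intra_community probability a positive nomination targets the
#'   ego's planted community (while candidates remain).
#' @param gender_homophily probability a positive nomination targets the
#'   ego's own gender (while candidates remain).
#' @param reciprocity_target fraction of positive nominations that are
#'   reciprocated; realized by mutual-dyad construction, see
#'   [generate_wave()].
#' @param neg_rate Poisson mean of the negative out-degree.
#' @param neg_intensity2_fraction fraction of negative nominations at the
#'   inner ("worst enemy") level.
#' @param neg_cross_community_bias probability a negative nomination targets
#'   a node outside the ego's planted community.
#' @param wave2_drift list with `delta_mean_C1`, `delta_circle_ratio` and
#'   `community_churn` (fraction of students reassigned to a different
#'   planted community in wave 2).
#' @param seed integer seed; all generator output is deterministic given it.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(n_groups = 5,
                             group_sizes = c(29, 31, 30, 30, 31),
                             girl_fraction = c(0.69, 0.5, 0.5, 0.37, 0.5),
                             community_size = 12,
                             community_gender_bias = 0.85,
                             mean_C1 = 14.5,
                             circle_ratio = 1.86,
                             p_intra_community = 0.35,
                             gender_homophily = 0.7,
                             reciprocity_target = 0.566,
                             neg_rate = 6.9,
                             neg_intensity2_fraction = 0.3,
                             neg_cross_community_bias = 0.8,
                             wave2_drift = list(delta_mean_C1 = -3.2,
                                                delta_circle_ratio = 0.67,
                                                community_churn = 0.3),
                             seed = 1) {
  cfg <- list(n_groups = as.integer(n_groups),
              group_sizes = as.integer(rep_len(group_sizes, n_groups)),
              girl_fraction = rep_len(girl_fraction, n_groups),
              community_size = community_size,
              community_gender_bias = community_gender_bias,
              mean_C1 = mean_C1, circle_ratio = circle_ratio,
              p_intra_community = p_intra_community,
              gender_homophily = gender_homophily,
              reciprocity_target = reciprocity_target,
              neg_rate = neg_rate,
              neg_intensity2_fraction = neg_intensity2_fraction,
              neg_cross_community_bias = neg_cross_community_bias,
              wave2_drift = utils::modifyList(
                list(delta_mean_C1 = 0, delta_circle_ratio = 0,
                     community_churn = 0), as.list(wave2_drift)),
              seed = as.integer(seed))
  props <- c(cfg$girl_fraction, cfg$community_gender_bias,
             cfg$p_intra_community, cfg$gender_homophily,
             cfg$reciprocity_target, cfg$neg_intensity2_fraction,
             cfg$neg_cross_community_bias, cfg$wave2_drift$community_churn)
  if (any(props < 0 | props > 1)) {
    stop_validation("all proportions must lie in [0, 1]")
  }
  if (any(cfg$group_sizes < 1)) stop_validation("group sizes must be positive")
  if (cfg$circle_ratio <= 1) stop_validation("circle_ratio must exceed 1")
  if (cfg$mean_C1 < 1) stop_validation("mean_C1 must be >= 1")
  n <- sum(cfg$group_sizes)
  for (w in 1:2) {
    mC1 <- cfg$mean_C1 + (w == 2) * cfg$wave2_drift$delta_mean_C1
    ratio <- cfg$circle_ratio + (w == 2) * cfg$wave2_drift$delta_circle_ratio
    if (mC1 < 1 || ratio <= 1) {
      stop_validation("wave-2 drift pushes mean_C1 below 1 or circle_ratio below 1")
    }
    if (mC1 * ratio >= n - 1) {
      stop_validation("requested circle sizes exceed the cohort: mean_C1 * ",
                      "circle_ratio must stay below the number of possible alters")
    }
  }
  structure(cfg, class = "generator_config")
}

# roster + planted communities, derived from the seed alone so that both
# waves share them
build_cohort <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, "roster"), {
    n <- sum(cfg$group_sizes)
    ids <- sprintf("s%03d", seq_len(n))
    grp <- rep(LETTERS[seq_len(cfg$n_groups)], cfg$group_sizes)
    gender <- unlist(lapply(seq_len(cfg$n_groups), function(g) {
      k <- cfg$group_sizes[g]
      ng <- round(cfg$girl_fraction[g] * k)
      sample(c(rep("F", ng), rep("M", k - ng)))
    }), use.names = FALSE)
    roster <- as_roster(data.frame(id = ids, group = grp, gender = gender,
                                   wave1 = TRUE, wave2 = TRUE,
                                   stringsAsFactors = FALSE))
    community <- character(n)
    for (g in unique(grp)) {
      members <- which(grp == g)
      k <- length(members)
      n_blocks <- max(1L, round(k / cfg$community_size))
      sizes <- diff(round(seq(0, k, length.out = n_blocks + 1)))
      # alternate majority genders across blocks, weighted by availability
      pool_f <- members[gender[members] == "F"]
      pool_m <- members[gender[members] == "M"]
      pool_f <- sample(pool_f); pool_m <- sample(pool_m)
      for (b in seq_len(n_blocks)) {
        maj <- if (b %% 2 == 1) {
          if (length(pool_f) >= length(pool_m)) "F" else "M"
        } else {
          if (length(pool_m) >= length(pool_f)) "M" else "F"
        }
        want_maj <- round(cfg$community_gender_bias * sizes[b])
        take <- function(pool, k) utils::head(pool, min(k, length(pool)))
        if (maj == "F") {
          t1 <- take(pool_f, want_maj); pool_f <- setdiff(pool_f, t1)
          t2 <- take(pool_m, sizes[b] - length(t1)); pool_m <- setdiff(pool_m, t2)
          t3 <- take(pool_f, sizes[b] - length(t1) - length(t2))
          pool_f <- setdiff(pool_f, t3)
        } else {
          t1 <- take(pool_m, want_maj); pool_m <- setdiff(pool_m, t1)
          t2 <- take(pool_f, sizes[b] - length(t1)); pool_f <- setdiff(pool_f, t2)
          t3 <- take(pool_m, sizes[b] - length(t1) - length(t2))
          pool_m <- setdiff(pool_m, t3)
        }
        community[c(t1, t2, t3)] <- paste0(g, b)
      }
    }
    list(roster = roster, community = stats::setNames(community, ids))
  })
}

# weighted sample of `size` distinct targets for one ego.
# Preference is expressed per draw: with probability p_comm the draw is
# restricted to same-community candidates (while any remain), and within the
# chosen pool same-gender candidates are preferred with probability p_gender.
pick_targets <- function(cand, same_comm, same_gender, size, p_comm, p_gender) {
  chosen <- integer(0)
  avail <- rep(TRUE, length(cand))
  for (d in seq_len(min(size, length(cand)))) {
    pool <- avail
    if (stats::runif(1) < p_comm && any(pool & same_comm)) {
      pool <- pool & same_comm
    }
    if (stats::runif(1) < p_gender && any(pool & same_gender)) {
      pool <- pool & same_gender
    }
    pick <- which(pool)
    pick <- if (length(pick) == 1) pick else sample(pick, 1)
    chosen <- c(chosen, pick)
    avail[pick] <- FALSE
  }
  cand[chosen]
}

#' Generate one wave of a synthetic nomination network
#'
#' Per ego the inner-circle size `C1` and the outer ring `C2 - C1` are drawn
#' from Poisson distributions with the configured means (wave-2 means
#' shifted by the drift), truncated to the number of available alters.
#' Targets are chosen with planted-community preference and gender
#' homophily. Reciprocity is realized structurally: the target number of
#' mutual dyads `D = round(t * m / 2)` (with `t` the reciprocity target and
#' `m` the total drawn out-degree) is matched between egos with remaining
#' out-capacity under the same preferences, and the remaining out-slots
#' become single arcs that are forbidden from closing a dyad by accident, so
#' the realized reciprocity `2D / m` hits the target without inflating the
#' drawn circle sizes. Negative nominations are drawn at `neg_rate`, avoid
#' the ego's positive targets, and are biased across planted communities.
#'
#' @param config a [generator_config()].
#' @param wave 1 or 2.
#' @return list with `roster`, `network` (a [signed_network()]),
#'   `records` (the nomination table the network resolves from) and `truth`
#'   (list: planted `community`, drawn `C1`/`C2` per ego, realized
#'   `reciprocity`, `n_dyads`).
#' @export
generate_wave <- function(config, wave = 1) {
  stopifnot(inherits(config, "generator_config"), wave %in% c(1, 2))
  cohort <- build_cohort(config)
  generate_wave_edges(config, wave, cohort)
}

generate_wave_edges <- function(config, wave, cohort) {
  cfg <- config
  roster <- cohort$roster
  community <- cohort$community
  n <- nrow(roster)
  mC1 <- cfg$mean_C1 + (wave == 2) * cfg$wave2_drift$delta_mean_C1
  ratio <- cfg$circle_ratio + (wave == 2) * cfg$wave2_drift$delta_circle_ratio
  withr::with_seed(stage_seed(cfg$seed, paste0("edges", wave)), {
    l1 <- stats::rpois(n, mC1)
    l2 <- stats::rpois(n, mC1 * (ratio - 1))
    over <- (l1 + l2) > (n - 1)
    l2[over] <- pmax(0L, (n - 1L) - l1[over])
    l1[over] <- pmin(l1[over], n - 1L)
    d <- l1 + l2

    gender <- roster$gender
    same_comm_mat <- NULL  # computed lazily per ego
    out_nbrs <- vector("list", n)
    in_nbrs <- vector("list", n)
    dyad_partner <- vector("list", n)

    # --- mutual dyads ---
    m_total <- sum(d)
    D <- round(cfg$reciprocity_target * m_total / 2)
    rem <- d
    made <- 0L
    stall <- 0L
    while (made < D && stall < 4L * n) {
      open <- which(rem > 0L)
      if (length(open) < 2L) break
      u <- if (length(open) == 1) open else
        sample(open, 1, prob = rem[open])
      cand <- setdiff(open, c(u, out_nbrs[[u]]))
      if (!length(cand)) { stall <- stall + 1L; next }
      w <- rep(1, length(cand))
      sc <- community[cand] == community[u]
      sg <- gender[cand] == gender[u]
      # convert per-draw preference probabilities into candidate weights
      if (any(sc) && any(!sc)) {
        w[sc] <- w[sc] * odds_weight(cfg$p_intra_community, sum(sc), sum(!sc))
      }
      if (any(sg) && any(!sg)) {
        w[sg] <- w[sg] * odds_weight(cfg$gender_homophily, sum(sg), sum(!sg))
      }
      v <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
      out_nbrs[[u]] <- c(out_nbrs[[u]], v); out_nbrs[[v]] <- c(out_nbrs[[v]], u)
      in_nbrs[[u]] <- c(in_nbrs[[u]], v); in_nbrs[[v]] <- c(in_nbrs[[v]], u)
      dyad_partner[[u]] <- c(dyad_partner[[u]], v)
      dyad_partner[[v]] <- c(dyad_partner[[v]], u)
      rem[u] <- rem[u] - 1L; rem[v] <- rem[v] - 1L
      made <- made + 1L
      stall <- 0L
    }

    # --- single arcs: fill remaining capacity, never closing a dyad ---
    # when the reciprocity target is 1 there is no single-arc quota: leftover
    # capacity is dropped so that every edge stays reciprocated
    if (cfg$reciprocity_target < 1) {
      for (u in sample.int(n)) {
        if (rem[u] <= 0L) next
        cand <- setdiff(seq_len(n), c(u, out_nbrs[[u]], in_nbrs[[u]]))
        if (!length(cand)) next
        sc <- community[cand] == community[u]
        sg <- gender[cand] == gender[u]
        picks <- pick_targets(cand, sc, sg, rem[u],
                              cfg$p_intra_community, cfg$gender_homophily)
        out_nbrs[[u]] <- c(out_nbrs[[u]], picks)
        for (v in picks) in_nbrs[[v]] <- c(in_nbrs[[v]], u)
        rem[u] <- rem[u] - length(picks)
      }
    }

    # --- intensities: each ego marks l1 of its targets as inner circle,
    # preferring community members ---
    rec_ego <- character(); rec_alter <- character(); rec_int <- integer()
    ids <- roster$id
    for (u in seq_len(n)) {
      tg <- out_nbrs[[u]]
      if (!length(tg)) next
      k1 <- min(l1[u], length(tg))
      inner <- if (k1 > 0) {
        w <- rep(1, length(tg))
        sc <- community[tg] == community[u]
        if (any(sc) && any(!sc)) {
          w[sc] <- w[sc] * odds_weight(cfg$p_intra_community, sum(sc), sum(!sc))
        }
        if (k1 == length(tg)) tg else sample(tg, k1, prob = w)
      } else integer(0)
      rec_ego <- c(rec_ego, rep(ids[u], length(tg)))
      rec_alter <- c(rec_alter, ids[tg])
      rec_int <- c(rec_int, ifelse(tg %in% inner, 1L, 2L))
    }
    pos_records <- if (length(rec_ego)) {
      data.frame(ego = rec_ego, alter = rec_alter, wave = wave,
                 sign = "positive", intensity = rec_int,
                 stringsAsFactors = FALSE)
    } else NULL

    # --- negative nominations ---
    n_neg <- stats::rpois(n, cfg$neg_rate)
    rec_ego <- character(); rec_alter <- character(); rec_int <- integer()
    for (u in seq_len(n)) {
      if (n_neg[u] == 0L) next
      cand <- setdiff(seq_len(n), c(u, out_nbrs[[u]]))
      if (!length(cand)) next
      cross <- community[cand] != community[u]
      sg <- rep(FALSE, length(cand))  # no gender preference for enmity
      picks <- pick_targets(cand, cross, sg, n_neg[u],
                            cfg$neg_cross_community_bias, 0)
      k <- length(picks)
      rec_ego <- c(rec_ego, rep(ids[u], k))
      rec_alter <- c(rec_alter, ids[picks])
      rec_int <- c(rec_int, ifelse(stats::runif(k) < cfg$neg_intensity2_fraction,
                                   1L, 2L))
    }
    neg_records <- if (length(rec_ego)) {
      data.frame(ego = rec_ego, alter = rec_alter, wave = wave,
                 sign = "negative", intensity = rec_int,
                 stringsAsFactors = FALSE)
    } else NULL

    records <- rbind(pos_records, neg_records)
    records <- as_nominations(records, roster)
    net <- resolve_weights(records, wave, roster)
    truth <- list(community = community,
                  C1_drawn = stats::setNames(l1, ids),
                  C2_drawn = stats::setNames(l1 + l2, ids),
                  n_dyads = made,
                  reciprocity = reciprocity(net, "positive"))
    list(roster = roster, network = net, records = records, truth = truth)
  })
}

# weight multiplier making P(draw in the preferred class) ~ p when the class
# holds n_in of n_in + n_out candidates
odds_weight <- function(p, n_in, n_out) {
  if (p >= 1) return(1e9)
  if (p <= 0) return(1e-9)
  (p * n_out) / ((1 - p) * n_in)
}

#' Generate a linked two-wave synthetic cohort
#'
#' Wave 1 is generated at the configured parameters; wave 2 reuses the same
#' roster and planted communities, except that a `community_churn` fraction
#' of students is reassigned to a different planted community within their
#' group (where the group has more than one), and the circle means are
#' shifted by the configured drift.
#'
#' @param config a [generator_config()].
#' @return list with `pair` (a [network_pair()]), per-wave `records`, and
#'   `truth` (list with `wave1`, `wave2` truth as in [generate_wave()]).
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- build_cohort(config)
  w1 <- generate_wave_edges(config, 1, cohort)
  churn <- config$wave2_drift$community_churn
  cohort2 <- cohort
  if (churn > 0) {
    withr::with_seed(stage_seed(config$seed, "churn"), {
      com <- cohort$community
      grp <- cohort$roster$group
      n <- length(com)
      move <- which(stats::runif(n) < churn)
      for (i in move) {
        others <- setdiff(unique(com[grp == grp[i]]), com[i])
        if (length(others)) {
          com[i] <- if (length(others) == 1) others else sample(others, 1)
        }
      }
      cohort2$community <- com
    })
  }
  w2 <- generate_wave_edges(config, 2, cohort2)
  list(pair = network_pair(w1$network, w2$network, cohort$roster),
       records = rbind(w1$records, w2$records),
       truth = list(wave1 = w1$truth, wave2 = w2$truth))
}

#' Generate a perfectly balanced two-faction network
#'
#' Positive edges appear only within each of the two factions (reciprocated,
#' density `p_within` over unordered pairs) and negative edges only between
#' factions (reciprocated, density `p_between`), so every triangle has an
#' even number of negative edges by construction: the canonical decomposition
#' of a perfectly balanced network into two positive subnetworks joined by
#' purely negative links.
#'
#' @param faction_sizes integer vector of length 2 (a size may be 0).
#' @param p_within,p_between densities in `[0, 1]`.
#' @param seed integer seed.
#' @return a [signed_network()] with weights +1 / -1.
#' @export
generate_balanced <- function(faction_sizes, p_within = 0.9, p_between = 0.5,
                              seed = 1) {
  stopifnot(length(faction_sizes) == 2, all(faction_sizes >= 0),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1)
  n <- sum(faction_sizes)
  ids <- sprintf("f%d_%02d", rep(1:2, faction_sizes),
                 unlist(lapply(faction_sizes, seq_len), use.names = FALSE))
  fac <- rep(1:2, faction_sizes)
  withr::with_seed(seed, {
    edges <- list()
    if (n >= 2) {
      pr <- utils::combn(n, 2)
      same <- fac[pr[1, ]] == fac[pr[2, ]]
      u <- stats::runif(ncol(pr))
      keep <- ifelse(same, u < p_within, u < p_between)
      a <- pr[1, keep]; b <- pr[2, keep]
      w <- ifelse(fac[a] == fac[b], 1, -1)
      edges <- data.frame(from = c(ids[a], ids[b]), to = c(ids[b], ids[a]),
                          weight = c(w, w), stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(from = character(), to = character(),
                          weight = numeric())
    }
    signed_network(ids, edges)
  })
}

#' Signed planted-partition benchmark
#'
#' Directed signed network with block structure: for every ordered pair the
#' edge is positive (+1) with the within/between positive probability, and
#' otherwise negative (-1) with the within/between negative probability.
#' A recoverable community signal needs `p_in_pos > p_out_pos` and
#' `p_in_neg < p_out_neg`.
#'
#' @param block_sizes integer vector of planted block sizes.
#' @param p_in_pos,p_out_pos positive-edge probabilities within / between
#'   blocks.
#' @param p_in_neg,p_out_neg negative-edge probabilities within / between
#'   blocks.
#' @param seed integer seed.
#' @return list with `network` (a [signed_network()]) and `truth` (named
#'   integer vector of planted block memberships).
#' @export
planted_partition_signed <- function(block_sizes, p_in_pos, p_out_pos,
                                     p_in_neg, p_out_neg, seed = 1) {
  probs <- c(p_in_pos, p_out_pos, p_in_neg, p_out_neg)
  if (any(probs < 0 | probs > 1)) {
    stop_validation("edge probabilities must lie in [0, 1]")
  }
  stopifnot(all(block_sizes >= 1))
  n <- sum(block_sizes)
  ids <- sprintf("v%03d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  withr::with_seed(seed, {
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), n)
    ok <- from != to
    from <- from[ok]; to <- to[ok]
    same <- block[from] == block[to]
    p_pos <- ifelse(same, p_in_pos, p_out_pos)
    p_neg <- ifelse(same, p_in_neg, p_out_neg)
    u <- stats::runif(length(from))
    is_pos <- u < p_pos
    # a pair cannot carry both signs; negatives are drawn among non-positive
    is_neg <- !is_pos & stats::runif(length(from)) < p_neg
    keep <- is_pos | is_neg
    edges <- data.frame(from = ids[from[keep]], to = ids[to[keep]],
                        weight = ifelse(is_pos[keep], 1, -1),
                        stringsAsFactors = FALSE)
    list(network = signed_network(ids, edges),
         truth = stats::setNames(block, ids))
  })
}
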