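#' Cross-wave community membership flows and composition
#'
#' Builds the contingency matrix of wave-1 community versus wave-2 community
#' membership over the students who participated in both waves, plus
#' per-community gender and roster-group composition tables for each wave
#' (the layout of the study's community-by-group tables).
#'
#' @param pair a [network_pair()].
#' @param partition1,partition2 partitions of the two waves
#'   ([as_partition()] objects or named membership vectors).
#' @param roster roster with `gender` and `group`; defaults to `pair$roster`.
#' @return object of class `community_flow`: list with `flow` (contingency
#'   matrix, rows = wave-1 communities, columns = wave-2), `n_common`, and
#'   per-wave composition tables `group_composition` / `gender_composition`
#'   (community x label counts).
#' @export
community_flows <- function(pair, partition1, partition2, roster = pair$roster) {
  m1 <- if (inherits(partition1, "partition")) partition1$membership else partition1
  m2 <- if (inherits(partition2, "partition")) partition2$membership else partition2
  common <- intersect(names(m1), names(m2))
  flow <- table(wave1 = factor(m1[common]), wave2 = factor(m2[common]))
  comp <- function(m, what) {
    idx <- match(names(m), roster$id)
    table(community = factor(m), label = roster[[what]][idx])
  }
  structure(list(flow = unclass(flow), n_common = length(common),
                 group_composition = list(wave1 = unclass(comp(m1, "group")),
                                          wave2 = unclass(comp(m2, "group"))),
                 gender_composition = list(wave1 = unclass(comp(m1, "gender")),
                                           wave2 = unclass(comp(m2, "gender")))),
            class = "community_flow")
}

#' @export
print.community_flow <- function(x, ...) {
  cat(sprintf("community flows over %d common participants\n", x$n_common))
  print(x$flow)
  invisible(x)
}

#' Community structure with and without negative links
#'
#' Optimizes the partition of the full signed network and of its
#' positive-only subnetwork, and reports which signed-analysis communities
#' merge when the negative links are removed: each signed community is
#' mapped to the positive-only community holding the majority of its
#' members, and communities sharing a target are flagged as merged.
#'
#' @param net a [signed_network()]; a warning is issued when it has no
#'   negative edges (the comparison is then vacuous).
#' @param seed,n_restarts passed to [optimize_partition()].
#' @return list with `signed` and `positive_only` optimizer results, a
#'   `merge_report` data frame (`signed_community`, `positive_community`,
#'   `fraction` of members mapped), and `merged_groups`, a list of signed
#'   community-id vectors that share a positive-only community.
#' @export
positive_only_comparison <- function(net, seed = 1, n_restarts = 10) {
  if (!any(net$edges$weight < 0)) {
    warning("network has no negative edges; the two analyses coincide",
            call. = FALSE)
  }
  full <- optimize_partition(net, n_restarts = n_restarts, seed = seed)
  pos <- subnetwork(net, sign = "positive")
  pos_fit <- optimize_partition(pos, n_restarts = n_restarts, seed = seed)
  ms <- full$partition$membership
  mp <- pos_fit$partition$membership[names(ms)]
  rep_rows <- lapply(sort(unique(ms)), function(c) {
    tgt <- table(mp[ms == c])
    data.frame(signed_community = c,
               positive_community = as.integer(names(tgt)[which.max(tgt)]),
               fraction = max(tgt) / sum(tgt))
  })
  report <- do.call(rbind, rep_rows)
  merged <- split(report$signed_community, report$positive_community)
  merged <- merged[lengths(merged) > 1]
  list(signed = full, positive_only = pos_fit, merge_report = report,
       merged_groups = unname(merged))
}
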