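#' Reciprocity of signed nominations
#'
#' Fraction of directed edges of the given sign whose reverse edge exists
#' with the same sign. Intensity is ignored: a "+2" nomination answered by a
#' "+1" counts as reciprocated.
#'
#' @param net a [signed_network()].
#' @param sign `"positive"` (default) or `"negative"`.
#' @return proportion in `[0, 1]`; `NA` with a warning when the network has
#'   no edge of the requested sign.
#' @export
reciprocity <- function(net, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  e <- net$edges
  e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  if (!nrow(e)) {
    warning("no ", sign, " edges; reciprocity undefined", call. = FALSE)
    return(NA_real_)
  }
  key <- paste(e$from, e$to, sep = "\r")
  rev <- paste(e$to, e$from, sep = "\r")
  mean(rev %in% key)
}

#' Rewiring null model for reciprocity
#'
#' Distribution of the reciprocity statistic when the nomination structure
#' is destroyed by random rewiring. The default mode redraws, for every ego,
#' its out-nominations uniformly at random among all other nodes (keeping
#' each ego's out-degree exactly, never producing self-loops or duplicate
#' edges); under it the expected null reciprocity is close to the mean
#' out-degree divided by `n - 1`. Mode `"double_edge_swap"` instead applies
#' repeated target swaps between random edge pairs, preserving both the out-
#' and in-degree sequences. Percentile confidence bounds are reported at
#' `conf_level`.
#'
#' @param net a [signed_network()].
#' @param n_samples number of rewired realizations (>= 100 for a stable CI).
#' @param seed integer seed; the null is reproducible given the seed.
#' @param mode `"outdegree_preserving"` (default) or `"double_edge_swap"`.
#' @param sign which sign's edges to rewire and score (default positive).
#' @param conf_level level of the percentile interval.
#' @param swaps_per_edge for `"double_edge_swap"`, attempted swaps per edge.
#' @return a [null_distribution()] whose `observed` slot is the empirical
#'   reciprocity of `net`.
#' @export
rewiring_null <- function(net, n_samples = 1000, seed = 1,
                          mode = c("outdegree_preserving", "double_edge_swap"),
                          sign = "positive", conf_level = 0.95,
                          swaps_per_edge = 10) {
  mode <- match.arg(mode)
  if (n_samples < 1) stop_validation("n_samples must be >= 1")
  if (n_samples < 100) {
    warning("fewer than 100 null samples; the percentile CI will be coarse",
            call. = FALSE)
  }
  observed <- reciprocity(net, sign)
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  e <- net$edges
  e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  if (!nrow(e)) stop_validation("no ", sign, " edges to rewire")
  ef <- unname(idx[e$from]); et <- unname(idx[e$to])
  deg <- tabulate(ef, nbins = n)
  if (any(deg > n - 1)) stop_validation("out-degree exceeds n - 1; rewiring impossible")
  egos <- which(deg > 0)
  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      if (mode == "outdegree_preserving") {
        from <- rep.int(egos, deg[egos])
        to <- unlist(lapply(egos, function(u) {
          t <- sample.int(n - 1L, deg[u])
          t + (t >= u)  # skip the ego itself
        }), use.names = FALSE)
      } else {
        from <- ef; to <- et
        m <- length(from)
        present <- logical(n * n)
        present[(from - 1L) * n + to] <- TRUE
        for (a in seq_len(swaps_per_edge * m)) {
          ij <- sample.int(m, 2L)
          i <- ij[1]; j <- ij[2]
          t1 <- to[j]; t2 <- to[i]
          if (from[i] == t1 || from[j] == t2) next
          k1 <- (from[i] - 1L) * n + t1; k2 <- (from[j] - 1L) * n + t2
          if (present[k1] || present[k2]) next
          present[(from[i] - 1L) * n + to[i]] <- FALSE
          present[(from[j] - 1L) * n + to[j]] <- FALSE
          present[k1] <- TRUE; present[k2] <- TRUE
          to[i] <- t1; to[j] <- t2
        }
      }
      key <- (from - 1L) * n + to
      mean(((to - 1L) * n + from) %in% key)
    }, numeric(1))
  })
  null_distribution(samples, observed = observed, conf_level = conf_level,
                    seed = seed)
}
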