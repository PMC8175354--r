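# Independent oracles and fixture builders. These deliberately use the
# slowest, most literal formulations (double loops, triple loops, exhaustive
# enumeration) so they stay independent of the package's optimized paths.

# literal double-sum evaluation of the signed modularity definition
naive_modularity <- function(net, membership, normalization = "2w") {
  nodes <- net$nodes
  n <- length(nodes)
  m <- membership[nodes]
  Wp <- matrix(0, n, n, dimnames = list(nodes, nodes))
  Wn <- Wp
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    if (e$weight > 0) Wp[e$from, e$to] <- e$weight
    else Wn[e$from, e$to] <- -e$weight
  }
  qpart <- function(W) {
    w <- sum(W)
    if (w == 0) return(list(q = 0, w = 0))
    N <- if (normalization == "2w") 2 * w else w
    so <- rowSums(W); si <- colSums(W)
    q <- 0
    for (i in 1:n) for (j in 1:n) {
      if (m[i] == m[j]) q <- q + W[i, j] - so[i] * si[j] / N
    }
    list(q = q / N, w = w)
  }
  p <- qpart(Wp); q <- qpart(Wn)
  list(Q = (p$w * p$q - q$w * q$q) / (p$w + q$w), Q_plus = p$q, Q_minus = q$q)
}

# random signed directed network with weights in {-2,-1,1,2}
random_signed_net <- function(n, p_pos = 0.25, p_neg = 0.1, seed = 1) {
  set.seed(seed)
  from <- integer(); to <- integer(); w <- numeric()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- runif(1)
    if (u < p_pos) {
      from <- c(from, i); to <- c(to, j); w <- c(w, sample(c(1, 2), 1))
    } else if (u < p_pos + p_neg) {
      from <- c(from, i); to <- c(to, j); w <- c(w, sample(c(-1, -2), 1))
    }
  }
  signed_network(paste0("v", seq_len(n)),
                 data.frame(from = paste0("v", from), to = paste0("v", to),
                            weight = w))
}

# literal triple-loop triangle census on a signed undirected graph
naive_triangle_census <- function(g) {
  n <- length(g$nodes)
  idx <- stats::setNames(seq_len(n), g$nodes)
  A <- matrix(FALSE, n, n); S <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(g$edges))) {
    i <- idx[g$edges$a[k]]; j <- idx[g$edges$b[k]]
    A[i, j] <- A[j, i] <- TRUE
    S[i, j] <- S[j, i] <- g$edges$negative[k]
  }
  cnt <- integer(4)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (A[i, j] && A[i, k] && A[j, k]) {
        neg <- S[i, j] + S[i, k] + S[j, k]
        cnt[neg + 1] <- cnt[neg + 1] + 1L
      }
    }
  }
  cnt
}

# random signed undirected graph (for census / embedding tests)
random_undirected <- function(n, p = 0.4, p_neg = 0.3, seed = 1) {
  set.seed(seed)
  pr <- utils::combn(n, 2)
  keep <- runif(ncol(pr)) < p
  ed <- data.frame(a = paste0("v", pr[1, keep]), b = paste0("v", pr[2, keep]),
                   negative = runif(sum(keep)) < p_neg,
                   stringsAsFactors = FALSE)
  structure(list(nodes = paste0("v", seq_len(n)), edges = ed),
            class = "signed_undirected")
}

# minimum unbalanced-triangle count over every placement of the graph's
# negative edges (exhaustive; graphs with few edges only)
min_unbalanced_exhaustive <- function(g) {
  m <- nrow(g$edges)
  k <- sum(g$edges$negative)
  stopifnot(m <= 14)
  combos <- utils::combn(m, k)
  best <- Inf
  for (c in seq_len(ncol(combos))) {
    gg <- g
    gg$edges$negative <- seq_len(m) %in% combos[, c]
    best <- min(best, triangle_census(gg)$unbalanced)
  }
  best
}

# roster + nomination fixture exercising every weight-resolution rule;
# mirrors inst/extdata/toy_{roster,nominations}.csv
toy_roster <- function() {
  as_roster(data.frame(id = paste0("s", 1:5),
                       group = c("A", "A", "A", "B", "B"),
                       gender = c("F", "M", "F", "M", "F"),
                       wave1 = TRUE, wave2 = TRUE, stringsAsFactors = FALSE))
}

# the signed comparison fixture: two complete +2 blocks of four, all
# cross-block dyads mutual +1 except a perfect matching of mutual -2 pairs.
# Dropping the negatives makes merging the blocks optimal; keeping them
# makes the two-block split optimal (verified by brute force in the tests).
two_block_fixture <- function() {
  ids <- paste0("n", 1:8)
  blk <- rep(1:2, each = 4)
  rows <- list()
  for (i in 1:8) for (j in 1:8) {
    if (i == j) next
    w <- if (blk[i] == blk[j]) 2 else if (abs(i - j) == 4) -2 else 1
    rows[[length(rows) + 1]] <- data.frame(from = ids[i], to = ids[j],
                                           weight = w)
  }
  signed_network(ids, do.call(rbind, rows))
}
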