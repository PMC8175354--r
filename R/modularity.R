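#' Signed, directed, weighted modularity
#'
#' Evaluates the signed modularity of a partition,
#' \deqn{Q = \frac{w^+}{w^+ + |w^-|} Q^+ - \frac{|w^-|}{w^+ + |w^-|} Q^-,}
#' where the positive part is
#' \deqn{Q^+ = \frac{1}{2w^+} \sum_{i,j} \left(w^+_{ij} -
#'   \frac{w^{+,out}_i w^{+,in}_j}{2w^+}\right) \delta(C_i, C_j)}
#' and \eqn{Q^-} is the analogous expression on the absolute values of the
#' negative weights. `Q` balances the tendency of positive links to bind
#' communities against the tendency of negative links to break them: positive
#' weight inside communities raises `Q`, negative weight inside communities
#' lowers it. With no negative edges `Q = Q+` exactly.
#'
#' The sum runs over all ordered pairs including `i = j`: networks carry no
#' self-loops, but the null-model term for `i = j` is included. The printed
#' `2w` normalization (both the prefactor and the null term) is the default;
#' some of the directed-modularity literature normalizes by `w` instead,
#' available as `normalization = "w"` (the two give different absolute `Q`
#' but the same optimal partitions are typical, not guaranteed).
#'
#' @param net a [signed_network()] with at least one edge.
#' @param membership named vector (names = node ids) of community labels
#'   covering every node of `net`, or an unnamed vector in `net$nodes` order.
#' @param normalization `"2w"` (as defined above, default) or `"w"`.
#' @return object of class `modularity_result`: list with `Q`, `Q_plus`,
#'   `Q_minus`, `w_plus`, `w_minus_abs`, `normalization`.
#' @export
modularity_signed <- function(net, membership, normalization = c("2w", "w")) {
  normalization <- match.arg(normalization)
  m <- align_membership(net, membership)
  e <- net$edges
  if (!nrow(e)) stop_validation("modularity is undefined on an edgeless network")
  part <- function(sign) {
    ee <- if (sign > 0) e[e$weight > 0, ] else e[e$weight < 0, ]
    w_tot <- sum(abs(ee$weight))
    if (w_tot == 0) return(list(Q = 0, w = 0))
    norm <- if (normalization == "2w") 2 * w_tot else w_tot
    within <- sum(abs(ee$weight)[m[ee$from] == m[ee$to]])
    s <- node_strengths(net, if (sign > 0) "positive" else "negative")
    sout_c <- rowsum(s$out, m[names(s$out)])
    sin_c <- rowsum(s$`in`, m[names(s$`in`)])
    null <- sum(sout_c[, 1] * sin_c[rownames(sout_c), 1]) / norm
    list(Q = (within - null) / norm, w = w_tot)
  }
  p <- part(+1); q <- part(-1)
  denom <- p$w + q$w
  structure(list(Q = (p$w * p$Q - q$w * q$Q) / denom,
                 Q_plus = p$Q, Q_minus = q$Q,
                 w_plus = p$w, w_minus_abs = q$w,
                 normalization = normalization),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf("Q = %.5f  (Q+ = %.5f, Q- = %.5f; w+ = %g, |w-| = %g, norm %s)\n",
              x$Q, x$Q_plus, x$Q_minus, x$w_plus, x$w_minus_abs,
              x$normalization))
  invisible(x)
}

# normalize a membership spec into a named vector over net$nodes with
# integer community ids contiguous from 1
align_membership <- function(net, membership) {
  if (is.null(names(membership))) {
    if (length(membership) != length(net$nodes)) {
      stop_validation("unnamed membership must have one entry per node")
    }
    names(membership) <- net$nodes
  }
  missing <- setdiff(net$nodes, names(membership))
  if (length(missing)) {
    stop_validation("membership missing node(s): ",
                    paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- membership[net$nodes]
  stats::setNames(as.integer(factor(m, levels = unique(m))), net$nodes)
}

#' Canonical partition object
#'
#' @param membership named vector mapping node ids to community labels.
#' @return object of class `partition`: list with `membership` (named
#'   integer, community ids contiguous from 1), `n_communities`, `members`
#'   (list of node-id vectors).
#' @export
as_partition <- function(membership) {
  m <- stats::setNames(as.integer(factor(membership,
                                         levels = unique(membership))),
                       names(membership))
  structure(list(membership = m,
                 n_communities = max(m, 0L),
                 members = split(names(m), m)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d communities (sizes %s)\n",
              length(x$membership), x$n_communities,
              paste(lengths(x$members), collapse = ", ")))
  invisible(x)
}

# ---- internal optimizer machinery ------------------------------------------
# Dense per-sign adjacency matrices and aggregates reused across moves.

build_mod_env <- function(net, normalization) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  Wp <- matrix(0, n, n); Wn <- matrix(0, n, n)
  e <- net$edges
  pos <- e$weight > 0
  if (any(pos)) Wp[cbind(idx[e$from[pos]], idx[e$to[pos]])] <- e$weight[pos]
  if (any(!pos)) Wn[cbind(idx[e$from[!pos]], idx[e$to[!pos]])] <- -e$weight[!pos]
  wp <- sum(Wp); wn <- sum(Wn)
  list(n = n, nodes = net$nodes, Wp = Wp, Wn = Wn,
       so_p = rowSums(Wp), si_p = colSums(Wp),
       so_n = rowSums(Wn), si_n = colSums(Wn),
       Np = if (normalization == "2w") 2 * wp else wp,
       Nn = if (normalization == "2w") 2 * wn else wn,
       alpha = if (wp + wn > 0) wp / (wp + wn) else 0,
       beta = if (wp + wn > 0) wn / (wp + wn) else 0)
}

# Q computed from scratch for a membership vector (integer, length n)
mod_eval <- function(env, m) {
  qpart <- function(W, so, si, N) {
    if (N == 0) return(0)
    within <- sum(W[m[row(W)] == m[col(W)]])
    a <- rowsum(so, m); b <- rowsum(si, m)
    (within - sum(a[, 1] * b[rownames(a), 1]) / N) / N
  }
  env$alpha * qpart(env$Wp, env$so_p, env$si_p, env$Np) -
    env$beta * qpart(env$Wn, env$so_n, env$si_n, env$Nn)
}

# fast Q for many memberships: same as mod_eval but avoids matrix logical
mod_eval_fast <- function(ef, et, wp_e, wn_e, so_p, si_p, so_n, si_n,
                          Np, Nn, alpha, beta, m) {
  same <- m[ef] == m[et]
  qp <- 0; qn <- 0
  if (Np > 0) {
    a <- rowsum(so_p, m); b <- rowsum(si_p, m)
    qp <- (sum(wp_e[same]) - sum(a[, 1] * b[rownames(a), 1]) / Np) / Np
  }
  if (Nn > 0) {
    a <- rowsum(so_n, m); b <- rowsum(si_n, m)
    qn <- (sum(wn_e[same]) - sum(a[, 1] * b[rownames(a), 1]) / Nn) / Nn
  }
  alpha * qp - beta * qn
}

# one full local-move phase: sweep nodes in the given order, moving each to
# the community (existing or fresh) with the largest positive gain;
# ties broken toward the lowest community id. Modifies m in place (returns it).
local_move_phase <- function(env, m, order_, tol = 1e-12) {
  n <- env$n
  repeat {
    moved <- FALSE
    for (i in order_) {
      a <- m[i]
      # community aggregates excluding i are derived from full sums below
      cm <- sort(unique(m))
      fresh <- max(cm) + 1L
      cand <- c(cm[cm != a], fresh)
      if (!length(cand)) next
      mp_out <- grouped_sum(env$Wp[i, ], m, c(cand, a))
      mp_in <- grouped_sum(env$Wp[, i], m, c(cand, a))
      mn_out <- grouped_sum(env$Wn[i, ], m, c(cand, a))
      mn_in <- grouped_sum(env$Wn[, i], m, c(cand, a))
      Sout_p <- grouped_sum(env$so_p, m, c(cand, a))
      Sin_p <- grouped_sum(env$si_p, m, c(cand, a))
      Sout_n <- grouped_sum(env$so_n, m, c(cand, a))
      Sin_n <- grouped_sum(env$si_n, m, c(cand, a))
      ca <- as.character(a)
      gain_part <- function(mo, mi, So, Si, so_i, si_i, N) {
        if (N == 0) return(numeric(length(cand)))
        So_c <- So[as.character(cand)]; Si_c <- Si[as.character(cand)]
        # community a without i
        Sa_o <- So[ca] - so_i; Sa_i <- Si[ca] - si_i
        ((mo[as.character(cand)] + mi[as.character(cand)]) -
           (mo[ca] + mi[ca]) -
           (so_i * Si_c + si_i * So_c - so_i * Sa_i - si_i * Sa_o) / N) / N
      }
      gp <- gain_part(mp_out, mp_in, Sout_p, Sin_p,
                      env$so_p[i], env$si_p[i], env$Np)
      gn <- gain_part(mn_out, mn_in, Sout_n, Sin_n,
                      env$so_n[i], env$si_n[i], env$Nn)
      gain <- env$alpha * gp - env$beta * gn
      best <- which(gain > tol)
      if (length(best)) {
        best <- best[order(-gain[best], cand[best])][1]
        m[i] <- cand[best]
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  m
}

# sums of x grouped by membership m, returned as a named vector covering
# `wanted` ids (zeros where a community is empty / fresh)
grouped_sum <- function(x, m, wanted) {
  s <- rowsum(x, m)
  out <- stats::setNames(numeric(length(wanted)), as.character(wanted))
  hit <- intersect(rownames(s), names(out))
  out[hit] <- s[hit, 1]
  out
}

# merge phase: greedily merge the community pair with the largest positive
# gain until no merge improves Q
merge_phase <- function(env, m, tol = 1e-12) {
  repeat {
    cm <- sort(unique(m))
    k <- length(cm)
    if (k < 2) break
    mm <- match(m, cm)
    agg <- function(W) {
      A <- rowsum(W, mm)
      t(rowsum(t(A), mm))
    }
    Bp <- agg(env$Wp); Bn <- agg(env$Wn)
    Sout_p <- rowsum(env$so_p, mm)[, 1]; Sin_p <- rowsum(env$si_p, mm)[, 1]
    Sout_n <- rowsum(env$so_n, mm)[, 1]; Sin_n <- rowsum(env$si_n, mm)[, 1]
    gain_mat <- matrix(0, k, k)
    if (env$Np > 0) {
      gain_mat <- gain_mat + env$alpha *
        ((Bp + t(Bp)) - (outer(Sout_p, Sin_p) + t(outer(Sout_p, Sin_p))) / env$Np) / env$Np
    }
    if (env$Nn > 0) {
      gain_mat <- gain_mat - env$beta *
        ((Bn + t(Bn)) - (outer(Sout_n, Sin_n) + t(outer(Sout_n, Sin_n))) / env$Nn) / env$Nn
    }
    diag(gain_mat) <- -Inf
    gain_mat[lower.tri(gain_mat)] <- -Inf
    best <- which.max(gain_mat)
    if (gain_mat[best] <= tol) break
    ij <- arrayInd(best, dim(gain_mat))
    m[m == cm[ij[2]]] <- cm[ij[1]]
  }
  m
}

#' Maximize signed modularity
#'
#' Heuristic optimizer for the signed directed modularity, agnostic to the
#' number of communities. Restarts are diversified over three families of
#' initial partitions (singletons, one community, random assignments with a
#' random number of communities); each restart alternates greedy local moves
#' (every node may move to any existing community or open a new one) with
#' greedy community merges until neither improves `Q`, then attempts a few
#' perturbation-and-reconverge escapes (a random fraction of nodes is
#' reassigned and the search rerun, keeping the perturbed solution only when
#' it improves). The best partition over all restarts is returned.
#' Deterministic given `seed`.
#'
#' @param net a non-empty [signed_network()].
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed controlling the restart shuffles.
#' @param normalization passed to [modularity_signed()].
#' @param n_perturb perturbation escapes attempted per restart.
#' @return list with `partition` (a [as_partition()] object) and
#'   `modularity` (a `modularity_result`).
#' @export
optimize_partition <- function(net, n_restarts = 10, seed = 1,
                               normalization = c("2w", "w"), n_perturb = 3) {
  normalization <- match.arg(normalization)
  if (!nrow(net$edges)) stop_validation("cannot optimize an edgeless network")
  env <- build_mod_env(net, normalization)
  n <- env$n
  converge <- function(m, ord) {
    repeat {
      m <- local_move_phase(env, m, ord)
      q1 <- mod_eval(env, m)
      m2 <- merge_phase(env, m)
      q2 <- mod_eval(env, m2)
      if (q2 > q1 + 1e-12) m <- m2 else break
    }
    m
  }
  best_m <- NULL; best_q <- -Inf
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      m <- if (r == 1) {
        seq_len(n)                      # singletons
      } else if (r == 2) {
        rep(1L, n)                      # one community
      } else if (r %% 2 == 1) {
        seq_len(n)
      } else {
        sample.int(min(n, sample(2:8, 1)), n, replace = TRUE)
      }
      ord <- sample.int(n)
      m <- converge(m, ord)
      q <- mod_eval(env, m)
      for (p in seq_len(n_perturb)) {
        mp <- m
        hit <- stats::runif(n) < 0.25
        if (any(hit)) {
          mp[hit] <- sample.int(max(mp) + 1L, sum(hit), replace = TRUE)
        }
        mp <- converge(mp, sample.int(n))
        qp <- mod_eval(env, mp)
        if (qp > q + 1e-12) { m <- mp; q <- qp }
      }
      if (q > best_q + 1e-12) { best_q <- q; best_m <- m }
    }
  })
  membership <- stats::setNames(best_m, net$nodes)
  part <- as_partition(membership)
  list(partition = part,
       modularity = modularity_signed(net, part$membership, normalization))
}

#' Globally optimal partition by exhaustive enumeration
#'
#' Enumerates every set partition of the node set (Bell-number growth, hence
#' capped at 10 nodes) and returns the partition maximizing signed
#' modularity. Serves as the exact oracle for [optimize_partition()].
#'
#' @inheritParams optimize_partition
#' @return as [optimize_partition()].
#' @export
brute_force_partition <- function(net, normalization = c("2w", "w")) {
  normalization <- match.arg(normalization)
  n <- length(net$nodes)
  if (n > 10) {
    stop_validation("brute_force_partition enumerates set partitions and ",
                    "refuses networks with more than 10 nodes (got ", n, ")")
  }
  if (!nrow(net$edges)) stop_validation("cannot optimize an edgeless network")
  env <- build_mod_env(net, normalization)
  idx <- stats::setNames(seq_len(n), net$nodes)
  e <- net$edges
  pos <- e$weight > 0
  ef <- idx[e$from]; et <- idx[e$to]
  wp_e <- ifelse(pos, e$weight, 0); wn_e <- ifelse(pos, 0, -e$weight)
  parts <- set_partitions(n)
  best_q <- -Inf; best <- NULL
  for (i in seq_len(nrow(parts))) {
    m <- parts[i, ]
    q <- mod_eval_fast(ef, et, wp_e, wn_e, env$so_p, env$si_p, env$so_n,
                       env$si_n, env$Np, env$Nn, env$alpha, env$beta, m)
    if (q > best_q) { best_q <- q; best <- m }
  }
  part <- as_partition(stats::setNames(best, net$nodes))
  list(partition = part,
       modularity = modularity_signed(net, part$membership, normalization))
}

# all set partitions of n elements as restricted growth strings
# (rows = partitions, entries = community ids starting at 1)
set_partitions <- function(n) {
  if (n == 0) return(matrix(integer(), 0, 0))
  rows <- list(c(1L))
  for (el in seq_len(n - 1L)) {
    rows <- unlist(lapply(rows, function(r) {
      k <- max(r)
      lapply(seq_len(k + 1L), function(c) c(r, c))
    }), recursive = FALSE)
  }
  do.call(rbind, rows)
}
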