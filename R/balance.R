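#' Project a signed directed network onto an undirected signed graph
#'
#' Balance theory is defined on undirected signed graphs, while nominations
#' are directed and the two directions of a dyad often disagree in sign.
#' Every unordered pair connected in at least one direction receives an
#' undirected edge; intensity is discarded. Two projection criteria decide
#' the sign:
#' * criterion `"a"`: the edge is negative only when both directions are
#'   present and both are negative (conflict confirmed by both parties);
#' * criterion `"b"`: the edge is negative as soon as either direction is
#'   negative (a single negative report already evidences conflict).
#'
#' Criterion (b)'s negative edge set always contains criterion (a)'s.
#'
#' @param net a [signed_network()].
#' @param criterion `"a"` or `"b"`.
#' @return object of class `signed_undirected`: list with `nodes` and
#'   `edges` (data frame `a`, `b`, `negative` with `a < b`).
#' @export
project_signed <- function(net, criterion = c("a", "b")) {
  criterion <- match.arg(criterion)
  e <- net$edges
  if (nrow(e)) {
    a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
    key <- paste(a, b, sep = "\r")
    neg <- e$weight < 0
    n_dir <- tapply(neg, key, length)
    n_neg <- tapply(neg, key, sum)
    negative <- if (criterion == "a") {
      n_dir == 2 & n_neg == 2
    } else {
      n_neg >= 1
    }
    pk <- do.call(rbind, strsplit(names(n_dir), "\r", fixed = TRUE))
    edges <- data.frame(a = pk[, 1], b = pk[, 2],
                        negative = as.vector(negative),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(), negative = logical())
  }
  structure(list(nodes = net$nodes, edges = edges), class = "signed_undirected")
}

#' @export
print.signed_undirected <- function(x, ...) {
  cat(sprintf("signed_undirected: %d nodes, %d edges (%d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$negative)))
  invisible(x)
}

# internal: triangle list as a T x 3 matrix of edge indices, plus igraph
triangle_index <- function(g) {
  if (!nrow(g$edges) || length(g$nodes) < 3) {
    return(list(tri = matrix(integer(), 0, 3)))
  }
  ig <- igraph::graph_from_data_frame(g$edges[, c("a", "b")], directed = FALSE,
                                      vertices = data.frame(name = g$nodes))
  tv <- matrix(as.integer(igraph::triangles(ig)), nrow = 3)
  if (!ncol(tv)) return(list(tri = matrix(integer(), 0, 3)))
  pairs <- rbind(tv[c(1, 2), , drop = FALSE], tv[c(1, 3), , drop = FALSE],
                 tv[c(2, 3), , drop = FALSE])
  eids <- igraph::get_edge_ids(ig, as.vector(pairs))
  list(tri = matrix(eids, ncol = 3, byrow = TRUE,
                    dimnames = list(NULL, c("e12", "e13", "e23"))))
}

#' Triangle census of a signed undirected graph
#'
#' Counts triangles stratified by their number of negative edges. Triangles
#' with an odd number of negative edges (one or three) are the unbalanced
#' configurations of structural balance theory; balanced triangles have an
#' even number (zero or two).
#'
#' @param g a `signed_undirected` graph from [project_signed()].
#' @return object of class `triangle_census`: list with `counts` (named
#'   vector `n0`..`n3`), `balanced` (`n0 + n2`), `unbalanced` (`n1 + n3`)
#'   and `total`.
#' @export
triangle_census <- function(g) {
  ti <- triangle_index(g)
  nneg <- if (nrow(ti$tri)) {
    s <- g$edges$negative
    s[ti$tri[, 1]] + s[ti$tri[, 2]] + s[ti$tri[, 3]]
  } else integer()
  counts <- vapply(0:3, function(k) sum(nneg == k), integer(1))
  names(counts) <- paste0("n", 0:3)
  structure(list(counts = counts,
                 balanced = counts[["n0"]] + counts[["n2"]],
                 unbalanced = counts[["n1"]] + counts[["n3"]],
                 total = sum(counts)),
            class = "triangle_census")
}

#' @export
print.triangle_census <- function(x, ...) {
  cat(sprintf("triangles: %d total (0/1/2/3 negative edges: %s); %d balanced, %d unbalanced\n",
              x$total, paste(x$counts, collapse = "/"), x$balanced,
              x$unbalanced))
  invisible(x)
}

#' Edge embedding index
#'
#' The embedding of an edge is the number of triangles it belongs to. Edges
#' are partitioned into embedding classes (equal embedding count); these
#' classes are the strata within which signs are permuted by
#' [permutation_balance_test()], because positive and negative subnetworks
#' have very different embedding profiles and unrestricted permutation would
#' distort the network's nature.
#'
#' @param g a `signed_undirected` graph.
#' @return object of class `edge_embedding`: list with `edges` (the graph's
#'   edge data frame plus an `embedding` column) and `classes` (named list
#'   mapping each embedding value to the edge row indices in that class).
#' @export
edge_embedding <- function(g) {
  ti <- triangle_index(g)
  emb <- tabulate(as.vector(ti$tri), nbins = nrow(g$edges))
  edges <- g$edges
  edges$embedding <- emb
  classes <- split(seq_len(nrow(edges)), emb)
  structure(list(edges = edges, classes = classes), class = "edge_embedding")
}

#' Embedding-preserving permutation test of structural balance
#'
#' Tests whether the observed number of unbalanced triangles is small given
#' the graph's topology and its stock of negative edges. Each null
#' realization shuffles edge signs uniformly *within each embedding class*,
#' preserving the topology, the embedding index, and the per-class (hence
#' total) number of negative edges, then recounts unbalanced triangles. The
#' headline quantity is the fraction of realizations with strictly fewer
#' unbalanced triangles than observed: a fraction of zero means no null
#' configuration improves on the observed network, evidence of a strong
#' bias toward balance.
#'
#' @param g a `signed_undirected` graph with at least one negative edge.
#' @param n_realizations number of null realizations (default `1e4`).
#' @param seed integer seed.
#' @param conf_level level for the null percentile interval.
#' @return object of class `balance_test`: list with `observed`
#'   (a [triangle_census()]), `null` (a [null_distribution()] of unbalanced
#'   counts), `fraction_below`, `n_realizations` and `degenerate` (`TRUE`
#'   when every embedding class is a singleton, in which case the null is
#'   constant and the test uninformative).
#' @export
permutation_balance_test <- function(g, n_realizations = 1e4, seed = 1,
                                     conf_level = 0.95) {
  if (n_realizations < 1) stop_validation("n_realizations must be >= 1")
  if (!any(g$edges$negative)) {
    stop_validation("the graph has no negative edge; the balance test needs one")
  }
  ti <- triangle_index(g)
  obs <- triangle_census(g)
  emb <- tabulate(as.vector(ti$tri), nbins = nrow(g$edges))
  classes <- split(seq_len(nrow(g$edges)), emb)
  degenerate <- all(lengths(classes) == 1)
  if (degenerate) {
    warning("all embedding classes are singletons; the null is degenerate",
            call. = FALSE)
  }
  # only classes that can change anything: >1 edge and mixed signs
  s0 <- g$edges$negative
  active <- Filter(function(ix) length(ix) > 1 &&
                     length(unique(s0[ix])) > 1, classes)
  tri <- ti$tri
  samples <- withr::with_seed(seed, {
    vapply(seq_len(n_realizations), function(r) {
      s <- s0
      for (ix in active) s[ix] <- s[sample(ix)]
      if (!nrow(tri)) return(0L)
      sum((s[tri[, 1]] + s[tri[, 2]] + s[tri[, 3]]) %% 2L == 1L)
    }, integer(1))
  })
  null <- null_distribution(as.numeric(samples), observed = obs$unbalanced,
                            conf_level = conf_level, seed = seed)
  structure(list(observed = obs, null = null,
                 fraction_below = mean(samples < obs$unbalanced),
                 n_realizations = n_realizations, degenerate = degenerate),
            class = "balance_test")
}

#' @export
print.balance_test <- function(x, ...) {
  print(x$observed)
  cat(sprintf("null unbalanced: mean %.1f, %d%% CI (%.0f; %.0f) over %d realizations\n",
              x$null$mean, round(100 * x$null$ci_level), x$null$ci_low,
              x$null$ci_high, x$n_realizations))
  cat(sprintf("fraction of realizations with fewer unbalanced triangles: %g\n",
              x$fraction_below))
  invisible(x)
}
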