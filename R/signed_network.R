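#' Construct a signed directed network
#'
#' The central container of the package: a directed graph over surveyed
#' students whose edge weights encode friendship nominations merged to two
#' intensity levels per sign. Allowed weights are -2 ("worst enemy"),
#' -1 ("enemy"), +1 ("friend") and +2 ("best friend"). Self-loops, zero
#' weights and duplicate ordered pairs are invalid.
#'
#' @param nodes character vector of node identifiers (student ids). May
#'   include isolates.
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @return An object of class `signed_network`: a list with elements `nodes`
#'   (character) and `edges` (data frame `from`, `to`, `weight`).
#' @examples
#' net <- signed_network(c("s1", "s2", "s3"),
#'                       data.frame(from = c("s1", "s2"),
#'                                  to = c("s2", "s1"),
#'                                  weight = c(2, -1)))
#' net
#' @export
signed_network <- function(nodes = character(),
                           edges = data.frame(from = character(),
                                              to = character(),
                                              weight = numeric())) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop_validation("duplicate node ids")
  require_columns(edges, c("from", "to", "weight"), "edge table")
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (!all(edges$weight %in% c(-2, -1, 1, 2))) {
      stop_validation("edge weights must lie in {-2, -1, 1, 2}")
    }
    if (any(edges$from == edges$to)) stop_validation("self-loops are not allowed")
    bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(bad)) {
      stop_validation("edge endpoints not in node set: ",
                      paste(utils::head(bad, 5), collapse = ", "))
    }
    if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
      stop_validation("duplicate ordered pairs in edge table")
    }
  }
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  w <- network_totals(x)
  cat(sprintf("signed_network: %d nodes, %d edges (w+ = %g, w- = %g)\n",
              length(x$nodes), nrow(x$edges), w$w_plus, w$w_minus))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

#' Total positive and negative strength of a network
#'
#' @param net a [signed_network()].
#' @return list with `w_plus` (sum of positive weights, >= 0) and `w_minus`
#'   (sum of negative weights, <= 0).
#' @export
network_totals <- function(net) {
  w <- net$edges$weight
  list(w_plus = sum(w[w > 0]), w_minus = sum(w[w < 0]))
}

# per-node out/in strengths for one sign; negative strengths are returned in
# absolute value, as the modularity expressions consume |w-|
node_strengths <- function(net, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  e <- net$edges
  e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  w <- abs(e$weight)
  out <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  inn <- out
  if (nrow(e)) {
    s <- rowsum(w, e$from)
    out[rownames(s)] <- s[, 1]
    s <- rowsum(w, e$to)
    inn[rownames(s)] <- s[, 1]
  }
  list(out = out, "in" = inn)
}

#' Induced subnetwork by student group and/or edge sign
#'
#' Restricts a network to the students of the given roster groups (keeping
#' only edges whose two endpoints survive) and optionally to edges of one
#' sign. Mirrors the per-group analyses where only links within a group are
#' considered, and the comparison of community structure with and without
#' negative links.
#'
#' @param net a [signed_network()].
#' @param roster a roster as returned by [load_roster()]; required when
#'   `groups` is given.
#' @param groups optional character vector of group labels to keep.
#' @param sign optional, `"positive"` or `"negative"`: keep only edges of
#'   that sign.
#' @return a [signed_network()].
#' @export
subnetwork <- function(net, roster = NULL, groups = NULL, sign = NULL) {
  nodes <- net$nodes
  if (!is.null(groups)) {
    if (is.null(roster)) stop_validation("a roster is required to select groups")
    unknown <- setdiff(groups, unique(roster$group))
    if (length(unknown)) {
      stop_validation("unknown group label(s): ", paste(unknown, collapse = ", "))
    }
    keep_ids <- roster$id[roster$group %in% groups]
    nodes <- intersect(nodes, keep_ids)
  }
  e <- net$edges
  e <- e[e$from %in% nodes & e$to %in% nodes, ]
  if (!is.null(sign)) {
    sign <- match.arg(sign, c("positive", "negative"))
    e <- if (sign == "positive") e[e$weight > 0, ] else e[e$weight < 0, ]
  }
  signed_network(nodes, e)
}

#' Convert a signed network to an igraph object
#'
#' @param net a [signed_network()].
#' @param roster optional roster; when given, `group` and `gender` are
#'   attached as vertex attributes.
#' @return a directed `igraph` graph with edge attribute `weight`.
#' @export
as_igraph <- function(net, roster = NULL) {
  vdf <- data.frame(name = net$nodes, stringsAsFactors = FALSE)
  if (!is.null(roster)) {
    idx <- match(net$nodes, roster$id)
    vdf$group <- roster$group[idx]
    vdf$gender <- roster$gender[idx]
  }
  igraph::graph_from_data_frame(net$edges, directed = TRUE, vertices = vdf)
}

#' Write / read a signed network as GraphML
#'
#' GraphML export keeps node attributes `group` and `gender` (when a roster
#' is supplied) and the integer edge attribute `weight`; the round trip is
#' the identity on nodes, edges, weights and attributes.
#'
#' @param net a [signed_network()].
#' @param path file path.
#' @param roster optional roster supplying node attributes.
#' @return `write_graphml` returns `path` invisibly; `read_graphml` returns a
#'   list with `network` (a [signed_network()]) and `node_attributes` (a data
#'   frame with columns `id` and any stored attributes).
#' @export
write_graphml <- function(net, path, roster = NULL) {
  ig <- as_igraph(net, roster)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) stop_format("malformed GraphML file: ",
                                                 conditionMessage(e)))
  nodes <- igraph::V(ig)$name
  el <- igraph::as_data_frame(ig, what = "edges")
  edges <- data.frame(from = el$from, to = el$to,
                      weight = round(el$weight), stringsAsFactors = FALSE)
  attrs <- data.frame(id = nodes, stringsAsFactors = FALSE)
  # "id" is a GraphML artifact igraph adds on read; our writer never sets it
  for (a in setdiff(igraph::vertex_attr_names(ig), c("name", "id"))) {
    attrs[[a]] <- igraph::vertex_attr(ig, a)
  }
  list(network = signed_network(nodes, edges), node_attributes = attrs)
}

#' Bundle the two survey waves and their roster
#'
#' @param wave1,wave2 resolved [signed_network()] objects for each wave.
#' @param roster the roster both node sets must be drawn from.
#' @return object of class `network_pair`.
#' @export
network_pair <- function(wave1, wave2, roster) {
  stopifnot(inherits(wave1, "signed_network"), inherits(wave2, "signed_network"))
  bad <- setdiff(c(wave1$nodes, wave2$nodes), roster$id)
  if (length(bad)) {
    stop_validation("network nodes absent from roster: ",
                    paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(wave1 = wave1, wave2 = wave2, roster = roster),
            class = "network_pair")
}

#' @export
print.network_pair <- function(x, ...) {
  cat("network_pair over", nrow(x$roster), "students\n")
  cat("  wave 1: "); print(x$wave1)
  cat("  wave 2: "); print(x$wave2)
  invisible(x)
}
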