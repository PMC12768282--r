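# Exhaustive state-space analysis of asynchronous Boolean networks:
# fixed points, terminal strongly connected components, reachability.

#' Enumerate fixed points of a Boolean network
#'
#' Scans all `2^f` assignments of the free nodes (clamped nodes held at their
#' clamp) and returns the states `x` with `f(x) = x`. Fixed points are the
#' steady states of the asynchronous dynamics: states with no successor
#' distinct from themselves.
#'
#' @param net a `boolean_network`.
#' @param max_free guard on the number of free nodes (default 24); exceeding
#'   it is an error suggesting input clamping.
#' @return a list of `network_state` vectors in ascending bit order.
#' @export
enumerate_fixed_points <- function(net, max_free = 24L) {
  cn <- compile_network(net)
  codes <- .fixed_point_codes(cn, max_free)
  lapply(codes, function(cd) code_to_state(cn, cd))
}

.fixed_point_codes <- function(cn, max_free = 24L) {
  f <- .guard_free(cn, max_free, "fixed-point enumeration")
  if (f == 0L) return(0)
  # chunked so the 2^f scan stays within memory at the guard limit
  chunk <- 2^min(f, 20L)
  out <- numeric(0)
  lo <- 0
  while (lo < 2^f) {
    codes <- lo + seq_len(min(chunk, 2^f - lo)) - 1
    vals <- .node_values(cn, codes)
    nxt <- .next_values(cn, codes, vals)
    stable <- rep.int(TRUE, length(codes))
    for (i in cn$free_idx) stable <- stable & (nxt[[i]] == vals[[i]])
    out <- c(out, codes[stable])
    lo <- lo + chunk
  }
  out
}

#' Find all attractors of the asynchronous dynamics
#'
#' An attractor is a terminal strongly connected component of the
#' asynchronous state transition graph: a set of states no transition
#' leaves. Fixed points are singleton attractors; larger terminal SCCs are
#' cyclic (complex) attractors. The search is exact: the full transition
#' relation over the free nodes is built and condensed
#' (via \pkg{igraph}).
#'
#' @param net a `boolean_network`.
#' @param max_free hard guard on free-node count (default 22).
#' @param scc_limit free-node count up to which the full SCC condensation is
#'   run (default 18). Between `scc_limit` and `max_free` only the fixed-point
#'   scan is performed and a warning notes that cyclic attractors, if any,
#'   would be missed.
#' @return a list of `attractor` objects, each with fields `states` (list of
#'   `network_state`), `codes`, and `is_steady`; ordered lexicographically by
#'   smallest state code.
#' @export
find_attractors <- function(net, max_free = 22L, scc_limit = 18L) {
  cn <- compile_network(net)
  f <- .guard_free(cn, max_free, "attractor search")
  if (f > scc_limit) {
    warning(sprintf(paste0("%d free nodes exceeds scc_limit = %d: only fixed points are ",
                           "reported; cyclic attractors, if present, are missed"),
                    f, scc_limit))
    codes <- .fixed_point_codes(cn, max_free)
    return(lapply(codes, function(cd) .mk_attractor(cn, cd)))
  }
  comp <- .terminal_sccs(cn)
  comp <- comp[order(vapply(comp, min, numeric(1)))]
  lapply(comp, function(codes) .mk_attractor(cn, sort(codes)))
}

.mk_attractor <- function(cn, codes) {
  structure(list(states = lapply(codes, function(cd) code_to_state(cn, cd)),
                 codes = codes, is_steady = length(codes) == 1L),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("<attractor> %s, %d state(s)\n",
              if (x$is_steady) "steady state" else "cyclic", length(x$states)))
  for (s in head(x$states, 4L))
    cat("  ", paste(sprintf("%s=%d", names(s), s), collapse = " "), "\n")
  if (length(x$states) > 4L) cat("  ...\n")
  invisible(x)
}

# Terminal SCCs of the asynchronous STG over free-node codes.
.terminal_sccs <- function(cn) {
  f <- length(cn$free_idx)
  if (f == 0L) return(list(0))
  codes <- 0:(2^f - 1L)
  vals <- .node_values(cn, codes)
  nxt <- .next_values(cn, codes, vals)
  from <- integer(0); to <- integer(0)
  for (p in seq_len(f)) {
    i <- cn$free_idx[p]
    chg <- which(nxt[[i]] != vals[[i]])
    if (length(chg)) {
      from <- c(from, codes[chg])
      to <- c(to, bitwXor(codes[chg], bitwShiftL(1L, p - 1L)))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to) + 1L, directed = TRUE)
  if (igraph::vcount(g) < 2^f) g <- igraph::add_vertices(g, 2^f - igraph::vcount(g))
  memb <- igraph::components(g, mode = "strong")$membership
  # an SCC is terminal iff no edge leaves it
  leaves <- memb[from + 1L] != memb[to + 1L]
  nonterminal <- unique(memb[from + 1L][leaves])
  term <- setdiff(unique(memb), nonterminal)
  lapply(term, function(m) codes[memb == m])
}

#' Attractors reachable from a start state
#'
#' Forward breadth-first search over the implicit asynchronous successor
#' relation from `start`, intersected with the network's attractors. Because
#' an attractor is a terminal SCC, reaching any of its states reaches all of
#' them.
#'
#' @param net a `boolean_network`.
#' @param start a state over `net$nodes` (e.g. from [network_state()]).
#' @inheritParams find_attractors
#' @return list of reachable `attractor` objects.
#' @export
reachable_attractors <- function(net, start, max_free = 22L, scc_limit = 18L) {
  cn <- compile_network(net)
  f <- .guard_free(cn, max_free, "reachability analysis")
  att <- find_attractors(net, max_free = max_free, scc_limit = scc_limit)
  reach <- .forward_reachable(cn, state_to_code(cn, start))
  keep <- vapply(att, function(a) any(a$codes %in% reach), logical(1))
  att[keep]
}

.forward_reachable <- function(cn, start_code) {
  f <- length(cn$free_idx)
  if (f == 0L) return(start_code)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  frontier <- start_code
  assign(as.character(start_code), TRUE, envir = seen)
  out <- start_code
  while (length(frontier)) {
    vals <- .node_values(cn, frontier)
    nxt <- .next_values(cn, frontier, vals)
    succ <- numeric(0)
    for (p in seq_len(f)) {
      i <- cn$free_idx[p]
      chg <- which(nxt[[i]] != vals[[i]])
      if (length(chg)) succ <- c(succ, bitwXor(frontier[chg], bitwShiftL(1L, p - 1L)))
    }
    succ <- unique(succ)
    new <- succ[!vapply(as.character(succ), exists, logical(1), envir = seen)]
    for (cd in as.character(new)) assign(cd, TRUE, envir = seen)
    out <- c(out, new)
    frontier <- new
  }
  out
}

#' Build the full asynchronous state transition graph
#'
#' Materializes the STG over all `2^f` free-node assignments, including
#' self-loop transitions (one per state per stable node, collapsed to a
#' single self-loop edge). Intended for inspection and export of small
#' systems.
#'
#' @param net a `boolean_network`.
#' @param max_free guard (default 16).
#' @return an object of class `stg`: a list with the \pkg{igraph} `graph`
#'   (vertex attribute `label` holds `node=value` strings), the `net`, and
#'   `codes`.
#' @export
build_stg <- function(net, max_free = 16L) {
  cn <- compile_network(net)
  f <- .guard_free(cn, max_free, "STG construction")
  codes <- if (f == 0L) 0 else 0:(2^f - 1L)
  vals <- .node_values(cn, codes)
  nxt <- .next_values(cn, codes, vals)
  from <- integer(0); to <- integer(0)
  has_self <- rep.int(f == 0L, length(codes))
  for (p in seq_len(f)) {
    i <- cn$free_idx[p]
    chg <- nxt[[i]] != vals[[i]]
    from <- c(from, codes[chg])
    to <- c(to, bitwXor(codes[chg], bitwShiftL(1L, p - 1L)))
    has_self <- has_self | !chg
  }
  from <- c(from, codes[has_self])
  to <- c(to, codes[has_self])
  g <- igraph::graph_from_edgelist(cbind(from, to) + 1L, directed = TRUE)
  if (igraph::vcount(g) < length(codes))
    g <- igraph::add_vertices(g, length(codes) - igraph::vcount(g))
  labs <- vapply(codes, function(cd) {
    s <- code_to_state(cn, cd)
    paste(sprintf("%s=%d", names(s), s), collapse = " ")
  }, "")
  igraph::V(g)$label <- labs
  igraph::V(g)$name <- as.character(codes)
  structure(list(graph = g, net = net, codes = codes), class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("<stg> %d states, %d transitions (self-loops included)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}
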