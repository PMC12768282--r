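# Shared fixtures: small hand-written networks and an independent
# brute-force attractor oracle.

toy_swap <- function() boolean_network(c(X = "Y", Y = "X"))

toy_negation <- function() boolean_network(c(X = "!X"))

# two absorbing states reachable from (A=0, B=1): (0,0) and (1,0)
toy_orchain <- function() boolean_network(c(A = "A | B", B = "0"))

toy_chain3 <- function() boolean_network(c(X = "Y", Y = "X & Z", Z = "Z"))

# All 2^f states of a network as a list of full named states, using only the
# public expression evaluator (no truth-table compilation).
all_states <- function(net) {
  free <- free_nodes(net)
  f <- length(free)
  lapply(0:(2^f - 1L), function(code) {
    bits <- bitwAnd(bitwShiftR(code, seq_len(f) - 1L), 1L)
    network_state(net, setNames(bits, free))
  })
}

state_key <- function(s) paste(s, collapse = "")

# Independent attractor oracle: a state belongs to an attractor iff every
# state reachable from it can reach it back (mutual reachability), computed
# by per-state BFS over async_successors. Returns a list of sorted key sets.
brute_attractors <- function(net) {
  states <- all_states(net)
  keys <- vapply(states, state_key, "")
  succ <- lapply(states, function(s)
    vapply(async_successors(net, s), state_key, ""))
  names(succ) <- keys
  reach <- function(k0) {
    seen <- k0
    frontier <- k0
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(succ[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  fwd <- lapply(keys, reach)
  names(fwd) <- keys
  in_att <- vapply(keys, function(k) all(vapply(fwd[[k]], function(t)
    k %in% fwd[[t]], logical(1))), logical(1))
  att_keys <- keys[in_att]
  groups <- list()
  remaining <- att_keys
  while (length(remaining)) {
    k <- remaining[1L]
    grp <- intersect(fwd[[k]], att_keys)
    grp <- grp[vapply(grp, function(t) k %in% fwd[[t]], logical(1))]
    groups[[length(groups) + 1L]] <- sort(grp)
    remaining <- setdiff(remaining, grp)
  }
  groups[order(vapply(groups, `[`, "", 1L))]
}

attractor_key_sets <- function(atts) {
  sets <- lapply(atts, function(a) sort(vapply(a$states, state_key, "")))
  sets[order(vapply(sets, `[`, "", 1L))]
}

# truth-table equivalence of the effective update functions (clamped nodes
# behave as constants) of two networks over the same node set
nets_equivalent <- function(a, b, n_random = 500L) {
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  n <- length(a$nodes)
  eff <- function(net, nm, env) {
    if (nm %in% names(net$clamps)) net$clamps[[nm]]
    else cardiobn:::.eval_lx(net$rules[[nm]], env)
  }
  assigns <- if (n <= 12L) {
    lapply(0:(2^n - 1L), function(code)
      setNames(as.list(bitwAnd(bitwShiftR(code, seq_len(n) - 1L), 1L)), a$nodes))
  } else {
    lapply(seq_len(n_random), function(i)
      setNames(as.list(as.integer(runif(n) < 0.5)), a$nodes))
  }
  for (env in assigns)
    for (nm in a$nodes)
      if (eff(a, nm, env) != eff(b, nm, env)) return(FALSE)
  TRUE
}
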