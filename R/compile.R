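# Truth-table compilation of a boolean_network.
#
# Each free node is compiled to (regulator index vector, truth table of
# length 2^k); clamped nodes compile to an empty regulator set and the
# constant. The engine, the Markov solver and the C++ population simulator
# all consume this form, so rule evaluation cost is paid once per network.

compile_network <- function(net, max_regulators = 16L) {
  n <- length(net$nodes)
  free <- free_nodes(net)
  regs <- vector("list", n)
  tts <- vector("list", n)
  clamped <- net$nodes %in% names(net$clamps)
  clampval <- integer(n)
  for (i in seq_len(n)) {
    nm <- net$nodes[i]
    if (clamped[i]) {
      regs[[i]] <- integer()
      clampval[i] <- net$clamps[[nm]]
      tts[[i]] <- clampval[i]
      next
    }
    vars <- expr_vars(net$rules[[nm]])
    vars <- vars[order(match(vars, net$nodes))]
    k <- length(vars)
    if (k > max_regulators)
      stop(sprintf("rule for %s has %d regulators (limit %d)", nm, k, max_regulators),
           call. = FALSE)
    regs[[i]] <- match(vars, net$nodes)
    if (k == 0L) {
      tts[[i]] <- .eval_lx(net$rules[[nm]], list())
    } else {
      assign_bits <- lapply(seq_len(k), function(j)
        bitwAnd(bitwShiftR(0:(2^k - 1L), j - 1L), 1L))
      names(assign_bits) <- vars
      tts[[i]] <- as.integer(.eval_lx(net$rules[[nm]], assign_bits))
    }
  }
  list(n = n, nodes = net$nodes, regulators = regs, truth_tables = tts,
       clamped = clamped, clamp_values = clampval,
       free_idx = match(free, net$nodes))
}

# Encode/decode between full named states and integers over the free bits.
# Bit p (value 2^(p-1)) is the p-th free node in network order.

state_to_code <- function(cn, state) {
  bits <- as.integer(state[cn$free_idx])
  sum(bits * 2^(seq_along(bits) - 1L))
}

code_to_state <- function(cn, code) {
  s <- setNames(integer(cn$n), cn$nodes)
  s[cn$clamped] <- cn$clamp_values[cn$clamped]
  f <- length(cn$free_idx)
  if (f > 0L)
    s[cn$free_idx] <- bitwAnd(bitwShiftR(as.integer(code), seq_len(f) - 1L), 1L)
  class(s) <- "network_state"
  s
}

# Vectorized: value of every node over a vector of state codes.
# Returns a list (per node) of integer vectors.
.node_values <- function(cn, codes) {
  f <- length(cn$free_idx)
  vals <- vector("list", cn$n)
  pos <- integer(cn$n)              # free position of each node (0 if clamped)
  pos[cn$free_idx] <- seq_len(f)
  for (i in seq_len(cn$n)) {
    vals[[i]] <- if (cn$clamped[i]) rep.int(cn$clamp_values[i], length(codes))
                 else bitwAnd(bitwShiftR(codes, pos[i] - 1L), 1L)
  }
  vals
}

# Vectorized: next value of every free node over a vector of state codes.
.next_values <- function(cn, codes, vals = .node_values(cn, codes)) {
  nxt <- vector("list", cn$n)
  for (i in cn$free_idx) {
    regs <- cn$regulators[[i]]
    if (length(regs) == 0L) {
      nxt[[i]] <- rep.int(cn$truth_tables[[i]], length(codes))
    } else {
      idx <- rep.int(1L, length(codes))
      for (j in seq_along(regs)) idx <- idx + vals[[regs[j]]] * 2L^(j - 1L)
      nxt[[i]] <- cn$truth_tables[[i]][idx]
    }
  }
  nxt
}

.guard_free <- function(cn, limit, what) {
  f <- length(cn$free_idx)
  if (f > limit)
    stop(sprintf("%s requires at most %d free nodes, got %d; clamp input nodes to reduce the state space",
                 what, limit, f), call. = FALSE)
  f
}
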