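# Synthetic fixtures: random Boolean networks and random initial
# populations for engine validation, plus an exact Markov absorption solver
# that serves as the independent oracle for the Monte-Carlo simulator.

#' Draw a random initial state
#'
#' Clamped nodes take their clamp value; every free node is independently
#' Bernoulli(0.5) — the "heterogeneous population" initial condition. Uses
#' R's RNG.
#'
#' @param net a `boolean_network`.
#' @return a `network_state`.
#' @export
random_initial_state <- function(net) {
  free <- free_nodes(net)
  network_state(net, setNames(as.integer(runif(length(free)) < 0.5), free))
}

#' Generate a random Boolean network
#'
#' Each node receives between 1 and `k` distinct random regulators and a
#' random truth table over them (each output bit Bernoulli(`p_one`)). The
#' rule is materialized as a disjunctive-normal-form expression, so the
#' network round-trips through the `.bnet` writer. Reproducible from the
#' R RNG state.
#'
#' @param n node count.
#' @param k maximum in-degree (default 2).
#' @param p_one probability of a 1 in the truth table (default 0.5).
#' @return a `boolean_network` with nodes `V1..Vn`.
#' @export
random_boolean_network <- function(n, k = 2L, p_one = 0.5) {
  stopifnot(n >= 1L, k >= 1L)
  nodes <- paste0("V", seq_len(n))
  rules <- vector("list", n)
  names(rules) <- nodes
  for (i in seq_len(n)) {
    ki <- sample.int(min(k, n), 1L)
    regs <- nodes[sample.int(n, ki)]
    tt <- as.integer(runif(2^ki) < p_one)
    rules[[i]] <- .tt_to_expr(regs, tt)
  }
  boolean_network(rules)
}

# truth table -> DNF logic_expr; assignment j (0-based) maps bit b-1 of j to
# the b-th regulator
.tt_to_expr <- function(regs, tt) {
  if (all(tt == 0L)) return(lx_const(0L))
  if (all(tt == 1L)) return(lx_const(1L))
  terms <- lapply(which(tt == 1L) - 1L, function(j) {
    lits <- lapply(seq_along(regs), function(b) {
      v <- lx_var(regs[b])
      if (bitwAnd(bitwShiftR(j, b - 1L), 1L) == 1L) v else lx_not(v)
    })
    if (length(lits) == 1L) lits[[1L]] else do.call(lx_and, lits)
  })
  if (length(terms) == 1L) terms[[1L]] else do.call(lx_or, terms)
}

#' Exact absorption probabilities of the uniform-update Markov chain
#'
#' Builds the full Markov chain over the `2^f` free-node states, in which
#' each of the n nodes (clamped and stable ones included) is selected with
#' probability 1/n per step, and solves the linear absorption system
#' exactly (sparse LU via \pkg{Matrix}). Terminal SCCs of size greater than
#' one are lumped into single absorbing classes, since only absorption
#' identity matters for cell-type counting; self-loop (null-step)
#' probability mass is kept in the transition matrix and provably does not
#' affect the result.
#'
#' @param net a `boolean_network`.
#' @param start optional start state; when `NULL` the uniform distribution
#'   over all `2^f` states is used (the random-population initial
#'   condition).
#' @param max_free guard (default 12).
#' @return list with `attractors` (as in [find_attractors()]) and
#'   `probabilities` (numeric vector summing to 1, one entry per
#'   attractor, in the same order).
#' @export
exact_absorption_probabilities <- function(net, start = NULL, max_free = 12L) {
  cn <- compile_network(net)
  f <- .guard_free(cn, max_free, "exact absorption solve")
  atts <- find_attractors(net)
  m <- length(atts)
  N <- 2^f
  if (f == 0L) return(list(attractors = atts, probabilities = 1))
  codes <- 0:(N - 1L)
  vals <- .node_values(cn, codes)
  nxt <- .next_values(cn, codes, vals)
  n_tot <- cn$n
  from <- integer(0); to <- integer(0)
  for (p in seq_along(cn$free_idx)) {
    i <- cn$free_idx[p]
    chg <- which(nxt[[i]] != vals[[i]])
    if (length(chg)) {
      from <- c(from, codes[chg])
      to <- c(to, bitwXor(codes[chg], bitwShiftL(1L, p - 1L)))
    }
  }
  # membership: which absorbing class (0 = transient)
  memb <- integer(N)
  for (a in seq_len(m)) memb[atts[[a]]$codes + 1L] <- a
  transient <- which(memb == 0L)  # 1-based state indices
  # initial distribution
  init <- if (is.null(start)) rep(1 / N, N) else {
    v <- numeric(N)
    v[state_to_code(cn, start) + 1L] <- 1
    v
  }
  probs <- numeric(m)
  for (a in seq_len(m)) probs[a] <- sum(init[memb == a])
  if (length(transient)) {
    tr_id <- match(seq_len(N), transient)  # state -> transient row
    e_tr <- !is.na(tr_id[from + 1L])
    # Q: transient -> transient (off-diagonal moves only; self mass on the
    # diagonal cancels in (I - Q) up to row scaling and can be dropped
    # because absorption probabilities are invariant to self-loops -- we
    # keep it for the literal chain)
    q_from <- tr_id[from + 1L][e_tr & !is.na(tr_id[to + 1L])]
    keep <- e_tr & !is.na(tr_id[to + 1L])
    q_to <- tr_id[to + 1L][keep]
    q_from <- tr_id[from + 1L][keep]
    nt <- length(transient)
    # off-diagonal mass 1/n per changing node; diagonal = 1 - moves/n
    moves <- tabulate(tr_id[from + 1L][e_tr], nbins = nt)
    Q <- Matrix::sparseMatrix(i = c(q_from, seq_len(nt)),
                              j = c(q_to, seq_len(nt)),
                              x = c(rep(1 / n_tot, length(q_from)),
                                    1 - moves / n_tot),
                              dims = c(nt, nt))
    R <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(nt, m))
    abs_e <- e_tr & is.na(tr_id[to + 1L])
    if (any(abs_e)) {
      R <- R + Matrix::sparseMatrix(i = tr_id[from + 1L][abs_e],
                                    j = memb[to[abs_e] + 1L],
                                    x = rep(1 / n_tot, sum(abs_e)),
                                    dims = c(nt, m))
    }
    B <- Matrix::solve(Matrix::Diagonal(nt) - Q, R)   # nt x m
    probs <- probs + as.numeric(Matrix::crossprod(B, init[transient]))
  }
  list(attractors = atts, probabilities = probs)
}
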