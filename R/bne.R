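# Boolean Network Extension: continuous [0,1] relaxation of the logic
# rules (AND -> product, OR -> probabilistic sum, NOT -> complement),
# polynomial algebra for symbolic verification, fixed-point iteration, and
# the retinoic-acid dose-response sweep.
#
# Polynomials are named numeric vectors: names are canonical monomial keys
# ("1" for the constant term, "RA", "GATA4_6*RA", "RA^2"), values are
# coefficients. The transformation of a rule tree in which every regulator
# appears once yields the multilinear extension of the Boolean function.

.mono_parse <- function(key) {
  if (key == "1") return(setNames(integer(), character()))
  parts <- strsplit(key, "*", fixed = TRUE)[[1L]]
  pow <- vapply(parts, function(p) {
    if (grepl("^", p, fixed = TRUE)) as.integer(sub(".*\\^", "", p)) else 1L
  }, integer(1))
  names(pow) <- sub("\\^.*", "", parts)
  pow
}

.mono_key <- function(pow) {
  pow <- pow[pow > 0L]
  if (length(pow) == 0L) return("1")
  pow <- pow[order(names(pow))]
  paste(ifelse(pow == 1L, names(pow), paste0(names(pow), "^", pow)),
        collapse = "*")
}

poly_const <- function(c) setNames(as.numeric(c), "1")
poly_var <- function(v) setNames(1, v)

poly_add <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out[out != 0]
}

poly_scale <- function(a, s) a * s

poly_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(setNames(numeric(), character()))
  out <- list()
  for (i in seq_along(a)) {
    pa <- .mono_parse(names(a)[i])
    for (j in seq_along(b)) {
      pb <- .mono_parse(names(b)[j])
      keys <- union(names(pa), names(pb))
      pow <- setNames(integer(length(keys)), keys)
      pow[names(pa)] <- pa
      pow[names(pb)] <- pow[names(pb)] + pb
      k <- .mono_key(pow)
      out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) +
        unname(a[[i]]) * unname(b[[j]])
    }
  }
  v <- unlist(out)
  if (is.null(v)) setNames(numeric(), character()) else v[v != 0]
}

poly_one_minus <- function(a) poly_add(poly_const(1), poly_scale(a, -1))

#' Polynomial helpers for the continuous extension
#'
#' `poly_equal()` tests exact symbolic equality of two polynomials in their
#' canonical form; `poly_substitute()` substitutes a polynomial (or scalar)
#' for a variable; `poly_eval()` evaluates at a named numeric point;
#' `poly_from_expr()` transforms a logic expression.
#'
#' @param a,b polynomials (named coefficient vectors as produced by
#'   [transform_to_real()] components or `poly_from_expr()`).
#' @param tol coefficient tolerance for equality (default 1e-12; the
#'   transformation itself produces integer coefficients).
#' @return `poly_equal()`: logical.
#' @export
poly_equal <- function(a, b, tol = 1e-12) {
  d <- poly_add(a, poly_scale(b, -1))
  length(d) == 0L || all(abs(d) <= tol)
}

#' @rdname poly_equal
#' @param p a polynomial.
#' @param var variable name to substitute.
#' @param value a polynomial or a numeric scalar.
#' @export
poly_substitute <- function(p, var, value) {
  if (is.numeric(value) && is.null(names(value)) && length(value) == 1L)
    value <- poly_const(value)
  out <- poly_const(0)
  for (i in seq_along(p)) {
    pow <- .mono_parse(names(p)[i])
    term <- setNames(p[[i]], .mono_key(pow[setdiff(names(pow), var)]))
    if (var %in% names(pow)) {
      for (r in seq_len(pow[[var]])) term <- poly_mul(term, value)
    }
    out <- poly_add(out, term)
  }
  out
}

#' @rdname poly_equal
#' @param values named numeric vector of variable values.
#' @export
poly_eval <- function(p, values) {
  tot <- 0
  for (i in seq_along(p)) {
    pow <- .mono_parse(names(p)[i])
    tot <- tot + p[[i]] * prod(values[names(pow)]^pow)
  }
  tot
}

#' @rdname poly_equal
#' @param expr a `logic_expr`.
#' @export
poly_from_expr <- function(expr) {
  switch(expr$op,
    const = poly_const(expr$value),
    var = poly_var(expr$name),
    not = poly_one_minus(poly_from_expr(expr$args[[1L]])),
    and = Reduce(poly_mul, lapply(expr$args, poly_from_expr)),
    or = Reduce(function(a, b) poly_add(poly_add(a, b), poly_scale(poly_mul(a, b), -1)),
                lapply(expr$args, poly_from_expr)))
}

#' Transform a Boolean network to its continuous extension
#'
#' Applies the relaxation `x AND y -> x*y`, `x OR y -> x + y - x*y`,
#' `NOT x -> 1 - x` recursively to every update rule, yielding a
#' discrete-time real-valued system on `[0,1]^n` that coincides with the
#' Boolean network at binary states. Input nodes (clamped nodes and
#' self-sustaining nodes, or an explicit `inputs` set) become free
#' parameters with identity update.
#'
#' @param net a `boolean_network`.
#' @param inputs character vector of input/parameter nodes; defaults to
#'   clamped nodes plus nodes whose rule is the self-loop `x' = x`.
#' @return an object of class `real_update_system` with fields `polys`
#'   (named list of polynomials), `nodes`, `inputs`.
#' @export
transform_to_real <- function(net, inputs = NULL) {
  if (is.null(inputs)) {
    selfloop <- vapply(net$nodes, function(nm) {
      r <- net$rules[[nm]]
      r$op == "var" && r$name == nm
    }, logical(1))
    inputs <- union(names(net$clamps), net$nodes[selfloop])
  }
  inputs <- canonical_node(inputs)
  polys <- setNames(vector("list", length(net$nodes)), net$nodes)
  for (nm in net$nodes) {
    polys[[nm]] <- if (nm %in% inputs) poly_var(nm)
                   else poly_from_expr(net$rules[[nm]])
  }
  # corner check: at binary regulator values the polynomial equals the rule
  for (nm in setdiff(net$nodes, inputs)) {
    vars <- expr_vars(net$rules[[nm]])
    k <- length(vars)
    if (k == 0L) next
    for (j in 0:(2^k - 1L)) {
      v <- setNames(bitwAnd(bitwShiftR(j, seq_len(k) - 1L), 1L), vars)
      stopifnot(abs(poly_eval(polys[[nm]], v) -
                    .eval_lx(net$rules[[nm]], as.list(v))) < 1e-12)
    }
  }
  structure(list(polys = polys, nodes = net$nodes, inputs = inputs),
            class = "real_update_system")
}

#' @export
print.real_update_system <- function(x, ...) {
  cat(sprintf("<real_update_system> %d nodes, inputs: %s\n",
              length(x$nodes), paste(x$inputs, collapse = ", ")))
  invisible(x)
}

.poly_show <- function(p) {
  if (length(p) == 0L) return("0")
  paste(sprintf("%+g%s", unname(p),
                ifelse(names(p) == "1", "", paste0("*", names(p)))),
        collapse = " ")
}

#' Iterate the continuous system to a fixed point
#'
#' Synchronous iteration of the transformed update functions from an
#' agnostic interior start (all non-input nodes at 0.5) with the input
#' parameters held fixed, until the max-norm change drops below `tol`.
#' The iterates remain in `[0,1]^n` because multilinear maps preserve the
#' unit cube.
#'
#' @param sys a `real_update_system`.
#' @param inputs named numeric vector in `[0,1]` covering `sys$inputs`
#'   (for the subtype model: `RA`, `GATA4_6`, `NOTCH`).
#' @param init initial value of non-input nodes (default 0.5) or a full
#'   named state.
#' @param tol convergence tolerance (default 1e-9).
#' @param max_iter iteration budget (default 10000). At the degenerate
#'   corner RA = GATA4/6 = 0 the HAND2/IRX4 block is a neutral 2-cycle and
#'   the iteration correctly fails rather than fabricating a value.
#' @return named numeric fixed point with attributes `iterations`,
#'   `residual`.
#' @export
iterate_to_fixed_point <- function(sys, inputs, init = 0.5, tol = 1e-9,
                                   max_iter = 10000L) {
  names(inputs) <- canonical_node(names(inputs))
  miss <- setdiff(sys$inputs, names(inputs))
  if (length(miss)) stop("missing input value(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  stopifnot(all(inputs >= 0 & inputs <= 1))
  state <- if (length(init) == 1L) setNames(rep(init, length(sys$nodes)), sys$nodes)
           else init[sys$nodes]
  state[names(inputs)] <- inputs
  frees <- setdiff(sys$nodes, sys$inputs)
  for (it in seq_len(max_iter)) {
    nxt <- state
    for (nm in frees) nxt[[nm]] <- poly_eval(sys$polys[[nm]], state)
    resid <- max(abs(nxt - state))
    state <- nxt
    if (resid < tol) {
      attr(state, "iterations") <- it
      attr(state, "residual") <- resid
      return(state)
    }
  }
  stop(sprintf("continuous iteration did not converge in %d steps (residual %.3g)",
               max_iter, resid), call. = FALSE)
}

#' Closed-form steady state of the subtype model's continuous extension
#'
#' The algebraic solution of the transformed cardiomyocyte-subtype system at
#' steady state, as a function of the input intensities rho (RA), gamma
#' (GATA4/6) and nu (NOTCH): `NR2F2 = rho`, `HEY2 = nu*gamma*(1-rho)`,
#' `MYL7 = rho*(1 - nu*gamma*(1-rho))`, and the coupled block
#' `HAND2 = gamma / (rho + gamma - rho*gamma)`, `IRX4 = HAND2*(1-rho)`,
#' `MYL2 = IRX4*(1-rho)`.
#'
#' @param rho,gamma,nu input intensities in `[0,1]`; `(rho, gamma) = (0, 0)`
#'   degenerates the coupled block's denominator and is an error.
#' @return named numeric state (inputs included).
#' @export
closed_form_cm_steady_state <- function(rho, gamma, nu = 1) {
  stopifnot(rho >= 0, rho <= 1, gamma >= 0, gamma <= 1, nu >= 0, nu <= 1)
  den <- rho + gamma - rho * gamma
  if (den <= 0)
    stop("degenerate corner rho = gamma = 0: the HAND2/IRX4 block is a neutral 2-cycle",
         call. = FALSE)
  hand2 <- gamma / den
  irx4 <- hand2 * (1 - rho)
  hey2 <- nu * gamma * (1 - rho)
  c(NOTCH = nu, RA = rho, GATA4_6 = gamma,
    NR2F2 = rho, HAND2 = hand2, IRX4 = irx4, HEY2 = hey2,
    MYL2 = irx4 * (1 - rho), MYL7 = rho * (1 - hey2))
}

#' Retinoic-acid dose-response sweep
#'
#' Sweeps the RA input intensity over a grid on `[0,1]` while holding the
#' other signaling inputs constant (default: fully active), records the
#' steady activity of every node, and locates the atrial/ventricular
#' crossover `rho*` where the MYL2 and MYL7 activities are equal, by
#' bisection between the bracketing grid points. At fully active GATA4/6
#' and NOTCH the marker activities are `MYL2 = (1-rho)^2`,
#' `MYL7 = rho^2`, so `rho* = 0.5`.
#'
#' @param sys a `real_update_system` for the subtype model.
#' @param gamma,nu constant GATA4/6 and NOTCH intensities (default 1).
#' @param grid_size number of grid points (default 101, minimum 11).
#' @param tol iteration and bisection tolerance.
#' @return object of class `ra_sweep`: list with `grid` (data.frame of rho
#'   and node activities) and `crossover` (`rho*`, or `NA` if no sign
#'   change on the grid).
#' @export
ra_sweep_and_threshold <- function(sys, gamma = 1, nu = 1, grid_size = 101L,
                                   tol = 1e-9) {
  stopifnot(grid_size >= 11L)
  rhos <- seq(0, 1, length.out = grid_size)
  fp_at <- function(r) iterate_to_fixed_point(
    sys, c(RA = r, GATA4_6 = gamma, NOTCH = nu), tol = tol)
  states <- t(vapply(rhos, function(r) unclass(fp_at(r))[sys$nodes],
                     numeric(length(sys$nodes))))
  colnames(states) <- sys$nodes
  grid <- data.frame(rho = rhos, states, check.names = FALSE)
  d <- grid$MYL2 - grid$MYL7
  cross <- NA_real_
  sgn <- sign(d)
  hit <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
  if (any(d == 0)) {
    cross <- rhos[which(d == 0)[1L]]
  } else if (length(hit)) {
    lo <- rhos[hit[1L]]; hi <- rhos[hit[1L] + 1L]
    flo <- d[hit[1L]]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      s <- fp_at(mid)
      fm <- s[["MYL2"]] - s[["MYL7"]]
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    cross <- (lo + hi) / 2
  }
  structure(list(grid = grid, crossover = cross, gamma = gamma, nu = nu),
            class = "ra_sweep")
}

#' @export
print.ra_sweep <- function(x, ...) {
  cat(sprintf("<ra_sweep> %d grid points, gamma = %g, nu = %g; crossover rho* = %s\n",
              nrow(x$grid), x$gamma, x$nu,
              if (is.na(x$crossover)) "none" else format(x$crossover)))
  invisible(x)
}
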