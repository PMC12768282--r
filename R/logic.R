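#' @useDynLib cardiobn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils head modifyList
NULL

# -- node names ---------------------------------------------------------------

.default_aliases <- c(
  COUP_TFII = "NR2F2", COUPTF_II = "NR2F2", COUPTFII = "NR2F2",
  GATAS = "GATA4_6", GATA4 = "GATA4_6", GATA6 = "GATA4_6",
  FOXC1_FOXC2 = "FOXC1_2", FOXC1 = "FOXC1_2", FOXC2 = "FOXC1_2",
  EXWNT = "EX_WNT", EXBMP2 = "EX_BMP2", EXFGF8 = "EX_FGF8"
)

#' Canonical node identifiers
#'
#' Node names are normalized to a canonical form so that the synonyms used in
#' the cardiac literature ("COUP-TFII", "NKX2.5", "GATA4/6", "GATAs") all map
#' to a single identifier: names are upper-cased, the characters `/`, `-`,
#' `.` and whitespace are replaced by `_`, and a small alias table maps
#' printed synonyms (e.g. `COUP-TFII` to `NR2F2`) onto their canonical gene
#' symbol.
#'
#' @param x character vector of node names.
#' @param aliases named character vector mapping normalized synonyms to
#'   canonical identifiers; the package default covers the cardiac models.
#' @return character vector of canonical identifiers.
#' @examples
#' canonical_node(c("COUP-TFII", "NKX2.5", "GATA4/6"))
#' @export
canonical_node <- function(x, aliases = .default_aliases) {
  y <- toupper(as.character(x))
  y <- gsub("[-/.[:space:]]+", "_", y)
  y <- gsub("_+", "_", y)
  hit <- match(y, names(aliases))
  y[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  y
}

# -- logic expressions --------------------------------------------------------

lx_var <- function(name) structure(list(op = "var", name = name), class = "logic_expr")
lx_const <- function(value) structure(list(op = "const", value = as.integer(value)), class = "logic_expr")
lx_not <- function(e) structure(list(op = "not", args = list(e)), class = "logic_expr")
lx_and <- function(...) structure(list(op = "and", args = list(...)), class = "logic_expr")
lx_or <- function(...) structure(list(op = "or", args = list(...)), class = "logic_expr")

#' Parse a Boolean update rule
#'
#' Parses the BoolNet expression dialect: `&` (AND), `|` (OR), `!` (NOT),
#' parentheses, the constants `0`/`1`, and node identifiers. Standard
#' precedence applies (NOT binds tighter than AND, AND tighter than OR).
#' Identifiers are passed through [canonical_node()] before being resolved
#' against `nodes`.
#'
#' @param text a single rule string, e.g. `"NR2F2 & !HEY2"`.
#' @param nodes optional character vector of declared node names; when given,
#'   any identifier not resolving to one of them is an error.
#' @return an object of class `logic_expr`.
#' @examples
#' parse_boolean_rule("NR2F2 & !HEY2")
#' parse_boolean_rule("COUP-TFII | 0")   # alias resolves to NR2F2
#' @export
parse_boolean_rule <- function(text, nodes = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .tokenize_rule(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  peek <- function() if (st$pos <= nrow(st$toks)) st$toks$type[st$pos] else "eof"
  take <- function() {
    t <- st$toks[st$pos, , drop = FALSE]
    st$pos <- st$pos + 1L
    t
  }
  fail <- function(msg, at = NULL) {
    where <- if (is.null(at)) {
      if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else nchar(text) + 1L
    } else at
    stop(sprintf("parse error in rule '%s' at position %d: %s", text, where, msg),
         call. = FALSE)
  }
  p_expr <- function() {
    terms <- list(p_term())
    while (peek() == "or") { take(); terms <- c(terms, list(p_term())) }
    if (length(terms) == 1L) terms[[1L]] else do.call(lx_or, terms)
  }
  p_term <- function() {
    facs <- list(p_factor())
    while (peek() == "and") { take(); facs <- c(facs, list(p_factor())) }
    if (length(facs) == 1L) facs[[1L]] else do.call(lx_and, facs)
  }
  p_factor <- function() {
    ty <- peek()
    if (ty == "not") { take(); return(lx_not(p_factor())) }
    if (ty == "lparen") {
      open <- take()
      e <- p_expr()
      if (peek() != "rparen") fail("expected ')' for '(' ", at = open$at)
      take()
      return(e)
    }
    if (ty == "const") { t <- take(); return(lx_const(as.integer(t$text))) }
    if (ty == "ident") {
      t <- take()
      nm <- canonical_node(t$text)
      if (!is.null(nodes) && !(nm %in% nodes))
        stop(sprintf("unknown node '%s' (canonical '%s') in rule '%s'",
                     t$text, nm, text), call. = FALSE)
      return(lx_var(nm))
    }
    fail(sprintf("unexpected %s", if (ty == "eof") "end of input" else sprintf("'%s'", st$toks$text[st$pos])))
  }
  e <- p_expr()
  if (peek() != "eof") fail(sprintf("trailing input '%s'", st$toks$text[st$pos]))
  e
}

.tokenize_rule <- function(text) {
  pats <- c(ident = "^[A-Za-z][A-Za-z0-9_/\\.\\-]*", const = "^[01]",
            and = "^(&&|&|\\bAND\\b)", or = "^(\\|\\||\\||\\bOR\\b)",
            not = "^(!|\\bNOT\\b)", lparen = "^\\(", rparen = "^\\)")
  out <- list()
  i <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    sp <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(sp) == 1L) {
      i <- i + nchar(sp); rest <- substring(rest, nchar(sp) + 1L); next
    }
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m) == 1L) {
        out[[length(out) + 1L]] <- data.frame(type = ty, text = m, at = i,
                                              stringsAsFactors = FALSE)
        i <- i + nchar(m); rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("parse error in rule '%s' at position %d: unexpected character '%s'",
                   text, i, substring(rest, 1L, 1L)), call. = FALSE)
  }
  if (length(out) == 0L)
    stop(sprintf("parse error in rule '%s': empty rule", text), call. = FALSE)
  do.call(rbind, out)
}

#' Render a logic expression in the `.bnet` dialect
#'
#' Inverse of [parse_boolean_rule()] up to truth-table equivalence:
#' `parse_boolean_rule(format_logic_expr(e))` evaluates identically to `e`.
#'
#' @param expr a `logic_expr`.
#' @return a single string using `&`, `|`, `!` and parentheses.
#' @export
format_logic_expr <- function(expr) .fmt_lx(expr, 0L)

.fmt_lx <- function(e, parent_prec) {
  prec <- switch(e$op, or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  s <- switch(e$op,
    var = e$name,
    const = as.character(e$value),
    not = paste0("!", .fmt_lx(e$args[[1L]], prec)),
    and = paste(vapply(e$args, .fmt_lx, "", prec), collapse = " & "),
    or = paste(vapply(e$args, .fmt_lx, "", prec), collapse = " | "))
  if (prec < parent_prec) paste0("(", s, ")") else s
}

#' @export
print.logic_expr <- function(x, ...) {
  cat("<logic_expr> ", format_logic_expr(x), "\n", sep = "")
  invisible(x)
}

expr_vars <- function(e) {
  switch(e$op,
    var = e$name,
    const = character(),
    unique(unlist(lapply(e$args, expr_vars))))
}

#' Evaluate a logic expression
#'
#' @param expr a `logic_expr`.
#' @param state a named integer (0/1) vector, or a named list of equal-length
#'   0/1 vectors for vectorized evaluation over many states at once.
#' @return an integer 0/1 vector.
#' @export
eval_logic <- function(expr, state) {
  if (!is.list(state)) state <- as.list(state)
  .eval_lx(expr, state)
}

.eval_lx <- function(e, env) {
  switch(e$op,
    const = e$value,
    var = {
      v <- env[[e$name]]
      if (is.null(v)) stop(sprintf("node '%s' absent from state", e$name), call. = FALSE)
      v
    },
    not = 1L - .eval_lx(e$args[[1L]], env),
    and = {
      v <- .eval_lx(e$args[[1L]], env)
      for (a in e$args[-1L]) v <- v * .eval_lx(a, env)
      as.integer(v)
    },
    or = {
      v <- .eval_lx(e$args[[1L]], env)
      for (a in e$args[-1L]) { w <- .eval_lx(a, env); v <- v + w - v * w }
      as.integer(v)
    })
}

# -- Boolean networks ---------------------------------------------------------

#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of nodes, one logical update function
#' per node, and an optional clamp map holding input nodes at a fixed value.
#' A clamped node's update function is overridden by the clamped constant and
#' the node is excluded from the free-node set used in state-space
#' enumeration and asynchronous updating.
#'
#' @param rules named list (or named character vector of rule strings) giving
#'   one update function per node; names define the node order.
#' @param clamps named 0/1 vector of clamped input values (may be empty).
#' @param perturbed character vector of node names whose clamps arise from a
#'   knockout/overexpression rather than a signaling condition (used by
#'   attractor classification to exclude those markers).
#' @return an object of class `boolean_network` with fields `nodes`, `rules`,
#'   `clamps` and `perturbed`.
#' @examples
#' net <- boolean_network(c(x = "y", y = "x & z", z = "z"))
#' @export
boolean_network <- function(rules, clamps = integer(), perturbed = character()) {
  if (is.character(rules)) rules <- lapply(rules, parse_boolean_rule)
  if (length(rules) == 0L)
    return(structure(list(nodes = character(), rules = list(),
                          clamps = setNames(integer(), character()),
                          perturbed = character()),
                     class = "boolean_network"))
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))))
  nodes <- canonical_node(names(rules))
  if (anyDuplicated(nodes))
    stop("duplicate node after canonicalization: ",
         paste(nodes[duplicated(nodes)], collapse = ", "), call. = FALSE)
  names(rules) <- nodes
  rules <- lapply(rules, function(r) {
    if (is.character(r)) r <- parse_boolean_rule(r)
    stopifnot(inherits(r, "logic_expr"))
    r
  })
  for (nm in nodes) {
    unknown <- setdiff(expr_vars(rules[[nm]]), nodes)
    if (length(unknown))
      stop(sprintf("rule for %s references undeclared node(s): %s",
                   nm, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  clamps <- .check_clamps(clamps, nodes)
  perturbed <- canonical_node(perturbed)
  stopifnot(all(perturbed %in% nodes))
  structure(list(nodes = nodes, rules = rules, clamps = clamps,
                 perturbed = perturbed),
            class = "boolean_network")
}

.check_clamps <- function(clamps, nodes) {
  if (length(clamps) == 0L) return(setNames(integer(), character()))
  stopifnot(!is.null(names(clamps)))
  names(clamps) <- canonical_node(names(clamps))
  bad <- setdiff(names(clamps), nodes)
  if (length(bad)) stop("clamp on undeclared node(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(all(clamps %in% c(0L, 1L)))
  storage.mode(clamps) <- "integer"
  clamps
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (%d clamped, %d free)\n",
              length(x$nodes), length(x$clamps), length(free_nodes(x))))
  for (nm in x$nodes) {
    tag <- if (nm %in% names(x$clamps))
      sprintf("  [= %d%s]", x$clamps[[nm]],
              if (nm %in% x$perturbed) ", perturbed" else ", clamped")
    else ""
    cat(sprintf("  %s, %s%s\n", nm, format_logic_expr(x$rules[[nm]]), tag))
  }
  invisible(x)
}

#' Free (unclamped) nodes of a network
#' @param net a `boolean_network`.
#' @return character vector in declaration order.
#' @export
free_nodes <- function(net) setdiff(net$nodes, names(net$clamps))

#' Set or replace input clamps
#'
#' @param net a `boolean_network`.
#' @param clamps named 0/1 vector; use `set_clamps(net, c(RA = 1))`.
#' @param replace if `TRUE` the existing clamp map is discarded first;
#'   otherwise new clamps are merged over it.
#' @return the modified network.
#' @export
set_clamps <- function(net, clamps, replace = FALSE) {
  clamps <- .check_clamps(clamps, net$nodes)
  merged <- if (replace) clamps else {
    old <- net$clamps[setdiff(names(net$clamps), names(clamps))]
    c(old, clamps)
  }
  net$clamps <- merged[order(match(names(merged), net$nodes))]
  net
}

# -- states -------------------------------------------------------------------

#' Construct a network state
#'
#' A state is a named 0/1 vector over all nodes in network order. Clamped
#' nodes are forced to their clamped value.
#'
#' @param net a `boolean_network`.
#' @param values named 0/1 vector for (a subset of) the free nodes;
#'   unspecified free nodes default to 0.
#' @return named integer vector of class `network_state`.
#' @export
network_state <- function(net, values = integer()) {
  s <- setNames(integer(length(net$nodes)), net$nodes)
  if (length(values)) {
    names(values) <- canonical_node(names(values))
    bad <- setdiff(names(values), net$nodes)
    if (length(bad)) stop("state value for undeclared node(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    s[names(values)] <- as.integer(values)
  }
  s[names(net$clamps)] <- net$clamps
  stopifnot(all(s %in% c(0L, 1L)))
  class(s) <- "network_state"
  s
}

#' Synchronous update step
#'
#' All free nodes simultaneously take the value of their update function;
#' clamped nodes keep their clamped value.
#'
#' @param net a `boolean_network`.
#' @param state a state vector over `net$nodes`.
#' @return the successor state.
#' @export
sync_step <- function(net, state) {
  stopifnot(length(state) == length(net$nodes))
  env <- as.list(state)
  nxt <- state
  for (nm in free_nodes(net)) nxt[[nm]] <- .eval_lx(net$rules[[nm]], env)
  nxt[names(net$clamps)] <- net$clamps
  nxt
}

#' Asynchronous successor states
#'
#' Under the asynchronous update mode one node is updated at a time. The
#' candidate successors of a state are the states obtained by applying a
#' single free node's update function; the state itself is among them
#' whenever some node is already stable. The returned set is de-duplicated,
#' so a fixed point yields a singleton containing itself.
#'
#' @param net a `boolean_network`.
#' @param state a state vector over `net$nodes`.
#' @return a list of distinct successor states.
#' @export
async_successors <- function(net, state) {
  stopifnot(length(state) == length(net$nodes))
  env <- as.list(state)
  out <- list()
  seen <- character()
  for (nm in free_nodes(net)) {
    s2 <- state
    s2[[nm]] <- .eval_lx(net$rules[[nm]], env)
    key <- paste(s2, collapse = "")
    if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- s2 }
  }
  if (length(out) == 0L) out <- list(state)  # all nodes clamped
  out
}

# -- perturbations ------------------------------------------------------------

#' In-silico genetic perturbations
#'
#' A knockout forces a node permanently to 0, constitutive overexpression
#' forces it to 1: the node's update function is replaced by the constant and
#' the node is excluded from free-node enumeration, exactly like a clamped
#' input.
#'
#' @param node node name (synonyms accepted).
#' @param mode `"ko"` (force 0) or `"oe"` (force 1).
#' @return an object of class `perturbation`.
#' @seealso [apply_perturbation()]
#' @export
perturbation <- function(node, mode = c("ko", "oe")) {
  mode <- match.arg(mode)
  structure(list(node = canonical_node(node), mode = mode), class = "perturbation")
}

#' @rdname perturbation
#' @export
ko <- function(node) perturbation(node, "ko")

#' @rdname perturbation
#' @export
oe <- function(node) perturbation(node, "oe")

#' Apply perturbations to a network
#'
#' Returns a new network in which each perturbed node carries the constant
#' update function 0 (knockout) or 1 (overexpression). Applying the same
#' perturbation twice is idempotent; two conflicting modes on one node are an
#' error.
#'
#' @param net a `boolean_network`.
#' @param perturbations a list of [perturbation()] objects (a single one is
#'   also accepted).
#' @return the perturbed network; the input network is unmodified.
#' @export
apply_perturbation <- function(net, perturbations) {
  if (inherits(perturbations, "perturbation")) perturbations <- list(perturbations)
  if (length(perturbations) == 0L) return(net)
  val <- integer()
  for (p in perturbations) {
    stopifnot(inherits(p, "perturbation"))
    if (!(p$node %in% net$nodes))
      stop(sprintf("cannot perturb unknown node '%s'", p$node), call. = FALSE)
    v <- if (p$mode == "ko") 0L else 1L
    if (p$node %in% names(val) && val[[p$node]] != v)
      stop(sprintf("conflicting perturbations on node '%s'", p$node), call. = FALSE)
    val[[p$node]] <- v
  }
  for (nm in names(val)) net$rules[[nm]] <- lx_const(val[[nm]])
  net <- set_clamps(net, val)
  net$perturbed <- union(net$perturbed, names(val))
  net
}
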