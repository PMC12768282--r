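# BoolNet-style .bnet interchange: "targets, factors" header, one
# "NODE, rule" line per node, '#' comments, &/|/! operators, constants 0/1.

#' Read a Boolean network from a `.bnet` file
#'
#' @param path path to a `.bnet` file, or a character vector of lines via
#'   `text`.
#' @param text optional character vector of file lines (overrides `path`).
#' @return a `boolean_network` with node order equal to file order.
#' @export
read_bnet <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  src <- if (!is.null(text)) "<text>" else path
  keep <- which(!grepl("^[[:space:]]*(#|$)", lines))
  if (length(keep) == 0L)
    stop(sprintf("%s: empty .bnet file", src), call. = FALSE)
  hdr <- lines[keep[1L]]
  if (!grepl("^[[:space:]]*targets[[:space:]]*,[[:space:]]*factors[[:space:]]*$",
             hdr, ignore.case = TRUE))
    stop(sprintf("%s: missing 'targets, factors' header (line %d)", src, keep[1L]),
         call. = FALSE)
  body <- keep[-1L]
  targets <- character(0)
  rule_txt <- character(0)
  for (ln in body) {
    parts <- regmatches(lines[ln], regexpr(",", lines[ln]), invert = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop(sprintf("%s: line %d is not 'target, factors'", src, ln), call. = FALSE)
    tg <- canonical_node(trimws(parts[1L]))
    if (tg %in% targets)
      stop(sprintf("%s: line %d: duplicate target '%s'", src, ln, tg), call. = FALSE)
    targets <- c(targets, tg)
    rule_txt <- c(rule_txt, trimws(parts[2L]))
  }
  rules <- vector("list", length(targets))
  names(rules) <- targets
  for (i in seq_along(targets)) {
    rules[[i]] <- tryCatch(parse_boolean_rule(rule_txt[i]),
      error = function(e) stop(sprintf("%s: line %d: %s", src, body[i],
                                       conditionMessage(e)), call. = FALSE))
    undecl <- setdiff(expr_vars(rules[[i]]), targets)
    if (length(undecl))
      stop(sprintf("%s: line %d: undeclared factor(s): %s", src, body[i],
                   paste(undecl, collapse = ", ")), call. = FALSE)
  }
  boolean_network(rules)
}

#' Serialize a Boolean network to `.bnet` text
#'
#' Clamped nodes are written as their clamped constant, with the unclamped
#' rule preserved in a comment line; re-reading the text therefore yields a
#' network truth-table-equivalent to the clamped original.
#'
#' @param net a `boolean_network`.
#' @param path optional path to write to.
#' @return the file lines, invisibly when `path` is given.
#' @export
write_bnet <- function(net, path = NULL) {
  lines <- "targets, factors"
  for (nm in net$nodes) {
    if (nm %in% names(net$clamps)) {
      lines <- c(lines,
        sprintf("# %s clamped to %d; unclamped rule: %s",
                nm, net$clamps[[nm]], format_logic_expr(net$rules[[nm]])),
        sprintf("%s, %d", nm, net$clamps[[nm]]))
    } else {
      lines <- c(lines, sprintf("%s, %s", nm, format_logic_expr(net$rules[[nm]])))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export a state transition graph to DOT or GraphML
#'
#' States are labeled by `node=value` strings. Following the usual display
#' convention for asynchronous STGs, self-loop transitions can be suppressed
#' (fixed points then render as sink vertices).
#'
#' @param stg an `stg` from [build_stg()].
#' @param hide_self_loops drop self-loop edges (default `TRUE`).
#' @param path optional output path.
#' @return DOT text lines (invisibly when `path` given).
#' @export
export_stg_dot <- function(stg, hide_self_loops = TRUE, path = NULL) {
  g <- stg$graph
  el <- igraph::as_edgelist(g, names = FALSE)
  if (hide_self_loops) el <- el[el[, 1L] != el[, 2L], , drop = FALSE]
  labs <- igraph::V(g)$label
  lines <- c("digraph STG {",
             "  node [shape=box, fontsize=10];",
             sprintf("  s%d [label=\"%s\"];", seq_along(labs) - 1L, labs),
             sprintf("  s%d -> s%d;", el[, 1L] - 1L, el[, 2L] - 1L),
             "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname export_stg_dot
#' @export
export_stg_graphml <- function(stg, hide_self_loops = TRUE, path) {
  g <- stg$graph
  if (hide_self_loops) {
    el <- igraph::as_edgelist(g, names = FALSE)
    g <- igraph::delete_edges(g, which(el[, 1L] == el[, 2L]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
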