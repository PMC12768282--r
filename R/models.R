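# Packaged cardiac model definitions and their validation against the
# published steady-state tables.

.models_sidecar <- function() {
  path <- system.file("extdata", "models.json", package = "cardiobn")
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Load a packaged cardiac network model
#'
#' Three models are shipped: `"cm_subtype"` (9 nodes; RA/NR2F2 switch between
#' atrial and ventricular identity), `"heart_field"` (11 nodes; WNT/BMP-driven
#' first vs second heart field specification) and `"unified"` (21 nodes;
#' both stages coupled through GATA4/6 and NKX2-5). Models are stored as
#' `.bnet` rule files with a JSON sidecar declaring inputs, default clamps,
#' cell-type signatures and provenance. Default clamps (e.g. constitutively
#' active NOTCH and exogenous BMP2) are applied on load.
#'
#' @param name one of `"cm_subtype"`, `"heart_field"`, `"unified"`.
#' @return an object of class `model_definition`: a list with `name`,
#'   `network` (a `boolean_network` with default clamps applied), `inputs`,
#'   `condition_inputs`, `signatures`, `steady_state_table`, `provenance`,
#'   `expected_lineage` (unified only) and `path`.
#' @examples
#' m <- load_model("cm_subtype")
#' length(m$network$nodes)
#' @export
load_model <- function(name = c("cm_subtype", "heart_field", "unified")) {
  name <- match.arg(name)
  meta <- .models_sidecar()[[name]]
  path <- system.file("extdata", meta$file, package = "cardiobn")
  net <- read_bnet(path)
  default_clamps <- unlist(meta$default_clamps)
  if (length(default_clamps)) net <- set_clamps(net, default_clamps)
  sigs <- lapply(meta$signatures, function(s) unlist(s))
  tab <- lapply(meta$steady_state_table, function(cond) {
    list(condition = cond$condition,
         clamps = if (length(cond$clamps)) unlist(cond$clamps) else integer(),
         expected = lapply(cond$expected, function(e)
           list(label = e$label, state = unlist(e$state))))
  })
  structure(list(
    name = name,
    network = net,
    inputs = unlist(meta$inputs),
    condition_inputs = unlist(meta$condition_inputs),
    signatures = sigs,
    steady_state_table = tab,
    provenance = meta$provenance,
    expected_lineage = if (!is.null(meta$expected_lineage)) unlist(meta$expected_lineage),
    path = path), class = "model_definition")
}

#' @export
print.model_definition <- function(x, ...) {
  cat(sprintf("<model_definition> %s: %d nodes, inputs: %s\n",
              x$name, length(x$network$nodes), paste(x$inputs, collapse = ", ")))
  cat("  default clamps:",
      paste(sprintf("%s=%d", names(x$network$clamps), x$network$clamps), collapse = " "), "\n")
  cat("  cell types:", paste(names(x$signatures), collapse = ", "), "\n")
  invisible(x)
}

#' The four (WNT, RA) signaling conditions of the unified model
#'
#' @param model a `model_definition` (usually `load_model("unified")`).
#' @return a named list of clamp vectors, one per condition, keyed
#'   `"WNT=0,RA=0"` etc. (the WNT condition clamps the exogenous `EX_WNT`
#'   node); ordered as in the published efficiency table.
#' @export
signaling_conditions <- function(model = load_model("unified")) {
  stopifnot(identical(model$condition_inputs, c("EX_WNT", "RA")))
  keys <- c("WNT=0,RA=0", "WNT=1,RA=0", "WNT=0,RA=1", "WNT=1,RA=1")
  out <- lapply(keys, function(k) {
    v <- as.integer(regmatches(k, gregexpr("[01]", k))[[1L]])
    c(EX_WNT = v[1L], RA = v[2L])
  })
  names(out) <- keys
  out
}

#' Classify a steady state by cell-type signature
#'
#' A signature is a partial assignment over marker nodes (e.g. atrial:
#' `MYL7=1, MYL2=0`). A state is classified as the unique matching signature;
#' constraints on nodes fixed by an active perturbation are ignored, since a
#' knocked-out marker cannot report the fate it labels.
#'
#' @param state a `network_state` (or named 0/1 vector).
#' @param signatures named list of constraint vectors, e.g.
#'   `model$signatures`.
#' @param exclude node names whose constraints are dropped (defaults to
#'   none); perturbed nodes of the originating network are the typical use.
#' @return the matching label, or `"unclassified"`; two matches are an error.
#' @export
classify_attractor <- function(state, signatures, exclude = character()) {
  exclude <- canonical_node(exclude)
  hits <- character()
  for (lab in names(signatures)) {
    sig <- signatures[[lab]]
    use <- setdiff(names(sig), exclude)
    if (length(use) == 0L) next
    if (all(state[use] == sig[use])) hits <- c(hits, lab)
  }
  if (length(hits) > 1L)
    stop("signatures are not mutually exclusive on this state: ",
         paste(hits, collapse = ", "), call. = FALSE)
  if (length(hits) == 0L) "unclassified" else hits
}

#' Verify a model against its published steady-state table
#'
#' For every clamp condition declared in the model's steady-state table,
#' computes the attractors of the clamped network and checks that (a) each
#' expected state is realized as a steady state (compared on the nodes the
#' table lists) and (b) no unexpected attractor exists.
#'
#' @param model a `model_definition`.
#' @param table optional replacement table in the same structure as
#'   `model$steady_state_table` (used for negative controls).
#' @return an object of class `sstable_report`: a data.frame of per-row
#'   results with attributes `pass`, `unexpected`.
#' @export
verify_steady_state_tables <- function(model, table = model$steady_state_table) {
  rows <- list()
  unexpected <- list()
  for (cond in table) {
    net <- if (length(cond$clamps)) set_clamps(model$network, cond$clamps)
           else model$network
    atts <- find_attractors(net)
    steady <- atts[vapply(atts, function(a) a$is_steady, logical(1))]
    states <- lapply(steady, function(a) a$states[[1L]])
    matched <- rep(FALSE, length(states))
    for (e in cond$expected) {
      nds <- names(e$state)
      hit <- which(vapply(states, function(s) all(s[nds] == e$state[nds]), logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond$condition, label = e$label,
        found = length(hit) > 0L, stringsAsFactors = FALSE)
      matched[hit] <- TRUE
    }
    extra <- c(atts[!vapply(atts, function(a) a$is_steady, logical(1))],
               steady[!matched])
    if (length(extra))
      unexpected[[cond$condition]] <- extra
  }
  rep <- do.call(rbind, rows)
  structure(rep, class = c("sstable_report", class(rep)),
            pass = all(rep$found) && length(unexpected) == 0L,
            unexpected = unexpected)
}

#' @export
print.sstable_report <- function(x, ...) {
  cat(sprintf("Steady-state table verification: %s\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  df <- x; class(df) <- "data.frame"
  print(df, row.names = FALSE)
  ux <- attr(x, "unexpected")
  if (length(ux))
    cat("Unexpected attractors under:", paste(names(ux), collapse = "; "), "\n")
  invisible(x)
}
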