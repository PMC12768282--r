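# Probabilistic (Markov-chain) population simulation: uniform single-node
# updates to absorption, per-condition cell-type counts, lineage fidelity.

.compiled_for_cpp <- function(cn) {
  list(regulators = lapply(cn$regulators, function(r) as.integer(r - 1L)),
       truth_tables = lapply(cn$truth_tables, as.integer),
       clamped = cn$clamped, clamp_values = as.integer(cn$clamp_values))
}

#' Simulate one cell to absorption
#'
#' Repeatedly selects one of the n nodes uniformly at random (probability
#' 1/n each, stable and clamped nodes included as null steps) and applies
#' its update function, until the state is a fixed point of the clamped
#' network or the step budget is exhausted. Uses R's RNG: seed with
#' [set.seed()] for reproducibility.
#'
#' @param net a `boolean_network`.
#' @param start a state over `net$nodes`.
#' @param max_steps step budget; default `10000 * n` (the model has no
#'   cyclic attractors, so non-convergence signals either a short budget or
#'   a genuine cycle and is flagged, never silently dropped).
#' @return list with `state` (terminal `network_state`), `converged`,
#'   `steps`.
#' @export
simulate_cell <- function(net, start, max_steps = NULL) {
  cn <- compile_network(net)
  if (is.null(max_steps)) max_steps <- 10000 * cn$n
  args <- .compiled_for_cpp(cn)
  init <- matrix(as.integer(start[cn$nodes]), nrow = 1L)
  res <- cpp_simulate_runs(args$regulators, args$truth_tables, args$clamped,
                           args$clamp_values, init, max_steps)
  s <- setNames(as.integer(res$terminal[1L, ]), cn$nodes)
  class(s) <- "network_state"
  list(state = s, converged = res$converged[1L], steps = res$steps[1L])
}

#' Simulate a heterogeneous cell population
#'
#' Emulates a heterogeneous population of progenitor cells: for each
#' signaling condition, input nodes are clamped, every free node of every
#' cell is initialized independently at 0 or 1 with probability one half,
#' and each cell is run to absorption under uniform single-node updates.
#' Terminal states are classified by the model's cell-type signatures.
#'
#' @param model a `model_definition` (or a bare `boolean_network`, in which
#'   case `signatures` must be supplied).
#' @param runs simulated cells per condition (published setting: 100000).
#' @param conditions named list of clamp vectors; defaults to the model's
#'   four (WNT, RA) combinations for the unified model, or a single
#'   unclamped condition otherwise.
#' @param seed master seed; when non-NULL, `set.seed(seed)` is called, and
#'   per-cell substreams are consumed sequentially from that stream.
#' @param max_steps per-cell step budget (default `10000 * n`).
#' @param signatures optional signature list overriding the model's.
#' @return an object of class `absorption_counts`: a data.frame with one
#'   row per condition and one column per cell-type label, plus
#'   `unclassified`, `non_converged` and `runs`; per row the counts sum to
#'   `runs`.
#' @examples
#' \donttest{
#' counts <- simulate_population(load_model("unified"), runs = 2000, seed = 1)
#' lineage_fraction(counts)
#' }
#' @export
simulate_population <- function(model, runs = 100000L, conditions = NULL,
                                seed = NULL, max_steps = NULL,
                                signatures = NULL) {
  if (inherits(model, "boolean_network"))
    model <- structure(list(name = "custom", network = model,
                            signatures = signatures), class = "model_definition")
  if (is.null(signatures)) signatures <- model$signatures
  if (is.null(conditions)) {
    conditions <- if (identical(model$name, "unified")) signaling_conditions(model)
                  else list(default = integer())
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- names(signatures)
  out <- list()
  for (ck in names(conditions)) {
    net <- if (length(conditions[[ck]])) set_clamps(model$network, conditions[[ck]])
           else model$network
    cn <- compile_network(net)
    ms <- if (is.null(max_steps)) 10000 * cn$n else max_steps
    f <- length(cn$free_idx)
    init <- matrix(0L, nrow = runs, ncol = cn$n)
    if (f > 0L)
      init[, cn$free_idx] <- matrix(as.integer(runif(runs * f) < 0.5),
                                    nrow = runs, ncol = f)
    args <- .compiled_for_cpp(cn)
    res <- cpp_simulate_runs(args$regulators, args$truth_tables, args$clamped,
                             args$clamp_values, init, ms)
    term <- res$terminal
    colnames(term) <- cn$nodes
    lab <- rep("unclassified", runs)
    for (lb in labels) {
      sig <- signatures[[lb]]
      use <- setdiff(names(sig), net$perturbed)
      if (length(use) == 0L) next
      hit <- rep(TRUE, runs)
      for (nd in use) hit <- hit & (term[, nd] == sig[[nd]])
      multi <- hit & lab != "unclassified"
      if (any(multi))
        stop("signatures are not mutually exclusive on simulated terminals", call. = FALSE)
      lab[hit] <- lb
    }
    lab[!res$converged] <- "non_converged"
    cnt <- table(factor(lab, levels = c(labels, "unclassified", "non_converged")))
    out[[ck]] <- data.frame(condition = ck, as.list(cnt), runs = runs,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(df, class = c("absorption_counts", class(df)),
            labels = labels, seed = seed)
}

#' Fraction of cells following the expected lineage
#'
#' Pools the absorption counts over conditions and reports the fraction of
#' simulated cells that terminated in the cell type expected for their
#' condition (WNT off/RA off: FHF ventricular; WNT on/RA off: SHF
#' ventricular; WNT off/RA on: FHF atrial; WNT on/RA on: SHF atrial), with
#' a binomial standard error.
#'
#' @param counts an `absorption_counts` from [simulate_population()].
#' @param expected_map named character vector mapping condition keys to
#'   expected labels; defaults to the unified model's lineage map.
#' @return list with `fraction`, `se`, `expected_cells`, `total`.
#' @export
lineage_fraction <- function(counts,
                             expected_map = load_model("unified")$expected_lineage) {
  missing <- setdiff(counts$condition, names(expected_map))
  if (length(missing))
    stop("no expected lineage for condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  good <- vapply(seq_len(nrow(counts)), function(i)
    counts[i, expected_map[[counts$condition[i]]]], numeric(1))
  total <- sum(counts$runs)
  p <- sum(good) / total
  list(fraction = p, se = sqrt(p * (1 - p) / total),
       expected_cells = sum(good), total = total)
}

#' @export
print.absorption_counts <- function(x, ...) {
  df <- x; class(df) <- "data.frame"
  print(df, row.names = FALSE)
  invisible(x)
}
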