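# Knockout/overexpression validation battery: simulate literature
# perturbations across the four (WNT, RA) signaling conditions and score
# agreement with the expected presence/absence of each cell type.

#' Load the perturbation battery definition
#'
#' The battery is data, not code: a JSON file listing the experiments
#' (wild type plus seven published knockouts/overexpressions), the four
#' signaling conditions, and the literature-expected presence of each
#' condition's cell type. New literature perturbations can be added by
#' editing (a copy of) the file.
#'
#' @param path path to a battery JSON; defaults to the packaged battery.
#' @return list with elements `conditions` and `experiments`.
#' @export
battery_experiments <- function(path = system.file("extdata", "perturbation_battery.json",
                                                   package = "cardiobn")) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

.condition_subtype_constraints <- function(cell_type) {
  # subtype markers only: heart-field attribution under perturbation follows
  # the WNT input condition, because perturbations can silence heart-field
  # markers without abolishing the branch itself
  if (grepl("aCM$", cell_type)) c(MYL7 = 1L, MYL2 = 0L) else c(MYL2 = 1L, MYL7 = 0L)
}

#' Presence of a condition's cell type under perturbation
#'
#' Applies the given perturbations and condition clamps to the model, finds
#' all attractors, and reports whether some steady state carries the
#' condition's subtype markers (atrial `MYL7+ MYL2-` when RA is on,
#' ventricular `MYL2+ MYL7-` when RA is off). Marker constraints on
#' perturbed nodes are dropped, and heart-field attribution follows the WNT
#' clamp of the condition.
#'
#' @param model a `model_definition` (the unified model).
#' @param perturbations list of [perturbation()] objects (may be empty).
#' @param condition named clamp vector, e.g. `c(EX_WNT = 0, RA = 1)`.
#' @param cell_type the condition's cell-type label (e.g. `"FHF_aCM"`);
#'   defaults to the label implied by the condition's clamps.
#' @return logical: is the cell type realized as a steady state?
#' @export
simulated_presence <- function(model, perturbations, condition, cell_type = NULL) {
  names(condition) <- canonical_node(names(condition))
  if (is.null(cell_type)) {
    branch <- if (condition[["EX_WNT"]] == 1L) "SHF" else "FHF"
    sub <- if (condition[["RA"]] == 1L) "aCM" else "vCM"
    cell_type <- paste(branch, sub, sep = "_")
  }
  net <- set_clamps(model$network, condition)
  net <- apply_perturbation(net, perturbations)
  atts <- find_attractors(net)
  steady <- atts[vapply(atts, function(a) a$is_steady, logical(1))]
  sig <- .condition_subtype_constraints(cell_type)
  use <- setdiff(names(sig), net$perturbed)
  if (length(use) == 0L) return(NA)
  any(vapply(steady, function(a) all(a$states[[1L]][use] == sig[use]), logical(1)))
}

#' Run the knockout/overexpression battery
#'
#' Evaluates every experiment of the battery under every signaling condition
#' and scores simulated against literature-expected presence. The global
#' score counts matches over the full experiment-by-condition grid.
#'
#' @param model a `model_definition` (the unified model).
#' @param battery a battery definition from [battery_experiments()].
#' @return an object of class `success_matrix`: a data.frame with one row
#'   per experiment x condition (`expected`, `simulated`, `match`), with
#'   attributes `matches`, `cells`, `rates` (per-experiment success rate, %).
#' @examples
#' \donttest{
#' sm <- run_battery(load_model("unified"))
#' attr(sm, "matches")  # 27 of 32
#' }
#' @export
run_battery <- function(model, battery = battery_experiments()) {
  rows <- list()
  for (ex in battery$experiments) {
    perts <- c(lapply(ex$ko, ko), lapply(ex$oe, oe))
    for (cond in battery$conditions) {
      clamps <- unlist(cond$clamps)
      sim <- simulated_presence(model, perts, clamps, cond$cell_type)
      expd <- as.logical(ex$expected[[cond$key]])
      rows[[length(rows) + 1L]] <- data.frame(
        experiment = ex$id, label = ex$label, condition = cond$key,
        cell_type = cond$cell_type, expected = expd, simulated = sim,
        match = identical(sim, expd), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rates <- vapply(split(df$match, factor(df$experiment, levels = unique(df$experiment))),
                  function(m) 100 * mean(m), numeric(1))
  structure(df, class = c("success_matrix", class(df)),
            matches = sum(df$match), cells = nrow(df), rates = rates)
}

#' @export
print.success_matrix <- function(x, ...) {
  df <- x; class(df) <- "data.frame"
  wide <- lapply(split(df, factor(df$experiment, levels = unique(df$experiment))),
                 function(d) ifelse(d$match, ifelse(d$simulated, "present", "absent"), "MISMATCH"))
  tab <- do.call(cbind, wide)
  rownames(tab) <- df$condition[seq_len(nrow(tab))]
  print(tab, quote = FALSE)
  rates <- attr(x, "rates")
  cat("success rate (%):", paste(sprintf("%s=%g", names(rates), rates), collapse = " "), "\n")
  cat(sprintf("total: %d/%d matches\n", attr(x, "matches"), attr(x, "cells")))
  invisible(x)
}
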