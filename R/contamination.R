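#' Destination wells requiring a part
#'
#' @param scenario A `tip_scenario`.
#' @param part A part name from the catalogue.
#' @return A tibble with columns `construct` (row index into the construct
#'   table), `slot`, `well`, in construct input order.
#' @export
wells_requiring <- function(scenario, part) {
  stopifnot(inherits(scenario, "tip_scenario"))
  if (!part %in% part_catalogue(scenario)) {
    abort(paste0("part not in catalogue: ", part), class = "tipsaver_error")
  }
  idx <- which(vapply(scenario$constructs$recipe, function(r) part %in% r, logical(1)))
  tibble(
    construct = idx,
    slot = scenario$constructs$slot[idx],
    well = scenario$constructs$well[idx]
  )
}

#' Well contents immediately before a distribution step
#'
#' Before the part of rank `step` in the order is dispensed, a destination
#' well contains exactly those of its recipe parts whose rank is smaller
#' than `step`. This closed form (rather than mutable planner state) is what
#' the contamination costs are computed from; the rank-`step` part itself is
#' never counted, as it is about to be delivered.
#'
#' @param scenario A `tip_scenario`.
#' @param order A [part_order()] (or character vector over the catalogue).
#' @param step 1-based rank into `order`.
#' @return A tibble with columns `construct`, `slot`, `well` and a list
#'   column `contents` (character vector of parts already present).
#' @export
well_contents <- function(scenario, order, step) {
  stopifnot(inherits(scenario, "tip_scenario"))
  if (step < 1 || step > length(order)) {
    abort("invalid step", class = "tipsaver_error")
  }
  earlier <- order[seq_len(step - 1)]
  cs <- scenario$constructs
  tibble(
    construct = seq_len(nrow(cs)),
    slot = cs$slot,
    well = cs$well,
    contents = lapply(cs$recipe, function(r) r[r %in% earlier])
  )
}

#' Per-part contamination cost graph
#'
#' For the part at rank `step`, the customers are the wells requiring it.
#' A directed edge i -> j costs 0 when every part already present in well i
#' is also present in well j (so a tip moving i -> j cannot introduce a new
#' part), and 1 otherwise. The depot -- the merged abstraction of the part's
#' source well and the tip waste, where every tip route starts and ends --
#' is connected to every customer with zero cost in both directions. Because
#' the zero-cost condition is set inclusion, it is transitive: a tip route
#' that only uses zero-cost edges has nested contents along its whole walk.
#'
#' @param scenario A `tip_scenario`.
#' @param order A [part_order()].
#' @param step 1-based rank into `order`.
#' @return A `tip_graph`: list with `part`, `wells` (customer tibble in
#'   construct order), `contents` (list of part sets) and `cost` (n x n 0/1
#'   matrix over customers; the all-zero depot edges are implicit).
#' @export
cost_graph <- function(scenario, order, step) {
  part <- order[[step]]
  wells <- wells_requiring(scenario, part)
  if (nrow(wells) == 0) abort("empty customer set", class = "tipsaver_error")
  contents <- well_contents(scenario, order, step)$contents[wells$construct]
  g <- cost_graph_from_contents(contents, part = part,
                                wells = paste0(wells$slot, ":", wells$well))
  g$wells <- wells
  g
}

#' Build a contamination graph directly from content sets
#'
#' Mainly useful for testing the routing solvers on arbitrary instances
#' without constructing a full scenario.
#'
#' @param contents A list of character vectors: the parts already present in
#'   each customer well.
#' @param part Name of the part being distributed.
#' @param wells Optional customer labels.
#' @return A `tip_graph`.
#' @export
cost_graph_from_contents <- function(contents, part = "part", wells = NULL) {
  n <- length(contents)
  if (n == 0) abort("empty customer set", class = "tipsaver_error")
  cost <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && !all(contents[[i]] %in% contents[[j]])) cost[i, j] <- 1L
    }
  }
  structure(
    list(
      part = part,
      wells = wells %||% paste0("w", seq_len(n)),
      contents = contents,
      cost = cost,
      n = n
    ),
    class = "tip_graph"
  )
}

#' @export
print.tip_graph <- function(x, ...) {
  cat(sprintf("<tip_graph> part %s: %d customer wells, %d zero-cost arcs\n",
              x$part, x$n, sum(x$cost == 0L) - x$n))
  invisible(x)
}

#' Edge list of a contamination graph
#'
#' @param graph A `tip_graph`.
#' @param include_depot Include the (always zero-cost) depot edges, with the
#'   depot as node 0.
#' @return A tibble with columns `from`, `to`, `cost` (node indices;
#'   customers are 1..n in construct order).
#' @export
graph_edges <- function(graph, include_depot = TRUE) {
  n <- graph$n
  idx <- which(row(graph$cost) != col(graph$cost))
  out <- tibble(
    from = row(graph$cost)[idx],
    to = col(graph$cost)[idx],
    cost = graph$cost[idx]
  )
  if (include_depot) {
    depot <- tibble(
      from = c(rep(0L, n), seq_len(n)),
      to = c(seq_len(n), rep(0L, n)),
      cost = 0L
    )
    out <- dplyr::bind_rows(depot, out)
  }
  dplyr::arrange(out, .data$from, .data$to)
}

#' DOT rendering of a contamination graph (for debugging)
#'
#' @param graph A `tip_graph`.
#' @return A single string in Graphviz DOT syntax; zero-cost customer arcs
#'   are solid, cost-one arcs dashed, depot edges omitted for legibility.
#' @export
graph_dot <- function(graph) {
  e <- graph_edges(graph, include_depot = FALSE)
  lab <- if (is.data.frame(graph$wells)) graph$wells$well else graph$wells
  lines <- c(
    sprintf("digraph \"%s\" {", graph$part),
    sprintf("  v%d [label=\"%s\"];", seq_len(graph$n), lab),
    sprintf("  v%d -> v%d [style=%s];", e$from, e$to,
            ifelse(e$cost == 0, "solid", "dashed")),
    "}"
  )
  paste(lines, collapse = "\n")
}
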