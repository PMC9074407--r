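#' Optimize a full assembly scenario into a pipetting plan
#'
#' Iterates the part-distribution order; for each part it builds the
#' contamination graph over the wells requiring it, solves the capacitated
#' minimum-tip routing problem exactly, and appends the resulting pipetting
#' commands. The total tip count T is therefore minimal for the given part
#' order and capacity (each per-part subproblem is solved to optimality; the
#' order itself is an input, not optimized over).
#'
#' Each tip route becomes the command block `pick_tip`, one `aspirate` of
#' route length x aliquot volume from the part's source well, one `dispense`
#' of one aliquot per visited well, then `drop_tip`. Routes of one part are
#' emitted in ascending order of their first customer; parts follow the
#' order's ranks.
#'
#' @param scenario A `tip_scenario`.
#' @param order A [part_order()]; default is the scenario's attached order
#'   mode (as-read unless a config said otherwise).
#' @param capacity Per-tip dispense capacity; defaults to
#'   [effective_capacity()] of the scenario.
#' @param verbose Print one line per part (rank, part, wells, tips).
#' @return A `tip_plan`: list with the scenario, `order`, `route_sets`,
#'   `commands` (tibble `step,verb,part,slot,well,volume_ul`), total
#'   additions `A` and total tips `T`.
#' @examples
#' sc <- scenario(
#'   tibble::tibble(well = c("A1", "B1"),
#'                  recipe = list(c("GFP", "DVK"), c("YFP", "DVK"))),
#'   tibble::tibble(part = c("GFP", "YFP", "DVK"), well = c("A1", "B1", "C1")),
#'   capacity = 2
#' )
#' plan <- optimize_scenario(sc)
#' glance(plan) # 4 additions served by 3 tips: 25% saved
#' @export
optimize_scenario <- function(scenario, order = NULL, capacity = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(scenario, "tip_scenario"))
  if (is.null(order)) {
    mode <- attr(scenario, "order_mode") %||% "as_read"
    order <- part_order(scenario, mode, seed = attr(scenario, "order_seed"))
  }
  catalogue <- part_catalogue(scenario)
  if (!setequal(order, catalogue) || length(order) != length(catalogue)) {
    abort("`order` must be a permutation of the part catalogue")
  }
  kappa <- capacity %||% effective_capacity(scenario)
  aliquot <- scenario$aliquot_volume %||% NA_real_

  route_sets <- vector("list", length(order))
  commands <- vector("list", length(order))
  tips_so_far <- 0L
  for (h in seq_along(order)) {
    g <- cost_graph(scenario, order, h)
    rs <- min_tip_routes(g, kappa)
    route_sets[[h]] <- rs
    tips_so_far <- tips_so_far + rs$K
    if (verbose) {
      message(sprintf("h=%d part=%s wells=%d tips=%d (cumulative %d)",
                      h, order[[h]], rs$n, rs$K, tips_so_far))
    }
    src <- scenario$sources[scenario$sources$part == order[[h]], ]
    commands[[h]] <- purrr::map_dfr(rs$routes, function(route) {
      w <- g$wells[route, ]
      dplyr::bind_rows(
        tibble(verb = "pick_tip", part = order[[h]],
               slot = NA_character_, well = NA_character_, volume_ul = NA_real_),
        tibble(verb = "aspirate", part = order[[h]],
               slot = src$slot, well = src$well,
               volume_ul = length(route) * aliquot),
        tibble(verb = "dispense", part = order[[h]],
               slot = w$slot, well = w$well, volume_ul = aliquot),
        tibble(verb = "drop_tip", part = order[[h]],
               slot = NA_character_, well = NA_character_, volume_ul = NA_real_)
      )
    })
  }
  commands <- dplyr::bind_rows(commands)
  commands <- dplyr::mutate(commands, step = dplyr::row_number(),
                            .before = "verb")
  structure(
    list(
      scenario = scenario,
      order = order,
      capacity = kappa,
      route_sets = route_sets,
      commands = commands,
      A = total_additions(scenario),
      T = tips_so_far
    ),
    class = "tip_plan"
  )
}

#' @export
print.tip_plan <- function(x, ...) {
  cat(sprintf(
    "<tip_plan> %d part additions served by %d tips (%.2f%% tips saved)\n",
    x$A, x$T, 100 * (x$A - x$T) / x$A
  ))
  invisible(x)
}

#' @describeIn optimize_scenario One row per distribution step: rank `h`,
#'   `part`, number of wells served and tips used.
#' @param x A `tip_plan`.
#' @param ... Unused.
#' @method tidy tip_plan
#' @export
tidy.tip_plan <- function(x, ...) {
  tibble(
    h = seq_along(x$order),
    part = as.character(unclass(x$order)),
    n_wells = vapply(x$route_sets, function(r) r$n, integer(1)),
    tips = vapply(x$route_sets, function(r) r$K, integer(1))
  )
}

#' @describeIn optimize_scenario One-row plan summary with additions, tips
#'   and percent saved.
#' @method glance tip_plan
#' @export
glance.tip_plan <- function(x, ...) {
  dplyr::mutate(savings_report(x),
                n_constructs = nrow(x$scenario$constructs),
                n_parts = length(x$order))
}

#' Tip-savings summary of a plan
#'
#' The savings are reported against the baseline in which every part
#' addition uses a fresh tip, i.e. A tips for A additions:
#' `percent_saved = 100 * (A - T) / A`.
#'
#' @param plan A `tip_plan`.
#' @return A tibble with columns `additions` (A), `tips` (T),
#'   `percent_saved`.
#' @export
savings_report <- function(plan) {
  stopifnot(inherits(plan, "tip_plan"))
  tibble(
    additions = plan$A,
    tips = plan$T,
    percent_saved = 100 * (plan$A - plan$T) / plan$A
  )
}

#' Independently validate a pipetting plan
#'
#' Re-simulates the command list from scratch against the scenario, without
#' trusting any planner state: wells start empty and accumulate parts as
#' dispenses execute. A contamination violation is flagged whenever a tip
#' dispenses into a well while some earlier well visited by the same tip
#' holds a part the later well does not (the later well would acquire it).
#' Also checked: every recipe addition happens exactly once, no tip exceeds
#' the capacity, and every tip block has the shape pick_tip, aspirate,
#' dispense(s), drop_tip with conserved volume.
#'
#' @param scenario The `tip_scenario` the plan was built for.
#' @param plan A `tip_plan`, or a commands tibble with columns
#'   `verb,part,slot,well,volume_ul`.
#' @param capacity Capacity to enforce; defaults to the plan's (or the
#'   scenario's effective) capacity.
#' @return A `plan_validation`: list with `valid` flag and a `violations`
#'   tibble (`type`, `details`).
#' @export
validate_plan <- function(scenario, plan, capacity = NULL) {
  stopifnot(inherits(scenario, "tip_scenario"))
  if (inherits(plan, "tip_plan")) {
    if (!identical(plan$scenario$constructs, scenario$constructs) ||
        !identical(plan$scenario$sources, scenario$sources)) {
      abort("foreign plan", class = "tipsaver_error")
    }
    kappa <- capacity %||% plan$capacity
    cmds <- plan$commands
  } else {
    kappa <- capacity %||% effective_capacity(scenario)
    cmds <- as_tibble(plan)
  }

  violations <- list()
  flag <- function(type, details) {
    violations[[length(violations) + 1L]] <<- tibble(type = type,
                                                     details = details)
  }

  cs <- scenario$constructs
  dest_key <- paste(cs$slot, cs$well, sep = ":")
  contents <- stats::setNames(vector("list", nrow(cs)), dest_key)
  recipe_of <- stats::setNames(cs$recipe, dest_key)
  added <- character(0) # "slot:well|part" keys of performed additions

  tip_open <- FALSE
  tip_part <- NA_character_
  tip_aspirated <- NA_real_
  tip_dispensed <- 0
  tip_dispense_count <- 0L
  tip_visited <- character(0)

  close_tip <- function(at) {
    if (tip_dispense_count == 0L) {
      flag("malformed_tip_block", paste0("tip dropped without dispensing (", at, ")"))
    }
    if (isTRUE(abs(tip_aspirated - tip_dispensed) > 1e-9)) {
      flag("malformed_tip_block",
           sprintf("aspirated %.3f ul but dispensed %.3f ul (%s)",
                   tip_aspirated, tip_dispensed, at))
    }
  }

  for (i in seq_len(nrow(cmds))) {
    verb <- cmds$verb[i]
    if (verb == "pick_tip") {
      if (tip_open) flag("malformed_tip_block", sprintf("step %d: tip already held", i))
      tip_open <- TRUE
      tip_part <- cmds$part[i]
      tip_aspirated <- NA_real_
      tip_dispensed <- 0
      tip_dispense_count <- 0L
      tip_visited <- character(0)
    } else if (verb == "aspirate") {
      if (!tip_open || tip_dispense_count > 0L) {
        flag("malformed_tip_block",
             sprintf("step %d: aspirate outside a fresh tip block", i))
      }
      tip_aspirated <- cmds$volume_ul[i]
    } else if (verb == "dispense") {
      if (!tip_open) {
        flag("malformed_tip_block", sprintf("step %d: dispense without a tip", i))
        next
      }
      key <- paste(cmds$slot[i], cmds$well[i], sep = ":")
      if (!key %in% dest_key) {
        flag("malformed_tip_block",
             sprintf("step %d: dispense into unknown well %s", i, key))
        next
      }
      part <- cmds$part[i]
      if (!identical(part, tip_part)) {
        flag("malformed_tip_block",
             sprintf("step %d: tip holds %s but dispenses %s", i, tip_part, part))
      }
      # contamination: every earlier well of this tip must be a subset of
      # the target's current (pre-dispense) contents; the part being
      # delivered is excluded, since this tip adds it to every well anyway
      for (prev in tip_visited) {
        extra <- setdiff(setdiff(contents[[prev]], part), contents[[key]])
        if (length(extra) > 0) {
          flag("contamination",
               sprintf("step %d: tip carries %s from %s into %s",
                       i, paste(extra, collapse = "+"), prev, key))
        }
      }
      add_key <- paste(key, part, sep = "|")
      if (add_key %in% added) {
        flag("duplicate_addition", sprintf("step %d: %s already added to %s",
                                           i, part, key))
      } else if (!part %in% recipe_of[[key]]) {
        flag("malformed_tip_block",
             sprintf("step %d: %s is not in the recipe of %s", i, part, key))
      }
      added <- c(added, add_key)
      contents[[key]] <- union(contents[[key]], part)
      tip_visited <- c(tip_visited, key)
      tip_dispensed <- tip_dispensed + cmds$volume_ul[i]
      tip_dispense_count <- tip_dispense_count + 1L
      if (!is.infinite(kappa) && tip_dispense_count > kappa) {
        flag("capacity_exceeded",
             sprintf("step %d: tip served %d wells with capacity %d",
                     i, tip_dispense_count, kappa))
      }
    } else if (verb == "drop_tip") {
      if (!tip_open) {
        flag("malformed_tip_block", sprintf("step %d: no tip to drop", i))
      } else {
        close_tip(sprintf("step %d", i))
      }
      tip_open <- FALSE
    } else {
      flag("malformed_tip_block", sprintf("step %d: unknown verb %s", i, verb))
    }
  }
  if (tip_open) flag("malformed_tip_block", "plan ends with a tip in hand")

  for (k in dest_key) {
    missing <- setdiff(recipe_of[[k]], sub("^.*\\|", "", added[startsWith(added, paste0(k, "|"))]))
    if (length(missing) > 0) {
      flag("missing_addition",
           sprintf("well %s never received %s", k, paste(missing, collapse = ", ")))
    }
  }

  violations <- if (length(violations) > 0) {
    dplyr::bind_rows(violations)
  } else {
    tibble(type = character(0), details = character(0))
  }
  structure(list(valid = nrow(violations) == 0, violations = violations),
            class = "plan_validation")
}

#' @export
print.plan_validation <- function(x, ...) {
  if (x$valid) {
    cat("<plan_validation> valid: no violations\n")
  } else {
    cat(sprintf("<plan_validation> INVALID: %d violation(s)\n",
                nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Write a plan's command list and savings to disk
#'
#' @param plan A `tip_plan`.
#' @param commands_csv Path for the command table
#'   (`step,verb,part,slot,well,volume_ul`).
#' @param plan_json Optional path for a JSON rendering of the plan
#'   (commands plus savings).
#' @return The plan, invisibly.
#' @export
write_plan <- function(plan, commands_csv, plan_json = NULL) {
  stopifnot(inherits(plan, "tip_plan"))
  write.csv(as.data.frame(plan$commands), commands_csv,
            row.names = FALSE, quote = FALSE)
  if (!is.null(plan_json)) {
    jsonlite::write_json(
      list(
        part_order = as.character(unclass(plan$order)),
        capacity = if (is.infinite(plan$capacity)) "unbounded" else plan$capacity,
        savings = savings_report(plan),
        commands = plan$commands
      ),
      plan_json, auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(plan)
}
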