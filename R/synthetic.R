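#' Combinatorial DNA part library
#'
#' Describes a one-part-per-category combinatorial design. The default
#' mirrors a Start-Stop-style expression-unit library: one of 6 promoters,
#' one of 4 ribosome-binding sites, one of 3 coding sequences and one of 3
#' terminators per construct (216 possible constructs).
#'
#' @param categories Named integer vector: category name -> number of
#'   library variants, in recipe order.
#' @param prefixes Optional part-id prefixes per category; defaults to the
#'   category names (the built-in categories use Prom/RBS/CDS/Term, so part
#'   ids read Prom3, RBS1, ...).
#' @return A `part_library` tibble with columns `category`, `count`,
#'   `prefix`.
#' @export
part_library <- function(categories = c(promoter = 6, RBS = 4, CDS = 3,
                                        terminator = 3),
                         prefixes = NULL) {
  if (any(categories < 1)) abort("all category counts must be >= 1")
  default_prefix <- c(promoter = "Prom", RBS = "RBS", CDS = "CDS",
                      terminator = "Term")
  prefixes <- prefixes %||%
    ifelse(names(categories) %in% names(default_prefix),
           default_prefix[names(categories)], names(categories))
  structure(
    tibble(category = names(categories), count = as.integer(categories),
           prefix = unname(prefixes)),
    class = c("part_library", "tbl_df", "tbl", "data.frame")
  )
}

library_parts <- function(library) {
  unlist(lapply(seq_len(nrow(library)), function(i) {
    paste0(library$prefix[i], seq_len(library$count[i]))
  }))
}

#' Generate a random parallel-assembly scenario
#'
#' Each construct draws one part per library category uniformly at random;
#' recipes keep the category order (promoter, RBS, CDS, terminator for the
#' default library). With `distinct = TRUE` (the default) constructs are
#' sampled without replacement over the full combination space, since
#' assembling the same construct twice in parallel is unusual. Destination
#' wells are laid out row-major (A1, A2, ..., H12) on a 96-well construct
#' plate; part sources live on a separate labware slot, also row-major.
#'
#' @param library A [part_library()].
#' @param n_constructs Number of constructs to draw.
#' @param seed Integer seed; the same seed always reproduces the same
#'   scenario.
#' @param distinct Sample construct combinations without replacement.
#' @param aliquot_volume,tip_volume,capacity Volume/capacity settings for
#'   the resulting scenario, as in [scenario()]. The defaults (1.5 ul
#'   aliquots from a 10 ul tip) give a per-tip capacity of 6 dispenses.
#' @return A `tip_scenario`.
#' @export
generate_scenario <- function(library = part_library(), n_constructs, seed,
                              distinct = TRUE,
                              aliquot_volume = 1.5, tip_volume = 10,
                              capacity = NULL) {
  stopifnot(inherits(library, "part_library"), n_constructs >= 1)
  counts <- library$count
  n_combos <- prod(counts)
  if (distinct && n_constructs > n_combos) {
    abort("library exhausted", class = "tipsaver_error")
  }
  picks <- with_local_seed(as.integer(seed), {
    if (distinct) {
      combos <- sample.int(n_combos, n_constructs)
      # decode mixed-radix combination index -> one variant per category
      t(vapply(combos - 1L, function(x) {
        v <- integer(length(counts))
        for (i in seq_along(counts)) {
          v[i] <- x %% counts[i] + 1L
          x <- x %/% counts[i]
        }
        v
      }, integer(length(counts))))
    } else {
      vapply(counts, function(k) sample.int(k, n_constructs, replace = TRUE),
             integer(n_constructs))
    }
  })
  picks <- matrix(picks, nrow = n_constructs)
  recipes <- lapply(seq_len(n_constructs), function(i) {
    paste0(library$prefix, picks[i, ])
  })

  constructs <- tibble(
    slot = paste0("construct_plate_", (seq_len(n_constructs) - 1L) %/% 96L + 1L),
    well = plate_wells(n_constructs),
    recipe = recipes
  )
  parts <- library_parts(library)
  sources <- tibble(
    part = parts,
    slot = "source_plate",
    well = plate_wells(length(parts))
  )
  scenario(constructs, sources, aliquot_volume = aliquot_volume,
           tip_volume = tip_volume, capacity = capacity)
}

# row-major 96-well labels, recycling across plates: A1..A12, B1..B12, ...
plate_wells <- function(n) {
  idx <- (seq_len(n) - 1L) %% 96L
  paste0(LETTERS[idx %/% 12L + 1L], idx %% 12L + 1L)
}

#' Savings-versus-scale benchmark sweep
#'
#' For each requested number of constructs, generates `reps` random
#' scenarios, optimizes each with the given part-order policy, and records
#' the mean and standard deviation of the percentage of tips saved. The
#' random stream of each (n, rep) cell is derived from `(seed, n, rep)`
#' only, so enlarging `reps` or `n_values` never perturbs earlier draws.
#'
#' @param library A [part_library()].
#' @param n_values Integer vector of construct counts to sweep.
#' @param reps Random scenarios per construct count.
#' @param seed Master seed for the sweep.
#' @param order_mode `"as_read"` or `"random"` part-distribution order.
#' @param distinct Passed to [generate_scenario()].
#' @param aliquot_volume,tip_volume,capacity Volume/capacity settings
#'   passed to [generate_scenario()].
#' @return A `savings_table` tibble with columns `n_constructs`, `reps`,
#'   `mean_percent_saved`, `sd_percent_saved`, `order_mode`, `capacity`.
#' @export
benchmark_sweep <- function(library = part_library(), n_values, reps = 50,
                            seed = 1, order_mode = c("as_read", "random"),
                            distinct = TRUE,
                            aliquot_volume = 1.5, tip_volume = 10,
                            capacity = NULL) {
  order_mode <- match.arg(order_mode)
  stopifnot(reps >= 1)
  rows <- purrr::map_dfr(n_values, function(n) {
    saved <- vapply(seq_len(reps), function(rep) {
      s <- derive_seed(seed, n, rep)
      sc <- generate_scenario(library, n, seed = s, distinct = distinct,
                              aliquot_volume = aliquot_volume,
                              tip_volume = tip_volume, capacity = capacity)
      ord <- part_order(sc, order_mode, seed = derive_seed(s, 1L))
      plan <- optimize_scenario(sc, ord)
      savings_report(plan)$percent_saved
    }, numeric(1))
    tibble(
      n_constructs = as.integer(n),
      reps = as.integer(reps),
      mean_percent_saved = mean(saved),
      sd_percent_saved = if (reps > 1) sd(saved) else 0,
      order_mode = order_mode,
      capacity = {
        k <- capacity %||% floor(tip_volume / aliquot_volume)
        if (is.infinite(k)) NA_real_ else as.numeric(k)
      }
    )
  })
  structure(rows, class = c("savings_table", class(tibble())))
}

#' Plot a savings sweep
#'
#' Mean percentage of tips saved against the number of constructs assembled
#' in parallel, with a plus/minus one standard deviation ribbon.
#'
#' @param object A `savings_table` from [benchmark_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot savings_table
#' @export
autoplot.savings_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n_constructs, y = .data$mean_percent_saved,
    colour = .data$order_mode, fill = .data$order_mode
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_percent_saved - .data$sd_percent_saved,
      ymax = .data$mean_percent_saved + .data$sd_percent_saved
    ), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "constructs assembled in parallel",
      y = "tips saved vs fresh tip per addition (%)",
      colour = "part order", fill = "part order"
    ) +
    ggplot2::theme_minimal()
}
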