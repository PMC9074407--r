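#' Build an assembly scenario
#'
#' A scenario is the full problem instance for tip-efficient DNA part
#' distribution: which parts go into which destination wells (the construct
#' recipes), where each part solution is sourced, and how many dispenses a
#' single tip can perform (its capacity).
#'
#' The per-tip capacity counts dispenses from a single aspiration: a tip
#' never returns to the source well after its first dispense, because
#' re-aspiration would contaminate the source. The effective capacity is
#' `capacity` when given, otherwise `floor(tip_volume / aliquot_volume)`,
#' otherwise unbounded (`Inf`).
#'
#' @param constructs A data frame with columns `well` (destination well
#'   label), optionally `slot` (labware slot, default `"2"`), and `recipe`
#'   (a list column of character vectors naming the DNA parts of each
#'   construct, in recipe order).
#' @param sources A data frame with columns `part`, `well` and optionally
#'   `slot` (default `"1"`) giving the source well of each part solution.
#' @param aliquot_volume Volume in microlitres dispensed per part addition
#'   (optional).
#' @param tip_volume Working volume of one tip in microlitres (optional).
#' @param capacity Direct per-tip dispense capacity; overrides the volume
#'   ratio. Use `Inf` for an explicitly unbounded tip.
#'
#' @return A `tip_scenario` object: a list with tibbles `constructs` and
#'   `sources`, the volume settings and the derived `capacity`.
#' @examples
#' sc <- scenario(
#'   constructs = tibble::tibble(
#'     well = c("A1", "B1"),
#'     recipe = list(c("GFP", "DVK"), c("YFP", "DVK"))
#'   ),
#'   sources = tibble::tibble(
#'     part = c("GFP", "YFP", "DVK"),
#'     well = c("A1", "B1", "C1")
#'   ),
#'   tip_volume = 10, aliquot_volume = 1.5
#' )
#' effective_capacity(sc) # floor(10 / 1.5) = 6
#' @export
scenario <- function(constructs, sources, aliquot_volume = NULL,
                     tip_volume = NULL, capacity = NULL) {
  constructs <- as_tibble(constructs)
  sources <- as_tibble(sources)
  if (!"slot" %in% names(constructs)) constructs$slot <- "2"
  if (!"slot" %in% names(sources)) sources$slot <- "1"
  constructs$well <- canonical_well(constructs$well)
  sources$well <- canonical_well(sources$well)
  constructs <- constructs[, c("slot", "well", "recipe")]
  sources <- sources[, c("part", "slot", "well")]

  sc <- structure(
    list(
      constructs = constructs,
      sources = sources,
      aliquot_volume = aliquot_volume,
      tip_volume = tip_volume,
      capacity_override = capacity
    ),
    class = "tip_scenario"
  )
  sc$capacity <- compute_capacity(sc)
  validate_scenario(sc)
}

compute_capacity <- function(sc) {
  if (!is.null(sc$capacity_override)) {
    k <- sc$capacity_override
    if (!is.infinite(k)) k <- as.integer(k)
    return(k)
  }
  if (!is.null(sc$tip_volume) && !is.null(sc$aliquot_volume)) {
    return(as.integer(floor(sc$tip_volume / sc$aliquot_volume)))
  }
  Inf
}

validate_scenario <- function(sc) {
  cs <- sc$constructs
  if (nrow(cs) == 0) abort("empty scenario", class = "tipsaver_error")
  if (!is.list(cs$recipe)) abort("`recipe` must be a list column of character vectors")
  for (i in seq_len(nrow(cs))) {
    r <- cs$recipe[[i]]
    if (length(r) == 0 || any(!nzchar(r))) {
      abort(sprintf("construct %s has an empty recipe", cs$well[i]))
    }
    if (anyDuplicated(r)) {
      abort(sprintf("duplicate part in construct %s", cs$well[i]),
            class = "tipsaver_error")
    }
  }
  dest_key <- paste(cs$slot, cs$well)
  if (anyDuplicated(dest_key)) abort("duplicate destination well")
  src <- sc$sources
  if (anyDuplicated(src$part)) abort("duplicate source entry for a part")
  catalogue <- unique(unlist(cs$recipe))
  missing <- setdiff(catalogue, src$part)
  if (length(missing) > 0) {
    abort(paste0("unresolved part source: ", paste(missing, collapse = ", ")),
          class = "tipsaver_error")
  }
  if (!is.infinite(sc$capacity) && sc$capacity < 1) {
    abort("tip cannot hold one aliquot", class = "tipsaver_error")
  }
  sc
}

#' @export
print.tip_scenario <- function(x, ...) {
  cat(sprintf(
    "<tip_scenario> %d constructs, %d catalogue parts, %d additions, capacity %s\n",
    nrow(x$constructs), length(part_catalogue(x)), total_additions(x),
    if (is.infinite(x$capacity)) "unbounded" else x$capacity
  ))
  invisible(x)
}

#' Effective per-tip dispense capacity of a scenario
#'
#' @param scenario A `tip_scenario`.
#' @return An integer, or `Inf` for an unbounded tip.
#' @export
effective_capacity <- function(scenario) {
  stopifnot(inherits(scenario, "tip_scenario"))
  scenario$capacity
}

#' All parts appearing in any recipe, in as-read order
#' @noRd
part_catalogue <- function(scenario) {
  unique(unlist(scenario$constructs$recipe))
}

total_additions <- function(scenario) {
  sum(lengths(scenario$constructs$recipe))
}

# Canonicalize well labels: upper-case row letters, no leading zeros ("a01" -> "A1").
canonical_well <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^[A-Za-z]+[0-9]+$", x)
  if (any(!ok)) abort(paste0("malformed well label: ", paste(x[!ok], collapse = ", ")))
  row <- toupper(sub("[0-9]+$", "", x))
  col <- as.integer(sub("^[A-Za-z]+", "", x))
  if (any(col < 1)) abort("well column index must be >= 1")
  paste0(row, col)
}

#' Read a scenario from delimited tables
#'
#' Two construct-table dialects are accepted. The wide dialect mirrors the
#' construct CSVs used by assembly-automation pipelines such as DNA-BOT: a
#' header row, a `well` column and then one column per recipe slot, blank
#' cells meaning the slot is unused. The long dialect has exactly two
#' columns, `well` and `part`, one row per addition, recipe order given by
#' file position. The sources table has columns `part,slot,well` (`slot`
#' optional).
#'
#' @param constructs_path Path to the constructs CSV.
#' @param sources_path Path to the sources CSV.
#' @param config Optional path to a YAML/JSON config file, or a named list,
#'   with any of the keys `aliquot_volume_ul`, `tip_volume_ul`, `capacity`,
#'   `part_order` (`"as_read"` or `"random"`), `seed`.
#' @return A validated [scenario()] object. The config's `part_order` and
#'   `seed` are attached as attributes `order_mode` and `order_seed`.
#' @export
read_scenario <- function(constructs_path, sources_path, config = NULL) {
  cfg <- read_config(config)
  ctab <- read.csv(constructs_path, check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (nrow(ctab) == 0) abort("empty scenario", class = "tipsaver_error")
  nm <- tolower(names(ctab))
  well_col <- which(nm == "well")[1]
  if (is.na(well_col)) abort("constructs table needs a `well` column")

  if (ncol(ctab) == 2 && "part" %in% nm) {
    # long dialect: one row per addition, file order is recipe order
    part_col <- which(nm == "part")[1]
    wells <- canonical_well(ctab[[well_col]])
    parts <- ctab[[part_col]]
    uw <- unique(wells)
    recipes <- lapply(uw, function(w) parts[wells == w])
    constructs <- tibble(well = uw, recipe = recipes)
  } else {
    slot_cols <- setdiff(seq_along(ctab), well_col)
    recipes <- lapply(seq_len(nrow(ctab)), function(i) {
      r <- as.character(ctab[i, slot_cols])
      r[!is.na(r) & nzchar(r)]
    })
    constructs <- tibble(well = canonical_well(ctab[[well_col]]), recipe = recipes)
  }

  stab <- read.csv(sources_path, check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  names(stab) <- tolower(names(stab))
  if (!all(c("part", "well") %in% names(stab))) {
    abort("sources table needs `part` and `well` columns")
  }
  sources <- tibble(
    part = stab$part,
    slot = if ("slot" %in% names(stab)) stab$slot else "1",
    well = canonical_well(stab$well)
  )

  sc <- scenario(
    constructs, sources,
    aliquot_volume = cfg$aliquot_volume_ul,
    tip_volume = cfg$tip_volume_ul,
    capacity = cfg$capacity
  )
  attr(sc, "order_mode") <- cfg$part_order %||% "as_read"
  attr(sc, "order_seed") <- cfg$seed
  sc
}

read_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.list(config)) return(config)
  if (grepl("\\.json$", config, ignore.case = TRUE)) {
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  yaml::read_yaml(config)
}

#' Write a scenario back to constructs/sources CSV files
#'
#' Uses the wide construct dialect, so `read_scenario()` on the written
#' files round-trips to an equal scenario.
#'
#' @param scenario A `tip_scenario`.
#' @param constructs_path,sources_path Output CSV paths.
#' @return The scenario, invisibly.
#' @export
write_scenario <- function(scenario, constructs_path, sources_path) {
  stopifnot(inherits(scenario, "tip_scenario"))
  cs <- scenario$constructs
  k <- max(lengths(cs$recipe))
  wide <- t(vapply(cs$recipe, function(r) c(r, rep("", k - length(r))),
                   character(k)))
  out <- data.frame(well = cs$well, wide, check.names = FALSE)
  names(out) <- c("well", paste0("part", seq_len(k)))
  write.csv(out, constructs_path, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(scenario$sources), sources_path,
            row.names = FALSE, quote = FALSE)
  invisible(scenario)
}

#' Global part-distribution order
#'
#' Every part in the catalogue is distributed to all wells requiring it
#' before the next part is touched, so the global sequence of parts must be
#' fixed up front. `"as_read"` scans the construct list in input order, each
#' recipe left to right, appending each part the first time it is seen.
#' `"random"` draws a uniformly random permutation of the catalogue,
#' reproducible for a fixed `seed`.
#'
#' @param scenario A `tip_scenario`.
#' @param mode `"as_read"` or `"random"`.
#' @param seed Integer seed, required for `mode = "random"`.
#' @return A character vector of part names (class `part_order`), a
#'   permutation of the catalogue.
#' @export
part_order <- function(scenario, mode = c("as_read", "random"), seed = NULL) {
  stopifnot(inherits(scenario, "tip_scenario"))
  mode <- match.arg(mode)
  catalogue <- part_catalogue(scenario)
  ord <- if (mode == "as_read") {
    catalogue
  } else {
    if (is.null(seed)) abort("`seed` is required for a random part order")
    with_local_seed(as.integer(seed), sample(catalogue))
  }
  structure(ord, class = "part_order", mode = mode)
}

# Run `expr` under a temporary RNG state so callers' RNG is untouched.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation (Lehmer-style mixing below 2^31).
derive_seed <- function(seed, ...) {
  m <- 2147483647
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271) %% m
    x <- (x + as.numeric(k) * 100003 + 1) %% m
  }
  as.integer((x * 48271) %% m)
}
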