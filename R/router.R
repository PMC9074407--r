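#' Minimum number of capacitated tip routes on a contamination graph
#'
#' Solves the routing problem that decides how many pipette tips are needed
#' to distribute one DNA part: every customer well must be visited exactly
#' once, a route may only use zero-cost (contamination-free) edges, no route
#' may serve more than `capacity` wells from one aspiration, and the number
#' of routes K is minimized. All routes implicitly start and end at the
#' depot (source well / waste), whose edges are free.
#'
#' Because the zero-cost relation between wells is a set-inclusion preorder
#' (transitive; wells with equal contents are mutually reachable), a
#' feasible route is exactly a chain of the preorder, and minimizing K is a
#' minimum chain cover with chain size bounded by the capacity. The solver
#' is exact: it computes a lower bound from a maximum bipartite matching on
#' the zero-cost arcs (the classical minimum-path-cover bound, valid here by
#' transitive closure) together with the pigeonhole bound `ceiling(n /
#' capacity)`, constructs upper-bound solutions by greedy first-fit and by
#' cutting an uncapacitated matching decomposition, and closes any remaining
#' gap with an exhaustive depth-first search over chain covers, so the
#' returned K is provably minimal. Ties between co-optimal route sets are
#' broken deterministically (routes are reported in ascending order of their
#' first customer).
#'
#' @param graph A `tip_graph` from [cost_graph()] or
#'   [cost_graph_from_contents()].
#' @param capacity Maximum wells served per tip; `Inf` for unbounded.
#' @return A `route_set`: list with `part`, `routes` (list of integer
#'   customer-index vectors in visit order), `K`, `n`, `capacity`.
#' @examples
#' g <- cost_graph_from_contents(list(c("GFP"), character(0)), part = "DVK")
#' min_tip_routes(g, capacity = 2)$K # 1: empty well first, then the GFP well
#' @export
min_tip_routes <- function(graph, capacity = Inf) {
  stopifnot(inherits(graph, "tip_graph"))
  n <- graph$n
  if (n < 1) abort("empty customer set", class = "tipsaver_error")
  if (capacity < 1) abort("tip cannot hold one aliquot", class = "tipsaver_error")
  kappa <- if (is.infinite(capacity)) n else as.integer(min(capacity, n))

  if (kappa == 1L) {
    return(new_route_set(graph, as.list(seq_len(n)), capacity))
  }

  Z <- graph$cost == 0L
  diag(Z) <- TRUE
  # the contamination rule is set inclusion, hence transitive; the solver
  # relies on it, so fail loudly on a malformed graph
  closure <- (Z %*% Z) > 0
  if (any(closure & !Z)) abort("zero-cost relation is not transitive")

  cls <- class_ids(Z)
  arc <- Z & !diag(TRUE, n)
  # linearize within equal-content classes to make the arc relation acyclic
  same <- outer(cls, cls, "==")
  arc[same & outer(seq_len(n), seq_len(n), ">=")] <- FALSE

  match_res <- matching_links(arc, n)
  K_inf <- n - match_res$size
  lb <- max(ceiling(n / kappa), K_inf)

  cand <- list(
    cut_chains(matching_chain_decomposition(match_res$succ, n), kappa),
    greedy_chains(Z, arc, kappa, n)
  )
  best <- cand[[which.min(vapply(cand, length, integer(1)))]]

  if (length(best) > lb) {
    exact <- exact_chain_cover(Z, cls, kappa, lb, length(best) - 1L, n)
    if (!is.null(exact)) best <- exact
  }
  new_route_set(graph, best, capacity)
}

# Equivalence classes of the mutual zero-cost relation (equal content sets).
class_ids <- function(Z) {
  mutual <- Z & t(Z)
  keys <- apply(mutual, 1, function(r) paste(which(r), collapse = ","))
  match(keys, unique(keys))
}

# Maximum matching on the acyclic zero-cost arcs; each matched pair is one
# tip transition saved. Returns the successor map.
matching_links <- function(arc, n) {
  idx <- which(arc, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(size = 0L, succ = rep(NA_integer_, n)))
  }
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), each = n),
    edges = as.vector(t(cbind(idx[, 1], idx[, 2] + n)))
  )
  m <- igraph::max_bipartite_match(g)
  succ <- m$matching[seq_len(n)]
  succ <- ifelse(is.na(succ), NA_integer_, as.integer(succ) - n)
  list(size = as.integer(m$matching_size), succ = succ)
}

# Follow successor links from the roots to get an uncapacitated chain cover.
matching_chain_decomposition <- function(succ, n) {
  haspred <- rep(FALSE, n)
  haspred[succ[!is.na(succ)]] <- TRUE
  lapply(which(!haspred), function(r) {
    chain <- r
    while (!is.na(succ[chain[length(chain)]])) {
      chain <- c(chain, succ[chain[length(chain)]])
    }
    chain
  })
}

# Split chains into consecutive runs of at most kappa wells. Consecutive
# pairs inside a run were consecutive before, so they remain zero-cost.
cut_chains <- function(chains, kappa) {
  unlist(lapply(chains, function(ch) {
    split(ch, ceiling(seq_along(ch) / kappa))
  }), recursive = FALSE, use.names = FALSE)
}

# First-fit greedy over a linear extension, preferring the chain whose top
# is deepest in the preorder (most constrained, so least future-flexible).
greedy_chains <- function(Z, arc, kappa, n) {
  depth <- colSums(Z)
  ord <- order(depth, seq_len(n))
  tops <- integer(0)
  counts <- integer(0)
  chains <- list()
  for (e in ord) {
    ok <- which(counts < kappa & arc[tops, e])
    if (length(ok) == 0) {
      chains[[length(chains) + 1L]] <- e
      tops <- c(tops, e)
      counts <- c(counts, 1L)
    } else {
      pick <- ok[order(-depth[tops[ok]], -counts[ok])][1]
      chains[[pick]] <- c(chains[[pick]], e)
      tops[pick] <- e
      counts[pick] <- counts[pick] + 1L
    }
  }
  chains
}

new_route_set <- function(graph, chains, capacity) {
  chains <- unname(chains[order(vapply(chains, function(r) r[1], numeric(1)))])
  chains <- lapply(chains, function(r) unname(as.integer(r)))
  kappa <- capacity
  for (r in chains) {
    if (length(r) > kappa) abort("internal error: route exceeds capacity")
    if (length(r) > 1) {
      steps <- cbind(r[-length(r)], r[-1])
      if (any(graph$cost[steps] != 0L)) {
        abort("internal error: contaminated route emitted")
      }
    }
  }
  if (!identical(sort(unlist(chains)), seq_len(graph$n))) {
    abort("internal error: routes do not partition the customer set")
  }
  structure(
    list(part = graph$part, routes = chains, K = length(chains),
         n = graph$n, capacity = capacity),
    class = "route_set"
  )
}

#' @export
print.route_set <- function(x, ...) {
  cat(sprintf("<route_set> part %s: %d wells served by %d tip(s) (capacity %s)\n",
              x$part, x$n, x$K,
              if (is.infinite(x$capacity)) "unbounded" else x$capacity))
  invisible(x)
}

#' Edges traveled by a route set
#'
#' Recovers the routing decision variables: one row per traveled edge,
#' including the depot (node 0) departures and returns, so the number of
#' rows with `from == 0` equals K.
#'
#' @param route_set A `route_set`.
#' @return A tibble with columns `from`, `to` (customer indices, 0 = depot).
#' @export
route_edges <- function(route_set) {
  purrr::map_dfr(route_set$routes, function(r) {
    tibble(from = c(0L, r), to = c(r, 0L))
  })
}

# ---- exact search ----------------------------------------------------------
# Minimum chain cover with bounded chain size, searched at the level of
# equal-content classes. Chains only ever move to strictly larger content
# sets between classes, so classes are processed along a linear extension
# and a chain is summarized by (top class, wells used). Feasibility for a
# given budget K is decided by exhaustive allocation of each class's wells
# to compatible open chains, with memoization on canonical (top, count)
# multisets. Persistent chain ids are threaded through the search (but kept
# out of the memo key) so a successful search directly yields the witness
# chain compositions.
exact_chain_cover <- function(Z, cls, kappa, lb, ub, n) {
  C <- max(cls)
  m <- tabulate(cls, C)
  reps <- match(seq_len(C), cls)
  rel <- Z[reps, reps, drop = FALSE] & !diag(TRUE, C) # strict class arcs
  depth <- colSums(Z)[reps]
  topo <- order(depth, reps)
  m <- m[topo]
  rel <- rel[topo, topo, drop = FALSE]

  # can a chain topped by class t still be extended at or after position p?
  can_extend <- matrix(FALSE, C, C + 1L)
  for (t in seq_len(C)) {
    for (p in C:1) {
      can_extend[t, p] <- rel[t, p] || can_extend[t, p + 1L]
    }
  }

  for (K in lb:ub) {
    witness <- feasible_cover(K, kappa, m, rel, can_extend, C)
    if (!is.null(witness)) {
      return(witness_to_routes(witness, cls, topo, C, n))
    }
  }
  NULL # the incoming upper-bound solution was already optimal
}

feasible_cover <- function(K, kappa, m, rel, can_extend, C) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  total <- sum(m)

  # state: live open chains (tops/cnts/ids), chains started, position.
  # On success returns the list of (id, class, take) allocation records.
  recurse <- function(pos, tops, cnts, ids, used, remaining) {
    if (pos > C) return(list())
    o <- order(tops, cnts)
    tops <- tops[o]; cnts <- cnts[o]; ids <- ids[o]
    key <- paste(pos, used, paste(tops, cnts, sep = ".", collapse = " "))
    if (!is.null(memo[[key]])) return(NULL)

    if (sum(kappa - cnts) + (K - used) * kappa < remaining) {
      memo[[key]] <- TRUE
      return(NULL)
    }

    need <- m[pos]
    compat <- which(rel[tops, pos] & cnts < kappa)
    types <- split(compat, paste(tops[compat], cnts[compat]))

    res <- allocate(types, 1L, need, pos, tops, cnts, ids, used,
                    remaining, list())
    if (is.null(res)) memo[[key]] <- TRUE
    res
  }

  finish_class <- function(pos, tops, cnts, ids, used, remaining, acc) {
    live <- cnts < kappa & can_extend[tops, pos + 1L]
    sub <- recurse(pos + 1L, tops[live], cnts[live], ids[live], used,
                   remaining - m[pos])
    if (is.null(sub)) return(NULL)
    c(acc, sub)
  }

  # distribute `need` wells of class `pos` over slot types in canonical
  # order (non-increasing takes within a type), then over new chains
  allocate <- function(types, tix, need, pos, tops, cnts, ids, used,
                       remaining, acc) {
    if (need == 0) {
      return(finish_class(pos, tops, cnts, ids, used, remaining, acc))
    }
    if (tix > length(types)) {
      return(alloc_new(need, pos, tops, cnts, ids, used, remaining, acc))
    }
    slots <- types[[tix]]
    k0 <- cnts[slots[1]]
    max_take <- kappa - k0
    choose_takes <- function(si, prev_take, need_left, tops, cnts, acc) {
      res <- allocate(types, tix + 1L, need_left, pos, tops, cnts, ids,
                      used, remaining, acc)
      if (!is.null(res)) return(res)
      if (si > length(slots) || need_left == 0) return(NULL)
      for (p in min(prev_take, max_take, need_left):1) {
        sl <- slots[si]
        tops2 <- tops; cnts2 <- cnts
        tops2[sl] <- pos; cnts2[sl] <- k0 + p
        res <- choose_takes(si + 1L, p, need_left - p, tops2, cnts2,
                            c(acc, list(c(ids[sl], pos, p))))
        if (!is.null(res)) return(res)
      }
      NULL
    }
    choose_takes(1L, kappa, need, tops, cnts, acc)
  }

  alloc_new <- function(need, pos, tops, cnts, ids, used, remaining, acc) {
    gen <- function(need_left, max_p, tops, cnts, ids, used, acc) {
      if (need_left == 0) {
        return(finish_class(pos, tops, cnts, ids, used, remaining, acc))
      }
      if (used >= K) return(NULL)
      for (p in min(max_p, need_left):1) {
        res <- gen(need_left - p, p,
                   c(tops, pos), c(cnts, p), c(ids, used + 1L), used + 1L,
                   c(acc, list(c(used + 1L, pos, p))))
        if (!is.null(res)) return(res)
      }
      NULL
    }
    gen(need, kappa, tops, cnts, ids, used, acc)
  }

  records <- recurse(1L, integer(0), integer(0), integer(0), 0L, total)
  if (is.null(records)) return(NULL)
  # group allocation records by chain id, preserving class order
  recs <- do.call(rbind, records)
  lapply(split(seq_len(nrow(recs)), recs[, 1]), function(rows) {
    recs[rows, 2:3, drop = FALSE]
  })
}

# Convert class-level chain segments back to concrete well indices, handing
# out each class's wells in ascending index order.
witness_to_routes <- function(seg_chains, cls, topo, C, n) {
  pools <- lapply(seq_len(C), function(t) which(cls == topo[t]))
  next_at <- rep(1L, C)
  lapply(seg_chains, function(segs) {
    out <- integer(0)
    for (r in seq_len(nrow(segs))) {
      t <- segs[r, 1]; take <- segs[r, 2]
      pick <- pools[[t]][next_at[t]:(next_at[t] + take - 1L)]
      next_at[t] <<- next_at[t] + take
      out <- c(out, pick)
    }
    out
  })
}

# ---- independent oracles ---------------------------------------------------

#' Brute-force minimum tip routing (test oracle)
#'
#' Exhaustively searches ordered set partitions of the customers into
#' routes that respect zero-cost adjacency and the capacity, by dynamic
#' programming over customer subsets. Independent of the main solver: it
#' uses only the raw cost matrix, never the preorder structure.
#'
#' @param graph A `tip_graph` with at most 8 customers.
#' @param capacity Maximum wells served per tip; `Inf` for unbounded.
#' @return A `route_set` with provably minimum K.
#' @export
brute_force_min_routes <- function(graph, capacity = Inf) {
  n <- graph$n
  if (n > 8) abort("oracle size exceeded", class = "tipsaver_error")
  if (capacity < 1) abort("tip cannot hold one aliquot", class = "tipsaver_error")
  kappa <- min(capacity, n)
  cost <- graph$cost

  # one feasible visit order of the element set, or NULL
  order_of <- function(els) {
    if (length(els) == 1) return(els)
    dfs <- function(seq, rest) {
      if (length(rest) == 0) return(seq)
      for (e in rest) {
        if (cost[seq[length(seq)], e] == 0L) {
          res <- dfs(c(seq, e), setdiff(rest, e))
          if (!is.null(res)) return(res)
        }
      }
      NULL
    }
    for (s in els) {
      res <- dfs(s, setdiff(els, s))
      if (!is.null(res)) return(res)
    }
    NULL
  }

  full <- bitwShiftL(1L, n) - 1L
  best <- rep(NA_integer_, full + 1L)
  choice <- vector("list", full + 1L)
  best[1] <- 0L
  for (mask in 1:full) {
    low <- bitwAnd(mask, -mask)
    sub <- mask
    while (sub > 0) {
      if (bitwAnd(sub, low) == low) {
        els <- which(bitwAnd(sub, bitwShiftL(1L, seq_len(n) - 1L)) > 0)
        if (length(els) <= kappa) {
          ord <- order_of(els)
          if (!is.null(ord)) {
            rest <- bitwAnd(mask, bitwNot(sub))
            cand <- best[rest + 1L] + 1L
            if (is.na(best[mask + 1L]) || cand < best[mask + 1L]) {
              best[mask + 1L] <- cand
              choice[[mask + 1L]] <- list(route = ord, rest = rest)
            }
          }
        }
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
  }
  routes <- list()
  mask <- full
  while (mask > 0) {
    ch <- choice[[mask + 1L]]
    routes[[length(routes) + 1L]] <- ch$route
    mask <- ch$rest
  }
  new_route_set(graph, routes, capacity)
}

#' Uncapacitated minimum tip count via bipartite matching (cross-check)
#'
#' With unbounded capacity, the minimum number of tips equals `n` minus the
#' size of a maximum bipartite matching on the zero-cost customer arcs: each
#' matched arc merges two routes into one. The matching bound is exact here
#' because the zero-cost relation is transitively closed (it is a set
#' inclusion preorder), so matched arcs always stitch into genuine routes.
#' Arcs inside an equal-content class are restricted to ascending index to
#' keep the relation acyclic.
#'
#' @param graph A `tip_graph`.
#' @return The minimum number of tips (integer) for unbounded capacity.
#' @export
matching_min_routes <- function(graph) {
  n <- graph$n
  Z <- graph$cost == 0L
  diag(Z) <- TRUE
  cls <- class_ids(Z)
  arc <- Z & !diag(TRUE, n)
  same <- outer(cls, cls, "==")
  arc[same & outer(seq_len(n), seq_len(n), ">=")] <- FALSE
  n - matching_links(arc, n)$size
}
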