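# Two-construct GFP/YFP-on-shared-backbone example used throughout:
# A1 receives GFP + DVK, B1 receives YFP + DVK.
fig_scenario <- function(capacity = 2) {
  scenario(
    constructs = tibble::tibble(
      well = c("A1", "B1"),
      recipe = list(c("GFP", "DVK"), c("YFP", "DVK"))
    ),
    sources = tibble::tibble(
      part = c("GFP", "YFP", "DVK"),
      well = c("A1", "B1", "C1")
    ),
    capacity = capacity
  )
}

# Random content-set instance for the routing solvers: n customers, each
# holding a random subset of at most `n_symbols` symbols.
random_contents <- function(n, n_symbols = 4) {
  lapply(seq_len(n), function(i) {
    sample(letters[seq_len(n_symbols)], sample(0:n_symbols, 1))
  })
}

# Random small scenario over a random library, for round-trip properties.
random_scenario <- function(seed, max_constructs = 12, capacity = NULL) {
  withr::with_seed(seed, {
    lib <- part_library(c(promoter = sample(2:4, 1), RBS = sample(2:3, 1),
                          CDS = sample(2:3, 1), terminator = sample(2:3, 1)))
    n <- sample(2:max_constructs, 1)
    kap <- capacity %||% sample(c(1, 2, 3, 6, Inf), 1)
    generate_scenario(lib, n, seed = sample.int(1e6, 1), distinct = FALSE,
                      capacity = kap)
  })
}

# Independent stepwise oracle for pre-step well contents: replay additions
# part by part instead of using the closed form.
simulate_contents_before <- function(scenario, order, step) {
  state <- lapply(scenario$constructs$recipe, function(r) character(0))
  for (h in seq_len(step - 1)) {
    for (i in seq_along(state)) {
      if (order[[h]] %in% scenario$constructs$recipe[[i]]) {
        state[[i]] <- c(state[[i]], order[[h]])
      }
    }
  }
  state
}

`%||%` <- rlang::`%||%`
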