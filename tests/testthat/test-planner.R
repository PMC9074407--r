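test_that("two-construct worked example needs three tips for four additions", {
  sc <- fig_scenario(capacity = 2)
  plan <- optimize_scenario(sc)
  expect_equal(plan$A, 4L)
  expect_equal(plan$T, 3L)
  expect_equal(savings_report(plan)$percent_saved, 25.0)
  expect_true(validate_plan(sc, plan)$valid)
  expect_equal(tidy(plan)$tips, c(1L, 1L, 1L))
})

test_that("degenerate plans hit the fresh-tip baseline", {
  # single construct: every part serves one well, so T = A
  sc <- scenario(tibble::tibble(well = "A1", recipe = list(c("P", "R", "C"))),
                 tibble::tibble(part = c("P", "R", "C"),
                                well = c("A1", "A2", "A3")))
  plan <- optimize_scenario(sc)
  expect_equal(plan$T, plan$A)
  expect_equal(savings_report(plan)$percent_saved, 0)

  # two identical constructs: equal contents at every step, one tip per part
  sc2 <- scenario(tibble::tibble(well = c("A1", "B1"),
                                 recipe = list(c("P", "R"), c("P", "R"))),
                  tibble::tibble(part = c("P", "R"), well = c("A1", "A2")),
                  capacity = 2)
  plan2 <- optimize_scenario(sc2)
  expect_equal(plan2$T, 2L)
  expect_equal(plan2$A, 4L)
})

test_that("per-tip commands follow pick/aspirate/dispense/drop with conserved volume", {
  sc <- scenario(
    tibble::tibble(well = c("A1", "B1", "C1"),
                   recipe = list(c("V", "X"), c("V", "Y"), c("V", "Z"))),
    tibble::tibble(part = c("V", "X", "Y", "Z"),
                   well = c("A1", "A2", "A3", "A4")),
    aliquot_volume = 1.5, tip_volume = 10
  )
  plan <- optimize_scenario(sc)
  cmds <- plan$commands
  expect_equal(sum(cmds$verb == "pick_tip"), plan$T)
  expect_equal(sum(cmds$verb == "drop_tip"), plan$T)
  expect_equal(sum(cmds$verb == "dispense"), plan$A)
  # aspirated volume equals the dispenses that follow until the drop
  blocks <- split(cmds, cumsum(cmds$verb == "pick_tip"))
  for (b in blocks) {
    expect_equal(b$verb[1:2], c("pick_tip", "aspirate"))
    expect_equal(b$verb[nrow(b)], "drop_tip")
    expect_equal(b$volume_ul[2], sum(b$volume_ul[b$verb == "dispense"]))
  }
  expect_true(validate_plan(sc, plan)$valid)
})

test_that("optimized plans validate for random scenarios at any capacity", {
  for (seed in 1:8) {
    sc <- random_scenario(seed)
    mode <- if (seed %% 2 == 0) "as_read" else "random"
    ord <- part_order(sc, mode, seed = seed)
    plan <- optimize_scenario(sc, ord)
    v <- validate_plan(sc, plan)
    expect_true(v$valid, info = paste("seed", seed))
  }
})

test_that("tips never increase with capacity; capacity 1 saves nothing", {
  sc <- generate_scenario(n_constructs = 10, seed = 21)
  tips <- vapply(c(1, 2, 4, 8, Inf), function(kap) {
    optimize_scenario(sc, capacity = kap)$T
  }, integer(1))
  expect_true(all(diff(tips) <= 0))
  plan1 <- optimize_scenario(sc, capacity = 1)
  expect_equal(savings_report(plan1)$percent_saved, 0)
  expect_equal(plan1$T, plan1$A)
})

test_that("validator catches hand-built contamination and bookkeeping faults", {
  sc <- fig_scenario(capacity = 2)
  # DVK tip visits the GFP-containing well first, then the well without GFP
  bad <- tibble::tibble(
    verb = c("pick_tip", "aspirate", "dispense", "drop_tip",
             "pick_tip", "aspirate", "dispense", "dispense", "drop_tip",
             "pick_tip", "aspirate", "dispense", "drop_tip"),
    part = c(rep("GFP", 4), rep("DVK", 5), rep("YFP", 4)),
    slot = c(NA, "1", "2", NA, NA, "1", "2", "2", NA, NA, "1", "2", NA),
    well = c(NA, "A1", "A1", NA, NA, "C1", "A1", "B1", NA, NA, "B1", "B1", NA),
    volume_ul = NA_real_
  )
  v <- validate_plan(sc, bad)
  expect_false(v$valid)
  expect_true("contamination" %in% v$violations$type)

  # fresh tip per addition is wasteful but valid
  fresh <- optimize_scenario(sc, capacity = 1)
  expect_equal(fresh$T, 4L)
  expect_true(validate_plan(sc, fresh)$valid)

  # dropping an addition must be reported
  miss <- fresh$commands[fresh$commands$part != "YFP", ]
  vm <- validate_plan(sc, miss[, c("verb", "part", "slot", "well", "volume_ul")])
  expect_true("missing_addition" %in% vm$violations$type)

  # repeating a tip block duplicates additions
  dup <- dplyr::bind_rows(fresh$commands, fresh$commands[1:4, ])
  vd <- validate_plan(sc, dup[, c("verb", "part", "slot", "well", "volume_ul")])
  expect_true("duplicate_addition" %in% vd$violations$type)

  # serving three wells on a capacity-2 tip
  sc3 <- scenario(tibble::tibble(well = c("A1", "B1", "C1"),
                                 recipe = list("V", "V", "V")),
                  tibble::tibble(part = "V", well = "A1"), capacity = 2)
  over <- optimize_scenario(sc3, capacity = 3)
  vo <- validate_plan(sc3, over$commands[, -1], capacity = 2)
  expect_true("capacity_exceeded" %in% vo$violations$type)

  expect_error(validate_plan(random_scenario(99),
                             optimize_scenario(fig_scenario())),
               "foreign plan")
})

test_that("plan summaries and files expose additions, tips and savings", {
  sc <- fig_scenario()
  plan <- optimize_scenario(sc)
  g <- glance(plan)
  expect_equal(g$additions, 4L)
  expect_equal(g$tips, 3L)
  expect_equal(g$percent_saved, 25)
  expect_equal(g$n_constructs, 2L)

  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(plan$commands))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$savings$percent_saved, 25)
})
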