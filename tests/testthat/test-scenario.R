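test_that("scenario construction validates its invariants", {
  sc <- fig_scenario()
  expect_s3_class(sc, "tip_scenario")
  expect_equal(nrow(sc$constructs), 2)
  expect_setequal(tipsaver:::part_catalogue(sc), c("GFP", "YFP", "DVK"))

  expect_error(
    scenario(tibble::tibble(well = character(0), recipe = list()),
             tibble::tibble(part = character(0), well = character(0))),
    "empty scenario"
  )
  expect_error(
    scenario(tibble::tibble(well = "A1", recipe = list(c("X", "X"))),
             tibble::tibble(part = "X", well = "A1")),
    "duplicate part in construct"
  )
  expect_error(
    scenario(tibble::tibble(well = "A1", recipe = list(c("X", "Y"))),
             tibble::tibble(part = "X", well = "A1")),
    "unresolved part source"
  )
  expect_error(
    scenario(tibble::tibble(well = "A1", recipe = list("X")),
             tibble::tibble(part = "X", well = "A1"),
             tip_volume = 1, aliquot_volume = 1.5),
    "tip cannot hold one aliquot"
  )
})

test_that("effective capacity follows override, volume ratio, then unbounded", {
  base_c <- tibble::tibble(well = "A1", recipe = list("X"))
  base_s <- tibble::tibble(part = "X", well = "A1")
  expect_equal(effective_capacity(
    scenario(base_c, base_s, tip_volume = 10, aliquot_volume = 1.5)), 6)
  expect_equal(effective_capacity(
    scenario(base_c, base_s, tip_volume = 10, aliquot_volume = 1.5,
             capacity = 3)), 3)
  expect_true(is.infinite(effective_capacity(scenario(base_c, base_s))))
})

test_that("well labels are canonicalized case-insensitively", {
  sc <- scenario(tibble::tibble(well = c("a1", "B01"),
                                recipe = list("X", "X")),
                 tibble::tibble(part = "X", well = "h12"))
  expect_equal(sc$constructs$well, c("A1", "B1"))
  expect_equal(sc$sources$well, "H12")
  expect_error(canonical_well <- tipsaver:::canonical_well("1A"),
               "malformed well label")
})

test_that("as-read part order appends parts at first encounter", {
  sc <- scenario(
    tibble::tibble(well = c("A1", "B1"),
                   recipe = list(c("GFP", "DVK"), c("YFP", "DVK"))),
    tibble::tibble(part = c("GFP", "YFP", "DVK"), well = c("A1", "B1", "C1"))
  )
  expect_equal(as.character(part_order(sc)), c("GFP", "DVK", "YFP"))

  sc2 <- scenario(
    tibble::tibble(well = c("A1", "B1"), recipe = list(c("A", "B"), c("B", "A"))),
    tibble::tibble(part = c("A", "B"), well = c("A1", "B1"))
  )
  expect_equal(as.character(part_order(sc2)), c("A", "B"))

  sc3 <- scenario(tibble::tibble(well = "A1", recipe = list("X")),
                  tibble::tibble(part = "X", well = "A1"))
  expect_equal(as.character(part_order(sc3)), "X")
})

test_that("random part order is a seeded permutation of the catalogue", {
  sc <- generate_scenario(n_constructs = 20, seed = 11)
  o1 <- part_order(sc, "random", seed = 5)
  o2 <- part_order(sc, "random", seed = 5)
  o3 <- part_order(sc, "random", seed = 6)
  expect_identical(o1, o2)
  expect_false(identical(as.character(o1), as.character(o3)))
  expect_setequal(as.character(o1), as.character(part_order(sc, "as_read")))
  expect_equal(length(o1), length(unique(o1)))
  expect_error(part_order(sc, "random"), "seed")
})

test_that("scenario tables round-trip through CSV read/write", {
  sc <- generate_scenario(n_constructs = 8, seed = 3)
  cpath <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_scenario(sc, cpath, spath)
  sc2 <- read_scenario(cpath, spath,
                       config = list(aliquot_volume_ul = 1.5,
                                     tip_volume_ul = 10))
  expect_equal(sc2$constructs$recipe, sc$constructs$recipe)
  expect_equal(sc2$constructs$well, sc$constructs$well)
  expect_equal(sc2$sources, sc$sources)
  expect_equal(effective_capacity(sc2), effective_capacity(sc))
})

test_that("reader accepts wide and long construct dialects and configs", {
  ctab <- system.file("extdata", "constructs.csv", package = "tipsaver")
  stab <- system.file("extdata", "sources.csv", package = "tipsaver")
  cfg <- system.file("extdata", "config.yaml", package = "tipsaver")
  sc <- read_scenario(ctab, stab, config = cfg)
  expect_equal(nrow(sc$constructs), 2)
  expect_equal(length(tipsaver:::part_catalogue(sc)), 3)
  expect_equal(effective_capacity(sc), 6)
  expect_equal(attr(sc, "order_mode"), "as_read")

  long <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,part", "A1,GFP", "A1,DVK", "B1,YFP", "B1,DVK"), long)
  sc_long <- read_scenario(long, stab)
  expect_equal(sc_long$constructs$recipe, sc$constructs$recipe)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("well,part1", empty)
  expect_error(read_scenario(empty, stab), "empty scenario")
})
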