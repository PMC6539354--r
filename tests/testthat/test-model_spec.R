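test_that("two-stage preset derives the expected per-stage dimensions", {
  spec <- two_stage_spec()
  d <- spec$dims
  p <- d[d$division == "production", ]
  expect_equal(unlist(p[c("m", "r1", "r2", "linkin", "ngood")]),
               c(m = 2L, r1 = 1L, r2 = 0L, linkin = 0L, ngood = 1L))
  h <- d[d$division == "health_treatment", ]
  expect_equal(unlist(h[c("m", "r1", "r2", "linkin", "ngood")]),
               c(m = 2L, r1 = 1L, r2 = 2L, linkin = 2L, ngood = 0L))
})

test_that("a minimal one-division spec validates with trivial dimensions", {
  spec <- minimal_spec()
  expect_equal(spec$dims$m, 1L)
  expect_equal(spec$dims$r1, 1L)
  expect_equal(spec$dims$r2 + spec$dims$linkin + spec$dims$ngood, 0L)
})

test_that("degenerate topologies are rejected", {
  expect_error(
    dea_spec(list(a = list(inputs = "x", good_outputs = "y")),
             links = data.frame(source = "a", target = "a",
                                variable = "l")),
    "cannot connect a division to itself")
  expect_error(
    dea_spec(list(a = list(inputs = "x", good_outputs = "y")),
             links = data.frame(source = "a", target = "ghost",
                                variable = "l")),
    "undeclared division")
  expect_error(
    dea_spec(list(a = list(inputs = "x", good_outputs = "x"))),
    "more than one role")
  expect_error(
    dea_spec(list(a = list(inputs = "x", good_outputs = "y")),
             division_weights = 0),
    "strictly positive")
})

test_that("validation is idempotent and weights are normalized", {
  spec <- dea_spec(list(a = list(inputs = "x", good_outputs = "y"),
                        b = list(inputs = "w", good_outputs = "v")),
                   links = data.frame(source = "a", target = "b",
                                      variable = "l"),
                   division_weights = c(3, 1))
  expect_identical(validate_spec(spec), spec)
  expect_equal(sum(spec$division_weights), 1)
  expect_equal(unname(spec$division_weights), c(0.75, 0.25))
})

test_that("derived dimensions account for every link and carry-over", {
  spec <- dea_spec(
    list(a = list(inputs = "x1", good_outputs = "y1"),
         b = list(inputs = "x2", good_outputs = "y2"),
         c = list(inputs = "x3", good_outputs = "y3")),
    links = data.frame(source = c("a", "a", "b"),
                       target = c("b", "c", "c"),
                       variable = c("l1", "l2", "l3")),
    carryovers = data.frame(division = c("a", "c"),
                            variable = c("z1", "z2")))
  expect_equal(sum(spec$dims$linkin), 3L)
  expect_equal(sum(spec$dims$ngood), 2L)
})

test_that("panel validation enforces completeness and nonnegativity", {
  spec <- minimal_spec()
  df <- long_panel(list(A = list(x = 1, y = 1), B = list(x = 2, y = 1)))
  expect_s3_class(dea_panel(df, spec), "dndea_panel")
  expect_error(dea_panel(df[-1, ], spec), "missing value for \\(A, p1")
  dfn <- df; dfn$value[1] <- -1
  expect_error(dea_panel(dfn, spec), "negative")
  expect_error(dea_panel(rbind(df, df[1, ]), spec), "duplicated")
})

test_that("zero values are replaced by 1e-6 x the column minimum, with a warning", {
  spec <- minimal_spec()
  df <- long_panel(list(A = list(x = 0, y = 1), B = list(x = 2, y = 1)))
  expect_warning(pan <- dea_panel(df, spec), "zero value")
  expect_equal(pan$values$unit$x["A", "p1"], 1e-6 * 2)
})

test_that("panel role column must agree with the spec", {
  spec <- minimal_spec()
  df <- long_panel(list(A = list(x = 1, y = 1)))
  df$role <- c("good_output", "input")
  expect_error(dea_panel(df, spec), "disagrees with the spec")
})

test_that("specs round-trip through JSON", {
  spec <- two_stage_spec(period_weights = c(1, 2, 3, 4))
  path <- tempfile(fileext = ".json")
  write_spec_json(spec, path)
  spec2 <- read_spec_json(path)
  expect_equal(spec2$dims, spec$dims)
  expect_equal(spec2$links, spec$links)
  expect_equal(spec2$carryovers, spec$carryovers)
  expect_equal(spec2$period_weights, spec$period_weights)
})
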