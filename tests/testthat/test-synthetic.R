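test_that("planted frontier units score 1 and dominated units score below 1", {
  spec <- two_stage_spec()
  pf <- generate_planted_frontier(spec, n_dmu = 8, n_periods = 2,
                                  n_efficient = 3, seed = 7)
  fit <- dndea(pf$panel, spec)
  ov <- coef(fit)
  expect_true(all(ov[pf$planted_efficient_ids] > 1 - 1e-9))
  dom <- ov[setdiff(names(ov), pf$planted_efficient_ids)]
  expect_true(all(dom < 1 - 1e-6))
})

test_that("dominance certificates reproduce the dominated units' values", {
  spec <- two_stage_spec()
  pf <- generate_planted_frontier(spec, n_dmu = 6, n_periods = 2,
                                  n_efficient = 2, seed = 3)
  sv <- dndea:::spec_variables(spec)
  for (d in names(pf$certificates)) {
    cert <- pf$certificates[[d]]
    for (i in seq_len(nrow(sv))) {
      k <- sv$division[i]; v <- sv$variable[i]
      M <- pf$panel$values[[k]][[v]]
      combo <- colSums(M[names(cert$weights), , drop = FALSE] * cert$weights)
      f <- cert$factors[[paste(k, v, sep = "/")]]
      expect_equal(unname(M[d, ]), unname(combo * f), tolerance = 1e-10)
      if (sv$role[i] %in% c("input", "link_in", "bad_output"))
        expect_gte(f, 1)
      else expect_lte(f, 1)
    }
  }
})

test_that("unit inflation factors make every unit efficient", {
  spec <- minimal_spec()
  pf <- generate_planted_frontier(spec, n_dmu = 5, n_periods = 1,
                                  n_efficient = 2, seed = 11,
                                  inflate_range = c(1, 1),
                                  deflate_range = c(1, 1))
  fit <- dndea(pf$panel, spec)
  expect_true(all(coef(fit) > 1 - 1e-7))
})

test_that("the same seed reproduces the panel exactly", {
  spec <- two_stage_spec()
  p1 <- generate_planted_frontier(spec, n_dmu = 6, seed = 42)
  p2 <- generate_planted_frontier(spec, n_dmu = 6, seed = 42)
  expect_identical(p1$panel$data, p2$panel$data)
  t1 <- generate_two_stage_panel(n_dmu = 5, seed = 9)
  t2 <- generate_two_stage_panel(n_dmu = 5, seed = 9)
  expect_identical(t1$panel$data, t2$panel$data)
  t3 <- generate_two_stage_panel(n_dmu = 5, seed = 10)
  expect_false(identical(t1$panel$data, t3$panel$data))
})

test_that("infeasible generator parameters raise generation errors", {
  expect_error(generate_planted_frontier(minimal_spec(), n_dmu = 3,
                                         n_efficient = 5),
               "n_efficient")
  only_goods <- dea_spec(list(unit = list(good_outputs = "y")))
  expect_error(generate_planted_frontier(only_goods, n_dmu = 3),
               "cost variable")
  expect_error(generate_two_stage_panel(stage1_dispersion = 0),
               "positive")
})

test_that("two-stage generator output validates with strictly positive values", {
  sim <- generate_two_stage_panel(n_dmu = 8, n_periods = 3, seed = 2)
  expect_s3_class(sim$panel, "dndea_panel")
  expect_true(all(sim$panel$data$value > 0))
  expect_equal(length(sim$panel$dmus), 8L)
  expect_equal(length(sim$panel$periods), 3L)
  # no zero-replacement warning at default settings
  expect_silent(dea_panel(sim$panel$data, two_stage_spec(),
                          periods = sim$panel$periods))
})

test_that("a unit dominating another in everything leaves it inefficient in both stages", {
  spec <- two_stage_spec()
  sv <- dndea:::spec_variables(spec)
  better <- list(input = 1, link_in = 1, bad_output = 1,
                 good_output = 10, carryover = 10)
  worse <- list(input = 4, link_in = 4, bad_output = 4,
                good_output = 5, carryover = 5)
  rows <- do.call(rbind, lapply(seq_len(nrow(sv)), function(i)
    data.frame(dmu = c("good", "bad"), period = "p1",
               division = sv$division[i], variable = sv$variable[i],
               value = c(better[[sv$role[i]]], worse[[sv$role[i]]]),
               stringsAsFactors = FALSE)))
  pan <- dea_panel(rows, spec)
  fit <- dndea(pan, spec)
  dv <- efficiency(fit, "division")
  expect_true(all(dv["bad", ] < 1 - 1e-6))
  expect_true(all(dv["good", ] > 1 - 1e-9))
})
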