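test_that("input-excess toy solves to its closed-form score", {
  toy <- toy_a()
  solB <- solve_dmu(toy$spec, toy$panel, "B")
  expect_equal(solB$theta, 0.5, tolerance = 1e-9)
  expect_equal(solB$slacks$slack[solB$slacks$variable == "x"], 1,
               tolerance = 1e-7)
  expect_equal(unname(solB$lambda["A", 1, 1]), 1, tolerance = 1e-7)
  solA <- solve_dmu(toy$spec, toy$panel, "A")
  expect_equal(solA$theta, 1, tolerance = 1e-9)
  expect_true(all(solA$slacks$slack < 1e-8))
})

test_that("bad-output toy solves to its closed-form score", {
  toy <- toy_b()
  solB <- solve_dmu(toy$spec, toy$panel, "B")
  expect_equal(solB$theta, 0.8, tolerance = 1e-9)
  expect_equal(solB$slacks$slack[solB$slacks$variable == "b"], 1,
               tolerance = 1e-7)
  expect_equal(solve_dmu(toy$spec, toy$panel, "A")$theta, 1,
               tolerance = 1e-9)
})

test_that("a single-DMU program only admits the self-solution", {
  spec <- minimal_spec()
  df <- long_panel(list(A = list(x = 3, y = 2)))
  pan <- dea_panel(df, spec)
  sol <- solve_dmu(spec, pan, "A")
  expect_equal(sol$theta, 1, tolerance = 1e-10)
  expect_true(all(abs(sol$slacks$slack) < 1e-10))
  expect_true(verify_solution(sol, spec, pan)$pass)
})

test_that("identical DMUs are all efficient", {
  spec <- minimal_spec()
  df <- long_panel(list(A = list(x = 2, y = 5), B = list(x = 2, y = 5),
                        C = list(x = 2, y = 5)))
  pan <- dea_panel(df, spec)
  sols <- solve_all(spec, pan)
  expect_true(all(vapply(sols, `[[`, 0, "theta") > 1 - 1e-9))
})

test_that("unknown DMU raises a lookup error", {
  toy <- toy_a()
  expect_error(solve_dmu(toy$spec, toy$panel, "nope"), "unknown DMU")
})

test_that("efficiency is invariant to weight rescaling", {
  inst <- random_network_panel(11)
  base <- solve_dmu(inst$spec, inst$panel, "d1")$theta
  spec10 <- dea_spec(inst$spec$divisions, links = inst$spec$links,
                     carryovers = inst$spec$carryovers,
                     period_weights = c(10, 10),
                     division_weights = c(10, 10))
  expect_equal(solve_dmu(spec10, inst$panel, "d1")$theta, base,
               tolerance = 1e-9)
})

test_that("engine scores match the brute-force vertex oracle", {
  for (s in c(3, 17, 42, 121)) {
    inst <- random_oracle_instance(s)
    for (d in inst$panel$dmus) {
      th <- solve_dmu(inst$spec, inst$panel, d, lex = FALSE)$theta
      expect_equal(th, oracle_theta(inst$spec, inst$panel, d),
                   tolerance = 2e-3,
                   label = sprintf("engine theta (seed %d, dmu %s)", s, d))
    }
  }
})

test_that("static single-period scores match a plain simplex-grid search", {
  # classical non-oriented VRS SBM reduction: K = 1, T = 1
  count <- 0L
  for (s in 1:30) {
    inst <- random_oracle_instance(s)
    if (inst$Tn != 1L) next
    count <- count + 1L
    d <- inst$panel$dmus[1]
    th <- solve_dmu(inst$spec, inst$panel, d, lex = FALSE)$theta
    expect_equal(th, oracle_theta_grid(inst$spec, inst$panel, d),
                 tolerance = 2e-3,
                 label = sprintf("grid oracle (seed %d)", s))
    if (count >= 5L) break
  }
  expect_gte(count, 3L)
})

test_that("the fractional program admits the self-solution at ratio 1", {
  inst <- random_network_panel(5)
  fp <- dndea:::assemble_program(inst$spec, inst$panel, "d2")
  n <- fp$n
  lam <- numeric(fp$n_lambda)
  for (k in fp$divisions) for (t in seq_len(fp$Tn))
    lam[(match(k, fp$divisions) - 1L) * fp$Tn * n + (t - 1L) * n + fp$o] <- 1
  v <- c(lam, rep(0, fp$nv - fp$n_lambda))
  expect_true(all(abs(fp$A %*% v - fp$b) < 1e-9))
})

test_that("verify_solution flags a perturbed solution", {
  toy <- toy_a()
  sol <- solve_dmu(toy$spec, toy$panel, "B")
  sol$lambda["A", 1, 1] <- sol$lambda["A", 1, 1] + 1e-2
  expect_false(verify_solution(sol, toy$spec, toy$panel)$pass)
})

test_that("lexicographic pass preserves the optimal score", {
  for (s in c(2, 9)) {
    inst <- random_network_panel(s)
    for (d in inst$panel$dmus[1:2]) {
      s0 <- solve_dmu(inst$spec, inst$panel, d, lex = FALSE)
      s1 <- solve_dmu(inst$spec, inst$panel, d, lex = TRUE)
      expect_equal(s1$theta, s0$theta, tolerance = 1e-7)
      # lexicographic slacks still reproduce theta through the mediant
      med <- sum(s1$Wkt * s1$N) / sum(s1$Wkt * s1$D)
      expect_equal(med, s1$theta, tolerance = 1e-6)
      expect_gte(sum(s1$slacks$ratio) + 1e-9, sum(s0$slacks$ratio))
    }
  }
})

test_that("numerator and denominator parts are properly bounded", {
  inst <- random_network_panel(13)
  for (d in inst$panel$dmus) {
    sol <- solve_dmu(inst$spec, inst$panel, d)
    expect_true(all(sol$N > 0 & sol$N <= 1 + 1e-9))
    expect_true(all(sol$D >= 1 - 1e-9))
  }
})

test_that("the internal LP solver agrees with boot::simplex where the latter works", {
  skip_if_not_installed("boot")
  set.seed(99)
  for (i in 1:5) {
    m <- 8; n <- 15
    A <- matrix(runif(m * n), m, n)
    b <- A %*% runif(n)
    cc <- runif(n)
    mine <- dndea:::lp_solve(cc, A, as.vector(b), rep("=", m))
    ref <- boot::simplex(a = cc, A3 = A, b3 = as.vector(b))
    expect_equal(mine$value, unname(ref$value), tolerance = 1e-7)
  }
})
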