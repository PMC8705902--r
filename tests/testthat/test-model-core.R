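test_that("stoichiometric matrix reproduces reaction columns", {
  m <- chain_model()
  S <- build_stoichiometric_matrix(m)
  expect_identical(rownames(S), c("A[e]", "B[e]"))
  expect_identical(colnames(S), c("C1", "EX_A", "EX_B"))
  expect_equal(as.numeric(S[, "C1"]), c(-1, 1))
  expect_equal(as.numeric(S[, "EX_A"]), c(-1, 0)) # single-entry exchange
  # empty model -> 0 x 0
  m0 <- metabolic_model("empty", "e",
                        metabolite_table(character(0), character(0)),
                        list())
  expect_equal(dim(build_stoichiometric_matrix(m0)), c(0L, 0L))
})

test_that("structural errors carry the offending reaction", {
  expect_error(
    metabolic_model("bad", "e", metabolite_table("A", "e"),
                    list(reaction("R1", c("A[e]" = -1, "Z[e]" = 1)))) |>
      validate_model(),
    "R1.*undeclared metabolite")
  expect_error(validate_model(
    metabolic_model("bad2", "e", metabolite_table("A", "e"),
                    list(reaction("EX_A", c("A[e]" = -2),
                                  kind = "exchange")))),
    "exactly one metabolite with coefficient -1")
})

test_that("FBA on the chain model hits the supply-limited optimum", {
  m <- chain_model()
  s <- solve_fba(m)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective_value, 10, tolerance = 1e-9)
  expect_lt(mass_balance_residual(m, s$fluxes), 1e-6)
  expect_true(all(s$fluxes >= vapply(m$reactions, `[[`, 0, "lb") - 1e-6))
  expect_true(all(s$fluxes <= vapply(m$reactions, `[[`, 0, "ub") + 1e-6))
  # all bounds zero -> optimum 0
  m2 <- set_bounds(m, "EX_A", lb = 0, ub = 0)
  expect_equal(solve_fba(m2)$objective_value, 0, tolerance = 1e-12)
  # inverted bounds rejected before solving
  m3 <- set_bounds(m, "EX_A", lb = 5, ub = -5)
  expect_error(solve_fba(m3), "inverted bounds")
})

test_that("FVA brackets the chain model as hand-computed", {
  m <- chain_model()
  f <- run_fva(m, "EX_B", gamma = 0)
  expect_equal(c(f$min, f$max), c(0, 10), tolerance = 1e-9)
  # objective pinned at its optimum
  f1 <- run_fva(m, "EX_B", gamma = 1)
  expect_equal(c(f1$min, f1$max), c(10, 10), tolerance = 1e-6)
  # structurally blocked reaction: B has no source
  m2 <- set_bounds(m, "EX_A", lb = 0, ub = 0)
  f2 <- run_fva(m2, c("C1", "EX_B"), gamma = 0)
  expect_equal(f2$min, c(0, 0), tolerance = 1e-12)
  expect_equal(f2$max, c(0, 0), tolerance = 1e-12)
  expect_error(run_fva(m, "nope"), "unknown reaction")
})

test_that("FVA sandwich: any FBA optimum lies inside the FVA range", {
  for (seed in c(3, 17, 29)) {
    m <- random_small_model(seed)
    s <- solve_fba(m)
    if (s$status != "optimal") next
    f <- run_fva(m, reaction_ids = names(s$fluxes), gamma = 0)
    i <- match(f$reaction, names(s$fluxes))
    expect_true(all(f$min - 1e-6 <= s$fluxes[i]),
                info = paste("seed", seed))
    expect_true(all(s$fluxes[i] <= f$max + 1e-6),
                info = paste("seed", seed))
  }
})

test_that("flux coupling confines coupled reactions to c*v_bio + u", {
  # A imported, converted to B; biomass reaction pinned at 0.01
  m <- metabolic_model(
    "cpl", "e",
    metabolite_table(c("A", "B", "X"), "e"),
    list(reaction("EX_A", c("A[e]" = -1), lb = -100, ub = 1000,
                  kind = "exchange"),
         reaction("C1", c("A[e]" = -1, "B[e]" = 1), lb = -1000, ub = 1000),
         reaction("EX_B", c("B[e]" = -1), lb = -1000, ub = 1000,
                  kind = "exchange"),
         reaction("BIO", c("X[e]" = 1), lb = 0.01, ub = 0.01,
                  kind = "biomass"),
         reaction("DM_X", c("X[e]" = -1), lb = 0, ub = 1000,
                  kind = "exchange")),
    objective = c(EX_B = 1))
  mc <- add_flux_coupling(m, list(s = list(reactions = c("C1", "EX_B"),
                                           biomass = "BIO")),
                          c = 400, u = 0)
  f <- run_fva(mc, "C1", gamma = 0)
  expect_equal(c(f$min, f$max), c(-4, 4), tolerance = 1e-6) # 400 * 0.01
  # zero biomass, zero slack: coupled fluxes forced to 0
  m0 <- set_bounds(m, "BIO", lb = 0, ub = 0)
  mc0 <- add_flux_coupling(m0, list(s = list(reactions = c("C1", "EX_B"),
                                             biomass = "BIO")),
                           c = 400, u = 0)
  f0 <- run_fva(mc0, c("C1", "EX_B"), gamma = 0)
  expect_equal(max(abs(c(f0$min, f0$max))), 0, tolerance = 1e-9)
  # invalid parameters and dangling anchors
  expect_error(add_flux_coupling(m, list(s = list(reactions = "C1",
                                                  biomass = "BIO")),
                                 c = -1), "nonnegative")
  expect_error(add_flux_coupling(m, list(s = list(reactions = "C1",
                                                  biomass = "NOPE"))),
               "anchor")
})

test_that("coupled secretion is non-decreasing in the biomass allowance", {
  caps <- c(0.005, 0.01, 0.02, 0.05)
  vmax <- numeric(length(caps))
  for (i in seq_along(caps)) {
    m <- metabolic_model(
      "mono", "e",
      metabolite_table(c("A", "B", "X"), "e"),
      list(reaction("EX_A", c("A[e]" = -1), lb = -100, ub = 0,
                    kind = "exchange"),
           reaction("C1", c("A[e]" = -1, "B[e]" = 1), lb = 0, ub = 1000),
           reaction("EX_B", c("B[e]" = -1), lb = 0, ub = 1000,
                    kind = "exchange"),
           reaction("BIO", c("X[e]" = 1), lb = 0, ub = caps[i],
                    kind = "biomass"),
           reaction("DM_X", c("X[e]" = -1), lb = 0, ub = 1000,
                    kind = "exchange")),
      objective = c(EX_B = 1))
    mc <- add_flux_coupling(m, list(s = list(reactions = c("C1", "EX_B"),
                                             biomass = "BIO")))
    vmax[i] <- run_fva(mc, "EX_B", gamma = 0)$max
  }
  expect_true(all(diff(vmax) >= -1e-9))
})
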