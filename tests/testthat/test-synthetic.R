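test_that("strain templates realise their stated yields", {
  # yield 1, supply 5, zero biomass demand -> max product exchange 5
  sp <- strain_template_spec("t1", substrates = "sub",
                             products = c(prod = 1),
                             biomass_demand = 0)
  m <- generate_strain_template(sp)
  m <- set_bounds(m, "EX_sub", lb = -5, ub = 0)
  m$objective <- c(EX_prod = 1)
  expect_equal(solve_fba(m)$objective_value, 5, tolerance = 1e-9)
  # yield 0 -> blocked product
  sp0 <- strain_template_spec("t2", substrates = "sub",
                              products = c(prod = 0))
  m0 <- generate_strain_template(sp0)
  f <- run_fva(m0, "EX_prod", gamma = 0)
  expect_equal(c(f$min, f$max), c(0, 0))
  # two products splitting one substrate, yields 1 and 1:
  # their combined export cannot exceed the supply
  sp2 <- strain_template_spec("t3", substrates = "sub",
                              products = c(p1 = 1, p2 = 1),
                              biomass_demand = 0)
  m2 <- generate_strain_template(sp2)
  m2 <- set_bounds(m2, "EX_sub", lb = -5, ub = 0)
  m2$objective <- c(EX_p1 = 1, EX_p2 = 1)
  expect_equal(solve_fba(m2)$objective_value, 5, tolerance = 1e-9)
  expect_error(strain_template_spec("bad", products = c(p = -1)),
               "negative yield")
})

test_that("scenario generation is deterministic in the seed", {
  b1 <- suppressMessages(generate_scenario(n_strains = 6, seed = 42))
  b2 <- suppressMessages(generate_scenario(n_strains = 6, seed = 42))
  expect_identical(b1$truth$abundance, b2$truth$abundance)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$truth$net_secretion, b2$truth$net_secretion)
  b3 <- suppressMessages(generate_scenario(n_strains = 6, seed = 43))
  expect_false(identical(b1$truth$abundance, b3$truth$abundance))
})

test_that("the default scenario mirrors the 7-timepoint study design", {
  b <- default_scenario()
  expect_equal(b$timepoints,
               paste0("day", c(0, 15, 30, 45, 60, 75, 105)))
  expect_length(b$models, 10)
  ab <- b$truth$abundance
  expect_true(all(diff(ab[, "str_folA"]) > 0))  # rising producer
  expect_true(all(diff(ab[, "str_mopB"]) < 0))  # falling producer
  expect_true(all(abs(rowSums(ab) - 1) < 1e-12))
  expect_error(generate_scenario(n_strains = 1), "at least 2")
})

test_that("clinical generator plants exact attainable correlations", {
  cl <- generate_clinical(
    7, targets = list(A = list(rho = 1, range = c(0, 1)),
                      B = list(rho = 25 / 28, range = c(0, 1))),
    seed = 5)
  rk <- attr(cl, "ranks")
  expect_equal(rk[, "A"], 1:7) # rho 1 -> identical ranks
  sb <- spearman(1:7, cl$B)
  expect_equal(sb$rho, 25 / 28, tolerance = 1e-12)
  # unattainable rho snaps to the lattice with a warning
  expect_warning(cl2 <- generate_clinical(
    7, targets = list(C = list(rho = 0.9, range = c(0, 1))), seed = 5),
    "not attainable")
  sc <- spearman(1:7, cl2$C)
  expect_equal(sc$rho, 25 / 28, tolerance = 1e-12) # nearest lattice point
})

test_that("analytic oracle covers supply- and coupling-limited regimes", {
  b <- default_scenario()
  tr <- b$truth$net_secretion
  cfg <- b$config
  a_fol <- b$truth$abundance[, "str_folA"] / (1 - 0.0005)
  cap <- cfg$coupling_c * a_fol * cfg$biomass_bounds[2] + cfg$coupling_u
  want <- pmin(0.5 * pmin(300, cap), cap)
  got <- tr$net_secretion[tr$metabolite == "fol"][
    match(b$timepoints, tr$sample[tr$metabolite == "fol"])]
  expect_equal(got, unname(want), tolerance = 1e-12)
  # zero-yield product nets zero everywhere
  expect_true(all(tr$net_secretion[tr$metabolite == "xin"] == 0))
  # non-chain custom models have no closed form
  b2 <- b
  b2$models[[1]]$meta$template <- NULL
  expect_error(analytic_net_secretion(b2), "no closed form")
})
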