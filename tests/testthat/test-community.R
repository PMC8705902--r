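test_that("cutoff filter drops sub-threshold strains and renormalises", {
  p <- abundance_profile("d0", c(s1 = 0.5, s2 = 0.4, s3 = 0.0995,
                                 s4 = 0.0005))
  f <- suppressMessages(filter_and_renormalize(p, 0.001))
  expect_named(f$abundances, c("s1", "s2", "s3"))
  expect_equal(unname(f$abundances),
               c(0.5, 0.4, 0.0995) / 0.9995, tolerance = 1e-15)
  expect_lt(abs(sum(f$abundances) - 1), 1e-12)
  # idempotent
  f2 <- filter_and_renormalize(f, 0.001)
  expect_equal(f2$abundances, f$abundances, tolerance = 1e-15)
  # already-unit profiles pass through unchanged
  q <- abundance_profile("d1", c(a = 0.6, b = 0.4))
  expect_equal(filter_and_renormalize(q, 0.001)$abundances, q$abundances)
  # degenerate inputs
  expect_error(filter_and_renormalize(
    abundance_profile("d2", c(a = 0.0005, b = 0.0004)), 0.001),
    "empty community")
  expect_error(abundance_profile("d3", c(a = -0.1)), "negative")
})

test_that("strain tagging creates IEX transports and disjoint id sets", {
  m <- generate_strain_template(producer_spec("s1"))
  t1 <- tag_strain_model(m, "S1")
  expect_true("S1_IEX_fol[u]tr" %in% reaction_ids(t1))
  expect_true("S1_IEX_fib[u]tr" %in% reaction_ids(t1))
  expect_false(any(grepl("^EX_", reaction_ids(t1)))) # exchanges replaced
  t2 <- tag_strain_model(m, "S2")
  expect_length(intersect(reaction_ids(t1), reaction_ids(t2)), 0)
  expect_error(tag_strain_model(t1, "S1"), "already tagged")
})

test_that("community bookkeeping is exact", {
  m1 <- generate_strain_template(producer_spec("s1"))
  m2 <- generate_strain_template(inert_spec("s2"))
  prof <- filter_and_renormalize(
    abundance_profile("d0", c(s1 = 0.6, s2 = 0.4)), 0.001)
  cm <- assemble_community(list(m1, m2), prof)
  reg <- cm$strain_registry
  n_tagged <- sum(vapply(reg, function(g) length(g$reactions), 0L))
  lumen <- cm$meta$lumen
  expect_length(cm$reactions, n_tagged + 4 * length(lumen) + 3)
  # community biomass stoichiometry equals the filtered abundances
  bio <- cm$reactions[[match("communityBiomass", reaction_ids(cm))]]
  expect_equal(unname(bio$stoich[reg$s1$biomass_met]), -0.6)
  expect_equal(unname(bio$stoich[reg$s2$biomass_met]), -0.4)
  # every lumen metabolite has all four layer reactions
  for (m in lumen)
    expect_true(all(c(sprintf("EX_%s[d]", m), sprintf("DUt_%s", m),
                      sprintf("UFEt_%s", m), sprintf("EX_%s[fe]", m)) %in%
                      reaction_ids(cm)))
  expect_error(assemble_community(list(m1), prof), "no model supplied")
})

test_that("a one-strain community reproduces the strain FBA optimum", {
  m <- generate_strain_template(producer_spec("s1"))
  # standalone under the same nutrient supply: growth limited by aa
  ms <- set_bounds(m, "EX_aa", lb = -0.35, ub = 0)
  ms <- set_bounds(ms, "EX_fib", lb = -10, ub = 0)
  s_alone <- solve_fba(ms)
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cm <- assemble_community(list(m), prof)
  cm <- apply_diet(cm, c(aa = 0.35, fib = 10))
  s_comm <- solve_fba(cm)
  expect_equal(s_comm$objective_value, s_alone$objective_value,
               tolerance = 1e-6)
})

test_that("diet application follows the uptake sign convention", {
  m <- generate_strain_template(producer_spec("s1"))
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cm <- assemble_community(list(m), prof)
  cmd <- apply_diet(cm, c(fib = 10, aa = 5))
  i <- match("EX_fib[d]", reaction_ids(cmd))
  expect_equal(cmd$reactions[[i]]$lb, -10)
  expect_equal(cmd$reactions[[i]]$ub, 0)
  # unknown metabolite skipped with warning, counted
  expect_warning(cmd2 <- apply_diet(cm, c(fib = 10, aa = 5, unobtainium = 1)),
                 "no lumen counterpart")
  expect_equal(cmd2$meta$diet_skipped, 1)
  expect_error(apply_diet(cm, c(fib = -1)), "nonnegative")
})

test_that("supplement policy rescues growth on a missing micronutrient", {
  # strain needs both aa and ion for biomass
  sp <- strain_template_spec("s1", substrates = "ion",
                             biomass_substrate = "aa", biomass_demand = 0.5)
  m <- generate_strain_template(sp)
  # add an ion requirement to the biomass reaction
  i <- match("BIO", reaction_ids(m))
  m$reactions[[i]]$stoich <- c(m$reactions[[i]]$stoich,
                               setNames(-0.05, "ion[c]"))
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cm <- assemble_community(list(m), prof)
  starved <- apply_diet(cm, c(aa = 100))
  expect_equal(solve_fba(starved)$status, "infeasible")
  fed <- apply_diet(cm, c(aa = 100),
                    supplement = list(metabolites = "ion", eps = 0.1))
  i2 <- match("EX_ion[d]", reaction_ids(fed))
  expect_equal(fed$reactions[[i2]]$lb, -0.1)
  s <- solve_fba(fed)
  expect_equal(s$status, "optimal")
  expect_gte(s$objective_value, 0.4)
})

test_that("halving the producer abundance cannot raise its secretion cap", {
  m1 <- generate_strain_template(producer_spec("s1"))
  m2 <- generate_strain_template(inert_spec("s2"))
  sec <- function(a1) {
    prof <- filter_and_renormalize(
      abundance_profile("d0", c(s1 = a1, s2 = 1 - a1)), 0.001)
    cm <- assemble_community(list(m1, m2), prof)
    cm <- apply_diet(cm, c(fib = 300, aa = 100))
    run_fva(cm, "EX_fol[fe]", gamma = 0)$max
  }
  expect_lte(sec(0.1), sec(0.2) + 1e-9)
})
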