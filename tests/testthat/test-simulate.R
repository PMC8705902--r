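test_that("net fluxes on a hand-checkable toy community", {
  # single strain converting fib -> fol 1:1; no growth requirement beyond
  # a tiny coupled biomass; fib supplied at 5, fol absent from the diet
  sp <- strain_template_spec("s1", substrates = "fib",
                             products = c(fol = 1),
                             biomass_substrate = "aa",
                             biomass_demand = 0.01)
  m <- generate_strain_template(sp)
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cfg <- community_config(gamma = 0)
  cm <- assemble_community(list(m), prof, cfg)
  cm <- apply_diet(cm, c(fib = 5, aa = 100))
  rec <- simulate_sample(cm, config = cfg)
  fol <- rec[rec$metabolite == "fol", ]
  expect_equal(fol$max_secretion, 5, tolerance = 1e-6)
  expect_equal(fol$min_uptake, 0)     # fol diet exchange closed
  expect_equal(fol$net_secretion, 5, tolerance = 1e-6)
  fib <- rec[rec$metabolite == "fib", ]
  expect_equal(fib$net_secretion, 0, tolerance = 1e-6) # passthrough cancels
  expect_equal(fib$net_uptake, 5, tolerance = 1e-6)
})

test_that("metabolite with no producer or consumer nets to zero", {
  sp <- strain_template_spec("s1", substrates = "fib",
                             products = c(fol = 0.5, xin = 0))
  m <- generate_strain_template(sp)
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cm <- assemble_community(list(m), prof)
  cm <- apply_diet(cm, c(fib = 5, aa = 100))
  rec <- simulate_sample(cm)
  xin <- rec[rec$metabolite == "xin", ]
  expect_equal(max(abs(unlist(xin[, 3:8]))), 0, tolerance = 1e-9)
})

test_that("a diet without the growth substrate is reported infeasible", {
  m <- generate_strain_template(producer_spec("s1"))
  prof <- filter_and_renormalize(abundance_profile("d0", c(s1 = 1)), 0.001)
  cm <- assemble_community(list(m), prof) # biomass lb = 0.4
  cm <- apply_diet(cm, c(fib = 5))        # no aa
  expect_error(simulate_sample(cm), "infeasible")
})

test_that("role classification partitions the metabolite universe", {
  run <- default_scenario_run()
  roles <- classify_exchange_roles(run$records)
  mets <- unique(run$records$metabolite)
  expect_setequal(names(roles), mets)
  counts <- table(factor(roles, levels = c("secreted_only", "uptake_only",
                                           "both", "inert")))
  expect_equal(sum(counts), length(mets))
  # the planted scenario exercises every role
  expect_equal(unname(roles["fol"]), "secreted_only")
  expect_equal(unname(roles["ac"]), "both")
  expect_equal(unname(roles["fib"]), "uptake_only")
  expect_equal(unname(roles["xin"]), "inert")
  # definitional cases
  toy <- data.frame(sample = c("a", "b"), metabolite = "m",
                    net_secretion = c(1, 0), net_uptake = c(0, 1))
  expect_equal(unname(classify_exchange_roles(toy)), "both")
  expect_length(classify_exchange_roles(toy[0, ]), 0)
})

test_that("subsystem totals sum positive net secretion per sample", {
  rec <- data.frame(sample = "d0",
                    metabolite = c("fol", "thf", "glc", "mystery", "waste"),
                    net_secretion = c(2, 3, 4, 1, -1))
  map <- c(fol = "vitamin and cofactor metabolism",
           thf = "vitamin and cofactor metabolism",
           glc = "carbohydrate metabolism")
  expect_warning(tot <- subsystem_totals(rec, map), "other")
  expect_equal(
    tot$net_secretion[tot$subsystem == "vitamin and cofactor metabolism"], 5)
  expect_equal(tot$net_secretion[tot$subsystem == "other"], 1)
  # negative net secretion excluded entirely
  expect_equal(sum(tot$net_secretion), 2 + 3 + 4 + 1)
  none <- subsystem_totals(rec[rec$net_secretion < 0, ], map)
  expect_equal(nrow(none), 0)
})

test_that("Shannon index has exact closed-form values and bounds", {
  expect_equal(shannon(abundance_profile("x", c(a = 0.25, b = 0.25,
                                                c = 0.25, d = 0.25))),
               log(4), tolerance = 1e-12)
  expect_equal(shannon(abundance_profile("x", c(a = 1))), 0)
  # zero entries ignored (0 * log 0 := 0)
  expect_equal(shannon(abundance_profile("x", c(a = 0.5, b = 0.5, c = 0))),
               log(2), tolerance = 1e-12)
  expect_error(shannon(c(a = -0.1, b = 1.1)), "negative")
  run <- default_scenario_run()
  H <- run$shannon
  n <- vapply(run$profiles, function(p) sum(p$abundances > 0), 0L)
  expect_true(all(H >= 0 & H <= log(n) + 1e-12))
  if (requireNamespace("vegan", quietly = TRUE)) {
    ref <- vapply(run$profiles, function(p)
      vegan::diversity(p$abundances, index = "shannon"), 0)
    expect_equal(unname(H), unname(ref), tolerance = 1e-12)
  }
})

test_that("contribution shares identify the sole producer", {
  run <- default_scenario_run()
  co <- run$contributions
  for (m in c("fol", "3mop", "ac")) {
    planted <- default_scenario()$truth$producers[[m]]
    x <- co[co$metabolite == m, ]
    expect_true(all(x$strain == planted | x$share == 0))
    expect_true(all(x$share[x$strain == planted] >= 0.99), info = m)
  }
})

test_that("individual strain maxima are superadditive over the community max", {
  # two identical producers at equal abundance
  m1 <- generate_strain_template(producer_spec("s1"))
  m2 <- generate_strain_template(producer_spec("s2"))
  prof <- filter_and_renormalize(
    abundance_profile("d0", c(s1 = 0.5, s2 = 0.5)), 0.001)
  cm <- assemble_community(list(m1, m2), prof)
  cm <- apply_diet(cm, c(fib = 300, aa = 100))
  co <- strain_contributions(cm, "fol")
  expect_equal(co$max_flux[1], co$max_flux[2], tolerance = 1e-6)
  expect_equal(co$share, c(0.5, 0.5), tolerance = 1e-6)
  comm_max <- run_fva(cm, "EX_fol[fe]",
                      gamma = cm$meta$config$gamma)$max
  expect_gte(sum(co$max_flux) + 1e-9, comm_max)
  # empty result for a metabolite nobody exchanges
  expect_error(strain_contributions(cm, "unobtainium"), "unknown")
})

test_that("simulated net secretion matches the analytic closed form", {
  bundle <- default_scenario()
  run <- default_scenario_run()
  truth <- bundle$truth$net_secretion
  merged <- merge(run$records, truth,
                  by.x = c("sample", "metabolite"),
                  by.y = c("sample", "metabolite"))
  expect_equal(nrow(merged), nrow(run$records))
  expect_lt(max(abs(merged$net_secretion.x - merged$net_secretion.y)), 1e-6)
})

test_that("raising the producer abundance never lowers its secretion", {
  bundle <- default_scenario()
  run <- default_scenario_run()
  fol <- run$records[run$records$metabolite == "fol", ]
  fol <- fol[match(bundle$timepoints, fol$sample), ]
  # planted abundance rises monotonically across the series
  expect_true(all(diff(fol$net_secretion) > 0))
})
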