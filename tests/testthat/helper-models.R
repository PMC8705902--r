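# shared toy fixtures, built in code

# linear chain: EX_A (uptake up to 10) -> C1: A -> B -> EX_B
chain_model <- function(lb_A = -10) {
  metabolic_model(
    "chain", "e",
    metabolite_table(c("A", "B"), "e"),
    list(reaction("EX_A", c("A[e]" = -1), lb = lb_A, ub = 0,
                  kind = "exchange"),
         reaction("C1", c("A[e]" = -1, "B[e]" = 1), lb = 0, ub = 1000),
         reaction("EX_B", c("B[e]" = -1), lb = 0, ub = 1000,
                  kind = "exchange")),
    objective = c(EX_B = 1))
}

# producer strain: fib -> fol (yield y), growth on aa
producer_spec <- function(name = "s1", yield = 0.5, demand = 0.5) {
  strain_template_spec(name, substrates = "fib",
                       products = setNames(yield, "fol"),
                       biomass_substrate = "aa", biomass_demand = demand)
}

inert_spec <- function(name = "s_inert") strain_template_spec(name)

# random small stoichiometric model over <= 6 metabolites, mixed
# reversibility; used for oracle-equivalence fuzzing
random_small_model <- function(seed) {
  set.seed(seed)
  n_met <- sample(2:6, 1)
  n_rxn <- sample(2:8, 1)
  ids <- LETTERS[seq_len(n_met)]
  mets <- metabolite_table(ids, "e")
  rxns <- vector("list", n_rxn)
  for (j in seq_len(n_rxn)) {
    k <- sample(1:min(3, n_met), 1)
    who <- sample(ids, k)
    coef <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    rev <- runif(1) < 0.5
    rxns[[j]] <- reaction(sprintf("R%02d", j),
                          setNames(coef, met_key(who, "e")),
                          lb = if (rev) -round(runif(1, 1, 10), 1) else 0,
                          ub = round(runif(1, 0, 10), 1))
  }
  metabolic_model(paste0("rand", seed), "e", mets, rxns,
                  objective = setNames(1, "R01"))
}

# memoised default-scenario run shared across test files
.scenario_cache <- new.env(parent = emptyenv())
default_scenario <- function() {
  if (is.null(.scenario_cache$bundle))
    .scenario_cache$bundle <- suppressMessages(
      generate_scenario(n_strains = 10, n_timepoints = 7, seed = 1))
  .scenario_cache$bundle
}
default_scenario_run <- function() {
  if (is.null(.scenario_cache$run))
    .scenario_cache$run <- suppressMessages(run_scenario(default_scenario()))
  .scenario_cache$run
}
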