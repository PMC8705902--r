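#' Synthetic data generation
#'
#' Toy strain models and full community scenarios with analytically known
#' answers. The generator emulates the shape of a single-subject dietary
#' intervention study: 7 stool sampling timepoints, a fixed diet, one
#' folate-producer strain whose abundance rises monotonically during the
#' intervention, one producer of a branched-chain ketoacid whose abundance
#' falls, a substrate competitor, a strain pinned below the abundance
#' cutoff, and inert filler strains. Clinical series (BMI, leptin,
#' adiponectin) are planted with exact rank correlations against the
#' rising producer's secretion profile.
#'
#' @name synthetic_data
NULL

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a toy strain model
#'
#' @param name strain id.
#' @param substrates character vector of substrate metabolite ids; the
#'   first is the catabolic substrate feeding the conversion reactions.
#' @param products named numeric vector: product id -> yield (mol product
#'   per mol of catabolic substrate). A yield of 0 creates a structurally
#'   blocked product (exchange present, no flux possible).
#' @param biomass_substrate metabolite consumed by growth (default
#'   `"aa"`; added to the substrate set automatically).
#' @param biomass_demand mol of biomass substrate per unit biomass flux.
#' @param reversible should conversion reactions be reversible?
#' @param subsystems named character vector mapping metabolite ids to
#'   subsystem labels (defaults to "other").
#' @export
strain_template_spec <- function(name, substrates = character(0),
                                 products = numeric(0),
                                 biomass_substrate = "aa",
                                 biomass_demand = 0.5,
                                 reversible = FALSE,
                                 subsystems = character(0)) {
  if (any(products < 0)) stop("negative yield in strain template ", name)
  if (biomass_demand < 0) stop("negative biomass demand in ", name)
  structure(list(name = name, substrates = substrates, products = products,
                 biomass_substrate = biomass_substrate,
                 biomass_demand = biomass_demand, reversible = reversible,
                 subsystems = subsystems),
            class = "strain_template_spec")
}

.subsys <- function(ids, map) {
  out <- rep("other", length(ids))
  hit <- ids %in% names(map)
  out[hit] <- unname(map[ids[hit]])
  out
}

#' Build a toy strain model from a template
#'
#' The model has an extracellular compartment `e` and a cytosol `c`.
#' Each substrate s gets an exchange `EX_s` and an uptake `U_s`
#' (e -> c); each product p gets a conversion `CONV_p`
#' (catabolic substrate -> yield * p), an export `E_p` (c -> e) and an
#' exchange `EX_p`. Growth (`BIO`) consumes the biomass substrate and
#' produces a `biomass` metabolite drained by the sink `DM_biomass`.
#' The objective is the biomass flux.
#'
#' @param spec a [strain_template_spec()].
#' @return an FBA-solvable [metabolic_model()] with `meta$biomass = "BIO"`.
#' @export
generate_strain_template <- function(spec) {
  stopifnot(inherits(spec, "strain_template_spec"))
  subs <- unique(c(spec$substrates, spec$biomass_substrate))
  prods <- names(spec$products)
  both <- intersect(subs, prods)
  if (length(both) > 0)
    stop("metabolite cannot be both substrate and product in a chain ",
         "template: ", both[1])
  cat_sub <- if (length(spec$substrates) > 0) spec$substrates[1] else
    spec$biomass_substrate

  ids <- c(subs, prods)
  mets <- rbind(
    metabolite_table(rep(ids, each = 2), rep(c("e", "c"), length(ids)),
                     subsystem = rep(.subsys(ids, spec$subsystems), each = 2)),
    metabolite_table("biomass", "c", name = "strain biomass",
                     subsystem = "other"))

  rxns <- list()
  for (s in subs) {
    rxns <- c(rxns, list(
      reaction(paste0("EX_", s), setNames(-1, met_key(s, "e")),
               lb = -1000, ub = 1000, kind = "exchange"),
      reaction(paste0("U_", s),
               setNames(c(-1, 1), met_key(s, c("e", "c"))),
               lb = if (spec$reversible) -1000 else 0, ub = 1000,
               kind = "transport")))
  }
  for (p in prods) {
    y <- spec$products[[p]]
    st <- if (y > 0)
      setNames(c(-1, y), c(met_key(cat_sub, "c"), met_key(p, "c")))
    else # blocked product: conversion pinned to zero flux
      setNames(c(-1, 1), c(met_key(cat_sub, "c"), met_key(p, "c")))
    rxns <- c(rxns, list(
      reaction(paste0("CONV_", p), st,
               lb = if (spec$reversible) -1000 else 0,
               ub = if (y > 0) 1000 else 0, kind = "internal"),
      reaction(paste0("E_", p),
               setNames(c(-1, 1), met_key(p, c("c", "e"))),
               lb = if (spec$reversible) -1000 else 0, ub = 1000,
               kind = "transport"),
      reaction(paste0("EX_", p), setNames(-1, met_key(p, "e")),
               lb = -1000, ub = 1000, kind = "exchange")))
  }
  bio_st <- setNames(1, met_key("biomass", "c"))
  if (spec$biomass_demand > 0)
    bio_st <- c(setNames(-spec$biomass_demand,
                         met_key(spec$biomass_substrate, "c")), bio_st)
  rxns <- c(rxns, list(
    reaction("BIO", bio_st, lb = 0, ub = 1000, kind = "biomass"),
    reaction("DM_biomass", setNames(-1, met_key("biomass", "c")),
             lb = 0, ub = 1000, kind = "exchange")))

  metabolic_model(spec$name, c("c", "e"), mets, rxns,
                  objective = c(BIO = 1),
                  meta = list(biomass = "BIO", template = spec))
}

# closed-form Spearman rho between two rank vectors (tie-free)
.rho_from_ranks <- function(r1, r2) {
  n <- length(r1)
  1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
}

# Find a permutation of 1..n with squared rank distance sum(d^2) == S
# against the identity, by seeded local search. Returns the permutation and
# the S actually achieved (the nearest attainable if S itself is not hit).
.perm_with_S <- function(n, S, seed) {
  with_seed(seed, {
    best <- seq_len(n); bestS <- 0
    cur <- best; curS <- 0
    for (iter in seq_len(50000L)) {
      if (bestS == S) break
      ij <- sample.int(n, 2)
      prop <- cur
      prop[ij] <- prop[rev(ij)]
      propS <- sum((prop - seq_len(n))^2)
      if (abs(propS - S) <= abs(curS - S) || stats::runif(1) < 0.1) {
        cur <- prop; curS <- propS
      }
      if (abs(curS - S) < abs(bestS - S)) { best <- cur; bestS <- curS }
    }
    list(perm = best, S = bestS)
  })
}

#' Generate clinical series with planted rank correlations
#'
#' Constructs, for each requested parameter, a rank permutation whose exact
#' Spearman correlation against the reference ranks 1..n equals the target
#' rho (targets are snapped to the nearest attainable value of the discrete
#' rho lattice 1 - 6S/(n(n^2-1)) with a warning when needed), then draws
#' values monotone in rank between the given range limits with seeded
#' jitter.
#'
#' @param n_timepoints number of timepoints (>= 4).
#' @param targets named list: parameter name -> list(rho = <target>,
#'   range = c(lo, hi)).
#' @param seed integer seed.
#' @param timepoints optional timepoint labels.
#' @return data.frame with a `timepoint` column and one column per
#'   parameter; attribute `"ranks"` holds the planted rank matrix and
#'   attribute `"reference"` the reference series (ranks 1..n).
#' @export
generate_clinical <- function(n_timepoints, targets, seed = 1,
                              timepoints = NULL) {
  stopifnot(n_timepoints >= 4)
  n <- n_timepoints
  if (is.null(timepoints)) timepoints <- paste0("t", seq_len(n))
  out <- data.frame(timepoint = timepoints, stringsAsFactors = FALSE)
  ranks <- matrix(NA_integer_, nrow = n, ncol = length(targets),
                  dimnames = list(NULL, names(targets)))
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    rho <- tg$rho
    stopifnot(rho >= -1, rho <= 1)
    S <- (1 - abs(rho)) * n * (n^2 - 1) / 6
    S_int <- round(S / 2) * 2 # sum(d^2) of a permutation is always even
    res <- .perm_with_S(n, S_int, seed + 1000 * k)
    got <- .rho_from_ranks(seq_len(n), res$perm)
    if (abs(S_int - S) > 1e-9 || res$S != S_int)
      warning(sprintf(
        "target rho %.6f for %s not attainable at n = %d; using %.6f",
        rho, names(targets)[k], n,
        if (rho < 0) -got else got))
    rk <- if (rho < 0) (n + 1L) - res$perm else res$perm
    ranks[, k] <- rk
    lo <- tg$range[1]; hi <- tg$range[2]
    incr <- with_seed(seed + 2000 * k, stats::runif(n, 0.5, 1.5))
    vals <- lo + (hi - lo) * cumsum(incr) / sum(incr)
    out[[names(targets)[k]]] <- vals[rk]
  }
  attr(out, "ranks") <- ranks
  attr(out, "reference") <- seq_len(n)
  out
}

#' Generate a complete synthetic scenario
#'
#' Produces strain models, an abundance time series, a fixed diet, planted
#' clinical series and the analytic truth needed to check every pipeline
#' stage. Regenerating with the same seed reproduces the bundle exactly.
#'
#' Scenario structure (strain roles by priority as `n_strains` grows):
#' a rising folate producer (always), a falling ketoacid producer
#' (n >= 3), a substrate competitor carrying a blocked product (n >= 4), a
#' strain pinned below the abundance cutoff (n >= 5), and inert fillers.
#'
#' @param n_strains number of strains (>= 2; default 10).
#' @param n_timepoints number of timepoints (>= 4; default 7, labelled as
#'   intervention days 0, 15, 30, 45, 60, 75, 105).
#' @param seed integer seed.
#' @param planted_rho target Spearman correlation between BMI and the
#'   rising producer's secretion ranks (default -25/28 = -0.892857..., the
#'   rho realised by a squared rank distance of 6 at n = 7).
#' @param config a [community_config()].
#' @return a `scenario_bundle`: list with `models`, `profiles` (list of
#'   raw [abundance_profile()]s), `diet`, `clinical`, `subsystems`,
#'   `truth` (producers, planted pairs, analytic expectations), `seed`,
#'   `config`, `timepoints`.
#' @export
generate_scenario <- function(n_strains = 10, n_timepoints = 7, seed = 1,
                              planted_rho = -25 / 28,
                              config = community_config()) {
  if (n_strains < 2) stop("need at least 2 strains")
  stopifnot(n_timepoints >= 4)
  n <- n_timepoints
  timepoints <- if (n == 7) paste0("day", c(0, 15, 30, 45, 60, 75, 105))
                else paste0("t", seq_len(n))

  subsystems <- c(fol = "vitamin and cofactor metabolism",
                  "3mop" = "amino acid metabolism",
                  ac = "central metabolism",
                  aa = "amino acid metabolism",
                  fib = "carbohydrate metabolism",
                  pept = "carbohydrate metabolism",
                  xin = "other")

  specs <- list(strain_template_spec(
    "str_folA", substrates = "fib", products = c(fol = 0.5),
    subsystems = subsystems))
  if (n_strains >= 3)
    specs <- c(specs, list(strain_template_spec(
      "str_mopB", substrates = "pept", products = c("3mop" = 0.8),
      subsystems = subsystems)))
  if (n_strains >= 4)
    specs <- c(specs, list(strain_template_spec(
      "str_acC", substrates = "fib", products = c(ac = 0.6, xin = 0),
      subsystems = subsystems)))
  if (n_strains >= 5)
    specs <- c(specs, list(strain_template_spec(
      "str_sub", subsystems = subsystems)))
  n_fill <- n_strains - length(specs)
  for (i in seq_len(n_fill))
    specs <- c(specs, list(strain_template_spec(
      sprintf("str_fill%02d", i), subsystems = subsystems)))
  models <- lapply(specs, generate_strain_template)
  strain_ids <- vapply(models, `[[`, "", "id")

  # abundance series; the sub-cutoff strain is constant so that the
  # retained mass (and hence the renormalisation factor) is identical at
  # every timepoint, preserving planted ranks exactly
  a_fol <- seq(0.02, 0.30, length.out = n)
  ab <- matrix(0, nrow = n, ncol = n_strains,
               dimnames = list(timepoints, strain_ids))
  ab[, "str_folA"] <- a_fol
  if ("str_mopB" %in% strain_ids) ab[, "str_mopB"] <- rev(a_fol)
  if ("str_acC" %in% strain_ids)
    ab[, "str_acC"] <- 0.10 + with_seed(seed + 11,
                                        stats::runif(n, -0.02, 0.02))
  if ("str_sub" %in% strain_ids) ab[, "str_sub"] <- 0.0005
  fill <- grep("^str_fill", strain_ids, value = TRUE)
  if (length(fill) >= 2) {
    # a dominant riser: its growth skews the community and makes the
    # Shannon diversity fall over the intervention, as observed in
    # high-fiber intervention cohorts
    ab[, fill[1]] <- seq(0.18, 0.36, length.out = n)
    fill <- fill[-1]
  }
  if (length(fill) > 0) {
    w <- with_seed(seed + 12,
                   matrix(stats::rgamma(n * length(fill), shape = 5),
                          nrow = n))
    w <- w / rowSums(w)
    rem <- 1 - rowSums(ab)
    ab[, fill] <- w * rem
  } else {
    # give any remainder to the last strain
    ab[, n_strains] <- ab[, n_strains] + (1 - rowSums(ab))
  }
  stopifnot(all(abs(rowSums(ab) - 1) < 1e-12), all(ab >= 0))
  profiles <- lapply(seq_len(n), function(i)
    abundance_profile(timepoints[i], ab[i, ]))
  names(profiles) <- timepoints

  diet <- c(fib = 300, pept = 300, aa = 100, ac = 5)

  clinical <- generate_clinical(
    n, targets = list(
      BMI = list(rho = planted_rho, range = c(40.2, 49.47)),
      leptin = list(rho = planted_rho, range = c(34.5, 63.8)),
      adiponectin = list(rho = -planted_rho, range = c(2.17, 5.39))),
    seed = seed, timepoints = timepoints)

  producers <- c(fol = "str_folA")
  if ("str_mopB" %in% strain_ids) producers["3mop"] <- "str_mopB"
  if ("str_acC" %in% strain_ids) producers["ac"] <- "str_acC"

  rk <- attr(clinical, "ranks")
  achieved <- apply(rk, 2, function(r) .rho_from_ranks(seq_len(n), r))

  bundle <- structure(list(
    models = models, profiles = profiles, diet = diet, clinical = clinical,
    subsystems = subsystems, timepoints = timepoints, seed = seed,
    config = config,
    truth = list(producers = producers,
                 planted_pairs = data.frame(
                   clinical = c("BMI", "leptin", "adiponectin"),
                   metabolite = "fol",
                   rho = unname(achieved[c("BMI", "leptin", "adiponectin")])),
                 abundance = ab)),
    class = "scenario_bundle")
  bundle$truth$net_secretion <- analytic_net_secretion(bundle)
  bundle
}

#' Analytic net-secretion oracle for chain-template scenarios
#'
#' Closed form for the expected net secretion of every scenario metabolite
#' under the coupled community FVA:
#' for a product of yield y from a substrate supplied at S by a producer of
#' filtered abundance a, net secretion is
#' `min(y * min(S, cap), cap)` with the coupling cap
#' `cap = c * a * v_max + u` (v_max the community biomass upper bound; the
#' slack u enters because the coupling inequality allows |v| up to
#' c*v_bio + u). Pure diet metabolites net to zero (the fecal maximum and
#' the obligatory diet minimum cancel) except the biomass substrate, whose
#' obligatory growth consumption at the FVA objective fraction gamma makes
#' its net secretion `-(sum_k a_k demand_k) * gamma * v_max`. Blocked
#' products net to zero.
#'
#' @param bundle a `scenario_bundle` from [generate_scenario()].
#' @return data.frame sample x metabolite of expected net secretion
#'   (mmol/day).
#' @export
analytic_net_secretion <- function(bundle) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  cfg <- bundle$config
  vmax <- cfg$biomass_bounds[2]
  specs <- lapply(bundle$models, function(m) m$meta$template)
  names(specs) <- vapply(bundle$models, `[[`, "", "id")
  for (sp in specs)
    if (!inherits(sp, "strain_template_spec"))
      stop("no closed form for non-chain models; use the brute-force LP oracle")

  mets <- sort(unique(unlist(c(
    lapply(specs, function(s) c(s$substrates, names(s$products),
                                s$biomass_substrate))))))
  out <- expand.grid(sample = bundle$timepoints, metabolite = mets,
                     stringsAsFactors = FALSE)
  out$net_secretion <- 0

  for (tp in bundle$timepoints) {
    prof <- filter_and_renormalize(bundle$profiles[[tp]], cfg$cutoff)
    a <- prof$abundances
    for (s in names(a)) {
      sp <- specs[[s]]
      if (length(sp$products) == 0) next
      cap <- cfg$coupling_c * a[[s]] * vmax + cfg$coupling_u
      supply <- unname(bundle$diet[sp$substrates[1]])
      if (is.na(supply)) supply <- 0
      for (p in names(sp$products)) {
        y <- sp$products[[p]]
        val <- if (y > 0) min(y * min(supply, cap), cap) else 0
        i <- out$sample == tp & out$metabolite == p
        out$net_secretion[i] <- out$net_secretion[i] + val
      }
    }
    # biomass substrates: obligatory growth consumption per substrate
    bm <- vapply(specs[names(a)], `[[`, "", "biomass_substrate")
    dk <- vapply(specs[names(a)], `[[`, 0, "biomass_demand")
    for (b in unique(bm)) {
      demand_b <- sum(unname(a)[bm == b] * dk[bm == b])
      i <- out$sample == tp & out$metabolite == b
      out$net_secretion[i] <- -demand_b * cfg$gamma * vmax
    }
  }
  out
}
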