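#' Community model construction
#'
#' Turns per-strain metabolic models plus a filtered abundance profile into
#' one multi-compartment community model. Each strain keeps its own
#' compartments; a shared lumen pool `[u]` connects the strains, fed by a
#' diet layer `[d]` and drained by a fecal layer `[fe]`. An
#' abundance-weighted community biomass reaction ties strain growth to the
#' community growth rate, and flux-coupling constraints tie every strain
#' reaction to that strain's biomass so organisms cannot metabolise without
#' growing.
#'
#' @name community
NULL

#' Per-sample abundance profile
#'
#' @param sample_id sample token (e.g. a day label).
#' @param abundances named numeric vector, strain id -> relative abundance
#'   fraction in \[0, 1\].
#' @param filtered whether the cutoff filter has been applied.
#' @param cutoff the cutoff used (NA before filtering).
#' @export
abundance_profile <- function(sample_id, abundances, filtered = FALSE,
                              cutoff = NA_real_) {
  if (any(abundances < 0)) stop("negative abundance in sample ", sample_id)
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stop("abundances must be named by strain id")
  abundances <- abundances[order(names(abundances), method = "radix")]
  structure(list(sample_id = sample_id, abundances = abundances,
                 filtered = filtered, cutoff = cutoff),
            class = "abundance_profile")
}

#' Abundance cutoff filter with renormalisation
#'
#' Drops strains below the relative-abundance cutoff (default 0.1%, applied
#' to the raw relative abundances before renormalisation; strains exactly at
#' the cutoff are retained) and rescales the remainder to sum to 1.
#'
#' @param profile an [abundance_profile()].
#' @param cutoff abundance fraction in \[0, 1) (default 0.001).
#' @return the filtered, renormalised profile; removals are reported via
#'   `message()`.
#' @export
filter_and_renormalize <- function(profile, cutoff = 0.001) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must be in [0, 1)")
  a <- profile$abundances
  if (any(a < 0)) stop("negative abundance in sample ", profile$sample_id)
  keep <- a >= cutoff
  if (!any(keep))
    stop("empty community: all strains below cutoff in sample ",
         profile$sample_id)
  dropped <- names(a)[!keep]
  if (length(dropped) > 0)
    message("sample ", profile$sample_id, ": dropped ", length(dropped),
            " strain(s) below cutoff: ", paste(dropped, collapse = ", "))
  a <- a[keep]
  if (abs(sum(a) - 1) > 1e-12) a <- a / sum(a) # exact idempotence
  abundance_profile(profile$sample_id, a, filtered = TRUE, cutoff = cutoff)
}

#' Community run configuration
#'
#' Bundles the tunable parameters of community construction and simulation.
#' The values mirror the common community-modelling toolbox conventions
#' and are all overridable per run.
#'
#' @param cutoff abundance cutoff fraction (default 0.001, i.e. 0.1%).
#' @param coupling_c coupling factor c (default 400).
#' @param coupling_u coupling slack u (default 0.01).
#' @param biomass_bounds community biomass flux bounds in 1/day
#'   (default c(0.4, 1)).
#' @param gamma FVA objective fraction (default 0.9999).
#' @param big_bound bound used for otherwise-unconstrained community-layer
#'   transports and fecal exchanges (mmol/day).
#' @param r_thresh,p_thresh correlation-network thresholds (|rho| > 0.7,
#'   FDR-adjusted p < 0.1).
#' @param supplement_eps trace diet flux for supplemented micronutrients
#'   (mmol/day).
#' @export
community_config <- function(cutoff = 0.001, coupling_c = 400,
                             coupling_u = 0.01, biomass_bounds = c(0.4, 1),
                             gamma = 0.9999, big_bound = 10000,
                             r_thresh = 0.7, p_thresh = 0.1,
                             supplement_eps = 0.1) {
  stopifnot(cutoff >= 0, cutoff < 1, coupling_c >= 0, coupling_u >= 0,
            length(biomass_bounds) == 2, biomass_bounds[1] <= biomass_bounds[2],
            gamma >= 0, gamma <= 1, r_thresh >= 0, r_thresh <= 1,
            p_thresh > 0, p_thresh <= 1, supplement_eps >= 0)
  structure(list(cutoff = cutoff, coupling_c = coupling_c,
                 coupling_u = coupling_u, biomass_bounds = biomass_bounds,
                 gamma = gamma, big_bound = big_bound, r_thresh = r_thresh,
                 p_thresh = p_thresh, supplement_eps = supplement_eps),
            class = "community_config")
}

#' Tag a strain model for community joining
#'
#' Prefixes all reaction ids with the strain id, renames the strain's
#' compartments to strain-private tags, removes the strain-level exchange
#' reactions, and replaces each extracellular exchange by an IEX transport
#' into the shared lumen `[u]` (positive IEX flux = secretion into the
#' lumen). The biomass sink is removed as well: in the community, strain
#' biomass is drawn exclusively by the community biomass reaction.
#'
#' @param model a single-strain [metabolic_model()] with exchange reactions
#'   and a `meta$biomass` reaction id.
#' @param strain strain id used as prefix.
#' @param extracellular tag of the strain's extracellular compartment
#'   (default `"e"`).
#' @return the tagged model; `meta$strain`, `meta$biomass`,
#'   `meta$biomass_met` and `meta$iex` describe the join points.
#' @export
tag_strain_model <- function(model, strain, extracellular = "e") {
  validate_model(model)
  if (!is.null(model$meta$strain))
    stop("model ", model$id, " is already tagged (strain ",
         model$meta$strain, ")")
  if (is.null(model$meta$biomass))
    stop("model ", model$id, " has no designated biomass reaction")
  pre <- paste0(strain, "_")
  if (any(startsWith(reaction_ids(model), pre)))
    stop("prefix collision: reaction ids in ", model$id,
         " already start with ", pre)
  comp_map <- setNames(paste0(strain, "_", model$compartments),
                       model$compartments)

  mt <- model$metabolites
  mt$compartment <- unname(comp_map[mt$compartment])
  mt$key <- met_key(mt$id, mt$compartment)

  iex <- character(0)
  lumen_new <- list()
  rxns <- list()
  for (r in model$reactions) {
    keys <- .split_key(names(r$stoich))
    new_names <- met_key(keys$id, unname(comp_map[keys$compartment]))
    if (r$kind == "exchange") {
      base <- keys$id[1]
      if (keys$compartment[1] == extracellular) {
        # replace with an IEX transport into the lumen
        iid <- sprintf("%s_IEX_%s[u]tr", strain, base)
        st <- setNames(c(-1, 1), c(new_names[1], met_key(base, "u")))
        rxns[[length(rxns) + 1L]] <-
          reaction(iid, st, lb = -1000, ub = 1000, kind = "transport")
        iex[base] <- iid
        i <- match(names(r$stoich)[1], model$metabolites$key)
        lumen_new[[base]] <- data.frame(
          id = base, compartment = "u", name = model$metabolites$name[i],
          subsystem = model$metabolites$subsystem[i],
          key = met_key(base, "u"), stringsAsFactors = FALSE)
      }
      # exchanges (incl. the biomass sink) are dropped: the community
      # layers replace them
      next
    }
    rxns[[length(rxns) + 1L]] <-
      reaction(paste0(pre, r$id), setNames(r$stoich, new_names),
               lb = r$lb, ub = r$ub, kind = r$kind)
  }
  mt <- rbind(mt, do.call(rbind, c(lumen_new, list(NULL))))
  meta <- model$meta
  meta$strain <- strain
  meta$biomass <- paste0(pre, meta$biomass)
  bio_i <- match(meta$biomass, vapply(rxns, `[[`, "", "id"))
  if (is.na(bio_i))
    stop("model ", model$id, ": biomass reaction ", model$meta$biomass,
         " not found among non-exchange reactions")
  bio_products <- names(rxns[[bio_i]]$stoich)[rxns[[bio_i]]$stoich > 0]
  if (length(bio_products) != 1L)
    stop("model ", model$id,
         ": biomass reaction must produce exactly one biomass metabolite")
  meta$biomass_met <- bio_products
  meta$iex <- iex
  metabolic_model(strain, c(unname(comp_map), "u"), mt, rxns,
                  objective = numeric(0), meta = meta)
}

#' Assemble a community model
#'
#' Joins tagged strain models through a shared lumen, adds the diet/fecal
#' exchange layers for every lumen metabolite, creates the
#' abundance-weighted community biomass reaction, and couples every strain
#' reaction to its own biomass flux. The objective is set to the fecal
#' export of community biomass.
#'
#' @param models list of single-strain [metabolic_model()]s (matched to
#'   strains by model `id`).
#' @param profile a filtered [abundance_profile()].
#' @param config a [community_config()].
#' @return a `community_model` (a [metabolic_model()] subclass with a
#'   `strain_registry`).
#' @export
assemble_community <- function(models, profile, config = community_config()) {
  stopifnot(inherits(profile, "abundance_profile"))
  if (!isTRUE(profile$filtered))
    stop("profile must be filtered before assembly; see filter_and_renormalize()")
  ids <- vapply(models, `[[`, "", "id")
  strains <- names(profile$abundances)
  missing <- setdiff(strains, ids)
  if (length(missing) > 0)
    stop("no model supplied for retained strain: ",
         paste(missing, collapse = ", "))

  tagged <- lapply(strains, function(s)
    tag_strain_model(models[[match(s, ids)]], s))
  names(tagged) <- strains

  mets <- do.call(rbind, lapply(tagged, `[[`, "metabolites"))
  mets <- mets[!duplicated(mets$key), , drop = FALSE]
  rxns <- do.call(c, lapply(tagged, `[[`, "reactions"))
  comps <- unique(do.call(c, lapply(tagged, `[[`, "compartments")))
  lumen <- sort(unique(do.call(c, lapply(tagged, function(m)
    names(m$meta$iex)))))

  big <- config$big_bound
  extra_mets <- list(); extra_rxns <- list()
  for (m in lumen) {
    i <- match(met_key(m, "u"), mets$key)
    extra_mets[[length(extra_mets) + 1L]] <- data.frame(
      id = m, compartment = c("d", "fe"), name = mets$name[i],
      subsystem = mets$subsystem[i],
      key = met_key(m, c("d", "fe")), stringsAsFactors = FALSE)
    extra_rxns <- c(extra_rxns, list(
      reaction(sprintf("EX_%s[d]", m), setNames(-1, met_key(m, "d")),
               lb = 0, ub = 0, kind = "exchange"),
      reaction(sprintf("DUt_%s", m),
               setNames(c(-1, 1), met_key(m, c("d", "u"))),
               lb = 0, ub = big, kind = "transport"),
      reaction(sprintf("UFEt_%s", m),
               setNames(c(-1, 1), met_key(m, c("u", "fe"))),
               lb = 0, ub = big, kind = "transport"),
      reaction(sprintf("EX_%s[fe]", m), setNames(-1, met_key(m, "fe")),
               lb = 0, ub = big, kind = "exchange")))
  }

  # abundance-weighted community biomass
  a <- profile$abundances
  bio_st <- setNames(-as.double(a),
                     vapply(tagged, function(m) m$meta$biomass_met, ""))
  bio_st <- c(bio_st, setNames(1, met_key("microbeBiomass", "u")))
  extra_mets[[length(extra_mets) + 1L]] <- data.frame(
    id = "microbeBiomass", compartment = c("u", "fe"),
    name = "community biomass", subsystem = "other",
    key = met_key("microbeBiomass", c("u", "fe")), stringsAsFactors = FALSE)
  extra_rxns <- c(extra_rxns, list(
    reaction("communityBiomass", bio_st, lb = 0, ub = big, kind = "biomass"),
    reaction("UFEt_microbeBiomass",
             setNames(c(-1, 1), met_key("microbeBiomass", c("u", "fe"))),
             lb = 0, ub = big, kind = "transport"),
    reaction("EX_microbeBiomass[fe]",
             setNames(-1, met_key("microbeBiomass", "fe")),
             lb = config$biomass_bounds[1], ub = config$biomass_bounds[2],
             kind = "exchange")))

  mets <- rbind(mets, do.call(rbind, extra_mets))
  rxns <- c(rxns, extra_rxns)
  comps <- unique(c(comps, "u", "d", "fe"))

  registry <- lapply(strains, function(s) {
    tm <- tagged[[s]]
    list(abundance = unname(a[s]),
         compartments = setdiff(tm$compartments, "u"),
         reactions = reaction_ids(tm),
         biomass = tm$meta$biomass,
         biomass_met = tm$meta$biomass_met,
         iex = tm$meta$iex)
  })
  names(registry) <- strains

  cm <- metabolic_model(
    paste0("community_", profile$sample_id), comps, mets, rxns,
    objective = setNames(1, "EX_microbeBiomass[fe]"),
    meta = list(sample_id = profile$sample_id, lumen = lumen,
                units = "community exchange layer in mmol/day",
                config = config))
  groups <- lapply(registry, function(g)
    list(reactions = setdiff(g$reactions, g$biomass), biomass = g$biomass))
  cm <- add_flux_coupling(cm, groups, c = config$coupling_c,
                          u = config$coupling_u)
  cm$strain_registry <- registry
  class(cm) <- c("community_model", class(cm))
  validate_model(cm)
  cm
}

.diet_base_ids <- function(nms) {
  sub("^EX_(.*)\\[d\\]$", "\\1", nms)
}

#' Apply a diet to a community model
#'
#' Opens each diet exchange `EX_m[d]` to allow uptake of at most the diet
#' flux (lb = -flux, ub = 0, in mmol/day); lumen metabolites absent from the
#' diet stay closed unless the supplement policy opens them at a trace flux.
#'
#' @param community a `community_model` from [assemble_community()].
#' @param diet named nonnegative numeric vector of flux magnitudes
#'   (mmol/day); names are metabolite ids or `"EX_m[d]"` reaction ids.
#' @param supplement optional `list(metabolites = <ids>, eps = <mmol/day>)`
#'   opening listed metabolites absent from the diet at the trace flux.
#' @return the constrained community model; skipped diet entries (no lumen
#'   counterpart) are reported in a warning and counted in
#'   `meta$diet_skipped`.
#' @export
apply_diet <- function(community, diet, supplement = NULL) {
  stopifnot(inherits(community, "community_model"))
  if (any(diet < 0)) stop("diet fluxes must be nonnegative magnitudes")
  base <- .diet_base_ids(names(diet))
  lumen <- community$meta$lumen
  known <- base %in% lumen
  if (any(!known))
    warning("skipped ", sum(!known),
            " diet metabolite(s) with no lumen counterpart: ",
            paste(base[!known], collapse = ", "))
  for (i in which(known)) {
    community <- set_bounds(community, sprintf("EX_%s[d]", base[i]),
                            lb = -as.double(diet[i]), ub = 0)
  }
  if (!is.null(supplement)) {
    eps <- supplement$eps
    if (is.null(eps) || eps < 0) stop("supplement eps must be nonnegative")
    extra <- setdiff(intersect(supplement$metabolites, lumen), base[known])
    for (m in extra)
      community <- set_bounds(community, sprintf("EX_%s[d]", m),
                              lb = -eps, ub = 0)
  }
  community$meta$diet <- setNames(as.double(diet[known]), base[known])
  community$meta$diet_skipped <- sum(!known)
  community
}
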