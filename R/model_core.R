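#' @importFrom stats setNames
#' @importFrom utils head
NULL

#' Metabolite key
#'
#' Metabolites are identified by a short VMH-style token plus a compartment
#' tag; the pair is rendered as `"id[compartment]"` throughout.
#' @param id metabolite token (e.g. `"fol"`, `"3mop"`).
#' @param compartment compartment tag (e.g. `"c"`, `"e"`, `"u"`).
#' @export
met_key <- function(id, compartment) sprintf("%s[%s]", id, compartment)

.split_key <- function(key) {
  m <- regmatches(key, regexec("^(.*)\\[([^]\\[]+)\\]$", key))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed metabolite key: ", key[bad][1])
  list(id = vapply(m, `[`, "", 2L), compartment = vapply(m, `[`, "", 3L))
}

#' Construct a reaction
#'
#' @param id reaction token.
#' @param stoich named numeric vector; names are metabolite keys
#'   (`"id[comp]"`), values the stoichiometric coefficients (negative =
#'   consumed). All coefficients must be nonzero.
#' @param lb,ub flux bounds (strain models in mmol/gDW/h; community exchange
#'   layers in mmol/day, recorded in the model's unit metadata).
#' @param kind one of `"internal"`, `"exchange"`, `"transport"`, `"biomass"`.
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000,
                     kind = c("internal", "exchange", "transport", "biomass")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction ", id, ": stoichiometry must be a named vector")
  if (any(stoich == 0))
    stop("reaction ", id, ": zero stoichiometric coefficient")
  if (anyDuplicated(names(stoich)))
    stop("reaction ", id, ": duplicated metabolite in stoichiometry")
  structure(list(id = id, stoich = stoich, lb = as.double(lb),
                 ub = as.double(ub), kind = kind), class = "fc_reaction")
}

#' Construct a metabolite table
#'
#' @param id,compartment,name,subsystem vectors (recycled) describing the
#'   metabolites; `subsystem` uses the field's category labels
#'   (e.g. "amino acid metabolism", "vitamin and cofactor metabolism").
#' @return data.frame with one row per metabolite and a `key` column.
#' @export
metabolite_table <- function(id, compartment, name = id, subsystem = "other") {
  if (length(id) == 0L)
    return(data.frame(id = character(0), compartment = character(0),
                      name = character(0), subsystem = character(0),
                      key = character(0), stringsAsFactors = FALSE))
  df <- data.frame(id = id, compartment = compartment, name = name,
                   subsystem = subsystem, stringsAsFactors = FALSE)
  df$key <- met_key(df$id, df$compartment)
  df
}

#' Construct a metabolic model
#'
#' A stoichiometric model for one strain or a whole community: a metabolite
#' registry, bounded reactions, a linear objective and optional flux-coupling
#' constraints. Metabolites and reactions are kept in lexicographic order so
#' all derived outputs are byte-stable.
#'
#' @param id model token.
#' @param compartments character vector of compartment tags.
#' @param metabolites data.frame from [metabolite_table()].
#' @param reactions list of [reaction()] objects.
#' @param objective named numeric vector (reaction id -> coefficient).
#' @param couplings data.frame with columns `reaction`, `anchor`, `c`, `u`
#'   (see [add_flux_coupling()]), or NULL.
#' @param meta free-form metadata list (e.g. unit system).
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            objective = numeric(0), couplings = NULL,
                            meta = list()) {
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  if (anyDuplicated(metabolites$key))
    stop("duplicate metabolites: ",
         paste(unique(metabolites$key[duplicated(metabolites$key)]),
               collapse = ", "))
  ord <- order(metabolites$key, method = "radix")
  metabolites <- metabolites[ord, , drop = FALSE]
  rownames(metabolites) <- NULL
  reactions <- reactions[order(rxn_ids, method = "radix")]
  if (is.null(couplings))
    couplings <- data.frame(reaction = character(0), anchor = character(0),
                            c = numeric(0), u = numeric(0))
  m <- structure(list(id = id, compartments = sort(unique(compartments)),
                      metabolites = metabolites, reactions = reactions,
                      objective = objective, couplings = couplings,
                      meta = meta),
                 class = "metabolic_model")
  m
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<%s> %s: %d metabolites, %d reactions, %d couplings\n",
              class(x)[1], x$id, nrow(x$metabolites), length(x$reactions),
              nrow(x$couplings)))
  invisible(x)
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

reaction_table <- function(model) {
  data.frame(id = reaction_ids(model),
             lb = vapply(model$reactions, `[[`, 0, "lb"),
             ub = vapply(model$reactions, `[[`, 0, "ub"),
             kind = vapply(model$reactions, `[[`, "", "kind"),
             stringsAsFactors = FALSE)
}

#' Validate model invariants
#'
#' Checks structural invariants: unique ids, declared compartments, nonzero
#' stoichiometry referencing declared metabolites, lb <= ub, exchange
#' reactions with a single -1 entry, objective and coupling references.
#' Called by the solvers before any LP is set up.
#'
#' @param model a [metabolic_model()].
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mt <- model$metabolites
  if (nrow(mt) > 0 && !all(mt$compartment %in% model$compartments))
    stop("metabolite in undeclared compartment: ",
         mt$key[!mt$compartment %in% model$compartments][1])
  rids <- reaction_ids(model)
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoich), mt$key)
    if (length(missing) > 0)
      stop("reaction ", r$id, " references undeclared metabolite: ",
           missing[1])
    if (r$lb > r$ub)
      stop("reaction ", r$id, ": inverted bounds (lb > ub)")
    if (r$kind == "exchange" &&
        !(length(r$stoich) == 1L && r$stoich[[1]] == -1))
      stop("exchange reaction ", r$id,
           " must have exactly one metabolite with coefficient -1")
  }
  if (length(model$objective) > 0 &&
      !all(names(model$objective) %in% rids))
    stop("objective references unknown reaction: ",
         setdiff(names(model$objective), rids)[1])
  cp <- model$couplings
  if (nrow(cp) > 0) {
    if (!all(cp$reaction %in% rids))
      stop("coupling references unknown reaction: ",
           setdiff(cp$reaction, rids)[1])
    if (!all(cp$anchor %in% rids))
      stop("coupling anchored to nonexistent reaction: ",
           setdiff(cp$anchor, rids)[1])
    if (any(cp$c < 0) || any(cp$u < 0))
      stop("coupling parameters c and u must be nonnegative")
  }
  invisible(model)
}

#' Stoichiometric matrix
#'
#' Sparse matrix with one row per metabolite (lexicographic by key) and one
#' column per reaction (lexicographic by id); entry (i, j) is the coefficient
#' of metabolite i in reaction j.
#'
#' @param model a [metabolic_model()].
#' @return a [Matrix::sparseMatrix()] with dimnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  keys <- model$metabolites$key
  rids <- reaction_ids(model)
  triplets <- lapply(model$reactions, function(r) {
    data.frame(met = names(r$stoich), rxn = r$id, coef = as.double(r$stoich),
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, c(triplets,
                         list(data.frame(met = character(0), rxn = character(0),
                                         coef = numeric(0)))))
  Matrix::sparseMatrix(i = match(tr$met, keys), j = match(tr$rxn, rids),
                       x = tr$coef, dims = c(length(keys), length(rids)),
                       dimnames = list(keys, rids))
}

# Translate a model into bounded-equality LP data. Coupling constraints
#   v_j - c v_a <= u  and  -v_j - c v_a <= u
# become equality rows with nonnegative slack columns.
model_lp_data <- function(model) {
  S <- as.matrix(build_stoichiometric_matrix(model))
  rt <- reaction_table(model)
  n <- nrow(rt)
  cp <- model$couplings
  ncp <- nrow(cp)
  A <- rbind(S, matrix(0, nrow = 2 * ncp, ncol = n))
  b <- c(rep(0, nrow(S)), rep(0, 2 * ncp))
  if (ncp > 0) {
    slack <- matrix(0, nrow = nrow(A), ncol = 2 * ncp)
    for (k in seq_len(ncp)) {
      j <- match(cp$reaction[k], rt$id)
      a <- match(cp$anchor[k], rt$id)
      r1 <- nrow(S) + 2 * k - 1
      r2 <- nrow(S) + 2 * k
      A[r1, j] <- 1;  A[r1, a] <- -cp$c[k]
      A[r2, j] <- -1; A[r2, a] <- -cp$c[k]
      slack[r1, 2 * k - 1] <- 1
      slack[r2, 2 * k] <- 1
      b[r1] <- cp$u[k]; b[r2] <- cp$u[k]
    }
    A <- cbind(A, slack)
  }
  lb <- c(rt$lb, rep(0, 2 * ncp))
  ub <- c(rt$ub, rep(Inf, 2 * ncp))
  obj <- numeric(ncol(A))
  if (length(model$objective) > 0)
    obj[match(names(model$objective), rt$id)] <- as.double(model$objective)
  list(A = A, b = b, lb = lb, ub = ub, obj = obj,
       rxn_ids = rt$id, n_rxn = n)
}

#' Flux balance analysis
#'
#' Maximises (or minimises) the model's linear objective subject to
#' steady-state mass balance S v = 0, flux bounds, and any flux-coupling
#' constraints.
#'
#' @param model a validated [metabolic_model()] with a non-empty objective.
#' @param sense `"max"` (default) or `"min"`.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective_value`, and `fluxes` (named by reaction id).
#' @export
solve_fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  validate_model(model)
  if (length(model$reactions) == 0L) stop("model has no reactions")
  if (length(model$objective) == 0L) stop("model has an empty objective")
  lpd <- model_lp_data(model)
  sol <- lp_solve(lpd$A, lpd$b, lpd$obj, lpd$lb, lpd$ub, sense = sense)
  fluxes <- NULL
  if (sol$status == "optimal")
    fluxes <- setNames(sol$x[seq_len(lpd$n_rxn)], lpd$rxn_ids)
  list(status = sol$status, objective_value = sol$objective, fluxes = fluxes)
}

#' Flux variability analysis
#'
#' Per-reaction LP minimum and maximum of flux subject to mass balance,
#' bounds and couplings; when `gamma > 0` the model's objective is first
#' maximised and constrained to stay at or above `gamma` times its optimum.
#' Successive LPs share the feasible region and are warm-started from the
#' previous optimal basis.
#'
#' @param model a [metabolic_model()].
#' @param reaction_ids reactions to range over (default: all exchange
#'   reactions).
#' @param gamma objective fraction in \[0, 1\] (default 0; community runs
#'   use the value in their [community_config()]).
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
run_fva <- function(model, reaction_ids = NULL, gamma = 0) {
  validate_model(model)
  stopifnot(gamma >= 0, gamma <= 1)
  rt <- reaction_table(model)
  if (is.null(reaction_ids)) reaction_ids <- rt$id[rt$kind == "exchange"]
  if (length(reaction_ids) == 0L) {
    warning("no reactions to range over; returning empty FVA table")
    return(data.frame(reaction = character(0), min = numeric(0),
                      max = numeric(0)))
  }
  unknown <- setdiff(reaction_ids, rt$id)
  if (length(unknown) > 0) stop("unknown reaction id: ", unknown[1])
  lpd <- model_lp_data(model)
  A <- lpd$A; b <- lpd$b; lb <- lpd$lb; ub <- lpd$ub
  if (gamma > 0) {
    if (all(lpd$obj == 0)) stop("gamma > 0 requires a non-empty objective")
    base <- lp_solve(A, b, lpd$obj, lb, ub, sense = "max")
    if (base$status != "optimal")
      stop("base model is ", base$status,
           ": check diet supply against the community biomass bounds")
    # objective >= gamma * optimum, as an equality with surplus column
    A <- rbind(A, c(lpd$obj, numeric(ncol(A) - length(lpd$obj))))
    A <- cbind(A, c(rep(0, nrow(A) - 1), -1))
    b <- c(b, gamma * base$objective)
    lb <- c(lb, 0); ub <- c(ub, Inf)
  }
  prob <- lp_prepare(A, b, lb, ub)
  state <- NULL
  res <- data.frame(reaction = sort(reaction_ids), min = NA_real_,
                    max = NA_real_)
  for (i in seq_len(nrow(res))) {
    j <- match(res$reaction[i], lpd$rxn_ids)
    obj <- numeric(ncol(A)); obj[j] <- 1
    for (sense in c("min", "max")) {
      sol <- lp_run(prob, obj, sense = sense, start = state)
      if (sol$status != "optimal")
        stop("FVA ", sense, " for reaction ", res$reaction[i],
             " ended with status ", sol$status)
      res[[sense]][i] <- sol$objective
      state <- sol$state
    }
  }
  # numerical guard: a tight LP pair can cross by roundoff
  swap <- res$min > res$max
  if (any(swap)) {
    tmp <- res$min[swap]; res$min[swap] <- res$max[swap]; res$max[swap] <- tmp
  }
  res
}

#' Add flux-coupling constraints
#'
#' Ties each listed reaction's flux magnitude to an anchor (biomass) flux:
#' |v_coupled| <= c * v_anchor + u. This is the standard community-modelling
#' device that silences reactions of strains whose biomass flux is zero.
#'
#' @param model a [metabolic_model()].
#' @param strain_groups named list; each element is
#'   `list(reactions = <ids>, biomass = <anchor id>)`.
#' @param c coupling factor (default 400).
#' @param u coupling slack (default 0.01).
#' @return the model with the extra coupling rows.
#' @export
add_flux_coupling <- function(model, strain_groups, c = 400, u = 0.01) {
  if (c < 0 || u < 0) stop("coupling parameters c and u must be nonnegative")
  rids <- reaction_ids(model)
  add <- lapply(names(strain_groups), function(s) {
    g <- strain_groups[[s]]
    if (!g$biomass %in% rids)
      stop("strain ", s, ": biomass anchor ", g$biomass, " not in model")
    bad <- setdiff(g$reactions, rids)
    if (length(bad) > 0)
      stop("strain ", s, ": coupled reaction not in model: ", bad[1])
    data.frame(reaction = setdiff(g$reactions, g$biomass), anchor = g$biomass,
               c = c, u = u, stringsAsFactors = FALSE)
  })
  model$couplings <- rbind(model$couplings, do.call(rbind, add))
  validate_model(model)
  model
}

#' Set reaction bounds
#'
#' @param model a [metabolic_model()].
#' @param id reaction id.
#' @param lb,ub new bounds (NULL leaves a bound unchanged).
#' @export
set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- match(id, reaction_ids(model))
  if (is.na(i)) stop("unknown reaction id: ", id)
  if (!is.null(lb)) model$reactions[[i]]$lb <- as.double(lb)
  if (!is.null(ub)) model$reactions[[i]]$ub <- as.double(ub)
  model
}

#' Mass-balance residual of a flux vector
#'
#' @param model a [metabolic_model()].
#' @param fluxes named flux vector as returned by [solve_fba()].
#' @return max-norm of S v.
#' @export
mass_balance_residual <- function(model, fluxes) {
  S <- build_stoichiometric_matrix(model)
  max(abs(as.vector(S %*% fluxes[colnames(S)])))
}
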