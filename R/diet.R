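#' Diet construction from food-intake records
#'
#' Converts food-intake tables (grams of each food per day, by intervention
#' period) and a nutrient-composition table (mass fraction of each
#' metabolite in each food) into a quantitative diet flux vector in
#' mmol/day, the unit consumed by [apply_diet()]. The nutrient composition
#' is a user-supplied table: it carries the responsibility for which
#' nutrient mass escapes host digestion and reaches the microbiota. A toy
#' synthetic composition table is packaged for the worked examples; it is
#' not a nutrient database.
#'
#' @name diet_builder
NULL

#' Read a food-intake table
#'
#' Wide TSV with columns `formula`, `food`, then one column per period;
#' `#`-prefixed lines are metadata. Returned in long form.
#'
#' @param path TSV path.
#' @return data.frame with columns `formula`, `food`, `period`,
#'   `grams_per_day`.
#' @export
read_intake_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("formula", "food")
  if (!all(need %in% names(df)))
    stop("intake table must have 'formula' and 'food' columns")
  periods <- setdiff(names(df), need)
  if (length(periods) == 0) stop("intake table has no period columns")
  long <- do.call(rbind, lapply(periods, function(p)
    data.frame(formula = df$formula, food = df$food, period = p,
               grams_per_day = as.numeric(df[[p]]),
               stringsAsFactors = FALSE)))
  if (any(is.na(long$grams_per_day))) stop("non-numeric intake value")
  if (any(long$grams_per_day < 0)) stop("negative intake value")
  if (anyDuplicated(long[, c("formula", "food", "period")]))
    stop("duplicate (formula, food, period) rows")
  long
}

#' Total daily intake of one food in one period
#'
#' Sums the intake rows of the food across formulas (a food can appear in
#' several formulas, e.g. a prebiotic fibre dosed in two preparations).
#'
#' @param table long intake table from [read_intake_tsv()].
#' @param period period token.
#' @param food food token.
#' @return grams per day.
#' @export
total_intake <- function(table, period, food) {
  if (!period %in% table$period)
    stop("unknown period '", period, "'; valid: ",
         paste(sort(unique(table$period)), collapse = ", "))
  if (!food %in% table$food)
    stop("unknown food '", food, "'; valid: ",
         paste(sort(unique(table$food)), collapse = ", "))
  sum(table$grams_per_day[table$period == period & table$food == food])
}

#' Compose a diet flux vector from intakes
#'
#' flux_m = sum over foods of grams/day * mass fraction of m in the food,
#' divided by the molar mass of m, times 1000 (g -> mmol). Metabolites
#' with zero total flux are omitted.
#'
#' @param intakes named numeric vector, food -> grams/day.
#' @param composition data.frame with columns `food`, `metabolite`,
#'   `fraction` (g nutrient per g food).
#' @param molar_masses named numeric vector, metabolite -> g/mol.
#' @return named numeric diet flux vector (mmol/day), sorted by
#'   metabolite id.
#' @export
compose_flux <- function(intakes, composition, molar_masses) {
  stopifnot(all(c("food", "metabolite", "fraction") %in% names(composition)))
  if (any(composition$fraction < 0 | composition$fraction > 1))
    stop("composition fractions must lie in [0, 1]")
  tot <- stats::aggregate(fraction ~ food, data = composition, FUN = sum)
  if (any(tot$fraction > 1 + 1e-9))
    stop("composition fractions of food '",
         tot$food[which(tot$fraction > 1 + 1e-9)[1]], "' sum above 1")
  comp <- composition[composition$food %in% names(intakes), , drop = FALSE]
  if (nrow(comp) == 0) return(setNames(numeric(0), character(0)))
  grams <- unname(intakes[comp$food]) * comp$fraction
  agg <- stats::aggregate(grams, by = list(metabolite = comp$metabolite),
                          FUN = sum)
  missing <- setdiff(agg$metabolite, names(molar_masses))
  if (length(missing) > 0)
    stop("missing molar mass for metabolite: ", missing[1])
  flux <- agg$x / unname(molar_masses[agg$metabolite]) * 1000
  keep <- flux > 0
  setNames(flux[keep], agg$metabolite[keep])[order(agg$metabolite[keep],
                                                   method = "radix")]
}

#' Supplement essential micronutrients at trace flux
#'
#' Adds every metabolite on the essential list that is absent from the
#' diet at the trace flux eps (mmol/day); present entries are untouched.
#' This emulates the diet-adaptation step needed to make tabulated diets
#' growth-feasible for strains with micronutrient requirements the food
#' composition table does not cover.
#'
#' @param diet named diet flux vector (mmol/day).
#' @param essential character vector of essential metabolite ids.
#' @param eps trace flux (mmol/day, >= 0).
#' @return the supplemented diet vector.
#' @export
supplement_micronutrients <- function(diet, essential, eps = 0.1) {
  if (eps < 0) stop("eps must be nonnegative")
  if (eps == 0) return(diet)
  add <- setdiff(essential, names(diet))
  out <- c(diet, setNames(rep(eps, length(add)), add))
  out[order(names(out), method = "radix")]
}

#' Read a nutrient-composition table
#'
#' @param path TSV with columns `food`, `metabolite`, `fraction`.
#' @export
read_composition_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("food", "metabolite", "fraction") %in% names(df)))
  df$fraction <- as.numeric(df$fraction)
  df
}

#' Read a molar-mass table
#'
#' @param path TSV with columns `metabolite`, `molar_mass` (g/mol).
#' @return named numeric vector.
#' @export
read_molar_mass_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite", "molar_mass") %in% names(df)))
  setNames(as.numeric(df$molar_mass), df$metabolite)
}
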