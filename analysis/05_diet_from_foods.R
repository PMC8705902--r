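#!/usr/bin/env Rscript
# Stage 5 (standalone): build a quantitative diet from food-intake records.
#
# Demonstrates the intake -> flux conversion on the packaged intervention
# food-intake table (three ready-to-eat formulas across three periods)
# with the synthetic nutrient-composition and molar-mass tables. Real
# analyses substitute a measured or database-derived composition table in
# the same format.

suppressMessages(library(fluxcomm))

intake <- read_intake_tsv(system.file("extdata", "food_intake_table1.tsv",
                                      package = "fluxcomm"))
comp <- read_composition_tsv(system.file(
  "extdata", "composition_synthetic.tsv", package = "fluxcomm"))
mw <- read_molar_mass_tsv(system.file(
  "extdata", "molar_mass_synthetic.tsv", package = "fluxcomm"))

cat("prebiotic fibre dose, summed across formulas (g/day):\n")
for (p in unique(intake$period))
  cat(sprintf("  %-12s %.2f\n", p, total_intake(intake, p, "Fibersol-2")))

dir.create("results/diet", recursive = TRUE, showWarnings = FALSE)
for (p in unique(intake$period)) {
  foods <- unique(intake$food[intake$period == p])
  g <- vapply(foods, function(f) total_intake(intake, p, f), 0)
  flux <- compose_flux(g, comp, mw)
  flux <- supplement_micronutrients(flux, essential = c("aa"), eps = 0.1)
  write_diet_tsv(flux, file.path("results/diet", paste0(p, ".tsv")))
  cat(sprintf("\n%s diet fluxes (mmol/day):\n", p))
  print(round(flux, 1))
}
cat("\nthe main-formula intake tapers across periods, so the fibre flux",
    "\nfrom whole grains falls while the supplemented prebiotic rises.\n")
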