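#' Readers, writers and the end-to-end pipeline
#'
#' All tables are TAB-separated UTF-8 with `#`-prefixed metadata lines;
#' metabolic models travel in a documented JSON dialect or an SBML Level 3
#' core subset (flux bounds via parameters, objective via the
#' flux-balance-constraints extension, reaction kinds via SBO terms).
#'
#' @name io
NULL

# ---------------------------------------------------------------- tables --

#' Write a data.frame as a TSV with metadata header lines
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta character vector of metadata lines (written `# `-prefixed).
#' @param digits significant digits for numeric columns (default 6;
#'   `NULL` writes full precision).
#' @export
write_table_tsv <- function(df, path, meta = character(0), digits = 6) {
  if (!is.null(digits))
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta) > 0) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_table_tsv()]
#' @param path file path.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# ------------------------------------------------------------- abundance --

#' Read a relative-abundance TSV
#'
#' Dialect of read-coverage tools: header `Genome<TAB>Relative Abundance
#' (%)`; percent values are converted to fractions (25 -> 0.25). An
#' `unmapped` row, if present, is dropped with a message; renormalisation
#' happens later, at the filter stage.
#'
#' @param path TSV path.
#' @param sample_id sample label (default: file name without extension).
#' @return an [abundance_profile()] (unfiltered).
#' @export
read_abundance_tsv <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  skip <- grepl("^#", lines)
  df <- utils::read.delim(text = lines[!skip], check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("Genome", "Relative Abundance (%)")
  if (!all(need %in% names(df)))
    stop("abundance TSV must have columns ",
         paste(sQuote(need), collapse = " and "))
  pct <- suppressWarnings(as.numeric(df[["Relative Abundance (%)"]]))
  if (any(is.na(pct))) {
    row <- which(is.na(pct))[1]
    line <- which(!skip)[row + 1L] # +1 for the header line
    stop("non-numeric abundance at line ", line, " of ", basename(path))
  }
  drop <- tolower(df$Genome) == "unmapped"
  if (any(drop)) {
    message("dropped 'unmapped' row (", sum(pct[drop]), "%) from ",
            basename(path))
    df <- df[!drop, , drop = FALSE]
    pct <- pct[!drop]
  }
  if (anyDuplicated(df$Genome))
    stop("duplicate strain rows in ", basename(path), ": ",
         df$Genome[duplicated(df$Genome)][1])
  abundance_profile(sample_id, setNames(pct / 100, df$Genome))
}

#' Write a relative-abundance TSV
#' @param profile an [abundance_profile()].
#' @param path output path.
#' @export
write_abundance_tsv <- function(profile, path) {
  df <- data.frame(Genome = names(profile$abundances),
                   pct = unname(profile$abundances) * 100,
                   check.names = FALSE)
  names(df)[2] <- "Relative Abundance (%)"
  write_table_tsv(df, path,
                  meta = paste0("sample: ", profile$sample_id),
                  digits = NULL)
}

# ------------------------------------------------------------------ diet --

#' Write / read a diet flux TSV
#'
#' Columns `metabolite` (bare id or `EX_m[d]` reaction id) and
#' `flux_mmol_per_day`.
#' @param diet named nonnegative numeric vector.
#' @param path file path.
#' @export
write_diet_tsv <- function(diet, path) {
  write_table_tsv(data.frame(metabolite = names(diet),
                             flux_mmol_per_day = unname(diet)),
                  path, meta = "diet fluxes (mmol/day)", digits = NULL)
}

#' @rdname write_diet_tsv
#' @export
read_diet_tsv <- function(path) {
  df <- read_table_tsv(path)
  stopifnot(all(c("metabolite", "flux_mmol_per_day") %in% names(df)))
  flux <- as.numeric(df$flux_mmol_per_day)
  if (any(is.na(flux) | flux < 0))
    stop("diet fluxes must be nonnegative numbers")
  setNames(flux, df$metabolite)
}

# -------------------------------------------------------------- clinical --

#' Write / read a clinical time-series CSV
#'
#' A `timepoint` column plus one numeric column per clinical parameter.
#' @param clinical data.frame.
#' @param path file path.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timepoint" %in% names(df))
    stop("clinical CSV must have a 'timepoint' column")
  df
}

# ------------------------------------------------------------ model JSON --

.meta_scalars <- function(meta) {
  keep <- vapply(meta, function(x)
    (is.character(x) || is.numeric(x)) && length(x) == 1L, FALSE)
  meta[keep]
}

#' Write a model in the JSON dialect
#'
#' Fields: `id`, `compartments`, `metabolites` (id, compartment, name,
#' subsystem), `reactions` (id, lb, ub, kind, stoichiometry as a
#' key -> coefficient map), `objective`, `couplings`, scalar `meta`
#' entries. Ordering is canonical, so equal models serialise to equal
#' bytes.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  obj <- list(
    id = model$id,
    compartments = model$compartments,
    metabolites = model$metabolites[, c("id", "compartment", "name",
                                        "subsystem")],
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, lb = r$lb, ub = r$ub, kind = r$kind,
           stoichiometry = as.list(r$stoich))),
    objective = as.list(model$objective),
    couplings = model$couplings,
    meta = .meta_scalars(model$meta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model from the JSON dialect
#' @param path JSON path.
#' @return a [metabolic_model()].
#' @export
read_model_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(o$metabolites, function(m)
    data.frame(id = m$id, compartment = m$compartment, name = m$name,
               subsystem = m$subsystem, stringsAsFactors = FALSE)))
  mets$key <- met_key(mets$id, mets$compartment)
  rxns <- lapply(o$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, lb = r$lb, ub = r$ub, kind = r$kind)
  })
  cp <- if (length(o$couplings) > 0)
    do.call(rbind, lapply(o$couplings, function(k)
      data.frame(reaction = k$reaction, anchor = k$anchor, c = k$c, u = k$u,
                 stringsAsFactors = FALSE)))
  else NULL
  obj <- unlist(o$objective)
  if (is.null(obj)) obj <- numeric(0)
  m <- metabolic_model(o$id, unlist(o$compartments), mets, rxns,
                       objective = obj, couplings = cp,
                       meta = lapply(o$meta, identity))
  validate_model(m)
  m
}

# ------------------------------------------------------------ model SBML --

.sbml_sanitize <- function(x) {
  x <- gsub("[", "__91__", x, fixed = TRUE)
  gsub("]", "__93__", x, fixed = TRUE)
}
.sbml_desanitize <- function(x) {
  x <- gsub("__91__", "[", x, fixed = TRUE)
  gsub("__93__", "]", x, fixed = TRUE)
}
.sbo_of_kind <- c(internal = "SBO:0000176", exchange = "SBO:0000627",
                  transport = "SBO:0000185", biomass = "SBO:0000629")

#' Write a model as SBML Level 3 (core subset)
#'
#' Flux bounds are written as constant parameters referenced through the
#' fbc extension; the objective uses an fbc objective; reaction kinds map
#' to SBO terms; metabolite subsystems travel in species notes. Coupling
#' constraints cannot be represented in this subset: writing a model that
#' has couplings raises an error unless `strip_couplings = TRUE`.
#'
#' @param model a [metabolic_model()].
#' @param path output path.
#' @param strip_couplings drop coupling constraints with a warning
#'   instead of erroring.
#' @export
write_model_sbml <- function(model, path, strip_couplings = FALSE) {
  validate_model(model)
  if (nrow(model$couplings) > 0) {
    if (!strip_couplings)
      stop("coupling constraints cannot be represented in the SBML subset; ",
           "use the JSON dialect or strip_couplings = TRUE")
    warning("dropping ", nrow(model$couplings),
            " coupling constraint(s) not representable in SBML")
  }
  fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="', fbc, '" level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', .sbml_sanitize(model$id)),
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>',
            .sbml_sanitize(model$compartments)),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  mt <- model$metabolites
  for (i in seq_len(nrow(mt))) {
    sid <- sprintf("M_%s_%s", .sbml_sanitize(mt$id[i]),
                   .sbml_sanitize(mt$compartment[i]))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
             'constant="false">'),
      sid, mt$name[i], .sbml_sanitize(mt$compartment[i])),
      "        <notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
      sprintf("          <p>SUBSYSTEM: %s</p>", mt$subsystem[i]),
      "        </body></notes>",
      "      </species>")
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions) {
    rid <- .sbml_sanitize(r$id)
    lines <- c(lines, sprintf(
      '      <parameter id="R_%s_lb" value="%.17g" constant="true"/>', rid,
      r$lb), sprintf(
      '      <parameter id="R_%s_ub" value="%.17g" constant="true"/>', rid,
      r$ub))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    rid <- .sbml_sanitize(r$id)
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" reversible="%s" fast="false" ',
             'sboTerm="%s" fbc:lowerFluxBound="R_%s_lb" ',
             'fbc:upperFluxBound="R_%s_ub">'),
      rid, tolower(r$lb < 0), .sbo_of_kind[[r$kind]], rid, rid))
    sub <- r$stoich[r$stoich < 0]; prd <- r$stoich[r$stoich > 0]
    spid <- function(keys) {
      k <- .split_key(keys)
      sprintf("M_%s_%s", .sbml_sanitize(k$id), .sbml_sanitize(k$compartment))
    }
    if (length(sub) > 0)
      lines <- c(lines, "        <listOfReactants>", sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        spid(names(sub)), -unname(sub)), "        </listOfReactants>")
    if (length(prd) > 0)
      lines <- c(lines, "        <listOfProducts>", sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        spid(names(prd)), unname(prd)), "        </listOfProducts>")
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (length(model$objective) > 0) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      sprintf(paste0('          <fbc:fluxObjective fbc:reaction="R_%s" ',
                     'fbc:coefficient="%.17g"/>'),
              .sbml_sanitize(names(model$objective)),
              unname(model$objective)),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a model from SBML Level 3 (core subset)
#'
#' Supports the constructs written by [write_model_sbml()]; anything else
#' (kinetic laws, rules, events) raises an unsupported-feature error
#' rather than being dropped silently. Without an fbc objective, a
#' reaction carrying the biomass SBO term becomes the objective.
#'
#' @param path SBML file path.
#' @return a [metabolic_model()].
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  unsupported <- c("kineticLaw", "listOfRules", "listOfEvents",
                   "listOfConstraints", "listOfFunctionDefinitions")
  for (u in unsupported)
    if (length(xml2::xml_find_all(doc, sprintf(".//*[local-name()='%s']", u))) > 0)
      stop("unsupported SBML construct: ", u)
  one <- function(xpath) xml2::xml_find_all(doc, xpath)
  model_node <- one(".//*[local-name()='model']")
  id <- .sbml_desanitize(xml2::xml_attr(model_node, "id"))
  comps <- .sbml_desanitize(
    xml2::xml_attr(one(".//*[local-name()='compartment']"), "id"))
  sp <- one(".//*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- .sbml_desanitize(xml2::xml_attr(sp, "compartment"))
  sp_base <- .sbml_desanitize(
    substr(sp_id, 3, nchar(sp_id) - nchar(xml2::xml_attr(sp, "compartment")) - 1))
  sp_name <- xml2::xml_attr(sp, "name")
  sp_sub <- vapply(sp, function(s) {
    p <- xml2::xml_text(xml2::xml_find_first(s, ".//*[local-name()='p']"))
    if (is.na(p)) "other" else sub("^SUBSYSTEM: ", "", p)
  }, "")
  mets <- metabolite_table(sp_base, sp_comp, name = sp_name,
                           subsystem = sp_sub)
  key_of_sid <- setNames(mets$key, sp_id)

  pars <- one(".//*[local-name()='parameter']")
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  sbo_to_kind <- setNames(names(.sbo_of_kind), unname(.sbo_of_kind))
  rx <- one(".//*[local-name()='reaction']")
  rxns <- lapply(rx, function(r) {
    rid_raw <- xml2::xml_attr(r, "id")
    rid <- .sbml_desanitize(sub("^R_", "", rid_raw))
    lbref <- xml2::xml_attr(r, "lowerFluxBound")
    ubref <- xml2::xml_attr(r, "upperFluxBound")
    if (is.na(lbref) || is.na(ubref))
      stop("unsupported SBML: reaction ", rid, " lacks fbc flux bounds")
    kind <- sbo_to_kind[xml2::xml_attr(r, "sboTerm")]
    if (is.na(kind)) kind <- "internal"
    reac <- xml2::xml_find_all(r, ".//*[local-name()='listOfReactants']/*")
    prod <- xml2::xml_find_all(r, ".//*[local-name()='listOfProducts']/*")
    st <- c(
      setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
               key_of_sid[xml2::xml_attr(reac, "species")]),
      setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
               key_of_sid[xml2::xml_attr(prod, "species")]))
    reaction(rid, st, lb = parval[[lbref]], ub = parval[[ubref]],
             kind = unname(kind))
  })
  fo <- one(".//*[local-name()='fluxObjective']")
  objective <- if (length(fo) > 0)
    setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
             .sbml_desanitize(sub("^R_", "", xml2::xml_attr(fo, "reaction"))))
  else {
    bio <- vapply(rxns, function(r) r$kind == "biomass", FALSE)
    if (any(bio)) setNames(1, rxns[[which(bio)[1]]]$id) else numeric(0)
  }
  meta <- list()
  if (length(objective) > 0 &&
      any(vapply(rxns, function(r) r$kind == "biomass", FALSE)))
    meta$biomass <- rxns[[which(
      vapply(rxns, function(r) r$kind == "biomass", FALSE))[1]]]$id
  m <- metabolic_model(id, comps, mets, rxns, objective = objective,
                       meta = meta)
  validate_model(m)
  m
}

#' Read or write a model, dispatching on file extension
#'
#' `.json` uses the JSON dialect; `.xml`/`.sbml` the SBML subset.
#' @param path model file path.
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = read_model_json(path),
         xml = ,
         sbml = read_model_sbml(path),
         stop("unknown model format: .", ext))
}

#' @rdname read_model
#' @param model a [metabolic_model()].
#' @export
write_model <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = write_model_json(model, path),
         xml = ,
         sbml = write_model_sbml(model, path),
         stop("unknown model format: .", ext))
}
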