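#' Scenario directories and the end-to-end pipeline
#'
#' A scenario directory holds everything one analysis run consumes:
#' strain models (JSON dialect), per-sample abundance TSVs, a diet TSV, a
#' clinical CSV, a metabolite-subsystem map, and (for synthetic scenarios)
#' the planted truth. [run_pipeline()] executes the nine analysis stages
#' over it and writes all result tables plus a machine-readable manifest;
#' outputs are byte-identical across reruns of the same inputs and
#' configuration.
#'
#' @name pipeline
NULL

#' Write a synthetic scenario to a directory
#'
#' @param bundle a `scenario_bundle` from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "abundance"), showWarnings = FALSE)
  for (m in bundle$models)
    write_model_json(m, file.path(dir, "models", paste0(m$id, ".json")))
  for (tp in bundle$timepoints)
    write_abundance_tsv(bundle$profiles[[tp]],
                        file.path(dir, "abundance", paste0(tp, ".tsv")))
  write_diet_tsv(bundle$diet, file.path(dir, "diet.tsv"))
  write_clinical_csv(bundle$clinical, file.path(dir, "clinical.csv"))
  write_table_tsv(data.frame(metabolite = names(bundle$subsystems),
                             subsystem = unname(bundle$subsystems)),
                  file.path(dir, "subsystems.tsv"), digits = NULL)
  jsonlite::write_json(
    list(seed = bundle$seed, timepoints = bundle$timepoints,
         config = unclass(bundle$config)),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(producers = as.list(bundle$truth$producers),
         planted_pairs = bundle$truth$planted_pairs,
         net_secretion = bundle$truth$net_secretion),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a scenario directory
#'
#' @param dir directory written by [write_scenario()] (or assembled by
#'   hand in the same layout).
#' @return a `scenario_bundle`.
#' @export
read_scenario <- function(dir) {
  sc <- jsonlite::read_json(file.path(dir, "scenario.json"),
                            simplifyVector = TRUE)
  config <- do.call(community_config, sc$config)
  models <- lapply(sort(list.files(file.path(dir, "models"),
                                   full.names = TRUE)), read_model_json)
  timepoints <- sc$timepoints
  profiles <- lapply(timepoints, function(tp)
    read_abundance_tsv(file.path(dir, "abundance", paste0(tp, ".tsv")),
                       sample_id = tp))
  names(profiles) <- timepoints
  diet <- read_diet_tsv(file.path(dir, "diet.tsv"))
  clinical <- read_clinical_csv(file.path(dir, "clinical.csv"))
  subs <- read_table_tsv(file.path(dir, "subsystems.tsv"))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tr <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- list(producers = unlist(tr$producers),
                  planted_pairs = tr$planted_pairs,
                  net_secretion = tr$net_secretion)
  }
  structure(list(models = models, profiles = profiles, diet = diet,
                 clinical = clinical,
                 subsystems = setNames(subs$subsystem, subs$metabolite),
                 timepoints = timepoints, seed = sc$seed, config = config,
                 truth = truth),
            class = "scenario_bundle")
}

#' Run the full analysis pipeline
#'
#' Executes the nine stages — filter, assemble, diet, simulate, classify,
#' subsystem, contributions, correlate, network — over a scenario
#' directory or an in-memory `scenario_bundle`, writing all result tables
#' (TSV), the network (GraphML) and a manifest (JSON) to `out_dir`. Any
#' stage error aborts with the stage name; messages and warnings raised
#' inside stages are collected into the manifest.
#'
#' @param input scenario directory path or a `scenario_bundle`.
#' @param out_dir output directory (created if needed).
#' @param config a [community_config()]; defaults to the scenario's.
#' @param focus clinical parameters anchoring the network (default BMI,
#'   leptin, adiponectin).
#' @param digits significant digits in output tables (default 6; `NULL`
#'   for full precision).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(input, out_dir, config = NULL,
                         focus = c("BMI", "leptin", "adiponectin"),
                         digits = 6) {
  bundle <- if (is.character(input)) read_scenario(input) else input
  stopifnot(inherits(bundle, "scenario_bundle"))
  if (is.null(config)) config <- bundle$config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- character(0)
  stages <- character(0)
  stage <- function(name, expr) {
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)),
      message = function(m) {
        log <<- c(log, paste0("[", name, "] ", sub("\n$", "",
                                                   conditionMessage(m))))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        log <<- c(log, paste0("[", name, "] WARN ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    stages <<- c(stages, name)
    res
  }

  profiles <- stage("filter", lapply(bundle$profiles,
                                     filter_and_renormalize, config$cutoff))
  communities <- stage("assemble", lapply(profiles, function(p)
    assemble_community(bundle$models, p, config)))
  communities <- stage("diet", lapply(communities, apply_diet, bundle$diet))
  records <- stage("simulate", do.call(rbind, c(
    lapply(bundle$timepoints, function(tp)
      simulate_sample(communities[[tp]], config = config)), list(NULL))))
  roles <- stage("classify", classify_exchange_roles(records))
  subsys <- stage("subsystem", subsystem_totals(records, bundle$subsystems))
  contrib <- stage("contributions", {
    secreted <- names(roles)[roles %in% c("secreted_only", "both")]
    do.call(rbind, c(unlist(lapply(bundle$timepoints, function(tp)
      lapply(secreted, function(m)
        strain_contributions(communities[[tp]], m, config))),
      recursive = FALSE), list(NULL)))
  })
  correlations <- stage("correlate", {
    mt <- stats::reshape(records[, c("sample", "metabolite",
                                     "net_secretion")],
                         idvar = "sample", timevar = "metabolite",
                         direction = "wide")
    rownames(mt) <- mt$sample
    mt <- as.matrix(mt[bundle$timepoints, -1, drop = FALSE])
    colnames(mt) <- sub("^net_secretion\\.", "", colnames(mt))
    clin <- derived_ratio(bundle$clinical)
    correlate_features(mt, clin, r_thresh = config$r_thresh,
                       p_thresh = config$p_thresh)
  })
  network <- stage("network", {
    agg <- if (!is.null(contrib) && nrow(contrib) > 0)
      stats::aggregate(share ~ metabolite + strain, data = contrib,
                       FUN = mean)
    else NULL
    build_network(correlations, agg, focus = focus)
  })

  shannon_df <- data.frame(sample = bundle$timepoints,
                           shannon = vapply(profiles[bundle$timepoints],
                                            shannon, 0))
  role_df <- data.frame(metabolite = names(roles), role = unname(roles))

  write_table_tsv(records, file.path(out_dir, "net_fluxes.tsv"),
                  meta = "per-sample FVA net secretion/uptake (mmol/day)",
                  digits = digits)
  write_table_tsv(role_df, file.path(out_dir, "roles.tsv"),
                  meta = "metabolite exchange roles across samples")
  write_table_tsv(subsys, file.path(out_dir, "subsystem_totals.tsv"),
                  meta = "summed positive net secretion per subsystem (mmol/day)",
                  digits = digits)
  if (!is.null(contrib))
    write_table_tsv(contrib, file.path(out_dir, "contributions.tsv"),
                    meta = "per-sample strain contributions (IEX FVA)",
                    digits = digits)
  write_table_tsv(correlations, file.path(out_dir, "correlations.tsv"),
                  meta = "metabolite x clinical Spearman tests (all pairs)",
                  digits = digits)
  write_table_tsv(shannon_df, file.path(out_dir, "shannon.tsv"),
                  meta = "Shannon diversity of filtered profiles (nats)",
                  digits = digits)
  write_network_graphml(network, file.path(out_dir, "network.graphml"))

  manifest <- list(
    package = "fluxcomm",
    version = as.character(utils::packageVersion("fluxcomm")),
    seed = bundle$seed,
    config = unclass(config),
    focus = focus,
    stages_completed = stages,
    n_samples = length(bundle$timepoints),
    n_strains = length(bundle$models),
    n_metabolites = length(unique(records$metabolite)),
    log = log,
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
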