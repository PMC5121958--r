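# End-to-end pipeline orchestration: simulate -> parameterize -> FBA/FVA ->
# transition dynamics -> minimal-adjustment chain -> covariation, with a
# reproducible manifest. A thin command-line wrapper over these functions
# ships in inst/cli/phaseflux.R.

#' Assemble and validate a pipeline configuration
#'
#' @param model Path to a model file, or a [metabolic_model()] object, or
#'   `NULL` to simulate a toy model.
#' @param growth_curve Path to a growth-curve CSV (with sidecar JSON), or a
#'   [growth_curve()] object, or `NULL` to simulate one.
#' @param dialect Model file dialect, see [read_model()].
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed driving all synthetic stages.
#' @param n_amino_acids,n_phases,noise_sd Scenario knobs used when simulating.
#' @param tolerance_activity Flux-carrying threshold (mmol gDW^-1 h^-1).
#' @param tolerance_change Minimal change in absolute flux that counts.
#' @param tolerance_steady_state Maximum steady-state residual tolerated.
#' @param fva_fraction FVA optimality fraction.
#' @param moma_norm `"L2"` or `"L1"`.
#' @param covariation_threshold Pearson threshold for covariation clusters.
#' @param scale Uptake-flux scaling mode, see [compute_uptake_fluxes()].
#' @param parsimonious Use the parsimonious FBA post-processing.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(model = NULL, growth_curve = NULL,
                            dialect = "auto", out_dir = tempfile("phaseflux_"),
                            seed = 1L, n_amino_acids = 6L, n_phases = 12L,
                            noise_sd = 0,
                            tolerance_activity = 1e-9,
                            tolerance_change = 1e-6,
                            tolerance_steady_state = 1e-6,
                            fva_fraction = 1,
                            moma_norm = "L2",
                            covariation_threshold = 0.7,
                            scale = "none",
                            parsimonious = FALSE) {
  cfg <- list(model = model, growth_curve = growth_curve, dialect = dialect,
              out_dir = out_dir, seed = as.integer(seed),
              n_amino_acids = as.integer(n_amino_acids),
              n_phases = as.integer(n_phases), noise_sd = noise_sd,
              tolerance_activity = tolerance_activity,
              tolerance_change = tolerance_change,
              tolerance_steady_state = tolerance_steady_state,
              fva_fraction = fva_fraction, moma_norm = moma_norm,
              covariation_threshold = covariation_threshold, scale = scale,
              parsimonious = isTRUE(parsimonious))
  for (tl in c("tolerance_activity", "tolerance_change", "tolerance_steady_state")) {
    if (!is.numeric(cfg[[tl]]) || cfg[[tl]] <= 0) {
      stop(tl, " must be a positive number", call. = FALSE)
    }
  }
  if (cfg$covariation_threshold <= -1 || cfg$covariation_threshold >= 1) {
    stop("covariation_threshold must lie in (-1, 1)", call. = FALSE)
  }
  if (!cfg$moma_norm %in% c("L2", "L1")) stop("moma_norm must be L2 or L1", call. = FALSE)
  if (is.character(cfg$model) && !file.exists(cfg$model)) {
    stop("model file not found: ", cfg$model, call. = FALSE)
  }
  if (is.character(cfg$growth_curve) && !file.exists(cfg$growth_curve)) {
    stop("growth-curve file not found: ", cfg$growth_curve, call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unknown keys are rejected; values are coerced to the types of
#' [pipeline_config()]'s defaults.
#'
#' @param path Config file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "), call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  defaults <- formals(pipeline_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  args <- stats::setNames(as.list(vals), keys)
  for (k in names(args)) {
    v <- args[[k]]
    if (v %in% c("TRUE", "FALSE", "true", "false")) {
      args[[k]] <- as.logical(toupper(v))
    } else if (grepl("^-?[0-9.eE+-]+$", v) && !is.na(suppressWarnings(as.numeric(v)))) {
      args[[k]] <- as.numeric(v)
    }
  }
  do.call(pipeline_config, args)
}

.stage_log <- function(quiet, ...) if (!quiet) message("[phaseflux] ", ...)

#' Run the full multi-phase modelling pipeline
#'
#' Executes, in order: scenario simulation (when no model/curve supplied),
#' growth-curve parameterization, phase-wise FBA, FVA, transition-dynamics
#' classification, the minimal-adjustment (nutritional-MOMA) chain, and
#' covariation clustering. Every stage writes its artifacts under
#' `config$out_dir`, and a JSON manifest records the package version, the
#' seed, the configuration and an md5 checksum per artifact.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  keep <- function(path) artifacts <<- c(artifacts, path)

  .stage_log(quiet, "stage 1/7: inputs")
  if (is.null(config$model)) {
    model <- make_toy_model(config$n_amino_acids, seed = config$seed)
    p <- file.path(config$out_dir, "model.json")
    write_model(model, p)
    keep(p)
  } else if (is.character(config$model)) {
    model <- read_model(config$model, dialect = config$dialect)
  } else {
    model <- validate_metabolic_model(config$model)
  }
  if (is.null(config$growth_curve)) {
    scen <- synthetic_scenario(n_amino_acids = config$n_amino_acids,
                               n_phases = config$n_phases,
                               noise_sd = config$noise_sd, seed = config$seed)
    curve <- make_growth_curve(scen)
    p <- file.path(config$out_dir, "growth_curve.csv")
    write_growth_curve(curve, p)
    keep(p)
    keep(paste0(p, ".json"))
  } else if (is.character(config$growth_curve)) {
    curve <- read_growth_curve(config$growth_curve)
  } else {
    curve <- config$growth_curve
  }

  .stage_log(quiet, "stage 2/7: parameterization")
  pp <- parameterize_growth(curve, scale = config$scale)
  p <- file.path(config$out_dir, "parameterization.tsv")
  write_parameterization(pp, p)
  keep(p)

  .stage_log(quiet, "stage 3/7: phase-wise FBA (", length(pp$phases), " phases)")
  fba_fm <- run_phase_fba(model, pp, parsimonious = config$parsimonious)
  p <- file.path(config$out_dir, "flux_matrix_fba.tsv")
  write_flux_matrix(fba_fm, p)
  keep(p)

  .stage_log(quiet, "stage 4/7: FVA")
  fva <- run_phase_fva(model, pp, optimality_fraction = config$fva_fraction)
  p <- file.path(config$out_dir, "fva_span.tsv")
  write_flux_matrix(fva$span, p)
  keep(p)

  .stage_log(quiet, "stage 5/7: transition dynamics")
  act <- activity_summary(fba_fm, tol = config$tolerance_activity)
  reports <- classify_transitions(fba_fm, tol_active = config$tolerance_activity,
                                  tol_change = config$tolerance_change)
  summ <- transition_summary(reports)
  p <- file.path(config$out_dir, "transition_summary.tsv")
  utils::write.table(summ, p, sep = "\t", row.names = FALSE, quote = FALSE)
  keep(p)
  p <- file.path(config$out_dir, "transition_reports.json")
  jsonlite::write_json(
    lapply(reports, function(r) r[c("transition", "increased", "decreased",
                                    "adjusted_decreased", "reversed",
                                    "turned_on", "turned_off")]),
    p, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  keep(p)
  p <- file.path(config$out_dir, "pathway_activity.tsv")
  pa <- pathway_activity(fba_fm, model, tol = config$tolerance_activity)
  utils::write.table(data.frame(subsystem = rownames(pa), pa, check.names = FALSE),
                     p, sep = "\t", row.names = FALSE, quote = FALSE)
  keep(p)

  .stage_log(quiet, "stage 6/7: nutritional-MOMA chain")
  chain <- run_moma_chain(model, pp, norm = config$moma_norm)
  p <- file.path(config$out_dir, "flux_matrix_nmoma.tsv")
  write_flux_matrix(chain$fluxes, p)
  keep(p)
  p <- file.path(config$out_dir, "moma_distances.tsv")
  utils::write.table(
    data.frame(transition = names(chain$distances), distance = chain$distances),
    p, sep = "\t", row.names = FALSE, quote = FALSE)
  keep(p)
  cmp <- compare_methods(fba_fm, chain$fluxes, model, tol = config$tolerance_activity)
  p <- file.path(config$out_dir, "method_comparison_per_phase.tsv")
  utils::write.table(cmp$per_phase, p, sep = "\t", row.names = FALSE, quote = FALSE)
  keep(p)
  p <- file.path(config$out_dir, "method_comparison_per_subsystem.tsv")
  utils::write.table(cmp$per_subsystem, p, sep = "\t", row.names = FALSE, quote = FALSE)
  keep(p)

  .stage_log(quiet, "stage 7/7: covariation clustering")
  cov <- find_covarying_clusters(fba_fm, model,
                                 threshold = config$covariation_threshold)
  p <- file.path(config$out_dir, "covariation_clusters.json")
  jsonlite::write_json(cov$clusters, p, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  keep(p)
  if (!is.null(cov$correlation)) {
    p <- file.path(config$out_dir, "covariation_correlation.tsv")
    utils::write.table(
      data.frame(reaction = rownames(cov$correlation), cov$correlation,
                 check.names = FALSE),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    keep(p)
    p <- file.path(config$out_dir, "covariation_diff_vectors.tsv")
    write_flux_matrix(cov$diff_vectors, p)
    keep(p)
  }
  if (length(cov$gene_sets)) {
    keep(export_gene_lists(cov$gene_sets, file.path(config$out_dir, "gene_lists")))
  }

  manifest <- list(
    package = "phaseflux",
    version = as.character(utils::packageVersion("phaseflux")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), c("model", "growth_curve"))],
    phases_modelled = pp$phases,
    artifacts = lapply(artifacts, function(a) {
      list(path = a, md5 = unname(tools::md5sum(a)))
    })
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .stage_log(quiet, "done: ", length(artifacts), " artifacts in ", config$out_dir)
  invisible(manifest)
}
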