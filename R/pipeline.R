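# End-to-end orchestration: simulate or load inputs, fit discounting, score
# BIS-11, build connectomes, compute topology, assemble the cohort table,
# and run the association battery, writing every artifact to an output
# directory with a machine-readable manifest.

#' Validate pipeline input files
#'
#' Schema-checks the choice CSV, BIS CSV, covariate CSV, node table and edge
#' list TSVs. Hard schema violations (missing columns, non-numeric fields,
#' out-of-range values) raise an error naming the file, column and line;
#' soft issues (subject-ID mismatches across files) are returned in the
#' report.
#'
#' @param paths list with elements `choices`, `bis`, `covariates`, `nodes`
#'   (file paths) and `edges` (vector of edge-list paths or a directory).
#' @return list with `issues` (character vector, empty when clean),
#'   `subjects` (IDs present in all behavioral files), `counts`.
#' @export
validate_inputs <- function(paths) {
  issues <- character(0)

  choices <- utils::read.csv(paths$choices, stringsAsFactors = FALSE)
  need <- c("subject_id", "immediate_amount", "delayed_amount",
            "delay_days", "choice")
  miss <- setdiff(need, names(choices))
  if (length(miss) > 0) {
    stop("choices file ", paths$choices, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in c("immediate_amount", "delayed_amount", "delay_days",
                "choice")) {
    v <- suppressWarnings(as.numeric(choices[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("choices file: non-numeric ", col, " on line ", bad[1] + 1)
    }
  }
  bad <- which(!(choices$choice %in% c(0, 1)))
  if (length(bad) > 0) {
    stop("choices file: choice must be 0 or 1, violated on line ",
         bad[1] + 1)  # +1 for the header line
  }

  bis <- utils::read.csv(paths$bis, stringsAsFactors = FALSE)
  cols <- sprintf("item%02d", 1:30)
  miss <- setdiff(c("subject_id", cols), names(bis))
  if (length(miss) > 0) {
    stop("BIS file ", paths$bis, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in cols) {
    bad <- which(!(bis[[col]] %in% 1:4))
    if (length(bad) > 0) {
      stop("BIS file: ", col, " out of range 1..4 on line ", bad[1] + 1)
    }
  }

  covariates <- utils::read.csv(paths$covariates, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(covariates)) {
    stop("covariates file ", paths$covariates, ": missing column subject_id")
  }

  nodes <- read_node_table(paths$nodes)
  if (any(nodes$volume_mm3 <= 0)) {
    stop("node table: nonpositive volume on line ",
         which(nodes$volume_mm3 <= 0)[1] + 1)
  }

  edge_files <- paths$edges
  if (length(edge_files) == 1 && dir.exists(edge_files)) {
    edge_files <- list.files(edge_files, pattern = "_edges\\.tsv$",
                             full.names = TRUE)
  }
  if (length(edge_files) == 0) stop("no edge-list files found")
  edge_ids <- sub("_edges\\.tsv$", "", basename(edge_files))
  for (f in edge_files) {
    e <- read_edge_list(f)
    if (nrow(e) > 0 && any(e$node_i < 0 | e$node_i >= nrow(nodes) |
                           e$node_j < 0 | e$node_j >= nrow(nodes))) {
      stop("edge list ", f, ": node index out of range 0..",
           nrow(nodes) - 1)
    }
  }

  ids <- list(choices = unique(choices$subject_id),
              bis = unique(bis$subject_id),
              covariates = unique(covariates$subject_id),
              edges = edge_ids)
  common <- Reduce(intersect, ids)
  for (nm in names(ids)) {
    extra <- setdiff(ids[[nm]], common)
    if (length(extra) > 0) {
      issues <- c(issues, sprintf(
        "subject(s) only partially present (seen in %s): %s",
        nm, paste(extra, collapse = ", ")))
    }
  }
  list(issues = issues, subjects = common,
       counts = c(choices = nrow(choices), bis = nrow(bis),
                  covariates = nrow(covariates),
                  n_nodes = nrow(nodes), edge_files = length(edge_files)))
}

#' Pipeline run configuration
#'
#' Exactly one of `simulate` (a [cohort_spec()]) or `inputs` (a list of
#' paths, see [validate_inputs()]) must be given.
#'
#' @param out_dir output directory for all artifacts.
#' @param simulate optional [cohort_spec()].
#' @param inputs optional list of input paths.
#' @param covariates covariate column names used by the battery.
#' @param behavioral behavioral score columns correlated with topology.
#' @param n_nulls,rewires_per_edge null-ensemble configuration.
#' @param degree_mode "strength" or "binary" degree centrality.
#' @param seed master seed for all stochastic stages.
#' @param force overwrite an existing output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, simulate = NULL, inputs = NULL,
                       covariates = c("age", "sex", "education_years"),
                       behavioral = c("log10_k", "bis_total",
                                      "bis_attentional", "bis_motor",
                                      "bis_nonplanning"),
                       n_nulls = 100, rewires_per_edge = 10,
                       degree_mode = "strength", seed = 1, force = FALSE) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be provided")
  }
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 covariates = covariates, behavioral = behavioral,
                 n_nulls = n_nulls, rewires_per_edge = rewires_per_edge,
                 degree_mode = degree_mode, seed = seed, force = force),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate` mapping
#' is passed to [cohort_spec()].
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(cohort_spec, y$simulate)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full behavior-to-topology pipeline
#'
#' Stages: (1) simulate a cohort or validate real inputs; (2) fit the
#' hyperbolic discounting model per subject, excluding single-option
#' responders; (3) score BIS-11; (4) build each subject's weighted
#' connectome and compute its topology report (null-normalized global
#' metrics plus nodal centralities and hubs); (5) assemble the cohort
#' table; (6) run the covariate-adjusted Spearman association battery at
#' the global (p < 0.05) and nodal (p < 1/n_nodes) thresholds.
#'
#' Artifacts written to `out_dir`: `fits.csv`, `exclusions.csv`,
#' `bis_scores.csv`, `topology_global.csv`, `topology_nodal.csv`,
#' `cohort.csv`, `associations_global.csv`, `associations_nodal.csv`,
#' `manifest.json`. All randomness derives from the single master seed, so
#' identical configurations reproduce identical files.
#'
#' @param config a [run_config()] or path to a YAML config file.
#' @return invisible list with the cohort table, the association tables and
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  if (dir.exists(out) && length(list.files(out)) > 0 && !config$force) {
    stop("output directory ", out, " is not empty; use force = TRUE")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # stage 1: inputs
  if (!is.null(config$simulate)) {
    spec <- config$simulate
    spec$seed <- derive_seed(config$seed, 101)
    data_dir <- file.path(out, "sim_data")
    simulate_cohort(spec, out_dir = data_dir)
    paths <- list(choices = file.path(data_dir, "choices.csv"),
                  bis = file.path(data_dir, "bis.csv"),
                  covariates = file.path(data_dir, "covariates.csv"),
                  nodes = file.path(data_dir, "nodes.tsv"),
                  edges = file.path(data_dir, "edges"))
  } else {
    paths <- config$inputs
  }
  report <- validate_inputs(paths)
  for (msg in report$issues) warning(msg, call. = FALSE)

  choices <- utils::read.csv(paths$choices, stringsAsFactors = FALSE)
  bis <- utils::read.csv(paths$bis, stringsAsFactors = FALSE)
  covariates <- utils::read.csv(paths$covariates, stringsAsFactors = FALSE)
  nodes <- read_node_table(paths$nodes)
  edge_files <- paths$edges
  if (length(edge_files) == 1 && dir.exists(edge_files)) {
    edge_files <- list.files(edge_files, pattern = "_edges\\.tsv$",
                             full.names = TRUE)
  }
  names(edge_files) <- sub("_edges\\.tsv$", "", basename(edge_files))
  subjects <- report$subjects

  # stage 2: discounting fits and exclusions
  fits <- fit_dd_cohort(choices[choices$subject_id %in% subjects, ])
  exclusions <- fits[fits$excluded, c("subject_id", "reason")]
  utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
  utils::write.csv(exclusions, file.path(out, "exclusions.csv"),
                   row.names = FALSE)
  included <- fits$subject_id[!fits$excluded]

  # stage 3: BIS scoring
  bis_scores <- score_bis_cohort(bis[bis$subject_id %in% subjects, ])
  utils::write.csv(bis_scores, file.path(out, "bis_scores.csv"),
                   row.names = FALSE)

  # stage 4: connectomes and topology
  glob_rows <- list()
  nodal_rows <- list()
  for (id in included) {
    net <- build_network(read_edge_list(edge_files[[id]]), nodes)
    rep_id <- topology_report(
      net, subject_id = id, n_nulls = config$n_nulls,
      seed = derive_seed(config$seed, 201, match(id, included)),
      rewires_per_edge = config$rewires_per_edge,
      degree_mode = config$degree_mode)
    glob_rows[[id]] <- rep_id$global
    nodal_rows[[id]] <- rep_id$nodal
  }
  topo_global <- do.call(rbind, glob_rows)
  topo_nodal <- do.call(rbind, nodal_rows)
  rownames(topo_global) <- rownames(topo_nodal) <- NULL
  utils::write.csv(topo_global, file.path(out, "topology_global.csv"),
                   row.names = FALSE)
  utils::write.csv(topo_nodal, file.path(out, "topology_nodal.csv"),
                   row.names = FALSE)

  # stage 5: cohort table (wide nodal columns deg_<label>, btw_<label>)
  cohort <- merge(fits[!fits$excluded,
                       c("subject_id", "k", "log10_k", "beta")],
                  bis_scores, by = "subject_id")
  cohort <- merge(cohort, covariates, by = "subject_id")
  cohort <- merge(cohort, topo_global[, c("subject_id", "Cp", "Lp", "gamma",
                                          "lambda", "sigma", "Eglob",
                                          "Eloc")],
                  by = "subject_id")
  deg_w <- stats::reshape(
    topo_nodal[, c("subject_id", "label", "degree_norm")],
    idvar = "subject_id", timevar = "label", direction = "wide")
  names(deg_w) <- sub("^degree_norm\\.", "deg_", names(deg_w))
  btw_w <- stats::reshape(
    topo_nodal[, c("subject_id", "label", "betweenness_norm")],
    idvar = "subject_id", timevar = "label", direction = "wide")
  names(btw_w) <- sub("^betweenness_norm\\.", "btw_", names(btw_w))
  cohort <- merge(merge(cohort, deg_w, by = "subject_id"),
                  btw_w, by = "subject_id")
  n_drop <- sum(stats::complete.cases(cohort) == FALSE)
  if (n_drop > 0) {
    warning(n_drop, " subject(s) dropped for missing covariates/metrics")
    cohort <- cohort[stats::complete.cases(cohort), , drop = FALSE]
  }
  cohort <- cohort[order(cohort$subject_id), , drop = FALSE]
  utils::write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)

  # stage 6: association battery
  n_nodes <- nrow(nodes)
  global_metrics <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                      "Eglob", "Eloc")
  nodal_metrics <- c(grep("^deg_", names(cohort), value = TRUE),
                     grep("^btw_", names(cohort), value = TRUE))
  behavioral <- intersect(config$behavioral, names(cohort))
  assoc <- run_association_battery(
    cohort, behavioral = behavioral, global_metrics = global_metrics,
    nodal_metrics = nodal_metrics, covariates = config$covariates,
    n_nodes = n_nodes)
  assoc_global <- assoc[assoc$family == "global", , drop = FALSE]
  assoc_nodal <- assoc[assoc$family == "nodal", , drop = FALSE]
  utils::write.csv(assoc_global, file.path(out, "associations_global.csv"),
                   row.names = FALSE)
  utils::write.csv(assoc_nodal, file.path(out, "associations_nodal.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "ddtopo",
    version = as.character(utils::packageVersion("ddtopo")),
    seed = config$seed, n_nulls = config$n_nulls,
    rewires_per_edge = config$rewires_per_edge,
    degree_mode = config$degree_mode,
    covariates = config$covariates, behavioral = behavioral,
    n_subjects_included = length(included),
    n_subjects_excluded = nrow(exclusions),
    n_nodes = n_nodes,
    simulated = !is.null(config$simulate))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, associations = assoc,
                 global = assoc_global, nodal = assoc_nodal,
                 fits = fits, exclusions = exclusions,
                 topology_global = topo_global, out_dir = out))
}
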