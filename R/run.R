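#' Run configuration
#'
#' Collects every tunable of the pipeline in one validated object.
#' `run_config()` accepts a YAML file path or a named list; omitted keys
#' take the package defaults (3.8 A / 150 degree H-bond criteria, 10
#' nearest candidates, DBSCAN at eps 1 A, conservation match 1 A, local
#' sphere 6 A, pair cutoff 2 A).
#'
#' @param config YAML file path or named list. Recognised keys:
#'   `input_dir` (directory of PDB files), `mode`, `alignment_file`
#'   (optional PIR/FASTA MSA), `reference` (structure id; default first
#'   lexicographically), `distance_cutoff`, `angle_cutoff`, `use_angle`,
#'   `neighbor_k`, `cluster_algorithm`, `eps`, `min_samples`,
#'   `min_cluster_size`, `match_distance`, `local_sphere`,
#'   `pair_distance`, `region` (list: `selection`, `radius`,
#'   `center_mode`), `grid_spacing`, `angle_references` (list of two
#'   3-vectors), `seed`.
#' @return A `run_config` object.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(sprintf("config file '%s' does not exist", config),
            class = "hydronet_validation_error")
    }
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    input_dir = NULL, mode = "full", alignment_file = NULL,
    reference = NULL, distance_cutoff = 3.8, angle_cutoff = 150,
    use_angle = NULL, neighbor_k = 10L, cluster_algorithm = "dbscan",
    eps = 1.0, min_samples = 5L, min_cluster_size = 5L,
    match_distance = 1.0, local_sphere = 6.0, pair_distance = 2.0,
    region = NULL, grid_spacing = 0.5, angle_references = NULL,
    seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
          class = "hydronet_validation_error")
  }
  cfg <- utils::modifyList(defaults, config, keep.null = FALSE)
  if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir)) {
    abort("config must name an existing input_dir of PDB structures",
          class = "hydronet_validation_error")
  }
  if (!is.null(cfg$alignment_file) && !file.exists(cfg$alignment_file)) {
    abort(sprintf("alignment_file '%s' does not exist", cfg$alignment_file),
          class = "hydronet_validation_error")
  }
  cfg$mode <- match.arg(cfg$mode, c("full", "water-water", "water-protein"))
  cfg$criteria <- hbond_criteria(cfg$distance_cutoff, cfg$angle_cutoff,
                                 cfg$use_angle, cfg$neighbor_k)
  cfg$cluster <- cluster_params(cfg$cluster_algorithm, cfg$eps,
                                cfg$min_samples, cfg$min_cluster_size)
  cfg$conservation <- conservation_params(cfg$match_distance,
                                          cfg$local_sphere,
                                          cfg$pair_distance)
  if (!is.null(cfg$region)) {
    cfg$region <- active_region(cfg$region$selection,
                                cfg$region$radius %||% 9,
                                cfg$region$center_mode %||% "com")
  }
  if (is.null(cfg$angle_references)) {
    cfg$angle_references <- ANGLE_REFERENCES
  } else {
    cfg$angle_references <- list(ref1 = as.numeric(cfg$angle_references[[1]]),
                                 ref2 = as.numeric(cfg$angle_references[[2]]))
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full water-network analysis pipeline
#'
#' Reads every PDB in the configured directory, aligns sequences (or
#' imports the supplied MSA), superposes all structures onto the
#' reference, builds hydrogen-bond networks, computes graph metrics,
#' clusters pooled waters into the summary network, and writes the full
#' result bundle: `metrics.csv`, `clustering.csv`, `edges.csv`,
#' `conservation_scores.csv`, `interaction_scores.csv`, `angles.csv`,
#' `alignment.fasta`, `pim.csv`, `summary.pdb`, `summary.csv`,
#' `summary.pml`, `density.dx`, and `run.log` recording all effective
#' parameters.
#'
#' @param config A [run_config()], list, or YAML path.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with `structures`, `alignment`, `networks`,
#'   `metrics`, `summary`, `scores`, `interaction_scores`, `angles`,
#'   `grid`, and `files` (paths written).
#' @export
run_analysis <- function(config, output_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(config$seed)

  stage <- "read"
  res <- tryCatch({
    paths <- sort(list.files(config$input_dir, pattern = "\\.pdb$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0) {
      abort(sprintf("no PDB files in '%s'", config$input_dir),
            class = "hydronet_validation_error")
    }
    structures <- setNames(lapply(paths, read_structure),
                           sub("\\.[^.]*$", "", basename(paths)))

    stage <- "align"
    alignment <- if (!is.null(config$alignment_file)) {
      import_alignment(config$alignment_file, structures)
    } else {
      align_structures(structures)
    }
    ref_id <- config$reference %||% sort(names(structures))[1]
    if (!ref_id %in% names(structures)) {
      abort(sprintf("reference '%s' not among the input structures", ref_id),
            class = "hydronet_validation_error")
    }
    superposed <- lapply(names(structures), function(id) {
      if (id == ref_id) return(structures[[id]])
      superpose(structures[[id]], structures[[ref_id]],
                alignment)$structure
    })
    names(superposed) <- names(structures)

    stage <- "network"
    networks <- lapply(superposed, build_network,
                       criteria = config$criteria, mode = config$mode,
                       region = config$region)

    stage <- "metrics"
    metrics <- bind_rows(lapply(networks, network_metrics))

    stage <- "conserve"
    points <- pool_positions(networks)
    summary <- cluster_waters(points, config$cluster, config$conservation,
                              config$criteria)
    scores <- if (summary$n_summary > 0) {
      conservation_scores(summary, networks, config$conservation)
    } else {
      tibble(structure_id = character(0), frame = integer(0),
             score = numeric(0))
    }
    iscores <- interaction_scores(networks, alignment)
    angles <- water_protein_angles(networks, alignment,
                                   config$angle_references$ref1,
                                   config$angle_references$ref2)
    grid <- density_hotspots(networks, config$grid_spacing)

    stage <- "export"
    files <- c(
      metrics = write_metrics_csv(networks, file.path(output_dir,
                                                      "metrics.csv")),
      clustering = write_clustering_csv(networks,
                                        file.path(output_dir,
                                                  "clustering.csv")),
      edges = write_network_csv(networks, file.path(output_dir,
                                                    "edges.csv")),
      alignment = write_alignment(alignment,
                                  file.path(output_dir, "alignment.fasta")),
      pim = write_pim(alignment, file.path(output_dir, "pim.csv")),
      scores = write_records_csv(scores,
                                 file.path(output_dir,
                                           "conservation_scores.csv")),
      iscores = write_records_csv(iscores,
                                  file.path(output_dir,
                                            "interaction_scores.csv")),
      angles = write_records_csv(angles, file.path(output_dir,
                                                   "angles.csv")),
      density = write_dx(grid, file.path(output_dir, "density.dx")))
    if (summary$n_summary > 0) {
      files <- c(files,
                 summary_pdb = write_summary_pdb(
                   summary, file.path(output_dir, "summary.pdb")),
                 summary_csv = write_summary_csv(
                   summary, file.path(output_dir, "summary.csv")),
                 summary_pml = write_pml(
                   summary, file.path(output_dir, "summary.pml")))
    }
    list(structures = superposed, alignment = alignment,
         networks = networks, metrics = metrics, summary = summary,
         scores = scores, interaction_scores = iscores, angles = angles,
         grid = grid, files = files)
  }, error = function(e) {
    if (inherits(e, "hydronet_stage_error")) stop(e)
    abort(sprintf("pipeline failed in stage '%s': %s", stage,
                  conditionMessage(e)),
          class = c("hydronet_stage_error", class(e)[1]), parent = e)
  })

  write_run_log(config, res, file.path(output_dir, "run.log"))
  invisible(res)
}

write_run_log <- function(config, res, path) {
  scalar_keys <- c("input_dir", "mode", "alignment_file", "reference",
                   "distance_cutoff", "angle_cutoff", "neighbor_k",
                   "cluster_algorithm", "eps", "min_samples",
                   "min_cluster_size", "match_distance", "local_sphere",
                   "pair_distance", "grid_spacing", "seed")
  lines <- c(
    sprintf("hydronet %s",
            as.character(utils::packageVersion("hydronet"))),
    sprintf("R %s.%s", R.version$major, R.version$minor),
    "",
    "parameters:",
    vapply(scalar_keys, function(k) {
      sprintf("  %s: %s", k,
              if (is.null(config[[k]])) "<default>"
              else paste(config[[k]], collapse = " "))
    }, character(1)),
    sprintf("  angle_ref1: %s",
            paste(config$angle_references$ref1, collapse = " ")),
    sprintf("  angle_ref2: %s",
            paste(config$angle_references$ref2, collapse = " ")),
    "",
    sprintf("structures: %d", length(res$structures)),
    sprintf("summary waters: %d", res$summary$n_summary),
    sprintf("outputs: %s", paste(basename(res$files), collapse = ", ")))
  writeLines(lines, path)
  invisible(path)
}
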