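#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @return Named list accepted by \code{\link{run_pipeline}}. Inputs are
#'   either \code{morphology_dir} (SWC files) plus \code{atlas_path}, or a
#'   \code{synthetic} block (\code{n}, \code{seed}, generator overrides).
#' @export
pipeline_defaults <- function(out_dir = "axonmap_out") {
  list(
    out_dir = out_dir,
    morphology_dir = NULL,
    atlas_path = NULL,
    space = list(orientation = "PIR", unit_um = 1),
    synthetic = NULL,
    areas = .canonical_areas,
    min_terminal_branches = 5,
    focality = list(min_terminals = 4, min_border_um = 200),
    cpd = list(max_iter = 60, tol = 0.001, w = 0, max_points = NULL, seed = 0),
    tsne = list(perplexity = 30, seed = 0),
    knn_k = 10,
    cluster_k = 3,
    euler = list(order = "xyz", intrinsic = FALSE),
    voxel_size_um = 10,
    occupancy_grid = NULL)   # default: derived from the atlas
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return Configuration list merged over \code{\link{pipeline_defaults}}.
#' @export
read_pipeline_config <- function(path) {
  utils::modifyList(pipeline_defaults(), yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, orientation normalization, topological-minor
#' reduction, projection profiles, motif census and significance, layer
#' distributions, the all-pairs CPD dissimilarity matrix, the t-SNE
#' embedding with gradient indices and morphological types, the
#' soma-to-terminal topography fit, occupancy maps and maximum-projection
#' plots. All tabular outputs, a run log and the effective configuration are
#' written to \code{config$out_dir}; re-running with the same configuration
#' and seeds reproduces all numeric outputs.
#'
#' @param config Configuration list (see \code{\link{pipeline_defaults}}) or
#'   a YAML path.
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(config = pipeline_defaults()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- utils::modifyList(pipeline_defaults(), config)

  # configuration errors before any compute
  if (is.null(config$synthetic)) {
    if (is.null(config$morphology_dir) || !dir.exists(config$morphology_dir))
      stop("configuration error: morphology_dir missing or not a directory",
           call. = FALSE)
    if (is.null(config$atlas_path) || !file.exists(config$atlas_path))
      stop("configuration error: atlas_path missing", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  cat("", file = logfile)
  t0 <- proc.time()[3L]
  log <- function(...) {
    line <- sprintf("[%8.2fs] %s", proc.time()[3L] - t0, sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  # -- ingest -----------------------------------------------------------
  if (!is.null(config$synthetic)) {
    log("generating synthetic population (n = %d, seed = %d)",
        config$synthetic$n, config$synthetic$seed)
    pop <- generate_population(
      n = config$synthetic$n,
      params = config$synthetic$params %||% list(),
      seed = config$synthetic$seed)
    morphs <- pop$morphologies
    atlas <- pop$atlas
    truth <- pop$truth
  } else {
    files <- list.files(config$morphology_dir, pattern = "\\.swc$",
                        full.names = TRUE)
    if (!length(files))
      stop("configuration error: no SWC files in morphology_dir", call. = FALSE)
    sp <- space_spec(config$space$orientation, config$space$unit_um)
    log("reading %d SWC files", length(files))
    morphs <- lapply(files, read_swc, space = sp)
    atlas <- read_atlas(config$atlas_path)
    truth <- NULL
  }
  ok <- vapply(morphs, function(m) any(m$structure == "axon"), logical(1))
  if (any(!ok)) log("quarantined %d morphologies without axonal points",
                    sum(!ok))
  morphs <- morphs[ok]
  morphs <- lapply(morphs, to_ccf_pir)
  ids <- vapply(morphs, `[[`, character(1), "neuron_id")
  somata <- t(vapply(morphs, function(m) m$points[m$soma_index, ], numeric(3)))
  rownames(somata) <- ids

  # -- topological minors & morphometrics -------------------------------
  log("reducing %d morphologies to topological minors", length(morphs))
  minors <- lapply(morphs, extract_topological_minor)
  morpho <- morphometric_table(minors,
                               file.path(config$out_dir, "morphometrics.tsv"))

  # -- projection statistics --------------------------------------------
  areas <- intersect(config$areas, unique(atlas$label_map$area))
  log("projection profiles over %d areas", length(areas))
  profiles <- lapply(minors, projection_profile, a = atlas, areas = areas)
  profile_table(profiles, file.path(config$out_dir, "profiles.tsv"),
                config$min_terminal_branches)
  census <- motif_census(profiles, config$min_terminal_branches)
  write.table(census$table, file.path(config$out_dir, "census.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- motif_significance(census)
  write.table(sig, file.path(config$out_dir, "motif_significance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  layers <- layer_distribution(profiles, areas)
  write.table(cbind(area = rownames(layers$totals),
                    as.data.frame(layers$totals, check.names = FALSE)),
              file.path(config$out_dir, "layer_totals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  foc <- vapply(seq_along(minors), function(i)
    classify_focality(minors[[i]], atlas,
                      extract_motif(profiles[[i]],
                                    config$min_terminal_branches),
                      config$focality$min_terminals,
                      config$focality$min_border_um), character(1))

  # -- CPD dissimilarity & embedding ------------------------------------
  log("CPD dissimilarity matrix (%d neurons)", length(minors))
  cfg <- cpd_config(config$cpd$max_iter, config$cpd$tol, config$cpd$w,
                    config$cpd$max_points, config$cpd$seed %||% 0L)
  D <- dissimilarity_matrix(minors, cfg)
  write_dissimilarity(D, file.path(config$out_dir, "dissimilarity.tsv"))

  log("t-SNE embedding + gradient")
  coords <- embed_tsne(D, perplexity = min(config$tsne$perplexity,
                                           nrow(D) - 1),
                       seed = config$tsne$seed)
  root <- select_root(coords, profiles, somata)
  grad <- gradient_index(coords, root, k = config$knn_k)
  types <- cluster_types(coords, k = config$cluster_k, gradient = grad)
  emb <- data.frame(neuron_id = ids, tsne1 = coords[, 1L],
                    tsne2 = coords[, 2L], gradient = grad,
                    morph_type = types, focality = foc,
                    stringsAsFactors = FALSE)
  write.table(emb, file.path(config$out_dir, "embedding.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  gradient_motifs <- motifs_along_gradient(profiles, grad,
                                           config$min_terminal_branches)
  write.table(gradient_motifs,
              file.path(config$out_dir, "motifs_along_gradient.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- topography --------------------------------------------------------
  log("topography fit")
  medoids <- t(vapply(minors, function(t) terminal_medoid(t$terminal_points),
                      numeric(3)))
  topo <- fit_topography(somata, medoids, unit = "voxel",
                         voxel_size_um = config$voxel_size_um,
                         order = config$euler$order,
                         intrinsic = config$euler$intrinsic)
  write_topography(topo, file.path(config$out_dir, "topography.json"))

  # -- occupancy & plots -------------------------------------------------
  log("occupancy maps and maximum projections")
  grid <- config$occupancy_grid %||% dim(atlas$labels)
  occ <- build_occupancy(somata, minors, types,
                         voxel_size_um = atlas$voxel_size_um,
                         grid_dims = grid)
  jsonlite::write_json(list(voxel_size_um = occ$voxel_size_um,
                            grid_dims = occ$grid_dims,
                            source = occ$source, target = occ$target),
                       file.path(config$out_dir, "occupancy.json"),
                       digits = NA)
  plots <- max_projection_plots(occ, config$out_dir, which = "source")
  max_projection_plots(occ, config$out_dir, which = "target")

  log("done")
  invisible(list(config = config, morphologies = morphs, atlas = atlas,
                 truth = truth, minors = minors, morphometrics = morpho,
                 profiles = profiles, census = census, significance = sig,
                 layers = layers, focality = foc, dissimilarity = D,
                 embedding = emb, root = root, gradient = grad,
                 types = types, gradient_motifs = gradient_motifs,
                 topography = topo, occupancy = occ, plots = plots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
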