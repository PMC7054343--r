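#' Pipeline configuration
#'
#' A single object driving the full simulate/load -> detect -> annotate
#' -> pathways -> network run.  Either `sim` (a [sim_config()]) or the
#' three input paths (`calls_path`, `probe_map_path`, `stage_map_path`)
#' must be supplied; `genes_path` (BED) and `pathways_path` (GMT) are
#' optional — without them the corresponding downstream stages are
#' skipped and marked so in the manifest.
#'
#' @param out_dir output directory; created if missing.
#' @param sim optional [sim_config()] for simulate-mode runs.
#' @param calls_path,probe_map_path,stage_map_path real-input TSV paths
#'   (see [read_call_matrix()]); ignored when `sim` is given.
#' @param genes_path optional gene BED.  In simulate mode, left `NULL`,
#'   genes are simulated.
#' @param pathways_path optional pathway GMT.  In simulate mode, left
#'   `NULL`, a pathway database is simulated over the simulated genes.
#' @param detection a [detection_config()].
#' @param stage_order ordered stage labels; defaults to the simulated
#'   stages or the sorted labels found in the stage map.
#' @param min_pathway_size,min_stages pathway filters (see
#'   [filter_and_cross_stage()]).
#' @param gene_basis edge basis for the network (see
#'   [build_evolution_network()]).
#' @param n_sim_genes,n_sim_pathways sizes of the simulated annotation
#'   and pathway database in simulate mode.
#' @param seed master seed for every stochastic step.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, calls_path = NULL,
                            probe_map_path = NULL, stage_map_path = NULL,
                            genes_path = NULL, pathways_path = NULL,
                            detection = detection_config(),
                            stage_order = NULL,
                            min_pathway_size = 5L, min_stages = 2L,
                            gene_basis = "hit",
                            n_sim_genes = 400L, n_sim_pathways = 20L,
                            seed = 1L) {
  if (is.null(sim) &&
      (is.null(calls_path) || is.null(probe_map_path) ||
       is.null(stage_map_path))) {
    stop("supply either a sim_config or calls/probe-map/stage-map paths")
  }
  structure(list(out_dir = out_dir, sim = sim, calls_path = calls_path,
                 probe_map_path = probe_map_path,
                 stage_map_path = stage_map_path, genes_path = genes_path,
                 pathways_path = pathways_path, detection = detection,
                 stage_order = stage_order,
                 min_pathway_size = as.integer(min_pathway_size),
                 min_stages = as.integer(min_stages),
                 gene_basis = gene_basis,
                 n_sim_genes = as.integer(n_sim_genes),
                 n_sim_pathways = as.integer(n_sim_pathways),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly to [pipeline_config()] arguments;
#' `detection:` and `sim:` sub-maps are passed to [detection_config()]
#' and [sim_config()] (the latter with `planted_regions:` entries
#' passed to [planted_region()]).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_config, y$detection %||% list())
  sim <- NULL
  if (!is.null(y$sim)) {
    plants <- lapply(y$sim$planted_regions %||% list(),
                     function(p) do.call(planted_region, p))
    args <- y$sim
    args$planted_regions <- plants
    args$chromosomes <- unlist(args$chromosomes)
    sim <- do.call(sim_config, args)
  }
  keep <- intersect(names(y), setdiff(names(formals(pipeline_config)),
                                      c("sim", "detection")))
  do.call(pipeline_config, c(y[keep], list(sim = sim, detection = det)))
}

#' Run the full stage-specific aberration pipeline
#'
#' Executes simulate (or load), per-stage gain/loss detection, gene
#' annotation, pathway mapping/filtering and network construction,
#' writing every intermediate artifact under `cfg$out_dir` and a JSON
#' manifest recording the config hash, seed, package version, per-stage
#' record counts and every file written.  Re-running with the same
#' config produces byte-identical outputs.  When no pathway database is
#' available the pathway and network stages are skipped and flagged in
#' the manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$out_dir, ...)
  files <- character(0)
  emit <- function(p) { files <<- c(files, basename(p)); p }
  stage_status <- list()
  fail <- function(stage, e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # -- input: simulate or load --------------------------------------
  genes <- pdb <- NULL
  tryCatch({
    if (!is.null(cfg$sim)) {
      simres <- simulate_stage_calls(cfg$sim)
      matrices <- simres$matrices
      write_call_matrix(matrices, cfg$out_dir)
      files <- c(files, c("calls.tsv", "probes.tsv", "stages.tsv"))
      write_truth_table(simres$truth, emit(path("planted_truth.tsv")))
      if (is.null(cfg$genes_path)) {
        genes <- simulate_gene_annotation(simres$probe_map, cfg$n_sim_genes,
                                          seed = cfg$seed + 1L)
        write_gene_bed(genes, emit(path("genes.bed")))
      }
      if (is.null(cfg$pathways_path) && !is.null(genes)) {
        pdb <- simulate_pathway_db(genes$gene_id, cfg$n_sim_pathways,
                                   seed = cfg$seed + 2L)
        write_gmt(pdb, emit(path("pathways.gmt")))
      }
    } else {
      matrices <- read_call_matrix(cfg$calls_path, cfg$probe_map_path,
                                   cfg$stage_map_path)
    }
    if (!is.null(cfg$genes_path)) genes <- read_gene_bed(cfg$genes_path)
    if (!is.null(cfg$pathways_path)) pdb <- read_gmt(cfg$pathways_path)
    stage_status$input <- "ok"
  }, error = function(e) fail("input", e))

  stage_order <- cfg$stage_order %||%
    (if (!is.null(cfg$sim)) cfg$sim$stages else sort(names(matrices)))
  unknown <- setdiff(names(matrices), stage_order)
  if (length(unknown)) {
    stop("pipeline stage 'input' failed: stages absent from stage_order: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  # -- detection ----------------------------------------------------
  regions <- tryCatch({
    det <- cfg$detection
    det$seed <- cfg$seed
    r <- detect_all_stages(matrices[stage_order], det)
    write_regions(r, emit(path("regions.tsv")), emit(path("regions.bed")))
    for (st in stage_order) {
      sp <- split_matrix(matrices[[st]])
      write_bedgraph(frequency_track(sp$AL),
                     emit(path(sprintf("freq_%s_gain.bedGraph", st))))
      write_bedgraph(frequency_track(sp$AD),
                     emit(path(sprintf("freq_%s_loss.bedGraph", st))))
    }
    stage_status$detect <- "ok"
    r
  }, error = function(e) fail("detect", e))

  # -- annotation ---------------------------------------------------
  gene_sets <- tryCatch({
    if (is.null(genes)) {
      stage_status$annotate <- "skipped"
      NULL
    } else {
      gs <- annotate_stages(regions, genes, stages = stage_order)
      write_gene_sets(gs, emit(path("stage_genes.tsv")))
      stage_status$annotate <- "ok"
      gs
    }
  }, error = function(e) fail("annotate", e))

  # -- pathways + network -------------------------------------------
  filtered <- net <- NULL
  if (is.null(pdb) || is.null(gene_sets)) {
    stage_status$pathways <- stage_status$network <- "skipped"
  } else {
    tryCatch({
      recs <- do.call(rbind, lapply(gene_sets, assign_genes_to_pathways,
                                    db = pdb))
      if (is.null(recs)) recs <- .empty_stage_pathways()
      filtered <- filter_and_cross_stage(recs, cfg$min_pathway_size,
                                         cfg$min_stages)
      write_stage_pathways(filtered, emit(path("stage_pathways.tsv")))
      stage_status$pathways <- "ok"
    }, error = function(e) fail("pathways", e))
    tryCatch({
      net <- build_evolution_network(filtered, stage_order,
                                     gene_basis = cfg$gene_basis, db = pdb)
      export_network(net, emit(path("network.graphml")), "graphml")
      export_network(net, emit(path("network.sif")), "sif")
      files <- c(files, "network.sif.edges.tsv")
      export_network(net, emit(path("network_edges.tsv")), "edge-tsv")
      stage_status$network <- "ok"
    }, error = function(e) fail("network", e))
  }

  manifest <- list(
    # hash the analysis configuration, not the output location
    config_hash = rlang::hash(unclass(cfg)[setdiff(names(cfg), "out_dir")]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("stageCNA")),
    stage_order = stage_order,
    stages = stage_status,
    counts = list(
      samples = vapply(matrices[stage_order],
                       function(m) nrow(m$values), 0L),
      probes = ncol(matrices[[1]]$values),
      regions = nrow(regions),
      regions_per_stage = vapply(
        stage_order, function(st) sum(regions$stage == st), 0L),
      genes_per_stage = if (is.null(gene_sets)) NULL else vapply(
        gene_sets, function(g) length(union(g$amplified, g$deleted)), 0L),
      pathways_per_stage = if (is.null(filtered)) NULL else vapply(
        stage_order, function(st) sum(filtered$stage == st), 0L),
      network_nodes = if (is.null(net)) NULL else nrow(net$nodes),
      network_edges = if (is.null(net)) NULL else nrow(net$edges)),
    files = sort(unique(files)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  missing <- files[!file.exists(file.path(cfg$out_dir, files))]
  if (length(missing)) {
    stop("manifest names files that were not written: ",
         paste(missing, collapse = ", "))
  }
  invisible(manifest)
}
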