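#' Squared-overlap score between two gene sets
#'
#' The edge weight of the pathway evolution network,
#' `W = k^2 / (p * q)`, with `k` the number of shared genes and `p`,
#' `q` the two set sizes.  `W` is symmetric, lies in `[0, 1]`, and
#' equals 1 exactly when the two sets are identical.
#'
#' @param genes_i,genes_j non-empty character vectors of gene ids
#'   (duplicates ignored).
#' @return named numeric vector `c(k, p, q, W)`.
#' @examples
#' overlap_score(c("a", "b", "c", "d"), c("a", "b", "x", "y", "z"))  # W = 0.2
#' @export
overlap_score <- function(genes_i, genes_j) {
  genes_i <- unique(genes_i); genes_j <- unique(genes_j)
  if (length(genes_i) == 0 || length(genes_j) == 0) {
    stop("overlap score is undefined for an empty gene set")
  }
  k <- length(intersect(genes_i, genes_j))
  p <- length(genes_i); q <- length(genes_j)
  c(k = k, p = p, q = q, W = k^2 / (p * q))
}

#' Build the pathway evolution network
#'
#' Nodes are the filtered stage-specific pathways; for each adjacent
#' stage pair in `stage_order`, every pair of distinct pathways — one
#' observed in the earlier stage, one in the later — that share genes
#' is connected by an edge weighted with [overlap_score()].  By
#' default the stage-specific aberrant (hit) gene subsets are compared,
#' so edge weights evolve with the stages; `gene_basis = "full"`
#' compares the full database gene sets instead (requires `db`).
#'
#' @param records filtered `stage_pathways` table (see
#'   [filter_and_cross_stage()]).
#' @param stage_order ordered character vector of stage labels; must
#'   cover every stage present in `records`.
#' @param gene_basis `"hit"` (default) or `"full"`.
#' @param db pathway database (needed for `gene_basis = "full"`).
#' @return a list of class `evolution_network`: `nodes` (data.frame
#'   `pathway_id`, `name`, `stages` ;-joined, `n_hit_genes` distinct
#'   hits across stages) and `edges` (data.frame `pathway_i`,
#'   `pathway_j`, `stage_from`, `stage_to`, `k`, `p`, `q`, `W`), both
#'   deterministically ordered.
#' @export
build_evolution_network <- function(records, stage_order,
                                    gene_basis = c("hit", "full"),
                                    db = NULL) {
  gene_basis <- match.arg(gene_basis)
  if (length(stage_order) < 2) {
    stop("at least two stages are needed to form adjacent pairs")
  }
  unknown <- setdiff(unique(records$stage), stage_order)
  if (length(unknown)) {
    stop("stages missing from stage_order: ", paste(unknown, collapse = ", "))
  }
  if (gene_basis == "full" && is.null(db)) {
    stop("gene_basis = 'full' requires the pathway database")
  }
  basis_genes <- function(row_idx) {
    if (gene_basis == "hit") return(records$hit_genes[[row_idx]])
    db$genes[[match(records$pathway_id[row_idx], db$pathway_id)]]
  }
  ids <- sort(unique(records$pathway_id))
  nodes <- data.frame(
    pathway_id = ids,
    name = records$name[match(ids, records$pathway_id)],
    stages = vapply(ids, function(id) {
      st <- unique(records$stage[records$pathway_id == id])
      paste(stage_order[stage_order %in% st], collapse = ";")
    }, ""),
    n_hit_genes = vapply(ids, function(id) {
      length(unique(unlist(records$hit_genes[records$pathway_id == id])))
    }, 0L),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- list()
  for (si in seq_len(length(stage_order) - 1L)) {
    s_from <- stage_order[si]; s_to <- stage_order[si + 1L]
    from_rows <- which(records$stage == s_from)
    to_rows <- which(records$stage == s_to)
    for (i in from_rows) {
      for (j in to_rows) {
        if (records$pathway_id[i] == records$pathway_id[j]) next
        sc <- overlap_score(basis_genes(i), basis_genes(j))
        if (sc[["k"]] < 1) next
        edges[[length(edges) + 1L]] <- data.frame(
          pathway_i = records$pathway_id[i],
          pathway_j = records$pathway_id[j],
          stage_from = s_from, stage_to = s_to,
          k = sc[["k"]], p = sc[["p"]], q = sc[["q"]], W = sc[["W"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(pathway_i = character(), pathway_j = character(),
               stage_from = character(), stage_to = character(),
               k = numeric(), p = numeric(), q = numeric(), W = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("pathway_i", "pathway_j",
                                       "stage_from", "stage_to")]), ,
                 drop = FALSE]
  edges <- edges[order(match(edges$stage_from, stage_order),
                       edges$pathway_i, edges$pathway_j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, stage_order = stage_order,
                 gene_basis = gene_basis),
            class = "evolution_network")
}

#' @export
print.evolution_network <- function(x, ...) {
  cat(sprintf("evolution_network: %d pathways, %d stage-adjacent edges (%s basis)\n",
              nrow(x$nodes), nrow(x$edges), x$gene_basis))
  invisible(x)
}

.as_igraph <- function(net) {
  vert <- data.frame(pathway_id = net$nodes$pathway_id,
                     label = net$nodes$name,
                     stages = net$nodes$stages,
                     n_hit_genes = net$nodes$n_hit_genes,
                     stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("pathway_i", "pathway_j", "stage_from", "stage_to",
                  "k", "p", "q", "W")],
    directed = TRUE, vertices = vert)
  if (nrow(net$edges)) igraph::E(g)$weight <- net$edges$W
  g
}

#' Export the evolution network for visualization
#'
#' `graphml` writes a single GraphML file carrying all node and edge
#' attributes (round-trippable with [read_network_graphml()]); `sif`
#' writes a Cytoscape simple-interaction file plus a sidecar
#' `<path>.edges.tsv` with the edge attributes; `edge-tsv` writes the
#' plain edge list.
#'
#' @param net an [build_evolution_network()] result.
#' @param path output file path.
#' @param format `"graphml"`, `"sif"` or `"edge-tsv"`.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "edge-tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown network format"))
  if (format == "graphml") {
    igraph::write_graph(.as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges)) {
      sprintf("%s\tevolves_%s_%s\t%s", net$edges$pathway_i,
              net$edges$stage_from, net$edges$stage_to, net$edges$pathway_j)
    } else {
      character(0)
    }
    iso <- setdiff(net$nodes$pathway_id,
                   c(net$edges$pathway_i, net$edges$pathway_j))
    writeLines(c(lines, iso), path)
    utils::write.table(net$edges, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read an exported GraphML network back
#'
#' @param path GraphML file written by [export_network()].
#' @return an `evolution_network` (stage order recovered from edge
#'   attributes).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::as_data_frame(g, what = "vertices")
  eat <- igraph::as_data_frame(g, what = "edges")
  nodes <- if (nrow(vat)) {
    data.frame(pathway_id = vat$name,
               name = vat$label %||% vat$name,
               stages = vat$stages,
               n_hit_genes = as.integer(vat$n_hit_genes),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pathway_id = character(), name = character(),
               stages = character(), n_hit_genes = integer(),
               stringsAsFactors = FALSE)
  }
  nodes <- nodes[order(nodes$pathway_id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- if (nrow(eat)) {
    data.frame(pathway_i = eat$from, pathway_j = eat$to,
               stage_from = eat$stage_from, stage_to = eat$stage_to,
               k = as.numeric(eat$k), p = as.numeric(eat$p),
               q = as.numeric(eat$q), W = as.numeric(eat$W),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pathway_i = character(), pathway_j = character(),
               stage_from = character(), stage_to = character(),
               k = numeric(), p = numeric(), q = numeric(), W = numeric(),
               stringsAsFactors = FALSE)
  }
  stage_order <- unique(c(edges$stage_from, edges$stage_to))
  structure(list(nodes = nodes, edges = edges, stage_order = stage_order,
                 gene_basis = NA_character_),
            class = "evolution_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
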