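#' Read and write pathway databases in GMT format
#'
#' GMT is the tab-separated gene-set format: one pathway per line,
#' fields `id`, `description`, then member gene ids.  Gene sets are
#' parsed with `fgsea::gmtPathways`; the description column (which
#' fgsea drops) is recovered from the raw lines.
#'
#' @param path GMT file path.
#' @return data.frame (`pathway_id`, `name`, `genes` list column,
#'   `size`).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  desc <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "", "")
  names(desc) <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(names(sets))) {
    stop("duplicated pathway ids in ", path)
  }
  data.frame(pathway_id = names(sets),
             name = ifelse(desc[names(sets)] == "", names(sets),
                           desc[names(sets)]),
             genes = I(unname(sets)),
             size = lengths(sets),
             stringsAsFactors = FALSE)
}

#' @rdname read_gmt
#' @param db pathway data.frame with `pathway_id`, `name` and a
#'   `genes` list column.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$pathway_id[i], db$name[i], db$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Map a stage's aberrant genes to pathways
#'
#' Pools the stage's amplified and deleted genes and intersects them
#' with every pathway's gene set; a gene belonging to several pathways
#' contributes to each of them.  One record is produced per pathway
#' with at least one hit.
#'
#' @param stage_set a `stage_gene_set` (see [genes_fully_within()]).
#' @param db pathway data.frame from [read_gmt()] or
#'   [simulate_pathway_db()].
#' @return data.frame of class `stage_pathways` with columns `stage`,
#'   `pathway_id`, `name`, `pathway_size` (database gene-set size),
#'   `n_hit_genes` and `hit_genes` (list column).
#' @export
assign_genes_to_pathways <- function(stage_set, db) {
  if (nrow(db) == 0) stop("pathway database is empty")
  aberrant <- union(stage_set$amplified, stage_set$deleted)
  hits <- lapply(db$genes, function(g) sort(intersect(g, aberrant)))
  keep <- lengths(hits) >= 1L
  out <- data.frame(stage = rep(stage_set$stage, sum(keep)),
                    pathway_id = db$pathway_id[keep],
                    name = db$name[keep],
                    pathway_size = lengths(db$genes)[keep],
                    n_hit_genes = lengths(hits)[keep],
                    hit_genes = I(hits[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("stage_pathways", "data.frame")
  out
}

.empty_stage_pathways <- function() {
  out <- data.frame(stage = character(), pathway_id = character(),
                    name = character(), pathway_size = integer(),
                    n_hit_genes = integer(),
                    hit_genes = I(list()), stringsAsFactors = FALSE)
  class(out) <- c("stage_pathways", "data.frame")
  out
}

#' Size and cross-stage pathway filters
#'
#' Applies the three filters used to define stage-specific pathways:
#' drop pathways whose database gene-set size is not strictly greater
#' than `min_pathway_size` (small sets carry little biological
#' content); collapse exact duplicate (pathway, stage) records; keep
#' only pathways observed in at least `min_stages` distinct stages.
#' Filtering is idempotent and never creates records.
#'
#' @param records combined `stage_pathways` rows across stages
#'   (rbind of [assign_genes_to_pathways()] outputs).
#' @param min_pathway_size size cutoff; pathways with
#'   `pathway_size <= min_pathway_size` are dropped (default 5, i.e.
#'   sizes of 6 and above survive).
#' @param min_stages minimum number of distinct stages a pathway must
#'   appear in (default 2).
#' @return filtered `stage_pathways` data.frame.
#' @export
filter_and_cross_stage <- function(records, min_pathway_size = 5L,
                                   min_stages = 2L) {
  stopifnot(min_pathway_size >= 1, min_stages >= 1)
  if (nrow(records) == 0) return(records)
  records <- records[records$pathway_size > min_pathway_size, , drop = FALSE]
  dup <- duplicated(records[, c("pathway_id", "stage")])
  records <- records[!dup, , drop = FALSE]
  if (nrow(records)) {
    n_stages <- tapply(records$stage, records$pathway_id,
                       function(s) length(unique(s)))
    keep <- records$pathway_id %in% names(n_stages)[n_stages >= min_stages]
    records <- records[keep, , drop = FALSE]
  }
  records <- records[order(records$stage, records$pathway_id), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Write a stage-pathway table as TSV
#'
#' @param records `stage_pathways` data.frame.
#' @param path output TSV; the `hit_genes` list column is ;-joined.
#' @export
write_stage_pathways <- function(records, path) {
  flat <- data.frame(stage = records$stage, pathway_id = records$pathway_id,
                     name = records$name,
                     pathway_size = records$pathway_size,
                     n_hit_genes = records$n_hit_genes,
                     hit_genes = vapply(records$hit_genes, paste, "",
                                        collapse = ";"),
                     stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
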