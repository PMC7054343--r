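#' Read and write gene annotations as BED
#'
#' On disk genes are BED (0-based, half-open); in memory coordinates
#' are 1-based inclusive.  rtracklayer performs the conversion.  The
#' BED name field carries the gene id; the symbol defaults to the id on
#' read.
#'
#' @param path BED file path.
#' @return data.frame (`gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = if (!is.null(gr$name)) gr$name else
               sprintf("G%04d", seq_along(gr)),
             symbol = if (!is.null(gr$name)) gr$name else
               sprintf("G%04d", seq_along(gr)),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_gene_bed
#' @param genes gene data.frame as returned by
#'   [simulate_gene_annotation()].
#' @export
write_gene_bed <- function(genes, path) {
  strand <- genes$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = strand, name = genes$gene_id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Genes fully contained in significant recurrent regions
#'
#' Implements the containment criterion used to call stage-specific
#' aberrant genes: a gene is selected for an aberration type if and
#' only if some significant region of that type on the gene's
#' chromosome contains it entirely, `region.start <= gene.start` and
#' `gene.end <= region.end` (closed intervals, boundary contact
#' counts).  Strand is ignored; a gene inside both a gain and a loss
#' region appears in both sets.
#'
#' @param regions region table for a single stage (see
#'   [detect_recurrent_regions()]).
#' @param genes gene table (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`).
#' @return a list of class `stage_gene_set`: `stage`, `amplified` and
#'   `deleted` (character vectors of gene ids), `provenance` (data.frame
#'   `gene_id`, `aberration_type`, `region` with one row per supporting
#'   region) and `genes` (the gene table rows selected).
#' @export
genes_fully_within <- function(regions, genes) {
  if (nrow(regions) && length(unique(regions$stage)) > 1) {
    stop("regions from multiple stages; use annotate_stages()")
  }
  st <- if (nrow(regions)) regions$stage[1] else NA_character_
  if (nrow(regions)) {
    unmatched <- setdiff(unique(regions$chrom), unique(genes$chrom))
    if (length(unmatched)) {
      stop("region chromosomes absent from the gene annotation: ",
           paste(unmatched, collapse = ", "))
    }
  }
  sel <- function(type) {
    rr <- regions[regions$aberration_type == type, , drop = FALSE]
    if (!nrow(rr) || !nrow(genes)) {
      return(data.frame(gene_id = character(), aberration_type = character(),
                        region = character(), stringsAsFactors = FALSE))
    }
    gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                       IRanges::IRanges(genes$start, genes$end))
    gr_reg <- GenomicRanges::GRanges(rr$chrom,
                                     IRanges::IRanges(rr$start_bp, rr$end_bp))
    hits <- GenomicRanges::findOverlaps(gr_genes, gr_reg, type = "within")
    data.frame(
      gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
      aberration_type = rep(type, length(hits)),
      region = sprintf("%s:%d-%d", rr$chrom[S4Vectors::subjectHits(hits)],
                       rr$start_bp[S4Vectors::subjectHits(hits)],
                       rr$end_bp[S4Vectors::subjectHits(hits)]),
      stringsAsFactors = FALSE)
  }
  prov <- rbind(sel("gain"), sel("loss"))
  prov <- prov[order(prov$gene_id, prov$aberration_type, prov$region), ,
               drop = FALSE]
  rownames(prov) <- NULL
  amp <- sort(unique(prov$gene_id[prov$aberration_type == "gain"]))
  del <- sort(unique(prov$gene_id[prov$aberration_type == "loss"]))
  structure(list(stage = st, amplified = amp, deleted = del,
                 provenance = prov,
                 genes = genes[genes$gene_id %in% unique(prov$gene_id), ,
                               drop = FALSE]),
            class = "stage_gene_set")
}

#' @export
print.stage_gene_set <- function(x, ...) {
  cat(sprintf("stage_gene_set [%s]: %d amplified, %d deleted genes\n",
              x$stage, length(x$amplified), length(x$deleted)))
  invisible(x)
}

#' Annotate every stage's regions with contained genes
#'
#' @param regions combined region table from [detect_all_stages()].
#' @param genes gene table.
#' @param stages stage labels to annotate (default: those present in
#'   `regions`).
#' @return named list of [genes_fully_within()] results, one per stage.
#' @export
annotate_stages <- function(regions, genes, stages = NULL) {
  if (is.null(stages)) stages <- sort(unique(regions$stage))
  out <- lapply(stages, function(st) {
    gs <- genes_fully_within(regions[regions$stage == st, , drop = FALSE],
                             genes)
    gs$stage <- st
    gs
  })
  names(out) <- stages
  out
}

#' Write per-stage gene lists as TSV
#'
#' @param gene_sets named list of `stage_gene_set`.
#' @param path output TSV.
#' @export
write_gene_sets <- function(gene_sets, path) {
  rows <- lapply(gene_sets, function(gs) {
    if (!nrow(gs$provenance)) return(NULL)
    agg <- stats::aggregate(region ~ gene_id + aberration_type,
                            gs$provenance, paste, collapse = ";")
    data.frame(stage = gs$stage, aberration_type = agg$aberration_type,
               gene_id = agg$gene_id, supporting_regions = agg$region,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(stage = character(), aberration_type = character(),
               gene_id = character(), supporting_regions = character(),
               stringsAsFactors = FALSE))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
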