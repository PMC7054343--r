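#' Construct and validate a probe map
#'
#' A probe map places every measured marker on the genome: one row per
#' probe with its identifier, chromosome and 1-based base-pair position.
#' Probes are stored in genome order (chromosomes in natural order, then
#' increasing position) and carry a `rank` column that is a bijection onto
#' `1..M`; ranks index the columns of every call matrix built on the map.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom chromosome name per probe.
#' @param pos 1-based base-pair position per probe; must be strictly
#'   increasing within each chromosome.
#' @return a `data.frame` of class `probe_map` with columns `probe_id`,
#'   `chrom`, `pos`, `rank`, sorted in genome order.
#' @examples
#' pm <- probe_map(paste0("P", 1:4), rep("chr1", 4), c(10, 20, 30, 40))
#' @export
probe_map <- function(probe_id, chrom, pos) {
  stopifnot(length(probe_id) == length(chrom), length(chrom) == length(pos))
  if (length(probe_id) == 0L) stop("probe map must contain at least one probe")
  if (anyDuplicated(probe_id)) {
    stop("duplicated probe ids: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  }
  pm <- data.frame(probe_id = as.character(probe_id),
                   chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   stringsAsFactors = FALSE)
  pm <- pm[order_genome(pm$chrom, pm$pos), , drop = FALSE]
  for (cn in unique(pm$chrom)) {
    p <- pm$pos[pm$chrom == cn]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", cn)
    }
  }
  pm$rank <- seq_len(nrow(pm))
  rownames(pm) <- NULL
  class(pm) <- c("probe_map", "data.frame")
  pm
}

# Natural genome ordering of chromosome names: a shared alphabetic prefix
# ("chr") is ignored, numeric bodies sort numerically, non-numeric ones
# (X, Y, MT) after them alphabetically.  Keeps results invariant to the
# order chromosomes appear in the input files.
chrom_order_key <- function(chrom) {
  body <- sub("^[Cc][Hh][Rr]", "", chrom)
  num <- suppressWarnings(as.numeric(body))
  is_num <- !is.na(num)
  key_num <- ifelse(is_num, num, Inf)
  list(key_num, body)
}

order_genome <- function(chrom, pos) {
  key <- chrom_order_key(chrom)
  order(key[[1]], key[[2]], pos)
}

#' @export
print.probe_map <- function(x, ...) {
  cat("probe_map: ", nrow(x), " probes on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Read or write a probe map as TSV
#'
#' The on-disk format is a three-column tab-separated table with header
#' `probe_id`, `chrom`, `pos`.
#'
#' @param path file path.
#' @return `read_probe_map` returns a [probe_map]; `write_probe_map`
#'   returns `path` invisibly.
#' @export
read_probe_map <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tb))) {
    stop("probe map file must have columns: ", paste(need, collapse = ", "))
  }
  probe_map(tb$probe_id, tb$chrom, tb$pos)
}

#' @rdname read_probe_map
#' @param pm a [probe_map].
#' @export
write_probe_map <- function(pm, path) {
  utils::write.table(pm[, c("probe_id", "chrom", "pos")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# First/last rank of the chromosome containing rank j (used to stop
# boundary expansion at chromosome ends).
chrom_span <- function(pm, rank) {
  cn <- pm$chrom[rank]
  r <- range(pm$rank[pm$chrom == cn])
  c(first = r[1], last = r[2])
}
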