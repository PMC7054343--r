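#' Ternary aberration call matrix
#'
#' The central container: an `N x M` matrix of discrete per-sample,
#' per-probe copy-number calls, with `+1` for a gain, `-1` for a loss and
#' `0` for no alteration.  Columns follow the genome order of the probe
#' map; rows are samples from a single pathology stage.
#'
#' @param values integer matrix with entries in `{-1, 0, 1}`.
#' @param sample_ids unique sample identifiers, one per row.
#' @param probe_map a [probe_map] whose probes match the columns (matched
#'   by probe id when `values` has column names, by order otherwise).
#' @param stage stage label of the cohort the samples belong to.
#' @return an object of class `call_matrix`.
#' @seealso [split_matrix()], [read_call_matrix()]
#' @export
call_matrix <- function(values, sample_ids, probe_map, stage = "unstaged") {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("call matrix must have at least one sample and one probe")
  }
  if (!all(values %in% c(-1L, 0L, 1L))) {
    bad <- which(matrix(!(values %in% c(-1L, 0L, 1L)), nrow(values)),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("cell (%d, %d) holds %s; calls must be -1, 0 or 1",
                 bad[1], bad[2], format(values[bad[1], bad[2]])))
  }
  if (length(sample_ids) != nrow(values)) stop("one sample id per row required")
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  stopifnot(inherits(probe_map, "probe_map"))
  if (!is.null(colnames(values))) {
    missing <- setdiff(colnames(values), probe_map$probe_id)
    if (length(missing)) {
      stop("probes absent from the probe map: ",
           paste(missing, collapse = ", "))
    }
    if (ncol(values) != nrow(probe_map)) {
      stop("matrix has ", ncol(values), " probes but the probe map has ",
           nrow(probe_map))
    }
    values <- values[, probe_map$probe_id, drop = FALSE]  # genome order
  } else {
    if (ncol(values) != nrow(probe_map)) {
      stop("matrix/probe map column count mismatch")
    }
    colnames(values) <- probe_map$probe_id
  }
  storage.mode(values) <- "integer"
  rownames(values) <- as.character(sample_ids)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 probe_map = probe_map,
                 stage = stage),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix [stage %s]: %d samples x %d probes (%d gains, %d losses)\n",
              x$stage, nrow(x$values), ncol(x$values),
              sum(x$values == 1L), sum(x$values == -1L)))
  invisible(x)
}

#' Binary gain or loss indicator matrix
#'
#' One half of the gain/loss split of a ternary call matrix: entries are
#' `1` where the sample carries the given aberration type at the marker
#' and `0` otherwise.
#'
#' @param values matrix with entries in `{0, 1}`.
#' @param aberration_type `"gain"` or `"loss"`.
#' @inheritParams call_matrix
#' @return an object of class `binary_matrix`.
#' @export
binary_matrix <- function(values, aberration_type = c("gain", "loss"),
                          sample_ids = rownames(values), probe_map,
                          stage = "unstaged") {
  aberration_type <- match.arg(aberration_type)
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L))) stop("binary matrix entries must be 0 or 1")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  cm <- call_matrix(values, sample_ids, probe_map, stage)  # reuse validation
  structure(list(values = cm$values,
                 aberration_type = aberration_type,
                 sample_ids = cm$sample_ids,
                 probe_map = cm$probe_map,
                 stage = cm$stage),
            class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix [%s, stage %s]: %d samples x %d probes, %d aberrant cells\n",
              x$aberration_type, x$stage, nrow(x$values), ncol(x$values),
              sum(x$values)))
  invisible(x)
}

#' Split a ternary call matrix into gain and loss indicator matrices
#'
#' Produces the pair `AL` (gains) and `AD` (losses): `AL = 1(A == +1)`,
#' `AD = 1(A == -1)`.  The two never overlap and `AL - AD` reconstructs
#' the original matrix.
#'
#' @param A a [call_matrix].
#' @return a list with elements `AL` and `AD`, both [binary_matrix].
#' @examples
#' pm <- probe_map(paste0("P", 1:3), rep("chr1", 3), c(1, 2, 3) * 100)
#' A <- call_matrix(rbind(c(1, 1, 0), c(0, -1, -1)), c("s1", "s2"), pm)
#' split_matrix(A)$AL$values
#' @export
split_matrix <- function(A) {
  stopifnot(inherits(A, "call_matrix"))
  mk <- function(ind, type) {
    binary_matrix((A$values == ind) * 1L, type,
                  sample_ids = A$sample_ids, probe_map = A$probe_map,
                  stage = A$stage)
  }
  list(AL = mk(1L, "gain"), AD = mk(-1L, "loss"))
}

#' Threshold a log2-ratio matrix into discrete calls
#'
#' Courtesy adapter for segmented log2-ratio input: values strictly above
#' `gain_thr` become gains (+1), strictly below `loss_thr` losses (-1),
#' everything else (ties at a threshold included) no alteration.
#'
#' @param seg_values numeric sample-by-probe matrix of log2 ratios; all
#'   entries must be finite.
#' @param gain_thr positive gain threshold (default 0.3).
#' @param loss_thr negative loss threshold (default -0.3).
#' @inheritParams call_matrix
#' @return a [call_matrix].
#' @export
discretize_log2 <- function(seg_values, probe_map,
                            gain_thr = 0.3, loss_thr = -0.3,
                            sample_ids = rownames(seg_values),
                            stage = "unstaged") {
  if (!(gain_thr > 0 && loss_thr < 0)) stop("need gain_thr > 0 > loss_thr")
  seg_values <- as.matrix(seg_values)
  if (any(!is.finite(seg_values))) {
    bad <- which(!is.finite(seg_values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log2 ratio at cell (%d, %d)", bad[1], bad[2]))
  }
  calls <- matrix(0L, nrow(seg_values), ncol(seg_values),
                  dimnames = dimnames(seg_values))
  calls[seg_values > gain_thr] <- 1L
  calls[seg_values < loss_thr] <- -1L
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  call_matrix(calls, sample_ids, probe_map, stage)
}

#' Expand SEG-style segments to a per-probe log2-ratio matrix
#'
#' Takes a segment table (`sample`, `chrom`, `start`, `end`, `log2`;
#' 1-based inclusive coordinates) and evaluates each probe of the map
#' inside each sample's segments.  Probes covered by no segment get 0
#' (diploid); overlapping segments within one sample are an error.
#'
#' @param seg data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log2`.
#' @param pm a [probe_map].
#' @return numeric matrix (samples x probes) suitable for
#'   [discretize_log2()].
#' @export
seg_to_matrix <- function(seg, pm) {
  need <- c("sample", "chrom", "start", "end", "log2")
  if (!all(need %in% names(seg))) {
    stop("segment table needs columns: ", paste(need, collapse = ", "))
  }
  samples <- unique(as.character(seg$sample))
  out <- matrix(0, length(samples), nrow(pm),
                dimnames = list(samples, pm$probe_id))
  probes <- GenomicRanges::GRanges(pm$chrom, IRanges::IRanges(pm$pos, pm$pos))
  for (s in samples) {
    rows <- seg[seg$sample == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(rows$chrom,
                                 IRanges::IRanges(rows$start, rows$end))
    if (length(gr) > 1 &&
        sum(IRanges::width(GenomicRanges::reduce(gr))) < sum(IRanges::width(gr))) {
      stop("overlapping segments for sample ", s)
    }
    hits <- GenomicRanges::findOverlaps(probes, gr)
    out[s, S4Vectors::queryHits(hits)] <- rows$log2[S4Vectors::subjectHits(hits)]
  }
  out
}

#' Read and write stage-grouped call matrices
#'
#' The call matrix TSV has one row per sample (first column `sample_id`)
#' and one column per probe id, with cells in `{-1, 0, 1}`.  A sidecar
#' stage file (`sample_id`, `stage`) assigns each sample to a pathology
#' stage; `read_call_matrix` partitions the rows accordingly and returns
#' one [call_matrix] per stage, columns re-sorted into genome order.
#'
#' @param path call matrix TSV.
#' @param probe_map_path probe map TSV (see [read_probe_map()]).
#' @param stage_map_path two-column TSV `sample_id`, `stage`.
#' @return named list of [call_matrix], one per stage, in natural stage
#'   order.
#' @export
read_call_matrix <- function(path, probe_map_path, stage_map_path) {
  pm <- read_probe_map(probe_map_path)
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tb)[1] != "sample_id") stop("first column must be 'sample_id'")
  sample_ids <- as.character(tb$sample_id)
  vals <- as.matrix(tb[, -1, drop = FALSE])
  bad <- which(matrix(!(vals %in% c(-1, 0, 1)), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid call %s at sample '%s', probe '%s'",
                 format(vals[bad[1, 1], bad[1, 2]]),
                 sample_ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  stages <- utils::read.delim(stage_map_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage") %in% names(stages))) {
    stop("stage map needs columns sample_id, stage")
  }
  missing <- setdiff(sample_ids, stages$sample_id)
  if (length(missing)) {
    stop("samples without a stage label: ", paste(missing, collapse = ", "))
  }
  lab <- stages$stage[match(sample_ids, stages$sample_id)]
  out <- lapply(sort(unique(lab)), function(st) {
    call_matrix(vals[lab == st, , drop = FALSE], sample_ids[lab == st],
                pm, stage = st)
  })
  names(out) <- sort(unique(lab))
  out
}

#' @rdname read_call_matrix
#' @param matrices named list of [call_matrix] (one per stage) sharing a
#'   probe map.
#' @param dir output directory; writes `calls.tsv`, `probes.tsv`,
#'   `stages.tsv`.
#' @export
write_call_matrix <- function(matrices, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- matrices[[1]]$probe_map
  vals <- do.call(rbind, lapply(matrices, function(m) m$values))
  df <- data.frame(sample_id = rownames(vals), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_probe_map(pm, file.path(dir, "probes.tsv"))
  st <- data.frame(
    sample_id = unlist(lapply(matrices, function(m) m$sample_ids)),
    stage = rep(vapply(matrices, function(m) m$stage, ""),
                vapply(matrices, function(m) length(m$sample_ids), 0L)))
  utils::write.table(st, file.path(dir, "stages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
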