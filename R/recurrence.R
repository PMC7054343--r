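#' Detection parameters for the recurrent-aberration detector
#'
#' @param q_thr FDR threshold on marker q-values; a marker belongs to a
#'   recurrent region only if its Benjamini-Hochberg q-value is at or
#'   below this (default 0.10).
#' @param h_thr homogeneity threshold in `[0, 1]` for boundary
#'   expansion: a region boundary crosses a marker junction only while
#'   the junction's h-value (mean per-sample discordance, see
#'   [h_profile()]) stays at or below it.  0 demands perfect
#'   concordance, 1 disables the homogeneity condition entirely.
#'   Default 0.12.
#' @param n_perm number of Monte-Carlo permutations for the per-marker
#'   null (default 10000).
#' @param max_iterations cap on peel-off rounds, i.e. on the number of
#'   independent regions reported per aberration type (default 10).
#' @param seed integer seed for the permutation null.
#' @return a list of class `detection_config`.
#' @export
detection_config <- function(q_thr = 0.10, h_thr = 0.12, n_perm = 10000L,
                             max_iterations = 10L, seed = 1L) {
  stopifnot(q_thr > 0, q_thr < 1, h_thr >= 0, h_thr <= 1,
            n_perm >= 100, max_iterations >= 1)
  structure(list(q_thr = q_thr, h_thr = h_thr, n_perm = as.integer(n_perm),
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "detection_config")
}

#' Per-marker aberrant sample counts
#'
#' @param B a [binary_matrix].
#' @return integer vector of length M: number of samples aberrant at
#'   each marker.
#' @export
marker_counts <- function(B) {
  stopifnot(inherits(B, "binary_matrix"))
  colSums(B$values)
}

# Deterministic substream seed for one chromosome / peel iteration, so
# p-values do not depend on the order chromosomes are processed in and
# each peel-off round gets a fresh null.  Polynomial string hash keeps
# distinct chromosome names apart ("chr12" vs "chr21").
.chrom_seed <- function(seed, chrom, iteration, type) {
  h <- 17
  for (ch in utf8ToInt(paste0(chrom, "/", type))) {
    h <- (h * 31 + ch) %% 1977326743  # 7^11, < 2^31
  }
  as.integer((seed + h + iteration * 99991) %% .Machine$integer.max)
}

#' Permutation significance of per-marker aberration counts
#'
#' For every marker the observed number of aberrant samples is compared
#' against a null in which each sample's calls are independently
#' permuted across the markers of the same chromosome, preserving the
#' per-sample aberration load.  Under such a permutation a sample with
#' load `L` on a chromosome of `M_c` markers is aberrant at any given
#' marker with probability `L / M_c`, independently across samples, so
#' the null count at a marker is drawn as the sum of those Bernoulli
#' indicators; one shared set of `n_perm` draws serves all markers of a
#' chromosome (their null distributions are identical by
#' exchangeability).  The add-one estimator
#' `p = (1 + #[null >= observed]) / (1 + n_perm)` never returns zero.
#' Loads are sorted before drawing, making p-values invariant to sample
#' order.
#'
#' @param B a [binary_matrix] with at least 2 samples.
#' @param cfg a [detection_config].
#' @param iteration internal peel-off round index; selects the RNG
#'   substream so each round uses a fresh null.
#' @return a list of class `significance_profile` with elements
#'   `counts`, `p_values`, `q_values` (length M), `n_perm`,
#'   `aberration_type`.
#' @export
permutation_pvalues <- function(B, cfg = detection_config(), iteration = 1L) {
  stopifnot(inherits(B, "binary_matrix"))
  N <- nrow(B$values)
  if (N < 2) stop("permutation null requires at least 2 samples")
  obs <- marker_counts(B)
  p <- numeric(length(obs))
  pm <- B$probe_map
  for (cn in unique(pm$chrom)) {
    idx <- which(pm$chrom == cn)
    Mc <- length(idx)
    loads <- sort(rowSums(B$values[, idx, drop = FALSE]))
    prob <- loads / Mc
    rng <- .fresh_rng(.chrom_seed(cfg$seed, cn, iteration, B$aberration_type))
    null_counts <- rng(function() {
      draws <- matrix(stats::runif(cfg$n_perm * N), cfg$n_perm, N)
      as.integer(rowSums(draws < rep(prob, each = cfg$n_perm)))
    })
    # tail[c+1] = #draws with null >= c, for c = 0..N
    tab <- tabulate(null_counts + 1L, nbins = N + 1L)
    tail <- rev(cumsum(rev(tab)))
    p[idx] <- (1 + tail[obs[idx] + 1L]) / (1 + cfg$n_perm)
  }
  structure(list(counts = obs, p_values = p, q_values = bh_qvalues(p),
                 n_perm = cfg$n_perm, aberration_type = B$aberration_type),
            class = "significance_profile")
}

# Run `expr()` under a private RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.fresh_rng <- function(seed) {
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr()
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values, clipped to `[0, 1]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order as `p`; empty input yields an
#'   empty vector.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(stats::p.adjust(p, method = "BH"), 1)
}

#' Adjacent-marker homogeneity matrix
#'
#' For every sample and every pair of adjacent markers (j, j+1) the
#' matrix H records how concordant the two calls are: `0` (maximum
#' homogeneity) when the two states are equal — both carrying the
#' aberration or both unaltered — `0.5` (medium) when both markers are
#' aberrant but at different magnitude levels (only possible when `B`
#' holds multi-level calls such as 1 = gain, 2 = high-level gain), and
#' `1` (minimum) when exactly one of the pair is aberrant.  Junctions
#' that pair the last marker of one chromosome with the first of the
#' next are meaningless and set to `NA`; they are never crossed by
#' boundary expansion.
#'
#' @param B a [binary_matrix] (or a matrix-bearing object whose values
#'   are non-negative integer aberration levels) with at least 2
#'   markers.
#' @return numeric `N x (M-1)` matrix of class `homogeneity_matrix`
#'   with entries in `{0, 0.5, 1}` (and `NA` at chromosome junctions).
#' @export
homogeneity_matrix <- function(B) {
  v <- B$values
  if (ncol(v) < 2) stop("homogeneity needs at least two markers")
  left <- v[, -ncol(v), drop = FALSE]
  right <- v[, -1, drop = FALSE]
  H <- matrix(1, nrow(v), ncol(v) - 1L)
  H[left == right] <- 0
  H[left != right & left > 0 & right > 0] <- 0.5
  pm <- B$probe_map
  cross <- which(pm$chrom[-nrow(pm)] != pm$chrom[-1])
  H[, cross] <- NA_real_
  colnames(H) <- paste0(pm$probe_id[-nrow(pm)], "|", pm$probe_id[-1])
  class(H) <- c("homogeneity_matrix", class(H))
  H
}

#' Per-junction homogeneity profile (h-values)
#'
#' The h-value of junction j is the column mean of the homogeneity
#' matrix, `h_j = (1/N) * sum_i H_ij`: 0 means every sample is
#' concordant across the junction, 1 means every sample is discordant.
#'
#' @param H a [homogeneity_matrix()].
#' @return numeric vector of length M-1 in `[0, 1]` (`NA` at
#'   chromosome junctions).
#' @export
h_profile <- function(H) {
  colMeans(unclass(H))
}

#' Expand a significant peak into a homogeneous region
#'
#' Starting from `l = r = peak_rank`, the left boundary moves one
#' marker left while `q[l-1] <= q_thr` and `h[l-1] <= h_thr` (the
#' junction between markers l-1 and l), and the right boundary moves
#' right while `q[r+1] <= q_thr` and `h[r] <= h_thr`.  Expansion never
#' crosses a chromosome boundary.
#'
#' @param q per-marker q-values (length M).
#' @param h per-junction h-values (length M-1), as from [h_profile()].
#' @param peak_rank genome rank of the peak marker; must itself satisfy
#'   `q <= q_thr`.
#' @param pm the [probe_map] the ranks refer to.
#' @param cfg a [detection_config] supplying `q_thr` and `h_thr`.
#' @return integer vector `c(l, r)` of final boundary ranks.
#' @export
expand_peak <- function(q, h, peak_rank, pm, cfg = detection_config()) {
  if (q[peak_rank] > cfg$q_thr) {
    stop("peak marker is not significant at q_thr = ", cfg$q_thr)
  }
  span <- chrom_span(pm, peak_rank)
  l <- r <- peak_rank
  repeat {
    moved <- FALSE
    if (l > span["first"] &&
        q[l - 1] <= cfg$q_thr &&
        !is.na(h[l - 1]) && h[l - 1] <= cfg$h_thr) {
      l <- l - 1L
      moved <- TRUE
    }
    if (r < span["last"] &&
        q[r + 1] <= cfg$q_thr &&
        !is.na(h[r]) && h[r] <= cfg$h_thr) {
      r <- r + 1L
      moved <- TRUE
    }
    if (!moved) break
  }
  c(l = as.integer(l), r = as.integer(r))
}

.empty_regions <- function() {
  data.frame(stage = character(), aberration_type = character(),
             chrom = character(), l = integer(), r = integer(),
             start_bp = numeric(), end_bp = numeric(),
             peak_rank = integer(), peak_q = numeric(),
             frequency = numeric(), iteration = integer(),
             stringsAsFactors = FALSE)
}

#' Detect stage-specific recurrent aberration regions
#'
#' The iterative homogeneous peel-off: compute per-marker permutation
#' p-values and genome-wide Benjamini-Hochberg q-values; stop when no
#' marker reaches `q_thr`; otherwise take the marker of minimum q (ties
#' broken by lowest genome rank) as the peak, expand it into a region
#' with [expand_peak()], record the region, and peel it off by zeroing
#' the calls of every sample aberrant at the peak marker across the
#' whole region, so that further independent events can surface.  The
#' loop runs at most `max_iterations` rounds; significance is
#' recomputed on the peeled matrix every round.
#'
#' @param B a [binary_matrix] for one stage and one aberration type.
#' @param cfg a [detection_config].
#' @return data.frame of recurrent regions with columns `stage`,
#'   `aberration_type`, `chrom`, `l`, `r` (boundary ranks), `start_bp`,
#'   `end_bp`, `peak_rank`, `peak_q`, `frequency` (peak count / N) and
#'   `iteration`; zero rows when nothing is significant.
#' @export
detect_recurrent_regions <- function(B, cfg = detection_config()) {
  stopifnot(inherits(B, "binary_matrix"))
  pm <- B$probe_map
  N <- nrow(B$values)
  work <- B
  out <- .empty_regions()
  for (it in seq_len(cfg$max_iterations)) {
    if (sum(work$values) == 0) break
    prof <- permutation_pvalues(work, cfg, iteration = it)
    q <- prof$q_values
    if (min(q) > cfg$q_thr) break
    peak <- which(q == min(q))[1]
    h <- h_profile(homogeneity_matrix(work))
    lr <- expand_peak(q, h, peak, pm, cfg)
    out <- rbind(out, data.frame(
      stage = B$stage, aberration_type = B$aberration_type,
      chrom = pm$chrom[peak], l = lr[["l"]], r = lr[["r"]],
      start_bp = pm$pos[lr[["l"]]], end_bp = pm$pos[lr[["r"]]],
      peak_rank = peak, peak_q = q[peak],
      frequency = prof$counts[peak] / N, iteration = it,
      stringsAsFactors = FALSE))
    carriers <- work$values[, peak] == 1L
    work$values[carriers, lr[["l"]]:lr[["r"]]] <- 0L
  }
  rownames(out) <- NULL
  out
}

#' Detect recurrent gains and losses for every stage
#'
#' Convenience wrapper: splits each stage's ternary matrix into gain and
#' loss indicators and runs [detect_recurrent_regions()] on both,
#' separately per stage (FDR control is applied per stage and per type).
#'
#' @param matrices named list of [call_matrix], one per stage.
#' @param cfg a [detection_config].
#' @return combined region data.frame (see [detect_recurrent_regions()]).
#' @export
detect_all_stages <- function(matrices, cfg = detection_config()) {
  res <- lapply(matrices, function(A) {
    sp <- split_matrix(A)
    rbind(detect_recurrent_regions(sp$AL, cfg),
          detect_recurrent_regions(sp$AD, cfg))
  })
  out <- do.call(rbind, c(res, list(.empty_regions())))
  rownames(out) <- NULL
  out
}

#' Maximal homogeneous sample-by-interval blocks
#'
#' Enumerates all maximal biclusters of a ternary call matrix: a
#' contiguous probe interval within one chromosome together with the
#' full set of samples carrying the same non-zero state across it, such
#' that neither widening the interval (the sample set would shrink) nor
#' adding a sample (none qualifies) is possible.
#'
#' @param A a [call_matrix].
#' @param min_samples minimum number of samples per block (>= 2).
#' @param min_span minimum number of probes per block (>= 1).
#' @return data.frame with columns `chrom`, `from`, `to` (probe ranks),
#'   `probe_from`, `probe_to`, `state` (+1/-1), `n_samples`, `samples`
#'   (comma-joined ids).
#' @export
find_shared_runs <- function(A, min_samples = 2L, min_span = 1L) {
  stopifnot(inherits(A, "call_matrix"), min_samples >= 2, min_span >= 1)
  pm <- A$probe_map
  v <- A$values
  rows <- list()
  for (cn in unique(pm$chrom)) {
    idx <- which(pm$chrom == cn)
    for (state in c(1L, -1L)) {
      ok <- v[, idx, drop = FALSE] == state
      for (a in seq_along(idx)) {
        in_run <- rep(TRUE, nrow(v))
        for (b in a:length(idx)) {
          in_run <- in_run & ok[, b]
          if (!any(in_run)) break
          span <- b - a + 1L
          if (sum(in_run) < min_samples || span < min_span) next
          # maximal iff extending either side strictly shrinks the set
          can_left <- a > 1L && all(ok[in_run, a - 1L])
          can_right <- b < length(idx) && all(ok[in_run, b + 1L])
          if (!can_left && !can_right) {
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = cn, from = idx[a], to = idx[b],
              probe_from = pm$probe_id[idx[a]], probe_to = pm$probe_id[idx[b]],
              state = state, n_samples = sum(in_run),
              samples = paste(A$sample_ids[in_run], collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), from = integer(), to = integer(),
                      probe_from = character(), probe_to = character(),
                      state = integer(), n_samples = integer(),
                      samples = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$from, out$to, -out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-probe aberration frequency track
#'
#' @param B a [binary_matrix].
#' @return data.frame (`chrom`, `pos`, `frequency`, `aberration_type`,
#'   `stage`), one row per probe, writable as bedGraph with
#'   [write_bedgraph()].
#' @export
frequency_track <- function(B) {
  stopifnot(inherits(B, "binary_matrix"))
  data.frame(chrom = B$probe_map$chrom, pos = B$probe_map$pos,
             frequency = marker_counts(B) / nrow(B$values),
             aberration_type = B$aberration_type, stage = B$stage,
             stringsAsFactors = FALSE)
}

#' Write a frequency track as bedGraph
#'
#' Each probe becomes a 1-bp interval scored with its aberration
#' frequency.
#'
#' @param track output of [frequency_track()].
#' @param path output file path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$pos, track$pos),
                               score = track$frequency)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write detected regions as TSV and BED
#'
#' @param regions region table from [detect_recurrent_regions()] or
#'   [detect_all_stages()].
#' @param tsv_path,bed_path output paths (either may be `NULL` to skip).
#' @export
write_regions <- function(regions, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    flat <- regions
    for (col in c("start_bp", "end_bp")) {  # plain digits, never 5e+05
      flat[[col]] <- format(flat[[col]], scientific = FALSE, trim = TRUE)
    }
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    if (nrow(regions)) {
      gr <- GenomicRanges::GRanges(
        regions$chrom, IRanges::IRanges(regions$start_bp, regions$end_bp),
        name = paste(regions$stage, regions$aberration_type,
                     regions$iteration, sep = "_"))
      rtracklayer::export(gr, bed_path, format = "BED")
    } else {
      file.create(bed_path)
    }
  }
  invisible(regions)
}
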