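# Shared fixtures and independent brute-force oracles.

# Simple single-chromosome probe map: P1..PM at 10kb spacing.
toy_pm <- function(M, chrom = "chr1") {
  probe_map(paste0("P", seq_len(M)), rep(chrom, M), seq_len(M) * 10000)
}

toy_binary <- function(vals, type = "gain", pm = NULL, stage = "t1") {
  vals <- rbind(vals)
  if (is.null(pm)) pm <- toy_pm(ncol(vals))
  binary_matrix(vals, type, sample_ids = paste0("S", seq_len(nrow(vals))),
                probe_map = pm, stage = stage)
}

# The worked 3x7 single-chromosome example: two homogeneous gain blocks,
# P4-P6 carried by S1 and S2, P5-P7 by S2 and S3.
fig_example_matrix <- function() {
  vals <- rbind(S1 = c(0, 0, 0, 1, 1, 1, 0),
                S2 = c(0, 0, 0, 1, 1, 1, 1),
                S3 = c(0, 0, 0, 0, 1, 1, 1))
  call_matrix(vals, rownames(vals), toy_pm(7), stage = "demo")
}

# Exact permutation null by brute force: enumerate every arrangement of
# each row's ones across the M markers (all rows jointly), and return
# the per-marker tail probability P(count_j >= c) for c = 0..N.
# Rows: binary matrix on a single chromosome.
enum_tail_probs <- function(vals) {
  M <- ncol(vals)
  N <- nrow(vals)
  row_arrangements <- lapply(seq_len(N), function(i) {
    L <- sum(vals[i, ])
    if (L == 0) return(matrix(0L, 1, M))
    pos <- utils::combn(M, L)
    t(apply(pos, 2, function(p) { v <- integer(M); v[p] <- 1L; v }))
  })
  counts_per_arr <- Reduce(function(acc, arr) {
    # cartesian accumulation of column-count matrices
    out <- matrix(0L, nrow(acc) * nrow(arr), M)
    r <- 1L
    for (i in seq_len(nrow(acc))) for (j in seq_len(nrow(arr))) {
      out[r, ] <- acc[i, ] + arr[j, ]
      r <- r + 1L
    }
    out
  }, row_arrangements[-1], row_arrangements[[1]])
  # tails[j, c+1] = P(count_j >= c)
  tails <- matrix(0, M, N + 1)
  for (cc in 0:N) tails[, cc + 1] <- colMeans(counts_per_arr >= cc)
  tails
}

# All-pairs closed-interval containment oracle.
brute_containment <- function(regions, genes, type) {
  rr <- regions[regions$aberration_type == type, , drop = FALSE]
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(rr))) {
      if (genes$chrom[i] == rr$chrom[j] &&
          rr$start_bp[j] <= genes$start[i] && genes$end[i] <= rr$end_bp[j]) {
        hit[i] <- TRUE
      }
    }
  }
  sort(genes$gene_id[hit])
}

# Exhaustive bicluster oracle: every (sample subset, contiguous interval)
# pair with a constant non-zero state, kept only if maximal by definition
# (no sample can be added, no boundary extended).
brute_biclusters <- function(A, min_samples, min_span) {
  v <- A$values
  pm <- A$probe_map
  N <- nrow(v)
  found <- list()
  subsets <- lapply(seq_len(2^N - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0))
  for (cn in unique(pm$chrom)) {
    idx <- which(pm$chrom == cn)
    for (a in seq_along(idx)) for (b in a:length(idx)) {
      if (b - a + 1 < min_span) next
      cols <- idx[a:b]
      for (S in subsets) {
        if (length(S) < min_samples) next
        for (state in c(1L, -1L)) {
          block <- v[S, cols, drop = FALSE]
          if (!all(block == state)) next
          # sample-maximal: no further row is constant `state` on cols
          others <- setdiff(seq_len(N), S)
          if (length(others) &&
              any(vapply(others, function(i) all(v[i, cols] == state), TRUE))) next
          # interval-maximal: extending either side keeps all of S
          if (a > 1 && all(v[S, idx[a - 1]] == state)) next
          if (b < length(idx) && all(v[S, idx[b + 1]] == state)) next
          found[[length(found) + 1]] <- list(chrom = cn, from = idx[a],
                                             to = idx[b], state = state,
                                             samples = sort(S))
        }
      }
    }
  }
  found
}

# Normalize find_shared_runs output for comparison with the oracle.
runs_as_keys <- function(runs) {
  paste(runs$chrom, runs$from, runs$to, runs$state, runs$samples, sep = "|")
}

bicluster_keys <- function(bcs, sample_ids) {
  vapply(bcs, function(b) {
    paste(b$chrom, b$from, b$to, b$state,
          paste(sample_ids[b$samples], collapse = ","), sep = "|")
  }, "")
}
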