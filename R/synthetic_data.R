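#' Planted recurrent region specification
#'
#' Ground truth for simulator output: a contiguous probe interval on one
#' chromosome that a configurable fraction of one stage's samples carry
#' as a gain or a loss.
#'
#' @param stage stage label the plant belongs to.
#' @param chrom chromosome name.
#' @param probe_start,probe_end within-chromosome probe indices
#'   (1-based, inclusive) of the planted span.
#' @param aberration_type `"gain"` or `"loss"`.
#' @param frequency probability in (0, 1] that a sample carries the
#'   plant.
#' @param carrier_overlap fraction of carriers that span the full
#'   region; the remainder carry a random contiguous sub-span, which
#'   lowers junction homogeneity inside the plant.  Default 1 (a fully
#'   homogeneous block).
#' @return a list of class `planted_region`.
#' @export
planted_region <- function(stage, chrom, probe_start, probe_end,
                           aberration_type = c("gain", "loss"),
                           frequency, carrier_overlap = 1) {
  aberration_type <- match.arg(aberration_type)
  stopifnot(probe_start >= 1, probe_start <= probe_end,
            frequency > 0, frequency <= 1,
            carrier_overlap >= 0, carrier_overlap <= 1)
  structure(list(stage = stage, chrom = chrom,
                 probe_start = as.integer(probe_start),
                 probe_end = as.integer(probe_end),
                 aberration_type = aberration_type,
                 frequency = frequency, carrier_overlap = carrier_overlap),
            class = "planted_region")
}

#' Simulation configuration
#'
#' Describes a stage-grouped cohort: stages in progression order, the
#' number of samples per stage, a genome as a set of chromosomes whose
#' probe spans sum to `n_probes`, planted recurrent regions, and an
#' i.i.d. per-cell background aberration rate.
#'
#' @param stages ordered character vector of stage labels.
#' @param n_samples_per_stage positive integer vector, one per stage.
#' @param chromosomes named integer vector: probes per chromosome; the
#'   sum defines the total probe count.
#' @param planted_regions list of [planted_region()].
#' @param background_rate per-cell, per-type probability of a spurious
#'   background call (default 0.01).
#' @param probe_spacing_bp distance between adjacent probe positions
#'   (default 10000).
#' @param seed master seed; each stage draws from its own substream so
#'   adding a stage never perturbs earlier stages.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(stages, n_samples_per_stage, chromosomes,
                       planted_regions = list(), background_rate = 0.01,
                       probe_spacing_bp = 10000, seed = 1L) {
  stopifnot(length(stages) == length(n_samples_per_stage),
            all(n_samples_per_stage >= 1),
            background_rate >= 0, background_rate < 1,
            length(chromosomes) >= 1, all(chromosomes >= 1),
            !is.null(names(chromosomes)))
  for (p in planted_regions) {
    stopifnot(inherits(p, "planted_region"))
    if (!p$stage %in% stages) stop("planted region in unknown stage ", p$stage)
    if (!p$chrom %in% names(chromosomes)) {
      stop("planted region on unknown chromosome ", p$chrom)
    }
    if (p$probe_end > chromosomes[[p$chrom]]) {
      stop("planted region exceeds probe span of ", p$chrom)
    }
  }
  # a cell holds one ternary value: opposite-type plants may not overlap
  for (i in seq_along(planted_regions)) {
    for (j in seq_len(i - 1L)) {
      a <- planted_regions[[i]]; b <- planted_regions[[j]]
      if (a$stage == b$stage && a$chrom == b$chrom &&
          a$aberration_type != b$aberration_type &&
          a$probe_start <= b$probe_end && b$probe_start <= a$probe_end) {
        stop("planted gain and loss overlap on ", a$chrom,
             " in stage ", a$stage)
      }
    }
  }
  structure(list(stages = as.character(stages),
                 n_samples_per_stage = as.integer(n_samples_per_stage),
                 chromosomes = chromosomes,
                 planted_regions = planted_regions,
                 background_rate = background_rate,
                 probe_spacing_bp = probe_spacing_bp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Probe map implied by a sim_config's genome.
.sim_probe_map <- function(cfg) {
  chrom <- rep(names(cfg$chromosomes), cfg$chromosomes)
  within <- unlist(lapply(cfg$chromosomes, seq_len), use.names = FALSE)
  probe_map(probe_id = sprintf("%s_P%d", chrom, within),
            chrom = chrom, pos = within * cfg$probe_spacing_bp)
}

#' Simulate stage-grouped aberration call matrices
#'
#' For every stage, carriers of each planted region are drawn once per
#' region (each sample independently with the plant's frequency); a
#' `carrier_overlap` fraction of them carries the full span, the rest a
#' random contiguous sub-span.  Background noise is added i.i.d. per
#' cell and per type at `background_rate`; when a background gain and
#' loss collide in one cell a seeded coin flip decides.  Planted calls
#' overwrite background.  Each stage consumes its own RNG substream
#' derived from the master seed, so output is byte-reproducible and
#' stages are independent.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `matrices` (named list of [call_matrix]
#'   per stage), `probe_map`, and `truth` (data.frame of planted
#'   regions with realized carrier counts and genome coordinates).
#' @export
simulate_stage_calls <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pm <- .sim_probe_map(cfg)
  M <- nrow(pm)
  stage_seeds <- .fresh_rng(cfg$seed)(function() {
    sample.int(.Machine$integer.max - 1L, length(cfg$stages))
  })
  truth <- list()
  matrices <- vector("list", length(cfg$stages))
  names(matrices) <- cfg$stages
  for (si in seq_along(cfg$stages)) {
    st <- cfg$stages[si]
    N <- cfg$n_samples_per_stage[si]
    sample_ids <- sprintf("%s_S%03d", st, seq_len(N))
    A <- .fresh_rng(stage_seeds[si])(function() {
      A <- matrix(0L, N, M)
      # background first, plants overwrite
      if (cfg$background_rate > 0) {
        g <- matrix(stats::runif(N * M) < cfg$background_rate, N, M)
        l <- matrix(stats::runif(N * M) < cfg$background_rate, N, M)
        both <- g & l
        gain_wins <- matrix(stats::runif(N * M) < 0.5, N, M)
        A[g & !both] <- 1L
        A[l & !both] <- -1L
        A[both & gain_wins] <- 1L
        A[both & !gain_wins] <- -1L
      }
      for (p in cfg$planted_regions) {
        if (p$stage != st) next
        offset <- min(pm$rank[pm$chrom == p$chrom]) - 1L
        lo <- offset + p$probe_start
        hi <- offset + p$probe_end
        carriers <- which(stats::runif(N) < p$frequency)
        if (!length(carriers)) next
        n_full <- ceiling(p$carrier_overlap * length(carriers))
        full <- carriers[seq_len(n_full)]
        val <- if (p$aberration_type == "gain") 1L else -1L
        A[full, lo:hi] <- val
        for (i in setdiff(carriers, full)) {
          ends <- sort(sample(lo:hi, 2, replace = TRUE))
          A[i, ends[1]:ends[2]] <- val
        }
      }
      A
    })
    matrices[[st]] <- call_matrix(A, sample_ids, pm, stage = st)
    for (p in cfg$planted_regions) {
      if (p$stage != st) next
      offset <- min(pm$rank[pm$chrom == p$chrom]) - 1L
      lo <- offset + p$probe_start
      hi <- offset + p$probe_end
      vals <- matrices[[st]]$values[, lo:hi, drop = FALSE]
      tv <- if (p$aberration_type == "gain") 1L else -1L
      truth[[length(truth) + 1L]] <- data.frame(
        stage = st, chrom = p$chrom, aberration_type = p$aberration_type,
        l = lo, r = hi, start_bp = pm$pos[lo], end_bp = pm$pos[hi],
        frequency = p$frequency,
        n_carriers = sum(apply(vals == tv, 1, any)),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(stage = character(), chrom = character(),
               aberration_type = character(), l = integer(), r = integer(),
               start_bp = numeric(), end_bp = numeric(),
               frequency = numeric(), n_carriers = integer(),
               stringsAsFactors = FALSE)
  list(matrices = matrices, probe_map = pm, truth = truth)
}

#' Simulate a gene annotation table
#'
#' Draws genes uniformly over the genome spanned by the probe map, with
#' lengths uniform in `length_range`.  With `fixture_region` set, the
#' first three genes are constructed deterministically relative to that
#' region: one fully inside, one straddling its left boundary and one
#' entirely outside, which pins down containment semantics in tests.
#'
#' @param pm a [probe_map].
#' @param n_genes number of genes (>= 1).
#' @param length_range `c(min, max)` gene length in bp.
#' @param seed integer seed.
#' @param fixture_region optional list `(chrom, start_bp, end_bp)`.
#' @return data.frame (`gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`), 1-based inclusive coordinates.
#' @export
simulate_gene_annotation <- function(pm, n_genes, length_range = c(2000, 20000),
                                     seed = 1L, fixture_region = NULL) {
  stopifnot(inherits(pm, "probe_map"))
  if (nrow(pm) == 0) stop("probe map is empty")
  if (n_genes < 1) stop("n_genes must be >= 1")
  stopifnot(length_range[1] > 0, length_range[1] <= length_range[2])
  spans <- vapply(split(pm$pos, pm$chrom), max, 0)
  .fresh_rng(seed)(function() {
    chrom <- sample(names(spans), n_genes, replace = TRUE,
                    prob = spans / sum(spans))
    len <- round(stats::runif(n_genes, length_range[1], length_range[2]))
    start <- vapply(seq_len(n_genes), function(i) {
      round(stats::runif(1, 1, max(1, spans[[chrom[i]]] - len[i])))
    }, 0)
    g <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                    symbol = sprintf("GENE%04d", seq_len(n_genes)),
                    chrom = chrom, start = start, end = start + len - 1,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
    fr <- fixture_region
    if (!is.null(fr) && n_genes >= 3) {
      w <- max(1, floor((fr$end_bp - fr$start_bp) / 4))
      g$chrom[1:3] <- fr$chrom
      g$start[1] <- fr$start_bp + w; g$end[1] <- fr$start_bp + 2 * w  # inside
      g$start[2] <- fr$start_bp - w; g$end[2] <- fr$start_bp + w      # straddles
      g$start[3] <- fr$end_bp + 10 * w; g$end[3] <- fr$end_bp + 11 * w # outside
    }
    g
  })
}

#' Simulate a pathway database
#'
#' Builds `n_pathways` gene sets from a gene pool.  A shared core pool
#' of `round(overlap_fraction * max(size))` genes is set aside; each
#' pathway draws `round(overlap_fraction * size)` of its members from
#' that pool and the remainder from pathway-exclusive genes, so
#' pairwise intersections grow with `overlap_fraction`:
#' `overlap_fraction = 0` yields pairwise disjoint sets and
#' `overlap_fraction = 1` with equal sizes yields identical sets.
#'
#' @param gene_pool character vector of available gene ids.
#' @param n_pathways number of pathways.
#' @param size_range `c(min, max)` genes per pathway; max must not
#'   exceed the pool size.
#' @param overlap_fraction in `[0, 1]`; controls pairwise sharing.
#' @param seed integer seed.
#' @return data.frame (`pathway_id`, `name`, `genes` as a list column).
#' @export
simulate_pathway_db <- function(gene_pool, n_pathways, size_range = c(6, 20),
                                overlap_fraction = 0.5, seed = 1L) {
  if (length(gene_pool) == 0) stop("gene pool is empty")
  stopifnot(n_pathways >= 1, size_range[1] >= 1,
            size_range[2] <= length(gene_pool),
            overlap_fraction >= 0, overlap_fraction <= 1)
  .fresh_rng(seed)(function() {
    sizes <- if (size_range[1] == size_range[2]) {
      rep(size_range[1], n_pathways)
    } else {
      sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    }
    pool_n <- round(overlap_fraction * max(sizes))
    pool <- sample(gene_pool)  # shuffle once; exclusive parts drawn in order
    core_pool <- pool[seq_len(pool_n)]
    rest <- if (pool_n > 0) pool[-seq_len(pool_n)] else pool
    core_ns <- round(overlap_fraction * sizes)
    if (sum(sizes - core_ns) > length(rest)) {
      stop("gene pool too small for ", n_pathways,
           " pathways at overlap_fraction ", overlap_fraction)
    }
    taken <- 0L
    genes <- lapply(seq_along(sizes), function(i) {
      core <- if (core_ns[i] > 0) sample(core_pool, core_ns[i]) else character(0)
      extra <- sizes[i] - core_ns[i]
      g <- c(core, rest[taken + seq_len(extra)])
      taken <<- taken + extra
      g
    })
    data.frame(pathway_id = sprintf("PW%03d", seq_len(n_pathways)),
               name = sprintf("Simulated pathway %d", seq_len(n_pathways)),
               genes = I(genes), stringsAsFactors = FALSE)
  })
}

#' Write the planted-truth table
#'
#' @param truth truth data.frame from [simulate_stage_calls()].
#' @param path output TSV path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
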