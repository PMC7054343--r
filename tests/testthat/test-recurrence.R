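test_that("marker counts tally aberrant samples per probe", {
  AL <- split_matrix(fig_example_matrix())$AL
  expect_equal(unname(marker_counts(AL)), c(0, 0, 0, 2, 3, 3, 2))
  expect_equal(unname(marker_counts(toy_binary(matrix(0, 2, 4)))), rep(0, 4))
  one <- toy_binary(rbind(c(1, 0, 1, 0), c(0, 0, 0, 0)))
  expect_equal(unname(marker_counts(one)), c(1, 0, 1, 0))
})

test_that("BH q-values match hand computation and preserve p order", {
  expect_equal(bh_qvalues(0.01), 0.01)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_qvalues(numeric(0)), numeric(0))
  set.seed(1)
  p <- runif(50)
  q <- bh_qvalues(p)
  expect_identical(order(q, p), order(p))  # rank order preserved
  expect_true(all(q >= p - 1e-12) && all(q <= 1))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("homogeneity matrix scores equal, multi-level and discordant pairs", {
  pm3 <- toy_pm(3)
  H <- homogeneity_matrix(toy_binary(rbind(c(1, 1, 1)), pm = pm3))
  expect_equal(unname(unclass(H))[1, ], c(0, 0))
  H2 <- homogeneity_matrix(toy_binary(rbind(c(0, 0)), pm = toy_pm(2)))
  expect_equal(unname(unclass(H2))[1, ], 0)  # concordantly unaltered
  H3 <- homogeneity_matrix(toy_binary(rbind(c(1, 0, 1)), pm = pm3))
  expect_equal(unname(unclass(H3))[1, ], c(1, 1))
  # medium homogeneity: both aberrant at different magnitude levels
  ml <- list(values = rbind(c(1, 2, 0)), probe_map = pm3)
  expect_equal(unname(unclass(homogeneity_matrix(ml)))[1, ], c(0.5, 1))
  expect_error(homogeneity_matrix(toy_binary(rbind(1), pm = toy_pm(1))),
               "two markers")
})

test_that("chromosome junctions are excluded from homogeneity", {
  pm <- probe_map(paste0("P", 1:4), c("chr1", "chr1", "chr2", "chr2"),
                  c(10, 20, 10, 20))
  H <- homogeneity_matrix(toy_binary(rbind(c(1, 1, 1, 1)), pm = pm))
  expect_equal(unname(unclass(H))[1, ], c(0, NA, 0))
})

test_that("h-profile is the per-junction column mean", {
  H <- structure(matrix(c(0, 0.5, 1), 3, 1), class = "homogeneity_matrix")
  expect_equal(unname(h_profile(H)), 0.5)
  Hz <- structure(matrix(0, 4, 3), class = "homogeneity_matrix")
  expect_equal(unname(h_profile(Hz)), c(0, 0, 0))
  H1 <- structure(matrix(c(1, 0), 1, 2), class = "homogeneity_matrix")
  expect_equal(unname(h_profile(H1)), c(1, 0))  # N = 1: h equals the row
  B <- split_matrix(fig_example_matrix())$AL
  expect_equal(unname(h_profile(homogeneity_matrix(B))),
               unname(colMeans(unclass(homogeneity_matrix(B)))))
})

test_that("degenerate matrices give p = 1 everywhere", {
  zero <- toy_binary(matrix(0, 3, 4))
  expect_equal(permutation_pvalues(zero)$p_values, rep(1, 4))
  full <- toy_binary(matrix(1, 3, 4))
  expect_equal(permutation_pvalues(full)$p_values, rep(1, 4))
  expect_error(permutation_pvalues(toy_binary(rbind(c(1, 0, 0, 0)))),
               "at least 2 samples")
})

test_that("Monte-Carlo p-values match the exact enumeration oracle", {
  cfg <- detection_config(n_perm = 10000, seed = 42)
  cases <- list(rbind(c(1, 0, 0), c(1, 1, 0)),
                rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 1, 1, 0)),
                rbind(c(1, 0), c(0, 1), c(1, 1)))
  for (vals in cases) {
    B <- toy_binary(vals)
    mc <- permutation_pvalues(B, cfg)
    tails <- enum_tail_probs(vals)
    obs <- colSums(vals)
    for (j in seq_len(ncol(vals))) {
      exact <- tails[j, obs[j] + 1]
      se <- sqrt(exact * (1 - exact) / cfg$n_perm)
      expect_lt(abs(mc$p_values[j] - exact), 3 * se + 2 / (cfg$n_perm + 1))
    }
  }
})

test_that("p-values are invariant to sample order and chromosome order", {
  set.seed(7)
  pm <- probe_map(paste0("P", 1:12), rep(c("chr1", "chr2"), each = 6),
                  rep(1:6 * 1000, 2))
  vals <- matrix(rbinom(8 * 12, 1, 0.3), 8, 12)
  B <- binary_matrix(vals, "gain", paste0("S", 1:8), pm)
  cfg <- detection_config(n_perm = 2000, seed = 3)
  p1 <- permutation_pvalues(B, cfg)$p_values
  perm <- sample(8)
  B2 <- binary_matrix(vals[perm, ], "gain", paste0("S", 1:8)[perm], pm)
  expect_equal(permutation_pvalues(B2, cfg)$p_values, p1)
  # same data presented with chromosomes swapped in the input ordering
  swap <- c(7:12, 1:6)
  pm_sw <- probe_map(paste0("P", 1:12)[swap], pm$chrom[swap], pm$pos[swap])
  vals_sw <- vals[, swap]
  colnames(vals_sw) <- paste0("P", 1:12)[swap]  # reordered on construction
  B3 <- binary_matrix(vals_sw, "gain", paste0("S", 1:8), pm_sw)
  p3 <- permutation_pvalues(B3, cfg)$p_values
  expect_equal(p3, p1)
})

test_that("peak expansion follows the q and h conditions exactly", {
  pm <- toy_pm(30)
  cfg <- detection_config(q_thr = 0.1, h_thr = 0.12)
  q <- rep(0.9, 30); q[15] <- 0.01
  h <- rep(0, 29)
  expect_equal(unname(expand_peak(q, h, 15, pm, cfg)), c(15, 15))
  q2 <- rep(0.9, 30); q2[10:20] <- 0.02
  expect_equal(unname(expand_peak(q2, h, 15, pm, cfg)), c(10, 20))
  # h_thr = 0 with strictly positive h forbids any expansion
  cfg0 <- detection_config(q_thr = 0.1, h_thr = 0)
  h_pos <- rep(0.01, 29)
  expect_equal(unname(expand_peak(q2, h_pos, 15, pm, cfg0)), c(15, 15))
  expect_error(expand_peak(q, h, 1, pm, cfg), "not significant")
})

test_that("expansion never crosses chromosome boundaries", {
  pm <- probe_map(paste0("P", 1:10), rep(c("chr1", "chr2"), each = 5),
                  rep(1:5 * 1000, 2))
  cfg <- detection_config(q_thr = 0.1, h_thr = 0.5)
  q <- rep(0.01, 10)
  h <- rep(0, 9)
  expect_equal(unname(expand_peak(q, h, 3, pm, cfg)), c(1, 5))
  expect_equal(unname(expand_peak(q, h, 8, pm, cfg)), c(6, 10))
})

test_that("every marker inside an expanded region is significant", {
  set.seed(5)
  pm <- toy_pm(40)
  cfg <- detection_config(q_thr = 0.1, h_thr = 0.3)
  for (i in 1:25) {
    q <- runif(40)
    h <- runif(39, 0, 0.6)
    sig <- which(q <= cfg$q_thr)
    if (!length(sig)) next
    peak <- sig[which.min(q[sig])]
    lr <- expand_peak(q, h, peak, pm, cfg)
    expect_true(all(q[lr[1]:lr[2]] <= cfg$q_thr))
  }
})

test_that("the detector recovers a planted region and stops", {
  cfg <- sim_config(stages = "t2", n_samples_per_stage = 50,
                    chromosomes = c(chr1 = 500),
                    planted_regions = list(
                      planted_region("t2", "chr1", 101, 120, "gain", 0.6)),
                    background_rate = 0.01, seed = 7)
  B <- split_matrix(simulate_stage_calls(cfg)$matrices$t2)$AL
  r <- detect_recurrent_regions(B, detection_config(seed = 7))
  expect_equal(nrow(r), 1)
  expect_lte(abs(r$l - 101), 2)
  expect_lte(abs(r$r - 120), 2)
  expect_equal(r$aberration_type, "gain")
  expect_lte(r$peak_q, 0.10)
  expect_gt(r$frequency, 0.4)
})

test_that("disjoint plants on different chromosomes give one region each", {
  cfg <- sim_config(stages = "t3", n_samples_per_stage = 50,
                    chromosomes = c(chr1 = 200, chr2 = 200),
                    planted_regions = list(
                      planted_region("t3", "chr1", 51, 70, "gain", 0.6),
                      planted_region("t3", "chr2", 101, 120, "gain", 0.6)),
                    background_rate = 0.01, seed = 13)
  B <- split_matrix(simulate_stage_calls(cfg)$matrices$t3)$AL
  r <- detect_recurrent_regions(B, detection_config(seed = 13))
  expect_equal(nrow(r), 2)
  expect_setequal(r$chrom, c("chr1", "chr2"))
  expect_true(all(table(r$chrom) == 1))
})

test_that("detection output is invariant to sample order", {
  cfg <- sim_config(stages = "t2", n_samples_per_stage = 40,
                    chromosomes = c(chr1 = 200),
                    planted_regions = list(
                      planted_region("t2", "chr1", 51, 70, "gain", 0.6)),
                    background_rate = 0.01, seed = 19)
  B <- split_matrix(simulate_stage_calls(cfg)$matrices$t2)$AL
  dc <- detection_config(n_perm = 2000, seed = 19)
  r1 <- detect_recurrent_regions(B, dc)
  set.seed(1); perm <- sample(40)
  B2 <- binary_matrix(B$values[perm, ], "gain", B$sample_ids[perm],
                      B$probe_map, B$stage)
  r2 <- detect_recurrent_regions(B2, dc)
  expect_equal(r1[, c("chrom", "l", "r", "peak_rank")],
               r2[, c("chrom", "l", "r", "peak_rank")])
})

test_that("peel-off terminates with distinct peaks and shrinking mass", {
  cfg <- sim_config(stages = "t2", n_samples_per_stage = 40,
                    chromosomes = c(chr1 = 150),
                    planted_regions = list(
                      planted_region("t2", "chr1", 21, 40, "gain", 0.7),
                      planted_region("t2", "chr1", 91, 105, "gain", 0.5)),
                    background_rate = 0.01, seed = 23)
  B <- split_matrix(simulate_stage_calls(cfg)$matrices$t2)$AL
  dc <- detection_config(seed = 23)
  r <- detect_recurrent_regions(B, dc)
  expect_lte(nrow(r), dc$max_iterations)
  expect_equal(anyDuplicated(r$peak_rank), 0)
  expect_gte(nrow(r), 2)  # both plants found
  zero <- toy_binary(matrix(0, 5, 10))
  expect_equal(nrow(detect_recurrent_regions(zero, dc)), 0)
})

test_that("raising plant frequency never lowers the detection rate", {
  rate <- function(freq) {
    hits <- 0L
    for (s in 1:10) {
      cfg <- sim_config(stages = "t2", n_samples_per_stage = 30,
                        chromosomes = c(chr1 = 150),
                        planted_regions = list(
                          planted_region("t2", "chr1", 51, 65, "gain", freq)),
                        background_rate = 0.01, seed = 100 + s)
      B <- split_matrix(simulate_stage_calls(cfg)$matrices$t2)$AL
      r <- detect_recurrent_regions(B, detection_config(n_perm = 2000,
                                                        seed = 100 + s))
      if (nrow(r) >= 1) hits <- hits + 1L
    }
    hits
  }
  expect_lte(rate(0.25), rate(0.7))
})

test_that("shared homogeneous runs match the worked example and the oracle", {
  A <- fig_example_matrix()
  r3 <- find_shared_runs(A, min_samples = 2, min_span = 3)
  expect_equal(nrow(r3), 2)
  expect_equal(r3$probe_from, c("P4", "P5"))
  expect_equal(r3$probe_to, c("P6", "P7"))
  expect_setequal(r3$samples, c("S1,S2", "S2,S3"))
  r2 <- find_shared_runs(A, min_samples = 2, min_span = 2)
  expect_equal(nrow(r2), 3)
  expect_true("S1,S2,S3" %in% r2$samples)
  expect_setequal(runs_as_keys(r2),
                  bicluster_keys(brute_biclusters(A, 2, 2), A$sample_ids))
  zero <- call_matrix(matrix(0L, 3, 5), paste0("S", 1:3), toy_pm(5))
  expect_equal(nrow(find_shared_runs(zero, 2, 1)), 0)
})

test_that("shared runs equal exhaustive enumeration on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    v <- matrix(sample(c(-1L, 0L, 1L), 4 * 6, replace = TRUE,
                       prob = c(0.25, 0.4, 0.35)), 4, 6)
    A <- call_matrix(v, paste0("S", 1:4), toy_pm(6))
    got <- runs_as_keys(find_shared_runs(A, 2, 2))
    want <- bicluster_keys(brute_biclusters(A, 2, 2), A$sample_ids)
    expect_setequal(got, want)
  }
})

test_that("frequency tracks report per-probe aberrant fractions", {
  AL <- split_matrix(fig_example_matrix())$AL
  tr <- frequency_track(AL)
  expect_equal(tr$frequency, c(0, 0, 0, 2/3, 1, 1, 2/3))
  expect_equal(frequency_track(toy_binary(matrix(0, 2, 3)))$frequency,
               rep(0, 3))
  p <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, p)
  back <- rtracklayer::import(p, format = "bedGraph")
  expect_equal(back$score, tr$frequency)
})
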