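mk_records <- function(...) {
  rows <- list(...)
  data.frame(stage = vapply(rows, `[[`, "", "stage"),
             pathway_id = vapply(rows, `[[`, "", "id"),
             name = vapply(rows, `[[`, "", "id"),
             pathway_size = 10L,
             n_hit_genes = vapply(rows, function(r) length(r$hits), 0L),
             hit_genes = I(lapply(rows, `[[`, "hits")),
             stringsAsFactors = FALSE)
}

test_that("overlap score implements k^2/(p*q) with its boundary cases", {
  s4 <- letters[1:4]
  expect_equal(overlap_score(s4, s4)[["W"]], 1)
  sc <- overlap_score(letters[1:4], c("a", "b", "x", "y", "z"))
  expect_equal(unname(sc), c(2, 4, 5, 0.2))  # k=2, p=4, q=5, W=4/20
  expect_equal(overlap_score(letters[1:3], letters[10:12])[["W"]], 0)
  expect_error(overlap_score(character(0), "a"), "empty")
})

test_that("overlap score is symmetric, bounded, and 1 iff identical", {
  set.seed(8)
  pool <- sprintf("g%02d", 1:30)
  for (i in 1:20) {
    a <- sample(pool, sample(1:15, 1))
    b <- sample(pool, sample(1:15, 1))
    sab <- overlap_score(a, b); sba <- overlap_score(b, a)
    expect_equal(sab[["W"]], sba[["W"]])
    expect_gte(sab[["W"]], 0); expect_lte(sab[["W"]], 1)
    expect_equal(sab[["W"]] == 1, setequal(a, b))
    # removing a shared gene from both sides never increases k
    if (sab[["k"]] >= 1 && length(a) > 1 && length(b) > 1) {
      g <- intersect(a, b)[1]
      expect_lte(overlap_score(setdiff(a, g), setdiff(b, g))[["k"]],
                 sab[["k"]])
    }
  }
})

test_that("evolution network connects gene-sharing pathways across adjacent stages", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = c("g1", "g2", "g3")),
                     list(stage = "t2", id = "Pb",
                          hits = c("g2", "g3", "g4", "g5")))
  net <- build_evolution_network(recs, c("t1", "t2"))
  expect_equal(nrow(net$edges), 1)
  e <- net$edges[1, ]
  expect_equal(c(e$k, e$p, e$q), c(2, 3, 4))
  expect_equal(e$W, 4 / 12)
  expect_equal(e$stage_from, "t1")
  expect_equal(net$nodes$stages, c("t1", "t2"))
})

test_that("network construction validates stages and skips disjoint pairs", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = "g1"),
                     list(stage = "t2", id = "Pb", hits = "g9"))
  expect_error(build_evolution_network(recs, "t1"), "two stages")
  expect_error(build_evolution_network(recs, c("t1", "t3")),
               "missing from stage_order")
  net <- build_evolution_network(recs, c("t1", "t2"))
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 2)
})

test_that("no self-loops; same pathway across stages becomes node membership", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = c("g1", "g2")),
                     list(stage = "t2", id = "Pa", hits = c("g1", "g2")),
                     list(stage = "t2", id = "Pb", hits = c("g2", "g3")))
  net <- build_evolution_network(recs, c("t1", "t2"))
  expect_false(any(net$edges$pathway_i == net$edges$pathway_j))
  expect_equal(net$nodes$stages[net$nodes$pathway_id == "Pa"], "t1;t2")
  expect_equal(nrow(net$edges), 1)  # only Pa(t1) -- Pb(t2)
})

test_that("edges are only formed between adjacent stages", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = c("g1", "g2")),
                     list(stage = "t3", id = "Pb", hits = c("g1", "g2")))
  net <- build_evolution_network(recs, c("t1", "t2", "t3"))
  expect_equal(nrow(net$edges), 0)  # t1 and t3 are not adjacent
})

test_that("edge count is invariant to within-stage pathway ordering", {
  set.seed(12)
  pool <- sprintf("g%02d", 1:20)
  rows <- lapply(1:8, function(i) {
    list(stage = sample(c("t1", "t2"), 1), id = sprintf("P%02d", i),
         hits = sample(pool, 5))
  })
  recs <- do.call(mk_records, rows)
  n1 <- build_evolution_network(recs, c("t1", "t2"))
  n2 <- build_evolution_network(recs[sample(nrow(recs)), ], c("t1", "t2"))
  expect_identical(n1$edges, n2$edges)
})

test_that("full-basis weights use database gene sets", {
  db <- data.frame(pathway_id = c("Pa", "Pb"), name = c("Pa", "Pb"),
                   genes = I(list(sprintf("g%02d", 1:10),
                                  sprintf("g%02d", 6:15))),
                   stringsAsFactors = FALSE)
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = "g06"),
                     list(stage = "t2", id = "Pb", hits = "g07"))
  expect_error(build_evolution_network(recs, c("t1", "t2"),
                                       gene_basis = "full"), "database")
  net <- build_evolution_network(recs, c("t1", "t2"), gene_basis = "full",
                                 db = db)
  expect_equal(net$edges$W, 25 / 100)  # k=5, p=q=10
})

test_that("GraphML export round-trips and counts match", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = c("g1", "g2")),
                     list(stage = "t2", id = "Pb", hits = c("g1", "g3")),
                     list(stage = "t2", id = "Pc", hits = c("g2", "g4")))
  net <- build_evolution_network(recs, c("t1", "t2"))
  p <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, p, "graphml")
  back <- read_network_graphml(p)
  expect_equal(back$nodes[, c("pathway_id", "stages", "n_hit_genes")],
               net$nodes[, c("pathway_id", "stages", "n_hit_genes")])
  expect_equal(back$edges[, c("pathway_i", "pathway_j", "k", "W")],
               net$edges[, c("pathway_i", "pathway_j", "k", "W")])
})

test_that("SIF and edge-TSV exports carry every node and edge", {
  recs <- mk_records(list(stage = "t1", id = "Pa", hits = c("g1", "g2")),
                     list(stage = "t2", id = "Pb", hits = c("g1", "g3")),
                     list(stage = "t2", id = "Pz", hits = "g9"))
  net <- build_evolution_network(recs, c("t1", "t2"))
  d <- withr::local_tempdir()
  sif <- file.path(d, "net.sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$edges) + 1)  # Pz is an isolated node
  expect_true(file.exists(paste0(sif, ".edges.tsv")))
  tsv <- file.path(d, "edges.tsv")
  export_network(net, tsv, "edge-tsv")
  expect_equal(nrow(read.delim(tsv)), nrow(net$edges))
  expect_error(export_network(net, file.path(d, "x"), "dot"),
               "unknown network format")
  empty <- build_evolution_network(mk_records(
    list(stage = "t1", id = "Pa", hits = "g1"))[0, ], c("t1", "t2"))
  g <- file.path(d, "empty.graphml")
  export_network(empty, g, "graphml")
  expect_equal(nrow(read_network_graphml(g)$edges), 0)
})
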