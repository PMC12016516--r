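make_edge_df <- function(bait, prey, sulfur = TRUE, pyruvate = TRUE,
                         rank = 5L, rescued = FALSE) {
  data.frame(bait = bait, prey = prey, sulfur = sulfur, pyruvate = pyruvate,
             rank = rank, rescued = rescued, stringsAsFactors = FALSE)
}

sort_within <- function(e) {
  e <- e[order(e$bait, e$prey, e$sulfur), ]
  rownames(e) <- NULL
  e
}

test_that("network assembly: one edge per significant (bait, prey, condition)", {
  rec <- rbind(
    make_records(c("TK0101", "TK0102", "TK0103"), bait_gene = "TK0001"),
    make_records(c("TK0103", "TK0104", "TK0105"), bait_gene = "TK0002")
  )
  class(rec) <- c("enrichment_records", "data.frame")
  rec$rank <- 5L
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 6L)                    # 2 baits x 3 preys
  expect_equal(length(unique(net$edges$prey)), 5L)     # one shared prey
  expect_equal(net$baits, c("TK0001", "TK0002"))
})

test_that("self-edges become purification-success annotations, not partner edges", {
  rec <- make_records(c("TK0001", "TK0002"), bait_gene = "TK0001")
  rec$rank <- 5L
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$self_edges$prey, "TK0001")
})

test_that("the same pair in two conditions yields two condition-tagged edges", {
  edges <- rbind(make_edge_df("TK0001", "TK0002", sulfur = TRUE),
                 make_edge_df("TK0001", "TK0002", sulfur = FALSE))
  net <- build_network(edges)
  expect_equal(nrow(net$edges), 2L)
  expect_setequal(net$edges$sulfur, c(TRUE, FALSE))
})

test_that("duplicate (bait, prey, condition) edges are a consistency error", {
  edges <- rbind(make_edge_df("TK0001", "TK0002"),
                 make_edge_df("TK0001", "TK0002"))
  expect_error(build_network(edges), "duplicate")
})

test_that("empty record sets build empty but valid networks", {
  net <- build_network(make_records(character(0)))
  expect_equal(nrow(net$edges), 0L)
  expect_s3_class(net, "bait_network")
})

test_that("rank filtering is monotone and bounded", {
  edges <- make_edge_df(paste0("TK000", 1:3), paste0("TK010", 1:3), rank = c(5L, 4L, 3L))
  net <- build_network(edges)
  expect_equal(nrow(filter_rank(net, 1)$edges), 3L)        # identity at min_rank 1
  expect_equal(nrow(filter_rank(net, 5)$edges), 1L)
  sizes <- vapply(1:5, function(r) nrow(filter_rank(net, r)$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))                       # monotone non-increasing
  expect_error(filter_rank(net, 6), "1..5")
  expect_error(filter_rank(net, 0), "1..5")
  # baits survive as nodes even when all their edges are filtered away
  expect_equal(filter_rank(net, 5)$baits, net$baits)
})

test_that("reciprocity between complexes requires both directions and excludes shared subunits", {
  vor <- complex_group("VOR", c("TK1978", "TK1979", "TK1980", "TK1981"))
  por <- complex_group("POR", c("TK1978", "TK1982", "TK1983", "TK1984"))

  edges <- rbind(
    make_edge_df("TK1979", "TK1983", sulfur = FALSE),   # VOR bait -> POR protein
    make_edge_df("TK1982", "TK1980", sulfur = FALSE),   # POR bait -> VOR protein
    make_edge_df("TK1979", "TK1978", sulfur = FALSE)    # edge to the shared gamma subunit
  )
  net <- build_network(edges)
  expect_warning(rp <- reciprocal_pairs(net, vor, por, sulfur = FALSE, pyruvate = TRUE),
                 "TK1978")
  expect_true(rp$reciprocal)
  expect_equal(rp$n_associations, 2L)                  # the shared-subunit edge is excluded
  expect_equal(rp$shared_excluded, "TK1978")

  # one direction only: not reciprocal
  net1 <- build_network(make_edge_df("TK1979", "TK1983", sulfur = FALSE))
  rp1 <- suppressWarnings(reciprocal_pairs(net1, vor, por, sulfur = FALSE, pyruvate = TRUE))
  expect_false(rp1$reciprocal)
})

test_that("group intersection returns preys shared by every complex", {
  g1 <- complex_group("A", "TK0001")
  g2 <- complex_group("B", "TK0002")
  edges <- rbind(make_edge_df("TK0001", c("TK0101", "TK0102")),
                 make_edge_df("TK0002", c("TK0102", "TK0103")))
  net <- build_network(edges)
  expect_equal(intersect_groups(net, list(g1, g2), TRUE, TRUE), "TK0102")
  # commutative in group order
  expect_equal(intersect_groups(net, list(g2, g1), TRUE, TRUE), "TK0102")
  # disjoint prey sets
  edges2 <- rbind(make_edge_df("TK0001", "TK0101"), make_edge_df("TK0002", "TK0103"))
  expect_length(intersect_groups(build_network(edges2), list(g1, g2), TRUE, TRUE), 0L)
  # a single group is a domain error
  expect_error(intersect_groups(net, list(g1), TRUE, TRUE), "two")
})

test_that("the bundled shared-partner fixture intersects to its eight preys", {
  net <- shared_partner_network()
  groups <- list(complex_group("OGOR", "TK1130"),
                 complex_group("MBS", "TK1215"),
                 complex_group("FDH", "TK2077"))
  shared <- intersect_groups(net, groups, sulfur = TRUE, pyruvate = TRUE)
  expect_length(shared, 8L)
  expect_true(all(c("TK2012", "TK2093") %in% shared))
  ann <- attr(net, "annotations")
  expect_match(ann$prey_annotation[ann$prey == "TK2012"], "ferredoxin 3")
  expect_match(ann$prey_annotation[ann$prey == "TK2093"], "MBH-N")
  # result is a subset of every group's prey set
  for (g in groups) {
    expect_true(all(shared %in% net$edges$prey[net$edges$bait %in% g$members]))
  }
})

test_that("network exports are deterministic and round-trip through GraphML", {
  edges <- rbind(make_edge_df("TK0001", "TK0101", rank = 5L),
                 make_edge_df("TK0001", "TK0102", rank = 4L, sulfur = FALSE,
                              rescued = TRUE))
  net <- build_network(edges)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(readLines(sif),
               c("TK0001\tcopurifies\tTK0101", "TK0001\tcopurifies\tTK0102"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_identical(sort_within(back$edges), sort_within(net$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back2 <- import_network(tsv, "tsv")
  expect_identical(sort_within(back2$edges), sort_within(net$edges))

  expect_error(export_network(net, tempfile(), "dot"), "unknown network format")
})

test_that("empty networks export valid documents that declare the baits", {
  rec <- make_records("TK0002", bait_gene = "TK0001", significant = FALSE)
  net <- build_network(rec)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(readLines(sif), "TK0001")

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_equal(back$baits, "TK0001")
  expect_equal(nrow(back$edges), 0L)
})
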