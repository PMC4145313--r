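## a rooted 3-tip tree used throughout: root -> I (1.0), I -> A (1.0),
## I -> B (2.0), root -> C (2.0)
fixture_tree <- function() read_newick("((A:1,B:2):1,C:2);")

minimal_jplace <- function(tree, records) {
  f <- tempfile(fileext = ".jplace")
  write_jplace(tree, records, f)
  f
}

test_that("read_jplace parses minimal documents and validates them", {
  tree <- fixture_tree()
  rec <- data.frame(query_id = "q1", edge_num = tree$edge_num[1],
                    offset = 0.2, pendant_length = 0.3,
                    like_weight_ratio = 1)
  ps <- read_jplace(minimal_jplace(tree, rec), tree = tree, sample_id = "s1")
  expect_s3_class(ps, "placement_set")
  expect_equal(nrow(ps$records), 1L)
  expect_equal(ps$records$offset, 0.2, tolerance = 1e-12)

  expect_error(read_jplace("{not json"), "malformed")
  bad <- jsonlite::toJSON(list(version = 3, tree = "x",
                               fields = list("edge_num", "likelihood"),
                               placements = list()), auto_unbox = TRUE)
  expect_error(read_jplace(as.character(bad)), "fields")
})

test_that("multi-placement queries keep all candidates with weights", {
  tree <- fixture_tree()
  doc <- list(version = 3, tree = write_newick(tree, edge_numbers = TRUE),
              fields = list("edge_num", "distal_length", "pendant_length",
                            "like_weight_ratio"),
              placements = list(list(
                p = list(list(tree$edge_num[1], 0.1, 0.2, 0.7),
                         list(tree$edge_num[2], 0.5, 0.1, 0.3)),
                n = list("q1"))))
  ps <- read_jplace(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE)),
                    tree = tree)
  expect_equal(nrow(ps$records), 2L)
  expect_setequal(ps$records$like_weight_ratio, c(0.7, 0.3))
  best <- best_placement(ps)
  expect_equal(best$like_weight_ratio, 0.7)

  doc$placements[[1]]$p[[1]][[4]] <- 0.9 # weights now sum to 1.2
  expect_error(read_jplace(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE)),
                           tree = tree), "exceed")
})

test_that("best_placement tie-breaks on the smaller edge number", {
  rec <- data.frame(query_id = c("q1", "q1", "q2"),
                    edge_num = c(5L, 2L, 1L),
                    distal_length = 0, pendant_length = 0,
                    like_weight_ratio = c(0.5, 0.5, 1))
  best <- best_placement(rec)
  expect_equal(best$edge_num[best$query_id == "q1"], 2L)
  expect_equal(nrow(best), 2L)
  expect_error(best_placement(rec[0, ]), "no placement")
})

test_that("query_tip_length follows the proximal-offset convention", {
  tree <- fixture_tree()
  ## edge I -> A: proximal node I at depth 1.0
  edge_a <- tree$edge_num[tree$phylo$edge[, 2] ==
                            match("A", tree$phylo$tip.label)]
  rec <- data.frame(query_id = "q", edge_num = edge_a, offset = 0.2,
                    pendant_length = 0.3, like_weight_ratio = 1)
  expect_equal(query_tip_length(tree, rec), 1.5)
  rec0 <- transform(rec, offset = 0, pendant_length = 0)
  expect_equal(query_tip_length(tree, rec0), 1.0)
  ## full offset on a tip edge with zero pendant = that tip's length
  rec_tip <- transform(rec, offset = 1.0, pendant_length = 0)
  expect_equal(query_tip_length(tree, rec_tip),
               unname(root_to_tip_lengths(tree)["A"]))
  expect_error(query_tip_length(tree, transform(rec, offset = 5)), "corrupt")
})

test_that("query_tip_length is monotone in offset and pendant", {
  tree <- fixture_tree()
  edge_b <- tree$edge_num[tree$phylo$edge[, 2] ==
                            match("B", tree$phylo$tip.label)]
  len_at <- function(off, pen) query_tip_length(tree, data.frame(
    query_id = "q", edge_num = edge_b, offset = off,
    pendant_length = pen, like_weight_ratio = 1))
  expect_true(all(diff(len_at(seq(0, 2, 0.25), 0.3)) >= -1e-12))
  expect_true(all(diff(len_at(0.5, seq(0, 1, 0.25))) >= -1e-12))
})

test_that("both offset conventions round-trip through jplace files", {
  sim <- simulate_reference_tree(20, 4, seed = 31)
  comp <- stats::setNames(rep(0.25, 4), sort(unique(sim$taxonomy$phylum)))
  pl <- simulate_placements(sim$tree, sim$taxonomy, comp, delta = 0.2,
                            n_markers = 30, seed = 8)
  for (conv in c("distal", "proximal")) {
    f <- tempfile(fileext = ".jplace")
    write_jplace(sim$tree, pl$records, f, offset_from = conv)
    ps <- read_jplace(f, tree = sim$tree, offset_from = conv)
    got <- query_tip_length(sim$tree, best_placement(ps))
    expect_equal(sort(got), sort(query_tip_length(sim$tree, pl$records)),
                 tolerance = 1e-9)
  }
  ## edge number missing from the tree is named
  bad <- pl$records
  bad$edge_num[1] <- 9999L
  f <- tempfile(fileext = ".jplace")
  write_jplace(sim$tree, transform(pl$records, edge_num = pmin(edge_num, 9998L)), f)
  ps <- read_jplace(f)
  ps$records$edge_num[1] <- 9999L
  expect_error(normalize_placements(ps, sim$tree), "absent from reference")
})
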