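test_that("read_newick parses trees and preserves branch lengths", {
  t <- read_newick("((A:1,B:2):1,C:3);")
  expect_equal(length(t$phylo$tip.label), 3L)
  expect_equal(nrow(t$phylo$edge), 4L)
  expect_setequal(t$phylo$edge.length, c(1, 2, 1, 3))
  expect_equal(sort(t$edge_num), 0:3)

  t1 <- read_newick("(A:1);")
  expect_equal(length(t1$phylo$tip.label), 1L)
  expect_equal(nrow(t1$phylo$edge), 1L)

  expect_error(read_newick("((A:1,B:2):1,C:3"), "malformed")
  expect_error(read_newick("((A:1,B),C:3);"), "branch length")
})

test_that("jplace-style edge numbers round-trip through newick", {
  t <- midpoint_root(read_newick("((A:1,B:2):1,C:3);"))
  txt <- write_newick(t, edge_numbers = TRUE)
  t2 <- read_newick(txt)
  ## same edge-number -> edge-length association
  m1 <- t$phylo$edge.length[order(t$edge_num)]
  m2 <- t2$phylo$edge.length[order(t2$edge_num)]
  expect_equal(m1, m2, tolerance = 1e-10)
  expect_error(read_newick("((A:1{0},B:2):1{2},C:3{3});"), "incomplete")
})

test_that("write/read round-trip preserves topology and lengths", {
  for (i in 1:25) {
    tr <- random_tree(sample(4:12, 1), seed = 1000 + i)
    rt <- read_newick(ape::write.tree(tr))
    back <- read_newick(write_newick(rt))
    d1 <- ape::cophenetic.phylo(rt$phylo)
    d2 <- ape::cophenetic.phylo(back$phylo)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  }
})

test_that("midpoint rooting matches the worked example", {
  rt <- midpoint_root(read_newick("((A:1,B:2):1,C:3);"))
  lens <- root_to_tip_lengths(rt)
  expect_equal(lens[c("A", "B", "C")], c(A = 2, B = 3, C = 3))
  expect_equal(total_tree_length(rt), 7)
})

test_that("midpoint rooting is idempotent and conserves total length", {
  tr <- random_tree(9, seed = 42)
  r1 <- midpoint_root(read_newick(ape::write.tree(tr)))
  r2 <- midpoint_root(r1)
  expect_equal(write_newick(r2), write_newick(midpoint_root(r2)))
  expect_equal(total_tree_length(r1), sum(tr$edge.length), tolerance = 1e-9)
  expect_equal(sort(unname(root_to_tip_lengths(r1))),
               sort(unname(root_to_tip_lengths(r2))), tolerance = 1e-9)
})

test_that("midpoint rooting minimizes the max root-to-tip distance", {
  for (i in 1:30) {
    tr <- random_tree(sample(4:12, 1), seed = 2000 + i)
    rt <- midpoint_root(read_newick(ape::write.tree(tr)))
    depths <- root_to_tip_lengths(rt)
    expect_equal(max(depths), brute_force_midpoint_value(tr),
                 tolerance = 1e-9)
    top2 <- sort(depths, decreasing = TRUE)[1:2]
    expect_lt(abs(top2[1] - top2[2]), 1e-9)
  }
})

test_that("midpoint rooting agrees with phangorn on root-to-tip depths", {
  skip_if_not_installed("phangorn")
  for (i in 1:10) {
    tr <- random_tree(sample(5:10, 1), seed = 3000 + i)
    ours <- root_to_tip_lengths(midpoint_root(read_newick(ape::write.tree(tr))))
    ph <- phangorn::midpoint(tr)
    theirs <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
    names(theirs) <- ph$tip.label
    expect_equal(ours[names(theirs)], theirs, tolerance = 1e-8)
  }
})

test_that("degenerate rootings are handled", {
  zero <- read_newick("((A:0,B:0):0,C:0);")
  expect_warning(rt <- midpoint_root(zero), "zero")
  expect_true(rt$rooted)
  expect_error(midpoint_root(read_newick("(A:1);")), "2 tips")
})

test_that("root_to_tip_lengths equals the parent-climbing oracle", {
  star <- midpoint_root(read_newick("(A:1,B:1,C:1,D:1);"))
  expect_true(all(abs(root_to_tip_lengths(star) - 1) < 1e-12))
  for (i in 1:20) {
    tr <- random_tree(sample(4:12, 1), seed = 4000 + i)
    rt <- midpoint_root(read_newick(ape::write.tree(tr)))
    expect_equal(root_to_tip_lengths(rt), oracle_root_to_tip(rt$phylo),
                 tolerance = 1e-12)
  }
  expect_error(root_to_tip_lengths(read_newick("(A:1,B:1,C:1);")), "unrooted")
})

test_that("phylum medians follow the stated even/odd rules", {
  nwk <- "((x1:0.5,x2:0.7):0.5,(x3:0.9,(y1:0.5,y2:1.5):0.5):0.5);"
  rt <- read_newick(nwk)
  rt$rooted <- TRUE # binary root: already rooted
  tax <- data.frame(taxon_id = c("x1", "x2", "x3", "y1", "y2"),
                    phylum = c("X", "X", "X", "Y", "Y"))
  med <- phylum_reference_medians(rt, tax)
  expect_equal(med[["X"]], 1.2)  # odd count: {1.0, 1.2, 1.4}
  expect_equal(med[["Y"]], 2.0)  # even count: mean(1.5, 2.5)
  expect_warning(
    phylum_reference_medians(rt, rbind(tax, data.frame(taxon_id = "z1",
                                                       phylum = "Z"))),
    "excluded")
  expect_error(phylum_reference_medians(rt, tax[-1, ]), "missing")
})

test_that("uniform branch scaling scales lengths and medians by c", {
  tr <- random_tree(8, seed = 77)
  rt <- midpoint_root(read_newick(ape::write.tree(tr)))
  tax <- data.frame(taxon_id = rt$phylo$tip.label,
                    phylum = rep(c("P", "Q"), length.out = 8))
  scaled <- rt
  scaled$phylo$edge.length <- scaled$phylo$edge.length * 10
  expect_equal(root_to_tip_lengths(scaled), 10 * root_to_tip_lengths(rt))
  expect_equal(phylum_reference_medians(scaled, tax),
               10 * phylum_reference_medians(rt, tax))
})
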