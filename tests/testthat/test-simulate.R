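test_that("simulated reference trees have monophyletic phyla and truth medians", {
  sim <- simulate_reference_tree(20, 4, seed = 3)
  expect_equal(length(sim$tree$phylo$tip.label), 20L)
  phyla <- split(sim$taxonomy$taxon_id, sim$taxonomy$phylum)
  expect_equal(length(phyla), 4L)
  for (tips in phyla) {
    expect_gte(length(tips), 2L)
    mrca <- ape::getMRCA(sim$tree$phylo, tips)
    clade <- ape::extract.clade(sim$tree$phylo, mrca)
    expect_setequal(clade$tip.label, tips) # monophyly
  }
  expect_equal(phylum_reference_medians(sim$tree, sim$taxonomy), sim$truth,
               tolerance = 1e-12)
  ## determinism
  expect_identical(write_newick(simulate_reference_tree(20, 4, seed = 3)$tree),
                   write_newick(sim$tree))
  expect_error(simulate_reference_tree(5, 4, seed = 1), "2 taxa per phylum")
})

test_that("simulate_placements injects the intended rERs exactly", {
  sim <- simulate_reference_tree(24, 4, seed = 19)
  comp <- stats::setNames(c(0.4, 0.3, 0.2, 0.1),
                          sort(unique(sim$taxonomy$phylum)))
  meds <- phylum_reference_medians(sim$tree, sim$taxonomy)

  exact <- simulate_placements(sim$tree, sim$taxonomy, comp, delta = 0,
                               n_markers = 50, seed = 2, sigma = 0)
  rers <- marker_rer(query_tip_length(sim$tree, exact$records),
                     unname(meds[exact$meta$phylum]))
  expect_lt(max(abs(rers)), 1e-9)
  expect_equal(community_rer(rers), 0, tolerance = 1e-9)

  noisy <- simulate_placements(sim$tree, sim$taxonomy, comp, delta = 0.3,
                               n_markers = 200, seed = 4, sigma = 0.05)
  rers2 <- marker_rer(query_tip_length(sim$tree, noisy$records),
                      unname(meds[noisy$meta$phylum]))
  expect_lt(abs(community_rer(rers2) - 0.3), 0.03)
  expect_equal(rers2, noisy$truth$target_rer, tolerance = 1e-9)

  ## round-trip through jplace reproduces intended tip lengths
  f <- tempfile(fileext = ".jplace")
  write_jplace(sim$tree, noisy$records, f)
  ps <- read_jplace(f, tree = sim$tree)
  got <- query_tip_length(sim$tree, best_placement(ps))
  want <- noisy$truth$tip_length[match(best_placement(ps)$query_id,
                                       noisy$truth$query_id)]
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("annotation generator honors tau and rejects unknown categories", {
  none <- simulate_annotation_table(2000, 0, seed = 6)
  expect_equal(sum(none$is_transposase), 0L)
  expect_error(simulate_annotation_table(10, 0.1, c(ZZ = 1), seed = 1),
               "unknown categories")
  kept <- filter_hits(none)
  expect_equal(nrow(kept), 2000L) # generated to pass the default filter
})

test_that("abundance generator supports the census and contrast regimes", {
  ## census regime: every taxon abundant => ACE equals true richness
  ab <- simulate_abundances(20, seed = 12, depth = 50000, sdlog = 0.3)
  expect_true(all(ab > 10))
  expect_equal(ace_richness(ab), 20)

  ## low vs high diversity regime mirrors the stated richness contrast
  lo <- vapply(1:18, function(i)
    ace_richness(simulate_abundances(150, seed = 100 + i, depth = 5000)),
    numeric(1))
  hi <- vapply(1:18, function(i)
    ace_richness(simulate_abundances(240, seed = 200 + i, depth = 5000)),
    numeric(1))
  wt <- suppressWarnings(wilcox.test(lo, hi, alternative = "less"))
  expect_lt(wt$p.value, 0.001)
})

test_that("simulate_study writes a parseable, byte-stable bundle", {
  cfg <- study_config(seed = 7, n_samples = 2, n_markers = 25, n_pairs = 4,
                      n_codons = 90, n_genes = 400, depth = 1500)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  md5 <- function(base, fs) unname(tools::md5sum(file.path(base, fs)))
  expect_identical(md5(d1, f1), md5(d2, f1))

  ## every generated file parses through its reader with zero warnings
  expect_no_warning({
    tree <- read_newick(file.path(d1, "tree.nwk"))
    tax <- read_taxonomy(file.path(d1, "taxonomy.tsv"))
    man <- read_study_manifest(file.path(d1, "manifest.tsv"))
    for (i in seq_len(nrow(man))) {
      ps <- read_jplace(file.path(d1, man$jplace[i]), tree = tree)
      read_query_manifest(file.path(d1, man$queries[i]))
      read_annotation(file.path(d1, man$annotation[i]))
      read_abundance(file.path(d1, man$abundance[i]))
      read_codon_pairs(file.path(d1, man$orthologs[i]))
    }
  })
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(length(truth$samples), 12L)
  expect_true(all(c("delta", "omega", "tau", "s_true", "composition") %in%
                    names(truth$samples[[1]])))
})
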