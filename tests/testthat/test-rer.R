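test_that("marker_rer implements the normalized deviation", {
  expect_equal(marker_rer(1.2, 1.0), 0.2, tolerance = 1e-12)
  expect_equal(marker_rer(1.0, 1.0), 0)
  expect_equal(marker_rer(12, 10), marker_rer(1.2, 1.0), tolerance = 1e-12)
  expect_equal(marker_rer(1.2, 1.0, method = "difference"), 0.2)
  expect_error(marker_rer(1, 0), "degenerate")
  expect_error(marker_rer(1, NA_real_), "missing")
})

test_that("community and habitat rERs follow the stated aggregation", {
  expect_equal(community_rer(c(0.1, 0.2, 0.9)), 0.2)
  expect_equal(community_rer(c(0.1, 0.3)), 0.2)
  expect_error(community_rer(numeric(0)), "pool")
  expect_equal(habitat_rer(c(0.2, 0.4)), 0.3)
  expect_equal(habitat_rer(0.25), 0.25)
  expect_error(habitat_rer(numeric(0)), "no community")
  set.seed(10)
  x <- rnorm(1001)
  expect_equal(community_rer(x), sort(x)[501]) # sort-based oracle
  expect_gte(community_rer(x), min(x))
  expect_lte(community_rer(x), max(x))
})

test_that("habitat_association handles perfect, reversed and degenerate cases", {
  ## tie-free case: one sample per habitat, rER monotone in score
  hs <- stats::setNames(1:12, sprintf("h%02d", 1:12))
  hab <- names(hs)
  rers <- 0.01 * (1:12)
  res <- habitat_association(rers, hab, hs, n_perm = 199, seed = 3)
  expect_equal(res$rho, 1, tolerance = 1e-9)
  expect_equal(res$p, 1 / 200)

  expect_equal(habitat_association(rev(rers), hab, hs, n_perm = 99,
                                   seed = 1)$rho, -1, tolerance = 1e-9)

  two <- c(a = 1, b = 2)
  hab2 <- rep(names(two), each = 3)
  expect_equal(habitat_association(rep(0.2, 6), hab2, two, n_perm = 99,
                                   seed = 1), list(rho = 0, p = 1))
  expect_error(habitat_association(rers, hab, hs, n_perm = 10), "99")
  expect_error(habitat_association(rers, rep("one", 12), c(one = 1),
                                   n_perm = 99), "2 habitats")
})

test_that("habitat_association p-values are calibrated under the null", {
  ## labels shuffled independently of rER: rejection rate near alpha
  set.seed(2024)
  hs <- c(a = 1, b = 2, c = 3)
  n_rep <- 600
  rej <- 0L
  for (r in seq_len(n_rep)) {
    hab <- sample(rep(names(hs), each = 5))
    rers <- rnorm(15)
    p <- habitat_association(rers, hab, hs, n_perm = 99,
                             seed = 10000 + r)$p
    if (p <= 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("pairwise habitat tests use exact small-sample p and BH", {
  vals <- c(1, 2, 3, 4, 5, 6)
  hab <- rep(c("g1", "g2"), each = 3)
  res <- pairwise_habitat_tests(vals, hab, alternative = "less")
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 20) # exact enumeration of C(6,3) labelings

  same <- pairwise_habitat_tests(rep(c(1, 2, 3), 2), hab,
                                 alternative = "two.sided")
  expect_gte(same$p, 0.99)

  ## BH step-up applied by hand to the raw p-vector {0.01, 0.02, 0.04}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  expect_warning(
    res3 <- pairwise_habitat_tests(c(vals, 9), c(hab, "tiny"),
                                   alternative = "two.sided"), "excluded")
  expect_equal(nrow(res3), 1L)
  expect_true(all(res3$p_adj >= res3$p))
})

test_that("rER is invariant under global rescaling of tree and placements", {
  sim <- simulate_reference_tree(20, 4, seed = 55)
  comp <- stats::setNames(rep(0.25, 4), sort(unique(sim$taxonomy$phylum)))
  pl <- simulate_placements(sim$tree, sim$taxonomy, comp, delta = 0.25,
                            n_markers = 40, seed = 9)
  meds <- phylum_reference_medians(sim$tree, sim$taxonomy)
  r1 <- marker_rer(query_tip_length(sim$tree, pl$records),
                   unname(meds[pl$meta$phylum]))
  scaled <- sim$tree
  scaled$phylo$edge.length <- scaled$phylo$edge.length * 7
  rec7 <- pl$records
  rec7$offset <- rec7$offset * 7
  rec7$pendant_length <- rec7$pendant_length * 7
  r7 <- marker_rer(query_tip_length(scaled, rec7),
                   unname(phylum_reference_medians(scaled, sim$taxonomy)[pl$meta$phylum]))
  expect_equal(r1, r7, tolerance = 1e-9)
})

test_that("two synthetic habitats with delta 0.30 vs 0.13 separate reliably", {
  ## scaled-down version of the acceptance criterion (10 seeds here)
  sim <- simulate_reference_tree(24, 4, seed = 61)
  comp <- stats::setNames(rep(0.25, 4), sort(unique(sim$taxonomy$phylum)))
  hits <- 0L
  for (s in 1:10) {
    com_rers <- list()
    for (hab in c("fast", "slow")) {
      delta <- if (hab == "fast") 0.30 else 0.13
      rers <- vapply(1:8, function(i) {
        pl <- simulate_placements(sim$tree, sim$taxonomy, comp, delta, 50,
                                  seed = derive_seed(1000 * s + i,
                                                     match(hab, c("fast", "slow"))))
        meds <- phylum_reference_medians(sim$tree, sim$taxonomy)
        community_rer(marker_rer(query_tip_length(sim$tree, pl$records),
                                 unname(meds[pl$meta$phylum])))
      }, numeric(1))
      com_rers[[hab]] <- rers
    }
    res <- pairwise_habitat_tests(c(com_rers$fast, com_rers$slow),
                                  rep(c("fast", "slow"), each = 8),
                                  alternative = "greater")
    ok_mean <- abs(mean(com_rers$fast) - 0.30) <= 0.05 &&
      abs(mean(com_rers$slow) - 0.13) <= 0.05
    if (ok_mean && res$p_adj < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
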