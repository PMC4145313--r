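## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: path sums by parent-pointer climbing, midpoint
## by exact per-edge minimax, NG86 by recursive pathway enumeration, Fisher
## by explicit hypergeometric sums.

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 2)
  tr
}

## exact minimax root search: for every edge, tips are assigned to the two
## sides by distance comparison and the optimal point solved in closed form
brute_force_midpoint_value <- function(phylo) {
  D <- ape::dist.nodes(phylo)
  n <- length(phylo$tip.label)
  best <- Inf
  for (k in seq_len(nrow(phylo$edge))) {
    a <- phylo$edge[k, 1L]; b <- phylo$edge[k, 2L]
    len <- phylo$edge.length[k]
    da <- D[seq_len(n), a]; db <- D[seq_len(n), b]
    a_side <- da <= db          # tips reached through a
    maxA <- if (any(a_side)) max(da[a_side]) else -Inf
    maxB <- if (any(!a_side)) max(db[!a_side]) else -Inf
    x <- min(max((maxB + len - maxA) / 2, 0), len)
    f <- max(maxA + x, maxB + len - x)
    best <- min(best, f)
  }
  best
}

## per-tip root-to-tip path sums by climbing parent pointers
oracle_root_to_tip <- function(phylo) {
  n <- length(phylo$tip.label)
  parent <- rep(NA_integer_, n + phylo$Nnode)
  elen <- rep(NA_real_, n + phylo$Nnode)
  parent[phylo$edge[, 2L]] <- phylo$edge[, 1L]
  elen[phylo$edge[, 2L]] <- phylo$edge.length
  vapply(seq_len(n), function(tip) {
    s <- 0; v <- tip
    while (!is.na(parent[v])) {
      s <- s + elen[v]
      v <- parent[v]
    }
    s
  }, numeric(1)) |> stats::setNames(phylo$tip.label)
}

## ---- NG86 oracle: recursive exhaustive pathway enumeration ---------------

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_site_counts <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, character(1))
    aas <- oracle_code[muts]
    ok <- aas != "*"
    if (any(ok)) s <- s + mean(aas[ok] == oracle_code[[codon]])
  }
  c(3 - s, s)
}

oracle_pathways <- function(c1, c2) {
  ## returns all (nd, sd) step-count pairs over stop-free pathways
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  recurse <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_code[[nxt]] == "*") next
      step <- if (oracle_code[[nxt]] == oracle_code[[cur]]) c(0, 1) else c(1, 0)
      for (tail in recurse(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <- step + tail
    }
    out
  }
  recurse(c1, pos)
}

oracle_diff_counts <- function(c1, c2) {
  paths <- oracle_pathways(c1, c2)
  if (!length(paths)) return(NULL) # all pathways stop-blocked
  m <- do.call(rbind, paths)
  colMeans(m)
}

random_sense_codon <- function(n = 1L) {
  sense <- names(oracle_code)[oracle_code != "*"]
  sample(sense, n, replace = TRUE)
}

## one-tailed Fisher p by explicit hypergeometric enumeration
oracle_fisher_one_tailed <- function(a, b, c, d) {
  n_focal <- a + b
  k_cat <- a + c
  n_tot <- a + b + c + d
  lo <- max(0L, n_focal - (n_tot - k_cat))
  hi <- min(n_focal, k_cat)
  support <- lo:hi
  probs <- vapply(support, function(x)
    choose(k_cat, x) * choose(n_tot - k_cat, n_focal - x) /
      choose(n_tot, n_focal), numeric(1))
  over <- a / (a + b) >= c / (c + d)
  if (over) sum(probs[support >= a]) else sum(probs[support <= a])
}

## largest-remainder allocation, written independently
oracle_allocation <- function(p, n) {
  p <- p[order(names(p))]
  quota <- p * n
  k <- floor(quota)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(quota - k, decreasing = TRUE)
    ## tie-break on names to mirror the stated determinism rule
    ord <- ord[order(-(quota - k)[ord], names(p)[ord])]
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(k), names(p))
}

## cached small synthetic study for pipeline tests
.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    dir <- file.path(tempdir(), "rerate_small_study")
    cfg <- study_config(seed = 99L, n_samples = 3L, n_markers = 40L,
                        n_pairs = 8L, n_codons = 120L, n_genes = 1200L,
                        depth = 3000L)
    simulate_study(cfg, dir)
    .fixture_env$study <- dir
  }
  .fixture_env$study
}

small_results <- function() {
  if (is.null(.fixture_env$results)) {
    out <- file.path(tempdir(), "rerate_small_results")
    .fixture_env$res_obj <- run_study(small_study(), out, seed = 5L, B = 60L)
    .fixture_env$results <- out
  }
  list(dir = .fixture_env$results, res = .fixture_env$res_obj)
}
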