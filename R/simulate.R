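## Synthetic-study generator.  Emits every input format the pipeline
## consumes (newick + taxonomy, jplace + query manifests, paired codon
## FASTA, annotation/abundance TSVs, read statistics) with known ground
## truth, so parameter recovery is testable end to end without downloads.
## Rate deviations are injected through the placement geometry (pendant /
## attachment lengths), which keeps the generator exact: a query generated
## with deviation delta has root-to-tip length (1 + delta + eps) * median.

#' The 31 universal phylogenetic marker gene families (COG ids)
#' @return character vector of COG identifiers.
#' @export
marker_cogs <- function() {
  c("COG0012", "COG0016", "COG0018", "COG0048", "COG0049", "COG0052",
    "COG0080", "COG0081", "COG0087", "COG0088", "COG0090", "COG0091",
    "COG0092", "COG0093", "COG0094", "COG0096", "COG0097", "COG0098",
    "COG0099", "COG0100", "COG0102", "COG0103", "COG0124", "COG0172",
    "COG0184", "COG0185", "COG0186", "COG0197", "COG0200", "COG0201",
    "COG0202")
}

cog_categories <- function() {
  c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
    "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")
}

default_cog_props <- function() {
  p <- c(J = 0.07, K = 0.07, L = 0.05, D = 0.02, V = 0.02, T = 0.04,
         M = 0.06, N = 0.02, U = 0.03, O = 0.04, C = 0.06, G = 0.06,
         E = 0.08, F = 0.03, H = 0.04, I = 0.03, P = 0.05, Q = 0.02,
         R = 0.12, S = 0.09)
  p / sum(p)
}

#' Simulate a reference phylogeny with monophyletic phyla
#'
#' Each phylum is an independent birth-death clade scaled to unit depth;
#' clades are joined at a root polytomy by stem branches, the tree is
#' midpoint rooted and edges are numbered post-order.
#'
#' @param n_taxa total number of tips (>= 2 per phylum).
#' @param n_phyla number of phyla.
#' @param seed integer seed.
#' @param scale multiplier applied to all branch lengths (default 0.5, so
#'   typical root-to-tip lengths are ~1 substitution/site).
#' @return list: `tree` (rooted `ref_tree`), `taxonomy` (data.frame),
#'   `truth` (per-phylum median root-to-tip lengths computed independently
#'   of [root_to_tip_lengths()]).
#' @export
simulate_reference_tree <- function(n_taxa, n_phyla, seed, scale = 0.5) {
  if (n_taxa < 2L * n_phyla)
    stop("need at least 2 taxa per phylum (n_taxa >= 2 * n_phyla)")
  set.seed(seed)
  sizes <- rep(n_taxa %/% n_phyla, n_phyla)
  extra <- n_taxa - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  subs <- character(n_phyla)
  taxonomy <- list()
  for (k in seq_len(n_phyla)) {
    sub <- ape::rphylo(sizes[k], birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(sub))
    sub$edge.length <- sub$edge.length / depth # unit depth per clade
    sub$tip.label <- sprintf("p%02d_t%03d", k, seq_len(sizes[k]))
    taxonomy[[k]] <- data.frame(taxon_id = sub$tip.label,
                                phylum = sprintf("phylum%02d", k),
                                stringsAsFactors = FALSE)
    txt <- ape::write.tree(sub, digits = 12)
    stem <- stats::runif(1, 0.5, 1.5)
    subs[k] <- paste0(sub("; *$", "", txt), ":", format(stem, digits = 12))
  }
  newick <- paste0("(", paste(subs, collapse = ","), ");")
  rt <- read_newick(newick)
  rt$phylo$edge.length <- rt$phylo$edge.length * scale
  rt <- midpoint_root(rt)
  taxonomy <- do.call(rbind, taxonomy)
  ## independent median bookkeeping via the node-distance matrix
  phylo <- rt$phylo
  root <- length(phylo$tip.label) + 1L
  d <- ape::dist.nodes(phylo)[root, seq_along(phylo$tip.label)]
  med <- tapply(d, taxonomy$phylum[match(phylo$tip.label,
                                         taxonomy$taxon_id)], stats::median)
  list(tree = rt, taxonomy = taxonomy,
       truth = stats::setNames(as.numeric(med), names(med))[sort(names(med))])
}

## edge rows of the clade spanned by a phylum's tips (stem edge included)
phylum_edge_rows <- function(phylo, tips) {
  tip_ids <- match(tips, phylo$tip.label)
  if (length(tip_ids) == 1L) return(which(phylo$edge[, 2L] == tip_ids))
  mrca <- ape::getMRCA(phylo, tip_ids)
  nodes <- mrca
  repeat {
    kids <- phylo$edge[phylo$edge[, 1L] %in% nodes, 2L]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  which(phylo$edge[, 2L] %in% nodes)
}

#' Simulate phylogenetic placements with a known rate deviation
#'
#' For each marker fragment a phylum is drawn from the sample composition
#' and the fragment is attached inside that phylum's clade so that its
#' root-to-query-tip length equals `(1 + delta + eps) * phylum_median`,
#' with `eps ~ Normal(0, sigma)` truncated so lengths stay positive.
#'
#' @param tree rooted `ref_tree`.
#' @param taxonomy taxon-to-phylum data.frame.
#' @param composition named phylum proportions (sum to 1).
#' @param delta injected rER deviation (> -1).
#' @param n_markers number of fragments.
#' @param seed integer seed.
#' @param sigma sd of the per-fragment rER noise (default 0.05).
#' @param sample_id used in query ids.
#' @return list: `records` (normalized placement records), `meta` (query
#'   manifest: query_id, marker_id, phylum), `truth` (intended per-query
#'   rER and tip length).
#' @export
simulate_placements <- function(tree, taxonomy, composition, delta,
                                n_markers, seed, sigma = 0.05,
                                sample_id = "s") {
  if (delta <= -1) stop("delta must exceed -1")
  set.seed(seed)
  meds <- phylum_reference_medians(tree, taxonomy)
  depths <- node_depths(tree)
  phylo <- tree$phylo
  rows_by_phylum <- lapply(stats::setNames(nm = names(composition)), function(ph) {
    phylum_edge_rows(phylo, taxonomy$taxon_id[taxonomy$phylum == ph])
  })
  phs <- sample(names(composition), n_markers, replace = TRUE,
                prob = composition)
  eps <- stats::rnorm(n_markers, 0, sigma)
  bad <- which(1 + delta + eps < 0.05)
  for (i in bad) {
    for (try in 1:100) {
      eps[i] <- stats::rnorm(1, 0, sigma)
      if (1 + delta + eps[i] >= 0.05) break
    }
  }
  target <- (1 + delta + eps) * meds[phs]
  rec <- vector("list", n_markers)
  for (i in seq_len(n_markers)) {
    rows <- rows_by_phylum[[phs[i]]]
    pdep <- depths[phylo$edge[rows, 1L]]
    feas <- rows[pdep <= target[i]]
    if (!length(feas))
      stop("no feasible attachment for phylum ", phs[i],
           " at target length ", format(target[i]))
    row <- if (length(feas) == 1L) feas else feas[sample.int(length(feas), 1L)]
    pd <- depths[phylo$edge[row, 1L]]
    elen <- phylo$edge.length[row]
    off <- stats::runif(1, 0, min(elen, target[i] - pd))
    rec[[i]] <- data.frame(
      query_id = sprintf("%s_q%04d", sample_id, i),
      edge_num = tree$edge_num[row],
      offset = off,
      pendant_length = target[i] - pd - off,
      like_weight_ratio = 1,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  markers <- sample(marker_cogs(), n_markers, replace = TRUE)
  meta <- data.frame(query_id = records$query_id, marker_id = markers,
                     phylum = phs, stringsAsFactors = FALSE)
  truth <- data.frame(query_id = records$query_id, phylum = phs,
                      target_rer = delta + eps,
                      tip_length = unname(target),
                      stringsAsFactors = FALSE)
  list(records = records, meta = meta, truth = truth)
}

#' Simulate pairwise codon alignments under a fixed omega
#'
#' Ancestral codons are drawn uniformly from the 61 sense codons; point
#' mutations arrive at the stated expected divergence and are accepted with
#' relative probability 1 (synonymous) or `omega` (nonsynonymous; for
#' `omega > 1` the synonymous acceptance is scaled down instead).  Stop
#' codons are never introduced.
#'
#' @param omega target dN/dS (>= 0).
#' @param n_pairs number of ortholog pairs.
#' @param n_codons codons per sequence.
#' @param seed integer seed.
#' @param divergence expected accepted-attempt rate per codon (default 0.3).
#' @return list of `c(seq1, seq2)` character pairs, named `pair0001`, ...
#' @export
simulate_codon_pairs <- function(omega, n_pairs, n_codons, seed,
                                 divergence = 0.3) {
  if (omega < 0) stop("omega must be >= 0")
  set.seed(seed)
  code <- standard_code()
  sense <- names(code)[code != "*"]
  p_non <- min(1, omega)
  p_syn <- if (omega > 1) 1 / omega else 1
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    anc <- sample(sense, n_codons, replace = TRUE)
    der <- anc
    n_events <- stats::rpois(1, divergence * n_codons)
    for (e in seq_len(n_events)) {
      i <- sample.int(n_codons, 1L)
      pos <- sample.int(3L, 1L)
      cur <- der[i]
      b <- sample(setdiff(ng86_bases, substr(cur, pos, pos)), 1L)
      cand <- cur
      substr(cand, pos, pos) <- b
      if (code[[cand]] == "*") next
      syn <- code[[cand]] == code[[cur]]
      keep <- stats::runif(1) < (if (syn) p_syn else p_non)
      if (keep) der[i] <- cand
    }
    pairs[[k]] <- c(paste(anc, collapse = ""), paste(der, collapse = ""))
  }
  names(pairs) <- sprintf("pair%04d", seq_len(n_pairs))
  pairs
}

write_codon_pairs <- function(pairs, file) {
  lines <- unlist(lapply(names(pairs), function(nm) {
    c(paste0(">", nm, "_a"), pairs[[nm]][1L],
      paste0(">", nm, "_b"), pairs[[nm]][2L])
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Simulate a gene annotation table
#'
#' Transposase flags are Bernoulli(`tau`); COG category letters follow the
#' base composition with per-category log-odds effects applied through a
#' softmax; the filter-relevant columns are generated to pass the default
#' thresholds.
#'
#' @param n_genes number of genes.
#' @param tau transposase fraction in [0, 1].
#' @param cog_effects named log-odds-ratio effects vs the base composition
#'   (categories must exist in `base_props`).
#' @param seed integer seed.
#' @param base_props named base category proportions.
#' @return annotation data.frame (gene_id, match_length, identity,
#'   coverage, score, cog, is_transposase).
#' @export
simulate_annotation_table <- function(n_genes, tau, cog_effects = NULL,
                                      seed = 1L,
                                      base_props = default_cog_props()) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  if (!is.null(cog_effects)) {
    unknown <- setdiff(names(cog_effects), names(base_props))
    if (length(unknown))
      stop("effects for unknown categories: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  lo <- log(base_props)
  if (!is.null(cog_effects)) lo[names(cog_effects)] <- lo[names(cog_effects)] + cog_effects
  probs <- exp(lo - max(lo))
  probs <- probs / sum(probs)
  data.frame(gene_id = sprintf("g%06d", seq_len(n_genes)),
             match_length = sample(100:400, n_genes, replace = TRUE),
             identity = round(stats::runif(n_genes, 50, 100), 1),
             coverage = round(stats::runif(n_genes, 50, 100), 1),
             score = round(stats::runif(n_genes, 60, 500), 1),
             cog = sample(names(probs), n_genes, replace = TRUE, prob = probs),
             is_transposase = stats::rbinom(n_genes, 1L, tau) == 1L,
             stringsAsFactors = FALSE)
}

#' Simulate a taxon abundance vector
#'
#' Lognormal relative abundances sampled multinomially at the stated depth.
#'
#' @param s_true true number of taxa.
#' @param seed integer seed.
#' @param depth sequencing depth (total count, >= 1).
#' @param sdlog lognormal shape (default 1).
#' @return named integer count vector (taxa with zero counts retained).
#' @export
simulate_abundances <- function(s_true, seed, depth = 5000L, sdlog = 1) {
  if (s_true < 1L) stop("s_true must be >= 1")
  if (depth < 1L) stop("depth must be >= 1")
  set.seed(seed)
  rel <- stats::rlnorm(s_true, meanlog = 0, sdlog = sdlog)
  counts <- stats::rmultinom(1L, depth, rel)[, 1L]
  stats::setNames(as.integer(counts), sprintf("taxon%04d", seq_len(s_true)))
}

simulate_proteins <- function(ogt, n_residues, seed) {
  f <- (ogt + 335) / 937
  if (f < 0 || f > 1) stop("OGT outside representable range")
  set.seed(seed)
  hot <- c("I", "V", "Y", "W", "R", "E", "L")
  cold <- setdiff(strsplit("ACDFGHKMNPQST", "")[[1]], hot)
  inset <- stats::rbinom(n_residues, 1L, f) == 1L
  res <- character(n_residues)
  res[inset] <- sample(hot, sum(inset), replace = TRUE)
  res[!inset] <- sample(cold, sum(!inset), replace = TRUE)
  paste(res, collapse = "")
}

#' Default study configuration
#'
#' Six habitats mirroring the study design the package targets: three
#' "extreme" habitats (acid mine drainage, saline lake, hot spring) with
#' high rER deviation, higher dN/dS and transposase levels and lower
#' richness, and three "normal" habitats (surface ocean, freshwater, soil)
#' with the reverse.  See the methods vignette for the rationale behind
#' each default.
#'
#' @param seed master seed.
#' @param n_samples samples per habitat (default 6).
#' @param n_taxa,n_phyla reference-tree size (default 40 taxa, 5 phyla).
#' @param n_markers marker fragments per sample (Poisson mean, default 60).
#' @param n_pairs,n_codons ortholog pairs per sample and codons per pair.
#' @param n_genes annotated genes per sample.
#' @param depth abundance sequencing depth.
#' @param avg_read_length average read length in bp.
#' @param sigma per-fragment rER noise sd.
#' @param divergence codon-pair divergence per codon.
#' @return a `study_config` list.
#' @export
study_config <- function(seed = 1L, n_samples = 6L, n_taxa = 40L,
                         n_phyla = 5L, n_markers = 60L, n_pairs = 30L,
                         n_codons = 150L, n_genes = 2000L, depth = 5000L,
                         avg_read_length = 400, sigma = 0.05,
                         divergence = 0.3) {
  habitats <- data.frame(
    habitat = c("amd", "saline_lake", "hot_spring",
                "surface_ocean", "freshwater", "soil"),
    group = c("extreme", "extreme", "extreme",
              "normal", "normal", "normal"),
    delta = c(0.32, 0.33, 0.22, 0.15, 0.13, 0.10),
    omega = c(0.25, 0.25, 0.22, 0.12, 0.12, 0.12),
    tau = c(0.010, 0.008, 0.006, 0.0006, 0.001, 0.002),
    s_true = c(150L, 150L, 160L, 240L, 240L, 260L),
    ogt = c(30, 25, 70, 20, 20, 20),
    ags = c(2.72e6, 2.72e6, 2.72e6, 3.13e6, 3.13e6, 3.13e6),
    cog_L_effect = c(log(2), 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  habitats$n_samples <- n_samples
  structure(list(seed = as.integer(seed), habitats = habitats,
                 n_taxa = n_taxa, n_phyla = n_phyla, n_markers = n_markers,
                 n_pairs = n_pairs, n_codons = n_codons, n_genes = n_genes,
                 depth = depth, avg_read_length = avg_read_length,
                 sigma = sigma, divergence = divergence,
                 marker_bp_per_genome = 15000),
            class = "study_config")
}

#' Generate a complete on-disk synthetic study
#'
#' Writes the reference tree (newick with edge numbers), taxonomy, a study
#' manifest, per-sample jplace/query-manifest/annotation/abundance/codon
#' FASTA/protein files, the serialized configuration and a `truth.json`
#' with every generator parameter.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; all paths are relative to
#'   `out_dir`.
#' @export
simulate_study <- function(config = study_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)
  ref <- simulate_reference_tree(config$n_taxa, config$n_phyla,
                                 derive_seed(config$seed, 0L))
  write_newick(ref$tree, file.path(out_dir, "tree.nwk"), edge_numbers = TRUE)
  write_tsv(ref$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  phyla <- sort(unique(ref$taxonomy$phylum))
  hab <- config$habitats
  manifest <- list()
  truth_samples <- list()
  sidx <- 0L
  for (h in seq_len(nrow(hab))) {
    for (r in seq_len(hab$n_samples[h])) {
      sidx <- sidx + 1L
      sid <- sprintf("%s_%02d", hab$habitat[h], r)
      sseed <- derive_seed(config$seed, sidx)
      set.seed(sseed)
      comp <- stats::rgamma(length(phyla), shape = 2)
      comp <- stats::setNames(comp / sum(comp), phyla)
      n_mark <- max(10L, stats::rpois(1L, config$n_markers))
      sim <- simulate_placements(ref$tree, ref$taxonomy, comp,
                                 hab$delta[h], n_mark,
                                 derive_seed(sseed, 1L),
                                 sigma = config$sigma, sample_id = sid)
      jp <- file.path("samples", paste0(sid, ".jplace"))
      write_jplace(ref$tree, sim$records, file.path(out_dir, jp))
      qm <- file.path("samples", paste0(sid, "_queries.tsv"))
      write_tsv(sim$meta, file.path(out_dir, qm))
      pairs <- simulate_codon_pairs(hab$omega[h], config$n_pairs,
                                    config$n_codons,
                                    derive_seed(sseed, 2L),
                                    divergence = config$divergence)
      fa <- file.path("samples", paste0(sid, "_orthologs.fasta"))
      write_codon_pairs(pairs, file.path(out_dir, fa))
      effects <- if (hab$cog_L_effect[h] != 0) c(L = hab$cog_L_effect[h]) else NULL
      ann <- simulate_annotation_table(config$n_genes, hab$tau[h], effects,
                                       seed = derive_seed(sseed, 3L))
      at <- file.path("samples", paste0(sid, "_annotation.tsv"))
      write_tsv(ann, file.path(out_dir, at))
      ab <- simulate_abundances(hab$s_true[h], derive_seed(sseed, 4L),
                                depth = config$depth)
      abt <- file.path("samples", paste0(sid, "_abundance.tsv"))
      write_tsv(data.frame(taxon = names(ab), count = unname(ab)),
                file.path(out_dir, abt))
      prot <- simulate_proteins(hab$ogt[h], 20000L, derive_seed(sseed, 5L))
      pf <- file.path("samples", paste0(sid, "_proteins.txt"))
      writeLines(prot, file.path(out_dir, pf))
      ## read stats chosen so the AGS estimator recovers the habitat truth
      total_bp <- n_mark * config$avg_read_length * hab$ags[h] /
        config$marker_bp_per_genome
      manifest[[sidx]] <- data.frame(
        sample_id = sid, habitat = hab$habitat[h], group = hab$group[h],
        pool_group = "", jplace = jp, queries = qm, annotation = at,
        abundance = abt, orthologs = fa, proteins = pf,
        avg_read_length = config$avg_read_length, total_bp = total_bp,
        stringsAsFactors = FALSE)
      truth_samples[[sid]] <- list(habitat = hab$habitat[h],
                                   delta = hab$delta[h],
                                   omega = hab$omega[h],
                                   tau = hab$tau[h],
                                   s_true = hab$s_true[h],
                                   ogt = hab$ogt[h], ags = hab$ags[h],
                                   composition = as.list(comp),
                                   n_markers = n_mark, seed = sseed)
    }
  }
  manifest <- do.call(rbind, manifest)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  cfg <- unclass(config)
  cfg$habitats <- NULL
  jsonlite::write_json(list(config = cfg,
                            habitats = config$habitats),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(seed = config$seed,
                            phylum_medians = as.list(ref$truth),
                            samples = truth_samples),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
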