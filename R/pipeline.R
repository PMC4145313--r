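## End-to-end orchestration.  A study directory (as produced by
## simulate_study(), or assembled by hand in the same layout) is driven by a
## manifest TSV; run_study() executes tree prep -> placement ingest -> rER ->
## composition-matched null -> dN/dS -> per-sample metrics -> enrichment ->
## clustering and writes deterministic TSV outputs plus a plain-text report.

#' Read a study manifest
#'
#' @param path manifest TSV; required columns: sample_id, habitat, group,
#'   pool_group, jplace, queries, annotation, abundance, orthologs,
#'   proteins, avg_read_length, total_bp.  File paths are relative to the
#'   manifest's directory.
#' @return data.frame with an attribute `base` (the study directory).
#' @export
read_study_manifest <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "habitat", "group", "pool_group", "jplace",
            "queries", "annotation", "abundance", "orthologs", "proteins",
            "avg_read_length", "total_bp")
  if (!all(need %in% colnames(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in manifest")
  df$pool_group[is.na(df$pool_group)] <- ""
  base <- dirname(path)
  files <- unlist(df[, c("jplace", "queries", "annotation", "abundance",
                         "orthologs", "proteins")])
  missing <- files[!file.exists(file.path(base, files))]
  if (length(missing))
    stop("manifest references missing files:\n  ",
         paste(missing, collapse = "\n  "))
  attr(df, "base") <- base
  df
}

## merge manifest rows sharing a non-empty pool_group into one analysis
## sample (paths become lists; read stats are combined)
apply_pooling <- function(manifest) {
  pooled <- manifest$pool_group != ""
  keys <- ifelse(pooled, manifest$pool_group, manifest$sample_id)
  groups <- split(seq_len(nrow(manifest)), keys)
  rows <- lapply(names(groups), function(key) {
    idx <- groups[[key]]
    m <- manifest[idx, , drop = FALSE]
    list(sample_id = key, habitat = m$habitat[1L], group = m$group[1L],
         jplace = m$jplace, queries = m$queries, annotation = m$annotation,
         abundance = m$abundance, orthologs = m$orthologs,
         proteins = m$proteins,
         avg_read_length = mean(m$avg_read_length),
         total_bp = sum(m$total_bp),
         n_merged = nrow(m))
  })
  names(rows) <- names(groups)
  rows[order(names(rows))]
}

#' Run the full community-rER study
#'
#' @param study_dir directory holding `tree.nwk`, `taxonomy.tsv`,
#'   `manifest.tsv` and the per-sample files the manifest references.
#' @param out_dir results directory (created if needed).
#' @param seed master seed controlling every stochastic stage.
#' @param B simulation replicates per sample for the deviation test.
#' @param alpha_deviation adjusted-p threshold for the deviation test.
#' @param alpha_group threshold reported for the extreme-vs-normal tests.
#' @param focal_habitat habitat whose summed COG counts are tested for
#'   enrichment (default: first extreme habitat in the manifest).
#' @param background_cog optional TSV (`category`, `count`) of background
#'   COG counts; default: all samples pooled.
#' @param rer_method rER formula, see [marker_rer()].
#' @param offset_from jplace offset convention, see [read_jplace()].
#' @param cluster_k number of clusters for the k-cut (default 2).
#' @return invisibly, a list with the main result tables.
#' @export
run_study <- function(study_dir, out_dir, seed = 1L, B = 200L,
                      alpha_deviation = 0.05, alpha_group = 0.001,
                      focal_habitat = NULL, background_cog = NULL,
                      rer_method = "ratio", offset_from = "distal",
                      cluster_k = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_study_manifest(file.path(study_dir, "manifest.tsv"))
  base <- attr(manifest, "base")
  tree <- read_newick(file.path(study_dir, "tree.nwk"))
  if (!tree$rooted) tree <- midpoint_root(tree)
  taxonomy <- read_taxonomy(file.path(study_dir, "taxonomy.tsv"))
  meds <- phylum_reference_medians(tree, taxonomy)
  samples <- apply_pooling(manifest)

  ## ---- rER stage ----------------------------------------------------------
  per_marker <- list()
  marker_hits <- integer(length(samples))
  names(marker_hits) <- names(samples)
  for (sid in names(samples)) {
    s <- samples[[sid]]
    parts <- lapply(seq_along(s$jplace), function(i) {
      ps <- read_jplace(file.path(base, s$jplace[i]), tree = tree,
                        offset_from = offset_from, sample_id = sid)
      qm <- read_query_manifest(file.path(base, s$queries[i]))
      rer_table(tree, meds, ps, qm, sample_id = sid, method = rer_method)
    })
    tab <- do.call(rbind, parts)
    tab$habitat <- s$habitat
    marker_hits[sid] <- nrow(tab)
    per_marker[[sid]] <- tab
  }
  per_marker <- do.call(rbind, per_marker)
  rownames(per_marker) <- NULL
  per_sample <- do.call(rbind, lapply(names(samples), function(sid) {
    rers <- per_marker$rer[per_marker$sample_id == sid]
    data.frame(sample_id = sid, habitat = samples[[sid]]$habitat,
               group = samples[[sid]]$group, n_markers = length(rers),
               community_rer = community_rer(rers), stringsAsFactors = FALSE)
  }))
  hab_rer <- do.call(rbind, lapply(split(per_sample, per_sample$habitat),
    function(d) data.frame(habitat = d$habitat[1L], n_samples = nrow(d),
                           habitat_rer = habitat_rer(d$community_rer),
                           stringsAsFactors = FALSE)))
  hab_rer <- hab_rer[order(hab_rer$habitat), , drop = FALSE]
  habitat_tests <- pairwise_habitat_tests(per_sample$community_rer,
                                          per_sample$habitat,
                                          alternative = "two.sided")
  write_tsv(per_marker[, c("sample_id", "habitat", "query_id", "marker_id",
                           "phylum", "tip_length", "phylum_median", "rer")],
            file.path(out_dir, "rer_per_marker.tsv"))
  write_tsv(per_sample, file.path(out_dir, "rer_per_sample.tsv"))
  write_tsv(hab_rer, file.path(out_dir, "habitat_rer.tsv"))
  write_tsv(habitat_tests, file.path(out_dir, "habitat_tests.tsv"))

  ## ---- composition-matched null -------------------------------------------
  deviation <- deviation_test_study(per_marker, B = B,
                                    seed = derive_seed(seed, 1L),
                                    alpha = alpha_deviation)
  write_tsv(deviation, file.path(out_dir, "deviation_tests.tsv"))

  ## ---- dN/dS --------------------------------------------------------------
  dnds_pairs <- list()
  dnds_sample <- list()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    pairs <- do.call(c, lapply(s$orthologs, function(p)
      read_codon_pairs(file.path(base, p))))
    tab <- sample_dnds(pairs)
    tab <- cbind(sample_id = sid, tab, stringsAsFactors = FALSE)
    dnds_pairs[[sid]] <- tab
    summ <- community_dnds(tab)
    dnds_sample[[sid]] <- data.frame(
      sample_id = sid, habitat = s$habitat, group = s$group,
      omega = summ$omega, iqr = summ$iqr,
      fraction_purifying = summ$fraction_purifying,
      n_ok = summ$n_ok, n_excluded = summ$n_excluded,
      stringsAsFactors = FALSE)
  }
  dnds_pairs <- do.call(rbind, dnds_pairs)
  rownames(dnds_pairs) <- NULL
  dnds_sample <- do.call(rbind, dnds_sample)
  rownames(dnds_sample) <- NULL
  write_tsv(dnds_pairs, file.path(out_dir, "dnds_per_pair.tsv"))
  write_tsv(dnds_sample, file.path(out_dir, "dnds_per_sample.tsv"))

  ## ---- per-sample metrics -------------------------------------------------
  metrics <- list()
  cog_counts <- list()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    ann <- do.call(rbind, lapply(s$annotation, function(p)
      read_annotation(file.path(base, p))))
    ann <- filter_hits(ann)
    abv <- Reduce(function(x, y) {
      all_t <- union(names(x), names(y))
      out <- stats::setNames(integer(length(all_t)), all_t)
      out[names(x)] <- out[names(x)] + x
      out[names(y)] <- out[names(y)] + y
      out
    }, lapply(s$abundance, function(p) read_abundance(file.path(base, p))))
    prot <- unlist(lapply(s$proteins, function(p)
      readLines(file.path(base, p), warn = FALSE)))
    ogt <- ogt_estimate(prot)
    metrics[[sid]] <- data.frame(
      sample_id = sid, habitat = s$habitat, group = s$group,
      ace = ace_richness(abv),
      ags = average_genome_size(s$avg_read_length, marker_hits[sid],
                                s$total_bp),
      ogt = ogt$ogt,
      transposase = transposase_level(ann)$fraction,
      stringsAsFactors = FALSE)
    cog_counts[[sid]] <- table(ann$cog)
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  write_tsv(metrics, file.path(out_dir, "sample_metrics.tsv"))

  ## ---- enrichment ---------------------------------------------------------
  sum_counts <- function(tabs) {
    cats <- sort(unique(unlist(lapply(tabs, names))))
    out <- stats::setNames(rep(0L, length(cats)), cats)
    for (tb in tabs) out[names(tb)] <- out[names(tb)] + as.integer(tb)
    out
  }
  if (is.null(focal_habitat)) {
    ext <- metrics$habitat[metrics$group == "extreme"]
    focal_habitat <- if (length(ext)) sort(unique(ext))[1L]
                     else sort(unique(metrics$habitat))[1L]
  }
  focal_ids <- metrics$sample_id[metrics$habitat == focal_habitat]
  focal <- sum_counts(cog_counts[focal_ids])
  background <- if (is.null(background_cog)) {
    sum_counts(cog_counts)
  } else {
    bg <- read_tsv(background_cog)
    stats::setNames(as.integer(bg$count), bg$category)
  }
  enrichment <- habitat_enrichment_profile(focal, background)
  write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))

  ## ---- clustering ---------------------------------------------------------
  evo <- data.frame(sample_id = per_sample$sample_id,
                    habitat = per_sample$habitat, group = per_sample$group,
                    rer = per_sample$community_rer,
                    dnds = dnds_sample$omega[match(per_sample$sample_id,
                                                   dnds_sample$sample_id)],
                    transposase = metrics$transposase[match(per_sample$sample_id,
                                                            metrics$sample_id)],
                    ace = metrics$ace[match(per_sample$sample_id,
                                            metrics$sample_id)],
                    stringsAsFactors = FALSE)
  m <- assemble_matrix(evo)
  cl <- hierarchical_cluster(m, k = cluster_k)
  clusters <- data.frame(sample_id = rownames(m),
                         habitat = attr(m, "habitat")[rownames(m)],
                         group = attr(m, "group")[rownames(m)],
                         cluster = unname(cl$labels[rownames(m)]),
                         stringsAsFactors = FALSE)
  write_tsv(clusters, file.path(out_dir, "clusters.tsv"))
  writeLines(cl$newick, file.path(out_dir, "dendrogram.nwk"))

  ## ---- extreme vs normal --------------------------------------------------
  group_tests <- NULL
  if (all(c("extreme", "normal") %in% evo$group)) {
    one <- function(var, alternative) {
      x <- evo[[var]][evo$group == "extreme"]
      y <- evo[[var]][evo$group == "normal"]
      wt <- suppressWarnings(stats::wilcox.test(x, y,
                                                alternative = alternative))
      data.frame(variable = var, alternative = alternative,
                 extreme_mean = mean(x), normal_mean = mean(y),
                 U = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }
    group_tests <- rbind(one("rer", "greater"), one("dnds", "greater"),
                         one("transposase", "greater"), one("ace", "less"))
    group_tests$alpha <- alpha_group
    write_tsv(group_tests, file.path(out_dir, "group_tests.tsv"))
  }

  ## ---- report + log -------------------------------------------------------
  rep_lines <- c(
    "community rER study report",
    sprintf("samples analysed: %d (manifest rows: %d)", nrow(per_sample),
            nrow(manifest)),
    "",
    "habitat rERs (mean of community rERs):",
    sprintf("  %-15s n=%-3d rER=%.4f", hab_rer$habitat, hab_rer$n_samples,
            hab_rer$habitat_rer),
    "",
    sprintf("deviation test: %d/%d samples deviate from composition-matched null (BH-adjusted p < %g)",
            sum(deviation$significant), nrow(deviation), alpha_deviation),
    "",
    if (!is.null(group_tests)) c(
      sprintf("extreme vs normal (one-tailed Mann-Whitney, alpha = %g):",
              alpha_group),
      sprintf("  %-12s extreme=%.4g normal=%.4g p=%.3g", group_tests$variable,
              group_tests$extreme_mean, group_tests$normal_mean,
              group_tests$p)) else character(0),
    "",
    sprintf("k=%d cluster cut (focal enrichment habitat: %s):", cluster_k,
            focal_habitat),
    sprintf("  cluster %d: %s", unique(clusters$cluster),
            vapply(unique(clusters$cluster), function(k)
              paste(clusters$sample_id[clusters$cluster == k],
                    collapse = ", "), character(1))))
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  log_lines <- c(
    sprintf("rerate version: %s",
            as.character(utils::packageVersion("rerate"))),
    sprintf("seed: %d", seed), sprintf("B: %d", B),
    sprintf("alpha_deviation: %g (BH correction)", alpha_deviation),
    sprintf("alpha_group: %g (one-tailed)", alpha_group),
    sprintf("rer_method: %s", rer_method),
    sprintf("offset_from: %s", offset_from))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(per_marker = per_marker, per_sample = per_sample,
                 habitat_rer = hab_rer, habitat_tests = habitat_tests,
                 deviation = deviation, dnds = dnds_sample,
                 metrics = metrics, enrichment = enrichment,
                 clusters = clusters, group_tests = group_tests))
}

## files each stage command is responsible for
stage_files <- list(
  rer = c("rer_per_marker.tsv", "rer_per_sample.tsv", "habitat_rer.tsv",
          "habitat_tests.tsv"),
  `null-test` = "deviation_tests.tsv",
  dnds = c("dnds_per_pair.tsv", "dnds_per_sample.tsv"),
  metrics = "sample_metrics.tsv",
  enrich = "enrichment.tsv",
  cluster = c("clusters.tsv", "dendrogram.nwk"),
  report = c("group_tests.tsv", "report.txt", "run_log.txt"))

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic study), `run` (full
#' pipeline), and the single stages `rer`, `null-test`, `dnds`, `metrics`,
#' `enrich`, `cluster`, `report`, each writing only its own output files
#' (bit-identical to the corresponding `run` outputs under the same seed).
#' Shared flags: `--seed`, `--out`, `--study`, `--B`, `--samples`.
#'
#' @param args character vector, defaults to [base::commandArgs()] output.
#' @return exit status, invisibly.
#' @examples
#' \dontrun{
#' Rscript -e 'rerate::rer_cli()' simulate --out study --seed 1
#' Rscript -e 'rerate::rer_cli()' run --study study --out results --seed 1
#' }
#' @export
rer_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: rer_cli",
                 "<simulate|run|rer|null-test|dnds|metrics|enrich|cluster|report>",
                 "[--flag value ...]")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  flags <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    if (!startsWith(rest[i], "--"))
      stop("unexpected argument: ", rest[i], "\n", usage)
    flags[[substring(rest[i], 3L)]] <- rest[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(flags$seed %||% "1")
  out <- flags$out %||% stop("--out is required")
  if (cmd == "simulate") {
    cfg <- if (is.null(flags$samples)) study_config(seed = seed)
           else study_config(seed = seed,
                             n_samples = as.integer(flags$samples))
    simulate_study(cfg, out)
    return(invisible(0L))
  }
  if (!(cmd %in% c("run", names(stage_files))))
    stop("unknown subcommand: ", cmd, "\n", usage)
  study <- flags$study %||% stop("--study is required")
  B <- as.integer(flags$B %||% "200")
  if (cmd == "run") {
    run_study(study, out, seed = seed, B = B)
  } else {
    tmp <- tempfile("stage")
    run_study(study, tmp, seed = seed, B = B)
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (f in stage_files[[cmd]]) {
      src <- file.path(tmp, f)
      if (file.exists(src)) file.copy(src, file.path(out, f), overwrite = TRUE)
    }
    unlink(tmp, recursive = TRUE)
  }
  invisible(0L)
}
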