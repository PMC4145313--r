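## Relative evolutionary rates.  A placed marker fragment's rER is the
## normalized deviation of its root-to-query-tip branch length from the
## median root-to-tip length of the reference taxa in the same phylum:
## rER = (L_query - median_phylum) / median_phylum.  The community rER of a
## sample is the median of its marker rERs; the habitat rER is the mean of
## its samples' community rERs.

#' Per-marker relative evolutionary rate
#'
#' @param query_length root-to-query-tip branch length(s).
#' @param phylum_median matching phylum baseline median(s), must be > 0.
#' @param method `"ratio"` (default; `(L - m)/m`, scale-invariant) or
#'   `"difference"` (`L - m`, in substitutions/site).
#' @return numeric rER vector.
#' @export
marker_rer <- function(query_length, phylum_median,
                       method = c("ratio", "difference")) {
  method <- match.arg(method)
  if (anyNA(phylum_median)) stop("missing phylum baseline median")
  if (any(phylum_median <= 0)) stop("phylum median must be > 0 (degenerate baseline)")
  if (method == "ratio") (query_length - phylum_median) / phylum_median
  else query_length - phylum_median
}

#' Community rER of one sample
#' @param marker_rers the sample's marker rERs (at least one).
#' @return their median.
#' @export
community_rer <- function(marker_rers) {
  if (length(marker_rers) == 0L)
    stop("no marker rERs; pool this sample with others (pool_group) or drop it")
  stats::median(marker_rers)
}

#' Habitat rER
#' @param community_rers community rERs of the habitat's samples.
#' @return their arithmetic mean.
#' @export
habitat_rer <- function(community_rers) {
  if (length(community_rers) == 0L) stop("no community rERs")
  mean(community_rers)
}

#' Assemble the per-query rER table for one sample
#'
#' Joins best placements with the query manifest (marker id and phylum per
#' query) and the phylum baseline medians.
#'
#' @param tree rooted `ref_tree`.
#' @param phylum_medians named vector from [phylum_reference_medians()].
#' @param placements normalized `placement_set`.
#' @param query_meta data.frame `query_id`, `marker_id`, `phylum`.
#' @param sample_id sample identifier for the output rows.
#' @param method rER formula, see [marker_rer()].
#' @return data.frame: sample_id, query_id, marker_id, phylum, tip_length,
#'   phylum_median, rer; rows ordered by (marker_id, query_id).
#' @export
rer_table <- function(tree, phylum_medians, placements, query_meta,
                      sample_id = placements$sample_id,
                      method = "ratio") {
  best <- best_placement(placements)
  meta_row <- match(best$query_id, query_meta$query_id)
  if (anyNA(meta_row))
    stop("queries missing from manifest: ",
         paste(best$query_id[is.na(meta_row)], collapse = ", "))
  phylum <- query_meta$phylum[meta_row]
  missing_phy <- setdiff(unique(phylum), names(phylum_medians))
  if (length(missing_phy))
    stop("no baseline median for phylum: ", paste(missing_phy, collapse = ", "))
  tip_len <- query_tip_length(tree, best)
  med <- unname(phylum_medians[phylum])
  out <- data.frame(sample_id = sample_id,
                    query_id = best$query_id,
                    marker_id = query_meta$marker_id[meta_row],
                    phylum = phylum,
                    tip_length = tip_len,
                    phylum_median = med,
                    rer = marker_rer(tip_len, med, method = method),
                    stringsAsFactors = FALSE)
  out <- out[order(out$marker_id, out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Habitat-association permutation test
#'
#' Spearman rank correlation between per-sample community rERs and a
#' user-supplied numeric habitat score, with a label-permutation p-value
#' using the +1 finite-sample correction.
#'
#' @param community_rers numeric vector, one per sample.
#' @param habitat character vector of habitat labels per sample.
#' @param habitat_scores named numeric vector scoring each habitat
#'   (ordinal coding is the caller's responsibility).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `rho` and `p`.
#' @export
habitat_association <- function(community_rers, habitat, habitat_scores,
                                n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (length(unique(habitat)) < 2L) stop("need >= 2 habitats")
  miss <- setdiff(unique(habitat), names(habitat_scores))
  if (length(miss)) stop("no score for habitat: ", paste(miss, collapse = ", "))
  if (length(unique(community_rers)) == 1L)
    return(list(rho = 0, p = 1))
  score <- unname(habitat_scores[habitat])
  rho_obs <- stats::cor(rank(community_rers), rank(score))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(habitat)
    rho_b <- stats::cor(rank(community_rers), rank(unname(habitat_scores[perm])))
    if (abs(rho_b) >= abs(rho_obs) - 1e-12) exceed <- exceed + 1L
  }
  list(rho = rho_obs, p = (1 + exceed) / (1 + n_perm))
}

#' Pairwise Mann-Whitney tests between habitats
#'
#' Exact p-values for small groups (combined n <= 12 and no ties), normal
#' approximation with tie correction otherwise; Benjamini-Hochberg
#' adjustment across all pairs.  The one-tailed direction, when requested,
#' is applied as first-vs-second in the alphabetically ordered pair.
#'
#' @param values numeric vector of community rERs (or any per-sample metric).
#' @param habitat habitat label per value.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return data.frame: habitat_a, habitat_b, n_a, n_b, U, p, p_adj.
#' @export
pairwise_habitat_tests <- function(values, habitat,
                                   alternative = c("two.sided", "less",
                                                   "greater")) {
  alternative <- match.arg(alternative)
  groups <- split(values, habitat)
  small <- names(groups)[vapply(groups, length, 1L) < 2L]
  if (length(small)) {
    warning("groups with < 2 values excluded: ", paste(small, collapse = ", "))
    groups <- groups[!(names(groups) %in% small)]
  }
  if (length(groups) < 2L) stop("need >= 2 groups with >= 2 values each")
  labs <- sort(names(groups))
  pairs <- utils::combn(labs, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- groups[[pr[1L]]]; y <- groups[[pr[2L]]]
    exact <- (length(x) + length(y) <= 12L) &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative, exact = exact))
    data.frame(habitat_a = pr[1L], habitat_b = pr[2L],
               n_a = length(x), n_b = length(y),
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
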