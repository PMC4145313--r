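## Per-sample companion estimators: annotation-hit filtering, ACE richness,
## average genome size (AGS), optimal growth temperature (OGT) from proteome
## composition, transposase level as an HGT proxy, and the transposase-HGT
## validation correlation.

#' Filter annotation hits
#'
#' Default thresholds: match length >= 100 aa, identity >= 50%,
#' coverage >= 50%, bit score >= 60.  Per-criterion removal tallies are
#' attached as attribute `"removed"`.  Idempotent.
#'
#' @param table data.frame with columns `match_length`, `identity`,
#'   `coverage`, `score` (additional columns pass through).
#' @param min_length,min_identity,min_coverage,min_score thresholds.
#' @return the filtered data.frame.
#' @export
filter_hits <- function(table, min_length = 100, min_identity = 50,
                        min_coverage = 50, min_score = 60) {
  need <- c("match_length", "identity", "coverage", "score")
  if (!all(need %in% colnames(table)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  fail_len <- table$match_length < min_length
  fail_id <- table$identity < min_identity
  fail_cov <- table$coverage < min_coverage
  fail_sc <- table$score < min_score
  keep <- !(fail_len | fail_id | fail_cov | fail_sc)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no annotation hits survive filtering")
  attr(out, "removed") <- c(match_length = sum(fail_len),
                            identity = sum(fail_id),
                            coverage = sum(fail_cov),
                            score = sum(fail_sc),
                            total = sum(!keep))
  out
}

#' ACE richness estimator (Chao & Lee)
#'
#' Abundance-based coverage estimator using the frequency counts of rare
#' taxa (counts <= `rare_threshold`, conventionally 10):
#' `ACE = S_abund + S_rare / C + (F1 / C) * gamma^2` with sample coverage
#' `C = 1 - F1 / N_rare` and the squared coefficient of variation
#' `gamma^2 = max(S_rare/C * sum(i (i-1) F_i) / (N_rare (N_rare - 1)) - 1, 0)`.
#'
#' Falls back to Chao1 when all rare taxa are singletons (C = 0) and to the
#' observed richness when `N_rare <= 1`, both with a warning.
#'
#' @param counts non-negative integer abundance vector (taxa with count 0
#'   are ignored).
#' @param rare_threshold rare/abundant cut (default 10).
#' @return the ACE estimate (a single number, >= observed richness).
#' @export
ace_richness <- function(counts, rare_threshold = 10) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) <= 0) stop("empty abundance vector")
  if (any(counts != round(counts))) stop("counts must be integers")
  s_obs <- length(counts)
  rare <- counts[counts <= rare_threshold]
  s_abund <- s_obs - length(rare)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_obs)
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_threshold)
  f1 <- f[1L]
  if (n_rare <= 1) {
    warning("N_rare <= 1; returning observed richness")
    return(s_obs)
  }
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare taxa are singletons; falling back to Chao1")
    f2 <- f[2L]
    return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  }
  i <- seq_len(rare_threshold)
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * f) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

#' Average genome size from marker-gene hit density
#'
#' Reconstruction of the single-copy marker density estimator: the fraction
#' of sequenced bases falling in the 31 universal markers is
#' `d = (sum_m R_m * L) / R_total`; dividing the summed marker length per
#' genome by `d` gives the average genome size.
#'
#' @param avg_read_length `L_s`, average read length in bp.
#' @param marker_hits `R_{m,s}`, marker hit counts (vector or total).
#' @param total_bp `R_s`, total sequenced bases of the sample.
#' @param marker_bp_per_genome calibration constant: approximate summed
#'   length of the 31 single-copy markers in one genome (default 15000 bp).
#' @return estimated average genome size in bp.
#' @export
average_genome_size <- function(avg_read_length, marker_hits, total_bp,
                                marker_bp_per_genome = 15000) {
  if (avg_read_length <= 0) stop("average read length must be > 0")
  hits <- sum(marker_hits)
  if (hits <= 0) stop("no marker hits; AGS undefined")
  if (hits * avg_read_length > total_bp)
    stop("marker bases exceed total sequenced bases; inconsistent input")
  d <- hits * avg_read_length / total_bp
  marker_bp_per_genome / d
}

#' Optimal growth temperature from proteome composition
#'
#' `OGT = 937 * F - 335` degrees Celsius, where F is the fraction of
#' residues in the set IVYWREL over the sample's predicted proteins.
#'
#' @param residues a character string (or vector, concatenated) of amino
#'   acid residues.
#' @return list with `F` and `ogt`.
#' @export
ogt_estimate <- function(residues) {
  aa <- strsplit(toupper(paste(residues, collapse = "")), "")[[1]]
  aa <- aa[aa %in% LETTERS]
  if (length(aa) == 0L) stop("no residues supplied")
  f <- mean(aa %in% c("I", "V", "Y", "W", "R", "E", "L"))
  list(F = f, ogt = 937 * f - 335)
}

#' Transposase level of a sample
#'
#' Fraction of (filtered) annotated genes flagged as transposases; the
#' package's proxy for community-wide horizontal gene transfer.
#'
#' @param table filtered annotation data.frame with logical/0-1 column
#'   `is_transposase`.
#' @return list with `fraction` and `percent`.
#' @export
transposase_level <- function(table) {
  if (nrow(table) == 0L) stop("no annotated genes")
  fr <- mean(as.logical(table$is_transposase))
  list(fraction = fr, percent = 100 * fr)
}

#' Transposase-HGT proxy validation
#'
#' Spearman correlation between per-genome transposase counts and known HGT
#' event counts (average ranks for ties, asymptotic p).
#'
#' @param transposases,hgt_events equal-length count vectors (>= 5 genomes).
#' @return list with `rho` and `p`.
#' @export
hgt_proxy_validation <- function(transposases, hgt_events) {
  if (length(transposases) != length(hgt_events))
    stop("input vectors differ in length")
  if (length(transposases) < 5L) stop("need >= 5 genomes")
  if (length(unique(transposases)) == 1L ||
      length(unique(hgt_events)) == 1L) {
    warning("constant column; rho reported as 0")
    return(list(rho = 0, p = 1))
  }
  ct <- suppressWarnings(
    stats::cor.test(transposases, hgt_events, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Read an annotation table
#' @param path TSV with columns gene_id, match_length, identity, coverage,
#'   score, cog, is_transposase.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  need <- c("gene_id", "match_length", "identity", "coverage", "score",
            "cog", "is_transposase")
  if (!all(need %in% colnames(df)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  df$is_transposase <- as.logical(df$is_transposase) |
    df$is_transposase == 1
  df
}

#' Read an abundance table
#' @param path TSV with columns `taxon`, `count`.
#' @return named integer vector.
#' @export
read_abundance <- function(path) {
  df <- read_tsv(path)
  if (!all(c("taxon", "count") %in% colnames(df)))
    stop("abundance table must have columns 'taxon' and 'count'")
  stats::setNames(as.integer(df$count), df$taxon)
}
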