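## COG-category odds-ratio enrichment (one-tailed Fisher tests in the
## direction of the observed odds ratio, Haldane-Anscombe correction for
## zero cells) and hierarchical clustering of samples on the four
## evolutionary variables (rER, dN/dS, transposase level, ACE richness).

#' Odds ratio and one-tailed Fisher test for one 2x2 table
#'
#' Cells: `a` focal genes in the category, `b` focal genes outside it,
#' `c` background genes in the category, `d` background genes outside it.
#' The one-tailed hypergeometric p is taken in the direction of the
#' observed proportion difference; the +0.5 correction is applied to all
#' cells for the odds ratio when any cell is zero.
#'
#' @param a,b,c,d non-negative counts; both margins must be positive.
#' @return list: a, b, c, d, odds_ratio, log_or, p, direction
#'   (`"over"`/`"under"`).
#' @export
cog_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  if (a + b == 0 || c + d == 0) stop("empty margin; both groups need genes")
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  over <- a / (a + b) >= c / (c + d)
  ## X ~ Hypergeom(white = a + c in-category, black = b + d, drawn = a + b)
  p <- if (over) {
    stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    stats::phyper(a, a + c, b + d, a + b, lower.tail = TRUE)
  }
  list(a = a, b = b, c = c, d = d, odds_ratio = or, log_or = log(or),
       p = p, direction = if (over) "over" else "under")
}

#' COG enrichment profile of a habitat against a background
#'
#' One 2x2 test per COG category: focal counts (summed over the habitat's
#' samples) against reference background counts.  Categories absent from
#' both are skipped.  Stars mark p < 0.01 (`**`) and p < 0.001 (`***`).
#'
#' @param focal,background named integer vectors of per-category gene
#'   counts over the same category universe.
#' @return data.frame: category, a, b, c, d, log_or, p, stars; ordered by
#'   category.
#' @export
habitat_enrichment_profile <- function(focal, background) {
  cats <- sort(union(names(focal), names(background)))
  fc <- stats::setNames(rep(0L, length(cats)), cats)
  bc <- fc
  fc[names(focal)] <- focal
  bc[names(background)] <- background
  keep <- fc + bc > 0
  cats <- cats[keep]; fc <- fc[keep]; bc <- bc[keep]
  nf <- sum(fc); nb <- sum(bc)
  rows <- lapply(cats, function(cat) {
    r <- cog_odds_ratio(fc[[cat]], nf - fc[[cat]], bc[[cat]], nb - bc[[cat]])
    data.frame(category = cat, a = r$a, b = r$b, c = r$c, d = r$d,
               log_or = r$log_or, p = r$p,
               stars = if (r$p < 0.001) "***" else if (r$p < 0.01) "**" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the samples x 4 evolutionary-variable matrix
#'
#' Joins per-sample community rER, community dN/dS, transposase level and
#' ACE richness; samples missing any variable are dropped with a warning;
#' columns are z-score standardized (constant columns become zeros with a
#' warning).
#'
#' @param metrics data.frame with columns `sample_id`, `rer`, `dnds`,
#'   `transposase`, `ace` and optionally `habitat`, `group`.
#' @return numeric matrix (rownames = sample ids, standardized columns)
#'   with attributes `habitat` and `group` when supplied.
#' @export
assemble_matrix <- function(metrics) {
  vars <- c("rer", "dnds", "transposase", "ace")
  if (!all(c("sample_id", vars) %in% colnames(metrics)))
    stop("metrics must have columns sample_id, ", paste(vars, collapse = ", "))
  complete <- stats::complete.cases(metrics[, vars])
  if (!all(complete))
    warning("samples dropped for missing variables: ",
            paste(metrics$sample_id[!complete], collapse = ", "))
  metrics <- metrics[complete, , drop = FALSE]
  metrics <- metrics[order(metrics$sample_id), , drop = FALSE]
  m <- as.matrix(metrics[, vars])
  rownames(m) <- metrics$sample_id
  for (j in seq_len(ncol(m))) {
    s <- stats::sd(m[, j])
    if (s == 0) {
      warning("constant column '", vars[j], "' standardized to zeros")
      m[, j] <- 0
    } else {
      m[, j] <- (m[, j] - mean(m[, j])) / s
    }
  }
  if ("habitat" %in% colnames(metrics))
    attr(m, "habitat") <- stats::setNames(metrics$habitat, metrics$sample_id)
  if ("group" %in% colnames(metrics))
    attr(m, "group") <- stats::setNames(metrics$group, metrics$sample_id)
  m
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the standardized evolutionary-variable
#' matrix (default: complete linkage on Euclidean distance), with a k-cut
#' and a newick export of the dendrogram.
#'
#' @param m matrix from [assemble_matrix()].
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @param k number of clusters for the cut (default 2).
#' @return list: `hclust`, `labels` (named cluster ids), `newick`.
#' @export
hierarchical_cluster <- function(m, distance = "euclidean",
                                 linkage = "complete", k = 2L) {
  if (nrow(m) < 2L) stop("need >= 2 samples")
  if (k > nrow(m)) stop("k exceeds the number of samples")
  hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  labels <- stats::cutree(hc, k = k)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, labels = labels,
       newick = ape::write.tree(phy, digits = 10))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b equal-length label vectors.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  expected <- sum_a * sum_b / n
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
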