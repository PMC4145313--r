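## Pairwise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
## correction.  Synonymous/nonsynonymous site fractions exclude mutations to
## stop codons from the denominator; multi-difference codons are resolved by
## averaging over all mutational pathway orderings, excluding pathways that
## pass through a stop codon.

ng86_bases <- c("T", "C", "A", "G")

standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

is_clean_codon <- function(codon) {
  nchar(codon) == 3L & !grepl("[^ACGT]", codon)
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the synonymous site fraction is the fraction of
#' the single-nucleotide mutations at that position that are synonymous,
#' with mutations to stop codons excluded from the denominator.  The codon
#' contributes `s_sites = sum of fractions` and `n_sites = 3 - s_sites`.
#'
#' @param codon a 3-letter DNA string (no gaps/ambiguity, not a stop codon).
#' @param code named genetic code (codon -> amino acid, `*` for stop).
#' @return c(n_sites, s_sites).
#' @export
codon_site_counts <- function(codon, code = standard_code()) {
  codon <- toupper(codon)
  if (!is_clean_codon(codon)) stop("ambiguous or gapped codon: ", codon)
  aa <- code[[codon]]
  if (aa == "*") stop("stop codon has no site counts: ", codon)
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; tot <- 0L
    for (b in ng86_bases) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      maa <- code[[mut]]
      if (maa == "*") next
      tot <- tot + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  c(n_sites = 3 - s, s_sites = s)
}

## Pathway-averaged (nonsynonymous, synonymous) difference counts between
## two sense codons; memoized in a local environment.  The caches assume a
## single genetic code per session (the default standard code).
ng86_cache <- new.env(parent = emptyenv())

## site counts for all sense codons, computed once per session
site_count_table <- function(code = standard_code()) {
  tab <- ng86_cache[["__site_table__"]]
  if (!is.null(tab)) return(tab)
  sense <- names(code)[code != "*"]
  tab <- t(vapply(sense, codon_site_counts, numeric(2), code = code))
  ng86_cache[["__site_table__"]] <- tab
  tab
}

codon_diff_counts <- function(c1, c2, code = standard_code()) {
  key <- paste(min(c1, c2), max(c1, c2))
  hit <- ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) {
    out <- c(nd = 0, sd = 0)
  } else {
    perms <- if (length(pos) == 1L) list(pos)
             else if (length(pos) == 2L) list(pos, rev(pos))
             else {
               idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                           c(3,1,2), c(3,2,1))
               lapply(idx, function(i) pos[i])
             }
    walk <- function(order_pos, allow_stop) {
      cur <- c1; nd <- 0; sd <- 0
      for (p in order_pos) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow_stop && code[[nxt]] == "*") return(NULL)
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(nd, sd)
    }
    counts <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
    if (!length(counts)) # all pathways blocked by stops: fall back
      counts <- lapply(perms, walk, allow_stop = TRUE)
    m <- Reduce(`+`, counts) / length(counts)
    out <- c(nd = m[1], sd = m[2])
  }
  ng86_cache[[key]] <- out
  out
}

#' Pairwise dN/dS (NG86 with Jukes-Cantor correction)
#'
#' Codons containing gaps or ambiguity codes in either sequence are dropped
#' pairwise; internal stop codons among the remaining codons are an error.
#' Sites are averaged over the two sequences; proportions are corrected with
#' `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param seq1,seq2 aligned coding sequences (equal length, multiple of 3).
#' @param code genetic code table.
#' @param min_codons minimum countable codons required (default 10).
#' @return list with N, S, Nd, Sd, pN, pS, dN, dS, omega, n_codons and
#'   `status` (`"ok"`, `"dS_zero"` or `"saturated"`).
#' @export
pairwise_dnds <- function(seq1, seq2, code = standard_code(),
                          min_codons = 10L) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("aligned sequences differ in length")
  if (nchar(seq1) %% 3L != 0L) stop("alignment length not a multiple of 3")
  starts <- seq(1L, nchar(seq1), by = 3L)
  c1 <- substring(seq1, starts, starts + 2L)
  c2 <- substring(seq2, starts, starts + 2L)
  keep <- is_clean_codon(c1) & is_clean_codon(c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (any(code[c1] == "*") || any(code[c2] == "*"))
    stop("internal stop codon in countable codons")
  if (length(c1) < min_codons)
    stop("fewer than ", min_codons, " countable codons")
  tab <- site_count_table(code)
  sites1 <- t(tab[c1, , drop = FALSE])
  sites2 <- t(tab[c2, , drop = FALSE])
  N <- (sum(sites1[1, ]) + sum(sites2[1, ])) / 2
  S <- (sum(sites1[2, ]) + sum(sites2[2, ])) / 2
  diffs <- mapply(function(a, b) codon_diff_counts(a, b, code), c1, c2)
  Nd <- sum(diffs[1, ]); Sd <- sum(diffs[2, ])
  pN <- Nd / N; pS <- Sd / S
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  dN <- jc(pN); dS <- jc(pS)
  status <- if (is.na(dN) || is.na(dS)) "saturated"
            else if (dS == 0) "dS_zero" else "ok"
  omega <- if (status == "ok") dN / dS else NA_real_
  list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
       dN = dN, dS = dS, omega = omega, n_codons = length(c1),
       status = status, method = "NG86+JC")
}

#' Community-level dN/dS summary
#'
#' @param results data.frame (or list of [pairwise_dnds()] results) with
#'   columns `omega` and `status`.
#' @param center `"median"` (default) or `"mean"`.
#' @return list: omega (central value over `status == "ok"` pairs), iqr,
#'   fraction_purifying (omega < 1), n_ok, n_excluded.
#' @export
community_dnds <- function(results, center = c("median", "mean")) {
  center <- match.arg(center)
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(omega = r$omega, status = r$status)))
  ok <- results$status == "ok"
  if (!any(ok)) stop("no pair with status 'ok'")
  om <- results$omega[ok]
  list(omega = if (center == "median") stats::median(om) else mean(om),
       iqr = unname(diff(stats::quantile(om, c(0.25, 0.75)))),
       fraction_purifying = mean(om < 1),
       n_ok = sum(ok), n_excluded = sum(!ok))
}

#' Read consecutive-record codon alignment pairs from FASTA
#'
#' Records are paired in file order (1st with 2nd, 3rd with 4th, ...).
#'
#' @param path FASTA file with an even number of aligned records.
#' @return list of character vectors `c(seq1, seq2)`, named by the first
#'   record of each pair.
#' @export
read_codon_pairs <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) %% 2L != 0L) stop("odd number of FASTA records; expected pairs")
  seqs <- as.character(ss)
  idx <- seq(1L, length(seqs), by = 2L)
  out <- lapply(idx, function(i) c(seqs[[i]], seqs[[i + 1L]]))
  names(out) <- names(ss)[idx]
  out
}

#' dN/dS over all ortholog pairs of one sample
#'
#' @param pairs list from [read_codon_pairs()].
#' @param ... passed to [pairwise_dnds()].
#' @return data.frame with one row per pair plus the pair id.
#' @export
sample_dnds <- function(pairs, ...) {
  rows <- lapply(seq_along(pairs), function(i) {
    r <- pairwise_dnds(pairs[[i]][1L], pairs[[i]][2L], ...)
    data.frame(pair_id = names(pairs)[i] %||% paste0("pair", i),
               N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
               dN = r$dN, dS = r$dS, omega = r$omega,
               n_codons = r$n_codons, status = r$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
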