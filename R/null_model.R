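## Composition-matched resampling null.  All marker records of a habitat are
## pooled; artificial communities are re-drawn from the pool stratified by
## phylum to match each sample's own phylogenetic composition, at the size of
## the smallest sample in the habitat (n_min).  The observed marker-rER
## distribution of a sample is then compared to the pooled simulated draws
## with a two-sided two-sample Kolmogorov-Smirnov test: a significant
## deviation means the sample's rERs are not explained by its composition.

#' Pool the marker records of a habitat
#'
#' @param records data.frame with columns `sample_id`, `phylum`, `rer`
#'   covering all samples of one habitat.
#' @param habitat habitat label stored on the pool.
#' @return a `habitat_pool`: list(habitat, records, n_min, samples).
#' @export
pool_habitat_markers <- function(records, habitat = NA_character_) {
  sizes <- table(records$sample_id)
  if (length(sizes) < 2L)
    stop("composition-matched null needs >= 2 samples in the habitat")
  structure(list(habitat = habitat, records = records,
                 n_min = as.integer(min(sizes)),
                 samples = names(sizes)),
            class = "habitat_pool")
}

## Largest-remainder allocation of n draws across phylum strata.
## Deterministic: remainder ties broken by phylum name.
stratum_allocation <- function(composition, n) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition proportions must sum to 1")
  composition <- composition[order(names(composition))]
  raw <- n * composition
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    give <- order(-frac, names(composition))[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  stats::setNames(as.integer(base), names(composition))
}

#' Simulate one composition-matched community from a habitat pool
#'
#' Draws `n` marker records stratified by phylum (largest-remainder
#' allocation of `n * proportion`), without replacement within each stratum
#' (with replacement when a stratum is exhausted, which is recorded).
#'
#' @param pool a `habitat_pool`.
#' @param composition named phylum proportions summing to 1.
#' @param n number of records to draw.
#' @param seed integer seed.
#' @return list with `rer` (median of the draw), `draws` (the drawn rER
#'   values) and `replaced` (phyla where sampling fell back to replacement).
#' @export
simulate_community <- function(pool, composition, n, seed) {
  miss <- setdiff(names(composition)[composition > 0],
                  unique(pool$records$phylum))
  if (length(miss))
    stop("phylum absent from habitat pool: ", paste(miss, collapse = ", "))
  alloc <- stratum_allocation(composition, n)
  alloc <- alloc[alloc > 0]
  set.seed(seed)
  strata <- split(pool$records$rer, pool$records$phylum)
  replaced <- character(0)
  draws <- lapply(names(alloc), function(ph) {
    vals <- strata[[ph]]
    k <- alloc[[ph]]
    if (k <= length(vals)) {
      vals[sample.int(length(vals), k)]
    } else {
      replaced <<- c(replaced, ph)
      vals[sample.int(length(vals), k, replace = TRUE)]
    }
  })
  draws <- unlist(draws, use.names = FALSE)
  list(rer = stats::median(draws), draws = draws, replaced = replaced)
}

#' Replicate composition-matched simulations
#'
#' @inheritParams simulate_community
#' @param B number of replicates (>= 1; >= 100 for inference).
#' @param seed master seed; replicate b uses `derive_seed(seed, b)`.
#' @return list with `medians` (length B) and `draws` (all simulated marker
#'   rERs, length B * n).
#' @export
expected_rer_distribution <- function(pool, composition, n, B, seed) {
  if (B < 1L) stop("B must be >= 1")
  meds <- numeric(B)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    sim <- simulate_community(pool, composition, n, derive_seed(seed, b))
    meds[b] <- sim$rer
    draws[[b]] <- sim$draws
  }
  list(medians = meds, draws = unlist(draws, use.names = FALSE))
}

#' Kolmogorov-Smirnov deviation test for one sample
#'
#' Two-sided two-sample KS test of the observed marker rERs against the
#' simulated (composition-matched) rERs.
#'
#' @param observed the sample's marker rER values.
#' @param expected simulated rER values (pooled over replicates).
#' @param expected_medians optional vector of per-replicate simulated
#'   community rERs, used for the signed deviation.
#' @return list: `D`, `p`, `observed_rer`, `deviation` (observed community
#'   rER minus median expected community rER, `NA` without
#'   `expected_medians`), `low_confidence` flag for n < 3.
#' @export
ks_deviation_test <- function(observed, expected, expected_medians = NULL) {
  if (length(observed) == 0L || length(expected) == 0L)
    stop("both observed and expected must be non-empty")
  low <- length(observed) < 3L || length(expected) < 3L
  if (low) warning("fewer than 3 values on one side; p is low-confidence")
  kt <- suppressWarnings(stats::ks.test(observed, expected))
  obs_rer <- stats::median(observed)
  dev <- if (is.null(expected_medians)) NA_real_
         else obs_rer - stats::median(expected_medians)
  list(D = unname(kt$statistic), p = kt$p.value,
       observed_rer = obs_rer, deviation = dev, low_confidence = low)
}

#' Run the deviation test across a study
#'
#' For each habitat with >= 2 samples: pool the marker records, and for each
#' member sample simulate B composition-matched communities of size n_min
#' (matching that sample's phylum composition), then KS-test the sample's
#' observed marker rERs against the pooled simulated values.
#' Benjamini-Hochberg adjustment is applied across all tested samples.
#'
#' @param records per-query rER table covering the study: columns
#'   `sample_id`, `habitat`, `phylum`, `rer`.
#' @param B simulation replicates per sample (default 1000).
#' @param seed master seed; sample i uses `derive_seed(seed, i)`.
#' @param alpha significance level applied to the adjusted p (default 0.05).
#' @return data.frame: sample_id, habitat, n_markers, observed_rer,
#'   expected_rer, deviation, D, p, p_adj, significant.
#' @export
deviation_test_study <- function(records, B = 1000L, seed = 1L, alpha = 0.05) {
  need <- c("sample_id", "habitat", "phylum", "rer")
  if (!all(need %in% colnames(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  rows <- list()
  i <- 0L
  for (hab in sort(unique(records$habitat))) {
    hrec <- records[records$habitat == hab, , drop = FALSE]
    if (length(unique(hrec$sample_id)) < 2L) {
      warning("habitat '", hab, "' has a single sample; deviation test skipped")
      next
    }
    pool <- pool_habitat_markers(hrec, habitat = hab)
    for (sid in sort(unique(hrec$sample_id))) {
      i <- i + 1L
      srec <- hrec[hrec$sample_id == sid, , drop = FALSE]
      comp <- table(srec$phylum) / nrow(srec)
      comp <- stats::setNames(as.numeric(comp), names(comp))
      sim <- expected_rer_distribution(pool, comp, pool$n_min, B,
                                       derive_seed(seed, i))
      kt <- ks_deviation_test(srec$rer, sim$draws, sim$medians)
      rows[[i]] <- data.frame(sample_id = sid, habitat = hab,
                              n_markers = nrow(srec),
                              observed_rer = kt$observed_rer,
                              expected_rer = stats::median(sim$medians),
                              deviation = kt$deviation,
                              D = kt$D, p = kt$p,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no habitat with >= 2 samples; null model undefined")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
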