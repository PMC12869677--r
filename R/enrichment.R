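#' Enrichment-walk score of a reference set in a ranking
#'
#' An unweighted GSEA-style running-sum statistic: walking down the ranking
#' (gene sets ordered from most to least significant), the sum increases by
#' 1/|reference| at each reference ("hit") set and decreases by
#' 1/(N - |reference|) at each other set. The score is the maximum positive
#' deviation of the walk, floored at 0, and lies in \[0, 1\]; a reference
#' occupying the top of the ranking scores 1.
#'
#' @param ranking Character vector of gene-set ids ordered by p-value from
#'   most to least prioritized.
#' @param reference Character vector of reference set ids, a non-empty
#'   proper subset of `ranking`.
#' @return A single number in \[0, 1\].
#' @export
enrichment_walk <- function(ranking, reference) {
  n <- length(ranking)
  k <- length(unique(reference))
  if (k == 0 || k >= n) {
    abort("reference must be a non-empty proper subset of the ranking",
          class = "bottomline_usage_error")
  }
  if (!all(reference %in% ranking)) {
    abort("all reference ids must appear in the ranking",
          class = "bottomline_usage_error")
  }
  hit <- ranking %in% reference
  steps <- ifelse(hit, 1 / k, -1 / (n - k))
  max(0, max(cumsum(steps)))
}

#' Permutation test for the enrichment-walk score
#'
#' Draws `B` random reference sets of the observed size uniformly without
#' replacement from the ranking and recomputes the walk score for each; the
#' permutation p-value uses the plus-one estimator
#' p = (1 + #\{permuted >= observed\}) / (1 + B), bounded in
#' \[1/(B+1), 1\].
#'
#' @inheritParams enrichment_walk
#' @param B Number of permutations (>= 1), default 1000.
#' @param seed Integer seed for the permutation draws.
#' @return A tibble with `score`, `p.value`, `B`; the permuted scores are
#'   attached as attribute `null_scores`.
#' @export
permutation_enrichment <- function(ranking, reference, B = 1000, seed = 1) {
  if (B < 1) {
    abort("B must be at least 1", class = "bottomline_usage_error")
  }
  obs <- enrichment_walk(ranking, reference)
  k <- length(unique(reference))
  null_scores <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      enrichment_walk(ranking, sample(ranking, k))
    }, numeric(1))
  })
  p <- (1 + sum(null_scores >= obs)) / (1 + B)
  out <- tibble::tibble(score = obs, p.value = p, B = as.integer(B))
  attr(out, "null_scores") <- null_scores
  out
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
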