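#' Assign lead variants to contiguous association regions
#'
#' Pools the lead SNPs of two GWAS, sorts them by chromosome and position,
#' and walks the sorted list: the first lead's position starts the first
#' region; each subsequent lead joins the current region if it is on the
#' same chromosome and less than 1 Mb from the region's start, otherwise it
#' starts a new region at its own position. A region is "shared" when it
#' contains at least one lead from each source.
#'
#' @param leads A tibble with columns `chrom`, `pos`, `label` (source
#'   GWAS label); extra columns are carried along.
#' @param max_span Region extent in bp from the start position (default 1e6;
#'   a lead joins iff pos - start < `max_span`).
#' @return A tibble of regions: `region_id`, `chrom`, `start`, `n_leads`,
#'   `shared`, `leads` (list column of the member lead rows).
#' @export
assign_regions <- function(leads, max_span = 1e6) {
  if (nrow(leads) == 0) {
    return(tibble::tibble(region_id = integer(), chrom = character(),
                          start = integer(), n_leads = integer(),
                          shared = logical(), leads = list()))
  }
  stopifnot(all(c("chrom", "pos", "label") %in% names(leads)))
  leads <- leads[order(leads$chrom, leads$pos), , drop = FALSE]
  region <- integer(nrow(leads))
  start <- leads$pos[1]
  chrom <- leads$chrom[1]
  rid <- 1L
  region[1] <- rid
  for (i in seq_len(nrow(leads))[-1]) {
    if (leads$chrom[i] == chrom && leads$pos[i] - start < max_span) {
      region[i] <- rid
    } else {
      rid <- rid + 1L
      start <- leads$pos[i]
      chrom <- leads$chrom[i]
      region[i] <- rid
    }
  }
  grp <- split(seq_len(nrow(leads)), region)
  dplyr::bind_rows(purrr::imap(grp, function(rows, id) {
    sub <- leads[rows, , drop = FALSE]
    tibble::tibble(region_id = as.integer(id), chrom = sub$chrom[1],
                   start = sub$pos[1], n_leads = nrow(sub),
                   shared = length(unique(sub$label)) > 1,
                   leads = list(sub))
  }))
}

#' Construct a credible set
#'
#' A credible set is a lead variant plus per-variant posterior inclusion
#' probabilities (PIPs) summing to at least 0.99.
#'
#' @param set_id Identifier.
#' @param source Source GWAS label.
#' @param lead Lead variant id (must be among the PIP'd variants).
#' @param pips Named numeric vector: variant id -> PIP in \[0, 1\].
#' @return A list of class `credible_set`.
#' @export
credible_set <- function(set_id, source, lead, pips) {
  stopifnot(is.numeric(pips), !is.null(names(pips)),
            all(pips >= 0), all(pips <= 1))
  if (!lead %in% names(pips)) {
    abort("credible set lead must be among its variants",
          class = "bottomline_usage_error")
  }
  if (sum(pips) < 0.99 - 1e-9) {
    abort(sprintf("credible set PIP sum %.4f < 0.99", sum(pips)),
          class = "bottomline_usage_error")
  }
  structure(list(set_id = set_id, source = source, lead = lead, pips = pips),
            class = "credible_set")
}

#' Match credible sets between two GWAS by shared PIP sum
#'
#' For every cross pair of credible sets (one from each GWAS, within one
#' shared region), the shared variants are the intersection of the two
#' variant sets; each side's PIPs are summed over the shared variants and
#' the smaller sum is the "shared PIP sum". Pairs classify as a complete
#' match (sum > 0.6), partial match (0 < sum <= 0.6) or non-match (sum = 0).
#'
#' @param a,b Lists of [credible_set] objects from the two GWAS.
#' @return A tibble with one row per cross pair: `set_a`, `set_b`,
#'   `shared_pip_sum`, `class`; a per-region summary (any complete / any
#'   partial) is attached as attribute `summary`.
#' @export
match_credible_sets <- function(a, b) {
  if (inherits(a, "credible_set")) a <- list(a)
  if (inherits(b, "credible_set")) b <- list(b)
  rows <- purrr::map(a, function(ca) {
    purrr::map(b, function(cb) {
      shared <- intersect(names(ca$pips), names(cb$pips))
      s <- min(sum(ca$pips[shared]), sum(cb$pips[shared]))
      tibble::tibble(set_a = ca$set_id, set_b = cb$set_id,
                     shared_pip_sum = s,
                     class = if (s > 0.6) "complete"
                             else if (s > 0) "partial" else "non_match")
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "summary") <- tibble::tibble(
    any_complete = any(out$class == "complete"),
    any_partial = any(out$class == "partial"))
  out
}

#' Read credible sets from a tab-separated file
#'
#' Expected columns: `source`, `set_id`, `lead_id`, `variant_id`, `pip`.
#' @param path File path.
#' @return A list of [credible_set] objects.
#' @export
read_credible_sets <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  purrr::map(split(df, df$set_id), function(g) {
    credible_set(g$set_id[1], g$source[1], g$lead_id[1],
                 setNames(g$pip, g$variant_id))
  })
}

#' Benjamini-Hochberg false-discovery-rate q-values
#'
#' Step-up BH q-values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1] with no missing values",
          class = "bottomline_usage_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Paired concordance between two result vectors
#'
#' Pearson or Spearman correlation with a two-sided asymptotic p-value, as
#' used to compare downstream estimates (heritabilities, genetic
#' correlations, enrichment betas, gene associations) produced from two
#' GWAS of the same trait.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble with `estimate`, `p.value`, `method`, `n`.
#' @export
paired_concordance <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must have equal length >= 2",
          class = "bottomline_usage_error")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 method = method, n = length(x))
}

#' Through-origin regression slope and downward bias
#'
#' Regresses y on x with a fixed zero intercept: slope = sum(x y) /
#' sum(x^2). The reported bias 1 - slope quantifies the systematic downward
#' shift of one GWAS's estimates relative to the other's (e.g. heritability
#' attenuation under standard-error inflation).
#'
#' @param x,y Numeric vectors of equal length >= 1; x not all zero.
#' @return A tibble with `slope` and `bias` (= 1 - slope).
#' @export
through_origin_slope <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) {
    abort("x and y must have equal length >= 1",
          class = "bottomline_usage_error")
  }
  if (all(x == 0)) {
    abort("x must not be all zero", class = "bottomline_usage_error")
  }
  slope <- sum(x * y) / sum(x^2)
  tibble::tibble(slope = slope, bias = 1 - slope)
}

#' Quality filter for enrichment-beta comparisons
#'
#' Drops annotations whose absolute enrichment beta exceeds `limit`
#' (default 100) in either GWAS before concordance analysis.
#'
#' @param df A data frame with two enrichment-beta columns.
#' @param cols Names of the two beta columns.
#' @param limit Absolute-value cutoff.
#' @return The filtered data frame.
#' @export
filter_enrichment_betas <- function(df, cols, limit = 100) {
  keep <- rowSums(abs(as.matrix(df[, cols])) > limit) == 0
  df[keep, , drop = FALSE]
}
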