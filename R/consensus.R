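#' Consensus by most significant estimate in any study ("any GWAS")
#'
#' For each variant, returns the full record from the study in which it is
#' most significant. Exact p ties are broken toward the study with the
#' larger per-variant sample size, then the lexicographically smaller
#' study id.
#'
#' @param studies List of [sumstats] objects, harmonized.
#' @return A [sumstats]-like tibble with an extra `source_study` column.
#' @export
consensus_any_gwas <- function(studies) {
  stopifnot(length(studies) >= 1)
  ids <- vapply(studies, function(s) attr(s, "study_id"), character(1))
  long <- dplyr::bind_rows(purrr::map2(studies, ids, function(s, id) {
    dplyr::mutate(tibble::as_tibble(as.data.frame(s)), source_study = id)
  }))
  long <- long[order(paste(long$chrom, long$pos, long$ref, long$alt, sep = ":"),
                     long$log10p, -ifelse(is.na(long$n), 0, long$n),
                     long$source_study), , drop = FALSE]
  best <- long[!duplicated(paste(long$chrom, long$pos, long$ref, long$alt,
                                 sep = ":")), , drop = FALSE]
  best <- best[order(best$chrom, best$pos, best$ref, best$alt), , drop = FALSE]
  m <- ss_meta(studies[[1]])
  out <- sumstats(best[, c(sumstats_cols, "source_study")],
                  study_id = "any_gwas", trait = m$trait,
                  ancestry = m$ancestry,
                  n_total = max(vapply(studies, function(s)
                    attr(s, "n_total") %||% NA_real_, numeric(1)), na.rm = TRUE))
  out$source_study <- best$source_study
  out
}

#' Consensus by the largest study ("largest GWAS")
#'
#' Returns verbatim the summary statistics of the study with the largest
#' declared total sample size (ties to the lexicographically smallest
#' study id).
#'
#' @inheritParams consensus_any_gwas
#' @return The selected [sumstats] object.
#' @export
consensus_largest <- function(studies) {
  stopifnot(length(studies) >= 1)
  studies[[largest_study_index(studies)]]
}

largest_study_index <- function(studies) {
  ns <- vapply(studies, function(s) attr(s, "n_total") %||% NA_real_,
               numeric(1))
  ids <- vapply(studies, function(s) attr(s, "study_id"), character(1))
  order(-ns, ids)[1]
}

#' Replication metrics of candidate signals against gold-standard signals
#'
#' A candidate signal is a true positive if its variant set intersects the
#' variant set of any gold-standard signal (the conservative same-signal
#' rule); otherwise it is a false positive. The replication rate is
#' TP / total, undefined (NA) at zero signals.
#'
#' @param signals,gold Signal tibbles (from [merge_by_shared_variants()]) or
#'   clump tibbles (a `members` list column); each row one signal.
#' @return A tibble with `total`, `tp`, `fp`, `rate`.
#' @export
replication_metrics <- function(signals, gold) {
  var_col <- function(x) if ("variants" %in% names(x)) x$variants else x$members
  gold_universe <- unique(unlist(var_col(gold)))
  sets <- var_col(signals)
  total <- length(sets)
  tp <- if (total == 0) 0L else
    sum(vapply(sets, function(v) any(v %in% gold_universe), logical(1)))
  tibble::tibble(total = total, tp = as.integer(tp),
                 fp = as.integer(total - tp),
                 rate = if (total > 0) tp / total else NA_real_)
}

#' Leave-one-out replication validation of consensus approaches
#'
#' Removes the largest study and treats its association signals (enumerated
#' with [adaptive_clump()]) as the gold standard; each requested consensus
#' approach is then run on the remaining studies, its result clumped at the
#' genome-wide lead threshold, and scored with [replication_metrics()].
#' The analysis is restricted to common variants (MAF > `maf_threshold`)
#' and requires at least two remaining studies.
#'
#' @param studies List of >= 3 [sumstats] objects of one trait-ancestry
#'   context.
#' @param panel [ld_panel] for the ancestry.
#' @param approaches Subset of `"any"`, `"largest"`, `"meta_uncorrected"`,
#'   `"meta_corrected"`.
#' @param p1,p2,r2,kb Clumping parameters for the approach signal lists (no
#'   adaptive relaxation, so false-positive semantics stay fixed).
#' @param maf_threshold Common-variant restriction.
#' @param z_cutoff,min_null Overlap-estimation parameters for the corrected
#'   meta-analysis.
#' @param log10p_bins Optional numeric breaks on lead -log10 p for a
#'   borderline-significance breakdown.
#' @return A tibble with one row per approach: `approach`, `total`, `tp`,
#'   `fp`, `rate`, plus `gold_n_signals` and `p1_gold`; when `log10p_bins`
#'   is given, a `by_bin` list column stratifies counts by lead
#'   significance. If fewer than 3 studies are supplied the context is
#'   excluded: a zero-row tibble with attribute `status = "excluded"`.
#' @export
leave_one_out_validate <- function(studies, panel,
                                   approaches = c("any", "largest",
                                                  "meta_uncorrected",
                                                  "meta_corrected"),
                                   p1 = 5e-8, p2 = 5e-6, r2 = 0.01,
                                   kb = 5000, maf_threshold = 0.05,
                                   z_cutoff = 1.96, min_null = 200,
                                   log10p_bins = NULL) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  if (length(studies) < 3) {
    out <- tibble::tibble(approach = character(), total = integer(),
                          tp = integer(), fp = integer(), rate = double())
    attr(out, "status") <- "excluded"
    return(out)
  }
  common_only <- function(s) partition_by_maf(s, maf_threshold)$common
  studies <- purrr::map(studies, common_only)
  gi <- largest_study_index(studies)
  gold_study <- studies[[gi]]
  rest <- studies[-gi]
  ac <- adaptive_clump(gold_study, panel, p2 = p2, r2 = r2, kb = kb)
  gold_clumps <- ac$clumps

  run_approach <- function(a) {
    s <- switch(a,
      any = consensus_any_gwas(rest),
      largest = consensus_largest(rest),
      meta_uncorrected = meta_as_sumstats(
        meta_fixed_effects(rest, model = NULL),
        study_id = "meta_uncorrected",
        ancestry = attr(rest[[1]], "ancestry")),
      meta_corrected = {
        om <- estimate_overlap_matrix(rest, z_cutoff = z_cutoff,
                                      min_null = min_null)
        meta_as_sumstats(meta_fixed_effects(rest, model = om),
                         study_id = "meta_corrected",
                         ancestry = attr(rest[[1]], "ancestry"))
      })
    greedy_clump(s, panel, p1 = p1, p2 = p2, r2 = r2, kb = kb)
  }
  rows <- purrr::map(approaches, function(a) {
    cl <- run_approach(a)
    met <- replication_metrics(cl, gold_clumps)
    row <- dplyr::mutate(met, approach = a, .before = 1)
    if (!is.null(log10p_bins)) {
      bin <- cut(-cl$lead_log10p, breaks = log10p_bins,
                 include.lowest = TRUE)
      gold_universe <- unique(unlist(gold_clumps$members))
      is_tp <- vapply(cl$members, function(v) any(v %in% gold_universe),
                      logical(1))
      row$by_bin <- list(dplyr::count(
        tibble::tibble(bin = bin, replicated = is_tp), .data$bin,
        .data$replicated))
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out$gold_n_signals <- nrow(gold_clumps)
  out$p1_gold <- ac$p1_used
  attr(out, "status") <- "ok"
  attr(out, "gold_study") <- attr(gold_study, "study_id")
  out
}
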