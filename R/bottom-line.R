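#' Bottom-line consensus statistics for one ancestry
#'
#' Produces a single association estimate per variant from all studies of
#' one trait-ancestry pair. Variants are MAF-partitioned: common variants
#' (MAF > `maf_threshold`) present in two or more studies are combined with
#' the overlap-corrected fixed-effects meta-analysis; common variants in a
#' single study pass through; low-frequency/rare variants (and variants
#' lacking an allele frequency, routed conservatively down the same path)
#' take their record verbatim from the largest dataset containing them.
#' A variant appearing in both MAF categories across datasets resolves to
#' the largest dataset's record.
#'
#' @param studies List of QC'd, harmonized [sumstats] for one ancestry.
#' @param overlap_model Optional pre-estimated `overlap_model`; estimated
#'   from the studies when NULL and two or more studies are present.
#' @param maf_threshold MAF threshold for the common/rare split.
#' @param z_cutoff,min_null Passed to [estimate_overlap_matrix()].
#' @return A [sumstats]-like tibble with a `provenance` column in
#'   `overlap_meta`, `largest_rare`, `single_study`, exactly one record per
#'   variant. The overlap model used (if any) is attached as attribute
#'   `overlap_model`.
#' @export
bottom_line_single_ancestry <- function(studies, overlap_model = NULL,
                                        maf_threshold = 0.05,
                                        z_cutoff = 1.96, min_null = 200) {
  if (length(studies) == 0) {
    abort("bottom_line_single_ancestry: empty study list",
          class = "bottomline_usage_error")
  }
  ids <- vapply(studies, function(s) attr(s, "study_id"), character(1))
  ns <- vapply(studies, function(s) attr(s, "n_total") %||% NA_real_,
               numeric(1))
  anc <- attr(studies[[1]], "ancestry")
  trait <- attr(studies[[1]], "trait")

  # variant-level classification across datasets
  long <- dplyr::bind_rows(purrr::map2(studies, seq_along(studies),
    function(s, i) {
      maf <- pmin(s$eaf, 1 - s$eaf)
      tibble::tibble(key = variant_key(s), study = i,
                     category = dplyr::if_else(
                       !is.na(maf) & maf > maf_threshold, "common", "rare"))
    }))
  cls <- long |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_common = sum(.data$category == "common"),
                     n_rare = sum(.data$category == "rare"),
                     k = dplyr::n(), .groups = "drop")
  meta_keys <- cls$key[cls$n_rare == 0 & cls$k >= 2]
  single_keys <- cls$key[cls$n_rare == 0 & cls$k == 1]
  largest_keys <- cls$key[cls$n_rare > 0]

  pieces <- list()
  if (length(meta_keys) > 0) {
    if (is.null(overlap_model) && length(studies) >= 2) {
      overlap_model <- estimate_overlap_matrix(studies, z_cutoff = z_cutoff,
                                               min_null = min_null)
    }
    sub <- purrr::map(studies, function(s) {
      ss_rewrap(s[variant_key(s) %in% meta_keys, , drop = FALSE], s)
    })
    sub <- sub[vapply(sub, nrow, integer(1)) > 0]
    met <- meta_fixed_effects(sub, model = overlap_model)
    pieces$meta <- tibble::tibble(
      chrom = met$chrom, pos = met$pos, ref = met$ref, alt = met$alt,
      eaf = met$eaf, beta = met$beta, se = met$se, p = met$p,
      log10p = met$log10p, n = met$n_eff, provenance = "overlap_meta")
  }
  take_from <- function(keys, provenance) {
    if (length(keys) == 0) return(NULL)
    # largest dataset containing each variant wins
    stacked <- dplyr::bind_rows(purrr::map2(studies, seq_along(studies),
      function(s, i) {
        hit <- variant_key(s) %in% keys
        out <- tibble::as_tibble(as.data.frame(s[hit, , drop = FALSE]))
        out$.n_total <- ns[i]
        out$.study_id <- ids[i]
        out
      }))
    stacked <- stacked[order(variant_key(stacked), -stacked$.n_total,
                             stacked$.study_id), , drop = FALSE]
    best <- stacked[!duplicated(variant_key(stacked)), , drop = FALSE]
    out <- best[, sumstats_cols]
    out$provenance <- provenance
    out
  }
  pieces$largest <- take_from(largest_keys, "largest_rare")
  pieces$single <- take_from(single_keys, "single_study")
  out <- dplyr::bind_rows(pieces)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  res <- sumstats(out, study_id = "bottom_line", trait = trait,
                  ancestry = anc,
                  n_total = suppressWarnings(max(ns, na.rm = TRUE)))
  attr(res, "overlap_model") <- overlap_model
  res
}

#' Bottom-line trans-ancestry statistics
#'
#' Fixed-effects meta-analysis across per-ancestry bottom-line statistics
#' (ancestries assumed sample-disjoint, no overlap correction). When a
#' published trans-ancestry study also carries a variant, the record with
#' the larger per-variant sample size wins (meta effective N versus the
#' published study's N). With no single-ancestry data at all, the published
#' trans-ancestry statistics are returned verbatim.
#'
#' @param per_ancestry List of per-ancestry [sumstats] (e.g. outputs of
#'   [bottom_line_single_ancestry()]), at most one per ancestry.
#' @param published_trans Optional published trans-ancestry [sumstats].
#' @return A [sumstats]-like tibble (ancestry "TA") with a `provenance`
#'   column in `trans_meta`, `published_trans`.
#' @export
bottom_line_trans <- function(per_ancestry, published_trans = NULL) {
  if (length(per_ancestry) == 0 && is.null(published_trans)) {
    abort("bottom_line_trans: no per-ancestry and no published trans-ancestry input",
          class = "bottomline_usage_error")
  }
  trait <- if (length(per_ancestry) > 0) attr(per_ancestry[[1]], "trait")
           else attr(published_trans, "trait")
  if (length(per_ancestry) == 0) {
    out <- tibble::as_tibble(as.data.frame(published_trans))[, sumstats_cols]
    out$provenance <- "published_trans"
    return(sumstats(out, study_id = "bottom_line_trans", trait = trait,
                    ancestry = "TA",
                    n_total = attr(published_trans, "n_total")))
  }
  met <- meta_trans_ancestry(per_ancestry)
  meta_tbl <- tibble::tibble(
    chrom = met$chrom, pos = met$pos, ref = met$ref, alt = met$alt,
    eaf = met$eaf, beta = met$beta, se = met$se, p = met$p,
    log10p = met$log10p, n = met$n_eff, provenance = "trans_meta")
  if (!is.null(published_trans)) {
    pub <- tibble::as_tibble(as.data.frame(published_trans))[, sumstats_cols]
    pub$provenance <- "published_trans"
    both <- dplyr::bind_rows(meta_tbl, pub)
    both$.n_cmp <- ifelse(is.na(both$n), 0, both$n)
    key <- paste(both$chrom, both$pos, both$ref, both$alt, sep = ":")
    # larger per-variant sample size wins; tie favors the meta-analysis
    ord <- order(key, -both$.n_cmp,
                 match(both$provenance, c("trans_meta", "published_trans")))
    both <- both[ord, , drop = FALSE]
    meta_tbl <- both[!duplicated(paste(both$chrom, both$pos, both$ref,
                                       both$alt, sep = ":")), , drop = FALSE]
    meta_tbl$.n_cmp <- NULL
  }
  meta_tbl <- meta_tbl[order(meta_tbl$chrom, meta_tbl$pos, meta_tbl$ref,
                             meta_tbl$alt), , drop = FALSE]
  n_tot <- suppressWarnings(max(meta_tbl$n, na.rm = TRUE))
  sumstats(meta_tbl, study_id = "bottom_line_trans", trait = trait,
           ancestry = "TA", n_total = n_tot)
}

#' Run the full bottom-line procedure for one trait
#'
#' Orchestrates, per trait: per-ancestry overlap-aware combination
#' ([bottom_line_single_ancestry()]), the trans-ancestry combination
#' ([bottom_line_trans()]), per-ancestry signal enumeration
#' ([adaptive_clump()] followed by [append_singletons()]), and the
#' trans-ancestry signal merge ([merge_by_shared_variants()] across the
#' per-ancestry clump lists).
#'
#' @param bundle A list describing one trait: `trait` (id), `ancestries`
#'   (named list; each element a list with `studies` — a list of [sumstats]
#'   — and `panel`, an [ld_panel]), and optionally `published_trans`
#'   (a [sumstats] with ancestry "TA").
#' @param clump Clumping parameters: list with `p1`, `p2`, `r2`, `kb`,
#'   `min_clumps`.
#' @param maf_threshold,z_cutoff,min_null As in
#'   [bottom_line_single_ancestry()].
#' @return An object of class `bottom_line_result`: `trait`, `per_ancestry`
#'   (named list of provenance-tagged [sumstats]), `trans`, `clumps` (named
#'   list of per-ancestry clump tibbles), `p1_used` (named numeric),
#'   `trans_signals` (merged signal tibble), `overlap_models`.
#' @export
run_bottom_line <- function(bundle,
                            clump = list(p1 = 5e-8, p2 = 5e-6, r2 = 0.01,
                                         kb = 5000, min_clumps = 50),
                            maf_threshold = 0.05, z_cutoff = 1.96,
                            min_null = 200) {
  trait <- bundle$trait %||% "trait"
  n_studies <- sum(vapply(bundle$ancestries, function(a)
    length(a$studies), integer(1)))
  if ((is.null(bundle$ancestries) || n_studies == 0) &&
      is.null(bundle$published_trans)) {
    abort(sprintf("trait '%s': no studies in bundle", trait),
          class = "bottomline_usage_error")
  }
  per_anc <- list()
  clumps <- list()
  p1_used <- numeric(0)
  models <- list()
  for (anc in names(bundle$ancestries)) {
    entry <- bundle$ancestries[[anc]]
    if (length(entry$studies) == 0) next
    bl <- withCallingHandlers(
      bottom_line_single_ancestry(entry$studies,
                                  maf_threshold = maf_threshold,
                                  z_cutoff = z_cutoff, min_null = min_null),
      error = function(e) {
        abort(sprintf("stage bottom_line_single_ancestry[%s]: %s", anc,
                      conditionMessage(e)), parent = e)
      })
    per_anc[[anc]] <- bl
    models[[anc]] <- attr(bl, "overlap_model")
    ac <- adaptive_clump(bl, entry$panel,
                         min_clumps = clump$min_clumps %||% 50,
                         p1_start = clump$p1 %||% 5e-8,
                         p2 = clump$p2 %||% 5e-6, r2 = clump$r2 %||% 0.01,
                         kb = clump$kb %||% 5000)
    cl <- append_singletons(ac$clumps, bl, entry$panel,
                            p1_used = ac$p1_used)
    clumps[[anc]] <- cl
    p1_used[[anc]] <- ac$p1_used
  }
  trans <- bottom_line_trans(unname(per_anc), bundle$published_trans)
  trans_signals <- merge_by_shared_variants(clumps)
  structure(list(trait = trait, per_ancestry = per_anc, trans = trans,
                 clumps = clumps, p1_used = p1_used,
                 trans_signals = trans_signals, overlap_models = models),
            class = "bottom_line_result")
}

#' @export
print.bottom_line_result <- function(x, ...) {
  cat(sprintf("# bottom_line_result: trait '%s'\n", x$trait))
  for (anc in names(x$per_ancestry)) {
    cat(sprintf("  %s: %d variants, %d clumps (p1 = %g)\n", anc,
                nrow(x$per_ancestry[[anc]]), nrow(x$clumps[[anc]]),
                x$p1_used[[anc]]))
  }
  cat(sprintf("  trans: %d variants, %d merged signals\n",
              nrow(x$trans), nrow(x$trans_signals)))
  invisible(x)
}

#' @export
tidy.bottom_line_result <- function(x, ...) {
  rows <- purrr::imap(x$per_ancestry, function(s, anc) {
    dplyr::mutate(tibble::as_tibble(as.data.frame(s)), ancestry = anc)
  })
  rows$TA <- dplyr::mutate(tibble::as_tibble(as.data.frame(x$trans)),
                           ancestry = "TA")
  dplyr::bind_rows(rows)
}

#' @export
glance.bottom_line_result <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    n_ancestries = length(x$per_ancestry),
    n_variants_trans = nrow(x$trans),
    n_signals_trans = nrow(x$trans_signals),
    n_clumps = sum(vapply(x$clumps, nrow, integer(1))))
}
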