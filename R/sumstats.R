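#' The fixed ancestry label set
#'
#' Curated GWAS datasets are assigned one of nine fixed ancestry labels
#' commonly represented in the field, including trans-ancestry ("TA") for
#' multi-ancestry studies.
#'
#' @return A tibble with columns `label` (short code used throughout the
#'   package) and `name` (long form).
#' @export
#' @examples
#' ancestry_labels()
ancestry_labels <- function() {
  tibble::tribble(
    ~label, ~name,
    "AA",   "African American or Afro-Caribbean",
    "AFR",  "African unspecified",
    "SSAF", "Sub-Saharan African",
    "EU",   "European",
    "EA",   "East Asian",
    "SA",   "South Asian",
    "HIS",  "Hispanic or Latin American",
    "GME",  "Greater Middle Eastern",
    "TA",   "Trans-ancestry"
  )
}

sumstats_cols <- c("chrom", "pos", "ref", "alt", "eaf", "beta", "se",
                   "p", "log10p", "n")

#' Construct a summary-statistics table
#'
#' A `sumstats` object is a tibble of per-variant association records for one
#' study of one trait in one ancestry, carrying the study metadata as
#' attributes. Variants are keyed by (chrom, pos, ref, alt) with `ref` the
#' non-effect allele and `alt` the effect allele; positions are 1-based
#' (GRCh37 assumed). P-values are carried alongside `log10p` (log10 of the
#' p-value, a non-positive number) so that extreme significance levels
#' survive double-precision underflow.
#'
#' @param records A data frame with columns chrom, pos, ref, alt, eaf, beta,
#'   se, p, n (and optionally log10p). Missing columns among eaf/log10p are
#'   filled; `log10p` is computed from `p` where absent.
#' @param study_id,trait Identifiers.
#' @param ancestry One of the labels in [ancestry_labels()].
#' @param n_total Declared total sample size of the study.
#' @return A tibble of class `sumstats`.
#' @export
sumstats <- function(records, study_id, trait = "trait", ancestry = "EU",
                     n_total = NULL) {
  records <- tibble::as_tibble(records)
  for (col in c("eaf", "log10p")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  missing_cols <- setdiff(sumstats_cols, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("sumstats records missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "bottomline_format_error")
  }
  records <- records[, union(sumstats_cols, names(records))]
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  fill <- is.na(records$log10p) & !is.na(records$p) & records$p > 0
  records$log10p[fill] <- log10(records$p[fill])
  # p exactly 0 in input: remap to smallest representable positive double
  zero_p <- !is.na(records$p) & records$p == 0 & is.na(records$log10p)
  if (any(zero_p)) {
    records$p[zero_p] <- .Machine$double.xmin
    records$log10p[zero_p] <- log10(.Machine$double.xmin)
    warn(sprintf("%d p-value(s) of 0 remapped to %.3g",
                 sum(zero_p), .Machine$double.xmin))
  }
  if (is.null(n_total)) {
    n_total <- if (all(is.na(records$n))) NA_real_ else max(records$n, na.rm = TRUE)
  }
  valid <- ancestry_labels()$label
  if (!ancestry %in% valid) {
    abort(sprintf("ancestry '%s' is not one of: %s", ancestry,
                  paste(valid, collapse = ", ")),
          class = "bottomline_usage_error")
  }
  structure(records,
            class = c("sumstats", class(tibble::tibble())),
            study_id = study_id, trait = trait, ancestry = ancestry,
            n_total = n_total)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("# sumstats: study '%s', trait '%s', ancestry %s, n_total %s, %d variants\n",
              attr(x, "study_id"), attr(x, "trait"), attr(x, "ancestry"),
              format(attr(x, "n_total")), nrow(x)))
  NextMethod()
}

ss_meta <- function(s) {
  list(study_id = attr(s, "study_id"), trait = attr(s, "trait"),
       ancestry = attr(s, "ancestry"), n_total = attr(s, "n_total"))
}

# rebuild a sumstats from a plain tibble, carrying metadata from `like`
ss_rewrap <- function(records, like) {
  m <- ss_meta(like)
  sumstats(tibble::as_tibble(as.data.frame(records)), study_id = m$study_id,
           trait = m$trait, ancestry = m$ancestry, n_total = m$n_total)
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated (optionally gzip-compressed) file with a header row
#' into a [sumstats] object. Rows whose required fields fail to parse are
#' retained with `NA` in the offending field; removing them is the job of
#' [qc_filter()].
#'
#' @param path File path; `.gz` handled transparently.
#' @param column_map Optional named character vector mapping standard field
#'   names (`chrom`, `pos`, `ref`, `alt`, `eaf`, `beta`, `se`, `p`, `log10p`,
#'   `n`) to the column names used in the file.
#' @inheritParams sumstats
#' @return A [sumstats] tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, study_id = basename(path),
                          trait = "trait", ancestry = "EU", n_total = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    abort(sprintf("empty summary-statistics file: %s", path),
          class = "bottomline_format_error")
  }
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) {
        abort(sprintf("column_map names '%s' for field '%s' but the file has no such column",
                      src, std), class = "bottomline_format_error")
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  required <- c("chrom", "pos", "ref", "alt", "beta", "se", "p")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
          class = "bottomline_format_error")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- tibble::tibble(
    chrom = as.character(raw$chrom),
    pos = suppressWarnings(as.integer(raw$pos)),
    ref = toupper(as.character(raw$ref)),
    alt = toupper(as.character(raw$alt)),
    eaf = if ("eaf" %in% names(raw)) num(raw$eaf) else NA_real_,
    beta = num(raw$beta),
    se = num(raw$se),
    p = num(raw$p),
    log10p = if ("log10p" %in% names(raw)) num(raw$log10p) else NA_real_,
    n = if ("n" %in% names(raw)) num(raw$n) else NA_real_
  )
  # prefer the explicit log10p column only where p underflowed or is absent
  has_p <- !is.na(rec$p) & rec$p > 0
  rec$log10p[has_p] <- log10(rec$p[has_p])
  sumstats(rec, study_id = study_id, trait = trait, ancestry = ancestry,
           n_total = n_total)
}

format_p_from_log10 <- function(log10p) {
  out <- rep(NA_character_, length(log10p))
  ok <- !is.na(log10p)
  ex <- floor(log10p[ok])
  man <- 10^(log10p[ok] - ex)
  # fold mantissas that round to 10 back into the next exponent
  up <- man >= 10 - 1e-12
  man[up] <- man[up] / 10
  ex[up] <- ex[up] + 1
  out[ok] <- sprintf("%.12ge%d", man, ex)
  out
}

#' Write summary statistics to tab-separated text
#'
#' Round-trip stable with [read_sumstats()]: numeric fields are written with
#' 15 significant digits and the p column is emitted in scientific notation
#' reconstructed from `log10p`, so p-values far below double underflow
#' (e.g. log10p = -400) survive via the `log10p` column.
#'
#' @param s A [sumstats] object.
#' @param path Output path; a `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.15g", x))
  out <- tibble::tibble(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    eaf = fmt(s$eaf), beta = fmt(s$beta), se = fmt(s$se),
    p = ifelse(is.na(s$log10p), ifelse(is.na(s$p), "NA", fmt(s$p)),
               format_p_from_log10(s$log10p)),
    log10p = fmt(s$log10p), n = fmt(s$n)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Removes records unusable for downstream combination: missing or invalid
#' p-values, effect sizes or standard errors, allele frequencies outside
#' \[0, 1\], and all records at multiallelic sites (a chrom:pos carrying more
#' than one distinct allele pair). Within-study duplicate variants keep the
#' record with the smallest p-value.
#'
#' @param s A [sumstats] object.
#' @return A list with elements `sumstats` (the filtered object) and `report`
#'   (a tibble of removal counts by reason). The report also counts retained
#'   records lacking an allele frequency (`no_eaf`, not removed).
#' @export
qc_filter <- function(s) {
  reasons <- c("missing_p", "invalid_p", "missing_beta", "missing_se",
               "invalid_se", "invalid_af", "multiallelic", "duplicate")
  counts <- setNames(integer(length(reasons)), reasons)
  bad <- rep(FALSE, nrow(s))
  mark <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    new <- cond & !bad
    counts[reason] <<- counts[reason] + sum(new)
    bad <<- bad | new
  }
  mark(is.na(s$p) & is.na(s$log10p), "missing_p")
  mark(!is.na(s$p) & (s$p <= 0 | s$p > 1), "invalid_p")
  mark(is.na(s$beta), "missing_beta")
  mark(is.na(s$se), "missing_se")
  mark(!is.na(s$se) & s$se <= 0, "invalid_se")
  mark(!is.na(s$eaf) & (s$eaf < 0 | s$eaf > 1), "invalid_af")

  keep <- s[!bad, , drop = FALSE]
  # multiallelic: >1 distinct unordered allele pair at a chrom:pos
  pair <- ifelse(keep$ref < keep$alt, paste(keep$ref, keep$alt),
                 paste(keep$alt, keep$ref))
  site <- paste(keep$chrom, keep$pos)
  npair <- tapply(pair, site, function(x) length(unique(x)))
  multi <- site %in% names(npair)[npair > 1]
  counts["multiallelic"] <- sum(multi)
  keep <- keep[!multi, , drop = FALSE]
  # duplicate records of the same variant: retain smallest p
  key <- variant_key(keep)
  if (anyDuplicated(key)) {
    ord <- order(key, keep$log10p)
    keep <- keep[ord, , drop = FALSE]
    dup <- duplicated(variant_key(keep))
    counts["duplicate"] <- sum(dup)
    warn(sprintf("%d duplicate variant record(s) dropped (kept smallest p)",
                 counts[["duplicate"]]))
    keep <- keep[!dup, , drop = FALSE]
    keep <- keep[order(keep$chrom, keep$pos, keep$ref, keep$alt), , drop = FALSE]
  }
  report <- tibble::tibble(reason = names(counts), n = as.integer(counts))
  report <- dplyr::bind_rows(report,
    tibble::tibble(reason = "no_eaf", n = sum(is.na(keep$eaf))))
  list(sumstats = ss_rewrap(keep, s), report = report)
}

#' Harmonize allele orientation against a reference panel
#'
#' Aligns each record's (ref, alt) orientation with an LD reference panel.
#' Records already matching the panel are unchanged; records with swapped
#' alleles are flipped (alleles swapped, beta negated, eaf complemented);
#' records whose alleles match neither orientation are dropped with a
#' warning; records at positions absent from the panel pass through
#' unchanged. Strand-ambiguous (A/T, C/G) variants are harmonized by allele
#' identity only; set `drop_ambiguous = TRUE` to remove them instead.
#'
#' @param s A [sumstats] object.
#' @param panel An [ld_panel].
#' @param drop_ambiguous Drop A/T and C/G variants entirely.
#' @return A [sumstats] object; the number of irreconcilable dropped records
#'   is attached as attribute `n_dropped_alleles`.
#' @export
harmonize_alleles <- function(s, panel, drop_ambiguous = FALSE) {
  x <- tibble::as_tibble(as.data.frame(s))
  if (drop_ambiguous) {
    amb <- (x$ref == "A" & x$alt == "T") | (x$ref == "T" & x$alt == "A") |
           (x$ref == "C" & x$alt == "G") | (x$ref == "G" & x$alt == "C")
    x <- x[!amb, , drop = FALSE]
  }
  pv <- panel$variants
  m <- dplyr::left_join(x, pv[, c("chrom", "pos", "ref", "alt")] |>
                          dplyr::mutate(.panel_ref = .data$ref,
                                        .panel_alt = .data$alt) |>
                          dplyr::select(-"ref", -"alt"),
                        by = c("chrom", "pos"))
  in_panel <- !is.na(m$.panel_ref)
  same <- in_panel & m$ref == m$.panel_ref & m$alt == m$.panel_alt
  swapped <- in_panel & m$ref == m$.panel_alt & m$alt == m$.panel_ref
  irreconcilable <- in_panel & !same & !swapped
  if (any(swapped)) {
    tmp <- m$ref[swapped]
    m$ref[swapped] <- m$alt[swapped]
    m$alt[swapped] <- tmp
    m$beta[swapped] <- -m$beta[swapped]
    m$eaf[swapped] <- 1 - m$eaf[swapped]
  }
  n_drop <- sum(irreconcilable)
  if (n_drop > 0) {
    warn(sprintf("%d record(s) dropped: alleles irreconcilable with panel", n_drop))
  }
  m <- m[!irreconcilable, setdiff(names(m), c(".panel_ref", ".panel_alt")),
         drop = FALSE]
  out <- ss_rewrap(m, s)
  attr(out, "n_dropped_alleles") <- n_drop
  out
}

#' Partition summary statistics by minor allele frequency
#'
#' Computes `maf = min(eaf, 1 - eaf)` and splits records into common
#' (maf > threshold) and low-frequency/rare (maf <= threshold, boundary
#' inclusive on the rare side). Records lacking an allele frequency cannot be
#' classified and are returned in a third bucket; the bottom-line procedure
#' routes them down the (conservative) rare path.
#'
#' @param s A [sumstats] object.
#' @param threshold MAF threshold, default 0.05.
#' @return A list of [sumstats]: `common`, `rare`, `missing_af`.
#' @export
partition_by_maf <- function(s, threshold = 0.05) {
  maf <- pmin(s$eaf, 1 - s$eaf)
  common <- !is.na(maf) & maf > threshold
  rare <- !is.na(maf) & maf <= threshold
  list(common = ss_rewrap(s[common, , drop = FALSE], s),
       rare = ss_rewrap(s[rare, , drop = FALSE], s),
       missing_af = ss_rewrap(s[is.na(maf), , drop = FALSE], s))
}
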