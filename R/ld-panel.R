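#' Construct an ancestry-specific LD reference panel
#'
#' An `ld_panel` holds a variant map and a sparse table of pairwise squared
#' correlations (r2). Pairs absent from the table have r2 = 0; every variant
#' has r2 = 1 with itself. The panel defines the reference allele
#' orientation used by [harmonize_alleles()] and the LD neighbourhoods used
#' by [greedy_clump()].
#'
#' @param variants Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   and optionally `eaf`.
#' @param r2 Tibble with columns `id_a`, `id_b`, `r2`; each unordered pair
#'   listed once suffices (symmetry is implied).
#' @param ancestry Ancestry label, see [ancestry_labels()].
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(variants, r2 = NULL, ancestry = "EU") {
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (anyDuplicated(variants$id)) {
    abort("duplicate variant ids in LD panel", class = "bottomline_usage_error")
  }
  if (is.null(r2) || ncol(tibble::as_tibble(r2)) == 0) {
    r2 <- tibble::tibble(id_a = character(), id_b = character(), r2 = double())
  }
  r2 <- tibble::as_tibble(r2)
  stopifnot(all(c("id_a", "id_b", "r2") %in% names(r2)))
  r2 <- r2[r2$id_a != r2$id_b, , drop = FALSE]
  if (nrow(r2) > 0 && (any(r2$r2 < 0) || any(r2$r2 > 1))) {
    abort("r2 values must lie in [0, 1]", class = "bottomline_usage_error")
  }
  # adjacency list over both directions for neighbourhood queries
  both <- tibble::tibble(a = c(r2$id_a, r2$id_b), b = c(r2$id_b, r2$id_a),
                         r2 = c(r2$r2, r2$r2))
  adj <- split(both[, c("b", "r2")], both$a)
  structure(list(variants = variants, r2 = r2, adj = adj, ancestry = ancestry),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("# ld_panel: ancestry %s, %d variants, %d r2 pairs\n",
              x$ancestry, nrow(x$variants), nrow(x$r2)))
  invisible(x)
}

#' Neighbours of a panel variant above an r2 threshold
#' @param panel An [ld_panel].
#' @param id Panel variant id.
#' @param min_r2 Minimum squared correlation.
#' @return Character vector of neighbour ids (excluding `id` itself).
#' @export
ld_neighbours <- function(panel, id, min_r2 = 0) {
  nb <- panel$adj[[id]]
  if (is.null(nb)) return(character())
  nb$b[nb$r2 >= min_r2]
}

#' Pairwise r2 lookup
#' @inheritParams ld_neighbours
#' @param id_a,id_b Panel variant ids.
#' @return The stored r2 (1 for identical ids, 0 for unrecorded pairs).
#' @export
ld_r2 <- function(panel, id_a, id_b) {
  if (id_a == id_b) return(1)
  nb <- panel$adj[[id_a]]
  if (is.null(nb)) return(0)
  hit <- match(id_b, nb$b)
  if (is.na(hit)) 0 else nb$r2[hit]
}

#' Read / write LD panel files
#'
#' The on-disk format is two tab-separated files: a variant map
#' (`id`, `chrom`, `pos`, `ref`, `alt`, `eaf`) and a pair table
#' (`id_a`, `id_b`, `r2`); either may be gzip-compressed.
#'
#' @param variants_path,pairs_path File paths.
#' @param ancestry Ancestry label.
#' @return For `read_ld_panel`, an [ld_panel]; for `write_ld_panel`, the
#'   paths, invisibly.
#' @export
read_ld_panel <- function(variants_path, pairs_path, ancestry = "EU") {
  for (p in c(variants_path, pairs_path)) {
    if (!file.exists(p)) {
      abort(sprintf("LD panel file not found: %s", p),
            class = "bottomline_io_error")
    }
  }
  v <- readr::read_tsv(variants_path, show_col_types = FALSE, progress = FALSE)
  r <- readr::read_tsv(pairs_path, show_col_types = FALSE, progress = FALSE)
  ld_panel(v, r, ancestry = ancestry)
}

#' @rdname read_ld_panel
#' @param panel An [ld_panel].
#' @export
write_ld_panel <- function(panel, variants_path, pairs_path) {
  readr::write_tsv(panel$variants, variants_path, progress = FALSE)
  readr::write_tsv(panel$r2, pairs_path, progress = FALSE)
  invisible(c(variants_path, pairs_path))
}
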