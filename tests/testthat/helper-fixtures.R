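# quick sumstats builder with sensible defaults
mk_ss <- function(df, study_id = "s1", trait = "t", ancestry = "EU",
                  n_total = NULL) {
  df <- tibble::as_tibble(df)
  n <- nrow(df)
  if (!"chrom" %in% names(df)) df$chrom <- "1"
  if (!"pos" %in% names(df)) df$pos <- seq_len(n) * 1000L
  if (!"ref" %in% names(df)) df$ref <- "A"
  if (!"alt" %in% names(df)) df$alt <- "G"
  if (!"eaf" %in% names(df)) df$eaf <- 0.3
  if (!"n" %in% names(df)) df$n <- 10000
  if (!"se" %in% names(df)) df$se <- 0.01
  if (!"beta" %in% names(df) && "p" %in% names(df)) {
    df$beta <- qnorm(df$p / 2, lower.tail = FALSE) * df$se
  }
  if (!"p" %in% names(df)) {
    z <- df$beta / df$se
    df$p <- pmax(2 * pnorm(-abs(z)), 1e-300)
  }
  sumstats(df, study_id = study_id, trait = trait, ancestry = ancestry,
           n_total = n_total)
}

# dense-matrix LD panel over n variants for oracle comparisons
mk_panel <- function(variants, r2_matrix = NULL, ancestry = "EU") {
  variants <- tibble::as_tibble(variants)
  if (!"id" %in% names(variants)) {
    variants$id <- sprintf("v%04d", seq_len(nrow(variants)))
  }
  pairs <- NULL
  if (!is.null(r2_matrix)) {
    idx <- which(upper.tri(r2_matrix) & r2_matrix > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      pairs <- tibble::tibble(id_a = variants$id[idx[, 1]],
                              id_b = variants$id[idx[, 2]],
                              r2 = r2_matrix[idx])
    }
  }
  ld_panel(variants, pairs, ancestry = ancestry)
}

vkey <- function(chrom, pos, ref = "A", alt = "G") {
  paste(chrom, as.integer(pos), ref, alt, sep = ":")
}
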