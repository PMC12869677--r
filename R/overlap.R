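# Expected Pearson correlation of a standard bivariate normal (correlation
# rho) after joint truncation to the box |x| < c, |y| < c, computed by
# Gauss-Legendre product quadrature. Selecting "null" variants by
# |z| < cutoff in both studies truncates exactly this way, attenuating the
# raw sample correlation; estimate_overlap_matrix inverts this map.
truncated_box_corr <- function(rho, cutoff, n_nodes = 64) {
  if (rho >= 1) return(1)
  if (rho <= 0) return(rho)
  k <- seq_len(n_nodes - 1)
  # Golub-Welsch: Gauss-Legendre nodes/weights on [-1, 1]
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n_nodes, n_nodes)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1, ]^2
  xs <- cutoff * x
  ws <- cutoff * w
  d <- 1 - rho^2
  f <- outer(xs, xs, function(u, v)
    exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * d)))
  W <- outer(ws, ws)
  m0 <- sum(W * f)
  mxy <- sum(W * outer(xs, xs) * f)
  mxx <- sum(W * outer(xs^2, rep(1, n_nodes)) * f)
  (mxy / m0) / (mxx / m0)
}

# invert truncated_box_corr by monotone interpolation over a rho grid
trunc_corr_inverse <- function(cutoff) {
  grid <- c(seq(0, 0.98, by = 0.02), 0.99, 0.995, 0.999, 1)
  obs <- vapply(grid, truncated_box_corr, numeric(1), cutoff = cutoff)
  function(r_obs) {
    if (is.na(r_obs)) return(NA_real_)
    if (r_obs <= 0) return(r_obs)
    if (r_obs >= 1) return(1)
    stats::approx(obs, grid, xout = r_obs, rule = 2)$y
  }
}

#' Estimate the inter-study correlation of association statistics
#'
#' Sample overlap between GWAS of the same trait induces correlation
#' r = n_overlap / sqrt(n1 * n2) between the studies' null association
#' z-statistics. This function estimates that correlation empirically for
#' every study pair from variants shared by the pair that look null in both
#' (|z| < `z_cutoff`). Because conditioning on |z| < cutoff truncates the
#' joint distribution and attenuates the sample correlation, the raw
#' estimate is de-biased by inverting the truncated-normal correlation map
#' (disable with `debias = FALSE`). Estimates are clipped to \[0, 1\]
#' (overlap cannot de-correlate studies) and the matrix is projected to the
#' nearest positive semi-definite correlation matrix by eigenvalue clipping.
#'
#' @param studies List of [sumstats] objects, harmonized to one orientation.
#' @param z_cutoff Null-definition threshold on |z|, default 1.96.
#' @param min_null Minimum shared null variants for a pair to be estimated;
#'   pairs below it get r = 0 with a warning.
#' @param debias Invert the truncation attenuation (default TRUE).
#' @return An object of class `overlap_model`: `study_ids`, correlation
#'   matrix `R` (diagonal 1), `n_null` (pairwise counts), `z_cutoff`.
#' @export
estimate_overlap_matrix <- function(studies, z_cutoff = 1.96,
                                    min_null = 1000, debias = TRUE) {
  if (length(studies) < 2) {
    abort("need at least 2 studies to estimate overlap",
          class = "bottomline_usage_error")
  }
  ids <- vapply(studies, function(s) attr(s, "study_id"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  k <- length(studies)
  zs <- purrr::map(studies, function(s) {
    setNames(s$beta / s$se, variant_key(s))
  })
  R <- diag(1, k)
  n_null <- matrix(0L, k, k, dimnames = list(ids, ids))
  inv <- if (debias) trunc_corr_inverse(z_cutoff) else identity
  low_pairs <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      shared <- intersect(names(zs[[i]]), names(zs[[j]]))
      zi <- zs[[i]][shared]
      zj <- zs[[j]][shared]
      nul <- abs(zi) < z_cutoff & abs(zj) < z_cutoff
      n_pair <- sum(nul, na.rm = TRUE)
      n_null[i, j] <- n_null[j, i] <- n_pair
      if (n_pair < min_null) {
        low_pairs <- low_pairs + 1L
        r <- 0
      } else if (isTRUE(all.equal(unname(zi[nul]), unname(zj[nul])))) {
        r <- 1  # identical z vectors: zero-variance guard for cor()
      } else {
        r <- suppressWarnings(cor(zi[nul], zj[nul]))
        if (is.na(r)) r <- 0
        r <- inv(min(max(r, 0), 1))
      }
      R[i, j] <- R[j, i] <- min(max(r, 0), 1)
    }
  }
  if (low_pairs > 0) {
    warn(sprintf("%d study pair(s) had fewer than %d shared null variants; r set to 0",
                 low_pairs, min_null))
  }
  R <- psd_project(R)
  dimnames(R) <- list(ids, ids)
  structure(list(study_ids = ids, R = R, n_null = n_null,
                 z_cutoff = z_cutoff, min_null = min_null),
            class = "overlap_model")
}

# nearest-PSD repair: clip negative eigenvalues, renormalize diagonal to 1
psd_project <- function(R) {
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(ev$values >= -1e-10)) return((R + t(R)) / 2)
  vals <- pmax(ev$values, 0)
  M <- ev$vectors %*% diag(vals, nrow = length(vals)) %*% t(ev$vectors)
  d <- sqrt(pmax(diag(M), .Machine$double.eps))
  M <- M / outer(d, d)
  diag(M) <- 1
  (M + t(M)) / 2
}

#' Identity overlap model (no shared samples assumed)
#' @param study_ids Character vector of study ids.
#' @return An `overlap_model` with R = I.
#' @export
identity_overlap_model <- function(study_ids) {
  k <- length(study_ids)
  R <- diag(1, k)
  dimnames(R) <- list(study_ids, study_ids)
  structure(list(study_ids = study_ids, R = R,
                 n_null = matrix(0L, k, k, dimnames = dimnames(R)),
                 z_cutoff = NA_real_, min_null = NA_integer_),
            class = "overlap_model")
}

#' @export
print.overlap_model <- function(x, ...) {
  cat(sprintf("# overlap_model: %d studies, z cutoff %s\n",
              length(x$study_ids), format(x$z_cutoff)))
  print(round(x$R, 3))
  invisible(x)
}

#' @export
tidy.overlap_model <- function(x, ...) {
  k <- length(x$study_ids)
  pairs <- which(upper.tri(x$R), arr.ind = TRUE)
  tibble::tibble(study_a = x$study_ids[pairs[, 1]],
                 study_b = x$study_ids[pairs[, 2]],
                 r = x$R[pairs],
                 n_null = x$n_null[pairs])
}

#' @export
glance.overlap_model <- function(x, ...) {
  off <- x$R[upper.tri(x$R)]
  tibble::tibble(n_studies = length(x$study_ids),
                 mean_r = if (length(off)) mean(off) else NA_real_,
                 max_r = if (length(off)) max(off) else NA_real_,
                 z_cutoff = x$z_cutoff)
}

#' Read / write an overlap model matrix file
#'
#' Serialized as a tab-separated matrix with study ids as header and first
#' column.
#' @param model An `overlap_model`.
#' @param path File path.
#' @export
write_overlap_model <- function(model, path) {
  df <- as.data.frame(model$R)
  df <- cbind(study_id = model$study_ids, df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_overlap_model
#' @export
read_overlap_model <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- df$study_id
  R <- as.matrix(df[, -1])
  dimnames(R) <- list(ids, ids)
  structure(list(study_ids = ids, R = R,
                 n_null = matrix(NA_integer_, length(ids), length(ids)),
                 z_cutoff = NA_real_, min_null = NA_integer_),
            class = "overlap_model")
}

#' Effective sample size under study overlap
#'
#' The independent-sample size giving the same precision as a set of
#' overlapping studies: with w_i = sqrt(n_i), N_eff = (sum n_i)^2 /
#' (w' R w). Equals sum(n) for independent studies and n for two fully
#' overlapping equal studies.
#'
#' @param ns Per-study sample sizes (> 0).
#' @param R Correlation matrix of association statistics over the same
#'   studies (or an `overlap_model`).
#' @return A single number.
#' @export
#' @examples
#' effective_sample_size(c(1000, 3000), diag(2))             # 4000
#' effective_sample_size(c(1000, 1000), matrix(c(1, 1, 1, 1), 2))  # 1000
effective_sample_size <- function(ns, R) {
  if (inherits(R, "overlap_model")) R <- R$R
  if (length(ns) != nrow(R) || nrow(R) != ncol(R)) {
    abort("dimension mismatch between ns and R",
          class = "bottomline_usage_error")
  }
  stopifnot(all(ns > 0))
  w <- sqrt(ns)
  sum(ns)^2 / drop(t(w) %*% R %*% w)
}

# two-sided normal log10 p from z, stable to |z| ~ 1e5 (log10p ~ -5000)
log10p_from_z <- function(z) {
  (log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

p_from_log10 <- function(log10p) {
  ifelse(log10p < -300, 10^pmax(log10p, -308), 10^log10p)
}

#' Fixed-effects meta-analysis with optional sample-overlap correction
#'
#' Inverse-variance-weighted combination generalized to correlated effect
#' estimates: per variant, over the subset S of studies containing it, with
#' weights w_i = 1/se_i^2 and Sigma_ij = R_ij se_i se_j,
#' beta = sum(w b) / sum(w) and var(beta) = (w' Sigma w) / (sum w)^2. With
#' the identity model (R = I, "overlap off") this is exactly the textbook
#' fixed-effects IVW; with an estimated [estimate_overlap_matrix()] model
#' ("overlap on") standard errors are inflated to undo the correlation
#' induced by shared samples.
#'
#' @param studies List of [sumstats] objects, allele-harmonized.
#' @param model An `overlap_model` covering all studies, or NULL for the
#'   identity (uncorrected) model.
#' @return A tibble of combined records: variant key columns, `eaf`
#'   (sample-size-weighted mean), `beta`, `se`, `z`, `log10p`, `p`,
#'   `n_eff` (overlap-aware effective sample size, in `n`), `k` (number of
#'   contributing studies).
#' @export
meta_fixed_effects <- function(studies, model = NULL) {
  stopifnot(length(studies) >= 1)
  ids <- vapply(studies, function(s) attr(s, "study_id"), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  if (is.null(model)) model <- identity_overlap_model(ids)
  if (!all(ids %in% model$study_ids)) {
    abort("overlap model does not cover all study ids",
          class = "bottomline_usage_error")
  }
  long <- dplyr::bind_rows(purrr::map2(studies, seq_along(studies), function(s, i) {
    tibble::tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                   eaf = s$eaf, beta = s$beta, se = s$se,
                   log10p = s$log10p, n = s$n, study = i)
  }))
  long <- long[!is.na(long$beta) & !is.na(long$se) & long$se > 0, ,
               drop = FALSE]
  Rfull <- model$R[ids, ids, drop = FALSE]
  key <- paste(long$chrom, long$pos, long$ref, long$alt, sep = ":")
  groups <- split(seq_len(nrow(long)), key)
  n_singular <- 0L
  res <- purrr::map(groups, function(rows) {
    b <- long$beta[rows]
    se <- long$se[rows]
    st <- long$study[rows]
    n <- long$n[rows]
    kk <- length(rows)
    if (kk == 1) {
      # pass-through: keep the study's own statistics, p included
      z <- b / se
      return(c(b, se, z, n, 1, long$log10p[rows]))
    }
    Rs <- Rfull[st, st, drop = FALSE]
    w <- 1 / se^2
    sw <- sum(w)
    beta <- sum(w * b) / sw
    # w' Sigma w with Sigma = R * outer(se, se); q_i = w_i se_i = 1/se_i
    q <- 1 / se
    varnum <- drop(t(q) %*% Rs %*% q)
    v <- varnum / sw^2
    if (!is.finite(v) || v <= 0) {
      n_singular <<- n_singular + 1L
      v <- drop(t(q) %*% diag(kk) %*% q) / sw^2
    }
    sem <- sqrt(v)
    nn <- n
    nn[is.na(nn)] <- 0
    neff <- if (all(nn > 0)) effective_sample_size(nn, Rs) else sum(nn)
    c(beta, sem, beta / sem, neff, kk, NA_real_)
  })
  if (n_singular > 0) {
    warn(sprintf("%d variant(s) had a singular covariance; identity fallback used",
                 n_singular))
  }
  mat <- unname(do.call(rbind, res))
  first <- unname(vapply(groups, `[`, numeric(1), 1))
  eaf_w <- unname(vapply(groups, function(rows) {
    e <- long$eaf[rows]
    n <- long$n[rows]
    if (all(is.na(e))) return(NA_real_)
    if (all(is.na(n))) return(mean(e, na.rm = TRUE))
    stats::weighted.mean(e, ifelse(is.na(n), 0, n), na.rm = TRUE)
  }, numeric(1)))
  out <- tibble::tibble(
    chrom = long$chrom[first], pos = long$pos[first],
    ref = long$ref[first], alt = long$alt[first],
    eaf = eaf_w, beta = mat[, 1], se = mat[, 2], z = mat[, 3],
    log10p = ifelse(is.na(mat[, 6]), log10p_from_z(mat[, 3]), mat[, 6]),
    n_eff = mat[, 4], k = as.integer(mat[, 5]))
  out$p <- p_from_log10(out$log10p)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), ]
  out[, c("chrom", "pos", "ref", "alt", "eaf", "beta", "se", "z",
          "log10p", "p", "n_eff", "k")]
}

#' Trans-ancestry fixed-effects meta-analysis
#'
#' Combines per-ancestry summary statistics assuming disjoint samples across
#' ancestries (identity overlap model, "overlap off"). Variants present in a
#' single ancestry pass through with their statistics unchanged.
#'
#' @param per_ancestry List of [sumstats] objects, at most one per ancestry
#'   label.
#' @return A tibble as [meta_fixed_effects()].
#' @export
meta_trans_ancestry <- function(per_ancestry) {
  anc <- vapply(per_ancestry, function(s) attr(s, "ancestry"), character(1))
  if (anyDuplicated(anc)) {
    abort("duplicate ancestry label in trans-ancestry meta-analysis inputs",
          class = "bottomline_usage_error")
  }
  meta_fixed_effects(per_ancestry, model = NULL)
}

#' Convert a meta-analysis table to a sumstats object
#'
#' The combined record table of [meta_fixed_effects()] re-expressed as a
#' [sumstats] object (with `n` = effective sample size) so it can be clumped
#' and fed back through the pipeline.
#'
#' @param meta Output of [meta_fixed_effects()].
#' @inheritParams sumstats
#' @return A [sumstats] object.
#' @export
meta_as_sumstats <- function(meta, study_id = "meta", trait = "trait",
                             ancestry = "EU", n_total = NULL) {
  rec <- tibble::tibble(chrom = meta$chrom, pos = meta$pos, ref = meta$ref,
                        alt = meta$alt, eaf = meta$eaf, beta = meta$beta,
                        se = meta$se, p = meta$p, log10p = meta$log10p,
                        n = meta$n_eff)
  sumstats(rec, study_id = study_id, trait = trait, ancestry = ancestry,
           n_total = n_total %||% suppressWarnings(max(meta$n_eff)))
}
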