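#' Configuration for a synthetic multi-study GWAS corpus
#'
#' Describes the generative model used by [simulate_studies()] and
#' [simulate_ld_panel()]: variants arranged in LD blocks (within-block
#' genotype correlation `rho`, so within-block r2 = rho^2; zero across
#' blocks), a sparse set of causal variants with standardized per-allele
#' effect `lambda`, a roster of studies with sample sizes spanning orders of
#' magnitude, and a matrix of pairwise shared-individual counts. Under the
#' standard null approximation, sharing n_o individuals between studies of
#' sizes n1 and n2 correlates their null association z-statistics by
#' r = n_o / sqrt(n1 n2); that law is the simulator's ground truth.
#'
#' @param seed Integer seed; identical configs produce identical corpora.
#' @param n_variants Total variant count.
#' @param block_sizes Integer vector of LD block sizes summing to
#'   `n_variants`.
#' @param rho Within-block genotype correlation in \[0, 1).
#' @param causal_fraction Fraction of variants given a causal effect.
#' @param lambda Standardized per-allele effect size of causal variants
#'   (per-study expected z is sqrt(n) * lambda).
#' @param studies Tibble with columns `n` (sample size) and `ancestry`.
#' @param overlap Square matrix of pairwise shared-individual counts
#'   n_o(i, j), 0 <= n_o <= min(n_i, n_j); diagonal ignored.
#' @param rare_fraction Fraction of variants drawn with MAF <= 5%.
#' @param spacing Base-pair spacing between adjacent variants.
#' @param artifacts Optional tibble (`study`, `n`, `z`) planting `n`
#'   study-private artifact variants with z-shift `z` in study `study`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_variants = 1000,
                       block_sizes = rep(10, n_variants / 10), rho = 0.9,
                       causal_fraction = 0, lambda = 0.05,
                       studies = tibble::tibble(n = c(10000, 10000),
                                                ancestry = "EU"),
                       overlap = NULL, rare_fraction = 0.1,
                       spacing = 10000L, artifacts = NULL) {
  block_sizes <- as.integer(block_sizes)
  if (sum(block_sizes) != n_variants) {
    abort("block sizes must sum to n_variants",
          class = "bottomline_usage_error")
  }
  stopifnot(rho >= 0, rho < 1, causal_fraction >= 0, causal_fraction <= 1,
            is.finite(lambda))
  studies <- tibble::as_tibble(studies)
  k <- nrow(studies)
  if (is.null(overlap)) overlap <- matrix(0, k, k)
  overlap <- as.matrix(overlap)
  if (!all(dim(overlap) == k)) {
    abort("overlap matrix dimension must match the number of studies",
          class = "bottomline_usage_error")
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && (overlap[i, j] < 0 ||
                   overlap[i, j] > min(studies$n[i], studies$n[j]))) {
      abort(sprintf("overlap n_o(%d,%d) outside [0, min(n_i, n_j)]", i, j),
            class = "bottomline_usage_error")
    }
  }
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 block_sizes = block_sizes, rho = rho,
                 causal_fraction = causal_fraction, lambda = lambda,
                 studies = studies, overlap = overlap,
                 rare_fraction = rare_fraction, spacing = as.integer(spacing),
                 artifacts = artifacts),
            class = "sim_config")
}

# deterministic variant frame shared by panel and study simulation
sim_variant_frame <- function(cfg) {
  with_local_seed(cfg$seed, {
    nv <- cfg$n_variants
    block <- rep(seq_along(cfg$block_sizes), cfg$block_sizes)
    rare <- runif(nv) < cfg$rare_fraction
    eaf <- ifelse(rare, runif(nv, 0.005, 0.05), runif(nv, 0.051, 0.5))
    flip <- runif(nv) < 0.5
    eaf <- ifelse(flip, 1 - eaf, eaf)
    causal <- rep(FALSE, nv)
    n_causal <- round(cfg$causal_fraction * nv)
    if (n_causal > 0) {
      # plant causal effects on common variants so power is frequency-free
      candidates <- which(pmin(eaf, 1 - eaf) > 0.05)
      causal[sample(candidates, min(n_causal, length(candidates)))] <- TRUE
    }
    tibble::tibble(
      id = sprintf("v%06d", seq_len(nv)),
      chrom = "1",
      pos = as.integer(seq_len(nv) * cfg$spacing),
      ref = "A", alt = "G",
      eaf = eaf, block = block, causal = causal,
      lambda = ifelse(causal, cfg$lambda, 0))
  })
}

#' Simulate an LD reference panel from a corpus configuration
#'
#' Variants are placed at regular spacing on one synthetic chromosome;
#' within each block every pair has r2 = rho^2 and pairs across blocks have
#' r2 = 0 (absent from the pair table). The panel round-trips through
#' [write_ld_panel()] / [read_ld_panel()].
#'
#' @param cfg A [sim_config].
#' @param ancestry Ancestry label for the panel.
#' @return An [ld_panel].
#' @export
simulate_ld_panel <- function(cfg, ancestry = NULL) {
  vf <- sim_variant_frame(cfg)
  ancestry <- ancestry %||% cfg$studies$ancestry[1]
  r2v <- cfg$rho^2
  pairs <- NULL
  if (r2v > 0) {
    pairs <- dplyr::bind_rows(purrr::map(split(vf$id, vf$block), function(ids) {
      m <- length(ids)
      if (m < 2) return(NULL)
      idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      tibble::tibble(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]], r2 = r2v)
    }))
  }
  ld_panel(vf[, c("id", "chrom", "pos", "ref", "alt", "eaf")], pairs,
           ancestry = ancestry)
}

#' Simulate a multi-study GWAS summary-statistics corpus
#'
#' Draws per-study association z-statistics jointly normal with mean
#' sqrt(n_i) * lambda_v, unit variance, cross-study covariance
#' n_o(i, j) / sqrt(n_i n_j) (the sample-overlap law), and within-study
#' cross-variant correlation rho inside each LD block (Kronecker
#' factorization: study correlation x LD correlation per block). Effect
#' sizes are beta = z * se with se = 1/sqrt(n) (standardized genotypes);
#' p-values come from the two-sided normal. Study-private artifact variants
#' (if configured) receive an additive z-shift in their study only,
#' emulating study-specific technical signals.
#'
#' @param cfg A [sim_config].
#' @param trait Trait id attached to each study.
#' @return A list of [sumstats] objects, one per configured study, named
#'   `study1`, `study2`, ...
#' @export
simulate_studies <- function(cfg, trait = "sim_trait") {
  vf <- sim_variant_frame(cfg)
  k <- nrow(cfg$studies)
  ns <- cfg$studies$n
  Rs <- diag(1, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) Rs[i, j] <- cfg$overlap[i, j] / sqrt(ns[i] * ns[j])
  }
  Cs <- chol_psd(Rs)
  z <- with_local_seed(cfg$seed + 1L, {
    zm <- matrix(0, k, cfg$n_variants)
    for (b in split(seq_len(cfg$n_variants), vf$block)) {
      m <- length(b)
      L <- matrix(cfg$rho, m, m)
      diag(L) <- 1
      E <- t(Cs) %*% matrix(rnorm(k * m), k, m) %*% chol_psd(L)
      zm[, b] <- E
    }
    zm <- zm + outer(sqrt(ns), vf$lambda)
    if (!is.null(cfg$artifacts)) {
      for (r in seq_len(nrow(cfg$artifacts))) {
        st <- cfg$artifacts$study[r]
        nart <- cfg$artifacts$n[r]
        null_idx <- which(!vf$causal)
        idx <- sample(null_idx, nart)
        zm[st, idx] <- zm[st, idx] + cfg$artifacts$z[r]
      }
    }
    zm
  })
  purrr::map(seq_len(k), function(i) {
    se <- 1 / sqrt(ns[i])
    zi <- z[i, ]
    l10 <- log10p_from_z(zi)
    rec <- tibble::tibble(
      chrom = vf$chrom, pos = vf$pos, ref = vf$ref, alt = vf$alt,
      eaf = vf$eaf, beta = zi * se, se = se, p = p_from_log10(l10),
      log10p = l10, n = ns[i])
    sumstats(rec, study_id = sprintf("study%d", i), trait = trait,
             ancestry = cfg$studies$ancestry[i], n_total = ns[i])
  }) |> setNames(sprintf("study%d", seq_len(k)))
}

# Cholesky factor tolerant of a semi-definite matrix
chol_psd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  sq <- ev$vectors %*% diag(sqrt(vals), nrow = length(vals)) %*% t(ev$vectors)
  # return an upper-triangular-like factor: t(sq) %*% sq == M
  t(sq)
}

#' Simulate paired credible sets
#'
#' Builds `n_regions` pairs of credible sets on shared per-region variant
#' pools. In `identical` mode the two sides carry equal PIPs; in
#' `perturbed` mode the second side's PIP mass is re-allocated by
#' multiplicative log-normal jitter (and renormalized); in `disjoint` mode
#' the two sides share no variants. Every set has PIP sum >= 0.99.
#'
#' @param n_regions Number of credible-set pairs.
#' @param jitter Log-scale jitter for `perturbed` mode.
#' @param mode One of `"identical"`, `"perturbed"`, `"disjoint"`.
#' @param seed Integer seed.
#' @param set_size Variants per credible set.
#' @return A list with elements `a` and `b`, each a list of
#'   [credible_set] objects.
#' @export
simulate_credible_set_pairs <- function(n_regions, jitter = 0.2,
                                        mode = c("identical", "perturbed",
                                                 "disjoint"),
                                        seed = 1, set_size = 5) {
  mode <- match.arg(mode)
  stopifnot(n_regions >= 1)
  target <- 0.995
  with_local_seed(seed, {
    pairs <- purrr::map(seq_len(n_regions), function(r) {
      vars_a <- sprintf("r%d_snp%d", r, seq_len(set_size))
      w <- sort(runif(set_size), decreasing = TRUE)
      pips_a <- setNames(target * w / sum(w), vars_a)
      if (mode == "identical") {
        pips_b <- pips_a
        vars_b <- vars_a
      } else if (mode == "perturbed") {
        w2 <- as.numeric(pips_a) * exp(rnorm(set_size, 0, jitter))
        pips_b <- setNames(target * w2 / sum(w2), vars_a)
        vars_b <- vars_a
      } else {
        vars_b <- sprintf("r%d_alt%d", r, seq_len(set_size))
        pips_b <- setNames(target * w / sum(w), vars_b)
      }
      list(a = credible_set(sprintf("A_r%d", r), "gwas_a",
                            vars_a[which.max(pips_a)], pips_a),
           b = credible_set(sprintf("B_r%d", r), "gwas_b",
                            vars_b[which.max(pips_b)], pips_b))
    })
    list(a = purrr::map(pairs, "a"), b = purrr::map(pairs, "b"))
  })
}

#' Simulate a pair of ranked gene-set tables
#'
#' Produces two gene-set p-value tables whose top-`top_k` membership
#' overlap is controlled by `signal_overlap` (1 = identical top sets in the
#' same order; 0 = the second table's top sets are drawn from outside the
#' first's top).
#'
#' @param n_sets Number of gene sets (>= 100).
#' @param signal_overlap Fraction in \[0, 1\] of the first ranking's top
#'   `top_k` sets that also occupy the second ranking's top `top_k`.
#' @param seed Integer seed.
#' @param top_k Size of the "top" stratum, default 50.
#' @return A list with tibbles `a` and `b`, each with columns `set_id`, `p`
#'   sorted by increasing p.
#' @export
simulate_ranked_genesets <- function(n_sets, signal_overlap = 1, seed = 1,
                                     top_k = 50) {
  stopifnot(n_sets >= 100, signal_overlap >= 0, signal_overlap <= 1)
  with_local_seed(seed, {
    ids <- sprintf("gs%05d", seq_len(n_sets))
    p_a <- sort(runif(n_sets)^3)  # skew toward small p at the top
    a <- tibble::tibble(set_id = ids, p = p_a)
    n_shared <- round(signal_overlap * top_k)
    b_top <- c(ids[seq_len(n_shared)],
               sample(ids[(top_k + 1):n_sets], top_k - n_shared))
    b_rest <- sample(setdiff(ids, b_top))
    b_ids <- c(b_top, b_rest)
    b <- tibble::tibble(set_id = b_ids, p = sort(runif(n_sets)^3))
    list(a = a, b = b)
  })
}

#' Ground truth of a simulated corpus
#'
#' The deterministic per-variant frame underlying [simulate_studies()] and
#' [simulate_ld_panel()] for a given configuration: positions, LD block
#' assignment, allele frequencies, and which variants are causal with what
#' standardized effect.
#'
#' @param cfg A [sim_config].
#' @return A tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`, `eaf`,
#'   `block`, `causal`, `lambda`.
#' @export
sim_truth <- function(cfg) {
  sim_variant_frame(cfg)
}
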