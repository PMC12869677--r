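log10_or_inf <- function(p) if (p <= 0) -Inf else log10(p)

new_clump_tbl <- function(rows) {
  cols <- c("lead", "chrom", "lead_pos", "lead_log10p", "span_start",
            "span_end", "n_members", "members", "ancestry")
  if (length(rows) == 0) {
    return(tibble::tibble(lead = character(), chrom = character(),
                          lead_pos = integer(), lead_log10p = double(),
                          span_start = integer(), span_end = integer(),
                          n_members = integer(), members = list(),
                          ancestry = character()))
  }
  dplyr::bind_rows(rows)[, cols]
}

#' Greedy LD clumping of association signals
#'
#' Enumerates independent association signals from summary statistics with
#' the standard greedy procedure: repeatedly take the most significant
#' unassigned panel-covered variant with p < `p1` as a lead, and assign to
#' its clump all unassigned variants with p < `p2` within the window around
#' the lead and in linkage disequilibrium r2 >= `r2` with it. Defaults are
#' the conservative settings used for consensus-signal enumeration
#' (`--clump-p1 5e-8 --clump-p2 5e-6 --clump-r2 0.01 --clump-kb 5000`, i.e. a
#' +/- 2.5 Mb window). Ties in p are broken by (chrom, pos, ref, alt) so the
#' output is deterministic.
#'
#' @param s A [sumstats] object, harmonized to the panel.
#' @param panel An [ld_panel] of the same ancestry.
#' @param p1 Lead-variant significance threshold.
#' @param p2 Secondary (member) significance threshold.
#' @param r2 Minimum squared correlation with the lead for membership.
#' @param kb Window size in kilobases; members must lie within
#'   +/- `kb`/2 x 1000 bp of the lead.
#' @return A tibble of clumps: `lead` (variant key chrom:pos:ref:alt),
#'   `chrom`, `lead_pos`, `lead_log10p`, `span_start`, `span_end`,
#'   `n_members`, `members` (list column of variant keys), `ancestry`.
#' @export
greedy_clump <- function(s, panel, p1 = 5e-8, p2 = 5e-6, r2 = 0.01, kb = 5000) {
  stopifnot(p1 > 0, p2 > 0, p1 <= p2, r2 >= 0, kb > 0)
  if (!is.null(attr(s, "ancestry")) && !is.null(panel$ancestry) &&
      attr(s, "ancestry") != panel$ancestry && attr(s, "ancestry") != "TA") {
    abort(sprintf("sumstats ancestry '%s' does not match panel ancestry '%s'",
                  attr(s, "ancestry"), panel$ancestry),
          class = "bottomline_usage_error")
  }
  half_window <- kb * 1000 / 2
  l10_p1 <- log10_or_inf(p1)
  l10_p2 <- log10_or_inf(p2)

  cov <- dplyr::inner_join(
    tibble::tibble(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                   log10p = s$log10p),
    panel$variants[, c("id", "chrom", "pos", "ref", "alt")],
    by = c("chrom", "pos", "ref", "alt"))
  cov <- cov[!is.na(cov$log10p), , drop = FALSE]
  cov <- cov[order(cov$log10p, cov$chrom, cov$pos, cov$ref, cov$alt), ,
             drop = FALSE]
  cov$key <- variant_key(cov)
  idx_of <- setNames(seq_len(nrow(cov)), cov$id)
  assigned <- rep(FALSE, nrow(cov))
  clumps <- list()
  lead_rows <- which(cov$log10p < l10_p1)
  for (i in lead_rows) {
    if (assigned[i]) next
    lead_id <- cov$id[i]
    nb_ids <- if (r2 > 0) ld_neighbours(panel, lead_id, min_r2 = r2) else
      cov$id[cov$chrom == cov$chrom[i]]
    nb_idx <- idx_of[nb_ids]
    nb_idx <- nb_idx[!is.na(nb_idx)]
    memb <- nb_idx[!assigned[nb_idx] &
                     cov$log10p[nb_idx] < l10_p2 &
                     cov$chrom[nb_idx] == cov$chrom[i] &
                     abs(cov$pos[nb_idx] - cov$pos[i]) <= half_window]
    memb <- sort(unique(c(i, memb)))
    assigned[memb] <- TRUE
    clumps[[length(clumps) + 1]] <- tibble::tibble(
      lead = cov$key[i], chrom = cov$chrom[i], lead_pos = cov$pos[i],
      lead_log10p = cov$log10p[i],
      span_start = min(cov$pos[memb]), span_end = max(cov$pos[memb]),
      n_members = length(memb), members = list(cov$key[memb]),
      ancestry = panel$ancestry)
  }
  new_clump_tbl(clumps)
}

#' Clumping with an adaptive lead threshold
#'
#' Runs [greedy_clump()] starting at `p1 = 5e-8`; while fewer than
#' `min_clumps` clumps are found, the lead threshold is relaxed in 10-fold
#' increments, never beyond the secondary threshold `p2`.
#'
#' @inheritParams greedy_clump
#' @param min_clumps Minimum acceptable number of clumps before relaxing.
#' @param p1_start Initial lead threshold.
#' @return A list with `clumps` (as [greedy_clump()]) and `p1_used`.
#' @export
adaptive_clump <- function(s, panel, min_clumps = 50, p1_start = 5e-8,
                           p2 = 5e-6, r2 = 0.01, kb = 5000) {
  p1 <- p1_start
  repeat {
    cl <- greedy_clump(s, panel, p1 = p1, p2 = p2, r2 = r2, kb = kb)
    if (nrow(cl) >= min_clumps || p1 >= p2) break
    p1 <- min(p1 * 10, p2)
  }
  list(clumps = cl, p1_used = p1)
}

#' Append panel-absent significant variants as single-variant clumps
#'
#' Variants (typically rare) that reach the lead threshold but are not
#' represented in the LD reference panel cannot be clumped. Those whose
#' position falls outside the span of every existing clump are appended as
#' single-variant clumps; those inside an existing clump's span are attached
#' as members of the covering clump (nearest lead when spans overlap).
#'
#' @param clumps Clump tibble from [greedy_clump()] on the same `s`.
#' @inheritParams greedy_clump
#' @param p1_used Lead threshold actually used (see [adaptive_clump()]).
#' @return An updated clump tibble.
#' @export
append_singletons <- function(clumps, s, panel, p1_used = 5e-8) {
  pv <- panel$variants
  covered <- paste(s$chrom, s$pos, s$ref, s$alt) %in%
    paste(pv$chrom, pv$pos, pv$ref, pv$alt)
  sig <- !is.na(s$log10p) & s$log10p < log10_or_inf(p1_used)
  cand <- s[sig & !covered, , drop = FALSE]
  if (nrow(cand) == 0) return(clumps)
  for (j in seq_len(nrow(cand))) {
    key <- variant_key(cand[j, ])
    inside <- which(clumps$chrom == cand$chrom[j] &
                      clumps$span_start <= cand$pos[j] &
                      clumps$span_end >= cand$pos[j])
    if (length(inside) > 0) {
      host <- inside[which.min(abs(clumps$lead_pos[inside] - cand$pos[j]))]
      clumps$members[[host]] <- unique(c(clumps$members[[host]], key))
      clumps$n_members[host] <- length(clumps$members[[host]])
      if (cand$log10p[j] < clumps$lead_log10p[host]) {
        # keep the lead the most significant member
        clumps$lead[host] <- key
        clumps$lead_pos[host] <- cand$pos[j]
        clumps$lead_log10p[host] <- cand$log10p[j]
      }
    } else {
      clumps <- dplyr::bind_rows(clumps, tibble::tibble(
        lead = key, chrom = cand$chrom[j], lead_pos = cand$pos[j],
        lead_log10p = cand$log10p[j], span_start = cand$pos[j],
        span_end = cand$pos[j], n_members = 1L, members = list(key),
        ancestry = if (nrow(clumps) > 0) clumps$ancestry[1] else
          panel$ancestry))
    }
  }
  clumps
}

#' Merge clumps into signals by shared variants
#'
#' Builds a graph whose vertices are variants and whose edges connect
#' variants co-occurring in any clump; each connected component is one
#' signal. This is both the cross-approach merge of the main comparison
#' analysis and the trans-ancestry clump merge ("merge clumps across single
#' ancestries which shared at least one variant").
#'
#' @param clump_sets A named list of clump tibbles (names are source
#'   labels), or a single clump tibble bearing a `label` column.
#' @return A tibble of signals: `signal_id`, `variants` (list of variant
#'   keys), `n_variants`, `labels` (list of contributing source labels),
#'   `leads` (list column of per-label lead tibbles with `label`, `lead`,
#'   `lead_log10p`).
#' @export
merge_by_shared_variants <- function(clump_sets) {
  if (is.data.frame(clump_sets)) {
    stopifnot("label" %in% names(clump_sets))
    labeled <- clump_sets
  } else {
    stopifnot(is.list(clump_sets), !is.null(names(clump_sets)))
    labeled <- dplyr::bind_rows(purrr::imap(clump_sets, function(cl, lab) {
      if (nrow(cl) == 0) return(NULL)
      dplyr::mutate(cl, label = lab)
    }))
  }
  if (is.null(labeled) || nrow(labeled) == 0) {
    return(tibble::tibble(signal_id = integer(), variants = list(),
                          n_variants = integer(), labels = list(),
                          leads = list()))
  }
  verts <- unique(unlist(labeled$members))
  edges <- purrr::map(labeled$members, function(m) {
    if (length(m) < 2) return(NULL)
    rbind(m[1], m[-1])  # star on the first member suffices for connectivity
  })
  edges <- do.call(cbind, purrr::compact(edges))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(verts)
  if (!is.null(edges)) g <- g + igraph::edges(as.vector(edges))
  comp <- igraph::components(g)
  membership <- comp$membership[verts]
  # deterministic signal ids: order components by their smallest variant key
  comp_min <- tapply(verts, membership, min)
  comp_order <- setNames(rank(comp_min, ties.method = "first"),
                         names(comp_min))
  clump_comp <- vapply(labeled$members,
                       function(m) unname(membership[m[1]]), numeric(1))
  out <- purrr::map(sort(unique(unname(comp_order))), function(sid) {
    cid <- as.numeric(names(comp_order)[comp_order == sid])
    vs <- sort(verts[membership == cid])
    rows <- labeled[clump_comp == cid, , drop = FALSE]
    tibble::tibble(
      signal_id = as.integer(sid), variants = list(vs),
      n_variants = length(vs),
      labels = list(sort(unique(rows$label))),
      leads = list(tibble::tibble(label = rows$label, lead = rows$lead,
                                  lead_log10p = rows$lead_log10p)))
  })
  dplyr::bind_rows(out)
}
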