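# Independent oracles, deliberately written in a different style from the
# package implementations they check.

# textbook fixed-effects inverse-variance meta-analysis for one variant
ivw_oracle <- function(b, se) {
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  list(beta = beta, se = sqrt(1 / sum(w)))
}

# brute-force greedy clumping over a dense r2 matrix: sort by p (ties by
# chrom, pos, ref, alt), sequentially assign
brute_clump <- function(records, in_panel, r2_matrix, p1, p2, kb, r2_min) {
  half <- kb * 1000 / 2
  ord <- order(records$p, records$chrom, records$pos, records$ref,
               records$alt)
  assigned <- rep(FALSE, nrow(records))
  clumps <- list()
  for (i in ord) {
    if (assigned[i] || !in_panel[i] || !(records$p[i] < p1)) next
    members <- i
    for (j in seq_len(nrow(records))) {
      if (j == i || assigned[j] || !in_panel[j]) next
      if (!(records$p[j] < p2)) next
      if (records$chrom[j] != records$chrom[i]) next
      if (abs(records$pos[j] - records$pos[i]) > half) next
      if (r2_matrix[i, j] < r2_min) next
      members <- c(members, j)
    }
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1]] <- list(lead = i, members = sort(members))
  }
  clumps
}

# union-find transitive closure over labeled variant sets
union_find_merge <- function(member_sets) {
  parent <- new.env()
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (p == x) return(x)
    root <- find(p)
    assign(x, root, envir = parent)
    root
  }
  union <- function(x, y) assign(find(x), find(y), envir = parent)
  for (s in member_sets) {
    for (v in s[-1]) union(s[1], v)
  }
  all_vars <- unique(unlist(member_sets))
  roots <- vapply(all_vars, find, character(1))
  unname(lapply(split(all_vars, roots), sort))
}

# brute-force BH step-up: q_i = min over j with rank >= rank(i) of m p_(j)/j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (r in seq_len(m)) {
    q_sorted[r] <- min(m * p[ord][r:m] / (r:m))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# random clumping instance generator for oracle equivalence checks
random_clump_instance <- function(seed) {
  set.seed(seed)
  n <- sample(20:200, 1)
  chrom <- sample(c("1", "2"), n, replace = TRUE)
  pos <- sample(1:8e6, n)
  lp <- -runif(n, 0, 12)  # log10 p in (-12, 0)
  records <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                            ref = "A", alt = "G", p = 10^lp, log10p = lp)
  records <- records[order(records$chrom, records$pos), ]
  records <- records[!duplicated(paste(records$chrom, records$pos)), ]
  n <- nrow(records)
  in_panel <- runif(n) < 0.9
  R <- matrix(0, n, n)
  n_pairs <- sample(0:(3 * n), 1)
  if (n_pairs > 0) {
    ij <- cbind(sample(n, n_pairs, replace = TRUE),
                sample(n, n_pairs, replace = TRUE))
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    vals <- runif(nrow(ij))
    R[ij] <- vals
    R[ij[, 2:1, drop = FALSE]] <- vals
  }
  diag(R) <- 1
  list(records = records, in_panel = in_panel, R = R)
}
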