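test_that("greedy clumping follows the hand-executed examples", {
  # A(p=1e-10), B(p=1e-9, r2(A,B)=0.5, 10 kb away), C(p=1e-7, r2(A,C)=0)
  vars <- tibble::tibble(chrom = "1", pos = c(100000L, 110000L, 150000L),
                         ref = "A", alt = "G")
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.5
  panel <- mk_panel(vars, R)
  s <- mk_ss(tibble::tibble(pos = vars$pos, beta = 1, se = 0.1,
                            p = c(1e-10, 1e-9, 1e-7)))
  cl <- greedy_clump(s, panel)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$lead, vkey("1", 100000))
  expect_setequal(cl$members[[1]], vkey("1", c(100000, 110000)))

  # no variant below p1: empty result
  weak <- mk_ss(tibble::tibble(pos = vars$pos, beta = 1, se = 0.1, p = 1e-6))
  expect_equal(nrow(greedy_clump(weak, panel)), 0)

  # two significant variants 6 Mb apart with recorded r2 but outside the
  # window: two singleton clumps
  far_vars <- tibble::tibble(chrom = "1", pos = c(1000000L, 7000000L),
                             ref = "A", alt = "G")
  Rfar <- matrix(c(1, 0.9, 0.9, 1), 2)
  far_panel <- mk_panel(far_vars, Rfar)
  far <- mk_ss(tibble::tibble(pos = far_vars$pos, beta = 1, se = 0.1,
                              p = c(1e-10, 1e-9)))
  cl_far <- greedy_clump(far, far_panel)
  expect_equal(nrow(cl_far), 2)
  expect_true(all(cl_far$n_members == 1))
})

test_that("greedy clumping matches the brute-force reference on random instances", {
  for (seed in 1:60) {
    inst <- random_clump_instance(seed)
    rec <- inst$records
    n <- nrow(rec)
    panel <- mk_panel(rec[inst$in_panel, c("chrom", "pos", "ref", "alt")],
                      inst$R[inst$in_panel, inst$in_panel, drop = FALSE])
    s <- mk_ss(rec[, c("chrom", "pos", "ref", "alt", "p")])
    p1 <- sample(c(5e-8, 5e-7, 1e-6), 1)
    cl <- greedy_clump(s, panel, p1 = p1)
    Rsub <- matrix(0, n, n)
    Rsub[inst$in_panel, inst$in_panel] <-
      inst$R[inst$in_panel, inst$in_panel]
    diag(Rsub) <- 1
    orc <- brute_clump(rec, inst$in_panel, Rsub, p1 = p1, p2 = 5e-6,
                       kb = 5000, r2_min = 0.01)
    expect_equal(nrow(cl), length(orc))
    if (length(orc) > 0) {
      orc_leads <- vapply(orc, function(c)
        vkey(rec$chrom[c$lead], rec$pos[c$lead]), character(1))
      orc_members <- lapply(orc, function(c)
        sort(vkey(rec$chrom[c$members], rec$pos[c$members])))
      expect_setequal(cl$lead, orc_leads)
      ord <- match(cl$lead, orc_leads)
      for (i in seq_len(nrow(cl))) {
        expect_equal(sort(cl$members[[i]]), orc_members[[ord[i]]])
      }
    }
  }
})

test_that("clump invariants: partition, member significance, lead dominance, determinism", {
  inst <- random_clump_instance(999)
  rec <- inst$records
  panel <- mk_panel(rec[inst$in_panel, c("chrom", "pos", "ref", "alt")],
                    inst$R[inst$in_panel, inst$in_panel, drop = FALSE])
  s <- mk_ss(rec[, c("chrom", "pos", "ref", "alt", "p")])
  cl <- greedy_clump(s, panel, p1 = 1e-6)
  all_members <- unlist(cl$members)
  expect_equal(anyDuplicated(all_members), 0)
  lp <- setNames(s$log10p, vkey(s$chrom, s$pos))
  for (i in seq_len(nrow(cl))) {
    expect_true(all(lp[cl$members[[i]]] < log10(5e-6)))
    expect_true(all(cl$lead_log10p[i] <= lp[cl$members[[i]]]))
  }
  expect_identical(cl, greedy_clump(s, panel, p1 = 1e-6))
})

test_that("adaptive clumping relaxes p1 in 10-fold steps capped at p2", {
  # 60 well-separated significant variants: no relaxation needed
  many <- mk_ss(tibble::tibble(pos = seq_len(60) * 6000000L, beta = 1,
                               se = 0.1, p = 1e-9))
  panel_many <- mk_panel(tibble::tibble(chrom = "1",
                                        pos = seq_len(60) * 6000000L,
                                        ref = "A", alt = "G"))
  res <- adaptive_clump(many, panel_many)
  expect_equal(res$p1_used, 5e-8)
  expect_equal(nrow(res$clumps), 60)

  # 10 variants at 1e-8 and 45 more at 1e-7: relaxing once reaches >= 50
  mixed <- mk_ss(tibble::tibble(pos = seq_len(55) * 6000000L, beta = 1,
                                se = 0.1,
                                p = c(rep(1e-8, 10), rep(1e-7, 45))))
  panel_mixed <- mk_panel(tibble::tibble(chrom = "1",
                                         pos = seq_len(55) * 6000000L,
                                         ref = "A", alt = "G"))
  res2 <- adaptive_clump(mixed, panel_mixed)
  expect_equal(res2$p1_used, 5e-7)
  expect_equal(nrow(res2$clumps), 55)

  # never beyond p2 even when still short of min_clumps
  few <- mk_ss(tibble::tibble(pos = seq_len(20) * 6000000L, beta = 1,
                              se = 0.1, p = 1e-7))
  panel_few <- mk_panel(tibble::tibble(chrom = "1",
                                       pos = seq_len(20) * 6000000L,
                                       ref = "A", alt = "G"))
  res3 <- adaptive_clump(few, panel_few)
  expect_equal(res3$p1_used, 5e-6)
  expect_equal(nrow(res3$clumps), 20)
})

test_that("panel-absent significant variants append as singletons or join covering clumps", {
  vars <- tibble::tibble(chrom = "1", pos = c(1000000L, 1100000L),
                         ref = "A", alt = "G")
  R <- matrix(c(1, 0.8, 0.8, 1), 2)
  panel <- mk_panel(vars, R)
  s <- mk_ss(tibble::tibble(
    pos = c(1000000L, 1100000L, 1050000L, 9000000L, 1070000L),
    ref = c("A", "A", "T", "T", "A"),
    alt = c("G", "G", "C", "C", "G"),
    beta = 1, se = 0.1,
    p = c(1e-10, 1e-9, 1e-9, 1e-9, 0.5)))
  cl <- greedy_clump(s, panel)
  expect_equal(nrow(cl), 1)
  out <- append_singletons(cl, s, panel, p1_used = 5e-8)
  # interior panel-absent variant attached to the covering clump
  expect_equal(nrow(out), 2)
  expect_true(vkey("1", 1050000, "T", "C") %in% out$members[[1]])
  # distant panel-absent variant appended as its own singleton clump
  singleton <- out[out$lead == vkey("1", 9000000, "T", "C"), ]
  expect_equal(singleton$n_members, 1)
  # panel-covered non-significant variant unaffected
  expect_false(any(vkey("1", 1070000) %in% unlist(out$members)))
})

test_that("signal merging equals the union-find oracle and its invariants hold", {
  mk_clump <- function(members, label) {
    tibble::tibble(lead = members[1], chrom = "1", lead_pos = 1L,
                   lead_log10p = -10, span_start = 1L, span_end = 2L,
                   n_members = length(members), members = list(members),
                   ancestry = "EU", label = label)
  }
  # worked example: {v1,v2} from X and {v2,v3} from Y merge into one signal
  sig <- merge_by_shared_variants(dplyr::bind_rows(
    mk_clump(c("v1", "v2"), "X"), mk_clump(c("v2", "v3"), "Y")))
  expect_equal(nrow(sig), 1)
  expect_setequal(sig$variants[[1]], c("v1", "v2", "v3"))
  expect_setequal(sig$labels[[1]], c("X", "Y"))

  # chain across three labels
  sig2 <- merge_by_shared_variants(dplyr::bind_rows(
    mk_clump(c("a", "b"), "L1"), mk_clump(c("b", "c"), "L2"),
    mk_clump(c("c", "d"), "L3")))
  expect_equal(sig2$n_variants, 4)
  expect_equal(length(sig2$labels[[1]]), 3)

  # disjoint clumps stay separate
  sig3 <- merge_by_shared_variants(dplyr::bind_rows(
    mk_clump(c("p", "q"), "X"), mk_clump(c("r"), "Y")))
  expect_equal(nrow(sig3), 2)

  # random collections against the union-find oracle
  set.seed(7)
  for (rep in 1:25) {
    n_clumps <- sample(1:30, 1)
    universe <- sprintf("s%02d", 1:40)
    sets <- purrr::map(seq_len(n_clumps), function(i) {
      sort(sample(universe, sample(1:6, 1)))
    })
    labeled <- dplyr::bind_rows(purrr::imap(sets, function(s, i)
      mk_clump(s, sprintf("lab%d", i %% 4))))
    got <- merge_by_shared_variants(labeled)
    want <- union_find_merge(sets)
    expect_equal(nrow(got), length(want))
    got_sets <- lapply(got$variants, sort)
    expect_setequal(purrr::map_chr(got_sets, paste, collapse = ","),
                    purrr::map_chr(want, paste, collapse = ","))
    # partition of the union
    expect_equal(sort(unlist(got_sets)), sort(unique(unlist(sets))))
    # idempotent under re-merging
    again <- merge_by_shared_variants(dplyr::bind_rows(
      purrr::imap(got$variants, function(v, i) mk_clump(v, "Z"))))
    expect_equal(nrow(again), nrow(got))
  }
})
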