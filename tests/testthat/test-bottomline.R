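test_that("rare variants take the largest dataset's record verbatim", {
  small <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.01,
                                beta = 0.123456789, se = 0.0456789,
                                p = 0.007, n = 10000),
                 study_id = "small", n_total = 10000)
  big <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.012,
                              beta = 0.3141592653589793, se = 0.02718281828,
                              p = 0.001, n = 50000),
               study_id = "big", n_total = 50000)
  bl <- bottom_line_single_ancestry(list(small, big))
  expect_equal(nrow(bl), 1)
  expect_equal(bl$provenance, "largest_rare")
  expect_identical(bl$beta, big$beta)
  expect_identical(bl$se, big$se)
  expect_identical(bl$p, big$p)
})

test_that("a variant in both MAF categories resolves to the largest dataset", {
  a <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.06, beta = 0.1, se = 0.05,
                            p = 0.04, n = 10000),
             study_id = "a", n_total = 10000)  # common here
  b <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.04, beta = 0.2, se = 0.03,
                            p = 0.03, n = 60000),
             study_id = "b", n_total = 60000)  # rare in the larger study
  bl <- bottom_line_single_ancestry(list(a, b))
  expect_equal(bl$beta, 0.2)
  expect_equal(bl$provenance, "largest_rare")
  # and symmetric: rare in the smaller study, common in the larger
  a2 <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.04, beta = 0.1, se = 0.05,
                             p = 0.04, n = 10000),
              study_id = "a", n_total = 10000)
  b2 <- mk_ss(tibble::tibble(pos = 100L, eaf = 0.06, beta = 0.2, se = 0.03,
                             p = 0.03, n = 60000),
              study_id = "b", n_total = 60000)
  bl2 <- bottom_line_single_ancestry(list(a2, b2))
  expect_equal(bl2$beta, 0.2)
})

test_that("common variants in multiple studies are overlap-meta-analyzed, singletons pass through", {
  cfg <- sim_config(seed = 9, n_variants = 3000, block_sizes = rep(1, 3000),
                    rho = 0, rare_fraction = 0,
                    studies = tibble::tibble(n = c(10000, 10000),
                                             ancestry = "EU"),
                    overlap = matrix(c(0, 5000, 5000, 0), 2))
  st <- simulate_studies(cfg)
  # drop some variants from study 2 to create single-study passthroughs
  st[[2]] <- bottomline:::ss_rewrap(st[[2]][-(1:100), ], st[[2]])
  bl <- bottom_line_single_ancestry(st, min_null = 200)
  expect_equal(nrow(bl), 3000)
  expect_setequal(unique(bl$provenance), c("overlap_meta", "single_study"))
  pass <- bl[bl$provenance == "single_study", ]
  expect_equal(nrow(pass), 100)
  expect_equal(pass$beta, st[[1]]$beta[1:100])
  # combined precision: corrected meta se within [max-overlap and none]
  met <- bl[bl$provenance == "overlap_meta", ]
  expect_true(all(met$n <= 20000 + 1e-6))
  expect_true(all(met$n >= 10000 - 1e-6))
})

test_that("single study in one ancestry reduces to that study's statistics", {
  s <- mk_ss(tibble::tibble(pos = c(100L, 200L), eaf = c(0.3, 0.02),
                            beta = c(0.1, 0.2), se = 0.05,
                            p = c(0.04, 0.001), n = 20000),
             study_id = "only", n_total = 20000)
  bl <- bottom_line_single_ancestry(list(s))
  expect_equal(bl$beta, s$beta)
  expect_equal(bl$se, s$se)
  expect_setequal(bl$provenance, c("single_study", "largest_rare"))
  expect_error(bottom_line_single_ancestry(list()), "empty")
})

test_that("trans rule keeps the record with the larger per-variant sample size", {
  eu <- mk_ss(tibble::tibble(pos = c(100L, 200L), beta = 0.1, se = 0.02,
                             p = 1e-6, n = 120000),
              study_id = "eu_bl", ancestry = "EU", n_total = 120000)
  ea <- mk_ss(tibble::tibble(pos = 100L, beta = 0.12, se = 0.03, p = 1e-4,
                             n = 80000),
              study_id = "ea_bl", ancestry = "EA", n_total = 80000)
  pub <- mk_ss(tibble::tibble(pos = c(100L, 300L), beta = 0.09, se = 0.02,
                              p = 1e-5, n = c(150000, 150000)),
               study_id = "pub", ancestry = "TA", n_total = 150000)
  bt <- bottom_line_trans(list(eu, ea), pub)
  # meta n_eff at pos 100 = 200000 > published 150000 -> meta record
  r100 <- bt[bt$pos == 100, ]
  expect_equal(r100$provenance, "trans_meta")
  expect_equal(r100$n, 200000, tolerance = 1e-6)
  # variant only in published trans: kept
  expect_equal(bt[bt$pos == 300, ]$provenance, "published_trans")
  # published larger than meta: published wins
  pub_big <- mk_ss(tibble::tibble(pos = 100L, beta = 0.09, se = 0.02,
                                  p = 1e-5, n = 500000),
                   study_id = "pub", ancestry = "TA", n_total = 500000)
  bt2 <- bottom_line_trans(list(eu, ea), pub_big)
  expect_equal(bt2[bt2$pos == 100, ]$provenance, "published_trans")
  # no published trans: meta verbatim
  bt3 <- bottom_line_trans(list(eu, ea))
  expect_true(all(bt3$provenance == "trans_meta"))
  # no single-ancestry data: published verbatim
  bt4 <- bottom_line_trans(list(), pub)
  expect_true(all(bt4$provenance == "published_trans"))
  expect_equal(nrow(bt4), 2)
  expect_error(bottom_line_trans(list()), "no per-ancestry")
})

test_that("bottom line emits exactly one record per variant with one provenance", {
  cfg <- sim_config(seed = 13, n_variants = 2000, block_sizes = rep(4, 500),
                    rho = 0.8, causal_fraction = 0.01, lambda = 0.08,
                    studies = tibble::tibble(n = c(30000, 12000),
                                             ancestry = "EU"),
                    overlap = matrix(c(0, 6000, 6000, 0), 2))
  st <- simulate_studies(cfg)
  bl <- bottom_line_single_ancestry(st, min_null = 100)
  expect_equal(anyDuplicated(paste(bl$chrom, bl$pos, bl$ref, bl$alt)), 0)
  expect_true(all(bl$provenance %in%
                    c("overlap_meta", "largest_rare", "single_study")))
})

test_that("run_bottom_line composes the stages deterministically", {
  mk_anc <- function(anc, seed) {
    cfg <- sim_config(seed = seed, n_variants = 1500,
                      block_sizes = rep(5, 300), rho = 0.9,
                      causal_fraction = 0.01, lambda = 0.08,
                      studies = tibble::tibble(n = c(25000, 10000),
                                               ancestry = anc),
                      overlap = matrix(c(0, 5000, 5000, 0), 2))
    list(studies = simulate_studies(cfg), panel = simulate_ld_panel(cfg))
  }
  bundle <- list(trait = "demo",
                 ancestries = list(EU = mk_anc("EU", 31),
                                   EA = mk_anc("EA", 32)))
  clump_cfg <- list(p1 = 5e-8, p2 = 5e-6, r2 = 0.01, kb = 5000,
                    min_clumps = 5)
  res <- run_bottom_line(bundle, clump = clump_cfg, min_null = 100)
  expect_s3_class(res, "bottom_line_result")
  expect_equal(length(res$per_ancestry), 2)
  expect_equal(attr(res$trans, "ancestry"), "TA")
  expect_gt(nrow(res$trans_signals), 0)
  expect_true(all(names(res$p1_used) %in% c("EU", "EA")))
  res2 <- run_bottom_line(bundle, clump = clump_cfg, min_null = 100)
  expect_equal(res$trans_signals, res2$trans_signals)
  expect_equal(as.data.frame(res$trans), as.data.frame(res2$trans))
  # tidiers
  td <- tidy(res)
  expect_true(all(c("ancestry", "provenance") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$trait, "demo")
  # empty bundle errors with the trait name
  expect_error(run_bottom_line(list(trait = "empty_trait",
                                    ancestries = list())),
               "empty_trait")
})

test_that("a signal hidden across overlapping studies surfaces only in the bottom line", {
  # one causal variant at sub-genome-wide significance in each of two
  # half-overlapping studies; combined it crosses 5e-8
  found <- 0
  for (seed in c(101, 102, 103)) {
    cfg <- sim_config(seed = seed, n_variants = 2000,
                      block_sizes = rep(4, 500), rho = 0.8,
                      causal_fraction = 1 / 2000, lambda = 0.049,
                      studies = tibble::tibble(n = c(10000, 10000),
                                               ancestry = "EU"),
                      overlap = matrix(c(0, 5000, 5000, 0), 2),
                      rare_fraction = 0)
    st <- simulate_studies(cfg)
    panel <- simulate_ld_panel(cfg)
    truth <- sim_truth(cfg)
    causal_key <- vkey(truth$chrom[truth$causal], truth$pos[truth$causal])
    per_study_p <- vapply(st, function(s)
      s$p[match(causal_key, vkey(s$chrom, s$pos))], numeric(1))
    if (any(per_study_p < 5e-8) || all(per_study_p > 1e-5)) next
    single_clumps <- purrr::map(st, greedy_clump, panel = panel)
    in_single <- any(purrr::map_lgl(single_clumps, function(cl)
      causal_key %in% unlist(cl$members)))
    bundle <- list(trait = "hidden",
                   ancestries = list(EU = list(studies = st, panel = panel)))
    res <- run_bottom_line(bundle,
                           clump = list(p1 = 5e-8, p2 = 5e-6, r2 = 0.01,
                                        kb = 5000, min_clumps = 1),
                           min_null = 100)
    in_bottom <- causal_key %in% unlist(res$clumps$EU$members)
    if (!in_single && in_bottom) found <- found + 1
  }
  expect_gte(found, 1)
})
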