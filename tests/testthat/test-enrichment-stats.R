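test_that("subpool rank enrichment detects members at the top of the ranking", {
  member <- c(rep(TRUE, 5), rep(FALSE, 95))
  expect_lt(mw_subpool_enrichment(member), 0.001)
  # perfectly interleaved equal groups sit near p = 0.5
  inter <- rep(c(TRUE, FALSE), 50)
  expect_gt(mw_subpool_enrichment(inter), 0.4)
  expect_lt(mw_subpool_enrichment(inter), 0.6)
  expect_error(mw_subpool_enrichment(rep(TRUE, 10)), "strict")
  expect_error(mw_subpool_enrichment(rep(FALSE, 10)), "strict")

  # exact enumeration oracle at tiny size
  set.seed(121)
  for (i in 1:8) {
    m <- sample(c(rep(TRUE, 3), rep(FALSE, 7)))
    expect_equal(mw_subpool_enrichment(m), oracle_mw_lower(m),
                 tolerance = 1e-12)
  }

  # ranking by fold values gives the same answer as pre-ranked input
  fold <- c(10, 8, 6, 5, 4, 3, 2, 1)
  memb <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(mw_subpool_enrichment(memb, fold = fold),
               mw_subpool_enrichment(memb))
})

test_that("subpool p-values are near-uniform under random membership", {
  set.seed(131)
  ps <- replicate(300, {
    mw_subpool_enrichment(sample(c(rep(TRUE, 20), rep(FALSE, 40))))
  })
  expect_gt(mean(ps < 0.5), 0.42)
  expect_lt(mean(ps < 0.5), 0.58)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.001)
})

test_that("permutation test follows the add-one rule and is reproducible", {
  ti <- seq_len(50)
  depleted <- ti > 40  # depleted shRNAs hold the top TI ranks
  res <- ti_permutation_test(ti, depleted, n_perm = 999, seed = 4)
  expect_equal(res$p_perm, 1 / 1000)
  expect_equal(length(res$null_w), 999L)

  res2 <- ti_permutation_test(ti, depleted, n_perm = 999, seed = 4)
  expect_identical(res$null_w, res2$null_w)  # bit-for-bit reproducible

  res1 <- ti_permutation_test(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE),
                              n_perm = 1, seed = 9)
  expect_true(res1$p_perm %in% c(0.5, 1))
  expect_error(ti_permutation_test(ti, rep(TRUE, 50)), "non-depleted")
})

test_that("permutation p converges to the analytic Mann-Whitney p without ties", {
  set.seed(141)
  ti <- rnorm(40)
  depleted <- sample(c(rep(TRUE, 15), rep(FALSE, 25)))
  res <- ti_permutation_test(ti, depleted, n_perm = 4000, seed = 17)
  p_exact <- stats::wilcox.test(ti[depleted], ti[!depleted],
                                alternative = "greater")$p.value
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$p_perm - p_exact), 3 * mc_se + 1 / 4001)
})

test_that("the observed W statistic matches wilcox.test", {
  set.seed(151)
  ti <- rnorm(30)
  depleted <- sample(c(rep(TRUE, 10), rep(FALSE, 20)))
  res <- ti_permutation_test(ti, depleted, n_perm = 10, seed = 1)
  w_ref <- unname(stats::wilcox.test(ti[depleted], ti[!depleted])$statistic)
  expect_equal(res$w_observed, w_ref)
})

test_that("Fisher's exact test matches exhaustive fixed-margin enumeration", {
  r <- fisher_seed_downreg(10, 10, 10, 10)
  expect_equal(r$p, 1)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(fisher_seed_downreg(0, 0, 5, 5)$p, 1)
  expect_true(is.na(fisher_seed_downreg(0, 0, 0, 0)$odds_ratio))

  tables <- list(c(9, 1, 1, 9), c(5, 0, 2, 8), c(1, 7, 6, 2),
                 c(12, 3, 4, 11), c(0, 4, 9, 2), c(3, 3, 3, 3))
  for (tb in tables) {
    got <- fisher_seed_downreg(tb[1], tb[2], tb[3], tb[4])$p
    want <- oracle_fisher_two_sided(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("binomial enrichment is the exact upper tail", {
  expect_equal(binomial_enrichment(0, 10, 0.3), 1)
  expect_equal(binomial_enrichment(3, 3, 0.5), 0.125)
  # survival-gene enrichment among downregulated genes: 6 of 11 at 6.6%
  expect_equal(binomial_enrichment(6, 11, 0.066),
               oracle_binom_upper(6, 11, 0.066), tolerance = 1e-12)
  expect_error(binomial_enrichment(5, 3, 0.5), "k <= n")
  expect_error(binomial_enrichment(1, 3, 0), "p0")
})

test_that("GC correlation recovers exact linear relations and flags degeneracies", {
  gc <- c(0, 0.2, 0.4, 0.6, 0.8)
  expect_equal(gc_correlation(gc, 2 * gc + 1)$r, 1)
  expect_equal(gc_correlation(gc, -3 * gc)$r, -1)
  two <- gc_correlation(c(0.1, 0.9), c(5, 1))
  expect_equal(two$r, -1)
  expect_true(is.na(two$p))
  expect_error(gc_correlation(rep(0.5, 5), 1:5), "zero variance")

  set.seed(161)
  ps <- replicate(200, gc_correlation(runif(20), rnorm(20))$p)
  expect_gt(mean(ps < 0.5), 0.4)
  expect_lt(mean(ps < 0.5), 0.6)
})

test_that("landscape is flat for absent words and signs flip with the ranking", {
  set.seed(171)
  rl <- gen_ranked_list(n_genes = 120, planted_word = NULL,
                        utr_len_median = 200, seed = 5)
  # a word that cannot occur: the generator never plants it, so scrub it out
  utrs <- gsub("ACGCGT", "ATTTTT", rl$utrs)
  land <- sylamer_landscape(rl$ranked_ids, utrs, k = 6, step = 40,
                            words = "ACGCGT")
  expect_true(all(land$signed_logp == 0))
  expect_true(all(land$lead_count == 0))

  planted <- gen_ranked_list(n_genes = 100, planted_word = "GTACCA",
                             top_fraction = 0.2, rate_top = 20,
                             rate_rest = 0, utr_len_median = 200, seed = 6)
  fw <- sylamer_landscape(planted$ranked_ids, planted$utrs, k = 6,
                          step = 20, words = "GTACCA")
  rv <- sylamer_landscape(rev(planted$ranked_ids), planted$utrs, k = 6,
                          step = 20, words = "GTACCA")
  expect_gt(fw$signed_logp[1], 0)   # enriched in the leading interval
  expect_lt(rv$signed_logp[1], 0)   # depleted when the ranking is reversed
})

test_that("landscape p-values equal the hypergeometric oracle and counts balance", {
  planted <- gen_ranked_list(n_genes = 100, planted_word = "TGCATG",
                             top_fraction = 0.2, rate_top = 15,
                             rate_rest = 0, utr_len_median = 150, seed = 7)
  land <- sylamer_landscape(planted$ranked_ids, planted$utrs, k = 6,
                            step = 20, words = "TGCATG")
  # independent bookkeeping: recount occurrences per gene with the oracle
  per_gene <- vapply(planted$utrs[planted$ranked_ids], oracle_count,
                     integer(1), word = "TGCATG")
  windows <- pmax(nchar(planted$utrs[planted$ranked_ids]) - 5L, 0L)
  for (j in seq_len(nrow(land))) {
    cut <- land$cutoff_rank[j]
    lead <- sum(per_gene[seq_len(cut)])
    expect_equal(land$lead_count[j], lead)
    expect_equal(land$total_count[j], sum(per_gene))
    # leading + trailing == total at every cutoff
    expect_equal(lead + sum(per_gene[-seq_len(cut)]), sum(per_gene))
  }
  # signed logp at the first cutoff equals the direct tail sum
  j <- 1L
  p_or <- oracle_hyper_upper(land$lead_count[j], land$total_count[j],
                             sum(windows), sum(windows[seq_len(20)]))
  expect_equal(land$signed_logp[j], -log10(p_or), tolerance = 1e-9)
})

test_that("single cutoff covers the whole list when step exceeds it", {
  rl <- gen_ranked_list(n_genes = 30, planted_word = NULL,
                        utr_len_median = 100, seed = 8)
  land <- sylamer_landscape(rl$ranked_ids, rl$utrs, k = 6, step = 200,
                            words = "AAAAAA")
  expect_equal(unique(land$cutoff_rank), 30L)
  # leading set == universe: no enrichment possible
  expect_equal(land$signed_logp, 0)
})
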