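test_that("Welch t matches hand arithmetic and basic symmetries", {
  es <- one_gene_es(normal = c(0, 2), disease = c(3, 5))
  expect_equal(welch_t(es)$score, sqrt(4) * 3 / sqrt(8), tolerance = 1e-12)

  es0 <- one_gene_es(normal = c(1, 2, 3), disease = c(1, 2, 3))
  expect_equal(welch_t(es0)$score, 0)

  # adding a large constant to the disease group flips the sign
  es_neg <- one_gene_es(normal = c(3, 5), disease = c(0, 2))
  expect_equal(welch_t(es_neg)$score, -welch_t(es)$score)
})

test_that("degenerate genes are flagged with a warning, not +-Inf", {
  es <- expr_set(rbind(flat = c(1, 1, 1, 1), ok = c(0, 1, 2, 3)),
                 group = c(0, 0, 1, 1))
  expect_warning(st <- welch_t(es), "degenerate")
  expect_true(st$degenerate[st$gene_id == "flat"])
  expect_true(is.na(st$score[st$gene_id == "flat"]))
  expect_false(any(is.infinite(st$score), na.rm = TRUE))
})

test_that("exact sign-sum reproduces hand enumerations including the H(0)=1 tie", {
  # complete separation
  es <- one_gene_es(normal = c(0.0, 0.1), disease = c(5.0, 6.0))
  expect_equal(sign_sum(es, subsample_scheme(1, 1, "exact"))$score, 1.0)

  # a=2, b=2 on (0,1,2) vs (1,3): single disease subset mean 2 beats all
  es2 <- one_gene_es(normal = c(0, 1, 2), disease = c(1, 3))
  expect_equal(sign_sum(es2, subsample_scheme(2, 2, "exact"))$score, 1.0)

  # disease (0,1): subset mean 0.5 ties the normal subset mean {0.5};
  # H(0)=1 makes the tied pair count, giving exactly 1/3
  es3 <- one_gene_es(normal = c(0, 1, 2), disease = c(0, 1))
  expect_equal(sign_sum(es3, subsample_scheme(2, 2, "exact"))$score, 1 / 3)
})

test_that("a=b=1 exact sign-sum equals the Mann-Whitney pair proportion", {
  set.seed(11)
  normal <- rnorm(20)
  disease <- rnorm(20, mean = 0.8)
  es <- one_gene_es(normal, disease)
  got <- sign_sum(es, subsample_scheme(1, 1, "exact"))$score
  expect_equal(got, pair_sign_proportion(normal, disease), tolerance = 1e-12)
  # scaled by n1*n0 it is the (tie-inclusive) Wilcoxon pair count
  expect_equal(got * 400, sum(outer(disease, normal, `>=`)))
})

test_that("exact sign-sum matches brute-force enumeration at general (a, b)", {
  set.seed(3)
  normal <- rnorm(6)
  disease <- rnorm(5, mean = 0.5)
  for (ab in list(c(1, 2), c(2, 1), c(2, 3), c(3, 2))) {
    es <- one_gene_es(normal, disease)
    got <- sign_sum(es, subsample_scheme(ab[1], ab[2], "exact"))$score
    expect_equal(got, enum_sign_sum(normal, disease, ab[1], ab[2]),
                 tolerance = 1e-12, info = paste(ab, collapse = ","))
  }
})

test_that("sign-sum scores obey range, granularity and symmetry invariants", {
  es <- random_es(p = 15, n0 = 6, n1 = 5, seed = 21, effect = 0.4)
  for (ab in list(c(1, 1), c(2, 2), c(1, 3))) {
    a <- ab[1]; b <- ab[2]
    sc <- sign_sum(es, subsample_scheme(a, b, "exact"))$score
    k1k0 <- choose(5, a) * choose(6, b)
    expect_true(all(sc >= 0 & sc <= 1))
    # exact scores are multiples of 1/(k1*k0)
    expect_equal(sc * k1k0, round(sc * k1k0), tolerance = 1e-9)

    # label-swap antisymmetry on tie-free data: swap groups and a<->b
    es_swap <- expr_set(es$values, 1L - es$group, es$gene_ids)
    sc_swap <- sign_sum(es_swap, subsample_scheme(b, a, "exact"))$score
    expect_equal(sc_swap, 1 - sc, tolerance = 1e-12)
  }
})

test_that("raising the disease group never decreases the exact sign-sum", {
  es <- random_es(p = 12, n0 = 5, n1 = 5, seed = 5)
  v2 <- es$values
  v2[, es$group == 1L] <- v2[, es$group == 1L] + 0.3
  es2 <- expr_set(v2, es$group, es$gene_ids)
  for (ab in list(c(1, 1), c(2, 3))) {
    s1 <- sign_sum(es, subsample_scheme(ab[1], ab[2], "exact"))$score
    s2 <- sign_sum(es2, subsample_scheme(ab[1], ab[2], "exact"))$score
    expect_true(all(s2 >= s1 - 1e-12))
  }
})

test_that("exact subsample t is the sqrt((a+b)/n) multiple of Welch t", {
  es <- random_es(p = 25, n0 = 7, n1 = 6, seed = 9, effect = 0.5)
  tt <- welch_t(es)$score
  n <- 13
  for (ab in list(c(1, 1), c(2, 2), c(3, 1))) {
    ut <- subsample_t(es, subsample_scheme(ab[1], ab[2], "exact"))$score
    expect_equal(ut, sqrt(sum(ab) / n) * tt, tolerance = 1e-10)
    # hence identical rankings
    expect_identical(order(-ut), order(-tt))
  }
  # degenerate enumeration a=n1, b=n0 recovers Welch t exactly
  ut_full <- subsample_t(es, subsample_scheme(6, 7, "exact"))$score
  expect_equal(ut_full, tt, tolerance = 1e-10)
})

test_that("scheme validation rejects impossible or oversized designs", {
  es <- random_es(p = 2, n0 = 4, n1 = 3, seed = 2)
  expect_error(sign_sum(es, subsample_scheme(4, 1, "exact")), "exceeds")
  expect_error(sign_sum(es, subsample_scheme(1, 5, "exact")), "exceeds")
  expect_error(
    sign_sum(es, subsample_scheme(2, 2, "exact", exact_ceiling = 10)),
    "monte_carlo")
})

test_that("Monte-Carlo estimates converge to the exact value with stderr coverage", {
  es <- random_es(p = 200, n0 = 10, n1 = 10, seed = 31, effect = 0.5)
  exact22 <- sign_sum(es, subsample_scheme(2, 2, "exact"))$score
  mc22 <- sign_sum(es, subsample_scheme(2, 2, "monte_carlo",
                                        n_draws = 4000, seed = 8))
  expect_true(mean(abs(mc22$score - exact22) <= 4 * mc22$mc_stderr) >= 0.95)

  # structured a = 1 sampling: same contract
  exact13 <- sign_sum(es, subsample_scheme(1, 3, "exact"))$score
  mc13 <- sign_sum(es, subsample_scheme(1, 3, "monte_carlo",
                                        n_draws = 4000, seed = 9))
  expect_true(mean(abs(mc13$score - exact13) <= 4 * mc13$mc_stderr) >= 0.95)

  # subsample t as well, on a 6+6 fixture with a large draw budget
  es6 <- random_es(p = 30, n0 = 6, n1 = 6, seed = 13, effect = 0.5)
  exact_t <- subsample_t(es6, subsample_scheme(2, 2, "exact"))$score
  mc_t <- subsample_t(es6, subsample_scheme(2, 2, "monte_carlo",
                                            n_draws = 20000, seed = 3))
  expect_true(mean(abs(mc_t$score - exact_t) <= 4 * mc_t$mc_stderr) >= 0.95)
  expect_equal(mc_t$score, exact_t, tolerance = 0.05)
})

test_that("Monte-Carlo scores are deterministic given the seed and gene-stable", {
  es <- random_es(p = 40, n0 = 8, n1 = 8, seed = 17, effect = 0.3)
  sch <- subsample_scheme(1, 4, "monte_carlo", n_draws = 2000, seed = 99)
  expect_identical(sign_sum(es, sch)$score, sign_sum(es, sch)$score)

  # per-gene streams: gene 7 scored inside the full matrix equals gene 7
  # scored in a reordered/smaller matrix only if streams follow gene index;
  # scoring the identical matrix with extra genes appended must not change
  # the leading genes' scores
  es_more <- random_es(p = 40, n0 = 8, n1 = 8, seed = 17, effect = 0.3)
  extra <- random_es(p = 5, n0 = 8, n1 = 8, seed = 1)
  es_big <- expr_set(rbind(es_more$values, extra$values),
                     es$group,
                     c(es$gene_ids, paste0("x", 1:5)))
  expect_identical(sign_sum(es_big, sch)$score[1:40], sign_sum(es, sch)$score)
})

test_that("top-k stability batching stops and preserves the contract", {
  es <- random_es(p = 50, n0 = 10, n1 = 10, seed = 23, effect = 0.6)
  sch <- subsample_scheme(1, 5, "monte_carlo", n_draws = 1000, seed = 4,
                          convergence = list(k = 10, tol = 0))
  st <- sign_sum(es, sch)
  expect_true(all(st$score >= 0 & st$score <= 1))
  expect_true(all(st$mc_stderr >= 0))
  expect_identical(st$score, sign_sum(es, sch)$score)

  sch_d <- subsample_scheme(1, 5, "monte_carlo", n_draws = 1000, seed = 4,
                            convergence = list(k = 10, tol = 1, double = TRUE))
  st_d <- sign_sum(es, sch_d)
  exact <- sign_sum(es, subsample_scheme(1, 5, "exact"))$score
  expect_equal(st_d$score, exact, tolerance = 0.08)
})

test_that("rank_genes sorts descending with deterministic tie-breaking", {
  st <- welch_t(random_es(p = 3, seed = 2, effect = 1))
  st$score <- c(0.1, 0.9, 0.5)
  st$full_t <- st$score
  r <- rank_genes(st, "signed")
  expect_identical(r$gene_id, c("gene2", "gene3", "gene1"))
  expect_identical(r$rank, 1:3)

  # tied scores fall back to |full t|, then gene id
  st2 <- st
  st2$score <- c(0.5, 0.5, 0.5)
  st2$full_t <- c(2, -3, 2)
  r2 <- rank_genes(st2, "signed")
  expect_identical(r2$gene_id, c("gene2", "gene1", "gene3"))
})

test_that("oriented ranking is invariant under reflecting a gene's values", {
  es <- random_es(p = 10, n0 = 8, n1 = 8, seed = 41, effect = 0.7)
  ranked <- rank_genes(sign_sum(es, subsample_scheme(1, 2, "exact")),
                       "oriented_by_full_t")
  v <- es$values
  v[4, ] <- -v[4, ]  # reflect gene 4 entirely
  es_refl <- expr_set(v, es$group, es$gene_ids)
  ranked_refl <- rank_genes(sign_sum(es_refl, subsample_scheme(1, 2, "exact")),
                            "oriented_by_full_t")
  expect_identical(ranked$gene_id, ranked_refl$gene_id)
  expect_equal(ranked$score, ranked_refl$score, tolerance = 1e-12)
})

test_that("orient_by_full_t flips exactly the negative-t genes", {
  es <- random_es(p = 20, n0 = 6, n1 = 6, seed = 19)
  or <- orient_by_full_t(es)
  expect_true(all(welch_t(or)$score >= 0))
  flipped <- attr(or, "flipped")
  expect_identical(or$values[flipped, ], -es$values[flipped, ])
  expect_identical(or$values[!flipped, ], es$values[!flipped, ])
})
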