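test_that("align_components recovers constructed permutations and flips", {
  set.seed(1)
  ref <- matrix(rnorm(52), 26, 2)
  cand <- ref[, 2:1]
  cand[, 1] <- -cand[, 1]
  a <- align_components(ref, cand)
  expect_equal(a$order, c(2L, 1L))
  expect_equal(a$signs, c(1, -1))
  expect_lt(max(abs(a$aligned - ref)), 1e-12)
  # identity
  b <- align_components(ref, ref)
  expect_equal(b$order, 1:2)
  expect_equal(b$signs, c(1, 1))
  expect_false(b$failed)
})

test_that("alignment succeeds under moderate perturbation, flags total failure", {
  ok <- vapply(1:100, function(i) {
    set.seed(i)
    ref <- qr.Q(qr(matrix(rnorm(26 * 2), 26, 2)))
    noise <- qr.Q(qr(matrix(rnorm(26 * 4), 26, 4)))[, 3:4]
    cand <- 0.9 * ref + sqrt(1 - 0.81) * noise        # congruence ~0.9
    a <- align_components(ref, cand)
    identical(a$order, 1:2) && all(a$signs == 1)
  }, logical(1))
  expect_equal(mean(ok), 1)
  # orthogonal candidate: all congruences ~0 -> failure flag, identity map
  set.seed(7)
  ref <- qr.Q(qr(matrix(rnorm(26 * 2), 26, 2)))
  cand <- qr.Q(qr(cbind(ref, matrix(rnorm(26 * 2), 26, 2))))[, 3:4]
  a <- align_components(ref, cand)
  expect_true(a$failed)
  expect_equal(a$order, 1:2)
})

test_that("percentile p-values follow the continuity-corrected sign-crossing rule", {
  # all replicates strictly positive -> p = 2/(B+1)
  expect_equal(loading_pvalue(rep(0.4, 999), 0.4), 2 / 1000)
  # symmetric replicates -> p ~ 1
  set.seed(2)
  expect_gt(loading_pvalue(rnorm(1000), 0.01), 0.9)
  # never zero, capped at 1
  expect_gt(loading_pvalue(rep(1, 5000), 1), 0)
  expect_lte(loading_pvalue(rnorm(501), 0), 1)
  expect_error(loading_pvalue(rnorm(50), 0.1), "B >= 100")
})

test_that("percentile and normal p-values agree where the normal tail is moderate", {
  set.seed(3)
  r <- rnorm(10000, mean = 0.2, sd = 0.1)
  pp <- loading_pvalue(r, 0.2, "percentile")
  pn <- loading_pvalue(r, 0.2, "normal")
  expect_lt(max(pp / pn, pn / pp), 2)
  # deep in the tail the percentile p floors at 2/(B+1)
  r2 <- rnorm(10000, mean = 0.5, sd = 0.1)
  expect_equal(loading_pvalue(r2, 0.5, "percentile"), 2 / 10001,
               tolerance = 1e-3)
  expect_error(loading_pvalue(rep(0.2, 200), 0.2, "normal"), "degenerate")
})

test_that("Benjamini-Hochberg step-up matches hand-computed rejections", {
  r <- benjamini_hochberg(rep(0.01, 4), q = 0.05)
  expect_true(all(r$reject))
  r <- benjamini_hochberg(c(0.01, 0.02, 0.2, 0.8), q = 0.05)
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.8 / 3, 0.8), tolerance = 1e-12)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  r <- benjamini_hochberg(1.0)
  expect_equal(r$p_adjusted, 1)
  expect_false(r$reject)
  expect_length(benjamini_hochberg(numeric())$p_adjusted, 0L)
})

test_that("Bonferroni scales by family size and caps at 1", {
  expect_equal(bonferroni(0.01), 0.01)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  # at the interaction family size m = 24
  expect_equal(bonferroni(rep(1e-4, 24))[1], 0.0024)
  expect_equal(bonferroni(c(0.5, 0.9)), c(1, 1))
})

test_that("adjustments are permutation equivariant and BH dominates Bonferroni", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))^2
    perm <- sample(seq_along(p))
    expect_equal(benjamini_hochberg(p)$p_adjusted[perm],
                 benjamini_hochberg(p[perm])$p_adjusted)
    # Bonferroni never rejects what BH does not
    bh <- benjamini_hochberg(p, q = 0.05)$reject
    bf <- bonferroni(p) <= 0.05
    expect_true(all(!bf | bh))
  }
})

test_that("bootstrap is deterministic and default-configured as documented", {
  expect_equal(eval(formals(bootstrap_cpca)$B), 1000)
  cohort <- small_cohort(n = 57, seed = 30)
  b1 <- suppressWarnings(bootstrap_cpca(cohort, B = 120, seed = 5))
  b2 <- suppressWarnings(bootstrap_cpca(cohort, B = 120, seed = 5))
  expect_equal(b1$tbl, b2$tbl)
  b3 <- suppressWarnings(bootstrap_cpca(cohort, B = 120, seed = 6))
  expect_false(identical(b1$tbl$conf.low, b3$tbl$conf.low))
})

test_that("point estimates do not depend on B; intervals bracket them", {
  cohort <- small_cohort(n = 57, seed = 31)
  b1 <- suppressWarnings(bootstrap_cpca(cohort, B = 120, seed = 5))
  b2 <- suppressWarnings(bootstrap_cpca(cohort, B = 160, seed = 5))
  expect_identical(b1$tbl$estimate, b2$tbl$estimate)
  inside <- with(b1$tbl, mean(conf.low <= estimate & estimate <= conf.high))
  expect_gte(inside, 0.9)
  expect_true(all(b1$tbl$p.value > 0 & b1$tbl$p.value <= 1))
})

test_that("bootstrap output covers every reported loading family", {
  cohort <- small_cohort(n = 57, seed = 32)
  b <- suppressWarnings(bootstrap_cpca(cohort, B = 120, seed = 1))
  counts <- table(b$tbl$family)
  expect_equal(as.vector(counts[c("regions", "predictors_main",
                                  "predictors_interaction")]),
               c(26L * 3L, 11L * 2L, 24L))
  expect_equal(glance(b)$n_loadings, 26L * 3L + 22L + 24L)
})
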