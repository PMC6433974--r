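test_that("hat_project matches a brute-force normal-equations oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 3), 20, 3)
    Y <- matrix(rnorm(20 * 4), 20, 4)
    oracle <- X %*% solve(crossprod(X), crossprod(X, Y))
    expect_lt(max(abs(hat_project(Y, X) - oracle)), 1e-8)
  }
})

test_that("hat_project handles span membership, intercepts and degeneracy", {
  set.seed(1)
  X <- matrix(rnorm(30 * 3), 30, 3)
  Y <- X %*% matrix(rnorm(6), 3, 2)     # Y already in span(X)
  expect_lt(max(abs(hat_project(Y, X) - Y)), 1e-10)
  # constant column: projection returns column means
  Y2 <- matrix(rnorm(60), 30, 2)
  fitted <- hat_project(Y2, matrix(1, 30, 1))
  expect_equal(fitted, matrix(colMeans(Y2), 30, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # N <= rank(X) is overdetermined
  expect_error(hat_project(matrix(rnorm(5), 5, 1), diag(5)), "overdetermined")
  # rank deficiency warns and still projects
  Xr <- cbind(X, X[, 1] + X[, 2])
  expect_warning(f <- hat_project(Y2, Xr), "rank-deficient")
  expect_lt(max(abs(f - hat_project(Y2, X))), 1e-8)
})

test_that("design matrices have the documented shapes and construction", {
  cohort <- quiet_sim(seed = 20)$cohort
  d <- build_design(cohort)
  expect_equal(dim(d$Z), c(57L, 26L))
  expect_equal(dim(d$X_main), c(57L, 11L))
  expect_equal(dim(d$X_int), c(57L, 24L))
  expect_identical(colnames(d$X_int), interaction_names())
  # interaction column is the re-standardized product of its parents
  codes <- encode_genotypes(cohort)
  invp <- standardize(as.matrix(cohort["invasive_procedures"]))
  prod <- standardize(cbind(x = invp[, 1] * codes[, "comt"]))
  expect_equal(unname(d$X_int[, "Invasive procedures x COMT"]),
               unname(prod[, 1]), tolerance = 1e-12)
  # constant predictor is a degenerate design
  bad <- cohort; bad$infection <- 0
  expect_error(build_design(bad), "degenerate")
})

test_that("complete-case filtering logs the excluded subjects", {
  cohort <- quiet_sim(seed = 21)$cohort
  cohort$snap2[4] <- NA
  d <- build_design(cohort)
  expect_equal(nrow(d$Z), 56L)
  expect_identical(d$excluded, cohort$subject_id[4])
})

test_that("external analysis conserves and orthogonally partitions variance", {
  for (seed in c(1, 5, 9)) {
    d <- build_design(quiet_sim(seed = seed)$cohort)
    parts <- suppressWarnings(external_analysis(d))
    expect_lt(max(abs(parts$M1 + parts$M2 + parts$E - d$Z)), 1e-8)
    lhs <- sum(d$Z^2)
    rhs <- sum(parts$M1^2) + sum(parts$M2^2) + sum(parts$E^2)
    expect_equal(rhs / lhs, 1, tolerance = 1e-8)
    # planted-null interaction: M2 nearly empty relative to M1
    expect_lt(sum(crossprod(parts$M1, parts$M2)^2), 1e-10 * sum(d$Z^2)^2)
  }
})

test_that("noise-free null interaction yields a vanishing interaction space", {
  sim <- quiet_sim(n_subjects = 120, seed = 3, interaction_scale = 0,
                   noise_sd = 0.02)
  d <- build_design(sim$cohort)
  parts <- suppressWarnings(external_analysis(d))
  # only overfitting of the two noise-only region columns remains
  expect_lt(sum(parts$M2^2) / sum(d$Z^2), 0.05)
})

test_that("internal analysis matches an eigendecomposition oracle", {
  set.seed(4)
  M <- scale(matrix(rnorm(50), 10, 5), scale = FALSE)
  sol <- internal_analysis(M, 5)
  ev <- eigen(crossprod(M), symmetric = TRUE)$values
  expect_equal(sol$singular_values, sqrt(ev[1:5]), tolerance = 1e-8)
  # scores mutually orthogonal
  g <- crossprod(sol$scores)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  # rank-1 input: first component explains everything
  M1 <- tcrossprod(rnorm(10), rnorm(5))
  s1 <- internal_analysis(M1, 1)
  expect_equal(s1$singular_values[1]^2, sum(M1^2), tolerance = 1e-10)
  expect_error(internal_analysis(M1, 3), "rank")
})

test_that("loadings are correlations: self-correlation 1, bounded in [-1, 1]", {
  set.seed(5)
  Z <- standardize(matrix(rnorm(200), 20, 10))
  expect_equal(unname(component_loadings(Z[, 1, drop = FALSE], Z)[1, 1]), 1)
  scores <- matrix(rnorm(40), 20, 2)
  L <- component_loadings(scores, Z)
  expect_true(all(abs(L) <= 1))
  expect_error(component_loadings(matrix(0, 20, 1), Z), "degenerate")
  # predictor loading of a predictor equal to a score vector is 1
  expect_equal(unname(predictor_loadings(scores[, 1, drop = FALSE],
                                         scores[, 1, drop = FALSE])[1, 1]), 1)
})

test_that("the default fit retains 2 main + 1 interaction component", {
  fit <- suppressWarnings(cpca(quiet_sim(seed = 22)$cohort))
  expect_identical(colnames(fit$scores), c("PC1", "PC2", "PC NCFxG"))
  expect_equal(dim(fit$region_loadings), c(26L, 3L))
  expect_equal(dim(fit$predictor_loadings_main), c(11L, 2L))
  expect_equal(dim(fit$predictor_loadings_int), c(24L, 1L))
  # sign convention: region loadings sum non-positive per component
  expect_true(all(colSums(fit$region_loadings) <= 1e-12))
})

test_that("main and interaction component scores are orthogonal", {
  for (seed in c(2, 12)) {
    fit <- suppressWarnings(cpca(quiet_sim(seed = seed)$cohort))
    cc <- stats::cor(fit$scores)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  }
})

test_that("variance table satisfies its arithmetic identities", {
  fit <- suppressWarnings(cpca(quiet_sim(seed = 23)$cohort))
  v <- fit$variance
  total <- v$variance[v$component == "overall"][1]
  expect_equal(total, 26 * 57 / 56, tolerance = 1e-10)
  expect_equal(v$pct_variance, 100 * v$variance / total, tolerance = 1e-10)
  expect_equal(v$pct_explained, 100 * v$explained_variance / total,
               tolerance = 1e-10)
  # combined = sum of per-component rows
  main_pc <- v[v$block == "main" & grepl("^PC", v$component), ]
  comb <- v[v$block == "main" & v$component == "combined", ]
  expect_equal(comb$variance, sum(main_pc$variance), tolerance = 1e-10)
  expect_equal(comb$explained_variance, sum(main_pc$explained_variance),
               tolerance = 1e-10)
  # explained never exceeds the variance along the component
  expect_true(all(v$explained_variance <= v$variance + 1e-10))
  # block-explained variances and the residual add up to the total
  resid <- sum(fit$E^2) / (nrow(fit$E) - 1)
  expl <- v$explained_variance[v$component == "overall"]
  expect_equal(sum(expl) + resid, total, tolerance = 1e-8)
})

test_that("results are invariant to a global rescaling of raw volumes", {
  cohort <- quiet_sim(seed = 24)$cohort
  f1 <- suppressWarnings(cpca(cohort))
  scaled <- cohort
  vcols <- c("tbv_mm3", region_columns())
  scaled[vcols] <- scaled[vcols] / 1000     # mm^3 -> cm^3
  f2 <- suppressWarnings(cpca(scaled))
  expect_equal(f1$region_loadings, f2$region_loadings, tolerance = 1e-10)
  expect_equal(f1$variance$pct_explained, f2$variance$pct_explained,
               tolerance = 1e-10)
})

test_that("the lean bootstrap path agrees with the reference pipeline", {
  cohort <- quiet_sim(seed = 25)$cohort
  fit <- suppressWarnings(cpca(cohort))
  m <- cpcage:::core_matrices(cohort)
  core <- cpcage:::cpca_core(m$clinical, m$codes, m$vols)
  expect_lt(max(abs(core$region - unname(fit$region_loadings))), 1e-10)
  expect_lt(max(abs(core$pred_main - unname(fit$predictor_loadings_main))), 1e-10)
  expect_lt(max(abs(core$pred_int - unname(fit$predictor_loadings_int))), 1e-10)
})

test_that("simultaneous entry still sums to Z but drops orthogonality guarantees", {
  d <- build_design(quiet_sim(seed = 26)$cohort)
  parts <- suppressWarnings(external_analysis(d, entry = "simultaneous"))
  expect_lt(max(abs(parts$M1 + parts$M2 + parts$E - d$Z)), 1e-8)
})
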