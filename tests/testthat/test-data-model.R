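test_that("region schema has 26 uniquely decomposable columns in fixed order", {
  rs <- region_schema()
  expect_equal(nrow(rs), 26L)
  expect_equal(sum(rs$hemisphere == "L"), 13L)
  expect_false(anyDuplicated(rs$column) > 0)
  expect_identical(rs$column, paste0(rs$hemisphere, "_", rs$structure))
  # canonical order is stable: left block then right block
  expect_identical(region_columns()[1], "L_CA1")
  expect_identical(region_columns()[26], "R_thalamus")
})

test_that("cohort CSV round-trips exactly", {
  cohort <- small_cohort(n = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_equal(back, cohort)
})

test_that("reading a file without a region column names the column", {
  cohort <- small_cohort(n = 12, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort[setdiff(names(cohort), "R_thalamus")], path)
  expect_error(read_cohort(path), "R_thalamus")
})

test_that("invalid genotype categories are rejected with subject and gene", {
  cohort <- small_cohort(n = 12, seed = 3)
  cohort$comt[2] <- "Val/Ala"
  err <- expect_error(validate_cohort(cohort), "comt")
  expect_match(conditionMessage(err), cohort$subject_id[2])
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path)
  expect_error(read_cohort(path), "comt")
})

test_that("validation enforces ranges, counts and positivity", {
  cohort <- small_cohort(n = 12, seed = 4)
  bad <- cohort; bad$ga_weeks[1] <- 40
  expect_error(validate_cohort(bad), "ga_weeks")
  bad <- cohort; bad$surgeries[3] <- -1
  expect_error(validate_cohort(bad), "surgeries")
  bad <- cohort; bad$L_CA1[5] <- 0
  expect_error(validate_cohort(bad), "L_CA1")
  # missing values are preserved, not rejected
  cohort$wisc_vci[1] <- NA
  expect_silent(validate_cohort(cohort))
})

test_that("genotype coding follows the reference-category convention", {
  gf <- geno_frame(
    bdnf = c("Val/Val", "Val/Met", "Met/Met", "Val/Met+Met/Met"),
    slc6a4 = c("L/L", "L/S", "S/S", "L/S+S/S"),
    comt = c("Val/Val", "Val/Met", "Met/Met", "Val/Met+Met/Met")
  )
  # default: carrier for BDNF/SLC6A4, recessive for COMT
  codes <- encode_genotypes(gf)
  expect_equal(unname(codes[, "bdnf"]), c(0, 1, 1, 1))
  expect_equal(unname(codes[, "slc6a4"]), c(0, 1, 1, 1))
  expect_equal(unname(codes[, "comt"]), c(0, 0, 1, 0))
  # recessive and additive schemes
  rec <- encode_genotypes(gf[1:3, ], c(bdnf = "recessive", slc6a4 = "recessive",
                                       comt = "recessive"))
  expect_equal(unname(rec[, "comt"]), c(0, 0, 1))
  add <- encode_genotypes(gf[1:3, ], c(bdnf = "additive", slc6a4 = "additive",
                                       comt = "additive"))
  expect_equal(unname(add[, "comt"]), c(0, 1, 2))
  # grouped category cannot be coded additively
  expect_error(
    encode_genotypes(gf, c(bdnf = "additive", slc6a4 = "carrier",
                           comt = "recessive")),
    "grouped"
  )
  # totality: codes never leave the declared sets
  cohort <- small_cohort(n = 60, seed = 5)
  expect_true(all(encode_genotypes(cohort) %in% c(0, 1)))
})

test_that("standardization matches the population-SD convention", {
  z <- standardize(cbind(x = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  zs <- standardize(cbind(x = c(1, 2, 3)),
                    standardization_convention("sample"))
  expect_equal(stats::sd(zs[, 1]), 1)
})

test_that("standardize is idempotent and rejects constant columns", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  z1 <- standardize(x)
  z2 <- standardize(z1)
  expect_lt(max(abs(z2 - z1)), 1e-10)
  x[, 2] <- 7
  expect_error(standardize(x), "b")
})

test_that("population-N scaling gives total variance p*N/(N-1) for any input", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:80, 1); p <- sample(3:30, 1)
    z <- standardize(matrix(rnorm(n * p) * 10 + 5, n, p))
    expect_equal(sum(apply(z, 2, stats::var)), p * n / (n - 1), tolerance = 1e-10)
  }
})

test_that("stored standardization parameters reproduce the transform", {
  set.seed(2)
  x <- matrix(rexp(80), 20, 4)
  z <- standardize(x)
  expect_equal(standardize_with(x, z), unclass(z)[, ], ignore_attr = TRUE)
})

test_that("write_tables rounds, round-trips and is bit-stable", {
  tbl <- tibble::tibble(term = c("a", "b"), loading = c(0.123456, -0.98765),
                        p = c(0.01234567, 0.9999))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tables(tbl, p1, digits = 3)
  write_tables(tbl, p2, digits = 3)
  expect_identical(readLines(p1), readLines(p2))
  back <- readr::read_csv(p1, show_col_types = FALSE)
  expect_equal(back$loading, round(tbl$loading, 3))
  expect_equal(back$p, round(tbl$p, 4))
  # empty table -> header-only CSV
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_tables(tbl[0, ], p3)
  expect_length(readLines(p3), 1L)
})
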