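#' Validate a cohort table
#'
#' Checks a subject-level cohort table against the data model: all expected
#' columns present, one row per subject, gestational age within 22--34 weeks,
#' non-negative counts and doses, genotype categories drawn from the allowed
#' sets, and strictly positive volumes. Missing values (`NA`) are allowed and
#' preserved; they are never silently replaced.
#'
#' @param cohort A data frame with the cohort columns (see [region_schema()],
#'   [clinical_predictors()], [outcome_measures()]).
#' @return The validated cohort as a tibble, with columns in canonical order.
#'   Invalid rows raise an error naming the subject and the failing field.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  expected <- cohort_columns()
  missing_cols <- setdiff(expected, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- cohort[expected]
  if (anyDuplicated(cohort$subject_id)) {
    stop("duplicated subject_id: ",
         paste(unique(cohort$subject_id[duplicated(cohort$subject_id)]),
               collapse = ", "), call. = FALSE)
  }

  fail <- function(rows, field, why) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      stop(sprintf("invalid %s for subject(s) %s: %s", field,
                   paste(cohort$subject_id[idx], collapse = ", "), why),
           call. = FALSE)
    }
  }

  fail(cohort$ga_weeks < 22 | cohort$ga_weeks > 34, "ga_weeks",
       "gestational age must lie in [22, 34] weeks")
  fail(!cohort$infection %in% c(0, 1, NA), "infection", "must be 0/1")
  for (cnt in c("invasive_procedures", "surgeries", "ventilation_days")) {
    fail(cohort[[cnt]] < 0 | cohort[[cnt]] != round(cohort[[cnt]]), cnt,
         "must be a non-negative integer count")
  }
  fail(cohort$snap2 < 0, "snap2", "must be non-negative")
  fail(cohort$morphine_mg_per_kg < 0, "morphine_mg_per_kg", "must be non-negative")

  lv <- genotype_levels()
  for (g in names(lv)) {
    bad <- !is.na(cohort[[g]]) & !cohort[[g]] %in% lv[[g]]
    fail(bad, g, paste0("category must be one of {",
                        paste(lv[[g]], collapse = ", "), "}"))
  }

  for (v in c("tbv_mm3", region_columns())) {
    fail(cohort[[v]] <= 0, v, "volumes must be strictly positive")
  }
  cohort
}

#' Read a cohort CSV
#'
#' Reads a UTF-8, comma-delimited cohort file with a header row and `NA` for
#' missing cells, then validates it with [validate_cohort()].
#'
#' @param path Path to the cohort CSV.
#' @param schema Region schema; defaults to [region_schema()]. Used to check
#'   that all 26 region columns are present.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema = region_schema()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  missing_regions <- setdiff(region_columns(schema), names(raw))
  if (length(missing_regions) > 0L) {
    stop("cohort file lacks region column(s): ",
         paste(missing_regions, collapse = ", "), call. = FALSE)
  }
  validate_cohort(raw)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: full precision, canonical column order, `NA`
#' for missing cells, so that read-after-write reproduces the table exactly.
#'
#' @param cohort A validated cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Encode genotype categories as numeric columns
#'
#' Minor alleles are coded 1 and major alleles 0, with the homozygous-major
#' genotype as reference. Three schemes per gene: `"carrier"` (any
#' minor-allele carrier is 1), `"recessive"` (homozygous-minor is 1),
#' `"additive"` (minor-allele count 0/1/2). The package default mirrors the
#' grouped presentation of the genotype table: carrier coding for BDNF and
#' SLC6A4, recessive coding for COMT (Met/Met against the rest).
#'
#' @param cohort A validated cohort tibble.
#' @param scheme Named character vector of coding schemes per gene; any of
#'   `"carrier"`, `"recessive"`, `"additive"`.
#' @return A numeric matrix with `nrow(cohort)` rows and columns
#'   `bdnf`, `slc6a4`, `comt`.
#' @examples
#' cohort <- simulate_cohort(sim_params(seed = 1))$cohort
#' head(encode_genotypes(cohort))
#' @export
encode_genotypes <- function(cohort,
                             scheme = c(bdnf = "carrier", slc6a4 = "carrier",
                                        comt = "recessive")) {
  genes <- c("bdnf", "slc6a4", "comt")
  stopifnot(all(genes %in% names(scheme)))
  hom_major <- c(bdnf = "Val/Val", slc6a4 = "L/L", comt = "Val/Val")
  het       <- c(bdnf = "Val/Met", slc6a4 = "L/S", comt = "Val/Met")
  hom_minor <- c(bdnf = "Met/Met", slc6a4 = "S/S", comt = "Met/Met")
  grouped   <- c(bdnf = "Val/Met+Met/Met", slc6a4 = "L/S+S/S",
                 comt = "Val/Met+Met/Met")

  out <- matrix(NA_real_, nrow(cohort), length(genes),
                dimnames = list(NULL, genes))
  for (g in genes) {
    sch <- match.arg(scheme[[g]], c("carrier", "recessive", "additive"))
    x <- cohort[[g]]
    if (sch == "additive" && any(x == grouped[[g]], na.rm = TRUE)) {
      stop(sprintf(
        "additive coding of %s impossible: grouped category '%s' present",
        g, grouped[[g]]), call. = FALSE)
    }
    code <- switch(sch,
      carrier = ifelse(x == hom_major[[g]], 0, 1),
      recessive = ifelse(x == hom_minor[[g]], 1, 0),
      additive = dplyr::case_when(
        x == hom_major[[g]] ~ 0, x == het[[g]] ~ 1, x == hom_minor[[g]] ~ 2
      )
    )
    out[, g] <- as.numeric(code)
  }
  out
}

#' Standardization convention
#'
#' The scaling step can divide by the population standard deviation
#' (denominator N) or the sample standard deviation (denominator N-1);
#' variance accounting downstream always uses N-1. Under the default
#' population-N scaling, a p-column standardized matrix has total variance
#' p*N/(N-1) — for 26 regions and 57 subjects, 26.46.
#'
#' @param scale_denominator `"population"` (divide by the N-denominator SD,
#'   the default) or `"sample"` (N-1).
#' @return An object of class `standardization_convention`.
#' @export
standardization_convention <- function(scale_denominator = c("population", "sample")) {
  structure(
    list(scale_denominator = match.arg(scale_denominator),
         variance_denominator = "sample"),
    class = "standardization_convention"
  )
}

#' @export
print.standardization_convention <- function(x, ...) {
  cat("Standardization convention: scale by", x$scale_denominator,
      "SD; variance accounted with N-1\n")
  invisible(x)
}

#' Column-standardize a matrix
#'
#' Centers every column to mean zero and scales to unit spread under the
#' chosen denominator convention. The centers and scales are attached as
#' attributes so the same transformation can be re-applied to resampled or
#' new data via [standardize_with()].
#'
#' @param x A numeric matrix (N x p), N >= 3.
#' @param convention A [standardization_convention()].
#' @return The standardized matrix with attributes `center`, `scale` and
#'   `convention`.
#' @examples
#' standardize(cbind(a = c(1, 2, 3)))
#' @export
standardize <- function(x, convention = standardization_convention()) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("standardize needs N >= 3 rows", call. = FALSE)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  ss <- colSums(xc^2)
  denom <- if (convention$scale_denominator == "population") nrow(x) else nrow(x) - 1L
  scl <- sqrt(ss / denom)
  degenerate <- scl <= sqrt(.Machine$double.eps) * (abs(ctr) + 1)
  if (any(degenerate)) {
    nm <- colnames(x)[degenerate]
    if (is.null(nm)) nm <- which(degenerate)
    stop("constant (degenerate) column(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  out <- sweep(xc, 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "convention") <- convention
  out
}

#' Re-apply a stored standardization
#'
#' @param x New data with the same columns as the matrix `params` came from.
#' @param params A matrix previously returned by [standardize()] (its
#'   `center`/`scale` attributes are reused), or a list with `center` and
#'   `scale` elements.
#' @return The transformed matrix.
#' @export
standardize_with <- function(x, params) {
  ctr <- attr(params, "center") %||% params$center
  scl <- attr(params, "scale") %||% params$scale
  sweep(sweep(as.matrix(x), 2L, ctr), 2L, scl, "/")
}

#' Write a report table to CSV
#'
#' Rounds numeric columns for presentation (default 2 decimals; columns whose
#' names contain `"p"` followed by nothing or `.value`/`_value`, and any
#' column listed in `p_cols`, get `p_digits`) and writes a header CSV that is
#' bit-stable across reruns with the same input.
#'
#' @param result A data frame (e.g. a variance, loading or correlation table).
#' @param path Output path.
#' @param digits Decimals for ordinary numeric columns (default 2).
#' @param p_digits Decimals for p-value-like columns (default 4).
#' @param p_cols Extra column names to round as p-values.
#' @return `path`, invisibly.
#' @export
write_tables <- function(result, path, digits = 2, p_digits = 4,
                         p_cols = character()) {
  result <- tibble::as_tibble(result)
  is_p <- function(nm) {
    nm %in% p_cols | grepl("^(p|p\\.value|p_value|p\\.bh|p_bh|p\\.bonferroni|p_bonferroni|fdr)$",
                           nm, ignore.case = TRUE)
  }
  rounded <- purrr::imap(result, function(col, nm) {
    if (is.numeric(col)) round(col, if (is_p(nm)) p_digits else digits) else col
  })
  readr::write_csv(tibble::as_tibble(rounded), path, na = "NA", progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
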