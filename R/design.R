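#' Names of the 24 interaction design columns
#'
#' Predictor-major, gene-minor order: each of the 8 clinical predictors
#' (including total brain volume) crossed with BDNF, SLC6A4 and COMT.
#'
#' @return Character vector of length 24.
#' @export
interaction_names <- function() {
  preds <- names(clinical_predictors())
  genes <- c("BDNF", "SLC6A4", "COMT")
  as.vector(t(outer(preds, genes, function(p, g) paste(p, "x", g))))
}

# Shared construction of the two standardized design blocks from a clinical
# matrix (N x 8, design order) and a 0/1 (or 0/1/2) genotype code matrix
# (N x 3). Interaction columns are the product of the standardized clinical
# column and the raw genotype code, re-standardized. Used by both the
# simulator and build_design so generator and engine agree exactly.
design_blocks <- function(clinical, codes,
                          convention = standardization_convention()) {
  colnames(clinical) <- names(clinical_predictors())
  colnames(codes) <- c("BDNF", "5HTTLPR", "COMT")
  clin_std <- standardize(clinical, convention)
  X_main <- standardize(cbind(clinical, codes), convention)

  prods <- do.call(cbind, lapply(seq_len(ncol(clin_std)), function(j) {
    m <- clin_std[, j] * codes
    colnames(m) <- paste(colnames(clin_std)[j], "x",
                         c("BDNF", "SLC6A4", "COMT"))
    m
  }))
  X_int <- standardize(prods[, interaction_names(), drop = FALSE], convention)
  list(X_main = X_main, X_int = X_int)
}

#' Build the CPCA design matrices
#'
#' Assembles the standardized response matrix `Z` (26 region volumes), the
#' main-effect block `X_main` (7 neonatal clinical factors + total brain
#' volume + 3 genotype codes = 11 columns) and the interaction block `X_int`
#' (8 continuous/flag predictors x 3 genotype codes = 24 columns, each the
#' elementwise product of the standardized predictor and the 0/1 genotype
#' code, re-standardized). Subjects with a missing value in any predictor or
#' volume are dropped (complete-case) and listed in the `excluded` element.
#'
#' @param cohort A validated cohort tibble.
#' @param scheme Genotype coding schemes, as in [encode_genotypes()].
#' @param convention A [standardization_convention()].
#' @param log_transform Optional character vector of clinical columns to
#'   log1p-transform before standardization (e.g.
#'   `c("invasive_procedures", "morphine_mg_per_kg")`); default none.
#' @return An object of class `cpca_design`: list with `Z` (N x 26),
#'   `X_main` (N x 11), `X_int` (N x 24), `subject_id`, `excluded`,
#'   `convention`, `scheme`.
#' @export
build_design <- function(cohort,
                         scheme = c(bdnf = "carrier", slc6a4 = "carrier",
                                    comt = "recessive"),
                         convention = standardization_convention(),
                         log_transform = character()) {
  cohort <- validate_cohort(cohort)
  pred_cols <- unname(clinical_predictors())
  vol_cols <- region_columns()
  used <- c(pred_cols, "bdnf", "slc6a4", "comt", vol_cols)
  complete <- stats::complete.cases(cohort[used])
  excluded <- cohort$subject_id[!complete]
  cc <- cohort[complete, ]
  if (nrow(cc) < 3L) stop("fewer than 3 complete cases", call. = FALSE)

  clinical <- as.matrix(cc[pred_cols])
  for (v in log_transform) {
    j <- match(v, pred_cols)
    if (is.na(j)) stop("unknown transform column: ", v, call. = FALSE)
    clinical[, j] <- log1p(clinical[, j])
  }
  codes <- encode_genotypes(cc, scheme)
  blocks <- tryCatch(
    design_blocks(clinical, codes, convention),
    error = function(e) {
      stop("degenerate design: ", conditionMessage(e), call. = FALSE)
    }
  )
  Z <- standardize(as.matrix(cc[vol_cols]), convention)

  structure(
    list(Z = Z, X_main = blocks$X_main, X_int = blocks$X_int,
         subject_id = cc$subject_id, excluded = excluded,
         convention = convention, scheme = scheme,
         log_transform = log_transform),
    class = "cpca_design"
  )
}

#' @export
print.cpca_design <- function(x, ...) {
  cat("CPCA design:", nrow(x$Z), "subjects;", ncol(x$Z), "regions;",
      ncol(x$X_main), "main-effect and", ncol(x$X_int),
      "interaction predictors\n")
  if (length(x$excluded)) {
    cat("  excluded (incomplete):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
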