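# Lean fit path used inside the bootstrap loop: same mathematics as
# build_design() + external_analysis() + internal_analysis() +
# component_loadings() under the default population-N convention, but
# operating directly on raw numeric matrices with cholesky solves, and
# returning only the loading matrices. Returns NULL on a degenerate
# resample (constant design column or singular cross-product), which the
# caller counts and discards. Agreement with the reference path is asserted
# in the test suite.

std_pop <- function(M) {
  n <- nrow(M)
  xc <- sweep(M, 2L, colMeans(M))
  ss <- colSums(xc^2)
  if (any(ss < 1e-10)) return(NULL)
  sweep(xc, 2L, sqrt(ss / n), "/")
}

# Projection onto span(X) via pivoted QR: tolerant of rank deficiency
# (minimum-norm fit, matching hat_project's documented behaviour).
proj_fit <- function(X, Y) {
  q <- qr(X)
  if (q$rank == 0L) return(NULL)
  qr.fitted(q, Y)
}

cpca_core <- function(clinical, codes, vols, k_main = 2, k_int = 1) {
  n <- nrow(vols)
  clin_std <- std_pop(clinical)
  if (is.null(clin_std)) return(NULL)
  Xm <- std_pop(cbind(clinical, codes))
  if (is.null(Xm)) return(NULL)
  prods <- matrix(0, n, 8L * 3L)
  for (j in 1:8) prods[, (j - 1L) * 3L + 1:3] <- clin_std[, j] * codes
  Xi <- std_pop(prods)
  if (is.null(Xi)) return(NULL)
  Z <- std_pop(vols)
  if (is.null(Z)) return(NULL)

  M1 <- proj_fit(Xm, Z)
  if (is.null(M1)) return(NULL)
  E1 <- Z - M1
  Xi_fit <- proj_fit(Xm, Xi)
  if (is.null(Xi_fit)) return(NULL)
  Xi_perp <- Xi - Xi_fit
  M2 <- proj_fit(Xi_perp, E1)
  if (is.null(M2)) return(NULL)

  sqn <- sqrt(n)
  extract <- function(M, k, X_block) {
    sv <- svd(M, nu = k, nv = 0L)
    if (sv$d[k] <= max(dim(M)) * .Machine$double.eps * sv$d[1]) return(NULL)
    U <- sv$u
    L <- crossprod(Z, U) / sqn          # cor(region, score): Z cols have norm sqrt(n)
    P <- crossprod(X_block, U) / sqn
    for (c in seq_len(k)) {
      if (sum(L[, c]) > 0) { L[, c] <- -L[, c]; P[, c] <- -P[, c] }
    }
    list(L = L, P = P)
  }
  main <- extract(M1, k_main, Xm)
  if (is.null(main)) return(NULL)
  int <- extract(M2, k_int, Xi)
  if (is.null(int)) return(NULL)
  list(region = cbind(main$L, int$L), pred_main = main$P, pred_int = int$P)
}

# Raw matrices for cpca_core from a cohort, complete cases only, with any
# log1p transform already applied (elementwise, so it commutes with row
# resampling).
core_matrices <- function(cohort, scheme = c(bdnf = "carrier",
                                             slc6a4 = "carrier",
                                             comt = "recessive"),
                          log_transform = character()) {
  cohort <- validate_cohort(cohort)
  pred_cols <- unname(clinical_predictors())
  used <- c(pred_cols, "bdnf", "slc6a4", "comt", region_columns())
  cc <- cohort[stats::complete.cases(cohort[used]), ]
  clinical <- as.matrix(cc[pred_cols])
  for (v in log_transform) clinical[, match(v, pred_cols)] <- log1p(clinical[, match(v, pred_cols)])
  list(clinical = clinical,
       codes = encode_genotypes(cc, scheme),
       vols = as.matrix(cc[region_columns()]),
       subject_id = cc$subject_id)
}
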