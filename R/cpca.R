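#' Orthogonal projection of a response matrix onto a design span
#'
#' Multivariate least squares: projects every column of `Y` onto the column
#' space of `X` (the hat-matrix product), returning the matrix of fitted
#' values. Rank deficiency is handled by projecting onto the attained column
#' space (minimum-norm fit) with a warning.
#'
#' @param Y Numeric matrix (N x q) of responses.
#' @param X Numeric matrix (N x p) of predictors.
#' @return The N x q matrix of fitted values.
#' @examples
#' X <- cbind(1, 1:6); Y <- cbind(2 * (1:6) + 3)
#' max(abs(hat_project(Y, X) - Y)) < 1e-10
#' @export
hat_project <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopifnot(nrow(Y) == nrow(X))
  qx <- qr(X)
  if (qx$rank >= nrow(X)) {
    stop("overdetermined projection: rank(X) = ", qx$rank,
         " >= N = ", nrow(X), call. = FALSE)
  }
  if (qx$rank < ncol(X)) {
    warning("rank-deficient design (rank ", qx$rank, " < ", ncol(X),
            " columns); minimum-norm projection used", call. = FALSE)
  }
  qr.fitted(qx, Y)
}

#' External analysis: hierarchical variance partition
#'
#' Partitions the standardized volume matrix `Z` into the main-effect
#' predicted matrix `M1` (projection onto the span of `X_main`), the
#' interaction predicted matrix `M2` (projection of the main-effect residual
#' onto the part of `X_int` orthogonal to `X_main`), and the residual `E`,
#' with `M1 + M2 + E = Z` and the three parts mutually orthogonal. With
#' `entry = "simultaneous"`, main effects and interactions are fitted jointly
#' and attributed by coefficient block; the parts then still sum to `Z` but
#' `M1` and `M2` are no longer orthogonal (the sequential default reproduces
#' the stated orthogonality of the extracted components).
#'
#' @param design A [build_design()] result.
#' @param entry `"sequential"` (default) or `"simultaneous"`.
#' @return List with matrices `M1`, `M2`, `E`.
#' @export
external_analysis <- function(design, entry = c("sequential", "simultaneous")) {
  stopifnot(inherits(design, "cpca_design"))
  entry <- match.arg(entry)
  Z <- design$Z; Xm <- design$X_main; Xi <- design$X_int
  if (entry == "sequential") {
    M1 <- hat_project(Z, Xm)
    E1 <- Z - M1
    Xi_perp <- Xi - hat_project(Xi, Xm)
    M2 <- hat_project(E1, Xi_perp)
    E <- E1 - M2
  } else {
    XB <- cbind(Xm, Xi)
    qx <- qr(XB)
    coef <- qr.coef(qx, Z)
    coef[is.na(coef)] <- 0
    M1 <- Xm %*% coef[seq_len(ncol(Xm)), , drop = FALSE]
    M2 <- Xi %*% coef[ncol(Xm) + seq_len(ncol(Xi)), , drop = FALSE]
    E <- Z - M1 - M2
  }
  list(M1 = M1, M2 = M2, E = E)
}

#' Internal analysis: PCA of a predicted matrix
#'
#' Singular value decomposition of a (column-centred) predicted matrix.
#' Components are ordered by decreasing explained variance; subject scores
#' are mutually orthogonal. Each component is oriented so that the sum of its
#' direction entries is non-positive (ties broken toward a negative first
#' non-zero entry), matching the all-negative presentation of the component
#' loading tables.
#'
#' @param M Predicted matrix (N x p).
#' @param k Number of components to retain; must not exceed `rank(M)`.
#' @return List with `scores` (N x k), `singular_values` (length k),
#'   `directions` (p x k, unit-norm right singular vectors) and `rank`.
#' @export
internal_analysis <- function(M, k) {
  M <- as.matrix(M)
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  attained <- sum(sv$d > tol)
  if (k > attained) {
    stop("k = ", k, " exceeds attained rank ", attained, call. = FALSE)
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (c in seq_len(k)) {
    s <- sum(V[, c])
    if (s > 0 || (s == 0 && {
      nz <- V[, c][V[, c] != 0]
      length(nz) > 0 && nz[1] > 0
    })) {
      V[, c] <- -V[, c]; U[, c] <- -U[, c]
    }
  }
  scores <- sweep(U, 2L, d, "*")
  list(scores = scores, singular_values = d, directions = V, rank = attained)
}

#' Component loadings: correlations of regions with component scores
#'
#' Entry (j, c) is the Pearson correlation between region j's standardized
#' volume and component c's subject scores; all entries lie in [-1, 1].
#'
#' @param scores N x k matrix of component scores.
#' @param Z N x p standardized response matrix, row-aligned with `scores`.
#' @return p x k matrix of loadings.
#' @export
component_loadings <- function(scores, Z) {
  scores <- as.matrix(scores); Z <- as.matrix(Z)
  stopifnot(nrow(scores) == nrow(Z))
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate component: zero-variance score vector", call. = FALSE)
  }
  stats::cor(Z, scores)
}

#' Predictor loadings: correlations of design columns with component scores
#'
#' @param scores N x k matrix of component scores.
#' @param X Standardized design block, row-aligned with `scores`.
#' @return `ncol(X)` x k matrix of loadings.
#' @export
predictor_loadings <- function(scores, X) component_loadings(scores, X)

#' Variance decomposition table
#'
#' Mirrors the published variance table: for the main-effect block, the total
#' variance of `Z` (N-1 accounting), the variance of `Z` along each retained
#' component direction, and the variance explained by the predictors (the
#' predicted-matrix eigenvalue \eqn{d_c^2/(N-1)}, equivalently the variance
#' of the component's scores attributable to the design span); analogously
#' for the interaction block. Percentages are of the total variance;
#' "combined" rows are sums over retained components.
#'
#' @param Z,M1,M2 Matrices from [build_design()] and [external_analysis()].
#' @param sol_main,sol_int [internal_analysis()] solutions for `M1` and `M2`.
#' @return A tibble with columns `block`, `component`, `variance`,
#'   `pct_variance`, `explained_variance`, `pct_explained`.
#' @export
variance_table <- function(Z, M1, M2, sol_main, sol_int) {
  n1 <- nrow(Z) - 1L
  total <- sum(Z^2) / n1
  row_for <- function(block, component, variance, explained) {
    tibble::tibble(block = block, component = component,
                   variance = variance,
                   pct_variance = 100 * variance / total,
                   explained_variance = explained,
                   pct_explained = 100 * explained / total)
  }
  comp_rows <- function(block, sol, prefix) {
    k <- length(sol$singular_values)
    vz <- vapply(seq_len(k), function(c) {
      sum((Z %*% sol$directions[, c])^2) / n1
    }, numeric(1))
    ve <- sol$singular_values^2 / n1
    labels <- if (block == "main") paste0("PC", seq_len(k)) else
      paste0("PC NCFxG", if (k > 1) seq_len(k) else "")
    out <- row_for(block, labels, vz, ve)
    if (k > 1) out <- dplyr::bind_rows(out, row_for(block, "combined",
                                                    sum(vz), sum(ve)))
    out
  }
  dplyr::bind_rows(
    row_for("main", "overall", total, sum(M1^2) / n1),
    comp_rows("main", sol_main, "PC"),
    row_for("interaction", "overall", total, sum(M2^2) / n1),
    comp_rows("interaction", sol_int, "PC NCFxG")
  )
}

#' Fit a constrained principal component analysis with interaction terms
#'
#' Runs the full two-step analysis on a cohort: builds the standardized
#' response and design matrices, partitions the response into main-effect,
#' interaction and residual parts (external analysis), extracts principal
#' components of each predicted part (internal analysis), and assembles
#' component loadings (region-by-component correlations), predictor loadings
#' and the variance decomposition table.
#'
#' @param cohort A validated cohort tibble (see [validate_cohort()]).
#' @param k_main Number of main-effect components to retain (default 2).
#' @param k_int Number of interaction components to retain (default 1).
#' @param scheme,convention,log_transform Passed to [build_design()].
#' @param entry Passed to [external_analysis()].
#' @return An object of class `cpca_fit`: list with `design`, `M1`, `M2`,
#'   `E`, `scores` (N x (k_main + k_int), predicted-space subject scores),
#'   `singular_values`, `directions`, `region_loadings` (26 x k),
#'   `predictor_loadings_main` (11 x k_main), `predictor_loadings_int`
#'   (24 x k_int), `variance` (the variance table) and the settings used.
#' @examples
#' sim <- simulate_cohort(sim_params(seed = 2))
#' fit <- cpca(sim$cohort)
#' fit$variance
#' @export
cpca <- function(cohort, k_main = 2, k_int = 1,
                 scheme = c(bdnf = "carrier", slc6a4 = "carrier",
                            comt = "recessive"),
                 convention = standardization_convention(),
                 entry = c("sequential", "simultaneous"),
                 log_transform = character()) {
  entry <- match.arg(entry)
  design <- if (inherits(cohort, "cpca_design")) cohort else
    build_design(cohort, scheme = scheme, convention = convention,
                 log_transform = log_transform)
  parts <- external_analysis(design, entry = entry)
  sol_main <- internal_analysis(parts$M1, k_main)
  sol_int <- internal_analysis(parts$M2, k_int)

  # orient components by the sign convention on region loadings: the sum of
  # each component's 26 loadings is <= 0
  orient <- function(sol) {
    L <- component_loadings(sol$scores, design$Z)
    for (c in seq_len(ncol(L))) {
      s <- sum(L[, c])
      if (s > 0 || (s == 0 && L[1, c] > 0)) {
        sol$scores[, c] <- -sol$scores[, c]
        sol$directions[, c] <- -sol$directions[, c]
      }
    }
    sol
  }
  sol_main <- orient(sol_main); sol_int <- orient(sol_int)

  comp_names <- c(paste0("PC", seq_len(k_main)),
                  if (k_int == 1) "PC NCFxG" else paste0("PC NCFxG", seq_len(k_int)))
  scores <- cbind(sol_main$scores, sol_int$scores)
  colnames(scores) <- comp_names

  region_l <- component_loadings(scores, design$Z)
  dimnames(region_l) <- list(region_columns(), comp_names)
  pred_main <- predictor_loadings(sol_main$scores, design$X_main)
  dimnames(pred_main) <- list(colnames(design$X_main), comp_names[seq_len(k_main)])
  pred_int <- predictor_loadings(sol_int$scores, design$X_int)
  dimnames(pred_int) <- list(interaction_names(), comp_names[k_main + seq_len(k_int)])

  structure(
    list(design = design, M1 = parts$M1, M2 = parts$M2, E = parts$E,
         scores = scores,
         singular_values = c(sol_main$singular_values, sol_int$singular_values),
         directions = cbind(sol_main$directions, sol_int$directions),
         region_loadings = region_l,
         predictor_loadings_main = pred_main,
         predictor_loadings_int = pred_int,
         variance = variance_table(design$Z, parts$M1, parts$M2,
                                   sol_main, sol_int),
         k_main = k_main, k_int = k_int, entry = entry,
         scheme = design$scheme, convention = design$convention),
    class = "cpca_fit"
  )
}

#' @export
print.cpca_fit <- function(x, ...) {
  v <- x$variance
  pct <- function(b, comp) round(v$pct_explained[v$block == b & v$component == comp], 1)
  cat("CPCA fit:", nrow(x$scores), "subjects,", x$k_main,
      "main +", x$k_int, "interaction component(s)\n")
  cat("  variance explained by predictors:", pct("main", "overall"),
      "% (main),", pct("interaction", "overall"), "% (interaction)\n")
  invisible(x)
}

#' Tidy a CPCA fit into a long loading table
#'
#' @param x A `cpca_fit`.
#' @param ... Unused.
#' @return A tibble with columns `family` (`"regions"`,
#'   `"predictors_main"`, `"predictors_interaction"`), `term`, `component`
#'   and `loading`.
#' @method tidy cpca_fit
#' @export
tidy.cpca_fit <- function(x, ...) {
  long <- function(mat, family) {
    tibble::as_tibble(mat, rownames = "term") |>
      tidyr::pivot_longer(-"term", names_to = "component",
                          values_to = "loading") |>
      dplyr::mutate(family = family, .before = 1L)
  }
  dplyr::bind_rows(
    long(x$region_loadings, "regions"),
    long(x$predictor_loadings_main, "predictors_main"),
    long(x$predictor_loadings_int, "predictors_interaction")
  )
}

#' One-row summary of a CPCA fit
#'
#' @param x A `cpca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, components retained, total variance,
#'   percent variance explained by the main-effect and interaction blocks.
#' @method glance cpca_fit
#' @export
glance.cpca_fit <- function(x, ...) {
  v <- x$variance
  tibble::tibble(
    n = nrow(x$scores),
    k_main = x$k_main,
    k_int = x$k_int,
    total_variance = v$variance[v$block == "main" & v$component == "overall"],
    pct_explained_main = v$pct_explained[v$block == "main" & v$component == "overall"],
    pct_explained_interaction = v$pct_explained[v$block == "interaction" & v$component == "overall"]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
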