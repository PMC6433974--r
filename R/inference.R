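#' Align a candidate component solution to a reference
#'
#' Bootstrap replicates of a PCA are only comparable after resolving
#' component order and sign indeterminacy. Candidate components are matched
#' greedily to reference components by absolute Tucker congruence of their
#' loading vectors, then sign-flipped so the matched congruence is positive.
#'
#' @param reference,candidate Loading matrices of equal shape (p x k).
#' @return A list with `order` (candidate column matched to each reference
#'   column), `signs` (+1/-1 per reference column), `congruence` (matched
#'   absolute congruences), `failed` (TRUE when every congruence is below
#'   0.3, in which case the identity mapping is returned), and `aligned`
#'   (the candidate with order and signs applied).
#' @examples
#' ref <- matrix(rnorm(26 * 2), 26, 2)
#' cand <- ref[, 2:1]; cand[, 1] <- -cand[, 1]
#' align_components(ref, cand)$order
#' @export
align_components <- function(reference, candidate) {
  reference <- as.matrix(reference); candidate <- as.matrix(candidate)
  stopifnot(all(dim(reference) == dim(candidate)))
  k <- ncol(reference)
  cg <- tucker_congruence(reference, candidate)
  cg <- matrix(cg, k, k)
  ord <- integer(k); sgn <- numeric(k); matched <- numeric(k)
  acg <- abs(cg)
  for (step in seq_len(k)) {
    best <- which(acg == max(acg), arr.ind = TRUE)[1L, ]
    i <- best[[1L]]; j <- best[[2L]]
    ord[i] <- j
    sgn[i] <- sign(cg[i, j])
    if (sgn[i] == 0) sgn[i] <- 1
    matched[i] <- acg[i, j]
    acg[i, ] <- -Inf; acg[, j] <- -Inf
  }
  failed <- all(matched < 0.3)
  if (failed) { ord <- seq_len(k); sgn <- rep(1, k); }
  aligned <- sweep(candidate[, ord, drop = FALSE], 2L, sgn, "*")
  list(order = ord, signs = sgn, congruence = matched, failed = failed,
       aligned = aligned)
}

#' Bootstrap p-value for a loading
#'
#' Percentile method (default): the two-sided sign-crossing probability with
#' a +1 continuity correction on both tails,
#' \eqn{p = \min(1,\; 2\min(\#\{r \le 0\}+1, \#\{r \ge 0\}+1)/(B+1))},
#' which is never exactly zero. Normal method: two-sided p from the
#' estimate divided by the replicate standard deviation.
#'
#' @param replicates Numeric vector of B aligned bootstrap replicates of the
#'   loading.
#' @param estimate The point estimate.
#' @param method `"percentile"` (requires B >= 100) or `"normal"`.
#' @return A p-value in (0, 1].
#' @examples
#' loading_pvalue(abs(rnorm(999)) + 0.01, 0.5)
#' @export
loading_pvalue <- function(replicates, estimate,
                           method = c("percentile", "normal")) {
  method <- match.arg(method)
  B <- length(replicates)
  if (method == "percentile") {
    if (B < 100) stop("percentile p-values need B >= 100", call. = FALSE)
    min(1, 2 * min(sum(replicates <= 0) + 1, sum(replicates >= 0) + 1) / (B + 1))
  } else {
    s <- stats::sd(replicates)
    if (s == 0) stop("degenerate replicate distribution (zero SD)", call. = FALSE)
    2 * stats::pnorm(-abs(estimate) / s)
  }
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up procedure (via [stats::p.adjust()]): adjusted p-values
#' are monotone non-decreasing in raw-p order, and a loading is flagged when
#' its adjusted p is at most `q`.
#'
#' @param pvals Vector of raw p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Bonferroni adjustment
#'
#' @param pvals Vector of raw p-values in [0, 1].
#' @return Adjusted p-values, `min(1, m * p)`.
#' @export
bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Case-resampling bootstrap of the full CPCA pipeline
#'
#' Draws `B` resamples of whole subjects with replacement, re-runs the entire
#' pipeline (re-standardization, external and internal analysis, loadings)
#' on each, aligns every replicate's components to the point estimate with
#' [align_components()], and summarises each loading's replicate
#' distribution with percentile confidence intervals, bootstrap p-values and
#' Benjamini-Hochberg / Bonferroni adjustment. Adjustment is applied within
#' each reported table family separately (each component's 26 region
#' loadings; each component's main-effect predictor loadings; each
#' interaction component's 24 interaction loadings). Resamples with a
#' constant design column are discarded and counted; more than 20% discarded
#' is an error.
#'
#' @param cohort A validated cohort tibble.
#' @param k_main,k_int,scheme,log_transform Passed to [cpca()].
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Master seed; replicate b uses a child seed derived from
#'   (seed, b), so results do not depend on execution order.
#' @param level Confidence level for percentile intervals (default 0.95).
#' @param q FDR level for the BH flags (default 0.05).
#' @param p_method `"percentile"` or `"normal"`, see [loading_pvalue()].
#' @param keep_replicates Keep the aligned replicate matrix (default TRUE).
#' @return An object of class `cpca_boot`: list with `tbl` (tibble of
#'   family, component, term, estimate, conf.low, conf.high, p.value, p.bh,
#'   significant, p.bonferroni), `fit` (the point-estimate `cpca_fit`),
#'   `replicates` (aligned B_effective x n_loadings matrix), `B`,
#'   `B_effective`, `diagnostics` (discarded and alignment-failure counts),
#'   `level`, `q`, `seed`.
#' @export
bootstrap_cpca <- function(cohort, k_main = 2, k_int = 1,
                           scheme = c(bdnf = "carrier", slc6a4 = "carrier",
                                      comt = "recessive"),
                           log_transform = character(),
                           B = 1000, seed = 1L, level = 0.95, q = 0.05,
                           p_method = c("percentile", "normal"),
                           keep_replicates = TRUE) {
  stopifnot(B >= 2)
  p_method <- match.arg(p_method)
  fit <- cpca(cohort, k_main = k_main, k_int = k_int, scheme = scheme,
              log_transform = log_transform)
  mats <- core_matrices(cohort, scheme = scheme, log_transform = log_transform)
  n <- nrow(mats$vols)
  k <- k_main + k_int

  ref_region <- fit$region_loadings
  est <- c(ref_region, fit$predictor_loadings_main, fit$predictor_loadings_int)

  reps <- matrix(NA_real_, B, length(est))
  discarded <- 0L; align_failures <- 0L
  main_idx <- seq_len(k_main); int_idx <- k_main + seq_len(k_int)
  for (b in seq_len(B)) {
    res <- with_seed(child_seed(seed, paste0("boot_", b)), {
      idx <- sample.int(n, n, replace = TRUE)
      cpca_core(mats$clinical[idx, , drop = FALSE],
                mats$codes[idx, , drop = FALSE],
                mats$vols[idx, , drop = FALSE],
                k_main = k_main, k_int = k_int)
    })
    if (is.null(res)) { discarded <- discarded + 1L; next }
    am <- align_components(ref_region[, main_idx, drop = FALSE],
                           res$region[, main_idx, drop = FALSE])
    ai <- align_components(ref_region[, int_idx, drop = FALSE],
                           res$region[, int_idx, drop = FALSE])
    if (am$failed || ai$failed) align_failures <- align_failures + 1L
    reg <- cbind(am$aligned, ai$aligned)
    pm <- sweep(res$pred_main[, am$order, drop = FALSE], 2L, am$signs, "*")
    pi_ <- sweep(res$pred_int[, ai$order, drop = FALSE], 2L, ai$signs, "*")
    reps[b, ] <- c(reg, pm, pi_)
  }
  if (discarded > 0.2 * B) {
    stop("inference degeneracy: ", discarded, " of ", B,
         " resamples discarded (> 20%)", call. = FALSE)
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]

  alpha <- (1 - level) / 2
  ci <- apply(reps, 2L, stats::quantile, probs = c(alpha, 1 - alpha))
  pvals <- vapply(seq_along(est), function(j) {
    loading_pvalue(reps[, j], est[j], method = p_method)
  }, numeric(1))

  comp_names <- colnames(fit$scores)
  tbl <- dplyr::bind_rows(
    tidyr::expand_grid(component = factor(comp_names, comp_names),
                       term = region_columns()) |>
      dplyr::mutate(family = "regions", .before = 1L) |>
      dplyr::arrange(.data$component),
    tidyr::expand_grid(component = factor(comp_names[main_idx], comp_names),
                       term = colnames(fit$design$X_main)) |>
      dplyr::mutate(family = "predictors_main", .before = 1L) |>
      dplyr::arrange(.data$component),
    tidyr::expand_grid(component = factor(comp_names[int_idx], comp_names),
                       term = interaction_names()) |>
      dplyr::mutate(family = "predictors_interaction", .before = 1L) |>
      dplyr::arrange(.data$component)
  )
  tbl$component <- as.character(tbl$component)
  tbl$estimate <- est
  tbl$conf.low <- ci[1L, ]
  tbl$conf.high <- ci[2L, ]
  tbl$p.value <- pvals
  tbl <- tbl |>
    dplyr::group_by(.data$family, .data$component) |>
    dplyr::mutate(
      p.bh = benjamini_hochberg(.data$p.value, q)$p_adjusted,
      significant = .data$p.bh <= q,
      p.bonferroni = bonferroni(.data$p.value)
    ) |>
    dplyr::ungroup()

  structure(
    list(tbl = tbl, fit = fit,
         replicates = if (keep_replicates) reps else NULL,
         B = B, B_effective = nrow(reps),
         diagnostics = list(discarded = discarded,
                            alignment_failures = align_failures),
         level = level, q = q, seed = seed, p_method = p_method),
    class = "cpca_boot"
  )
}

#' @export
print.cpca_boot <- function(x, ...) {
  cat("CPCA bootstrap:", x$B_effective, "of", x$B, "resamples used (",
      x$diagnostics$discarded, "discarded,",
      x$diagnostics$alignment_failures, "alignment failures )\n")
  cat("  ", sum(x$tbl$significant), "of", nrow(x$tbl),
      "loadings significant at BH q =", x$q, "\n")
  invisible(x)
}

#' Tidy a bootstrap result
#'
#' @param x A `cpca_boot`.
#' @param ... Unused.
#' @return The per-loading tibble (estimate, CI, p-values, adjustments).
#' @method tidy cpca_boot
#' @export
tidy.cpca_boot <- function(x, ...) x$tbl

#' One-row summary of a bootstrap result
#'
#' @param x A `cpca_boot`.
#' @param ... Unused.
#' @return A one-row tibble with B, effective B, diagnostics counts and the
#'   number of BH-significant loadings.
#' @method glance cpca_boot
#' @export
glance.cpca_boot <- function(x, ...) {
  tibble::tibble(
    B = x$B, B_effective = x$B_effective,
    discarded = x$diagnostics$discarded,
    alignment_failures = x$diagnostics$alignment_failures,
    n_loadings = nrow(x$tbl),
    n_significant_bh = sum(x$tbl$significant),
    level = x$level, q = x$q
  )
}
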