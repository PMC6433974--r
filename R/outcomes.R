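#' Correlate component scores with neurobehavioral outcomes
#'
#' Pearson correlation of each retained component's subject scores with each
#' of the 10 outcome measures, using pairwise-complete observations; the
#' two-sided p-value comes from the t transform with N-2 degrees of freedom
#' on the pairwise-complete rows. Outcome p-values are reported raw (an
#' optional BH-adjusted column is available), matching the presentation of
#' the published correlation table. A zero-variance outcome yields `NA`
#' correlations, never 0.
#'
#' @param scores N x k matrix of component scores (e.g. `fit$scores`).
#' @param outcomes N x 10 data frame or matrix of outcome scores,
#'   row-aligned with `scores`; columns named as in [outcome_measures()].
#' @param adjust Add a BH-adjusted p column per component (default FALSE).
#' @param min_n Minimum pairwise-complete N per cell (default 10).
#' @return A tibble with columns `outcome`, `component`, `r`, `p`, `n`
#'   (and `p.bh` when `adjust = TRUE`), rows ordered by outcome then
#'   component.
#' @examples
#' sim <- simulate_cohort(sim_params(seed = 3))
#' fit <- cpca(sim$cohort)
#' correlate_components_outcomes(fit$scores,
#'   sim$cohort[unname(outcome_measures())])
#' @export
correlate_components_outcomes <- function(scores, outcomes, adjust = FALSE,
                                          min_n = 10) {
  scores <- as.matrix(scores)
  outcomes <- as.data.frame(outcomes)
  stopifnot(nrow(scores) == nrow(outcomes))
  om <- outcome_measures()
  present <- om[om %in% names(outcomes)]
  if (length(present) == 0L) {
    stop("no recognised outcome columns present", call. = FALSE)
  }
  comp_names <- colnames(scores) %||% paste0("PC", seq_len(ncol(scores)))

  tbl <- tidyr::expand_grid(outcome = names(present),
                            component = comp_names) |>
    dplyr::mutate(purrr::map2_dfr(.data$outcome, .data$component, function(o, cmp) {
      y <- outcomes[[present[[o]]]]
      t <- scores[, cmp]
      ok <- stats::complete.cases(y, t)
      n <- sum(ok)
      if (n < min_n) {
        stop(sprintf("fewer than %d pairwise-complete observations for %s x %s",
                     min_n, o, cmp), call. = FALSE)
      }
      if (stats::sd(y[ok]) == 0) {
        return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
      }
      ct <- stats::cor.test(y[ok], t[ok], method = "pearson")
      tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
    }))
  if (adjust) {
    tbl <- tbl |>
      dplyr::group_by(.data$component) |>
      dplyr::mutate(p.bh = stats::p.adjust(.data$p, "BH")) |>
      dplyr::ungroup()
  }
  tbl
}
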