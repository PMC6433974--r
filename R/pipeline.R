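#' Pipeline run configuration
#'
#' Collects every setting of an end-to-end run: input cohort (a CSV path, a
#' cohort tibble, or `NULL` to simulate), output directory, standardization
#' convention, genotype coding schemes, optional predictor transforms,
#' component retention, bootstrap size, FDR level, CI level, master seed and
#' report rounding. Round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param input Cohort CSV path, a cohort data frame, or `NULL` to simulate
#'   a cohort from `sim` at run time.
#' @param output_dir Directory for report files.
#' @param sim A [sim_params()] object used when `input` is `NULL`.
#' @param k_main,k_int Components retained (defaults 2 and 1).
#' @param scheme Genotype coding schemes per gene.
#' @param convention A [standardization_convention()].
#' @param log_transform Clinical columns to log1p-transform.
#' @param B Bootstrap resamples (default 1000).
#' @param q FDR level (default 0.05).
#' @param level CI level (default 0.95).
#' @param seed Master seed for simulation and bootstrap.
#' @param exclude_subjects Subject IDs to drop before analysis (sensitivity
#'   reanalysis by case-wise deletion).
#' @param units Volume units of the input file: `"mm3"` (default) or
#'   `"cm3"` (converted to mm^3 on read).
#' @param digits,p_digits Report rounding (defaults 2 and 4).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("cpca_run_"),
                       sim = sim_params(),
                       k_main = 2, k_int = 1,
                       scheme = c(bdnf = "carrier", slc6a4 = "carrier",
                                  comt = "recessive"),
                       convention = standardization_convention(),
                       log_transform = character(),
                       B = 1000, q = 0.05, level = 0.95, seed = 1L,
                       exclude_subjects = character(),
                       units = c("mm3", "cm3"),
                       digits = 2, p_digits = 4) {
  units <- match.arg(units)
  stopifnot(k_main >= 1, k_int >= 1, B >= 2, q > 0, q < 1,
            level > 0, level < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- config
  ser$convention <- unclass(config$convention)
  ser$sim <- unclass(config$sim)
  ser$sim$allele_freq <- as.list(config$sim$allele_freq)
  ser$scheme <- as.list(config$scheme)
  if (is.data.frame(ser$input)) {
    stop("in-memory cohort inputs cannot be serialised; write the cohort ",
         "to CSV first", call. = FALSE)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML path written by [write_run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  conv <- standardization_convention(raw$convention$scale_denominator)
  sim <- do.call(sim_params, c(
    raw$sim[setdiff(names(raw$sim), "allele_freq")],
    list(allele_freq = unlist(raw$sim$allele_freq))
  ))
  run_config(
    input = raw$input, output_dir = raw$output_dir, sim = sim,
    k_main = raw$k_main, k_int = raw$k_int,
    scheme = unlist(raw$scheme), convention = conv,
    log_transform = as.character(raw$log_transform %||% character()),
    B = raw$B, q = raw$q, level = raw$level, seed = raw$seed,
    exclude_subjects = as.character(raw$exclude_subjects %||% character()),
    units = raw$units, digits = raw$digits, p_digits = raw$p_digits
  )
}

#' Run the full pipeline
#'
#' Orchestrates simulate/read, fit, bootstrap, outcome correlation and
#' report writing. Deterministic given the configuration and seed. The run
#' directory receives six report files — `variance_table.csv`,
#' `loadings_regions.csv`, `loadings_predictors_main.csv`,
#' `loadings_interactions.csv`, `outcome_correlations.csv`, `report.md` —
#' plus `manifest.json` (package version, config, seed, exclusions,
#' bootstrap diagnostics) and `log.txt` (one line per stage).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `fit`, `boot`, `outcomes`, `manifest` and
#'   `output_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "log.txt")
  cat("", file = log_path)
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }

  cohort <- if (is.null(config$input)) {
    sim <- config$sim; sim$seed <- config$seed
    log_line("simulate", paste("synthetic cohort, n =", sim$n_subjects,
                               "seed =", config$seed))
    simulate_cohort(sim)$cohort
  } else if (is.data.frame(config$input)) {
    validate_cohort(config$input)
  } else {
    log_line("read", config$input)
    read_cohort(config$input)
  }
  if (config$units == "cm3") {
    vcols <- c("tbv_mm3", region_columns())
    cohort[vcols] <- cohort[vcols] * 1000
  }
  excl <- intersect(config$exclude_subjects, cohort$subject_id)
  if (length(excl)) cohort <- cohort[!cohort$subject_id %in% excl, ]
  log_line("exclude", if (length(excl)) paste(excl, collapse = ", ") else "none")

  boot <- bootstrap_cpca(
    cohort, k_main = config$k_main, k_int = config$k_int,
    scheme = config$scheme, log_transform = config$log_transform,
    B = config$B, seed = config$seed, level = config$level, q = config$q,
    keep_replicates = FALSE
  )
  fit <- boot$fit
  log_line("fit", sprintf("n = %d, k_main = %d, k_int = %d",
                          nrow(fit$scores), config$k_main, config$k_int))
  log_line("bootstrap", sprintf("B = %d, discarded = %d, alignment failures = %d",
                                boot$B, boot$diagnostics$discarded,
                                boot$diagnostics$alignment_failures))

  out_cols <- unname(outcome_measures())
  keep <- fit$design$subject_id
  outcomes <- correlate_components_outcomes(
    fit$scores, cohort[match(keep, cohort$subject_id), out_cols]
  )
  log_line("outcomes", paste(nrow(outcomes), "correlation cells"))

  d <- config$digits; pd <- config$p_digits
  out <- function(f) file.path(config$output_dir, f)
  write_tables(fit$variance, out("variance_table.csv"), d, pd)
  btl <- tidy(boot)
  fam <- function(f) btl[btl$family == f, setdiff(names(btl), "family")]
  write_tables(fam("regions"), out("loadings_regions.csv"), 3, pd)
  write_tables(fam("predictors_main"), out("loadings_predictors_main.csv"), 3, pd)
  write_tables(fam("predictors_interaction"), out("loadings_interactions.csv"), 3, pd)
  write_tables(outcomes, out("outcome_correlations.csv"), 3, pd)

  manifest <- list(
    package = "cpcage",
    version = as.character(utils::packageVersion("cpcage")),
    seed = config$seed,
    convention = unclass(config$convention),
    scheme = as.list(config$scheme),
    k_main = config$k_main, k_int = config$k_int,
    B = config$B, q = config$q, level = config$level,
    units = config$units,
    excluded_subjects = c(excl, fit$design$excluded),
    bootstrap_diagnostics = boot$diagnostics,
    n_subjects = nrow(fit$scores)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(render_report(fit, boot, outcomes, q = config$q, digits = d,
                           p_digits = pd),
             out("report.md"))
  log_line("report", "written")

  invisible(list(fit = fit, boot = boot, outcomes = outcomes,
                 manifest = manifest, output_dir = config$output_dir))
}

#' Render a human-readable markdown summary
#'
#' One document with the variance decomposition, the three loading tables
#' (with bootstrap p-values when available, and BH-significant cells
#' flagged `*`), and the outcome correlation table. When `boot` is `NULL`
#' the loading tables are rendered without p columns, with a notice; when
#' `outcomes` is `NULL` or empty that section is omitted with a notice.
#'
#' @param fit A `cpca_fit`.
#' @param boot Optional `cpca_boot`.
#' @param outcomes Optional outcome correlation tibble.
#' @param q FDR flag level (default 0.05).
#' @param digits,p_digits Rounding (defaults 2 and 4).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(fit, boot = NULL, outcomes = NULL, q = 0.05,
                          digits = 2, p_digits = 4) {
  md_table <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ format(.x, trim = TRUE)))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  rnd <- function(x, d) round(x, d)

  lines <- c("# Constrained principal component analysis report", "",
             sprintf("%d subjects; %d main + %d interaction component(s).",
                     nrow(fit$scores), fit$k_main, fit$k_int), "",
             "## Variance decomposition", "",
             md_table(dplyr::mutate(fit$variance,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ rnd(.x, digits)))), "")

  loading_section <- function(title, family, point) {
    if (is.null(boot)) {
      df <- tibble::as_tibble(point, rownames = "term") |>
        dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ rnd(.x, 3)))
      c(sprintf("## %s", title), "",
        "(no bootstrap inference available: p-value columns omitted)", "",
        md_table(df), "")
    } else {
      df <- boot$tbl[boot$tbl$family == family, ] |>
        dplyr::transmute(.data$component, .data$term,
                         loading = rnd(.data$estimate, 3),
                         conf.low = rnd(.data$conf.low, 3),
                         conf.high = rnd(.data$conf.high, 3),
                         p = rnd(.data$p.value, p_digits),
                         fdr = rnd(.data$p.bh, p_digits),
                         flag = ifelse(.data$significant, "*", ""))
      c(sprintf("## %s", title), "", md_table(df), "")
    }
  }
  lines <- c(lines,
             loading_section("Component loadings (regions)", "regions",
                             fit$region_loadings),
             loading_section("Predictor loadings (main effects)",
                             "predictors_main", fit$predictor_loadings_main),
             loading_section("Predictor loadings (interactions)",
                             "predictors_interaction", fit$predictor_loadings_int))
  if (is.null(outcomes) || nrow(outcomes) == 0L) {
    lines <- c(lines, "## Outcome correlations", "",
               "(no outcome data available: section omitted)", "")
  } else {
    df <- dplyr::mutate(outcomes, r = rnd(.data$r, 3), p = rnd(.data$p, p_digits))
    lines <- c(lines, "## Outcome correlations", "", md_table(df), "")
  }
  lines
}
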