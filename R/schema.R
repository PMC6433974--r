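#' Region schema for the 26 subcortical volumes
#'
#' The volumetric response set comprises 13 structures segmented in each
#' hemisphere: five hippocampal subfields (CA1, subiculum, CA4/dentate gyrus,
#' CA2/CA3, stratum radiatum/lacunosum/moleculare), four hippocampus-related
#' white-matter tracts (alveus, fimbria, fornix, mammillary bodies), the
#' amygdala, and three basal-ganglia/diencephalic structures (striatum,
#' globus pallidus, thalamus). Column names follow the `<hemisphere>_<structure>`
#' convention (e.g. `L_CA1`, `R_thalamus`) and the order below is canonical:
#' left hemisphere first, then right, structures in the order listed.
#'
#' @return A tibble with one row per region column: `column` (canonical
#'   column name), `hemisphere` (`"L"` or `"R"`) and `structure`.
#' @examples
#' region_schema()
#' @export
region_schema <- function() {
  structures <- c(
    "CA1", "subiculum", "CA4DG", "CA2CA3", "stratum",
    "alveus", "fimbria", "fornix", "mammillary", "amygdala",
    "striatum", "globus_pallidus", "thalamus"
  )
  tibble::tibble(
    column = c(paste0("L_", structures), paste0("R_", structures)),
    hemisphere = rep(c("L", "R"), each = length(structures)),
    structure = rep(structures, 2L)
  )
}

#' Canonical region column names
#'
#' @param schema A region schema tibble, by default [region_schema()].
#' @return Character vector of the 26 region column names in canonical order.
#' @export
region_columns <- function(schema = region_schema()) schema$column

#' Names and order of the neonatal clinical factors
#'
#' The seven neonatal clinical factors (NCF) plus total brain volume, in the
#' order the main-effect design block uses: infection, invasive procedures,
#' morphine, surgeries, mechanical ventilation, SNAP-II, gestational age,
#' total brain volume.
#'
#' @return Named character vector mapping display labels to cohort columns.
#' @export
clinical_predictors <- function() {
  c(
    "Infection"              = "infection",
    "Invasive procedures"    = "invasive_procedures",
    "Morphine"               = "morphine_mg_per_kg",
    "Surgery"                = "surgeries",
    "Mechanical ventilation" = "ventilation_days",
    "SNAP-II"                = "snap2",
    "GA"                     = "ga_weeks",
    "Total brain volume"     = "tbv_mm3"
  )
}

#' Genotype columns and their allowed categories
#'
#' BDNF Val66Met and COMT Val158Met use Val/Met categories; the SLC6A4
#' 5HTTLPR length polymorphism uses L/S categories. Grouped categories
#' (e.g. `"Val/Met+Met/Met"`) are accepted on input and treated as
#' minor-allele carriers.
#'
#' @return Named list of allowed category vectors, one per gene column
#'   (`bdnf`, `slc6a4`, `comt`).
#' @export
genotype_levels <- function() {
  list(
    bdnf   = c("Val/Val", "Val/Met", "Met/Met", "Val/Met+Met/Met"),
    slc6a4 = c("L/L", "L/S", "S/S", "L/S+S/S"),
    comt   = c("Val/Val", "Val/Met", "Met/Met", "Val/Met+Met/Met")
  )
}

#' Outcome measures correlated with component scores
#'
#' Ten neurobehavioral outcomes at school age: WISC-IV composite indices
#' (verbal comprehension, perceptual reasoning, working memory, processing
#' speed), CBCL internalizing/externalizing T-scores, the BRIEF global
#' executive composite, and three Beery visual-motor scores.
#'
#' @return Named character vector mapping display labels to cohort columns.
#' @export
outcome_measures <- function() {
  c(
    "WISC-IV VCI"             = "wisc_vci",
    "WISC-IV PRI"             = "wisc_pri",
    "WISC-IV WMI"             = "wisc_wmi",
    "WISC-IV PSI"             = "wisc_psi",
    "CBCL Internalizing"      = "cbcl_internalizing",
    "CBCL Externalizing"      = "cbcl_externalizing",
    "BRIEF GEC"               = "brief_gec",
    "Beery VMI"               = "beery_vmi",
    "Beery Visual Perception" = "beery_visual_perception",
    "Beery Motor Coordination" = "beery_motor_coordination"
  )
}

# Full canonical column order of a cohort table.
cohort_columns <- function() {
  c(
    "subject_id", "ga_weeks", "infection", "invasive_procedures",
    "surgeries", "ventilation_days", "snap2", "morphine_mg_per_kg",
    "bdnf", "slc6a4", "comt", "tbv_mm3",
    region_columns(), unname(outcome_measures())
  )
}
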