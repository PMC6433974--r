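# Shared fixtures, generated in code at test time.

quiet_sim <- function(...) {
  suppressWarnings(simulate_cohort(sim_params(...)))
}

# small cohort for fast structural tests
small_cohort <- function(n = 40, seed = 42, ...) quiet_sim(n_subjects = n, seed = seed, ...)$cohort

# tiny hand-buildable cohort fragment for genotype tests
geno_frame <- function(bdnf, slc6a4, comt) {
  tibble::tibble(bdnf = bdnf, slc6a4 = slc6a4, comt = comt)
}
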