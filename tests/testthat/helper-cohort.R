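# One default synthetic cohort (fixed seed) fitted with both candidate
# models, shared across the recovery tests so the fits are computed once.
cohort_cache <- new.env(parent = emptyenv())

default_cohort_analysis <- function() {
  if (is.null(cohort_cache$res)) {
    cohort <- generate_cohort(master_seed = 101)
    fits <- fit_cohort(cohort$trials, c("M1", "M2"))
    evidence <- evidence_matrix(fits)
    cohort_cache$res <- list(
      cohort = cohort,
      fits = fits,
      evidence_control = evidence[grep("^control", rownames(evidence)), ],
      evidence_patient = evidence[grep("^patient", rownames(evidence)), ])
  }
  cohort_cache$res
}
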