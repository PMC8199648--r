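# Shared small cohorts, simulated once per test run.

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed = 1) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  .cohort_cache[[key]]
}

# tiny clinical table for format-level tests: 2 patients, paired
tiny_clinical <- function() {
  validate_clinical_table(data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    sample_id = c("P1_T", "P1_N", "P2_T", "P2_N"),
    tissue = c("tumor", "non_tumor", "tumor", "non_tumor"),
    grade = c(2, 2, 4, 4), size_group = c(0, 0, 1, 1),
    encapsulation = c(1, 1, 0, 0), degree_encapsulation = c(1, 1, 0, 0),
    vascular_invasion = c(0, 0, 1, 1), tumor_invasion = c(0, 0, 1, 1),
    stage_group = c(0, 0, 1, 1), os_time = c(30, 30, 12, 12),
    os_event = c(0, 0, 1, 1), stringsAsFactors = FALSE))
}
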