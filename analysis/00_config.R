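# Shared settings for the analysis workflow. Sourced by the numbered
# scripts; everything else comes from the imcoh package.
library(imcoh)

RESULTS_DIR <- "results"
EXAMPLE_DIR <- file.path(RESULTS_DIR, "example_subject")
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")
FIG_DIR <- file.path(RESULTS_DIR, "figures")

MASTER_SEED <- 20260927L

# acquisition/design constants: 8 channels (4 homologous pairs) at 3 kHz,
# 40 repetitions of three 5-s movement periods
sim_config <- simulation_config(seed = MASTER_SEED)

# full-cohort configuration: 11 subjects, default Welch settings
# (500-ms Hann, 75% overlap), alpha = 5%
cohort_config <- pipeline_config(simulation = sim_config, n_subjects = 11,
                                 seed = MASTER_SEED)

dir.create(RESULTS_DIR, showWarnings = FALSE)
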