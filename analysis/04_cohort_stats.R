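#!/usr/bin/env Rscript
# Step 4: full cohort run (11 simulated subjects) and the statistical
# layer: per-band two-way rmANOVAs on log IMC area (muscle pair x movement
# period) with Holm post hocs, delay rmANOVAs, one-way rmANOVAs on RMS
# activation, and one-sample t tests of band phase angles; all tables under
# results/cohort/, figures under results/figures/.
source("analysis/00_config.R")

message(sprintf("Running the pipeline for %d subjects (seed %d) ...",
                cohort_config$n_subjects, cohort_config$seed))
t0 <- proc.time()
res <- run_pipeline(cohort_config, out_dir = COHORT_DIR)
message(sprintf("done in %.0f s; tables in %s", (proc.time() - t0)[3],
                COHORT_DIR))

report(res, plot_dir = FIG_DIR)
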