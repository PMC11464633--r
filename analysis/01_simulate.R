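#!/usr/bin/env Rscript
# Step 1: write a synthetic study dataset.
#
# Nine patients, two music-assisted-relaxation sessions each except the last
# patient (17 sessions), with the study-like availability pattern: one
# session without ECG (lead disconnection), two without the EMG channel and
# one EMG sampled at 256 Hz (below the 512-Hz analysis gate). Effect
# profiles follow the directions reported for the original cohort:
# occipital alpha up / frontal delta-theta and frontotemporal fast-beta down
# during the intervention, HF up and LF down during the intervention, and
# the EMG mean frequency lowered by ~6.5 Hz during the intervention only.
#
# Raw signals land under scratch/ (they are large and regenerable); the
# session inventory goes to results/.

library(marphysio)

seed <- 1L
root <- "scratch/study_bids"
durations <- c(pre = 120, mti = 180, post = 120)   # scaled-down periods

unlink(root, recursive = TRUE)
inventory <- simulate_study_dataset(root, seed = seed, durations = durations)

dir.create("results", showWarnings = FALSE)
write_results(list(simulated_sessions = inventory), "results",
              overwrite = TRUE, config = list(seed = seed,
                                              durations = as.list(durations)),
              seed = seed)

cat(sprintf("wrote %d sessions to %s\n", nrow(inventory), root))
cat(sprintf("  with ECG: %d   with eligible EMG: %d\n",
            sum(inventory$ecg), sum(inventory$emg_eligible)))
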