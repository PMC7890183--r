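#!/usr/bin/env Rscript

# Step 1 — define the synthetic cohorts and materialize example raw
# files. The behavioral arm mirrors the study layout (two groups of 16,
# pre/post, three 60 s sway trials); the EEG arm is run at a reduced
# scale (12 channels, 250 Hz, 22 s runs, 8 subjects, 2 trials) so the
# whole workflow completes in minutes on a laptop. All downstream steps
# read the configurations written here.

suppressPackageStartupMessages(library(posturenet))
dir.create("results", showWarnings = FALSE)

beh_cfg <- study_config(
  n_subjects = 16L, n_trials = 3L, seed = 20240101L,
  cop = list(fs = 100, duration_s = 60)
)
write_study_config(beh_cfg, "results/config_behavioral.yaml")

eeg_cfg <- study_config(
  n_subjects = 8L, n_trials = 2L, seed = 20240102L,
  eeg = list(fs = 250, duration_s = 22, n_channels = 12L),
  scenario = list(eeg = list(n_pairs = 6L))
)
write_study_config(eeg_cfg, "results/config_connectome.yaml")

# a taste of the raw formats: one sway trial and one contaminated EEG run
tr <- gen_cop(cop_spec(duration_s = 60, fs = 100,
                       covariance = diag(c(0.65, 0.45)^2),
                       spectral_centroid_hz = 0.27, regularity = 0.5),
              seed = 1L)
write_cop(tr, "results/example_cop_trial.tsv")

rec <- gen_coupled_eeg(coupling_spec(list(c(1, 2), c(3, 4)), band = c(8, 13),
                                     coupling_strength = 0.6, snr_db = 10),
                       n_channels = 12L, fs = 250, duration_s = 10, seed = 2L)
sim <- gen_eog_artifacts(rec, blink_rate_hz = 0.2, amplitude_uV = 60,
                         propagation = 0.6 * exp(-(0:11) / 6), seed = 3L)
write_eeg_txt(sim$recording, "results/example_eeg_run.tsv")

cat("wrote cohort configurations and example raw files under results/\n")
cat(sprintf("behavioral cohort: %d x %d subjects, %d sessions, %d trials\n",
            length(beh_cfg$groups), beh_cfg$n_subjects,
            length(beh_cfg$sessions), beh_cfg$n_trials))
cat(sprintf("connectome cohort: %d x %d subjects, %d-channel EEG @ %g Hz\n",
            length(eeg_cfg$groups), eeg_cfg$n_subjects,
            eeg_cfg$eeg$n_channels, eeg_cfg$eeg$fs))
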