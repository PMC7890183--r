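# posturenet

Analysis pipeline for balance-training transfer experiments in R: from
raw center-of-pressure (COP) sway and multichannel scalp EEG to the
group-level statistics of a pre/post training comparison.

Studies of balance-skill transfer ask whether training on one task
(e.g. a stabilometer board) improves postural control on another (e.g.
foam standing), and whether the brain reorganizes toward a more
integrated functional network while doing so. The measurements are (1)
behavioral: sway amplitude, ellipse area, spectral mean frequency, and
sample entropy of the COP trajectory; and (2) neural: phase-lag-based
functional connectivity between EEG channels, summarized by the
topology of the strongest-connection spanning tree. posturenet is for
researchers running, or reanalyzing, this kind of protocol — and,
because raw recordings are rarely deposited, it includes a seeded
synthetic-data module that generates EEG, EOG, sway, and null p-value
inputs with known ground truth so every stage has a recovery test.

## What it computes

**Sway metrics** (per 6 Hz low-pass-conditioned trial):
RMS sway about the mean per axis (cm); 95% confidence ellipse area
`CEA = π · χ²₂,0.95 · √det(S)` (cm²) with `S` the AP/ML sample
covariance; Welch mean frequency `MF = Σ f·P(f) / Σ P(f)` (15 s Hann
windows, 25% overlap, 0.02 Hz grid, band (0, 6]); and sample entropy
`SampEn(m, r, N) = −log(ΣAᵢ / ΣBᵢ)` with m = 2, r = 0.2 SD, computed on
the 100 Hz-decimated trace. Stabilometer rounds get RMS task errors
(seconds 3–42) and round-1-standardized error percentages.

**Connectivity.** Instantaneous phase from the analytic signal;
`PLI = |E{sgn Δφ}|`; and the weighted phase-lag index

    wPLI = |E{Im Z}| / E{|Im Z|},   Z = a_x · conj(a_y),

which weights ±90° phase differences maximally and suppresses
zero-lag (volume-conducted) coupling. Computed for all channel pairs,
per 2 s artifact-free epoch, in the theta (4–8), alpha (8–13) and beta
(13–20 Hz) bands, after zero-phase 1–60 Hz FIR filtering, EOG
regression, and ±100 µV amplitude rejection.

**Network integration.** The maximum-weight spanning tree of each wPLI
matrix (Kruskal, deterministic tie-breaks) and four normalized
topology metrics: diameter, leaf fraction, average eccentricity, and
maximal betweenness `BC_max` — star-like (integrated) networks score
high on leaf fraction and `BC_max`, low on diameter and eccentricity.

**Statistics.** Paired t; paired Hotelling's T² on difference vectors
with `Wilks' Λ = (1 + T²/(n−1))⁻¹` and its exact F transform; and the
Simes procedure (reject `H₍ᵢ₎` iff `p₍ᵢ₎ ≤ i·α/m`) for post-hoc control
within each multivariate family.

## Worked example

```r
library(posturenet)

# one synthetic 60 s sway trial: SD 0.65/0.45 cm, centroid 0.27 Hz
spec <- cop_spec(duration_s = 60, fs = 100,
                 covariance = diag(c(0.65, 0.45)^2),
                 spectral_centroid_hz = 0.27, regularity = 0.5)
trial <- gen_cop(spec, seed = 1)
round(sway_metrics(trial), 3)
#>   rms_ap rms_ml   cea mf_ap mf_ml sampen_ap sampen_ml
#> 1  0.648  0.449 5.474 0.352 0.384     0.141     0.144

# five EEG channels, one alpha-band pair phase-locked near 90 degrees
eeg <- gen_coupled_eeg(coupling_spec(list(c(1, 2)), band = c(8, 13),
                                     phase_lag = pi / 2,
                                     coupling_strength = 0.9, snr_db = 10),
                       n_channels = 5, fs = 250, duration_s = 12, seed = 2)
epochs <- band_filter(epoch_recording(eeg), "alpha")
conn <- connectivity_matrices(epochs, method = "wpli")
round(conn[[1]]$w, 2)
#>      Fp1  Fp2   Fz   F3   F4
#> Fp1 0.00 1.00 0.35 0.23 0.01
#> Fp2 1.00 0.00 0.12 0.73 0.55
#> ...
tree <- max_spanning_tree(conn[[1]])
round(tree_metrics(tree), 3)
#>   diameter leaf_fraction avg_eccentricity bc_max
#> 1        1           0.5              0.8  0.667

simes(c(0.01, 0.2, 0.9))
#> Simes (alpha = 0.05): global REJECT
#>      p rank  threshold reject
#> 1 0.01    1 0.01666667   TRUE
#> 2 0.20    2 0.03333333  FALSE
#> 3 0.90    3 0.05000000  FALSE
```

Reading the numbers: the recovered sway SDs (0.648/0.449 cm) match the
planted covariance; the mean frequencies sit above the planted 0.27 Hz
centroid by the Welch small-sample bias discussed in the vignette; the
planted coupled pair (Fp1–Fp2) carries the matrix's strongest wPLI
(1.00, a near-perfect 90° lock) and becomes a tree edge; and the Simes
staircase (0.0167, 0.0333, 0.05) rejects only the smallest p-value.

## The full study replica

Numbered drivers under `analysis/` run the whole design on synthetic
cohorts and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohort configs + example raw files
Rscript analysis/02_behavioral.R   # sway metrics + paired Hotelling/Simes
Rscript analysis/03_connectome.R   # wPLI -> MST metrics + group tests
Rscript analysis/04_report.R       # pre/post outcome tables + figure
```

The planted scenario shifts the control group's post-session sway
(smaller, faster, more irregular along with its EEG coupling moving
onto a hub channel); the report shows the corresponding AP-direction
and alpha-band findings while the stroboscopic-vision group stays flat.

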