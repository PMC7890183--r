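# Study orchestration: a declarative cohort configuration (groups x
# subjects x sessions x trials, every tunable explicit), deterministic
# synthetic-cohort generation, and the two end-to-end chains --
# behavioral (COP metrics -> paired multivariate tests) and connectome
# (EEG -> wPLI -> spanning-tree metrics -> paired multivariate tests).

#' Study configuration
#'
#' Collects every tunable of the pipeline with the conventional
#' defaults: two training groups of 16 subjects, pre/post sessions,
#' three trials per session, 6 Hz COP conditioning, 1--60 Hz EEG
#' broadband, 2 s epochs with a 2 s discarded head, 100 uV rejection,
#' theta/alpha/beta sub-bands, the cross-spectrum wPLI estimator, and a
#' synthetic scenario whose post-session parameters shift only in the
#' full-vision (control) group.
#'
#' @param groups group labels.
#' @param n_subjects subjects per group.
#' @param sessions session labels (pre first).
#' @param n_trials trials per subject and session.
#' @param seed master seed; all cohort randomness derives from it.
#' @param cop list: `fs`, `duration_s`, `lowpass_hz`.
#' @param eeg list: `fs`, `duration_s`, `n_channels`, `broadband`,
#'   `epoch_s`, `discard_head_s`, `amp_threshold_uV`.
#' @param bands sub-band labels analyzed.
#' @param wpli_variant `"cross-spectrum"` or `"phase-weighted"`.
#' @param sampen list: `m`, `r_fraction`, `target_fs`.
#' @param welch list: `window_s`, `overlap_fraction`, `resolution_hz`,
#'   `band` (integration band for the mean frequency).
#' @param alpha significance level.
#' @param scenario generative ground truth of the synthetic cohort; see
#'   Details in the package vignette.
#' @return an object of class `study_config`.
#' @export
study_config <- function(groups = c("SV", "control"),
                         n_subjects = 16L,
                         sessions = c("pre", "post"),
                         n_trials = 3L,
                         seed = 1L,
                         cop = list(),
                         eeg = list(),
                         bands = c("theta", "alpha", "beta"),
                         wpli_variant = "cross-spectrum",
                         sampen = list(),
                         welch = list(),
                         alpha = 0.05,
                         scenario = list()) {
  cop <- utils::modifyList(list(fs = 100, duration_s = 60, lowpass_hz = 6), cop)
  eeg <- utils::modifyList(list(fs = 1000, duration_s = 30, n_channels = 30L,
                                broadband = c(1, 60), epoch_s = 2,
                                discard_head_s = 2, amp_threshold_uV = 100),
                           eeg)
  sampen <- utils::modifyList(list(m = 2L, r_fraction = 0.2, target_fs = 100), sampen)
  welch <- utils::modifyList(list(window_s = 15, overlap_fraction = 0.25,
                                  resolution_hz = 0.02, band = c(0, 6)), welch)
  scenario <- utils::modifyList(default_scenario(), scenario)
  if (length(sessions) != 2L) abort_param("exactly two sessions (pre, post) expected")
  if (n_subjects < 1L || n_trials < 1L) abort_param("cohort sizes must be positive")
  structure(list(groups = groups, n_subjects = as.integer(n_subjects),
                 sessions = sessions, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), cop = cop, eeg = eeg,
                 bands = bands, wpli_variant = wpli_variant,
                 sampen = sampen, welch = welch, alpha = alpha,
                 scenario = scenario),
            class = "study_config")
}

# Ground-truth generative parameters of the default synthetic cohort.
# Behavioral baselines sit at typical older-adult foam-stance values
# (sway SD ~0.6/0.45 cm AP/ML, sway centroid ~0.27 Hz); the post-session
# effects shift sway amplitude down and frequency/irregularity up in the
# control group only, the direction the pipeline is meant to detect.
default_scenario <- function() {
  list(
    behavioral = list(
      sd_ap = 0.65, sd_ml = 0.45, corr = 0, centroid_hz = 0.27,
      regularity = 0.5, subject_cv = 0.12, trial_cv = 0.05,
      effects = list(
        SV = list(post = list(sd_ap_scale = 1.0, sd_ml_scale = 1.0,
                              centroid_scale = 1.2, regularity_delta = -0.1)),
        control = list(post = list(sd_ap_scale = 0.92, sd_ml_scale = 0.98,
                                   centroid_scale = 1.12,
                                   regularity_delta = -0.08))
      )
    ),
    eeg = list(
      coupling_strength = 0.6, phase_lag = pi / 2, snr_db = 10,
      coupled_bands = "alpha", n_pairs = 4L, hub = 1L,
      topology = list(
        SV = list(pre = "distributed", post = "distributed"),
        control = list(pre = "distributed", post = "hub")
      ),
      artifacts = TRUE, blink_rate_hz = 0.2, blink_amplitude_uV = 60
    )
  )
}

#' Write / read a study configuration as YAML
#'
#' The configuration round-trips losslessly: every tunable written is
#' restored with its type.
#'
#' @param cfg a [study_config()].
#' @param path YAML file path.
#' @return `write_study_config` the path invisibly; `read_study_config`
#'   a [study_config()].
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw[c("groups", "n_subjects", "sessions", "n_trials",
                              "seed", "cop", "eeg", "bands", "wpli_variant",
                              "sampen", "welch", "alpha", "scenario")])
}

# Deterministic seed table: one sub-seed per atomic generation unit.
cohort_seeds <- function(cfg, n) {
  with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, n))
}

# Session effect block for one group, identity when none is declared.
session_effect <- function(scenario_beh, group, session) {
  eff <- list(sd_ap_scale = 1, sd_ml_scale = 1, centroid_scale = 1,
              regularity_delta = 0)
  hit <- scenario_beh$effects[[group]][[session]]
  if (!is.null(hit)) eff <- utils::modifyList(eff, hit)
  eff
}

#' Generate the behavioral arm of a synthetic cohort
#'
#' One [cop_trial()] per group x subject x session x trial, drawn from
#' the scenario's generative parameters: baseline sway SDs, spectral
#' centroid and regularity, lognormal between-subject variation,
#' session effects as declared, and trial-level jitter. Fully
#' deterministic given the master seed.
#'
#' @param cfg a [study_config()].
#' @return list of [cop_trial()] objects with metadata filled in.
#' @export
simulate_cohort_behavioral <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  sb <- cfg$scenario$behavioral
  n_units <- length(cfg$groups) * cfg$n_subjects * length(cfg$sessions) * cfg$n_trials
  seeds <- cohort_seeds(cfg, n_units + length(cfg$groups) * cfg$n_subjects)
  subj_seeds <- utils::tail(seeds, length(cfg$groups) * cfg$n_subjects)
  trials <- vector("list", n_units)
  u <- 0L
  si <- 0L
  for (g in cfg$groups) {
    for (s in seq_len(cfg$n_subjects)) {
      si <- si + 1L
      subj <- with_seed(subj_seeds[si], {
        list(sd_ap = sb$sd_ap * exp(stats::rnorm(1L, 0, sb$subject_cv)),
             sd_ml = sb$sd_ml * exp(stats::rnorm(1L, 0, sb$subject_cv)),
             centroid = sb$centroid_hz * exp(stats::rnorm(1L, 0, sb$subject_cv / 2)),
             regularity = min(0.95, max(0.05, sb$regularity +
                                          stats::rnorm(1L, 0, 0.05))))
      })
      for (sess in cfg$sessions) {
        eff <- session_effect(sb, g, sess)
        for (tr in seq_len(cfg$n_trials)) {
          u <- u + 1L
          jit <- with_seed(seeds[u], exp(stats::rnorm(2L, 0, sb$trial_cv)))
          sd_ap <- subj$sd_ap * eff$sd_ap_scale * jit[1]
          sd_ml <- subj$sd_ml * eff$sd_ml_scale * jit[2]
          cv <- matrix(c(sd_ap^2, sb$corr * sd_ap * sd_ml,
                         sb$corr * sd_ap * sd_ml, sd_ml^2), 2L, 2L)
          spec <- cop_spec(cfg$cop$duration_s, cfg$cop$fs, cv,
                           subj$centroid * eff$centroid_scale,
                           min(0.95, max(0, subj$regularity + eff$regularity_delta)))
          trials[[u]] <- gen_cop(spec, seed = seeds[u], trial_id = tr,
                                 subject_id = sprintf("%s%02d", g, s),
                                 session = sess, group = g)
        }
      }
    }
  }
  trials
}

# coupled-pair layout for one condition: "distributed" disjoint pairs
# scattered over the montage, "hub" couples one channel to every other
make_pairs <- function(type, n_channels, n_pairs, hub = 1L) {
  if (type == "hub") {
    others <- setdiff(seq_len(n_channels), hub)
    lapply(others, function(k) c(hub, k))
  } else {
    n_pairs <- min(n_pairs, n_channels %/% 2L)
    lapply(seq_len(n_pairs), function(k) c(2L * k - 1L, 2L * k))
  }
}

# one synthetic EEG trial: superposition of per-band narrowband
# components (coupling only in the scenario's coupled bands), then
# ocular contamination when the scenario asks for it
gen_cohort_eeg_trial <- function(cfg, topology, seed) {
  se <- cfg$scenario$eeg
  ec <- cfg$eeg
  dat <- NULL
  band_defs <- eeg_bands()[cfg$bands]
  for (b in seq_along(band_defs)) {
    coupled <- names(band_defs)[b] %in% se$coupled_bands
    pairs <- if (coupled) make_pairs(topology, ec$n_channels, se$n_pairs, se$hub)
             else list()
    spec <- coupling_spec(pairs, band_defs[[b]],
                          phase_lag = se$phase_lag,
                          coupling_strength = se$coupling_strength,
                          snr_db = se$snr_db)
    rec <- gen_coupled_eeg(spec, n_channels = ec$n_channels, fs = ec$fs,
                           duration_s = ec$duration_s, seed = seed + b)
    dat <- if (is.null(dat)) rec$data else dat + rec$data
  }
  rec <- eeg_recording(dat, ec$fs)
  if (isTRUE(se$artifacts)) {
    prop <- 0.6 * exp(-(seq_len(ec$n_channels) - 1L) / 6)
    sim <- gen_eog_artifacts(rec, blink_rate_hz = se$blink_rate_hz,
                             amplitude_uV = se$blink_amplitude_uV,
                             propagation = prop, seed = seed)
    rec <- sim$recording
  }
  rec
}

#' Run the behavioral chain of the study
#'
#' Per trial: 6 Hz low-pass conditioning and the full sway-metric
#' bundle; per subject: the 3-trial mean; per group: paired Hotelling's
#' T-squared over the (RMS, MF, SampEn) triple in each direction with
#' Simes post-hoc paired t-tests, plus a paired t on the ellipse area.
#'
#' @param cfg a [study_config()].
#' @param cohort optional list of [cop_trial()] objects (e.g. loaded
#'   from files); generated from the scenario when omitted.
#' @return list with `trial_metrics`, `subject_metrics` (tidy data
#'   frames) and `tests` (tidy table: group, family, variable,
#'   statistic, wilks_lambda, df, p, simes_threshold, reject).
#' @export
run_behavioral <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(cohort)) cohort <- simulate_cohort_behavioral(cfg)
  meta <- lapply(cohort, function(t)
    data.frame(group = t$group, subject = t$subject_id, session = t$session,
               trial = t$trial_id, stringsAsFactors = FALSE))
  meta <- do.call(rbind, meta)
  if (anyNA(meta$subject) || anyNA(meta$session))
    abort_param("cohort trials are missing subject or session metadata")
  scfg <- sampen_config(cfg$sampen$m, cfg$sampen$r_fraction, cfg$sampen$target_fs)
  rows <- lapply(cohort, function(t)
    sway_metrics(t, lowpass_hz = cfg$cop$lowpass_hz, sampen = scfg,
                 mf_window_s = cfg$welch$window_s, mf_band = cfg$welch$band))
  trial_metrics <- cbind(meta, do.call(rbind, rows))
  metric_cols <- setdiff(names(trial_metrics), names(meta))
  subject_metrics <- stats::aggregate(
    trial_metrics[metric_cols],
    by = trial_metrics[c("group", "subject", "session")], FUN = mean)
  tests <- group_tests_behavioral(cfg, subject_metrics)
  list(trial_metrics = trial_metrics, subject_metrics = subject_metrics,
       tests = tests)
}

# matched pre/post matrices for one group, erroring on pairing defects
paired_matrices <- function(subject_metrics, group, sessions, cols) {
  gm <- subject_metrics[subject_metrics$group == group, ]
  pre <- gm[gm$session == sessions[1], ]
  post <- gm[gm$session == sessions[2], ]
  pre <- pre[order(pre$subject), ]
  post <- post[order(post$subject), ]
  if (nrow(pre) != nrow(post) || !identical(pre$subject, post$subject))
    abort_param(sprintf("group %s: pre and post subject sets differ", group))
  if (nrow(pre) < 2L)
    abort_param(sprintf("group %s: paired statistics need at least 2 subjects", group))
  list(pre = as.matrix(pre[cols]), post = as.matrix(post[cols]),
       subjects = pre$subject)
}

group_tests_behavioral <- function(cfg, subject_metrics) {
  out <- list()
  families <- list(AP = c("rms_ap", "mf_ap", "sampen_ap"),
                   ML = c("rms_ml", "mf_ml", "sampen_ml"))
  for (g in cfg$groups) {
    for (fam in names(families)) {
      pm <- paired_matrices(subject_metrics, g, cfg$sessions, families[[fam]])
      ft <- paired_family_test(pm$pre, pm$post, labels = families[[fam]],
                               family = fam, alpha = cfg$alpha)
      ft$table$group <- g
      out[[length(out) + 1L]] <- ft$table
    }
    pm <- paired_matrices(subject_metrics, g, cfg$sessions, "cea")
    tt <- paired_t(pm$pre[, 1], pm$post[, 1])
    out[[length(out) + 1L]] <- data.frame(
      group = g, family = "CEA", variable = "cea", statistic = tt$statistic,
      wilks_lambda = NA_real_, df1 = tt$df, df2 = NA_real_, p = tt$p_value,
      simes_threshold = NA_real_, reject = tt$p_value <= cfg$alpha)
  }
  tab <- do.call(rbind, out)
  tab[c("group", setdiff(names(tab), "group"))]
}

#' Run the connectome chain of the study
#'
#' Per trial: synthetic EEG generation from the scenario's coupling
#' topology, preprocessing (broadband filter, ocular regression,
#' epoching, rejection), per-band wPLI per epoch, a maximum spanning
#' tree per epoch, and the four integration metrics averaged over
#' epochs; per subject: the trial mean; per group and metric: paired
#' Hotelling's T-squared across the three sub-bands with Simes post-hoc
#' paired t-tests.
#'
#' @param cfg a [study_config()].
#' @param progress print one line per processed trial.
#' @param tests run the group statistics (set `FALSE` for metric-only
#'   runs, e.g. cohorts too small for a stable multivariate test).
#' @return list with `trial_metrics`, `subject_metrics`, `tests` (tidy
#'   tables as in [run_behavioral()]; `family` is the tree metric and
#'   `variable` the sub-band; `NULL` when `tests = FALSE`).
#' @export
run_connectome <- function(cfg, progress = FALSE, tests = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  se <- cfg$scenario$eeg
  n_units <- length(cfg$groups) * cfg$n_subjects * length(cfg$sessions) * cfg$n_trials
  seeds <- cohort_seeds(cfg, n_units) + 10L  # offset from behavioral stream
  rows <- list()
  u <- 0L
  for (g in cfg$groups) {
    for (s in seq_len(cfg$n_subjects)) {
      for (sess in cfg$sessions) {
        topology <- se$topology[[g]][[sess]]
        if (is.null(topology)) topology <- "distributed"
        for (tr in seq_len(cfg$n_trials)) {
          u <- u + 1L
          rec <- gen_cohort_eeg_trial(cfg, topology, seeds[u])
          eps <- preprocess_eeg(rec, broadband = cfg$eeg$broadband,
                                epoch_s = cfg$eeg$epoch_s,
                                discard_head_s = cfg$eeg$discard_head_s,
                                amp_threshold_uV = cfg$eeg$amp_threshold_uV)
          n_kept <- sum(eps$mask$kept)
          for (b in cfg$bands) {
            beps <- band_filter(eps, b)
            cms <- connectivity_matrices(beps, method = "wpli",
                                         variant = cfg$wpli_variant)
            trees <- lapply(cms, max_spanning_tree)
            tm <- aggregate_metrics(trees)
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(group = g, subject = sprintf("%s%02d", g, s),
                         session = sess, trial = tr, band = b,
                         n_epochs = n_kept, stringsAsFactors = FALSE),
              tm)
          }
          if (progress)
            message(sprintf("%s %s %s trial %d: %d/%d epochs kept",
                            g, sprintf("%s%02d", g, s), sess, tr,
                            n_kept, length(eps$epochs)))
        }
      }
    }
  }
  trial_metrics <- do.call(rbind, rows)
  metric_cols <- c("diameter", "leaf_fraction", "avg_eccentricity", "bc_max")
  subject_metrics <- stats::aggregate(
    trial_metrics[metric_cols],
    by = trial_metrics[c("group", "subject", "session", "band")], FUN = mean)
  tests_tab <- if (tests) group_tests_connectome(cfg, subject_metrics, metric_cols)
               else NULL
  list(trial_metrics = trial_metrics, subject_metrics = subject_metrics,
       tests = tests_tab)
}

group_tests_connectome <- function(cfg, subject_metrics, metric_cols) {
  out <- list()
  for (g in cfg$groups) {
    for (metric in metric_cols) {
      wide <- stats::reshape(
        subject_metrics[subject_metrics$group == g,
                        c("subject", "session", "band", metric)],
        idvar = c("subject", "session"), timevar = "band",
        direction = "wide")
      names(wide) <- sub(paste0("^", metric, "\\."), "", names(wide))
      pm <- paired_matrices(cbind(wide, group = g), g, cfg$sessions, cfg$bands)
      ft <- paired_family_test(pm$pre, pm$post, labels = cfg$bands,
                               family = metric, alpha = cfg$alpha)
      ft$table$group <- g
      out[[length(out) + 1L]] <- ft$table
    }
  }
  tab <- do.call(rbind, out)
  tab[c("group", setdiff(names(tab), "group"))]
}

#' Render a tests table as a human-readable pre/post outcome table
#'
#' @param tests tidy tests table from [run_behavioral()] or
#'   [run_connectome()].
#' @return character vector of formatted lines.
#' @export
format_study_table <- function(tests) {
  lines <- character(0L)
  for (g in unique(tests$group)) {
    lines <- c(lines, sprintf("== group %s ==", g))
    gt <- tests[tests$group == g, ]
    for (fam in unique(gt$family)) {
      ft <- gt[gt$family == fam, ]
      mv <- ft[ft$variable == "(multivariate)", ]
      if (nrow(mv)) {
        lines <- c(lines, sprintf(
          "%-18s Wilks' lambda = %.3f, T2 = %.3f, p = %.3f%s",
          fam, mv$wilks_lambda, mv$statistic, mv$p,
          if (mv$reject) " *" else ""))
      }
      ph <- ft[ft$variable != "(multivariate)", ]
      for (k in seq_len(nrow(ph))) {
        lines <- c(lines, sprintf(
          "  %-16s t = %8.3f, p = %.3f%s", ph$variable[k],
          ph$statistic[k], ph$p[k],
          if (isTRUE(ph$reject[k]) && is.finite(ph$simes_threshold[k]))
            sprintf(" (Simes <= %.4f) *", ph$simes_threshold[k])
          else if (isTRUE(ph$reject[k])) " *" else ""))
      }
    }
  }
  lines
}
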