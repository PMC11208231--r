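## Synthetic cohorts with known ground truth: TMS mapping sessions with a
## Gaussian MEP-amplitude response surface, spiral-tracking trials with
## first-order lag + angular noise, QST raw records encoding planted
## outcome values, and a matched case-control subject table.

TRUNK_MUSCLES <- c("longissimus_L3", "longissimus_L5",
                   "obliquus_externus", "obliquus_internus")

CLINICAL_TESTS <- c("ts", "ppt", "cpm_rel", "cpm_abs",
                    "tpd", "graphaesthesia", "vibration",
                    "path", "angular_near", "time_near")

## Published group-difference coefficients used as the default planted
## effects (LBP minus control), and the standard errors from which the
## default noise scales are back-solved (sigma_total = SE * sqrt(n/2) at
## n = 25 per group).
.default_effects <- list(
  area = c(longissimus_L3 = -363.586, longissimus_L5 = 234.646,
           obliquus_externus = 1050.963, obliquus_internus = 3.591),
  cog_ap = c(longissimus_L3 = -0.622, longissimus_L5 = -1.989,
             obliquus_externus = -2.887, obliquus_internus = -2.064),
  cog_ml = c(longissimus_L3 = -4.120, longissimus_L5 = -5.916,
             obliquus_externus = 0.202, obliquus_internus = -2.807),
  cog_vert = c(longissimus_L3 = -1.298, longissimus_L5 = -2.231,
               obliquus_externus = -0.002, obliquus_internus = -2.709),
  clinical = c(ts = 0.992, ppt = -6.096, cpm_rel = 5.351, cpm_abs = -2.323,
               tpd = 1.533, graphaesthesia = 1.400, vibration = 0.027,
               path = -8.588, angular_near = 0.029, time_near = -1.203)
)

.default_se <- c(ts = 0.341, ppt = 6.157, cpm_rel = 6.157, cpm_abs = 6.157,
                 tpd = 4.511, graphaesthesia = 4.511, vibration = 0.226,
                 path = 8.380, angular_near = 0.084, time_near = 4.190)

.default_means <- c(ts = 1.0, ppt = 45, cpm_rel = 10, cpm_abs = 5,
                    tpd = 45, graphaesthesia = 20, vibration = 6.5,
                    path = 90, angular_near = 0.8, time_near = 60)

#' Simulation configuration for a synthetic cohort
#'
#' Assembles and validates the parameters of the synthetic-data generator.
#' The defaults reproduce the study conditions this package targets: a
#' 25 + 25 matched cohort, four trunk muscles mapped with 100 TMS
#' stimulations at pseudorandom scalp positions, a Gaussian MEP-amplitude
#' response surface centred on a muscle-specific true CoG, 6.5% of muscle
#' outcomes missing completely at random, two ~2-minute spiral-tracking
#' trials, and a QST battery whose planted group effects equal the
#' published case-control coefficients.
#'
#' @param n_per_group subjects per group (>= 2; default 25).
#' @param muscles muscle labels (default the four trunk muscles).
#' @param n_stims stimulations per mapping session (default 100).
#' @param scalp_extent extent (mm) of the axis-aligned rectangle of
#'   pseudorandom stimulation sites in the tangent plane (default 60 x 60).
#' @param site_z_sd out-of-plane (vertical) scatter of the stimulation
#'   sites in mm (default 1.5), emulating scalp curvature and coil
#'   placement variability.
#' @param true_cog named list, per-muscle control-group CoG (mm, 3-vector).
#' @param cog_group_shift named list, per-muscle LBP-minus-control CoG shift
#'   (mm, 3-vector); defaults to the published coefficients.
#' @param amplitude_peak peak of the MEP response surface (uV, default 400).
#' @param spatial_sd spatial SD of the Gaussian surface (mm, default 10).
#' @param noise_sd SD of the additive amplitude noise (uV, default 20).
#' @param emg_rate EMG sampling rate (Hz, default 2000).
#' @param cog_subject_sd between-subject SD of each subject's map position,
#'   one value per axis (medio-lateral, posterior-anterior, vertical; mm).
#'   The defaults are back-solved from the published per-axis standard
#'   errors (SE * sqrt(n/2) at n = 25 per group).
#' @param spatial_sd_cv between-subject coefficient of variation of the
#'   response-surface width (lognormal multiplier, default 0.3): map
#'   extents differ across individuals, which is what drives between-
#'   subject area variance.
#' @param missing_rate completely-at-random missing probability per
#'   subject x muscle outcome (default 0.065).
#' @param track_duration,track_rate,track_turns tracking-trial duration (s),
#'   sampling rate (Hz) and spiral turns (defaults 120 s, 60 Hz, 4).
#' @param track_lag first-order lag time constant of the simulated cursor
#'   (s, default 0.3).
#' @param track_noise_sd per-axis angular noise SD (degrees, default 0.5).
#' @param group_effects named vector of planted LBP-minus-control effects
#'   for the clinical/motor tests (units of each test); defaults to the
#'   published coefficients.
#' @param test_means named vector of control-group test means.
#' @param subject_sd between-subject random-intercept SD for the clinical
#'   tests; scalar, or named per test family. The default allots one third
#'   of each test's total variance (back-solved from the published standard
#'   errors) to the subject level, capped by the smallest-variance test of
#'   each model family so a single additive intercept is consistent within
#'   the family.
#' @param residual_sd named vector of per-test residual SDs; default
#'   back-solved from the published standard errors.
#' @param seed integer root seed. All entity-level streams are derived from
#'   it by stable hashing, so the same configuration is byte-identical
#'   across runs and adding subjects does not reshuffle existing ones.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 25,
                       muscles = TRUNK_MUSCLES,
                       n_stims = 100,
                       scalp_extent = c(60, 60),
                       site_z_sd = 1.5,
                       true_cog = NULL,
                       cog_group_shift = NULL,
                       amplitude_peak = 400,
                       spatial_sd = 10,
                       noise_sd = 20,
                       emg_rate = 2000,
                       cog_subject_sd = c(8.4, 10.0, 4.9),
                       spatial_sd_cv = 0.3,
                       missing_rate = 0.065,
                       track_duration = 120,
                       track_rate = 60,
                       track_turns = 4,
                       track_lag = 0.3,
                       track_noise_sd = 0.5,
                       group_effects = NULL,
                       test_means = NULL,
                       subject_sd = NULL,
                       residual_sd = NULL,
                       seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 2) {
    stop_field("n_per_group", "must be >= 2")
  }
  check_scalar(n_stims, "n_stims", lower = 1)
  check_scalar(amplitude_peak, "amplitude_peak", lower = 0,
               strict_lower = TRUE)
  check_scalar(spatial_sd, "spatial_sd", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(emg_rate, "emg_rate", lower = 120)
  if (!length(cog_subject_sd) %in% c(1L, 3L) || any(cog_subject_sd < 0)) {
    stop_field("cog_subject_sd", "needs 1 or 3 non-negative SDs (mm)")
  }
  cog_subject_sd <- rep_len(cog_subject_sd, 3L)
  check_scalar(spatial_sd_cv, "spatial_sd_cv", lower = 0)
  check_scalar(track_duration, "track_duration", lower = 0,
               strict_lower = TRUE)
  check_scalar(track_rate, "track_rate", lower = 0, strict_lower = TRUE)
  check_scalar(track_lag, "track_lag", lower = 0)
  check_scalar(track_noise_sd, "track_noise_sd", lower = 0)
  check_scalar(seed, "seed")
  if (length(scalp_extent) != 2L || any(scalp_extent <= 0)) {
    stop_field("scalp_extent", "must be two positive extents (mm)")
  }
  check_scalar(site_z_sd, "site_z_sd", lower = 0)

  if (is.null(true_cog)) {
    true_cog <- list(longissimus_L3 = c(12, -22, 72),
                     longissimus_L5 = c(10, -26, 70),
                     obliquus_externus = c(14, -18, 74),
                     obliquus_internus = c(13, -20, 71))[muscles]
    if (any(vapply(true_cog, is.null, TRUE))) {
      stop_field("true_cog", "required for non-default muscle labels")
    }
  }
  if (is.null(cog_group_shift)) {
    cog_group_shift <- lapply(muscles, function(m) {
      c(.default_effects$cog_ml[m], .default_effects$cog_ap[m],
        .default_effects$cog_vert[m])
    })
    names(cog_group_shift) <- muscles
    cog_group_shift <- lapply(cog_group_shift, function(v) {
      v[is.na(v)] <- 0
      unname(v)
    })
  }
  if (!all(muscles %in% names(true_cog)) ||
      !all(vapply(true_cog[muscles], length, 0L) == 3L)) {
    stop_field("true_cog", "needs a 3-vector per muscle")
  }
  if (is.null(group_effects)) group_effects <- .default_effects$clinical
  if (is.null(test_means)) test_means <- .default_means[names(group_effects)]
  sigma_tot <- .default_se * sqrt(n_per_group / 2)
  if (is.null(subject_sd)) {
    fam <- clinical_families()
    subject_sd <- numeric(0)
    for (f in names(fam)) {
      tests <- intersect(fam[[f]], names(group_effects))
      if (length(tests) == 0L) next
      s <- sqrt(1 / 3) * min(sigma_tot[tests], na.rm = TRUE)
      subject_sd[tests] <- s
    }
  }
  if (is.null(residual_sd)) {
    residual_sd <- sqrt(pmax(sigma_tot[names(group_effects)]^2 -
                               subject_sd[names(group_effects)]^2, 1e-12))
  }
  if (any(residual_sd < 0) || any(subject_sd < 0)) {
    stop_field("residual_sd", "SDs must be >= 0")
  }

  structure(list(
    n_per_group = as.integer(n_per_group), muscles = muscles,
    n_stims = as.integer(n_stims), scalp_extent = scalp_extent,
    site_z_sd = site_z_sd,
    true_cog = true_cog, cog_group_shift = cog_group_shift,
    amplitude_peak = amplitude_peak, spatial_sd = spatial_sd,
    noise_sd = noise_sd, emg_rate = emg_rate,
    cog_subject_sd = cog_subject_sd, spatial_sd_cv = spatial_sd_cv,
    missing_rate = missing_rate,
    track_duration = track_duration, track_rate = track_rate,
    track_turns = track_turns, track_lag = track_lag,
    track_noise_sd = track_noise_sd,
    group_effects = group_effects, test_means = test_means,
    subject_sd = subject_sd, residual_sd = residual_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Model families of the clinical and map outcomes
#'
#' The groupings under which tests are stacked into one multivariate mixed
#' model: four map families (area and the three CoG axes, with muscles as
#' the Test variable) and three clinical families (QST pain, sensory
#' accuracy, motor test).
#'
#' @return named list of test-label character vectors.
#' @export
clinical_families <- function() {
  list(qst_pain = c("ts", "ppt", "cpm_rel", "cpm_abs"),
       sensory_accuracy = c("tpd", "graphaesthesia", "vibration"),
       motor_test = c("path", "angular_near", "time_near"))
}

#' Synthetic MEP waveform
#'
#' One cycle of a windowed sine (default 100 Hz) at a 20 ms post-stimulus
#' latency, scaled so the raw epoch's peak-to-peak amplitude equals
#' `amplitude` exactly when the extremes fall on samples (the default
#' 2 kHz / 100 Hz combination guarantees this).
#'
#' @param amplitude target peak-to-peak amplitude in uV.
#' @param sampling_rate Hz.
#' @param duration epoch length s (default 0.5).
#' @param latency onset of the deflection s (default 0.02).
#' @param freq wavelet frequency Hz; the default, one twentieth of the
#'   sampling rate, puts the extremes exactly on samples at any rate.
#' @return numeric vector of `duration * sampling_rate` samples.
#' @export
mep_waveform <- function(amplitude, sampling_rate, duration = 0.5,
                         latency = 0.02, freq = sampling_rate / 20) {
  n <- as.integer(round(duration * sampling_rate))
  x <- numeric(n)
  n_cyc <- as.integer(round(sampling_rate / freq))
  i0 <- as.integer(round(latency * sampling_rate))
  idx <- seq_len(n_cyc) + i0
  idx <- idx[idx <= n]
  x[idx] <- (amplitude / 2) * sin(2 * pi * freq * (seq_along(idx)) /
                                    sampling_rate)
  x
}

#' Gaussian MEP-amplitude response surface
#'
#' Expected peak-to-peak amplitude at distance `d` from the map's true CoG:
#' `peak * exp(-d^2 / (2 * sd^2))`.
#'
#' @param d distance(s) from the true CoG in mm.
#' @param peak surface peak in uV.
#' @param spatial_sd spatial SD in mm.
#' @return expected amplitude(s) in uV.
#' @export
amplitude_surface <- function(d, peak, spatial_sd) {
  peak * exp(-d^2 / (2 * spatial_sd^2))
}

#' Simulate one TMS mapping session
#'
#' Draws `n_stims` stimulation sites uniformly over the configured scalp
#' patch (an axis-aligned rectangle in the tangent plane centred on the
#' session's true CoG), computes each site's expected MEP amplitude from
#' the Gaussian response surface plus amplitude noise, and synthesizes a
#' raw EMG epoch per stimulation whose peak-to-peak equals that amplitude.
#' Sites whose surface value falls below the 50 uV criterion produce
#' sub-threshold epochs. Sessions flagged `missing` have all amplitudes
#' scaled below threshold, emulating a muscle for which no MEPs could be
#' elicited.
#'
#' @param cfg a [sim_config()].
#' @param subject subject identifier (enters the RNG substream).
#' @param muscle muscle label; must be one of `cfg$muscles`.
#' @param group `"control"` or `"LBP"` (applies the planted CoG shift).
#' @param cog_offset optional per-subject 3-vector added to the true CoG.
#' @param hemisphere stimulated hemisphere; the configured CoGs are
#'   right-hemisphere coordinates and `"left"` mirrors the session's map
#'   (X to -X), the convention [pool_hemispheres()] undoes before group
#'   analysis.
#' @param missing generate an MEP-less session (default FALSE).
#' @param spatial_sd_mult subject-specific multiplier of the response-
#'   surface width (default 1).
#' @return list of class `tms_session`: `sites` data.frame
#'   (`stim_id`, `x`, `y`, `z`, `true_amplitude`), `epochs` matrix
#'   (n_stims x n_samples, uV), `sampling_rate`, `muscle`, `true_cog`.
#' @export
simulate_tms_session <- function(cfg, subject, muscle,
                                 group = c("control", "LBP"),
                                 cog_offset = c(0, 0, 0),
                                 hemisphere = c("right", "left"),
                                 missing = FALSE,
                                 spatial_sd_mult = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  group <- match.arg(group)
  hemisphere <- match.arg(hemisphere)
  if (!muscle %in% cfg$muscles) {
    stop_field("muscle", sprintf("unknown muscle '%s'", muscle))
  }
  true_cog <- cfg$true_cog[[muscle]] +
    (group == "LBP") * cfg$cog_group_shift[[muscle]] + cog_offset
  if (hemisphere == "left") true_cog[1] <- -true_cog[1]
  with_substream(cfg$seed, "tms", subject, muscle, expr = {
    ex <- cfg$scalp_extent
    x <- stats::runif(cfg$n_stims, true_cog[1] - ex[1] / 2,
                      true_cog[1] + ex[1] / 2)
    y <- stats::runif(cfg$n_stims, true_cog[2] - ex[2] / 2,
                      true_cog[2] + ex[2] / 2)
    z <- stats::rnorm(cfg$n_stims, true_cog[3], cfg$site_z_sd)
    d <- sqrt((x - true_cog[1])^2 + (y - true_cog[2])^2 +
                (z - true_cog[3])^2)
    amp <- amplitude_surface(d, cfg$amplitude_peak,
                             cfg$spatial_sd * spatial_sd_mult)
    if (missing) amp <- pmin(amp * 0, 30)   # no elicitable MEPs
    if (cfg$noise_sd > 0 && !missing) {
      amp <- amp + stats::rnorm(cfg$n_stims, 0, cfg$noise_sd)
    }
    amp <- pmax(amp, 0)
    n_samp <- as.integer(round(0.5 * cfg$emg_rate))
    epochs <- matrix(0, nrow = cfg$n_stims, ncol = n_samp)
    for (i in seq_len(cfg$n_stims)) {
      epochs[i, ] <- mep_waveform(amp[i], cfg$emg_rate)
    }
    structure(list(
      sites = data.frame(stim_id = seq_len(cfg$n_stims),
                         x = x, y = y, z = z, true_amplitude = amp),
      epochs = epochs, sampling_rate = cfg$emg_rate,
      muscle = muscle, true_cog = true_cog
    ), class = "tms_session")
  })
}

#' Simulate a spiral-tracking trial
#'
#' The target follows the Archimedean spiral of [spiral_target()]; the
#' simulated cursor is the target passed through a first-order lag with
#' time constant `cfg$track_lag` plus independent Gaussian angular noise
#' per axis. With zero lag and zero noise the cursor equals the target at
#' every sample.
#'
#' @param cfg a [sim_config()].
#' @param subject subject identifier (enters the RNG substream).
#' @param trial trial number (1 = practice).
#' @return data.frame of class `tracking_trial` with columns `t`,
#'   `target_x`, `target_y`, `actual_x`, `actual_y`, attribute
#'   `sampling_rate`.
#' @export
simulate_tracking_trial <- function(cfg, subject, trial = 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  tt <- seq(0, cfg$track_duration, by = 1 / cfg$track_rate)
  tgt <- spiral_target(tt, duration = cfg$track_duration,
                       n_turns = cfg$track_turns)
  with_substream(cfg$seed, "track", subject, trial, expr = {
    n <- length(tt)
    dt <- 1 / cfg$track_rate
    if (cfg$track_lag > 0) {
      a <- dt / (cfg$track_lag + dt)
      ax <- as.numeric(stats::filter(a * tgt$x, 1 - a, method = "recursive"))
      ay <- as.numeric(stats::filter(a * tgt$y, 1 - a, method = "recursive"))
    } else {
      ax <- tgt$x; ay <- tgt$y
    }
    if (cfg$track_noise_sd > 0) {
      ax <- ax + stats::rnorm(n, 0, cfg$track_noise_sd)
      ay <- ay + stats::rnorm(n, 0, cfg$track_noise_sd)
    }
    out <- data.frame(t = tt, target_x = tgt$x, target_y = tgt$y,
                      actual_x = ax, actual_y = ay)
    attr(out, "sampling_rate") <- cfg$track_rate
    class(out) <- c("tracking_trial", "data.frame")
    out
  })
}

#' Simulate a long outcome table with planted effects
#'
#' The statistical core of the generator: subject-level random intercepts
#' `u_i ~ N(0, subject_sd^2)` shared across the tests of one model family,
#' and per-record values
#' `value = mean_test + effect_test * 1[LBP] + u_i + N(0, residual_sd_test^2)`.
#' Used directly for the mixed-model recovery, coverage and type-I
#' validation suites, where the raw-signal route would only add noise that
#' the scorers remove again.
#'
#' @param n_per_group subjects per group.
#' @param tests test labels.
#' @param effects named planted LBP-minus-control effects (recycled if
#'   scalar).
#' @param means named control-group means (default 0).
#' @param subject_sd random-intercept SD (scalar).
#' @param residual_sd named per-test residual SD (recycled if scalar).
#' @param seed integer seed.
#' @param missing_rate completely-at-random record deletion rate.
#' @return long data.frame: `subject`, `group`, `test`, `value`, plus the
#'   planted truth in attribute `truth`.
#' @export
simulate_outcome_table <- function(n_per_group, tests, effects = 0,
                                   means = 0, subject_sd = 1,
                                   residual_sd = 1, seed = 1L,
                                   missing_rate = 0) {
  n_tests <- length(tests)
  eff <- rep_len(effects, n_tests); names(eff) <- tests
  if (!is.null(names(effects))) eff[names(effects)] <- effects
  mu <- rep_len(means, n_tests); names(mu) <- tests
  if (!is.null(names(means))) mu[names(means)] <- means
  rsd <- rep_len(residual_sd, n_tests); names(rsd) <- tests
  if (!is.null(names(residual_sd))) rsd[names(residual_sd)] <- residual_sd
  check_scalar(subject_sd, "subject_sd", lower = 0)
  check_scalar(missing_rate, "missing_rate", lower = 0, upper = 1,
               strict_upper = TRUE)

  subjects <- sprintf("S%03d", seq_len(2 * n_per_group))
  group <- rep(c("control", "LBP"), each = n_per_group)
  u <- vapply(subjects, function(s) {
    with_substream(seed, "intercept", s, expr = stats::rnorm(1, 0, subject_sd))
  }, numeric(1))
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    vals <- with_substream(seed, "value", subjects[i], expr = {
      mu + eff * (group[i] == "LBP") + u[i] +
        stats::rnorm(n_tests, 0, rsd)
    })
    rows[[i]] <- data.frame(subject = subjects[i], group = group[i],
                            test = tests, value = unname(vals),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (missing_rate > 0) {
    drop <- with_substream(seed, "missing", expr = {
      stats::runif(nrow(out)) < missing_rate
    })
    out <- out[!drop, , drop = FALSE]
  }
  out$group <- factor(out$group, levels = c("control", "LBP"))
  out$test <- factor(out$test, levels = tests)
  rownames(out) <- NULL
  attr(out, "truth") <- list(effects = eff, means = mu,
                             subject_sd = subject_sd, residual_sd = rsd,
                             intercepts = u)
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates every input of the end-to-end pipeline with known ground
#' truth: the subject table (balanced groups, matched age/sex structure,
#' 9:16 left:right hemisphere mix), one raw TMS mapping session per
#' subject x muscle (with completely-at-random missing muscle outcomes at
#' `cfg$missing_rate`, realized as sessions in which no epoch crosses the
#' 50 uV criterion), two tracking trials per subject (the first is the
#' practice trial), and QST raw records that score exactly to the planted
#' clinical outcome values (replicate trials are identical, so the
#' mean-based scorers reproduce the planted value; values are clamped to
#' their physical scales before encoding).
#'
#' @param cfg a [sim_config()].
#' @param raw_tms generate raw EMG sessions (default TRUE). With FALSE the
#'   `sessions` element is omitted (outcome-level work only), which is much
#'   lighter.
#' @return list of class `synthetic_cohort`: `subjects`, `sessions`
#'   (nested list `[[subject]][[muscle]]`), `tracking` (list per subject of
#'   two trials), `qst` (list per subject of raw records), `truth` (planted
#'   parameters, per-subject CoGs, pre-clamp outcome values, missing flags),
#'   `config`.
#' @export
simulate_cohort <- function(cfg, raw_tms = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_per_group
  subjects <- sprintf("S%03d", seq_len(2 * n))
  group <- rep(c("control", "LBP"), each = n)
  age <- vapply(subjects, function(s) {
    with_substream(cfg$seed, "age", s,
                   expr = round(stats::runif(1, 20, 64)))
  }, numeric(1))
  sex <- rep_len(c("M", "F"), 2 * n)
  hemi <- vapply(subjects, function(s) {
    with_substream(cfg$seed, "hemi", s, expr = {
      sample(c("left", "right"), 1, prob = c(9, 16))
    })
  }, character(1))
  subj_tab <- data.frame(subject = subjects,
                         group = factor(group,
                                        levels = c("control", "LBP")),
                         age = age, sex = sex, hemisphere = hemi,
                         stringsAsFactors = FALSE)
  rownames(subj_tab) <- NULL

  ## per-subject map offset and extent multiplier, shared across muscles
  cog_offset <- lapply(subjects, function(s) {
    with_substream(cfg$seed, "cogjit", s,
                   expr = stats::rnorm(3, 0, cfg$cog_subject_sd))
  })
  names(cog_offset) <- subjects
  sdlog <- sqrt(log(1 + cfg$spatial_sd_cv^2))
  sd_mult <- vapply(subjects, function(s) {
    with_substream(cfg$seed, "sdjit", s,
                   expr = exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)))
  }, numeric(1))

  ## completely-at-random missing muscle outcomes
  miss <- matrix(FALSE, nrow = 2 * n, ncol = length(cfg$muscles),
                 dimnames = list(subjects, cfg$muscles))
  for (s in subjects) {
    for (m in cfg$muscles) {
      miss[s, m] <- with_substream(cfg$seed, "miss", s, m, expr = {
        stats::runif(1) < cfg$missing_rate
      })
    }
  }

  sessions <- NULL
  if (raw_tms) {
    sessions <- lapply(subjects, function(s) {
      g <- if (subj_tab$group[subj_tab$subject == s] == "LBP") "LBP"
           else "control"
      h <- subj_tab$hemisphere[subj_tab$subject == s]
      out <- lapply(cfg$muscles, function(m) {
        simulate_tms_session(cfg, s, m, group = g,
                             cog_offset = cog_offset[[s]],
                             hemisphere = h,
                             missing = miss[s, m],
                             spatial_sd_mult = sd_mult[[s]])
      })
      names(out) <- cfg$muscles
      out
    })
    names(sessions) <- subjects
  }

  tracking <- lapply(subjects, function(s) {
    list(practice = simulate_tracking_trial(cfg, s, trial = 1L),
         test = simulate_tracking_trial(cfg, s, trial = 2L))
  })
  names(tracking) <- subjects

  ## planted clinical outcome values
  tests <- names(cfg$group_effects)
  values <- matrix(NA_real_, nrow = 2 * n, ncol = length(tests),
                   dimnames = list(subjects, tests))
  fam <- clinical_families()
  for (f in names(fam)) {
    ftests <- intersect(fam[[f]], tests)
    if (length(ftests) == 0L) next
    ssd <- unname(cfg$subject_sd[ftests[1]])
    for (i in seq_along(subjects)) {
      s <- subjects[i]
      u <- with_substream(cfg$seed, "clin-int", s, f,
                          expr = stats::rnorm(1, 0, ssd))
      e <- with_substream(cfg$seed, "clin-res", s, f, expr = {
        stats::rnorm(length(ftests), 0, cfg$residual_sd[ftests])
      })
      values[s, ftests] <- cfg$test_means[ftests] +
        cfg$group_effects[ftests] * (group[i] == "LBP") + u + e
    }
  }

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  qst <- lapply(seq_along(subjects), function(i) {
    v <- values[i, ]
    ppt <- clamp(v["ppt"], 5, Inf)
    list(
      vibration_trials = rep(clamp(v["vibration"], 0, 8), 3),
      ppt_trials = rep(ppt, 3),
      cpm_ppt_during = rep(clamp(ppt + v["cpm_abs"], 1, Inf), 3),
      ts_single = rep(clamp(1.0, 0, 10), 5),
      ts_train = rep(clamp(1.0 + v["ts"], 0, 10), 5),
      graph_incorrect = round(clamp(v["graphaesthesia"], 0, 100) / 100 * 20),
      tpd_location_means = rep(clamp(v["tpd"], 20, Inf), 6),
      cpm_nprs = rep(5, 3)
    )
  })
  names(qst) <- subjects

  structure(list(
    subjects = subj_tab, sessions = sessions, tracking = tracking,
    qst = qst,
    truth = list(config = cfg, cog_offset = cog_offset,
                 spatial_sd_mult = if (raw_tms) sd_mult else NULL,
                 missing = miss, clinical_values = values),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d + %d subjects, %d muscles x %d stimulations%s\n",
    sum(x$subjects$group == "control"), sum(x$subjects$group == "LBP"),
    length(x$config$muscles), x$config$n_stims,
    if (is.null(x$sessions)) " (no raw EMG)" else ""))
  invisible(x)
}
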