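#' Group profile for the synthetic cohort generator
#'
#' Bundles the parameters that define one study arm: per-channel band power
#' targets, spatial-covariance regularity per state, behavioral response
#' rates and latency moments, depression-score moments, and artifact
#' amplitudes. Behavioral defaults are control-arm group values typical of
#' a healthy adult cohort (omission 1.70%, commission 2.06%, response time
#' 363 +/- 47.8 ms, BDI 6.22 +/- 6.76); see [control_profile()] and
#' [mdd_profile()] for the two ready-made arms.
#'
#' @param band_power_profile 19 x 4 matrix of per-channel, per-band target
#'   power in uV^2 (rows in [tova_montage()] order, columns
#'   delta/theta/alpha/beta). Default [default_band_profile()].
#' @param regularity Named numeric `c(resting = , task = )`, each in `[0,1]`:
#'   how repetitive the spatial covariance pattern is across channel pairs
#'   (1 = smooth spatial kernel, 0 = seeded random mixing).
#' @param regularity_sd Between-subject SD of the regularity knob.
#' @param omission_rate,commission_rate Response error probabilities in `[0,1]`.
#' @param rt_mean,rt_sd Response-time moments in ms (truncated-normal draws,
#'   bounded to the 100-1900 ms response window).
#' @param bdi_mean,bdi_sd Beck Depression Inventory moments.
#' @param blink_rate Blink events per minute.
#' @param blink_amplitude Blink peak amplitude at Fp1/Fp2, uV.
#' @param drift_amplitude SD of the < 0.5 Hz baseline drift, uV.
#' @param line_amplitude Amplitude of the 60 Hz line interference, uV.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(band_power_profile = default_band_profile("control"),
                          regularity = c(resting = 0.55, task = 0.95),
                          regularity_sd = 0.10,
                          omission_rate = 0.017, commission_rate = 0.0206,
                          rt_mean = 363, rt_sd = 47.8,
                          bdi_mean = 6.22, bdi_sd = 6.76,
                          blink_rate = 15, blink_amplitude = 120,
                          drift_amplitude = 20, line_amplitude = 5) {
  stopifnot(all(band_power_profile >= 0),
            all(regularity >= 0 & regularity <= 1),
            omission_rate >= 0, omission_rate <= 1,
            commission_rate >= 0, commission_rate <= 1,
            rt_mean > 0, rt_sd >= 0, blink_rate >= 0,
            drift_amplitude >= 0, line_amplitude >= 0)
  if (!all(c("resting", "task") %in% names(regularity)))
    stop("regularity must be named c(resting=, task=)")
  structure(list(band_power_profile = band_power_profile,
                 regularity = regularity, regularity_sd = regularity_sd,
                 omission_rate = omission_rate, commission_rate = commission_rate,
                 rt_mean = rt_mean, rt_sd = rt_sd,
                 bdi_mean = bdi_mean, bdi_sd = bdi_sd,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 drift_amplitude = drift_amplitude,
                 line_amplitude = line_amplitude),
            class = "group_profile")
}

#' Default per-channel band power targets
#'
#' Realistic resting qEEG topography: flat delta, frontally weighted theta,
#' occipitally dominant alpha, flat beta (uV^2 per band). The `"mdd"` variant
#' elevates frontal theta (strongest at F7), the topographic contrast the
#' cordance analysis is designed to detect.
#'
#' @param group `"control"` or `"mdd"`.
#' @return 19 x 4 matrix (channels x delta/theta/alpha/beta).
#' @export
default_band_profile <- function(group = c("control", "mdd")) {
  group <- match.arg(group)
  pos <- electrode_positions()
  frontness <- (pos[, "y"] + 1) / 2
  m <- cbind(delta = rep(20, 19),
             theta = 12 * (1 + 0.3 * frontness),
             alpha = 12 + 18 * (1 - frontness),
             beta = rep(8, 19))
  rownames(m) <- tova_montage()
  if (group == "mdd") {
    frontal <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")
    m[frontal, "theta"] <- m[frontal, "theta"] * 1.4
    m["F7", "theta"] <- m["F7", "theta"] * 1.3
  }
  m
}

#' Spatially uniform band power targets
#'
#' Every channel gets the same band mix (delta/theta/alpha/beta =
#' 20/14/18/8 of the total, uV^2). With a uniform profile, channels driven
#' by the same latent source are exact copies, which makes the
#' covariance-image pixel classes exactly tied and the two-scale entropy
#' score maximally sensitive to the regularity knob; it is the profile used
#' by [crossover_spec()].
#'
#' @param total Total power per channel, uV^2.
#' @return 19 x 4 matrix (channels x bands).
#' @export
uniform_band_profile <- function(total = 60) {
  m <- matrix(rep(c(20, 14, 18, 8) / 60 * total, each = 19), 19, 4)
  dimnames(m) <- list(tova_montage(), names(qeeg_bands()))
  m
}

#' Ready-made study-arm profiles
#'
#' `control_profile()` and `mdd_profile()` carry the behavioral group values
#' of representative control and depressed cohorts (omission 1.70 vs 7.29%, commission 2.06 vs
#' 3.33%, response time 363 +/- 47.8 vs 450 +/- 92.5 ms, BDI 6.22 +/- 6.76 vs
#' 30.8 +/- 11.7) and the package's documented crossover covariance
#' regularity preset: the patient arm is *less* regular during the task and
#' *more* regular at rest (the crossover that makes task-state approximate
#' entropy rise in patients and fall in controls, with only a small resting
#' difference in the opposite direction).
#'
#' @param ... Overrides passed to [group_profile()].
#' @return A `group_profile`.
#' @export
control_profile <- function(...) {
  args <- list(...)
  defaults <- list(band_power_profile = default_band_profile("control"),
                   regularity = c(resting = 0.55, task = 0.95))
  do.call(group_profile, utils::modifyList(defaults, args))
}

#' @rdname control_profile
#' @export
mdd_profile <- function(...) {
  args <- list(...)
  defaults <- list(band_power_profile = default_band_profile("mdd"),
                   regularity = c(resting = 0.75, task = 0.30),
                   omission_rate = 0.0729, commission_rate = 0.0333,
                   rt_mean = 450, rt_sd = 92.5,
                   bdi_mean = 30.8, bdi_sd = 11.7)
  do.call(group_profile, utils::modifyList(defaults, args))
}

#' Cohort specification
#'
#' Defines the synthetic study: arm sizes, acquisition parameters (19
#' channels at 256 Hz), the TOVA schedule (648 two-second trials, 324
#' targets, four quarters), the 5-minute resting baseline, and the two
#' group profiles.
#'
#' @param n_control,n_patient Subjects per arm (study default 18 + 18).
#' @param fs Sampling rate, Hz.
#' @param channel_labels 19 unique 10-20 labels in front-to-occipital order.
#' @param rest_duration Resting baseline length, seconds.
#' @param trial_period Inter-stimulus period, seconds.
#' @param n_trials,n_targets Trial and target counts.
#' @param quarter_target_ratios Fraction of each quarter's trials that are
#'   targets, before scaling to a total of exactly `n_targets`. Default is
#'   the standard infrequent-then-frequent TOVA halves.
#' @param control,patient [group_profile()]s for the two arms.
#' @param seed Master seed; every downstream draw is derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 18, n_patient = 18, fs = 256,
                        channel_labels = tova_montage(),
                        rest_duration = 300, trial_period = 2.0,
                        n_trials = 648, n_targets = 324,
                        quarter_target_ratios = c(0.225, 0.225, 0.775, 0.775),
                        control = control_profile(), patient = mdd_profile(),
                        seed = 1L) {
  stopifnot(n_control >= 0, n_patient >= 0, fs > 0,
            rest_duration > 0, trial_period > 0,
            n_trials >= 1, n_targets >= 0, n_targets <= n_trials,
            length(quarter_target_ratios) == 4,
            all(quarter_target_ratios >= 0 & quarter_target_ratios <= 1))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != 19) stop("exactly 19 channel labels required")
  structure(list(n_control = n_control, n_patient = n_patient, fs = fs,
                 channel_labels = channel_labels,
                 rest_duration = rest_duration, trial_period = trial_period,
                 n_trials = n_trials, n_targets = n_targets,
                 quarter_target_ratios = quarter_target_ratios,
                 control = control, patient = patient, seed = seed),
            class = "cohort_spec")
}

#' Generate a TOVA stimulus schedule
#'
#' Produces `n_trials` trials at onsets `0, trial_period, 2*trial_period, ...`
#' split into four quarters. Target counts per quarter follow
#' `quarter_target_ratios`, rescaled by the largest-remainder method so the
#' total is exactly `n_targets`; target positions are randomized within each
#' quarter.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for the within-quarter randomization.
#' @return A [tova_session()] without response columns.
#' @export
make_schedule <- function(spec, seed = spec$seed) {
  n <- spec$n_trials
  q_size <- rep(n %/% 4, 4) + (seq_len(4) <= n %% 4)
  raw <- spec$quarter_target_ratios * q_size
  if (sum(raw) == 0) {
    if (spec$n_targets > 0)
      stop("quarter_target_ratios are all zero but n_targets = ", spec$n_targets)
    tq <- rep(0L, 4)
  } else {
    scaled <- raw * spec$n_targets / sum(raw)
    pos <- which(spec$quarter_target_ratios > 0)
    if (sum(q_size[pos]) < spec$n_targets) {
      worst <- pos[which.max(scaled[pos] - q_size[pos])]
      stop(sprintf(
        "quarter %d: ratios allocate %.1f targets but it has only %d trials (total target capacity %d < %d)",
        worst, scaled[worst], q_size[worst], sum(q_size[pos]), spec$n_targets))
    }
    # largest-remainder allocation among positive-ratio quarters, capped at
    # each quarter's capacity
    tq <- pmin(floor(scaled), q_size)
    while (sum(tq) < spec$n_targets) {
      open <- pos[tq[pos] < q_size[pos]]
      pick <- open[order(scaled[open] - tq[open], decreasing = TRUE)][1]
      tq[pick] <- tq[pick] + 1L
    }
  }
  stim <- with_seed(seed, {
    unlist(lapply(1:4, function(q) {
      s <- c(rep("target", tq[q]), rep("nontarget", q_size[q] - tq[q]))
      if (length(s) > 1) sample(s) else s
    }))
  })
  trials <- data.frame(
    trial_index = seq_len(n),
    onset_s = (seq_len(n) - 1) * spec$trial_period,
    stimulus = stim,
    quarter = rep(1:4, times = q_size))
  tova_session(trials, spec$trial_period)
}

#' Simulate behavioral responses to a schedule
#'
#' Each target is independently omitted with probability `omission_rate`,
#' otherwise pressed at a latency drawn from a truncated normal
#' (`rt_mean`, `rt_sd`, bounded to 100-1900 ms). Each nontarget is pressed
#' (a commission) with probability `commission_rate`. Trials are labeled
#' `target_correct`, `nontarget_correct`, `omission`, or `commission`.
#'
#' @param schedule A [tova_session()] (responses, if present, are replaced).
#' @param profile A [group_profile()].
#' @param seed Integer seed.
#' @return A [tova_session()] with response columns.
#' @export
simulate_responses <- function(schedule, profile, seed = 1L) {
  tr <- schedule$trials
  n <- nrow(tr)
  is_target <- tr$stimulus == "target"
  res <- with_seed(seed, {
    pressed <- logical(n)
    pressed[is_target] <- stats::runif(sum(is_target)) >= profile$omission_rate
    pressed[!is_target] <- stats::runif(sum(!is_target)) < profile$commission_rate
    lat <- rep(NA_real_, n)
    lat[pressed] <- rtruncnorm(sum(pressed), profile$rt_mean, profile$rt_sd,
                               100, 1900)
    list(pressed = pressed, lat = lat)
  })
  tr$press_latency_ms <- res$lat
  tr$classification <- ifelse(is_target,
                              ifelse(res$pressed, "target_correct", "omission"),
                              ifelse(res$pressed, "commission", "nontarget_correct"))
  tova_session(tr, schedule$trial_period, schedule$subject_id)
}

# band-limited unit-variance Gaussian noise, nrow series x n samples,
# passband [lo, hi) Hz realized by FFT masking
bandlimited_noise <- function(n_series, n, fs, lo, hi) {
  freqs <- (seq_len(n) - 1) * fs / n
  mirror <- fs - freqs
  keep <- (freqs >= lo & freqs < hi) | (mirror >= lo & mirror < hi)
  out <- matrix(0, n_series, n)
  for (k in seq_len(n_series)) {
    x <- stats::rnorm(n)
    xf <- stats::fft(x)
    xf[!keep] <- 0
    y <- Re(stats::fft(xf, inverse = TRUE)) / n
    s <- stats::sd(y)
    out[k, ] <- if (s > 0) y / s else y
  }
  out
}

# Latent-source channel assignment realizing the covariance-regularity knob.
#
# Channels are driven by N_LATENTS regional sources (anterior/posterior
# split in montage order). At regularity 1 the channel -> source map is the
# contiguous block pattern, so the spatial covariance pattern repeats across
# channel pairs at both the one-row (m ~ 20) and multi-row (m ~ 50) scales
# of the reshaped image. Lower regularity applies seeded random
# transpositions (up to MAX_SWAPS at regularity 0), fragmenting the blocks:
# short-range pattern repeats survive while multi-row repetition is
# destroyed, which is exactly the structure the two-scale entropy score is
# sensitive to. Module constants below.
N_LATENTS <- 2L
LATENT_COR <- 0.5      # correlation between the two regional sources
MAX_SWAPS <- 4L

latent_assignment <- function(regularity, seed) {
  l <- rep.int(seq_len(N_LATENTS), times = c(9L, 10L))
  n_swap <- round((1 - regularity) * MAX_SWAPS)
  if (n_swap > 0) {
    l <- with_seed(seed, {
      for (s in seq_len(n_swap)) {
        # always exchange two channels with different labels, so every
        # step fragments the pattern by a comparable amount
        i <- sample(which(l == 1L), 1L)
        j <- sample(which(l == 2L), 1L)
        l[c(i, j)] <- l[c(j, i)]
      }
      l
    })
  }
  l
}

#' Simulate one EEG recording
#'
#' Drives the 19 channels from band-limited Gaussian latent oscillators
#' through a state-dependent spatial structure: two correlated regional
#' sources assigned to channels by a contiguity pattern whose smoothness is
#' the profile's `regularity` knob (see the methods vignette), scaled per
#' channel to the profile's `band_power_profile`, then adds frontally
#' weighted blink transients, slow (< 0.5 Hz) baseline drift, and a 60 Hz
#' line sinusoid. With `schedule = NULL` a resting recording of
#' `rest_duration` seconds is produced; with a schedule, a task recording
#' covering the schedule span. Deterministic under `seed`.
#'
#' @param schedule A [tova_session()] or `NULL` for resting state.
#' @param profile A [group_profile()].
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param regularity Optional per-subject override of the profile's
#'   regularity for this state (used by [generate_cohort()] jitter).
#' @return An [eeg_recording()]; `$aux$blink` holds the injected blink
#'   time course (zeros when `blink_rate = 0`) for validation purposes.
#' @export
simulate_recording <- function(schedule, profile, spec, seed = spec$seed,
                               regularity = NULL) {
  state <- if (is.null(schedule)) "resting" else "tova"
  dur <- if (is.null(schedule)) spec$rest_duration
         else nrow(schedule$trials) * schedule$trial_period
  fs <- spec$fs
  n <- round(dur * fs)
  reg <- regularity %||%
    unname(profile$regularity[[if (state == "resting") "resting" else "task"]])
  seeds <- derive_seeds(seed, 8)
  lat <- latent_assignment(reg, seeds[1])
  a <- seq_len(N_LATENTS)
  CL <- LATENT_COR^abs(outer(a, a, "-"))
  eg <- eigen(CL, symmetric = TRUE)
  ML <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), N_LATENTS) %*% t(eg$vectors)
  bands <- qeeg_bands()
  bp <- profile$band_power_profile
  x <- with_seed(seeds[2], {
    acc <- matrix(0, 19, n)
    for (b in seq_along(bands)) {
      src <- bandlimited_noise(N_LATENTS, n, fs, bands[[b]][1], bands[[b]][2])
      L <- ML %*% src
      L <- L / apply(L, 1, stats::sd)
      acc <- acc + sqrt(bp[, b]) * L[lat, , drop = FALSE]
    }
    acc
  })
  # blink transients: 300 ms raised-cosine pulses, frontally loaded
  blink <- numeric(n)
  if (profile$blink_rate > 0) {
    blink <- with_seed(seeds[3], {
      n_ev <- stats::rpois(1, profile$blink_rate * dur / 60)
      tpl_len <- round(0.3 * fs)
      tpl <- (0.5 - 0.5 * cos(2 * pi * seq_len(tpl_len) / (tpl_len + 1)))^2
      bl <- numeric(n)
      if (n_ev > 0) {
        starts <- sort(sample.int(max(n - tpl_len, 1), n_ev, replace = TRUE))
        for (s in starts) {
          idx <- s:min(s + tpl_len - 1, n)
          bl[idx] <- bl[idx] + tpl[seq_along(idx)]
        }
      }
      bl
    })
    # slight left/right asymmetry keeps frontal channels distinguishable
    loadings <- stats::setNames(rep(0.05, 19), spec$channel_labels)
    loadings[c("Fp1", "Fp2")] <- c(1, 0.95)
    loadings[c("F7", "F8")] <- c(0.62, 0.58)
    loadings[c("F3", "F4")] <- c(0.26, 0.24)
    loadings["Fz"] <- 0.2
    x <- x + profile$blink_amplitude * outer(unname(loadings), blink)
  }
  if (profile$drift_amplitude > 0) {
    x <- x + with_seed(seeds[4],
      profile$drift_amplitude * bandlimited_noise(19, n, fs, 0.01, 0.5))
  }
  if (profile$line_amplitude > 0) {
    x <- x + with_seed(seeds[5], {
      phase <- stats::runif(1, 0, 2 * pi)
      gains <- stats::runif(19, 0.5, 1)
      profile$line_amplitude *
        outer(gains, sin(2 * pi * 60 * seq_len(n) / fs + phase))
    })
  }
  rec <- eeg_recording(x, fs, spec$channel_labels, state_tag = state)
  rec$aux <- list(blink = blink, regularity = reg)
  rec
}

#' Crossover cohort preset for entropy parameter recovery
#'
#' The package's documented reference preset: a cohort whose patient arm
#' has *less* regular task-state spatial covariance and *more* regular
#' resting covariance than the control arm (control resting/task 0.55/0.95,
#' patient 0.75/0.30), with uniform band topography and artifact amplitudes
#' set to zero so the covariance/entropy stages are exercised in isolation.
#' The regularity separations are calibrated so that, at 18 + 18 subjects,
#' the task-state entropy contrast is large and the resting contrast is
#' small and reversed, reproducing the crossover pattern of the group
#' entropy means.
#'
#' @param n_control,n_patient Subjects per arm.
#' @param ... Overrides passed to [cohort_spec()] (e.g. reduced `fs`,
#'   `n_trials`, `rest_duration` for quick simulations).
#' @return A [cohort_spec()].
#' @export
crossover_spec <- function(n_control = 18, n_patient = 18, ...) {
  clean <- list(band_power_profile = uniform_band_profile(),
                blink_rate = 0, drift_amplitude = 0, line_amplitude = 0)
  cohort_spec(
    n_control = n_control, n_patient = n_patient,
    control = do.call(control_profile, clean),
    patient = do.call(mdd_profile, clean),
    ...)
}

# deterministic cohort layout: ids, arms, per-subject seed rows
cohort_layout <- function(spec) {
  n_tot <- spec$n_control + spec$n_patient
  groups <- rep(c("control", "mdd"), c(spec$n_control, spec$n_patient))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "h", "m"),
                 c(seq_len(spec$n_control), seq_len(spec$n_patient)))
  seeds <- if (n_tot > 0) matrix(derive_seeds(spec$seed, n_tot * 6), nrow = n_tot)
           else matrix(integer(0), 0, 6)
  list(ids = ids, groups = groups, seeds = seeds)
}

#' Generate one cohort subject
#'
#' Builds subject `i` of the cohort defined by `spec`: jittered regularity,
#' BDI score, randomized schedule with simulated responses, and the resting
#' and task recordings. [generate_cohort()] is a loop over this function,
#' so a large cohort can be processed subject by subject without holding
#' every recording in memory.
#'
#' @param spec A [cohort_spec()].
#' @param i Subject index in `1..(n_control + n_patient)` (controls first).
#' @return List with `subject_id`, `group`, `bdi`, `regularity`, `session`,
#'   `resting`, `tova`.
#' @export
cohort_subject <- function(spec, i) {
  lay <- cohort_layout(spec)
  if (i < 1 || i > length(lay$ids)) stop("subject index out of range")
  seeds <- lay$seeds[i, ]
  group <- lay$groups[i]; id <- lay$ids[i]
  prof <- if (group == "control") spec$control else spec$patient
  jit <- with_seed(seeds[2], stats::rnorm(1, 0, prof$regularity_sd))
  reg <- pmin(pmax(prof$regularity + jit, 0.02), 0.98)
  bdi <- with_seed(seeds[3],
                   max(0, round(stats::rnorm(1, prof$bdi_mean, prof$bdi_sd))))
  schedule <- make_schedule(spec, seed = seeds[4])
  session <- simulate_responses(schedule, prof, seed = seeds[5])
  session$subject_id <- id
  rest <- simulate_recording(NULL, prof, spec, seed = seeds[1],
                             regularity = reg[["resting"]])
  task <- simulate_recording(session, prof, spec, seed = seeds[6],
                             regularity = reg[["task"]])
  rest$subject_id <- id; task$subject_id <- id
  list(subject_id = id, group = group, bdi = bdi, regularity = reg,
       session = session, resting = rest, tova = task)
}

#' Generate a full synthetic cohort
#'
#' Produces `n_control + n_patient` subjects: per-subject resting and task
#' recordings, a randomized TOVA schedule with simulated responses, and a
#' BDI score drawn from the arm's profile. Per-subject regularity is
#' jittered around the arm's preset (SD `regularity_sd`, both states moved
#' together, clamped to `[0.02, 0.98]`). All randomness derives from
#' `spec$seed`; two calls with the same spec are identical.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory: when given, recordings/sessions/scores are
#'   written as CSV and a `manifest.json` listing files and seeds is
#'   produced; recordings are then dropped from the returned bundle unless
#'   `keep_recordings` is `TRUE`.
#' @param keep_recordings Keep recordings in memory (default `TRUE` when
#'   `dir` is `NULL`).
#' @return A list with `subjects` (data frame: subject_id, group, bdi,
#'   regularity per state, seed), `recordings` (per subject: `resting`,
#'   `tova`), `sessions`, and `manifest`.
#' @export
generate_cohort <- function(spec, dir = NULL, keep_recordings = is.null(dir)) {
  n_tot <- spec$n_control + spec$n_patient
  lay <- cohort_layout(spec)
  ids <- lay$ids; groups <- lay$groups; seeds <- lay$seeds
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- data.frame(subject_id = ids, group = groups,
                         bdi = NA_real_, regularity_resting = NA_real_,
                         regularity_task = NA_real_,
                         seed = as.integer(seeds[, 1]))
  recordings <- list(); sessions <- list(); files <- list()
  for (i in seq_len(n_tot)) {
    sub <- cohort_subject(spec, i)
    subjects$regularity_resting[i] <- sub$regularity[["resting"]]
    subjects$regularity_task[i] <- sub$regularity[["task"]]
    subjects$bdi[i] <- sub$bdi
    session <- sub$session
    rest <- sub$resting; task <- sub$tova
    sessions[[ids[i]]] <- session
    if (!is.null(dir)) {
      f_rest <- file.path(dir, paste0(ids[i], "_resting.csv"))
      f_task <- file.path(dir, paste0(ids[i], "_tova.csv"))
      f_sess <- file.path(dir, paste0(ids[i], "_session.csv"))
      write_recording_csv(rest, f_rest)
      write_recording_csv(task, f_task)
      write_session_csv(session, f_sess)
      files[[ids[i]]] <- list(resting = basename(f_rest),
                              tova = basename(f_task),
                              session = basename(f_sess))
    }
    if (keep_recordings) recordings[[ids[i]]] <- list(resting = rest, tova = task)
  }
  manifest <- list(
    n_control = spec$n_control, n_patient = spec$n_patient,
    fs = spec$fs, n_trials = spec$n_trials, n_targets = spec$n_targets,
    rest_duration = spec$rest_duration, trial_period = spec$trial_period,
    seed = spec$seed,
    subjects = subjects[, c("subject_id", "group", "seed")],
    files = files)
  if (!is.null(dir)) {
    utils::write.csv(subjects, file.path(dir, "clinical_scores.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(subjects = subjects, recordings = recordings, sessions = sessions,
       manifest = manifest)
}
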