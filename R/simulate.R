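## Synthetic-cohort generator.  The generator is a statistical stand-in
## for the behaving animal: it produces trial schedules, latent startle
## amplitudes (lognormal, configurable CV), band-specific gap-filling
## tinnitus effects, psychometric PPI curves, movement artifacts and ABR
## threshold tables with the structure the analysis assumes.  It makes no
## attempt at biophysics.

#' Per-mouse generating parameters
#'
#' Bundles everything the simulator needs to emit one mouse's data:
#' baseline startle scale and variability, per-band gap inhibition, the
#' band-specific tinnitus effect (a multiplicative reduction of gap
#' inhibition, i.e. "gap-filling"), psychometric parameters per
#' frequency-discrimination task, timepoint modifiers, and artifact rates.
#'
#' @param mouse_id identifier.
#' @param group `"CONTROL"` or `"EXPOSED"`.
#' @param tinnitus_truth does this mouse truly develop tinnitus? (ground
#'   truth for the classifier, only meaningful for exposed mice).
#' @param base_startle mean SA startle amplitude (force units, > 0).
#' @param startle_cv coefficient of variation of trial amplitudes.
#' @param noise_sd baseline force-noise SD (pre-startle platform signal).
#' @param gap_inhibition fraction of the startle suppressed by a detected
#'   gap, per band: scalar or named vector over band labels, values in
#'   [0, 1].
#' @param tinnitus_effect fractional loss of gap inhibition in each band
#'   once tinnitus is active: scalar or named vector, values in [0, 1]
#'   (1 = the gap is fully "filled in").
#' @param tinnitus_onset first timepoint at which the tinnitus effect is
#'   active (default `"week4"`, when chronic tinnitus is expected).
#' @param psychometric named list over `"FD-medium"`/`"FD-high"`, each a
#'   numeric vector `c(a, b, c)` of generalized-logistic parameters.
#' @param timepoint_effects named list: per timepoint, per task, a list
#'   with optional `a_scale` and `c_scale` multipliers emulating
#'   post-exposure threshold elevation.
#' @param artifact_rate per-trial probability of a movement artifact.
#' @param artifact_factor inflation of pre-SS noise SD on artifact trials.
#' @return An object of class `mouse_params`.
#' @export
mouse_params <- function(mouse_id, group = c("CONTROL", "EXPOSED"),
                         tinnitus_truth = FALSE,
                         base_startle = 5, startle_cv = 0.2,
                         noise_sd = 0.2,
                         gap_inhibition = 0.65, tinnitus_effect = 0,
                         tinnitus_onset = "week4",
                         psychometric = list(
                           "FD-medium" = c(a = 160, b = 0, c = -0.1),
                           "FD-high"   = c(a = 160, b = 0, c = -0.1)),
                         timepoint_effects = list(),
                         artifact_rate = 0, artifact_factor = 3) {
  group <- match.arg(group)
  if (base_startle <= 0) stop_invalid("base_startle must be positive")
  if (startle_cv < 0 || noise_sd < 0)
    stop_invalid("startle_cv and noise_sd must be non-negative")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop_invalid("artifact_rate must be in [0, 1]")
  labs <- gap_bands()$label
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, length(labs)), labs)
    if (!all(labs %in% names(x)))
      stop_invalid(what, " must cover all bands")
    if (any(x < 0 | x > 1)) stop_invalid(what, " values must be in [0, 1]")
    x[labs]
  }
  if (!tinnitus_onset %in% TIMEPOINTS)
    stop_invalid("unknown tinnitus_onset timepoint")
  structure(list(
    mouse_id = as.character(mouse_id), group = group,
    tinnitus_truth = isTRUE(tinnitus_truth),
    base_startle = base_startle, startle_cv = startle_cv,
    noise_sd = noise_sd,
    gap_inhibition = expand(gap_inhibition, "gap_inhibition"),
    tinnitus_effect = expand(tinnitus_effect, "tinnitus_effect"),
    tinnitus_onset = tinnitus_onset,
    psychometric = psychometric,
    timepoint_effects = timepoint_effects,
    artifact_rate = artifact_rate, artifact_factor = artifact_factor
  ), class = "mouse_params")
}

check_timepoint <- function(timepoint) {
  if (!timepoint %in% TIMEPOINTS)
    stop_invalid("unknown timepoint label: ", timepoint,
                 " (expected one of ", paste(TIMEPOINTS, collapse = ", "), ")")
  timepoint
}

tinnitus_active <- function(mouse, timepoint) {
  mouse$tinnitus_truth &&
    match(timepoint, TIMEPOINTS) >= match(mouse$tinnitus_onset, TIMEPOINTS)
}

## Lognormal draws parameterised by mean and CV; degenerates to the mean
## at cv = 0 (startle amplitudes are positive and right-skewed).
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep_len(mean, n))
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

## Effective gap inhibition for one band at one timepoint.
effective_inhibition <- function(mouse, band, timepoint) {
  eff <- mouse$gap_inhibition[[band]]
  if (tinnitus_active(mouse, timepoint))
    eff <- eff * (1 - mouse$tinnitus_effect[[band]])
  eff
}

## Psychometric parameters for one task at one timepoint, after applying
## any timepoint modifiers (a_scale / c_scale).
psych_params_at <- function(mouse, task, timepoint) {
  p <- mouse$psychometric[[task]]
  if (is.null(p)) stop_invalid("mouse has no psychometric params for ", task)
  mod <- mouse$timepoint_effects[[timepoint]][[task]]
  if (!is.null(mod)) {
    if (!is.null(mod$a_scale)) p[["a"]] <- p[["a"]] * mod$a_scale
    if (!is.null(mod$c_scale)) p[["c"]] <- p[["c"]] * mod$c_scale
    if (!is.null(mod$b_shift)) p[["b"]] <- p[["b"]] + mod$b_shift
  }
  p
}

#' Simulate the force trace of a single trial
#'
#' Gaussian baseline noise plus a trapezoidal startle transient whose
#' plateau equals the trial's latent ASR amplitude, so that noiseless
#' traces round-trip exactly through [compute_asr_amplitude()] (also
#' after block-mean downsampling, since the 60 ms plateau spans whole
#' averaging blocks at the default rates).  On artifact trials the noise
#' SD in the 9 s window before SS onset is inflated by `artifact_factor`.
#'
#' @param spec one-row schedule entry (needs `ss_onset_s`, `kind`, and
#'   `band` for gap trials).
#' @param mouse a [mouse_params()] object.
#' @param noise_sd baseline noise SD (force units).
#' @param sample_rate_hz sampling rate of the emitted trace (Hz).
#' @param seed integer seed.
#' @param timepoint timepoint label (drives the tinnitus effect).
#' @param latent override the latent ASR amplitude (default: drawn from
#'   the mouse's lognormal amplitude model for this trial kind).
#' @param artifact force artifact status (default: Bernoulli with the
#'   mouse's `artifact_rate`).
#' @return A [startle_trace()].
#' @export
simulate_trace <- function(spec, mouse, noise_sd = mouse$noise_sd,
                           sample_rate_hz = 1000, seed,
                           timepoint = "baseline",
                           latent = NULL, artifact = NULL) {
  if (noise_sd < 0) stop_invalid("noise_sd must be non-negative")
  if (sample_rate_hz < 100)
    stop_invalid("sample_rate_hz too low to resolve the analysis windows")
  check_timepoint(timepoint)
  ss <- spec$ss_onset_s
  with_seed(seed, {
    if (is.null(latent)) {
      mean_amp <- mouse$base_startle
      if (identical(spec$kind, "GA"))
        mean_amp <- mean_amp *
          (1 - effective_inhibition(mouse, spec$band, timepoint))
      latent <- rlnorm_cv(1, mean_amp, mouse$startle_cv)
    }
    if (is.null(artifact)) artifact <- stats::runif(1) < mouse$artifact_rate
    n <- ceiling((ss + 0.6) * sample_rate_hz) + 1L
    t <- (seq_len(n) - 1) / sample_rate_hz
    sd_vec <- rep(noise_sd, n)
    if (artifact) sd_vec[t >= ss - 9 & t < ss] <- noise_sd * mouse$artifact_factor
    x <- stats::rnorm(n, 0, 1) * sd_vec
    ## trapezoid: rise 20 ms, plateau 60 ms, fall 20 ms, starting SS+20 ms
    rel <- t - (ss + 0.02)
    pulse <- pmin(pmax(rel / 0.02, 0), 1) * pmin(pmax((0.1 - rel) / 0.02, 0), 1)
    x <- x + latent * pulse
    tr <- startle_trace(x, sample_rate_hz, ss, spec)
    attr(tr, "latent") <- latent
    attr(tr, "artifact") <- artifact
    tr
  })
}

## Simulated pre-SS SD: a sample SD of the baseline noise over ~9 s,
## emulated without materialising the trace (chi distribution).
sim_pre_ss_sd <- function(n, noise_sd, artifact, artifact_factor,
                          df = 899L) {
  s <- noise_sd * ifelse(artifact, artifact_factor, 1)
  s * sqrt(stats::rchisq(n, df) / df)
}

#' Simulate one gap-detection session
#'
#' Draws a seeded trial schedule, then per-trial amplitudes: SA trials
#' around the mouse's baseline startle, GA trials reduced by the
#' effective gap inhibition
#' `gap_inhibition * (1 - tinnitus_effect)` (the tinnitus term applies
#' only when the mouse's tinnitus is active at `timepoint`).  Amplitudes
#' are lognormal with the mouse's CV; artifact trials get inflated
#' pre-SS SD.
#'
#' @param mouse a [mouse_params()].
#' @param timepoint timepoint label.
#' @param seed integer seed.
#' @param protocol a [gap_protocol()].
#' @return A `gpias_session` (exclusion flags not yet applied).
#' @export
simulate_gap_session <- function(mouse, timepoint, seed,
                                 protocol = gap_protocol()) {
  check_timepoint(timepoint)
  seeds <- derive_seeds(seed, 2L)
  sched <- build_gap_session_schedule(protocol, seeds[1])
  with_seed(seeds[2], {
    n <- nrow(sched)
    eff <- vapply(sched$band, effective_inhibition, numeric(1),
                  mouse = mouse, timepoint = timepoint)
    mean_amp <- mouse$base_startle * ifelse(sched$kind == "GA", 1 - eff, 1)
    sched$asr_amplitude <- rlnorm_cv(n, 1, mouse$startle_cv) * mean_amp
    artifact <- stats::runif(n) < mouse$artifact_rate
    sched$pre_ss_sd <- sim_pre_ss_sd(n, mouse$noise_sd, artifact,
                                     mouse$artifact_factor)
    sched$excluded <- FALSE
    sched$exclusion_reason <- NA_character_
    gpias_session(mouse$mouse_id, timepoint, "GAP", sched, protocol)
  })
}

#' Simulate one frequency-discrimination session
#'
#' Latent prepulse-trial amplitudes follow
#' `SA_mean * (1 - PPI(delta_f) / 100)` with PPI given by the mouse's
#' generalized-logistic parameters for the task (possibly modified by
#' `timepoint_effects`, emulating post-exposure threshold elevation).
#'
#' @param mouse a [mouse_params()].
#' @param task `"FD-medium"` or `"FD-high"`.
#' @param timepoint timepoint label.
#' @param seed integer seed.
#' @param protocol an [fd_protocol()]; defaults to the preset matching
#'   `task`.
#' @return A `gpias_session`.
#' @export
simulate_fd_session <- function(mouse, task = c("FD-medium", "FD-high"),
                                timepoint, seed, protocol = NULL) {
  task <- match.arg(task)
  check_timepoint(timepoint)
  if (is.null(protocol))
    protocol <- fd_protocol(if (task == "FD-medium") "medium" else "high")
  p <- psych_params_at(mouse, task, timepoint)
  seeds <- derive_seeds(seed, 2L)
  sched <- build_fd_session_schedule(protocol, seeds[1])
  with_seed(seeds[2], {
    n <- nrow(sched)
    ppi <- ifelse(is.na(sched$delta_f_pct), 0,
                  psych_logistic(sched$delta_f_pct, p[["a"]], p[["b"]], p[["c"]]))
    mean_amp <- pmax(mouse$base_startle * (1 - ppi / 100),
                     0.01 * mouse$base_startle)
    sched$asr_amplitude <- rlnorm_cv(n, 1, mouse$startle_cv) * mean_amp
    artifact <- stats::runif(n) < mouse$artifact_rate
    sched$pre_ss_sd <- sim_pre_ss_sd(n, mouse$noise_sd, artifact,
                                     mouse$artifact_factor)
    sched$excluded <- FALSE
    sched$exclusion_reason <- NA_character_
    gpias_session(mouse$mouse_id, timepoint, task, sched, protocol)
  })
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study design the package targets: 6 control and 22
#' tone-exposed mice of which 14 truly develop tinnitus, tested at
#' baseline and 1, 4 and 8 weeks post-exposure, three gap sessions and one
#' session per frequency-discrimination task per timepoint.  The default
#' tinnitus effect removes 80% of gap inhibition in the broadband and two
#' highest noise bands from week 4 on; frequency discrimination of
#' tinnitus mice is impaired (logistic slope halved, elevating the
#' threshold about two-fold) in both tasks at weeks 4 and 8, while exposed
#' non-tinnitus mice show a milder, transient mid-frequency impairment at
#' week 4 only.
#'
#' @param n_control,n_exposed group sizes.
#' @param n_tinnitus number of exposed mice with true tinnitus.
#' @param timepoints ordered timepoint labels.
#' @param gap_sessions,fd_sessions sessions per mouse per timepoint.
#' @param base_startle,startle_cv,noise_sd amplitude model (see
#'   [mouse_params()]).
#' @param gap_inhibition baseline per-band gap inhibition.
#' @param tinnitus_effect gap-filling effect size in `affected_bands`.
#' @param affected_bands band labels carrying the tinnitus effect.
#' @param psychometric generalized-logistic `c(a, b, c)` shared by both
#'   tasks at baseline.
#' @param fd_c_scale_tinnitus,fd_c_scale_exposed slope multipliers
#'   applied post-exposure (see Details in the package vignette).
#' @param between_mouse_cv,psych_slope_cv lognormal coefficients of
#'   variation of the stable per-mouse traits: the startle scale
#'   (`base_startle`) and the psychometric slope (`c`).  Drawn once per
#'   mouse and held fixed across timepoints, these give cohorts the
#'   persistent individual differences real startle data show.
#' @param artifact_rate,artifact_factor movement-artifact model.
#' @param include_fd simulate frequency-discrimination sessions?
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 6L, n_exposed = 22L, n_tinnitus = 14L,
                          timepoints = TIMEPOINTS,
                          gap_sessions = 3L, fd_sessions = 1L,
                          base_startle = 5, startle_cv = 0.2, noise_sd = 0.2,
                          between_mouse_cv = 0.25, psych_slope_cv = 0.12,
                          gap_inhibition = 0.65,
                          tinnitus_effect = 0.8,
                          affected_bands = c("BBN", "18-20", "26-28"),
                          psychometric = c(a = 160, b = 0, c = -0.1),
                          fd_c_scale_tinnitus = 0.5,
                          fd_c_scale_exposed = 0.7,
                          artifact_rate = 0.05, artifact_factor = 3,
                          include_fd = TRUE) {
  if (n_control < 1L || n_exposed < 1L)
    stop_invalid("both groups must be non-empty")
  if (n_tinnitus < 0L || n_tinnitus > n_exposed)
    stop_invalid("n_tinnitus must be between 0 and n_exposed")
  if (!all(affected_bands %in% gap_bands()$label))
    stop_invalid("unknown band label in affected_bands")
  structure(as.list(environment()), class = "cohort_config")
}

## One mouse's parameters; stable traits (startle scale, psychometric
## slope) are drawn here from the cohort RNG stream and persist across
## every timepoint and session of that mouse.
cohort_mouse <- function(config, i, group, tinnitus_truth) {
  te <- stats::setNames(rep(0, nrow(gap_bands())), gap_bands()$label)
  te[config$affected_bands] <- config$tinnitus_effect
  base_i <- rlnorm_cv(1, config$base_startle, config$between_mouse_cv)
  psych_i <- config$psychometric
  psych_i[["c"]] <- psych_i[["c"]] * rlnorm_cv(1, 1, config$psych_slope_cv)
  tp_eff <- list()
  if (group == "EXPOSED") {
    if (tinnitus_truth) {
      mod <- list(c_scale = config$fd_c_scale_tinnitus)
      tp_eff <- list(week4 = list("FD-medium" = mod, "FD-high" = mod),
                     week8 = list("FD-medium" = mod, "FD-high" = mod))
    } else {
      tp_eff <- list(week4 = list(
        "FD-medium" = list(c_scale = config$fd_c_scale_exposed)))
    }
  }
  mouse_params(
    mouse_id = sprintf("%s%02d", if (group == "CONTROL") "C" else "E", i),
    group = group, tinnitus_truth = tinnitus_truth,
    base_startle = base_i, startle_cv = config$startle_cv,
    noise_sd = config$noise_sd,
    gap_inhibition = config$gap_inhibition,
    tinnitus_effect = te,
    psychometric = list("FD-medium" = psych_i, "FD-high" = psych_i),
    timepoint_effects = tp_eff,
    artifact_rate = config$artifact_rate,
    artifact_factor = config$artifact_factor)
}

#' Simulate an ABR threshold table
#'
#' Tone-pip auditory-brainstem-response thresholds at 8, 12, 16, 22 and
#' 28 kHz on the 10--80 dB SPL grid in 10 dB steps.  Exposed mice gain a
#' sustained +20 dB threshold shift at 28 kHz from week 1 on; all entries
#' carry one 10 dB step of measurement jitter.
#'
#' @param mice list of [mouse_params()].
#' @param timepoints timepoint labels.
#' @param seed integer seed.
#' @return Data frame with columns `mouse_id`, `timepoint`,
#'   `frequency_khz`, `threshold_db`.
#' @export
simulate_abr_table <- function(mice, timepoints = TIMEPOINTS, seed) {
  freqs <- c(8, 12, 16, 22, 28)
  base <- c(30, 30, 30, 30, 40)
  with_seed(seed, {
    rows <- lapply(mice, function(m) {
      mouse_base <- base + 10 * sample(-1:1, length(freqs), replace = TRUE)
      do.call(rbind, lapply(timepoints, function(tp) {
        thr <- mouse_base
        if (m$group == "EXPOSED" && tp != "baseline")
          thr[freqs == 28] <- thr[freqs == 28] + 20
        thr <- thr + 10 * sample(-1:1, length(freqs), replace = TRUE)
        data.frame(mouse_id = m$mouse_id, timepoint = tp,
                   frequency_khz = freqs,
                   threshold_db = pmin(80, pmax(10, thr)),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
}

#' Simulate a full behavioural cohort
#'
#' Generates every mouse's gap-detection and frequency-discrimination
#' sessions at every timepoint plus an ABR threshold table, fully
#' reproducible from `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return An object of class `gpias_cohort`: list with `mice`,
#'   `sessions` (list of `gpias_session`), `abr`, `seed`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  n_mice <- config$n_control + config$n_exposed
  tasks <- if (config$include_fd) c("FD-medium", "FD-high") else character()
  per_mouse <- length(config$timepoints) *
    (config$gap_sessions + config$fd_sessions * length(tasks))
  all_seeds <- derive_seeds(seed, n_mice * per_mouse + 1L)
  mice <- with_seed(all_seeds[n_mice * per_mouse + 1L], c(
    lapply(seq_len(config$n_control), function(i)
      cohort_mouse(config, i, "CONTROL", FALSE)),
    lapply(seq_len(config$n_exposed), function(i)
      cohort_mouse(config, i, "EXPOSED", i <= config$n_tinnitus))
  ))
  seeds <- matrix(all_seeds[seq_len(n_mice * per_mouse)], nrow = n_mice)
  sessions <- list()
  for (i in seq_along(mice)) {
    k <- 0L
    for (tp in config$timepoints) {
      for (s in seq_len(config$gap_sessions)) {
        k <- k + 1L
        ses <- simulate_gap_session(mice[[i]], tp, seeds[i, k])
        ses$session_index <- s
        sessions[[length(sessions) + 1L]] <- ses
      }
      for (task in tasks) for (s in seq_len(config$fd_sessions)) {
        k <- k + 1L
        ses <- simulate_fd_session(mice[[i]], task, tp, seeds[i, k])
        ses$session_index <- s
        sessions[[length(sessions) + 1L]] <- ses
      }
    }
  }
  abr <- simulate_abr_table(mice, config$timepoints,
                            derive_seeds(seed + 1L, 1L))
  structure(list(mice = mice, sessions = sessions, abr = abr,
                 seed = seed, config = config),
            class = "gpias_cohort")
}

#' @export
print.gpias_cohort <- function(x, ...) {
  groups <- vapply(x$mice, `[[`, character(1), "group")
  cat(sprintf("gpias_cohort: %d mice (%d control, %d exposed), %d sessions, seed %d\n",
              length(x$mice), sum(groups == "CONTROL"),
              sum(groups == "EXPOSED"), length(x$sessions), x$seed))
  invisible(x)
}

#' Extract sessions from a cohort
#'
#' @param cohort a `gpias_cohort`.
#' @param mouse_id,task,timepoint optional filters.
#' @return List of `gpias_session` objects.
#' @export
cohort_sessions <- function(cohort, mouse_id = NULL, task = NULL,
                            timepoint = NULL) {
  keep <- vapply(cohort$sessions, function(s) {
    (is.null(mouse_id) || s$mouse_id %in% mouse_id) &&
      (is.null(task) || s$task %in% task) &&
      (is.null(timepoint) || s$timepoint %in% timepoint)
  }, logical(1))
  cohort$sessions[keep]
}
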