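#' Startle force trace
#'
#' Container for the force-transducer signal of one trial.  Sample `i` is
#' taken at time `(i - 1) / sample_rate_hz` seconds from trace start.
#'
#' @param samples numeric vector of force samples (arbitrary units).
#' @param sample_rate_hz sampling rate (Hz).
#' @param ss_onset_s startle-stimulus onset (s from trace start).
#' @param spec optional one-row trial-schedule entry this trace realises.
#' @return An object of class `startle_trace`.
#' @export
startle_trace <- function(samples, sample_rate_hz, ss_onset_s, spec = NULL) {
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop_invalid("sample_rate_hz must be positive")
  if (!is.numeric(ss_onset_s) || ss_onset_s < 0)
    stop_invalid("ss_onset_s must be non-negative")
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 ss_onset_s = ss_onset_s,
                 spec = spec),
            class = "startle_trace")
}

#' @export
print.startle_trace <- function(x, ...) {
  cat(sprintf("startle_trace: %d samples @ %g Hz (%.2f s), SS onset %.2f s\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$ss_onset_s))
  invisible(x)
}

trace_times <- function(trace) {
  (seq_along(trace$samples) - 1) / trace$sample_rate_hz
}

#' Downsample a trace by block averaging
#'
#' Decimates the signal by replacing each block of `factor` consecutive
#' samples with its mean (any trailing partial block is dropped).  The
#' sample rate is divided by `factor`; event timestamps are unchanged.
#'
#' @param trace a [startle_trace()].
#' @param factor integer decimation factor (default 100, matching a raw
#'   acquisition stream reduced to its analysis rate).
#' @return A [startle_trace()] at the reduced rate.
#' @export
downsample_trace <- function(trace, factor = 100L) {
  stopifnot(inherits(trace, "startle_trace"))
  factor <- as.integer(factor)
  if (factor < 1L) stop_invalid("factor must be >= 1")
  n <- length(trace$samples)
  if (factor > n) stop_invalid("factor exceeds the number of samples")
  if (factor == 1L) return(trace)
  n_blocks <- n %/% factor
  m <- matrix(trace$samples[seq_len(n_blocks * factor)], nrow = factor)
  startle_trace(colMeans(m), trace$sample_rate_hz / factor,
                trace$ss_onset_s, trace$spec)
}

#' Startle-response amplitude of one trial
#'
#' The ASR amplitude is the maximum force in the 550 ms following SS onset
#' minus the mean activity in the 500 ms preceding it.  The onset sample
#' itself belongs to the baseline window, i.e. the peak is searched over
#' `(onset, onset + 550 ms]` and the baseline averaged over
#' `[onset - 500 ms, onset)`.  The result may be negative.
#'
#' @param trace a [startle_trace()] spanning both windows.
#' @return Amplitude (force units).
#' @export
compute_asr_amplitude <- function(trace) {
  stopifnot(inherits(trace, "startle_trace"))
  t <- trace_times(trace)
  onset <- trace$ss_onset_s
  peak_win <- t > onset & t <= onset + 0.55
  base_win <- t >= onset - 0.5 & t < onset
  if (!any(peak_win) || !any(base_win) ||
      onset - 0.5 < -1e-9 || max(t) < onset + 0.55 - 1 / trace$sample_rate_hz)
    stop_invalid("trace does not span [SS-500ms, SS+550ms]")
  max(trace$samples[peak_win]) - mean(trace$samples[base_win])
}

#' Pre-startle movement variability of one trial
#'
#' Standard deviation of the force signal over the `window_s` seconds
#' preceding SS onset (population convention, divide by n).  Used by the
#' movement-artifact exclusion rule.
#'
#' @param trace a [startle_trace()].
#' @param window_s window length before SS onset (s), default 9.
#' @return Standard deviation (force units).
#' @export
compute_pre_ss_sd <- function(trace, window_s = 9) {
  stopifnot(inherits(trace, "startle_trace"))
  t <- trace_times(trace)
  onset <- trace$ss_onset_s
  if (onset - window_s < -1e-9)
    stop_invalid("trace does not span ", window_s, " s before SS onset")
  win <- t >= onset - window_s & t < onset
  pop_sd(trace$samples[win])
}

## Grouping key for the exclusion rule: noise band for gap sessions,
## prepulse frequency (SA trials pooled as their own group) for FD.
exclusion_groups <- function(trials, task) {
  if (task == "GAP") {
    ifelse(trials$bookend, "bookend", trials$band)
  } else {
    ifelse(trials$kind == "SA", "SA", paste0("pp_", trials$prepulse_khz))
  }
}

#' Flag movement-artifact trials within a session
#'
#' For each frequency group in the session (noise band for gap sessions,
#' prepulse frequency for frequency-discrimination sessions) the mean
#' pre-SS standard deviation over all of that group's trials (including
#' the candidate trial) is computed once; any trial whose pre-SS SD
#' strictly exceeds `(1 + threshold_fraction)` times that mean is marked
#' excluded.  The rule is single-pass: flags never feed back into the
#' group means, so it is idempotent.
#'
#' @param session a `gpias_session` whose trials carry `pre_ss_sd`.
#' @param threshold_fraction allowed excess over the group mean
#'   (default 0.30, i.e. "more than 30%" excludes).
#' @param fd_sessions also apply the rule to frequency-discrimination
#'   sessions (default TRUE), grouping by prepulse frequency.
#' @return The session with updated `excluded` / `exclusion_reason`.
#' @export
apply_exclusion_rule <- function(session, threshold_fraction = 0.30,
                                 fd_sessions = TRUE) {
  stopifnot(inherits(session, "gpias_session"))
  trials <- session$trials
  if (any(is.na(trials$pre_ss_sd)))
    stop_invalid("all trials must carry pre_ss_sd")
  if (session$task != "GAP" && !fd_sessions) return(session)
  grp <- exclusion_groups(trials, session$task)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 0L) {
      warning("empty frequency group '", g, "' skipped")
      next
    }
    lim <- (1 + threshold_fraction) * mean(trials$pre_ss_sd[idx])
    bad <- idx[trials$pre_ss_sd[idx] > lim]
    trials$excluded[bad] <- TRUE
    trials$exclusion_reason[bad] <- "movement artifact (pre-SS SD)"
  }
  session$trials <- trials
  session
}

#' Assemble a session from processed trials
#'
#' @param mouse_id mouse identifier.
#' @param timepoint timepoint label (e.g. `"baseline"`, `"week4"`).
#' @param task `"GAP"`, `"FD-medium"` or `"FD-high"`.
#' @param trials data frame with one row per trial: the schedule columns
#'   plus `asr_amplitude` and `pre_ss_sd`.
#' @param protocol the protocol the schedule was built from.
#' @return An object of class `gpias_session`.
#' @export
gpias_session <- function(mouse_id, timepoint, task, trials, protocol) {
  stopifnot(task %in% c("GAP", "FD-medium", "FD-high"))
  if (!all(c("kind", "asr_amplitude", "pre_ss_sd") %in% names(trials)))
    stop_invalid("trials must carry kind, asr_amplitude and pre_ss_sd")
  if (is.null(trials$excluded)) trials$excluded <- FALSE
  if (is.null(trials$exclusion_reason))
    trials$exclusion_reason <- NA_character_
  structure(list(mouse_id = mouse_id, timepoint = timepoint, task = task,
                 trials = trials, protocol = protocol),
            class = "gpias_session")
}

#' @export
print.gpias_session <- function(x, ...) {
  cat(sprintf("%s session: mouse %s, %s, %d trials (%d excluded)\n",
              x$task, x$mouse_id, x$timepoint, nrow(x$trials),
              sum(x$trials$excluded)))
  invisible(x)
}

#' Process raw traces into a session of per-trial amplitudes
#'
#' Computes the ASR amplitude and pre-SS SD for each trace and assembles a
#' session; apply [apply_exclusion_rule()] afterwards.
#'
#' @param traces list of [startle_trace()]s, one per scheduled trial, each
#'   carrying its schedule row in `$spec`.
#' @inheritParams gpias_session
#' @param sd_window_s pre-SS SD window (s); 9 for gap sessions.
#' @return A `gpias_session`.
#' @export
process_traces <- function(traces, mouse_id, timepoint, task, protocol,
                           sd_window_s = 9) {
  trials <- do.call(rbind, lapply(traces, function(tr) tr$spec))
  trials$asr_amplitude <- vapply(traces, compute_asr_amplitude, numeric(1))
  trials$pre_ss_sd <- vapply(traces, compute_pre_ss_sd, numeric(1),
                             window_s = sd_window_s)
  gpias_session(mouse_id, timepoint, task, trials, protocol)
}
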