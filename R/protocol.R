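#' Noise bands used in the gap-detection assay
#'
#' The six background-noise bands in which a silent gap is embedded:
#' five narrow bands plus a 2--32 kHz broadband condition (labelled
#' \code{"BBN"}).
#'
#' @return A data frame with columns `label`, `low_khz`, `high_khz`.
#' @export
#' @examples
#' gap_bands()
gap_bands <- function() {
  data.frame(
    label    = c("6-8", "10-12", "14-16", "18-20", "26-28", "BBN"),
    low_khz  = c(6, 10, 14, 18, 26, 2),
    high_khz = c(8, 12, 16, 20, 28, 32),
    stringsAsFactors = FALSE
  )
}

#' Gap-detection session protocol
#'
#' Describes one GPIAS session: 98 trials in total, of which the first and
#' last are startle-only (SA) bookends and the remaining 96 are 8 SA plus
#' 8 gap (GA) trials in each of six noise bands, randomly intermixed.
#' The 40 ms silent gap starts 100 ms before startle-stimulus (SS) onset.
#'
#' @param bands data frame of noise bands (default [gap_bands()]).
#' @param n_sa_per_band,n_ga_per_band trials of each kind per band.
#' @param background_level_db,startle_level_db sound levels (dB SPL),
#'   carried as metadata only.
#' @param startle_dur_ms,gap_dur_ms,gap_lead_ms timing constants (ms).
#' @param pre_startle_background_s two-element range (s) from which each
#'   trial's background duration before the SS is drawn.
#' @param post_startle_background_ms background resumption after the SS (ms).
#' @return An object of class `gap_protocol`.
#' @export
gap_protocol <- function(bands = gap_bands(),
                         n_sa_per_band = 8L, n_ga_per_band = 8L,
                         background_level_db = 60, startle_level_db = 115,
                         startle_dur_ms = 50, gap_dur_ms = 40,
                         gap_lead_ms = 100,
                         pre_startle_background_s = c(10, 20),
                         post_startle_background_ms = 500) {
  stopifnot(is.data.frame(bands),
            all(c("label", "low_khz", "high_khz") %in% names(bands)))
  if (anyDuplicated(bands$label))
    stop_invalid("band labels must be unique")
  if (any(bands$low_khz >= bands$high_khz))
    stop_invalid("each band needs low_khz < high_khz")
  if (length(pre_startle_background_s) != 2L ||
      diff(pre_startle_background_s) < 0)
    stop_invalid("pre_startle_background_s must be an increasing range")
  structure(list(
    bands = bands,
    n_sa_per_band = as.integer(n_sa_per_band),
    n_ga_per_band = as.integer(n_ga_per_band),
    background_level_db = background_level_db,
    startle_level_db = startle_level_db,
    startle_dur_ms = startle_dur_ms,
    gap_dur_ms = gap_dur_ms,
    gap_lead_ms = gap_lead_ms,
    pre_startle_background_s = pre_startle_background_s,
    post_startle_background_ms = post_startle_background_ms
  ), class = c("gap_protocol", "gpias_protocol"))
}

#' Frequency-discrimination session protocol
#'
#' Describes one PPI-based frequency-discrimination session.  A session is
#' 9 leading SA trials, 120 prepulse trials in pseudorandom order, and one
#' trailing SA trial.  The prepulse is an 80 ms shift of the background
#' tone to one of nine frequencies (one of which equals the background and
#' serves as the no-shift reference).
#'
#' Two presets are defined: `"medium"` (12 kHz background, upward shifts)
#' and `"high"` (22 kHz background, downward shifts).
#'
#' @param task `"medium"` or `"high"`, or `NULL` when `background_khz` and
#'   `prepulse_khz` are given explicitly.
#' @param background_khz background tone frequency (kHz).
#' @param prepulse_khz nine prepulse frequencies (kHz); exactly one must
#'   equal `background_khz`.
#' @param background_level_db,startle_level_db levels (dB SPL), metadata.
#' @param startle_dur_ms,prepulse_dur_ms,ramp_ms timing constants (ms).
#' @param n_lead_sa,n_prepulse_trials,n_tail_sa trial counts.
#' @param iti_s two-element inter-trial-interval range (s).
#' @return An object of class `fd_protocol`.
#' @export
#' @examples
#' fd_protocol("medium")$background_khz  # 12
fd_protocol <- function(task = c("medium", "high"),
                        background_khz = NULL, prepulse_khz = NULL,
                        background_level_db = 70, startle_level_db = 120,
                        startle_dur_ms = 20, prepulse_dur_ms = 80,
                        ramp_ms = 1,
                        n_lead_sa = 9L, n_prepulse_trials = 120L,
                        n_tail_sa = 1L, iti_s = c(10, 20)) {
  if (is.null(background_khz)) {
    task <- match.arg(task)
    if (task == "medium") {
      background_khz <- 12
      prepulse_khz <- c(15.84, 13.84, 13.20, 12.96, 12.72,
                        12.48, 12.24, 12.12, 12)
    } else {
      background_khz <- 22
      prepulse_khz <- c(14.96, 18.48, 19.80, 20.24, 20.68,
                        21.12, 21.56, 21.78, 22)
    }
  } else {
    task <- if (is.character(task)) match.arg(task) else "custom"
  }
  if (background_khz <= 0) stop_invalid("background_khz must be positive")
  if (sum(prepulse_khz == background_khz) != 1L)
    stop_invalid("exactly one prepulse frequency must equal the background")
  structure(list(
    task = paste0("FD-", task),
    background_khz = background_khz,
    prepulse_khz = prepulse_khz,
    background_level_db = background_level_db,
    startle_level_db = startle_level_db,
    startle_dur_ms = startle_dur_ms,
    prepulse_dur_ms = prepulse_dur_ms,
    ramp_ms = ramp_ms,
    n_lead_sa = as.integer(n_lead_sa),
    n_prepulse_trials = as.integer(n_prepulse_trials),
    n_tail_sa = as.integer(n_tail_sa),
    iti_s = iti_s
  ), class = c("fd_protocol", "gpias_protocol"))
}

#' Percent frequency shift relative to a background tone
#'
#' Expresses a test frequency as the absolute percent change from the
#' background tone: `100 * |background - test| / background`.
#'
#' @param background_khz background frequency (kHz), positive.
#' @param test_khz test frequency (kHz); vectorised.
#' @return Percent shift(s), non-negative.
#' @export
#' @examples
#' delta_f_percent(12, 15.84)  # 32
#' delta_f_percent(22, 21.78)  # 1
delta_f_percent <- function(background_khz, test_khz) {
  if (!is.numeric(background_khz) || any(background_khz <= 0))
    stop_invalid("background frequency must be positive")
  100 * abs(background_khz - test_khz) / background_khz
}

#' Build a seeded gap-session trial schedule
#'
#' Trials 1 and 98 are SA bookends (drawn a random band context each); the
#' 96 interior trials are a seeded random permutation of 8 SA + 8 GA
#' trials for each band.  Per-trial background durations are drawn
#' uniformly from the protocol's range; the gap (GA trials) starts
#' `gap_lead_ms` before SS onset.
#'
#' @param protocol a [gap_protocol()].
#' @param seed integer seed; the schedule is a deterministic function of
#'   `(protocol, seed)`.
#' @return A data frame of trials with columns `index`, `kind`
#'   (`"SA"`/`"GA"`), `band`, `bookend`, `bg_dur_s`, `ss_onset_s`,
#'   `gap_onset_s` (NA for SA trials).
#' @export
build_gap_session_schedule <- function(protocol = gap_protocol(), seed) {
  stopifnot(inherits(protocol, "gap_protocol"))
  labs <- protocol$bands$label
  interior <- data.frame(
    kind = rep(rep(c("SA", "GA"),
                   c(protocol$n_sa_per_band, protocol$n_ga_per_band)),
               times = length(labs)),
    band = rep(labs, each = protocol$n_sa_per_band + protocol$n_ga_per_band),
    stringsAsFactors = FALSE
  )
  n_int <- nrow(interior)
  with_seed(seed, {
    interior <- interior[sample.int(n_int), , drop = FALSE]
    sched <- data.frame(
      index = seq_len(n_int + 2L),
      kind = c("SA", interior$kind, "SA"),
      band = c(sample(labs, 1L), interior$band, sample(labs, 1L)),
      bookend = c(TRUE, rep(FALSE, n_int), TRUE),
      stringsAsFactors = FALSE
    )
    rng <- protocol$pre_startle_background_s
    sched$bg_dur_s <- stats::runif(nrow(sched), rng[1], rng[2])
    sched$ss_onset_s <- sched$bg_dur_s
    sched$gap_onset_s <- ifelse(
      sched$kind == "GA",
      sched$ss_onset_s - protocol$gap_lead_ms / 1000, NA_real_)
    rownames(sched) <- NULL
    sched
  })
}

#' Build a seeded frequency-discrimination trial schedule
#'
#' 9 leading SA trials, then 120 prepulse trials in seeded pseudorandom
#' order, then 1 trailing SA trial.  The 120 prepulse trials are spread
#' across the nine frequencies as evenly as possible (counts of 13 or 14);
#' the frequencies receiving the extra trial are fixed by list position so
#' the per-frequency trial multiset does not depend on the seed.
#'
#' @param protocol an [fd_protocol()].
#' @param seed integer seed.
#' @return A data frame of trials with columns `index`, `kind`
#'   (`"SA"`/`"PREPULSE"`), `prepulse_khz` (NA for SA), `delta_f_pct`,
#'   `iti_s`, `ss_onset_s`, `prepulse_onset_s`.
#' @export
build_fd_session_schedule <- function(protocol, seed) {
  stopifnot(inherits(protocol, "fd_protocol"))
  freqs <- protocol$prepulse_khz
  n_f <- length(freqs)
  base_n <- protocol$n_prepulse_trials %/% n_f
  extra <- protocol$n_prepulse_trials %% n_f
  counts <- rep(base_n, n_f) + c(rep(1L, extra), rep(0L, n_f - extra))
  pp <- rep(freqs, times = counts)
  with_seed(seed, {
    pp <- pp[sample.int(length(pp))]
    n <- protocol$n_lead_sa + length(pp) + protocol$n_tail_sa
    sched <- data.frame(
      index = seq_len(n),
      kind = c(rep("SA", protocol$n_lead_sa), rep("PREPULSE", length(pp)),
               rep("SA", protocol$n_tail_sa)),
      prepulse_khz = c(rep(NA_real_, protocol$n_lead_sa), pp,
                       rep(NA_real_, protocol$n_tail_sa)),
      stringsAsFactors = FALSE
    )
    sched$delta_f_pct <- ifelse(
      is.na(sched$prepulse_khz), NA_real_,
      delta_f_percent(protocol$background_khz, sched$prepulse_khz))
    sched$iti_s <- stats::runif(n, protocol$iti_s[1], protocol$iti_s[2])
    sched$ss_onset_s <- sched$iti_s
    sched$prepulse_onset_s <- ifelse(
      sched$kind == "PREPULSE",
      sched$ss_onset_s - protocol$prepulse_dur_ms / 1000, NA_real_)
    rownames(sched) <- NULL
    sched
  })
}

#' Read a protocol preset from a YAML file
#'
#' Presets for the default gap protocol and the two frequency-
#' discrimination tasks ship with the package under
#' `system.file("extdata", package = "gpias")`.
#'
#' @param path path to a YAML protocol description with a `type` key of
#'   `"gap"` or `"fd"` and fields mirroring the constructor arguments.
#' @return A `gap_protocol` or `fd_protocol` object.
#' @export
read_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$type
  cfg$type <- NULL
  if (identical(type, "gap")) {
    if (!is.null(cfg$bands))
      cfg$bands <- do.call(rbind.data.frame, c(cfg$bands, stringsAsFactors = FALSE))
    do.call(gap_protocol, cfg)
  } else if (identical(type, "fd")) {
    cfg$prepulse_khz <- as.numeric(cfg$prepulse_khz)
    do.call(fd_protocol, cfg)
  } else stop_invalid("unknown protocol type: ", type)
}

#' @export
print.gpias_protocol <- function(x, ...) {
  if (inherits(x, "gap_protocol")) {
    cat("Gap-detection protocol:", nrow(x$bands), "bands,",
        2L + nrow(x$bands) * (x$n_sa_per_band + x$n_ga_per_band),
        "trials/session\n")
    cat("  bands:", paste(x$bands$label, collapse = ", "), "\n")
  } else {
    cat(x$task, "protocol: background", x$background_khz, "kHz,",
        x$n_lead_sa + x$n_prepulse_trials + x$n_tail_sa, "trials/session\n")
    cat("  prepulse (kHz):", paste(x$prepulse_khz, collapse = ", "), "\n")
  }
  invisible(x)
}
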