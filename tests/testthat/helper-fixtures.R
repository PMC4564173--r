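## Shared fixtures built in code.

## A gap session assembled directly from per-trial amplitudes (one band
## unless more are given), bypassing the simulator.
make_gap_session <- function(sa, ga, band = "6-8", pre_ss_sd = 1,
                             mouse_id = "m1", timepoint = "baseline") {
  trials <- data.frame(
    index = seq_len(length(sa) + length(ga)),
    kind = rep(c("SA", "GA"), c(length(sa), length(ga))),
    band = band,
    bookend = FALSE,
    asr_amplitude = c(sa, ga),
    pre_ss_sd = pre_ss_sd,
    stringsAsFactors = FALSE
  )
  gpias_session(mouse_id, timepoint, "GAP", trials, gap_protocol())
}

## An FD session with given per-frequency amplitudes (recycled over
## `reps` trials each).
make_fd_session <- function(prepulse_khz, amplitudes, reps = 1,
                            protocol = fd_protocol("medium"),
                            mouse_id = "m1", timepoint = "baseline") {
  trials <- data.frame(
    index = seq_len(length(prepulse_khz) * reps),
    kind = "PREPULSE",
    prepulse_khz = rep(prepulse_khz, each = reps),
    asr_amplitude = rep(amplitudes, each = reps),
    pre_ss_sd = 1,
    stringsAsFactors = FALSE
  )
  gpias_session(mouse_id, timepoint, protocol$task, trials, protocol)
}

## Noise-free PPI points on a known logistic.
logistic_points <- function(a = 160, b = 0, c = -0.1,
                            delta_f = c(0, 1, 2, 4, 6, 8, 10, 16, 32),
                            base = 5, sd_asr = 0, n = 13) {
  ppi <- psych_logistic(delta_f, a, b, c)
  ppi_points(delta_f, base * (1 - ppi / 100), sd_asr = sd_asr, n = n)
}

## A small cohort configuration that keeps end-to-end tests fast.
small_config <- function(...) {
  cohort_config(n_control = 3L, n_exposed = 6L, n_tinnitus = 4L,
                gap_sessions = 2L, fd_sessions = 1L, ...)
}

## Independent brute-force within-subject sums of squares, computed with
## explicit loops straight from the definitions (oracle for the ANOVA).
brute_force_ss <- function(d, value, subject, within) {
  s <- factor(d[[subject]]); A <- factor(d[[within[1]]]); B <- factor(d[[within[2]]])
  y <- d[[value]]
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  Y <- array(NA_real_, c(n, a, b))
  for (r in seq_len(nrow(d)))
    Y[as.integer(s)[r], as.integer(A)[r], as.integer(B)[r]] <- y[r]
  gm <- mean(Y)
  ss <- c(A = 0, B = 0, AB = 0, errA = 0, errB = 0, errAB = 0)
  for (j in 1:a) ss["A"] <- ss["A"] + n * b * (mean(Y[, j, ]) - gm)^2
  for (k in 1:b) ss["B"] <- ss["B"] + n * a * (mean(Y[, , k]) - gm)^2
  for (j in 1:a) for (k in 1:b)
    ss["AB"] <- ss["AB"] + n * (mean(Y[, j, k]) - mean(Y[, j, ]) -
                                  mean(Y[, , k]) + gm)^2
  for (i in 1:n) for (j in 1:a)
    ss["errA"] <- ss["errA"] + b * (mean(Y[i, j, ]) - mean(Y[i, , ]) -
                                      mean(Y[, j, ]) + gm)^2
  for (i in 1:n) for (k in 1:b)
    ss["errB"] <- ss["errB"] + a * (mean(Y[i, , k]) - mean(Y[i, , ]) -
                                      mean(Y[, , k]) + gm)^2
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    ss["errAB"] <- ss["errAB"] +
      (Y[i, j, k] - mean(Y[i, j, ]) - mean(Y[i, , k]) - mean(Y[, j, k]) +
         mean(Y[i, , ]) + mean(Y[, j, ]) + mean(Y[, , k]) - gm)^2
  ss
}
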