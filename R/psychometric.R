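#' Generalized logistic prepulse-inhibition curve
#'
#' The psychometric model linking percent frequency shift to percent
#' prepulse inhibition:
#' `PPI(df) = a / (1 + exp(b + c * df)) - a / 2`.
#' With `b = 0` the curve passes through the origin and saturates at
#' `a / 2` for large shifts (for negative `c`).  An alternative
#' two-asymptote reading `PPI(df) = a1 / (1 + exp(b + c * df)) - a2` is
#' available through [fit_psychometric()]'s `form` argument.
#'
#' @param delta_f percent frequency shift(s).
#' @param a,b,c parameters: `a` scales the dynamic range (saturation at
#'   `a/2`), `b` offsets the curve at zero shift, `c` (per percent shift)
#'   sets slope and direction.
#' @return PPI value(s) in percent.
#' @export
#' @examples
#' psych_logistic(0, 160, 0, -0.1)    # 0
#' psych_logistic(1e6, 160, 0, -0.1)  # 80 (= a/2)
psych_logistic <- function(delta_f, a, b, c) {
  a / (1 + exp(b + c * delta_f)) - a / 2
}

#' Per-frequency prepulse inhibition for one session
#'
#' Averages non-excluded ASR amplitudes per prepulse frequency and
#' normalises to the session's own zero-shift point: the trials whose
#' prepulse equals the background tone define `ASRnopps`, and
#' `PPI = 100 * (ASRnopps - ASRpps) / ASRnopps`.  PPI at zero shift is
#' exactly 0 by construction; negative values (facilitation) are kept.
#'
#' @param session a `gpias_session` with an FD task, exclusion applied.
#' @return Data frame of class `ppi_points` with one row per prepulse
#'   frequency: `prepulse_khz`, `delta_f_pct`, `mean_asr`, `sd_asr`, `n`,
#'   `ppi_pct`; the background frequency is attached as
#'   `attr(, "background_khz")`.
#' @export
compute_ppi <- function(session) {
  stopifnot(inherits(session, "gpias_session"))
  if (!session$task %in% c("FD-medium", "FD-high"))
    stop_invalid("not a frequency-discrimination session")
  tr <- session$trials
  tr <- tr[!tr$excluded & tr$kind == "PREPULSE", , drop = FALSE]
  bg <- session$protocol$background_khz
  freqs <- sort(unique(session$protocol$prepulse_khz))
  rows <- lapply(freqs, function(f) {
    amp <- tr$asr_amplitude[tr$prepulse_khz == f]
    if (length(amp) == 0L) return(NULL)
    data.frame(prepulse_khz = f,
               delta_f_pct = delta_f_percent(bg, f),
               mean_asr = mean(amp), sd_asr = stats::sd(amp),
               n = length(amp), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ref <- res$mean_asr[res$delta_f_pct == 0]
  if (length(ref) != 1L || is.na(ref) || ref == 0)
    stop_invalid("zero-shift reference (ASRnopps) missing or zero; cannot normalise")
  res$ppi_pct <- 100 * (ref - res$mean_asr) / ref
  rownames(res) <- NULL
  structure(res, background_khz = bg,
            class = c("ppi_points", "data.frame"))
}

#' Build a PPI point table directly from summary values
#'
#' Convenience constructor for fitting or bootstrapping from tabulated
#' per-frequency ASR means and SDs (e.g. group-pooled data).
#'
#' @param delta_f_pct percent shifts (must include 0).
#' @param mean_asr,sd_asr,n per-frequency ASR summaries; `ppi_pct` is
#'   recomputed from the zero-shift point.
#' @param prepulse_khz optional frequencies (kHz).
#' @return A `ppi_points` data frame.
#' @export
ppi_points <- function(delta_f_pct, mean_asr, sd_asr = 0,
                       n = 1L, prepulse_khz = NA_real_) {
  ref <- mean_asr[delta_f_pct == 0]
  if (length(ref) != 1L || ref == 0)
    stop_invalid("need exactly one zero-shift point with non-zero mean")
  res <- data.frame(prepulse_khz = prepulse_khz, delta_f_pct = delta_f_pct,
                    mean_asr = mean_asr,
                    sd_asr = rep_len(sd_asr, length(mean_asr)),
                    n = rep_len(as.integer(n), length(mean_asr)),
                    ppi_pct = 100 * (ref - mean_asr) / ref,
                    stringsAsFactors = FALSE)
  structure(res, class = c("ppi_points", "data.frame"))
}

## Closed-form threshold of the symmetric logistic: PPI(th) = level.
logistic_threshold <- function(a, b, c, level) {
  if (level >= a / 2) return(NA_real_)
  arg <- a / (level + a / 2) - 1
  if (arg <= 0) return(NA_real_)
  (log(arg) - b) / c
}

#' Fit the psychometric function to PPI points
#'
#' Nonlinear least squares (Levenberg--Marquardt) of the generalized
#' logistic to per-frequency PPI values, with multi-start initialisation:
#' `a` starts at twice the largest observed PPI (clamped to (0, 200]),
#' `b` at 0, and `c` over a coarse grid of magnitudes and both signs.
#' The discrimination threshold at `level` percent inhibition is
#' extracted in closed form from the fitted parameters.
#'
#' @param points a `ppi_points` data frame (or any data frame with
#'   `delta_f_pct` and `ppi_pct`), at least 4 distinct shifts.
#' @param level inhibition level defining the threshold (percent,
#'   default 40).
#' @param form `"symmetric"` for `a/(1+exp(b+c*df)) - a/2` or
#'   `"two-asymptote"` for `a1/(1+exp(b+c*df)) - a2` (free lower
#'   asymptote).
#' @param weights optional per-point weights for the least squares.
#' @return An object of class `psychfit` with components `coefficients`
#'   (`a`, `b`, `c`, plus `a2` for the two-asymptote form), `converged`,
#'   `rss`, `th`, `th_level`, `form`, `points`.
#' @export
#' @examples
#' pts <- ppi_points(c(0, 1, 2, 4, 8, 16, 32),
#'                   5 * (1 - psych_logistic(c(0, 1, 2, 4, 8, 16, 32),
#'                                           160, 0, -0.1) / 100))
#' fit <- fit_psychometric(pts)
#' coef(fit)
#' fit$th  # ~11 percent shift
fit_psychometric <- function(points, level = 40,
                             form = c("symmetric", "two-asymptote"),
                             weights = NULL) {
  form <- match.arg(form)
  df <- points$delta_f_pct
  y <- points$ppi_pct
  keep <- is.finite(df) & is.finite(y)
  df <- df[keep]; y <- y[keep]
  if (length(unique(df)) < 4L)
    stop_invalid("need at least 4 distinct shift values to fit")
  a0 <- min(max(2 * max(abs(y)), 10), 200)
  c_grid <- c(-1, -0.1, -0.01, 1, 0.1, 0.01)
  dat <- data.frame(df = df, y = y)
  w <- if (is.null(weights)) rep(1, length(y)) else weights[keep]
  best <- NULL
  for (c0 in c_grid) {
    fit <- tryCatch({
      ## maxiter chatter is suppressed; fit quality is judged by the RSS
      ## comparison across starts and the converged flag
      if (form == "symmetric")
        suppressWarnings(minpack.lm::nlsLM(y ~ a / (1 + exp(b + c * df)) - a / 2,
                          data = dat, weights = w,
                          start = list(a = a0, b = 0, c = c0),
                          lower = c(a = 1e-6, b = -Inf, c = -Inf),
                          upper = c(a = 200, b = Inf, c = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200)))
      else
        suppressWarnings(minpack.lm::nlsLM(y ~ a / (1 + exp(b + c * df)) - a2,
                          data = dat, weights = w,
                          start = list(a = a0, b = 0, c = c0, a2 = a0 / 2),
                          lower = c(a = 1e-6, b = -Inf, c = -Inf, a2 = -Inf),
                          upper = c(a = 200, b = Inf, c = Inf, a2 = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200)))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(coefficients = c(a = NA_real_, b = NA_real_,
                                           c = NA_real_),
                          converged = FALSE, rss = NA_real_,
                          th = NA_real_, th_level = level,
                          form = form, points = points),
                     class = "psychfit"))
  }
  cf <- stats::coef(best$fit)
  ## a degenerate (flat) solution carries no slope information
  flat <- stats::sd(y) < 1e-10
  converged <- !flat && is.finite(best$rss)
  th <- if (converged) {
    if (form == "symmetric")
      logistic_threshold(cf[["a"]], cf[["b"]], cf[["c"]], level)
    else {
      arg <- cf[["a"]] / (level + cf[["a2"]]) - 1
      if (arg > 0) (log(arg) - cf[["b"]]) / cf[["c"]] else NA_real_
    }
  } else NA_real_
  structure(list(coefficients = cf, converged = converged, rss = best$rss,
                 th = th, th_level = level, form = form, points = points),
            class = "psychfit")
}

#' Extract the discrimination threshold from a fitted curve
#'
#' Closed-form inversion of the fitted logistic at `level` percent
#' inhibition; defined only when `level` lies below the curve's upper
#' asymptote (`a/2` for the symmetric form).
#'
#' @param fit a `psychfit`.
#' @param level inhibition level (percent).
#' @return The shift (percent) at which fitted PPI equals `level`, or
#'   `NA` if undefined or the fit did not converge.
#' @export
threshold_from_fit <- function(fit, level = 40) {
  stopifnot(inherits(fit, "psychfit"))
  if (!fit$converged) return(NA_real_)
  cf <- fit$coefficients
  if (fit$form == "symmetric")
    logistic_threshold(cf[["a"]], cf[["b"]], cf[["c"]], level)
  else {
    arg <- cf[["a"]] / (level + cf[["a2"]]) - 1
    if (arg > 0) (log(arg) - cf[["b"]]) / cf[["c"]] else NA_real_
  }
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
print.psychfit <- function(x, ...) {
  cat("Generalized-logistic psychometric fit (", x$form, " form)\n", sep = "")
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat("  ", paste(sprintf("%s = %.4g", names(x$coefficients),
                          x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g; Th at %g%% inhibition = %s\n", x$rss,
              x$th_level,
              if (is.na(x$th)) "undefined" else sprintf("%.3f%% shift", x$th)))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  out <- list(coefficients = object$coefficients,
              converged = object$converged, rss = object$rss,
              th = object$th, th_level = object$th_level,
              n_points = nrow(object$points),
              residuals = if (object$converged)
                object$points$ppi_pct -
                  predict(object, object$points$delta_f_pct) else NULL)
  class(out) <- "summary.psychfit"
  out
}

#' @export
print.summary.psychfit <- function(x, ...) {
  cat("Psychometric fit over", x$n_points, "PPI points\n")
  print(x$coefficients)
  cat(sprintf("converged: %s, RSS = %.4g, Th%g = %.4g\n",
              x$converged, x$rss, x$th_level, x$th))
  invisible(x)
}

#' Predicted PPI at given shifts
#'
#' @param object a `psychfit`.
#' @param newdata percent shifts (vector) or data frame with
#'   `delta_f_pct`; defaults to the fitted points.
#' @param ... unused.
#' @return Predicted PPI (percent).
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop_invalid("fit did not converge")
  df <- if (is.null(newdata)) object$points$delta_f_pct
        else if (is.data.frame(newdata)) newdata$delta_f_pct
        else as.numeric(newdata)
  cf <- object$coefficients
  if (object$form == "symmetric")
    psych_logistic(df, cf[["a"]], cf[["b"]], cf[["c"]])
  else
    cf[["a"]] / (1 + exp(cf[["b"]] + cf[["c"]] * df)) - cf[["a2"]]
}

#' @export
residuals.psychfit <- function(object, ...) {
  object$points$ppi_pct - predict(object, object$points$delta_f_pct)
}

#' @export
plot.psychfit <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$delta_f_pct, pts$ppi_pct, pch = 19,
                 xlab = expression(paste(Delta, "f (%)")),
                 ylab = "PPI (%)", ...)
  if (x$converged) {
    grid <- seq(0, max(pts$delta_f_pct), length.out = 200)
    graphics::lines(grid, predict(x, grid))
    if (!is.na(x$th)) {
      graphics::abline(h = x$th_level, lty = 3)
      graphics::abline(v = x$th, lty = 3)
    }
  }
  invisible(x)
}

#' Parametric bootstrap of the discrimination threshold
#'
#' For each of `n_draws` replicates, every frequency's ASR is redrawn
#' from `Normal(mean_asr, sd_asr)` (clipped at a small positive floor,
#' since amplitudes are forces), PPI is recomputed against the drawn
#' zero-shift reference, the psychometric function refit (initialised at
#' the point-estimate parameters), and the threshold extracted.  Draws
#' whose refit fails or yields an undefined threshold are discarded and
#' counted.
#'
#' @param points a `ppi_points` table with `mean_asr`, `sd_asr`, `n`.
#' @param n_draws number of bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param level threshold level (percent).
#' @param floor lower clip for drawn amplitudes (force units).
#' @return An object of class `th_boot`: `mean`, `sd`, `draws`,
#'   `n_draws`, `n_failed`, `unreliable` (TRUE when more than half the
#'   draws failed), `point_th`.
#' @export
bootstrap_thresholds <- function(points, n_draws = 1000L, seed,
                                 level = 40, floor = 1e-6) {
  stopifnot(all(c("delta_f_pct", "mean_asr", "sd_asr") %in% names(points)))
  point_fit <- fit_psychometric(points, level = level)
  start <- if (point_fit$converged) point_fit$coefficients else NULL
  i0 <- which(points$delta_f_pct == 0)
  if (length(i0) != 1L) stop_invalid("need exactly one zero-shift point")
  ths <- with_seed(seed, {
    vapply(seq_len(n_draws), function(k) {
      asr <- pmax(stats::rnorm(nrow(points), points$mean_asr,
                               points$sd_asr), floor)
      ppi <- 100 * (asr[i0] - asr) / asr[i0]
      fit <- refit_quick(points$delta_f_pct, ppi, start, level)
      fit
    }, numeric(1))
  })
  ok <- is.finite(ths)
  structure(list(mean = if (any(ok)) mean(ths[ok]) else NA_real_,
                 sd = if (sum(ok) > 1L) stats::sd(ths[ok]) else 0,
                 draws = ths[ok], n_draws = n_draws,
                 n_failed = sum(!ok), unreliable = sum(!ok) > n_draws / 2,
                 point_th = point_fit$th, level = level),
            class = "th_boot")
}

## One fast bootstrap refit: warm-started Levenberg-Marquardt, falling
## back to the multi-start fitter when the warm start fails.
refit_quick <- function(delta_f, ppi, start, level) {
  dat <- data.frame(df = delta_f, y = ppi)
  fit <- NULL
  if (!is.null(start)) {
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(y ~ a / (1 + exp(b + c * df)) - a / 2, data = dat,
                          start = as.list(start),
                          lower = c(a = 1e-6, b = -Inf, c = -Inf),
                          upper = c(a = 200, b = Inf, c = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    f <- tryCatch(fit_psychometric(data.frame(delta_f_pct = delta_f,
                                              ppi_pct = ppi), level = level),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    return(if (is.null(f$th)) NA_real_ else f$th)
  }
  cf <- stats::coef(fit)
  th <- logistic_threshold(cf[["a"]], cf[["b"]], cf[["c"]], level)
  if (is.null(th)) NA_real_ else th
}

#' @export
print.th_boot <- function(x, ...) {
  cat(sprintf("Bootstrap threshold at %g%% inhibition: mean = %.3f, sd = %.3f (%d draws, %d failed%s)\n",
              x$level, x$mean, x$sd, x$n_draws, x$n_failed,
              if (x$unreliable) "; UNRELIABLE" else ""))
  invisible(x)
}

#' Compare a post-exposure threshold distribution to baseline
#'
#' The significance rule for bootstrap threshold distributions: the
#' change is significant when the post mean lies at least one baseline
#' standard deviation away from the baseline mean.
#'
#' @param baseline,post `th_boot` objects from [bootstrap_thresholds()].
#' @return An object of class `th_comparison`: baseline/post means and
#'   SDs, `significant`, `unreliable`, `n_failed_fits`.
#' @export
compare_threshold_to_baseline <- function(baseline, post) {
  stopifnot(inherits(baseline, "th_boot"), inherits(post, "th_boot"))
  structure(list(th_baseline_mean = baseline$mean,
                 th_baseline_sd = baseline$sd,
                 th_post_mean = post$mean, th_post_sd = post$sd,
                 n_draws = baseline$n_draws,
                 n_failed_fits = baseline$n_failed + post$n_failed,
                 significant = isTRUE(
                   abs(post$mean - baseline$mean) >= baseline$sd),
                 unreliable = baseline$unreliable || post$unreliable),
            class = "th_comparison")
}

#' @export
print.th_comparison <- function(x, ...) {
  cat(sprintf("Threshold change: baseline %.3f (sd %.3f) -> post %.3f: %s%s\n",
              x$th_baseline_mean, x$th_baseline_sd, x$th_post_mean,
              if (x$significant) "SIGNIFICANT (>= 1 baseline SD)"
              else "not significant",
              if (x$unreliable) " [unreliable]" else ""))
  invisible(x)
}
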