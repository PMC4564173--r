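#' Per-band gap-induced startle inhibition for one session
#'
#' For each noise band, the mean ASR amplitude over non-excluded SA and GA
#' trials (bookend trials are session-integrity checks and never enter the
#' band means), with percent inhibition
#' `100 * (mean_SA - mean_GA) / mean_SA`.  Negative values indicate
#' facilitation and are reported as-is; a zero SA mean leaves the
#' inhibition undefined (`NA` with a warning).
#'
#' @param session a `gpias_session` with `task == "GAP"`, exclusion rule
#'   already applied.
#' @return Data frame with one row per band: `band`, `mean_sa`, `mean_ga`,
#'   `sem_sa`, `sem_ga`, `n_sa`, `n_ga`, `inhibition_pct`.
#' @export
#' @examples
#' m <- mouse_params("m1", "CONTROL")
#' s <- apply_exclusion_rule(simulate_gap_session(m, "baseline", seed = 1))
#' compute_gap_inhibition(s)
compute_gap_inhibition <- function(session) {
  stopifnot(inherits(session, "gpias_session"))
  if (session$task != "GAP") stop_invalid("not a gap session")
  tr <- session$trials
  tr <- tr[!tr$excluded & !tr$bookend, , drop = FALSE]
  present <- session$protocol$bands$label[
    session$protocol$bands$label %in% session$trials$band]
  out <- lapply(present, function(b) {
    sa <- tr$asr_amplitude[tr$band == b & tr$kind == "SA"]
    ga <- tr$asr_amplitude[tr$band == b & tr$kind == "GA"]
    if (length(sa) == 0L || length(ga) == 0L) {
      warning("band ", b, " has no usable SA or GA trials; dropped")
      return(NULL)
    }
    inh <- if (mean(sa) == 0) {
      warning("band ", b, ": zero mean SA amplitude, inhibition undefined")
      NA_real_
    } else 100 * (mean(sa) - mean(ga)) / mean(sa)
    data.frame(band = b, mean_sa = mean(sa), mean_ga = mean(ga),
               sem_sa = sem(sa), sem_ga = sem(ga),
               n_sa = length(sa), n_ga = length(ga),
               inhibition_pct = inh, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Average per-band inhibition across a mouse's sessions
#'
#' Unweighted mean of the per-session percent-inhibition values in each
#' band, with the between-session SEM and the number of contributing
#' sessions.  Bands missing from some sessions are averaged over the
#' sessions that carry them.
#'
#' @param sessions list of `gpias_session` (gap task, one mouse and
#'   timepoint) or list of data frames as returned by
#'   [compute_gap_inhibition()].
#' @return Data frame with columns `band`, `inhibition_pct`, `sem`,
#'   `n_sessions`.
#' @export
aggregate_inhibition <- function(sessions) {
  if (length(sessions) == 0L) stop_invalid("need at least one session")
  tabs <- lapply(sessions, function(s) {
    if (inherits(s, "gpias_session")) compute_gap_inhibition(s) else s
  })
  long <- do.call(rbind, lapply(seq_along(tabs), function(i)
    cbind(tabs[[i]][c("band", "inhibition_pct")], session = i)))
  bands <- unique(long$band)
  res <- do.call(rbind, lapply(bands, function(b) {
    v <- long$inhibition_pct[long$band == b]
    v <- v[!is.na(v)]
    data.frame(band = b, inhibition_pct = mean(v),
               sem = sem(v), n_sessions = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

## Per-(band, session) inhibition table for classification pairing.
session_inhibition_table <- function(sessions) {
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    tab <- compute_gap_inhibition(s)
    idx <- if (!is.null(s$session_index)) s$session_index else i
    data.frame(band = tab$band, session = idx,
               inhibition_pct = tab$inhibition_pct,
               stringsAsFactors = FALSE)
  }))
}

## Paired GA-vs-SA amplitude table (alternative classification contrast).
session_ga_sa_table <- function(sessions) {
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    tab <- compute_gap_inhibition(s)
    idx <- if (!is.null(s$session_index)) s$session_index else i
    data.frame(band = tab$band, session = idx,
               sa = tab$mean_sa, ga = tab$mean_ga,
               stringsAsFactors = FALSE)
  }))
}

#' Classify a mouse as Tinnitus(+) or Tinnitus(-)
#'
#' The operational tinnitus label: a mouse is Tinnitus(+) when its gap
#' detection shows a significant decrease at 4 weeks post-exposure,
#' pooling over all frequency bands (two-tailed paired t-test at `alpha`,
#' gated on the direction of the change).
#'
#' Two contrasts are supported.  The default, `"inhibition-change"`,
#' pairs per-band percent inhibition at baseline against week 4 (pairing
#' on band and session index when both timepoints have the same number of
#' sessions, otherwise on per-band means).  The alternative `"ga-vs-sa"`
#' contrast pairs week-4 GA against SA amplitudes directly, ignoring
#' baseline.
#'
#' @param baseline,week4 lists of gap `gpias_session`s for one mouse at
#'   the two timepoints, or data frames with columns `band`, `session`,
#'   `inhibition_pct` (for `mode = "ga-vs-sa"`, `week4` may also be a
#'   data frame with columns `band`, `session`, `sa`, `ga`).
#' @param alpha significance level (default 0.05).
#' @param mode classification contrast, see Details.
#' @return An object of class `tinnitus_call`: list with `mouse_id`,
#'   `label` (`"TINNITUS_POS"`/`"TINNITUS_NEG"`), `t_statistic`, `df`,
#'   `p_value`, `direction`, `n_pairs`, `degenerate`.
#' @export
classify_tinnitus <- function(baseline, week4, alpha = 0.05,
                              mode = c("inhibition-change", "ga-vs-sa")) {
  mode <- match.arg(mode)
  mouse_id <- NA_character_
  as_inh_table <- function(x) {
    if (is.data.frame(x)) {
      if (is.null(x$session)) x$session <- 1L
      x
    } else {
      if (length(x) && inherits(x[[1]], "gpias_session"))
        mouse_id <<- x[[1]]$mouse_id
      session_inhibition_table(x)
    }
  }
  if (mode == "inhibition-change") {
    b <- as_inh_table(baseline)
    w <- as_inh_table(week4)
    common <- intersect(unique(b$band), unique(w$band))
    if (length(common) < 2L)
      stop_invalid("need at least 2 common bands to classify")
    b <- b[b$band %in% common, ]
    w <- w[w$band %in% common, ]
    same_layout <- identical(sort(paste(b$band, b$session)),
                             sort(paste(w$band, w$session)))
    if (same_layout) {
      key <- function(d) d[order(d$band, d$session), ]
      x <- key(b)$inhibition_pct
      y <- key(w)$inhibition_pct
    } else {
      ## unequal session counts: fall back to per-band means
      x <- tapply(b$inhibition_pct, b$band, mean)[common]
      y <- tapply(w$inhibition_pct, w$band, mean)[common]
    }
    tt <- paired_ttest(x, y)
    decreased <- mean(x - y) > 0
  } else {
    w <- if (is.data.frame(week4)) week4 else session_ga_sa_table(week4)
    if (!is.data.frame(week4) && length(week4) &&
        inherits(week4[[1]], "gpias_session"))
      mouse_id <- week4[[1]]$mouse_id
    if (nrow(w) < 2L) stop_invalid("need at least 2 pairs to classify")
    ## tinnitus = GA amplitudes NOT suppressed: test SA vs GA, a decrease
    ## in gap detection shows as GA approaching SA, so significance of
    ## suppression is inverted; here we test inhibition > 0 at week 4.
    tt <- paired_ttest(w$sa, w$ga)
    decreased <- mean(w$sa - w$ga) <= 0 || tt$p >= alpha
    ## in this mode a mouse is Tinnitus(+) when suppression is absent
    label <- if (tt$degenerate || decreased) "TINNITUS_POS" else "TINNITUS_NEG"
    return(structure(list(mouse_id = mouse_id, label = label,
                          t_statistic = tt$t, df = tt$df, p_value = tt$p,
                          direction = if (decreased) "none" else "decreased",
                          n_pairs = nrow(w), degenerate = tt$degenerate,
                          mode = mode, alpha = alpha),
                     class = "tinnitus_call"))
  }
  direction <- if (tt$degenerate) "none"
    else if (decreased) "decreased" else "increased"
  label <- if (!tt$degenerate && tt$p < alpha && direction == "decreased")
    "TINNITUS_POS" else "TINNITUS_NEG"
  if (tt$degenerate)
    warning("degenerate paired differences (zero variance); labelled TINNITUS_NEG")
  structure(list(mouse_id = mouse_id, label = label,
                 t_statistic = tt$t, df = tt$df, p_value = tt$p,
                 direction = direction, n_pairs = length(x),
                 degenerate = tt$degenerate, mode = mode, alpha = alpha),
            class = "tinnitus_call")
}

#' @export
print.tinnitus_call <- function(x, ...) {
  cat(sprintf("Tinnitus call%s: %s\n",
              if (is.na(x$mouse_id)) "" else paste0(" for ", x$mouse_id),
              if (x$label == "TINNITUS_POS") "Tinnitus(+)" else "Tinnitus(-)"))
  cat(sprintf("  paired t = %.3f, df = %d, p = %.4g (%s, %d pairs, alpha = %g)\n",
              x$t_statistic, x$df, x$p_value, x$direction, x$n_pairs, x$alpha))
  invisible(x)
}

#' Classify every exposed mouse in a cohort
#'
#' Applies the exclusion rule to each gap session and runs
#' [classify_tinnitus()] per exposed mouse (baseline vs week 4).
#'
#' @param cohort a `gpias_cohort`.
#' @param alpha significance level.
#' @param mode see [classify_tinnitus()].
#' @return Data frame: `mouse_id`, `group`, `tinnitus_truth`, `label`,
#'   `t_statistic`, `p_value`, `n_pairs`.
#' @export
classify_cohort <- function(cohort, alpha = 0.05,
                            mode = "inhibition-change") {
  exposed <- Filter(function(m) m$group == "EXPOSED", cohort$mice)
  rows <- lapply(exposed, function(m) {
    b <- lapply(cohort_sessions(cohort, m$mouse_id, "GAP", "baseline"),
                apply_exclusion_rule)
    w <- lapply(cohort_sessions(cohort, m$mouse_id, "GAP", "week4"),
                apply_exclusion_rule)
    call <- classify_tinnitus(b, w, alpha = alpha, mode = mode)
    data.frame(mouse_id = m$mouse_id, group = m$group,
               tinnitus_truth = m$tinnitus_truth, label = call$label,
               t_statistic = call$t_statistic, p_value = call$p_value,
               n_pairs = call$n_pairs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
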