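#' Paired t-test as a closed-form primitive
#'
#' Thin wrapper around the classical paired t on differences, returning
#' the statistic, degrees of freedom and two-tailed p-value, with an
#' explicit degeneracy flag when the differences have zero variance.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  if (length(x) < 2L) stop_invalid("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                df = length(d) - 1L, p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, m * p)` elementwise.  Unlike [stats::p.adjust()], the family
#' size `m` may differ from the number of p-values supplied, matching
#' follow-up batteries where only a subset of a family is reported.
#'
#' @param p_values p-values in [0, 1].
#' @param m family size (default: number of p-values).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

## Orthonormal contrast matrix for a k-level within factor.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

## Greenhouse-Geisser epsilon from the covariance of orthonormal
## contrast scores: (tr S)^2 / (d * tr(S^2)), bounded in [1/d, 1].
gg_epsilon <- function(S) {
  d <- ncol(S)
  if (d == 1L) return(1)
  tr <- sum(diag(S))
  denom <- d * sum(S * S)
  if (denom <= 0) return(1)
  min(1, max(1 / d, tr^2 / denom))
}

## Mauchly's sphericity test on the contrast-score covariance (n = number
## of subjects, p_full = number of levels/cells of the effect).  Uses the
## Box chi-square approximation with the second-order correction term, so
## p-values agree with stats::mauchly.test on the same design.  Trivially
## p = 1 for 2-level factors; NA when too few subjects to test.
mauchly_p <- function(S, n, p_full = ncol(S) + 1L) {
  d <- ncol(S)
  if (d == 1L) return(list(W = 1, p = 1))
  if (n - 1L < d) return(list(W = NA_real_, p = NA_real_))
  W <- det(S) / (sum(diag(S)) / d)^d
  if (!is.finite(W) || W <= 0) return(list(W = W, p = NA_real_))
  nd <- n - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nd)
  z <- -nd * rho * log(W)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * p_full + 2) /
    (288 * (nd * d * rho)^2)
  f <- d * (d + 1) / 2 - 1
  pr1 <- stats::pchisq(z, f, lower.tail = FALSE)
  pr2 <- stats::pchisq(z, f + 4, lower.tail = FALSE)
  list(W = W, p = pr1 + w2 * (pr2 - pr1))
}

one_effect <- function(effect, ss_eff, df_eff, ss_err, df_err, Z, n,
                       sphericity_gate, p_full = ncol(Z) + 1L) {
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  ## a zero effect SS is a zero F even when the error SS also vanishes
  f_stat <- if (ms_err > 0) ms_eff / ms_err
            else if (ms_eff == 0) 0 else NA_real_
  S <- stats::cov(Z)
  eps <- gg_epsilon(S)
  mau <- mauchly_p(S, n, p_full)
  corrected <- is.finite(mau$p) && mau$p < sphericity_gate && ncol(Z) > 1L
  df1 <- if (corrected) eps * df_eff else df_eff
  df2 <- if (corrected) eps * df_err else df_err
  p <- if (is.na(f_stat)) NA_real_
       else stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  data.frame(effect = effect, ss = ss_eff, ss_error = ss_err,
             f_statistic = f_stat, df1 = df1, df2 = df2, p_value = p,
             gg_epsilon = eps, sphericity_w = mau$W, sphericity_p = mau$p,
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Two-way repeated-measures ANOVA with sphericity handling
#'
#' Classical univariate within-subject decomposition for a complete,
#' balanced subjects x factor-A x factor-B design (both factors within
#' subject): main effects and interaction are each tested against their
#' own subject-by-effect error term.  Sphericity is assessed per effect
#' with Mauchly's test on the effect's orthonormalised contrast scores
#' (for the interaction, on the Kronecker product of the two factors'
#' contrasts); effects failing the test at `sphericity_gate` get
#' Greenhouse--Geisser-scaled degrees of freedom.
#'
#' @param data data frame in long format.
#' @param value,subject,within column names: the response, the subject
#'   identifier, and the two within-subject factors (character vector of
#'   length 2, e.g. `c("timepoint", "band")`).
#' @param sphericity_gate Mauchly p-value below which the correction is
#'   applied (default 0.05).
#' @return A data frame of class `gpias_anova` with one row per effect
#'   (`A`, `B`, `A:B`): `f_statistic`, `df1`, `df2` (epsilon-scaled when
#'   `corrected`), `p_value`, `gg_epsilon`, `sphericity_w`,
#'   `sphericity_p`, `corrected`.
#' @export
rm_anova_two_way <- function(data, value, subject, within,
                             sphericity_gate = 0.05) {
  stopifnot(length(within) == 2L,
            all(c(value, subject, within) %in% names(data)))
  s <- factor(data[[subject]])
  A <- factor(data[[within[1]]])
  B <- factor(data[[within[2]]])
  y <- data[[value]]
  n <- nlevels(s); a <- nlevels(A); b <- nlevels(B)
  if (n < 2L) stop_invalid("need at least 2 subjects")
  counts <- table(s, A, B)
  if (any(counts != 1L)) {
    miss <- which(counts == 0L, arr.ind = TRUE)
    stop_invalid("design not complete/balanced; missing or duplicated cells, e.g. ",
                 paste(apply(utils::head(miss, 5), 1, function(i)
                   paste(levels(s)[i[1]], levels(A)[i[2]], levels(B)[i[3]],
                         sep = "/")), collapse = ", "))
  }
  Y <- array(NA_real_, dim = c(n, a, b))
  Y[cbind(as.integer(s), as.integer(A), as.integer(B))] <- y
  gm <- mean(Y)
  m_s <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_sa <- apply(Y, c(1, 2), mean); m_sb <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)

  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  dev_ab <- m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + gm
  ss_ab <- n * sum(dev_ab^2)
  dev_sa <- m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + gm
  ss_sa <- b * sum(dev_sa^2)
  dev_sb <- m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + gm
  ss_sb <- a * sum(dev_sb^2)
  resid <- Y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- Y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - gm
  ss_res <- sum(resid^2)

  Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
  ## subject-level cell matrix, columns ordered A-major then B
  M <- matrix(aperm(Y, c(1, 3, 2)), nrow = n)  # columns: (A1B1..A1Bb, A2B1..)
  ## reorder to A-major with B fastest: aperm gives (n, b, a) flattened as
  ## B fastest within each A, which matches kronecker(Ca, Cb) ordering.
  res <- rbind(
    one_effect(within[1], ss_a, a - 1, ss_sa, (a - 1) * (n - 1),
               m_sa %*% Ca, n, sphericity_gate),
    one_effect(within[2], ss_b, b - 1, ss_sb, (b - 1) * (n - 1),
               m_sb %*% Cb, n, sphericity_gate),
    one_effect(paste(within, collapse = ":"), ss_ab, (a - 1) * (b - 1),
               ss_res, (a - 1) * (b - 1) * (n - 1),
               M %*% kronecker(Ca, Cb), n, sphericity_gate,
               p_full = a * b)
  )
  rownames(res) <- NULL
  class(res) <- c("gpias_anova", "data.frame")
  attr(res, "n_subjects") <- n
  res
}

#' One-way repeated-measures ANOVA
#'
#' Single within-subject factor version of [rm_anova_two_way()], used for
#' the frequency-discrimination battery (timepoint as the within factor,
#' PPI averaged per subject and timepoint as the response).
#'
#' @inheritParams rm_anova_two_way
#' @param within single within-subject factor column name.
#' @return A one-row `gpias_anova` data frame.
#' @export
rm_anova_one_way <- function(data, value, subject, within,
                             sphericity_gate = 0.05) {
  stopifnot(length(within) == 1L,
            all(c(value, subject, within) %in% names(data)))
  s <- factor(data[[subject]]); A <- factor(data[[within]])
  y <- data[[value]]
  n <- nlevels(s); a <- nlevels(A)
  if (n < 2L) stop_invalid("need at least 2 subjects")
  counts <- table(s, A)
  if (any(counts != 1L))
    stop_invalid("design not complete/balanced (one value per subject x level)")
  Y <- matrix(NA_real_, n, a)
  Y[cbind(as.integer(s), as.integer(A))] <- y
  gm <- mean(Y); m_s <- rowMeans(Y); m_a <- colMeans(Y)
  ss_a <- n * sum((m_a - gm)^2)
  dev <- Y - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + gm
  ss_err <- sum(dev^2)
  res <- one_effect(within, ss_a, a - 1, ss_err, (a - 1) * (n - 1),
                    Y %*% orthonormal_contrasts(a), n, sphericity_gate)
  rownames(res) <- NULL
  class(res) <- c("gpias_anova", "data.frame")
  attr(res, "n_subjects") <- n
  res
}

#' @export
print.gpias_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", attr(x, "n_subjects"), " subjects)\n",
      sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: F(%.4g, %.4g) = %.3f, p = %.4g%s\n",
                x$effect[i], x$df1[i], x$df2[i], x$f_statistic[i],
                x$p_value[i],
                if (isTRUE(x$corrected[i]))
                  sprintf(" [GG-corrected, eps = %.3f]", x$gg_epsilon[i])
                else ""))
  }
  invisible(x)
}

#' Paired ABR threshold comparisons per tone frequency
#'
#' Compares auditory-brainstem-response thresholds between two timepoints
#' with a paired t-test at each tone frequency, across the mice present
#' at both timepoints.
#'
#' @param table ABR table: columns `mouse_id`, `timepoint`,
#'   `frequency_khz`, `threshold_db`.
#' @param baseline_label,post_label the two timepoints to compare.
#' @return Data frame: `frequency_khz`, `n`, `mean_shift_db`, `t`, `df`,
#'   `p_value`, `degenerate`.
#' @export
compare_abr <- function(table, baseline_label = "baseline", post_label) {
  need <- c("mouse_id", "timepoint", "frequency_khz", "threshold_db")
  if (!all(need %in% names(table)))
    stop_invalid("ABR table must have columns ", paste(need, collapse = ", "))
  freqs <- sort(unique(table$frequency_khz))
  rows <- lapply(freqs, function(f) {
    b <- table[table$frequency_khz == f & table$timepoint == baseline_label, ]
    p <- table[table$frequency_khz == f & table$timepoint == post_label, ]
    ids <- intersect(b$mouse_id, p$mouse_id)
    if (length(ids) < 2L)
      return(data.frame(frequency_khz = f, n = length(ids),
                        mean_shift_db = NA_real_, t = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    x <- p$threshold_db[match(ids, p$mouse_id)]
    y <- b$threshold_db[match(ids, b$mouse_id)]
    tt <- paired_ttest(x, y)
    data.frame(frequency_khz = f, n = length(ids),
               mean_shift_db = tt$mean_diff, t = tt$t, df = tt$df,
               p_value = tt$p, degenerate = tt$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
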