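test_that("percent inhibition follows 100 * (SA - GA) / SA", {
  s <- make_gap_session(sa = rep(4, 8), ga = rep(1, 8))
  expect_equal(compute_gap_inhibition(s)$inhibition_pct, 75)

  s0 <- make_gap_session(sa = rep(4, 8), ga = rep(4, 8))
  expect_equal(compute_gap_inhibition(s0)$inhibition_pct, 0)

  sf <- make_gap_session(sa = rep(4, 8), ga = rep(5, 8))
  expect_equal(compute_gap_inhibition(sf)$inhibition_pct, -25)
})

test_that("inhibition ignores excluded and bookend trials and scaling", {
  s <- make_gap_session(sa = c(4, 4, 100), ga = rep(1, 3))
  s$trials$excluded[3] <- TRUE
  s$trials$exclusion_reason[3] <- "movement artifact (pre-SS SD)"
  expect_equal(compute_gap_inhibition(s)$inhibition_pct, 75)

  sb <- make_gap_session(sa = c(4, 4, 999), ga = rep(1, 3))
  sb$trials$bookend[3] <- TRUE
  tab <- compute_gap_inhibition(sb)
  expect_equal(tab$mean_sa, 4)
  expect_equal(tab$n_sa, 2L)

  ## invariant to rescaling all amplitudes
  sk <- make_gap_session(sa = 7 * rep(4, 8), ga = 7 * rep(1, 8))
  expect_equal(compute_gap_inhibition(sk)$inhibition_pct, 75)

  sz <- make_gap_session(sa = rep(0, 4), ga = rep(1, 4))
  expect_warning(tabz <- compute_gap_inhibition(sz), "zero mean SA")
  expect_true(is.na(tabz$inhibition_pct))
})

test_that("aggregation averages per-band inhibition across sessions", {
  mk <- function(inh) data.frame(band = "6-8", inhibition_pct = inh)
  agg <- aggregate_inhibition(list(mk(70), mk(75), mk(80)))
  expect_equal(agg$inhibition_pct, 75)
  expect_equal(agg$n_sessions, 3L)
  expect_equal(agg$sem, sd(c(70, 75, 80)) / sqrt(3))

  one <- aggregate_inhibition(list(mk(70)))
  expect_equal(one$inhibition_pct, 70)
  expect_true(is.na(one$sem))

  ## a band missing from one session is averaged over the sessions
  ## carrying it, with n recorded
  two_bands <- data.frame(band = c("6-8", "BBN"),
                          inhibition_pct = c(60, 40))
  agg2 <- aggregate_inhibition(list(mk(70), two_bands, mk(80)))
  expect_equal(agg2$inhibition_pct[agg2$band == "6-8"], mean(c(70, 60, 80)))
  expect_equal(agg2$inhibition_pct[agg2$band == "BBN"], 40)
  expect_equal(agg2$n_sessions[agg2$band == "BBN"], 1L)
})

test_that("classification matches the closed-form paired t on band pairs", {
  bands <- gap_bands()$label
  base <- data.frame(band = bands, session = 1L,
                     inhibition_pct = c(70, 72, 74, 76, 78, 80))
  wk4 <- base
  wk4$inhibition_pct <- base$inhibition_pct - (1:6)  # differences 1..6
  call <- classify_tinnitus(base, wk4)
  d <- 1:6
  t_exp <- mean(d) / (sd(d) / sqrt(6))
  p_exp <- 2 * pt(-abs(t_exp), 5)
  expect_equal(call$t_statistic, t_exp, tolerance = 1e-10)
  expect_equal(call$p_value, p_exp, tolerance = 1e-10)
  expect_equal(round(call$t_statistic, 3), 4.583)
  expect_lt(call$p_value, 0.05)
  expect_identical(call$label, "TINNITUS_POS")
  expect_identical(call$direction, "decreased")

  ## unchanged inhibition: degenerate, negative call
  expect_warning(same <- classify_tinnitus(base, base), "degenerate")
  expect_identical(same$label, "TINNITUS_NEG")

  ## a significant INCREASE is not tinnitus
  up <- base; up$inhibition_pct <- base$inhibition_pct + (1:6)
  expect_identical(classify_tinnitus(base, up)$label, "TINNITUS_NEG")

  expect_error(classify_tinnitus(base[1, ], wk4[1, ]), "2 common bands")
})

test_that("session-resolved pairing uses (band, session) pairs", {
  bands <- gap_bands()$label
  mk <- function(shift) do.call(rbind, lapply(1:3, function(s)
    data.frame(band = bands, session = s,
               inhibition_pct = 70 + seq_along(bands) * (1 - shift * s * 0.1))))
  call <- classify_tinnitus(mk(0), mk(1))
  expect_equal(call$n_pairs, 18L)
  ## unequal session counts fall back to per-band means
  b <- mk(0); w <- mk(1); w <- w[w$session < 3, ]
  call2 <- classify_tinnitus(b, w)
  expect_equal(call2$n_pairs, 6L)
})

test_that("strongly affected mice are flagged, unaffected mostly are not", {
  te <- setNames(rep(0, 6), gap_bands()$label)
  te[c("BBN", "18-20", "26-28")] <- 0.8
  labels <- vapply(1:30, function(i) {
    m <- mouse_params("m", "EXPOSED", tinnitus_truth = TRUE,
                      tinnitus_effect = te, startle_cv = 0.2)
    b <- lapply(1:3, function(s)
      apply_exclusion_rule(simulate_gap_session(m, "baseline",
                                                seed = i * 100 + s)))
    w <- lapply(1:3, function(s)
      apply_exclusion_rule(simulate_gap_session(m, "week4",
                                                seed = i * 100 + 50 + s)))
    classify_tinnitus(b, w)$label
  }, character(1))
  expect_gte(mean(labels == "TINNITUS_POS"), 0.9)
})

test_that("the literal GA-vs-SA contrast mode is available", {
  bands <- gap_bands()$label
  ## strong suppression at week 4: gap detection intact, Tinnitus(-)
  intact <- data.frame(band = bands, session = 1L, sa = 5, ga = 1 + 0.01 * (1:6))
  expect_identical(classify_tinnitus(NULL, intact, mode = "ga-vs-sa")$label,
                   "TINNITUS_NEG")
  ## no suppression left: Tinnitus(+)
  gone <- data.frame(band = bands, session = 1L,
                     sa = 5 + 0.1 * (1:6), ga = 5 + 0.11 * (1:6))
  expect_identical(classify_tinnitus(NULL, gone, mode = "ga-vs-sa")$label,
                   "TINNITUS_POS")
})
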