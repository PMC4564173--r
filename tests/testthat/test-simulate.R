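test_that("noiseless traces round-trip the latent amplitude exactly", {
  spec <- data.frame(index = 1, kind = "SA", band = "BBN", bookend = FALSE,
                     bg_dur_s = 10, ss_onset_s = 10, gap_onset_s = NA)
  m <- mouse_params("m1", "CONTROL", startle_cv = 0, noise_sd = 0)
  tr <- simulate_trace(spec, m, noise_sd = 0, sample_rate_hz = 1000,
                       seed = 1, latent = 5)
  expect_equal(compute_asr_amplitude(tr), 5)
  ## the plateau survives block-mean decimation to the analysis rate
  expect_equal(compute_asr_amplitude(downsample_trace(tr, 10)), 5)
})

test_that("trace simulation is deterministic in the seed", {
  spec <- data.frame(index = 1, kind = "SA", band = "BBN", bookend = FALSE,
                     bg_dur_s = 10, ss_onset_s = 10, gap_onset_s = NA)
  m <- mouse_params("m1", "CONTROL")
  t1 <- simulate_trace(spec, m, sample_rate_hz = 500, seed = 42)
  t2 <- simulate_trace(spec, m, sample_rate_hz = 500, seed = 42)
  expect_identical(t1$samples, t2$samples)
  t3 <- simulate_trace(spec, m, sample_rate_hz = 500, seed = 43)
  expect_false(identical(t1$samples, t3$samples))
})

test_that("artifact trials inflate the pre-SS noise by the set factor", {
  spec <- data.frame(index = 1, kind = "SA", band = "BBN", bookend = FALSE,
                     bg_dur_s = 10, ss_onset_s = 10, gap_onset_s = NA)
  m <- mouse_params("m1", "CONTROL", noise_sd = 0.2, artifact_factor = 3)
  sds <- vapply(1:100, function(i) {
    art <- compute_pre_ss_sd(simulate_trace(spec, m, sample_rate_hz = 200,
                                            seed = i, artifact = TRUE))
    clean <- compute_pre_ss_sd(simulate_trace(spec, m, sample_rate_hz = 200,
                                              seed = 1000 + i,
                                              artifact = FALSE))
    c(art, clean)
  }, numeric(2))
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_lt(abs(ratio - 3) / 3, 0.10)
})

test_that("gap sessions realise the generating inhibition fractions", {
  ## zero CV, no tinnitus: per-band inhibition equals the generator value
  m <- mouse_params("m1", "EXPOSED", tinnitus_truth = FALSE,
                    startle_cv = 0, gap_inhibition = 0.75)
  tab <- compute_gap_inhibition(
    apply_exclusion_rule(simulate_gap_session(m, "baseline", seed = 1)))
  expect_equal(tab$inhibition_pct, rep(75, 6))

  ## a full gap-filling effect zeroes inhibition in the affected band only
  te <- setNames(rep(0, 6), gap_bands()$label); te["26-28"] <- 1
  m2 <- mouse_params("m2", "EXPOSED", tinnitus_truth = TRUE,
                     startle_cv = 0, gap_inhibition = 0.75,
                     tinnitus_effect = te)
  tab2 <- compute_gap_inhibition(
    apply_exclusion_rule(simulate_gap_session(m2, "week4", seed = 1)))
  expect_equal(tab2$inhibition_pct[tab2$band == "26-28"], 0)
  expect_equal(tab2$inhibition_pct[tab2$band != "26-28"], rep(75, 5))

  ## before onset the effect is inactive
  tab3 <- compute_gap_inhibition(
    apply_exclusion_rule(simulate_gap_session(m2, "baseline", seed = 1)))
  expect_equal(tab3$inhibition_pct, rep(75, 6))

  expect_error(simulate_gap_session(m, "week12", seed = 1), "timepoint")
})

test_that("high-band tinnitus lowers high-band inhibition across a cohort", {
  te <- setNames(rep(0, 6), gap_bands()$label)
  te[c("18-20", "26-28")] <- 0.8
  vals <- vapply(1:20, function(i) {
    m <- mouse_params(paste0("m", i), "EXPOSED", tinnitus_truth = TRUE,
                      tinnitus_effect = te, startle_cv = 0.2)
    tab <- compute_gap_inhibition(
      apply_exclusion_rule(simulate_gap_session(m, "week4", seed = i)))
    c(high = mean(tab$inhibition_pct[tab$band %in% c("18-20", "26-28")]),
      mid = mean(tab$inhibition_pct[tab$band %in% c("10-12", "14-16")]))
  }, numeric(2))
  expect_lt(t.test(vals["high", ], vals["mid", ])$p.value, 1e-6)
  expect_lt(mean(vals["high", ]), mean(vals["mid", ]))
})

test_that("effect injection is localized to the affected bands", {
  te <- setNames(rep(0, 6), gap_bands()$label); te["26-28"] <- 0.8
  inh_at <- function(truth, seeds) vapply(seeds, function(i) {
    m <- mouse_params("m", "EXPOSED", tinnitus_truth = truth,
                      tinnitus_effect = te, startle_cv = 0.2)
    tab <- compute_gap_inhibition(
      apply_exclusion_rule(simulate_gap_session(m, "week4", seed = i)))
    tab$inhibition_pct[tab$band == "10-12"]
  }, numeric(1))
  p <- t.test(inh_at(TRUE, 1:25), inh_at(FALSE, 101:125))$p.value
  expect_gt(p, 0.01)
})

test_that("FD sessions realise the generating psychometric curve", {
  m <- mouse_params("m1", "CONTROL", startle_cv = 0)
  s <- simulate_fd_session(m, "FD-medium", "baseline", seed = 3)
  pts <- compute_ppi(apply_exclusion_rule(s))
  expect_equal(pts$ppi_pct,
               psych_logistic(pts$delta_f_pct, 160, 0, -0.1),
               tolerance = 1e-9)
  ## fitted threshold recovers the generating closed-form threshold
  fit <- fit_psychometric(pts)
  th_true <- log(3) / 0.1
  expect_lt(abs(fit$th - th_true) / th_true, 0.01)

  ## timepoint modifiers shift the curve (halved slope doubles Th)
  m2 <- mouse_params("m2", "EXPOSED", timepoint_effects = list(
    week4 = list("FD-medium" = list(c_scale = 0.5))), startle_cv = 0)
  s2 <- simulate_fd_session(m2, "FD-medium", "week4", seed = 3)
  fit2 <- fit_psychometric(compute_ppi(apply_exclusion_rule(s2)))
  expect_lt(abs(fit2$th - 2 * th_true) / (2 * th_true), 0.01)
})

test_that("cohorts have the configured composition and are reproducible", {
  cfg <- small_config()
  co <- simulate_cohort(cfg, seed = 9)
  expect_length(co$mice, 9L)
  groups <- vapply(co$mice, `[[`, character(1), "group")
  expect_equal(sum(groups == "CONTROL"), 3L)
  expect_equal(sum(groups == "EXPOSED"), 6L)
  truth <- vapply(co$mice, `[[`, logical(1), "tinnitus_truth")
  expect_equal(sum(truth), 4L)
  ## sessions: (2 gap + 2 fd) per mouse per timepoint
  expect_length(co$sessions, 9L * 4L * 4L)

  co2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(cohort_to_bundle(co)$gap_table,
                   cohort_to_bundle(co2)$gap_table)
  expect_identical(co$abr, co2$abr)

  expect_error(cohort_config(n_control = 0), "non-empty")
  expect_error(cohort_config(n_tinnitus = 30), "between 0 and")
})

test_that("ABR tables stay on the 10-80 dB grid with the exposure shift", {
  mice <- list(mouse_params("c1", "CONTROL"),
               mouse_params("e1", "EXPOSED", tinnitus_truth = TRUE))
  abr <- simulate_abr_table(mice, seed = 4)
  expect_setequal(unique(abr$frequency_khz), c(8, 12, 16, 22, 28))
  expect_true(all(abr$threshold_db >= 10 & abr$threshold_db <= 80))
  expect_true(all(abr$threshold_db %% 10 == 0))
  expect_equal(nrow(abr), 2L * 4L * 5L)
})
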