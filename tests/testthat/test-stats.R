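test_that("paired t matches its closed form to machine precision", {
  ## symmetric null
  r1 <- paired_ttest(c(1, 0, -1), c(0, 0, 0))
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 1)

  ## differences 1, 2, 3
  r2 <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r2$df, 2)
  expect_equal(r2$p, 2 * pt(-2 / (1 / sqrt(3)), 2), tolerance = 1e-12)
  expect_equal(round(r2$t, 4), 3.4641)

  ## degenerate: identical samples
  r3 <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_true(r3$degenerate)

  ## random inputs against the textbook formula
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    r <- paired_ttest(x, y)
    d <- x - y
    expect_equal(r$t, mean(d) / (sd(d) / sqrt(8)), tolerance = 1e-12)
    expect_equal(r$p, 2 * pt(-abs(r$t), 7), tolerance = 1e-12)
  }
  expect_error(paired_ttest(1:3, 1:4), "paired")
})

test_that("Bonferroni adjustment is min(1, m p) with explicit family size", {
  expect_equal(bonferroni_adjust(0.01, m = 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, m = 6), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.4), m = 1), c(0.2, 0.4))
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni_adjust(1.2), "0, 1")
})

test_that("two-way RM-ANOVA matches brute-force sums of squares", {
  for (seed in c(42, 7, 19)) {
    set.seed(seed)
    d <- expand.grid(subj = factor(1:8), t = factor(1:4), f = factor(1:6))
    d$y <- rnorm(nrow(d)) + 0.3 * as.numeric(d$t) +
      rnorm(8)[as.integer(d$subj)] + 0.2 * as.numeric(d$t) * as.numeric(d$f)
    res <- rm_anova_two_way(d, "y", "subj", c("t", "f"))
    ss <- brute_force_ss(d, "y", "subj", c("t", "f"))
    expect_equal(res$ss, unname(ss[c("A", "B", "AB")]), tolerance = 1e-8)
    expect_equal(res$ss_error, unname(ss[c("errA", "errB", "errAB")]),
                 tolerance = 1e-8)
    f_exp <- (ss[c("A", "B", "AB")] / c(3, 5, 15)) /
      (ss[c("errA", "errB", "errAB")] / (c(3, 5, 15) * 7))
    expect_equal(res$f_statistic, unname(f_exp), tolerance = 1e-8)
  }
})

test_that("RM-ANOVA agrees with aov's Error-stratum decomposition", {
  set.seed(5)
  d <- expand.grid(subj = factor(1:6), t = factor(1:3), f = factor(1:4))
  d$y <- rnorm(nrow(d)) + as.numeric(d$f) * 0.5
  res <- rm_anova_two_way(d, "y", "subj", c("t", "f"))
  s <- summary(aov(y ~ t * f + Error(subj / (t * f)), data = d))
  expect_equal(res$f_statistic[1], s[["Error: subj:t"]][[1]]["t", "F value"],
               tolerance = 1e-10)
  expect_equal(res$f_statistic[2], s[["Error: subj:f"]][[1]]["f", "F value"],
               tolerance = 1e-10)
  expect_equal(res$f_statistic[3],
               s[["Error: subj:t:f"]][[1]]["t:f", "F value"],
               tolerance = 1e-10)
})

test_that("sphericity statistics match stats::mauchly.test", {
  set.seed(12)
  n <- 10; a <- 4; b <- 3
  d <- expand.grid(subj = factor(1:n), t = factor(1:a), f = factor(1:b))
  d$y <- rnorm(nrow(d)) + rep(rnorm(n), a * b) *
    rep(as.numeric(d$t) / 2, 1)  # heteroscedastic across t levels
  res <- rm_anova_two_way(d, "y", "subj", c("t", "f"))
  Y <- with(d, tapply(y, list(subj, t, f), mean))
  for (eff in 1:2) {
    M <- apply(Y, c(1, eff + 1), mean)
    k <- ncol(M)
    mt <- mauchly.test(lm(M ~ 1), X = ~1,
                       idata = data.frame(w = factor(1:k)), M = ~w)
    expect_equal(res$sphericity_w[eff], unname(mt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$sphericity_p[eff], mt$p.value, tolerance = 1e-10)
  }
})

test_that("epsilon bounds and degenerate designs behave", {
  ## 2-level factor forces epsilon = 1
  set.seed(3)
  d2 <- expand.grid(subj = factor(1:6), t = factor(1:2), f = factor(1:3))
  d2$y <- rnorm(nrow(d2))
  res2 <- rm_anova_two_way(d2, "y", "subj", c("t", "f"))
  expect_equal(res2$gg_epsilon[1], 1)

  ## 1/(k-1) <= eps <= 1 on random designs
  for (seed in 1:5) {
    set.seed(seed)
    d <- expand.grid(subj = factor(1:7), t = factor(1:5), f = factor(1:3))
    d$y <- rnorm(nrow(d)) * rep(seq(0.2, 2, length.out = 5),
                                each = 7)[seq_len(nrow(d)) %% 35 + 1]
    res <- rm_anova_two_way(d, "y", "subj", c("t", "f"))
    ## contrast dimensions per effect: t has 4, f has 2, t:f has 8
    expect_true(all(res$gg_epsilon >= 1 / c(4, 2, 8) - 1e-12))
    expect_true(all(res$gg_epsilon <= 1 + 1e-12))
  }

  ## all-equal responses give F = 0 everywhere
  dc <- expand.grid(subj = factor(1:4), t = factor(1:3), f = factor(1:3))
  dc$y <- 5
  resc <- rm_anova_two_way(dc, "y", "subj", c("t", "f"))
  expect_equal(resc$f_statistic, rep(0, 3))

  ## F is invariant to adding a constant
  set.seed(8)
  d <- expand.grid(subj = factor(1:5), t = factor(1:3), f = factor(1:4))
  d$y <- rnorm(nrow(d))
  d2 <- d; d2$y <- d$y + 100
  expect_equal(rm_anova_two_way(d, "y", "subj", c("t", "f"))$f_statistic,
               rm_anova_two_way(d2, "y", "subj", c("t", "f"))$f_statistic,
               tolerance = 1e-9)

  ## incomplete designs are rejected with the missing cells named
  dm <- d[-1, ]
  expect_error(rm_anova_two_way(dm, "y", "subj", c("t", "f")),
               "not complete")
})

test_that("one-way RM-ANOVA reduces to the textbook decomposition", {
  set.seed(21)
  d <- expand.grid(subj = factor(1:9), t = factor(1:4))
  d$y <- rnorm(nrow(d)) + as.numeric(d$t) * 0.4
  res <- rm_anova_one_way(d, "y", "subj", "t")
  s <- summary(aov(y ~ t + Error(subj / t), data = d))
  expect_equal(res$f_statistic, s[["Error: subj:t"]][[1]]["t", "F value"],
               tolerance = 1e-10)
  ## nominal df1 = k - 1 (epsilon-scaled only when corrected)
  expect_equal(res$df1 / ifelse(res$corrected, res$gg_epsilon, 1), 3)
})

test_that("ABR comparisons detect a selective high-frequency shift", {
  mk_abr <- function(seed, shift28 = 0) {
    set.seed(seed)
    freqs <- c(8, 12, 16, 22, 28)
    do.call(rbind, lapply(sprintf("m%d", 1:6), function(id) {
      base <- 30 + runif(5, -5, 5)
      post <- base + runif(5, -5, 5)
      post[freqs == 28] <- post[freqs == 28] + shift28
      rbind(data.frame(mouse_id = id, timepoint = "baseline",
                       frequency_khz = freqs, threshold_db = base),
            data.frame(mouse_id = id, timepoint = "week4",
                       frequency_khz = freqs, threshold_db = post))
    }))
  }
  ## follow-up selectivity judged on Bonferroni-adjusted p-values, as in
  ## the battery (family = 5 tone frequencies)
  hits <- vapply(1:100, function(i) {
    res <- compare_abr(mk_abr(i, shift28 = 20), "baseline", "week4")
    p_adj <- bonferroni_adjust(res$p_value, m = 5)
    p_adj[res$frequency_khz == 28] < 0.05 &&
      all(p_adj[res$frequency_khz != 28] >= 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## identical tables: every frequency degenerate
  tab <- mk_abr(1, 0)
  tab$threshold_db[tab$timepoint == "week4"] <-
    tab$threshold_db[tab$timepoint == "baseline"]
  res0 <- compare_abr(tab, "baseline", "week4")
  expect_true(all(res0$degenerate))

  ## constant differences are flagged degenerate, not significant
  one <- data.frame(mouse_id = rep(sprintf("m%d", 1:4), 2),
                    timepoint = rep(c("baseline", "week4"), each = 4),
                    frequency_khz = 28,
                    threshold_db = c(rep(30, 4), rep(40, 4)))
  r1 <- compare_abr(one, "baseline", "week4")
  expect_true(r1$degenerate)
  expect_equal(r1$mean_shift_db, 10)
})
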