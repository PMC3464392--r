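test_that("two-sample t test matches the textbook formula", {
  a <- c(1.0, 1.1, 0.9); b <- c(0.3, 0.35, 0.25)
  out <- ttest2(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(out$p.value, p_hand, tolerance = 1e-12)
  expect_lt(out$p.value, 0.001)
})

test_that("degenerate variance follows the stated conventions", {
  expect_equal(ttest2(c(1, 1, 1), c(1, 1, 1))$p.value, 1)
  z <- ttest2(c(1, 1, 1), c(2, 2, 2))
  expect_equal(z$p.value, 0)
  expect_true(z$degenerate)
  expect_error(ttest2(1, c(1, 2)), ">= 2")
})

test_that("per-timepoint tests compare matched timepoints of two groups", {
  dat <- tidyr::expand_grid(condition = c("EP", "control"),
                            replicate = 1:3, time_s = c(0, 60, 120))
  dat$value <- ifelse(dat$condition == "EP" & dat$time_s == 60,
                      0.5, 1) + 0.01 * dat$replicate
  out <- timepoint_ttest(dat)
  expect_equal(out$time_s, c(0, 60, 120))
  expect_lt(out$p.value[out$time_s == 60], 0.01)
  expect_gt(min(out$p.value[out$time_s != 60]), 0.5)
  # identical groups -> p = 1 everywhere
  same <- dat; same$value <- rep(c(1, 1.1, 0.9), length.out = nrow(same))
  out2 <- timepoint_ttest(same)
  expect_true(all(out2$p.value == 1))
})

test_that("the sustained recovery rule ignores transient dips", {
  t <- seq(60, 1800, by = 60)
  p <- rep(0.01, length(t))
  p[t > 840] <- 0.5
  expect_equal(recovery_time(tibble::tibble(time_s = t, p.value = p)), 900)
  # one non-significant dip at 300 s does not count as recovery
  p2 <- p; p2[t == 300] <- 0.7
  expect_equal(recovery_time(tibble::tibble(time_s = t, p.value = p2)), 900)
  # significance throughout -> none
  expect_true(is.na(recovery_time(tibble::tibble(time_s = t,
                                                 p.value = rep(0.01, length(t))))))
  expect_error(recovery_time(numeric(0)), "empty")
})

test_that("recovery time is monotone in alpha", {
  set.seed(99)
  for (i in 1:25) {
    t <- seq(60, 1200, by = 60)
    p <- runif(length(t))
    r1 <- recovery_time(tibble::tibble(time_s = t, p.value = p), alpha = 0.01)
    r2 <- recovery_time(tibble::tibble(time_s = t, p.value = p), alpha = 0.05)
    # lowering alpha never yields a later recovery time
    expect_true(is.na(r2) || (!is.na(r1) && r1 <= r2) || is.na(r2))
    if (!is.na(r1) && !is.na(r2)) expect_lte(r1, r2)
    if (is.na(r1)) expect_true(is.na(r2))
  }
})

test_that("one-way ANOVA agrees with hand-computed sums of squares", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7))
  out <- oneway_anova(g)
  means <- vapply(g, mean, numeric(1)); grand <- mean(unlist(g))
  ssb <- sum(3 * (means - grand)^2)            # 26
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))  # 6
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(ssb, 26)
  expect_equal(ssw, 6)
  expect_equal(out$statistic, f_hand, tolerance = 1e-12)
  expect_equal(out$df1, 2); expect_equal(out$df2, 6)
  expect_equal(out$p.value, pf(f_hand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA degenerate conventions and input checks hold", {
  expect_equal(oneway_anova(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(oneway_anova(list(c(2, 2), c(2, 2)))$p.value, 1)
  z <- oneway_anova(list(c(1, 1), c(2, 2)))
  expect_equal(z$p.value, 0); expect_true(z$degenerate)
  expect_error(oneway_anova(list(c(1, 2), c(3))), ">= 2")
  df <- data.frame(value = c(1, 2, 3, 4), group = c("a", "a", "b", "b"))
  expect_equal(oneway_anova(df)$df1, 1)
})

test_that("Holm-Sidak reproduces the direct threshold evaluation", {
  out <- holm_sidak(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(out$threshold, 1 - 0.95^(1 / c(3, 2, 1)), tolerance = 1e-6)
  expect_equal(out$threshold, c(0.016952, 0.025321, 0.05), tolerance = 1e-4)
  expect_true(all(out$reject))
  none <- holm_sidak(c(0.04, 0.04, 0.04), alpha = 0.05)
  expect_false(any(none$reject))      # first step fails: 0.04 > 0.016952
  one <- holm_sidak(0.03, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$p.adjusted, 0.03)
  expect_error(holm_sidak(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Holm-Sidak agrees with a brute-force step-down on random inputs", {
  brute <- function(p, alpha) {
    m <- length(p); ord <- order(p); rej <- logical(m)
    for (i in seq_len(m)) {
      thr <- 1 - (1 - alpha)^(1 / (m - i + 1))
      if (p[ord[i]] <= thr) rej[ord[i]] <- TRUE else break
    }
    adj <- numeric(m); run <- 0
    for (i in seq_len(m)) {
      run <- max(run, 1 - (1 - p[ord[i]])^(m - i + 1))
      adj[ord[i]] <- min(run, 1)
    }
    list(reject = rej, adjusted = adj)
  }
  set.seed(7)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    out <- holm_sidak(p, alpha = 0.05)
    ref <- brute(p, 0.05)
    expect_identical(out$reject, ref$reject)
    expect_equal(out$p.adjusted, ref$adjusted, tolerance = 1e-12)
  }
})

test_that("Holm-Sidak sits between Bonferroni and unadjusted testing", {
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(2:10, 1))
    hs <- holm_sidak(p, alpha = 0.05)$reject
    bonf <- p.adjust(p, "bonferroni") <= 0.05
    expect_true(all(bonf[hs == FALSE] == FALSE) || all(hs[bonf]))
    expect_true(all(hs[bonf]))          # rejects a superset of Bonferroni
    expect_true(all(p[hs] <= 0.05))     # and a subset of unadjusted
  }
})

test_that("adjusted p-values are monotone and permutation invariant", {
  set.seed(3)
  p <- runif(7)
  out <- holm_sidak(p)
  expect_true(all(diff(out$p.adjusted[order(out$p.value)]) >= -1e-12))
  perm <- sample(7)
  out_p <- holm_sidak(p[perm])
  expect_equal(out_p$p.adjusted, out$p.adjusted[perm])
  expect_equal(out_p$reject, out$reject[perm])
})
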