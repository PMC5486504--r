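test_that("the normality gate keeps its nominal level and detects skew", {
  set.seed(1)
  pass <- replicate(200, test_normality(rnorm(5000)) >= 0.05)
  expect_gt(mean(pass), 0.92)  # ~95% expected at the 5% gate
  set.seed(2)
  reject <- replicate(100, test_normality(rlnorm(1000, sdlog = 1)) < 0.05)
  expect_gte(mean(reject), 0.99)
  expect_error(test_normality(rep(3, 20)), "constant")
  expect_error(test_normality(c(1, 2, 3)), "n >= 5")
})

test_that("identical samples give t = 0, p = 1", {
  x <- c(1.2, 3.4, 2.2, 4.1, 0.5, 2.9, 3.3, 1.8)
  cc <- compare_groups(x, x)
  expect_identical(cc$test_used, "t")
  expect_equal(cc$statistic, 0)
  expect_equal(cc$p_two_sided, 1)
  # swapping group order flips the sign and preserves p
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  c1 <- compare_groups(a, b, force = "t")
  c2 <- compare_groups(b, a, force = "t")
  expect_equal(c2$statistic, -c1$statistic, tolerance = 1e-12)
  expect_equal(c2$p_two_sided, c1$p_two_sided, tolerance = 1e-12)
})

test_that("fully separated small samples give U = 0 and exact p = 0.1", {
  cc <- compare_groups(c(1, 2, 3), c(4, 5, 6), force = "mann_whitney")
  expect_equal(unname(cc$statistic), 0)
  expect_equal(cc$p_two_sided, 0.1, tolerance = 1e-12)
  oracle <- mw_exact_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(cc$statistic), oracle$U)
  expect_equal(cc$p_two_sided, oracle$p, tolerance = 1e-12)
})

test_that("Mann-Whitney agrees with exhaustive enumeration for all small partitions", {
  sizes <- list(c(3, 3), c(3, 4), c(3, 5), c(3, 6), c(3, 7),
                c(4, 4), c(4, 5), c(4, 6), c(5, 5))
  set.seed(4)
  for (sz in sizes) {
    for (rep in 1:3) {
      a <- runif(sz[1]); b <- runif(sz[2], 0.2, 1.2)  # continuous: no ties
      cc <- compare_groups(a, b, force = "mann_whitney")
      oracle <- mw_exact_oracle(a, b)
      expect_equal(unname(cc$statistic), oracle$U)
      expect_equal(cc$p_two_sided, oracle$p, tolerance = 1e-12)
    }
  }
})

test_that("descriptive style matches the selected test", {
  set.seed(5)
  cn <- compare_groups(rnorm(30), rnorm(30))
  if (cn$test_used == "t") {
    expect_true(all(c("mean", "sd") %in% names(cn$descriptives)))
  }
  cs <- compare_groups(rlnorm(40, sdlog = 1.5), rlnorm(40, sdlog = 1.5))
  expect_identical(cs$test_used, "mann_whitney")
  expect_true(all(c("median", "q1", "q3") %in% names(cs$descriptives)))
})

test_that("the adaptive pipeline holds its type-I error under a normal null", {
  set.seed(6)
  n_rep <- 2000
  rej <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    rej[k] <- compare_groups(rnorm(30), rnorm(30))$p_two_sided < 0.05
  }
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Spearman correlation: perfect monotone, ties oracle, monotone invariance", {
  df <- data.frame(MWSS = 1:8, HWSS = 8:1,
                   aspect_ratio = c(1.1, 2.3, 3.1, 4.0, 5.2, 6.1, 7.9, 8.4))
  sp <- spearman_matrix(df, hemodynamic = c("MWSS", "HWSS"),
                        morphology = "aspect_ratio")
  expect_equal(sp$rho[sp$hemodynamic == "MWSS"], 1)
  expect_equal(sp$rho[sp$hemodynamic == "HWSS"], -1)

  # tie-corrected ranks against a hand-computed Pearson-on-ranks oracle
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(3, 1, 4, 4, 2, 6, 7, 9)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sp2 <- spearman_matrix(data.frame(MWSS = x, HWSS = x, aspect_ratio = y),
                         hemodynamic = "MWSS", morphology = "aspect_ratio")
  expect_equal(sp2$rho, oracle, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  sp3 <- spearman_matrix(data.frame(MWSS = exp(x), HWSS = x,
                                    aspect_ratio = y^3),
                         hemodynamic = "MWSS", morphology = "aspect_ratio")
  expect_equal(sp3$rho, oracle, tolerance = 1e-12)

  # constant column flagged
  sp4 <- spearman_matrix(data.frame(MWSS = rep(1, 8), HWSS = x,
                                    aspect_ratio = y),
                         hemodynamic = "MWSS", morphology = "aspect_ratio")
  expect_true(sp4$degenerate)
})

test_that("the univariate screen has the nominal false-positive rate and good power", {
  set.seed(7)
  n_rep <- 200
  hits <- 0L; total <- 0L
  for (k in seq_len(n_rep)) {
    df <- data.frame(m1 = rnorm(60), m2 = rnorm(60),
                     rupture_label = rep(c("ruptured", "unruptured"),
                                         each = 30))
    sc <- univariate_screen(df, c("m1", "m2"))
    hits <- hits + sum(sc$screened)
    total <- total + 2L
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.05), 0.02)

  # a 3-SD separated candidate is essentially always screened
  set.seed(8)
  found <- replicate(50, {
    df <- data.frame(
      sig = c(rnorm(30), rnorm(30, 3)), noise = rnorm(60),
      rupture_label = rep(c("ruptured", "unruptured"), each = 30))
    sc <- univariate_screen(df, c("sig", "noise"))
    "sig" %in% attr(sc, "screened")
  })
  expect_gt(mean(found), 0.99)

  # an empty screen is allowed and announced
  df0 <- data.frame(m1 = rep(c(1, 2, 3, 4, 5), 8),
                    m2 = rep(c(3, 4, 5, 6, 7), 8),
                    rupture_label = rep(c("ruptured", "unruptured"),
                                        each = 20))
  expect_message(sc0 <- univariate_screen(df0, c("m1", "m2")),
                 "skipped")
  expect_length(attr(sc0, "screened"), 0)
})

test_that("stepwise logistic recovers a strong predictor and sheds noise", {
  set.seed(9)
  n <- 200
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x1))
  df <- data.frame(x1 = x1, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                   rupture_label = ifelse(y == 1, "ruptured", "unruptured"))
  fit <- backward_stepwise_logistic(df, c("x1", "n1", "n2", "n3"),
                                    event = "ruptured")
  expect_true("x1" %in% fit$retained)
  est <- fit$coefficients[["x1"]]
  se <- summary(fit$fit)$coefficients["x1", 2]
  expect_true(abs(est - 2) < 1.96 * se)

  # over replicates: noise removed before the true predictor >= 90%
  set.seed(10)
  ok <- replicate(100, {
    x1 <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * x1))
    df <- data.frame(x1 = x1, n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                     rupture_label = ifelse(y == 1, "ruptured", "unruptured"))
    fit <- backward_stepwise_logistic(df, c("x1", "n1", "n2", "n3"),
                                      event = "ruptured")
    "x1" %in% fit$retained && !"x1" %in% fit$trace$removed
  })
  expect_gte(mean(ok), 0.9)
})

test_that("the stepwise trace replays to the final coefficients", {
  set.seed(11)
  n <- 150
  df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$rupture_label <- ifelse(
    rbinom(n, 1, plogis(1.5 * df$x1 - 0.2)) == 1, "ruptured", "unruptured")
  fit <- backward_stepwise_logistic(df, c("x1", "x2", "x3"),
                                    event = "ruptured")
  kept <- setdiff(c("x1", "x2", "x3"), fit$trace$removed)
  expect_setequal(kept, fit$retained)
  if (length(kept) > 0) {
    dat <- df[, kept, drop = FALSE]
    dat$.y <- as.integer(df$rupture_label == "ruptured")
    refit <- glm(.y ~ ., data = dat, family = binomial())
    expect_identical(unname(coef(refit)), unname(fit$coefficients))
  }
})

test_that("pure-noise predictors can empty the model, with a full trace", {
  set.seed(12)
  n <- 120
  df <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                   rupture_label = sample(c("ruptured", "unruptured"), n,
                                          replace = TRUE))
  fit <- backward_stepwise_logistic(df, c("n1", "n2", "n3"),
                                    event = "ruptured")
  expect_equal(length(fit$retained) + nrow(fit$trace), 3L)
})

test_that("complete separation is flagged rather than silently reported", {
  df <- data.frame(x = c(rnorm(20, -5), rnorm(20, 5)),
                   rupture_label = rep(c("unruptured", "ruptured"),
                                       each = 20))
  df$noise <- rnorm(40)
  fit <- backward_stepwise_logistic(df, c("x", "noise"), event = "ruptured")
  expect_true(fit$separation_flag)
})

test_that("comparison tables cover the four splits with the fixed row schema", {
  cohort <- sample_metric_cohort(cohort_config(seed = 13))
  tabs <- build_comparison_tables(cohort)
  expect_setequal(names(tabs),
                  c("rupture", "neck", "narrow_stratum", "wide_stratum"))
  for (tb in tabs) {
    expect_equal(tb$metric,
                 c("MWSS", "PWSS", "LSAR", "HWSS", "MP_ratio", "HP_ratio"))
    expect_true(all(tb$p >= 0 & tb$p <= 1))
    expect_true(all(tb$test_used %in% c("t", "mann_whitney")))
  }
  # single-label input skips the rupture table
  sub <- cohort[cohort$rupture_label == "ruptured", ]
  expect_message(tabs2 <- build_comparison_tables(sub), "skipped")
  expect_null(tabs2$rupture)
})

test_that("identical group distributions produce no excess significance", {
  set.seed(14)
  n_rep <- 60
  sig <- replicate(n_rep, {
    df <- data.frame(MWSS = rnorm(40, 3), PWSS = rnorm(40, 7),
                     LSAR = runif(40), HWSS = rnorm(40, 9),
                     MP_ratio = rnorm(40, 0.5, 0.1),
                     HP_ratio = rnorm(40, 1.3, 0.2),
                     rupture_label = rep(c("ruptured", "unruptured"),
                                         each = 20),
                     neck_category = "narrow")
    tb <- aneuflow:::comparison_table(df, "rupture_label",
                                      "ruptured", "unruptured")
    mean(tb$p < 0.05)
  })
  expect_lt(mean(sig), 0.12)  # nominal 5% with simulation slack
})
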