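#' Normality test (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample Kolmogorov-Smirnov test of composite normality with estimated
#' mean and variance, using Lilliefors-corrected critical values (the
#' uncorrected estimated-parameter KS test is anti-conservative). The
#' decision gate used throughout the pipeline is: treat the sample as
#' normal iff `p >= 0.05`.
#'
#' @param x Numeric sample, `n >= 5` (the Lilliefors critical values need
#'   at least five observations).
#' @return Two-sided p-value for departure from normality.
#' @export
test_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("degenerate-sample error: need n >= 5")
  if (stats::sd(x) == 0) stop("degenerate-sample error: constant sample")
  nortest::lillie.test(x)$p.value
}

mw_policy <- function(n1, n2, ties) {
  # exact enumeration for small untied samples; tie-corrected normal
  # approximation with continuity correction otherwise
  exact <- (min(n1, n2) <= 8) && !ties
  list(exact = exact, correct = !exact)
}

#' Two-group comparison with a normality gate
#'
#' Applies the normality gate per group (both groups must pass at
#' `p >= 0.05`) and runs the equal-variance independent-samples t test if
#' both pass, otherwise the Mann-Whitney U test. Descriptives are styled to
#' match: mean +- SD for the t test, median with quartiles (Q1, Q3)
#' otherwise. Mann-Whitney uses exact enumeration when the smaller group
#' has at most 8 observations and there are no ties, and the tie-corrected
#' normal approximation with continuity correction otherwise.
#'
#' @param a,b Numeric samples (`n >= 3` each).
#' @param parameter Optional parameter name carried into the result.
#' @param force `NULL` (gate decides), `"t"`, or `"mann_whitney"`.
#' @param var_equal Use the pooled-variance t test (the classical
#'   independent-samples form); set `FALSE` for Welch.
#' @return An object of class `group_comparison`: `parameter`, `test_used`,
#'   `statistic` (t, or Mann-Whitney U for the first sample), `p_two_sided`,
#'   `normal_gate` (per-group normality p-values, when evaluated) and
#'   `descriptives` (one row per group).
#' @export
compare_groups <- function(a, b, parameter = NA_character_, force = NULL,
                           var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("degenerate samples: need n >= 3 per group")
  }
  gate <- c(NA_real_, NA_real_)
  if (is.null(force)) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
      stop("degenerate samples: both groups constant and identical")
    }
    can_gate <- length(a) >= 5 && length(b) >= 5 &&
      stats::sd(a) > 0 && stats::sd(b) > 0
    if (can_gate) {
      gate <- c(test_normality(a), test_normality(b))
      test_used <- if (all(gate >= 0.05)) "t" else "mann_whitney"
    } else {
      test_used <- "mann_whitney"
    }
  } else {
    test_used <- match.arg(force, c("t", "mann_whitney"))
  }

  if (test_used == "t") {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    statistic <- unname(ht$statistic)
    p <- ht$p.value
    desc <- data.frame(group = c("a", "b"),
                       n = c(length(a), length(b)),
                       mean = c(mean(a), mean(b)),
                       sd = c(stats::sd(a), stats::sd(b)))
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    pol <- mw_policy(length(a), length(b), ties)
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = pol$exact, correct = pol$correct))
    statistic <- unname(ht$statistic)  # U for the first sample
    p <- ht$p.value
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
    desc <- data.frame(group = c("a", "b"),
                       n = c(length(a), length(b)),
                       median = c(qa[2], qb[2]),
                       q1 = c(qa[1], qb[1]),
                       q3 = c(qa[3], qb[3]))
  }
  structure(list(parameter = parameter, test_used = test_used,
                 statistic = statistic, p_two_sided = p,
                 normal_gate = gate, descriptives = desc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s test, statistic %.4g, two-sided p = %.4g\n",
              if (is.na(x$parameter)) "comparison" else x$parameter,
              ifelse(x$test_used == "t", "t", "Mann-Whitney U"),
              x$statistic, x$p_two_sided))
  print(x$descriptives, row.names = FALSE)
  invisible(x)
}

#' Spearman correlations between hemodynamic and morphology factors
#'
#' Rank correlation (average ranks under ties) with two-sided p-values for
#' every hemodynamic-by-morphology pair. Constant columns yield `NA` for
#' their pairs and are flagged.
#'
#' @param records Data frame (e.g. an `aneurysm_cohort`).
#' @param hemodynamic,morphology Column names to correlate.
#' @return Data frame with one row per pair: `hemodynamic`, `morphology`,
#'   `rho`, `p`, `degenerate`.
#' @export
spearman_matrix <- function(records,
                            hemodynamic = c("MWSS", "HWSS", "PWSS", "LSAR",
                                            "MP_ratio", "HP_ratio"),
                            morphology = c("aspect_ratio", "height",
                                           "neck_width", "dome_measure")) {
  if (nrow(records) < 5) stop("need n >= 5 records")
  out <- expand.grid(hemodynamic = hemodynamic, morphology = morphology,
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_
  out$p <- NA_real_
  out$degenerate <- FALSE
  for (k in seq_len(nrow(out))) {
    x <- records[[out$hemodynamic[k]]]
    y <- records[[out$morphology[k]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$degenerate[k] <- TRUE
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    out$rho[k] <- unname(ct$estimate)
    out$p[k] <- ct$p.value
  }
  out
}

#' Univariate screen of candidate rupture predictors
#'
#' Compares each candidate between outcome classes with the normality-gated
#' two-group test and returns those significant at the screening threshold
#' (two-sided p < 0.05).
#'
#' @param records Data frame.
#' @param candidates Candidate column names (>= 2).
#' @param label Outcome column (two classes).
#' @param threshold Screening significance level.
#' @return Data frame `parameter`, `test_used`, `p`, `screened`; the
#'   screened subset is in `attr(, "screened")`.
#' @export
univariate_screen <- function(records, candidates, label = "rupture_label",
                              threshold = 0.05) {
  if (length(candidates) < 2) stop("need >= 2 candidate parameters")
  cls <- unique(records[[label]])
  if (length(cls) != 2) stop("outcome must have exactly two classes")
  res <- lapply(candidates, function(pn) {
    cc <- compare_groups(records[[pn]][records[[label]] == cls[1]],
                         records[[pn]][records[[label]] == cls[2]],
                         parameter = pn)
    data.frame(parameter = pn, test_used = cc$test_used,
               p = cc$p_two_sided)
  })
  res <- do.call(rbind, res)
  res$screened <- res$p < threshold
  attr(res, "screened") <- res$parameter[res$screened]
  if (!any(res$screened)) {
    message("univariate screen: no candidate reached p < ", threshold,
            "; downstream regression will be skipped")
  }
  res
}

#' Backward stepwise binary logistic regression (p-value removal)
#'
#' Fits the full binomial logistic model on the screened parameters, then
#' iteratively removes the least significant parameter (largest Wald p)
#' while that p exceeds the removal threshold (default 0.10), refitting at
#' each step. The removal trace reconstructs the final model. Complete or
#' quasi-complete separation is detected and flagged; a flagged result
#' carries the last finite fit and should not be interpreted as converged
#' coefficients.
#'
#' @param records Data frame.
#' @param params Screened parameter names (>= 1).
#' @param label Outcome column; coerced so the second level is the event.
#' @param removal_threshold Wald-p threshold for removal.
#' @param event Level of `label` treated as the event; default: the
#'   alphabetically later level.
#' @return An object of class `stepwise_logistic`: `retained`,
#'   `coefficients`, `p_values`, `trace` (data frame: step, removed, p),
#'   `separation_flag`, and the final `glm` fit (or `NULL` when no
#'   parameter survives).
#' @export
backward_stepwise_logistic <- function(records, params,
                                       label = "rupture_label",
                                       removal_threshold = 0.10,
                                       event = NULL) {
  if (length(params) < 1) stop("need >= 1 screened parameter")
  yvals <- records[[label]]
  lev <- sort(unique(as.character(yvals)))
  if (length(lev) != 2) stop("outcome must have exactly two classes")
  event <- event %||% lev[2]
  y <- as.integer(as.character(yvals) == event)
  if (all(y == 0) || all(y == 1)) stop("outcome has a single class")

  current <- params
  trace <- data.frame(step = integer(), removed = character(),
                      p = numeric())
  sep_flag <- FALSE
  fit <- NULL
  step_i <- 0L
  repeat {
    dat <- records[, current, drop = FALSE]
    dat$.y <- y
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep_flag <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    coefs <- summary(fit)$coefficients
    pv <- coefs[rownames(coefs) != "(Intercept)", 4]
    names(pv) <- rownames(coefs)[rownames(coefs) != "(Intercept)"]
    if (length(pv) == 0 || max(pv) <= removal_threshold) break
    worst <- names(pv)[which.max(pv)]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, removed = worst,
                                     p = unname(max(pv))))
    current <- setdiff(current, worst)
    if (length(current) == 0) {
      fit <- NULL
      pv <- numeric()
      break
    }
  }
  if (max(abs(stats::coef(fit) %||% 0), na.rm = TRUE) > 50) sep_flag <- TRUE
  structure(list(
    retained = if (is.null(fit)) character() else setdiff(
      names(stats::coef(fit)), "(Intercept)"),
    coefficients = if (is.null(fit)) numeric() else stats::coef(fit),
    p_values = pv,
    trace = trace,
    separation_flag = sep_flag,
    event = event,
    fit = fit), class = "stepwise_logistic")
}

#' @export
print.stepwise_logistic <- function(x, ...) {
  cat("Backward stepwise logistic regression (event: ", x$event, ")\n",
      sep = "")
  if (length(x$retained) == 0) {
    cat("  final model: empty (all parameters removed)\n")
  } else {
    cat("  retained:", paste(x$retained, collapse = ", "), "\n")
    cat("  coefficients:\n")
    print(signif(x$coefficients, 4))
  }
  if (nrow(x$trace) > 0) {
    cat("  removal trace:\n")
    print(x$trace, row.names = FALSE)
  }
  if (x$separation_flag) cat("  WARNING: separation detected\n")
  invisible(x)
}

table_metric_labels <- c(
  MWSS = "Mean aneurysm WSS (Pa)",
  PWSS = "Mean parent artery WSS (Pa)",
  LSAR = "Low shear area ratio",
  HWSS = "Highest aneurysm WSS (Pa)",
  MP_ratio = "Mean aneurysm-parent WSS ratio",
  HP_ratio = "Highest aneurysm-parent WSS ratio")

comparison_table <- function(records, split_col, level_a, level_b,
                             metrics = names(table_metric_labels)) {
  rows <- lapply(metrics, function(mn) {
    a <- records[[mn]][records[[split_col]] == level_a]
    b <- records[[mn]][records[[split_col]] == level_b]
    cc <- compare_groups(a, b, parameter = mn)
    da <- cc$descriptives[1, ]; db <- cc$descriptives[2, ]
    fmt <- function(d) {
      if (cc$test_used == "t") {
        sprintf("%.3f +- %.3f", d$mean, d$sd)
      } else {
        sprintf("%.3f (Q1 %.3f, Q3 %.3f)", d$median, d$q1, d$q3)
      }
    }
    data.frame(parameter = unname(table_metric_labels[mn]),
               metric = mn,
               test_used = cc$test_used,
               group_a = fmt(da), group_b = fmt(db),
               statistic = cc$statistic, p = cc$p_two_sided)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(level_a, level_b)
  out
}

#' Build the four group-comparison tables
#'
#' Produces the study's comparison-table analogs from a cohort:
#' 1. ruptured vs unruptured (all aneurysms);
#' 2. narrow-necked vs wide-necked (all aneurysms);
#' 3. ruptured vs unruptured within the narrow-necked stratum;
#' 4. ruptured vs unruptured within the wide-necked stratum.
#' Rows follow the fixed metric order (mean aneurysm WSS, mean parent WSS,
#' low shear area ratio, highest aneurysm WSS, and the two ratios); each
#' row records the gate-selected test, style-matched descriptives and the
#' two-sided p. Stratified tables whose stratum is empty are skipped with a
#' notice.
#'
#' @param records An `aneurysm_cohort` or compatible data frame.
#' @return Named list of data frames
#'   (`rupture`, `neck`, `narrow_stratum`, `wide_stratum`; absent strata
#'   omitted).
#' @export
build_comparison_tables <- function(records) {
  out <- list()
  two_sided <- function(col) {
    length(unique(records[[col]])) == 2 && min(table(records[[col]])) >= 3
  }
  if (two_sided("rupture_label")) {
    out$rupture <- comparison_table(records, "rupture_label",
                                    "ruptured", "unruptured")
  } else {
    message("rupture classes missing or too small; rupture table skipped")
  }
  if (two_sided("neck_category")) {
    out$neck <- comparison_table(records, "neck_category", "narrow", "wide")
  } else {
    message("neck strata missing or too small; neck table skipped")
  }
  for (stratum in c("narrow", "wide")) {
    sub <- records[records$neck_category == stratum, , drop = FALSE]
    nm <- paste0(stratum, "_stratum")
    if (nrow(sub) >= 6 && length(unique(sub$rupture_label)) == 2 &&
        min(table(sub$rupture_label)) >= 3) {
      out[[nm]] <- comparison_table(sub, "rupture_label",
                                    "ruptured", "unruptured")
    } else {
      message("stratum '", stratum,
              "' lacks both rupture classes; table skipped")
    }
  }
  out
}
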