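#' Orientation registry for Learning Indices
#'
#' Positive Learning Index always means improvement: success-type metrics
#' increase with learning (index = last day minus first day), while miss,
#' vain, no-try, distance and extent metrics decrease (index = first day
#' minus last day).
#'
#' @param metric Metric name (e.g. `"pct_success_by_reach"`,
#'   `"delta_y_px"`).
#' @return `"increase"` or `"decrease"`.
#' @export
li_orientation <- function(metric) {
  if (grepl("success", metric)) "increase" else "decrease"
}

#' Per-subject Learning Index
#'
#' The Learning Index of a subject is the difference in a metric between the
#' first and last training day, normalising learning to the animal's own
#' baseline: `day1 - dayD` for metrics that decrease with learning,
#' `dayD - day1` for metrics that increase. Subjects missing either endpoint
#' day get a missing index (and are excluded from group tests, with the
#' count reported there).
#'
#' @param curves Tibble with columns `subject`, `day`, `value` (one row per
#'   subject-day; missing values allowed); any other columns (genotype, sex,
#'   condition, ...) are carried through per subject.
#' @param orientation `"decrease"` or `"increase"`; see [li_orientation()].
#' @param day_first,day_last Endpoint days (default the min and max of
#'   `curves$day`).
#' @return Tibble with one row per subject: metadata columns and
#'   `learning_index`.
#' @export
learning_index <- function(curves, orientation = c("decrease", "increase"),
                           day_first = NULL, day_last = NULL) {
  orientation <- match.arg(orientation)
  day_first <- day_first %||% min(curves$day)
  day_last <- day_last %||% max(curves$day)
  meta <- setdiff(names(curves), c("day", "value"))
  wide <- dplyr::summarise(
    dplyr::group_by(curves, dplyr::across(dplyr::all_of(meta))),
    v_first = value_at_day(.data$day, .data$value, day_first),
    v_last = value_at_day(.data$day, .data$value, day_last),
    .groups = "drop"
  )
  sgn <- if (orientation == "decrease") 1 else -1
  dplyr::mutate(
    wide,
    learning_index = sgn * (.data$v_first - .data$v_last),
    v_first = NULL, v_last = NULL
  )
}

value_at_day <- function(day, value, d) {
  v <- value[day == d]
  if (length(v) == 0 || all(is.na(v))) NA_real_ else v[!is.na(v)][1]
}

new_reach_test <- function(method, branch, statistic, df, p.value, n,
                           estimate = NA_real_, shapiro_p = NA_real_,
                           n_missing = 0L) {
  structure(
    list(method = method, branch = branch, statistic = statistic, df = df,
         p.value = p.value, n = n, estimate = estimate,
         shapiro_p = shapiro_p, n_missing = n_missing),
    class = "reach_test"
  )
}

#' @export
print.reach_test <- function(x, ...) {
  cat(sprintf(
    "<reach_test> %s (branch: %s)\n  statistic = %.4g, df = %s, p = %.4g, n = %s\n",
    x$method, x$branch, x$statistic,
    paste(signif(x$df, 4), collapse = ", "), x$p.value,
    paste(x$n, collapse = "/")
  ))
  invisible(x)
}

#' @export
tidy.reach_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, branch = x$branch, statistic = x$statistic,
    df = x$df[1], p.value = x$p.value, estimate = x$estimate,
    n = sum(x$n), shapiro_p = x$shapiro_p
  )
}

#' @export
glance.reach_test <- function(x, ...) tidy(x)

#' Paired first-day versus last-day comparison
#'
#' Tests within-subject change between the first and last training day.
#' Normality of the paired differences is assessed with a Shapiro-Wilk test;
#' if its p-value is at least `alpha_normality` a paired t test is run,
#' otherwise a Wilcoxon matched-pairs signed-rank test. The branch taken is
#' recorded in the result. Identical endpoint vectors (all differences zero)
#' short-circuit to a null result (statistic 0, p = 1).
#'
#' @param curves Tibble with `subject`, `day`, `value` (see
#'   [learning_index()]).
#' @param alpha_normality Shapiro-Wilk threshold for the t branch
#'   (default 0.05).
#' @param day_first,day_last Endpoint days (default min and max of
#'   `curves$day`).
#' @return A `reach_test` object; `tidy()` it for a one-row tibble.
#' @export
day1_vs_day8_test <- function(curves, alpha_normality = 0.05,
                              day_first = NULL, day_last = NULL) {
  day_first <- day_first %||% min(curves$day)
  day_last <- day_last %||% max(curves$day)
  wide <- dplyr::summarise(
    dplyr::group_by(curves, .data$subject),
    v1 = value_at_day(.data$day, .data$value, day_first),
    v2 = value_at_day(.data$day, .data$value, day_last),
    .groups = "drop"
  )
  ok <- complete.cases(wide[, c("v1", "v2")])
  n_missing <- sum(!ok)
  v1 <- wide$v1[ok]
  v2 <- wide$v2[ok]
  if (length(v1) < 3) abort("need at least 3 complete subject pairs")
  d <- v2 - v1
  if (all(d == 0)) {
    return(new_reach_test("paired t test", "t", 0, length(d) - 1, 1,
                          length(d), estimate = 0, n_missing = n_missing))
  }
  sw <- shapiro.test(d)$p.value
  if (sw >= alpha_normality) {
    tt <- t.test(v2, v1, paired = TRUE)
    new_reach_test("paired t test", "t", unname(tt$statistic),
                   unname(tt$parameter), tt$p.value, length(d),
                   estimate = mean(d), shapiro_p = sw, n_missing = n_missing)
  } else {
    wt <- suppressWarnings(wilcox.test(v2, v1, paired = TRUE))
    new_reach_test("Wilcoxon matched-pairs signed-rank test", "wilcoxon",
                   unname(wt$statistic), NA_real_, wt$p.value, length(d),
                   estimate = median(d), shapiro_p = sw,
                   n_missing = n_missing)
  }
}

#' Welch test between two groups of Learning Indices
#'
#' Unpaired two-sided comparison of per-subject Learning Indices (or any
#' per-subject scalar) between two groups, using Welch's unequal-variance t
#' test. Groups with identical constant values short-circuit to a null
#' result. Missing indices are dropped and counted.
#'
#' @param li Tibble from [learning_index()] with a grouping column.
#' @param by Name of the grouping column (must have exactly two levels).
#' @param value Name of the value column (default `"learning_index"`).
#' @return A `reach_test` object. The statistic's sign follows
#'   first-level-minus-second-level order (levels in order of appearance).
#' @export
group_li_test <- function(li, by = "genotype", value = "learning_index") {
  if (!by %in% names(li)) abort(sprintf("grouping column '%s' not found", by))
  g <- li[[by]]
  lev <- unique(g)
  if (length(lev) != 2) abort("group_li_test() needs exactly two groups")
  a <- li[[value]][g == lev[1]]
  b <- li[[value]][g == lev[2]]
  n_missing <- sum(is.na(a)) + sum(is.na(b))
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("need at least 3 non-missing indices per group")
  }
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
    return(new_reach_test("Welch's t test", "welch", 0,
                          length(a) + length(b) - 2, 1,
                          c(length(a), length(b)),
                          estimate = 0, n_missing = n_missing))
  }
  tt <- t.test(a, b)
  new_reach_test("Welch's t test", "welch", unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, c(length(a), length(b)),
                 estimate = mean(a) - mean(b), n_missing = n_missing)
}

#' Longitudinal two-factor model of a learning curve
#'
#' Compares learning time courses between groups. When the subject-by-day
#' table is complete, a repeated-measures two-way ANOVA is run (split-plot
#' strata via [stats::aov()], subject as the repeated unit) with a
#' Greenhouse-Geisser sphericity correction applied to the within-subject
#' effects (day and the interaction). When any subject-day value is missing
#' — typically because a mouse made no attempts — the model switches to a
#' linear mixed model with a subject-level random intercept
#' (`value ~ group * day + (1 | subject)`, Satterthwaite F tests via
#' lmerTest). The branch taken is a pure function of the data and is
#' reported.
#'
#' @param curves Tibble with `subject`, `day`, `value` and the grouping
#'   column.
#' @param between Name of the between-subject factor column (e.g.
#'   `"genotype"`, `"condition"`, or `"sex"`).
#' @param gg_correction Apply the Greenhouse-Geisser correction in the
#'   repeated-measures branch (default TRUE; the uncorrected test is
#'   reported when FALSE).
#' @return An object of class `reach_longitudinal` with a `terms` tibble
#'   (term, statistic, df1, df2, p.value), the `model_type`
#'   (`"rm_anova"` or `"mixed"`), and the sphericity `epsilon` (NA for the
#'   mixed branch). Use `tidy()`/`glance()`.
#' @export
longitudinal_model <- function(curves, between = "genotype",
                               gg_correction = TRUE) {
  if (!between %in% names(curves)) {
    abort(sprintf("between-factor column '%s' not found", between))
  }
  dat <- tibble::tibble(
    subject = factor(curves$subject),
    group = factor(curves[[between]]),
    day = factor(curves$day),
    value = curves$value
  )
  if (nlevels(dat$group) < 2) abort("need >= 2 levels of the between factor")
  if (nlevels(dat$day) < 2) abort("need >= 2 days")
  n_per <- table(unique(dat[, c("subject", "group")])$group)
  if (any(n_per < 3)) abort("need >= 3 subjects per group level")

  full <- tidyr::crossing(
    unique(dat[, c("subject", "group")]), day = levels(dat$day)
  )
  obs <- dat[!is.na(dat$value), ]
  complete <- nrow(obs) == nrow(dat) && nrow(dat) == nrow(full) &&
    !anyDuplicated(dat[, c("subject", "day")])

  if (complete) {
    fit <- aov(value ~ group * day + Error(subject), data = dat)
    s <- summary(fit)
    between_tab <- s[["Error: subject"]][[1]]
    within_tab <- s[["Error: Within"]][[1]]
    grab <- function(tab, term) {
      i <- match(term, trimws(rownames(tab)))
      list(F = tab[i, "F value"], df1 = tab[i, "Df"],
           df2 = tab[nrow(tab), "Df"])
    }
    bg <- grab(between_tab, "group")
    wd <- grab(within_tab, "day")
    wi <- grab(within_tab, "group:day")
    eps <- gg_epsilon(dat)
    adj <- if (gg_correction) eps else 1
    terms <- tibble::tibble(
      term = c("group", "day", "group:day"),
      statistic = c(bg$F, wd$F, wi$F),
      df1 = c(bg$df1, wd$df1 * adj, wi$df1 * adj),
      df2 = c(bg$df2, wd$df2 * adj, wi$df2 * adj)
    )
    terms$p.value <- pf(terms$statistic, terms$df1, terms$df2,
                        lower.tail = FALSE)
    out <- list(terms = terms, model_type = "rm_anova", epsilon = eps,
                between = between, n_per_group = as.integer(n_per))
  } else {
    fit <- lmerTest::lmer(value ~ group * day + (1 | subject), data = obs)
    a <- anova(fit, type = 3)
    terms <- tibble::tibble(
      term = c("group", "day", "group:day"),
      statistic = a[c("group", "day", "group:day"), "F value"],
      df1 = a[c("group", "day", "group:day"), "NumDF"],
      df2 = a[c("group", "day", "group:day"), "DenDF"],
      p.value = a[c("group", "day", "group:day"), "Pr(>F)"]
    )
    out <- list(terms = terms, model_type = "mixed", epsilon = NA_real_,
                between = between, n_per_group = as.integer(n_per))
  }
  structure(out, class = "reach_longitudinal")
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x day matrix, using orthonormal contrasts.
gg_epsilon <- function(dat) {
  wide <- tidyr::pivot_wider(
    dat, id_cols = c("subject", "group"), names_from = "day",
    values_from = "value"
  )
  Y <- as.matrix(wide[, -(1:2)])
  groups <- wide$group
  k <- ncol(Y)
  Yc <- Y
  for (g in levels(groups)) {
    i <- groups == g
    Yc[i, ] <- sweep(Y[i, , drop = FALSE], 2, colMeans(Y[i, , drop = FALSE]))
  }
  S <- crossprod(Yc) / (nrow(Y) - nlevels(groups))
  C <- qr.Q(qr(stats::contr.helmert(k)))
  M <- t(C) %*% S %*% C
  eps <- sum(diag(M))^2 / ((k - 1) * sum(M^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' @export
print.reach_longitudinal <- function(x, ...) {
  cat(sprintf(
    "<reach_longitudinal> %s (between: %s%s)\n",
    if (x$model_type == "rm_anova") {
      "repeated-measures two-way ANOVA"
    } else {
      "linear mixed model (random intercept per subject)"
    },
    x$between,
    if (x$model_type == "rm_anova") {
      sprintf("; GG epsilon = %.3f", x$epsilon)
    } else ""
  ))
  print(as.data.frame(x$terms), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.reach_longitudinal <- function(x, ...) x$terms

#' @export
glance.reach_longitudinal <- function(x, ...) {
  tibble::tibble(
    model_type = x$model_type, epsilon = x$epsilon,
    between = x$between, n_subjects = sum(x$n_per_group)
  )
}
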