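# Survival estimation and association statistics: Kaplan-Meier curves,
# log-rank tests, Cox proportional-hazards fits, Bonferroni adjustment,
# Spearman correlation, and the subgroup x metric survival screen.

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' subjects censored at an event time remain in the risk set at that time.
#'
#' @param times Positive observation times.
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   one row per distinct observation time.
#' @export
#' @examples
#' km_curve(c(1, 2, 3), c(TRUE, FALSE, TRUE))
km_curve <- function(times, events) {
  if (length(times) == 0) abort("km_curve() needs at least one observation")
  if (length(times) != length(events)) abort("times and events must align")
  if (any(times <= 0)) abort("times must be strictly positive")
  fit <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv
  )
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group A is
#' compared with its hypergeometric expectation given the pooled risk set;
#' the standardized sum is chi-squared with 1 degree of freedom.
#'
#' @param times Positive observation times.
#' @param events Logical (or 0/1) event indicators.
#' @param group Two-level grouping vector.
#' @return One-row tibble `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("logrank_test() needs exactly two non-empty groups")
  }
  if (!any(as.logical(events))) {
    abort("logrank_test() needs at least one event")
  }
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ group)
  chisq <- sd$chisq
  tibble(chisq = chisq, df = 1L, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood with Efron handling of tied event
#' times. Rows with missing covariates are dropped (their count is
#' reported via a message). Monotone likelihood (complete separation,
#' divergent coefficients) is an error; failure to converge within the
#' iteration limit is flagged on the returned object, never silent.
#'
#' @param data Data frame holding times, events and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names of the observation time and event
#'   indicator (defaults `"os_days"`, `"event"`).
#' @return An object of class `ig_cox` wrapping the `coxph` fit, with
#'   elements `fit`, `n`, `n_events`, `n_dropped`, `converged`.
#' @export
cox_fit <- function(data, covariates, time = "os_days", event = "event") {
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cox_fit() columns absent from data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- complete.cases(data[, c(time, event, covariates), drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("cox_fit(): dropped ", n_dropped, " row(s) with missing covariates")
  }
  data <- data[keep, , drop = FALSE]
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(paste0("`", covariates, "`"), collapse = " + ")
  ))

  converged <- TRUE
  separated <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("infinite|converged before", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("Ran out of iterations", msg)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  # a divergent coefficient signals monotone partial likelihood
  if (separated || any(abs(fit$coefficients) > 15)) {
    abort("complete separation in Cox fit: a coefficient diverges")
  }
  structure(
    list(fit = fit, n = fit$n, n_events = fit$nevent,
         n_dropped = n_dropped, converged = converged),
    class = "ig_cox"
  )
}

#' @export
print.ig_cox <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties): n =", x$n,
      ", events =", x$n_events,
      if (!x$converged) ", DID NOT CONVERGE" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `ig_cox` object.
#' @param conf.level Confidence level for the hazard-ratio interval.
#' @param ... Unused.
#' @return Tibble with one row per covariate: `term`, `estimate` (log
#'   hazard), `std.error`, `statistic` (Wald z), `p.value`,
#'   `hazard_ratio`, `conf.low`, `conf.high`.
#' @export
tidy.ig_cox <- function(x, conf.level = 0.95, ...) {
  co <- x$fit$coefficients
  se <- sqrt(diag(x$fit$var))
  z <- co / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble(
    term = names(co),
    estimate = unname(co),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    hazard_ratio = unname(exp(co)),
    conf.low = unname(exp(co - q * se)),
    conf.high = unname(exp(co + q * se))
  )
}

#' Glance at a Cox fit
#'
#' @param x An `ig_cox` object.
#' @param ... Unused.
#' @return One-row tibble: sample size, events, dropped rows, concordance,
#'   likelihood-ratio / score statistics and convergence flag.
#' @export
glance.ig_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n,
    n_events = x$n_events,
    n_dropped = x$n_dropped,
    concordance = unname(s$concordance["C"]),
    logLik = unname(x$fit$loglik[2]),
    statistic.log = unname(s$logtest["test"]),
    statistic.sc = unname(s$sctest["test"]),
    p.value.sc = unname(s$sctest["pvalue"]),
    converged = x$converged
  )
}

#' Compare survival between a high and a low group
#'
#' Kaplan-Meier curves per group, the two-group log-rank test, and the
#' hazard ratio of the high group relative to the low group from a
#' univariate Cox fit on the high/low indicator (high = 1): a hazard ratio
#' below 1 means the high group survives longer. Patients labelled
#' `"excluded"` are dropped.
#'
#' @param data Data frame with observation time, event indicator, and a
#'   `group` column with values `"high"`/`"low"` (and possibly
#'   `"excluded"`).
#' @param time,event,group Column names (defaults `"os_days"`, `"event"`,
#'   `"group"`).
#' @return An object of class `ig_survcomp` with elements `table` (one-row
#'   tibble `n_high`, `n_low`, `hazard_ratio`, `conf.low`, `conf.high`,
#'   `logrank_chisq`, `p.value`) and `curves` (per-group KM tibble).
#' @export
compare_survival <- function(data, time = "os_days", event = "event",
                             group = "group") {
  data <- data[data[[group]] %in% c("high", "low"), , drop = FALSE]
  n_high <- sum(data[[group]] == "high")
  n_low <- sum(data[[group]] == "low")
  if (n_high == 0 || n_low == 0) {
    abort("compare_survival() needs non-empty high and low groups")
  }
  lr <- logrank_test(data[[time]], data[[event]], data[[group]])
  cox_data <- tibble(
    t = data[[time]], e = as.logical(data[[event]]),
    high = as.integer(data[[group]] == "high")
  )
  cox <- cox_fit(cox_data, covariates = "high", time = "t", event = "e")
  ct <- tidy(cox)

  curves <- purrr::map(c("high", "low"), function(g) {
    sel <- data[[group]] == g
    km <- km_curve(data[[time]][sel], data[[event]][sel])
    km$group <- g
    km
  }) |> purrr::list_rbind()

  structure(
    list(
      table = tibble(
        n_high = n_high, n_low = n_low,
        hazard_ratio = ct$hazard_ratio, conf.low = ct$conf.low,
        conf.high = ct$conf.high,
        logrank_chisq = lr$chisq, p.value = lr$p
      ),
      curves = curves
    ),
    class = "ig_survcomp"
  )
}

#' @export
print.ig_survcomp <- function(x, ...) {
  cat("Survival comparison (high vs low):\n")
  print(x$table)
  invisible(x)
}

#' Tidy a survival comparison
#'
#' @param x An `ig_survcomp` object.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @export
tidy.ig_survcomp <- function(x, ...) x$table

#' Plot a survival comparison
#'
#' Kaplan-Meier step curves for the high and low groups.
#'
#' @param object An `ig_survcomp` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ig_survcomp <- function(object, ...) {
  curves <- object$curves |>
    group_by(.data$group) |>
    group_modify(~ bind_rows(tibble(time = 0, survival = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "overall survival",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a family of `m` comparisons.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' bonferroni_adjust(0.01, 12)
bonferroni_adjust <- function(p, m) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p must lie in [0, 1]")
  if (m < 1) abort("family size m must be >= 1")
  pmin(1, p * m)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' p-value from the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value in either vector are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @param min_n Minimum number of complete pairs (default 5).
#' @return One-row tibble `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_corr(c(1, 2, 3, 4, 5), c(1, 3, 2, 4, 5))
spearman_corr <- function(x, y, min_n = 5) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n) abort(paste0("spearman_corr() needs at least ", min_n, " pairs"))
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("spearman_corr() is undefined for a constant vector")
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}

#' Subgroup-by-metric survival screen
#'
#' For every (subgroup, metric) pair: patients in the subgroup are split at
#' the median of the metric (within the subgroup by default), survival of
#' the high versus low group is compared by log-rank and univariate Cox,
#' and the log-rank p-value is Bonferroni-adjusted for the number of
#' subgroups screened per metric. Pairs where the split or the comparison
#' is degenerate (too few patients, no events, constant metric) yield a row
#' of `NA` statistics rather than aborting the screen.
#'
#' @param data Data frame with one row per patient carrying `os_days`,
#'   `event`, the metric columns, and one logical membership column per
#'   subgroup (e.g. the join of [isotype_profiles()], the clinical table
#'   and [assign_subgroups()]).
#' @param metrics Character vector of metric column names.
#' @param subgroups Character vector of subgroup column names (default
#'   [subgroup_names()]).
#' @param median_scope `"subgroup"` (default) computes the split median
#'   within each subgroup; `"cohort"` uses the whole-cohort median.
#' @param m Bonferroni family size; defaults to `length(subgroups)`.
#' @return Tibble with one row per (subgroup, metric): group sizes, hazard
#'   ratio with 95% CI, log-rank chi-square, raw and adjusted p.
#' @export
survival_screen <- function(data, metrics, subgroups = subgroup_names(),
                            median_scope = c("subgroup", "cohort"),
                            m = NULL) {
  median_scope <- match.arg(median_scope)
  m <- m %||% length(subgroups)
  missing_cols <- setdiff(c(metrics, subgroups), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("survival_screen() columns absent from data: ",
                 paste(missing_cols, collapse = ", ")))
  }

  grid <- tidyr::expand_grid(subgroup = subgroups, metric = metrics)
  purrr::pmap(grid, function(subgroup, metric) {
    sub <- data[data[[subgroup]], , drop = FALSE]
    row <- tibble(
      subgroup = subgroup, metric = metric,
      n_high = NA_integer_, n_low = NA_integer_,
      hazard_ratio = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      logrank_chisq = NA_real_, p.value = NA_real_, p.adjusted = NA_real_
    )
    res <- tryCatch({
      vals <- sub[[metric]]
      if (median_scope == "cohort") {
        med <- median(data[[metric]], na.rm = TRUE)
        labels <- ifelse(is.na(vals), "excluded",
                         ifelse(vals > med, "high", "low"))
      } else {
        labels <- median_split(vals)
      }
      sub$group <- labels
      cmp <- compare_survival(sub)
      cmp$table
    }, error = function(e) NULL)
    if (!is.null(res)) {
      row$n_high <- res$n_high
      row$n_low <- res$n_low
      row$hazard_ratio <- res$hazard_ratio
      row$conf.low <- res$conf.low
      row$conf.high <- res$conf.high
      row$logrank_chisq <- res$logrank_chisq
      row$p.value <- res$p.value
      row$p.adjusted <- bonferroni_adjust(res$p.value, m)
    }
    row
  }) |> purrr::list_rbind()
}

#' Forest plot of a survival screen
#'
#' Hazard ratios (log scale) with 95% confidence intervals for one metric
#' across subgroups.
#'
#' @param screen Tibble from [survival_screen()].
#' @param metric Metric to display (default: first metric present).
#' @return A ggplot object.
#' @export
plot_screen_forest <- function(screen, metric = NULL) {
  metric <- metric %||% screen$metric[1]
  sub <- screen |> filter(.data$metric == .env$metric, !is.na(.data$hazard_ratio))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$hazard_ratio,
                                    y = .data$subgroup)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0("hazard ratio (high vs low ", metric, ")"),
                  y = NULL) +
    ggplot2::theme_minimal()
}
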