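test_that("km_curve reproduces the hand product-limit example", {
  km <- km_curve(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  # risk sets {3, 2, 1}: S(1) = 2/3, censoring at 2, S(3) = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 3], 0)

  all_censored <- km_curve(c(5, 8, 13), c(FALSE, FALSE, FALSE))
  expect_true(all(all_censored$survival == 1))

  expect_error(km_curve(numeric(0), logical(0)), "at least one")
})

test_that("km estimates are frequency-based and match empirical survival", {
  set.seed(31)
  times <- sample(1:50, 20, replace = TRUE)
  events <- rbinom(20, 1, 0.7) == 1
  km <- km_curve(times, events)
  km2 <- km_curve(rep(times, 2), rep(events, 2))
  expect_equal(km$survival, km2$survival)

  # no censoring: product-limit equals the empirical survival function
  km3 <- km_curve(times, rep(TRUE, 20))
  expect_equal(km3$survival,
               vapply(km3$time, function(t) mean(times > t), numeric(1)))
})

test_that("log-rank is null for identical groups and symmetric in labels", {
  times <- c(3, 6, 8, 12, 15)
  events <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(times, times), c(events, events),
                     rep(c("A", "B"), each = 5))
  expect_lt(lr$chisq, 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)

  set.seed(8)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.8); g <- rep(c("high", "low"), 15)
  swap <- ifelse(g == "high", "low", "high")
  expect_equal(logrank_test(t2, e2, g)$chisq,
               logrank_test(t2, e2, swap)$chisq, tolerance = 1e-12)
})

test_that("log-rank chi-square equals brute-force hypergeometric summation", {
  # single event time: A all die at t=1, B all censored at t=2
  times <- c(rep(1, 10), rep(2, 10))
  events <- c(rep(TRUE, 10), rep(FALSE, 10))
  grp <- rep(c("A", "B"), each = 10)
  expect_equal(logrank_test(times, events, grp)$chisq,
               logrank_oracle(times, events, grp == "A"), tolerance = 1e-9)

  set.seed(17)
  for (i in 1:10) {
    t <- runif(24, 1, 100)   # continuous, tie-free
    e <- rbinom(24, 1, 0.7) == 1
    g <- rep(c("A", "B"), 12)
    if (sum(e) == 0) next
    expect_equal(logrank_test(t, e, g)$chisq, logrank_oracle(t, e, g == "A"),
                 tolerance = 1e-9)
  }
})

test_that("cox_fit recovers the hazard ratio direction and reports Wald stats", {
  set.seed(2)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.01 * exp(log(0.4) * x))
  c <- runif(n, 0, 250)
  d <- tibble::tibble(os_days = pmin(t, c), event = as.integer(t <= c),
                      high = x)
  fit <- cox_fit(d, covariates = "high")
  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_lt(abs(td$estimate - log(0.4)), 2.5 * td$std.error)
  expect_true(td$conf.low < td$hazard_ratio & td$hazard_ratio < td$conf.high)
  expect_true(fit$converged)
  g <- glance(fit)
  expect_equal(g$n, n)
})

test_that("cox_fit drops incomplete rows with a message and errors on separation", {
  d <- tibble::tibble(os_days = c(5, 10, 15, 20, 25, 30),
                      event = c(1, 1, 1, 1, 0, 1),
                      x = c(1, NA, 0, 1, 0, 0))
  expect_message(cox_fit(d, covariates = "x"), "dropped 1")

  # complete separation: all events in one arm, observed before the other
  sep <- tibble::tibble(
    os_days = c(1, 2, 3, 10, 11, 12),
    event = c(1, 1, 1, 0, 0, 0),
    x = c(1, 1, 1, 0, 0, 0)
  )
  expect_error(cox_fit(sep, covariates = "x"), "separation")
})

test_that("cox coefficient is unbiased with nominal CI coverage", {
  set.seed(55)
  true_betas <- c(-1, -0.5, 0, 0.5, 1)
  for (beta in true_betas) {
    est <- se <- numeric(100)
    for (r in 1:100) {
      x <- rbinom(400, 1, 0.5)
      t <- rexp(400, rate = 0.002 * exp(beta * x))
      c <- runif(400, 0, 1500)
      d <- tibble::tibble(os_days = pmin(t, c), event = as.integer(t <= c),
                          x = x)
      td <- tidy(cox_fit(d, covariates = "x"))
      est[r] <- td$estimate; se[r] <- td$std.error
    }
    expect_lt(abs(mean(est) - beta), 0.05)
    coverage <- mean(abs(est - beta) <= 1.96 * se)
    expect_gte(coverage, 0.90)
    expect_lte(coverage, 0.99)
  }
})

test_that("compare_survival reports sizes, HR direction and curves", {
  set.seed(12)
  n <- 120
  grp <- rep(c("high", "low"), each = n / 2)
  t <- rexp(n, 0.002 * exp(log(0.4) * (grp == "high")))
  d <- tibble::tibble(os_days = pmin(t, 900), event = as.integer(t <= 900),
                      group = c(grp[1:(n - 2)], "excluded", "excluded"))
  cmp <- compare_survival(d)
  tab <- tidy(cmp)
  expect_equal(tab$n_high + tab$n_low, n - 2)
  expect_lt(tab$hazard_ratio, 1)
  expect_true(all(cmp$curves$survival >= 0 & cmp$curves$survival <= 1))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 12), 0.12)
  expect_equal(bonferroni_adjust(0.2, 12), 1)
  expect_equal(bonferroni_adjust(0.03, 1), 0.03)
  expect_error(bonferroni_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("spearman correlation uses mid-ranks and the t approximation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)

  # exact rank arithmetic: sum of squared rank differences = 2
  res <- spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4), min_n = 4)
  expect_equal(res$rho, 1 - 6 * 2 / (4 * (4^2 - 1)))

  # agrees with the reference implementation (ties handled by mid-ranks)
  set.seed(9)
  a <- rpois(30, 4); b <- a + rpois(30, 6)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  mine <- spearman_corr(a, b)
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)

  # invariant under strictly monotone transforms
  expect_equal(spearman_corr(exp(a), log(b + 1))$rho, mine$rho)

  expect_error(spearman_corr(rep(1, 10), 1:10), "constant")
})

test_that("survival_screen returns one row per pair and flags degeneracies", {
  bundle <- simulate_cohort(sim_config(n_patients = 80, seed = 14))
  calls <- filter_mutation_calls(bundle$mutations)
  sg <- assign_subgroups(bundle$clinical, calls, bundle$expression)
  prof <- isotype_profiles(bundle$expression)
  data <- dplyr::left_join(bundle$clinical, prof,
                           by = c(patient_id = "sample_id")) |>
    dplyr::left_join(sg, by = "patient_id")

  metrics <- c("IGHG1_over_IGH", "IGH")
  screen <- survival_screen(data, metrics, m = 12)
  expect_equal(nrow(screen), 12 * length(metrics))
  ok <- !is.na(screen$p.value)
  expect_true(all(screen$p.adjusted[ok] >= screen$p.value[ok]))
  expect_true(all(screen$p.adjusted[ok] <= 1))
  # a subgroup with no members yields an NA row, not an error
  data$EMPTY <- FALSE
  s2 <- survival_screen(data, "IGH", subgroups = "EMPTY", m = 1)
  expect_true(is.na(s2$hazard_ratio))
})
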