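arm_data <- function(times, events = 1L, arm = "A") {
  tibble::tibble(animal_id = paste0(arm, seq_along(times)), arm = arm,
                 time_months = times, event = rep_len(events, length(times)))
}

test_that("km_median reduces to the empirical median on uncensored data", {
  d <- arm_data(c(24, 26, 28, 30, 31))
  expect_equal(km_median(d, "A"), 28)
  # even n: lower median (smallest time with survivor <= 0.5)
  expect_equal(km_median(arm_data(c(10, 20, 30, 40)), "A"), 20)
  expect_message(
    out <- km_median(arm_data(c(5, 6), events = 0L), "A"), "undefined")
  expect_true(is.na(out))
})

test_that("km_curve and km_median agree with a product-limit oracle", {
  set.seed(99)
  for (rep in 1:5) {
    t <- round(rweibull(40, 4, 26), 1)
    ev <- rbinom(40, 1, 0.8)
    if (sum(ev) == 0) ev[1] <- 1L
    d <- arm_data(t, ev)
    oracle <- km_oracle(t, ev)
    curve <- km_curve(d)
    at_deaths <- curve[curve$time %in% oracle$time & curve$n_event > 0, ]
    expect_equal(at_deaths$survival, oracle$surv)
    expect_equal(km_median(d, "A"), oracle$median)
    # KM curve is non-increasing and starts at/below 1
    expect_true(all(diff(curve$survival) <= 1e-12))
    expect_lte(max(curve$survival), 1)
  }
})

test_that("max_lifespan takes the longest observed death, excluding censoring", {
  d <- tibble::tibble(animal_id = 1:3, arm = "A",
                      time_months = c(24, 31, 33), event = c(1L, 1L, 0L))
  expect_equal(max_lifespan(d, "A"), 31)
  expect_equal(max_lifespan(arm_data(29.5), "A"), 29.5)
  set.seed(3)
  sim <- simulate_survival(30, 30, survival_params(seed = 3))
  veh <- sim[sim$arm == "Veh", ]
  expect_equal(max_lifespan(sim, "Veh"),
               max(veh$time_months[veh$event == 1]))
})

test_that("lifespan_change reproduces the published arithmetic", {
  med <- lifespan_change(25.95, 28.2)
  expect_equal(med$delta_months, 2.25)
  expect_equal(round(med$pct, 1), 8.7)
  mx <- lifespan_change(29.5, 33.6)
  expect_equal(mx$delta_months, 4.1)
  expect_equal(round(mx$pct, 1), 13.9)
  same <- lifespan_change(20, 20)
  expect_equal(same$delta_months, 0)
  expect_equal(same$pct, 0)
  expect_error(lifespan_change(0, 10), "reference_months")
})

test_that("logrank_test: identical arms give statistic 0, p = 1", {
  d <- dplyr::bind_rows(arm_data(c(10, 20, 30), arm = "A"),
                        arm_data(c(10, 20, 30), arm = "B"))
  lr <- logrank_test(d, "A", "B")
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(d, "A", "C"), "absent")
})

test_that("exact permutation p on the 2+2 example equals 2/6", {
  d <- dplyr::bind_rows(arm_data(c(1, 2), arm = "A"),
                        arm_data(c(3, 4), arm = "B"))
  lr <- logrank_test(d, "A", "B", exact = TRUE)
  expect_equal(lr$n_permutations, 6L)
  expect_equal(lr$p_exact, 2 / 6)
})

test_that("logrank agrees with survival::survdiff and is arm-symmetric", {
  set.seed(17)
  for (rep in 1:5) {
    d <- dplyr::bind_rows(
      arm_data(rweibull(25, 5, 25), rbinom(25, 1, 0.85), arm = "A"),
      arm_data(rweibull(25, 5, 28), rbinom(25, 1, 0.85), arm = "B"))
    lr <- logrank_test(d, "A", "B")
    sd_fit <- survival::survdiff(
      survival::Surv(time_months, event) ~ arm, data = d)
    expect_equal(lr$statistic, sd_fit$chisq, tolerance = 1e-10)
    expect_equal(lr$p_value,
                 pchisq(sd_fit$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    swapped <- logrank_test(d, "B", "A")
    expect_equal(swapped$statistic, lr$statistic)
    expect_equal(swapped$p_value, lr$p_value)
  }
})

test_that("a planted +2.25-month median shift is recovered at large n", {
  diffs <- purrr::map_dbl(1:10, function(s) {
    surv <- simulate_survival(
      200, 200,
      survival_params(baseline_median_months = 25.95,
                      treatment_median_shift_months = 2.25, seed = 500 + s))
    km_median(surv, "Hes") - km_median(surv, "Veh")
  })
  expect_lt(abs(mean(diffs) - 2.25), 0.5)
})

test_that("compare_lifespan bundles medians, maxima, and the log-rank test", {
  sim <- simulate_survival(60, 60, survival_params(seed = 21))
  cmp <- compare_lifespan(sim, "Veh", "Hes")
  g <- glance(cmp)
  expect_equal(g$delta_median_months,
               km_median(sim, "Hes") - km_median(sim, "Veh"))
  expect_equal(g$pct_median,
               100 * g$delta_median_months / km_median(sim, "Veh"))
  expect_equal(g$logrank_p, logrank_test(sim, "Veh", "Hes")$p_value)
  arms <- tidy(cmp)
  expect_equal(arms$arm, c("Veh", "Hes"))
  expect_equal(tidy(cmp$logrank)$p.value, g$logrank_p)
})
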