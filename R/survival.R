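#' Kaplan-Meier survival curve per arm
#'
#' Product-limit estimate per treatment arm via [survival::survfit()].
#'
#' @param data Tibble with `arm`, `time_months`, `event` (1 = death,
#'   0 = censored).
#' @param arms Optional subset of arm labels.
#' @return Tibble with `arm`, `time`, `n_risk`, `n_event`, `survival`; one
#'   row per distinct observed time per arm.
#' @export
km_curve <- function(data, arms = NULL) {
  data <- check_survival_data(data, arms)
  purrr::map_dfr(split(data, data$arm), function(d) {
    fit <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = d)
    tibble(arm = d$arm[1], time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, survival = fit$surv)
  })
}

#' Kaplan-Meier median lifespan
#'
#' The smallest time at which the KM survivor estimate drops to 0.5 or
#' below. With fully observed data this is the empirical median of the death
#' times (lower median for even n). An arm with no events has no defined
#' median and returns `NA`.
#'
#' @inheritParams km_curve
#' @param arm Single arm label.
#' @return Median lifespan in months, or `NA_real_` when undefined.
#' @export
km_median <- function(data, arm) {
  curve <- km_curve(data, arms = arm)
  if (sum(curve$n_event) == 0L) {
    inform(sprintf("Arm '%s' has no observed deaths; KM median undefined.", arm))
    return(NA_real_)
  }
  below <- curve$time[curve$survival <= 0.5 + 1e-12]
  if (length(below) == 0L) return(NA_real_)
  min(below)
}

#' Maximum lifespan of an arm
#'
#' The longest *observed* death time; censored follow-up times are excluded.
#'
#' @inheritParams km_median
#' @return Months, or `NA_real_` if the arm has no events.
#' @export
max_lifespan <- function(data, arm) {
  data <- check_survival_data(data, arms = arm)
  deaths <- data$time_months[data$event == 1]
  if (length(deaths) == 0L) {
    inform(sprintf("Arm '%s' has no observed deaths; maximum lifespan undefined.", arm))
    return(NA_real_)
  }
  max(deaths)
}

#' Absolute and percentage lifespan change
#'
#' @param reference_months Reference (e.g. vehicle) lifespan summary, > 0.
#' @param treated_months Treated-arm lifespan summary.
#' @return Tibble with `delta_months` (treated - reference) and `pct`
#'   (100 * delta / reference), both at full precision; round `pct` to one
#'   decimal for display.
#' @examples
#' lifespan_change(25.95, 28.2) # +2.25 months, 8.7%
#' @export
lifespan_change <- function(reference_months, treated_months) {
  check_positive(reference_months, "reference_months")
  if (!is.numeric(treated_months) || !is.finite(treated_months)) {
    abort("`treated_months` must be a finite number.")
  }
  delta <- treated_months - reference_months
  tibble(delta_months = delta, pct = 100 * delta / reference_months)
}

# Unweighted log-rank statistic (hypergeometric variance) for a two-level
# group vector; returns observed-minus-expected for group 1 and its variance.
logrank_uv <- function(time, event, grp1) {
  death_times <- sort(unique(time[event == 1]))
  u <- 0; v <- 0
  for (t in death_times) {
    at_risk <- time >= t
    nt <- sum(at_risk)
    n1t <- sum(at_risk & grp1)
    dt <- sum(event == 1 & time == t)
    d1t <- sum(event == 1 & time == t & grp1)
    u <- u + d1t - dt * n1t / nt
    if (nt > 1) {
      v <- v + dt * (n1t / nt) * (1 - n1t / nt) * (nt - dt) / (nt - 1)
    }
  }
  c(u = u, v = v)
}

#' Log-rank (Mantel-Cox) comparison of two survival arms
#'
#' Standard unweighted log-rank test with ties handled by the hypergeometric
#' variance, referred to a 1-df chi-square. With `exact = TRUE` an exact
#' label-permutation p-value is added: the proportion of all assignments of
#' arm labels to animals whose chi-square statistic is at least the observed
#' one (suitable for small cohorts; requires `choose(n, n_A) <= max_permutations`).
#'
#' @inheritParams km_curve
#' @param arm_a,arm_b The two arm labels to compare.
#' @param exact Also compute the exact permutation p-value.
#' @param max_permutations Guard on the number of label assignments
#'   enumerated for the exact test.
#' @return A `logrank_test` object with `statistic` (chi-square), `df`,
#'   `p_value`, per-arm observed/expected event counts, and `p_exact` when
#'   requested. [tidy()] and [glance()] methods return one-row tibbles.
#' @export
logrank_test <- function(data, arm_a, arm_b, exact = FALSE,
                         max_permutations = 20000) {
  data <- check_survival_data(data, arms = c(arm_a, arm_b))
  if (sum(data$event) == 0L) abort("No observed events in the two arms.")
  grp1 <- data$arm == arm_a
  uv <- logrank_uv(data$time_months, data$event, grp1)
  stat <- if (uv["v"] > 0) unname(uv["u"]^2 / uv["v"]) else 0
  p <- if (uv["v"] > 0) pchisq(stat, df = 1, lower.tail = FALSE) else 1

  expected_a <- sum(data$event[grp1]) - uv["u"]
  res <- structure(
    list(statistic = stat, df = 1L, p_value = p,
         arms = tibble(arm = c(arm_a, arm_b),
                       n = c(sum(grp1), sum(!grp1)),
                       observed = c(sum(data$event[grp1]),
                                    sum(data$event[!grp1])),
                       expected = c(unname(expected_a),
                                    sum(data$event) - unname(expected_a))),
         method = "log-rank (Mantel-Cox)"),
    class = "logrank_test"
  )
  if (exact) {
    n <- nrow(data); n1 <- sum(grp1)
    n_perm <- choose(n, n1)
    if (n_perm > max_permutations) {
      abort(sprintf("Exact test needs %d label assignments (> %d); use the chi-square p instead.",
                    n_perm, max_permutations))
    }
    combos <- combn(n, n1)
    stats <- apply(combos, 2L, function(ix) {
      g <- logical(n); g[ix] <- TRUE
      uv_p <- logrank_uv(data$time_months, data$event, g)
      if (uv_p["v"] > 0) uv_p["u"]^2 / uv_p["v"] else 0
    })
    res$p_exact <- mean(stats >= stat - 1e-12)
    res$n_permutations <- ncol(combos)
  }
  res
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("%s: chi-square = %.4g on %d df, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.null(x$p_exact)) {
    cat(sprintf("exact permutation p = %.4g (%d assignments)\n",
                x$p_exact, x$n_permutations))
  }
  print(x$arms)
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         p.exact = x$p_exact %||% NA_real_)
}

#' @export
glance.logrank_test <- function(x, ...) tidy(x)

#' Lifespan comparison between two arms
#'
#' Bundles the Fig.-1-style arithmetic for a two-arm lifespan study: KM
#' median and maximum lifespan per arm, absolute and percentage change of
#' each (treated relative to reference), and the log-rank test.
#'
#' @inheritParams km_curve
#' @param reference_arm,comparison_arm Arm labels; percentages are relative
#'   to the reference arm.
#' @param exact Passed to [logrank_test()].
#' @return A `lifespan_summary` object; `tidy()` gives the per-arm table,
#'   `glance()` the one-row comparison (deltas, percentages, log-rank p).
#' @examples
#' surv <- simulate_survival(50, 50, survival_params(seed = 1))
#' glance(compare_lifespan(surv, "Veh", "Hes"))
#' @export
compare_lifespan <- function(data, reference_arm, comparison_arm,
                             exact = FALSE) {
  data <- check_survival_data(data, arms = c(reference_arm, comparison_arm))
  arms <- tibble(
    arm = c(reference_arm, comparison_arm),
    n = c(sum(data$arm == reference_arm), sum(data$arm == comparison_arm)),
    km_median_months = c(km_median(data, reference_arm),
                         km_median(data, comparison_arm)),
    max_lifespan_months = c(max_lifespan(data, reference_arm),
                            max_lifespan(data, comparison_arm))
  )
  med <- lifespan_change(arms$km_median_months[1], arms$km_median_months[2])
  mx <- lifespan_change(arms$max_lifespan_months[1],
                        arms$max_lifespan_months[2])
  lr <- logrank_test(data, reference_arm, comparison_arm, exact = exact)
  structure(
    list(arms = arms,
         comparison = tibble(
           reference = reference_arm, comparison = comparison_arm,
           delta_median_months = med$delta_months, pct_median = med$pct,
           delta_max_months = mx$delta_months, pct_max = mx$pct,
           logrank_chisq = lr$statistic, logrank_p = lr$p_value,
           logrank_p_exact = lr$p_exact %||% NA_real_),
         logrank = lr),
    class = "lifespan_summary"
  )
}

#' @export
print.lifespan_summary <- function(x, ...) {
  print(x$arms)
  with(x$comparison, cat(sprintf(
    "median: %+.2f months (%+.1f%%); maximum: %+.2f months (%+.1f%%); log-rank p = %.3g\n",
    delta_median_months, pct_median, delta_max_months, pct_max, logrank_p)))
  invisible(x)
}

#' @export
tidy.lifespan_summary <- function(x, ...) x$arms

#' @export
glance.lifespan_summary <- function(x, ...) x$comparison

check_survival_data <- function(data, arms = NULL) {
  check_columns(data, c("arm", "time_months", "event"), "survival data")
  if (any(!is.finite(data$time_months)) || any(data$time_months <= 0)) {
    abort("`time_months` must be positive and finite.")
  }
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  if (!is.null(arms)) {
    absent <- setdiff(arms, unique(data$arm))
    if (length(absent)) {
      abort(sprintf("Arm(s) absent from data: %s.",
                    paste(absent, collapse = ", ")))
    }
    data <- data[data$arm %in% arms, , drop = FALSE]
  }
  if (nrow(data) == 0L) abort("No animals in the requested arm(s).")
  data
}
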