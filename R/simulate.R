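#' Vectorized Monte-Carlo simulation of adaptive two-stage trials
#'
#' Simulates complete two-stage trials under a blinded reassessment rule by
#' drawing per-group sufficient statistics from their exact sampling
#' distributions: stage means from \eqn{N(\mu_i, \sigma^2/n)} and
#' within-group sums of squares from \eqn{\sigma^2 \chi^2_{n-1}}. This is
#' identical in distribution to simulating raw observations (a raw-observation
#' reference path is kept in [simulate_trials_raw()]) but orders of magnitude
#' faster. Each replicate computes the blinded interim variance, applies the
#' rule, recruits \code{n2} patients per group (by default the ceiling of the
#' real-valued rule output, clamped to the design's range), and produces the
#' final estimates and confidence bounds.
#'
#' @param design A [bssr_design()].
#' @param scenario A [bssr_scenario()] (true delta and sigma).
#' @param rule A [reassessment_rule()] (or any vectorized function of
#'   \code{s1_os2} returning sizes within the design's range).
#' @param nrep Number of simulated trials, >= 1.
#' @param seed Optional integer seed; when given, the stream is reproducible
#'   (identical seed and configuration give bit-identical output).
#' @param rounding \code{"ceiling"} (default: integer recruitment via
#'   [realized_n2()]) or \code{"none"} (keep the real-valued rule output;
#'   fractional \code{n2} uses a chi-square with fractional degrees of
#'   freedom \code{max(n2 - 1, 0)}, which matches the analytic bias integrals
#'   for rules with values outside (0, 1) and serves as their oracle).
#' @return A data frame with one row per trial and columns \code{s1_os2,
#'   n2, delta_bar, s2, lower, upper, ci_lo, ci_hi} (the fixed outcome-batch
#'   column order).
#' @seealso [summarize_trials()], [simulate_summary()]
#' @export
simulate_trials <- function(design, scenario, rule, nrep, seed = NULL,
                            rounding = c("ceiling", "none")) {
  stopifnot(inherits(design, "bssr_design"),
            inherits(scenario, "bssr_scenario"))
  rounding <- match.arg(rounding)
  if (nrep < 1) stop("'nrep' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta

  ma1 <- stats::rnorm(nrep, 0, sigma / sqrt(n1))
  mb1 <- stats::rnorm(nrep, delta, sigma / sqrt(n1))
  ssa1 <- sigma^2 * stats::rchisq(nrep, n1 - 1)
  ssb1 <- sigma^2 * stats::rchisq(nrep, n1 - 1)
  s1os2 <- (ssa1 + ssb1 + (n1 / 2) * (mb1 - ma1)^2) / (2 * n1 - 1)

  n2 <- rule(s1os2)
  if (rounding == "ceiling") n2 <- realized_n2(n2, design)
  n <- n1 + n2

  delta_bar <- mb1 - ma1
  ss_tot <- ssa1 + ssb1
  pos <- which(n2 > 0)
  if (length(pos)) {
    n2p <- n2[pos]
    ma2 <- stats::rnorm(length(pos), 0, sigma / sqrt(n2p))
    mb2 <- stats::rnorm(length(pos), delta, sigma / sqrt(n2p))
    ssa2 <- sigma^2 * stats::rchisq(length(pos), pmax(n2p - 1, 0))
    ssb2 <- sigma^2 * stats::rchisq(length(pos), pmax(n2p - 1, 0))
    w <- n1 * n2p / (n1 + n2p)
    ss_tot[pos] <- ss_tot[pos] + ssa2 + ssb2 +
      w * ((ma1[pos] - ma2)^2 + (mb1[pos] - mb2)^2)
    delta_bar[pos] <- (n1 * mb1[pos] + n2p * mb2) / (n1 + n2p) -
      (n1 * ma1[pos] + n2p * ma2) / (n1 + n2p)
  }
  s2 <- ss_tot / (2 * n - 2)

  se <- sqrt(s2 * 2 / n)
  t1 <- stats::qt(1 - design$alpha, df = 2 * n - 2)
  data.frame(s1_os2 = s1os2, n2 = n2, delta_bar = delta_bar, s2 = s2,
             lower = delta_bar - t1 * se, upper = delta_bar + t1 * se,
             ci_lo = delta_bar - t1 * se, ci_hi = delta_bar + t1 * se)
}

#' Raw-observation reference simulator
#'
#' Slow per-observation counterpart of [simulate_trials()], drawing
#' individual normal observations and running them through
#' [stage_from_data()], [trial_outcome()] and the rule. Used as the
#' distributional oracle for the sufficient-statistic path; intended for
#' small \code{nrep} only.
#'
#' @inheritParams simulate_trials
#' @return Same data frame layout as [simulate_trials()].
#' @export
simulate_trials_raw <- function(design, scenario, rule, nrep, seed = NULL) {
  stopifnot(inherits(design, "bssr_design"),
            inherits(scenario, "bssr_scenario"))
  if (!is.null(seed)) set.seed(seed)
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta
  rows <- vector("list", nrep)
  for (i in seq_len(nrep)) {
    a1 <- stats::rnorm(n1, 0, sigma)
    b1 <- stats::rnorm(n1, delta, sigma)
    st1 <- stage_from_data(a1, b1)
    n2 <- realized_n2(rule(blinded_variance(st1)), design)
    st2 <- if (n2 > 0)
      stage_from_data(stats::rnorm(n2, 0, sigma), stats::rnorm(n2, delta, sigma))
    else NULL
    out <- trial_outcome(st1, st2, design)
    rows[[i]] <- as.data.frame(unclass(out))
  }
  do.call(rbind, rows)
}

#' Summarize simulated trials into bias, coverage and variance diagnostics
#'
#' Computes, with Monte-Carlo standard errors: the bias of the final mean and
#' variance estimators; empirical coverage of the lower, upper and two-sided
#' confidence bounds (closed-bound convention, \code{lower <= delta} etc.);
#' the average estimated variance of the mean \eqn{\hat S_e^2 = 2 S^2 / n},
#' the average fixed-design variance \eqn{\sigma_f^2 = 2 \sigma^2 / n} at the
#' realized sizes, and the actual empirical variance of
#' \eqn{\bar\Delta} across replicates; plus the mean and standard deviation
#' of the realized second-stage size.
#'
#' @param outcomes Data frame from [simulate_trials()] (>= 2 rows).
#' @param design A [bssr_design()].
#' @param scenario The [bssr_scenario()] the trials were simulated under.
#' @return An object of class \code{"bssr_sim_summary"}.
#' @export
summarize_trials <- function(outcomes, design, scenario) {
  stopifnot(inherits(design, "bssr_design"),
            inherits(scenario, "bssr_scenario"))
  m <- nrow(outcomes)
  if (is.null(m) || m < 2) stop("need at least 2 outcomes", call. = FALSE)
  delta <- scenario$delta
  sigma2 <- scenario$sigma^2
  n <- design$n1 + outcomes$n2
  prop <- function(x) {
    p <- mean(x)
    c(p, sqrt(p * (1 - p) / m))
  }
  cl <- prop(outcomes$lower <= delta)
  cu <- prop(outcomes$upper >= delta)
  ct <- prop(outcomes$ci_lo <= delta & delta <= outcomes$ci_hi)
  structure(list(
    n_reps = m,
    bias_mean = mean(outcomes$delta_bar) - delta,
    bias_mean_se = stats::sd(outcomes$delta_bar) / sqrt(m),
    bias_var = mean(outcomes$s2) - sigma2,
    bias_var_se = stats::sd(outcomes$s2) / sqrt(m),
    cover_lower = cl[1], cover_lower_se = cl[2],
    cover_upper = cu[1], cover_upper_se = cu[2],
    cover_two_sided = ct[1], cover_two_sided_se = ct[2],
    mean_est_var_hat = mean(2 * outcomes$s2 / n),
    mean_fixed_var = mean(2 * sigma2 / n),
    actual_var_mean = stats::var(outcomes$delta_bar),
    mean_n2 = mean(outcomes$n2),
    sd_n2 = stats::sd(outcomes$n2)
  ), class = "bssr_sim_summary")
}

#' @export
print.bssr_sim_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary over %d trials\n", x$n_reps))
  cat(sprintf("  mean bias:      %+.5f (se %.5f)\n",
              x$bias_mean, x$bias_mean_se))
  cat(sprintf("  variance bias:  %+.5f (se %.5f)\n",
              x$bias_var, x$bias_var_se))
  cat(sprintf("  coverage lower/upper/two-sided: %.4f / %.4f / %.4f\n",
              x$cover_lower, x$cover_upper, x$cover_two_sided))
  cat(sprintf("  mean n2: %.2f (sd %.2f)\n", x$mean_n2, x$sd_n2))
  invisible(x)
}

#' One-call simulation summary
#'
#' @inheritParams simulate_trials
#' @return A \code{"bssr_sim_summary"} (see [summarize_trials()]).
#' @export
simulate_summary <- function(design, scenario, rule, nrep, seed = NULL,
                             rounding = c("ceiling", "none")) {
  summarize_trials(
    simulate_trials(design, scenario, rule, nrep, seed, rounding),
    design, scenario)
}
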