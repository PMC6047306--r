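#' Final point estimates after both stages
#'
#' Combines the per-stage sufficient statistics into the standard unblinded
#' end-of-trial estimates: the mean difference \eqn{\bar\Delta} over all
#' \code{n = n1 + n2} observations per group and the pooled variance
#' \eqn{S^2} with \code{2n - 2} degrees of freedom (within-group sums of
#' squares about each group's overall mean). Per group the stages merge via
#' the exact identity
#' \deqn{SS = SS_1 + SS_2 + \frac{n_1 n_2}{n_1 + n_2}
#'   (\bar X_1 - \bar X_2)^2.}
#' With an empty second stage (\code{n2 = 0}) the stage-1 two-sample
#' estimates are returned with \code{2 n1 - 2} degrees of freedom.
#'
#' @param stage1 A [stage_summary()] with \code{n >= 2}.
#' @param stage2 A [stage_summary()] with \code{n >= 0}; \code{NULL} is
#'   treated as \code{n2 = 0}.
#' @return A list with \code{delta_bar}, \code{s2}, \code{n1}, \code{n2},
#'   \code{n} and \code{df = 2 n - 2}.
#' @export
final_estimates <- function(stage1, stage2 = NULL) {
  stopifnot(inherits(stage1, "bssr_stage"))
  n1 <- stage1$n
  if (n1 < 2)
    stop("final estimation requires a first-stage per-group size n1 >= 2",
         call. = FALSE)
  if (is.null(stage2)) stage2 <- stage_summary(0, 0, 0, 0, 0)
  stopifnot(inherits(stage2, "bssr_stage"))
  n2 <- stage2$n
  n <- n1 + n2
  if (n2 == 0) {
    delta_bar <- stage1$mean_b - stage1$mean_a
    s2 <- (stage1$ss_a + stage1$ss_b) / (2 * n1 - 2)
  } else {
    w <- n1 * n2 / n
    mean_a <- (n1 * stage1$mean_a + n2 * stage2$mean_a) / n
    mean_b <- (n1 * stage1$mean_b + n2 * stage2$mean_b) / n
    ss_a <- stage1$ss_a + stage2$ss_a +
      w * (stage1$mean_a - stage2$mean_a)^2
    ss_b <- stage1$ss_b + stage2$ss_b +
      w * (stage1$mean_b - stage2$mean_b)^2
    delta_bar <- mean_b - mean_a
    s2 <- (ss_a + ss_b) / (2 * n - 2)
  }
  list(delta_bar = delta_bar, s2 = s2, n1 = n1, n2 = n2, n = n,
       df = 2L * n - 2L)
}

#' Fixed-sample t confidence bounds for the mean difference
#'
#' One-sided lower and upper \code{1 - alpha} bounds of the classical pooled
#' two-sample t procedure, evaluated at the realized total per-group size
#' \code{n}:
#' \deqn{\bar\Delta \mp t_{2n-2,\,1-\alpha}\; S \sqrt{2/n},}
#' and the two-sided interval formed as their intersection, which has
#' confidence level \code{1 - 2 alpha} (95\% for the default one-sided
#' \code{alpha = 0.025}). Pairing 97.5\% one-sided bounds with the 95\%
#' two-sided interval is the standard convention and makes the two-sided
#' non-coverage the exact sum of the two disjoint one-sided non-coverage
#' events. These are the intervals a fixed design would report; their actual
#' coverage under data-dependent \code{n} is exactly what the bias/coverage
#' machinery of this package quantifies.
#'
#' @param estimates A list as returned by [final_estimates()] (fields
#'   \code{delta_bar}, \code{s2}, \code{n}, \code{df}).
#' @param design A [bssr_design()] supplying \code{alpha}.
#' @return A list with \code{lower}, \code{upper} (one-sided \code{1 - alpha}
#'   bounds), \code{ci_lo}, \code{ci_hi} (two-sided \code{1 - 2 alpha}
#'   interval) and \code{degenerate} (\code{TRUE} with a warning when
#'   \code{s2 = 0}, in which case all bounds collapse to \code{delta_bar}).
#' @export
confidence_bounds <- function(estimates, design) {
  stopifnot(inherits(design, "bssr_design"))
  n <- estimates$n
  if (n < 2) stop("confidence bounds require n = n1 + n2 >= 2", call. = FALSE)
  s2 <- estimates$s2
  if (s2 < 0) stop("'s2' must be non-negative", call. = FALSE)
  degenerate <- s2 == 0
  if (degenerate)
    warning("zero variance estimate: confidence bounds degenerate to a point")
  se <- sqrt(s2 * 2 / n)
  t1 <- stats::qt(1 - design$alpha, df = estimates$df)
  d <- estimates$delta_bar
  list(lower = d - t1 * se, upper = d + t1 * se,
       ci_lo = d - t1 * se, ci_hi = d + t1 * se,
       degenerate = degenerate)
}

#' Complete trial outcome from per-stage statistics
#'
#' Convenience wrapper running the full end-of-trial pipeline: blinded
#' interim variance, final estimates and confidence bounds.
#'
#' @inheritParams final_estimates
#' @param design A [bssr_design()].
#' @return An object of class \code{"bssr_outcome"}: a list with
#'   \code{s1_os2}, \code{n2}, \code{delta_bar}, \code{s2}, \code{lower},
#'   \code{upper}, \code{ci_lo}, \code{ci_hi}.
#' @export
trial_outcome <- function(stage1, stage2, design) {
  est <- final_estimates(stage1, stage2)
  cb <- confidence_bounds(est, design)
  structure(list(s1_os2 = blinded_variance(stage1), n2 = est$n2,
                 delta_bar = est$delta_bar, s2 = est$s2,
                 lower = cb$lower, upper = cb$upper,
                 ci_lo = cb$ci_lo, ci_hi = cb$ci_hi),
            class = "bssr_outcome")
}

#' @export
print.bssr_outcome <- function(x, ...) {
  cat("Two-stage trial outcome\n")
  cat(sprintf("  interim S1,OS^2: %.4g   realized n2: %g\n", x$s1_os2, x$n2))
  cat(sprintf("  delta_bar: %.4g   S^2: %.4g\n", x$delta_bar, x$s2))
  cat(sprintf("  one-sided bounds: [%.4g, %.4g]\n", x$lower, x$upper))
  cat(sprintf("  two-sided interval: [%.4g, %.4g]\n", x$ci_lo, x$ci_hi))
  invisible(x)
}

# fixed column order for outcome batches (documented external interface)
.outcome_cols <- c("s1_os2", "n2", "delta_bar", "s2",
                   "lower", "upper", "ci_lo", "ci_hi")

#' Write a batch of trial outcomes as CSV
#'
#' Columns, in fixed order: \code{s1_os2, n2, delta_bar, s2, lower, upper,
#' ci_lo, ci_hi}.
#'
#' @param outcomes A data frame of outcomes (e.g. from [simulate_trials()]).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  utils::write.csv(outcomes[, .outcome_cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}
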