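#' Two-stage trial design with blinded sample size reassessment
#'
#' Bundles the pre-specified parameters of a two-stage parallel-group
#' superiority trial in which the second-stage per-group sample size is
#' recalculated at a blinded interim analysis: the one-sided significance
#' level, the target power, the effect size \code{delta0} the trial is powered
#' for, the a-priori standard deviation \code{sigma0} used at the planning
#' stage, the first-stage per-group size \code{n1}, and lower/upper caps on
#' the reassessed second-stage per-group size.
#'
#' @param alpha One-sided significance level, in (0, 0.5).
#' @param power Target power 1 - beta, in (0, 1).
#' @param delta0 Planning effect size (difference of means, outcome units),
#'   must be positive.
#' @param sigma0 A-priori standard deviation (outcome units), must be
#'   positive.
#' @param n1 First-stage per-group sample size, integer >= 2.
#' @param n2min Minimum second-stage per-group size, integer >= 0.
#' @param n2max Maximum second-stage per-group size; may be \code{Inf} for
#'   unrestricted reassessment. Must exceed \code{n2min}.
#' @return An object of class \code{"bssr_design"}: a list with the validated
#'   fields above plus \code{z_factor}, the z-test sample size multiplier
#'   \eqn{2 (z_{1-\alpha} + z_{1-\beta})^2}.
#' @examples
#' d <- bssr_design(alpha = 0.025, power = 0.8, delta0 = 5.5, sigma0 = 8,
#'                  n1 = 15)
#' fixed_design_n(d)
#' @export
bssr_design <- function(alpha = 0.025, power = 0.8, delta0, sigma0,
                        n1, n2min = 0, n2max = Inf) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be a single value in (0, 0.5)", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || power <= 0 || power >= 1)
    stop("'power' must be a single value in (0, 1)", call. = FALSE)
  if (!is.numeric(delta0) || length(delta0) != 1L || delta0 <= 0)
    stop("'delta0' must be a single positive value", call. = FALSE)
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 <= 0)
    stop("'sigma0' must be a single positive value", call. = FALSE)
  if (!is.numeric(n1) || length(n1) != 1L || n1 < 2 || n1 != floor(n1))
    stop("'n1' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(n2min) || length(n2min) != 1L || n2min < 0 ||
      n2min != floor(n2min))
    stop("'n2min' must be a single integer >= 0", call. = FALSE)
  if (!is.numeric(n2max) || length(n2max) != 1L ||
      (is.finite(n2max) && n2max != floor(n2max)))
    stop("'n2max' must be a single integer or Inf", call. = FALSE)
  if (n2min >= n2max)
    stop("'n2min' must be strictly smaller than 'n2max'", call. = FALSE)
  structure(
    list(alpha = alpha, power = power, delta0 = delta0, sigma0 = sigma0,
         n1 = as.integer(n1), n2min = n2min, n2max = n2max,
         z_factor = 2 * (stats::qnorm(1 - alpha) + stats::qnorm(power))^2),
    class = "bssr_design")
}

#' @export
print.bssr_design <- function(x, ...) {
  cat("Two-stage design with blinded sample size reassessment\n")
  cat(sprintf("  one-sided alpha: %g   target power: %g\n", x$alpha, x$power))
  cat(sprintf("  planning effect delta0: %g   a-priori sd sigma0: %g\n",
              x$delta0, x$sigma0))
  cat(sprintf("  first-stage n1: %d per group   stage-2 range: [%g, %g]\n",
              x$n1, x$n2min, x$n2max))
  invisible(x)
}

#' True state of nature for bias and coverage evaluation
#'
#' A scenario fixes the true mean difference \code{delta = mu_b - mu_a} and
#' the true common standard deviation \code{sigma} of the normal endpoint
#' under which the operating characteristics of a design are evaluated.
#'
#' @param delta True effect size (outcome units); any real number.
#' @param sigma True common standard deviation (outcome units), positive.
#' @return An object of class \code{"bssr_scenario"}.
#' @export
bssr_scenario <- function(delta, sigma) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("'delta' must be a single finite value", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 ||
      !is.finite(sigma))
    stop("'sigma' must be a single positive finite value", call. = FALSE)
  structure(list(delta = delta, sigma = sigma), class = "bssr_scenario")
}

#' @export
print.bssr_scenario <- function(x, ...) {
  cat(sprintf("Scenario: true delta = %g, true sigma = %g\n",
              x$delta, x$sigma))
  invisible(x)
}

#' Per-stage sufficient statistics of a two-arm sample
#'
#' Stores per-group sample means and within-group sums of squared deviations
#' for one stage of the trial; these are sufficient for all estimators used
#' here, so raw observation vectors never need to be retained.
#'
#' @param mean_a,mean_b Per-group sample means (outcome units).
#' @param ss_a,ss_b Per-group within-group sums of squared deviations about
#'   the own group mean; must be >= 0 and exactly 0 when \code{n <= 1}.
#' @param n Per-group sample size for this stage (integer >= 0).
#' @return An object of class \code{"bssr_stage"}.
#' @seealso [stage_from_data()] to compute the statistics from raw vectors.
#' @export
stage_summary <- function(mean_a, mean_b, ss_a, ss_b, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n))
    stop("'n' must be a single integer >= 0", call. = FALSE)
  if (ss_a < 0 || ss_b < 0)
    stop("sums of squares must be non-negative", call. = FALSE)
  if (n <= 1 && (ss_a != 0 || ss_b != 0))
    stop("with n <= 1 the within-group sums of squares must be 0",
         call. = FALSE)
  structure(list(mean_a = mean_a, mean_b = mean_b,
                 ss_a = ss_a, ss_b = ss_b, n = as.integer(n)),
            class = "bssr_stage")
}

#' @rdname stage_summary
#' @param a,b Numeric vectors of raw observations for groups a and b (equal
#'   length, the per-group stage size).
#' @export
stage_from_data <- function(a, b) {
  if (length(a) != length(b))
    stop("groups must have equal per-group size", call. = FALSE)
  n <- length(a)
  ss <- function(x) if (length(x) > 1L) sum((x - mean(x))^2) else 0
  stage_summary(mean_a = if (n) mean(a) else NA_real_,
                mean_b = if (n) mean(b) else NA_real_,
                ss_a = ss(a), ss_b = ss(b), n = n)
}

#' Fixed-design sample size of the one-sided z-test
#'
#' Per-group sample size of the classical fixed design powered for effect
#' \code{delta0} at a-priori standard deviation \code{sigma0}, based on the
#' normal approximation:
#' \eqn{n = \lceil 2 (z_{1-\alpha} + z_{1-\beta})^2 \sigma_0^2 /
#' \delta_0^2 \rceil}. The conventional internal-pilot split allocates half
#' of it (rounded up) to the first stage.
#'
#' @param design A [bssr_design()].
#' @return A list with \code{n} (fixed-design per-group size) and \code{n1}
#'   (first-stage per-group size, half of \code{n} rounded up).
#' @examples
#' d <- bssr_design(delta0 = 5.5, sigma0 = 8, n1 = 15)
#' fixed_design_n(d)$n   # 34 per group
#' @export
fixed_design_n <- function(design) {
  stopifnot(inherits(design, "bssr_design"))
  n <- ceiling(design$z_factor * design$sigma0^2 / design$delta0^2)
  list(n = as.integer(n), n1 = as.integer(ceiling(n / 2)))
}
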