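#' @title Exact bias of the final estimators under blinded reassessment
#' @description
#' The final mean-difference estimator \eqn{\bar\Delta} and pooled variance
#' estimator \eqn{S^2} of a two-stage design are biased whenever the realized
#' sample size depends on the data through a non-constant blinded rule
#' \eqn{n_2(S_{1,OS}^2)}. Both biases admit exact double-integral
#' representations over the joint distribution of the stage-1 pooled
#' within-group variance \eqn{q} (scaled chi-square, \eqn{2 n_1 - 2} df) and
#' the stage-1 mean difference (normal, variance \eqn{2\sigma^2/n_1}), with
#' the rule entering through
#' \deqn{r(q, y) = n_2\!\left(\tfrac{2(n_1-1)}{2n_1-1} q +
#'   \tfrac{n_1}{2(2n_1-1)} y^2\right) / n_1,}
#' the relative second-stage size at interim variance reconstructed from
#' \eqn{(q, y)}. These functions evaluate the integrals by nested adaptive
#' quadrature; inside the integrands the rule is used real-valued (no
#' rounding), matching the analytic derivations.
#' @name bias_exact
NULL

# nested adaptive quadrature: outer over the stage-1 pooled variance q
# (domain truncated at the 1e-12 chi-square quantiles), inner over the
# stage-1 mean deviation t (truncated at +-10 sd)
.bias_quad <- function(design, scenario, inner_fn, rel.tol) {
  n1 <- design$n1
  sigma <- scenario$sigma
  gam <- (2 * n1 - 2) / sigma^2
  qlo <- stats::qchisq(1e-12, 2 * n1 - 2) / gam
  qhi <- stats::qchisq(1 - 1e-12, 2 * n1 - 2) / gam
  outer_fn <- function(q)
    vapply(q, inner_fn, numeric(1)) * stats::dchisq(q * gam, 2 * n1 - 2) * gam
  res <- tryCatch(
    stats::integrate(outer_fn, qlo, qhi, rel.tol = rel.tol,
                     subdivisions = 500L, stop.on.error = FALSE),
    error = function(e)
      stop("quadrature failed: ", conditionMessage(e), call. = FALSE))
  structure(list(value = res$value, abs_error = res$abs.error,
                 method = "quadrature"),
            class = "bssr_bias")
}

#' @export
print.bssr_bias <- function(x, ...) {
  cat(sprintf("Bias value %+.6g (error estimate %.2g, method: %s)\n",
              x$value, x$abs_error, x$method))
  invisible(x)
}

# rule on the (q, y) parameterization: relative second-stage size r(q, y)
.r_of <- function(rule, n1) {
  a <- 2 * (n1 - 1) / (2 * n1 - 1)
  b <- n1 / (2 * (2 * n1 - 1))
  function(q, y) rule(a * q + b * y^2) / n1
}

#' @describeIn bias_exact Bias \eqn{E(\bar\Delta) - \delta} of the final
#'   mean-difference estimator. The integrand is folded over the sign of the
#'   stage-1 mean deviation \eqn{t}, so it vanishes identically at
#'   \eqn{\delta = 0} (the estimator is exactly unbiased under the null);
#'   for monotone rules the bias is negative for \eqn{\delta > 0}, positive
#'   for \eqn{\delta < 0}, antisymmetric in \eqn{\delta}, and tends to 0 as
#'   \eqn{|\delta| \to \infty} when the rule is unbounded.
#' @param design A [bssr_design()].
#' @param rule A [reassessment_rule()] (used real-valued).
#' @param scenario A [bssr_scenario()].
#' @param rel.tol Relative tolerance of the adaptive quadrature.
#' @return A \code{"bssr_bias"}: list with \code{value}, \code{abs_error}
#'   (quadrature error estimate) and \code{method}.
#' @export
mean_bias_exact <- function(design, rule, scenario, rel.tol = 1e-8) {
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta
  rfun <- .r_of(rule, n1)
  sd1 <- sigma * sqrt(2 / n1)
  inner <- function(q) {
    stats::integrate(function(t) {
      rp <- rfun(q, delta + t)
      rm <- rfun(q, delta - t)
      t * (rm - rp) / ((1 + rp) * (1 + rm)) * stats::dnorm(t, 0, sd1)
    }, 0, 10 * sd1, rel.tol = rel.tol, subdivisions = 500L,
    stop.on.error = FALSE)$value
  }
  .bias_quad(design, scenario, inner, rel.tol)
}

#' @describeIn bias_exact Bias \eqn{E(S^2) - \sigma^2} of the final pooled
#'   variance estimator. Conditional on the stage-1 pooled variance \eqn{q}
#'   and mean deviation \eqn{t} (and with \eqn{n = n_1(1 + r)}), the bias
#'   contribution is
#'   \deqn{\frac{(2n_1-2)(q - \sigma^2) +
#'     \frac{n_2}{n}\left(\frac{n_1 t^2}{2} - \sigma^2\right)}{2n - 2},}
#'   derived from the exact two-sample pooling identity and validated against
#'   Monte-Carlo simulation. The bias is symmetric in \eqn{\delta}, negative
#'   for the power-targeting rules, and tends to 0 as
#'   \eqn{|\delta| \to \infty} for unbounded rules.
#' @export
variance_bias_exact <- function(design, rule, scenario, rel.tol = 1e-8) {
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta
  rfun <- .r_of(rule, n1)
  sd1 <- sigma * sqrt(2 / n1)
  inner <- function(q) {
    stats::integrate(function(t) {
      r <- rfun(q, delta + t)
      n2 <- n1 * r
      n <- n1 + n2
      ((2 * n1 - 2) * (q - sigma^2) +
         (n2 / n) * (n1 * t^2 / 2 - sigma^2)) / (2 * n - 2) *
        stats::dnorm(t, 0, sd1)
    }, -10 * sd1, 10 * sd1, rel.tol = rel.tol, subdivisions = 500L,
    stop.on.error = FALSE)$value
  }
  .bias_quad(design, scenario, inner, rel.tol)
}

#' Expected first-stage effect estimate given the blinded interim variance
#'
#' The conditional mean \eqn{E(\bar\Delta_1 \mid S_{1,OS}^2)} of the
#' (unblinded) stage-1 mean difference given the blinded one-sample variance:
#' the key quantity behind the worst-case blinded reassessment rule. It is a
#' ratio of one-dimensional integrals over the support
#' \eqn{x \in (-b, b)}, \eqn{b = \sqrt{2 S_{1,OS}^2 (2 n_1 - 1) / n_1}}, of
#' the normal density of \eqn{\bar\Delta_1} times the chi-square density of
#' the within-group sum of squares implied by the pair
#' \eqn{(S_{1,OS}^2, x)}. The integrand is rescaled by its maximum before
#' integration so the ratio survives far into the tails of
#' \eqn{S_{1,OS}^2}.
#'
#' @param s1_os2 Blinded interim variance value(s), > 0 (vectorized).
#' @param design A [bssr_design()].
#' @param scenario A [bssr_scenario()].
#' @param rel.tol Quadrature relative tolerance.
#' @return Conditional mean(s), each lying in \eqn{(-b, b)}. Errors if the
#'   normalizer underflows to zero.
#' @export
conditional_mean_delta1 <- function(s1_os2, design, scenario,
                                    rel.tol = 1e-9) {
  stopifnot(inherits(design, "bssr_design"),
            inherits(scenario, "bssr_scenario"))
  if (any(s1_os2 <= 0))
    stop("'s1_os2' must be positive", call. = FALSE)
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta
  sd1 <- sigma * sqrt(2 / n1)
  one <- function(s) {
    b <- sqrt(2 * s * (2 * n1 - 1) / n1)
    g <- function(x)
      stats::dnorm(x, delta, sd1) *
        stats::dchisq(((2 * n1 - 1) * s - x^2 * n1 / 2) / sigma^2,
                      2 * n1 - 2)
    # rescale by the grid maximum of the unnormalized density
    g0 <- max(g(seq(-b, b, length.out = 129L)))
    if (!is.finite(g0) || g0 <= 0)
      stop("conditional-mean normalizer underflowed at s1_os2 = ", s,
           call. = FALSE)
    num <- stats::integrate(function(x) x * g(x) / g0, -b, b,
                            rel.tol = rel.tol, subdivisions = 500L,
                            stop.on.error = FALSE)$value
    den <- stats::integrate(function(x) g(x) / g0, -b, b,
                            rel.tol = rel.tol, subdivisions = 500L,
                            stop.on.error = FALSE)$value
    if (den <= 0)
      stop("conditional-mean normalizer underflowed at s1_os2 = ", s,
           call. = FALSE)
    num / den
  }
  vapply(s1_os2, one, numeric(1))
}

#' Worst-case (oracle) blinded reassessment rule
#'
#' The blinded rule that maximizes the absolute bias of the final mean
#' estimator among all rules confined to \code{[n2min, n2max]}: it switches
#' between the extremes at the point where the conditional mean
#' \eqn{E(\bar\Delta_1 \mid S_{1,OS}^2)} crosses the true \eqn{\delta}. The
#' positive-bias maximizer takes \code{n2min} when the conditional mean
#' exceeds \eqn{\delta} and \code{n2max} otherwise; the negative-bias
#' maximizer swaps the branches. The rule depends on the true scenario, so it
#' is a bound-generating oracle, not a practicable design.
#'
#' @param s1_os2 Blinded interim variance value(s), > 0.
#' @param ctx A [worst_case_context()].
#' @param direction \code{"positive"} (default) or \code{"negative"} bias
#'   maximizer.
#' @return Second-stage size(s), each either \code{n2min} or \code{n2max}.
#' @export
worst_case_rule <- function(s1_os2, ctx,
                            direction = c("positive", "negative")) {
  stopifnot(inherits(ctx, "bssr_wc_context"))
  direction <- match.arg(direction)
  cm <- ctx$condmean(s1_os2)
  hit <- cm > ctx$scenario$delta
  if (direction == "negative") hit <- !hit
  ifelse(hit, ctx$design$n2min, ctx$design$n2max)
}

#' @rdname worst_case_rule
#' @param design A [bssr_design()].
#' @param scenario The true [bssr_scenario()] the oracle is allowed to use.
#' @return For \code{worst_case_context}: an object of class
#'   \code{"bssr_wc_context"} caching the conditional-mean function.
#' @export
worst_case_context <- function(design, scenario) {
  structure(list(design = design, scenario = scenario,
                 condmean = function(s)
                   conditional_mean_delta1(s, design, scenario)),
            class = "bssr_wc_context")
}

#' Sharp upper bound for the mean bias of blinded reassessment
#'
#' The maximal bias of \eqn{\bar\Delta} attainable by any blinded rule
#' confined to \code{[n2min, n2max]}:
#' \deqn{\left(\frac{n_1}{n_1+n_{2min}} - \frac{n_1}{n_1+n_{2max}}\right)
#'   E\left[(\bar\Delta_1 - \delta)\,
#'   1\{E(\bar\Delta_1 \mid S_{1,OS}^2) > \delta\}\right].}
#' The outer expectation is evaluated by Monte-Carlo over stage-1 sufficient
#' statistics; the indicator uses the cached conditional-mean function
#' evaluated exactly on an interpolation grid spanning the sampled range of
#' \eqn{S_{1,OS}^2}. With \code{n2min = 0} and \code{n2max = Inf} the leading
#' factor is 1. For growing \eqn{|\delta|} the value approaches the unblinded
#' bound [unblinded_bias_bound()]; it is 0 at \eqn{\delta = 0}, where the
#' worst-case rule degenerates to a constant.
#'
#' @param design A [bssr_design()].
#' @param scenario A [bssr_scenario()].
#' @param nrep Monte-Carlo replicates for the outer expectation.
#' @param seed Optional seed.
#' @param grid_n Size of the conditional-mean interpolation grid.
#' @return A \code{"bssr_bias"} with \code{method = "monte_carlo"} and
#'   \code{abs_error} the Monte-Carlo standard error.
#' @export
max_bias_blinded <- function(design, scenario, nrep = 1e6, seed = NULL,
                             grid_n = 200L) {
  stopifnot(inherits(design, "bssr_design"),
            inherits(scenario, "bssr_scenario"))
  if (design$n2min >= design$n2max)
    stop("requires n2min < n2max", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n1 <- design$n1
  sigma <- scenario$sigma
  delta <- scenario$delta
  fac <- n1 / (n1 + design$n2min) - n1 / (n1 + design$n2max)
  d1 <- stats::rnorm(nrep, delta, sigma * sqrt(2 / n1))
  ss <- sigma^2 * stats::rchisq(nrep, 2 * n1 - 2)
  s1os2 <- (ss + (n1 / 2) * d1^2) / (2 * n1 - 1)
  if (delta == 0) {
    # conditional mean is identically 0, the indicator event is empty
    ind <- rep(FALSE, nrep)
  } else {
    sgrid <- seq(min(s1os2), max(s1os2), length.out = grid_n)
    cmg <- conditional_mean_delta1(sgrid, design, scenario)
    cm <- stats::approx(sgrid, cmg, xout = s1os2, rule = 2)$y
    ind <- cm > delta
  }
  x <- (d1 - delta) * ind
  structure(list(value = fac * mean(x),
                 abs_error = fac * stats::sd(x) / sqrt(nrep),
                 method = "monte_carlo"),
            class = "bssr_bias")
}

#' Upper bound for the mean bias of unblinded reassessment
#'
#' The maximal absolute bias of \eqn{\bar\Delta} over all reassessment rules
#' that may use the fully unblinded interim data, confined to
#' \code{[n2min, n2max]}:
#' \deqn{\left(\frac{n_1}{n_1+n_{2min}} - \frac{n_1}{n_1+n_{2max}}\right)
#'   \frac{1}{\sqrt{2\pi}}\; \sigma \sqrt{2/n_1},}
#' where \eqn{1/\sqrt{2\pi} \approx 0.4} is the maximal truncated-normal mean
#' factor. It is attained by the rule taking \code{n2min} when
#' \eqn{\bar\Delta_1 \le \delta} and \code{n2max} otherwise (negative-bias
#' direction), and bounds every blinded rule as a special case. Linear in
#' \eqn{\sigma}; zero when \code{n2min = n2max}.
#'
#' @param design A [bssr_design()].
#' @param sigma True standard deviation.
#' @return The bound, in outcome units.
#' @export
unblinded_bias_bound <- function(design, sigma) {
  stopifnot(inherits(design, "bssr_design"))
  fac <- design$n1 / (design$n1 + design$n2min) -
    design$n1 / (design$n1 + design$n2max)
  fac * sigma * sqrt(2 / design$n1) / sqrt(2 * pi)
}

#' Closed-form bounds for the variance-estimator bias (unadjusted rule)
#'
#' Under the unadjusted power-targeting rule and \eqn{\delta = 0}, the bias
#' of the final pooled variance estimator satisfies
#' \deqn{-\frac{2 n_1 - 1}{2 n_1 - 3}\,\frac{1}{v} < E(S^2) - \sigma^2 < 0,
#'   \qquad v = \frac{2 (z_{1-\alpha} + z_{1-\beta})^2}{\delta_0^2},}
#' and with \code{n2max = Inf} the bias converges to the lower bound as
#' \eqn{\sigma^2 \to \infty}. The bound does not apply to the adjusted rule,
#' whose absolute variance bias peaks at a finite \eqn{\sigma}.
#'
#' @param design A [bssr_design()] (rule understood as unadjusted).
#' @return A list with \code{lower} (negative, units squared) and
#'   \code{upper} (0).
#' @examples
#' d <- bssr_design(delta0 = 5.5, sigma0 = 8, n1 = 15)
#' variance_bias_bounds(d)$lower  # about -2.07
#' @export
variance_bias_bounds <- function(design) {
  stopifnot(inherits(design, "bssr_design"))
  n1 <- design$n1
  v <- design$z_factor / design$delta0^2
  list(lower = -(2 * n1 - 1) / (2 * n1 - 3) / v, upper = 0)
}
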