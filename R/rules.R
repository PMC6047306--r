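#' Blinded one-sample interim variance
#'
#' The lumped variance of all first-stage observations about the pooled mean,
#' ignoring treatment labels (divisor \code{2 n1 - 1}). From per-group
#' sufficient statistics it satisfies the exact decomposition
#' \deqn{(2 n_1 - 1)\, S_{1,OS}^2 = (ss_a + ss_b) +
#'   \frac{n_1}{2}(\bar X_b - \bar X_a)^2,}
#' so blinding costs nothing computationally. The estimator is unbiased for
#' \eqn{\sigma^2} under delta = 0 and positively biased by
#' \eqn{\delta^2 n_1 / (4 n_1 - 2)} otherwise.
#'
#' @param stage1 A [stage_summary()] with per-group size \code{n >= 2}.
#' @return The blinded one-sample variance (outcome units squared).
#' @examples
#' blinded_variance(stage_from_data(c(0, 0), c(1, 1)))  # 1/3
#' @export
blinded_variance <- function(stage1) {
  stopifnot(inherits(stage1, "bssr_stage"))
  n1 <- stage1$n
  if (n1 < 2)
    stop("blinded variance requires a first-stage per-group size n1 >= 2",
         call. = FALSE)
  d1 <- stage1$mean_b - stage1$mean_a
  (stage1$ss_a + stage1$ss_b + (n1 / 2) * d1^2) / (2 * n1 - 1)
}

#' Sample size reassessment rules based on the blinded interim variance
#'
#' Real-valued second-stage per-group sample sizes recalculated from the
#' blinded one-sample variance \code{s1_os2}, targeting the design's power at
#' effect \code{delta0} via the z-test formula. The unadjusted rule plugs
#' \code{s1_os2} in directly; the adjusted rule first subtracts the bias term
#' \eqn{\delta_0^2 n_1 / (4 n_1 - 2)} that the lumped variance carries under
#' the planning alternative, and is therefore never larger. Both rules are
#' clamped to \code{[n2min, n2max]} and are nondecreasing in \code{s1_os2}.
#' The "+ 1" term follows the analytic form of the rule; sizes are left
#' real-valued here and rounded only by [realized_n2()] when patients are
#' actually recruited.
#'
#' @param s1_os2 Blinded one-sample interim variance(s), >= 0 (vectorized).
#' @param design A [bssr_design()].
#' @return Real-valued second-stage per-group size(s) in
#'   \code{[n2min, n2max]}.
#' @examples
#' d <- bssr_design(delta0 = 5.5, sigma0 = 8, n1 = 15)
#' n2_unadjusted(36, d)  # 4.68...
#' n2_adjusted(36, d)    # 0.62...
#' @export
n2_unadjusted <- function(s1_os2, design) {
  stopifnot(inherits(design, "bssr_design"))
  if (any(s1_os2 < 0))
    stop("'s1_os2' must be non-negative", call. = FALSE)
  raw <- design$z_factor * s1_os2 / design$delta0^2 - design$n1 + 1
  pmin(design$n2max, pmax(design$n2min, raw))
}

#' @rdname n2_unadjusted
#' @export
n2_adjusted <- function(s1_os2, design) {
  stopifnot(inherits(design, "bssr_design"))
  if (any(s1_os2 < 0))
    stop("'s1_os2' must be non-negative", call. = FALSE)
  n1 <- design$n1
  raw <- design$z_factor *
    (s1_os2 / design$delta0^2 - n1 / (4 * n1 - 2)) - n1 + 1
  pmin(design$n2max, pmax(design$n2min, raw))
}

#' Integer second-stage size actually recruited
#'
#' Rounds a real-valued reassessed size up to the next integer (a fractional
#' patient must be recruited in full to preserve the power target) and clamps
#' to the design's \code{[n2min, n2max]} range. Zero is allowed when
#' \code{n2min = 0} and the raw size is exactly 0.
#'
#' @param raw Real-valued second-stage size(s), >= 0 (vectorized).
#' @param design A [bssr_design()].
#' @return Integer-valued second-stage per-group size(s).
#' @export
realized_n2 <- function(raw, design) {
  stopifnot(inherits(design, "bssr_design"))
  if (any(raw < 0)) stop("'raw' must be non-negative", call. = FALSE)
  pmin(design$n2max, pmax(design$n2min, ceiling(raw)))
}

#' Construct a tagged reassessment rule function
#'
#' Wraps one of the built-in blinded reassessment rules (or a custom mapping)
#' as a function \code{s1_os2 -> real-valued n2}, tagged with its type and
#' whether it is nondecreasing; the tags let downstream code assert
#' monotonicity-dependent properties of the bias theory.
#'
#' @param design A [bssr_design()].
#' @param type One of \code{"unadjusted"}, \code{"adjusted"},
#'   \code{"constant"}, \code{"custom"}.
#' @param n2 For \code{type = "constant"}: the fixed second-stage size
#'   (must lie in \code{[n2min, n2max]}).
#' @param fn For \code{type = "custom"}: a vectorized function of
#'   \code{s1_os2}; its values are clamped to \code{[n2min, n2max]}.
#' @param monotone For \code{type = "custom"}: declare whether \code{fn} is
#'   nondecreasing.
#' @return A function of class \code{"bssr_rule"} with attributes
#'   \code{rule_type} and \code{monotone}.
#' @export
reassessment_rule <- function(design,
                              type = c("unadjusted", "adjusted", "constant",
                                       "custom"),
                              n2 = NULL, fn = NULL, monotone = NA) {
  stopifnot(inherits(design, "bssr_design"))
  type <- match.arg(type)
  f <- switch(type,
    unadjusted = function(s1_os2) n2_unadjusted(s1_os2, design),
    adjusted   = function(s1_os2) n2_adjusted(s1_os2, design),
    constant   = {
      if (is.null(n2) || n2 < design$n2min || n2 > design$n2max)
        stop("constant rule needs 'n2' within [n2min, n2max]", call. = FALSE)
      force(n2)
      function(s1_os2) rep(n2, length(s1_os2))
    },
    custom     = {
      if (!is.function(fn)) stop("custom rule needs 'fn'", call. = FALSE)
      force(fn)
      function(s1_os2) pmin(design$n2max, pmax(design$n2min, fn(s1_os2)))
    })
  attr(f, "rule_type") <- type
  attr(f, "monotone") <- switch(type, unadjusted = TRUE, adjusted = TRUE,
                                constant = TRUE, custom = isTRUE(monotone))
  class(f) <- c("bssr_rule", "function")
  f
}

#' @export
print.bssr_rule <- function(x, ...) {
  cat(sprintf("Blinded sample size reassessment rule: %s (monotone: %s)\n",
              attr(x, "rule_type"), attr(x, "monotone")))
  invisible(x)
}
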