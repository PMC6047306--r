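test_that("the final mean estimate is exactly unbiased under the null", {
  d <- pilot_design(n1 = 8)
  sc0 <- bssr_scenario(0, 1.5)
  for (rule_type in c("unadjusted", "adjusted"))
    expect_lt(abs(mean_bias_exact(d, reassessment_rule(d, rule_type),
                                  sc0)$value), 1e-9)
})

test_that("mean bias has the sign opposite to delta and is antisymmetric", {
  d <- pilot_design(n1 = 8)
  rule <- reassessment_rule(d, "unadjusted")
  for (delta in c(0.5, 1, 2)) for (sigma in c(1, 2)) {
    pos <- mean_bias_exact(d, rule, bssr_scenario(delta, sigma))$value
    neg <- mean_bias_exact(d, rule, bssr_scenario(-delta, sigma))$value
    expect_lt(pos, 0)
    expect_gt(neg, 0)
    expect_equal(pos, -neg, tolerance = 1e-7)
  }
})

test_that("bias of mean and variance vanishes for extreme effect sizes", {
  # with an unbounded monotone rule both biases fade as |delta| grows
  d <- pilot_design(n1 = 8)
  rule <- reassessment_rule(d, "unadjusted")
  near_m <- abs(mean_bias_exact(d, rule, bssr_scenario(2, 1))$value)
  far_m <- abs(mean_bias_exact(d, rule, bssr_scenario(20, 1))$value)
  near_v <- abs(variance_bias_exact(d, rule, bssr_scenario(2, 1))$value)
  far_v <- abs(variance_bias_exact(d, rule, bssr_scenario(20, 1))$value)
  expect_lt(far_m, near_m / 10)
  expect_lt(far_v, near_v / 10)
})

test_that("variance bias is symmetric in delta and negative", {
  d <- pilot_design(n1 = 8)
  rule <- reassessment_rule(d, "adjusted")
  for (delta in c(0.8, 1.6)) {
    a <- variance_bias_exact(d, rule, bssr_scenario(delta, 1))$value
    b <- variance_bias_exact(d, rule, bssr_scenario(-delta, 1))$value
    expect_equal(a, b, tolerance = 1e-7)
    expect_lt(a, 0)
  }
})

test_that("quadrature matches simulation exactly for real-valued rules", {
  # with a rule bounded below by one patient the fractional-df simulator is
  # an exact model match for the bias integrals
  d <- pilot_design(n1 = 6, n2min = 1, n2max = 40)
  rule <- reassessment_rule(d, "custom", fn = function(s) 1 + 8 * s,
                            monotone = TRUE)
  for (delta in c(0, 0.7)) {
    sc <- bssr_scenario(delta, 1.2)
    out <- simulate_trials(d, sc, rule, 2e5, seed = 101 + delta * 10,
                           rounding = "none")
    s <- summarize_trials(out, d, sc)
    mq <- mean_bias_exact(d, rule, sc)$value
    vq <- variance_bias_exact(d, rule, sc)$value
    expect_lt(abs(mq - s$bias_mean), 3 * s$bias_mean_se)
    expect_lt(abs(vq - s$bias_var), 3 * s$bias_var_se)
  }
})

test_that("quadrature tracks the integer-recruitment simulator closely", {
  # ceiling rounding perturbs n2 by less than one patient; agreement is
  # within Monte-Carlo error plus a small rounding allowance
  d <- case_design()
  rule <- reassessment_rule(d, "unadjusted")
  sc <- bssr_scenario(-7.98, 5)
  s <- simulate_summary(d, sc, rule, 1e5, seed = 111)
  mq <- mean_bias_exact(d, rule, sc)$value
  expect_lt(abs(mq - s$bias_mean), 3 * s$bias_mean_se)
  expect_equal(mq, 0.205, tolerance = 0.005)
})

test_that("conditional mean of the stage-1 effect behaves as derived", {
  d <- pilot_design(n1 = 8)
  # null case: odd integrand, conditional mean identically zero
  expect_lt(max(abs(conditional_mean_delta1(c(0.5, 1, 3), d,
                                            bssr_scenario(0, 1)))), 1e-8)
  # support constraint: value inside (-b, b)
  sc <- bssr_scenario(1.5, 1)
  s_vals <- c(0.2, 0.7, 1.5, 4, 9)
  cm <- conditional_mean_delta1(s_vals, d, sc)
  b <- sqrt(2 * s_vals * (2 * d$n1 - 1) / d$n1)
  expect_true(all(abs(cm) < b))
  expect_error(conditional_mean_delta1(-1, d, sc), "positive")
})

test_that("conditional mean matches binned Monte-Carlo stage-1 draws", {
  # tower property: within any bin of S1os^2 the average of the pointwise
  # conditional means must equal the average observed stage-1 effect
  d <- pilot_design(n1 = 8)
  sc <- bssr_scenario(1, 1)
  set.seed(121)
  s1 <- draw_stage1(2e5, d$n1, sc$delta, sc$sigma)
  grid <- seq(min(s1$s1_os2), max(s1$s1_os2), length.out = 300)
  pred <- approx(grid, conditional_mean_delta1(grid, d, sc),
                 xout = s1$s1_os2)$y
  bins <- cut(s1$s1_os2, quantile(s1$s1_os2, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  obs_mean <- tapply(s1$d1, bins, mean)
  obs_se <- tapply(s1$d1, bins, sd) / sqrt(tabulate(bins))
  pred_mean <- tapply(pred, bins, mean)
  expect_true(all(abs(obs_mean - pred_mean) < 3 * obs_se))
})

test_that("worst-case rule switches at the conditional-mean crossing", {
  d <- pilot_design(n1 = 8, n2min = 0, n2max = 100)
  sc <- bssr_scenario(1, 1)
  ctx <- worst_case_context(d, sc)
  # locate the crossing of E(dbar1 | S1os^2) with delta
  cross <- uniroot(function(s) ctx$condmean(s) - sc$delta,
                   lower = 0.05, upper = 20)$root
  expect_equal(worst_case_rule(cross * c(1.2, 0.8), ctx),
               c(d$n2min, d$n2max))
  expect_equal(worst_case_rule(cross * c(1.2, 0.8), ctx, "negative"),
               c(d$n2max, d$n2min))
  # under the null the conditional mean never exceeds delta = 0, so the
  # positive-direction oracle degenerates to the constant rule n2max
  ctx0 <- worst_case_context(d, bssr_scenario(0, 1))
  expect_equal(worst_case_rule(c(0.3, 1, 5), ctx0), rep(d$n2max, 3))
})

test_that("sharp blinded bound dominates the rules and obeys the caps", {
  d <- pilot_design(n1 = 8)
  for (delta in c(0.7, 2)) for (sigma in c(1, 2)) {
    sc <- bssr_scenario(delta, sigma)
    wc <- max_bias_blinded(d, sc, nrep = 2e5, seed = 131)
    for (rule_type in c("unadjusted", "adjusted")) {
      mb <- mean_bias_exact(d, reassessment_rule(d, rule_type), sc)
      expect_gt(wc$value + 3 * wc$abs_error, abs(mb$value))
    }
    expect_lt(wc$value - 3 * wc$abs_error, unblinded_bias_bound(d, sigma))
  }
  # null case: the indicator event is empty and the bound collapses to 0
  expect_equal(max_bias_blinded(d, bssr_scenario(0, 1), nrep = 1e4,
                                seed = 132)$value, 0)
  # restricting [n2min, n2max] only rescales the leading factor
  db <- pilot_design(n1 = 8, n2min = 2, n2max = 30)
  sc <- bssr_scenario(1, 1)
  wu <- max_bias_blinded(d, sc, nrep = 2e5, seed = 133)
  wb <- max_bias_blinded(db, sc, nrep = 2e5, seed = 133)
  fac <- 8 / (8 + 2) - 8 / (8 + 30)
  expect_equal(wb$value, fac * wu$value, tolerance = 1e-10)
})

test_that("blinded worst case approaches the unblinded bound as delta grows", {
  d <- pilot_design(n1 = 8)
  ub <- unblinded_bias_bound(d, 1)
  vals <- vapply(c(1, 3, 8), function(delta)
    max_bias_blinded(d, bssr_scenario(delta, 1), nrep = 2e5,
                     seed = 141)$value, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3] / ub, 0.9)
  expect_lt(vals[3], ub)
})

test_that("unblinded bound is linear in sigma and realized by its rule", {
  d <- pilot_design(n1 = 8, n2min = 0, n2max = 50)
  expect_equal(unblinded_bias_bound(d, 4), 2 * unblinded_bias_bound(d, 2))
  # simulate the realizing rule: n2min when dbar1 <= delta, else n2max;
  # it attains the bound with a negative sign
  delta <- 1; sigma <- 1
  set.seed(151)
  s1 <- draw_stage1(1e6, d$n1, delta, sigma)
  n2 <- ifelse(s1$d1 <= delta, d$n2min, d$n2max)
  d2 <- rnorm(1e6, delta, sigma * sqrt(2 / pmax(n2, 1)))
  dbar <- ifelse(n2 == 0, s1$d1, (d$n1 * s1$d1 + n2 * d2) / (d$n1 + n2))
  bias <- mean(dbar) - delta
  se <- sd(dbar) / sqrt(1e6)
  expect_lt(abs(-bias - unblinded_bias_bound(d, sigma)), 3 * se)
})

test_that("closed-form variance-bias bounds bracket the exact bias", {
  # case-study design: lower bound about -2.07
  d <- case_design()
  vb <- variance_bias_bounds(d)
  z2 <- 2 * (qnorm(0.975) + qnorm(0.8))^2
  expect_equal(vb$lower, -(29 / 27) / (z2 / 5.5^2), tolerance = 1e-12)
  expect_equal(vb$lower, -2.07, tolerance = 0.005)
  expect_identical(vb$upper, 0)
  # minimal first stage: |lower| = 3 / (2 (z_{0.975} + z_{0.8})^2)
  d2 <- pilot_design(n1 = 2)
  expect_equal(variance_bias_bounds(d2)$lower, -3 / z2, tolerance = 1e-12)
  expect_lt(abs(abs(variance_bias_bounds(d2)$lower) - 0.19), 0.005)
  # the ratio (2n1-1)/(2n1-3) tends to 1 for large first stages
  dbig <- bssr_design(delta0 = 1, sigma0 = 1, n1 = 5000)
  expect_equal(variance_bias_bounds(dbig)$lower, -1 / z2, tolerance = 1e-3)
  # the exact bias lies strictly inside (lower, 0) under the null
  for (n1 in c(8, 15)) for (sigma in c(2, 8)) {
    dd <- if (n1 == 15) case_design() else pilot_design(n1 = n1)
    bias <- variance_bias_exact(dd, reassessment_rule(dd, "unadjusted"),
                                bssr_scenario(0, sigma))$value
    expect_gt(bias, variance_bias_bounds(dd)$lower)
    expect_lt(bias, 0)
  }
})
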