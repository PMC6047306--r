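# shared fixtures: the kava case-study design and the standardized pilot
# designs with delta0 = 1 used throughout the tests
case_design <- function(n2min = 0, n2max = Inf)
  bssr_design(alpha = 0.025, power = 0.8, delta0 = 5.5, sigma0 = 8,
              n1 = 15, n2min = n2min, n2max = n2max)

pilot_design <- function(n1 = 8, sigma0 = 1, n2min = 0, n2max = Inf)
  bssr_design(alpha = 0.025, power = 0.8, delta0 = 1, sigma0 = sigma0,
              n1 = n1, n2min = n2min, n2max = n2max)

# stage-1 sufficient statistics drawn from their exact sampling distribution
draw_stage1 <- function(nrep, n1, delta, sigma) {
  d1 <- stats::rnorm(nrep, delta, sigma * sqrt(2 / n1))
  ss <- sigma^2 * stats::rchisq(nrep, 2 * n1 - 2)
  list(d1 = d1, ss = ss, s1_os2 = (ss + n1 / 2 * d1^2) / (2 * n1 - 1))
}
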