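test_that("membership ratios follow the unweighted density ratio and sum to one", {
  m <- mprA_mixture()
  # far below the lognormal mass: the Gaussian claims the event entirely
  expect_equal(membership_ratios(-100, m)$g1, 1)
  # direct-substitution oracle at x = 150 using stats densities
  g <- membership_ratios(150, m)
  p1 <- dnorm(150, 97.3366, 103.0731 / 2)
  p2 <- dlnorm(150, 5.95526, 0.17618)
  expect_equal(g$g1, p1 / (p1 + p2), tolerance = 1e-12)
  expect_equal(g$g2, p2 / (p1 + p2), tolerance = 1e-12)
  xs <- seq(1, 1500, length.out = 200)
  gg <- membership_ratios(xs, m)
  expect_true(all(gg$g1 >= 0 & gg$g1 <= 1))
  expect_equal(gg$g1 + gg$g2, rep(1, length(xs)))
  # weighted posterior option rescales by the time-point weights
  gw <- membership_ratios(150, m, weighted = TRUE, t = "18h")
  expect_equal(gw$g1, 0.5 * p1 / (0.5 * p1 + 0.5 * p2))
  far <- mixture_model(gaussian_component(0, 0.1),
                       lognormal_component(20, 0.1),
                       data.frame(time = "t", C1 = 0.5, C2 = 0.5))
  expect_error(membership_ratios(1e6, far), "undefined")
})

test_that("stochastic binning is seeded, boundary-correct, and binomially consistent", {
  m <- mprA_mixture()
  l1 <- stochastic_binning(c(-200, -150, -100), m, seed = 1)
  expect_true(all(l1 == "L"))
  set.seed(99)
  x <- runif(500, 0, 1200)
  a <- stochastic_binning(x, m, seed = 2)
  b <- stochastic_binning(x, m, seed = 2)
  expect_identical(as.character(a), as.character(b))
  # find an intensity whose membership is ~0.7 and check the binomial law
  xs <- seq(100, 600, by = 0.5)
  g1s <- membership_ratios(xs, m)$g1
  x70 <- xs[which.min(abs(g1s - 0.7))]
  p <- membership_ratios(x70, m)$g1
  n <- 1e5
  lab <- stochastic_binning(rep(x70, n), m, seed = 3)
  expect_lt(abs(mean(lab == "L") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("subpopulation summaries reproduce textbook statistics and preserve the pooled mean", {
  s <- subpopulation_summary(c(1, 2, 3, 700, 800), c("L", "L", "L", "H", "H"))
  L <- s[s$subpopulation == "L", ]
  expect_equal(L$mean, 2)
  expect_equal(L$var, 1)
  expect_equal(L$cv, 0.5)
  expect_equal(L$omega, 0.6)
  allH <- subpopulation_summary(c(5, 6), c("H", "H"))
  expect_equal(allH$omega, c(0, 1))
  expect_true(is.na(allH$var[allH$subpopulation == "L"]))
  # marginal preservation: the omega-weighted subpopulation means recompose
  # the full-sample mean exactly
  m <- mprA_mixture()
  x <- generate_flow_timecourse(
    synthetic_scenario(times_h = 20, omega2 = 0.5, n_events = 5000,
                       seed = 8))$intensity
  lab <- stochastic_binning(x, m, seed = 9)
  st <- subpopulation_summary(x, lab)
  expect_equal(sum(st$omega * st$mean), mean(x), tolerance = 1e-12)
  expect_identical(sum(st$N), length(x))
})

test_that("binned H fractions recover the scheduled truth at acquisition scale", {
  sc <- synthetic_scenario(times_h = c(18, 21, 24),
                           omega2 = c(0.1, 0.5, 0.9),
                           n_events = 20000, seed = 31)
  d <- generate_flow_timecourse(sc)
  m <- mprA_mixture(times = unique(d$time), C2 = c(0.1, 0.5, 0.9))
  rep_ <- analyze_timecourse(d, m, seed = 32)
  w2 <- rep_$stats$omega[rep_$stats$subpopulation == "H"]
  expect_true(all(abs(w2 - c(0.1, 0.5, 0.9)) < 0.02))
})

test_that("binning means converge to the posterior-weighted component means", {
  m <- mprA_mixture()
  n <- 1e5
  sc <- synthetic_scenario(times_h = 20, omega2 = 0.5, n_events = n,
                           seed = 77)
  x <- generate_flow_timecourse(sc)$intensity
  lab <- stochastic_binning(x, m, seed = 78)
  st <- subpopulation_summary(x, lab)
  # quadrature oracle: E[X | assigned to L] with assignment probability
  # g1(x) under the density-mode mixture f(x)
  f <- function(x) 0.5 * gaussian_pdf(x, m$gaussian) +
    0.5 * lognormal_pdf(x, m$lognormal)
  g1 <- function(x) {
    p1 <- gaussian_pdf(x, m$gaussian)
    p2 <- lognormal_pdf(x, m$lognormal)
    ifelse(p1 + p2 > 0, p1 / (p1 + p2), 0)
  }
  zL <- integrate_density(function(x) g1(x) * f(x), -500, 3000)
  muL <- integrate_density(function(x) x * g1(x) * f(x), -500, 3000) / zL
  zH <- integrate_density(function(x) (1 - g1(x)) * f(x), -500, 3000)
  muH <- integrate_density(function(x) x * (1 - g1(x)) * f(x), -500, 3000) / zH
  seL <- sqrt(st$var[1] / st$N[1])
  seH <- sqrt(st$var[2] / st$N[2])
  expect_lt(abs(st$mean[1] - muL), 3 * seL)
  expect_lt(abs(st$mean[2] - muH), 3 * seH)
})

test_that("transition rates implement the one-way per-capita flux with its closed forms", {
  flat <- data.frame(time_h = c(10, 12, 14), omega2 = rep(0.3, 3))
  expect_true(all(transition_rate_series(flat)$rate == 0))
  r <- transition_rate_series(data.frame(time_h = c(0, 2),
                                         omega2 = c(0.2, 0.4)))
  expect_equal(r$rate, 0.125)
  expect_equal(r$time_h, 1)
  # closed-form oracle: for a logistic schedule with scale tau the
  # per-capita rate equals omega2/tau in the continuum limit (the forward
  # difference is O(dt)-biased where omega1 gets small, so compare on a
  # fine grid away from saturation)
  tt <- seq(14, 26, by = 0.1)
  w2 <- logistic_weight_schedule(tt, midpoint = 20, scale = 2)
  rr <- transition_rate_series(data.frame(time_h = tt, omega2 = w2))
  w2_mid <- logistic_weight_schedule(rr$time_h, midpoint = 20, scale = 2)
  sel <- rr$time_h <= 24
  expect_lt(max(abs(rr$rate[sel] / (w2_mid[sel] / 2) - 1)), 0.03)
  # and hence monotone increasing for a pure logistic: no interior peak
  expect_true(all(diff(rr$rate) > 0))
  # undefined when the L pool is empty
  r0 <- transition_rate_series(data.frame(time_h = c(0, 1),
                                          omega2 = c(1, 1)))
  expect_true(is.na(r0$rate))
})

test_that("a mid-course L-noise burst co-locates the CV peak with the transition-rate peak", {
  tt <- seq(14, 26, by = 2)
  sc <- synthetic_scenario(
    times_h = tt,
    omega2 = 0.85 * logistic_weight_schedule(tt, midpoint = 20, scale = 2),
    n_events = 20000, seed = 91,
    l_noise_factor = 3, l_noise_window = c(20, 22)
  )
  d <- generate_flow_timecourse(sc)
  m <- mprA_mixture(times = unique(d$time), C2 = sc$omega2)
  rep_ <- analyze_timecourse(d, m, seed = 92)
  t_cv <- rep_$cv_L$time_h[which.max(rep_$cv_L$cv)]
  t_rate <- rep_$rates$time_h[which.max(rep_$rates$rate)]
  expect_lte(abs(t_cv - t_rate), 2)
})

test_that("timecourse analysis validates inputs and degrades to a single time point", {
  m <- mprA_mixture()
  expect_error(analyze_timecourse(list("18h" = numeric(0)), m), "18h")
  one <- analyze_timecourse(list("18h" = c(50, 80, 120, 300)), m, seed = 4)
  expect_null(one$rates)
  expect_identical(nrow(one$stats), 2L)
})
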