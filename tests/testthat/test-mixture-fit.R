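test_that("single-family MLE recovers generating parameters within asymptotic error", {
  n <- 20000
  ln <- mprA_lognormal()
  x <- sample_component(ln, n, seed = 101)
  fit <- fit_component_mle(x, "lognormal")
  expect_lt(abs(fit$component$log_mean - ln$log_mean),
            3 * ln$log_sd / sqrt(n))
  expect_lt(abs(fit$component$log_sd - ln$log_sd),
            3 * ln$log_sd / sqrt(2 * n))
  # gamma fit on exponential draws recovers shape ~ 1
  ex <- sample_component(gamma_component(1, 300), n, seed = 102)
  gfit <- fit_component_mle(ex, "gamma")
  expect_equal(gfit$component$shape, 1, tolerance = 0.05)
  expect_error(fit_component_mle(c(-1, x[1:20]), "lognormal"), "> 0")
  expect_error(fit_component_mle(x[1:5], "gaussian"), "at least 10")
})

test_that("constant-valued sample yields a flagged degenerate Gaussian fit", {
  fit <- fit_component_mle(rep(42, 50), "gaussian")
  expect_true(fit$degenerate)
  expect_equal(fit$component$center, 42)
})

test_that("joint EM recovers shared components and per-time weights from synthetic truth", {
  sc <- synthetic_scenario(times_h = c(18, 21, 24),
                           omega2 = c(0.1, 0.5, 0.9),
                           n_events = 20000, seed = 5)
  d <- generate_flow_timecourse(sc)
  fit <- fit_joint_timecourse(d)
  g <- fit$model$gaussian
  l <- fit$model$lognormal
  truth <- attr(d, "truth")
  expect_lt(abs(g$center / truth$gaussian$center - 1), 0.05)
  expect_lt(abs(g$width / truth$gaussian$width - 1), 0.05)
  expect_lt(abs(l$log_mean / truth$lognormal$log_mean - 1), 0.05)
  expect_lt(abs(l$log_sd / truth$lognormal$log_sd - 1), 0.05)
  expect_true(all(abs(fit$model$weights$C2 - c(0.1, 0.5, 0.9)) < 0.03))
  expect_true(all(abs(fit$model$weights$C1 + fit$model$weights$C2 - 1) < 1e-12))
  expect_false(fit$label_swapped)
  # joint log-likelihood is monotone over EM iterations
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik)))
})

test_that("purely Gaussian time points are assigned vanishing H weight", {
  g <- mprA_gaussian()
  d <- data.frame(
    time = rep(c("10h", "12h"), each = 5000),
    intensity = sample_component(g, 10000, seed = 9)
  )
  fit <- suppressWarnings(fit_joint_timecourse(d))
  expect_true(all(fit$model$weights$C2 <= 0.02))
  expect_identical(fit$boundary, "gaussian")
})

test_that("shared component estimates are invariant to time-point order", {
  sc <- synthetic_scenario(times_h = c(18, 21, 24),
                           omega2 = c(0.2, 0.5, 0.8),
                           n_events = 2000, seed = 21)
  d <- generate_flow_timecourse(sc)
  rev_d <- do.call(rbind, rev(split(d, d$time)))
  f1 <- fit_joint_timecourse(d)
  f2 <- fit_joint_timecourse(rev_d)
  expect_equal(f1$model$gaussian$center, f2$model$gaussian$center,
               tolerance = 1e-6)
  expect_equal(f1$model$lognormal$log_mean, f2$model$lognormal$log_mean,
               tolerance = 1e-6)
})

test_that("joint fit on replicated single-family data reproduces the direct MLE", {
  ln <- mprA_lognormal()
  x <- sample_component(ln, 4000, seed = 33)
  d <- data.frame(time = rep(c("a", "b"), each = 2000), intensity = x)
  joint <- suppressWarnings(fit_joint_timecourse(d))
  direct <- fit_component_mle(x, "lognormal")
  expect_equal(joint$model$lognormal$log_mean, direct$component$log_mean,
               tolerance = 0.01)
  expect_equal(joint$model$lognormal$log_sd, direct$component$log_sd,
               tolerance = 0.05)
  expect_true(all(joint$model$weights$C2 > 0.95))
})

test_that("family comparison separates strongly skewed lognormal data and ties near-symmetric gamma", {
  x <- sample_component(lognormal_component(6, 0.8), 1e4, seed = 55)
  cmp <- compare_families(x)
  tab <- cmp$table
  expect_identical(cmp$best, "lognormal")
  expect_lt(tab$AIC[tab$family == "lognormal"],
            tab$AIC[tab$family == "gamma"])
  # near-symmetric gamma (large shape) mimics the lognormal: similar fits
  y <- sample_component(gamma_component(50, 10), 1e4, seed = 56)
  tab2 <- compare_families(y)$table
  expect_lt(abs(diff(tab2$AIC)), 0.01 * abs(mean(tab2$AIC)))
  one <- compare_families(x, "lognormal")
  expect_identical(nrow(one$table), 1L)
  expect_error(compare_families(x, character()), "at least one")
})
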