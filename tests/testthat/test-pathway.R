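test_that("pathway RHS has the trivial fixed point and the linear-decay limit", {
  p0 <- pathway_params(basal_mprAB = 0)
  expect_equal(unname(pathway_rhs(pathway_state(), p0)), rep(0, 7))

  # with theta = 0 the decay is (gamma + phi) * species: subtracting the
  # pure-production RHS (gamma = phi = 0) must leave exactly that
  s <- pathway_state(MprA = 0.4, MprB = 0.3, MprAP = 0.2, MprBP = 0.1,
                     SigE = 0.25, Rel = 0.6, GFP = 0.5)
  p_lin <- pathway_params(theta = 0)
  p_prod <- pathway_params(theta = 0, gamma = 0, phi = 0)
  decay <- pathway_rhs(s, p_prod) - pathway_rhs(s, p_lin)
  expect_equal(unname(decay),
               unname((p_lin$gamma + p_lin$phi) * s), tolerance = 1e-12)
  expect_error(pathway_rhs(pathway_state() - 1, pathway_params()),
               "negative")
})

test_that("steady-state finder returns self-consistent, correctly classified states", {
  # far below the window: a single stable (uninduced) state
  p_mono <- pathway_params(k_auto = 0.1)
  ss_mono <- find_steady_states(p_mono, n_starts = 6, seed = 1)
  expect_identical(sum(ss_mono$stable), 1L)

  # inside the window: two stable states separated by a saddle
  p_bi <- pathway_params(k_auto = 0.7)
  ss <- find_steady_states(p_bi, n_starts = 8, seed = 2)
  expect_identical(sum(ss$stable), 2L)
  expect_identical(sum(!ss$stable), 1L)
  for (i in seq_len(nrow(ss$states))) {
    expect_lt(max(abs(pathway_rhs(ss$states[i, ], p_bi))), 1e-8)
  }
  # no duplicated roots
  d <- as.matrix(dist(ss$states))
  expect_true(all(d[upper.tri(d)] > 1e-3))

  # stability agrees with perturbed long-horizon integration
  for (i in which(ss$stable)) {
    y0 <- ss$states[i, ] * 1.05 + 1e-4
    tr <- simulate_pathway(p_bi, y0, c(0, 400, 800))
    yend <- unlist(tr[nrow(tr), PATHWAY_SPECIES])
    expect_lt(max(abs(yend - ss$states[i, ])),
              1e-3 * (1 + max(ss$states[i, ])))
  }
})

test_that("trajectories stay on verified equilibria and scale with concentration units", {
  p <- pathway_params(k_auto = 0.7)
  ss <- find_steady_states(p, n_starts = 6, seed = 3)
  hi <- ss$states[nrow(ss$states), ]
  tr <- simulate_pathway(p, hi, seq(0, 100, by = 10))
  drift <- max(abs(unlist(tr[nrow(tr), PATHWAY_SPECIES]) - hi))
  expect_lt(drift, 1e-6 * (1 + max(hi)))

  # doubling all conc-dimensioned parameters doubles the trajectory:
  # conc/h rates and conc constants x2, 1/(conc h) rates and per-conc
  # theta /2, 1/h rates unchanged
  c2 <- pathway_params(
    basal_mprAB = p$basal_mprAB * 2, act_mprAB = p$act_mprAB * 2,
    K_mprAB = p$K_mprAB * 2, k_auto = p$k_auto,
    k_transfer = p$k_transfer / 2, k_phosphatase = p$k_phosphatase / 2,
    act_sigE = p$act_sigE * 2, K_sigE = p$K_sigE * 2,
    act_rel = p$act_rel * 2, K_rel = p$K_rel * 2,
    act_gfp = p$act_gfp * 2, K_gfp = p$K_gfp * 2,
    gamma = p$gamma, phi = p$phi, theta = p$theta / 2
  )
  tgrid <- seq(0, 60, by = 2)
  base <- simulate_pathway(p, pathway_state(MprA = 0.2), tgrid)
  scaled <- simulate_pathway(c2, pathway_state(MprA = 0.4), tgrid)
  expect_equal(as.matrix(scaled[PATHWAY_SPECIES]),
               2 * as.matrix(base[PATHWAY_SPECIES]), tolerance = 1e-6)
})

test_that("hysteresis sweeps separate inside the bistable window and only there", {
  p <- pathway_params()
  kk <- seq(0.05, 1.5, length.out = 25)
  bw <- bistable_window(p, kk, t_settle = 400)
  expect_false(bw$empty)
  expect_lt(bw$k_lo, bw$k_hi)
  inside <- bw$separated
  # up-branch below down-branch inside; branches coincide outside
  expect_true(all(bw$up$GFP[inside] < bw$down$GFP[inside]))
  outside <- !inside
  expect_lt(max(abs(bw$up$GFP[outside] - bw$down$GFP[outside]) /
                  pmax(bw$down$GFP[outside], 1e-6)), 0.05)
})

test_that("no bistability without growth retardation when feedback is noncooperative", {
  kk <- seq(0.05, 1.5, length.out = 25)
  p0 <- pathway_params(theta = 0)
  expect_true(pathway_params()$hill_n == 1)
  bw0 <- bistable_window(p0, kk, t_settle = 300)
  expect_true(bw0$empty)
  # brute-force: random multistart root search finds a unique state per k
  for (k in c(0.1, 0.4, 0.8, 1.4)) {
    pk <- pathway_params(theta = 0, k_auto = k)
    ss <- find_steady_states(pk, n_starts = 12, seed = 7)
    expect_identical(nrow(ss$states), 1L)
    expect_true(ss$stable)
  }
})

test_that("bistable window widens with the retardation strength on the tested grid", {
  kk <- seq(0.05, 1.5, length.out = 25)
  widths <- sapply(c(0, 0.5, 1), function(th) {
    bistable_window(pathway_params(theta = th), kk, t_settle = 300)$width
  })
  expect_true(all(diff(widths) >= 0))
  expect_gt(widths[3], 0)
})

test_that("nonlinear decay produces the lagged sigmoidal induction; linear decay does not", {
  # k_auto above the window, low initial state
  p <- pathway_params(k_auto = 1.0)
  sh <- induction_shape(p, t_max = 300)
  expect_identical(sh$inflections, 1L)  # single interior inflection
  expect_gt(sh$lag10, 5)                # multi-hour lag phase
  p_lin <- pathway_params(k_auto = 1.0, theta = 0)
  sh0 <- induction_shape(p_lin, t_max = 60)
  expect_lt(sh0$lag10, 5)               # near-immediate relaxation
  expect_gt(sh$amplitude, 50 * sh0$amplitude)
})
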