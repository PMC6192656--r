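test_that("linearization wires private and shared sources correctly", {
  toy <- make_two_protein_toy()
  lnm <- linearize(toy)
  expect_equal(dim(lnm$W), c(2, 2))
  expect_identical(unname(lnm$W), diag(2))
  expect_identical(unname(lnm$gcc), c(-0.25, 0.25))

  # single-protein cell: the driver coefficient (1 - phi0) vanishes
  one <- cell_model(protein("only", 1, theta = 0.4, beta = 2, gcc = 0),
                    mu0 = 0.8)
  expect_identical(unname(stationary_cv(one)), 0)

  # operon wiring sums to one across members
  m <- build_many_protein("fast", seed = 1)
  lnm2 <- linearize(m)
  op <- lnm2$W["N_O", ]
  expect_equal(sum(op), 1)
  expect_equal(unname(op[c("Y", "Z", "G")]), rep(1 / 3, 3))
})

test_that("stationary CVs match the hand-evaluated closed form for the toy", {
  lnm <- linearize(make_two_protein_toy())
  expect_equal(unname(stationary_cv(lnm)["Y"]), toy_cv_oracle(),
               tolerance = 1e-12)
  # the X-side comes out of the same formula with roles reversed
  v <- 0.03125 / 5
  expect_equal(unname(stationary_cv(lnm)["X"]),
               sqrt((1 - 0.67)^2 / 0.67^2 * v + v), tolerance = 1e-12)
})

test_that("concentration statistics are independent of the GCC vector", {
  a <- make_two_protein_toy(gcc_Y = 0.25)
  b <- make_two_protein_toy(gcc_Y = 0.9)
  expect_identical(stationary_cv(linearize(a)), stationary_cv(linearize(b)))
})

test_that("basis correlators match the quadrature oracles", {
  tau <- seq(-3, 3, length.out = 25)
  bf <- basis_functions(ou_noise("s", 0.5, 4), mu0 = 1, tau = tau)
  expect_lt(max(abs(bf$A - oracle_A(0.5, 4, 1, tau))), 1e-8)
  expect_lt(max(abs(bf$S - oracle_S(0.5, 4, 1, tau))), 1e-8)
  expect_equal(bf$B, 0.03125 * exp(-4 * abs(tau)))

  # confluent (repeated-root) case beta == mu0
  bfc <- basis_functions(ou_noise("s", 0.5, 1), mu0 = 1, tau = tau)
  expect_lt(max(abs(bfc$A - oracle_A(0.5, 1, 1, tau))), 1e-8)
  expect_lt(max(abs(bfc$S - oracle_S(0.5, 1, 1, tau))), 1e-8)

  # symmetries and the OU e-folding identity
  expect_equal(bf$S, rev(bf$S))
  expect_equal(bf$B, rev(bf$B))
  bfe <- basis_functions(ou_noise("s", 0.5, 4), mu0 = 1, tau = c(0, 0.25))
  expect_equal(bfe$B[1] / bfe$B[2], exp(1))
  expect_false(isTRUE(all.equal(bf$A, rev(bf$A))))
})

test_that("analytic cross-correlations decompose additively and stay in [-1, 1]", {
  tau <- seq(-4, 4, length.out = 81)
  m <- build_many_protein("intermediate", seed = 2)
  lnm <- linearize(m)
  for (sig in c("concentration", "production")) {
    xc <- xcorr_analytic(lnm, "G", sig, tau)
    modes <- xc$control + xc$control_private + xc$autogenic +
      xc$autogenic_private + xc$dilution + xc$transmission
    expect_equal(xc$total, modes, tolerance = 1e-15)
    expect_true(all(abs(xc$total) <= 1 + 1e-12))
    expect_lt(max(abs(diff(xc$total))), 0.1) # continuity on a fine grid
  }
  # concentration has no transmission mode; production no dilution mode
  expect_true(all(xcorr_analytic(lnm, "G", "concentration", tau)$transmission == 0))
  expect_true(all(xcorr_analytic(lnm, "G", "production", tau)$dilution == 0))
  expect_error(xcorr_analytic(lnm, "G", "concentration", numeric(0)), "empty")
  expect_error(xcorr_analytic(lnm, "nope", "concentration", 0), "unknown")
})

test_that("mode amplitudes scale with the focal GCC and source variance", {
  tau <- seq(-2, 2, length.out = 41)
  # doubling C_Y doubles the control mode (covariance scale); the
  # concentration fluctuations themselves are GCC-independent
  a <- xcorr_analytic(linearize(make_two_protein_toy(gcc_Y = 0.25)),
                      "Y", "concentration", tau)
  b <- xcorr_analytic(linearize(make_two_protein_toy(gcc_Y = 0.5)),
                      "Y", "concentration", tau)
  cov_a <- a$control * attr(a, "sd_x") * attr(a, "sd_mu")
  cov_b <- b$control * attr(b, "sd_x") * attr(b, "sd_mu")
  expect_equal(cov_b, 2 * cov_a, tolerance = 1e-12)

  # doubling Var(N_Y) (theta * sqrt(2)) doubles the autogenic mode
  c1 <- make_two_protein_toy()
  c2 <- make_two_protein_toy()
  c2$proteins$theta[c2$proteins$id == "Y"] <- 0.5 * sqrt(2)
  xa <- xcorr_analytic(linearize(c1), "Y", "concentration", tau)
  xb <- xcorr_analytic(linearize(c2), "Y", "concentration", tau)
  expect_equal(xb$autogenic * attr(xb, "sd_x") * attr(xb, "sd_mu"),
               2 * xa$autogenic * attr(xa, "sd_x") * attr(xa, "sd_mu"),
               tolerance = 1e-12)
})

test_that("the pure autogenic regime matches simulation", {
  # zero GCCs, single dominant source on Y: the concentration-growth
  # correlation reduces to the asymmetric A-type shape
  m <- cell_model(rbind(protein("X", 0.67, theta = 0.02, beta = 4, gcc = 0),
                        protein("Y", 0.33, theta = 0.5, beta = 4, gcc = 0)),
                  mu0 = 1)
  tr <- simulate_cell(m, duration = 1200, dt = 1e-3, seed = 14)
  emp <- estimate_xcorr(tr, "phi:Y", "mu", max_lag = 2, lag_dt = 0.25,
                        seed = 15)
  ana <- xcorr_analytic(linearize(m), "Y", "concentration", emp$tau)
  expect_true(all(abs(emp$r - ana$total) <= 3 * emp$se))
  # asymmetry: the peak side is positive tau (growth precedes concentration)
  expect_gt(ana$total[ana$tau == 0.5], ana$total[ana$tau == -0.5])
  expect_gt(xcorr_asymmetry(ana), 0)
})

test_that("dual-reporter covariance is negative without extrinsic sources", {
  dr <- dual_reporter_covariance(0.05, ou_noise("b", 0.5, 4), mu0 = 1)
  expect_lt(dr$total, 0)
  expect_identical(dr$total, dr$transmission)
  v_b <- 0.03125 / 5
  expect_equal(dr$transmission, -2 * (1 - 0.05) / 0.05 * v_b)

  # zero reporter noise leaves only the non-negative extrinsic term
  bg <- list(ou_noise("e1", 0.2, 2), ou_noise("e2", 0.1, 3))
  dr0 <- dual_reporter_covariance(0.05, ou_noise("b", 0, 4), bg, mu0 = 1)
  expect_identical(dr0$transmission, 0)
  expect_equal(dr0$total, dr0$other_sources)
  expect_gt(dr0$total, 0)
})

test_that("noise amplitudes invert the stationary CVs (round trip)", {
  th <- noise_amplitudes_from_cvs(
    stationary_cv(linearize(make_two_protein_toy())),
    beta = 4, mu0 = 1, phi0 = c(X = 0.67, Y = 0.33),
    ratios = data.frame(source = "X", ref = "Y", ratio = 1))
  expect_equal(unname(th), c(0.5, 0.5), tolerance = 1e-10)

  set.seed(99)
  for (k in 1:10) {
    m <- random_feasible_model(n = sample(3:8, 1))
    lnm <- linearize(m)
    target <- stationary_cv(lnm)
    th <- noise_amplitudes_from_cvs(target, beta = m$proteins$beta,
                                    mu0 = m$mu0,
                                    phi0 = setNames(m$proteins$f, m$proteins$id))
    expect_equal(unname(th), m$proteins$theta, tolerance = 1e-10)
  }

  # a target below the extrinsic floor is reported as infeasible, by source
  expect_error(
    noise_amplitudes_from_cvs(c(a = 0.01, b = 1, c = 1), beta = 4, mu0 = 1,
                              phi0 = c(a = 0.2, b = 0.4, c = 0.4)),
    "extrinsic floor.*a")
})
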