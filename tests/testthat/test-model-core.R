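test_that("OU noise specs validate and expose the stationary variance", {
  src <- ou_noise("Y", theta = 0.5, beta = 4)
  expect_equal(ou_var(src), 0.5^2 / 8)
  expect_equal(ou_var(0.3, beta = 2), 0.3^2 / 4)
  expect_error(ou_noise("a", -0.1, 1), "non-negative")
  expect_error(ou_noise("a", 0.1, 0), "positive")
})

test_that("steady state is phi0 = f with mu0 from the growth function", {
  one <- cell_model(protein("only", f = 1), mu0 = 0.5)
  expect_identical(unname(steady_state(one)$phi0), 1)

  m <- cell_model(rbind(protein("A", 0.33), protein("B", 0.67)), mu0 = 1)
  ss <- steady_state(m)
  expect_identical(ss$phi0, c(A = 0.33, B = 0.67))
  expect_identical(ss$mu0, 1)

  # lac-like slow condition: phi_O = 0.3 * phi_half on a Monod curve
  lac <- cell_model(rbind(protein("O", 0.0015), protein("rest", 0.9985)),
                    growth = growth_monod(0.8, 0.005, "O"))
  expect_equal(steady_state(lac)$mu0, 0.8 * 0.3 / 1.3, tolerance = 1e-12)

  nog <- structure(list(proteins = rbind(protein("A", 0.4), protein("B", 0.6)),
                        shared = list(), growth = NULL, mu0 = NULL),
                   class = "gn_model")
  expect_error(steady_state(nog), "growth function or mu0")
})

test_that("model validation enforces the structural invariants", {
  expect_error(cell_model(rbind(protein("A", 0.5), protein("B", 0.6)),
                          mu0 = 1), "sum to 1")
  expect_error(protein("A", 1.2), "\\[0, 1\\]")
  expect_error(protein("h", 0.25, gcc = 0.1, nonmetabolic = TRUE), "-f")
  expect_silent(validate_model(
    cell_model(rbind(protein("h", 0.25, gcc = -0.25, nonmetabolic = TRUE),
                     protein("m", 0.75, gcc = 0.25)), mu0 = 1)))
  expect_error(
    cell_model(rbind(protein("A", 0.5), protein("B", 0.5)),
               shared = shared_noise("s", 0.1, 1, c(A = 0.5, NOPE = 0.5)),
               mu0 = 1),
    "unknown proteins")
  expect_error(shared_noise("s", 0.1, 1, c(A = 0.7, B = 0.7)), "sum to 1")
  expect_error(shared_noise("s", 0.1, 1, c(A = -0.2, B = 1.2)), "non-negative")
})

test_that("growth functions are intensive (degree-0 homogeneous)", {
  monod <- growth_monod(0.8, 0.005, "O")
  lin <- growth_linear(1, gcc = c(O = 0.2, rest = -0.2),
                       phi0 = c(O = 0.1, rest = 0.9))
  phi <- c(O = 0.1, rest = 0.9)
  for (alpha in c(0.5, 2, 10)) {
    expect_lt(abs(mu_d(monod, alpha * phi) - mu_d(monod, phi)), 1e-12)
    expect_lt(abs(mu_d(lin, alpha * phi) - mu_d(lin, phi)), 1e-12)
  }
})

test_that("numeric GCCs match the closed-form Monod derivative and sum to 0", {
  monod <- growth_monod(0.8, 0.005, "O")
  phi0 <- c(O = 0.0015, rest = 0.9985)
  gcc <- gcc_numeric(monod, phi0)
  # intensive extension derivative: (phi_half/(phi_half+phi_O)) * (1-phi_O)
  closed <- (0.005 / 0.0065) * (1 - 0.0015)
  expect_equal(unname(gcc["O"]), closed, tolerance = 1e-6)
  expect_lt(abs(sum(gcc)), 1e-6)

  # a constant growth function has no composition dependence at all
  const <- growth_linear(0.7, gcc = c(a = 0, b = 0), phi0 = c(a = 0.3, b = 0.7))
  expect_equal(unname(gcc_numeric(const, c(a = 0.3, b = 0.7))), c(0, 0),
               tolerance = 1e-9)

  expect_error(gcc_numeric(monod, c(O = 0, rest = 1)), "positive")
})

test_that("the Monod log-slope reproduces the printed operon GCCs", {
  slopes <- monod_log_slope(0.8, 0.005, c(0.3, 1.3, 15) * 0.005)
  expect_equal(slopes, c(1 / 1.3, 1 / 2.3, 1 / 16), tolerance = 1e-12)
  # and differs from the intensive multivariate derivative by (1 - phi_O)
  expect_gt(slopes[1], gcc_numeric(growth_monod(0.8, 0.005, "O"),
                                   c(O = 0.0015, r = 0.9985))["O"])
  expect_error(monod_log_slope(0.8, 0.005, 0), "positive")
})

test_that("GCC/FCC conversion fills the missing vector and reports residuals", {
  ca <- gcc_fcc_convert(fcc = c(0.4, 0.6), phi0 = c(0.4, 0.6))
  expect_equal(ca$gcc, c(0, 0))

  ca <- gcc_fcc_convert(fcc = c(1, 0), phi0 = c(0.4, 0.6))
  expect_equal(ca$gcc, c(0.6, -0.6))
  expect_equal(ca$residual_gcc, 0)
  expect_equal(ca$residual_fcc, 0)

  # non-metabolic protein: zero flux control implies gcc = -phi
  ca <- gcc_fcc_convert(fcc = c(0, 1), phi0 = c(0.25, 0.75))
  expect_equal(ca$gcc[1], -0.25)

  expect_error(gcc_fcc_convert(phi0 = c(0.5, 0.5)), "exactly one")
  expect_error(gcc_fcc_convert(gcc = 0.1, fcc = 0.2, phi0 = 1), "exactly one")
})

test_that("the non-metabolic sector forces equal positive metabolic control", {
  m <- cell_model(rbind(protein("h", 0.25, gcc = -0.25, nonmetabolic = TRUE),
                        protein("m", 0.75, gcc = 0.25)), mu0 = 1)
  expect_equal(nonmetabolic_sector(m),
               list(phiH = 0.25, residual_metabolic_control = 0.25))
  none <- cell_model(rbind(protein("a", 0.4), protein("b", 0.6)), mu0 = 1)
  expect_equal(nonmetabolic_sector(none)$phiH, 0)
})

test_that("the two-protein toy has the documented defaults", {
  toy <- make_two_protein_toy()
  expect_equal(sum(toy$proteins$gcc), 0)
  expect_equal(ou_var(toy$proteins$theta[2], toy$proteins$beta[2]), 0.03125)
  ss <- steady_state(toy)
  # phi0 is f, exactly
  expect_identical(ss$phi0, setNames(toy$proteins$f, toy$proteins$id))
  expect_equal(ss$phi0, c(X = 0.67, Y = 0.33))
  expect_identical(ss$mu0, 1)
})

test_that("rounding half away from zero matches printed two-figure values", {
  expect_equal(signif_half_up(c(1 / 1.3, 1 / 2.3, 0.0625), 2),
               c(0.77, 0.43, 0.063))
  expect_equal(signif_half_up(-0.0625, 2), -0.063)
  expect_equal(signif_half_up(0, 2), 0)
})

test_that("model configs round-trip losslessly through YAML and JSON", {
  toy <- make_two_protein_toy()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("toy.", ext))
    write_model_config(toy, path)
    back <- read_model_config(path)
    expect_identical(back$proteins$f, toy$proteins$f)
    expect_identical(back$proteins$theta, toy$proteins$theta)
    expect_identical(back$proteins$gcc, toy$proteins$gcc)
    expect_identical(back$mu0, toy$mu0)
  }
  # with a shared source and a Monod growth function
  m <- cell_model(rbind(protein("A", 0.5, theta = 0.2, beta = 2, operon = "op"),
                        protein("B", 0.5, theta = 0.3, beta = 2, operon = "op")),
                  shared = shared_noise("op", 0.1, 2, c(A = 0.5, B = 0.5)),
                  growth = growth_monod(0.8, 0.005, c("A")))
  path <- file.path(tempdir(), "op.yaml")
  write_model_config(m, path)
  back <- read_model_config(path)
  expect_identical(back$shared[[1]]$members, m$shared[[1]]$members)
  expect_s3_class(back$growth, "gn_growth_monod")
  expect_identical(back$growth$phi_half, 0.005)
})
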