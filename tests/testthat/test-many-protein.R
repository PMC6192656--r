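test_that("the synthetic proteome is deterministic with the stated structure", {
  a <- generate_background_proteome(seed = 3)
  b <- generate_background_proteome(seed = 3)
  expect_identical(a, b)
  expect_identical(nrow(a), 1018L)
  expect_true(all(a$mean_abundance > 0) && all(a$cv > 0))

  # extrinsic-floor limit of the CV law on the top-abundance decile of a
  # high-abundance draw: eta^2 -> b within the log-normal scatter
  big <- generate_background_proteome(seed = 4, abund_meanlog10 = 4,
                                      cv_a = 1, cv_b = 0.03)
  top <- big[big$mean_abundance >= quantile(big$mean_abundance, 0.9), ]
  expect_lt(abs(median(log10(top$cv^2 / 0.03))), 0.1)

  expect_error(generate_background_proteome(n_species = 1), "at least 2")
  expect_error(generate_background_proteome(cv_b = 0), "invalid")
})

test_that("proteome tables round-trip through TSV with validation", {
  tab <- generate_background_proteome(n_species = 25, seed = 1)
  path <- file.path(tempdir(), "prot.tsv")
  write_proteome(tab, path)
  back <- read_proteome(path)
  expect_equal(back$mean_abundance, tab$mean_abundance)
  expect_equal(back$cv, tab$cv)
  bad <- tab
  bad$mean_abundance[1] <- -1
  write_proteome(bad, path)
  expect_error(read_proteome(path), "positive")
  dup <- tab
  dup$id[2] <- dup$id[1]
  write_proteome(dup, path)
  expect_error(read_proteome(path), "unique")
})

test_that("growth conditions sit on the printed Monod operating points", {
  slow <- growth_condition("slow")
  expect_equal(slow$phi_O, 0.0015)
  expect_equal(slow$mu0, 0.8 * 0.3 / 1.3)
  expect_equal(signif_half_up(slow$gcc_O, 2), 0.77)
  inter <- growth_condition("intermediate")
  expect_equal(inter$mu0, 0.8 * 1.3 / 2.3)
  expect_equal(signif_half_up(inter$gcc_O, 2), 0.43)
  fast <- growth_condition("fast")
  expect_equal(fast$phi_O, 0.075)
  expect_equal(fast$mu0, 0.75)
  expect_equal(signif_half_up(fast$gcc_O, 2), 0.063)
})

test_that("the lac construct reserves one third of the operon mass per gene", {
  tab <- generate_background_proteome(seed = 1)
  m <- add_lac_construct(tab, growth_condition("fast"))
  expect_identical(nrow(m$proteins), 1021L)
  lac <- m$proteins$f[m$proteins$id %in% c("Y", "Z", "G")]
  expect_equal(lac, rep(0.075 / 3, 3), tolerance = 1e-12)
  expect_lt(abs(sum(m$proteins$f) - 1), 1e-12)
  mslow <- add_lac_construct(tab, growth_condition("slow"))
  expect_equal(sum(mslow$proteins$f[mslow$proteins$id %in% c("Y", "Z", "G")]),
               0.0015, tolerance = 1e-12)
})

test_that("GCC assignment honors the sum rule and the reporter identities", {
  for (cond in c("slow", "fast")) {
    m <- build_many_protein(cond, seed = 5)
    p <- m$proteins
    expect_lt(abs(sum(p$gcc)), 1e-10)
    gG <- p$gcc[p$id == "G"]
    expect_equal(gG, -p$f[p$id == "G"])
    gO <- growth_condition(cond)$gcc_O
    expect_equal(p$gcc[p$id == "Y"], (gO - gG) / 2, tolerance = 1e-12)
    expect_equal(p$gcc[p$id == "Y"], p$gcc[p$id == "Z"])
    # every flagged protein carries gcc = -phi
    h <- p$nonmetabolic
    expect_equal(p$gcc[h], -p$f[h])
  }
  # printed fast-condition reporter values: gcc_O = 0.063, gcc_G = -0.025,
  # hence gcc_Y = gcc_Z = 0.044
  m <- build_many_protein("fast", seed = 5)
  expect_equal(signif_half_up(m$meta$gcc_O, 2), 0.063)
  expect_equal(signif_half_up(m$proteins$gcc[m$proteins$id == "G"], 2), -0.025)
  expect_equal(signif_half_up(m$proteins$gcc[m$proteins$id == "Y"], 2), 0.044)
})

test_that("the non-metabolic sector lands near the target mass", {
  for (s in 1:4) {
    m <- build_many_protein("intermediate", seed = s)
    expect_lt(abs(nonmetabolic_sector(m)$phiH - 0.25), 0.03)
  }
})

test_that("the noise fit reproduces its constraints", {
  m <- build_many_protein("slow", seed = 2)
  expect_true(all(m$proteins$beta == 3.2))
  expect_equal(m$shared[[1]]$beta, 3.2)
  cv <- stationary_cv(m)
  expect_equal(unname(cv[c("Y", "Z", "G")]), rep(0.15, 3), tolerance = 1e-8)
  thG <- m$proteins$theta[m$proteins$id == "G"]
  expect_equal(m$shared[[1]]$theta / thG, 1.5, tolerance = 1e-8)
  # background CVs match the proteome table
  tab <- m$meta$proteome
  expect_equal(unname(cv[tab$id]), tab$cv, tolerance = 1e-8)
})

test_that("built models validate and are reproducible under seed", {
  m1 <- build_many_protein("fast", seed = 9)
  m2 <- build_many_protein("fast", seed = 9)
  expect_identical(m1$proteins, m2$proteins)
  expect_silent(validate_model(m1))
  expect_equal(steady_state(build_many_protein("intermediate", seed = 1))$mu0,
               0.8 * 1.3 / 2.3)
})
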