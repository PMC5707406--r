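test_that("torsion sampling is a pure function of (spec, seed)", {
  sp <- cdn_torsion_spec("purine")
  s1 <- sample_torsion_ensemble(sp, 200, seed = 4)
  s2 <- sample_torsion_ensemble(sp, 200, seed = 4)
  expect_identical(s1, s2)
  s3 <- sample_torsion_ensemble(sp, 200, seed = 5)
  expect_false(identical(s1$residues$res1$chi, s3$residues$res1$chi))
})

test_that("concentration limits behave: point mass and circular mean", {
  sp <- torsion_spec(gamma = data.frame(mean = 53, kappa = 1e7, weight = 1))
  s <- sample_torsion_ensemble(sp, 100, seed = 1, n_residues = 1)
  expect_true(all(abs(s$residues$res1$gamma - 53) < 1))
  ## n = 10000, kappa = 50: circular mean within 3 SE of the true mean
  sp2 <- torsion_spec(gamma = data.frame(mean = 53, kappa = 50, weight = 1))
  g <- sample_torsion_ensemble(sp2, 10000, seed = 2,
                               n_residues = 1)$residues$res1$gamma
  cmean <- atan2(mean(sin(orc_d2r(g))), mean(cos(orc_d2r(g)))) * 180 / pi
  se_deg <- (1 / sqrt(10000 * 50)) * 180 / pi
  expect_lt(abs(cmean - 53), 3 * se_deg)
})

test_that("spec validation rejects malformed mixtures", {
  expect_error(torsion_spec(chi = data.frame(mean = 1, kappa = -2,
                                             weight = 1)), ">= 0")
  expect_error(torsion_spec(chi = data.frame(mean = c(0, 10),
                                             kappa = c(5, 5),
                                             weight = c(0.6, 0.6))),
               "sum to 1")
  expect_error(sample_torsion_ensemble(list(), 10), "torsion_spec")
  expect_error(sample_torsion_ensemble(cdn_torsion_spec(), 0), ">= 1")
})

test_that("coupling generation round-trips through the pucker fit", {
  reg <- load_karplus_registry()
  sets <- generate_ribose_couplings(0, 41, 1, sigma = 0, n_replicates = 1)
  fit <- fit_two_state_pucker(sets[[1]], registry = reg)
  expect_equal(fit$P_N, 0, tolerance = 1e-3)
  expect_equal(fit$psi_N, 41, tolerance = 1e-3)
  expect_equal(fit$f_N, 1, tolerance = 1e-4)
  ## f_N = 0 boundary: the pure fixed-S prediction
  s0 <- generate_ribose_couplings(20, 41, 0, sigma = 0)[[1]]
  expect_equal(s0$J_Hz,
               unname(predict_ribose_jhh(pucker_params(163, 38), reg)),
               tolerance = 1e-12)
  expect_error(generate_ribose_couplings(0, 41, 1, sigma = -1), "sigma")
  expect_error(generate_ribose_couplings(0, 41, 1.4), "f_N")
  ## seed reproducibility with noise
  a <- generate_ribose_couplings(0, 41, 1, sigma = 0.3, seed = 9)
  b <- generate_ribose_couplings(0, 41, 1, sigma = 0.3, seed = 9)
  expect_identical(a[[1]]$J_Hz, b[[1]]$J_Hz)
})

test_that("full pipeline recovery: sampled class fractions are recovered", {
  ## known syn weight; binomial 99% bounds at n = 5000 (pooled 2 residues)
  w_syn <- 0.157
  sp <- cdn_torsion_spec("purine")  # syn weight = exp(-1/kT)/(1+exp(-1/kT))
  w_spec <- sp$chi$weight[2]
  expect_equal(w_spec, w_syn, tolerance = 0.01)
  s <- sample_torsion_ensemble(sp, 5000, seed = 13)
  fr <- population_fractions(s, "glycosidic")
  n_tot <- 10000
  bound <- qnorm(0.995) * sqrt(w_spec * (1 - w_spec) / n_tot)
  expect_lt(abs(fr[["syn"]] - w_spec), bound + 0.01)
})

test_that("macrocycle template realizes requested torsions", {
  e1 <- make_template(delta = 84)
  e2 <- make_template(delta = 84)
  expect_identical(e1$frames[[1]], e2$frames[[1]])  # bitwise deterministic
  s <- compute_torsion_series(e1)
  r1 <- s$residues$res1[1, ]
  r2 <- s$residues$res2[1, ]
  ## torsions on the construction tree reproduce to 1e-3 degrees
  expect_equal(r1$delta, 84, tolerance = 1e-3)
  expect_equal(r2$delta, 84, tolerance = 1e-3)
  for (tor in c("beta", "gamma", "chi")) {
    expect_equal(r1[[tor]], c(beta = -172, gamma = 53, chi = -149)[[tor]],
                 tolerance = 1e-3)
    expect_equal(r2[[tor]], c(beta = -172, gamma = 53, chi = -149)[[tor]],
                 tolerance = 1e-3)
  }
  expect_equal(r1$epsilon, -155, tolerance = 1e-3)
  expect_equal(r1$zeta, 70, tolerance = 1e-3)
  expect_equal(r2$alpha, 75, tolerance = 1e-3)
  ## nu0/nu4 derived from (P, psi_m)
  expect_equal(r1$nu0, orc_nu(10, 41, 0), tolerance = 1e-3)
  expect_equal(r1$nu4, orc_nu(10, 41, 4), tolerance = 1e-3)
  expect_error(build_macrocycle_template(list(res1 = list(beta = 1))),
               "incomplete torsion set")
})
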