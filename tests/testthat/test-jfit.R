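reg <- load_karplus_registry()
j_obs <- function(fragment, J) {
  suppressWarnings(jcoupling_set(fragment, J, registry = reg))
}

test_that("two-state fit recovers a pure N state exactly", {
  j <- predict_ribose_jhh(pucker_params(0, 41), reg)
  fit <- fit_two_state_pucker(j_obs(names(j), j), registry = reg)
  expect_equal(fit$P_N, 0, tolerance = 1e-3)
  expect_equal(fit$psi_N, 41, tolerance = 1e-3)
  expect_equal(fit$f_N, 1, tolerance = 1e-4)
  expect_lt(fit$rmsd_J, 1e-4)
})

test_that("two-state mixture fit agrees with the brute-force grid oracle", {
  jm <- 0.6 * orc_ribose_j(10, 38, reg) + 0.4 * orc_ribose_j(163, 38, reg)
  fit <- fit_two_state_pucker(j_obs(names(jm), jm), registry = reg)
  oracle <- orc_two_state_grid(jm, reg)
  expect_lt(abs(fit$P_N - oracle$P), 1)
  expect_lt(abs(fit$psi_N - oracle$psi), 1)
  expect_lt(abs(fit$f_N - oracle$f), 0.02)
})

test_that("fit residual is self-consistent with its returned parameters", {
  jm <- 0.8 * orc_ribose_j(5, 40, reg) + 0.2 * orc_ribose_j(163, 38, reg)
  jm <- jm + c(0.1, -0.2, 0.15)  # deliberate misfit
  fit <- fit_two_state_pucker(j_obs(names(jm), jm), registry = reg)
  pred <- fit$f_N * predict_ribose_jhh(pucker_params(fit$P_N, fit$psi_N),
                                       reg) +
    (1 - fit$f_N) * predict_ribose_jhh(fit$fixed_S, reg)
  expect_equal(fit$rmsd_J, sqrt(mean((pred - jm)^2)), tolerance = 1e-10)
})

test_that("underdetermined fits error and name the parameters to fix", {
  two <- j_obs(c("H1'H2'", "H2'H3'"), c(1.2, 4.3))
  expect_error(fit_two_state_pucker(two, registry = reg), "underdetermined")
  expect_error(fit_two_state_pucker(two, registry = reg), "P_N|psi_N|f_N")
  ## fixing one parameter makes two couplings sufficient
  fit <- fit_two_state_pucker(two, fix = list(psi_N = 41), registry = reg)
  expect_equal(fit$psi_N, 41)
  one <- j_obs("H1'H2'", 1.2)
  expect_error(fit_two_state_pucker(one, registry = reg), "at least two")
})

test_that("rotamer fit recovers pure states and oracle-checked mixtures", {
  for (i in 1:3) {
    gam <- c(53, 180, -70)[i]
    j <- predict_gamma_jhh(gam, reg)
    fit <- fit_gamma_rotamers(j[1], j[2], registry = reg)
    want <- c(0, 0, 0); want[i] <- 1
    expect_equal(unname(fit$fractions), want, tolerance = 1e-6)
  }
  Jmat <- t(predict_gamma_jhh(c(53, 180, -70), reg))
  set.seed(3)
  for (rep in 1:4) {
    f_true <- as.numeric(stats::rmultinom(1, 40, c(1, 1, 1))) / 40
    jm <- as.numeric(Jmat %*% f_true)
    fit <- fit_gamma_rotamers(jm[1], jm[2], registry = reg)
    oracle <- orc_rotamer_grid(jm, Jmat)
    expect_lt(max(abs(fit$fractions - oracle$f)), 0.01)
    ## valid probability vector
    expect_true(all(fit$fractions >= 0))
    expect_equal(sum(fit$fractions), 1, tolerance = 1e-9)
    ## residual self-consistency
    expect_equal(fit$residual,
                 sqrt(mean((Jmat %*% fit$fractions - jm)^2)),
                 tolerance = 1e-10)
  }
})

test_that("rotamer fit is invariant to swapping couplings with the map", {
  jm <- as.numeric(t(predict_gamma_jhh(c(53, 180, -70), reg)) %*%
                     c(0.5, 0.3, 0.2))
  fit1 <- fit_gamma_rotamers(jm[1], jm[2], registry = reg)
  reg_sw <- reg
  reg_sw$proton_torsion_map[c("H4'H5'", "H4'H5''")] <-
    reg$proton_torsion_map[c("H4'H5''", "H4'H5'")]
  fit2 <- fit_gamma_rotamers(jm[2], jm[1], registry = reg_sw)
  expect_equal(fit1$fractions, fit2$fractions, tolerance = 1e-8)
})

test_that("rotamer misfit beyond 1 Hz warns", {
  expect_warning(fit_gamma_rotamers(14.5, 14.5, registry = reg), "misfit")
})

test_that("backbone scan finds the generating torsion and matches the scan oracle", {
  ## self-consistency at exactly 180 degrees
  j180 <- predict_backbone_j(180, "beta", reg)[1, ]
  scan <- estimate_backbone_torsion(j_obs(names(j180), j180), "beta",
                                    registry = reg)
  expect_true(any(scan$candidates$angle == 180 |
                    scan$candidates$angle == -180))
  expect_lt(scan$candidates$residual[1], 1e-10)
  ## two-coupling synthetic case vs the duplicated exhaustive scan
  frags <- c("H5'P", "C4'Pb")
  jobs <- predict_backbone_j(-73, "beta", reg)[1, frags]
  scan2 <- estimate_backbone_torsion(j_obs(frags, jobs), "beta",
                                     registry = reg)
  oracle <- orc_backbone_scan(jobs, reg$backbone_fragment_map[frags], reg)
  o_rmsd <- sqrt(oracle$min_sse / length(frags))
  o_ang <- sort(oracle$minima[o_rmsd <= 2 * min(o_rmsd) + 1e-9])
  ## same candidate angles, angle for angle (sorted)
  expect_equal(sort(scan2$candidates$angle), o_ang)
  expect_equal(scan2$candidates$angle[1], -73)
})

test_that("backbone scan errors without relevant couplings", {
  obs <- j_obs("H1'H2'", 2.2)
  expect_error(estimate_backbone_torsion(obs, "beta", registry = reg),
               "beta.*H5'P|expected")
  expect_error(estimate_backbone_torsion(obs, "epsilon", registry = reg),
               "epsilon")
})

test_that("candidate list is sorted by residual with the best flagged", {
  frags <- c("H3'P", "C2'P", "C4'Pe")
  jobs <- predict_backbone_j(-150, "epsilon", reg)[1, frags]
  scan <- estimate_backbone_torsion(j_obs(frags, jobs), "epsilon",
                                    registry = reg)
  expect_true(!is.unsorted(scan$candidates$residual))
  expect_identical(scan$best, 1L)
  expect_equal(scan$candidates$angle[1], -150)
})
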