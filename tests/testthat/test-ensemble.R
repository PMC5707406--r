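test_that("dihedral_angle reproduces constructed geometries", {
  ## four points built to have a known 60-degree dihedral
  p1 <- c(cos(pi / 3), sin(pi / 3), -1)  # rotated 60 deg about z from x-axis
  p2 <- c(0, 0, 0)
  p3 <- c(0, 0, 1)
  p4 <- c(1, 0, 2)
  expect_equal(dihedral_angle(p1, p2, p3, p4), -60, tolerance = 1e-9)
  expect_equal(dihedral_angle(p4, p3, p2, p1), -60, tolerance = 1e-9)
})

test_that("dihedral_angle matches the independent oracle on random points", {
  set.seed(99)
  for (i in 1:1000) {
    q <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ]),
                 orc_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-6)
  }
})

test_that("compute_torsion_series is deterministic and oracle-consistent", {
  e1 <- make_template()
  e2frames <- list(e1$frames[[1]], e1$frames[[1]])
  e2 <- conformer_ensemble(e2frames, e1$atoms)
  s <- compute_torsion_series(e2)
  expect_equal(s$residues$res1[1, ], s$residues$res1[2, ],
               ignore_attr = TRUE)
  ## random multi-frame ensemble: every dihedral matches the oracle
  set.seed(21)
  frames <- lapply(1:50, function(i) {
    e1$frames[[1]] + matrix(rnorm(length(e1$frames[[1]]), sd = 0.05),
                            ncol = 3)
  })
  er <- conformer_ensemble(frames, e1$atoms)
  sr <- compute_torsion_series(er)
  idx <- function(rid, nm) which(e1$atoms$res_id == rid &
                                   e1$atoms$atom_name == nm)
  for (f in c(1, 25, 50)) {
    m <- frames[[f]]
    chi_o <- orc_dihedral(m[idx(1, "O4'"), ], m[idx(1, "C1'"), ],
                          m[idx(1, "N9"), ], m[idx(1, "C4"), ])
    expect_equal(sr$residues$res1$chi[f], chi_o, tolerance = 1e-6)
    del_o <- orc_dihedral(m[idx(2, "C5'"), ], m[idx(2, "C4'"), ],
                          m[idx(2, "C3'"), ], m[idx(2, "O3'"), ])
    expect_equal(sr$residues$res2$delta[f], del_o, tolerance = 1e-6)
    ## wrap-around alpha of residue 1 uses O3' of residue 2
    alp_o <- orc_dihedral(m[idx(2, "O3'"), ], m[idx(1, "P"), ],
                          m[idx(1, "O5'"), ], m[idx(1, "C5'"), ])
    expect_equal(sr$residues$res1$alpha[f], alp_o, tolerance = 1e-6)
  }
})

test_that("missing atoms produce a named error", {
  e <- make_template()
  keep <- !(e$atoms$res_id == 2 & e$atoms$atom_name == "O3'")
  e_bad <- conformer_ensemble(list(e$frames[[1]][keep, ]),
                              e$atoms[keep, ])
  expect_error(compute_torsion_series(e_bad), "O3'")
  expect_error(compute_torsion_series(e_bad), "alpha|delta|epsilon|zeta")
})

test_that("population fractions count constructed mixtures exactly", {
  s <- structure(list(residues = list(res1 = data.frame(
    chi = c(rep(60, 70), rep(180, 30)),
    P = rep(10, 100),
    gamma = rep(84, 100))), n_frames = 100), class = "torsion_series")
  fr <- population_fractions(s, "glycosidic")
  expect_equal(unname(fr), c(0.70, 0.30))
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(population_fractions(s, "pucker")[["N"]], 1)
  expect_equal(population_fractions(s, "rotamer",
                                    torsion = "gamma")[["g+"]], 1)
  expect_equal(sum(population_fractions(s, "rotamer", torsion = "gamma")),
               1, tolerance = 1e-12)
  expect_error(population_fractions(s, "rotamer"), "torsion")
  s_all_anti <- structure(list(residues = list(res1 = data.frame(
    chi = rep(180, 5))), n_frames = 5), class = "torsion_series")
  expect_equal(population_fractions(s_all_anti, "glycosidic")[["anti"]], 1)
})

test_that("free-energy landscape obeys its closed forms", {
  ## perfectly uniform: every occupied bin at G = 0
  mids <- seq(-177.5, 177.5, by = 5)
  chi <- rep(mids, times = length(mids))
  P <- rep(mids, each = length(mids))
  l <- free_energy_landscape(chi, P, nbins = 72, T = 300)
  expect_true(all(l$counts == 1))
  expect_true(all(abs(l$G) < 1e-12))
  ## half-max bin at 300 K: G = kB * 300 * ln 2 = 0.413 kcal/mol
  l2 <- free_energy_landscape(c(rep(0, 4), rep(100, 2)),
                              c(rep(0, 4), rep(100, 2)), nbins = 8,
                              T = 300)
  expect_equal(sort(unique(as.numeric(l2$G[!is.na(l2$G)]))),
               c(0, 0.0019872 * 300 * log(2)), tolerance = 1e-9)
  expect_equal(0.0019872 * 300 * log(2), 0.413, tolerance = 1e-3)
  ## empty bins undefined, never zero; min over occupied bins exactly 0
  expect_true(anyNA(l2$G))
  expect_identical(min(l2$G, na.rm = TRUE), 0)
  expect_error(free_energy_landscape(0, 0, T = -3), "'T'")
  expect_error(free_energy_landscape(0, 0, nbins = 1), "nbins")
})

test_that("landscape G is invariant under count scaling", {
  set.seed(5)
  chi <- runif(500, -180, 180)
  P <- runif(500, -90, 90)
  l1 <- free_energy_landscape(chi, P, nbins = 12)
  l3 <- free_energy_landscape(rep(chi, 3), rep(P, 3), nbins = 12)
  expect_equal(l1$G, l3$G, tolerance = 1e-12)
})

test_that("basin counting distinguishes unimodal from bimodal landscapes", {
  ts_uni <- sample_torsion_ensemble(cdn_torsion_spec("pyrimidine"),
                                    8000, seed = 31)
  chi <- unlist(lapply(ts_uni$residues, `[[`, "chi"), use.names = FALSE)
  P <- unlist(lapply(ts_uni$residues, `[[`, "P"), use.names = FALSE)
  l <- free_energy_landscape(chi, P, nbins = 24)
  b <- landscape_basins(l, 1.5)
  expect_identical(b$n_basins, 1L)
  ts_bi <- sample_torsion_ensemble(cdn_torsion_spec("purine"),
                                   8000, seed = 32)
  chi2 <- unlist(lapply(ts_bi$residues, `[[`, "chi"), use.names = FALSE)
  P2 <- unlist(lapply(ts_bi$residues, `[[`, "P"), use.names = FALSE)
  l2 <- free_energy_landscape(chi2, P2, nbins = 24)
  b2 <- landscape_basins(l2, 2)
  expect_identical(b2$n_basins, 2L)
  ## threshold below the shallow basin depth: only the deep basin remains
  b3 <- landscape_basins(l2, 0.5)
  expect_identical(b3$n_basins, 1L)
  expect_error(landscape_basins(l2, 0), "threshold")
})
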