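test_that("proposed steps have fixed length and the right moments", {
  set.seed(3)
  st <- propose_step(1e5, D = 1, dt = 0.01)
  expect_true(all(abs(abs(st) - sqrt(0.02)) < 1e-12))
  # per-component mean square displacement = 2 D dt within 3 SDs; the
  # component is +/-L so the MSD check reduces to the mean of L^2 exactly,
  # and the mean displacement must vanish statistically
  se <- sqrt(0.02) / sqrt(1e5)
  expect_lt(abs(mean(st[, 1])), 3 * se)
  expect_lt(abs(mean(st[, 3])), 3 * se)
  expect_equal(mean(st^2), 0.02, tolerance = 1e-12)
  expect_equal(abs(st[1, 1]), 0.1414, tolerance = 1e-3)
})

test_that("transit probabilities follow the hybrid model", {
  expect_equal(transit_probability(0, 0.5), 0)
  expect_gt(transit_probability(1e9, 0.5), 1 - 1e-8)
  expect_equal(transit_probability(0.01, 0.5, D_ics = 1),
               0.01 / 1.01, tolerance = 1e-12)
  # extracellular to intracellular pays the diffusivity-step factor
  expect_equal(transit_probability(0.01, 0.5, 1, 2.5, "ECS->ICS"),
               0.01 / 1.01 * (1 / 2.5), tolerance = 1e-12)
  expect_equal(transit_probability(0.01, 0.5, 1, 2.5, "ECS->ICS",
                                   pd_exponent = 0.5),
               0.01 / 1.01 * sqrt(1 / 2.5), tolerance = 1e-12)
  # clamped dx floor keeps the probability positive on-membrane
  expect_gt(transit_probability(0.01, 1e-12), 0)
})

test_that("membrane advance reflects, crosses, and leaves free paths exact", {
  s <- square_cell_substrate(icd_depth = 0)
  cd <- myowalk:::substrate_cdata(s)
  # impermeable wall at x = 1.5: mirror image of the unimpeded endpoint
  r <- myowalk:::mw_advance(cd, c(1.6, 1.0, 5), c(-0.3, 0.1, 0),
                            1, 2.5, 0, 0, 1, 50, 1)
  expect_equal(r$pos, c(1.7, 1.1, 5), tolerance = 1e-7)
  expect_equal(r$comp, -1L)
  # effectively infinite permeability, equal diffusivities: straight through
  r2 <- myowalk:::mw_advance(cd, c(1.6, 1.0, 5), c(-0.3, 0.1, 0),
                             2.5, 2.5, 1e9, 1e9, 1, 50, 1)
  expect_equal(r2$pos, c(1.3, 1.1, 5), tolerance = 1e-7)
  expect_equal(r2$comp, 0L)
  # no membrane: exact displacement
  r3 <- myowalk:::mw_advance(cd, c(0.2, 0.2, 5), c(0.05, 0.05, 0.05),
                             1, 2.5, 0, 0, 1, 50, 1)
  expect_equal(r3$pos, c(0.25, 0.25, 5.05), tolerance = 1e-12)
  # crossing into the cell rescales the remaining path by sqrt(D_in/D_out)
  r4 <- myowalk:::mw_advance(cd, c(1.6, 1.0, 5), c(-0.2, 0, 0),
                             1, 4, 1e9, 1e9, 1, 50, 1)
  expect_equal(r4$pos[1], 1.5 - 0.1 * sqrt(1 / 4), tolerance = 1e-7)
})

test_that("walker seeding matches compartment volumes and is reproducible", {
  s <- packed_substrate(30, voxel = c(500, 500, 500))
  cfg <- walk_config(Np = 20000, Nt = 10, seed = 6)
  w1 <- seed_walkers(s, cfg, buffer = 0)
  w2 <- seed_walkers(s, cfg, buffer = 0)
  expect_identical(w1, w2)
  expect_true(all(abs(w1$x) <= 250 & abs(w1$y) <= 250 & abs(w1$z) <= 250))
  target <- ecv(s$block$cross_sections)
  se <- sqrt(target * (1 - target) / nrow(w1))
  expect_lt(abs(mean(w1$compartment == "ECS") - target), 3 * se)
})

test_that("free diffusion reproduces exp(-b D) and signal bounds hold", {
  s <- empty_substrate(voxel = c(500, 500, 500))
  cfg <- walk_config(Np = 2e4, Nt = 2000, seed = 7)
  sig <- run_diffusion(s, list(PGSE = sequence_spec("PGSE")), cfg,
                       encoding_scheme(b = 0.6, bref = 0.15))
  sig2 <- run_diffusion(s, list(PGSE = sequence_spec("PGSE")), cfg,
                        encoding_scheme(b = 0.6, bref = 0.15))
  expect_identical(sig$S_over_S0, sig2$S_over_S0)     # determinism
  expect_true(all(sig$S_over_S0 >= 0 & sig$S_over_S0 <= 1))
  n <- sig$n_walkers[1]
  for (b in c(0.15, 0.6)) {
    Sexp <- exp(-b * 2.5)
    Sobs <- sig$S_over_S0[sig$b == b]
    expect_true(all(abs(Sobs - Sexp) < 3 * phasor_se(Sexp, n)))
  }
  # monotone non-increasing in b per direction
  lo <- sig[sig$b == 0.15, ]
  hi <- sig[sig$b == 0.6, ]
  expect_true(all(hi$S_over_S0 < lo$S_over_S0))
  # b = 0 measurement is exactly 1
  sig0 <- run_diffusion(s, sequence_spec("PGSE"), cfg,
                        encoding_scheme(b = 0.6, bref = 0))
  expect_equal(sig0$S_over_S0[sig0$b == 0], 1)
})

test_that("transit model conserves compartment occupancy at equilibrium", {
  s <- packed_substrate(30)
  cfg <- walk_config(Np = 6000, Nt = 600, kappa_sarco = 0.02, seed = 4)
  sig <- run_diffusion(s, list(PGSE = sequence_spec("PGSE")), cfg)
  st <- attr(sig, "walk_stats")
  p0 <- st$ics_frac_init
  se <- sqrt(p0 * (1 - p0) / cfg$Np)
  expect_lt(abs(st$ics_frac_final - p0), 3 * se)
  expect_equal(st$overflow, 0)
})

test_that("restricted diffusion in the packed substrate is anisotropic", {
  s <- packed_substrate(30)
  cfg <- walk_config(Np = 4000, Nt = 500, seed = 5)
  sig <- run_diffusion(s, list(PGSE = sequence_spec("PGSE")), cfg)
  ft <- fit_tensor(sig, bref = 0.15)
  # principal diffusion along the cardiomyocyte long axis, restricted across
  expect_gt(abs(ft$eigenvectors[3, 1]), 0.9)
  expect_gt(ft$eigenvalues[1], ft$eigenvalues[2])
  expect_gt(ft$FA, 0.2)
  expect_lt(ft$eigenvalues[1], 2.5)
  # raising permeability reduces the anisotropy
  cfgk <- walk_config(Np = 4000, Nt = 500, kappa_sarco = 0.05, seed = 5)
  ftk <- fit_tensor(run_diffusion(s, list(PGSE = sequence_spec("PGSE")), cfgk),
                    bref = 0.15)
  expect_lt(ftk$FA, ft$FA)
})
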