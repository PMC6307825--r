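test_that("planted H-bond occupancy is exact and seed-stable in truth", {
  cx <- make_complex_ensemble(100, hbonds = list(list(occupancy = 0.70)),
                              seed = 1)
  spec <- cx$truth$hbond_specs[[1]]
  present <- vapply(cx$ensemble$frames, hbond_present, TRUE, spec = spec)
  expect_equal(sum(present), 70L)
  expect_identical(present, as.vector(cx$truth$hbond_frames[, 1]))
  # different seeds: different coordinates, identical truth summary
  cx2 <- make_complex_ensemble(100, hbonds = list(list(occupancy = 0.70)),
                               seed = 2)
  expect_false(identical(cx$ensemble$frames[[1]], cx2$ensemble$frames[[1]]))
  expect_identical(cx$truth$hbond_occupancies, cx2$truth$hbond_occupancies)
  # same seed: bit-reproducible
  cx3 <- make_complex_ensemble(100, hbonds = list(list(occupancy = 0.70)),
                               seed = 1)
  expect_identical(cx$ensemble$frames, cx3$ensemble$frames)
})

test_that("planted stacking geometry is detected in every frame", {
  cx <- make_complex_ensemble(20, stacks = list(list(d = 0.35, theta = 10)),
                              seed = 5)
  spec <- cx$truth$stack_specs[[1]]
  for (fr in cx$ensemble$frames) {
    expect_true(stack_present(fr, spec))
    g <- rnadynr:::stack_geometry(fr, spec)
    expect_equal(g[[1]], 0.35, tolerance = 1e-9)
    expect_equal(g[[2]], 10, tolerance = 1e-6)
  }
})

test_that("dihedral fixture plants exact minority fractions", {
  fx <- make_dihedral_fixture(200, plan = list(
    list(mode = "fluct", center = c(-63, -43), sigma = 5),
    list(mode = "switch", major = c(-63, -43), minor = c(-120, 130),
         fraction = 0.40, sigma = 5),
    list(mode = "switch", major = c(-63, -43), minor = c(-120, 130),
         fraction = 0.10, sigma = 5)), seed = 4)
  expect_equal(fx$truth$minority_fractions, c(0, 0.40, 0.10))
  expect_length(fx$phi[[2]]$values, 200L)
  expect_error(make_dihedral_fixture(10, plan = list(
    list(mode = "switch", major = c(0, 0), minor = c(90, 90),
         fraction = 1.2))), "fraction")
})

test_that("work samples satisfy the Gaussian Crooks closed form", {
  kT <- kT_at(298)
  dg <- 3 * kT; sigma <- 2 * kT  # sigma^2 = 4 kT^2
  ws <- make_work_samples(dg, sigma, 40000, 40000, 298, seed = 6)
  # mu_F = dG + sigma^2/(2 kT) = 5 kT; mu_R = -dG + sigma^2/(2 kT) = -1 kT
  expect_equal(mean(ws$forward) / kT, 5, tolerance = 0.05)
  expect_equal(mean(ws$reverse) / kT, -1, tolerance = 0.1)
  expect_equal(sd(ws$forward) / kT, 2, tolerance = 0.05)
  # zero-dissipation limit
  ws0 <- make_work_samples(1.3, 0, 5, 5, 298, seed = 1)
  expect_true(all(ws0$forward == 1.3) && all(ws0$reverse == -1.3))
  # seed contract
  expect_identical(make_work_samples(1, 0.5, 10, 10, 298, 9)$forward,
                   make_work_samples(1, 0.5, 10, 10, 298, 9)$forward)
})

test_that("cluster mixture plants separable labelled conformers", {
  mix <- make_cluster_mixture(3, 30, separation = 1.0, noise = 0.02,
                              seed = 8)
  sel <- mix$ensemble$topology$atom_index
  for (a in 1:2) for (b in (a + 1):3)
    expect_gte(superposed_rmsd(mix$truth$conformers[[a]],
                               mix$truth$conformers[[b]], sel), 1.0)
  # noise 0 -> frames identical to their conformer
  mix0 <- make_cluster_mixture(2, 6, separation = 1.0, noise = 0,
                               seed = 2)
  for (f in seq_len(6))
    expect_equal(mix0$ensemble$frames[[f]],
                 mix0$truth$conformers[[mix0$truth$labels[f]]])
  expect_identical(sort(unique(make_cluster_mixture(1, 5, seed = 1)$truth$labels)),
                   1L)
  expect_warning(make_cluster_mixture(2, 10, separation = 0.05,
                                      noise = 0.02, seed = 1),
                 "unidentifiable")
})

test_that("NOE fixture plants exact satisfaction status and margins", {
  cx <- make_complex_ensemble(10, hbonds = list(list(occupancy = 0.5)),
                              seed = 3)
  fx <- make_noe_fixture(cx$ensemble, 8, 2, margin = 0.05, seed = 2)
  expect_length(fx$restraints, 10L)
  for (i in seq_along(fx$restraints)) {
    r <- backcalc_noe(cx$ensemble, fx$restraints[[i]])
    if (fx$truth$violated[i])
      expect_equal(r - fx$restraints[[i]]$bound_nm, 0.05, tolerance = 1e-9)
    else
      expect_equal(fx$restraints[[i]]$bound_nm - r, 0.05, tolerance = 1e-9)
  }
  expect_error(make_noe_fixture(cx$ensemble, 2, 2, margin = 0), "positive")
})
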