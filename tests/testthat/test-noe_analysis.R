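test_that("r^-6 averaging matches hand-computable cases", {
  topo <- data.frame(atom_index = 0:1, atom_name = c("H1", "H2"),
                     element = c("H", "H"), residue_index = c(1L, 2L),
                     residue_name = "GLY", chain_id = "A",
                     stringsAsFactors = FALSE)
  at <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  r <- noe_restraint("A:1:H1", "A:2:H2", 0.5, "intra_protein")
  # single frame: identity
  expect_equal(backcalc_noe(ensemble(topo, list(at(0.30))), r), 0.30)
  # two frames at 0.2 / 0.4 nm
  ens2 <- ensemble(topo, list(at(0.2), at(0.4)))
  expect_equal(backcalc_noe(ens2, r),
               ((0.2^-6 + 0.4^-6) / 2)^(-1 / 6), tolerance = 1e-12)
  expect_equal(backcalc_noe(ens2, r), 0.224, tolerance = 1e-2)
  # constant distance over any number of frames
  ens5 <- ensemble(topo, rep(list(at(0.33)), 5))
  expect_equal(backcalc_noe(ens5, r), 0.33, tolerance = 1e-12)
})

test_that("r^-6 average is a generalized mean and pools over frames", {
  ens <- random_toy_ensemble(6, seed = 31)
  r <- noe_restraint("A:1:CA", "R:2:P", 0.4, "intermolecular")
  per_frame <- vapply(ens$frames, function(fr)
    sqrt(sum((fr[1, ] - fr[2, ])^2)), 0)
  avg <- backcalc_noe(ens, r)
  expect_gte(avg, min(per_frame) - 1e-12)
  expect_lte(avg, max(per_frame) + 1e-12)
  # duplicating a frame leaves the constant-weight mean property intact:
  # report on pooled frames equals Eq 3 on the concatenation
  ens_dup <- ensemble(ens$topology, c(ens$frames, ens$frames))
  expect_equal(backcalc_noe(ens_dup, r), avg, tolerance = 1e-12)
  ensA <- ensemble(ens$topology, ens$frames[1:2])
  ensB <- ensemble(ens$topology, ens$frames[3:6])
  pooled <- mean(c(per_frame[1:2]^-6, per_frame[3:6]^-6))^(-1 / 6)
  expect_equal(backcalc_noe(ens, r), pooled, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    pooled, mean(c(backcalc_noe(ensA, r), backcalc_noe(ensB, r))))))
})

test_that("multi-atom groups combine by per-frame r^-6 summation", {
  topo <- data.frame(atom_index = 0:2,
                     atom_name = c("H1", "H2", "HX"),
                     element = "H", residue_index = c(1L, 1L, 2L),
                     residue_name = "GLY", chain_id = "A",
                     stringsAsFactors = FALSE)
  fr <- rbind(c(0, 0, 0), c(0, 0.1, 0), c(0.3, 0, 0))
  ens <- ensemble(topo, list(fr))
  r <- noe_restraint("A:1:H1,A:1:H2", "A:2:HX", 0.5, "intra_protein")
  d1 <- 0.3; d2 <- sqrt(0.3^2 + 0.1^2)
  expect_equal(backcalc_noe(ens, r), (d1^-6 + d2^-6)^(-1 / 6),
               tolerance = 1e-12)
  expect_equal(backcalc_noe(ens, r, group_mode = "min"), 0.3,
               tolerance = 1e-12)
})

test_that("violation reports recover planted truth and thresholds", {
  cx <- make_complex_ensemble(20, hbonds = list(list(occupancy = 0.5)),
                              seed = 13)
  fx <- make_noe_fixture(cx$ensemble, 8, 2, margin = 0.04, seed = 5)
  rep <- violation_report(cx$ensemble, fx$restraints)
  expect_equal(rep$summary$satisfied_fraction, 0.80)
  expect_identical(rep$table$violated, fx$truth$violated)
  expect_equal(rep$summary$avg_violation_over_violated_nm, 0.04,
               tolerance = 1e-9)
  expect_equal(rep$summary$avg_violation_over_all_nm, 0.04 * 2 / 10,
               tolerance = 1e-9)
  # threshold counts: planted margins 0.06 and 0.02 -> one count > 0.05
  fx2 <- make_noe_fixture(cx$ensemble, 0, 1, margin = 0.06, seed = 6)
  fx3 <- make_noe_fixture(cx$ensemble, 0, 1, margin = 0.02, seed = 7)
  rep2 <- violation_report(cx$ensemble,
                           c(fx2$restraints, fx3$restraints))
  expect_equal(rep2$summary$n_violations_gt_0.05nm, 1L)
  expect_equal(rep2$summary$n_violations_gt_0.3nm, 0L)
  # no violations -> zero averages
  fx4 <- make_noe_fixture(cx$ensemble, 5, 0, margin = 0.01, seed = 8)
  rep4 <- violation_report(cx$ensemble, fx4$restraints)
  expect_equal(rep4$summary$n_violated, 0L)
  expect_equal(rep4$summary$avg_violation_over_all_nm, 0)
})

test_that("per-frame violation counts are exact and monotone in bounds", {
  ens <- random_toy_ensemble(5, seed = 41)
  fx <- make_noe_fixture(ens, 4, 3, margin = 0.03, seed = 9)
  counts <- vapply(seq_len(5) - 1L, per_frame_violation_count, 0L,
                   ens = ens, restraints = fx$restraints)
  expect_true(all(counts >= 0))
  # shrinking every bound can never decrease the count
  shrunk <- lapply(fx$restraints, function(r)
    noe_restraint(r$group1, r$group2, r$bound_nm * 0.7, r$category))
  counts2 <- vapply(seq_len(5) - 1L, per_frame_violation_count, 0L,
                    ens = ens, restraints = shrunk)
  expect_true(all(counts2 >= counts))
})

test_that("NOE-adapted ensemble retains planted best frames and conformers", {
  set.seed(101)
  mix <- make_cluster_mixture(2, 10, separation = 1.0, noise = 0.02,
                              seed = 55)
  good <- mix$ensemble$frames
  bad <- lapply(1:90, function(i) {
    f <- mix$truth$conformers[[1 + i %% 2]] +
      matrix(rnorm(nrow(mix$ensemble$topology) * 3, sd = 0.02),
             ncol = 3)
    f[1:3, 2] <- f[1:3, 2] + 5  # pull three atoms away -> violations
    f
  })
  ord <- sample.int(100)  # interleave good and bad frames
  frames <- c(good, bad)[ord]
  truth_good <- which(ord <= 10)
  ens <- ensemble(mix$ensemble$topology, frames, label = "adapted-fixture")
  # restraints on the displaced atoms, satisfied by all good frames
  mk <- function(i, j) {
    dmax <- max(vapply(good, function(f) sqrt(sum((f[i, ] - f[j, ])^2)), 0))
    noe_restraint(sprintf("A:%d:CA", i), sprintf("A:%d:CA", j),
                  dmax + 0.05, "intra_protein")
  }
  restraints <- list(mk(1, 5), mk(2, 6), mk(3, 7))
  res <- select_md_adapted_ensemble(ens, restraints, frame_fraction = 0.10,
                                    k = 2, seed = 3)
  expect_setequal(res$retained_frames + 1L, truth_good)
  # the two centroids sit near the two planted conformers
  sel <- ens$topology$atom_index
  noise_rmsd <- sqrt(3) * 0.02
  d <- vapply(1:2, function(ci) min(vapply(1:2, function(co)
    superposed_rmsd(res$ensemble$frames[[ci]],
                    mix$truth$conformers[[co]], sel), 0)), 0)
  expect_true(all(d < 2 * noise_rmsd))
  expect_error(select_md_adapted_ensemble(ens, restraints,
                                          frame_fraction = 0.02, k = 5),
               "exceeds")
})
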