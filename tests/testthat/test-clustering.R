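test_that("interface selection matches a brute-force shell scan", {
  cx <- make_complex_ensemble(2, hbonds = list(list(occupancy = 1),
                                               list(occupancy = 1)),
                              seed = 81)
  ens <- cx$ensemble
  topo <- ens$topology
  rna_res <- unique(topo$residue_index[topo$chain_id == "R"])[1]
  sel <- interface_selection(ens, "R", rna_res, cutoff = 0.45)
  # brute force: every protein residue with any heavy atom within cutoff
  fr <- ens$frames[[1]]
  heavy <- topo$element != "H"
  nuc_rows <- which(topo$chain_id == "R" & topo$residue_index == rna_res &
                    heavy)
  included <- topo$atom_index[topo$chain_id == "R" &
                              topo$residue_index == rna_res]
  for (res in unique(topo$residue_index[topo$chain_id == "A"])) {
    rows <- which(topo$chain_id == "A" & topo$residue_index == res & heavy)
    mind <- min(sapply(rows, function(a) min(sapply(nuc_rows, function(b)
      sqrt(sum((fr[a, ] - fr[b, ])^2))))))
    if (mind <= 0.45)
      included <- c(included,
                    topo$atom_index[topo$chain_id == "A" &
                                    topo$residue_index == res])
  }
  expect_setequal(as.integer(sel), included)
  # cutoff 0: nucleotide atoms only
  sel0 <- suppressWarnings(interface_selection(ens, "R", rna_res,
                                               cutoff = 0))
  expect_setequal(as.integer(sel0),
                  topo$atom_index[topo$chain_id == "R" &
                                  topo$residue_index == rna_res])
})

test_that("k-means recovers a planted 3-conformer mixture exactly", {
  mix <- make_cluster_mixture(3, 30, separation = 1.0, noise = 0.02,
                              seed = 82)
  sel <- mix$ensemble$topology$atom_index
  cl <- kmeans_conformers(mix$ensemble, sel, k = 3, seed = 2)
  conf <- table(cl$labels, mix$truth$labels)
  # perfect recovery up to label permutation: one nonzero cell per row
  expect_true(all(rowSums(conf > 0) == 1))
  expect_equal(sum(cl$populations), 1)
  # k = 1: everything in one cluster
  cl1 <- kmeans_conformers(mix$ensemble, sel, k = 1, seed = 1)
  expect_equal(cl1$populations, 1)
  # duplicated ensemble: identical populations (scale-free)
  dup <- ensemble(mix$ensemble$topology,
                  c(mix$ensemble$frames, mix$ensemble$frames))
  cl2 <- kmeans_conformers(dup, sel, k = 3, seed = 2)
  expect_setequal(round(cl2$populations, 10),
                  round(cl$populations, 10))
  expect_error(kmeans_conformers(mix$ensemble, sel, k = 0), "k must")
  expect_error(kmeans_conformers(mix$ensemble, sel, k = 31), "exceeds")
})

test_that("populations are invariant under frame permutation", {
  mix <- make_cluster_mixture(3, 24, separation = 1.0, noise = 0.02,
                              seed = 83)
  sel <- mix$ensemble$topology$atom_index
  cl <- kmeans_conformers(mix$ensemble, sel, k = 3, seed = 4)
  set.seed(99); perm <- sample.int(24)
  permuted <- ensemble(mix$ensemble$topology, mix$ensemble$frames[perm])
  cl2 <- kmeans_conformers(permuted, sel, k = 3, seed = 4)
  expect_setequal(round(cl$populations, 10), round(cl2$populations, 10))
})

test_that("merged-then-parsed clustering matches each source's makeup", {
  mixA <- make_cluster_mixture(2, 20, separation = 1.2, noise = 0.02,
                               seed = 84)
  # second ensemble around the same conformers, different composition
  confs <- mixA$truth$conformers
  set.seed(85)
  labB <- rep(c(1L, 2L), c(15L, 5L))
  framesB <- lapply(labB, function(l)
    confs[[l]] + matrix(rnorm(length(confs[[l]]), sd = 0.02), ncol = 3))
  ensB <- ensemble(mixA$ensemble$topology, framesB)
  merged <- ensemble(mixA$ensemble$topology,
                     c(mixA$ensemble$frames, framesB))
  sel <- merged$topology$atom_index
  cl <- kmeans_conformers(merged, sel, k = 2, seed = 5)
  labs_a <- cl$labels[1:20]; labs_b <- cl$labels[21:40]
  # per-source populations match each source's planted composition
  expect_setequal(as.numeric(table(labs_a)) / 20,
                  as.numeric(table(mixA$truth$labels)) / 20)
  expect_setequal(as.numeric(table(labs_b)) / 20, c(0.75, 0.25))
})

test_that("medoids match brute-force all-pairs RMSD and are rigid-stable", {
  mix <- make_cluster_mixture(1, 8, noise = 0.05, seed = 86)
  ens <- mix$ensemble
  sel <- ens$topology$atom_index
  members <- 0:7
  got <- centroid_frame(ens, sel, members)
  cum <- sapply(members, function(a) sum(sapply(members[members != a],
    function(b) superposed_rmsd(ens$frames[[a + 1]], ens$frames[[b + 1]],
                                sel))))
  expect_equal(got, members[which.min(cum)])
  # singleton and tie rules
  expect_equal(centroid_frame(ens, sel, 5L), 5L)
  same <- ensemble(ens$topology, rep(ens$frames[1], 4))
  expect_equal(centroid_frame(same, sel, 0:3), 0L)
  # rigid transforms applied per frame leave the medoid unchanged
  moved <- ensemble(ens$topology, lapply(seq_along(ens$frames), function(i)
    random_rigid(ens$frames[[i]], seed = 100 + i)))
  expect_equal(centroid_frame(moved, sel, members), got)
})
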