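test_that("DRID features match brute-force moment computation", {
  # equilateral triangle, side 0.5 nm: mu = 2 nm^-1, nu = xi = 0
  tri <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.25, 0.25 * sqrt(3), 0))
  f <- drid_features(tri, 0:2)
  expect_equal(as.vector(f["mu", ]), rep(2, 3), tolerance = 1e-12)
  expect_equal(as.vector(f["nu", ]), rep(0, 3), tolerance = 1e-9)
  expect_equal(as.vector(f["xi", ]), rep(0, 3), tolerance = 1e-9)
  # random 6-anchor frame vs direct moments
  set.seed(61)
  x <- matrix(runif(18, 0, 2), 6, 3)
  f6 <- drid_features(x, 0:5)
  for (i in 1:6) {
    inv <- sapply(setdiff(1:6, i), function(j)
      1 / sqrt(sum((x[i, ] - x[j, ])^2)))
    mu <- sum(inv) / 5
    m2 <- sum((inv - mu)^2) / 5
    m3 <- sum((inv - mu)^3) / 5
    expect_equal(unname(f6["mu", i]), mu, tolerance = 1e-12)
    expect_equal(unname(f6["nu", i]), sqrt(m2), tolerance = 1e-12)
    expect_equal(unname(f6["xi", i]), sign(m3) * abs(m3)^(1 / 3),
                 tolerance = 1e-12)
  }
  expect_error(drid_features(rbind(tri, tri[1, ]), 0:3), "coincident")
})

test_that("DRID distance is a per-anchor feature-space metric", {
  set.seed(62)
  a <- matrix(runif(18, 0, 2), 6, 3)
  b <- a + matrix(rnorm(18, sd = 0.1), 6, 3)
  expect_equal(drid_distance(a, a, 0:5), 0, tolerance = 1e-14)
  # rigid-motion invariance
  expect_lt(drid_distance(random_rigid(a, 5), a, 0:5), 1e-12)
  # brute-force evaluation of the printed prefactor
  va <- drid_features(a, 0:5); vb <- drid_features(b, 0:5)
  brute <- sum(sapply(1:6, function(i)
    sqrt(sum((va[, i] - vb[, i])^2)))) / (3 * 6)
  expect_equal(drid_distance(b, a, 0:5), brute, tolerance = 1e-12)
  # triangle inequality on random triples
  for (s in 1:15) {
    set.seed(s)
    x <- matrix(runif(18, 0, 2), 6, 3)
    y <- x + matrix(rnorm(18, sd = 0.2), 6, 3)
    z <- x + matrix(rnorm(18, sd = 0.2), 6, 3)
    expect_lte(drid_distance(x, z, 0:5),
               drid_distance(x, y, 0:5) + drid_distance(y, z, 0:5) + 1e-12)
  }
})

test_that("native contact lists match an exhaustive pair scan", {
  ens <- random_toy_ensemble(1, n_atoms = 12, seed = 63)
  topo <- ens$topology
  fr <- ens$frames[[1]]
  sel_a <- topo$atom_index[topo$chain_id == "A"]
  sel_b <- topo$atom_index[topo$chain_id == "R"]
  cl <- suppressWarnings(native_contacts(fr, topo, sel_a, sel_b, 0.45))
  brute <- list()
  for (i in sel_a) for (j in sel_b) {
    d <- sqrt(sum((fr[i + 1, ] - fr[j + 1, ])^2))
    if (d < 0.45) brute[[length(brute) + 1]] <- c(i, j, d)
  }
  expect_equal(nrow(cl), length(brute))
  if (nrow(cl) > 0) {
    bm <- do.call(rbind, brute)
    bm <- bm[order(bm[, 1], bm[, 2]), , drop = FALSE]
    expect_equal(cl$i, as.integer(bm[, 1]))
    expect_equal(cl$j, as.integer(bm[, 2]))
    expect_equal(cl$r0_nm, bm[, 3], tolerance = 1e-12)
  }
  # two atoms at 0.3 nm -> exactly one contact; far apart -> empty + flag
  topo2 <- ens$topology[1:2, ]
  near <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  one <- native_contacts(near, topo2, 0, 1)
  expect_equal(nrow(one), 1L)
  far <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_warning(none <- native_contacts(far, topo2, 0, 1), "no native")
  expect_true(attr(none, "empty"))
  expect_error(native_contacts(near, topo2, 0:1, 1), "disjoint")
})

test_that("Q matches brute-force evaluation and its limits", {
  set.seed(64)
  ens <- random_toy_ensemble(2, n_atoms = 12, seed = 64)
  topo <- ens$topology
  ref <- ens$frames[[1]]
  cl <- suppressWarnings(native_contacts(
    ref, topo, topo$atom_index[topo$chain_id == "A"],
    topo$atom_index[topo$chain_id == "R"], 1.5))
  fr <- ens$frames[[2]]
  q <- q_fraction(fr, cl, beta = 50, lambda = 1.8)
  brute <- mean(sapply(seq_len(nrow(cl)), function(p) {
    r <- sqrt(sum((fr[cl$i[p] + 1, ] - fr[cl$j[p] + 1, ])^2))
    1 / (1 + exp(50 * (r - 1.8 * cl$r0_nm[p])))
  }))
  expect_equal(q, brute, tolerance = 1e-12)
  # reference frame with generous r0: each term's exponent is deeply negative
  big <- cl; big$r0_nm <- pmax(big$r0_nm, 0.3)
  expect_gte(q_fraction(ref, big), 0.99)
  # all distances inflated -> Q collapses; midpoint r = lambda r0 -> 0.5
  expect_lt(q_fraction(ref * 50, cl), 1e-6)
  mid <- data.frame(i = 0L, j = 1L, r0_nm = 0.3)
  frame_mid <- rbind(c(0, 0, 0), c(0.54, 0, 0))
  expect_equal(q_fraction(frame_mid, mid), 0.5, tolerance = 1e-12)
  # rigid-motion invariance
  expect_equal(q_fraction(random_rigid(fr, 8), cl), q, tolerance = 1e-12)
  # monotone non-increasing under uniform inflation
  qs <- sapply(c(1, 1.2, 1.5, 2, 4), function(s) q_fraction(fr * s, cl))
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("KDE maps normalise to 1 and find planted modes", {
  set.seed(65)
  pts <- rbind(cbind(rnorm(400, 0, 0.05), rnorm(400, 0, 0.05)),
               cbind(rnorm(400, 1, 0.05), rnorm(400, 1, 0.05)))
  k <- kde_density(pts, grid_size = 80)
  integral <- sum(k$z) * diff(k$x[1:2]) * diff(k$y[1:2])
  expect_equal(integral, 1, tolerance = 1e-3)
  # two local maxima within one grid cell of the planted centres
  peak <- which(k$z == max(k$z), arr.ind = TRUE)[1, ]
  cell <- c(diff(k$x[1:2]), diff(k$y[1:2]))
  centers <- rbind(c(0, 0), c(1, 1))
  d_peak <- min(abs(k$x[peak[1]] - centers[, 1]) +
                abs(k$y[peak[2]] - centers[, 2]))
  expect_lt(d_peak, sum(cell) * 2)
  # single tight cluster: unimodal, peaked at the mean
  one <- cbind(rnorm(300, 0.5, 0.02), rnorm(300, 0.2, 0.02))
  k1 <- kde_density(one, grid_size = 60)
  p1 <- which(k1$z == max(k1$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(k1$x[p1[1]] - 0.5), 0.05)
  expect_lt(abs(k1$y[p1[2]] - 0.2), 0.05)
  expect_error(kde_density(cbind(rep(1, 10), rnorm(10))), "variance")
})

test_that("cv_series reports per-frame Q and DRID against the reference", {
  cx <- make_complex_ensemble(8, hbonds = list(list(occupancy = 0.5),
                                               list(occupancy = 0.8)),
                              seed = 66)
  topo <- cx$ensemble$topology
  anchors <- topo$atom_index[topo$atom_name %in% c("CA", "P")]
  cl <- suppressWarnings(native_contacts(
    cx$ensemble$frames[[1]], topo,
    topo$atom_index[topo$chain_id == "R"],
    topo$atom_index[topo$chain_id == "A"], 1.0))
  cv <- cv_series(cx$ensemble, cl, anchors)
  expect_equal(nrow(cv), 8L)
  expect_equal(cv$drid[1], 0, tolerance = 1e-14)
  expect_equal(cv$q[1], q_fraction(cx$ensemble$frames[[1]], cl),
               tolerance = 1e-12)
})
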