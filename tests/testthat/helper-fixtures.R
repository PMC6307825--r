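# Shared helpers: independent oracles and small geometric utilities used
# across the suite. Oracles are deliberately written with different
# algorithms than the package code they check.

# Random rigid transform (rotation + translation) applied to a frame.
random_rigid <- function(frame, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(frame %*% t(R), 2L, rnorm(3), `+`)
}

# Brute-force r^-6 ensemble average by explicit loops (oracle for Eq 3).
brute_noe_average <- function(ens, g1_rows, g2_rows) {
  acc <- 0
  for (fr in ens$frames) {
    s <- 0
    for (a in g1_rows) for (b in g2_rows) {
      r <- sqrt(sum((fr[a, ] - fr[b, ])^2))
      s <- s + r^-6
    }
    acc <- acc + (s^(-1 / 6))^-6
  }
  (acc / length(ens$frames))^(-1 / 6)
}

# Textbook dihedral (praxeolitic single-atan2 formulation) as an
# independent formula oracle.
oracle_dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1; b1 <- p2 - p1; b2 <- p3 - p2
  b1 <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  atan2(y, x) * 180 / pi
}

# Quaternion-method optimal superposition RMSD (Horn 1987), an
# independent check on the Kabsch SVD route.
oracle_quaternion_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2L, colMeans(P)); Q0 <- sweep(Q, 2L, colMeans(Q))
  Sxx <- crossprod(P0, Q0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- Sxx[1, 1] + Sxx[2, 2] + Sxx[3, 3]
  K[1, 2] <- K[2, 1] <- Sxx[2, 3] - Sxx[3, 2]
  K[1, 3] <- K[3, 1] <- Sxx[3, 1] - Sxx[1, 3]
  K[1, 4] <- K[4, 1] <- Sxx[1, 2] - Sxx[2, 1]
  K[2, 2] <- Sxx[1, 1] - Sxx[2, 2] - Sxx[3, 3]
  K[2, 3] <- K[3, 2] <- Sxx[1, 2] + Sxx[2, 1]
  K[2, 4] <- K[4, 2] <- Sxx[1, 3] + Sxx[3, 1]
  K[3, 3] <- -Sxx[1, 1] + Sxx[2, 2] - Sxx[3, 3]
  K[3, 4] <- K[4, 3] <- Sxx[2, 3] + Sxx[3, 2]
  K[4, 4] <- -Sxx[1, 1] - Sxx[2, 2] + Sxx[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Tiny ensemble with a chosen number of random frames over a CA/P topology.
random_toy_ensemble <- function(n_frames, n_atoms = 8L, seed = 1L) {
  set.seed(seed)
  topo <- data.frame(
    atom_index = seq_len(n_atoms) - 1L,
    atom_name = rep(c("CA", "P"), length.out = n_atoms),
    element = rep(c("C", "P"), length.out = n_atoms),
    residue_index = seq_len(n_atoms),
    residue_name = rep(c("GLY", "ADE"), length.out = n_atoms),
    chain_id = rep(c("A", "R"), length.out = n_atoms),
    stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames), function(f)
    matrix(runif(3L * n_atoms, 0, 2), n_atoms, 3L))
  ensemble(topo, frames, label = "toy")
}

kT_at <- function(temperature_k = 298) 1.9872e-3 * temperature_k
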