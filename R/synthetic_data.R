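# Seeded generators for every fixture the pipeline needs, with planted
# ground truth. The scaffold is a minimal two-chain abstraction (protein-like
# chain "A" with CA/N backbone markers, RNA-like chain "R" with P atoms):
# analysis stages consume geometry only, so no attempt is made at chemically
# valid molecules. Occupancies are planted by frame counting, not
# probabilistically, so downstream occupancy assertions are exact.

HB_LEN_DH <- 0.10      # donor-hydrogen bond length, nm
HB_BOUND_D <- 0.29     # planted heavy-heavy distance when an H-bond is formed
HB_BOUND_ANGLE <- 165  # planted D-H-A angle when formed
HB_BROKEN_D <- 0.60    # planted heavy-heavy distance when broken

# Position a hydrogen so that the D-H-A angle equals `target` exactly,
# with |D-H| = HB_LEN_DH, donor at origin and acceptor at (d, 0, 0).
hydrogen_for_angle <- function(d, target) {
  f <- function(delta) {
    h <- c(HB_LEN_DH, delta, 0)
    a <- -h; b <- c(d, 0, 0) - h
    acos(sum(a * b) / sqrt(sum(a * a) * sum(b * b))) * 180 / pi - target
  }
  delta <- uniroot(f, c(1e-9, 1.5), tol = 1e-14)$root
  c(HB_LEN_DH, delta, 0)
}

hexagon <- function(center, radius = 0.139) {
  th <- seq(0, by = pi / 3, length.out = 6)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th),
        center[3])
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3,
         byrow = TRUE)
}

#' Generate a toy two-chain complex ensemble with planted interactions
#'
#' Builds an ensemble of a protein-like chain `"A"` and an RNA-like chain
#' `"R"` in which each requested hydrogen bond is geometrically formed
#' (heavy-heavy distance 0.29 nm, D-H-A angle 165 deg) in exactly
#' `round(occupancy * n_frames)` frames and broken (distance 0.60 nm) in the
#' rest, and each stacking pair is built at its exact planted centre
#' distance and plane angle in every frame. Scaffold marker atoms (CA, P)
#' get small seeded jitter so frames and seeds differ without disturbing
#' the planted geometry.
#'
#' @param n_frames number of frames.
#' @param hbonds list of `list(occupancy = , label = )`; one donor/hydrogen/
#'   acceptor triple is built per entry (donor `ND` + hydrogen `HD` on chain
#'   A, acceptor `OA` on chain R).
#' @param stacks list of `list(d = , theta = , label = )`: centre-of-geometry
#'   distance (nm) and plane angle (deg) for a protein-ring/base-ring pair.
#' @param seed integer seed; the generator is deterministic given it.
#' @return list with `ensemble` (an [ensemble()]) and `truth`, which records
#'   `hbond_specs` ([hbond_spec()] list), `hbond_occupancies`,
#'   `hbond_frames` (logical matrix frame x interaction), `stack_specs`
#'   ([stack_spec()] list) and `stack_geometries`.
#' @export
make_complex_ensemble <- function(n_frames, hbonds = list(), stacks = list(),
                                  seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  set.seed(seed)
  nh <- length(hbonds); ns <- length(stacks)
  if (nh + ns == 0L) stop("plant at least one interaction")

  topo <- list(); coords <- list()
  add_atom <- function(name, elem, resi, resn, chain, xyz) {
    topo[[length(topo) + 1L]] <<- data.frame(
      atom_index = NA_integer_, atom_name = name, element = elem,
      residue_index = resi, residue_name = resn, chain_id = chain,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- xyz
  }

  hb_atoms <- list()  # per hbond: donor/h/acceptor row numbers (1-based)
  for (i in seq_len(nh)) {
    base <- c(0, (i - 1) * 2.0, 0)
    hpos <- hydrogen_for_angle(HB_BOUND_D, HB_BOUND_ANGLE)
    add_atom("CA", "C", i, "GLY", "A", base + c(-0.35, 0, 0))
    add_atom("ND", "N", i, "GLY", "A", base)
    add_atom("HD", "H", i, "GLY", "A", base + hpos)
    add_atom("OA", "O", 100L + i, "ADE", "R", base + c(HB_BOUND_D, 0, 0))
    add_atom("P", "P", 100L + i, "ADE", "R", base + c(0.75, 0.15, 0))
    n0 <- (i - 1L) * 5L  # rows for this slot: CA, ND, HD, OA, P
    hb_atoms[[i]] <- c(donor = n0 + 2L, h = n0 + 3L, acceptor = n0 + 4L)
  }

  stack_atoms <- list()
  for (j in seq_len(ns)) {
    base <- c(3.0, (j - 1) * 2.0, 0)
    ringA <- hexagon(base)
    ringB <- hexagon(c(0, 0, 0)) %*% t(rot_x(stacks[[j]]$theta))
    ringB <- sweep(ringB, 2L, base + c(0, 0, stacks[[j]]$d), `+`)
    r1 <- length(topo) + 1L
    for (a in 1:6)
      add_atom(paste0("CG", a), "C", 50L + j, "PHE", "A", ringA[a, ])
    add_atom("CA", "C", 50L + j, "PHE", "A", base + c(-0.5, 0, 0))
    r2 <- length(topo) + 1L
    for (a in 1:6)
      add_atom(paste0("C", a), "C", 150L + j, "GUA", "R", ringB[a, ])
    add_atom("P", "P", 150L + j, "GUA", "R", base + c(0.8, 0, stacks[[j]]$d))
    stack_atoms[[j]] <- list(ringA = (r1):(r1 + 5L), ringB = (r2):(r2 + 5L))
  }

  topo <- do.call(rbind, topo)
  topo$atom_index <- seq_len(nrow(topo)) - 1L
  base_xyz <- do.call(rbind, coords)

  # which frames each H-bond is formed in: exact seeded counts
  formed <- matrix(FALSE, n_frames, max(nh, 1L))
  occ <- numeric(nh)
  for (i in seq_len(nh)) {
    k <- round(hbonds[[i]]$occupancy * n_frames)
    if (k > 0L) formed[sample.int(n_frames, k), i] <- TRUE
    occ[i] <- k / n_frames
  }

  jitter_rows <- which(topo$atom_name %in% c("CA", "P"))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    x <- base_xyz
    for (i in seq_len(nh)) {
      if (!formed[f, i]) {
        acc <- hb_atoms[[i]]["acceptor"]
        don <- hb_atoms[[i]]["donor"]
        x[acc, ] <- x[don, ] + c(HB_BROKEN_D, 0, 0)
      }
    }
    x[jitter_rows, ] <- x[jitter_rows, ] +
      matrix(rnorm(3L * length(jitter_rows), sd = 0.01),
             length(jitter_rows), 3L)
    frames[[f]] <- x
  }

  ens <- ensemble(topo, frames, label = sprintf("synthetic-complex-seed%d",
                                                seed))
  hb_specs <- lapply(seq_len(nh), function(i) {
    a <- hb_atoms[[i]]
    hbond_spec(donor = a[["donor"]] - 1L, hydrogen = a[["h"]] - 1L,
               acceptor = a[["acceptor"]] - 1L,
               label = hbonds[[i]]$label %||% paste0("hb", i))
  })
  st_specs <- lapply(seq_len(ns), function(j)
    stack_spec(ring_a = stack_atoms[[j]]$ringA - 1L,
               ring_b = stack_atoms[[j]]$ringB - 1L,
               label = stacks[[j]]$label %||% paste0("stack", j)))
  truth <- list(
    hbond_specs = hb_specs,
    hbond_occupancies = occ,
    hbond_frames = formed[, seq_len(nh), drop = FALSE],
    stack_specs = st_specs,
    stack_geometries = lapply(stacks, function(s) c(d = s$d,
                                                    theta = s$theta)))
  list(ensemble = ens, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate per-residue dihedral series with planted dynamics
#'
#' Each residue follows one of two plans: pure fluctuation (wrapped-normal
#' scatter of both phi and psi around a single Ramachandran mode) or
#' two-state switching, where exactly `round(fraction * n_frames)` frames
#' sit in a planted minority mode and the rest in the major mode.
#'
#' @param n_frames frames per series.
#' @param plan named list, one entry per residue:
#'   `list(mode = "fluct", center = c(phi, psi), sigma = )` or
#'   `list(mode = "switch", major = c(phi, psi), minor = c(phi, psi),
#'   fraction = , sigma = )`.
#' @param seed integer seed.
#' @return list with `phi` and `psi` (lists of [dihedral_series()], one per
#'   residue, residue indices 1..n) and `truth` recording the planted
#'   minority fraction per residue (0 for pure fluctuation).
#' @export
make_dihedral_fixture <- function(n_frames, plan, seed = 1L) {
  set.seed(seed)
  phi <- list(); psi <- list(); frac <- numeric(length(plan))
  for (r in seq_along(plan)) {
    p <- plan[[r]]
    sigma <- p$sigma %||% 5
    if (identical(p$mode, "fluct")) {
      ph <- rnorm(n_frames, p$center[1], sigma)
      ps <- rnorm(n_frames, p$center[2], sigma)
      frac[r] <- 0
    } else if (identical(p$mode, "switch")) {
      if (p$fraction <= 0 || p$fraction >= 1)
        stop("minority fraction must be in (0, 1)")
      k <- round(p$fraction * n_frames)
      minor_at <- sample.int(n_frames, k)
      ph <- rnorm(n_frames, p$major[1], sigma)
      ps <- rnorm(n_frames, p$major[2], sigma)
      ph[minor_at] <- rnorm(k, p$minor[1], sigma)
      ps[minor_at] <- rnorm(k, p$minor[2], sigma)
      frac[r] <- k / n_frames
    } else stop("unknown plan mode '", p$mode, "'")
    phi[[r]] <- dihedral_series("A", r, "phi", ph)
    psi[[r]] <- dihedral_series("A", r, "psi", ps)
  }
  list(phi = phi, psi = psi,
       truth = list(minority_fractions = frac))
}

#' Generate bidirectional work samples obeying the Crooks relation
#'
#' Draws forward works from `Normal(dg + sigma^2 / (2 kT), sigma^2)` and
#' reverse works from `Normal(-dg + sigma^2 / (2 kT), sigma^2)`; equal
#' variances make the pair satisfy the Crooks fluctuation theorem exactly
#' in expectation, with planted free-energy difference `dg`.
#'
#' @param dg planted free-energy difference, kcal/mol.
#' @param sigma work standard deviation, kcal/mol (> 0; 0 allowed for the
#'   zero-dissipation limit).
#' @param n_f,n_r numbers of forward and reverse transitions (>= 2).
#' @param temperature_k temperature in kelvin.
#' @param seed integer seed.
#' @return a [work_set()].
#' @export
make_work_samples <- function(dg, sigma, n_f, n_r, temperature_k = 298,
                              seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_f < 2L || n_r < 2L) stop("need at least 2 samples per direction")
  set.seed(seed)
  kT <- GAS_CONSTANT_KCAL * temperature_k
  diss <- sigma^2 / (2 * kT)
  wf <- rnorm(n_f, dg + diss, sigma)
  wr <- rnorm(n_r, -dg + diss, sigma)
  work_set(forward = wf, reverse = wr, temperature_k = temperature_k,
           labels = c("A", "B"))
}

#' Generate a cluster-structured conformer mixture
#'
#' Builds `k` rigid conformers of a CA-trace scaffold whose pairwise
#' superposed RMSD is at least `separation`, then draws frames around them
#' with isotropic per-coordinate Gaussian noise. Frames are assigned to
#' conformers as evenly as possible in a seeded random order.
#'
#' @param k number of conformers.
#' @param n_frames total frames.
#' @param separation minimum pairwise superposed RMSD between conformers,
#'   nm.
#' @param noise per-coordinate noise sd, nm; `separation <= 4 * noise` is
#'   flagged as unidentifiable with a warning.
#' @param n_atoms scaffold size.
#' @param seed integer seed.
#' @return list with `ensemble` and `truth` (`labels`: planted per-frame
#'   1-based cluster labels; `conformers`: list of coordinate matrices).
#' @export
make_cluster_mixture <- function(k, n_frames, separation = 1.0,
                                 noise = 0.02, n_atoms = 20L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (n_frames < k) stop("need at least one frame per conformer")
  if (k > 1L && separation <= 4 * noise)
    warning("separation <= 4 * noise: clusters may be unidentifiable")
  set.seed(seed)
  scaffold <- cbind(seq_len(n_atoms) * 0.38, 0, 0) +
    matrix(rnorm(3L * n_atoms, sd = 0.15), n_atoms, 3L)
  sel <- seq_len(n_atoms) - 1L
  conformers <- list(scaffold)
  if (k > 1L) {
    disp <- lapply(seq_len(k - 1L),
                   function(i) matrix(rnorm(3L * n_atoms), n_atoms, 3L))
    s <- separation  # scale displacements until pairwise RMSD clears bar
    repeat {
      conformers <- c(list(scaffold),
                      lapply(disp, function(D) scaffold + s * D /
                               sqrt(mean(rowSums(D^2)))))
      ok <- TRUE
      for (a in 1:(k - 1)) for (b in (a + 1):k)
        if (superposed_rmsd(conformers[[a]], conformers[[b]], sel) <
            separation) ok <- FALSE
      if (ok) break
      s <- s * 1.3
    }
  }
  labels <- rep(seq_len(k), length.out = n_frames)[sample.int(n_frames)]
  frames <- lapply(seq_len(n_frames), function(f)
    conformers[[labels[f]]] +
      matrix(rnorm(3L * n_atoms, sd = noise), n_atoms, 3L))
  topo <- data.frame(
    atom_index = sel, atom_name = "CA", element = "C",
    residue_index = seq_len(n_atoms), residue_name = "GLY", chain_id = "A",
    stringsAsFactors = FALSE)
  list(ensemble = ensemble(topo, frames,
                           label = sprintf("mixture-k%d-seed%d", k, seed)),
       truth = list(labels = labels, conformers = conformers))
}

#' Derive an NOE restraint table with known satisfaction status
#'
#' Picks seeded random atom pairs from the ensemble topology, back-calculates
#' their r^-6 ensemble-averaged distances, and sets upper bounds to
#' `<r> + margin` (satisfied) or `<r> - margin` (violated by exactly
#' `margin`). Categories follow the chains involved.
#'
#' @param ens an [ensemble()].
#' @param n_satisfied,n_violated counts of restraints to plant.
#' @param margin positive bound offset, nm.
#' @param seed integer seed.
#' @return list with `restraints` (list of [noe_restraint()]) and `truth`
#'   (`violated`: logical vector; `avg_r`: the back-calculated `<r>` used).
#' @export
make_noe_fixture <- function(ens, n_satisfied, n_violated, margin = 0.05,
                             seed = 1L) {
  if (margin <= 0) stop("margin must be positive")
  if (n_frames(ens) < 1L) stop("empty ensemble")
  set.seed(seed)
  topo <- ens$topology
  n <- n_satisfied + n_violated
  if (nrow(topo) < 2L) stop("topology too small")
  pairs <- matrix(NA_integer_, n, 2L)
  for (i in seq_len(n)) pairs[i, ] <- sample.int(nrow(topo), 2L)
  spec_of <- function(row) paste(topo$chain_id[row], topo$residue_index[row],
                                 topo$atom_name[row], sep = ":")
  violated <- rep(c(FALSE, TRUE), c(n_satisfied, n_violated))
  restraints <- vector("list", n); avg_r <- numeric(n)
  for (i in seq_len(n)) {
    g1 <- spec_of(pairs[i, 1]); g2 <- spec_of(pairs[i, 2])
    ch <- topo$chain_id[pairs[i, ]]
    cat_i <- if (ch[1] != ch[2]) "intermolecular"
             else if (ch[1] == "R") "intra_rna" else "intra_protein"
    r <- backcalc_noe(ens, noe_restraint(g1, g2, 1, cat_i))
    avg_r[i] <- r
    bound <- if (violated[i]) r - margin else r + margin
    if (bound <= 0) stop("margin too large for planted pair distance ", r)
    restraints[[i]] <- noe_restraint(g1, g2, bound, cat_i)
  }
  list(restraints = restraints,
       truth = list(violated = violated, avg_r = avg_r))
}
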