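# Geometric kernels shared by all analysis stages. All distances in nm,
# all angles in degrees. No periodic imaging: inputs are whole-molecule
# (NMR-style) ensembles.

RAD2DEG <- 180 / pi

#' Euclidean distance between two atoms in a frame
#' @param frame numeric `n x 3` coordinate matrix (nm).
#' @param i,j 0-based atom indices; `i == j` returns 0.
#' @return distance in nm.
#' @export
atom_distance <- function(frame, i, j) {
  d <- frame[i + 1L, ] - frame[j + 1L, ]
  sqrt(sum(d * d))
}

#' Angle at a vertex atom
#'
#' Returns the i-j-k angle at vertex `j` in degrees, in `[0, 180]`.
#'
#' @param frame coordinate matrix (nm).
#' @param i,j,k 0-based atom indices; `j` must be distinct from both arms.
#' @return angle in degrees.
#' @export
atom_angle <- function(frame, i, j, k) {
  a <- frame[i + 1L, ] - frame[j + 1L, ]
  b <- frame[k + 1L, ] - frame[j + 1L, ]
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na < 1e-12 || nb < 1e-12)
    stop("undefined angle: zero-length arm at vertex")
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * RAD2DEG
}

#' Signed dihedral angle of four atoms
#'
#' IUPAC convention: looking down the j-k bond, the angle from the i-j-k
#' plane to the j-k-l plane, signed, in `(-180, 180]`.
#'
#' @param frame coordinate matrix (nm).
#' @param i,j,k,l 0-based atom indices.
#' @return dihedral in degrees.
#' @export
atom_dihedral <- function(frame, i, j, k, l) {
  b1 <- frame[j + 1L, ] - frame[i + 1L, ]
  b2 <- frame[k + 1L, ] - frame[j + 1L, ]
  b3 <- frame[l + 1L, ] - frame[k + 1L, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-20 || sum(n2 * n2) < 1e-20)
    stop("undefined dihedral: collinear atom triple")
  m1 <- cross3(n1, b2 / sqrt(sum(b2 * b2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * RAD2DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Unit normal of the best-fit plane through a set of atoms
#'
#' Least-squares plane through the selected atoms; the normal is the
#' direction of least coordinate variance (smallest singular vector of the
#' centred coordinates). Its sign is arbitrary.
#'
#' @param frame coordinate matrix (nm).
#' @param sel 0-based atom indices (>= 3 non-collinear atoms).
#' @return length-3 unit vector.
#' @export
ring_plane_normal <- function(frame, sel) {
  x <- frame[as.integer(sel) + 1L, , drop = FALSE]
  if (nrow(x) < 3L) stop("a plane needs at least 3 atoms")
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("collinear ring atoms: plane undefined")
  n <- sv$v[, 3L]
  n / sqrt(sum(n * n))
}

#' Angle between two planes, folded to [0, 90] degrees
#'
#' Ring normals have arbitrary sign, so the inter-plane angle is
#' `acos(|n1 . n2|)`.
#'
#' @param n1,n2 plane normals (need not be unit length).
#' @return angle in degrees in `[0, 90]`.
#' @export
plane_angle <- function(n1, n2) {
  c1 <- n1 / sqrt(sum(n1 * n1)); c2 <- n2 / sqrt(sum(n2 * n2))
  acos(min(1, abs(sum(c1 * c2)))) * RAD2DEG
}

#' Kabsch superposition of one frame onto another
#'
#' Optimal rigid-body least-squares fit of `mobile` onto `reference`
#' computed on the atoms in `sel`, with the determinant correction that
#' excludes reflections. The RMSD is evaluated on the selection after
#' fitting.
#'
#' @param mobile,reference coordinate matrices (nm) over the same topology.
#' @param sel 0-based atom indices to fit on (>= 3, non-degenerate).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3, nm),
#'   `rmsd` (nm), and `fitted` (the whole mobile frame after the transform).
#' @export
kabsch_superpose <- function(mobile, reference, sel) {
  idx <- as.integer(sel) + 1L
  if (length(idx) < 3L) stop("superposition needs >= 3 atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2L, pc); Q0 <- sweep(Q, 2L, qc)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted_sel <- P0 %*% t(R)
  dif <- fitted_sel - Q0
  rmsd <- sqrt(sum(dif * dif) / length(idx))
  fitted <- sweep(mobile, 2L, pc) %*% t(R)
  fitted <- sweep(fitted, 2L, qc, `+`)
  list(rotation = R, translation = qc - as.vector(R %*% pc),
       rmsd = rmsd, fitted = fitted)
}

#' RMSD between two frames after Kabsch superposition
#' @inheritParams kabsch_superpose
#' @return RMSD on the selection, nm.
#' @export
superposed_rmsd <- function(mobile, reference, sel)
  kabsch_superpose(mobile, reference, sel)$rmsd

#' Extract a backbone or side-chain dihedral time series
#'
#' Evaluates the dihedral defined by four named atoms across all frames of
#' an ensemble, yielding a `dihedral_series`.
#'
#' @param ens an [ensemble()].
#' @param chain_id,residue_index residue the series belongs to.
#' @param angle_name label, e.g. `"phi"`, `"psi"`, `"chi1"`.
#' @param atoms length-4 integer vector of 0-based atom indices (i,j,k,l).
#' @return a [dihedral_series()].
#' @export
dihedral_series_from_ensemble <- function(ens, chain_id, residue_index,
                                          angle_name, atoms) {
  vals <- vapply(ens$frames, function(fr)
    atom_dihedral(fr, atoms[1], atoms[2], atoms[3], atoms[4]), 0)
  dihedral_series(chain_id, residue_index, angle_name, vals)
}

#' Construct a per-residue dihedral angle time series
#'
#' @param chain_id,residue_index residue identity.
#' @param angle_name one of `phi`, `psi`, `chi1`..`chi5`.
#' @param values per-frame angles in degrees, wrapped into `(-180, 180]`.
#' @return object of class `dihedral_series`.
#' @export
dihedral_series <- function(chain_id, residue_index, angle_name, values) {
  values <- wrap_angle(as.numeric(values))
  structure(list(chain_id = chain_id, residue_index = residue_index,
                 angle_name = angle_name, values = values),
            class = "dihedral_series")
}

#' Wrap angles into the interval (-180, 180]
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}
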