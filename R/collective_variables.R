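# Collective variables for comparing conformational sampling between
# simulations: DRID (distribution of reciprocal interatomic distances),
# the smoothed fraction of native contacts Q, and 2-D Gaussian KDE maps
# of the (Q, DRID) plane.

#' DRID feature matrix of a frame
#'
#' For each anchor atom (conventionally the CA and P atoms), the inverse
#' distances to all other anchors are summarised by three features: the
#' mean mu, the square root of the second central moment nu, and the
#' signed cube root of the third central moment xi (signed so negative
#' skew is preserved). Units nm^-1.
#'
#' @param frame coordinate matrix (nm).
#' @param anchors 0-based anchor atom indices (>= 3, no coincident pairs).
#' @return `3 x N` matrix with rows `mu`, `nu`, `xi`.
#' @export
drid_features <- function(frame, anchors) {
  idx <- as.integer(anchors) + 1L
  n <- length(idx)
  if (n < 3L) stop("DRID needs at least 3 anchors")
  x <- frame[idx, , drop = FALSE]
  d2 <- outer(rowSums(x^2), rowSums(x^2), `+`) - 2 * tcrossprod(x)
  d <- sqrt(pmax(d2, 0))
  diag(d) <- NA
  if (any(d < 1e-9, na.rm = TRUE)) stop("coincident anchor atoms")
  inv <- 1 / d
  feat <- vapply(seq_len(n), function(i) {
    v <- inv[i, -i]
    mu <- mean(v)
    m2 <- mean((v - mu)^2)
    m3 <- mean((v - mu)^3)
    c(mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }, numeric(3))
  rownames(feat) <- c("mu", "nu", "xi")
  feat
}

#' DRID distance between a frame and a reference
#'
#' `(1 / (3N)) * sum_i || v_n(., i) - v_0(., i) ||` over the N anchors,
#' with the Euclidean norm of each anchor's 3-feature difference.
#'
#' @param frame,reference coordinate matrices (nm) over one topology.
#' @param anchors 0-based anchor atom indices shared by both.
#' @return non-negative score, nm^-1.
#' @export
drid_distance <- function(frame, reference, anchors) {
  va <- drid_features(frame, anchors)
  vb <- drid_features(reference, anchors)
  n <- ncol(va)
  sum(sqrt(colSums((va - vb)^2))) / (3 * n)
}

#' Build a native-contact list from a reference frame
#'
#' All heavy-atom cross pairs between the two selections whose reference
#' distance is below `r_define`, storing the reference distances `r0`.
#'
#' @param reference coordinate matrix (nm).
#' @param topology topology data.frame (for heavy-atom filtering).
#' @param sel_a,sel_b disjoint 0-based atom index vectors (e.g. RNA loop
#'   heavy atoms and protein heavy atoms).
#' @param r_define contact-defining cut-off, nm (default 0.45).
#' @return object of class `contact_list`: data.frame with `i`, `j`
#'   (0-based), `r0_nm`; attribute `empty` flags an empty list.
#' @export
native_contacts <- function(reference, topology, sel_a, sel_b,
                            r_define = 0.45) {
  if (length(intersect(sel_a, sel_b)) > 0L)
    stop("selections must be disjoint")
  heavy <- topology$atom_index[topology$element != "H"]
  a <- intersect(as.integer(sel_a), heavy)
  b <- intersect(as.integer(sel_b), heavy)
  xa <- reference[a + 1L, , drop = FALSE]
  xb <- reference[b + 1L, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d < r_define, arr.ind = TRUE)
  out <- data.frame(i = a[hit[, 1]], j = b[hit[, 2]],
                    r0_nm = d[hit])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no native contacts found below ", r_define, " nm")
  structure(out, class = c("contact_list", "data.frame"),
            empty = nrow(out) == 0L)
}

#' Fraction of native contacts Q of a frame
#'
#' `Q = (1/N) sum_{(i,j)} 1 / (1 + exp(beta * (r_ij - lambda * r0_ij)))`.
#' `beta` defaults to 50 nm^-1 (equivalently 5 A^-1), the standard
#' smoothing constant for this logistic form; `lambda = 1.8` absorbs
#' thermal fluctuation of formed contacts.
#'
#' @param frame coordinate matrix (nm).
#' @param contacts a [native_contacts()] list.
#' @param beta smoothing, nm^-1.
#' @param lambda reference-distance scaling.
#' @return Q in (0, 1).
#' @export
q_fraction <- function(frame, contacts, beta = 50, lambda = 1.8) {
  if (nrow(contacts) == 0L) stop("empty contact list")
  a <- frame[contacts$i + 1L, , drop = FALSE]
  b <- frame[contacts$j + 1L, , drop = FALSE]
  r <- sqrt(rowSums((a - b)^2))
  mean(1 / (1 + exp(beta * (r - lambda * contacts$r0_nm))))
}

#' Per-frame (Q, DRID) collective-variable time series
#'
#' @param ens an [ensemble()].
#' @param contacts a [native_contacts()] list.
#' @param anchors DRID anchor atom indices (0-based).
#' @param reference_frame 0-based index of the DRID reference frame
#'   (default 0).
#' @param beta,lambda passed to [q_fraction()].
#' @return data.frame with `frame`, `q`, `drid`.
#' @export
cv_series <- function(ens, contacts, anchors, reference_frame = 0L,
                      beta = 50, lambda = 1.8) {
  ref <- ens$frames[[reference_frame + 1L]]
  vref <- drid_features(ref, anchors)
  n <- ncol(vref)
  data.frame(
    frame = seq_len(n_frames(ens)) - 1L,
    q = vapply(ens$frames, q_fraction, 0, contacts = contacts,
               beta = beta, lambda = lambda),
    drid = vapply(ens$frames, function(fr) {
      v <- drid_features(fr, anchors)
      sum(sqrt(colSums((v - vref)^2))) / (3 * n)
    }, 0))
}

#' 2-D Gaussian kernel density map of collective-variable samples
#'
#' Gaussian KDE with Scott's bandwidth per dimension, evaluated on a
#' regular grid and normalised so the grid integral is 1.
#'
#' @param points two-column matrix or data.frame of CV samples (e.g. Q,
#'   DRID), >= 2 rows with nonzero spread in both dimensions.
#' @param grid_size grid resolution per axis (default 64).
#' @param pad fractional margin added around the data range.
#' @return list with `x`, `y` (grid axes), `z` (density matrix), and
#'   `bandwidth`.
#' @export
kde_density <- function(points, grid_size = 64L, pad = 0.15) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) < 2L) stop("need at least 2 points")
  sx <- sd(pts[, 1]); sy <- sd(pts[, 2])
  if (sx < 1e-12 || sy < 1e-12)
    stop("zero-variance dimension: jitter the data or drop the axis")
  n <- nrow(pts)
  # Scott's rule per dimension (d = 2): h = sigma * n^(-1/6)
  hx <- sx * n^(-1 / 6); hy <- sy * n^(-1 / 6)
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  ex <- diff(rx) * pad + 4 * hx; ey <- diff(ry) * pad + 4 * hy
  # MASS::kde2d's h is the kernel sd times 4 (it divides by 4 internally)
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = c(4 * hx, 4 * hy),
                   n = grid_size,
                   lims = c(rx[1] - ex, rx[2] + ex, ry[1] - ey, ry[2] + ey))
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  total <- sum(k$z) * cell
  list(x = k$x, y = k$y, z = k$z / total, bandwidth = c(hx, hy))
}
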