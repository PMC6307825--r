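# Conformational clustering: k-means on superposed flattened coordinates
# (the usual practical stand-in for RMSD-metric clustering; true RMSD is
# not a vector-space metric) and medoid extraction under pairwise
# superposed RMSD.

#' Interface atom selection around a set of nucleotides
#'
#' All atoms of the named nucleotide residues plus all atoms of every
#' non-RNA-chain residue that has at least one heavy atom within `cutoff`
#' of any heavy atom of those nucleotides, evaluated in the reference
#' frame.
#'
#' @param ens an [ensemble()] (topology provider).
#' @param rna_chain chain id of the RNA-like chain.
#' @param rna_residues integer vector of nucleotide residue indices.
#' @param cutoff shell cut-off, nm (default 0.45).
#' @param reference_frame 0-based frame index used for distances.
#' @return 0-based atom index vector (class `atom_selection`); attribute
#'   `shell_residues` lists the included protein residues. An empty
#'   protein shell is flagged with a warning.
#' @export
interface_selection <- function(ens, rna_chain, rna_residues,
                                cutoff = 0.45, reference_frame = 0L) {
  topo <- ens$topology
  fr <- ens$frames[[reference_frame + 1L]]
  nuc <- topo$chain_id == rna_chain & topo$residue_index %in% rna_residues
  if (!any(nuc)) stop("no atoms found for the named nucleotides")
  heavy <- topo$element != "H"
  nuc_xyz <- fr[which(nuc & heavy), , drop = FALSE]
  shell_res <- character(0)
  keep <- nuc
  others <- which(topo$chain_id != rna_chain)
  if (length(others) && cutoff > 0) {
    resid_key <- paste(topo$chain_id, topo$residue_index)
    for (rk in unique(resid_key[others])) {
      rows <- which(resid_key == rk & heavy)
      if (!length(rows)) next
      x <- fr[rows, , drop = FALSE]
      d2 <- outer(rowSums(x^2), rowSums(nuc_xyz^2), `+`) -
        2 * tcrossprod(x, nuc_xyz)
      if (min(d2) <= cutoff^2) {
        keep[resid_key == rk] <- TRUE
        shell_res <- c(shell_res, rk)
      }
    }
  }
  if (length(shell_res) == 0L && length(others))
    warning("no protein residues within ", cutoff, " nm of the nucleotides")
  structure(as.integer(topo$atom_index[keep]), class = "atom_selection",
            expression = sprintf("interface(%s:%s, %.3g nm)", rna_chain,
                                 paste(range(rna_residues), collapse = "-"),
                                 cutoff),
            empty = !any(keep), shell_residues = shell_res)
}

# Superpose every frame onto the first on `sel` and flatten the selected
# coordinates into a frames x (3*n_sel) matrix.
superposed_coordinate_matrix <- function(ens, sel) {
  ref <- ens$frames[[1L]]
  idx <- as.integer(sel) + 1L
  t(vapply(ens$frames, function(fr) {
    fit <- kabsch_superpose(fr, ref, sel)
    as.vector(t(fit$fitted[idx, , drop = FALSE]))
  }, numeric(3L * length(idx))))
}

# k-means++ initial centres (Arthur & Vassilvitskii) on rows of X.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1], ])^2)
  for (c in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) <= 0)
      centers[c] <- sample.int(n, 1L)
    else
      centers[c] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[c], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' k-means conformational clustering of an ensemble
#'
#' Frames are superposed onto the first frame on the selection, the
#' selected coordinates flattened, and k-means run with seeded k-means++
#' initialisation (10 restarts, best inertia kept, <= 500 iterations).
#' Deterministic given the seed.
#'
#' @param ens an [ensemble()].
#' @param sel 0-based atom indices to cluster on.
#' @param k number of clusters (`1 <= k <=` frame count).
#' @param seed integer seed.
#' @param restarts k-means++ restarts (default 10).
#' @return object of class `cluster_result`: list with `labels` (1-based
#'   per-frame cluster), `populations` (fractions, sum 1),
#'   `centroid_frames` (0-based medoid frame per cluster), `inertia`.
#' @export
kmeans_conformers <- function(ens, sel, k, seed = 1L, restarts = 10L) {
  nf <- n_frames(ens)
  if (k < 1L) stop("k must be >= 1")
  if (k > nf) stop("k exceeds frame count")
  if (length(sel) == 0L) stop("empty selection")
  X <- superposed_coordinate_matrix(ens, sel)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(X, k)
    km <- suppressWarnings(
      kmeans(X, centers = cen, iter.max = 500L, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  labels <- best$cluster
  pops <- as.numeric(table(factor(labels, levels = seq_len(k)))) / nf
  centroids <- vapply(seq_len(k), function(c) {
    members <- which(labels == c) - 1L
    if (length(members) == 0L) return(NA_integer_)
    centroid_frame(ens, sel, members)
  }, integer(1))
  structure(list(labels = labels, populations = pops,
                 centroid_frames = centroids,
                 inertia = best$tot.withinss),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k = %d, populations = %s>\n",
              length(x$populations),
              paste(sprintf("%.2f", x$populations), collapse = ", ")))
  invisible(x)
}

#' Medoid frame of a cluster
#'
#' The member with the lowest cumulative pairwise superposed RMSD to every
#' other member; ties broken by lowest frame index.
#'
#' @param ens an [ensemble()].
#' @param sel 0-based atom indices the RMSD is computed on.
#' @param members 0-based frame indices of the cluster.
#' @return 0-based frame index of the medoid.
#' @export
centroid_frame <- function(ens, sel, members) {
  members <- as.integer(members)
  if (length(members) == 0L) stop("empty member set")
  if (length(members) == 1L) return(members)
  m <- length(members)
  cum <- numeric(m)
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    r <- superposed_rmsd(ens$frames[[members[a] + 1L]],
                         ens$frames[[members[b] + 1L]], sel)
    cum[a] <- cum[a] + r; cum[b] <- cum[b] + r
  }
  members[order(cum, members)[1L]]
}
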