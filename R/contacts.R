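# Hydrogen-bond and stacking occupancy analysis. Interactions are declared
# explicitly (curated lists), never auto-perceived: occupancy tables report
# a chosen set of interface contacts, as is usual for interface studies.

#' Declare a hydrogen bond to monitor
#'
#' @param donor,hydrogen,acceptor 0-based atom indices of the donor heavy
#'   atom, its hydrogen, and the acceptor heavy atom; all distinct.
#' @param label text used in tables.
#' @return object of class `hbond_spec`.
#' @export
hbond_spec <- function(donor, hydrogen, acceptor, label = "") {
  ids <- c(donor, hydrogen, acceptor)
  if (anyDuplicated(ids)) stop("donor, hydrogen, acceptor must be distinct")
  structure(list(donor = as.integer(donor),
                 hydrogen = as.integer(hydrogen),
                 acceptor = as.integer(acceptor), label = label),
            class = "hbond_spec")
}

#' Declare a stacking pair to monitor
#'
#' @param ring_a,ring_b 0-based atom-index vectors of the two rings
#'   (>= 5 atoms each, non-collinear).
#' @param label text used in tables.
#' @return object of class `stack_spec`.
#' @export
stack_spec <- function(ring_a, ring_b, label = "") {
  if (length(ring_a) < 5L || length(ring_b) < 5L)
    stop("each ring needs at least 5 atoms")
  structure(list(ring_a = as.integer(ring_a), ring_b = as.integer(ring_b),
                 label = label), class = "stack_spec")
}

#' Is a hydrogen bond present in a frame?
#'
#' Present iff the donor-acceptor heavy-atom distance is at most `d_cut`
#' and the donor-hydrogen-acceptor angle (at the intervening hydrogen) is
#' at least `a_cut`.
#'
#' @param frame coordinate matrix (nm).
#' @param spec an [hbond_spec()].
#' @param d_cut heavy-heavy distance cut-off, nm (default 0.35).
#' @param a_cut D-H-A angle cut-off, degrees (default 135).
#' @return logical.
#' @export
hbond_present <- function(frame, spec, d_cut = 0.35, a_cut = 135) {
  d <- atom_distance(frame, spec$donor, spec$acceptor)
  if (d > d_cut) return(FALSE)
  atom_angle(frame, spec$donor, spec$hydrogen, spec$acceptor) >= a_cut
}

# Geometry of one H-bond in one frame: c(distance_nm, angle_deg).
hbond_geometry <- function(frame, spec) {
  c(atom_distance(frame, spec$donor, spec$acceptor),
    atom_angle(frame, spec$donor, spec$hydrogen, spec$acceptor))
}

#' Is a stacking interaction present in a frame?
#'
#' Present iff the ring centre distance is below `d_cut` and the folded
#' angle between the two best-fit ring planes is below `theta_cut`. Ring
#' centres are unweighted centres of geometry by default; set
#' `mass_weighted = TRUE` to weight by rough atomic masses.
#'
#' @param frame coordinate matrix (nm).
#' @param spec a [stack_spec()].
#' @param d_cut centre-centre cut-off, nm (default 0.5).
#' @param theta_cut plane-angle cut-off, degrees (default 30).
#' @param mass_weighted use mass-weighted ring centres.
#' @param topology required when `mass_weighted` (element lookup).
#' @return logical.
#' @export
stack_present <- function(frame, spec, d_cut = 0.5, theta_cut = 30,
                          mass_weighted = FALSE, topology = NULL) {
  g <- stack_geometry(frame, spec, mass_weighted, topology)
  g[1] < d_cut && g[2] < theta_cut
}

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                 P = 30.974, S = 32.06)

ring_center <- function(frame, idx, mass_weighted = FALSE,
                        topology = NULL) {
  x <- frame[idx + 1L, , drop = FALSE]
  if (!mass_weighted) return(colMeans(x))
  if (is.null(topology)) stop("mass weighting needs the topology")
  el <- topology$element[match(idx, topology$atom_index)]
  w <- ATOMIC_MASS[el]; w[is.na(w)] <- 12
  colSums(x * w) / sum(w)
}

# c(center_distance_nm, plane_angle_deg)
stack_geometry <- function(frame, spec, mass_weighted = FALSE,
                           topology = NULL) {
  c1 <- ring_center(frame, spec$ring_a, mass_weighted, topology)
  c2 <- ring_center(frame, spec$ring_b, mass_weighted, topology)
  n1 <- ring_plane_normal(frame, spec$ring_a)
  n2 <- ring_plane_normal(frame, spec$ring_b)
  c(sqrt(sum((c1 - c2)^2)), plane_angle(n1, n2))
}

#' Per-trajectory occupancy table for declared interactions
#'
#' For each interaction and each ensemble, occupancy is
#' `100 * present-frames / total-frames`. Geometry means and standard
#' deviations (distance; angle) are pooled over the present frames of all
#' ensembles, the convention used for interface-contact tables; per-frame
#' geometry never includes frames where the interaction is absent.
#'
#' @param ensembles named list of [ensemble()] objects over one topology.
#' @param hbonds list of [hbond_spec()].
#' @param stacks list of [stack_spec()].
#' @param d_cut_hb,a_cut_hb,d_cut_stack,theta_cut_stack geometric criteria
#'   (defaults 0.35 nm / 135 deg for H-bonds, 0.5 nm / 30 deg for stacks).
#' @return data.frame of class `occupancy_table`: one row per interaction
#'   with `label`, `type`, `mean_distance_nm`, `sd_distance_nm`,
#'   `mean_angle_deg`, `sd_angle_deg`, then one `occ_<name>` column (%)
#'   per ensemble. Geometry fields are `NA` for interactions never present.
#' @export
occupancy_table <- function(ensembles, hbonds = list(), stacks = list(),
                            d_cut_hb = 0.35, a_cut_hb = 135,
                            d_cut_stack = 0.5, theta_cut_stack = 30) {
  if (length(ensembles) == 0L) stop("no ensembles supplied")
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles))))
    names(ensembles) <- paste0("traj", seq_along(ensembles))
  specs <- c(hbonds, stacks)
  types <- rep(c("hbond", "stack"), c(length(hbonds), length(stacks)))
  rows <- lapply(seq_along(specs), function(s) {
    spec <- specs[[s]]
    occ <- numeric(length(ensembles))
    geom <- list()
    for (e in seq_along(ensembles)) {
      ens <- ensembles[[e]]
      pres <- logical(n_frames(ens))
      for (f in seq_len(n_frames(ens))) {
        fr <- ens$frames[[f]]
        if (types[s] == "hbond") {
          g <- hbond_geometry(fr, spec)
          pres[f] <- g[1] <= d_cut_hb && g[2] >= a_cut_hb
        } else {
          g <- stack_geometry(fr, spec)
          pres[f] <- g[1] < d_cut_stack && g[2] < theta_cut_stack
        }
        if (pres[f]) geom[[length(geom) + 1L]] <- g
      }
      occ[e] <- 100 * sum(pres) / n_frames(ens)
    }
    gm <- if (length(geom)) do.call(rbind, geom) else
      matrix(NA_real_, 0, 2)
    out <- data.frame(
      label = spec$label, type = types[s],
      mean_distance_nm = if (nrow(gm)) mean(gm[, 1]) else NA_real_,
      sd_distance_nm = if (nrow(gm) > 1) sd(gm[, 1]) else NA_real_,
      mean_angle_deg = if (nrow(gm)) mean(gm[, 2]) else NA_real_,
      sd_angle_deg = if (nrow(gm) > 1) sd(gm[, 2]) else NA_real_,
      stringsAsFactors = FALSE)
    for (e in seq_along(ensembles))
      out[[paste0("occ_", names(ensembles)[e])]] <- occ[e]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("occupancy_table", class(out))
  out
}
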