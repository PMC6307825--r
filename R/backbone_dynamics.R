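# Backbone plasticity profiling and dihedral-histogram conformational
# entropy.
#
# Local plasticity is measured on the Ramachandran angle sum
# omega = wrap(phi + psi) as the circular standard deviation
# sqrt(-2 ln Rbar), where Rbar is the mean resultant length. Residues are
# additionally tagged by how they move between Ramachandran regions:
#   F - pure fluctuation within one region,
#   T - long transitions (minority regions occupied >= 30% of frames),
#   t - short transitions (minority occupancy between the noise floor and
#       30%).
# Entropy uses first-order dihedral histograms,
#   S = -R sum_bins p ln p per angle, summed over a residue's angles,
# with R = 1.9872e-3 kcal/mol/K; this is a qualitative comparative measure
# (no mutual-information corrections).

GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal / (mol K)

#' Circular dispersion of the Ramachandran angle sum
#'
#' Computes `omega_t = wrap(phi_t + psi_t)` and returns its circular
#' standard deviation `sqrt(-2 ln Rbar)` in degrees.
#'
#' @param series_phi,series_psi [dihedral_series()] of equal length >= 2.
#' @return dispersion in degrees (0 for a constant series).
#' @export
pad_dispersion <- function(series_phi, series_psi) {
  if (length(series_phi$values) != length(series_psi$values))
    stop("phi and psi series lengths differ")
  if (length(series_phi$values) < 2L) stop("need at least 2 frames")
  omega <- wrap_angle(series_phi$values + series_psi$values) * pi / 180
  rbar <- sqrt(mean(cos(omega))^2 + mean(sin(omega))^2)
  rbar <- min(rbar, 1)
  sqrt(-2 * log(max(rbar, 1e-300))) * 180 / pi
}

#' Default Ramachandran region map
#'
#' Three rectangular regions (beta, alpha, left-handed alpha) plus an
#' implicit catch-all `"other"`; each region is
#' `list(phi = c(lo, hi), psi = c(lo, hi))` with half-open `[lo, hi)`
#' membership. Boundaries are conventional secondary-structure basins and
#' are fully configurable.
#'
#' @return named list of regions.
#' @export
default_ramachandran_regions <- function() {
  list(
    beta = list(phi = c(-180, -45), psi = c(45, 180.001)),
    alpha = list(phi = c(-160, -20), psi = c(-90, 45)),
    alphaL = list(phi = c(20, 100), psi = c(-45, 90)))
}

# Assign each frame to a named region ("other" if none matches).
assign_regions <- function(phi, psi, regions) {
  lab <- rep("other", length(phi))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    hit <- phi >= r$phi[1] & phi < r$phi[2] &
           psi >= r$psi[1] & psi < r$psi[2] & lab == "other"
    lab[hit] <- nm
  }
  lab
}

#' Tag a residue as fluctuating (F) or transitioning (t/T)
#'
#' Frames are assigned to Ramachandran regions; the modal region is the
#' most occupied one. If every non-modal region's occupancy is at or below
#' `noise_floor` the residue is a pure fluctuator (`"F"`). Otherwise the
#' pooled minority occupancy decides: at least `minority_threshold` means
#' long transitions (`"T"`), less means short transitions (`"t"`).
#'
#' @param series_phi,series_psi [dihedral_series()].
#' @param regions region map as from [default_ramachandran_regions()].
#' @param minority_threshold long-transition threshold (default 0.30).
#' @param noise_floor occupancy below which a region is noise (default
#'   0.01).
#' @return list with `tag` (`"F"`, `"t"` or `"T"`), `occupancy` (named
#'   region fractions), `modal_region`, `minority_fraction`.
#' @export
tag_transitions <- function(series_phi, series_psi,
                            regions = default_ramachandran_regions(),
                            minority_threshold = 0.30,
                            noise_floor = 0.01) {
  if (length(regions) == 0L) stop("empty region map")
  lab <- assign_regions(series_phi$values, series_psi$values, regions)
  occ <- table(factor(lab, levels = c(names(regions), "other")))
  occ <- as.numeric(occ) / length(lab)
  names(occ) <- c(names(regions), "other")
  modal <- names(occ)[which.max(occ)]
  minority <- occ[names(occ) != modal]
  minority_frac <- sum(minority)
  tag <- if (all(minority <= noise_floor)) "F"
         else if (minority_frac >= minority_threshold) "T"
         else "t"
  list(tag = tag, occupancy = occ, modal_region = modal,
       minority_fraction = minority_frac)
}

#' Per-residue profile of dispersion and transition tags
#'
#' @param phi_list,psi_list lists of [dihedral_series()], matched by
#'   position.
#' @param ... passed to [tag_transitions()].
#' @return data.frame with `chain_id`, `residue_index`, `dispersion_deg`,
#'   `tag`, `minority_fraction`.
#' @export
pad_profile <- function(phi_list, psi_list, ...) {
  stopifnot(length(phi_list) == length(psi_list))
  rows <- lapply(seq_along(phi_list), function(i) {
    tg <- tag_transitions(phi_list[[i]], psi_list[[i]], ...)
    data.frame(chain_id = phi_list[[i]]$chain_id,
               residue_index = phi_list[[i]]$residue_index,
               dispersion_deg = pad_dispersion(phi_list[[i]], psi_list[[i]]),
               tag = tg$tag, minority_fraction = tg$minority_fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Histogram probabilities over (-180, 180] with right-closed bins.
angle_bin_probs <- function(values, bin_width) {
  nb <- 360 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 360")
  nb <- as.integer(round(nb))
  # right-closed bins: (-180, -180 + w], ..., (180 - w, 180]
  idx <- ceiling((values + 180) / bin_width)
  idx[idx < 1L] <- 1L; idx[idx > nb] <- nb
  tabulate(idx, nbins = nb) / length(values)
}

#' First-order dihedral-histogram conformational entropy of one residue
#'
#' Each angle's samples are histogrammed over `(-180, 180]` with
#' right-closed bins of width `bin_width`; `S = -R sum p ln p` per angle
#' (empty bins contribute 0), summed over the residue's angles as
#' independent first-order terms.
#'
#' @param series_list list of [dihedral_series()] for one residue
#'   (phi, psi, chi_n ...).
#' @param bin_width histogram bin width in degrees; must divide 360
#'   (default 10).
#' @return entropy in kcal/(mol K).
#' @export
dihedral_entropy <- function(series_list, bin_width = 10) {
  if (length(series_list) == 0L) stop("need at least one angle series")
  s_per_angle <- vapply(series_list, function(ds) {
    p <- angle_bin_probs(ds$values, bin_width)
    p <- p[p > 0]
    -GAS_CONSTANT_KCAL * sum(p * log(p))
  }, 0)
  sum(s_per_angle)
}

#' Entropy difference between two states with bootstrap uncertainty
#'
#' `T * (S_a - S_b)` for one residue, with a block bootstrap over frames
#' (contiguous blocks of 10% of frames, resampled with replacement) for the
#' uncertainty; block resampling respects the serial correlation of
#' trajectory data.
#'
#' @param state_a,state_b lists of [dihedral_series()] with identical angle
#'   inventories (matched by position and `angle_name`).
#' @param temperature_k temperature (default 298 K).
#' @param bin_width histogram bin width, degrees.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed bootstrap seed.
#' @return list with `tds_kcal_mol`, `stderr_kcal_mol`, `s_a`, `s_b`
#'   (kcal/(mol K)), `temperature_k`.
#' @export
entropy_difference <- function(state_a, state_b, temperature_k = 298,
                               bin_width = 10, n_boot = 200L, seed = 1L) {
  if (length(state_a) != length(state_b) ||
      !identical(vapply(state_a, function(d) d$angle_name, ""),
                 vapply(state_b, function(d) d$angle_name, "")))
    stop("angle inventories of the two states differ")
  s_a <- dihedral_entropy(state_a, bin_width)
  s_b <- dihedral_entropy(state_b, bin_width)
  boot_entropy <- function(series_list) {
    n <- length(series_list[[1]]$values)
    blk <- max(1L, floor(0.10 * n))
    starts <- seq(1L, n - blk + 1L)
    nblk <- ceiling(n / blk)
    pick <- sample(starts, nblk, replace = TRUE)
    idx <- unlist(lapply(pick, function(s) s:(s + blk - 1L)))[seq_len(n)]
    resampled <- lapply(series_list, function(ds)
      dihedral_series(ds$chain_id, ds$residue_index, ds$angle_name,
                      ds$values[idx]))
    dihedral_entropy(resampled, bin_width)
  }
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    temperature_k * (boot_entropy(state_a) - boot_entropy(state_b)), 0)
  list(tds_kcal_mol = temperature_k * (s_a - s_b),
       stderr_kcal_mol = sd(boots),
       s_a = s_a, s_b = s_b, temperature_k = temperature_k)
}
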