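# NOE back-calculation and violation scoring.
#
# The ensemble-effective distance is the r^-6 average
#   <r> = ( (1/N_f) sum_f r_f^-6 )^(-1/6),
# where for multi-atom (pseudo-atom) groups the per-frame distance r_f is
# itself the r^-6-summed effective distance over all cross pairs,
#   r_f = ( sum_{a in g1, b in g2} r_ab^-6 )^(-1/6).
# This pseudo-atom convention reflects NOE physics; a minimum-distance
# alternative is available via `group_mode = "min"`.

# Per-frame effective distances for one restraint across all frames.
frame_effective_distances <- function(ens, restraint,
                                      group_mode = c("r6sum", "min")) {
  group_mode <- match.arg(group_mode)
  g1 <- resolve_group(ens, restraint$group1)
  g2 <- resolve_group(ens, restraint$group2)
  if (length(intersect(g1, g2)) > 0L)
    stop("NOE groups overlap: ", restraint$group1, " / ", restraint$group2)
  vapply(ens$frames, function(fr) {
    a <- fr[g1 + 1L, , drop = FALSE]
    b <- fr[g2 + 1L, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
    d <- sqrt(pmax(d2, 0))
    if (group_mode == "min") min(d) else sum(d^-6)^(-1 / 6)
  }, 0)
}

#' Back-calculate the r^-6 ensemble-averaged NOE distance
#'
#' @param ens an [ensemble()].
#' @param restraint a [noe_restraint()]; multi-atom groups are combined by
#'   r^-6 summation within each frame (see `group_mode`).
#' @param group_mode `"r6sum"` (pseudo-atom convention, default) or `"min"`
#'   (per-frame minimum cross-pair distance).
#' @return the effective distance `<r>` in nm.
#' @export
backcalc_noe <- function(ens, restraint, group_mode = "r6sum") {
  r <- frame_effective_distances(ens, restraint, group_mode)
  mean(r^-6)^(-1 / 6)
}

#' Score an ensemble against a set of NOE upper bounds
#'
#' A restraint is violated iff its upper bound is below the back-calculated
#' `<r>`. The report carries, per restraint, `<r>` and the violation
#' magnitude, and in its summary: per-category satisfied fractions,
#' violation counts above 0.05 nm and 0.3 nm, and the average violation in
#' both conventions — over violated restraints only and over all restraints
#' (both as non-negative magnitudes, explicitly labelled).
#'
#' @param ens an [ensemble()].
#' @param restraints non-empty list of [noe_restraint()].
#' @param group_mode see [backcalc_noe()].
#' @return object of class `noe_report`: list with `table` (data.frame:
#'   group1, group2, bound_nm, category, avg_r_nm, violated,
#'   violation_nm) and `summary` (list).
#' @export
violation_report <- function(ens, restraints, group_mode = "r6sum") {
  if (length(restraints) == 0L) stop("no restraints supplied")
  avg_r <- vapply(restraints, function(r)
    backcalc_noe(ens, r, group_mode), 0)
  bound <- vapply(restraints, function(r) r$bound_nm, 0)
  categ <- vapply(restraints, function(r) r$category, "")
  violated <- bound < avg_r
  vmag <- ifelse(violated, avg_r - bound, 0)
  tab <- data.frame(
    group1 = vapply(restraints, function(r) r$group1, ""),
    group2 = vapply(restraints, function(r) r$group2, ""),
    bound_nm = bound, category = categ, avg_r_nm = avg_r,
    violated = violated,
    violation_nm = ifelse(violated, vmag, NA_real_),
    stringsAsFactors = FALSE)
  sat_by_cat <- tapply(!violated, categ, mean)
  summ <- list(
    n_restraints = length(restraints),
    n_violated = sum(violated),
    satisfied_fraction = mean(!violated),
    satisfied_fraction_by_category = as.list(sat_by_cat),
    n_violations_gt_0.05nm = sum(vmag > 0.05),
    n_violations_gt_0.3nm = sum(vmag > 0.3),
    avg_violation_over_violated_nm =
      if (any(violated)) mean(vmag[violated]) else 0,
    avg_violation_over_all_nm = sum(vmag) / length(restraints))
  structure(list(table = tab, summary = summ), class = "noe_report")
}

#' @export
print.noe_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<noe_report: %d restraints, %.1f%% satisfied, %d violations (%d > 0.05 nm, %d > 0.3 nm)>\n",
    s$n_restraints, 100 * s$satisfied_fraction, s$n_violated,
    s$n_violations_gt_0.05nm, s$n_violations_gt_0.3nm))
  invisible(x)
}

#' Write an NOE report as TSV (per-restraint rows) plus a JSON summary
#' @param report a `noe_report`.
#' @param tsv_path,json_path output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_noe_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(report$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$summary, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}

#' Count restraints violated by a single frame
#'
#' The single-frame r^-6 average reduces to the plain per-frame effective
#' distance, so this counts restraints whose per-frame effective distance
#' exceeds the bound (no tolerance).
#'
#' @param ens an [ensemble()] (topology provider).
#' @param frame_index 0-based frame index.
#' @param restraints list of [noe_restraint()].
#' @param group_mode see [backcalc_noe()].
#' @return integer violation count.
#' @export
per_frame_violation_count <- function(ens, frame_index, restraints,
                                      group_mode = "r6sum") {
  pm <- per_frame_violation_matrix(ens, restraints, group_mode)
  sum(pm$dist[frame_index + 1L, ] > pm$bound)
}

# All per-frame effective distances (frames x restraints) plus bounds.
per_frame_violation_matrix <- function(ens, restraints,
                                       group_mode = "r6sum") {
  dm <- vapply(restraints,
               function(r) frame_effective_distances(ens, r, group_mode),
               numeric(n_frames(ens)))
  if (is.null(dim(dm))) dm <- matrix(dm, nrow = n_frames(ens))
  list(dist = dm, bound = vapply(restraints, function(r) r$bound_nm, 0))
}

#' Select an NOE-adapted representative ensemble
#'
#' Retains the `frame_fraction` of frames with fewest per-frame NOE
#' violations (ties broken by total violation magnitude, then frame order),
#' superposes them onto the first retained frame over the whole complex,
#' clusters them with seeded k-means, and returns the per-cluster medoid
#' frames ordered by cluster population.
#'
#' @param ens an [ensemble()].
#' @param restraints list of [noe_restraint()].
#' @param frame_fraction fraction of frames to retain (default 0.10).
#' @param k number of clusters / output conformers (default 20).
#' @param seed k-means seed.
#' @param group_mode see [backcalc_noe()].
#' @return list with `ensemble` (the k medoid frames as a new ensemble, in
#'   decreasing cluster-population order), `retained_frames` (0-based
#'   indices into `ens`), `cluster` (the [kmeans_conformers()] result on
#'   the retained frames) and `centroid_source_frames` (0-based indices
#'   into `ens` of the emitted conformers).
#' @export
select_md_adapted_ensemble <- function(ens, restraints,
                                       frame_fraction = 0.10, k = 20L,
                                       seed = 1L, group_mode = "r6sum") {
  pm <- per_frame_violation_matrix(ens, restraints, group_mode)
  exceed <- sweep(pm$dist, 2L, pm$bound, `>`)
  counts <- rowSums(exceed)
  mags <- rowSums(pmax(sweep(pm$dist, 2L, pm$bound, `-`), 0) * exceed)
  n_keep <- max(1L, round(frame_fraction * n_frames(ens)))
  ord <- order(counts, mags, seq_along(counts))
  kept <- sort(ord[seq_len(n_keep)])
  if (k > n_keep) stop("k (", k, ") exceeds retained frame count (",
                       n_keep, ")")
  sub <- ensemble(ens$topology, ens$frames[kept],
                  label = paste0(ens$label, "-md-adapted"))
  all_atoms <- ens$topology$atom_index
  cl <- kmeans_conformers(sub, all_atoms, k = k, seed = seed)
  ord_cl <- order(-cl$populations, seq_len(k))
  centroids_local <- cl$centroid_frames[ord_cl]          # 0-based in sub
  centroid_src <- kept[centroids_local + 1L] - 1L        # 0-based in ens
  out <- ensemble(ens$topology, sub$frames[centroids_local + 1L],
                  label = paste0(ens$label, "-md-adapted-centroids"))
  list(ensemble = out, retained_frames = kept - 1L, cluster = cl,
       centroid_source_frames = centroid_src)
}
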