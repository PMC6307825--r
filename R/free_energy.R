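# Free-energy estimation from bidirectional non-equilibrium work samples.
#
# The Crooks fluctuation theorem, P_F(W) / P_R(-W) = exp[(W - dG) / kT],
# underlies the maximum-likelihood (Bennett-type) estimator: dG solves
#
#   sum_F 1/(1 + exp(M + (W_F - dG)/kT)) =
#   sum_R 1/(1 + exp(-M + (dG + W_R)/kT)),    M = ln(n_F / n_R),
#
# where W_F are forward (A->B) works and W_R reverse (B->A) works. The
# residual is monotone in dG, so a bracketed root search converges; the
# bracket [min(-W_R), max(W_F)] spans the region where forward and
# reversed-reverse work distributions can intersect, and failure to
# bracket a root signals catastrophic non-overlap.

#' Bundle bidirectional non-equilibrium work samples
#'
#' @param forward forward (A to B) work values, kcal/mol.
#' @param reverse reverse (B to A) work values, kcal/mol.
#' @param temperature_k temperature, K.
#' @param labels length-2 state labels.
#' @param replicate_f,replicate_r optional replicate ids per sample,
#'   preserved for hierarchical bootstrapping.
#' @return object of class `work_set`.
#' @export
work_set <- function(forward, reverse, temperature_k = 298,
                     labels = c("A", "B"), replicate_f = NULL,
                     replicate_r = NULL) {
  if (!all(is.finite(forward)) || !all(is.finite(reverse)))
    stop("work values must be finite")
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse),
                 temperature_k = temperature_k, labels = labels,
                 replicate_f = replicate_f, replicate_r = replicate_r),
            class = "work_set")
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf(
    "<work_set %s->%s: %d forward, %d reverse works at %g K>\n",
    x$labels[1], x$labels[2], length(x$forward), length(x$reverse),
    x$temperature_k))
  invisible(x)
}

#' Read a work-value TSV table
#'
#' Columns: `direction` (`forward`/`reverse`), `work_kcal_mol`, optional
#' `replicate`.
#'
#' @param path TSV file path.
#' @param temperature_k temperature to attach, K.
#' @return a [work_set()].
#' @export
read_work_table <- function(path, temperature_k = 298) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("direction", "work_kcal_mol") %in% names(df)))
    stop("work table needs columns: direction, work_kcal_mol")
  bad <- setdiff(unique(df$direction), c("forward", "reverse"))
  if (length(bad))
    stop("unknown direction token(s): ", paste(bad, collapse = ", "))
  fwd <- df$direction == "forward"
  if (!any(fwd)) stop("no forward work values in ", path)
  if (!any(!fwd)) stop("no reverse work values in ", path)
  rep_col <- if ("replicate" %in% names(df)) df$replicate else NULL
  work_set(df$work_kcal_mol[fwd], df$work_kcal_mol[!fwd],
           temperature_k = temperature_k,
           replicate_f = rep_col[fwd], replicate_r = rep_col[!fwd])
}

# Histogram-overlap diagnostic between forward works and negated reverse
# works: sum of bin-wise minima of the two normalised histograms, in [0,1].
work_overlap <- function(ws, n_bins = 30L) {
  a <- ws$forward; b <- -ws$reverse
  lo <- min(a, b); hi <- max(a, b)
  if (hi - lo < 1e-12) return(1)
  brk <- seq(lo, hi, length.out = n_bins + 1L)
  ca <- tabulate(pmin(pmax(findInterval(a, brk, rightmost.closed = TRUE),
                           1L), n_bins), n_bins) / length(a)
  cb <- tabulate(pmin(pmax(findInterval(b, brk, rightmost.closed = TRUE),
                           1L), n_bins), n_bins) / length(b)
  sum(pmin(ca, cb))
}

crooks_residual <- function(dg, wf, wr, kT) {
  M <- log(length(wf) / length(wr))
  sum(1 / (1 + exp(M + (wf - dg) / kT))) -
    sum(1 / (1 + exp(-M + (dg + wr) / kT)))
}

solve_crooks <- function(wf, wr, kT) {
  lo <- min(-wr); hi <- max(wf)
  if (abs(hi - lo) < 1e-12) return((lo + hi) / 2)
  if (lo > hi) return(NA_real_)  # disjoint work distributions
  flo <- crooks_residual(lo, wf, wr, kT)
  fhi <- crooks_residual(hi, wf, wr, kT)
  if (flo * fhi > 0) return(NA_real_)
  uniroot(crooks_residual, c(lo, hi), wf = wf, wr = wr, kT = kT,
          tol = 1e-12)$root
}

#' Crooks-theorem maximum-likelihood free-energy estimate
#'
#' Solves the Bennett self-consistent maximum-likelihood equation for
#' bidirectional work data (with the `ln(n_F/n_R)` sample-size offset) by
#' bracketed root search, and attaches a seeded bootstrap standard error
#' and a forward/reverse histogram-overlap diagnostic. Estimation refuses
#' (with the overlap in the error message) when the bracket
#' `[min(-W_R), max(W_F)]` contains no root, which indicates the two work
#' distributions do not overlap.
#'
#' @param ws a [work_set()] with >= 2 samples per direction.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return object of class `free_energy_estimate`: list with
#'   `delta_g_kcal_mol`, `stderr_kcal_mol`, `estimator`, `overlap`,
#'   `n_f`, `n_r`, `temperature_k`.
#' @export
crooks_mle <- function(ws, n_boot = 1000L, seed = 1L) {
  wf <- ws$forward; wr <- ws$reverse
  if (length(wf) < 2L || length(wr) < 2L)
    stop("need at least 2 work values per direction")
  kT <- GAS_CONSTANT_KCAL * ws$temperature_k
  dg <- solve_crooks(wf, wr, kT)
  ov <- work_overlap(ws)
  if (is.na(dg))
    stop(sprintf(
      "no root in bracket: forward/reverse work distributions do not overlap (overlap = %.3f)",
      ov))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    solve_crooks(wf[sample.int(length(wf), replace = TRUE)],
                 wr[sample.int(length(wr), replace = TRUE)], kT)
  }, 0)
  structure(list(delta_g_kcal_mol = dg,
                 stderr_kcal_mol = sd(boots, na.rm = TRUE),
                 estimator = "crooks_mle", overlap = ov,
                 n_f = length(wf), n_r = length(wr),
                 temperature_k = ws$temperature_k),
            class = "free_energy_estimate")
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<%s: dG = %.3f +/- %.3f kcal/mol (n_F = %d, n_R = %d, overlap = %.2f)>\n",
              x$estimator, x$delta_g_kcal_mol, x$stderr_kcal_mol,
              x$n_f, x$n_r, x$overlap))
  invisible(x)
}

#' Crooks Gaussian-intersection free-energy estimate
#'
#' Fits Gaussians to the forward works and the negated reverse works and
#' returns their intersection point, a standard cross-check for the
#' maximum-likelihood estimator. With (near-)equal variances the
#' intersection degenerates to the midpoint of the two means, which is the
#' value returned in that case.
#'
#' @param ws a [work_set()].
#' @param n_boot,seed bootstrap settings for the standard error.
#' @return a `free_energy_estimate`.
#' @export
crooks_gaussian_intersection <- function(ws, n_boot = 1000L, seed = 1L) {
  gi <- function(wf, wr) {
    m1 <- mean(wf); s1 <- sd(wf)
    m2 <- mean(-wr); s2 <- sd(-wr)
    if (abs(s1 - s2) < 1e-8 * max(s1, s2, 1e-12)) return((m1 + m2) / 2)
    a <- 1 / s1^2 - 1 / s2^2
    b <- -2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return((m1 + m2) / 2)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    # take the root between the two means (the physical intersection)
    inside <- roots >= min(m1, m2) & roots <= max(m1, m2)
    if (any(inside)) roots[inside][1] else
      roots[which.min(abs(roots - (m1 + m2) / 2))]
  }
  wf <- ws$forward; wr <- ws$reverse
  if (length(wf) < 2L || length(wr) < 2L)
    stop("need at least 2 work values per direction")
  dg <- gi(wf, wr)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    gi(wf[sample.int(length(wf), replace = TRUE)],
       wr[sample.int(length(wr), replace = TRUE)]), 0)
  structure(list(delta_g_kcal_mol = dg,
                 stderr_kcal_mol = sd(boots),
                 estimator = "crooks_gaussian_intersection",
                 overlap = work_overlap(ws),
                 n_f = length(wf), n_r = length(wr),
                 temperature_k = ws$temperature_k),
            class = "free_energy_estimate")
}

#' Thermodynamic-cycle binding free-energy change
#'
#' `ddG = dG_complex - dG_free`, errors combined in quadrature. Negative
#' `ddG` means the mutation favours binding.
#'
#' @param dg_complex,dg_free `free_energy_estimate` objects for the
#'   mutation in the complex and in the free molecule, at one temperature.
#' @return list with `ddg_kcal_mol`, `stderr_kcal_mol`, `temperature_k`.
#' @export
thermo_cycle_ddg <- function(dg_complex, dg_free) {
  if (!isTRUE(all.equal(dg_complex$temperature_k, dg_free$temperature_k)))
    stop("temperature mismatch between the two legs")
  list(ddg_kcal_mol =
         dg_complex$delta_g_kcal_mol - dg_free$delta_g_kcal_mol,
       stderr_kcal_mol = sqrt(dg_complex$stderr_kcal_mol^2 +
                              dg_free$stderr_kcal_mol^2),
       temperature_k = dg_complex$temperature_k)
}
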