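# Planning utilities for replica exchange with solute tempering (REST2):
# geometric lambda ladders between stated endpoints, and selection of the
# partial-scaling solute region around mutated nucleotides. In REST2,
# solute-solute interactions are scaled by lambda, solute-solvent by
# lambda^1/2, and solvent-solvent left unscaled, so only the (scaled)
# solute is effectively heated: T_eff = T / lambda.

#' Geometric lambda ladder for REST2 replicas
#'
#' `lambda_i = lambda_min^(i / (n - 1))`, i = 0..n-1: strictly decreasing
#' from 1 (the reference, unbiased replica) to `lambda_min`, with constant
#' ratio between neighbours.
#'
#' @param n number of replicas (>= 2).
#' @param lambda_min final scaling factor, in (0, 1).
#' @param temperature_k base temperature for the effective-temperature
#'   report.
#' @return object of class `lambda_ladder`: list with `lambdas`,
#'   `n_replicas`, `lambda_min`, `effective_temperatures_k`.
#' @export
geometric_ladder <- function(n, lambda_min, temperature_k = 298) {
  if (n < 2L) stop("need at least 2 replicas")
  if (lambda_min <= 0 || lambda_min >= 1)
    stop("lambda_min must be in (0, 1)")
  lam <- lambda_min^((seq_len(n) - 1L) / (n - 1L))
  structure(list(lambdas = lam, n_replicas = as.integer(n),
                 lambda_min = lambda_min,
                 effective_temperatures_k = temperature_k / lam),
            class = "lambda_ladder")
}

#' @export
print.lambda_ladder <- function(x, ...) {
  cat(sprintf("<lambda_ladder: %d replicas, 1 -> %g (ratio %.4f)>\n",
              x$n_replicas, x$lambda_min, x$lambdas[2] / x$lambdas[1]))
  invisible(x)
}

PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O5'", "OP3")

#' Partial-scaling solute region around mutated nucleotides
#'
#' The scaled atom set comprises the mutated nucleotides, their flanking
#' phosphate groups on both the 5' side (the residue's own `P`/`OP1`/
#' `OP2`/`O5'` atoms) and the 3' side (the same atoms of the following
#' residue in the chain), and every whole protein residue with at least
#' one heavy atom within `cutoff` of any heavy atom of the mutated
#' nucleotides. The three interaction classes of REST2 partial scaling are
#' reported: scaled-scaled (lambda), scaled-unscaled (lambda^1/2) and
#' unscaled-unscaled (1).
#'
#' @param ens an [ensemble()].
#' @param rna_chain chain id of the RNA-like chain.
#' @param mutated_nucleotides residue indices of the mutated nucleotides.
#' @param cutoff protein-shell cut-off, nm (default 0.5).
#' @param flanking `"both"` (default), `"three_prime"` or `"none"`: which
#'   flanking phosphates to include beyond the residues' own.
#' @param reference_frame 0-based frame used for distances.
#' @return object of class `scaling_region`: list with `scaled_atoms`
#'   (0-based indices), `shell_residues` (protein residues included),
#'   `classes` (interaction-class descriptions) and `listing`
#'   (data.frame of scaled atoms: chain, residue, atom).
#' @export
partial_scaling_region <- function(ens, rna_chain, mutated_nucleotides,
                                   cutoff = 0.5,
                                   flanking = c("both", "three_prime",
                                                "none"),
                                   reference_frame = 0L) {
  flanking <- match.arg(flanking)
  topo <- ens$topology
  nuc_sel <- interface_selection(ens, rna_chain, mutated_nucleotides,
                                 cutoff = cutoff,
                                 reference_frame = reference_frame)
  keep <- topo$atom_index %in% as.integer(nuc_sel)
  if (flanking != "none") {
    flank_res <- unique(c(mutated_nucleotides + 1L,
                          if (flanking == "both") mutated_nucleotides))
    flank <- topo$chain_id == rna_chain &
      topo$residue_index %in% flank_res &
      topo$atom_name %in% PHOSPHATE_ATOMS
    keep <- keep | flank
  }
  scaled <- topo$atom_index[keep]
  listing <- data.frame(chain_id = topo$chain_id[keep],
                        residue_index = topo$residue_index[keep],
                        residue_name = topo$residue_name[keep],
                        atom_name = topo$atom_name[keep],
                        stringsAsFactors = FALSE)
  structure(list(
    scaled_atoms = as.integer(scaled),
    shell_residues = attr(nuc_sel, "shell_residues"),
    classes = list(
      scaled_scaled = "lambda",
      scaled_unscaled = "lambda^1/2",
      unscaled_unscaled = "1"),
    listing = listing), class = "scaling_region")
}

#' @export
print.scaling_region <- function(x, ...) {
  cat(sprintf("<scaling_region: %d scaled atoms, %d shell residues>\n",
              length(x$scaled_atoms), length(x$shell_residues)))
  invisible(x)
}

#' Write a REST2 plan (ladder + region) as JSON
#' @param ladder a [geometric_ladder()].
#' @param region a [partial_scaling_region()] result, or `NULL`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rest2_plan <- function(ladder, region = NULL, path) {
  plan <- list(lambdas = ladder$lambdas,
               n_replicas = ladder$n_replicas,
               effective_temperatures_k = ladder$effective_temperatures_k)
  if (!is.null(region))
    plan <- c(plan, list(scaled_atoms = region$scaled_atoms,
                         shell_residues = region$shell_residues,
                         classes = region$classes))
  jsonlite::write_json(plan, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
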