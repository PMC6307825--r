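#' @importFrom stats rnorm runif sd kmeans uniroot quantile
#' @importFrom utils read.delim write.table head tail
NULL

# Internal length unit is nanometres throughout; PDB I/O converts from/to
# Angstrom at the boundary.

#' Construct an ensemble of frames over a fixed atom topology
#'
#' An `ensemble` is the universal container consumed by every analysis stage:
#' an ordered atom topology (one row per atom) plus an ordered list of frames,
#' each an `n_atoms x 3` coordinate matrix in nanometres.
#'
#' @param topology data.frame with columns `atom_index` (0-based, unique),
#'   `atom_name`, `element`, `residue_index` (1-based within chain),
#'   `residue_name`, `chain_id`.
#' @param frames list of numeric `n_atoms x 3` matrices, coordinates in nm.
#' @param label free-text label carried through reports.
#' @return object of class `ensemble` with elements `topology`, `frames`,
#'   `label`.
#' @export
ensemble <- function(topology, frames, label = "") {
  req <- c("atom_index", "atom_name", "element", "residue_index",
           "residue_name", "chain_id")
  if (!all(req %in% names(topology)))
    stop("topology is missing columns: ",
         paste(setdiff(req, names(topology)), collapse = ", "))
  if (anyDuplicated(topology$atom_index))
    stop("atom_index values must be unique")
  key <- paste(topology$chain_id, topology$residue_index, topology$atom_name)
  if (anyDuplicated(key))
    stop("(chain_id, residue_index, atom_name) must be unique")
  if (length(frames) < 1L) stop("an ensemble needs at least one frame")
  na <- nrow(topology)
  for (f in seq_along(frames)) {
    x <- frames[[f]]
    if (!is.matrix(x) || ncol(x) != 3L || nrow(x) != na)
      stop("frame ", f, ": expected a ", na, " x 3 coordinate matrix")
    if (!all(is.finite(x)))
      stop("frame ", f, ": non-finite coordinates")
  }
  structure(list(topology = topology, frames = frames, label = label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble '%s': %d frames, %d atoms, %d chains>\n",
              x$label, n_frames(x), nrow(x$topology),
              length(unique(x$topology$chain_id))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an `ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Read a multi-model PDB file into an ensemble
#'
#' One frame per `MODEL` block; coordinates are converted from the PDB's
#' Angstrom to nanometres. The topology (atom names, residue numbering,
#' chains, elements) is taken from the first model; any model with a
#' different atom count is rejected. Only the first alternate location is
#' kept and insertion codes are rejected, matching the conventions of the
#' NMR-style ensembles this package targets.
#'
#' @param path PDB file path.
#' @param label optional ensemble label (defaults to the file name).
#' @return an [ensemble()] with coordinates in nm.
#' @export
read_multimodel_pdb <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  # pre-scan: every MODEL block must carry the same number of atom records
  raw <- readLines(path, warn = FALSE)
  model_at <- grepl("^MODEL", raw)
  if (any(model_at)) {
    block <- cumsum(model_at)
    is_atom <- grepl("^(ATOM|HETATM)", raw) & block > 0
    counts <- table(block[is_atom])
    if (length(unique(as.integer(counts))) > 1L)
      stop("models differ in atom count (topology mismatch) in ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stop("insertion codes are not supported")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (nrow(xyz) < 1L || nrow(at) < 1L) stop("no models found in ", path)
  idx <- which(keep)
  cols <- as.vector(rbind(3L * (idx - 1L) + 1L,
                          3L * (idx - 1L) + 2L,
                          3L * (idx - 1L) + 3L))
  xyz <- xyz[, cols, drop = FALSE]
  if (anyNA(xyz))
    stop("models differ in atom count (topology mismatch) in ", path)
  chain <- ifelse(is.na(at$chain), "", at$chain)
  elem <- trimws(at$elesy)
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1L, 1L)
  topo <- data.frame(
    atom_index = seq_len(nrow(at)) - 1L,
    atom_name = trimws(at$elety),
    element = elem,
    residue_index = at$resno,
    residue_name = trimws(at$resid),
    chain_id = chain,
    stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE) / 10  # Angstrom -> nm
    dimnames(m) <- NULL
    m
  })
  ensemble(topo, frames, label = label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom; each frame becomes one
#' `MODEL`/`ENDMDL` block numbered from 1.
#'
#' @param ens an [ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ens, path) {
  topo <- ens$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(ens$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$frames[[f]] * 10  # nm -> Angstrom
    nm <- topo$atom_name
    # PDB atom-name column convention: names of length < 4 start in column 14
    nm4 <- ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(topo)) - 1L) %% 99999L + 1L, nm4,
      substr(topo$residue_name, 1L, 3L), substr(topo$chain_id, 1L, 1L),
      topo$residue_index, xyz[, 1L], xyz[, 2L], xyz[, 3L],
      1, 0, substr(topo$element, 1L, 2L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms with a small expression grammar
#'
#' The grammar is a conjunction of clauses joined by `and`. Clauses:
#' \describe{
#'   \item{`chain X`}{one or more chain ids, comma-separated.}
#'   \item{`resi 28-33` / `resi 1,5,9`}{residue indices, ranges allowed.}
#'   \item{`name CA,P`}{atom names.}
#'   \item{`elem C,N`}{element symbols.}
#' }
#' Selection order follows topology order and is deterministic; an empty
#' result is allowed but carries attribute `empty = TRUE`.
#'
#' @param ens an [ensemble()].
#' @param expression selection string, e.g. `"chain R and resi 28-33"`.
#' @return object of class `atom_selection`: integer vector of 0-based atom
#'   indices with attributes `expression` and `empty`.
#' @export
select_atoms <- function(ens, expression) {
  topo <- ens$topology
  clauses <- strsplit(expression, "\\band\\b")[[1]]
  keep <- rep(TRUE, nrow(topo))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "") stop("empty clause in selection '", expression, "'")
    m <- regmatches(cl, regexec("^(chain|resi|name|elem)\\s+(\\S.*)$", cl))[[1]]
    if (length(m) != 3L)
      stop("cannot parse selection clause '", cl, "'")
    kw <- m[2]; arg <- gsub("\\s", "", m[3])
    parts <- strsplit(arg, ",", fixed = TRUE)[[1]]
    if (kw == "resi") {
      vals <- integer(0)
      for (p in parts) {
        if (grepl("^-?[0-9]+--?[0-9]+$", p) || grepl("^[0-9]+-[0-9]+$", p)) {
          ab <- as.integer(strsplit(p, "(?<=[0-9])-", perl = TRUE)[[1]])
          if (ab[1] <= ab[2]) vals <- c(vals, seq(ab[1], ab[2]))
          # descending range (e.g. "2-1") selects nothing
        } else if (grepl("^-?[0-9]+$", p)) {
          vals <- c(vals, as.integer(p))
        } else stop("bad residue token '", p, "' in '", expression, "'")
      }
      keep <- keep & topo$residue_index %in% vals
    } else if (kw == "chain") {
      keep <- keep & topo$chain_id %in% parts
    } else if (kw == "name") {
      keep <- keep & topo$atom_name %in% parts
    } else {  # elem
      keep <- keep & topo$element %in% parts
    }
  }
  idx <- topo$atom_index[keep]
  if (length(idx) == 0L)
    warning("selection '", expression, "' matched no atoms")
  structure(as.integer(idx), class = "atom_selection",
            expression = expression, empty = length(idx) == 0L)
}

#' Read a tab-separated NOE restraint table
#'
#' Expected columns (tab-separated, with header): `group1`, `group2`,
#' `bound_nm`, `category`. Group specifications name one or more atoms as
#' comma-separated `chain:residue:atom` triples, e.g. `"A:29:H1"` or
#' `"R:30:H2',R:30:H2''"`; multi-atom groups are treated as NOE pseudo-atoms
#' and combined by r^-6 summation during back-calculation.
#'
#' @param path TSV file path.
#' @return list of `noe_restraint` objects, in file order.
#' @seealso [noe_restraint()], [backcalc_noe()]
#' @export
read_noe_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("group1", "group2", "bound_nm", "category")
  if (!all(req %in% names(df)))
    stop("NOE table must have columns: ", paste(req, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    noe_restraint(df$group1[i], df$group2[i], df$bound_nm[i], df$category[i]))
}

#' Write a list of NOE restraints as a TSV table
#' @param restraints list of [noe_restraint()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_noe_table <- function(restraints, path) {
  df <- data.frame(
    group1 = vapply(restraints, function(r) r$group1, ""),
    group2 = vapply(restraints, function(r) r$group2, ""),
    bound_nm = vapply(restraints, function(r) r$bound_nm, 0),
    category = vapply(restraints, function(r) r$category, ""),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a single NOE upper-bound distance restraint
#'
#' @param group1,group2 atom-group specifications (`chain:resi:atom`,
#'   comma-separated for pseudo-atom groups).
#' @param bound_nm upper-bound distance in nm; must be positive.
#' @param category one of `"intra_protein"`, `"intra_rna"`,
#'   `"intermolecular"`.
#' @return object of class `noe_restraint`.
#' @export
noe_restraint <- function(group1, group2, bound_nm,
                          category = c("intermolecular", "intra_protein",
                                       "intra_rna")) {
  category <- match.arg(category)
  bound_nm <- as.numeric(bound_nm)
  if (!is.finite(bound_nm) || bound_nm <= 0)
    stop("NOE upper bound must be positive, got ", bound_nm)
  if (!nzchar(group1) || !nzchar(group2)) stop("empty atom group")
  structure(list(group1 = group1, group2 = group2, bound_nm = bound_nm,
                 category = category), class = "noe_restraint")
}

# Resolve "chain:resi:atom[,chain:resi:atom...]" to 0-based atom indices.
resolve_group <- function(ens, spec) {
  topo <- ens$topology
  parts <- strsplit(gsub("\\s", "", spec), ",", fixed = TRUE)[[1]]
  idx <- vapply(parts, function(p) {
    f <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(f) != 3L) stop("bad atom spec '", p, "' (want chain:resi:atom)")
    hit <- which(topo$chain_id == f[1] &
                 topo$residue_index == as.integer(f[2]) &
                 topo$atom_name == f[3])
    if (length(hit) != 1L)
      stop("atom spec '", p, "' resolves to ", length(hit), " atoms")
    topo$atom_index[hit]
  }, integer(1))
  unname(idx)
}
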