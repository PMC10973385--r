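# Protein structure container, fixed-column PDB I/O, and geometric
# primitives (atom-pair distance, dihedral, radius of gyration).
# pLDDT confidence values travel in the B-factor column, following the
# convention of structure-prediction tools.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Construct a protein structure
#'
#' A light container for a single-chain protein model: one row per atom
#' with author residue numbering, residue and atom names, coordinates in
#' Angstrom, and a per-residue confidence (pLDDT, 0-100) repeated on each
#' atom of a residue.
#'
#' @param atoms data.frame with columns `residue_number`, `residue_name`,
#'   `atom_name`, `x`, `y`, `z`, `plddt`.
#' @param provenance optional named list, e.g.
#'   `list(replicate = 1, seed = 17, model = 3)` or `list(label = "6XR6")`.
#' @return object of class `protein_structure`.
#' @export
new_structure <- function(atoms, provenance = list()) {
  need <- c("residue_number", "residue_name", "atom_name", "x", "y", "z", "plddt")
  if (!all(need %in% names(atoms))) {
    stop_validation("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_validation("non-finite coordinates")
  }
  rn <- unique(atoms$residue_number)
  if (is.unsorted(rn, strictly = TRUE)) {
    stop_validation("residue numbers must be strictly increasing along the chain")
  }
  structure(list(atoms = as.data.frame(atoms), provenance = provenance),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  prov <- if (length(x$provenance)) {
    paste0(" [", paste(names(x$provenance), unlist(x$provenance),
                       sep = "=", collapse = ", "), "]")
  } else ""
  cat(sprintf("protein_structure: %d atoms, %d residues, mean pLDDT %.1f%s\n",
              nrow(x$atoms), length(unique(x$atoms$residue_number)),
              mean_plddt(x), prov))
  invisible(x)
}

#' Residue numbers present in a structure
#' @param s a `protein_structure`.
#' @export
residue_numbers <- function(s) unique(s$atoms$residue_number)

#' Mean pLDDT over CA atoms
#' @param s a `protein_structure`.
#' @param residues optional residue numbers to restrict to.
#' @export
mean_plddt <- function(s, residues = NULL) {
  a <- s$atoms[s$atoms$atom_name == "CA", ]
  if (!is.null(residues)) a <- a[a$residue_number %in% residues, ]
  mean(a$plddt)
}

# n x 3 coordinate matrix for selected atoms, ordered by (residue, atom
# rank) so two structures with the same residues pair row-by-row. Column
# vectors are used throughout: this sits on the hot path of ensemble
# projection.
atom_coords <- function(s, residues = NULL, atom_names = BACKBONE_ATOMS) {
  rn <- s$atoms$residue_number
  rank <- match(s$atoms$atom_name, atom_names)
  sel <- !is.na(rank)
  if (!is.null(residues)) sel <- sel & (rn %in% residues)
  rn <- rn[sel]; rank <- rank[sel]
  ord <- order(rn, rank)
  idx <- which(sel)[ord]
  list(xyz = cbind(s$atoms$x[idx], s$atoms$y[idx], s$atoms$z[idx]),
       key = rn[ord] * (length(atom_names) + 1L) + rank[ord])
}

# Pair atoms between two structures by (residue_number, atom_name).
paired_coords <- function(a, b, residues, atom_names = BACKBONE_ATOMS) {
  ca <- atom_coords(a, residues, atom_names)
  cb <- atom_coords(b, residues, atom_names)
  common <- intersect(ca$key, cb$key)
  list(a = ca$xyz[match(common, ca$key), , drop = FALSE],
       b = cb$xyz[match(common, cb$key), , drop = FALSE],
       n = length(common))
}

lookup_atom <- function(s, residue_number, atom_name) {
  i <- which(s$atoms$residue_number == residue_number &
               s$atoms$atom_name == atom_name)
  if (length(i) == 0L) {
    stop_validation("atom not found: residue ", residue_number, " atom ",
                    atom_name)
  }
  unlist(s$atoms[i[1L], c("x", "y", "z")], use.names = FALSE)
}

#' Euclidean distance between two named atoms
#'
#' Used for observables such as the Abl1 activation-loop distances
#' (backbone O of E377 to backbone O of L409, and backbone O of L409 to
#' backbone O of G457) or the GMCSF H15-H83 CA distance.
#'
#' @param s a `protein_structure`.
#' @param a,b atom specs `c(residue_number, atom_name)`, e.g. `c(377, "O")`.
#' @return distance in Angstrom.
#' @export
atom_pair_distance <- function(s, a, b) {
  pa <- lookup_atom(s, as.integer(a[[1]]), as.character(a[[2]]))
  pb <- lookup_atom(s, as.integer(b[[1]]), as.character(b[[2]]))
  sqrt(sum((pa - pb)^2))
}

#' Signed dihedral angle of four atoms
#'
#' @param s a `protein_structure`.
#' @param atoms list of four atom specs `c(residue_number, atom_name)`.
#' @return torsion angle in degrees in (-180, 180].
#' @export
dihedral <- function(s, atoms) {
  if (length(atoms) != 4L) stop_validation("dihedral needs exactly 4 atom specs")
  p <- lapply(atoms, function(sp)
    lookup_atom(s, as.integer(sp[[1]]), as.character(sp[[2]])))
  dihedral_points(p[[1]], p[[2]], p[[3]], p[[4]])
}

# Torsion from raw coordinates; atan2 formulation.
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    stop_validation("undefined torsion: collinear atom triad")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  bn <- sqrt(sum(b2^2))
  # IUPAC sign convention (clockwise positive viewed from atom 2 to 3)
  ang <- -atan2(sum(m1 * n2) / bn, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Radius of gyration
#'
#' Mass-unweighted RMS distance of atoms from their centroid; used as a
#' compactness proxy when screening for partially unfolded predictions.
#'
#' @param s a `protein_structure`.
#' @param atom_names atoms to include (default backbone set).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(s, atom_names = BACKBONE_ATOMS) {
  xyz <- atom_coords(s, atom_names = atom_names)$xyz
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2)))
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM records of a single model; the B-factor column
#' is interpreted as per-residue pLDDT. Provenance is parsed from
#' filenames of the form `{replicate}_{seed}_{model}.pdb` when present.
#'
#' @param path PDB file path.
#' @return a `protein_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  end <- grep("^ENDMDL", lines)
  if (length(end)) lines <- lines[seq_len(end[1L] - 1L)]
  if (length(lines) == 0L) stop_format("no ATOM records in ", path)
  atoms <- data.frame(
    residue_number = as.integer(substr(lines, 23, 26)),
    residue_name = trimws(substr(lines, 18, 20)),
    atom_name = trimws(substr(lines, 13, 16)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    plddt = as.numeric(substr(lines, 61, 66))
  )
  if (anyNA(atoms$x) || anyNA(atoms$residue_number)) {
    stop_format("malformed ATOM records in ", path)
  }
  prov <- list()
  m <- regmatches(basename(path),
                  regexec("^(\\d+)_(\\d+)_(\\d+)\\.pdb$", basename(path)))[[1]]
  if (length(m) == 4L) {
    prov <- list(replicate = as.integer(m[2]), seed = as.integer(m[3]),
                 model = as.integer(m[4]))
  } else {
    prov <- list(label = sub("\\.pdb$", "", basename(path)))
  }
  new_structure(atoms, provenance = prov)
}

#' Write a structure as a PDB file
#'
#' Fixed-column ATOM records, chain A, occupancy 1.00, pLDDT in the
#' B-factor column. Coordinates are stored at the PDB precision of
#' 0.001 Angstrom.
#'
#' @param s a `protein_structure`.
#' @param path output file path.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  name4 <- ifelse(nchar(a$atom_name) < 4L,
                  sprintf(" %-3s", a$atom_name), a$atom_name)
  rec <- sprintf("ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
                 seq_len(nrow(a)), name4, a$residue_name, a$residue_number,
                 a$x, a$y, a$z, 1.0, a$plddt, substr(a$atom_name, 1, 1))
  writeLines(c(rec, "END"), path)
  invisible(path)
}
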