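# Core containers: small molecules as explicit atom/bond tables
# ("mol_structure"), proteins as per-chain residue/atom tables wrapped with a
# ligand into a "protein_complex". Both are plain S3 lists so they serialise
# and diff cleanly.

#' Construct a molecular structure
#'
#' The fundamental small-molecule container: an atom table (element, Cartesian
#' coordinates in Angstrom, formal charge, optional aromatic flag and
#' substructure label) plus a bond table (1-based atom index pair and bond
#' order). Substructure labels partition a degrader into its functional units:
#' \code{"warhead"}, \code{"linker"}, \code{"e3_binder"} or
#' \code{"unassigned"}.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param bonds data.frame with columns \code{a}, \code{b} (1-based atom
#'   indices) and \code{order} (1, 2, 3; aromatic bonds carry
#'   \code{order = 1.5}).
#' @param charges integer formal charges, recycled (default 0).
#' @param labels per-atom substructure labels (default "unassigned").
#' @param name optional molecule name carried through file I/O.
#' @return an object of class \code{mol_structure}.
#' @export
mol_structure <- function(elements, coords, bonds, charges = 0L,
                          labels = "unassigned", name = "MOL") {
  elements <- normalize_element(elements)
  n <- length(elements)
  if (n < 1L) stop("a molecular structure needs at least one atom")
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != n)
    stop("coords must be an n x 3 numeric matrix")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = numeric())
  } else {
    bonds <- as.data.frame(bonds)[, c("a", "b", "order")]
    bonds$a <- as.integer(bonds$a); bonds$b <- as.integer(bonds$b)
    if (any(bonds$a < 1L | bonds$a > n | bonds$b < 1L | bonds$b > n))
      stop("bond indices out of range")
    if (any(bonds$a == bonds$b)) stop("self-bonds are not allowed")
  }
  labels <- rep_len(as.character(labels), n)
  bad <- setdiff(unique(labels), c("warhead", "linker", "e3_binder", "unassigned"))
  if (length(bad)) stop("unknown substructure label: ", paste(bad, collapse = ", "))
  structure(list(
    elements = elements,
    coords = coords,
    bonds = bonds,
    charges = rep_len(as.integer(charges), n),
    labels = labels,
    name = as.character(name)
  ), class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  nh <- sum(x$elements != "H")
  cat(sprintf("<mol_structure> %s: %d atoms (%d heavy), %d bonds\n",
              x$name, n_atoms(x), nh, nrow(x$bonds)))
  lab <- table(x$labels)
  if (length(lab) > 1L || names(lab)[1] != "unassigned")
    cat("  labels:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param mol a \code{mol_structure}
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Indices of heavy (non-hydrogen) atoms
#' @param mol a \code{mol_structure}
#' @export
heavy_atoms <- function(mol) which(mol$elements != "H")

#' @keywords internal
is_mol <- function(x) inherits(x, "mol_structure")

#' Extract a sub-structure by atom indices
#'
#' Keeps the selected atoms (original order preserved) and every bond whose
#' endpoints are both selected. The mapping back to the parent is recorded in
#' attribute \code{"parent_indices"}.
#'
#' @param mol a \code{mol_structure}
#' @param idx atom indices to keep
#' @return a \code{mol_structure} with attribute \code{parent_indices}
#' @export
subset_mol <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (!length(idx)) stop("cannot take an empty substructure")
  remap <- integer(n_atoms(mol)); remap[idx] <- seq_along(idx)
  keep <- mol$bonds$a %in% idx & mol$bonds$b %in% idx
  b <- mol$bonds[keep, , drop = FALSE]
  b$a <- remap[b$a]; b$b <- remap[b$b]
  out <- mol_structure(mol$elements[idx], mol$coords[idx, , drop = FALSE], b,
                       mol$charges[idx], mol$labels[idx], mol$name)
  attr(out, "parent_indices") <- idx
  out
}

#' Replace the coordinates of a structure
#' @param mol a \code{mol_structure}
#' @param coords replacement n x 3 matrix
#' @export
set_coords <- function(mol, coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == n_atoms(mol), ncol(coords) == 3L)
  mol$coords <- coords
  dimnames(mol$coords) <- list(NULL, c("x", "y", "z"))
  mol
}

# --- protein complexes -------------------------------------------------------

#' Construct a protein complex
#'
#' A protein (one or more chains of residues, each with at least a Calpha
#' atom) together with a bound small-molecule ligand. Residue numbering is
#' 1-based and preserved from the source file; sequences are stored one-letter
#' per residue for alignment-based residue mapping.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname} (three-letter), \code{atom} (atom name, "CA" marks the
#'   Calpha), \code{elem}, \code{x}, \code{y}, \code{z}.
#' @param ligand a \code{mol_structure}.
#' @param id provenance identifier.
#' @return an object of class \code{protein_complex}.
#' @export
protein_complex <- function(atoms, ligand, id = "complex") {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "resname", "atom", "elem", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("protein atom table must have columns: ", paste(need, collapse = ", "))
  if (!is_mol(ligand) || n_atoms(ligand) < 1L)
    stop("ligand must be a non-empty mol_structure")
  atoms$elem <- normalize_element(atoms$elem)
  key <- paste(atoms$chain, atoms$resno)
  has_ca <- tapply(atoms$atom == "CA", key, any)
  if (!all(has_ca)) stop("every residue must carry a Calpha (CA) atom")
  structure(list(atoms = atoms, ligand = ligand, id = as.character(id)),
            class = "protein_complex")
}

#' @export
print.protein_complex <- function(x, ...) {
  ch <- chain_ids(x)
  cat(sprintf("<protein_complex> %s: %d chain(s) [%s], %d protein atoms, ligand %d atoms\n",
              x$id, length(ch), paste(ch, collapse = ","), nrow(x$atoms),
              n_atoms(x$ligand)))
  invisible(x)
}

#' Chain identifiers of a protein complex
#' @param px a \code{protein_complex}
#' @export
chain_ids <- function(px) unique(px$atoms$chain)

#' One-letter sequence of a chain
#' @param px a \code{protein_complex}
#' @param chain chain id
#' @return named character vector, names are residue numbers
#' @export
chain_sequence <- function(px, chain) {
  a <- px$atoms[px$atoms$chain == chain & px$atoms$atom == "CA", ]
  a <- a[order(a$resno), ]
  setNames(aa3_to_1(a$resname), a$resno)
}

#' Calpha coordinates of a chain
#' @param px a \code{protein_complex}
#' @param chain chain id
#' @return matrix with rownames = residue numbers
#' @export
calpha_coords <- function(px, chain) {
  a <- px$atoms[px$atoms$chain == chain & px$atoms$atom == "CA", ]
  a <- a[order(a$resno), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Heavy-atom coordinates of the protein part
#' @param px a \code{protein_complex}
#' @export
protein_heavy_coords <- function(px) {
  a <- px$atoms[px$atoms$elem != "H", ]
  as.matrix(a[, c("x", "y", "z")])
}

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

aa3_to_1 <- function(res3) {
  out <- .AA3[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa1_to_3 <- function(res1) {
  inv <- setNames(names(.AA3), .AA3)
  out <- inv[toupper(res1)]
  out[is.na(out)] <- "GLY"
  unname(out)
}

#' Apply a rigid transform to a coordinate matrix
#' @param coords n x 3 matrix
#' @param transform a \code{rigid_transform}
#' @export
transform_coords <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Apply a rigid transform to a whole protein complex (protein and ligand)
#' @param px a \code{protein_complex}
#' @param transform a \code{rigid_transform}
#' @export
transform_complex <- function(px, transform) {
  xyz <- transform_coords(as.matrix(px$atoms[, c("x", "y", "z")]), transform)
  px$atoms$x <- xyz[, 1]; px$atoms$y <- xyz[, 2]; px$atoms$z <- xyz[, 3]
  px$ligand <- set_coords(px$ligand, transform_coords(px$ligand$coords, transform))
  px
}
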