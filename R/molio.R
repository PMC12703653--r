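# Structure I/O: SDF through ChemmineR, mol2 and PDB through bio3d, with
# converters to/from the package containers. Molecule formats carry bonds;
# PDB ligand bonds are perceived from interatomic distances.

#' @importClassesFrom ChemmineR SDF SDFset
NULL

.METALS <- c("Li", "Na", "K", "Mg", "Ca", "Mn", "Fe", "Co", "Ni", "Cu",
             "Zn", "Cd", "Hg", "Al")

#' Read a molecular structure or protein complex
#'
#' \code{mol2} and \code{sdf} yield a \code{mol_structure} (first record of a
#' multi-record file; see \code{\link{read_sdf_ensemble}} for all records).
#' \code{pdb} yields a \code{protein_complex}: ATOM records become protein
#' chains (1-based residue numbering preserved from the source), and the
#' ligand is taken from HETATM records with residue name \code{ligand_id}
#' (default: the largest non-water HETATM residue), its bonds perceived from
#' interatomic distances against covalent-radius sums.
#'
#' @param path file path.
#' @param format one of "mol2", "sdf", "pdb"; guessed from the extension
#'   when omitted.
#' @param ligand_id HETATM residue name of the ligand (pdb only).
#' @param add_hydrogens for molecule formats, fill missing hydrogens from
#'   standard valences (default TRUE).
#' @return a \code{mol_structure} or \code{protein_complex}.
#' @export
read_structure <- function(path, format = NULL, ligand_id = NULL,
                           add_hydrogens = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
    mol2 = {
      mol <- .mol2_to_mol(bio3d::read.mol2(path))
      if (add_hydrogens) mol <- add_missing_hydrogens(mol)
      mol
    },
    sdf = {
      mols <- read_sdf_ensemble(path)
      mol <- mols[[1]]
      if (add_hydrogens) mol <- add_missing_hydrogens(mol)
      mol
    },
    pdb = .pdb_to_complex(path, ligand_id),
    stop("unsupported format: ", format)
  )
}

#' Write a molecular structure or protein complex
#' @param x a \code{mol_structure} or \code{protein_complex}.
#' @param path output path.
#' @param format "mol2", "sdf" or "pdb"; guessed from the extension.
#' @export
write_structure <- function(x, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (is_mol(x)) {
    switch(format,
      sdf = write_sdf_ensemble(list(x), path),
      mol2 = .write_mol2(x, path),
      stop("cannot write a molecule as ", format))
  } else if (inherits(x, "protein_complex")) {
    if (format != "pdb") stop("protein complexes are written as pdb")
    .write_complex_pdb(x, path)
  } else stop("unsupported object")
  invisible(path)
}

# --- SDF ---------------------------------------------------------------------

.SDF_ORDER_OUT <- function(order) {
  if (order == 1.5) 4L else as.integer(order)
}
.SDF_ORDER_IN <- function(code) {
  if (code == 4) 1.5 else as.numeric(code)
}

.mol_to_sdf <- function(mol, fields = character()) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  ab <- cbind(mol$coords, matrix(0, n, 12))
  dimnames(ab) <- list(paste(mol$elements, seq_len(n), sep = "_"),
                       c("C1", "C2", "C3", paste0("C", 5:16)))
  bb <- if (nb) cbind(mol$bonds$a, mol$bonds$b,
                      vapply(mol$bonds$order, .SDF_ORDER_OUT, integer(1)), 0L)
        else matrix(integer(), 0, 4)
  dimnames(bb) <- list(if (nb) seq_len(nb) else NULL, paste0("C", 1:4))
  h <- c(Molecule_Name = mol$name, Source = "protaconf", Comment = "",
         Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                               n, nb))
  db <- if (length(fields)) vapply(fields, as.character, character(1))
        else character(0)
  methods::new("SDF", header = h, atomblock = ab, bondblock = bb,
               datablock = db)
}

.sdf_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  bad <- !normalize_element(elems) %in% c(.ELEMENTS$symbol, .METALS)
  if (any(bad))
    stop("unknown atom type '", elems[which(bad)[1]], "' (atom ",
         which(bad)[1], ")")
  bonds <- if (nrow(bb)) data.frame(
    a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
    order = vapply(bb[, 3], .SDF_ORDER_IN, numeric(1))
  ) else NULL
  nm <- unname(ChemmineR::header(sdf)["Molecule_Name"])
  mol <- mol_structure(elems, ab[, 1:3, drop = FALSE], bonds,
                       name = if (is.na(nm)) "MOL" else nm)
  attr(mol, "sdf_fields") <- ChemmineR::datablock(sdf)
  mol
}

#' Read every record of a (multi-conformer) SDF
#' @param path file path
#' @return list of \code{mol_structure}; per-record data fields are kept in
#'   attribute \code{"sdf_fields"}
#' @export
read_sdf_ensemble <- function(path) {
  set <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("cannot parse SDF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  lapply(ChemmineR::cid(set), function(id) .sdf_to_mol(set[[id]]))
}

#' Write molecules (e.g. a conformer ensemble) to a multi-record SDF
#' @param mols list of \code{mol_structure}
#' @param path output path
#' @param fields optional list (one element per molecule) of named character
#'   vectors written as SDF data fields
#' @export
write_sdf_ensemble <- function(mols, path, fields = NULL) {
  sdfs <- lapply(seq_along(mols), function(i)
    .mol_to_sdf(mols[[i]], if (is.null(fields)) character() else fields[[i]]))
  set <- ChemmineR::SDFset(sdfs, as.character(seq_along(sdfs)))
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

# --- mol2 --------------------------------------------------------------------

.SYBYL_AROMATIC <- c("C.ar", "N.ar")

.mol2_to_mol <- function(m2) {
  at <- m2$atom
  elems <- sub("\\..*$", "", at$elety)
  known <- c(.ELEMENTS$symbol, .METALS)
  bad <- !normalize_element(elems) %in% known
  if (any(bad))
    stop("unknown atom type '", at$elety[which(bad)[1]], "' (atom ",
         at$elena[which(bad)[1]], ")")
  bonds <- NULL
  if (!is.null(m2$bond) && nrow(m2$bond)) {
    type <- tolower(m2$bond$type)
    order <- ifelse(type == "ar", 1.5, ifelse(type == "am", 1,
                    suppressWarnings(as.numeric(type))))
    if (any(is.na(order)))
      stop("unknown mol2 bond type '", type[which(is.na(order))[1]], "'")
    bonds <- data.frame(a = m2$bond$origin, b = m2$bond$target, order = order)
  }
  mol_structure(elems, cbind(at$x, at$y, at$z), bonds,
                name = if (is.null(m2$name) || !nzchar(m2$name)) "MOL"
                       else m2$name)
}

.mol_to_mol2 <- function(mol) {
  n <- n_atoms(mol)
  arom <- .aromatic_atoms(mol)
  elety <- vapply(seq_len(n), function(i) {
    e <- mol$elements[i]
    if (e == "H") "H"
    else if (arom[i] && e %in% c("C", "N")) paste0(e, ".ar")
    else if (e %in% c("C", "N", "O", "S", "P")) paste0(e, ".3")
    else e
  }, character(1))
  type <- vapply(mol$bonds$order, function(o)
    if (o == 1.5) "ar" else as.character(as.integer(o)), character(1))
  atom <- data.frame(
    eleno = seq_len(n),
    elena = paste0(mol$elements, seq_len(n)),
    x = mol$coords[, 1], y = mol$coords[, 2], z = mol$coords[, 3],
    elety = elety, resno = 1, resid = "LIG",
    charge = as.numeric(mol$charges), statbit = NA_character_)
  bond <- data.frame(id = seq_len(nrow(mol$bonds)), origin = mol$bonds$a,
                     target = mol$bonds$b, type = type,
                     statbit = NA_character_)
  structure(list(atom = atom, bond = bond, substructure = NULL,
                 xyz = as.numeric(t(mol$coords)),
                 info = c(n, nrow(mol$bonds), 1, NA, NA), name = mol$name),
            class = "mol2")
}

.aromatic_atoms <- function(mol) {
  arom <- rep(FALSE, n_atoms(mol))
  sel <- mol$bonds$order == 1.5
  arom[unique(c(mol$bonds$a[sel], mol$bonds$b[sel]))] <- TRUE
  arom
}

.write_mol2 <- function(mol, path) {
  bio3d::write.mol2(.mol_to_mol2(mol), file = path)
  invisible(path)
}

# --- PDB ---------------------------------------------------------------------

.pdb_to_complex <- function(path, ligand_id = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  prot <- at[at$type == "ATOM", ]
  het <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT")), ]
  if (is.null(ligand_id)) {
    if (!nrow(het)) stop("no HETATM ligand in ", path)
    sizes <- table(het$resid)
    ligand_id <- names(sizes)[which.max(sizes)]
  }
  lig <- het[het$resid == ligand_id, ]
  if (!nrow(lig)) stop("ligand id '", ligand_id, "' absent from ", path)
  elem <- function(d) {
    e <- d$elesy
    miss <- is.na(e) | !nzchar(trimws(e))
    e[miss] <- substr(trimws(d$elety[miss]), 1, 1)
    normalize_element(trimws(e))
  }
  lig_mol <- mol_structure(elem(lig), cbind(lig$x, lig$y, lig$z),
                           .perceive_bonds(elem(lig),
                                           cbind(lig$x, lig$y, lig$z)),
                           name = ligand_id)
  # orders are unknown (distance perception); downstream MCS matches on
  # topology + elements only for such ligands
  attr(lig_mol, "perceived_bonds") <- TRUE
  atoms <- data.frame(chain = prot$chain, resno = prot$resno,
                      resname = prot$resid, atom = trimws(prot$elety),
                      elem = elem(prot), x = prot$x, y = prot$y, z = prot$z)
  protein_complex(atoms, lig_mol, id = basename(path))
}

# distance-based bond perception: bonded iff d < 1.3 x covalent-radius sum
.perceive_bonds <- function(elems, coords, scale = 1.3) {
  n <- length(elems)
  if (n < 2L) return(NULL)
  r <- covalent_radius(elems)
  d <- as.matrix(stats::dist(coords))
  lim <- outer(r, r, `+`) * scale
  idx <- which(d < lim & upper.tri(d), arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  data.frame(a = idx[, 1], b = idx[, 2], order = 1)
}

.write_complex_pdb <- function(px, path) {
  a <- px$atoms
  lig <- px$ligand
  nl <- n_atoms(lig)
  xyz <- c(t(as.matrix(a[, c("x", "y", "z")])), t(lig$coords))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = c(rep("ATOM", nrow(a)), rep("HETATM", nl)),
    resno = c(a$resno, rep(max(a$resno) + 1L, nl)),
    resid = c(a$resname, rep("LIG", nl)),
    chain = c(a$chain, rep("X", nl)),
    eleno = seq_len(nrow(a) + nl),
    elety = c(a$atom, paste0(lig$elements, seq_len(nl))),
    elesy = c(a$elem, lig$elements))
  invisible(path)
}

# --- complex cleaning --------------------------------------------------------

#' Clean a monomer protein-ligand complex
#'
#' Removes waters, metals and non-ligand heteroatoms (for complexes read
#' from PDB this has largely happened at parse time), and drops every
#' protein chain without at least one heavy atom within
#' \code{proximity_cutoff} of a ligand heavy atom, retaining only chains in
#' close contact with the degrader-binding site (e.g. elongin B/C subunits
#' fall away from a VHL complex).
#'
#' @param px a \code{protein_complex}.
#' @param proximity_cutoff chain-retention cutoff in Angstrom (default 8).
#' @return the cleaned \code{protein_complex}.
#' @export
clean_complex <- function(px, proximity_cutoff = 8) {
  stopifnot(inherits(px, "protein_complex"), proximity_cutoff > 0)
  a <- px$atoms
  a <- a[!(a$resname %in% c("HOH", "WAT")), ]
  a <- a[!(a$elem %in% .METALS), ]
  lig_xyz <- px$ligand$coords[heavy_atoms(px$ligand), , drop = FALSE]
  keep_chain <- vapply(unique(a$chain), function(ch) {
    xyz <- a[a$chain == ch & a$elem != "H", c("x", "y", "z")]
    if (!nrow(xyz)) return(FALSE)
    d2 <- outer(rowSums(as.matrix(xyz)^2), rowSums(lig_xyz^2), `+`) -
      2 * as.matrix(xyz) %*% t(lig_xyz)
    min(d2) <= proximity_cutoff^2
  }, logical(1))
  a <- a[a$chain %in% unique(a$chain)[keep_chain], ]
  if (!nrow(a)) stop("no chain within ", proximity_cutoff, " A of the ligand")
  protein_complex(a, px$ligand, px$id)
}

# --- hydrogen filling --------------------------------------------------------

.VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
              F = 1, Cl = 1, Br = 1, I = 1)

#' Fill missing hydrogens from standard valences
#'
#' Adds explicit hydrogens so each heavy atom reaches its standard valence
#' (charge-adjusted), placed 1.0 Angstrom away opposite the mean direction
#' of existing neighbours. Geometry is approximate: hydrogens are ignored in
#' all scoring, and torsion driving moves them rigidly with their heavy
#' atom's side.
#'
#' @param mol a \code{mol_structure}
#' @return the molecule with hydrogens appended (input order preserved)
#' @export
add_missing_hydrogens <- function(mol) {
  adj <- mol_adjacency(mol)
  new_xyz <- NULL; new_bond_to <- integer()
  for (i in seq_len(n_atoms(mol))) {
    e <- mol$elements[i]
    if (!(e %in% names(.VALENCE))) next
    # two aromatic bonds sum to 3, the effective valence they consume
    used <- sum(mol$bonds$order[mol$bonds$a == i | mol$bonds$b == i])
    miss <- .VALENCE[[e]] + mol$charges[i] * (if (e %in% c("N", "P")) 1 else -1) - used
    if (miss <= 0) next
    nb <- adj[[i]]
    dir <- if (length(nb)) {
      v <- -colSums(mol$coords[nb, , drop = FALSE] -
                    matrix(mol$coords[i, ], length(nb), 3, byrow = TRUE))
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) c(0, 0, 1) else v / nv
    } else c(0, 0, 1)
    for (k in seq_len(miss)) {
      # spread multiple hydrogens around the base direction
      perp <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * dir) * dir
      perp <- perp / sqrt(sum(perp^2))
      ang <- (k - 1) * 2 * pi / max(miss, 1)
      u <- cos(ang) * perp +
        sin(ang) * c(dir[2] * perp[3] - dir[3] * perp[2],
                     dir[3] * perp[1] - dir[1] * perp[3],
                     dir[1] * perp[2] - dir[2] * perp[1])
      h_dir <- 0.8 * dir + 0.6 * u
      h_dir <- h_dir / sqrt(sum(h_dir^2))
      new_xyz <- rbind(new_xyz, mol$coords[i, ] + h_dir)
      new_bond_to <- c(new_bond_to, i)
    }
  }
  if (!length(new_bond_to)) return(mol)
  n0 <- n_atoms(mol)
  mol_structure(
    c(mol$elements, rep("H", length(new_bond_to))),
    rbind(mol$coords, new_xyz),
    rbind(mol$bonds, data.frame(a = new_bond_to,
                                b = n0 + seq_along(new_bond_to), order = 1)),
    c(mol$charges, rep(0L, length(new_bond_to))),
    c(mol$labels, mol$labels[new_bond_to]),
    mol$name)
}
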