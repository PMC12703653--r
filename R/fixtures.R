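# Deterministic synthetic test systems: toy degraders (two rigid aromatic
# caps joined by an ether-like linker with a controlled number of free
# rotatable bonds), toy pseudo-proteins (Calpha + sidechain-centroid
# residues around a ligand pocket), and wrapped-normal torsion-observation
# samplers. Everything is bit-reproducible from (parameters, seed). These
# emulate the topology of degrader systems, not their chemistry: pseudo-
# proteins have no folds or binding-site interactions, and the caps are
# generic aromatics.

#' Build a toy degrader with a known linker
#'
#' Two rigid aromatic caps, a fluorobenzene and a pyridine, joined by an
#' alternating C/O ether chain. The first and last two chain atoms belong to
#' the frozen cap fragments (monomer ligands in real inputs typically cover
#' the attachment atoms), which leaves exactly \code{n_linker_bonds} free
#' rotatable bonds. With \code{n_linker_bonds = 0} the chain has one atom
#' and the single constrained fragment covers the whole molecule.
#'
#' @param n_linker_bonds number of free rotatable bonds (>= 0).
#' @param seed embedding seed.
#' @return list: \code{molecule} (labelled \code{mol_structure}),
#'   \code{linker_smarts}, \code{fragmentation} (from
#'   \code{\link{fragment_chimera}}), \code{constraint_atoms} (list of two
#'   parent-index vectors, or one covering all atoms when
#'   \code{n_linker_bonds = 0}), \code{n_linker_bonds}.
#' @export
make_toy_degrader <- function(n_linker_bonds, seed = 1L) {
  stopifnot(n_linker_bonds >= 0L)
  k <- if (n_linker_bonds == 0L) 1L else n_linker_bonds + 1L
  chain_elems <- rep(c("C", "O"), length.out = k)
  chain_smiles <- paste(chain_elems, collapse = "")
  smiles <- paste0("Fc1ccc(", chain_smiles, "c2ccncc2)cc1")
  smarts <- paste0("[C:1]-", paste(chain_elems, collapse = "-"), "-[C:2]")
  mol <- embed_from_smiles(smiles, seed = seed)
  mol$name <- sprintf("toy_degrader_n%d", n_linker_bonds)
  fr <- fragment_chimera(mol, smarts)
  mol <- fr$molecule
  if (n_linker_bonds == 0L) {
    constraint_atoms <- list(seq_len(n_atoms(mol)))
  } else {
    constraint_atoms <- list(
      .cap_constraint(mol, fr, "warhead"),
      .cap_constraint(mol, fr, "e3_binder"))
  }
  list(molecule = mol, linker_smarts = smarts, fragmentation = fr,
       constraint_atoms = constraint_atoms, n_linker_bonds = n_linker_bonds)
}

# cap fragment atoms + the two nearest linker atoms (walk from the anchor)
.cap_constraint <- function(mol, fr, side) {
  side_atoms <- which(mol$labels == side)
  anchor <- if (side == "warhead") fr$anchor1 else fr$anchor2
  adj <- mol_adjacency(mol)
  l1 <- intersect(adj[[anchor]], fr$linker_atoms)
  stopifnot(length(l1) == 1L)
  l2 <- setdiff(intersect(adj[[l1]], fr$linker_atoms), l1)
  ext <- c(l1, l2[mol$elements[l2] != "H"])
  # hydrogens riding on the included atoms join the rigid unit
  h <- which(mol$elements == "H" &
             vapply(adj, function(v) any(v %in% c(side_atoms, ext)),
                    logical(1)))
  sort(unique(c(side_atoms, ext, h)))
}

#' Build a toy pseudo-protein complex
#'
#' Residues carry a Calpha and one sidechain-centroid pseudo-atom ("CB"),
#' traced along a helix (rise 1.5 A, 100 degrees/residue, radius 2.3 A) or a
#' seeded self-avoiding globular walk. A random one-letter sequence is
#' drawn for alignment tests. The ligand is placed in a shallow pocket
#' offset from the trace so protein-ligand contacts stay small and
#' countable.
#'
#' @param n_residues at least 5.
#' @param shape "helix" or "globular".
#' @param seed RNG seed.
#' @param ligand a \code{mol_structure}; default is a 3-atom toy.
#' @param chain chain identifier (default "A").
#' @param id provenance id.
#' @return a \code{protein_complex}.
#' @export
make_toy_protein <- function(n_residues, shape = c("helix", "globular"),
                             seed = 1L, ligand = NULL, chain = "A",
                             id = "toy_protein") {
  shape <- match.arg(shape)
  stopifnot(n_residues >= 5L)
  dat <- with_local_seed(seed, {
    seq1 <- sample(names(.AA3)[.AA3 != "X"], n_residues, replace = TRUE)
    ca <- if (shape == "helix") {
      t <- (seq_len(n_residues) - 1) * 100 * pi / 180
      cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n_residues) - 1))
    } else {
      steps <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * 3.8
      apply(steps, 2, cumsum)
    }
    list(seq1 = seq1, ca = ca)
  })
  ca <- dat$ca
  ctr <- colMeans(ca)
  # sidechain centroids point away from the trace centroid
  dir <- sweep(ca, 2, ctr)
  nrm <- sqrt(rowSums(dir^2)); nrm[nrm < 1e-6] <- 1
  cb <- ca + dir / nrm * 1.5
  if (is.null(ligand)) {
    ligand <- mol_structure(c("C", "C", "O"),
                            rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.2, 0)),
                            data.frame(a = c(1, 2), b = c(2, 3), order = 1),
                            name = "toy_ligand")
  }
  # pocket: translate the protein trace so it flanks the ligand (the ligand
  # keeps its own frame so a bound-fragment pose can double as the ligand)
  lig_ctr <- colMeans(ligand$coords[heavy_atoms(ligand), , drop = FALSE])
  span <- max(sqrt(rowSums(sweep(ca, 2, ctr)^2)))
  shift <- lig_ctr + c(span + 4, 0, 0) - ctr
  ca <- sweep(ca, 2, shift, `+`)
  cb <- sweep(cb, 2, shift, `+`)
  atoms <- data.frame(
    chain = chain,
    resno = rep(seq_len(n_residues), each = 2L),
    resname = rep(aa1_to_3(dat$seq1), each = 2L),
    atom = rep(c("CA", "CB"), n_residues),
    elem = "C",
    x = as.numeric(t(cbind(ca[, 1], cb[, 1]))),
    y = as.numeric(t(cbind(ca[, 2], cb[, 2]))),
    z = as.numeric(t(cbind(ca[, 3], cb[, 3]))))
  protein_complex(atoms, ligand, id = id)
}

#' Sample dihedral observations from a wrapped-normal mixture
#'
#' @param modes data.frame with columns \code{angle} (degrees),
#'   \code{weight} (relative), \code{sd} (degrees).
#' @param n number of samples (>= 1).
#' @param seed RNG seed.
#' @param pattern dihedral SMARTS carried on the observation set.
#' @return a \code{torsion_observations}.
#' @export
sample_torsion_observations <- function(modes, n, seed = 1L,
                                        pattern = "[C:1][C:2][C:3][C:4]") {
  modes <- as.data.frame(modes)
  stopifnot(all(c("angle", "weight", "sd") %in% names(modes)), n >= 1L)
  with_local_seed(seed, {
    comp <- sample.int(nrow(modes), n, replace = TRUE,
                       prob = modes$weight / sum(modes$weight))
    raw <- stats::rnorm(n, mean = modes$angle[comp], sd = modes$sd[comp])
    torsion_observations(pattern, .wrap_angle(raw))
  })
}

#' Build a complete toy degrader/protein system
#'
#' A \code{\link{make_toy_degrader}} plus, per side, a protein-bound
#' fragment conformation (the cap fragment with its two linker-adjacent
#' torsions driven to fixed, non-embedded values and the whole fragment
#' rigidly moved) and a toy monomer protein built around that ligand. The
#' ground-truth relative pose of the two proteins under the input degrader
#' conformation is recorded for assembly bookkeeping tests.
#'
#' @param n_linker_bonds free rotatable bonds in the linker.
#' @param seed master seed.
#' @param n_residues residues per toy protein.
#' @return a \code{toy_system} list; see Details.
#' @details Components: \code{degrader} (bound-pose torsions applied),
#'   \code{linker_smarts}, \code{bound_warhead}/\code{bound_e3}
#'   (\code{mol_structure}s), \code{constraints}
#'   (\code{\link{constrained_fragment}} list), \code{poi_complex},
#'   \code{e3_complex}, \code{free_bonds} (data.frame), \code{truth}
#'   (list: per-side fragment torsion values, inter-protein centroid
#'   distance under identity placement).
#' @export
make_toy_system <- function(n_linker_bonds = 2L, seed = 1L,
                            n_residues = 8L) {
  td <- make_toy_degrader(n_linker_bonds, seed = seed)
  mol <- td$molecule
  fr <- td$fragmentation

  sides <- list(
    warhead = list(anchor = fr$anchor1, atoms = td$constraint_atoms[[1]]),
    e3_binder = list(anchor = fr$anchor2,
                     atoms = td$constraint_atoms[[min(2L,
                       length(td$constraint_atoms))]]))

  bound <- list(); torsion_truth <- list()
  for (nm in names(sides)) {
    frag <- subset_mol(mol, sides[[nm]]$atoms)
    # drive the fragment-internal acyclic torsions to fixed bound-pose values
    vals <- c(170, -65)
    rb <- rotatable_bonds(frag)
    set_vals <- numeric(0)
    if (nrow(rb)) {
      for (i in seq_len(min(nrow(rb), length(vals)))) {
        frag <- set_torsion(frag, rb$a[i], rb$b[i], vals[i])
        set_vals <- c(set_vals, vals[i])
      }
    }
    # a seeded rigid move: the monomer pose shares no frame with the degrader
    tr <- with_local_seed(seed + match(nm, names(sides)), {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      rigid_transform(.rotation_about_axis(ax, stats::runif(1, 0, pi)),
                      stats::rnorm(3, sd = 20))
    })
    frag <- set_coords(frag, transform_coords(frag$coords, tr))
    frag$name <- paste0("bound_", nm)
    bound[[nm]] <- frag
    torsion_truth[[nm]] <- set_vals
  }

  # transfer bound torsions onto the degrader and freeze the fragments
  constraints <- list()
  for (nm in names(sides)) {
    par_idx <- sides[[nm]]$atoms
    mm <- structure(list(mapping = data.frame(
      a = seq_along(par_idx), b = par_idx)), class = "fragment_match")
    mol <- apply_bound_torsions(mol, bound[[nm]], mm)
    constraints[[nm]] <- constrained_fragment(par_idx, bound[[nm]]$coords)
  }
  if (n_linker_bonds == 0L)
    constraints <- list(all = constrained_fragment(seq_len(n_atoms(mol)),
                                                   mol$coords))

  poi <- make_toy_protein(n_residues, "helix", seed = seed + 11L,
                          ligand = bound$warhead, chain = "A",
                          id = "toy_poi")
  e3 <- make_toy_protein(n_residues, "helix", seed = seed + 23L,
                         ligand = bound$e3_binder, chain = "B",
                         id = "toy_e3")

  free <- {
    rb <- rotatable_bonds(mol)
    keep <- rep(TRUE, nrow(rb))
    for (i in seq_len(nrow(rb))) {
      quad <- torsion_atoms(mol, rb$a[i], rb$b[i])
      if (is.null(quad)) { keep[i] <- FALSE; next }
      for (fc in constraints)
        if (all(quad %in% fc$atoms)) { keep[i] <- FALSE; break }
    }
    rb[keep, , drop = FALSE]
  }

  # ground-truth inter-protein centroid distance under identity placement:
  # superpose each monomer ligand onto its fragment in the degrader frame
  truth_dist <- local({
    ctrs <- lapply(names(sides), function(nm) {
      par_idx <- sides[[nm]]$atoms
      hv_f <- heavy_atoms(bound[[nm]])
      sup <- kabsch_superpose(bound[[nm]]$coords[hv_f, , drop = FALSE],
                              mol$coords[par_idx[hv_f], , drop = FALSE])
      px <- if (nm == "warhead") poi else e3
      colMeans(transform_coords(protein_heavy_coords(px), sup$transform))
    })
    sqrt(sum((ctrs[[1]] - ctrs[[2]])^2))
  })

  structure(list(
    degrader = mol, linker_smarts = td$linker_smarts,
    bound_warhead = bound$warhead, bound_e3 = bound$e3_binder,
    constraints = unname(constraints),
    poi_complex = poi, e3_complex = e3,
    free_bonds = free,
    truth = list(fragment_torsions = torsion_truth,
                 centroid_distance = truth_dist),
    n_linker_bonds = n_linker_bonds, seed = seed
  ), class = "toy_system")
}

#' Write a toy input bundle to a directory
#'
#' Emits the full set of files a shell run needs: degrader SDF, bound
#' fragments as mol2, both monomer complexes as PDB, the linker SMARTS and
#' a YAML run configuration.
#'
#' @param system a \code{\link{make_toy_system}} result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_toy_bundle <- function(system, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(system$degrader, file.path(dir, "degrader.sdf"))
  write_structure(system$bound_warhead, file.path(dir, "warhead_bound.mol2"))
  write_structure(system$bound_e3, file.path(dir, "e3_binder_bound.mol2"))
  write_structure(system$poi_complex, file.path(dir, "poi_complex.pdb"))
  write_structure(system$e3_complex, file.path(dir, "e3_complex.pdb"))
  cfg <- list(
    protac = "degrader.sdf", warhead_bound = "warhead_bound.mol2",
    e3_binder_bound = "e3_binder_bound.mol2",
    poi_complex = "poi_complex.pdb", e3_complex = "e3_complex.pdb",
    linker_smarts = system$linker_smarts,
    max_conformers = 5000L, seed = system$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
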