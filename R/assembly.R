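# Rigid-body ternary-complex construction: each monomer protein is carried
# onto a degrader conformer by the Kabsch transform that superposes its
# ligand's MCS-matched heavy atoms onto the matching conformer atoms. Raw
# clash/surface scores count inter-unit heavy-atom pairs in distance shells,
# with the unbound-monomer counts subtracted so only degrader-mediated
# contacts remain.

#' Distance thresholds for contact counting
#' @param clash_max clashes are pairs with d < clash_max (default 2.0 A)
#' @param surface_min,surface_max surface contacts are pairs with
#'   surface_min <= d < surface_max (defaults 2.0, 4.0 A)
#' @export
contact_thresholds <- function(clash_max = 2.0, surface_min = 2.0,
                               surface_max = 4.0) {
  stopifnot(clash_max > 0, surface_min == clash_max,
            surface_max > surface_min)
  structure(list(clash_max = clash_max, surface_min = surface_min,
                 surface_max = surface_max), class = "contact_thresholds")
}

#' Count atom pairs in a distance shell
#'
#' Number of cross pairs (one atom from each set) with
#' \code{dmin <= d < dmax}; with \code{dmin = 0} this is "closer than dmax".
#' Exact integer, vectorised over the full pair matrix.
#'
#' @param atoms_a,atoms_b coordinate matrices (heavy atoms).
#' @param dmin,dmax shell bounds in Angstrom (half-open: [dmin, dmax)).
#' @return integer count.
#' @export
count_pairs_in_shell <- function(atoms_a, atoms_b, dmin, dmax) {
  a <- as.matrix(atoms_a); b <- as.matrix(atoms_b)
  if (!nrow(a) || !nrow(b)) return(0L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  sum(d2 >= dmin^2 & d2 < dmax^2)
}

#' Assemble a ternary-complex model from a conformer
#'
#' For each monomer complex, the maximum common subgraph between its ligand
#' and the conformer's corresponding fragment (by substructure label:
#' "warhead" for the POI side, "e3_binder" for the E3 side; unlabelled
#' degraders fall back to whole-molecule MCS) gives paired heavy atoms; the
#' Kabsch transform superposing the monomer-ligand atoms onto the conformer
#' atoms is applied to all monomer atoms. Assembly is invariant to any rigid
#' pre-transform of either monomer complex.
#'
#' @param conformer the degrader conformer (\code{mol_structure}, labelled).
#' @param poi_complex,e3_complex monomer \code{protein_complex}es; the POI
#'   ligand must match the warhead side, the E3 ligand the E3-binder side.
#' @param min_mcs smallest acceptable ligand/fragment overlap (default 5).
#' @param rank conformer rank carried into the model (default NA).
#' @param mappings optional precomputed MCS mappings (list with components
#'   \code{poi}, \code{e3}, each a \code{fragment_match} whose \code{b}
#'   column indexes the full conformer); computed here when NULL. An
#'   ensemble shares one molecular graph, so \code{\link{assemble_ensemble}}
#'   computes them once.
#' @return a \code{ternary_model}: transformed POI/E3 complexes, degrader,
#'   per-side ligand-placement RMSDs; raw/normalised scores filled later.
#' @export
assemble_ternary <- function(conformer, poi_complex, e3_complex,
                             min_mcs = 5L, rank = NA_integer_,
                             mappings = NULL) {
  stopifnot(is_mol(conformer), inherits(poi_complex, "protein_complex"),
            inherits(e3_complex, "protein_complex"))
  if (is.null(mappings))
    mappings <- ternary_mappings(conformer, poi_complex, e3_complex, min_mcs)
  place <- function(px, mm) {
    mob <- px$ligand$coords[mm$mapping$a, , drop = FALSE]
    tgt <- conformer$coords[mm$mapping$b, , drop = FALSE]
    sup <- kabsch_superpose(mob, tgt)
    list(complex = transform_complex(px, sup$transform),
         rmsd = sup$rmsd, n_mcs = nrow(mm$mapping))
  }
  poi <- place(poi_complex, mappings$poi)
  e3 <- place(e3_complex, mappings$e3)
  structure(list(
    rank = rank,
    degrader = conformer,
    poi = poi$complex, e3 = e3$complex,
    placement_rmsd = c(poi = poi$rmsd, e3 = e3$rmsd),
    mcs_size = c(poi = poi$n_mcs, e3 = e3$n_mcs),
    lig_rmsd = NA_real_,
    raw_clash = NA_integer_, raw_surface = NA_integer_,
    clash_score = NA_real_, surface_score = NA_real_
  ), class = "ternary_model")
}

#' @export
print.ternary_model <- function(x, ...) {
  cat(sprintf(
    "<ternary_model> rank %s: placement RMSD poi=%.3g e3=%.3g A, raw clash=%s surface=%s\n",
    x$rank, x$placement_rmsd["poi"], x$placement_rmsd["e3"],
    x$raw_clash, x$raw_surface))
  invisible(x)
}

#' MCS mappings from monomer ligands onto a degrader
#'
#' The POI ligand is matched against the warhead-labelled atoms, the E3
#' ligand against the e3_binder-labelled atoms (plus, in both cases, any
#' linker atoms, since bound ligands often cover the attachment atoms);
#' unlabelled degraders fall back to whole-molecule matching.
#'
#' @param conformer a \code{mol_structure}.
#' @param poi_complex,e3_complex monomer complexes.
#' @param min_mcs smallest acceptable overlap.
#' @return list with \code{fragment_match} components \code{poi},
#'   \code{e3}; \code{b} columns index the full conformer.
#' @export
ternary_mappings <- function(conformer, poi_complex, e3_complex,
                             min_mcs = 5L) {
  side <- function(px, side_label, side_name) {
    atoms <- which(conformer$labels %in% c(side_label, "linker"))
    if (!length(atoms)) atoms <- seq_len(n_atoms(conformer))
    sub <- subset_mol(conformer, atoms)
    ord <- !isTRUE(attr(px$ligand, "perceived_bonds"))
    mm <- tryCatch(max_common_subgraph(px$ligand, sub, min_size = min_mcs,
                                       match_order = ord),
                   error = function(e) stop("insufficient overlap on the ",
                                            side_name, " side: ",
                                            conditionMessage(e),
                                            call. = FALSE))
    structure(list(mapping = data.frame(a = mm$mapping$a,
                                        b = atoms[mm$mapping$b])),
              class = "fragment_match")
  }
  list(poi = side(poi_complex, "warhead", "POI"),
       e3 = side(e3_complex, "e3_binder", "E3"))
}

#' Raw clash and surface scores of a ternary model
#'
#' Counts heavy-atom pairs between units of the assembled model and
#' subtracts the corresponding counts inside each isolated monomer complex
#' (protein against its own ligand), flooring at zero, so intra-monomer
#' protein-ligand contacts cancel and the score isolates degrader-mediated
#' inter-unit contacts. Pair selection is switchable: \code{"all_inter_unit"}
#' counts POI-E3, POI-degrader and E3-degrader pairs; \code{"protein_only"}
#' counts POI-E3 pairs alone (baseline then zero by construction).
#'
#' @param model a \code{ternary_model}.
#' @param poi_complex,e3_complex the untransformed monomer complexes whose
#'   internal contacts form the baseline.
#' @param thresholds a \code{\link{contact_thresholds}}.
#' @param pairs "all_inter_unit" (default) or "protein_only".
#' @return the model with \code{raw_clash}/\code{raw_surface} filled.
#' @export
raw_scores <- function(model, poi_complex, e3_complex,
                       thresholds = contact_thresholds(),
                       pairs = c("all_inter_unit", "protein_only")) {
  pairs <- match.arg(pairs)
  poi_xyz <- protein_heavy_coords(model$poi)
  e3_xyz <- protein_heavy_coords(model$e3)
  deg_xyz <- model$degrader$coords[heavy_atoms(model$degrader), , drop = FALSE]
  shell <- function(a, b, lo, hi) count_pairs_in_shell(a, b, lo, hi)
  count_all <- function(lo, hi) {
    n <- shell(poi_xyz, e3_xyz, lo, hi)
    if (pairs == "all_inter_unit")
      n <- n + shell(poi_xyz, deg_xyz, lo, hi) + shell(e3_xyz, deg_xyz, lo, hi)
    n
  }
  baseline <- function(px, lo, hi) {
    if (pairs == "protein_only") return(0L)
    shell(protein_heavy_coords(px),
          px$ligand$coords[heavy_atoms(px$ligand), , drop = FALSE], lo, hi)
  }
  th <- thresholds
  clash <- count_all(0, th$clash_max) -
    baseline(poi_complex, 0, th$clash_max) -
    baseline(e3_complex, 0, th$clash_max)
  surface <- count_all(th$surface_min, th$surface_max) -
    baseline(poi_complex, th$surface_min, th$surface_max) -
    baseline(e3_complex, th$surface_min, th$surface_max)
  model$raw_clash <- max(0L, as.integer(clash))
  model$raw_surface <- max(0L, as.integer(surface))
  model
}

#' Assemble and score a whole ensemble
#'
#' Convenience driver: \code{\link{assemble_ternary}} +
#' \code{\link{raw_scores}} per conformer, then ensemble-wide 1-10
#' normalisation of both scores.
#'
#' @param ensemble a \code{conformer_ensemble} (labelled template).
#' @param poi_complex,e3_complex monomer complexes.
#' @param thresholds a \code{\link{contact_thresholds}}.
#' @param min_mcs minimum ligand/fragment overlap.
#' @param pairs see \code{\link{raw_scores}}.
#' @return list of \code{ternary_model} with normalised scores filled.
#' @export
assemble_ensemble <- function(ensemble, poi_complex, e3_complex,
                              thresholds = contact_thresholds(),
                              min_mcs = 5L, pairs = "all_inter_unit") {
  mappings <- ternary_mappings(ensemble$template, poi_complex, e3_complex,
                               min_mcs)
  models <- lapply(ensemble$conformers, function(cf) {
    m <- assemble_ternary(set_coords(ensemble$template, cf$coords),
                          poi_complex, e3_complex, min_mcs = min_mcs,
                          rank = cf$rank, mappings = mappings)
    m$lig_rmsd <- cf$lig_rmsd
    raw_scores(m, poi_complex, e3_complex, thresholds, pairs)
  })
  normalize_models(models)
}

#' Fill normalised 1-10 scores across a model list
#' @param models list of scored \code{ternary_model}
#' @return the list with \code{clash_score}/\code{surface_score} set
#' @export
normalize_models <- function(models) {
  cl <- normalize_ensemble(vapply(models, `[[`, numeric(1), "raw_clash"))
  su <- normalize_ensemble(vapply(models, `[[`, numeric(1), "raw_surface"))
  for (i in seq_along(models)) {
    models[[i]]$clash_score <- cl[i]
    models[[i]]$surface_score <- su[i]
  }
  models
}

#' Score table of a model list
#' @param models list of \code{ternary_model}
#' @return data.frame: rank, raw and normalised scores, placement RMSDs
#' @export
score_table <- function(models) {
  data.frame(
    rank = vapply(models, `[[`, integer(1), "rank"),
    raw_clash = vapply(models, `[[`, integer(1), "raw_clash"),
    raw_surface = vapply(models, `[[`, integer(1), "raw_surface"),
    clash_score = vapply(models, `[[`, numeric(1), "clash_score"),
    surface_score = vapply(models, `[[`, numeric(1), "surface_score"),
    placement_rmsd_poi = vapply(models, function(m)
      unname(m$placement_rmsd["poi"]), numeric(1)),
    placement_rmsd_e3 = vapply(models, function(m)
      unname(m$placement_rmsd["e3"]), numeric(1))
  )
}

#' Write a ternary model as a PDB file
#'
#' POI chains are renamed A, E3 chains B, and the degrader is written as
#' HETATM residue LIG.
#' @param model a \code{ternary_model}
#' @param path output path
#' @export
write_ternary_pdb <- function(model, path) {
  poi <- model$poi$atoms; e3 <- model$e3$atoms
  deg <- model$degrader
  nl <- n_atoms(deg)
  xyz <- c(t(as.matrix(poi[, c("x", "y", "z")])),
           t(as.matrix(e3[, c("x", "y", "z")])), t(deg$coords))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = c(rep("ATOM", nrow(poi) + nrow(e3)), rep("HETATM", nl)),
    resno = c(poi$resno, e3$resno, rep(1L, nl)),
    resid = c(poi$resname, e3$resname, rep("LIG", nl)),
    chain = c(rep("A", nrow(poi)), rep("B", nrow(e3)), rep("X", nl)),
    eleno = seq_len(nrow(poi) + nrow(e3) + nl),
    elety = c(poi$atom, e3$atom, paste0(deg$elements, seq_len(nl))),
    elesy = c(poi$elem, e3$elem, deg$elements))
  invisible(path)
}
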