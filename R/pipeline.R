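# End-to-end orchestration: a validated run configuration, conformer
# generation from degrader + bound fragments, and the optional
# assembly/scoring/reduction stage, with machine-readable JSON manifests so
# any completed run is reproducible from its manifest.

#' Build and validate a run configuration
#'
#' Inputs may be file paths (read at run time) or in-memory package objects;
#' numeric fields are range-checked here so failures surface before any
#' computation.
#'
#' @param protac degrader: path (sdf/mol2), SMILES string prefixed
#'   "smiles:", or a \code{mol_structure}.
#' @param warhead_bound,e3_binder_bound bound fragment poses: path or
#'   \code{mol_structure}.
#' @param linker_smarts anchor-mapped linker SMARTS.
#' @param poi_complex,e3_complex optional monomer complexes: path (pdb) or
#'   \code{protein_complex}; both required for assembly.
#' @param reference optional reference degrader structure for lig_RMSD.
#' @param torsion_library path to a torsion-library file or a
#'   \code{torsion_library}; NULL uses the bundled default.
#' @param max_conformers cap on emitted conformers (default 5000).
#' @param prune a \code{\link{prune_settings}}.
#' @param thresholds a \code{\link{contact_thresholds}}.
#' @param window a \code{\link{plausibility_window}}.
#' @param k_range candidate cluster counts (NULL = automatic).
#' @param alpha compromise-weight regularisation (default 0.1).
#' @param pairs contact-pair selection, see \code{\link{raw_scores}}.
#' @param seed RNG seed for every stochastic step (default 1).
#' @param threads accepted for interface compatibility; the search is
#'   serial (its output contract is serial emission order regardless).
#' @param output_dir where run artifacts are written (default: tempdir).
#' @param reduce run the ensemble-reduction stage (default TRUE).
#' @return a validated \code{run_config}.
#' @export
run_config <- function(protac, warhead_bound, e3_binder_bound, linker_smarts,
                       poi_complex = NULL, e3_complex = NULL,
                       reference = NULL, torsion_library = NULL,
                       max_conformers = 5000L, prune = prune_settings(),
                       thresholds = contact_thresholds(),
                       window = plausibility_window(), k_range = NULL,
                       alpha = 0.1, pairs = "all_inter_unit", seed = 1L,
                       threads = 1L, output_dir = tempfile("pcgrun"),
                       reduce = TRUE) {
  stopifnot(max_conformers >= 1L, alpha >= 0, threads >= 1L)
  for (p in list(protac, warhead_bound, e3_binder_bound, poi_complex,
                 e3_complex, reference)) {
    if (is.character(p) && length(p) == 1L && !startsWith(p, "smiles:") &&
        !file.exists(p))
      stop("input file not found: ", p)
  }
  linker_spec(linker_smarts)  # must parse with two anchors
  structure(list(
    protac = protac, warhead_bound = warhead_bound,
    e3_binder_bound = e3_binder_bound, linker_smarts = linker_smarts,
    poi_complex = poi_complex, e3_complex = e3_complex,
    reference = reference, torsion_library = torsion_library,
    max_conformers = as.integer(max_conformers), prune = prune,
    thresholds = thresholds, window = window, k_range = k_range,
    alpha = alpha, pairs = pairs, seed = as.integer(seed),
    threads = as.integer(threads), output_dir = output_dir,
    reduce = isTRUE(reduce)
  ), class = "run_config")
}

#' Read a YAML run configuration
#' @param path YAML file; relative input paths resolve against its directory
#' @param ... overrides passed to \code{\link{run_config}}
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (f in c("protac", "warhead_bound", "e3_binder_bound", "poi_complex",
              "e3_complex", "reference", "torsion_library")) {
    if (!is.null(y[[f]]) && is.character(y[[f]]) &&
        !startsWith(y[[f]], "smiles:") && !file.exists(y[[f]]))
      y[[f]] <- file.path(base, y[[f]])
  }
  args <- utils::modifyList(y, list(...))
  do.call(run_config, args)
}

.load_mol <- function(x) {
  if (is_mol(x)) return(x)
  if (is.character(x) && startsWith(x, "smiles:"))
    return(embed_from_smiles(sub("^smiles:", "", x)))
  read_structure(x)
}

.load_complex <- function(x) {
  if (is.null(x) || inherits(x, "protein_complex")) return(x)
  read_structure(x, format = "pdb")
}

.load_library <- function(x) {
  if (is.null(x)) return(default_torsion_library())
  if (inherits(x, "torsion_library")) return(x)
  read_torsion_library(x)
}

# Decide which bound fragment corresponds to which degrader side by MCS
# size, relabelling the degrader if the larger overlaps are crossed.
.orient_bound <- function(mol, fr, bound_w, bound_e) {
  side_atoms <- function(side) {
    atoms <- which(mol$labels == side)
    anchor <- if (side == "warhead") fr$anchor1 else fr$anchor2
    adj <- mol_adjacency(mol)
    l1 <- intersect(adj[[anchor]], fr$linker_atoms)
    l2 <- if (length(l1)) setdiff(unlist(adj[l1]), c(anchor, l1)) else integer()
    l2 <- intersect(l2, fr$linker_atoms)
    sort(unique(c(atoms, l1, l2)))
  }
  mcs_size <- function(bound, atoms) {
    sub <- subset_mol(mol, atoms)
    tryCatch(nrow(max_common_subgraph(bound, sub, min_size = 1L)$mapping),
             error = function(e) 0L)
  }
  w_atoms <- side_atoms("warhead"); e_atoms <- side_atoms("e3_binder")
  straight <- mcs_size(bound_w, w_atoms) + mcs_size(bound_e, e_atoms)
  crossed <- mcs_size(bound_w, e_atoms) + mcs_size(bound_e, w_atoms)
  if (crossed > straight) {
    # swap side labels so "warhead" is the side the POI-bound fragment matches
    wl <- mol$labels == "warhead"; el <- mol$labels == "e3_binder"
    mol$labels[wl] <- "e3_binder"; mol$labels[el] <- "warhead"
    tmp <- w_atoms; w_atoms <- e_atoms; e_atoms <- tmp
  }
  list(molecule = mol, warhead_atoms = w_atoms, e3_atoms = e_atoms)
}

#' Generate a conformer ensemble from a run configuration
#'
#' Reads the degrader and the two protein-bound fragment conformations,
#' identifies the linker, orients the bound fragments onto their degrader
#' sides by MCS, transfers the bound torsions, freezes the matched
#' fragments, enumerates conformers and writes a multi-record SDF (fields
#' \code{rank}, \code{probability}, and \code{lig_rmsd} when a reference is
#' given) plus a JSON manifest.
#'
#' @param config a \code{\link{run_config}} (or YAML path).
#' @return list: \code{ensemble}, \code{sdf} (path), \code{manifest}
#'   (path), \code{constraints}, \code{molecule} (labelled degrader).
#' @export
run_generate <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  protac <- .load_mol(config$protac)
  bound_w <- .load_mol(config$warhead_bound)
  bound_e <- .load_mol(config$e3_binder_bound)
  reference <- if (!is.null(config$reference)) .load_mol(config$reference)
  lib <- .load_library(config$torsion_library)

  fr <- fragment_chimera(protac, config$linker_smarts)
  ori <- .orient_bound(fr$molecule, fr, bound_w, bound_e)
  mol <- ori$molecule

  constraints <- list()
  for (side in c("warhead", "e3_binder")) {
    bound <- if (side == "warhead") bound_w else bound_e
    atoms <- if (side == "warhead") ori$warhead_atoms else ori$e3_atoms
    sub <- subset_mol(mol, atoms)
    mm <- max_common_subgraph(bound, sub, min_size = 3L)
    parent_map <- structure(list(mapping = data.frame(
      a = mm$mapping$a, b = atoms[mm$mapping$b])), class = "fragment_match")
    mol <- apply_bound_torsions(mol, bound, parent_map)
    constraints[[side]] <- constrained_fragment(
      atoms[mm$mapping$b], bound$coords[mm$mapping$a, , drop = FALSE])
  }

  ens <- enumerate_conformers(mol, unname(constraints), lib,
                              max_conformers = config$max_conformers,
                              prune = config$prune, reference = reference)

  sdf_path <- file.path(config$output_dir, "conformers.sdf")
  mols <- lapply(ens$conformers, function(cf) set_coords(mol, cf$coords))
  fields <- lapply(ens$conformers, function(cf) {
    f <- c(rank = as.character(cf$rank),
           probability = sprintf("%.12g", cf$probability))
    if (!is.na(cf$lig_rmsd)) f <- c(f, lig_rmsd = sprintf("%.6f", cf$lig_rmsd))
    f
  })
  write_sdf_ensemble(mols, sdf_path, fields)

  manifest <- list(
    stage = "generate", package_version = as.character(
      utils::packageVersion("protaconf")),
    seed = config$seed, max_conformers = config$max_conformers,
    prune = unclass(config$prune), linker_smarts = config$linker_smarts,
    n_conformers = length(ens$conformers),
    n_free_bonds = ens$settings$n_free_bonds,
    threads = config$threads)
  man_path <- file.path(config$output_dir, "generate_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(ensemble = ens, sdf = sdf_path, manifest = man_path,
       constraints = unname(constraints), molecule = mol)
}

#' Assemble, score and (optionally) reduce an ensemble
#'
#' When both monomer complexes are configured, every conformer is assembled
#' into a ternary model, raw and normalised clash/surface scores are
#' computed, the score table is written as CSV, and unless
#' \code{config$reduce} is FALSE the plausibility-filtered ensemble is
#' clustered and reduced to representatives (clusters.csv, one PDB per
#' representative, JSON manifest). Without monomer complexes the assembly
#' stage is skipped with a warning and the conformers stand as the result.
#'
#' @param config a \code{\link{run_config}} (or YAML path).
#' @param generated optional result of \code{\link{run_generate}} (re-run
#'   otherwise).
#' @return list: \code{models}, \code{scores} (data.frame), \code{reduction}
#'   (or NULL), \code{files} (paths written).
#' @export
run_assemble_score_reduce <- function(config, generated = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(generated)) generated <- run_generate(config)
  poi <- .load_complex(config$poi_complex)
  e3 <- .load_complex(config$e3_complex)
  if (is.null(poi) || is.null(e3)) {
    warning("monomer complexes not provided; assembly skipped")
    return(list(models = NULL, scores = NULL, reduction = NULL,
                files = list(sdf = generated$sdf)))
  }
  models <- assemble_ensemble(generated$ensemble, poi, e3,
                              thresholds = config$thresholds,
                              pairs = config$pairs)
  scores <- score_table(models)
  files <- list(sdf = generated$sdf)
  files$scores <- file.path(config$output_dir, "scores.csv")
  utils::write.csv(scores, files$scores, row.names = FALSE)

  reduction <- NULL
  if (config$reduce) {
    reduction <- tryCatch(
      reduce_ensemble(models, window = config$window,
                      k_range = config$k_range, alpha = config$alpha,
                      seed = config$seed),
      error = function(e) {
        warning("reduction skipped: ", conditionMessage(e))
        NULL
      })
  }
  if (!is.null(reduction)) {
    sel <- reduction$selection
    cl_df <- data.frame(
      model = seq_along(reduction$models),
      rank = vapply(reduction$models, `[[`, integer(1), "rank"),
      cluster = sel$assignments,
      compromise_score = sel$compromise,
      selected = seq_along(reduction$models) %in% sel$representatives)
    files$clusters <- file.path(config$output_dir, "clusters.csv")
    utils::write.csv(cl_df, files$clusters, row.names = FALSE)
    rep_paths <- character()
    for (i in seq_along(sel$representatives)) {
      p <- file.path(config$output_dir,
                     sprintf("representative_%02d.pdb", i))
      write_ternary_pdb(reduction$models[[sel$representatives[i]]], p)
      rep_paths <- c(rep_paths, p)
    }
    files$representatives <- rep_paths
    manifest <- list(
      stage = "assemble_score_reduce",
      k = reduction$k,
      weights = list(w_clash = reduction$weights$w_clash,
                     w_surface = reduction$weights$w_surface,
                     alpha = reduction$weights$alpha),
      seed = config$seed,
      window = unclass(config$window),
      thresholds = unclass(config$thresholds),
      n_models = length(models),
      n_plausible = length(reduction$models),
      n_representatives = length(sel$representatives))
    files$manifest <- file.path(config$output_dir, "reduce_manifest.json")
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(models = models, scores = scores, reduction = reduction,
       files = files)
}
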