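# Constrained knowledge-based conformer generation. The warhead and
# E3-recruiting fragments are internally frozen in their protein-bound
# geometries (only bonds whose four torsion-defining atoms all lie inside a
# constrained fragment are frozen); the remaining "free" rotatable bonds are
# enumerated depth-first, trying representative angles in descending
# empirical probability, with dynamic pruning on steric clashes, on the
# running probability product, and on similarity to already-kept conformers.
# The search is fully deterministic: no stochastic step anywhere.

#' Define a constrained (frozen) fragment
#' @param atoms parent atom indices of the fragment.
#' @param reference n x 3 matrix: the bound-pose coordinates, same order as
#'   \code{atoms}.
#' @export
constrained_fragment <- function(atoms, reference) {
  atoms <- as.integer(atoms)
  reference <- as.matrix(reference)
  stopifnot(length(atoms) >= 1L, nrow(reference) == length(atoms),
            ncol(reference) == 3L)
  structure(list(atoms = atoms, reference = reference),
            class = "constrained_fragment")
}

#' Pruning thresholds for conformer enumeration
#'
#' @param clash_factor a branch is cut when any heavy-atom pair at graph
#'   distance >= 4 bonds comes closer than \code{clash_factor} times the sum
#'   of the two van der Waals radii; 0 disables the check (default 0.6).
#' @param min_probability floor on the running product of per-torsion peak
#'   probabilities; 0 disables (default 1e-6).
#' @param similarity_rmsd completed conformers within this heavy-atom RMSD
#'   (after superposition, symmetry-blind for speed) of an already-kept one
#'   are rejected; 0 disables (default 0.5 Angstrom).
#' @export
prune_settings <- function(clash_factor = 0.6, min_probability = 1e-6,
                           similarity_rmsd = 0.5) {
  stopifnot(clash_factor >= 0, clash_factor <= 1,
            min_probability >= 0, similarity_rmsd >= 0)
  structure(list(clash_factor = clash_factor,
                 min_probability = min_probability,
                 similarity_rmsd = similarity_rmsd),
            class = "prune_settings")
}

# internal: exact dihedral driving over an arbitrary quad
.set_dihedral <- function(mol, i, a, b, j, angle_deg) {
  side <- bond_side(mol, a, b)
  cur <- measure_dihedral(mol$coords, i, a, b, j)
  delta <- -.wrap_angle(angle_deg - cur) * pi / 180  # sign: see set_torsion
  axis <- mol$coords[b, ] - mol$coords[a, ]
  axis <- axis / sqrt(sum(axis^2))
  R <- .rotation_about_axis(axis, delta)
  origin <- mol$coords[b, ]
  moving <- setdiff(side, b)
  if (length(moving)) {
    rel <- sweep(mol$coords[moving, , drop = FALSE], 2, origin)
    mol$coords[moving, ] <- sweep(rel %*% t(R), 2, origin, `+`)
  }
  mol
}

#' Transfer bound-pose torsions onto a degrader fragment
#'
#' Sets every acyclic torsion whose four defining atoms all lie inside the
#' matched fragment to its value in the protein-bound fragment conformation,
#' so the fragment's internal geometry reproduces the bound pose (rings keep
#' their input geometry, consistent with torsion-only adjustment).
#'
#' @param protac the full degrader \code{mol_structure}.
#' @param bound_fragment the protein-bound fragment conformation.
#' @param match a \code{fragment_match} whose \code{mapping$a} indexes
#'   \code{bound_fragment} and \code{mapping$b} indexes \code{protac}.
#' @return the degrader with adjusted coordinates.
#' @export
apply_bound_torsions <- function(protac, bound_fragment, match) {
  stopifnot(is_mol(protac), is_mol(bound_fragment),
            inherits(match, "fragment_match"))
  mp <- match$mapping
  to_parent <- setNames(mp$b, mp$a)
  if (nrow(mp) < 4L) {
    warning("match too small to define any torsion; degrader unchanged")
    return(protac)
  }
  ring_p <- ring_bonds(protac)
  n_set <- 0L
  for (k in seq_len(nrow(bound_fragment$bonds))) {
    ba <- bound_fragment$bonds$a[k]; bb <- bound_fragment$bonds$b[k]
    if (!(ba %in% mp$a && bb %in% mp$a)) next
    pa <- to_parent[[as.character(ba)]]; pb <- to_parent[[as.character(bb)]]
    # parent bond must exist and be acyclic
    row <- which((protac$bonds$a == pa & protac$bonds$b == pb) |
                 (protac$bonds$a == pb & protac$bonds$b == pa))
    if (!length(row) || ring_p[row[1]]) next
    quad <- torsion_atoms(protac, pa, pb)
    if (is.null(quad)) next
    # all four parent atoms must be images of mapped bound atoms
    pre <- match(quad, mp$b)
    if (any(is.na(pre))) next
    target <- measure_dihedral(bound_fragment$coords,
                               mp$a[pre[1]], mp$a[pre[2]],
                               mp$a[pre[3]], mp$a[pre[4]])
    protac <- .set_dihedral(protac, quad[1], quad[2], quad[3], quad[4], target)
    n_set <- n_set + 1L
  }
  if (n_set == 0L)
    warning("match defines no settable torsion; degrader unchanged")
  protac
}

#' Maximum deviation of a frozen fragment's internal distances
#' @param mol a conformer \code{mol_structure}
#' @param fragment a \code{constrained_fragment}
#' @return max absolute difference (Angstrom) between the fragment's internal
#'   heavy-atom distance matrix in \code{mol} and in its bound pose
#' @export
fragment_deviation <- function(mol, fragment) {
  cur <- mol$coords[fragment$atoms, , drop = FALSE]
  ref <- fragment$reference
  max(abs(stats::dist(cur) - stats::dist(ref)))
}

#' Enumerate linker conformers depth-first
#'
#' Free rotatable bonds are those of \code{\link{rotatable_bonds}} whose four
#' torsion-defining atoms do not all lie inside one constrained fragment. For
#' each free bond the representative angles of its assigned rule are tried in
#' descending probability (ties: smaller absolute angle first, then positive
#' before negative). Branches are cut by the \code{\link{prune_settings}}
#' criteria; the clash check at an internal node only considers atom pairs
#' whose relative geometry is already fixed (pairs not separated by any
#' still-unset free bond), so pruning never discards a branch a deeper
#' rotation could still rescue. Ranks are assigned in emission order; the
#' first emitted conformer therefore carries the maximal probability product.
#'
#' @param protac the degrader with bound-pose fragment geometry already
#'   applied (see \code{\link{apply_bound_torsions}}).
#' @param constraints list of \code{\link{constrained_fragment}}.
#' @param rules a \code{torsion_library}, or a precomputed assignment from
#'   \code{\link{assign_rules}}.
#' @param max_conformers emission cap (default 5000).
#' @param prune a \code{\link{prune_settings}}, or NULL to disable all
#'   pruning.
#' @param reference optional reference \code{mol_structure}; when given each
#'   conformer carries its symmetry-aware \code{lig_rmsd}.
#' @return a \code{conformer_ensemble}.
#' @export
enumerate_conformers <- function(protac, constraints = list(),
                                 rules = default_torsion_library(),
                                 max_conformers = 5000L,
                                 prune = prune_settings(),
                                 reference = NULL) {
  stopifnot(is_mol(protac), max_conformers >= 1L)
  if (is.null(prune)) prune <- prune_settings(0, 0, 0)
  rb <- rotatable_bonds(protac)
  frozen <- rep(FALSE, nrow(rb))
  for (i in seq_len(nrow(rb))) {
    quad <- torsion_atoms(protac, rb$a[i], rb$b[i])
    if (is.null(quad)) { frozen[i] <- TRUE; next }
    for (fr in constraints) {
      if (all(quad %in% fr$atoms)) { frozen[i] <- TRUE; break }
    }
  }
  free <- rb[!frozen, , drop = FALSE]
  if (inherits(rules, "torsion_library")) {
    assignment <- assign_rules(protac, rules, free)
  } else {
    assignment <- rules
    stopifnot(nrow(assignment) == nrow(free))
  }
  settings <- list(max_conformers = as.integer(max_conformers), prune = prune,
                   n_free_bonds = nrow(free))

  emit <- function(mol, prob, torsions) {
    conf <- list(coords = mol$coords, rank = NA_integer_, probability = prob,
                 torsions = torsions,
                 lig_rmsd = if (!is.null(reference))
                   lig_rmsd(set_coords(protac, mol$coords), reference)
                 else NA_real_)
    conf
  }

  if (!nrow(free)) {
    conf <- emit(protac, 1.0,
                 data.frame(a = integer(), b = integer(), angle = numeric()))
    conf$rank <- 1L
    return(.new_ensemble(protac, list(conf), settings))
  }

  # per-bond angle menus, descending probability with deterministic tie-break
  menus <- lapply(assignment$rule, function(r) {
    p <- r$peaks
    ord <- order(-p$probability, abs(p$angle), -sign(p$angle), method = "radix")
    p[ord, , drop = FALSE]
  })

  hv <- heavy_atoms(protac)
  gi <- .mol_igraph(protac, heavy_only = TRUE)
  topo <- igraph::distances(gi$graph)
  vdw <- vdw_radius(protac$elements[hv])
  cutoff <- outer(vdw, vdw, `+`) * prune$clash_factor

  # Pairs whose relative geometry becomes fixed at each DFS depth: contract
  # the still-unset free bonds and group heavy atoms into rigid components.
  comp_at_depth <- function(d) {
    unset <- if (d < nrow(free)) (d + 1L):nrow(free) else integer()
    b <- protac$bonds
    drop_rows <- free$bond_row[unset]
    b <- b[setdiff(seq_len(nrow(b)), drop_rows), , drop = FALSE]
    b <- b[b$a %in% hv & b$b %in% hv, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = match(b$a, hv), to = match(b$b, hv)),
      directed = FALSE, vertices = data.frame(name = seq_along(hv)))
    igraph::components(g)$membership
  }
  membs <- lapply(0:nrow(free), comp_at_depth)
  # new same-component heavy pairs appearing at depth d (>= 4 bonds apart)
  new_pairs <- vector("list", nrow(free) + 1L)
  for (d in 0:nrow(free)) {
    m_now <- membs[[d + 1L]]
    m_prev <- if (d == 0L) NULL else membs[[d]]
    prs <- which(outer(m_now, m_now, `==`) & upper.tri(diag(length(hv))) &
                 topo >= 4, arr.ind = TRUE)
    if (!is.null(m_prev) && nrow(prs)) {
      old <- m_prev[prs[, 1]] == m_prev[prs[, 2]]
      prs <- prs[!old, , drop = FALSE]
    }
    new_pairs[[d + 1L]] <- prs
  }

  has_clash <- function(coords, d) {
    if (prune$clash_factor <= 0) return(FALSE)
    prs <- new_pairs[[d + 1L]]
    if (!nrow(prs)) return(FALSE)
    p1 <- coords[hv[prs[, 1]], , drop = FALSE]
    p2 <- coords[hv[prs[, 2]], , drop = FALSE]
    dd <- sqrt(rowSums((p1 - p2)^2))
    any(dd < cutoff[prs])
  }

  kept <- list()
  kept_heavy <- list()
  n_free <- nrow(free)

  dfs <- function(mol, depth, prob, torsions) {
    if (length(kept) >= max_conformers) return()
    if (depth == n_free) {
      if (prune$similarity_rmsd > 0 && length(kept)) {
        cur <- mol$coords[hv, , drop = FALSE]
        for (kh in kept_heavy) {
          if (superposed_rmsd(cur, kh) < prune$similarity_rmsd) return()
        }
      }
      conf <- emit(mol, prob, torsions)
      conf$rank <- length(kept) + 1L
      kept[[length(kept) + 1L]] <<- conf
      kept_heavy[[length(kept_heavy) + 1L]] <<- mol$coords[hv, , drop = FALSE]
      return()
    }
    d <- depth + 1L
    menu <- menus[[d]]
    for (r in seq_len(nrow(menu))) {
      p_new <- prob * menu$probability[r]
      if (prune$min_probability > 0 && p_new < prune$min_probability) next
      m2 <- set_torsion(mol, free$a[d], free$b[d], menu$angle[r])
      if (has_clash(m2$coords, d)) next
      t2 <- rbind(torsions, data.frame(a = free$a[d], b = free$b[d],
                                       angle = menu$angle[r]))
      dfs(m2, d, p_new, t2)
      if (length(kept) >= max_conformers) return()
    }
  }

  # root-level clash check (depth 0: pairs fixed before any rotation)
  base <- protac
  if (!has_clash(base$coords, 0L) || prune$clash_factor <= 0) {
    dfs(base, 0L, 1.0,
        data.frame(a = integer(), b = integer(), angle = numeric()))
  }
  .new_ensemble(protac, kept, settings)
}

.new_ensemble <- function(template, conformers, settings) {
  structure(list(template = template, conformers = conformers,
                 settings = settings),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d conformer(s) of %s (%d free bonds)\n",
              length(x$conformers), x$template$name, x$settings$n_free_bonds))
  if (length(x$conformers))
    cat(sprintf("  rank 1 probability %.4g\n", x$conformers[[1]]$probability))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$conformers)

#' Extract one conformer as a molecule
#' @param ensemble a \code{conformer_ensemble}
#' @param rank which conformer (1-based emission rank)
#' @export
ensemble_conformer <- function(ensemble, rank) {
  stopifnot(rank >= 1L, rank <= length(ensemble$conformers))
  set_coords(ensemble$template, ensemble$conformers[[rank]]$coords)
}

#' Summarise an ensemble as a data.frame
#' @param object a \code{conformer_ensemble}
#' @param ... unused
#' @export
summary.conformer_ensemble <- function(object, ...) {
  data.frame(
    rank = vapply(object$conformers, `[[`, integer(1), "rank"),
    probability = vapply(object$conformers, `[[`, numeric(1), "probability"),
    lig_rmsd = vapply(object$conformers, `[[`, numeric(1), "lig_rmsd")
  )
}
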