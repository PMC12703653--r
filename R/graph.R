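# Molecular-graph utilities: adjacency, ring perception, rotatable bonds,
# fragmentation by a linker spec, maximum common subgraph (McGregor-style
# branch and bound) and element-coloured graph automorphisms.

#' Adjacency list of a molecule
#' @param mol a \code{mol_structure}
#' @return list: neighbours of each atom (all atoms, hydrogens included)
#' @export
mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, function(v) if (is.null(v)) integer() else sort(v))
}

.mol_igraph <- function(mol, heavy_only = TRUE) {
  idx <- if (heavy_only) heavy_atoms(mol) else seq_len(n_atoms(mol))
  b <- mol$bonds[mol$bonds$a %in% idx & mol$bonds$b %in% idx, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(b$a, idx), to = match(b$b, idx)),
    directed = FALSE, vertices = data.frame(name = seq_along(idx)))
  list(graph = g, index = idx, bonds = b)
}

#' Which bonds are in rings?
#' @param mol a \code{mol_structure}
#' @return logical vector over rows of \code{mol$bonds}; a bond is cyclic iff
#'   it is not a bridge of the molecular graph
#' @export
ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical())
  g <- igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$a, to = mol$bonds$b), directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
  br <- igraph::bridges(g)
  out <- rep(TRUE, nrow(mol$bonds))
  out[as.integer(br)] <- FALSE
  out
}

#' Rotatable bonds of a molecule
#'
#' A bond is rotatable when it is an acyclic single bond between two
#' non-terminal heavy atoms (terminal means a single heavy neighbour, so
#' methyl and halogen rotations are never sampled). Amide C-N bonds (a
#' carbon double-bonded to oxygen, bonded to nitrogen) are excluded by
#' default because their torsional preference is essentially planar.
#'
#' @param mol a \code{mol_structure}
#' @param exclude_amide drop amide C-N bonds (default TRUE)
#' @return data.frame with columns \code{a}, \code{b} (heavy atom indices,
#'   a < b) and \code{bond_row} (row in \code{mol$bonds})
#' @export
rotatable_bonds <- function(mol, exclude_amide = TRUE) {
  if (!nrow(mol$bonds))
    return(data.frame(a = integer(), b = integer(), bond_row = integer()))
  ring <- ring_bonds(mol)
  adj <- mol_adjacency(mol)
  heavy_deg <- vapply(adj, function(v) sum(mol$elements[v] != "H"), integer(1))
  keep <- integer()
  for (k in seq_len(nrow(mol$bonds))) {
    if (ring[k] || mol$bonds$order[k] != 1) next
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]
    if (mol$elements[a] == "H" || mol$elements[b] == "H") next
    if (heavy_deg[a] < 2L || heavy_deg[b] < 2L) next
    if (exclude_amide && .is_amide_bond(mol, adj, a, b)) next
    keep <- c(keep, k)
  }
  data.frame(a = pmin(mol$bonds$a[keep], mol$bonds$b[keep]),
             b = pmax(mol$bonds$a[keep], mol$bonds$b[keep]),
             bond_row = keep)
}

.is_amide_bond <- function(mol, adj, a, b) {
  for (pr in list(c(a, b), c(b, a))) {
    cc <- pr[1]; nn <- pr[2]
    if (mol$elements[cc] == "C" && mol$elements[nn] == "N") {
      dbl_o <- any(vapply(seq_len(nrow(mol$bonds)), function(k) {
        o <- mol$bonds[k, ]
        o$order == 2 &&
          ((o$a == cc && mol$elements[o$b] == "O") ||
           (o$b == cc && mol$elements[o$a] == "O"))
      }, logical(1)))
      if (dbl_o) return(TRUE)
    }
  }
  FALSE
}

#' Atoms on the distal side of a bond
#'
#' BFS from \code{b} with the edge a-b removed; errors if the bond is cyclic
#' (the two sides are then not separable).
#' @param mol a \code{mol_structure}
#' @param a,b bonded atom indices; the returned side contains \code{b}
#' @export
bond_side <- function(mol, a, b) {
  adj <- mol_adjacency(mol)
  seen <- rep(FALSE, n_atoms(mol)); seen[a] <- TRUE; seen[b] <- TRUE
  queue <- b; side <- b
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        seen[nb] <- TRUE
        queue <- c(queue, nb); side <- c(side, nb)
      }
    }
  }
  # cyclic iff some neighbour of a other than b was reached from b's side
  if (any(setdiff(adj[[a]], b) %in% side))
    stop("bond (", a, ",", b, ") is part of a ring; sides are not separable")
  sort(side)
}

#' Match a linker specification against a degrader
#'
#' Requires exactly one substructure match (after deduplication of mappings
#' covering the same atom set); zero matches or two or more distinct matches
#' are fatal, mirroring the requirement that linker patterns be curated to
#' match uniquely. The matched atoms are labelled \code{"linker"} except the
#' two anchors.
#'
#' @param protac a \code{mol_structure}
#' @param spec a \code{linker_spec} (or SMARTS string)
#' @return list: \code{linker_atoms} (excluding anchors), \code{anchor1},
#'   \code{anchor2} (molecule atom indices), \code{molecule} (relabelled)
#' @export
match_linker <- function(protac, spec) {
  if (is.character(spec)) spec <- linker_spec(spec)
  stopifnot(inherits(spec, "linker_spec"))
  hits <- match_substructure(protac, spec$query, unique_sets = TRUE)
  if (length(hits) == 0L)
    stop("linker pattern '", spec$smarts, "' has no match in the degrader")
  if (length(hits) > 1L)
    stop("linker pattern '", spec$smarts, "' matches ", length(hits),
         " distinct substructures; patterns must match uniquely")
  hit <- hits[[1]]
  a1 <- hit[spec$anchor1]; a2 <- hit[spec$anchor2]
  linker <- setdiff(hit, c(a1, a2))
  protac$labels[linker] <- "linker"
  list(linker_atoms = sort(linker), anchor1 = a1, anchor2 = a2,
       molecule = protac)
}

#' Split a degrader into warhead and E3-binder fragments
#'
#' Removes the linker atoms identified by \code{\link{match_linker}} (anchors
#' stay with their adjacent fragments) and requires the remainder to fall into
#' exactly two connected components. Hydrogens follow their heavy atom. Which
#' component is the warhead versus the E3 binder is decided downstream by MCS
#' against the monomer ligands; here the component containing anchor [:1] is
#' returned first and labelled \code{"warhead"}, the other \code{"e3_binder"}.
#'
#' @param protac a \code{mol_structure}
#' @param spec a \code{linker_spec} or SMARTS string
#' @return list: \code{warhead}, \code{e3_binder} (each with attribute
#'   \code{parent_indices}), \code{linker_atoms}, \code{anchor1},
#'   \code{anchor2}, \code{molecule} (fully labelled degrader)
#' @export
fragment_chimera <- function(protac, spec) {
  lm <- match_linker(protac, spec)
  mol <- lm$molecule
  # hydrogens riding on linker atoms leave with the linker
  adj <- mol_adjacency(mol)
  lh <- which(mol$elements == "H" &
              vapply(adj, function(v) any(v %in% lm$linker_atoms), logical(1)))
  lm$linker_atoms <- sort(unique(c(lm$linker_atoms, lh)))
  keep <- setdiff(seq_len(n_atoms(mol)), lm$linker_atoms)
  b <- mol$bonds[mol$bonds$a %in% keep & mol$bonds$b %in% keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(b$a, keep), to = match(b$b, keep)),
    directed = FALSE, vertices = data.frame(name = seq_along(keep)))
  comp <- igraph::components(g)
  # only consider components holding heavy atoms (stray H cannot occur since
  # hydrogens bond to their heavy atom, which is kept unless in the linker)
  if (comp$no != 2L)
    stop("linker removal must leave exactly two fragments, got ", comp$no)
  memb <- comp$membership
  c1 <- keep[memb == memb[match(lm$anchor1, keep)]]
  c2 <- keep[memb == memb[match(lm$anchor2, keep)]]
  if (lm$anchor2 %in% c1)
    stop("both anchors fell into one fragment; malformed linker pattern")
  mol$labels[c1] <- "warhead"
  mol$labels[c2] <- "e3_binder"
  mol$labels[lm$linker_atoms] <- "linker"
  list(warhead = subset_mol(mol, c1), e3_binder = subset_mol(mol, c2),
       linker_atoms = lm$linker_atoms, anchor1 = lm$anchor1,
       anchor2 = lm$anchor2, molecule = mol)
}

# --- maximum common subgraph -------------------------------------------------

#' Maximum common connected subgraph of two molecules
#'
#' Finds a largest connected common subgraph on heavy atoms, requiring
#' element equality on atoms and order equality on bonds (McGregor-style
#' depth-first branch and bound). Ring-membership matching is off: a ring
#' atom may match a chain atom of the same element.
#'
#' @param a,b \code{mol_structure}s
#' @param min_size smallest acceptable mapping (heavy atoms); an
#'   insufficient-overlap error is raised below it
#' @param match_order require equal bond orders (default TRUE). Set FALSE
#'   when one side carries only distance-perceived bonds of unknown order
#'   (e.g. a ligand extracted from PDB), where topology + elements is the
#'   reliable signal.
#' @return a \code{fragment_match}: data.frame \code{mapping} with columns
#'   \code{a}, \code{b} (atom indices into each parent)
#' @export
max_common_subgraph <- function(a, b, min_size = 3L, match_order = TRUE) {
  stopifnot(is_mol(a), is_mol(b))
  ha <- heavy_atoms(a); hb <- heavy_atoms(b)
  if (!length(ha) || !length(hb)) stop("both molecules must have heavy atoms")
  adj_a <- .heavy_bond_map(a); adj_b <- .heavy_bond_map(b)
  nA <- length(ha); nB <- length(hb)
  best <- list(size = 0L, map = NULL)
  seen <- new.env(parent = emptyenv(), size = 4096L)

  # Grow connected mappings pair by pair: an extension (x, y) must share a
  # bond of equal order with at least one already-mapped pair in both graphs.
  grow <- function(map_a, map_b) {
    key <- paste(paste(map_a[order(map_a)], map_b[order(map_a)], sep = ":"),
                 collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    size <- length(map_a)
    if (size > best$size) best <<- list(size = size, map = cbind(map_a, map_b))
    if (best$size == min(nA, nB)) return()
    cand_a <- setdiff(unique(unlist(adj_a$nb[map_a])), map_a)
    for (x in cand_a) {
      # b-side candidates: neighbours (through an equal-order bond) of the
      # images of x's mapped A-neighbours
      ys <- integer()
      for (k in seq_along(map_a)) {
        o <- adj_a$order[[paste(min(x, map_a[k]), max(x, map_a[k]))]]
        if (is.null(o)) next
        for (y in adj_b$nb[[map_b[k]]]) {
          ob <- adj_b$order[[paste(min(y, map_b[k]), max(y, map_b[k]))]]
          if (!is.null(ob) && (!match_order || ob == o)) ys <- c(ys, y)
        }
      }
      ys <- setdiff(unique(ys), map_b)
      ys <- ys[b$elements[ys] == a$elements[x]]
      for (y in ys) grow(c(map_a, x), c(map_b, y))
    }
  }

  compat <- outer(a$elements[ha], b$elements[hb], `==`)
  for (ia in seq_len(nA)) {
    for (ib in seq_len(nB)) {
      if (compat[ia, ib]) grow(ha[ia], hb[ib])
      if (best$size == min(nA, nB)) break
    }
    if (best$size == min(nA, nB)) break
  }
  if (best$size < min_size)
    stop("insufficient overlap: best common subgraph has ", best$size,
         " atoms, need >= ", min_size)
  mp <- data.frame(a = best$map[, 1], b = best$map[, 2])
  structure(list(mapping = mp), class = "fragment_match")
}

.heavy_bond_map <- function(mol) {
  hv <- heavy_atoms(mol)
  b <- mol$bonds[mol$bonds$a %in% hv & mol$bonds$b %in% hv, , drop = FALSE]
  nb <- vector("list", n_atoms(mol))
  order <- new.env(parent = emptyenv())
  ord <- list()
  for (k in seq_len(nrow(b))) {
    i <- b$a[k]; j <- b$b[k]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    ord[[paste(min(i, j), max(i, j))]] <- b$order[k]
  }
  list(nb = lapply(nb, function(v) if (is.null(v)) integer() else sort(v)),
       order = ord)
}

#' Element-coloured automorphisms of a molecular heavy-atom graph
#'
#' All permutations of heavy atoms preserving elements, adjacency and bond
#' order. Used for symmetry-aware RMSD. The count is capped to protect
#' against combinatorial blow-up on highly symmetric inputs.
#'
#' @param mol a \code{mol_structure}
#' @param max_autos cap on the number returned (default 10000)
#' @return list of integer permutations over heavy-atom positions
#' @export
mol_automorphisms <- function(mol, max_autos = 10000L) {
  hv <- heavy_atoms(mol)
  gi <- .mol_igraph(mol, heavy_only = TRUE)
  elems <- mol$elements[hv]
  domains <- lapply(seq_along(hv), function(i) which(elems == elems[i]))
  maps <- igraph::subgraph_isomorphisms(gi$graph, gi$graph, method = "lad",
                                        induced = TRUE, domains = domains)
  border <- setNames(gi$bonds$order,
                     paste(pmin(gi$bonds$a, gi$bonds$b),
                           pmax(gi$bonds$a, gi$bonds$b)))
  out <- list()
  for (mp in maps) {
    p <- as.integer(mp)
    ok <- TRUE
    for (k in seq_len(nrow(gi$bonds))) {
      i <- match(gi$bonds$a[k], hv); j <- match(gi$bonds$b[k], hv)
      oi <- hv[p[i]]; oj <- hv[p[j]]
      o <- border[[paste(min(oi, oj), max(oi, oj))]]
      if (is.null(o) || o != gi$bonds$order[k]) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- p
    if (length(out) >= max_autos) break
  }
  out
}
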