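# A documented SMARTS/SMILES *subset* parser and substructure matcher.
#
# Supported grammar (sufficient for linker specs, dihedral patterns and the
# toy chemistry this package generates):
#   atoms     : organic-subset symbols B C N O P S F Cl Br I, aromatic
#               lowercase c n o s, wildcard '*', and bracket atoms
#               [<elem|*>(H<d>)?(+|-)*(:<map>)?]  e.g. [C:1], [NH2], [O-]
#   bonds     : - (single), = (double), # (triple), : (aromatic), ~ (any);
#               default bond is single-or-aromatic
#   branches  : parentheses; ring closures: digits and %nn
# Not supported (error): charge-range/degree/ring-count primitives, logical
# operators (&,;!), recursive SMARTS, stereo, isotopes.
#
# Matching is monomorphism-based: pattern atoms map injectively onto molecule
# atoms so that every pattern bond is realised by a molecule bond of
# compatible order. Implemented over igraph LAD with per-atom candidate
# domains, then bond-order post-filtering.

.ORGANIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")

#' Parse a SMARTS/SMILES subset expression
#'
#' @param s the expression string.
#' @return a \code{query_graph}: list with \code{atoms} (data.frame: elem,
#'   aromatic, wildcard, charge, hcount, map) and \code{bonds} (a, b, type
#'   where type is "single", "double", "triple", "aromatic", "any",
#'   "default").
#' @export
parse_smarts <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) stop("empty SMARTS/SMILES expression")
  chars <- strsplit(s, "")[[1]]
  i <- 1L; n <- length(chars)
  atoms <- list(); bonds <- list()
  prev_stack <- integer()      # branch stack
  prev <- NA_integer_          # previous atom index
  pending_bond <- "default"
  ring_open <- list()          # digit -> list(atom, bond)

  add_atom <- function(elem, aromatic, wildcard = FALSE, charge = 0L,
                       hcount = NA_integer_, map = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(elem = elem, aromatic = aromatic,
                                         wildcard = wildcard, charge = charge,
                                         hcount = hcount, map = map)
    idx <- length(atoms)
    if (!is.na(prev)) bonds[[length(bonds) + 1L]] <<-
        list(a = prev, b = idx, type = pending_bond)
    pending_bond <<- "default"
    prev <<- idx
    idx
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in '", s, "'")
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) stop("unbalanced ')' in '", s, "'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]; i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double",
                             "#" = "triple", ":" = "aromatic", "~" = "any",
                             "single")  # stereo slashes read as single
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("truncated %nn ring closure in '", s, "'")
        d <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { d <- ch; i <- i + 1L }
      if (is.na(prev)) stop("ring closure before any atom in '", s, "'")
      if (!is.null(ring_open[[d]])) {
        op <- ring_open[[d]]
        bt <- if (pending_bond != "default") pending_bond
              else if (op$bond != "default") op$bond else "default"
        bonds[[length(bonds) + 1L]] <- list(a = op$atom, b = prev, type = bt)
        ring_open[[d]] <- NULL
      } else {
        ring_open[[d]] <- list(atom = prev, bond = pending_bond)
      }
      pending_bond <- "default"
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in '", s, "'")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- .parse_bracket_atom(body, s)
      add_atom(at$elem, at$aromatic, at$wildcard, at$charge, at$hcount, at$map)
      i <- j + 1L
    } else if (ch == "*") {
      add_atom("*", FALSE, wildcard = TRUE); i <- i + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE); i <- i + 1L
      } else if (ch %in% c("c", "n", "o", "s")) {
        add_atom(toupper(ch), TRUE); i <- i + 1L
      } else {
        stop("unsupported SMARTS token '", ch, "' in '", s, "'")
      }
    }
  }
  if (length(prev_stack)) stop("unbalanced '(' in '", s, "'")
  open <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open)) stop("unclosed ring bond(s) ", paste(open, collapse = ","),
                         " in '", s, "'")
  atoms <- do.call(rbind, lapply(atoms, function(a)
    data.frame(elem = a$elem, aromatic = a$aromatic, wildcard = a$wildcard,
               charge = a$charge, hcount = a$hcount, map = a$map)))
  bonds <- if (length(bonds)) do.call(rbind, lapply(bonds, function(b)
    data.frame(a = b$a, b = b$b, type = b$type))) else
    data.frame(a = integer(), b = integer(), type = character())
  structure(list(atoms = atoms, bonds = bonds, source = s),
            class = "query_graph")
}

.parse_bracket_atom <- function(body, full) {
  m <- regmatches(body, regexec(
    "^([A-Za-z][a-z]?|\\*)(H[0-9]*)?([+-]+|[+-][0-9])?(:([0-9]+))?$", body))[[1]]
  if (!length(m))
    stop("unsupported bracket atom '[", body, "]' in '", full, "'")
  sym <- m[2]
  wildcard <- sym == "*"
  aromatic <- !wildcard && sym %in% c("c", "n", "o", "s", "p")
  elem <- if (wildcard) "*" else normalize_element(sym)
  hcount <- NA_integer_
  if (nzchar(m[3])) {
    hcount <- if (m[3] == "H") 1L else as.integer(substring(m[3], 2))
  }
  charge <- 0L
  if (nzchar(m[4])) {
    cm <- m[4]
    charge <- if (grepl("[0-9]", cm)) {
      as.integer(substring(cm, 2)) * if (substring(cm, 1, 1) == "-") -1L else 1L
    } else sum(ifelse(strsplit(cm, "")[[1]] == "+", 1L, -1L))
  }
  map <- if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  list(elem = elem, aromatic = aromatic, wildcard = wildcard,
       charge = charge, hcount = hcount, map = map)
}

# bond-order compatibility between a query bond type and a molecule bond order
.bond_compatible <- function(type, order) {
  switch(type,
         any = TRUE,
         single = order == 1,
         double = order == 2,
         triple = order == 3,
         aromatic = order == 1.5,
         default = order == 1 | order == 1.5,
         FALSE)
}

.atom_compatible <- function(qatom, elem, charge, n_h) {
  if (!qatom$wildcard && qatom$elem != elem) return(FALSE)
  if (!is.na(qatom$hcount) && n_h != qatom$hcount) return(FALSE)
  # charge constraint only enforced when written explicitly (non-zero)
  if (qatom$charge != 0L && charge != qatom$charge) return(FALSE)
  TRUE
}

#' Find all substructure matches of a query in a molecule
#'
#' Heavy-atom monomorphism matching of a parsed SMARTS subset query against a
#' \code{mol_structure}. Hydrogens in the molecule never match query atoms but
#' are counted for explicit \code{H<n>} constraints.
#'
#' @param mol a \code{mol_structure}.
#' @param query a \code{query_graph} from \code{\link{parse_smarts}} or a
#'   string (parsed on the fly).
#' @param unique_sets if TRUE (default), matches that cover the same atom set
#'   are collapsed to the first found (pattern-automorphism deduplication).
#' @return list of integer vectors; element k of a vector is the molecule atom
#'   matched by query atom k.
#' @export
match_substructure <- function(mol, query, unique_sets = TRUE) {
  if (is.character(query)) query <- parse_smarts(query)
  stopifnot(inherits(query, "query_graph"), is_mol(mol))
  hv <- heavy_atoms(mol)
  if (nrow(query$atoms) > length(hv)) return(list())
  # hydrogen counts per heavy atom
  adj <- mol_adjacency(mol)
  n_h <- vapply(seq_len(n_atoms(mol)), function(i)
    sum(mol$elements[adj[[i]]] == "H"), integer(1))
  # candidate domains, in heavy-atom indexing
  hv_map <- match(hv, hv)
  domains <- lapply(seq_len(nrow(query$atoms)), function(qi) {
    q <- query$atoms[qi, ]
    ok <- vapply(hv, function(ai) .atom_compatible(
      q, mol$elements[ai], mol$charges[ai], n_h[ai]), logical(1))
    which(ok)
  })
  if (any(!lengths(domains))) return(list())
  nq <- nrow(query$atoms)
  if (nq == 1L) {
    res <- lapply(domains[[1]], function(i) hv[i])
  } else {
    qg <- igraph::graph_from_data_frame(
      data.frame(from = query$bonds$a, to = query$bonds$b),
      directed = FALSE, vertices = data.frame(name = seq_len(nq)))
    hb <- mol$bonds[mol$bonds$a %in% hv & mol$bonds$b %in% hv, , drop = FALSE]
    mg <- igraph::graph_from_data_frame(
      data.frame(from = match(hb$a, hv), to = match(hb$b, hv)),
      directed = FALSE, vertices = data.frame(name = seq_along(hv)))
    maps <- igraph::subgraph_isomorphisms(qg, mg, method = "lad",
                                          induced = FALSE, domains = domains)
    # post-filter for bond orders
    border <- setNames(hb$order, paste(pmin(hb$a, hb$b), pmax(hb$a, hb$b)))
    res <- list()
    for (mp in maps) {
      ai <- hv[as.integer(mp)]
      ok <- TRUE
      for (bi in seq_len(nrow(query$bonds))) {
        qa <- ai[query$bonds$a[bi]]; qb <- ai[query$bonds$b[bi]]
        o <- border[[paste(min(qa, qb), max(qa, qb))]]
        if (is.null(o) || !.bond_compatible(query$bonds$type[bi], o)) {
          ok <- FALSE; break
        }
      }
      if (ok) res[[length(res) + 1L]] <- ai
    }
  }
  if (unique_sets && length(res) > 1L) {
    keys <- vapply(res, function(v) paste(sort(v), collapse = ","), character(1))
    res <- res[!duplicated(keys)]
  }
  res
}

#' Parse an anchor-mapped linker specification
#'
#' A linker spec is a SMARTS subset expression containing exactly two
#' atom-mapped anchors, conventionally written \code{[C:1]...[O:2]}: the
#' anchor atoms flank the linker and stay with the adjacent fragments when
#' the linker is excised.
#'
#' @param smarts the SMARTS string.
#' @return a \code{linker_spec}: the parsed query plus \code{anchor1}/
#'   \code{anchor2} query-atom indices.
#' @export
linker_spec <- function(smarts) {
  q <- parse_smarts(smarts)
  anchors <- which(!is.na(q$atoms$map))
  maps <- q$atoms$map[anchors]
  if (length(anchors) != 2L || !setequal(maps, c(1L, 2L)))
    stop("linker SMARTS must contain exactly two anchor maps [:1] and [:2]")
  structure(list(query = q, smarts = smarts,
                 anchor1 = anchors[which(maps == 1L)],
                 anchor2 = anchors[which(maps == 2L)]),
            class = "linker_spec")
}
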