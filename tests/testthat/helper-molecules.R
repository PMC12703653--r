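# Shared in-code fixtures: small molecules with exact hand-set geometry.

# n-atom heavy chain (default all carbon) in a zig-zag: bond 1.53 A,
# angle 112 deg, all torsions trans. Returns a mol_structure.
chain_mol <- function(n, elems = rep("C", n), name = "chain") {
  stopifnot(n >= 1)
  # planar zig-zag: step headings alternate +/-34 deg off x, giving a
  # 112 deg bond angle at every interior atom
  half <- (180 - 112) / 2 * pi / 180
  coords <- matrix(0, n, 3)
  if (n >= 2) {
    for (i in 2:n) {
      head <- if (i %% 2 == 0) half else -half
      coords[i, ] <- coords[i - 1, ] + 1.53 * c(cos(head), sin(head), 0)
    }
  }
  bonds <- if (n >= 2) data.frame(a = 1:(n - 1), b = 2:n, order = 1) else NULL
  mol_structure(elems, coords, bonds, name = name)
}

# planar benzene: 6 aromatic carbons, C-C 1.39 A
benzene_mol <- function(name = "benzene") {
  t <- (0:5) * pi / 3
  coords <- cbind(1.39 * cos(t), 1.39 * sin(t), 0)
  bonds <- data.frame(a = 1:6, b = c(2:6, 1), order = 1.5)
  mol_structure(rep("C", 6), coords, bonds, name = name)
}

# toluene: benzene + methyl carbon on atom 1
toluene_mol <- function() {
  b <- benzene_mol("toluene")
  coords <- rbind(b$coords, c(2.90, 0, 0))
  bonds <- rbind(b$bonds, data.frame(a = 1, b = 7, order = 1))
  mol_structure(c(b$elements, "C"), coords, bonds, name = "toluene")
}

# independent brute-force oracle: count cross pairs in [dmin, dmax) by loop
brute_shell_count <- function(a, b, dmin, dmax) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d >= dmin && d < dmax) n <- n + 1L
  }
  n
}

# independent MCS oracle for small molecules: largest connected atom subset
# of `a` that maps into `b` preserving elements and bond orders, found by
# exhaustive growth over connected subsets + igraph isomorphism checks.
brute_mcs_size <- function(a, b) {
  ha <- heavy_atoms(a); hb <- heavy_atoms(b)
  adj <- mol_adjacency(a)
  bond_order <- function(mol, i, j) {
    r <- mol$bonds[(mol$bonds$a == i & mol$bonds$b == j) |
                   (mol$bonds$a == j & mol$bonds$b == i), ]
    if (nrow(r)) r$order[1] else NA_real_
  }
  # enumerate connected heavy-atom subsets of a (grown from each seed)
  subsets <- new.env(parent = emptyenv())
  grow <- function(set) {
    key <- paste(sort(set), collapse = ",")
    if (!is.null(subsets[[key]])) return()
    subsets[[key]] <- set
    nb <- setdiff(intersect(unique(unlist(adj[set])), ha), set)
    for (x in nb) grow(c(set, x))
  }
  for (s in ha) grow(s)
  all_sets <- as.list(subsets)
  sizes <- vapply(all_sets, length, integer(1))
  # try to embed each subset into b, largest first (permutation search)
  embeds <- function(set) {
    k <- length(set)
    perm_try <- function(map_a, map_b) {
      if (length(map_a) == k) return(TRUE)
      x <- setdiff(set, map_a)[1]
      for (y in setdiff(hb, map_b)) {
        if (b$elements[y] != a$elements[x]) next
        ok <- TRUE
        for (t in seq_along(map_a)) {
          oa <- bond_order(a, x, map_a[t])
          ob <- bond_order(b, y, map_b[t])
          # common subgraph: an a-bond inside the subset must exist in b
          if (!is.na(oa) && (is.na(ob) || oa != ob)) { ok <- FALSE; break }
        }
        if (ok && perm_try(c(map_a, x), c(map_b, y))) return(TRUE)
      }
      FALSE
    }
    perm_try(integer(), integer())
  }
  for (sz in sort(unique(sizes), decreasing = TRUE)) {
    for (st in all_sets[sizes == sz]) {
      # connectivity within b is implied for trees; verify via the match in
      # the main implementation contract instead: require the a-subset
      # bonds to embed, which keeps the common graph connected because the
      # subset itself is connected through existing a-bonds that must map.
      if (embeds(st)) return(sz)
    }
  }
  0L
}

# random proper rotation matrix (seeded by caller)
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, pi)
  protaconf:::.rotation_about_axis(ax, th)
}

# seeded random rigid transform
with_seed_rotation <- function(seed) {
  set.seed(seed)
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 10))
}

# default 3-peak test rule: 180/0.5, 60/0.3, -60/0.2
three_peak_rule <- function() {
  torsion_rule("*", data.frame(angle = c(180, 60, -60),
                               probability = c(0.5, 0.3, 0.2)))
}

circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
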