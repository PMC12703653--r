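# Torsion driving, bound-pose transfer and depth-first conformer
# enumeration with pruning.

test_that("set_torsion drives a dihedral exactly and is an involution", {
  mol <- chain_mol(4)
  orig <- measure_dihedral(mol$coords, 1, 2, 3, 4)
  m60 <- set_torsion(mol, 2, 3, 60)
  expect_equal(measure_dihedral(m60$coords, 1, 2, 3, 4), 60,
               tolerance = 1e-6)
  # only the distal side moved; bond lengths and angles intact
  expect_equal(m60$coords[1:3, ], mol$coords[1:3, ], tolerance = 1e-12)
  d_orig <- as.numeric(stats::dist(mol$coords))[c(1, 5, 6)]
  d_new <- as.numeric(stats::dist(m60$coords))[c(1, 5, 6)]
  expect_equal(d_new, d_orig, tolerance = 1e-9)
  back <- set_torsion(m60, 2, 3, orig)
  expect_equal(back$coords, mol$coords, tolerance = 1e-6)
  expect_error(set_torsion(benzene_mol(), 1, 2, 10), "ring")
})

test_that("bound-pose torsions transfer onto the degrader fragment", {
  ts <- make_toy_system(2, seed = 1)
  # by construction the fragment torsion was driven to 170 in the bound pose
  expect_equal(unname(unlist(ts$truth$fragment_torsions)), c(170, 170))
  for (fr in ts$constraints)
    expect_lt(fragment_deviation(ts$degrader, fr), 1e-6)
  # fixed point: re-applying the transfer leaves coordinates untouched
  for (nm in c("bound_warhead", "bound_e3")) {
    b <- ts[[nm]]
    par_idx <- attr(b, "parent_indices")
    mm <- structure(list(mapping = data.frame(a = seq_along(par_idx),
                                              b = par_idx)),
                    class = "fragment_match")
    again <- apply_bound_torsions(ts$degrader, b, mm)
    expect_equal(again$coords, ts$degrader$coords, tolerance = 1e-6)
    # distance-matrix oracle: fragment internal distances equal bound pose
    cur <- ts$degrader$coords[par_idx, ]
    expect_lt(max(abs(stats::dist(cur) - stats::dist(b$coords))), 1e-3)
  }
  # a too-small match warns and no-ops
  tiny <- structure(list(mapping = data.frame(a = 1:2, b = 1:2)),
                    class = "fragment_match")
  expect_warning(out <- apply_bound_torsions(ts$degrader, ts$bound_warhead,
                                             tiny), "no-op|too small")
  expect_identical(out$coords, ts$degrader$coords)
})

test_that("unpruned enumeration matches the cartesian product oracle", {
  ts <- make_toy_system(2, seed = 1)
  lib <- torsion_library(fallback = three_peak_rule())
  ens <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                              max_conformers = 100, prune = NULL)
  expect_length(ens, 9L)
  s <- summary(ens)
  expect_equal(s$rank, 1:9)
  expect_equal(s$probability[1], 0.25)
  expect_equal(ens$conformers[[1]]$torsions$angle, c(180, 180))
  # oracle: full cartesian product of per-bond menus in DFS order
  menu <- data.frame(angle = c(180, 60, -60), p = c(0.5, 0.3, 0.2))
  oracle <- expand.grid(b2 = 1:3, b1 = 1:3)[, c("b1", "b2")]
  oracle_p <- menu$p[oracle$b1] * menu$p[oracle$b2]
  expect_equal(s$probability, oracle_p)
  expect_equal(max(s$probability), s$probability[1])
  # max_conformers keeps the DFS prefix
  ens5 <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                               max_conformers = 5, prune = NULL)
  expect_length(ens5, 5L)
  expect_equal(summary(ens5)$probability, oracle_p[1:5])
})

test_that("a fully constrained molecule yields a single conformer", {
  ts <- make_toy_system(0, seed = 2)
  ens <- enumerate_conformers(ts$degrader, ts$constraints,
                              torsion_library(), prune = NULL)
  expect_length(ens, 1L)
  expect_equal(ens$conformers[[1]]$probability, 1.0)
  expect_equal(ens$conformers[[1]]$rank, 1L)
})

test_that("probability floor and similarity pruning cut branches", {
  ts <- make_toy_system(2, seed = 1)
  lib <- torsion_library(fallback = three_peak_rule())
  flo <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                              prune = prune_settings(0, 0.1, 0))
  s <- summary(flo)
  expect_true(all(s$probability >= 0.1))
  # surviving products: 0.25, 0.15, 0.10, 0.15, 0.10
  expect_length(flo, 5L)
  sim <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                              prune = prune_settings(0, 0, 50))
  expect_length(sim, 1L)  # everything within 50 A RMSD of the first
})

test_that("clash pruning discards the self-colliding branches only", {
  ts <- make_toy_system(3, seed = 1)
  lib <- torsion_library(fallback = three_peak_rule())
  all27 <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                                prune = NULL)
  pruned <- enumerate_conformers(ts$degrader, ts$constraints, lib,
                                 prune = prune_settings(0.6, 0, 0))
  expect_lte(length(pruned), length(all27))
  # every kept conformer is genuinely clash-free at the same criterion
  hv <- heavy_atoms(ts$degrader)
  gi <- protaconf:::.mol_igraph(ts$degrader, heavy_only = TRUE)
  topo <- igraph::distances(gi$graph)
  vdw <- protaconf:::vdw_radius(ts$degrader$elements[hv])
  for (cf in pruned$conformers) {
    xyz <- cf$coords[hv, ]
    d <- as.matrix(stats::dist(xyz))
    lim <- outer(vdw, vdw, `+`) * 0.6
    viol <- d < lim & topo >= 4 & upper.tri(d)
    expect_false(any(viol))
  }
})

test_that("enumeration is deterministic bit-for-bit", {
  ts <- make_toy_system(2, seed = 9)
  lib <- torsion_library(fallback = three_peak_rule())
  e1 <- enumerate_conformers(ts$degrader, ts$constraints, lib)
  e2 <- enumerate_conformers(ts$degrader, ts$constraints, lib)
  expect_identical(e1, e2)
})

test_that("lig_rmsd is symmetry-aware and superposition-invariant", {
  ts <- make_toy_system(2, seed = 1)
  mol <- ts$degrader
  expect_equal(lig_rmsd(mol, mol), 0, tolerance = 1e-9)
  tr <- with_seed_rotation(31)
  moved <- set_coords(mol, transform_coords(mol$coords, tr))
  expect_equal(lig_rmsd(moved, mol), 0, tolerance = 1e-9)
  # benzene relabelled by a ring rotation still scores zero
  b <- benzene_mol()
  perm <- c(2:6, 1)
  b2 <- mol_structure(b$elements[perm], b$coords[perm, ],
                      data.frame(a = 1:6, b = c(2:6, 1), order = 1.5))
  expect_equal(lig_rmsd(b2, b), 0, tolerance = 1e-9)
  # a genuinely different conformer scores > 0
  other <- set_torsion(mol, ts$free_bonds$a[1], ts$free_bonds$b[1], 60)
  expect_gt(lig_rmsd(other, mol), 0.1)
})
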