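# Kabsch superposition, contact counting and ternary assembly/scoring.

test_that("Kabsch recovers identity, translations and rotations", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  id <- kabsch_superpose(pts, pts)
  expect_equal(id$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(id$rmsd, 0, tolerance = 1e-9)

  tr <- kabsch_superpose(pts, sweep(pts, 2, c(5, 0, 0), `+`))
  expect_equal(tr$transform$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)

  set.seed(77)
  R <- random_rotation()
  rot <- kabsch_superpose(pts, pts %*% t(R))
  expect_equal(rot$transform$rotation, R, tolerance = 1e-9)
  expect_equal(rot$rmsd, 0, tolerance = 1e-9)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("shell counts are exact at boundaries and versus brute force", {
  far_a <- matrix(0, 3, 3); far_b <- matrix(100, 3, 3)
  expect_equal(count_pairs_in_shell(far_a, far_b, 0, 2), 0L)
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(1.9, 0, 0), 1)
  expect_equal(count_pairs_in_shell(a, b, 0, 2), 1L)
  expect_equal(count_pairs_in_shell(a, b, 2, 4), 0L)
  b2 <- matrix(c(2.0, 0, 0), 1)
  expect_equal(count_pairs_in_shell(a, b2, 0, 2), 0L)   # half-open boundary
  expect_equal(count_pairs_in_shell(a, b2, 2, 4), 1L)
  set.seed(5)
  for (i in 1:5) {
    pa <- matrix(runif(150, 0, 10), 50, 3)
    pb <- matrix(runif(150, 0, 10), 50, 3)
    expect_identical(count_pairs_in_shell(pa, pb, 0, 2),
                     brute_shell_count(pa, pb, 0, 2))
    expect_identical(count_pairs_in_shell(pa, pb, 2, 4),
                     brute_shell_count(pa, pb, 2, 4))
  }
})

test_that("assembly places monomers onto the conformer exactly", {
  ts <- make_toy_system(2, seed = 1)
  model <- assemble_ternary(ts$degrader, ts$poi_complex, ts$e3_complex)
  expect_lt(model$placement_rmsd["poi"], 1e-6)
  expect_lt(model$placement_rmsd["e3"], 1e-6)
  # alignment-invariance: pre-moving a whole monomer changes nothing
  moved_e3 <- transform_complex(ts$e3_complex, with_seed_rotation(13))
  model2 <- assemble_ternary(ts$degrader, ts$poi_complex, moved_e3)
  expect_equal(protein_heavy_coords(model2$e3),
               protein_heavy_coords(model$e3), tolerance = 1e-6)
  # recovered inter-protein centroid distance matches construction truth
  d <- sqrt(sum((colMeans(protein_heavy_coords(model$poi)) -
                 colMeans(protein_heavy_coords(model$e3)))^2))
  expect_equal(d, ts$truth$centroid_distance, tolerance = 1e-6)
  # insufficient overlap names the failing side
  alien <- ts$poi_complex
  alien$ligand <- chain_mol(8, rep(c("N", "S"), 4))
  expect_error(assemble_ternary(ts$degrader, alien, ts$e3_complex), "POI")
})

test_that("raw scores subtract the unbound baseline and floor at zero", {
  ts <- make_toy_system(2, seed = 1)
  model <- assemble_ternary(ts$degrader, ts$poi_complex, ts$e3_complex)
  model <- raw_scores(model, ts$poi_complex, ts$e3_complex)
  expect_gte(model$raw_clash, 0L)
  expect_gte(model$raw_surface, 0L)
  # oracle: recompute both terms by brute force
  th <- contact_thresholds()
  units <- list(poi = protein_heavy_coords(model$poi),
                e3 = protein_heavy_coords(model$e3),
                deg = model$degrader$coords[heavy_atoms(model$degrader), ])
  cross <- function(lo, hi)
    brute_shell_count(units$poi, units$e3, lo, hi) +
    brute_shell_count(units$poi, units$deg, lo, hi) +
    brute_shell_count(units$e3, units$deg, lo, hi)
  base <- function(px, lo, hi)
    brute_shell_count(protein_heavy_coords(px),
                      px$ligand$coords[heavy_atoms(px$ligand), ], lo, hi)
  expect_identical(model$raw_clash,
                   max(0L, cross(0, 2) - base(ts$poi_complex, 0, 2) -
                             base(ts$e3_complex, 0, 2)))
  expect_identical(model$raw_surface,
                   max(0L, cross(2, 4) - base(ts$poi_complex, 2, 4) -
                             base(ts$e3_complex, 2, 4)))
  # scores are invariant under a global rigid motion of the whole model
  tr <- with_seed_rotation(99)
  moved <- model
  moved$poi <- transform_complex(model$poi, tr)
  moved$e3 <- transform_complex(model$e3, tr)
  moved$degrader <- set_coords(model$degrader,
                               transform_coords(model$degrader$coords, tr))
  moved <- raw_scores(moved, ts$poi_complex, ts$e3_complex)
  expect_identical(moved$raw_clash, model$raw_clash)
  expect_identical(moved$raw_surface, model$raw_surface)
})

test_that("an intra-monomer contact cancels out of the score", {
  # one engineered inter-protein clash pair; monomer baselines zero
  lig <- chain_mol(5)
  lig$labels <- rep("warhead", 5)
  poi_atoms <- data.frame(chain = "A", resno = 1:5, resname = "GLY",
                          atom = "CA", elem = "C",
                          x = seq(10, 22, 3), y = 0, z = 0)
  e3_atoms <- data.frame(chain = "B", resno = 1:5, resname = "ALA",
                         atom = "CA", elem = "C",
                         x = seq(10, 22, 3), y = 1.5, z = 0)
  # degrader = two copies of the ligand chain joined conceptually: use the
  # same chain labelled half warhead, half e3_binder for mapping purposes
  deg <- chain_mol(5)
  deg$labels <- rep("warhead", 5)
  poi <- protein_complex(poi_atoms, lig, "poi")
  e3l <- chain_mol(5)
  e3 <- protein_complex(e3_atoms, e3l, "e3")
  deg2 <- deg; deg2$labels <- rep("unassigned", 5)
  model <- assemble_ternary(deg2, poi, e3, min_mcs = 3)
  scored <- raw_scores(model, poi, e3)
  # nearest A-B protein pair is 1.5 A apart -> at least one clash pair and
  # the monomer baselines (protein vs own far ligand) cannot push it below 0
  expect_gte(scored$raw_clash, 1L)
})

test_that("separating the proteins monotonically removes clashes", {
  ts <- make_toy_system(2, seed = 1)
  model <- assemble_ternary(ts$degrader, ts$poi_complex, ts$e3_complex)
  axis <- colMeans(protein_heavy_coords(model$e3)) -
    colMeans(protein_heavy_coords(model$poi))
  axis <- axis / sqrt(sum(axis^2))
  clashes <- vapply(c(0, 2, 5, 10, 20), function(s) {
    m <- model
    m$e3 <- transform_complex(model$e3, rigid_transform(diag(3), axis * s))
    raw_scores(m, ts$poi_complex, ts$e3_complex)$raw_clash
  }, integer(1))
  expect_true(all(diff(clashes) <= 0))
})

test_that("ensemble assembly normalises scores onto [1, 10]", {
  ts <- make_toy_system(2, seed = 1)
  lib <- torsion_library(fallback = three_peak_rule())
  ens <- enumerate_conformers(ts$degrader, ts$constraints, lib, prune = NULL)
  models <- assemble_ensemble(ens, ts$poi_complex, ts$e3_complex)
  tab <- score_table(models)
  expect_true(all(tab$clash_score >= 1 & tab$clash_score <= 10))
  expect_true(all(tab$surface_score >= 1 & tab$surface_score <= 10))
  expect_equal(min(tab$clash_score), 1)
  if (max(tab$raw_clash) > min(tab$raw_clash))
    expect_equal(max(tab$clash_score), 10)
})
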