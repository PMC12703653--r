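# Structure I/O: SDF/mol2 round-trips, PDB complexes, cleaning, embedding.

test_that("SDF round-trips coordinates, elements and bonds", {
  ts <- make_toy_system(2, seed = 3)
  mol <- ts$degrader
  path <- withr::local_tempfile(fileext = ".sdf")
  write_structure(mol, path)
  back <- read_structure(path, add_hydrogens = FALSE)
  expect_identical(back$elements, mol$elements)
  expect_equal(back$coords, mol$coords, tolerance = 1e-4)
  expect_equal(back$bonds[order(back$bonds$a, back$bonds$b), ],
               mol$bonds[order(mol$bonds$a, mol$bonds$b), ],
               ignore_attr = TRUE)
})

test_that("multi-record SDF keeps per-conformer data fields", {
  m1 <- chain_mol(4); m2 <- set_torsion(chain_mol(4), 2, 3, 60)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_ensemble(list(m1, m2), path,
                     fields = list(c(rank = "1", probability = "0.5"),
                                   c(rank = "2", probability = "0.25")))
  back <- read_sdf_ensemble(path)
  expect_length(back, 2L)
  expect_equal(unname(attr(back[[2]], "sdf_fields")["rank"]), "2")
  expect_equal(back[[2]]$coords, m2$coords, tolerance = 1e-4)
})

test_that("mol2 round-trips through bio3d", {
  mol <- chain_mol(5, c("C", "C", "O", "C", "N"))
  path <- withr::local_tempfile(fileext = ".mol2")
  write_structure(mol, path)
  back <- read_structure(path, add_hydrogens = FALSE)
  expect_identical(back$elements, mol$elements)
  expect_equal(back$coords, mol$coords, tolerance = 1e-4)
  expect_equal(nrow(back$bonds), nrow(mol$bonds))
})

test_that("unknown mol2 atom types are reported by atom", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "bad", " 1 0 1", "SMALL", "NO_CHARGES",
               "", "@<TRIPOS>ATOM",
               "      1 X1          0.0  0.0  0.0 Xx.3      1 LIG  0.0000"),
             path)
  suppressWarnings(expect_error(read_structure(path), "unknown atom type"))
})

test_that("PDB complexes round-trip chains, sequences and ligand", {
  ts <- make_toy_system(2, seed = 5)
  px <- ts$poi_complex
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(px, path)
  back <- read_structure(path, format = "pdb", ligand_id = "LIG")
  expect_equal(chain_ids(back), chain_ids(px))
  expect_equal(unname(chain_sequence(back, "A")),
               unname(chain_sequence(px, "A")))
  expect_equal(calpha_coords(back, "A"), calpha_coords(px, "A"),
               tolerance = 1e-3)
  expect_equal(n_atoms(back$ligand), sum(ts$bound_warhead$elements != "H") +
                 sum(ts$bound_warhead$elements == "H"))
  # two chains stay two chains
  two <- protein_complex(rbind(px$atoms,
                               transform(px$atoms, chain = "B", x = x + 40)),
                         px$ligand, "two")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(two, p2)
  back2 <- read_structure(p2, format = "pdb", ligand_id = "LIG")
  expect_setequal(chain_ids(back2), c("A", "B"))
})

test_that("clean_complex strips waters and distant chains", {
  ts <- make_toy_system(2, seed = 7)
  px <- ts$poi_complex
  wat <- data.frame(chain = "W", resno = 900 + 1:30, resname = "HOH",
                    atom = "CA", elem = "O",
                    x = rnorm(30, 50), y = rnorm(30), z = rnorm(30))
  far <- transform(px$atoms, chain = "Z", x = x + 80)
  dirty <- protein_complex(rbind(px$atoms, wat, far), px$ligand, "dirty")
  cleaned <- clean_complex(dirty, proximity_cutoff = 8)
  expect_false(any(cleaned$atoms$resname == "HOH"))
  expect_false("Z" %in% chain_ids(cleaned))
  expect_true("A" %in% chain_ids(cleaned))
  # two chains in contact are both retained
  near <- transform(px$atoms, chain = "B", z = z + 3)
  both <- protein_complex(rbind(px$atoms, near), px$ligand, "both")
  expect_setequal(chain_ids(clean_complex(both, 8)), c("A", "B"))
  expect_error(clean_complex(px, -1))
})

test_that("SMILES embedding yields sane, deterministic geometry", {
  m <- embed_from_smiles("CCO", seed = 4)
  hv <- heavy_atoms(m)
  expect_length(hv, 3L)
  d_cc <- sqrt(sum((m$coords[1, ] - m$coords[2, ])^2))
  d_co <- sqrt(sum((m$coords[2, ] - m$coords[3, ])^2))
  expect_true(d_cc > 1.3 && d_cc < 1.7)
  expect_true(d_co > 1.2 && d_co < 1.7)
  expect_identical(embed_from_smiles("CCO", seed = 4)$coords, m$coords)
  # 3-ring closes within covalent bounds
  ring <- embed_from_smiles("C1CC1", seed = 2)
  d <- as.numeric(stats::dist(ring$coords[heavy_atoms(ring), ]))
  expect_true(all(abs(d - 1.52) < 0.25))
  expect_error(embed_from_smiles("C(("), "unbalanced")
})

test_that("hydrogen filling honours standard valences", {
  eth <- add_missing_hydrogens(chain_mol(2))
  expect_equal(sum(eth$elements == "H"), 6L)          # ethane
  benz <- add_missing_hydrogens(benzene_mol())
  expect_equal(sum(benz$elements == "H"), 6L)         # one H per ring C
  # bond lengths to H near 1.0 A
  hb <- benz$bonds[benz$elements[benz$bonds$b] == "H", ]
  d <- sqrt(rowSums((benz$coords[hb$a, ] - benz$coords[hb$b, ])^2))
  expect_true(all(abs(d - 1.0) < 1e-6))
})
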