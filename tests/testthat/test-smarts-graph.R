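# SMARTS subset parsing, substructure matching, linker handling,
# fragmentation and maximum common subgraph.

test_that("the SMARTS subset parser handles atoms, bonds, rings, anchors", {
  q <- parse_smarts("[C:1]-C-O-[C:2]")
  expect_equal(nrow(q$atoms), 4L)
  expect_equal(q$atoms$map, c(1L, NA, NA, 2L))
  expect_true(all(q$bonds$type == "single"))

  ring <- parse_smarts("c1ccccc1")
  expect_equal(nrow(ring$atoms), 6L)
  expect_equal(nrow(ring$bonds), 6L)
  expect_true(all(ring$atoms$aromatic))

  expect_error(parse_smarts("C(("), "unbalanced")
  expect_error(parse_smarts("C1CC"), "unclosed ring")
  expect_error(parse_smarts("[C&R1]"), "unsupported")
  expect_error(parse_smarts(""), "empty")
})

test_that("substructure matching respects elements and bond orders", {
  mol <- chain_mol(5, c("C", "C", "O", "C", "N"))
  hits <- match_substructure(mol, "COC")
  expect_length(hits, 1L)
  expect_setequal(hits[[1]], c(2L, 3L, 4L))
  # explicit single bond does not match aromatic rings
  expect_length(match_substructure(benzene_mol(), "C-C"), 0L)
  expect_gt(length(match_substructure(benzene_mol(), "C:C",
                                      unique_sets = FALSE)), 0L)
  # wildcard matches any heavy atom
  expect_length(match_substructure(mol, "O~*", unique_sets = TRUE), 2L)
})

test_that("linker specs need exactly two anchors and a unique match", {
  expect_error(linker_spec("CCO"), "exactly two anchor")
  expect_error(linker_spec("[C:1]C[C:1]"), "exactly two anchor")
  spec <- linker_spec("[C:1]-O-[C:2]")
  expect_s3_class(spec, "linker_spec")

  mol <- chain_mol(5, c("C", "C", "O", "C", "C"))
  lm <- match_linker(mol, "[C:1]-O-[C:2]")
  expect_equal(lm$linker_atoms, 3L)
  expect_setequal(c(lm$anchor1, lm$anchor2), c(2L, 4L))

  expect_error(match_linker(mol, "[C:1]-N-[C:2]"), "no match")
  # two distinct ether sites -> ambiguity
  mol2 <- chain_mol(8, c("C", "C", "O", "C", "C", "O", "C", "C"))
  expect_error(match_linker(mol2, "[C:1]-O-[C:2]"), "match")
})

test_that("fragmentation partitions heavy atoms into two sides + linker", {
  td <- make_toy_degrader(2, seed = 1)
  fr <- td$fragmentation
  mol <- fr$molecule
  hv <- heavy_atoms(mol)
  lab <- mol$labels[hv]
  expect_setequal(unique(lab), c("warhead", "linker", "e3_binder"))
  w <- attr(fr$warhead, "parent_indices")
  e <- attr(fr$e3_binder, "parent_indices")
  expect_length(intersect(w, e), 0L)
  expect_setequal(c(w, e, fr$linker_atoms), seq_len(n_atoms(mol)))
  # anchors stay with their fragments
  expect_true(fr$anchor1 %in% w)
  expect_true(fr$anchor2 %in% e)
  # a "linker" inside a ring leaves the molecule in one piece -> error
  t <- (0:5) * pi / 3
  fpyr <- mol_structure(
    c("N", "C", "C", "C", "C", "C", "F"),
    rbind(cbind(1.39 * cos(t), 1.39 * sin(t), 0), c(2.9 * cos(t[3]), 2.9 * sin(t[3]), 0)),
    rbind(data.frame(a = 1:6, b = c(2:6, 1), order = 1.5),
          data.frame(a = 3, b = 7, order = 1)))
  expect_error(fragment_chimera(fpyr, "F-C:[C:1]:[C:2]"),
               "exactly two fragments")
})

test_that("MCS finds identity, ring-in-ring and respects min_size", {
  b <- benzene_mol()
  mm <- max_common_subgraph(b, b, min_size = 3)
  expect_equal(nrow(mm$mapping), 6L)
  tol <- toluene_mol()
  mm2 <- max_common_subgraph(b, tol, min_size = 3)
  expect_equal(nrow(mm2$mapping), 6L)
  expect_true(all(mm2$mapping$b <= 6))  # methyl carbon unmatched
  ch4 <- mol_structure("C", matrix(0, 1, 3), NULL)
  h2o <- mol_structure("O", matrix(0, 1, 3), NULL)
  expect_error(max_common_subgraph(ch4, h2o, min_size = 3),
               "insufficient overlap")
})

test_that("MCS agrees with the exhaustive oracle on small molecules", {
  cases <- list(
    list(a = chain_mol(4, c("C", "C", "O", "C")),
         b = chain_mol(5, c("C", "C", "O", "C", "N"))),
    list(a = benzene_mol(), b = toluene_mol()),
    list(a = chain_mol(6, c("C", "N", "C", "C", "O", "C")),
         b = chain_mol(4, c("C", "C", "O", "C")))
  )
  for (cs in cases) {
    got <- nrow(max_common_subgraph(cs$a, cs$b, min_size = 1)$mapping)
    expect_equal(got, brute_mcs_size(cs$a, cs$b))
  }
})

test_that("rotatable bonds exclude rings, terminals and amides", {
  expect_equal(nrow(rotatable_bonds(benzene_mol())), 0L)
  # butane: only the central bond
  rb <- rotatable_bonds(chain_mol(4))
  expect_equal(nrow(rb), 1L)
  expect_equal(c(rb$a, rb$b), c(2L, 3L))
  # N-methylacetamide-like: C-C(=O)-N-C, amide C-N excluded by default
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0), c(2.2, -1.3, 0),
                  c(3.7, -1.4, 0))
  amide <- mol_structure(c("C", "C", "O", "N", "C"), coords,
                         data.frame(a = c(1, 2, 2, 4), b = c(2, 3, 4, 5),
                                    order = c(1, 2, 1, 1)))
  expect_equal(nrow(rotatable_bonds(amide)), 0L)
  expect_equal(nrow(rotatable_bonds(amide, exclude_amide = FALSE)), 1L)
})

test_that("graph automorphisms capture molecular symmetry", {
  autos <- mol_automorphisms(benzene_mol())
  expect_length(autos, 12L)   # dihedral group of the 6-ring
  autos_tol <- mol_automorphisms(toluene_mol())
  expect_length(autos_tol, 2L)  # mirror only
})
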