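test_that("a handcrafted structure parses into chains and ligand groups", {
  f <- write_tmp_pdb(tiny_pdb_lines())
  rec <- parse_structure(f)
  expect_length(rec$chains, 1L)
  expect_identical(rec$chains[["A"]]$sequence, c("A", "G", "L"))
  expect_identical(rec$chains[["A"]]$atoms$seq_index, 1:3)
  expect_length(rec$ligands, 1L)
  expect_identical(rec$ligands[[1]]$het_code, "HEM")
})

test_that("waters are excluded and never change labels", {
  base <- tiny_pdb_lines()
  withwat <- c(base[1:4],
               pdb_atom_line(5, "O", "HOH", "A", 201, 5, 1, 0,
                             record = "HETATM", elem = "O"),
               "END")
  r1 <- parse_structure(write_tmp_pdb(base))
  r2 <- parse_structure(write_tmp_pdb(withwat))
  expect_length(r2$ligands, 1L)
  l1 <- label_structure(r1)[["A"]]
  l2 <- label_structure(r2)[["A"]]
  expect_identical(l1$labels, l2$labels)
})

test_that("only the highest-occupancy altloc conformer is kept", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6,
                           alt = "A", elem = "C"),
             pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.4,
                           alt = "B", elem = "C"),
             pdb_atom_line(3, "CA", "GLY", "A", 2, 5, 0, 0, elem = "C"),
             "END")
  rec <- parse_structure(write_tmp_pdb(lines))
  res1 <- rec$chains[["A"]]$atoms[rec$chains[["A"]]$atoms$seq_index == 1, ]
  expect_identical(nrow(res1), 1L)
  expect_equal(res1$x, 0)   # the occ-0.6 A conformer
})

test_that("non-standard polymer residues map to X but keep their atoms", {
  lines <- c(pdb_atom_line(1, "CA", "MSE", "A", 1, 5, 1, 0, elem = "C"),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 50, 0, 0, elem = "C"),
             pdb_atom_line(3, "FE", "HEM", "A", 101, 5, 4, 0,
                           record = "HETATM", elem = "FE"),
             "END")
  rec <- parse_structure(write_tmp_pdb(lines))
  expect_identical(rec$chains[["A"]]$sequence, c("X", "G"))
  labs <- label_structure(rec)[["A"]]
  expect_identical(labs$labels, c(TRUE, FALSE))  # MSE at 3 A from FE
})

test_that("parse errors are raised for missing or chain-free files", {
  expect_error(parse_structure(tempfile()), "cannot read")
  onlyhet <- c(pdb_atom_line(1, "FE", "HEM", "A", 1, 0, 0, 0,
                             record = "HETATM", elem = "FE"), "END")
  expect_error(parse_structure(write_tmp_pdb(onlyhet)),
               "no polymer chains")
})

test_that("identify_ligands keeps contacting groups and drops distant ones", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"),
             pdb_atom_line(2, "FE", "HEM", "A", 101, 4, 0, 0,
                           record = "HETATM", elem = "FE"),
             pdb_atom_line(3, "ZN", "ZN", "A", 102, 10, 0, 0,
                           record = "HETATM", elem = "ZN"),
             "END")
  rec <- parse_structure(write_tmp_pdb(lines))
  expect_length(rec$ligands, 2L)
  kept <- identify_ligands(rec)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$het_code, "HEM")
  # brute-force check: the kept group is the one whose min distance < 4.5
  dmin <- vapply(rec$ligands, function(l) {
    P <- rec$chains[["A"]]$atoms
    min(sqrt((l$atoms$x - P$x)^2 + (l$atoms$y - P$y)^2 +
               (l$atoms$z - P$z)^2))
  }, 0)
  expect_identical(vapply(kept, `[[`, "", "het_code"),
                   vapply(rec$ligands[dmin < 4.5], `[[`, "", "het_code"))
})

test_that("the 4.5 A boundary is strict: exactly 4.5 labels negative", {
  lines <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 4.5, 0, 0, elem = "C"),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 4.4, 0, 0, elem = "C"),
             pdb_atom_line(3, "FE", "HEM", "A", 101, 0, 0, 0,
                           record = "HETATM", elem = "FE"),
             "END")
  rec <- parse_structure(write_tmp_pdb(lines))
  labs <- label_binding_residues(rec$chains[["A"]], rec$ligands)
  expect_identical(labs$labels, c(FALSE, TRUE))
  incl <- label_binding_residues(rec$chains[["A"]], rec$ligands,
                                 inclusive = TRUE)
  expect_identical(incl$labels, c(TRUE, TRUE))
})

test_that("labels match the embedded truth on a simulated pocket", {
  f <- withr::local_tempfile(fileext = ".pdb")
  sim <- simulate_structure(10, pocket_positions = 4:6,
                            pocket_distance = 3, seed = 5, path = f)
  rec <- parse_structure(f)
  labs <- label_structure(rec)[["A"]]
  expect_identical(labs$labels, sim$labels$labels)
  expect_identical(which(labs$labels), 4:6)
  expect_length(labs$labels, 10L)
})

test_that("labels are monotone in the cutoff", {
  f <- withr::local_tempfile(fileext = ".pdb")
  simulate_structure(12, pocket_positions = c(2, 7), pocket_distance = 3,
                     decoy_distance = 7, seed = 9, path = f)
  rec <- parse_structure(f)
  lig <- rec$ligands
  cuts <- c(1, 3.5, 4.5, 6, 8, 25)
  prev <- rep(FALSE, 12)
  for (cu in cuts) {
    cur <- label_binding_residues(rec$chains[["A"]], lig,
                                  cutoff = cu)$labels
    expect_true(all(cur[prev]), info = paste("cutoff", cu))
    prev <- cur
  }
  expect_true(all(label_binding_residues(rec$chains[["A"]], lig,
                                         cutoff = 25)$labels))
})

test_that("prefilter labeling equals the exhaustive all-pairs scan", {
  for (seed in 1:10) {
    f <- withr::local_tempfile(fileext = ".pdb")
    n <- 5 + seed
    simulate_structure(n, pocket_positions = seq(2, n, by = 3),
                       pocket_distance = 3, decoy_distance = 6,
                       seed = seed, path = f)
    rec <- parse_structure(f)
    for (cu in c(2.9, 4.5, 6.2)) {
      a <- label_binding_residues(rec$chains[["A"]], rec$ligands,
                                  cutoff = cu, method = "prefilter")
      b <- label_binding_residues(rec$chains[["A"]], rec$ligands,
                                  cutoff = cu, method = "exhaustive")
      expect_identical(a$labels, b$labels)
    }
  }
})

test_that("empty ligand list yields all-false labels, not an error", {
  f <- write_tmp_pdb(tiny_pdb_lines())
  rec <- parse_structure(f)
  labs <- label_binding_residues(rec$chains[["A"]], list())
  expect_identical(labs$labels, rep(FALSE, 3))
})

test_that("label TSV and chain FASTA round-trip the parsed structure", {
  f <- write_tmp_pdb(tiny_pdb_lines())
  rec <- parse_structure(f)
  sets <- label_structure(rec)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_labels_tsv(rec, sets, tsv)
  back <- read_labels_tsv(tsv)
  expect_identical(back[["A"]], sets[["A"]]$labels)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_chain_fasta(rec, fa)
  expect_identical(unname(read_fasta_sequences(fa)[1]), "AGL")
})

test_that("multi-model files honour model_index", {
  m1 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 1, 0, 0, elem = "C"),
          pdb_atom_line(2, "FE", "HEM", "A", 9, 0, 0, 0,
                        record = "HETATM", elem = "FE"))
  m2 <- c(pdb_atom_line(1, "CA", "ALA", "A", 1, 9, 0, 0, elem = "C"),
          pdb_atom_line(2, "FE", "HEM", "A", 9, 0, 0, 0,
                        record = "HETATM", elem = "FE"))
  lines <- c("MODEL        1", m1, "ENDMDL",
             "MODEL        2", m2, "ENDMDL", "END")
  f <- write_tmp_pdb(lines)
  r1 <- parse_structure(f, model_index = 1)
  r2 <- parse_structure(f, model_index = 2)
  expect_equal(r1$chains[["A"]]$atoms$x[1], 1)
  expect_equal(r2$chains[["A"]]$atoms$x[1], 9)
})
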