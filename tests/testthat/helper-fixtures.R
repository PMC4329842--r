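# fixtures built in code: handcrafted PDB/PSSM texts and small datasets

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          record = "ATOM", occ = 1, alt = " ",
                          elem = substr(name, 1, 1)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resn, chain, resno, " ",
          x, y, z, occ, 0, elem)
}

# 3 residues along x, one HEM group 4 A from residue 2's CA
tiny_pdb_lines <- function() {
  c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 5, 0, 0, elem = "C"),
    pdb_atom_line(3, "CA", "LEU", "A", 3, 10, 0, 0, elem = "C"),
    pdb_atom_line(4, "FE", "HEM", "A", 101, 5, 4, 0, record = "HETATM",
                  elem = "FE"),
    "END")
}

write_tmp_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# random encoded dataset with both classes
random_dataset <- function(m = 40, d = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- c(TRUE, FALSE, runif(m - 2) < 0.4)
    x <- matrix(rnorm(m * d), m, d) + outer(as.numeric(y), rep(1, d))
    encoded_dataset(x, y, data.frame(chain_id = "c",
                                     seq_index = seq_len(m)))
  })
}

# exhaustive evaluation of the naive Bayes joint on a discrete problem:
# P(c) * prod_i P(x_i | c) with frequencies straight from the training
# table; independent of the classifier's log-space ratio path
joint_prob_oracle <- function(x_df, y, x_row, cls) {
  pri <- if (cls) mean(y) else mean(!y)
  sel <- if (cls) y else !y
  p <- pri
  for (i in seq_along(x_df)) {
    p <- p * mean(x_df[[i]][sel] == x_row[[i]])
  }
  p
}
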