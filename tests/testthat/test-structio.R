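test_that("a toy PDB parses into chains, residues and heavy-atom flags", {
  m <- read_structure(toy_pdb_3atoms())
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(model_chains(m), c("A", "B"))
  expect_equal(m$atoms$residue_index, c(1L, 2L, 1L))
  expect_true(all(m$atoms$is_heavy))

  withh <- write_toy_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "H", "ALA", "A", 1, 0.5, 0, 0, element = "H")
  ))
  mh <- read_structure(withh)
  expect_equal(mh$atoms$is_heavy, c(TRUE, FALSE))
})

test_that("malformed and degenerate PDB input is rejected with diagnostics", {
  bad <- pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0)
  substr(bad, 31, 38) <- "   12.3X"
  expect_error(read_structure(write_toy_pdb(c("REMARK", bad))),
               "line 2")
  expect_error(read_structure(write_toy_pdb("")), "empty")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("HETATM records are skipped by default and waters always", {
  p <- write_toy_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "O", "HOH", "W", 1, 9, 9, 9, record = "HETATM"),
    pdb_line(3, "ZN", "ZN", "Z", 1, 5, 5, 5, record = "HETATM",
             element = "ZN")
  ))
  expect_equal(nrow(read_structure(p)$atoms), 1L)
  mh <- read_structure(p, include_hetatm = TRUE)
  expect_equal(nrow(mh$atoms), 2L)  # zinc kept, water still skipped
  expect_equal(mh$atoms$element, c("C", "ZN"))
})

test_that("altloc policy keeps the highest-occupancy copy, tie to first", {
  p <- write_toy_pdb(c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.6, altloc = "B"),
    pdb_line(3, "CB", "ALA", "A", 1, 2, 0, 0, occ = 0.5, altloc = "A"),
    pdb_line(4, "CB", "ALA", "A", 1, 3, 0, 0, occ = 0.5, altloc = "B")
  ))
  m <- read_structure(p)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(1, 2))  # occ winner, then tie -> first
})

test_that("structures round-trip through the PDB writer field-by-field", {
  m1 <- read_structure(toy_pdb_3atoms())
  out <- tempfile(fileext = ".pdb")
  write_structure(m1, out)
  m2 <- read_structure(out)
  cols <- c("chain_id", "residue_index", "residue_name", "atom_name",
            "element", "x", "y", "z", "is_heavy", "residue_key")
  expect_equal(m2$atoms[, cols], m1$atoms[, cols], ignore_attr = TRUE)
})

test_that("parser agrees with bio3d on a mixed fixture", {
  skip_if_not_installed("bio3d")
  p <- write_toy_pdb(c(
    pdb_line(1, "N", "MET", "A", 1, 1.1, 2.2, 3.3),
    pdb_line(2, "CA", "MET", "A", 1, 2.5, 2.2, 3.3),
    pdb_line(3, "CA", "TRP", "A", 2, 6.1, 2.0, 3.0),
    pdb_line(4, "CA", "LEU", "B", 10, 0.0, 5.0, 1.0),
    "END"
  ))
  m <- read_structure(p)
  ref <- bio3d::read.pdb(p, verbose = FALSE)$atom
  expect_equal(m$atoms$x, ref$x)
  expect_equal(m$atoms$residue_index, ref$resno)
  expect_equal(m$atoms$chain_id, ref$chain)
  expect_equal(m$atoms$atom_name, ref$elety)
})

test_that("multi-model files become ordered ensembles", {
  one_model <- function(x) c("MODEL", pdb_line(1, "CA", "ALA", "A", 1, x, 0, 0),
                             "ENDMDL")
  p <- write_toy_pdb(unlist(lapply(1:3, one_model)))
  e <- read_ensemble(p)
  expect_equal(length(e$models), 3L)
  expect_equal(vapply(e$models, `[[`, integer(1), "model_id"), 1:3)
  expect_equal(vapply(e$models, function(m) m$atoms$x, numeric(1)), c(1, 2, 3))

  # single-model file without MODEL keyword -> ensemble of 1
  e1 <- read_ensemble(toy_pdb_3atoms())
  expect_equal(length(e1$models), 1L)

  expect_error(read_ensemble(tempfile()), "not found")
  d <- tempfile(); dir.create(d)
  expect_error(read_ensemble(d), "no PDB files")
})

test_that("ensemble read from a directory equals the per-file reads in order", {
  d <- tempfile(); dir.create(d)
  for (i in 1:3) {
    writeLines(pdb_line(1, "CA", "ALA", "A", 1, i, 0, 0),
               file.path(d, sprintf("model_%02d.pdb", i)))
  }
  e <- read_ensemble(d)
  xs <- vapply(e$models, function(m) m$atoms$x, numeric(1))
  expect_equal(xs, c(1, 2, 3))
})

test_that("inconsistent ensemble atom counts warn, or error in strict mode", {
  p <- write_toy_pdb(c(
    "MODEL", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "ENDMDL",
    "MODEL", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CB", "ALA", "A", 1, 1, 0, 0), "ENDMDL"
  ))
  expect_warning(read_ensemble(p), "inconsistent")
  expect_error(read_ensemble(p, strict = TRUE), "inconsistent")
})

test_that("trajectories align frames to the topology and check counts", {
  topo <- toy_pdb_3atoms()
  frames <- write_toy_pdb(unlist(lapply(1:5, function(k) {
    c("MODEL",
      pdb_line(1, "CA", "ALA", "A", 1, 0, 0, k),
      pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, k),
      pdb_line(3, "CA", "LEU", "B", 1, 0, 5, k),
      "ENDMDL")
  })))
  tr <- read_trajectory(topo, frames)
  expect_equal(length(tr$frames), 5L)
  expect_equal(tr$frames[[3]][, 3], rep(3, 3))

  # frame with wrong atom count -> error naming the frame
  short <- write_toy_pdb(c(
    "MODEL", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0),
    pdb_line(3, "CA", "LEU", "B", 1, 2, 0, 0), "ENDMDL",
    "MODEL", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0), "ENDMDL",
    "MODEL", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 1, 0, 0), "ENDMDL"
  ))
  expect_error(read_trajectory(topo, short), "frame 2")
})

test_that("XYZ frame blocks parse and identical frames have zero deltas", {
  topo <- toy_pdb_3atoms()
  xyz <- tempfile(fileext = ".xyz")
  writeLines(rep(c("3", "frame", "C 0 0 0", "C 3.8 0 0", "C 0 5 0"), 4), xyz)
  tr <- read_trajectory(topo, xyz)
  expect_equal(length(tr$frames), 4L)
  for (k in 2:4) expect_equal(tr$frames[[k]], tr$frames[[1]])
})

test_that("FASTA reading uppercases, validates and preserves order", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acdef", ">b desc", "WXYL", "IVAA"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$sequence, "ACDEF")
  expect_equal(recs[[2]]$sequence, "WXYLIVAA")

  writeLines(c("ACDEF", ">a"), f)
  expect_error(read_fasta(f), "before any")
  writeLines(c(">a", "AC1DE"), f)
  expect_error(read_fasta(f), "'1'")
})

test_that("FASTA reader agrees with Biostrings on a clean file", {
  skip_if_not_installed("Biostrings")
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKWVLL", "ACDE", ">p2", "wyyl"), f)
  ours <- read_fasta(f)
  ref <- Biostrings::readAAStringSet(f)
  expect_equal(vapply(ours, `[[`, character(1), "sequence"),
               toupper(unname(as.character(ref))))
})

test_that("schema-validated tables reject bad headers and keep NA as NA", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("cell_id\twell_id\treplicate\tcondition\tgenotype\tval",
               "c1\tw1\t1\tUT\tWT\t1.5",
               "c2\tw1\t1\tUT\tWT\t",
               "c3\tw2\t1\tEBSS\tWT\tNaN"), f)
  df <- read_table_schema(f, "cells")
  expect_equal(df$val, c(1.5, NA, NA))  # blanks/NaN are missing, never 0

  writeLines(c("cell_id\twell_id\treplicate\tgenotype\tval", "c1\tw1\t1\tWT\t1"), f)
  expect_error(read_table_schema(f, "cells"), "condition")
  writeLines(c("cell_id\tcell_id\twell_id\treplicate\tcondition\tgenotype",
               "a\tb\tw\t1\tUT\tWT"), f)
  expect_error(read_table_schema(f, "cells"), "duplicate")
})

test_that("LFQ matrix + sample sheet assemble into an annotated matrix", {
  mf <- tempfile(fileext = ".tsv"); sf <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tb1\tb2\tb3\tc1\tc2\tc3",
               "P1\t10\t11\t12\t1\t2\t3",
               "P2\t\t5\t6\t7\t8\t9"), mf)
  writeLines(c("sample_id\tcondition\treplicate",
               "b1\tbait\t1", "b2\tbait\t2", "b3\tbait\t3",
               "c1\tctrl\t1", "c2\tctrl\t2", "c3\tctrl\t3"), sf)
  lfq <- read_lfq(mf, sf)
  expect_equal(dim(lfq$intensities), c(2L, 6L))
  expect_true(is.na(lfq$intensities["P2", "b1"]))
  expect_equal(unique(lfq$samples$condition), c("bait", "ctrl"))
})
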