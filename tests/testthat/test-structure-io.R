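test_that("a minimal three-residue fragment parses into residues and chains", {
  p <- read_membrane_pdb(fragment_pdb())
  expect_s3_class(p, "membrane_protein")
  expect_equal(nrow(p$residues), 3)
  expect_identical(p$chains, "A")
  expect_true(all(p$residues$has_ca))
})

test_that("waters and ligand HETATM records are excluded from residues", {
  lines <- c(fragment_pdb()[1:12],
    "HETATM   90  O   HOH A 101      10.000  10.000  10.000  1.00  0.00           O",
    "HETATM   91  C1  LIG A 102      11.000  11.000  11.000  1.00  0.00           C",
    "END")
  p <- read_membrane_pdb(lines)
  expect_equal(nrow(p$residues), 3)
  expect_false(any(p$atom$resname %in% c("HOH", "LIG")))
})

test_that("malformed coordinates fail with the offending line number", {
  lines <- fragment_pdb()
  substr(lines[5], 31, 38) <- "  xx.yyy"
  expect_error(read_membrane_pdb(lines), "line 5")
  expect_error(read_membrane_pdb("REMARK only"), "no ATOM records")
})

test_that("alternate locations keep the first-listed conformer", {
  at <- data.frame(name = c("N", "CA", "CA", "C", "O"), resseq = 1,
                   chain = "A", resname = "ALA",
                   x = c(0, 1, 5, 2, 3), y = 0, z = 0,
                   alt = c(" ", "A", "B", " ", " "))
  p <- read_membrane_pdb(tiny_pdb(at))
  ca <- p$atom[p$atom$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 1)
})

test_that("read/write round trip preserves coordinates and atom order", {
  fx <- make_helical_bundle(n_units = 7, ring_radius = 10)
  out <- write_annotated_pdb(fx$protein, labels = NULL)
  p2 <- read_membrane_pdb(out)
  expect_identical(p2$atom$name, fx$protein$atom$name)
  expect_identical(p2$atom$reskey, fx$protein$atom$reskey)
  expect_equal(ca_coords(p2), ca_coords(fx$protein), tolerance = 1e-3)
})

test_that("annotation writes 50.00/0.00 per residue and touches only columns 61-66", {
  fx <- make_helical_bundle(n_units = 3, ring_radius = 9)
  res <- fx$protein$residues$reskey
  lab <- setNames(rep(c("lipid_exposed", "buried"), length.out = length(res)), res)

  out_all <- write_annotated_pdb(fx$protein, setNames(rep("lipid_exposed", length(res)), res))
  atom_all <- out_all[startsWith(out_all, "ATOM")]
  expect_true(all(substr(atom_all, 61, 66) == " 50.00"))

  out_none <- write_annotated_pdb(fx$protein, NULL)
  expect_true(all(substr(out_none[startsWith(out_none, "ATOM")], 61, 66) == "  0.00"))

  out_mix <- write_annotated_pdb(fx$protein, lab)
  p2 <- read_membrane_pdb(out_mix)
  b_by_res <- tapply(p2$atom$b, p2$atom$reskey, unique)
  expect_true(all(lengths(b_by_res) == 1))   # all atoms of a residue share the value
  expect_equal(as.numeric(unlist(b_by_res[res])),
               as.numeric(ifelse(lab == "lipid_exposed", 50, 0)))

  # diff restricted to the B-factor column
  orig <- fx$protein$raw_lines
  expect_length(out_mix, length(orig))
  for (i in seq_along(orig)) {
    if (startsWith(orig[i], "ATOM")) {
      expect_identical(substr(out_mix[i], 1, 60), substr(orig[i], 1, 60))
      expect_identical(substr(out_mix[i], 67, nchar(orig[i])),
                       substr(orig[i], 67, nchar(orig[i])))
    } else {
      expect_identical(out_mix[i], orig[i])
    }
  }

  expect_error(write_annotated_pdb(fx$protein, c(`Z:999` = "lipid_exposed")),
               "unknown residue")
})

test_that("span files parse, enforce count consistency, and round trip", {
  txt <- c("TM span prediction", "2 120", "antiparallel", "n2c",
           "    5    29", "   40    64")
  s <- read_span_file(txt)
  expect_equal(n_spans(s), 2)
  expect_equal(s$start, c(5, 40))
  expect_equal(s$end, c(29, 64))

  expect_error(read_span_file(txt[-6]), "declares 2 spans but lists 1")
  bad <- txt; bad[5] <- "    5   abc"
  expect_error(read_span_file(bad), "non-numeric")

  rt <- read_span_file(write_span_file(s, n_res = 120))
  expect_equal(rt$start, s$start)
  expect_equal(rt$end, s$end)
})

test_that("span derivation finds crossings and ignores non-crossing helices", {
  single <- make_single_helix()
  expect_equal(n_spans(derive_spans(single$protein)), 1)

  hp <- read_membrane_pdb(hairpin_pdb())
  expect_equal(n_spans(derive_spans(hp)), 2)

  surf <- read_membrane_pdb(surface_helix_pdb())
  expect_equal(n_spans(derive_spans(surf)), 0)
})

test_that("span derivation is invariant under rotation about the membrane normal", {
  fx <- make_helical_bundle(n_units = 5, ring_radius = 10)
  s0 <- derive_spans(fx$protein)
  rot <- read_membrane_pdb(rotate_pdb_z(fx$pdb, 73))
  s1 <- derive_spans(rot)
  expect_equal(as.data.frame(s0), as.data.frame(s1))
})

test_that("the coloring script is static and names both B-factor values", {
  a <- write_color_script()
  b <- write_color_script()
  expect_identical(a, b)
  expect_true(any(grepl("50", a)))
  expect_true(any(grepl("\\b0\\b", a)))
})

test_that("coordinate parsing agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  fx <- make_beta_barrel(n_units = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(fx$pdb, f)
  ref <- bio3d::read.pdb(f)
  ref_ca <- ref$atom[ref$atom$elety == "CA", c("x", "y", "z")]
  expect_equal(unname(as.matrix(ref_ca)), unname(ca_coords(fx$protein)),
               tolerance = 1e-6)
})
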