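test_that("PDB fixture parses with header metadata and hetero inventory", {
  m <- read_structure(write_tiny_pdb())
  rt <- residue_table(m)
  expect_s3_class(m, "StructureModel")
  expect_equal(nrow(rt), 2L)
  expect_equal(unique(rt$chain), "A")
  expect_equal(structure_sequence(m, "A"), "GA")
  expect_equal(m$resolution, 1.8)
  expect_match(m$experimental_method, "X-RAY")
  expect_equal(unique(m$hetero$resid), "HOH")  # kept, not dropped
})

test_that("mmCIF reader reproduces the PDB content", {
  mp <- read_structure(write_tiny_pdb())
  mc <- read_structure(write_tiny_cif())
  expect_equal(structure_sequence(mc, "A"), "GA")
  expect_equal(mc$resolution, 1.8)
  expect_equal(mc$atoms[, c("x", "y", "z")], mp$atoms[, c("x", "y", "z")],
               tolerance = 1e-6)
  expect_equal(nrow(mc$hetero), 1L)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  lines <- tiny_pdb_lines()
  ca <- grep("CA  GLY", lines)
  lines[ca] <- "ATOM      2  CA AGLY A   1       1.458   0.000   0.000  0.60 10.00           C"
  lines <- append(lines,
    "ATOM      2  CA BGLY A   1       9.999   0.000   0.000  0.40 10.00           C",
    after = ca)
  m <- read_structure(write_tiny_pdb(lines = lines))
  ca_row <- m$atoms[m$atoms$elety == "CA" & m$atoms$resno == 1, ]
  expect_equal(nrow(ca_row), 1L)
  expect_equal(ca_row$x, 1.458)       # altloc A (occ 0.60) retained
  # occupancy, not altloc letter, decides: B wins at 0.80
  lines[ca + 1] <- sub("0.40", "0.80", lines[ca + 1])
  mB <- read_structure(write_tiny_pdb(lines = lines))
  expect_equal(mB$atoms$x[mB$atoms$elety == "CA" & mB$atoms$resno == 1], 9.999)
  # tie in occupancy: first in file wins
  lines[ca + 1] <- sub("0.80", "0.60", lines[ca + 1])
  m2 <- read_structure(write_tiny_pdb(lines = lines))
  expect_equal(m2$atoms$x[m2$atoms$elety == "CA" & m2$atoms$resno == 1], 1.458)
})

test_that("unreadable and empty inputs raise named errors", {
  expect_error(read_structure(tempfile()), "not found")
  only_water <- c(tiny_pdb_lines()[1:3],
                  grep("^HETATM", tiny_pdb_lines(), value = TRUE), "END")
  expect_error(read_structure(write_tiny_pdb(lines = only_water)),
               "empty model")
})

test_that("molecular weight matches the residue-mass oracle and is additive", {
  # oracle: sum of published average residue masses + one water
  expect_equal(molecular_weight("G"), (57.0519 + 18.0153) / 1000,
               tolerance = 1e-9)
  expect_equal(molecular_weight(strrep("A", 10)),
               (10 * 71.0788 + 18.0153) / 1000, tolerance = 1e-9)
  expect_error(molecular_weight(""), "non-empty")
  expect_error(molecular_weight("AZB"), "non-standard")
  s1 <- "ACDEFGHIK"; s2 <- "LMNPQRSTVWY"
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) -
                 scaffpatch:::WATER_MASS / 1000, tolerance = 1e-12)
})

test_that("candidate filter applies the published bounds with strictness", {
  good <- synthetic_structure(120, seed = 7, resolution = 2.0)  # ~14 kDa
  v <- candidate_filter(good)
  expect_true(v$passed)
  expect_identical(v$reasons, character(0))
  expect_true(all(c("molecular_weight_kda", "resolution", "chain_count",
                    "cysteine_count") %in% names(v$metrics)))

  big <- synthetic_structure(260, seed = 7, resolution = 2.0)   # ~30 kDa
  expect_false(candidate_filter(big)$passed)
  expect_true("molecular_weight" %in% candidate_filter(big)$reasons)

  low_res <- synthetic_structure(120, seed = 7, resolution = 3.5)
  expect_true("resolution" %in% candidate_filter(low_res)$reasons)
  at_bound <- synthetic_structure(120, seed = 7, resolution = 3.0)
  expect_true("resolution" %in% candidate_filter(at_bound)$reasons)  # strict <
  just_in <- synthetic_structure(120, seed = 7, resolution = 2.99)
  expect_false("resolution" %in% candidate_filter(just_in)$reasons)

  no_res <- synthetic_structure(120, seed = 7, resolution = NA)
  expect_true("resolution_unknown" %in% candidate_filter(no_res)$reasons)

  dimer <- good
  half <- dimer$atoms$resno > 60
  dimer$atoms$chain[half] <- "B"
  dimer$atoms$key <- scaffpatch:::residue_key(dimer$atoms$chain,
                                              dimer$atoms$resno)
  expect_true("oligomeric" %in% candidate_filter(dimer)$reasons)

  cys_seq <- paste0(strrep("A", 50), strrep("C", 3), strrep("L", 70))
  cys_model <- synthetic_structure(123, sequence = cys_seq, resolution = 2)
  expect_true("cysteine_count" %in% candidate_filter(cys_model)$reasons)

  # purity: same model + criteria give an identical verdict
  expect_identical(candidate_filter(good), candidate_filter(good))
})

test_that("annotated PDB writing puts scores in B-factors and round-trips", {
  m <- read_structure(write_tiny_pdb())
  out <- tempfile(fileext = ".pdb")
  write_annotated_structure(m, c("A:1" = 55), out)
  back <- bio3d::read.pdb(out, verbose = FALSE)
  b <- back$atom$b[back$atom$type == "ATOM"]
  expect_equal(unique(b[back$atom$resno[back$atom$type == "ATOM"] == 1]), 55)
  expect_equal(unique(b[back$atom$resno[back$atom$type == "ATOM"] == 2]), 0)
  m2 <- read_structure(out)
  expect_equal(m2$atoms[, c("x", "y", "z")], m$atoms[, c("x", "y", "z")],
               tolerance = 1e-3)
  expect_warning(write_annotated_structure(m, c("A:1" = 1234.5), out),
                 "clipped")
  b2 <- bio3d::read.pdb(out, verbose = FALSE)$atom$b
  expect_equal(max(b2), 999.99)
})
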