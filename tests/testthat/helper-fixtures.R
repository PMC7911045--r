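# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files these helpers write to
# tempdirs.

# Two-residue GLY-ALA PDB with full backbone, 1.80 A resolution header.
tiny_pdb_lines <- function() {
  c("HEADER    TEST PROTEIN                            01-JAN-20   TST1",
    "REMARK   2 RESOLUTION. 1.80 ANGSTROMS.",
    "EXPDTA    X-RAY DIFFRACTION",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 10.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00 10.00           O",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00 10.00           N",
    "ATOM      6  CA  ALA A   2       3.988   2.839   0.000  1.00 10.00           C",
    "ATOM      7  C   ALA A   2       5.504   2.693   0.000  1.00 10.00           C",
    "ATOM      8  O   ALA A   2       6.030   1.580   0.000  1.00 10.00           O",
    "ATOM      9  CB  ALA A   2       3.580   3.650   1.230  1.00 10.00           C",
    "HETATM   10  O   HOH A 101       8.000   8.000   8.000  1.00 20.00           O",
    "END")
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"),
                           lines = tiny_pdb_lines()) {
  writeLines(lines, path)
  path
}

# Same two residues in minimal mmCIF form.
write_tiny_cif <- function(path = tempfile(fileext = ".cif")) {
  atoms <- tiny_pdb_lines()
  atoms <- atoms[grepl("^(ATOM|HETATM)", atoms)]
  rows <- vapply(atoms, function(l) {
    sprintf("%s %s %s %s A %s ? %s %s %s 1.00 %s",
            trimws(substr(l, 1, 6)), trimws(substr(l, 77, 78)),
            trimws(substr(l, 13, 16)), trimws(substr(l, 18, 20)),
            trimws(substr(l, 23, 26)), trimws(substr(l, 31, 38)),
            trimws(substr(l, 39, 46)), trimws(substr(l, 47, 54)),
            trimws(substr(l, 61, 66)))
  }, "", USE.NAMES = FALSE)
  writeLines(c(
    "data_TST1",
    "_entry.id TST1",
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_d_res_high 1.80",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    rows, "#"), path)
  path
}

# StructureModel with one representative point per residue at the given
# coordinates (CA atoms, carbon), author numbers 1..n on chain A.
point_model <- function(coords, aa = NULL, chain = "A") {
  n <- nrow(coords)
  aa <- aa %||% rep("A", n)
  atoms <- data.frame(
    chain = chain, resno = seq_len(n), ins = "",
    resid = unname(scaffpatch:::AA3[aa]), elety = "CA", element = "C",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occ = 1, type = "ATOM", stringsAsFactors = FALSE)
  scaffpatch:::new_structure_model("PTS", atoms, atoms[0, , drop = FALSE],
                                   NA_real_, NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

residue_key_vec <- function(m) residue_table(m)$key

with_seed_local <- function(seed, expr) scaffpatch:::with_seed(seed, expr)

# Hand-rolled residue-profile table for patch tests.
make_profiles <- function(keys, mutability, conservation = 50,
                          surface = TRUE) {
  kp <- scaffpatch:::key_parts(keys)
  data.frame(key = keys, chain = kp$chain, seq_num = kp$seq_num, aa = "A",
             sasa = 100, rsasa = 0.5,
             surface = rep_len(surface, length(keys)),
             conservation = rep_len(conservation, length(keys)),
             mutability = rep_len(mutability, length(keys)),
             stringsAsFactors = FALSE)
}

# Independent quaternion-based RMSD oracle (Horn 1987): the optimal
# superposition RMSD follows from the largest eigenvalue of the 4x4
# quaternion matrix built from the cross-covariance. No SVD, no Kabsch.
horn_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  M <- t(Bc) %*% Ac
  S <- c(sum(Ac^2), sum(Bc^2))
  N <- matrix(0, 4, 4)
  N[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  N[1, 2] <- N[2, 1] <- M[2, 3] - M[3, 2]
  N[1, 3] <- N[3, 1] <- M[3, 1] - M[1, 3]
  N[1, 4] <- N[4, 1] <- M[1, 2] - M[2, 1]
  N[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  N[2, 3] <- N[3, 2] <- M[1, 2] + M[2, 1]
  N[2, 4] <- N[4, 2] <- M[3, 1] + M[1, 3]
  N[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  N[3, 4] <- N[4, 3] <- M[2, 3] + M[3, 2]
  N[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(S) - 2 * lambda)) / nrow(A))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
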