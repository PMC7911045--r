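# Seeded synthetic-data generators with planted ground truth: an ideal
# alpha-helical backbone trace, alignments with controlled per-column
# substitution rates, and ddG matrices with designated mutable positions.
# Every stage of the pipeline can therefore be exercised end-to-end, offline,
# against known answers. All randomness goes through an explicit seed; the
# caller's RNG state is never touched.

#' Synthetic alpha-helical structure
#'
#' Generates an ideal helical C-alpha trace (rise 1.5 A per residue, radius
#' 2.3 A, 100 degrees per residue) with a pseudo-C-beta placed 1.5 A radially
#' outward from each C-alpha. With only two atoms per residue on an exposed
#' helix, every residue is solvent-exposed by construction. Residue types are
#' drawn uniformly from the 18 standard amino acids excluding Gly and Cys
#' (so each residue has a C-beta and the cysteine filter is untouched) unless
#' a sequence is supplied.
#'
#' @param n_residues Number of residues (>= 5).
#' @param seed RNG seed for the residue sequence.
#' @param sequence Optional one-letter sequence overriding the random one.
#' @param resolution Nominal resolution stamped on the model (default 1.5 A,
#'   marking it as a usable high-resolution entry for the candidate filter).
#' @return A \code{StructureModel} with chain \code{"A"}, residues numbered
#'   from 1.
#' @export
synthetic_structure <- function(n_residues, seed = 1,
                                sequence = NULL, resolution = 1.5) {
  if (n_residues < 5) stop("n_residues must be >= 5", call. = FALSE)
  aa_pool <- setdiff(AA1, c("G", "C"))
  aa <- if (is.null(sequence)) {
    with_seed(seed, sample(aa_pool, n_residues, replace = TRUE))
  } else {
    assert_aa_string(sequence, "sequence")
  }
  if (length(aa) != n_residues)
    stop("sequence length must equal n_residues", call. = FALSE)
  i <- seq_len(n_residues) - 1L
  theta <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
  cb <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * i)
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(n_residues), each = 2L),
    ins = "",
    resid = rep(AA3[aa], each = 2L),
    elety = rep(c("CA", "CB"), n_residues),
    element = "C",
    x = as.vector(rbind(ca[, 1], cb[, 1])),
    y = as.vector(rbind(ca[, 2], cb[, 2])),
    z = as.vector(rbind(ca[, 3], cb[, 3])),
    occ = 1, type = "ATOM", stringsAsFactors = FALSE)
  new_structure_model("SYNT", atoms,
                      atoms[0, , drop = FALSE], resolution, "SYNTHETIC")
}

#' Synthetic multiple sequence alignment
#'
#' The reference record is the given sequence; every other record mutates
#' each column independently with that column's substitution probability to
#' a uniformly chosen different residue. Expected conservation at a column
#' is therefore 100 x (1 - sub_prob) as the number of records grows.
#'
#' @param ref_sequence Reference (scaffold) sequence, one-letter.
#' @param n_seqs Total records including the reference (>= 2).
#' @param sub_prob Per-column substitution probability: scalar or vector of
#'   length nchar(ref_sequence).
#' @param seed RNG seed.
#' @return An \code{Alignment} with the reference first (\code{ref_index} 1).
#' @export
synthetic_msa <- function(ref_sequence, n_seqs, sub_prob, seed = 1) {
  letters1 <- assert_aa_string(ref_sequence, "ref_sequence")
  if (n_seqs < 2) stop("n_seqs must be >= 2", call. = FALSE)
  L <- length(letters1)
  p <- rep_len(sub_prob, L)
  if (any(p < 0 | p > 1)) stop("sub_prob must lie in [0, 1]", call. = FALSE)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_seqs - 1L), function(.) {
      s <- letters1
      hit <- stats::runif(L) < p
      if (any(hit))
        s[hit] <- vapply(s[hit], function(a)
          sample(setdiff(AA1, a), 1L), "")
      paste(s, collapse = "")
    }, "")
  })
  new_alignment(c("ref", sprintf("hom_%03d", seq_len(n_seqs - 1L))),
                c(ref_sequence, seqs), ref_id = "ref")
}

#' Synthetic ddG matrix with planted mutable positions
#'
#' Planted positions receive at least 14 of 20 substitution ddG values below
#' 0.5 kcal/mol (mutability score > 50% guaranteed, enforced after drawing);
#' all other positions receive at most 8 below (score <= 40%). The self
#' substitution is always exactly 0.
#'
#' @param sequence Wild-type one-letter sequence (defines wt_aa per position).
#' @param planted_mutable Integer positions (1-based) designated mutable.
#' @param seed RNG seed.
#' @param chain Chain id for the residue keys (default \code{"A"}).
#' @return A \code{DdgMatrix} with \code{source = "surrogate"}.
#' @export
synthetic_ddg <- function(sequence, planted_mutable, seed = 1, chain = "A") {
  letters1 <- assert_aa_string(sequence, "sequence")
  L <- length(letters1)
  planted_mutable <- as.integer(planted_mutable)
  if (any(planted_mutable < 1L | planted_mutable > L))
    stop("planted_mutable outside the sequence", call. = FALSE)
  mat <- with_seed(seed, {
    m <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA1))
    for (pos in seq_len(L)) {
      n_low <- if (pos %in% planted_mutable) sample(14:18, 1L)
               else sample(2:8, 1L)
      low <- stats::runif(n_low, -1.5, 0.45)
      high <- stats::runif(20L - n_low, 0.8, 3.0)
      vals <- sample(c(low, high))
      m[pos, ] <- vals
      m[pos, letters1[pos]] <- 0   # self; slot already counted in n_low
    }
    m
  })
  # enforce the planted contract post-draw (self overwrite can shift counts)
  for (pos in seq_len(L)) {
    n_below <- sum(mat[pos, ] < 0.5)
    target_ok <- if (pos %in% planted_mutable) n_below >= 14 else n_below <= 8
    if (!target_ok) {
      others <- setdiff(AA1, letters1[pos])
      if (pos %in% planted_mutable) {
        fix <- others[mat[pos, others] >= 0.5]
        mat[pos, fix[seq_len(14 - n_below)]] <- 0.2
      } else {
        fix <- others[mat[pos, others] < 0.5]
        mat[pos, fix[seq_len(n_below - 8)]] <- 1.5
      }
    }
  }
  keys <- data.frame(chain = chain, seq_num = seq_len(L), wt_aa = letters1,
                     stringsAsFactors = FALSE)
  new_ddg_matrix(keys, mat, source = "surrogate")
}

#' Write a ddG matrix in position-scan TSV dialect
#'
#' @param ddg A \code{DdgMatrix}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_positionscan <- function(ddg, path) {
  stopifnot(inherits(ddg, "DdgMatrix"))
  rows <- do.call(rbind, lapply(seq_len(nrow(ddg$ddg)), function(i) {
    k <- ddg$keys[i, ]
    data.frame(position = paste0(k$wt_aa, k$chain, k$seq_num),
               mutant = AA1, ddG = unname(ddg$ddg[i, AA1]),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An \code{Alignment}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "Alignment"))
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$seqs)), path)
  invisible(path)
}

#' Generate a complete on-disk fixture bundle
#'
#' Writes a synthetic structure (PDB), an MSA (aligned FASTA) whose planted
#' columns evolve fast (low conservation) while the rest stay near-invariant,
#' a position-scan ddG table with the planted positions mutable, and a YAML
#' pipeline config wiring them together. The planted residue set is the
#' ground-truth mutable surface patch.
#'
#' @param dir Output directory (created if needed).
#' @param n_residues Structure length (default 60).
#' @param planted Planted patch positions (default 20:29, a spatially
#'   contiguous helical stretch).
#' @param seed RNG seed driving structure sequence, MSA and ddG.
#' @param n_seqs MSA depth (default 50).
#' @return List of paths (\code{structure}, \code{msa}, \code{ddg},
#'   \code{config}) plus \code{planted_keys}, the ground-truth residue keys.
#' @export
fixture_bundle <- function(dir, n_residues = 60, planted = 20:29, seed = 1,
                           n_seqs = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- synthetic_structure(n_residues, seed = seed)
  seqs <- structure_sequence(model, "A")
  sub_prob <- rep(0.02, n_residues)
  sub_prob[planted] <- 0.5
  msa <- synthetic_msa(seqs, n_seqs = n_seqs, sub_prob = sub_prob,
                       seed = seed + 1L)
  ddg <- synthetic_ddg(seqs, planted_mutable = planted, seed = seed + 2L)
  paths <- list(structure = file.path(dir, "structure.pdb"),
                msa = file.path(dir, "msa.fasta"),
                ddg = file.path(dir, "ddg.tsv"),
                config = file.path(dir, "config.yaml"))
  write_annotated_structure(model, numeric(0), paths$structure)
  write_alignment_fasta(msa, paths$msa)
  write_positionscan(ddg, paths$ddg)
  cfg <- list(structure = paths$structure, msa = paths$msa, ddg = paths$ddg,
              ref_id = "ref", out_dir = file.path(dir, "out"), seed = seed)
  yaml::write_yaml(cfg, paths$config)
  paths$planted_keys <- residue_key("A", planted)
  paths
}
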