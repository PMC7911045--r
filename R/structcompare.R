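# Rigid-body superposition of a variant structure onto its parent scaffold,
# reporting C-alpha RMSD to verify fold retention after mutagenesis.
#
# Pairing defaults to sequence alignment rather than residue numbers:
# evolved variants carry mutations, and number matching can silently
# misalign renumbered entries. The Kabsch rotation is reflection-corrected,
# so the returned matrix is always a proper rotation (det = +1).

#' Pair residues between two structures
#'
#' @param modelA,modelB \code{StructureModel} objects.
#' @param chainA,chainB Chain ids (default: first chain of each model).
#' @param method \code{"seq_align"} (global Needleman-Wunsch on the chain
#'   sequences; aligned residue pairs with C-alpha in both are kept) or
#'   \code{"by_number"} (match author numbering).
#' @param min_identity Abort if the alignment identity falls below this
#'   percentage (default 20; unrelated sequences do not superpose
#'   meaningfully).
#' @return A \code{ResiduePairing}: list with \code{pairs} (data frame
#'   \code{key_a}, \code{key_b}), \code{method}, \code{identity} (percent).
#' @export
pair_residues <- function(modelA, modelB, chainA = NULL, chainB = NULL,
                          method = c("seq_align", "by_number"),
                          min_identity = 20) {
  method <- match.arg(method)
  rtA <- residue_table(modelA); rtB <- residue_table(modelB)
  chainA <- chainA %||% rtA$chain[1]; chainB <- chainB %||% rtB$chain[1]
  rtA <- rtA[rtA$chain == chainA, , drop = FALSE]
  rtB <- rtB[rtB$chain == chainB, , drop = FALSE]
  hasCA_A <- rtA$key %in% modelA$atoms$key[modelA$atoms$elety == "CA"]
  hasCA_B <- rtB$key %in% modelB$atoms$key[modelB$atoms$elety == "CA"]
  if (method == "by_number") {
    common <- intersect(rtA$seq_num[hasCA_A], rtB$seq_num[hasCA_B])
    pairs <- data.frame(
      key_a = rtA$key[match(common, rtA$seq_num)],
      key_b = rtB$key[match(common, rtB$seq_num)], stringsAsFactors = FALSE)
    identity <- if (nrow(pairs))
      100 * mean(rtA$aa[match(common, rtA$seq_num)] ==
                 rtB$aa[match(common, rtB$seq_num)]) else 0
  } else {
    ga <- global_alignment(paste(rtA$aa, collapse = ""),
                           paste(rtB$aa, collapse = ""))
    identity <- ga$identity
    p <- ga$pairs
    keep <- hasCA_A[p$ref_pos] & hasCA_B[p$sub_pos]
    pairs <- data.frame(key_a = rtA$key[p$ref_pos[keep]],
                        key_b = rtB$key[p$sub_pos[keep]],
                        stringsAsFactors = FALSE)
  }
  if (identity < min_identity)
    stop(sprintf("chain sequences align at %.1f%% identity (< %.0f%%); %s",
                 identity, min_identity,
                 "structures look unrelated"), call. = FALSE)
  if (nrow(pairs) < 3L)
    stop("fewer than 3 usable residue pairs", call. = FALSE)
  structure(list(pairs = pairs, method = method, identity = identity),
            class = "ResiduePairing")
}

#' @keywords internal
ca_coords <- function(model, keys) {
  at <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  idx <- match(keys, at$key)
  if (anyNA(idx)) stop("missing C-alpha for ",
                       paste(keys[is.na(idx)], collapse = ", "), call. = FALSE)
  as.matrix(at[idx, c("x", "y", "z")])
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' \code{R \%*\% b + t} against the matched points of A. A reflection in the
#' raw SVD solution is corrected by flipping the smallest singular
#' direction, so \code{det(rotation) = +1} always holds, including for
#' mirror-image inputs.
#'
#' @param coordsA,coordsB Matched n x 3 coordinate matrices (n >= 3,
#'   not all collinear).
#' @return A \code{Superposition}: list with \code{rotation} (3 x 3),
#'   \code{translation} (length 3), \code{rmsd} (Angstrom), \code{n_atoms}.
#'   The transform maps B onto A: \code{t(rotation \%*\% t(coordsB)) +
#'   translation}.
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || ncol(coordsA) != 3 ||
      ncol(coordsB) != 3)
    stop("coordinate sets must be matched n x 3 matrices", call. = FALSE)
  n <- nrow(coordsA)
  if (n < 3) stop("need at least 3 matched points", call. = FALSE)
  cenA <- colMeans(coordsA); cenB <- colMeans(coordsB)
  Ac <- sweep(coordsA, 2, cenA); Bc <- sweep(coordsB, 2, cenB)
  sv_check <- svd(Ac)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1))
    stop("degenerate geometry: points are collinear", call. = FALSE)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Brot <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Brot - Ac)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cenA - R %*% cenB),
                 rmsd = rmsd, n_atoms = n),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD %.3f A over %d atoms (det R = %+.0f)\n",
              x$rmsd, x$n_atoms, det(x$rotation)))
  invisible(x)
}

#' Superpose a variant structure onto its parent
#'
#' Pairs residues (sequence alignment by default), extracts the common
#' C-alpha set and runs the Kabsch superposition.
#'
#' @param modelA Parent \code{StructureModel} (reference frame).
#' @param modelB Variant \code{StructureModel} (moved).
#' @param ... Passed to \code{\link{pair_residues}}.
#' @return A \code{Superposition} with the pairing attached as attribute
#'   \code{"pairing"}.
#' @export
superpose_models <- function(modelA, modelB, ...) {
  pairing <- pair_residues(modelA, modelB, ...)
  sup <- kabsch_superpose(ca_coords(modelA, pairing$pairs$key_a),
                          ca_coords(modelB, pairing$pairs$key_b))
  attr(sup, "pairing") <- pairing
  sup
}

#' Compare a variant structure file to its parent scaffold
#'
#' Convenience wrapper: reads both files, superposes the variant onto the
#' parent over the common C-alpha set and reports the RMSD, atom count and
#' alignment identity. Used to verify that an evolved variant retains the
#' parent fold.
#'
#' @param parent_path,variant_path Structure files (PDB or mmCIF).
#' @param ... Passed to \code{\link{superpose_models}}.
#' @return List with \code{rmsd}, \code{n_atoms}, \code{identity},
#'   \code{superposition}.
#' @export
compare_to_parent <- function(parent_path, variant_path, ...) {
  parent <- read_structure(parent_path)
  variant <- read_structure(variant_path)
  sup <- superpose_models(parent, variant, ...)
  list(rmsd = sup$rmsd, n_atoms = sup$n_atoms,
       identity = attr(sup, "pairing")$identity,
       superposition = sup)
}

#' Write a superposition as JSON
#'
#' @param sup A \code{Superposition}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_superposition_json <- function(sup, path) {
  jsonlite::write_json(list(rotation = sup$rotation,
                            translation = sup$translation,
                            rmsd = sup$rmsd, n_atoms = sup$n_atoms),
                       path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
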