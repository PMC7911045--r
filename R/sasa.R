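# Solvent-accessible surface area by the Shrake-Rupley numerical method.
# Sphere points come from a deterministic golden-spiral lattice, so results
# are bit-stable across runs and platforms (no RNG involved).

#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  theta <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points are placed on a sphere of radius
#' (van der Waals radius + probe radius); the accessible fraction is the
#' share of points not buried inside any neighbouring atom's expanded sphere.
#' Hydrogens are excluded by default (most X-ray entries lack them).
#'
#' @param model A \code{StructureModel}.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere points per atom (>= 24); accuracy improves roughly
#'   as 1/n.
#' @param include_hydrogens Include H atoms in the calculation.
#' @return Numeric vector of per-atom areas (Angstrom^2), with the atom's
#'   residue key as names.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960,
                         include_hydrogens = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  if (n_points < 24) stop("n_points must be >= 24", call. = FALSE)
  at <- model$atoms
  if (!include_hydrogens) at <- at[at$element != "H", , drop = FALSE]
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    stop("atoms with missing coordinates", call. = FALSE)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- vdw_radius(at$element)
  sasa_points(xyz, radii, probe_radius, n_points, at$key)
}

#' @keywords internal
vdw_radius <- function(elements) {
  r <- VDW_RADII[elements]
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(elements[is.na(r)]), collapse = ", "),
            "; using fallback van der Waals radius ", VDW_FALLBACK, " A")
    r[is.na(r)] <- VDW_FALLBACK
  }
  unname(r)
}

# Core numerical kernel, shared by compute_sasa and tests on raw coordinates.
#' @keywords internal
sasa_points <- function(xyz, radii, probe_radius = 1.4, n_points = 960,
                        keys = NULL) {
  n <- nrow(xyz)
  sphere <- golden_spiral_points(n_points)
  ext <- radii + probe_radius
  out <- numeric(n)
  # neighbour lists from the pairwise distance matrix (fine for protein-sized
  # inputs; the contact cutoff is the sum of expanded radii)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cut2 <- (ext[i] + ext)^2
    nb <- which(d2[i, ] < cut2 & seq_len(n) != i)
    if (!length(nb)) { out[i] <- 4 * pi * ext[i]^2; next }
    pts <- sphere * ext[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    centres <- xyz[nb, , drop = FALSE]
    pd2 <- outer(rowSums(pts^2), rowSums(centres^2), "+") -
      2 * pts %*% t(centres)
    thr2 <- matrix(ext[nb]^2, nrow = n_points, ncol = length(nb), byrow = TRUE)
    accessible <- rowSums(pd2 < thr2) == 0L
    out[i] <- 4 * pi * ext[i]^2 * mean(accessible)
  }
  if (!is.null(keys)) names(out) <- keys
  out
}

#' Aggregate atom SASA to residues
#'
#' @param model A \code{StructureModel}.
#' @param atom_sasa Output of \code{\link{compute_sasa}}.
#' @return Named numeric vector: residue key -> SASA (Angstrom^2). Residues
#'   whose atoms were all excluded (e.g. hydrogens only) get 0.
#' @export
residue_sasa <- function(model, atom_sasa) {
  rt <- residue_table(model)
  agg <- tapply(atom_sasa, names(atom_sasa), sum)
  out <- stats::setNames(rep(0, nrow(rt)), rt$key)
  out[names(agg)] <- agg
  out
}

#' Relative solvent accessibility and surface classification
#'
#' Divides each residue's SASA by its residue type's theoretical maximum
#' (Tien et al. 2013 theoretical values, embedded as package data). A residue
#' is classified as surface when its relative SASA reaches \code{threshold}.
#' Relative values slightly above 1 occur for extended conformations and are
#' reported as computed.
#'
#' @param model A \code{StructureModel}.
#' @param res_sasa Named vector from \code{\link{residue_sasa}}.
#' @param threshold Relative-SASA surface cutoff (default 0.25).
#' @return Data frame: \code{key}, \code{chain}, \code{seq_num}, \code{ins},
#'   \code{aa}, \code{sasa}, \code{rsasa}, \code{surface}.
#' @export
relative_sasa <- function(model, res_sasa, threshold = 0.25) {
  rt <- residue_table(model)
  maxasa <- MAX_ASA[rt$aa]
  if (anyNA(maxasa)) {
    warning("residue type(s) without a max-ASA entry (",
            paste(unique(rt$aa[is.na(maxasa)]), collapse = ", "),
            "); using the table mean")
    maxasa[is.na(maxasa)] <- mean(MAX_ASA)
  }
  sasa <- unname(res_sasa[rt$key])
  sasa[is.na(sasa)] <- 0
  rsasa <- sasa / unname(maxasa)
  data.frame(key = rt$key, chain = rt$chain, seq_num = rt$seq_num,
             ins = rt$ins, aa = rt$aa, sasa = sasa, rsasa = rsasa,
             surface = rsasa >= threshold, stringsAsFactors = FALSE)
}
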