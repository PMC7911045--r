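# Grouping mutable surface residues into spatially contiguous patches,
# completing undersized patches from neighbouring surface residues, and
# assessing pairwise patch independence.
#
# Residues are represented by their C-beta atom (C-alpha for glycine or when
# C-beta is missing), the usual side-chain-direction proxy. Patches are the
# connected components of the contact graph at the chosen distance cutoff:
# the simplest faithful reading of "continuous surface regions". Components
# larger than the target window are flagged, never truncated.

#' Representative point per residue (C-beta, else C-alpha)
#'
#' @param model A \code{StructureModel}.
#' @param residues Character vector of residue keys.
#' @return Matrix of coordinates (rows named by residue key).
#' @export
representative_points <- function(model, residues) {
  at <- model$atoms
  out <- matrix(NA_real_, length(residues), 3,
                dimnames = list(residues, c("x", "y", "z")))
  for (i in seq_along(residues)) {
    ra <- at[at$key == residues[i], , drop = FALSE]
    if (!nrow(ra)) stop("residue ", residues[i], " not in model", call. = FALSE)
    row <- ra[ra$elety == "CB", , drop = FALSE]
    if (!nrow(row)) row <- ra[ra$elety == "CA", , drop = FALSE]
    if (!nrow(row))
      stop("residue ", residues[i], " has neither CB nor CA", call. = FALSE)
    out[i, ] <- as.numeric(row[1, c("x", "y", "z")])
  }
  out
}

#' Build the residue contact graph
#'
#' Edge between two residues iff the Euclidean distance between their
#' representative points is at most \code{cutoff}.
#'
#' @param model A \code{StructureModel}.
#' @param residues Residue keys to include as nodes.
#' @param cutoff Contact distance in Angstrom (default 8.0).
#' @return A \code{ContactGraph}: list with \code{nodes}, \code{coords},
#'   \code{edges} (data frame \code{a}, \code{b}, \code{dist}), \code{cutoff}.
#' @export
build_contact_graph <- function(model, residues, cutoff = 8.0) {
  residues <- as.character(residues)
  coords <- representative_points(model, residues)
  n <- length(residues)
  edges <- data.frame(a = character(0), b = character(0), dist = numeric(0))
  if (n >= 2) {
    d <- as.matrix(stats::dist(coords))
    idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
    edges <- data.frame(a = residues[idx[, 1]], b = residues[idx[, 2]],
                        dist = d[idx], stringsAsFactors = FALSE)
  }
  structure(list(nodes = residues, coords = coords, edges = edges,
                 cutoff = cutoff),
            class = "ContactGraph")
}

#' @export
print.ContactGraph <- function(x, ...) {
  cat(sprintf("ContactGraph: %d nodes, %d edges (cutoff %.1f A)\n",
              length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' @keywords internal
new_surface_patch <- function(seed_members, completion_members, coords,
                              profiles = NULL, flags = character(0)) {
  members <- c(seed_members, completion_members)
  kp <- key_parts(members)
  mean_mut <- NA_real_
  if (!is.null(profiles)) {
    mut <- stats::setNames(profiles$mutability, profiles$key)[members]
    mean_mut <- mean(mut, na.rm = TRUE)
  }
  structure(list(
    seed_members = seed_members,
    completion_members = completion_members,
    size = length(members),
    mean_mutability = mean_mut,
    sequence_span = max(kp$seq_num) - min(kp$seq_num) + 1L,
    centroid = colMeans(coords[members, , drop = FALSE]),
    flags = flags),
    class = "SurfacePatch")
}

#' @export
print.SurfacePatch <- function(x, ...) {
  cat(sprintf("SurfacePatch: %d residue(s) (%d seed + %d completion)\n",
              x$size, length(x$seed_members), length(x$completion_members)))
  cat("  members:", paste(c(x$seed_members, x$completion_members),
                          collapse = " "), "\n")
  cat(sprintf("  mean mutability %.1f%% | sequence span %d | centroid (%.1f, %.1f, %.1f)\n",
              x$mean_mutability, x$sequence_span,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Find mutable surface patches as connected components
#'
#' Partitions the contact graph's nodes into connected components and returns
#' them as seed-only patches, ordered by size (descending), then mean
#' mutability (descending), then smallest author number (ascending).
#' Singleton components are retained and flagged \code{"singleton"}.
#'
#' @param graph A \code{ContactGraph} built on the mutable residue set.
#' @param profiles Optional \code{\link{residue_profiles}} data frame used for
#'   mean mutability in the ordering.
#' @return List of \code{SurfacePatch} objects (possibly empty).
#' @export
find_patches <- function(graph, profiles = NULL) {
  stopifnot(inherits(graph, "ContactGraph"))
  if (!length(graph$nodes)) return(list())
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)
  membership <- comp$membership[graph$nodes]
  patches <- lapply(split(graph$nodes, membership), function(members) {
    flags <- if (length(members) == 1L) "singleton" else character(0)
    new_surface_patch(members, character(0), graph$coords, profiles, flags)
  })
  min_seq <- vapply(patches,
                    function(p) min(key_parts(p$seed_members)$seq_num), 0L)
  mut <- vapply(patches, function(p) p$mean_mutability, 0)
  mut[is.na(mut)] <- -Inf
  ord <- order(-vapply(patches, function(p) p$size, 0L), -mut, min_seq)
  unname(patches[ord])
}

#' Complete an undersized patch with neighbouring surface residues
#'
#' While the patch is smaller than \code{target_min}, the surface residue
#' outside the patch that lies within \code{cutoff} of at least one member
#' and has the highest mutability score is added (ties: lower conservation,
#' then lower author number). Completion stops inside the
#' [\code{target_min}, \code{target_max}] window or when no eligible
#' neighbour remains (flag \code{"undersized"}). Patches already at or above
#' \code{target_min} return unchanged; larger than \code{target_max} gains
#' the flag \code{"oversized"} (truncation is a user decision).
#'
#' @param patch A \code{SurfacePatch}.
#' @param model A \code{StructureModel}.
#' @param profiles Data frame from \code{\link{residue_profiles}}; candidates
#'   are its surface residues.
#' @param target_min,target_max Patch size window (defaults 10 and 12).
#' @param cutoff Neighbour distance in Angstrom (default 8.0).
#' @return The completed \code{SurfacePatch} with provenance in
#'   \code{completion_members}.
#' @export
complete_patch <- function(patch, model, profiles, target_min = 10,
                           target_max = 12, cutoff = 8.0) {
  stopifnot(inherits(patch, "SurfacePatch"))
  members <- c(patch$seed_members, patch$completion_members)
  if (patch$size > target_max) {
    coords <- representative_points(model, members)
    return(new_surface_patch(patch$seed_members, patch$completion_members,
                             coords, profiles,
                             flags = union(patch$flags, "oversized")))
  }
  if (patch$size >= target_min) return(patch)
  pool <- profiles[profiles$surface & !is.na(profiles$mutability), ,
                   drop = FALSE]
  added <- character(0)
  flags <- setdiff(patch$flags, "undersized")
  repeat {
    if (length(members) >= target_min) break
    cand <- pool[!pool$key %in% members, , drop = FALSE]
    if (nrow(cand)) {
      pts <- representative_points(model, c(members, cand$key))
      d <- as.matrix(stats::dist(pts))
      near <- apply(d[-seq_along(members), seq_along(members),
                      drop = FALSE], 1, min) <= cutoff
      cand <- cand[near, , drop = FALSE]
    }
    if (!nrow(cand)) { flags <- c(flags, "undersized"); break }
    cons <- ifelse(is.na(cand$conservation), Inf, cand$conservation)
    pick <- cand$key[order(-cand$mutability, cons, cand$seq_num)][1]
    members <- c(members, pick)
    added <- c(added, pick)
  }
  coords <- representative_points(model, members)
  new_surface_patch(patch$seed_members,
                    c(patch$completion_members, added),
                    coords, profiles, flags = flags)
}

#' Pairwise patch independence report
#'
#' Two patches are independent iff their member sets are disjoint and the
#' minimum distance between their representative points exceeds
#' \code{min_separation}. Both facts are reported so either reading of
#' "independent" can be applied.
#'
#' @param patches List of \code{SurfacePatch} objects (>= 2).
#' @param model A \code{StructureModel}.
#' @param min_separation Minimum inter-patch distance in Angstrom (default 8).
#' @return Data frame: \code{patch_a}, \code{patch_b}, \code{disjoint},
#'   \code{min_dist}, \code{independent}.
#' @export
patch_independence <- function(patches, model, min_separation = 8.0) {
  if (length(patches) < 2L)
    stop("need at least two patches", call. = FALSE)
  all_members <- lapply(patches, function(p)
    c(p$seed_members, p$completion_members))
  pairs <- utils::combn(length(patches), 2)
  out <- data.frame(patch_a = pairs[1, ], patch_b = pairs[2, ],
                    disjoint = NA, min_dist = NA_real_, independent = NA)
  for (k in seq_len(ncol(pairs))) {
    ma <- all_members[[pairs[1, k]]]
    mb <- all_members[[pairs[2, k]]]
    disjoint <- !length(intersect(ma, mb))
    pa <- representative_points(model, ma)
    pb <- representative_points(model, mb)
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    mind <- sqrt(max(0, min(d2)))
    out$disjoint[k] <- disjoint
    out$min_dist[k] <- mind
    out$independent[k] <- disjoint && mind > min_separation
  }
  out
}

#' Patch report as a data frame
#'
#' @param patches List of \code{SurfacePatch} objects.
#' @return Data frame: \code{patch_id}, \code{residue} (chain:num), \code{role}
#'   (seed/completion), \code{mean_mutability}, \code{span}, \code{flags}.
#' @export
patch_report <- function(patches) {
  if (!length(patches)) return(data.frame())
  do.call(rbind, lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    members <- c(p$seed_members, p$completion_members)
    data.frame(patch_id = i, residue = members,
               role = rep(c("seed", "completion"),
                          c(length(p$seed_members),
                            length(p$completion_members))),
               mean_mutability = p$mean_mutability,
               span = p$sequence_span,
               flags = paste(p$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
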