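# Per-position evolutionary conservation from a multiple sequence alignment,
# and its transfer onto structure residues.
#
# The conservation statistic is the identity-to-reference fraction: the share
# of alignment records (reference included, gap-containing records included in
# the denominator) whose symbol at a column equals the reference symbol. This
# matches a selection gate phrased as "identity conservation"; column entropy
# is deliberately not the default. 'X' never matches anything, itself included.

ALN_ALPHABET <- c("-", "X", "A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V")

#' Read a multiple sequence alignment
#'
#' @param path Aligned FASTA or Clustal file.
#' @param format \code{"auto"} (detect by content), \code{"fasta"} or
#'   \code{"clustal"}.
#' @param ref_id Identifier of the scaffold's own (reference) record;
#'   defaults to the first record.
#' @return An \code{Alignment}: list with \code{ids}, \code{seqs} (upper-case
#'   aligned strings of equal length), \code{length}, \code{ref_index}.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           ref_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*>", first)) "fasta" else "clustal"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e) stop("alignment parse error: ",
                                             conditionMessage(e), call. = FALSE))
    ids <- names(set)
    seqs <- toupper(as.character(set))
  } else {
    parsed <- parse_clustal(path)
    ids <- parsed$ids
    seqs <- parsed$seqs
  }
  new_alignment(ids, seqs, ref_id)
}

# Clustal block format: a CLUSTAL header line, then blocks of
# "<id> <whitespace> <segment>" lines separated by blanks; conservation
# annotation lines (leading whitespace) are skipped. Segments per id are
# concatenated across blocks.
#' @keywords internal
parse_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    stop("alignment parse error: missing CLUSTAL header in ", path,
         call. = FALSE)
  body <- lines[-1]
  seqs <- list()
  order <- character(0)
  for (ln in body) {
    if (!nzchar(trimws(ln)) || grepl("^\\s", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*-]+)\\s*\\d*\\s*$", ln))[[1]]
    if (length(m) != 3L)
      stop("alignment parse error: unparseable Clustal line: ", ln,
           call. = FALSE)
    id <- m[2]; seg <- m[3]
    if (is.null(seqs[[id]])) { seqs[[id]] <- ""; order <- c(order, id) }
    seqs[[id]] <- paste0(seqs[[id]], seg)
  }
  if (!length(order))
    stop("alignment parse error: no sequence lines in ", path, call. = FALSE)
  list(ids = order, seqs = unlist(seqs[order], use.names = FALSE))
}

#' Build an alignment from in-memory sequences
#'
#' @param ids Record identifiers.
#' @param seqs Aligned sequences (equal length, letters + gaps).
#' @param ref_id Reference record id (default: first record).
#' @return An \code{Alignment}.
#' @export
new_alignment <- function(ids, seqs, ref_id = NULL) {
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length",
                                        call. = FALSE)
  if (length(seqs) < 2L) stop("alignment needs at least 2 records",
                              call. = FALSE)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: record lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 ALN_ALPHABET)
  if (length(bad))
    stop("alignment contains invalid symbols: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ref_index <- if (is.null(ref_id)) 1L else match(ref_id, ids)
  if (is.na(ref_index)) stop("reference id '", ref_id, "' not in alignment",
                             call. = FALSE)
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 length = unname(lens[1]), ref_index = ref_index),
            class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d records x %d columns (reference: %s)\n",
              length(x$ids), x$length, x$ids[x$ref_index]))
  invisible(x)
}

#' Remove duplicate alignment records
#'
#' Records with identical aligned strings are collapsed to a single
#' representative: the first occurrence, except that the reference record is
#' always the one kept for its own class.
#'
#' @param aln An \code{Alignment}.
#' @return Deduplicated \code{Alignment} with updated \code{ref_index}.
#' @export
dedupe <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  cls <- match(aln$seqs, unique(aln$seqs))
  keep <- !duplicated(cls)
  ref_cls <- cls[aln$ref_index]
  keep[cls == ref_cls] <- FALSE
  keep[aln$ref_index] <- TRUE
  if (sum(keep) == 1L)   # every record identical to the reference
    return(structure(list(ids = aln$ids[keep], seqs = aln$seqs[keep],
                          length = aln$length, ref_index = 1L),
                     class = "Alignment"))
  new_alignment(aln$ids[keep], aln$seqs[keep],
                ref_id = aln$ids[aln$ref_index])
}

#' Per-position conservation relative to the reference sequence
#'
#' For every column where the reference record has a residue, the
#' conservation percentage is 100 x (records matching the reference symbol) /
#' (total records). Gaps in non-reference records count as mismatches;
#' columns where the reference is gapped yield no entry. Positions are
#' numbered along the ungapped reference sequence (1-based).
#'
#' @param aln A deduplicated \code{Alignment}.
#' @return A \code{ConservationProfile}: list with \code{values} (named
#'   percentage vector, names = reference positions), \code{ref_aa},
#'   \code{ref_sequence} (ungapped), \code{n_sequences}.
#' @export
column_conservation <- function(aln) {
  stopifnot(inherits(aln, "Alignment"))
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  ref <- mat[aln$ref_index, ]
  res_cols <- which(ref != "-")
  n <- nrow(mat)
  pct <- vapply(res_cols, function(j) {
    r <- ref[j]
    if (r == "X") return(0)               # X never matches, itself included
    100 * sum(mat[, j] == r) / n
  }, 0)
  positions <- seq_along(res_cols)
  structure(list(values = stats::setNames(pct, positions),
                 ref_aa = stats::setNames(ref[res_cols], positions),
                 ref_sequence = paste(ref[res_cols], collapse = ""),
                 n_sequences = n),
            class = "ConservationProfile")
}

#' @export
print.ConservationProfile <- function(x, ...) {
  cat(sprintf("ConservationProfile: %d positions, %d sequences, mean %.1f%%\n",
              length(x$values), x$n_sequences, mean(x$values)))
  invisible(x)
}

#' Transfer a conservation profile onto structure residues
#'
#' The profile's reference sequence is globally aligned to the structure
#' chain's sequence (Needleman-Wunsch, BLOSUM62, affine gaps) and conservation
#' values are transferred through aligned pairs. Structure residues left
#' unaligned get no score. An alignment identity below \code{min_identity}
#' aborts: the MSA most likely belongs to a different protein.
#'
#' @param profile A \code{ConservationProfile}.
#' @param model A \code{StructureModel}.
#' @param chain Chain id (default: first chain).
#' @param min_identity Abort threshold on percent identity (default 50).
#' @return Named numeric vector residue key -> conservation percent, with
#'   attributes \code{identity} (percent) and \code{n_aligned}.
#' @export
map_to_structure <- function(profile, model, chain = NULL, min_identity = 50) {
  stopifnot(inherits(profile, "ConservationProfile"),
            inherits(model, "StructureModel"))
  rt <- residue_table(model)
  chain <- chain %||% rt$chain[1]
  rt <- rt[rt$chain == chain, , drop = FALSE]
  struct_seq <- paste(rt$aa, collapse = "")
  pa <- global_alignment(profile$ref_sequence, struct_seq)
  if (pa$identity < min_identity)
    stop(sprintf(paste0("reference/structure alignment identity %.1f%% is ",
                        "below %.0f%%; wrong MSA for this structure?"),
                 pa$identity, min_identity), call. = FALSE)
  out <- stats::setNames(rep(NA_real_, nrow(rt)), rt$key)
  vals <- profile$values[as.character(pa$pairs$ref_pos)]
  out[rt$key[pa$pairs$sub_pos]] <- unname(vals)
  out <- out[!is.na(out)]
  attr(out, "identity") <- pa$identity
  attr(out, "n_aligned") <- nrow(pa$pairs)
  out
}

# Global Needleman-Wunsch via Biostrings, returning aligned position pairs.
#' @keywords internal
global_alignment <- function(seq_a, seq_b) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  pa <- Biostrings::pairwiseAlignment(
    pattern = seq_a, subject = seq_b, type = "global",
    substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(ga != "-")
  ib <- cumsum(gb != "-")
  both <- ga != "-" & gb != "-"
  pairs <- data.frame(ref_pos = ia[both], sub_pos = ib[both],
                      ref_aa = ga[both], sub_aa = gb[both],
                      stringsAsFactors = FALSE)
  identity <- if (nrow(pairs)) 100 * mean(pairs$ref_aa == pairs$sub_aa) else 0
  list(pairs = pairs, identity = identity)
}

#' Write a conservation profile as a tab-separated table
#'
#' Columns: position, ref_aa, conservation_pct, n_seqs.
#'
#' @param profile A \code{ConservationProfile}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_conservation_tsv <- function(profile, path) {
  df <- data.frame(position = as.integer(names(profile$values)),
                   ref_aa = unname(profile$ref_aa),
                   conservation_pct = unname(profile$values),
                   n_seqs = profile$n_sequences)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
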