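#' Read a protein structure from PDB or mmCIF
#'
#' Parses a coordinate file into a \code{StructureModel}: polymer residues
#' (ATOM records) with per-atom coordinates, plus a separate non-polymer
#' inventory (waters, ligands, ions from HETATM records) which is kept, never
#' silently dropped. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order).
#'
#' @param path Path to a structure file.
#' @param format One of \code{"auto"}, \code{"pdb"}, \code{"mmcif"}.
#'   \code{"auto"} detects by extension, then by content.
#' @return A \code{StructureModel}: list with \code{entry_id}, \code{atoms}
#'   (polymer atom table), \code{hetero} (non-polymer inventory),
#'   \code{resolution} (Angstrom, \code{NA} if absent) and
#'   \code{experimental_method}.
#' @examples
#' pdb <- synthetic_structure(20, seed = 1)
#' tf <- tempfile(fileext = ".pdb")
#' write_annotated_structure(pdb, numeric(0), tf)
#' m <- read_structure(tf)
#' structure_sequence(m, "A")
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- detect_format(path)
  model <- switch(format,
    pdb = read_structure_pdb(path),
    mmcif = read_structure_mmcif(path))
  if (nrow(model$atoms) == 0L)
    stop("empty model: no polymer residues in ", path, call. = FALSE)
  model
}

#' @keywords internal
detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head_lines)) || any(grepl("^loop_", head_lines)))
    return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|REMARK)", head_lines)))
    return("pdb")
  stop("cannot detect structure format of ", path, call. = FALSE)
}

#' @keywords internal
new_structure_model <- function(entry_id, atoms, hetero, resolution, method) {
  atoms$aa <- unname(ifelse(atoms$resid %in% names(AA3_TO_1),
                            AA3_TO_1[atoms$resid], "X"))
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$ins)
  structure(list(entry_id = entry_id, atoms = atoms, hetero = hetero,
                 resolution = resolution, experimental_method = method),
            class = "StructureModel")
}

#' @keywords internal
read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  resolution <- parse_remark2_resolution(lines)
  method <- parse_expdta(lines)
  pdb <- tryCatch(suppressWarnings(
    bio3d::read.pdb(path, verbose = FALSE, multi = FALSE, rm.alt = FALSE)),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  at <- pdb$atom
  at$chain[is.na(at$chain)] <- "A"
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  df <- data.frame(
    chain = at$chain, resno = at$resno, ins = at$insert, resid = at$resid,
    elety = at$elety, element = toupper(at$elesy),
    x = at$x, y = at$y, z = at$z, occ = at$o,
    alt = ifelse(is.na(at$alt), "", at$alt),
    type = at$type, stringsAsFactors = FALSE)
  df$element[is.na(df$element) | df$element == ""] <-
    guess_element(df$elety[is.na(df$element) | df$element == ""])
  df <- resolve_altlocs(df)
  poly <- df[df$type == "ATOM", , drop = FALSE]
  het <- df[df$type != "ATOM", , drop = FALSE]
  entry_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) && nchar(hdr[1]) >= 66) {
    id <- trimws(substr(hdr[1], 63, 66))
    if (nchar(id) == 4L) entry_id <- id
  }
  new_structure_model(entry_id, poly, het, resolution, method)
}

#' @keywords internal
parse_remark2_resolution <- function(lines) {
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (!length(rl)) return(NA_real_)
  m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
  if (!length(m)) return(NA_real_)
  as.numeric(m)
}

#' @keywords internal
parse_expdta <- function(lines) {
  el <- grep("^EXPDTA", lines, value = TRUE)
  if (!length(el)) return(NA_character_)
  trimws(sub("^EXPDTA", "", el[1]))
}

# Atom-name based element fallback for files without element columns.
#' @keywords internal
guess_element <- function(elety) {
  e <- toupper(substr(trimws(elety), 1, 1))
  e[!e %in% names(VDW_RADII)] <- "C"
  e
}

# Keep one conformer per (chain, resno, ins, atom name): highest occupancy,
# ties by first occurrence in the file.
#' @keywords internal
resolve_altlocs <- function(df) {
  if (!any(df$alt != "")) { df$alt <- NULL; return(df) }
  id <- paste(df$chain, df$resno, df$ins, df$elety, sep = "\r")
  ord <- order(id, -df$occ, seq_len(nrow(df)))
  keep <- !duplicated(id[ord])
  out <- df[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out$alt <- NULL
  out
}

#' @keywords internal
read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  res <- cif_scalar(lines, c("_reflns.d_resolution_high",
                             "_refine.ls_d_res_high"))
  method <- cif_scalar(lines, "_exptl.method")
  entry <- cif_scalar(lines, "_entry.id") %||% NA_character_
  tab <- cif_atom_site(lines, path)
  df <- data.frame(
    chain = tab$auth_asym_id, resno = as.integer(tab$auth_seq_id),
    ins = ifelse(tab$ins %in% c("?", ".", NA), "", tab$ins),
    resid = tab$comp_id, elety = tab$atom_id,
    element = toupper(tab$type_symbol),
    x = as.numeric(tab$x), y = as.numeric(tab$y), z = as.numeric(tab$z),
    occ = as.numeric(tab$occ),
    alt = ifelse(tab$alt %in% c(".", "?", NA), "", tab$alt),
    type = tab$group, stringsAsFactors = FALSE)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z))
    stop("mmCIF parse error in ", path, ": non-numeric coordinates",
         call. = FALSE)
  df$occ[is.na(df$occ)] <- 1
  df <- resolve_altlocs(df)
  poly <- df[df$type == "ATOM", , drop = FALSE]
  het <- df[df$type != "ATOM", , drop = FALSE]
  id <- if (is.na(entry)) sub("\\.(cif|mmcif)$", "", basename(path)) else entry
  new_structure_model(id, poly, het,
                      if (is.null(res)) NA_real_ else as.numeric(res),
                      if (is.null(method)) NA_character_ else gsub("'", "", method))
}

#' @keywords internal
cif_scalar <- function(lines, keys) {
  for (key in keys) {
    hit <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
    if (length(hit)) {
      val <- trimws(sub(paste0("^", key, "\\s+"), "", hit[1]))
      if (!val %in% c("?", ".")) return(val)
    }
  }
  NULL
}

# Minimal _atom_site loop reader: whitespace-separated fields, no multi-line
# values (atom_site loops in deposited files satisfy this).
#' @keywords internal
cif_atom_site <- function(lines, path) {
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1L
    fields <- character(0)
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
      rows[[length(rows) + 1L]] <- scan(text = ln, what = "", quiet = TRUE)
      i <- i + 1L
    }
    if (!length(rows)) stop("mmCIF parse error in ", path,
                            ": empty _atom_site loop", call. = FALSE)
    nf <- length(fields)
    bad <- which(vapply(rows, length, 0L) != nf)
    if (length(bad))
      stop("mmCIF parse error in ", path, ": row ", bad[1],
           " of _atom_site has wrong field count", call. = FALSE)
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_atom_site\\.", "", fields)
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% colnames(m)) return(m[, nm])
      rep(NA_character_, nrow(m))
    }
    return(data.frame(
      group = pick("group_PDB"),
      atom_id = gsub('"', "", pick("auth_atom_id", "label_atom_id")),
      comp_id = pick("auth_comp_id", "label_comp_id"),
      auth_asym_id = pick("auth_asym_id", "label_asym_id"),
      auth_seq_id = pick("auth_seq_id", "label_seq_id"),
      ins = pick("pdbx_PDB_ins_code"),
      alt = pick("label_alt_id"),
      type_symbol = pick("type_symbol"),
      x = pick("Cartn_x"), y = pick("Cartn_y"), z = pick("Cartn_z"),
      occ = pick("occupancy"), stringsAsFactors = FALSE))
  }
  stop("mmCIF parse error in ", path, ": no _atom_site loop found",
       call. = FALSE)
}

#' Residue-level view of a structure
#'
#' @param model A \code{StructureModel}.
#' @return Data frame with one row per polymer residue, in file order:
#'   \code{key}, \code{chain}, \code{seq_num}, \code{ins}, \code{aa}.
#' @export
residue_table <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  first <- !duplicated(at$key)
  data.frame(key = at$key[first], chain = at$chain[first],
             seq_num = at$resno[first], ins = at$ins[first],
             aa = at$aa[first], stringsAsFactors = FALSE)
}

#' One-letter sequence of a chain
#'
#' @param model A \code{StructureModel}.
#' @param chain Chain identifier; defaults to the first chain.
#' @return One-letter amino-acid string (non-standard residues as \code{"X"}).
#' @export
structure_sequence <- function(model, chain = NULL) {
  rt <- residue_table(model)
  chain <- chain %||% rt$chain[1]
  paste(rt$aa[rt$chain == chain], collapse = "")
}

#' @keywords internal
structure_chains <- function(model) unique(model$atoms$chain)

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water, reported in kDa.
#'
#' @param sequence One-letter amino-acid string (20 standard letters).
#' @return Mass in kDa.
#' @examples
#' molecular_weight("G")  # 0.0750672 kDa
#' @export
molecular_weight <- function(sequence) {
  letters1 <- assert_aa_string(sequence)
  (sum(AA_RESIDUE_MASS[letters1]) + WATER_MASS) / 1000
}

#' Screen a structure against scaffold candidate criteria
#'
#' Applies the search rules used to shortlist scaffold candidates: molecular
#' weight within 10--25 kDa (inclusive), X-ray resolution strictly below
#' 3.0 Angstrom, a single polymer chain of at least 50 residues (monomer in
#' the coordinate file; biological-assembly records are not expanded), and at
#' most \code{max_cys} cysteines. Non-computable curation rules (toxicity,
#' immunogenicity, literature solubility) can be carried as free-text notes in
#' \code{criteria$notes}; they are echoed in the verdict, never evaluated.
#'
#' @param model A \code{StructureModel}.
#' @param criteria Optional list overriding \code{mw_min}, \code{mw_max} (kDa),
#'   \code{res_max} (Angstrom), \code{max_cys}, \code{min_chain_res},
#'   \code{notes}.
#' @return A \code{FilterVerdict}: list with \code{passed}, \code{reasons}
#'   (labels of violated rules) and \code{metrics} (every evaluated value).
#' @export
candidate_filter <- function(model, criteria = list()) {
  stopifnot(inherits(model, "StructureModel"))
  cr <- utils::modifyList(list(mw_min = 10, mw_max = 25, res_max = 3.0,
                               max_cys = 2, min_chain_res = 50,
                               notes = NULL), criteria)
  rt <- residue_table(model)
  seq_all <- paste(rt$aa, collapse = "")
  mw <- (sum(AA_RESIDUE_MASS[strsplit(gsub("X", "", seq_all), "")[[1]]],
             na.rm = TRUE) + WATER_MASS) / 1000
  chains <- unique(rt$chain)
  n_cys <- sum(rt$aa == "C")
  reasons <- character(0)
  if (mw < cr$mw_min || mw > cr$mw_max) reasons <- c(reasons, "molecular_weight")
  if (is.na(model$resolution)) reasons <- c(reasons, "resolution_unknown")
  else if (model$resolution >= cr$res_max) reasons <- c(reasons, "resolution")
  if (length(chains) != 1L) reasons <- c(reasons, "oligomeric")
  else if (nrow(rt) < cr$min_chain_res) reasons <- c(reasons, "chain_too_short")
  if (n_cys > cr$max_cys) reasons <- c(reasons, "cysteine_count")
  structure(list(
    passed = length(reasons) == 0L,
    reasons = reasons,
    metrics = list(molecular_weight_kda = mw,
                   resolution = model$resolution,
                   chain_count = length(chains),
                   chain_length = nrow(rt),
                   cysteine_count = n_cys,
                   notes = cr$notes)),
    class = "FilterVerdict")
}

#' @export
print.FilterVerdict <- function(x, ...) {
  cat("Scaffold candidate filter:",
      if (x$passed) "PASSED" else "FAILED", "\n")
  m <- x$metrics
  cat(sprintf("  MW %.2f kDa | resolution %s A | %d chain(s), %d residues | %d Cys\n",
              m$molecular_weight_kda,
              ifelse(is.na(m$resolution), "?", format(m$resolution)),
              m$chain_count, m$chain_length, m$cysteine_count))
  if (length(x$reasons))
    cat("  violated:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.StructureModel <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("StructureModel %s: %d residue(s) in %d chain(s), %d atoms\n",
              x$entry_id, nrow(rt), length(unique(rt$chain)), nrow(x$atoms)))
  if (!is.na(x$resolution))
    cat(sprintf("  resolution %.2f A (%s)\n", x$resolution,
                ifelse(is.na(x$experimental_method), "method unknown",
                       x$experimental_method)))
  if (nrow(x$hetero))
    cat(sprintf("  non-polymer inventory: %d HETATM atoms (%s)\n",
                nrow(x$hetero),
                paste(utils::head(unique(x$hetero$resid), 5), collapse = ", ")))
  invisible(x)
}

#' Write a structure as PDB with per-residue scores in the B-factor column
#'
#' Used to visualise conservation, mutability or patch membership in a
#' molecular viewer. Scores are clipped to [0, 999.99] (PDB field width);
#' residues without a score get 0.
#'
#' @param model A \code{StructureModel}.
#' @param scores Named numeric vector keyed by residue key
#'   (\code{"chain:seq_num"}), or a data frame with \code{chain},
#'   \code{seq_num} and \code{score} columns. May cover any subset of residues.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_annotated_structure <- function(model, scores, path) {
  stopifnot(inherits(model, "StructureModel"))
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$score,
                              residue_key(scores$chain, scores$seq_num,
                                          scores$ins %||% ""))
  at <- model$atoms
  b <- unname(scores[at$key])
  b[is.na(b)] <- 0
  if (any(b > 999.99 | b < 0)) {
    warning("scores outside [0, 999.99] clipped to PDB B-factor range")
    b <- pmin(pmax(b, 0), 999.99)
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  if (!is.na(model$resolution))
    writeLines(sprintf("REMARK   2 RESOLUTION. %5.2f ANGSTROMS.",
                       model$resolution), con)
  name4 <- ifelse(nchar(at$elety) >= 4, substr(at$elety, 1, 4),
                  sprintf(" %-3s", at$elety))
  writeLines(sprintf(
    "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, at$resid, at$chain, at$resno,
    ifelse(at$ins == "", " ", at$ins), at$x, at$y, at$z, at$occ, b,
    at$element), con)
  writeLines("END", con)
  invisible(path)
}
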