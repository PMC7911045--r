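# Saturation-mutagenesis ddG handling and the per-position mutability score.
#
# A position's mutability is the percentage of the 20 standard substitutions
# (self included: its ddG is 0 by definition and counts toward the numerator)
# whose folding ddG lies strictly below a tolerance threshold, 0.5 kcal/mol by
# default. The stabilising case (ddG < 0) is subsumed by the single strict
# inequality. The denominator is always 20, so scores are multiples of 5.

#' Construct a ddG matrix
#'
#' @param keys Data frame with \code{chain}, \code{seq_num}, \code{wt_aa}.
#' @param ddg Numeric L x 20 matrix, columns named by the 20 one-letter codes;
#'   values are folding free-energy changes (mutant minus wild type, kcal/mol).
#' @param source \code{"file"} or \code{"surrogate"}.
#' @return A \code{DdgMatrix}.
#' @export
new_ddg_matrix <- function(keys, ddg, source = c("file", "surrogate")) {
  source <- match.arg(source)
  stopifnot(is.matrix(ddg), nrow(keys) == nrow(ddg))
  if (!setequal(colnames(ddg), AA1))
    stop("ddG matrix must have exactly the 20 standard amino-acid columns",
         call. = FALSE)
  ddg <- ddg[, AA1, drop = FALSE]
  self <- ddg[cbind(seq_len(nrow(ddg)), match(keys$wt_aa, AA1))]
  if (any(abs(self) > 0.01, na.rm = TRUE))
    warning("self-substitution ddG exceeds 0.01 kcal/mol at ",
            sum(abs(self) > 0.01), " position(s); expected 0 by definition")
  keys$key <- residue_key(keys$chain, keys$seq_num)
  rownames(ddg) <- keys$key
  structure(list(keys = keys, ddg = ddg, source = source),
            class = "DdgMatrix")
}

#' @export
print.DdgMatrix <- function(x, ...) {
  cat(sprintf("DdgMatrix: %d positions x 20 substitutions (source: %s)\n",
              nrow(x$ddg), x$source))
  invisible(x)
}

#' Read a position-scan ddG table
#'
#' Reads the tab-separated dialect produced by saturation-mutagenesis
#' position scans: one row per substitution, header line, either three
#' columns (\code{position_token}, \code{mutant_aa}, \code{ddG}) or two
#' columns (\code{token_with_mutant}, \code{ddG}). A position token encodes
#' wild-type residue, chain and author number, e.g. \code{GA131} = Gly,
#' chain A, residue 131; in the two-column form the mutant letter is appended
#' (\code{GA131W}). Each position must have all 20 substitutions; duplicates
#' are resolved last-wins with a warning.
#'
#' @param path TSV file path.
#' @return A \code{DdgMatrix} with \code{source = "file"}.
#' @export
read_positionscan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) == 2L) {
    token <- sub(".$", "", raw[[1]])
    mutant <- toupper(substr(raw[[1]], nchar(raw[[1]]), nchar(raw[[1]])))
    ddg_chr <- raw[[2]]
  } else if (ncol(raw) >= 3L) {
    token <- raw[[1]]
    mutant <- toupper(raw[[2]])
    ddg_chr <- raw[[3]]
  } else {
    stop("positionscan file must have 2 or 3 tab-separated columns",
         call. = FALSE)
  }
  rowno <- seq_len(length(token)) + 1L   # +1: header line
  ok_tok <- grepl("^[A-Za-z][A-Za-z][0-9]+$", token)
  if (any(!ok_tok))
    stop("malformed position token at row(s) ",
         paste(utils::head(rowno[!ok_tok], 5), collapse = ", "),
         " (expected e.g. GA131)", call. = FALSE)
  ddg <- suppressWarnings(as.numeric(ddg_chr))
  if (anyNA(ddg))
    stop("non-numeric ddG at row(s) ",
         paste(utils::head(rowno[is.na(ddg)], 5), collapse = ", "),
         call. = FALSE)
  if (any(!mutant %in% AA1))
    stop("unknown mutant amino acid at row(s) ",
         paste(utils::head(rowno[!mutant %in% AA1], 5), collapse = ", "),
         call. = FALSE)
  wt <- toupper(substr(token, 1, 1))
  chain <- substr(token, 2, 2)
  seq_num <- as.integer(sub("^..", "", token))
  pos_id <- paste(chain, seq_num, wt, sep = "\r")
  dup <- duplicated(cbind(pos_id, mutant), fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate substitution row(s); keeping the last")
    keep <- !dup
    pos_id <- pos_id[keep]; mutant <- mutant[keep]; ddg <- ddg[keep]
    wt <- wt[keep]; chain <- chain[keep]; seq_num <- seq_num[keep]
  }
  upos <- unique(pos_id)
  first <- match(upos, pos_id)
  mat <- matrix(NA_real_, length(upos), 20,
                dimnames = list(NULL, AA1))
  mat[cbind(match(pos_id, upos), match(mutant, AA1))] <- ddg
  if (anyNA(mat)) {
    gaps <- which(is.na(mat), arr.ind = TRUE)
    gp <- upos[gaps[1, "row"]]
    stop("incomplete position ", gsub("\r", "", gp), ": missing mutant(s) ",
         paste(AA1[gaps[gaps[, "row"] == gaps[1, "row"], "col"]],
               collapse = ", "), call. = FALSE)
  }
  keys <- data.frame(chain = chain[first], seq_num = seq_num[first],
                     wt_aa = wt[first], stringsAsFactors = FALSE)
  new_ddg_matrix(keys, mat, source = "file")
}

#' Mutability score of one position
#'
#' Percentage of the 20 substitutions (self included) with ddG strictly below
#' \code{threshold} kcal/mol.
#'
#' @param values Numeric vector of exactly 20 ddG values (kcal/mol).
#' @param threshold Tolerance threshold (default 0.5 kcal/mol).
#' @return Score in percent; always a multiple of 5.
#' @examples
#' mutability_score(rep(0, 20))           # 100
#' mutability_score(c(0, rep(2, 19)))     # 5
#' @export
mutability_score <- function(values, threshold = 0.5) {
  if (length(values) != 20L)
    stop("expected exactly 20 ddG values, got ", length(values), call. = FALSE)
  if (anyNA(values) || any(is.nan(values)))
    stop("ddG values contain NA/NaN", call. = FALSE)
  100 * sum(values < threshold) / 20
}

#' Mutability profile over all positions of a ddG matrix
#'
#' @param ddg A \code{DdgMatrix}.
#' @param threshold ddG tolerance (kcal/mol).
#' @return Data frame: \code{key}, \code{chain}, \code{seq_num}, \code{wt_aa},
#'   \code{score_pct}, \code{n_below_threshold}.
#' @export
mutability_profile <- function(ddg, threshold = 0.5) {
  stopifnot(inherits(ddg, "DdgMatrix"))
  n_below <- rowSums(ddg$ddg < threshold)
  data.frame(key = ddg$keys$key, chain = ddg$keys$chain,
             seq_num = ddg$keys$seq_num, wt_aa = ddg$keys$wt_aa,
             score_pct = 100 * n_below / 20,
             n_below_threshold = as.integer(n_below),
             stringsAsFactors = FALSE)
}

#' Surrogate ddG model from burial and amino-acid dissimilarity
#'
#' A deliberately simple stand-in for force-field position scans, intended for
#' pipeline testing and teaching: ddG(wt -> a) = lambda x (1 - min(rSASA, 1))
#' x Grantham(wt, a) / 100. Fully exposed residues get ddG = 0 for every
#' substitution (mutability 100%); buried residues are penalised in
#' proportion to the physicochemical distance of the substitution. Output is
#' tagged \code{source = "surrogate"} so it is never mistaken for force-field
#' results; production users should supply position-scan files.
#'
#' @param model A \code{StructureModel}.
#' @param rsasa Data frame from \code{\link{relative_sasa}}.
#' @param lambda Energy scale (kcal/mol) of a fully buried, maximally
#'   dissimilar substitution (default 1.0).
#' @return A \code{DdgMatrix} with \code{source = "surrogate"}.
#' @export
surrogate_ddg <- function(model, rsasa, lambda = 1.0) {
  stopifnot(inherits(model, "StructureModel"))
  rt <- residue_table(model)
  known <- rt$aa %in% AA1
  if (any(!known))
    warning("skipping ", sum(!known), " residue(s) with non-standard type")
  rt <- rt[known, , drop = FALSE]
  rs <- stats::setNames(rsasa$rsasa, rsasa$key)[rt$key]
  if (anyNA(rs))
    stop("relative SASA missing for ", sum(is.na(rs)), " residue(s)",
         call. = FALSE)
  burial <- 1 - pmin(unname(rs), 1)
  mat <- lambda * burial * GRANTHAM[rt$aa, , drop = FALSE] / 100
  dimnames(mat) <- list(NULL, AA1)
  keys <- data.frame(chain = rt$chain, seq_num = rt$seq_num, wt_aa = rt$aa,
                     stringsAsFactors = FALSE)
  new_ddg_matrix(keys, mat, source = "surrogate")
}

#' Merge per-residue evidence into residue profiles
#'
#' @param rsasa Data frame from \code{\link{relative_sasa}}.
#' @param conservation Named vector from \code{\link{map_to_structure}}
#'   (residue key -> percent), or \code{NULL}.
#' @param mutability Data frame from \code{\link{mutability_profile}}, or
#'   \code{NULL}.
#' @return Data frame keyed by residue: \code{key}, \code{chain},
#'   \code{seq_num}, \code{aa}, \code{sasa}, \code{rsasa}, \code{surface},
#'   \code{conservation}, \code{mutability}.
#' @export
residue_profiles <- function(rsasa, conservation = NULL, mutability = NULL) {
  out <- rsasa[, c("key", "chain", "seq_num", "aa", "sasa", "rsasa",
                   "surface")]
  out$conservation <- if (is.null(conservation)) NA_real_
                      else unname(conservation[out$key])
  out$mutability <- if (is.null(mutability)) NA_real_
                    else stats::setNames(mutability$score_pct,
                                         mutability$key)[out$key]
  out$mutability <- unname(out$mutability)
  out
}

#' Select mutable residues by the combined gates
#'
#' A residue is mutable when its identity conservation is strictly below
#' \code{cons_max} percent AND its mutability score is strictly above
#' \code{mut_min} percent AND (by default) it is a surface residue. Residues
#' lacking either score are excluded and listed in the \code{diagnostics}
#' attribute, never silently dropped.
#'
#' @param profiles Data frame from \code{\link{residue_profiles}}.
#' @param cons_max Conservation ceiling in percent (default 90; strict <).
#' @param mut_min Mutability floor in percent (default 50; strict >).
#' @param require_surface Require the surface flag (default TRUE).
#' @return Character vector of selected residue keys, with a
#'   \code{diagnostics} attribute naming residues excluded for missing scores.
#' @export
select_mutable <- function(profiles, cons_max = 90, mut_min = 50,
                           require_surface = TRUE) {
  missing_score <- is.na(profiles$conservation) | is.na(profiles$mutability)
  sel <- !missing_score &
    profiles$conservation < cons_max &
    profiles$mutability > mut_min
  if (require_surface) sel <- sel & profiles$surface
  keys <- profiles$key[sel]
  attr(keys, "diagnostics") <- profiles$key[missing_score]
  keys
}
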