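# Degenerate-codon (NNK) library design: codon expansion, exact diversity
# statistics, ribosome-display cassette assembly, and variant sampling.
#
# Diversity counts are computed in exact integer arithmetic: products are
# accumulated as decimal big integers (base-1e4 schoolbook multiplication),
# so counts like 32^10 are exact regardless of magnitude; the numeric value
# is also returned (exact whenever below 2^53).

#' Expand a degenerate codon to its concrete codons
#'
#' @param codon Three IUPAC nucleotide symbols, e.g. \code{"NNK"}.
#' @return Character vector of concrete codons (Cartesian expansion).
#' @examples
#' length(expand_degenerate_codon("NNK"))  # 32
#' @export
expand_degenerate_codon <- function(codon) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("codon must be a single 3-letter string", call. = FALSE)
  syms <- strsplit(codon, "")[[1]]
  bad <- setdiff(syms, names(IUPAC_NT))
  if (length(bad))
    stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  grid <- expand.grid(IUPAC_NT[[syms[3]]], IUPAC_NT[[syms[2]]],
                      IUPAC_NT[[syms[1]]], stringsAsFactors = FALSE)
  sort(paste0(grid[[3]], grid[[2]], grid[[1]]))
}

#' Amino acids encoded by a degenerate codon
#'
#' Translates every concrete expansion with the standard genetic code.
#'
#' @param codon Three IUPAC symbols.
#' @return List with \code{aa_counts} (named integer vector: amino acid ->
#'   number of encoding codons), \code{stop_codons} (count),
#'   \code{codons_by_aa} (list of codon vectors), \code{n_codons}.
#' @examples
#' enc <- encoded_amino_acids("NNK")
#' enc$stop_codons        # 1 (TAG)
#' enc$aa_counts[["L"]]   # 3 (TTG, CTT, CTG)
#' @export
encoded_amino_acids <- function(codon) {
  codons <- expand_degenerate_codon(codon)
  aa <- Biostrings::GENETIC_CODE[codons]
  stops <- aa == "*"
  counts <- table(aa[!stops])
  list(aa_counts = stats::setNames(as.integer(counts), names(counts)),
       stop_codons = sum(stops),
       codons_by_aa = split(codons, aa),
       n_codons = length(codons))
}

# --- exact big-integer products (decimal strings, base-1e4 limbs) ----------

#' @keywords internal
big_from_int <- function(x) as.integer(x)   # limb vector, little-endian

#' @keywords internal
big_mult_small <- function(limbs, m) {
  carry <- 0
  out <- integer(0)
  for (l in limbs) {
    v <- l * m + carry
    out <- c(out, v %% 10000L)
    carry <- v %/% 10000L
  }
  while (carry > 0) { out <- c(out, carry %% 10000L); carry <- carry %/% 10000L }
  out
}

#' @keywords internal
big_to_string <- function(limbs) {
  n <- length(limbs)
  paste0(limbs[n], paste(sprintf("%04d", rev(limbs[-n])), collapse = ""))
}

#' @keywords internal
exact_product <- function(factors) {
  limbs <- big_from_int(1L)
  for (f in factors) limbs <- big_mult_small(limbs, as.integer(f))
  big_to_string(limbs)
}

#' Construct a degenerate library design
#'
#' @param scaffold_protein One-letter protein sequence of the parent scaffold.
#' @param positions Protein positions (1-based, unique, within sequence) to
#'   randomize.
#' @param codon Degenerate codon used at every randomized position
#'   (default \code{"NNK"}), or a character vector, one codon per position.
#' @return A \code{LibraryDesign} with a \code{diversity} record (see
#'   \code{\link{library_diversity}}); diversity is recomputed at
#'   construction.
#' @export
library_design <- function(scaffold_protein, positions, codon = "NNK") {
  letters1 <- assert_aa_string(scaffold_protein, "scaffold_protein")
  positions <- as.integer(positions)
  if (!length(positions)) stop("need at least one randomized position",
                               call. = FALSE)
  if (anyDuplicated(positions)) stop("positions must be unique", call. = FALSE)
  if (any(positions < 1L | positions > length(letters1)))
    stop("positions outside the scaffold sequence", call. = FALSE)
  codons <- if (length(codon) == 1L) rep(codon, length(positions)) else codon
  if (length(codons) != length(positions))
    stop("codon must be length 1 or one per position", call. = FALSE)
  ord <- order(positions)
  design <- structure(list(scaffold_protein = toupper(scaffold_protein),
                           randomized_positions = positions[ord],
                           codon_per_position = toupper(codons[ord]),
                           diversity = NULL),
                      class = "LibraryDesign")
  design$diversity <- library_diversity(design)
  design
}

#' @export
print.LibraryDesign <- function(x, ...) {
  cat(sprintf("LibraryDesign: %d randomized positions on a %d-residue scaffold\n",
              length(x$randomized_positions), nchar(x$scaffold_protein)))
  cat("  positions:",
      paste(sprintf("%s%d(%s)",
                    strsplit(x$scaffold_protein, "")[[1]][x$randomized_positions],
                    x$randomized_positions, x$codon_per_position),
            collapse = " "), "\n")
  d <- x$diversity
  cat(sprintf("  DNA diversity %s | stop-free protein diversity %s | stop-free fraction %.3f\n",
              d$dna_diversity_exact, d$protein_diversity_exact,
              d$stop_free_fraction))
  invisible(x)
}

#' Exact library diversity statistics
#'
#' DNA diversity is the product over positions of the number of concrete
#' codons; protein diversity counts stop-free protein sequences (product of
#' distinct encoded amino acids per position) -- a stop-containing variant is
#' not a library member; the stop-free fraction is the probability that a
#' uniform DNA draw contains no stop codon.
#'
#' @param design A \code{LibraryDesign}.
#' @return List with \code{dna_diversity}, \code{protein_diversity} (numeric;
#'   exact below 2^53), \code{dna_diversity_exact},
#'   \code{protein_diversity_exact} (decimal strings, always exact) and
#'   \code{stop_free_fraction}.
#' @examples
#' d <- library_design(strrep("A", 20), 1:10, "NNK")
#' d$diversity$protein_diversity_exact  # "10240000000000" = 20^10
#' @export
library_diversity <- function(design) {
  stopifnot(inherits(design, "LibraryDesign"))
  enc <- lapply(design$codon_per_position, encoded_amino_acids)
  n_codons <- vapply(enc, `[[`, 0L, "n_codons")
  n_aa <- vapply(enc, function(e) length(e$aa_counts), 0L)
  n_stop <- vapply(enc, `[[`, 0L, "stop_codons")
  list(dna_diversity = prod(n_codons),
       protein_diversity = prod(n_aa),
       dna_diversity_exact = exact_product(n_codons),
       protein_diversity_exact = exact_product(n_aa),
       stop_free_fraction = prod(1 - n_stop / n_codons))
}

#' Back-translate a protein to DNA
#'
#' Uses the most-frequent codon per amino acid from an embedded E. coli
#' usage table by default; vendor-optimised constructs will differ, so the
#' table is overridable.
#'
#' @param protein One-letter protein string.
#' @param usage Named character vector amino acid -> codon.
#' @return DNA string of length 3 x nchar(protein).
#' @export
back_translate <- function(protein, usage = ECOLI_CODON) {
  letters1 <- assert_aa_string(protein, "protein")
  paste(usage[letters1], collapse = "")
}

#' @keywords internal
translate_dna <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna) - 2, by = 3),
                      seq(3, nchar(dna), by = 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# Representative cassette element templates. These are generic published
# motifs (T7 promoter, Shine-Dalgarno, Strep-tag II, c-Myc tag) plus
# synthetic linkers -- NOT any vendor's proprietary construct; supply real
# sequences through `layout_config` for production work.
#' @keywords internal
default_cassette_templates <- function() {
  list(
    t7_promoter  = "TAATACGACTCACTATAGGG",
    stem_loop_5p = "GGGAGACCGGAATTCTCCC",
    rbs          = "TTAACTTTAAGAAGGAGATATACAT",
    strep_tag    = back_translate("MWSHPQFEKGA"),
    c_myc_tag    = back_translate("EQKLISEEDL"),
    tola_spacer  = back_translate("GSGSGSAEAAAKEAAAKAGS"),
    stem_loop_3p = "GGGCGGCGTTTTCGCCGCCC")
}

#' Assemble the ribosome-display cassette
#'
#' Element order: T7 promoter, 5' stem-loop, ribosome binding site,
#' N-terminal Strep-tag, scaffold ORF, C-terminal c-Myc tag, TolA spacer,
#' 3' stem-loop. The translated fusion (Strep-tag through TolA) must contain
#' no stop codon -- ribosome display requires an open reading frame without a
#' stop -- and the wild-type back-translation of the ORF must round-trip to
#' the scaffold protein. Randomized positions carry their degenerate codon
#' symbols in the library DNA string.
#'
#' @param design A \code{LibraryDesign}.
#' @param layout_config Optional named list overriding element DNA templates
#'   (names as in the returned layout).
#' @return A \code{CassetteLayout}: list with \code{elements} (named DNA),
#'   \code{coords} (1-based inclusive feature table), \code{dna} (wild-type
#'   cassette), \code{library_dna} (degenerate positions as IUPAC symbols).
#' @export
assemble_cassette <- function(design, layout_config = NULL) {
  stopifnot(inherits(design, "LibraryDesign"))
  tpl <- utils::modifyList(default_cassette_templates(),
                           layout_config %||% list())
  orf_wt <- back_translate(design$scaffold_protein)
  orf_lib <- orf_wt
  for (i in seq_along(design$randomized_positions)) {
    p <- design$randomized_positions[i]
    substr(orf_lib, 3 * p - 2, 3 * p) <- design$codon_per_position[i]
  }
  elements <- list(t7_promoter = tpl$t7_promoter,
                   stem_loop_5p = tpl$stem_loop_5p,
                   rbs = tpl$rbs,
                   strep_tag = tpl$strep_tag,
                   orf = orf_wt,
                   c_myc_tag = tpl$c_myc_tag,
                   tola_spacer = tpl$tola_spacer,
                   stem_loop_3p = tpl$stem_loop_3p)
  coding <- c("strep_tag", "orf", "c_myc_tag", "tola_spacer")
  for (el in coding) {
    if (nchar(elements[[el]]) %% 3 != 0)
      stop("cassette assembly error: element '", el,
           "' is not a whole number of codons", call. = FALSE)
    if (grepl("\\*", translate_dna(elements[[el]])))
      stop("cassette assembly error: in-frame stop codon inside element '",
           el, "'", call. = FALSE)
  }
  if (translate_dna(orf_wt) != design$scaffold_protein)
    stop("cassette assembly error: ORF does not back-translate to the scaffold",
         call. = FALSE)
  fusion <- paste(unlist(elements[coding]), collapse = "")
  if (grepl("\\*", translate_dna(fusion)))
    stop("cassette assembly error: in-frame stop codon in the fusion ORF",
         call. = FALSE)
  lens <- vapply(elements, nchar, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  coords <- data.frame(element = names(elements), start = starts, end = ends,
                       frame = ifelse(names(elements) %in% coding,
                                      (starts - starts[["strep_tag"]]) %% 3,
                                      NA_integer_),
                       row.names = NULL, stringsAsFactors = FALSE)
  lib_elements <- elements
  lib_elements$orf <- orf_lib
  structure(list(elements = elements, coords = coords,
                 dna = paste(unlist(elements), collapse = ""),
                 library_dna = paste(unlist(lib_elements), collapse = "")),
            class = "CassetteLayout")
}

#' @export
print.CassetteLayout <- function(x, ...) {
  cat("Ribosome-display cassette layout (", nchar(x$dna), " bp):\n", sep = "")
  print(x$coords, row.names = FALSE)
  invisible(x)
}

#' GenBank-style flat annotation of a cassette
#'
#' @param cassette A \code{CassetteLayout}.
#' @return Character vector of annotation lines (1-based inclusive
#'   coordinates).
#' @export
format_cassette_annotation <- function(cassette) {
  c("FEATURES             Location/Qualifiers",
    unlist(lapply(seq_len(nrow(cassette$coords)), function(i) {
      r <- cassette$coords[i, ]
      c(sprintf("     misc_feature    %d..%d", r$start, r$end),
        sprintf("                     /label=\"%s\"", r$element))
    })))
}

#' Sample concrete library variants
#'
#' Draws codons i.i.d. uniformly from each randomized position's expansion;
#' non-randomized positions keep the wild-type back-translation. With
#' \code{exclude_stops}, stop codons are rejected and redrawn per position.
#' An optional per-base synthesis error rate mutates bases of the sampled
#' ORF uniformly (default 0 = perfect synthesis).
#'
#' @param design A \code{LibraryDesign}.
#' @param n Number of variants (>= 1).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param exclude_stops Reject stop codons at randomized positions
#'   (default TRUE).
#' @param error_rate Per-base error probability applied after sampling
#'   (default 0).
#' @return List with \code{dna} and \code{protein} character vectors
#'   (length n).
#' @export
sample_variants <- function(design, n, seed, exclude_stops = TRUE,
                            error_rate = 0) {
  stopifnot(inherits(design, "LibraryDesign"), n >= 1)
  expansions <- lapply(design$codon_per_position, expand_degenerate_codon)
  if (exclude_stops)
    expansions <- lapply(expansions, function(e)
      e[Biostrings::GENETIC_CODE[e] != "*"])
  orf_wt <- back_translate(design$scaffold_protein)
  with_seed(seed, {
    dna <- vapply(seq_len(n), function(.) {
      v <- orf_wt
      for (i in seq_along(design$randomized_positions)) {
        p <- design$randomized_positions[i]
        substr(v, 3 * p - 2, 3 * p) <- sample(expansions[[i]], 1L)
      }
      if (error_rate > 0) {
        bases <- strsplit(v, "")[[1]]
        hit <- stats::runif(length(bases)) < error_rate
        bases[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
        v <- paste(bases, collapse = "")
      }
      v
    }, "")
    list(dna = dna, protein = vapply(dna, translate_dna, "",
                                     USE.NAMES = FALSE))
  })
}
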