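# Internal helpers shared across modules.

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route their randomness through
# this so nothing perturbs (or depends on) the global stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Residue keys are "chain:seq_num" or "chain:seq_num:ins" when an insertion
# code is present. Author numbering is preserved verbatim.
#' @keywords internal
residue_key <- function(chain, seq_num, ins = "") {
  n <- max(length(chain), length(seq_num), length(ins))
  chain <- rep_len(chain, n); seq_num <- rep_len(seq_num, n)
  ins <- rep_len(ins, n)
  ins[is.na(ins) | ins == " "] <- ""
  ifelse(ins == "", paste(chain, seq_num, sep = ":"),
         paste(chain, seq_num, ins, sep = ":"))
}

#' @keywords internal
key_parts <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    key = keys,
    chain = vapply(parts, `[`, "", 1L),
    seq_num = as.integer(vapply(parts, `[`, "", 2L)),
    ins = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", ""),
    stringsAsFactors = FALSE)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_aa_string <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters1), AA1)
  if (length(bad))
    stop(what, " contains non-standard letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  letters1
}
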