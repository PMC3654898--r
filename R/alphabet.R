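# Residue alphabet and shared validation helpers.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
PEPTIDE_LENGTH <- 6L
POSITION_NAMES <- paste0("P", seq_len(6L))
LABEL_LEVELS <- c("amyloid", "non_amyloid", "unlabeled")

# package-level cache for bundled constants
.cache <- new.env(parent = emptyenv())

#' The 20-residue amino acid alphabet
#'
#' One-letter codes of the 20 standard amino acids, in alphabetical order.
#' This is the only alphabet accepted anywhere in the package: ambiguity
#' codes (B, Z, X), selenocysteine (U) and lowercase letters are rejected
#' rather than remapped, because every bundled 20-row table enumerates
#' exactly these residues.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

# Validate peptide/protein sequences. `exact_length = NULL` allows any
# length >= min_length. Errors name the offending entry.
assert_sequences <- function(x, exact_length = PEPTIDE_LENGTH,
                             min_length = PEPTIDE_LENGTH,
                             what = "sequence") {
  if (!is.character(x) || length(x) == 0 || anyNA(x))
    stop(sprintf("%ss must be a non-empty character vector without NA", what),
         call. = FALSE)
  if (!is.null(exact_length)) {
    bad <- which(nchar(x) != exact_length)
    if (length(bad))
      stop(sprintf("%s %d ('%s') has length %d; expected %d",
                   what, bad[1], x[bad[1]], nchar(x[bad[1]]), exact_length),
           call. = FALSE)
  } else {
    bad <- which(nchar(x) < min_length)
    if (length(bad))
      stop(sprintf("%s %d ('%s') is shorter than %d residues",
                   what, bad[1], x[bad[1]], min_length), call. = FALSE)
  }
  ok <- grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")), x)
  if (!all(ok)) {
    i <- which(!ok)[1]
    ch <- setdiff(strsplit(x[i], "")[[1]], AA_ALPHABET)[1]
    stop(sprintf("%s %d ('%s') contains invalid residue letter '%s'",
                 what, i, x[i], ch), call. = FALSE)
  }
  invisible(x)
}

# Normalize label tokens to the canonical enum; errors on unknown tokens.
normalize_labels <- function(x) {
  lx <- tolower(trimws(x))
  lx[lx == "non-amyloid"] <- "non_amyloid"
  bad <- which(!lx %in% LABEL_LEVELS)
  if (length(bad))
    stop(sprintf("unknown label token '%s' (record %d); expected one of %s",
                 x[bad[1]], bad[1],
                 paste(LABEL_LEVELS, collapse = ", ")), call. = FALSE)
  factor(lx, levels = LABEL_LEVELS)
}

# Split hexapeptides into an n x 6 matrix of alphabet indices.
residue_index_matrix <- function(sequences) {
  matrix(match(unlist(strsplit(sequences, "", fixed = TRUE)), AA_ALPHABET),
         ncol = PEPTIDE_LENGTH, byrow = TRUE)
}

# Validate a 20 x 6 numeric matrix; returns it with canonical dimnames.
assert_matrix20x6 <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m) || any(dim(m) != c(20L, 6L)))
    stop(sprintf("%s must be a numeric 20 x 6 matrix", what), call. = FALSE)
  if (is.null(rownames(m)))
    stop(sprintf("%s must have one-letter residue rownames", what),
         call. = FALSE)
  if (!setequal(rownames(m), AA_ALPHABET) || anyDuplicated(rownames(m)))
    stop(sprintf("%s rownames must be the 20 standard residues", what),
         call. = FALSE)
  m <- m[AA_ALPHABET, , drop = FALSE]
  colnames(m) <- POSITION_NAMES
  if (any(!is.finite(m)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
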