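# 20 x 6 matrix I/O and the bundled published constants.

#' Read a 20 x 6 residue-by-position matrix
#'
#' Expects a tab-separated file with optional `#` comment lines, a header row
#' naming the six positions `1..6`, and exactly 20 data rows keyed by
#' one-letter residue code. Rows are returned in alphabetical residue order
#' with columns `P1..P6`.
#'
#' @param path Path to the matrix file.
#' @return Numeric 20 x 6 matrix.
#' @seealso [write_matrix()], [read_potentials()]
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2) stop("matrix file has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (length(hdr) != 7 || !identical(trimws(hdr[-1]), as.character(1:6)))
    stop("matrix header must name positions 1..6", call. = FALSE)
  body <- fields[-1]
  res <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(res))
    stop(sprintf("duplicate residue row '%s'", res[duplicated(res)][1]),
         call. = FALSE)
  unknown <- setdiff(res, AA_ALPHABET)
  if (length(unknown))
    stop(sprintf("unknown residue row '%s'", unknown[1]), call. = FALSE)
  missing <- setdiff(AA_ALPHABET, res)
  if (length(missing))
    stop(sprintf("matrix is missing residue row(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  short <- which(lengths(body) != 7)
  if (length(short))
    stop(sprintf("row '%s' has %d value(s); expected 6",
                 res[short[1]], lengths(body)[short[1]] - 1L), call. = FALSE)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[2:7]), numeric(6)))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 2, anyNA))[1]
    stop(sprintf("non-numeric or missing cell in residue row '%s'", res[bad]),
         call. = FALSE)
  }
  m <- t(vals)
  rownames(m) <- res
  assert_matrix20x6(m)
}

#' Write a 20 x 6 matrix
#'
#' Values are written at fixed decimal precision (3 by default, matching the
#' precision at which published potentials are reported), so
#' `read_matrix(write_matrix(m))` reproduces `m` to that precision.
#'
#' @param m Numeric 20 x 6 matrix with residue rownames.
#' @param path Output path.
#' @param digits Decimal places to keep.
#' @param comment Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, digits = 3, comment = NULL) {
  m <- assert_matrix20x6(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("residue", 1:6), collapse = "\t"), con)
  fmt <- paste0("%.", digits, "f")
  for (r in rownames(m))
    writeLines(paste(c(r, sprintf(fmt, m[r, ])), collapse = "\t"), con)
  invisible(path)
}

#' Tag a 20 x 6 matrix as a statistical potential matrix
#'
#' A `potential_matrix` stores position-specific statistical energies
#' \eqn{\phi(i,j) = -RT \ln propensity(i,j)} in kcal/mol, together with the
#' thermal constant `rt` and a 20 x 6 logical `observed` map. Cells whose
#' underlying residue/position count was zero are stored as exactly 0 with
#' `observed = FALSE`; this mirrors the convention of the published matrices,
#' where unobserved cells are printed as 0.000.
#'
#' @param m Numeric 20 x 6 matrix (kcal/mol), residue rownames.
#' @param rt Thermal constant RT in kcal/mol (0.6 corresponds to ~300 K).
#' @param observed Logical 20 x 6 matrix; defaults to `m != 0`, the
#'   convention used when reading published matrices in which unobserved
#'   cells are printed as zero.
#' @return A `potential_matrix`.
#' @export
as_potential_matrix <- function(m, rt = 0.6, observed = NULL) {
  m <- assert_matrix20x6(m, "potential matrix")
  stopifnot(is.numeric(rt), length(rt) == 1, rt > 0)
  if (is.null(observed)) observed <- m != 0
  observed <- assert_matrix20x6(observed + 0, "observed map") > 0
  m[!observed] <- 0
  structure(m, rt = rt, observed = observed,
            class = c("potential_matrix", "matrix", "array"))
}

#' @export
print.potential_matrix <- function(x, ...) {
  cat(sprintf("potential_matrix (kcal/mol), RT = %g; %d unobserved cell(s)\n",
              attr(x, "rt"), sum(!attr(x, "observed"))))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read a potential matrix file
#'
#' @inheritParams read_matrix
#' @param rt Thermal constant RT in kcal/mol.
#' @return A [as_potential_matrix()] object; zero cells are flagged
#'   unobserved.
#' @export
read_potentials <- function(path, rt = 0.6)
  as_potential_matrix(read_matrix(path), rt = rt)

extdata <- function(...)
  system.file("extdata", ..., package = "hexamyloid", mustWork = TRUE)

#' Bundled published potential matrices
#'
#' The two 20 x 6 statistical potential matrices (kcal/mol) derived from the
#' reference compilation of 139 amyloid-fibril-forming and 168 non-amyloid
#' hexapeptides, as published at 3-decimal precision. `amyloid_potentials()`
#' holds the amyloid-class matrix, `nonamyloid_potentials()` the non-amyloid
#' one. Zero cells are flagged unobserved.
#'
#' @param rt Thermal constant RT in kcal/mol used when converting back to
#'   propensities.
#' @return A `potential_matrix`.
#' @export
#' @examples
#' amyloid_potentials()["S", "P1"]   # -1.036
amyloid_potentials <- function(rt = 0.6) {
  key <- paste0("amy_", rt)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- read_potentials(extdata("potentials_amyloid.tsv"), rt)
  .cache[[key]]
}

#' @rdname amyloid_potentials
#' @export
nonamyloid_potentials <- function(rt = 0.6) {
  key <- paste0("non_", rt)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- read_potentials(extdata("potentials_nonamyloid.tsv"), rt)
  .cache[[key]]
}

#' Reference composition of globular proteins
#'
#' The bundled percent composition of the 20 amino acids in globular
#' proteins, used as the background when converting position-specific
#' compositions into propensities.
#'
#' @return Named numeric vector of length 20 (percent).
#' @export
#' @examples
#' globular_composition()[["A"]]   # 8.47
globular_composition <- function() {
  if (is.null(.cache$glob)) {
    tab <- utils::read.delim(extdata("globular_composition.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    v <- stats::setNames(tab$percent, tab$residue)[AA_ALPHABET]
    if (anyNA(v) || any(v <= 0))
      stop("corrupt bundled globular composition", call. = FALSE)
    .cache$glob <- v
  }
  .cache$glob
}
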