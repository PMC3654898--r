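# Compositions, position-specific propensities, statistical potentials and
# preferred/avoided residue classification.

#' Overall amino acid composition of a peptide class
#'
#' Computes `Comp(i) = 100 * n_i / N` over all residues of all peptides of
#' the requested class, where `n_i` counts residues of type `i` and `N` is
#' the total residue count. Values are percentages and sum to 100.
#'
#' @param ds A [peptide_dataset()].
#' @param label Class to summarize (`"amyloid"` or `"non_amyloid"`).
#' @return Named numeric vector of length 20 (percent), with attribute
#'   `n_total` (total residue count N); class `composition_table`.
#' @export
#' @examples
#' ds <- peptide_dataset("STVIIE", "amyloid")
#' overall_composition(ds, "amyloid")[["I"]]   # 33.33 percent
overall_composition <- function(ds, label) {
  sub <- class_records(ds, label)
  idx <- residue_index_matrix(sub$sequence)
  counts <- tabulate(idx, nbins = 20L)
  names(counts) <- AA_ALPHABET
  structure(100 * counts / sum(counts), n_total = sum(counts),
            class = "composition_table")
}

#' Position-specific amino acid composition
#'
#' Computes `Comp(i, j) = 100 * n_ij / N_j` for residue `i` at position
#' `j = 1..6`, where `N_j` equals the number of peptides of the class. An
#' optional pseudo-count is added to every cell count (off by default, to
#' match the published matrices which were derived from raw counts).
#'
#' @inheritParams overall_composition
#' @param pseudocount Non-negative count added to each of the 120 cells
#'   before normalization; the per-position denominator becomes
#'   `N_j + 20 * pseudocount`.
#' @return 20 x 6 percent matrix (each column sums to 100) with attributes
#'   `n_per_position` and `observed` (raw count > 0); class
#'   `positional_composition`.
#' @export
positional_composition <- function(ds, label, pseudocount = 0) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1,
            pseudocount >= 0)
  sub <- class_records(ds, label)
  idx <- residue_index_matrix(sub$sequence)
  counts <- vapply(seq_len(PEPTIDE_LENGTH),
                   function(j) tabulate(idx[, j], nbins = 20L),
                   numeric(20L))
  dimnames(counts) <- list(AA_ALPHABET, POSITION_NAMES)
  observed <- (counts + pseudocount) > 0
  padded <- counts + pseudocount
  values <- sweep(padded, 2, colSums(padded), "/") * 100
  structure(values,
            n_per_position = stats::setNames(rep(nrow(sub), 6L),
                                             POSITION_NAMES),
            observed = observed,
            class = c("positional_composition", "matrix", "array"))
}

#' Position-specific propensities
#'
#' Normalizes a position-specific composition by a reference background
#' composition: `Propen(i, j) = Comp(i, j) / Comp_ref(i)`. The default
#' reference is the bundled percent composition of globular proteins. Since
#' both numerator and reference are in percent, the identity
#' `sum_i Propen(i, j) * Comp_ref(i) = 100` holds at every position.
#'
#' @param pos A [positional_composition()] matrix.
#' @param ref Named numeric reference composition in percent (all 20
#'   residues, strictly positive).
#' @return 20 x 6 dimensionless matrix with attributes `observed` and
#'   `reference`; class `propensity_matrix`.
#' @export
positional_propensity <- function(pos, ref = globular_composition()) {
  stopifnot(inherits(pos, "positional_composition"))
  if (!is.numeric(ref) || is.null(names(ref)) ||
      !setequal(names(ref), AA_ALPHABET))
    stop("ref must be a named composition over the 20 residues",
         call. = FALSE)
  ref <- ref[AA_ALPHABET]
  if (any(ref <= 0)) stop("reference composition must be strictly positive",
                          call. = FALSE)
  values <- unclass(pos) / ref
  structure(values, observed = attr(pos, "observed"), reference = ref,
            class = c("propensity_matrix", "matrix", "array"))
}

#' Convert propensities to statistical energy potentials
#'
#' Applies the Boltzmann relation `phi(i, j) = -RT * ln Propen(i, j)` to the
#' observed cells. Unobserved cells (zero count, where the logarithm is
#' undefined) are stored as exactly 0 with `observed = FALSE`, matching the
#' published convention of printing such cells as 0.000.
#'
#' @param prop A [positional_propensity()] matrix.
#' @param rt Thermal constant RT in kcal/mol (default 0.6, ~300 K).
#' @return A [as_potential_matrix()] object (kcal/mol).
#' @export
propensity_to_potential <- function(prop, rt = 0.6) {
  stopifnot(inherits(prop, "propensity_matrix"))
  observed <- attr(prop, "observed")
  phi <- matrix(0, 20L, 6L, dimnames = dimnames(prop))
  phi[observed] <- -rt * log(unclass(prop)[observed])
  as_potential_matrix(phi, rt = rt, observed = observed)
}

#' Recover propensities from a potential matrix
#'
#' Inverse of [propensity_to_potential()]: `Propen = exp(-phi / RT)` on
#' observed cells; unobserved cells are returned as propensity 0 with
#' `observed = FALSE`.
#'
#' @param pot A [as_potential_matrix()] object.
#' @param ref Reference composition attached to the result (used by
#'   downstream normalization identities).
#' @return A `propensity_matrix`.
#' @export
potential_to_propensity <- function(pot, ref = globular_composition()) {
  stopifnot(inherits(pot, "potential_matrix"))
  observed <- attr(pot, "observed")
  values <- matrix(0, 20L, 6L, dimnames = dimnames(pot))
  values[observed] <- exp(-unclass(pot)[observed] / attr(pot, "rt"))
  structure(values, observed = observed, reference = ref[AA_ALPHABET],
            class = c("propensity_matrix", "matrix", "array"))
}

#' Derive a potential matrix from a labeled dataset
#'
#' End-to-end pipeline: position-specific composition, normalization to
#' propensities, Boltzmann conversion to energies. `normalization` selects
#' the background: `"globular"` (default; composition of globular proteins)
#' or `"self"` (the class's own overall composition). The globular
#' background is the one under which the bundled published matrices were
#' derived and the only mode exercised by the package's validation suite.
#'
#' @inheritParams positional_composition
#' @param rt Thermal constant RT in kcal/mol.
#' @param normalization Background choice, see above.
#' @param ref Reference composition override (percent); ignored for
#'   `normalization = "self"`.
#' @return A [as_potential_matrix()] object.
#' @export
#' @examples
#' ds <- sample_dataset(n_amyloid = 200, n_nonamyloid = 0, seed = 1)
#' derive_potentials(ds, "amyloid")["S", "P1"]
derive_potentials <- function(ds, label, rt = 0.6, pseudocount = 0,
                              normalization = c("globular", "self"),
                              ref = globular_composition()) {
  normalization <- match.arg(normalization)
  pos <- positional_composition(ds, label, pseudocount = pseudocount)
  if (normalization == "self")
    ref <- unclass(overall_composition(ds, label))
  propensity_to_potential(positional_propensity(pos, ref), rt = rt)
}

#' Preferred and avoided residues per position
#'
#' A residue is *preferred* at a position when it is observed there with a
#' propensity at or above `preferred_min` (default 1.2) and *avoided* when
#' its propensity is at or below `avoided_max` (default 0.8; unobserved
#' residues, propensity 0, are always avoided).
#'
#' @param prop A `propensity_matrix`, or a `potential_matrix` (converted via
#'   [potential_to_propensity()] first).
#' @param preferred_min Propensity threshold for preference.
#' @param avoided_max Propensity threshold for avoidance; must satisfy
#'   `preferred_min > avoided_max > 0`.
#' @return List with elements `preferred` and `avoided`, each a list of six
#'   character vectors (positions `P1..P6`); class `residue_preferences`.
#' @export
#' @examples
#' classify_preferences(amyloid_potentials())$preferred$P1   # includes "S"
classify_preferences <- function(prop, preferred_min = 1.2,
                                 avoided_max = 0.8) {
  if (inherits(prop, "potential_matrix"))
    prop <- potential_to_propensity(prop)
  stopifnot(inherits(prop, "propensity_matrix"))
  if (!(preferred_min > avoided_max && avoided_max > 0))
    stop("thresholds must satisfy preferred_min > avoided_max > 0",
         call. = FALSE)
  observed <- attr(prop, "observed")
  v <- unclass(prop)
  pick <- function(mask) lapply(stats::setNames(seq_len(6L), POSITION_NAMES),
                                function(j) AA_ALPHABET[mask[, j]])
  structure(list(preferred = pick(observed & v >= preferred_min),
                 avoided = pick(v <= avoided_max),
                 preferred_min = preferred_min, avoided_max = avoided_max),
            class = "residue_preferences")
}

#' @export
print.residue_preferences <- function(x, ...) {
  cat(sprintf("residue preferences (propensity >= %g / <= %g)\n",
              x$preferred_min, x$avoided_max))
  for (j in POSITION_NAMES)
    cat(sprintf("  %s  preferred: %-22s avoided: %s\n", j,
                paste(x$preferred[[j]], collapse = ","),
                paste(x$avoided[[j]], collapse = ",")))
  invisible(x)
}
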