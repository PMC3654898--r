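# Total-energy scoring, the delta-phi sign discriminator, window scanning
# and per-position energy-differential distributions.

# Sum phi(residue_j, j) over the six positions; vectorized over sequences.
phi_total <- function(sequences, pot) {
  stopifnot(inherits(pot, "potential_matrix"))
  idx <- residue_index_matrix(sequences)
  n <- length(sequences)
  vals <- matrix(unclass(pot)[cbind(as.vector(idx),
                                    rep(seq_len(6L), each = n))],
                 nrow = n)
  rowSums(vals)
}

#' Score hexapeptides under a pair of potential matrices
#'
#' For each peptide the total potential `phi_tot = sum_j phi(r_j, j)` is
#' computed under the amyloid-derived and non-amyloid-derived matrices, and
#' the discriminator `delta_phi = phi_amyloid - phi_nonamyloid` is formed.
#' A negative `delta_phi` predicts amyloid-fibril formation; zero or
#' positive values predict non-amyloid (ties resolve to non-amyloid).
#'
#' @param sequence Character vector of hexapeptides.
#' @param amy,non Amyloid- and non-amyloid-class [as_potential_matrix()]
#'   objects; default to the bundled published matrices.
#' @return Data frame with columns `sequence`, `phi_amyloid`,
#'   `phi_nonamyloid`, `delta_phi` (kcal/mol) and `call`.
#' @export
#' @examples
#' score_peptide(c("STVIIE", "VQIVYK"))
score_peptide <- function(sequence, amy = amyloid_potentials(),
                          non = nonamyloid_potentials()) {
  assert_sequences(sequence)
  pa <- phi_total(sequence, amy)
  pn <- phi_total(sequence, non)
  d <- pa - pn
  data.frame(sequence = sequence, phi_amyloid = pa, phi_nonamyloid = pn,
             delta_phi = d,
             call = factor(ifelse(d < 0, "amyloid", "non_amyloid"),
                           levels = c("amyloid", "non_amyloid")),
             stringsAsFactors = FALSE)
}

#' Confusion counts
#'
#' Container for true/false positive/negative counts with the amyloid class
#' as positive.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(counts), names(counts))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Classify a labeled dataset with the delta-phi rule
#'
#' Scores every labeled record with [score_peptide()] and tallies confusion
#' counts, with amyloid as the positive class.
#'
#' @param ds A [peptide_dataset()] with no unlabeled records.
#' @inheritParams score_peptide
#' @return A [confusion_counts()] object.
#' @export
classify_dataset <- function(ds, amy = amyloid_potentials(),
                             non = nonamyloid_potentials()) {
  stopifnot(inherits(ds, "peptide_dataset"))
  if (any(ds$label == "unlabeled"))
    stop("dataset contains unlabeled records", call. = FALSE)
  call <- score_peptide(ds$sequence, amy, non)$call
  truth <- as.character(ds$label)
  confusion_counts(tp = sum(truth == "amyloid" & call == "amyloid"),
                   fp = sum(truth == "non_amyloid" & call == "amyloid"),
                   tn = sum(truth == "non_amyloid" & call == "non_amyloid"),
                   fn = sum(truth == "amyloid" & call == "non_amyloid"))
}

#' Scan a protein sequence for aggregation-prone hexapeptide windows
#'
#' Slides a 6-residue window along the sequence (step 1) and scores each
#' window with [score_peptide()]. Coordinates are reported both 0-based
#' half-open (`start0`, `end0`) and 1-based inclusive (`start1`, `end1`).
#'
#' @param sequence Single protein sequence (length >= 6) over the standard
#'   alphabet.
#' @inheritParams score_peptide
#' @param id Optional sequence identifier copied into the output.
#' @return Data frame with one row per window: `seq_id`, `start0`, `end0`,
#'   `start1`, `end1`, `sequence`, `phi_amyloid`, `phi_nonamyloid`,
#'   `delta_phi`, `call`.
#' @export
#' @examples
#' scan_sequence("KVQIVYKPL")
scan_sequence <- function(sequence, amy = amyloid_potentials(),
                          non = nonamyloid_potentials(), id = "seq") {
  stopifnot(is.character(sequence), length(sequence) == 1)
  assert_sequences(sequence, exact_length = NULL, what = "protein sequence")
  L <- nchar(sequence)
  start1 <- seq_len(L - PEPTIDE_LENGTH + 1L)
  windows <- substring(sequence, start1, start1 + PEPTIDE_LENGTH - 1L)
  sc <- score_peptide(windows, amy, non)
  cbind(data.frame(seq_id = id, start0 = start1 - 1L,
                   end0 = start1 - 1L + PEPTIDE_LENGTH,
                   start1 = start1, end1 = start1 + PEPTIDE_LENGTH - 1L,
                   stringsAsFactors = FALSE),
        sc)
}

#' Per-position energy-differential distribution
#'
#' For every labeled peptide, extracts a per-position energy statistic at
#' `position` — by default the differential
#' `phi_amy(r_j, j) - phi_non(r_j, j)` — bins it per class, and reports the
#' per-class fraction of peptides at or below an energy cutoff. Bin edges
#' are aligned so that the cutoff is an edge (default bin width 0.2 kcal/mol
#' with cutoff -0.2 kcal/mol).
#'
#' @param ds A labeled [peptide_dataset()].
#' @inheritParams score_peptide
#' @param position Hexapeptide position, 1..6.
#' @param bin_width Bin width in kcal/mol.
#' @param cutoff Energy cutoff in kcal/mol; the comparison is `<= cutoff`,
#'   so a value exactly at the cutoff counts.
#' @param statistic `"differential"` (default), or the class-specific
#'   energies `"amyloid"` / `"non_amyloid"`.
#' @return List with `position`, `statistic`, `bin_edges`,
#'   `class_frequencies` (classes x bins; rows sum to 1), `cutoff`,
#'   `cutoff_fractions`; class `energy_distribution`.
#' @export
energy_differential_distribution <- function(ds, amy = amyloid_potentials(),
                                             non = nonamyloid_potentials(),
                                             position, bin_width = 0.2,
                                             cutoff = -0.2,
                                             statistic = c("differential",
                                                           "amyloid",
                                                           "non_amyloid")) {
  stopifnot(inherits(ds, "peptide_dataset"),
            position %in% seq_len(6L), bin_width > 0)
  statistic <- match.arg(statistic)
  labeled <- ds[ds$label != "unlabeled", , drop = FALSE]
  if (nrow(labeled) == 0) stop("dataset has no labeled records",
                               call. = FALSE)
  idx <- residue_index_matrix(labeled$sequence)[, position]
  val <- switch(statistic,
                differential = unclass(amy)[cbind(idx, position)] -
                  unclass(non)[cbind(idx, position)],
                amyloid = unclass(amy)[cbind(idx, position)],
                non_amyloid = unclass(non)[cbind(idx, position)])
  classes <- unique(as.character(labeled$label))
  lo <- cutoff - bin_width * ceiling((cutoff - min(val)) / bin_width + 1e-9)
  hi <- cutoff + bin_width * ceiling((max(val) - cutoff) / bin_width + 1e-9)
  edges <- seq(lo, hi, by = bin_width)
  freq <- t(vapply(classes, function(cl) {
    v <- val[labeled$label == cl]
    bins <- findInterval(v, edges)  # [edge_i, edge_{i+1}) intervals
    tabulate(bins, nbins = length(edges) - 1L) / length(v)
  }, numeric(length(edges) - 1L)))
  rownames(freq) <- classes
  fractions <- vapply(classes, function(cl)
    mean(val[labeled$label == cl] <= cutoff), numeric(1))
  structure(list(position = as.integer(position), statistic = statistic,
                 bin_edges = edges, class_frequencies = freq,
                 cutoff = cutoff, cutoff_fractions = fractions),
            class = "energy_distribution")
}

#' @export
print.energy_distribution <- function(x, ...) {
  cat(sprintf("energy distribution at position %d (%s), bin %g kcal/mol\n",
              x$position, x$statistic, diff(x$bin_edges[1:2])))
  cat(sprintf("fraction at or below %g kcal/mol: %s\n", x$cutoff,
              paste(sprintf("%s %.3f", names(x$cutoff_fractions),
                            x$cutoff_fractions), collapse = ", ")))
  invisible(x)
}
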