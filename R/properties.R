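# Per-residue property scales: registry, peptide totals, class summaries,
# histograms and profile comparison.

#' Construct a per-residue property scale
#'
#' @param name Scale identifier.
#' @param values Named numeric vector over the 20 standard residues; may
#'   contain NA only for placeholder (incomplete) registry entries.
#' @param description Free-text description.
#' @param units Units of the per-residue values.
#' @return A `property_scale` list with a `complete` flag; only complete
#'   scales can be used for computation.
#' @export
property_scale <- function(name, values, description = "", units = "") {
  if (!is.numeric(values) || is.null(names(values)))
    stop("values must be a named numeric vector", call. = FALSE)
  full <- stats::setNames(rep(NA_real_, 20L), AA_ALPHABET)
  known <- intersect(names(values), AA_ALPHABET)
  if (any(!names(values) %in% AA_ALPHABET))
    stop(sprintf("scale '%s' names non-standard residue(s): %s", name,
                 paste(setdiff(names(values), AA_ALPHABET), collapse = ", ")),
         call. = FALSE)
  full[known] <- values[known]
  structure(list(name = as.character(name), values = full,
                 description = as.character(description),
                 units = as.character(units),
                 complete = !anyNA(full)),
            class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("property_scale '%s' (%s)%s: %s\n", x$name, x$units,
              if (x$complete) "" else " [incomplete placeholder]",
              x$description))
  if (x$complete) print(round(x$values, 3))
  invisible(x)
}

#' Read a property-scale registry file
#'
#' The registry is a tab-separated file with columns `scale`, `description`,
#' `units` and the 20 residue columns `A..Y`. Rows without values are kept
#' as incomplete placeholders (usable as named slots a user can fill in, not
#' for computation). The bundled registry carries the published
#' retention-time hydrophobicity coefficients (`mant_hydrophobicity`),
#' textbook isoelectric points (`isoelectric_point`), a synthetic stand-in
#' long-range non-bonded energy scale (`longrange_energy_synthetic`), and
#' placeholder rows naming a standard 49-property compilation whose numeric
#' tables are distributed externally.
#'
#' @param path Registry path; defaults to the bundled file.
#' @return Named list of [property_scale()] objects.
#' @export
read_property_scales <- function(path = NULL) {
  path <- path %||% extdata("property_scales.tsv")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (!identical(hdr[1:3], c("scale", "description", "units")) ||
      !identical(hdr[-(1:3)], AA_ALPHABET))
    stop("registry header must be: scale, description, units, A..Y",
         call. = FALSE)
  scales <- lapply(fields[-1], function(f) {
    vals <- if (length(f) >= 23)
      stats::setNames(suppressWarnings(as.numeric(f[4:23])), AA_ALPHABET)
    else stats::setNames(rep(NA_real_, 20), AA_ALPHABET)
    property_scale(f[1], vals, description = f[2], units = f[3])
  })
  names(scales) <- vapply(scales, `[[`, "", "name")
  if (anyDuplicated(names(scales)))
    stop("duplicate scale names in registry", call. = FALSE)
  scales
}

scale_registry <- function() {
  if (is.null(.cache$scales)) .cache$scales <- read_property_scales()
  .cache$scales
}

#' Fetch a bundled property scale by name
#'
#' @param name Scale identifier in the bundled registry.
#' @return A [property_scale()].
#' @export
#' @examples
#' get_property_scale("mant_hydrophobicity")$values[["W"]]   # 100
get_property_scale <- function(name) {
  reg <- scale_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown property scale '%s'", name), call. = FALSE)
  reg[[name]]
}

#' The published retention-time hydrophobicity scale
#'
#' Per-residue hydrophobicity coefficients `h` measured as reversed-phase
#' liquid chromatography retention times; summing them over a hexapeptide
#' gives its total hydrophobicity H_T.
#'
#' @return A [property_scale()].
#' @export
mant_hydrophobicity <- function() get_property_scale("mant_hydrophobicity")

#' Total property of hexapeptides
#'
#' Computes `P_total = sum_j P(r_j)`, the sum of a per-residue scale value
#' over the six residues of each peptide.
#'
#' @param sequence Character vector of hexapeptides.
#' @param scale A complete [property_scale()].
#' @return Numeric vector of totals.
#' @export
#' @examples
#' total_property("STVIIE", mant_hydrophobicity())   # 209.95
total_property <- function(sequence, scale) {
  stopifnot(inherits(scale, "property_scale"))
  if (!scale$complete)
    stop(sprintf("scale '%s' is an incomplete placeholder", scale$name),
         call. = FALSE)
  assert_sequences(sequence)
  idx <- residue_index_matrix(sequence)
  rowSums(matrix(scale$values[as.vector(idx)], nrow = length(sequence)))
}

#' Total hydrophobicity H_T
#'
#' Convenience wrapper: [total_property()] under the bundled
#' [mant_hydrophobicity()] scale.
#'
#' @inheritParams total_property
#' @return Numeric vector of H_T values.
#' @export
total_hydrophobicity <- function(sequence)
  total_property(sequence, mant_hydrophobicity())

#' Per-class summary of peptide property totals
#'
#' For each scale, computes the mean and sample standard deviation (n - 1
#' denominator) of the per-peptide totals within the amyloid and non-amyloid
#' classes, and their difference (amyloid minus non-amyloid).
#'
#' @param ds A [peptide_dataset()] containing both classes.
#' @param scales A [property_scale()] or list of them (complete scales).
#' @return Data frame with one row per scale: `scale`, `mean_amyloid`,
#'   `sd_amyloid`, `mean_nonamyloid`, `sd_nonamyloid`, `difference`.
#' @export
class_property_summary <- function(ds, scales) {
  if (inherits(scales, "property_scale")) scales <- list(scales)
  stopifnot(length(scales) >= 1)
  amy <- class_records(ds, "amyloid")$sequence
  non <- class_records(ds, "non_amyloid")$sequence
  rows <- lapply(scales, function(sc) {
    ta <- total_property(amy, sc)
    tn <- total_property(non, sc)
    data.frame(scale = sc$name,
               mean_amyloid = mean(ta), sd_amyloid = stats::sd(ta),
               mean_nonamyloid = mean(tn), sd_nonamyloid = stats::sd(tn),
               difference = mean(ta) - mean(tn),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-class histogram of total hydrophobicity
#'
#' Bins each class's H_T (or other property total) values into fixed-width
#' bins and reports per-class frequencies (each class sums to 1).
#'
#' @param ds A labeled [peptide_dataset()].
#' @param bin_width Bin width in scale units (default 50).
#' @param origin Bin alignment origin (default 0, so edges are 0, 50, ...).
#' @param scale Property scale to total; defaults to
#'   [mant_hydrophobicity()].
#' @return List with `bin_edges` and `class_frequencies` (classes x bins);
#'   class `property_histogram`.
#' @export
hydrophobicity_histogram <- function(ds, bin_width = 50, origin = 0,
                                     scale = mant_hydrophobicity()) {
  stopifnot(inherits(ds, "peptide_dataset"), bin_width > 0)
  labeled <- ds[ds$label != "unlabeled", , drop = FALSE]
  if (nrow(labeled) == 0) stop("dataset has no labeled records",
                               call. = FALSE)
  tot <- total_property(labeled$sequence, scale)
  lo <- origin + bin_width * floor((min(tot) - origin) / bin_width)
  hi <- origin + bin_width * (floor((max(tot) - origin) / bin_width) + 1L)
  edges <- seq(lo, hi, by = bin_width)
  classes <- unique(as.character(labeled$label))
  freq <- t(vapply(classes, function(cl) {
    v <- tot[labeled$label == cl]
    tabulate(findInterval(v, edges), nbins = length(edges) - 1L) / length(v)
  }, numeric(length(edges) - 1L)))
  rownames(freq) <- classes
  structure(list(bin_edges = edges, class_frequencies = freq,
                 scale = scale$name),
            class = "property_histogram")
}

#' Compare two property profiles
#'
#' Computes the Pearson correlation and a chi-square-style agreement
#' statistic `sum 2 * (a - b)^2 / (|a| + |b|)` between two vectors of
#' per-scale means (pairs where both values are 0 contribute 0). Inputs can
#' be named numeric vectors or [class_property_summary()] data frames (the
#' requested mean columns are compared; scale sets must match).
#'
#' @param a,b Named numeric vectors, or summary data frames.
#' @param value_a,value_b Columns used when `a`/`b` are summaries.
#' @return List with `r`, `chisq` and `n_scales`.
#' @export
compare_property_profiles <- function(a, b, value_a = "mean_amyloid",
                                      value_b = value_a) {
  pull <- function(x, col) {
    if (is.data.frame(x)) stats::setNames(x[[col]], x$scale)
    else if (is.numeric(x) && !is.null(names(x))) x
    else stop("profiles must be summaries or named numeric vectors",
              call. = FALSE)
  }
  va <- pull(a, value_a)
  vb <- pull(b, value_b)
  if (!setequal(names(va), names(vb)))
    stop("profiles cover different scale sets", call. = FALSE)
  vb <- vb[names(va)]
  denom <- abs(va) + abs(vb)
  terms <- ifelse(denom == 0, 0, 2 * (va - vb)^2 / denom)
  list(r = stats::cor(va, vb), chisq = sum(terms), n_scales = length(va))
}
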